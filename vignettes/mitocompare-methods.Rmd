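---
title: "Methods: comparing maintainer and CMS mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing maintainer and CMS mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

`mitocompare` compares circular plant mitochondrial genomes between
cytoplasmic male-sterile (CMS) lines and their maintainer lines. The
underlying biological model is the standard one for plant CMS: the
mitochondrial genome of a CMS line differs from its maintainer by
repeat-mediated rearrangements (inversions, translocations), gains and
losses of non-homologous sequence, copy-number changes of conserved genes,
codon-level polymorphisms in respiratory-chain genes, and novel ORFs —
often clustered in one CMS-specific region — that have no near-identical
counterpart in the fertile genome.

Every module works on one coordinate convention: 0-based, half-open,
forward strand. GenBank and GFF3 conversion (1-based, closed) happens only
at the I/O boundary. Origin-spanning features are removed by rotating the
genome at read time (the rotation is recorded and can be undone); features
that come to wrap the origin after a user-requested rotation keep their
start in `[0, L)` and an end beyond `L`.

# Alignment engines

Two engines back every analysis:

* `local_align()` — exact Smith–Waterman with affine gaps, used as the
  oracle. It is capped (default 10^6 DP cells) because it is quadratic.
* `anchored_align()` — the production aligner: exact k-mer seeds (default
  `k = 12`) on both strands, merged into maximal exact segments, grouped
  into chains when their diagonals stay within `band = 32` and their
  query gap within `max_gap = 500`, stitched with Needleman–Wunsch across
  inter-anchor gaps, and extended at both ends by a best-prefix DP over a
  `ext_window = 600` bp flank.

Scoring defaults are BLASTN-like (`match = +1, mismatch = -2, gap open
-5, gap extend -2`); identity is matches over alignment columns with gap
columns counted, the BLAST "identities / alignment length" convention.
All tie-breaking is deterministic (row-major first maximum in the DP;
diagonal-first traceback), so outputs are bit-for-bit reproducible.

Two numerical details matter downstream. First, chains are only evaluated
when their total exact-anchor length reaches 20 bp at genome scale
(every chain is kept for small inputs); this suppresses the ~10^4
single-seed chance matches a 0.4 Mb self-comparison produces while keeping
every ≥ 20 bp repeat that is findable with 12-mer seeds at all. Second,
an indel larger than `band` splits a seed chain in two, and both halves
then extend across the indel; the two resulting hits can overlap by up to
about twice the extension window. The synteny-block chainer therefore
accepts continuation hits overlapping by up to `overlap_tol = 1300` bp,
while refusing continuations whose gap sizes on the two genomes differ by
more than `indel_tol = 300` bp — those are repeat cross-matches, not
block continuations.

# Repeats

A dispersed repeat is a self-alignment pair whose identity strictly
exceeds 0.90 ("more than 90%"): exactly 0.90 is excluded, which the test
suite asserts. Size classes are small (< 50 bp), intermediate (50–500 bp
inclusive) and large (> 500 bp). Forward pairs are direct repeats (DR),
reverse pairs inverted repeats (IR). Seed offsets smaller than `k` in the
self-comparison are tandem-array territory and are left to the SSR
detector; self-hits whose two intervals largely coincide (palindromic or
tandem self-maps) are likewise not reported as dispersed pairs.

`find_palindromes()` is a separate exact scanner: maximal pairs of
reverse-complementary arms separated by at most `max_spacer` (default 0,
i.e. contiguous). Exactness is deliberate — planted and biological large
palindromes are near-perfect, and an exact scan is O(genome) — but it
means a palindrome with internal substitutions is reported with shortened
arms.

SSRs are maximal tandem runs of primitive 1–6 bp motifs, reported under
the lexicographically least motif rotation, with MISA-style copy minimums
(12/6/4/3/3/3 for motif sizes 1–6) and a 12 bp minimum run. These
minimums are a documented choice: the method description this package
follows reports SSR counts per genome in the mid-double digits, which
implies substantial thresholds, but states none.

# Synteny, rearrangement classes and CMS-specific regions

Blocks are chains of co-oriented, co-spaced hits (`block_gap = 2000`,
`min_block = 3000` by default; 1000 reproduces a finer block inventory),
made mutually non-overlapping by score with boundary trimming.

Because both genomes are circles, "order" is only defined up to rotation.
`classify_blocks()` evaluates every rotation of the block order on genome
A against every rotation of the coordinate on genome B and keeps the
combination maximizing the number (then total length) of forward blocks
in the longest increasing subsequence. Blocks in that chain are
collinear; a reverse block whose position is consistent with its
neighbours is an inversion; a forward block out of order is a
translocation; a reverse block out of order is a combined
translocation + inversion. This makes classification well-defined and
rotation-invariant (the rotation cut can still split one collinear block
in two — the classes are invariant, block counts need not be).

CMS-specific regions are maximal intervals ≥ 3 kb of a CMS genome not
covered by any block to its maintainer; covered islands up to
`slack = 200` bp inside a region are absorbed, which keeps one biological
insertion from fragmenting over alignment end-trimming. With several CMS
lines, a region is kept only when it aligns to a region of every other
CMS line with identity above 0.90 over at least half of the shorter
region — the sharing threshold reuses the repeat-identity convention
since no other value is stated anywhere.

# Gene clusters

Clusters are maximal runs of gene features with inter-gene gaps of at
most `max_gap = 2000` bp, circular-aware, with trans-spliced exon groups
of one gene collapsing into a single member. The 2 kb default is a
documented choice: it reproduces the expected cluster inventory under
typical organelle gene spacing, and no threshold is stated in the method
description this package follows. Conserved clusters are maximal
base-name signatures present (as a contiguous sub-run, in either
orientation) in every genome; a signature equals its reversal.

# ORF screening

ORFs are ATG→stop frames, both strands, all three frames, circular-aware
(an ORF may span the origin; nested ATGs sharing a stop yield only the
longest frame). `nt_length` includes the stop codon and must strictly
exceed 300 bp; `aa_length` excludes the stop, which reproduces the
"orf<aa>" naming convention (letter suffixes on collision, in genomic
order). Alternative start codons are not used.

Specificity is evaluated against the whole maintainer genome, not only
its ORF set: the CMS genome is aligned to the maintainer once, a
per-position match profile is derived, and an ORF is specific when the
matched fraction of its span is strictly below 0.99. Using the profile's
union over hits makes the estimate an upper bound of any single
alignment's identity, i.e. the screen errs on the side of excluding an
ORF — the conservative direction for claiming CMS-specificity. Shared
specific ORFs require a reciprocal-best match at identity ≥ 0.99 in every
other CMS line.

# Candidate genes

Homologs are paired by base gene name; multi-copy genes by reciprocal
best CDS identity (greedy over the identity matrix, deterministic).
Trans-spliced genes are compared on their exon parts concatenated in
part-suffix order. `compare_gene()` reports each mismatch at the first
nucleotide of its maintainer codon (1-based in the CDS), with changed
bases uppercased, and classifies substitutions under the standard genetic
code — a documented simplification: plant mitochondrial RNA editing is
not modelled. Indels are reported as position ranges with lengths.

One caveat is inherent to alignment-based indel calling: when the bases
flanking a deletion are locally periodic, several gap placements score
equally and the reported position can shift by a few bases from the
mutational event. Substitution positions have no such ambiguity. The
acceptance checks therefore require deletion lengths exactly and
positions within a ±4 bp window.

# Phylogenies

Character matrices come in two forms: a SNP concatenation (per-reference
position alleles at sites covered in all samples where at least one
sample differs, reference-anchored through the genome aligner) and a
candidate-gene concatenation (per-gene columns anchored on the first
taxon's CDS). Reference anchoring stands in for a full multiple
alignment; insertions relative to the anchor are ignored, deletions
appear as gaps.

Maximum parsimony uses Fitch small parsimony (gaps and ambiguity treated
as missing) with exhaustive topology enumeration up to 8 taxa and
stepwise addition + NNI beyond; ties are resolved to the first topology
in canonical newick order and the tie count is attached. Neighbor joining
uses p-distances (mismatches over comparable sites; a pair with no
comparable sites is an error) with negative branch lengths clamped to
zero. Bootstrap supports resample site weights; for MP the per-site Fitch
costs of all topologies are precomputed so each replicate is a weighted
argmin, and a bipartition counts as supported in a replicate only when it
appears in the strict consensus of that replicate's co-optimal
topologies. An all-constant matrix therefore yields zero supports rather
than spurious 100s.

# The synthetic quartet: what it emulates, and what it does not

`generate_quartet()` builds two maintainer genomes and derives a CMS
genome from each, with every feature class planted and truth-tracked:

* Maintainer: 430 kb circular sequence at GC 0.40; a built-in inventory
  of conserved mitochondrial genes arranged into the 13 expected
  conserved clusters (including part-suffixed trans-spliced genes, the
  108 bp rps3/rpl16 overlap, and extra "D2"-style copies); dispersed
  repeat families in three size classes (second copies mutated at 2% for
  intermediate/large, exact for small — so planted identity has a
  closed-form expectation); and an SSR complement planted one copy above
  the detection minimum, because a boundary base can be phase-absorbed by
  the flanking sequence.
* CMS derivation, in order: gene-copy deletions, inversions,
  translocations (plain and inverted), ≥ 2.3 kb anonymous deletions, a
  shared 41,147 bp CMS-specific insertion carrying 16 specific ORFs (the
  region is sanitized so no chance ORF > 300 bp survives in it, keeping
  the shared-ORF count exact), a private insertion carrying a large
  palindrome (arms 5,778 / 1,491 bp) and a line-private SSR, and finally
  codon-level candidate-gene edits. The private insertion is sized so the
  net expansion lands at 40 kb, inside the observed 30–60 kb band.
* The two cultivars differ by background substitutions placed outside
  gene features (coding sequence is conserved between cultivars, which is
  what makes the candidate-gene tree separate CMS from maintainer
  cleanly) plus planted copy-number differences. Both CMS lines share the
  region-1 sequence and a small set of candidate-gene substitutions (the
  common cytoplasm), and carry cultivar-specific edit plans: 18
  polymorphic genes in cultivar a, 6 in cultivar b, intersecting in
  atp6, cox2, nad2 and sdh3.

Edit breakpoints avoid all planted features with margins, and successive
breakpoints keep ≥ 3.2 kb apart so every conserved segment is detectable
at the 3 kb block threshold. Everything is driven by one seed;
regeneration is byte-identical.

The background sequence is i.i.d. at the target GC — there is no
higher-order composition, no chloroplast- or nucleus-derived segments, no
substoichiometric molecules, and chance-ORF density is lower than in real
AT-rich organelle sequence. Repeat copies are mutated by substitution
only (by default), and structural edits never nest. Passing the planted
recovery checks therefore demonstrates that the detectors recover exactly
what the generative model plants at realistic scales; it does not
demonstrate robustness to the full compositional complexity of real
mitochondrial genomes, for which the thresholds above remain the tunable
surface.

# Problem sizes and determinism

The test suite exercises the alignment oracle on ≥ 200 random pairs up to
300 bp, the ORF scanner against exhaustive enumeration on 3 kb circles,
the SSR scanner against a brute-force motif scan, Fitch parsimony against
exhaustive ancestral-state enumeration on ≤ 6 leaves, and MP search
against exhaustive topology scoring at 7 taxa; planted recovery runs on
the full-scale default quartet (430 kb maintainers). All randomness in
tests and in `scripts/acceptance.R` flows from fixed seeds, and every
detector is deterministic given its inputs.
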