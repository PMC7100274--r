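# mitocompare

Comparative analysis of circular plant mitochondrial genomes between
cytoplasmic male-sterile (CMS) lines and their fertile maintainer lines.

Plant CMS — the maternally inherited failure to produce functional pollen —
is carried by the mitochondrial genome, typically through rearrangements,
novel chimeric open reading frames (ORFs), and polymorphisms in respiratory
genes. Diagnosing it from assembled genomes requires a battery of
comparative analyses that are usually stitched together from many
stand-alone tools. `mitocompare` implements that battery as one tested R
package, for researchers comparing maintainer/CMS genome pairs (for
example in tobacco, pepper, radish or rice):

- **Alignment core** — an exact Smith–Waterman aligner with affine gaps
  (the oracle, for small inputs) and a k-mer anchored seed-and-extend
  aligner (the production engine, for 0.5 Mb genomes), with the BLAST
  identity convention (matches / alignment columns, gaps included).
- **Repeat landscape** — genome self-comparison repeats classified as
  direct (DR) or inverted (IR) and by size (small < 50 bp, intermediate
  50–500 bp, large > 500 bp; a repeat requires identity strictly above
  0.90), palindromes (contiguous IR arms), and SSRs with 1–6 bp primitive
  motifs.
- **Synteny and rearrangements** — alignment hits chained into synteny
  blocks, classified on circular order as collinearity, translocation,
  inversion, or combined translocation + inversion; aligned fractions; and
  CMS-specific regions (≥ 3 kb, non-syntenic, shared across CMS lines).
- **Gene clusters** — runs of neighbouring genes (putative
  co-transcriptional units), intersected across genomes by base gene name
  with orientation normalization, and mapped onto synteny-block classes.
- **ORF screening** — circular six-frame ATG→stop prediction (> 300 bp,
  strict), removal of ORFs with a near-identical maintainer home
  (identity ≥ 0.99), and cross-line intersection of the surviving
  CMS-specific ORFs.
- **Candidate genes** — homolog pairing (copies by reciprocal best
  identity), codon-resolved polymorphism calls (`58 tAt (Y) → 58 tCt (S)`
  style), synonymous/nonsynonymous classification, copy-number tables,
  and cross-cultivar intersection.
- **Phylogenies** — SNP-matrix and gene-concatenation character matrices,
  Fitch maximum parsimony with exhaustive topology search (heuristic
  beyond 8 taxa), p-distance neighbor joining, and seeded bootstrap
  supports.
- **Synthetic data** — a fully seeded maintainer/CMS quartet generator
  that plants every feature class with a machine-readable truth table, so
  the entire pipeline is testable without any downloads.

## Worked example

```r
library(mitocompare)

# a two-cultivar maintainer/CMS quartet with planted truth
q <- generate_quartet(sim_config(seed = 1))
q$genomes$M1
#> CircularGenome 'M1': 430,000 bp, circular, 58 gene features, GC 40.05%
q$genomes$S1
#> CircularGenome 'S1': 470,167 bp, circular, 53 gene features, GC 40.20%

# rearrangements between the first CMS line and its maintainer
blocks <- classify_blocks(build_synteny_blocks(q$genomes$S1, q$genomes$M1))
table(blocks$rearrangement_class)
#>  collinearity     inversion     trans_inv translocation
#>            17             2             1             2
aligned_fraction(blocks, "a")   # percent of the CMS genome in blocks
#> [1] 87.67

# CMS-specific ORFs shared by both CMS lines
sp1 <- screen_specific_orfs(q$genomes$S1, q$genomes$M1)
sp2 <- screen_specific_orfs(q$genomes$S2, q$genomes$M2)
nrow(shared_specific_orfs(list(sp1, sp2))$shared)
#> [1] 16

# candidate-gene polymorphisms, e.g. atp6
pa <- call_polymorphisms(q$genomes$M1, q$genomes$S1)
pa$atp6
#> Gene atp6: length 1161 -> 1161, 6 event(s)
#>   58 tAt (Y) -> tCt (S) [nonsynonymous]
#>   91 aTg (M) -> aCg (T) [nonsynonymous]
#>   253 Ttg (L) -> Ctg (L) [synonymous]
#>   418 Tca (S) -> Cca (P) [nonsynonymous]
#>   766 tcT (S) -> tcC (S) [synonymous]
#>   1156 tCt (S) -> tAt (Y) [nonsynonymous]

# the candidate-gene parsimony tree separates the CMS lines
gm <- gene_concat_matrix(q$genomes, c("atp6", "cox2", "nad2", "sdh3"))
tree <- bootstrap_support(gm, "mp", n_reps = 1000, seed = 1)
ape::write.tree(tree)
#> [1] "((S1,S2)98,M1,M2);"
```

The printed polymorphisms follow the field's table convention: the event
position is the first nucleotide of the affected codon (1-based in the
maintainer CDS), changed bases are uppercased, and the amino acids are
given in parentheses. `run_pipeline()` executes every stage over a set of
pairs and writes the full TSV/BED/newick report bundle.

Real genomes are read with `read_genbank()` (annotated GenBank flat
files) or `read_fasta()` + `read_gff3()`; all coordinates are 0-based
half-open internally and converted at the I/O boundary.

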