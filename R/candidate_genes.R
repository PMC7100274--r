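translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  out <- unname(gc[codon])
  out[is.na(out)] <- "X"
  out
}

#' Classify a codon substitution
#'
#' Standard genetic code; identical amino acids give "synonymous".
#'
#' @param codon_a,codon_b two distinct in-frame codons over ACGT.
#' @return "synonymous", "nonsynonymous" or "unclassified" (codons with N).
#' @export
classify_substitution <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (codon_a == codon_b) stop("identical codons are not a substitution")
  if (grepl("N", codon_a) || grepl("N", codon_b)) return("unclassified")
  if (translate_codon(codon_a) == translate_codon(codon_b)) "synonymous"
  else "nonsynonymous"
}

# Table-style codon rendering: changed bases uppercase, the rest lowercase
render_codon <- function(codon, changed) {
  ch <- strsplit(tolower(codon), "")[[1]]
  ch[changed] <- toupper(ch[changed])
  paste(ch, collapse = "")
}

empty_events <- function() {
  data.frame(position = integer(), type = character(), length = integer(),
             codon_before = character(), codon_after = character(),
             aa_before = character(), aa_after = character(),
             synonymy = character(), stringsAsFactors = FALSE)
}

# extract the coding sequence of one gene copy (exon parts concatenated in
# part-suffix order, strand-aware)
gene_cds <- function(genome, base, copy = "main") {
  g <- genome$genes
  lab <- ifelse(!is.na(g$part) & grepl("^D", g$part), g$part, "main")
  sel <- g$name == base & lab == copy
  if (!any(sel)) return(NULL)
  g <- g[sel, , drop = FALSE]
  part_key <- ifelse(is.na(g$part), "", sub("D[0-9]+$", "", g$part))
  g <- g[order(part_key, g$start), , drop = FALSE]
  paste(vapply(seq_len(nrow(g)), function(i) {
    s <- genome_subseq(genome, g$start[i], g$end[i])
    if (g$strand[i] == "-") revcomp(s) else s
  }, ""), collapse = "")
}

gene_copy_labels <- function(genome, base) {
  g <- genome$genes
  sel <- g$name == base
  lab <- ifelse(!is.na(g$part[sel]) & grepl("^D", g$part[sel]),
                g$part[sel], "main")
  unique(lab)
}

#' Pair homologous protein-coding genes between two genomes
#'
#' Genes are paired by base name; multi-copy genes by best reciprocal
#' sequence identity of their coding sequences.  Unpaired copies are
#' reported separately as copy-number differences.
#'
#' @param gA,gB annotated `CircularGenome`s (maintainer, CMS).
#' @return list with `pairs` (gene, copy_a, copy_b, identity), `a_only` and
#'   `b_only` (gene, copy).
#' @export
match_homologs <- function(gA, gB) {
  coding <- function(g) unique(g$genes$name[g$genes$kind == "protein"])
  na_ <- coding(gA); nb <- coding(gB)
  pairs <- list(); a_only <- list(); b_only <- list()
  for (gene in sort(union(na_, nb))) {
    ca <- if (gene %in% na_) gene_copy_labels(gA, gene) else character()
    cb <- if (gene %in% nb) gene_copy_labels(gB, gene) else character()
    if (length(ca) == 0L) {
      for (c2 in cb) b_only[[length(b_only) + 1L]] <- c(gene, c2)
      next
    }
    if (length(cb) == 0L) {
      for (c1 in ca) a_only[[length(a_only) + 1L]] <- c(gene, c1)
      next
    }
    if (length(ca) == 1L && length(cb) == 1L) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene = gene, copy_a = ca, copy_b = cb, identity = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    # multi-copy: reciprocal best identity, greedy by identity
    seq_a <- lapply(ca, gene_cds, genome = gA, base = gene)
    seq_b <- lapply(cb, gene_cds, genome = gB, base = gene)
    idm <- outer(seq_along(ca), seq_along(cb),
                 Vectorize(function(i, j) {
                   g <- global_align(seq_a[[i]], seq_b[[j]])
                   g$matches / g$columns
                 }))
    ord <- order(-idm)
    used_a <- logical(length(ca)); used_b <- logical(length(cb))
    for (o in ord) {
      i <- (o - 1L) %% length(ca) + 1L; j <- (o - 1L) %/% length(ca) + 1L
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene = gene, copy_a = ca[i], copy_b = cb[j], identity = idm[i, j],
        stringsAsFactors = FALSE)
    }
    for (i in which(!used_a)) a_only[[length(a_only) + 1L]] <- c(gene, ca[i])
    for (j in which(!used_b)) b_only[[length(b_only) + 1L]] <- c(gene, cb[j])
  }
  tod <- function(x) {
    if (length(x) == 0L)
      return(data.frame(gene = character(), copy = character(),
                        stringsAsFactors = FALSE))
    m <- do.call(rbind, x)
    data.frame(gene = m[, 1L], copy = m[, 2L], stringsAsFactors = FALSE)
  }
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(gene = character(), copy_a = character(),
                    copy_b = character(), identity = numeric()),
       a_only = tod(a_only), b_only = tod(b_only))
}

#' Compare a gene between maintainer and CMS copies
#'
#' Global alignment of the two coding sequences; every mismatch is reported
#' at its maintainer codon (position = first nucleotide of the affected
#' codon, 1-based in the maintainer CDS) with changed bases uppercased;
#' indels are reported as position ranges with lengths; substitutions are
#' classified as synonymous/nonsynonymous under the standard genetic code.
#'
#' @param seq_a maintainer CDS (in frame, codon 1 first).
#' @param seq_b CMS CDS.
#' @param gene optional gene name carried through.
#' @return list (`PolymorphismRecord`): `gene`, `length_a`, `length_b`,
#'   `events` data frame.
#' @export
compare_gene <- function(seq_a, seq_b, gene = NA_character_) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) %% 3L != 0L || nchar(seq_b) %% 3L != 0L)
    warning("CDS length not a multiple of 3; frame-sensitive events may be",
            " classified as indel")
  rec <- list(gene = gene, length_a = nchar(seq_a), length_b = nchar(seq_b),
              events = empty_events())
  class(rec) <- "PolymorphismRecord"
  if (seq_a == seq_b) return(rec)
  g <- global_align(seq_a, seq_b)
  ca <- strsplit(g$aln_a, "")[[1]]; cb <- strsplit(g$aln_b, "")[[1]]
  apos <- cumsum(ca != "-")          # 1-based maintainer position (0 in gaps)
  bpos <- cumsum(cb != "-")
  events <- list()
  # --- indels: maximal runs of gap columns
  gap_a <- ca == "-"; gap_b <- cb == "-"
  runs <- function(x) {
    r <- rle(x); e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    cbind(s, e)[r$values, , drop = FALSE]
  }
  for (r in seq_len(nrow(runs(gap_b)))) {
    m <- runs(gap_b)[r, ]
    events[[length(events) + 1L]] <- data.frame(
      position = apos[m[1L]], type = "deletion", length = m[2L] - m[1L] + 1L,
      codon_before = paste0(apos[m[1L]], "-", apos[m[2L]]),
      codon_after = "-", aa_before = NA_character_, aa_after = NA_character_,
      synonymy = "indel", stringsAsFactors = FALSE)
  }
  for (r in seq_len(nrow(runs(gap_a)))) {
    m <- runs(gap_a)[r, ]
    events[[length(events) + 1L]] <- data.frame(
      position = apos[m[1L]] + 1L, type = "insertion",
      length = m[2L] - m[1L] + 1L, codon_before = "-",
      codon_after = paste0(bpos[m[1L]], "-", bpos[m[2L]]),
      aa_before = NA_character_, aa_after = NA_character_,
      synonymy = "indel", stringsAsFactors = FALSE)
  }
  # --- substitutions grouped by maintainer codon
  mism <- !gap_a & !gap_b & ca != cb
  if (any(mism)) {
    codon_idx <- (apos[mism] - 1L) %/% 3L
    for (ci in unique(codon_idx)) {
      cols <- which(!gap_a & (apos - 1L) %/% 3L == ci)
      codon_a <- paste(ca[cols], collapse = "")
      codon_b_cols <- cb[cols]
      if (any(codon_b_cols == "-") || nchar(codon_a) != 3L) next # indel edge
      codon_b <- paste(codon_b_cols, collapse = "")
      if (codon_a == codon_b) next
      changed <- which(ca[cols] != cb[cols])
      syn <- classify_substitution(codon_a, codon_b)
      events[[length(events) + 1L]] <- data.frame(
        position = 3L * ci + 1L, type = "substitution",
        length = length(changed),
        codon_before = render_codon(codon_a, changed),
        codon_after = render_codon(codon_b, changed),
        aa_before = translate_codon(codon_a),
        aa_after = translate_codon(codon_b),
        synonymy = syn, stringsAsFactors = FALSE)
    }
  }
  if (length(events)) {
    ev <- do.call(rbind, events)
    ev <- ev[order(ev$position), , drop = FALSE]
    rownames(ev) <- NULL
    rec$events <- ev
  }
  rec
}

#' @export
print.PolymorphismRecord <- function(x, ...) {
  cat(sprintf("Gene %s: length %d -> %d, %d event(s)\n",
              x$gene, x$length_a, x$length_b, nrow(x$events)))
  if (nrow(x$events) > 0L) {
    with(x$events, cat(sprintf("  %d %s (%s) -> %s (%s) [%s]\n",
                               position, codon_before,
                               ifelse(is.na(aa_before), "-", aa_before),
                               codon_after,
                               ifelse(is.na(aa_after), "-", aa_after),
                               synonymy), sep = ""))
  }
  invisible(x)
}

#' Call polymorphisms for all homologous gene pairs
#'
#' @param gA maintainer genome; @param gB CMS genome.
#' @return named list of `PolymorphismRecord`s for every matched pair.
#' @export
call_polymorphisms <- function(gA, gB) {
  hm <- match_homologs(gA, gB)
  recs <- list()
  for (i in seq_len(nrow(hm$pairs))) {
    gene <- hm$pairs$gene[i]
    sa <- gene_cds(gA, gene, hm$pairs$copy_a[i])
    sb <- gene_cds(gB, gene, hm$pairs$copy_b[i])
    key <- if (hm$pairs$copy_a[i] == "main") gene
           else paste0(gene, "-", hm$pairs$copy_a[i])
    recs[[key]] <- compare_gene(sa, sb, gene = gene)
  }
  recs
}

#' Gene copy-number table across genomes
#'
#' Copies per base gene name: part-suffixed exon sets of one copy merge,
#' "D2"-style labels count as separate copies.
#'
#' @param genomes list of annotated `CircularGenome`s.
#' @return integer matrix, genes x genomes.
#' @export
copy_numbers <- function(genomes) {
  ids <- vapply(genomes, `[[`, "", "id")
  genes <- sort(unique(unlist(lapply(genomes, function(g) g$genes$name))))
  m <- matrix(0L, length(genes), length(genomes),
              dimnames = list(genes, ids))
  for (j in seq_along(genomes)) {
    for (gene in genes) {
      m[gene, j] <- length(gene_copy_labels(genomes[[j]], gene))
    }
  }
  m
}

#' Intersect polymorphic gene sets across cultivars
#'
#' @param polymorphic_sets list (>= 2) of character vectors of base gene
#'   names with at least one polymorphism event in that cultivar.
#' @return sorted intersection.
#' @export
intersect_candidates <- function(polymorphic_sets) {
  stopifnot(length(polymorphic_sets) >= 2L)
  sort(Reduce(intersect, polymorphic_sets))
}
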