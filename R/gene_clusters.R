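#' Detect gene clusters
#'
#' Maximal runs of neighbouring genes whose inter-gene gap does not exceed
#' `max_gap`; putative co-transcriptional units.  Circular-aware: a run may
#' span the origin.  Singletons are excluded.  Consecutive features of the
#' same base gene (trans-spliced exon groups) collapse into one member.
#'
#' @param genome an annotated `CircularGenome`.
#' @param max_gap maximum inter-gene gap in bp (default 2000).
#' @return list of clusters; each has `genome_id`, `members` (base names in
#'   order), `signature`, `start`, `end` (may exceed the genome length when
#'   the cluster wraps the origin) and `strands`.
#' @export
detect_clusters <- function(genome, max_gap = 2000) {
  g <- genome$genes
  if (nrow(g) < 2L) return(list())
  g <- g[order(g$start), , drop = FALSE]
  L <- genome_length(genome)
  n <- nrow(g)
  gap_next <- g$start[c(2:n, 1L)] - g$end       # gap to the next gene
  gap_next[n] <- gap_next[n] + if (genome$circular) L else Inf
  linked <- gap_next <= max_gap & gap_next > -Inf
  if (all(linked)) {                            # one cluster spanning all
    runs <- list(seq_len(n))
  } else {
    # start runs after each unlinked gene, circular order
    brk <- which(!linked)
    runs <- list()
    for (k in seq_along(brk)) {
      from <- brk[k] %% n + 1L
      to <- brk[if (k < length(brk)) k + 1L else 1L]
      idx <- if (from <= to) from:to else c(from:n, 1:to)
      if (length(idx) >= 2L) runs[[length(runs) + 1L]] <- idx
    }
  }
  out <- list()
  for (idx in runs) {
    base <- g$name[idx]
    keep <- c(TRUE, base[-1L] != base[-length(base)])  # collapse exon parts
    members <- base[keep]
    if (length(members) < 2L) next
    wrap <- any(diff(idx) < 0L)
    out[[length(out) + 1L]] <- list(
      genome_id = genome$id, members = members,
      signature = paste(members, collapse = "-"),
      start = g$start[idx[1L]],
      end = if (wrap) g$end[idx[length(idx)]] + L else g$end[idx[length(idx)]],
      strands = g$strand[idx])
  }
  out[order(vapply(out, `[[`, 0, "start"))]
}

# canonical form of a base-name signature (orientation-normalized)
canonical_signature <- function(members) {
  fwd <- paste(members, collapse = "-")
  rev_ <- paste(rev(members), collapse = "-")
  if (rev_ < fwd) rev(members) else members
}

# is `sub` a contiguous sub-run of `run` (forward or reversed)?
is_subrun <- function(sub, run) {
  ns <- length(sub); nr <- length(run)
  if (ns > nr) return(FALSE)
  for (i in seq_len(nr - ns + 1L)) {
    w <- run[i:(i + ns - 1L)]
    if (all(w == sub) || all(w == rev(sub))) return(TRUE)
  }
  FALSE
}

#' Conserved gene clusters across genomes
#'
#' A conserved cluster is a maximal run of base gene names that occurs,
#' possibly as a contiguous sub-run of a larger cluster and in either
#' orientation, in every genome of the input set.  Part suffixes are
#' dropped before comparison and a signature equals its reversal.
#'
#' @param genomes list of annotated `CircularGenome`s (>= 2).
#' @param clusters_per_genome optional precomputed list of
#'   [detect_clusters()] outputs (same order as `genomes`).
#' @param max_gap passed to [detect_clusters()].
#' @return list of conserved clusters, each with the canonical `signature`
#'   and per-genome `instances` (genome id, start, end).
#' @export
conserved_clusters <- function(genomes, clusters_per_genome = NULL,
                               max_gap = 2000) {
  stopifnot(length(genomes) >= 2L)
  if (is.null(clusters_per_genome))
    clusters_per_genome <- lapply(genomes, detect_clusters, max_gap = max_gap)
  runs_of <- function(cl) lapply(cl, `[[`, "members")
  all_runs <- lapply(clusters_per_genome, runs_of)
  # candidate signatures: every contiguous sub-run (>= 2) of genome 1
  cands <- list()
  for (r in all_runs[[1L]]) {
    n <- length(r)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      cands[[length(cands) + 1L]] <- r[i:j]
  }
  # dedupe by canonical string
  key <- vapply(cands, function(x) paste(canonical_signature(x),
                                         collapse = "-"), "")
  cands <- cands[!duplicated(key)]
  present_everywhere <- vapply(cands, function(s) {
    all(vapply(all_runs, function(runs)
      any(vapply(runs, function(r) is_subrun(s, r), NA)), NA))
  }, NA)
  cands <- cands[present_everywhere]
  if (length(cands) == 0L) return(list())
  # keep maximal signatures only
  maximal <- vapply(seq_along(cands), function(i) {
    !any(vapply(seq_along(cands), function(j) {
      j != i && length(cands[[j]]) > length(cands[[i]]) &&
        is_subrun(cands[[i]], cands[[j]])
    }, NA))
  }, NA)
  cands <- cands[maximal]

  locate <- function(sig, clusters) {
    for (cl in clusters) {
      if (is_subrun(sig, cl$members))
        return(list(genome_id = cl$genome_id, start = cl$start,
                    end = cl$end, cluster_signature = cl$signature))
    }
    NULL
  }
  lapply(cands, function(s) {
    inst <- lapply(clusters_per_genome, locate, sig = s)
    names(inst) <- vapply(genomes, `[[`, "", "id")
    list(signature = canonical_signature(s),
         signature_string = paste(canonical_signature(s), collapse = "-"),
         instances = inst, block_context = NULL)
  })
}

#' Map conserved clusters onto synteny-block classes
#'
#' For each genome instance of each conserved cluster, the rearrangement
#' class of the synteny block containing the cluster span
#' (majority-overlap rule); `"none"` when uncovered.
#'
#' @param conserved output of [conserved_clusters()].
#' @param blocks_per_genome named list (genome id -> classified block table
#'   whose "a" side is that genome, see [classify_blocks()]).
#' @return `conserved` with `block_context` filled (named by genome id).
#' @export
map_clusters_to_blocks <- function(conserved, blocks_per_genome) {
  lapply(conserved, function(cc) {
    ctx <- lapply(names(blocks_per_genome), function(id) {
      inst <- cc$instances[[id]]
      if (is.null(inst)) return(NA_character_)
      b <- blocks_per_genome[[id]]
      if (nrow(b) == 0L) return("none")
      ov <- overlap_len(inst$start, inst$end, b$a_start, b$a_end)
      if (max(ov) == 0L) return("none")
      b$rearrangement_class[which.max(ov)]
    })
    names(ctx) <- names(blocks_per_genome)
    cc$block_context <- ctx
    cc
  })
}

#' Overlapping gene pairs
#'
#' All pairs of gene features overlapping by at least 1 bp.
#'
#' @param genome an annotated `CircularGenome`.
#' @return data frame with `gene_a`, `gene_b`, `overlap_bp`.
#' @export
gene_overlaps <- function(genome) {
  g <- genome$genes
  out <- data.frame(gene_a = character(), gene_b = character(),
                    overlap_bp = integer(), stringsAsFactors = FALSE)
  if (nrow(g) < 2L) return(out)
  g <- g[order(g$start), , drop = FALSE]
  for (i in seq_len(nrow(g) - 1L)) {
    for (j in (i + 1L):nrow(g)) {
      ov <- overlap_len(g$start[i], g$end[i], g$start[j], g$end[j])
      if (ov > 0L)
        out <- rbind(out, data.frame(gene_a = g$name[i], gene_b = g$name[j],
                                     overlap_bp = ov,
                                     stringsAsFactors = FALSE))
    }
  }
  out
}
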