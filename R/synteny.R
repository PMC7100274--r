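#' Build synteny blocks between two genomes
#'
#' Anchored-aligner hits are chained into maximal co-oriented, co-spaced
#' blocks; overlapping chains are resolved by score and blocks shorter than
#' `min_block` are dropped.  Query ("a") intervals refer to `gA`, subject
#' ("b") intervals to `gB`.
#'
#' @param gA,gB `CircularGenome` objects.
#' @param min_block minimum block length in bp (default 3000, the
#'   CMS-region granularity; use 1000 for a finer block inventory).
#' @param min_identity minimum block identity.
#' @param block_gap maximum gap (bp) bridged when chaining hits into blocks.
#' @param indel_tol largest indel (difference between the two genomes' gap
#'   sizes) bridged inside one block.
#' @param ... passed to [anchored_align()].
#' @return data frame of blocks sorted by `a_start`, with attributes
#'   `a_id`, `b_id`, `a_len`, `b_len`.
#' @export
build_synteny_blocks <- function(gA, gB, min_block = 3000,
                                 min_identity = 0.90, block_gap = 2000,
                                 indel_tol = 300, ...) {
  hits <- anchored_align(gA$seq, gB$seq, min_identity = 0, min_len = 50, ...)
  blocks <- chain_hits_to_blocks(hits, block_gap, indel_tol)
  blocks <- blocks[blocks$identity >= min_identity &
                     pmin(blocks$a_end - blocks$a_start,
                          blocks$b_end - blocks$b_start) >= min_block, ,
                   drop = FALSE]
  blocks <- resolve_block_overlaps(blocks)
  blocks <- blocks[order(blocks$a_start), , drop = FALSE]
  rownames(blocks) <- NULL
  attr(blocks, "a_id") <- gA$id; attr(blocks, "b_id") <- gB$id
  attr(blocks, "a_len") <- genome_length(gA)
  attr(blocks, "b_len") <- genome_length(gB)
  blocks
}

# chain co-oriented, co-spaced alignment hits into blocks
chain_hits_to_blocks <- function(hits, block_gap, indel_tol = 300,
                                 overlap_tol = 1300) {
  empty <- data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      orientation = character(), identity = numeric(),
                      matches = integer(), columns = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[order(hits$q_start), , drop = FALSE]
  used <- rep(FALSE, nrow(hits))
  out <- list()
  for (i in seq_len(nrow(hits))) {
    if (used[i]) next
    cur <- hits[i, ]; used[i] <- TRUE
    repeat {
      # among eligible continuations prefer the diagonal-consistent one
      # (repeats offer off-diagonal alternatives)
      best_j <- NA_integer_; best_key <- c(Inf, Inf)
      for (j in which(!used)) {
        if (hits$orientation[j] != cur$orientation) next
        dq <- hits$q_start[j] - cur$q_end
        # end extensions of two chains split by an indel can overlap by up
        # to about twice the extension window
        if (dq < -overlap_tol || dq > block_gap) next
        ds <- if (cur$orientation == "forward")
          hits$s_start[j] - cur$s_end else cur$s_start - hits$s_end[j]
        if (ds < -overlap_tol || ds > block_gap) next
        # within one block only small indels are bridged; a large offset
        # between the two genomes is a repeat cross-match, not continuation
        if (abs(ds - dq) > indel_tol) next
        key <- c(abs(ds - dq), dq)
        if (key[1L] < best_key[1L] ||
            (key[1L] == best_key[1L] && key[2L] < best_key[2L])) {
          best_key <- key; best_j <- j
        }
      }
      if (is.na(best_j)) break
      j <- best_j
      cur$q_end <- max(cur$q_end, hits$q_end[j])
      cur$s_start <- min(cur$s_start, hits$s_start[j])
      cur$s_end <- max(cur$s_end, hits$s_end[j])
      cur$matches <- cur$matches + hits$matches[j]
      cur$columns <- cur$columns + hits$columns[j]
      cur$score <- cur$score + hits$score[j]
      used[j] <- TRUE
    }
    out[[length(out) + 1L]] <-
      data.frame(a_start = cur$q_start, a_end = cur$q_end,
                 b_start = cur$s_start, b_end = cur$s_end,
                 orientation = cur$orientation,
                 identity = cur$matches / cur$columns,
                 matches = cur$matches, columns = cur$columns,
                 score = cur$score, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# make blocks mutually non-overlapping on both genomes (score-greedy)
resolve_block_overlaps <- function(blocks) {
  if (nrow(blocks) <= 1L) return(blocks)
  blocks <- blocks[order(-blocks$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(blocks))
  for (i in seq_len(nrow(blocks))[-1L]) {
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      ao <- overlap_len(blocks$a_start[i], blocks$a_end[i],
                        blocks$a_start[j], blocks$a_end[j])
      bo <- overlap_len(blocks$b_start[i], blocks$b_end[i],
                        blocks$b_start[j], blocks$b_end[j])
      li <- min(blocks$a_end[i] - blocks$a_start[i],
                blocks$b_end[i] - blocks$b_start[i])
      if (max(ao, bo) > 0.5 * li) { keep[i] <- FALSE; break }
      # trim small boundary overlaps on the a side
      if (ao > 0L) {
        if (blocks$a_start[i] < blocks$a_start[j]) {
          blocks$a_end[i] <- blocks$a_start[j]
        } else {
          blocks$a_start[i] <- blocks$a_end[j]
        }
      }
    }
  }
  blocks[keep, , drop = FALSE]
}

#' Classify synteny blocks into rearrangement classes
#'
#' Because both genomes are circles, block order is judged after choosing
#' the rotation of genome B that maximizes the number of collinear blocks
#' (ties broken by collinear length).  Collinearity: forward orientation and
#' membership in the longest forward-ordered chain; inversion: reverse
#' orientation at an order-consistent position; translocation: forward
#' orientation at an order-inconsistent position; trans_inv: both.
#'
#' @param blocks output of [build_synteny_blocks()].
#' @return `blocks` with a `rearrangement_class` column.
#' @export
classify_blocks <- function(blocks) {
  n <- nrow(blocks)
  if (n == 0L) { blocks$rearrangement_class <- character(0); return(blocks) }
  blocks <- blocks[order(blocks$a_start), , drop = FALSE]
  bmid <- (blocks$b_start + blocks$b_end) / 2
  fwd <- blocks$orientation == "forward"
  blen <- blocks$b_end - blocks$b_start

  # longest increasing subsequence (indices) of x restricted to `cand`
  lis <- function(rank_b, cand) {
    idx <- which(cand)
    if (length(idx) == 0L) return(integer(0))
    x <- rank_b[idx]
    best_len <- integer(length(x)); prev <- integer(length(x))
    for (i in seq_along(x)) {
      best_len[i] <- 1L; prev[i] <- 0L
      for (j in seq_len(i - 1L)) {
        if (x[j] < x[i] && best_len[j] + 1L > best_len[i]) {
          best_len[i] <- best_len[j] + 1L; prev[i] <- j
        }
      }
    }
    e <- which.max(best_len); path <- integer(0)
    while (e != 0L) { path <- c(e, path); e <- prev[e] }
    idx[path]
  }

  best <- NULL; best_key <- c(-1, -1)
  for (ra in seq_len(n)) {          # rotation of the a-order
    ord <- c(ra:n, seq_len(ra - 1L))
    for (tb in seq_len(n)) {        # rotation of the b-coordinate
      rank_b <- rank((bmid - bmid[tb]) %% (max(blocks$b_end) + 1))
      sel <- lis(rank_b[ord], fwd[ord])   # positions within ord
      cnt <- length(sel); len <- sum(blen[ord][sel])
      if (cnt > best_key[1] || (cnt == best_key[1] && len > best_key[2])) {
        best_key <- c(cnt, len)
        best <- list(ord = ord, rank_b = rank_b, sel = sel)
      }
    }
  }
  ord <- best$ord; rank_b <- best$rank_b
  collinear <- rep(FALSE, n); collinear[ord[best$sel]] <- TRUE

  # a block not in the chain is order-consistent if its b-rank fits between
  # its collinear neighbours in a-order
  cls <- character(n)
  chain_pos <- which(collinear[ord])          # positions in ord
  for (p in seq_len(n)) {
    i <- ord[p]
    if (collinear[i]) { cls[i] <- "collinearity"; next }
    lo <- chain_pos[chain_pos < p]; hi <- chain_pos[chain_pos > p]
    rlo <- if (length(lo)) rank_b[ord[max(lo)]] else -Inf
    rhi <- if (length(hi)) rank_b[ord[min(hi)]] else Inf
    consistent <- rank_b[i] > rlo && rank_b[i] < rhi
    # a forward block that fits the order but is outside the chain was
    # excluded by overlap resolution; it still reads as a translocation
    cls[i] <- if (fwd[i]) "translocation"
              else if (consistent) "inversion" else "trans_inv"
  }
  blocks$rearrangement_class <- cls
  blocks
}

#' Fraction of a genome covered by synteny blocks
#'
#' @param blocks classified or unclassified block table from
#'   [build_synteny_blocks()].
#' @param which_genome `"a"` or `"b"`.
#' @return percentage of that genome's positions covered by blocks.
#' @export
aligned_fraction <- function(blocks, which_genome = c("a", "b")) {
  which_genome <- match.arg(which_genome)
  L <- attr(blocks, paste0(which_genome, "_len"))
  if (is.null(L)) stop("blocks lack genome-length attributes")
  if (nrow(blocks) == 0L) return(0)
  s <- blocks[[paste0(which_genome, "_start")]]
  e <- blocks[[paste0(which_genome, "_end")]]
  100 * interval_union_len(s, pmin(e, L)) / L
}

#' Find CMS-specific (non-syntenic) regions
#'
#' Per CMS genome, maximal intervals of at least `min_len` bp not covered by
#' any synteny block to its paired maintainer (block overlap up to `slack`
#' bp at region borders is tolerated).  With several CMS genomes, only
#' regions shared between all CMS genomes (mutual alignment identity
#' strictly above `share_identity` over at least half of the shorter
#' region) are kept.
#'
#' @param cms_list list of CMS `CircularGenome`s.
#' @param maintainer_list list of paired maintainer genomes (same order).
#' @param min_len minimum region length (default 3000).
#' @param min_block passed to [build_synteny_blocks()].
#' @param slack covered islands up to this size inside a region are absorbed.
#' @param share_identity identity defining a shared region.
#' @param ... passed to [build_synteny_blocks()].
#' @return list of unique regions; each has `genome_id`, `start`, `end`,
#'   `length`, `seq` and (after [annotate_region()]) `contained`.
#' @export
find_unique_regions <- function(cms_list, maintainer_list, min_len = 3000,
                                min_block = 3000, slack = 200,
                                share_identity = 0.90, ...) {
  stopifnot(length(cms_list) == length(maintainer_list),
            length(cms_list) >= 1L)
  per_genome <- lapply(seq_along(cms_list), function(i) {
    cms <- cms_list[[i]]
    blocks <- build_synteny_blocks(cms, maintainer_list[[i]],
                                   min_block = min_block, ...)
    L <- genome_length(cms)
    if (nrow(blocks) > 0L) {
      cov <- merge_intervals(blocks$a_start, pmin(blocks$a_end, L),
                             gap = 0L)
      cov <- cov[cov[, "end"] - cov[, "start"] > slack, , drop = FALSE]
    } else cov <- cbind(start = integer(), end = integer())
    # complement of the coverage
    bounds <- c(0L, as.vector(t(cov)), L)
    gaps <- matrix(bounds, ncol = 2, byrow = TRUE)
    gaps <- gaps[gaps[, 2] - gaps[, 1] >= min_len, , drop = FALSE]
    lapply(seq_len(nrow(gaps)), function(r)
      list(genome_id = cms$id, start = gaps[r, 1], end = gaps[r, 2],
           length = gaps[r, 2] - gaps[r, 1],
           seq = genome_subseq(cms, gaps[r, 1], gaps[r, 2])))
  })
  if (length(cms_list) == 1L) return(per_genome[[1L]])
  # keep regions of genome 1 shared with every other CMS genome
  shared_with <- function(region, others) {
    all(vapply(others, function(o) {
      any(vapply(o, function(r2) {
        h <- anchored_align(region$seq, r2$seq, min_identity = 0,
                            min_len = 100)
        h <- h[h$identity > share_identity, , drop = FALSE]
        if (nrow(h) == 0L) return(FALSE)
        cov <- interval_union_len(h$q_start, h$q_end)
        cov > 0.5 * min(region$length, r2$length)
      }, NA))
    }, NA))
  }
  keep <- vapply(per_genome[[1L]], shared_with, NA,
                 others = per_genome[-1L])
  per_genome[[1L]][keep]
}

#' Annotate a unique region with its contents
#'
#' Fills the region's `contained` lists with gene features, ORFs and repeats
#' overlapping the region by at least 1 bp, each with region-relative
#' coordinates.
#'
#' @param region one region from [find_unique_regions()].
#' @param genome the `CircularGenome` the region lives on.
#' @param orfs optional ORF table ([find_orfs()]).
#' @param repeats optional repeat table ([find_dispersed_repeats()]).
#' @return the region with a filled `contained` list.
#' @export
annotate_region <- function(region, genome, orfs = NULL, repeats = NULL) {
  pick <- function(df, s, e) {
    if (is.null(df) || nrow(df) == 0L)
      return(df[integer(0), , drop = FALSE])
    hit <- overlap_len(s, e, region$start, region$end) > 0L
    out <- df[hit, , drop = FALSE]
    out$rel_start <- s[hit] - region$start
    rownames(out) <- NULL
    out
  }
  g <- genome$genes
  contained <- list(
    genes = pick(g, g$start, g$end),
    orfs = if (is.null(orfs)) NULL else pick(orfs, orfs$start, orfs$end),
    repeats = if (is.null(repeats)) NULL else {
      r1 <- pick(repeats, repeats$start1, repeats$end1)
      r2 <- pick(repeats, repeats$start2, repeats$end2)
      unique(rbind(r1, r2))
    })
  region$contained <- contained
  region
}
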