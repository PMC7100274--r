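#' Classify a repeat by size
#'
#' Small repeats are shorter than 50 bp, intermediate repeats span 50-500 bp
#' inclusive, large repeats exceed 500 bp.
#'
#' @param length_bp repeat length(s) in bp (alignment columns).
#' @return character vector: "small", "intermediate" or "large".
#' @export
classify_repeat_size <- function(length_bp) {
  if (any(length_bp < 1)) stop("repeat length must be positive")
  ifelse(length_bp < 50, "small",
         ifelse(length_bp <= 500, "intermediate", "large"))
}

#' Find dispersed repeats by genome self-comparison
#'
#' The genome is aligned against itself (and against its reverse complement)
#' with the anchored aligner; the trivial full-length self-hit and mirror
#' duplicates are suppressed.  A pair counts as a repeat only when its
#' identity strictly exceeds `min_identity`.  Forward pairs are direct
#' repeats (DR), reverse pairs inverted repeats (IR); IR pairs whose arms
#' are separated by at most `max_spacer` bp are flagged palindromic.
#'
#' @param genome a `CircularGenome`.
#' @param min_identity identity that must be strictly exceeded (default 0.90).
#' @param min_len minimum repeat length in bp (default 20).
#' @param k seed length for the anchored aligner.
#' @param max_spacer maximum arm separation for the palindromic flag.
#' @param ... further arguments for [anchored_align()].
#' @return data frame of repeat pairs (`start1 < start2`, 0-based half-open)
#'   with orientation, identity, length, size class and palindromic flag.
#' @export
find_dispersed_repeats <- function(genome, min_identity = 0.90, min_len = 20,
                                   k = 12, max_spacer = 0, ...) {
  s <- genome$seq
  if (nchar(s) < 2 * min_len) stop("genome shorter than two repeat copies")
  hits <- anchored_align(s, s, k = k, min_identity = 0, min_len = min_len,
                         self = TRUE, ...)
  hits <- hits[hits$identity > min_identity, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(data.frame(start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      orientation = character(), identity = numeric(),
                      length = integer(), size_class = character(),
                      palindromic = logical(), stringsAsFactors = FALSE))
  }
  out <- data.frame(start1 = hits$q_start, end1 = hits$q_end,
                    start2 = hits$s_start, end2 = hits$s_end,
                    orientation = ifelse(hits$orientation == "forward",
                                         "DR", "IR"),
                    identity = hits$identity, length = hits$columns,
                    stringsAsFactors = FALSE)
  out$size_class <- classify_repeat_size(out$length)
  out$palindromic <- out$orientation == "IR" &
    (out$start2 - out$end1) >= 0 & (out$start2 - out$end1) <= max_spacer
  out <- out[order(out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find palindromes (adjacent inverted repeat arms)
#'
#' Exact maximal pairs of reverse-complementary arms whose spacer does not
#' exceed `max_spacer` ("continuous" inverted repeats at the default
#' spacer 0).
#'
#' @param genome a `CircularGenome`.
#' @param min_len minimum arm length (default 10).
#' @param max_spacer maximum separation between the two arms (default 0).
#' @return repeat-pair data frame with `palindromic = TRUE` and `arm` length.
#' @export
find_palindromes <- function(genome, min_len = 10, max_spacer = 0) {
  stopifnot(min_len >= 1)
  m <- palindrome_scan_cpp(genome$seq, as.integer(min_len),
                           as.integer(max_spacer))
  if (nrow(m) == 0L) {
    return(data.frame(start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      orientation = character(), identity = numeric(),
                      length = integer(), arm = integer(),
                      size_class = character(), palindromic = logical(),
                      stringsAsFactors = FALSE))
  }
  arm <- m[, "arm_len"]
  out <- data.frame(start1 = m[, "left_start"],
                    end1 = m[, "left_start"] + arm,
                    start2 = m[, "left_start"] + arm + m[, "spacer"],
                    end2 = m[, "left_start"] + 2L * arm + m[, "spacer"],
                    orientation = "IR", identity = 1.0,
                    length = arm, arm = arm,
                    stringsAsFactors = FALSE)
  out$size_class <- classify_repeat_size(out$length)
  out$palindromic <- TRUE
  out <- out[order(out$start1), , drop = FALSE]
  rownames(out) <- NULL
  out
}

ssr_class_names <- c("monomer", "dimer", "trimer", "tetramer", "pentamer",
                     "hexamer")

# lexicographically least rotation of a motif
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    ch <- strsplit(m, "")[[1]]
    rots <- vapply(seq_along(ch), function(i)
      paste(c(ch[i:length(ch)], ch[seq_len(i - 1L)]), collapse = ""), "")
    min(rots)
  }, "", USE.NAMES = FALSE)
}

#' Find simple sequence repeats (SSRs)
#'
#' Maximal tandem runs of primitive motifs of 1-6 bp.  A run is reported
#' when it reaches the per-motif-size minimum copy number and the minimum
#' total length; overlapping calls are resolved longest-first, then
#' leftmost.  Motifs are reported in canonical form (lexicographically
#' least rotation).
#'
#' @param genome a `CircularGenome` or DNA string.
#' @param motif_sizes motif lengths to scan (subset of 1:6).
#' @param min_total_len minimum run length in bp.
#' @param min_copies integer vector of minimum full copy numbers indexed by
#'   motif size.
#' @return data frame of SSR records.
#' @export
find_ssrs <- function(genome, motif_sizes = 1:6, min_total_len = 12,
                      min_copies = c(12, 6, 4, 3, 3, 3)) {
  s <- if (inherits(genome, "CircularGenome")) genome$seq else toupper(genome)
  m <- ssr_runs_cpp(s, max(motif_sizes))
  empty <- data.frame(motif = character(), motif_len = integer(),
                      copies = numeric(), start = integer(), end = integer(),
                      length = integer(), motif_class = character(),
                      stringsAsFactors = FALSE)
  if (nrow(m) == 0L) return(empty)
  ml <- m[, "motif_len"]; run <- m[, "run_len"]; st <- m[, "start"]
  keep <- ml %in% motif_sizes & run >= min_total_len &
    (run %/% ml) >= min_copies[ml]
  if (!any(keep)) return(empty)
  ml <- ml[keep]; run <- run[keep]; st <- st[keep]
  out <- data.frame(motif = canonical_motif(substr(rep(s, length(st)),
                                                   st + 1L, st + ml)),
                    motif_len = ml, copies = round(run / ml, 2),
                    start = st, end = st + run, length = run,
                    motif_class = ssr_class_names[ml],
                    stringsAsFactors = FALSE)
  # overlap resolution: longest first, then leftmost
  out <- out[order(-out$length, out$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  if (nrow(out) > 1L) {
    for (i in seq_len(nrow(out))[-1L]) {
      prior <- which(keep[seq_len(i - 1L)])
      if (any(overlap_len(out$start[i], out$end[i],
                          out$start[prior], out$end[prior]) > 0L))
        keep[i] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize the repeat landscape of a genome
#'
#' Counts of dispersed repeats by size class and orientation, SSR count,
#' and the unioned repeat footprint in bp and as a fraction of the genome.
#'
#' @param genome a `CircularGenome`.
#' @param repeats optional precomputed [find_dispersed_repeats()] output.
#' @param ssrs optional precomputed [find_ssrs()] output.
#' @param ... passed to [find_dispersed_repeats()].
#' @return list with `counts_by_size`, `counts_by_orientation`, `ssr_count`,
#'   `total_repeat_bp`, `repeat_fraction`.
#' @export
summarize_repeats <- function(genome, repeats = NULL, ssrs = NULL, ...) {
  if (is.null(repeats)) repeats <- find_dispersed_repeats(genome, ...)
  if (is.null(ssrs)) ssrs <- find_ssrs(genome)
  size <- setNames(integer(3), c("small", "intermediate", "large"))
  tb <- table(factor(repeats$size_class, levels = names(size)))
  size[names(tb)] <- as.integer(tb)
  orient <- c(DR = sum(repeats$orientation == "DR"),
              IR = sum(repeats$orientation == "IR"),
              SSR = nrow(ssrs))
  starts <- c(repeats$start1, repeats$start2, ssrs$start)
  ends <- c(repeats$end1, repeats$end2, ssrs$end)
  tot <- interval_union_len(starts, ends)
  list(counts_by_size = size, counts_by_orientation = orient,
       ssr_count = nrow(ssrs), total_repeat_bp = tot,
       repeat_fraction = tot / genome_length(genome))
}

#' Fraction of a genome aligned to a reference
#'
#' Percent of genome positions covered by at least one anchored-aligner hit
#' to the reference that passes the identity and length thresholds.
#'
#' @param genome a `CircularGenome`.
#' @param reference a `CircularGenome` or DNA string.
#' @param min_identity minimum hit identity.
#' @param min_len minimum hit length (bp).
#' @param ... passed to [anchored_align()].
#' @return percentage in \[0, 100\].
#' @export
fraction_aligned_to <- function(genome, reference, min_identity = 0.90,
                                min_len = 100, ...) {
  ref <- if (inherits(reference, "CircularGenome")) reference$seq
         else toupper(reference)
  if (nchar(ref) == 0L) stop("empty reference")
  hits <- anchored_align(genome$seq, ref, min_identity = min_identity,
                         min_len = min_len, ...)
  if (nrow(hits) == 0L) return(0)
  cov <- interval_union_len(hits$q_start, pmin(hits$q_end,
                                               genome_length(genome)))
  100 * cov / genome_length(genome)
}
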