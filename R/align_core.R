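#' Alignment scoring scheme
#'
#' BLASTN-like defaults: match +1, mismatch -2, gap open -5, gap extend -2.
#' A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param match positive match score.
#' @param mismatch mismatch penalty (<= 0).
#' @param gap_open gap opening penalty (<= 0).
#' @param gap_extend per-base gap extension penalty (<= 0).
#' @export
scoring_scheme <- function(match = 1, mismatch = -2, gap_open = -5,
                           gap_extend = -2) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

empty_hits <- function() {
  data.frame(q_start = integer(), q_end = integer(), s_start = integer(),
             s_end = integer(), orientation = character(),
             identity = numeric(), matches = integer(), columns = integer(),
             score = numeric(), aln_q = character(), aln_s = character(),
             stringsAsFactors = FALSE)
}

# score an alignment (two equal-length gapped strings) under a scheme
score_alignment <- function(aa, ab, scoring) {
  ca <- strsplit(aa, "")[[1]]; cb <- strsplit(ab, "")[[1]]
  ga <- ca == "-"; gb <- cb == "-"
  mat <- !ga & !gb & ca == cb & ca != "N"
  mis <- !ga & !gb & !mat
  gap_runs <- function(g) {
    r <- rle(g); sum(r$values)
  }
  n_open <- gap_runs(ga) + gap_runs(gb)
  n_gap <- sum(ga) + sum(gb)
  list(score = sum(mat) * scoring$match + sum(mis) * scoring$mismatch +
         n_open * scoring$gap_open + n_gap * scoring$gap_extend,
       matches = sum(mat), columns = length(ca))
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Exact dynamic-programming local aligner used as the oracle for the
#' k-mer anchored production aligner.  Limited to `cap` DP cells.
#'
#' @param a,b DNA strings.
#' @param scoring a [scoring_scheme()].
#' @param cap maximum allowed `nchar(a) * nchar(b)` (default 1e6 cells).
#' @return a one-row alignment-hit data frame (zero-score hits have empty
#'   intervals).
#' @export
local_align <- function(a, b, scoring = scoring_scheme(), cap = 1e6) {
  a <- toupper(a); b <- toupper(b)
  if (as.double(nchar(a)) * nchar(b) > cap)
    stop("input exceeds the DP oracle cap (", cap,
         " cells); use anchored_align() for large sequences")
  r <- affine_dp_cpp(a, b, scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_extend, 0L)
  data.frame(q_start = r$a_start, q_end = r$a_end, s_start = r$b_start,
             s_end = r$b_end, orientation = "forward",
             identity = if (r$columns > 0) r$matches / r$columns else NA_real_,
             matches = r$matches, columns = r$columns, score = r$score,
             aln_q = r$aln_a, aln_s = r$aln_b, stringsAsFactors = FALSE)
}

#' Global alignment (Needleman-Wunsch, affine gaps)
#'
#' @inheritParams local_align
#' @return list with `score`, `aln_a`, `aln_b`, `matches`, `columns`.
#' @export
global_align <- function(a, b, scoring = scoring_scheme()) {
  r <- affine_dp_cpp(toupper(a), toupper(b), scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_extend, 1L)
  list(score = r$score, aln_a = r$aln_a, aln_b = r$aln_b,
       matches = r$matches, columns = r$columns)
}

# best-prefix extension of a vs b anchored at their first bases
extend_align <- function(a, b, scoring) {
  if (nchar(a) == 0L || nchar(b) == 0L)
    return(list(a_len = 0L, b_len = 0L, aln_a = "", aln_b = "", score = 0))
  r <- affine_dp_cpp(a, b, scoring$match, scoring$mismatch, scoring$gap_open,
                     scoring$gap_extend, 2L)
  if (r$score <= 0)
    return(list(a_len = 0L, b_len = 0L, aln_a = "", aln_b = "", score = 0))
  list(a_len = r$a_end, b_len = r$b_end, aln_a = r$aln_a, aln_b = r$aln_b,
       score = r$score)
}

reverse_string <- function(x) {
  paste(rev(strsplit(x, "")[[1]]), collapse = "")
}

# group merged k-mer segments into candidate chains
chain_segments <- function(segs, band, max_gap) {
  if (nrow(segs) == 0L) return(list())
  d <- segs[, "q_start"] - segs[, "s_start"]
  o <- order(d, segs[, "q_start"])
  segs <- segs[o, , drop = FALSE]; d <- d[o]
  g1 <- cumsum(c(TRUE, diff(d) > band))
  out <- list()
  for (grp in split(seq_len(nrow(segs)), g1)) {
    sub <- segs[grp, , drop = FALSE]
    sub <- sub[order(sub[, "q_start"]), , drop = FALSE]
    qe <- cummax(sub[, "q_start"] + sub[, "len"])
    brk <- cumsum(c(TRUE, sub[-1L, "q_start"] > qe[-nrow(sub)] + max_gap))
    for (cc in split(seq_len(nrow(sub)), brk))
      out[[length(out) + 1L]] <- sub[cc, , drop = FALSE]
  }
  out
}

# turn one chain of exact segments into a full alignment hit
stitch_chain <- function(a, b, chain, scoring, ext_window) {
  chain <- chain[order(chain[, "q_start"], chain[, "s_start"]), , drop = FALSE]
  # drop segments stepping backwards in s, then trim overlaps
  keep <- logical(nrow(chain)); se <- -1L
  for (i in seq_len(nrow(chain))) {
    if (chain[i, "s_start"] + chain[i, "len"] > se) {
      keep[i] <- TRUE; se <- chain[i, "s_start"] + chain[i, "len"]
    }
  }
  chain <- chain[keep, , drop = FALSE]
  qa <- character(0); sa <- character(0)
  pq <- ps <- NA_integer_
  for (i in seq_len(nrow(chain))) {
    q0 <- chain[i, "q_start"]; s0 <- chain[i, "s_start"]; l <- chain[i, "len"]
    if (i > 1L) {
      cut <- max(pq - q0, ps - s0, 0L)
      q0 <- q0 + cut; s0 <- s0 + cut; l <- l - cut
      if (l <= 0L) next
      gq <- substr(a, pq + 1L, q0); gs <- substr(b, ps + 1L, s0)
      if (nchar(gq) > 0L || nchar(gs) > 0L) {
        if (nchar(gq) == 0L) {
          qa <- c(qa, strrep("-", nchar(gs))); sa <- c(sa, gs)
        } else if (nchar(gs) == 0L) {
          qa <- c(qa, gq); sa <- c(sa, strrep("-", nchar(gq)))
        } else {
          g <- global_align(gq, gs, scoring)
          qa <- c(qa, g$aln_a); sa <- c(sa, g$aln_b)
        }
      }
    }
    seg <- substr(a, q0 + 1L, q0 + l)
    qa <- c(qa, seg); sa <- c(sa, substr(b, s0 + 1L, s0 + l))
    pq <- q0 + l; ps <- s0 + l
  }
  if (is.na(pq)) return(NULL)
  q_from <- chain[1L, "q_start"]; s_from <- chain[1L, "s_start"]
  # left extension (on reversed flanks)
  la <- reverse_string(substr(a, max(1L, q_from - ext_window + 1L), q_from))
  lb <- reverse_string(substr(b, max(1L, s_from - ext_window + 1L), s_from))
  el <- extend_align(la, lb, scoring)
  # right extension
  ra <- substr(a, pq + 1L, min(nchar(a), pq + ext_window))
  rb <- substr(b, ps + 1L, min(nchar(b), ps + ext_window))
  er <- extend_align(ra, rb, scoring)
  aln_q <- paste0(reverse_string(el$aln_a), paste(qa, collapse = ""), er$aln_a)
  aln_s <- paste0(reverse_string(el$aln_b), paste(sa, collapse = ""), er$aln_b)
  sc <- score_alignment(aln_q, aln_s, scoring)
  data.frame(q_start = q_from - el$a_len, q_end = pq + er$a_len,
             s_start = s_from - el$b_len, s_end = ps + er$b_len,
             orientation = "forward",
             identity = sc$matches / sc$columns, matches = sc$matches,
             columns = sc$columns, score = sc$score,
             aln_q = aln_q, aln_s = aln_s, stringsAsFactors = FALSE)
}

# drop hits that substantially duplicate a higher-scoring hit
dedupe_hits <- function(hits, frac = 0.5) {
  if (nrow(hits) <= 1L) return(hits)
  o <- order(-hits$score, hits$q_start)
  hits <- hits[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1L]) {
    for (j in seq_len(i - 1L)) {
      if (!keep[j] || hits$orientation[i] != hits$orientation[j]) next
      qo <- overlap_len(hits$q_start[i], hits$q_end[i],
                        hits$q_start[j], hits$q_end[j])
      so <- overlap_len(hits$s_start[i], hits$s_end[i],
                        hits$s_start[j], hits$s_end[j])
      li <- min(hits$q_end[i] - hits$q_start[i], hits$s_end[i] - hits$s_start[i])
      if (qo > frac * li && so > frac * li) { keep[i] <- FALSE; break }
    }
  }
  hits[keep, , drop = FALSE]
}

#' k-mer anchored seed-and-extend pairwise aligner
#'
#' The production aligner: exact k-mer seeds on both strands are merged into
#' maximal exact segments, grouped into co-diagonal chains, stitched with
#' banded dynamic programming across inter-anchor gaps, and extended at both
#' ends.  Reverse-orientation hits report the subject interval on the forward
#' strand with `orientation = "reverse"` (their alignment strings are in
#' reverse-complement orientation).
#'
#' @param a,b DNA strings (query, subject).
#' @param k seed length (>= 8).
#' @param min_identity minimum identity of an emitted hit.
#' @param min_len minimum aligned length (columns) of an emitted hit.
#' @param scoring a [scoring_scheme()].
#' @param band maximum diagonal drift when grouping seeds into one chain.
#' @param max_gap maximum unseeded gap bridged within a chain (bp).
#' @param max_occ k-mers occurring more often than this in the subject are
#'   not used as seeds (tandem arrays are the SSR detector's job).
#' @param ext_window flank window used for end extension (bp).
#' @param min_anchor minimum total exact-anchor length for a chain to be
#'   evaluated; `NULL` (default) keeps every chain for small inputs
#'   (< 1e7 DP-cell equivalent) and uses 20 bp at genome scale.
#' @param both_strands also search the reverse strand.
#' @param self self-comparison mode: the trivial main-diagonal hit and
#'   mirror duplicates are suppressed.
#' @return data frame of alignment hits sorted by query interval.
#' @export
anchored_align <- function(a, b, k = 12, min_identity = 0.0, min_len = 30,
                           scoring = scoring_scheme(), band = 32,
                           max_gap = 500, max_occ = 50, ext_window = 600,
                           min_anchor = NULL, both_strands = TRUE,
                           self = FALSE) {
  stopifnot(k >= 8, nchar(a) > 0, nchar(b) > 0)
  a <- toupper(a); b <- toupper(b)
  if (is.null(min_anchor))
    min_anchor <- if (as.double(nchar(a)) * nchar(b) <= 1e7) k else 20L

  run_strand <- function(bstr, self_mode) {
    segs <- kmer_segments_cpp(a, bstr, as.integer(k), as.integer(max_occ),
                              as.integer(self_mode))
    chains <- chain_segments(segs, band, max_gap)
    chains <- Filter(function(ch) sum(ch[, "len"]) >= min_anchor, chains)
    hits <- lapply(chains, function(ch) stitch_chain(a, bstr, ch, scoring,
                                                     ext_window))
    hits <- hits[!vapply(hits, is.null, NA)]
    if (length(hits) == 0L) return(empty_hits())
    do.call(rbind, hits)
  }

  fwd <- run_strand(b, if (self) 1L else 0L)
  out <- fwd
  if (both_strands) {
    rb <- revcomp(b)
    rev <- run_strand(rb, 0L)
    if (nrow(rev) > 0L) {
      Lb <- nchar(b)
      s0 <- Lb - rev$s_end; s1 <- Lb - rev$s_start
      rev$s_start <- s0; rev$s_end <- s1
      rev$orientation <- "reverse"
      if (self) {
        # canonical ordering: drop mirror duplicates
        rev <- rev[rev$q_start <= rev$s_start, , drop = FALSE]
      }
      out <- rbind(out, rev)
    }
  }
  if (nrow(out) == 0L) return(out)
  if (self) {
    # a hit largely coinciding with itself (tandem/palindromic self-map)
    # is not a dispersed pair
    self_ov <- overlap_len(out$q_start, out$q_end, out$s_start, out$s_end)
    shorter <- pmin(out$q_end - out$q_start, out$s_end - out$s_start)
    out <- out[self_ov <= 0.5 * shorter, , drop = FALSE]
  }
  out <- out[out$columns >= min_len & out$identity >= min_identity, ,
             drop = FALSE]
  out <- dedupe_hits(out)
  out <- out[order(out$q_start, out$q_end, out$s_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent identity of an alignment hit
#'
#' Identity is matches / alignment columns; gap columns count in the
#' denominator (the BLAST "identities / alignment length" convention).
#'
#' @param hit a one-row (or multi-row) alignment-hit data frame.
#' @return numeric vector of identities in \[0, 1\].
#' @export
percent_identity <- function(hit) {
  if (any(hit$columns == 0L)) stop("zero-column alignment has no identity")
  hit$matches / hit$columns
}
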