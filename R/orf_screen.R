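STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Predict open reading frames on a circular genome
#'
#' All ATG-to-stop frames on both strands and all three frames,
#' circular-aware (an ORF may span the origin; its length cannot exceed the
#' genome length).  For nested ATGs sharing a stop only the longest frame is
#' reported.  `nt_length` includes the stop codon; `aa_length` excludes it.
#' ORFs are kept when `nt_length` strictly exceeds `min_len`.
#'
#' @param genome a `CircularGenome`.
#' @param min_len length in bp that an ORF must exceed (default 300).
#' @return data frame of ORFs sorted by start with ids assigned by
#'   [name_orf()] convention ("orf" + aa length, letter suffix on
#'   collision).  For origin-spanning ORFs `end` exceeds the genome length.
#' @export
find_orfs <- function(genome, min_len = 300) {
  L <- genome_length(genome)
  scan_strand <- function(s, strand) {
    S <- if (genome$circular) paste0(s, s) else s
    rows <- list()
    for (f in 0:2) {
      starts <- seq.int(f + 1L, nchar(S) - 2L, by = 3L)
      cods <- substring(S, starts, starts + 2L)
      is_stop <- cods %in% STOP_CODONS
      is_atg <- cods == "ATG"
      # segment id: increments after each stop; the longest frame per stop
      # starts at the segment's first ATG
      seg <- cumsum(c(FALSE, is_stop[-length(is_stop)]))
      stop_idx <- which(is_stop)
      atg_idx <- which(is_atg)
      if (length(stop_idx) == 0L || length(atg_idx) == 0L) next
      sa <- seg[atg_idx]
      first_atg <- setNames(atg_idx[!duplicated(sa)], sa[!duplicated(sa)])
      a0 <- unname(first_atg[as.character(seg[stop_idx])])
      ok <- !is.na(a0)
      si <- stop_idx[ok]; a0 <- a0[ok]
      nt <- (si - a0 + 1L) * 3L
      start0 <- starts[a0] - 1L
      keep <- start0 < L & nt <= L & nt > min_len
      if (any(keep))
        rows[[length(rows) + 1L]] <-
          cbind(start = start0[keep], nt = nt[keep], frame = f)
    }
    if (length(rows) == 0L) return(NULL)
    m <- do.call(rbind, rows)
    df <- data.frame(start_s = m[, "start"], nt_length = m[, "nt"],
                     frame = m[, "frame"], strand = strand,
                     stringsAsFactors = FALSE)
    df$seq <- vapply(seq_len(nrow(df)), function(i) {
      e <- df$start_s[i] + df$nt_length[i]
      if (genome$circular) substr(paste0(s, s), df$start_s[i] + 1L, e)
      else substr(s, df$start_s[i] + 1L, e)
    }, "")
    df
  }
  fw <- scan_strand(genome$seq, "+")
  rc <- revcomp(genome$seq)
  rv <- scan_strand(rc, "-")
  if (!is.null(rv)) {
    # map reverse-strand coordinates back to the forward strand
    e_rc <- rv$start_s + rv$nt_length
    rv$start_s <- (L - e_rc) %% L
  }
  df <- rbind(fw, rv)
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(id = character(), start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      nt_length = integer(), aa_length = integer(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  out <- data.frame(start = as.integer(df$start_s),
                    end = as.integer(df$start_s + df$nt_length),
                    strand = df$strand, frame = as.integer(df$frame),
                    nt_length = as.integer(df$nt_length),
                    aa_length = as.integer(df$nt_length / 3L - 1L),
                    seq = df$seq, stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  out <- cbind(id = name_orfs(out$aa_length), out)
  out$id <- as.character(out$id)
  rownames(out) <- NULL
  out
}

#' Name an ORF after its amino-acid length
#'
#' Convention: "orf" + amino-acid length; colliding lengths get letter
#' suffixes "b", "c", ... in genomic order.
#'
#' @param aa_length amino-acid length of the ORF to name.
#' @param existing_names ids already assigned, in genomic order.
#' @return the id string.
#' @export
name_orf <- function(aa_length, existing_names = character()) {
  base <- paste0("orf", aa_length)
  prior <- sum(grepl(paste0("^", base, "[b-z]?$"), existing_names))
  if (prior == 0L) base else paste0(base, letters[prior + 1L])
}

# vectorized naming in genomic order
name_orfs <- function(aa_lengths) {
  ids <- character(length(aa_lengths))
  for (i in seq_along(aa_lengths)) ids[i] <- name_orf(aa_lengths[i], ids[seq_len(i - 1L)])
  ids
}

# per-position TRUE where the genome matches `other` in some alignment hit
match_profile <- function(genome_seq, other_seq, ...) {
  hits <- anchored_align(genome_seq, other_seq, min_identity = 0,
                         min_len = 50, ...)
  prof <- logical(nchar(genome_seq))
  for (i in seq_len(nrow(hits))) {
    qa <- strsplit(hits$aln_q[i], "")[[1]]
    sa <- strsplit(hits$aln_s[i], "")[[1]]
    qgap <- qa == "-"
    qpos <- hits$q_start[i] + cumsum(!qgap)        # 1-based genome position
    ok <- !qgap & sa != "-" & qa == sa & qa != "N"
    prof[qpos[ok]] <- TRUE
  }
  prof
}

#' Screen for CMS-specific ORFs
#'
#' Predicts ORFs on the CMS genome and keeps those without a near-identical
#' home anywhere in the paired maintainer genome: an ORF is specific when
#' the fraction of its positions matched in the best maintainer alignment is
#' strictly below `sim_threshold`.  Matching uses genome-wide anchored
#' alignment of the CMS genome against the maintainer, so an ORF inside a
#' maintainer non-coding region is still non-specific.
#'
#' @param cms_genome,maintainer_genome `CircularGenome` objects.
#' @param min_len passed to [find_orfs()].
#' @param sim_threshold identity below which an ORF counts as specific
#'   (default 0.99, strict `<`).
#' @param orfs optional precomputed ORF table for the CMS genome.
#' @return the specific subset of the ORF table, with an
#'   `identity_vs_maintainer` column.
#' @export
screen_specific_orfs <- function(cms_genome, maintainer_genome,
                                 min_len = 300, sim_threshold = 0.99,
                                 orfs = NULL) {
  if (is.null(orfs)) orfs <- find_orfs(cms_genome, min_len = min_len)
  if (nrow(orfs) == 0L) return(orfs)
  prof <- match_profile(cms_genome$seq, maintainer_genome$seq)
  L <- genome_length(cms_genome)
  ident <- vapply(seq_len(nrow(orfs)), function(i) {
    pos <- (orfs$start[i]:(orfs$end[i] - 1L)) %% L + 1L
    sum(prof[pos]) / orfs$nt_length[i]
  }, 0)
  orfs$identity_vs_maintainer <- ident
  out <- orfs[ident < sim_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# global identity between two ORF sequences (tries both strands)
orf_identity <- function(sa, sb) {
  if (sa == sb) return(1.0)
  if (abs(nchar(sa) - nchar(sb)) > 0.05 * max(nchar(sa), nchar(sb)))
    return(0.0)
  g1 <- global_align(sa, sb)
  g2 <- global_align(sa, revcomp(sb))
  max(g1$matches / g1$columns, g2$matches / g2$columns)
}

#' Shared CMS-specific ORFs across CMS lines
#'
#' ORFs from the first CMS line's specific set with a reciprocal-best match
#' of identity at least `min_identity` in every other CMS line's specific
#' set.
#'
#' @param specific_sets list (>= 2) of [screen_specific_orfs()] outputs.
#' @param min_identity reciprocal-match identity (default 0.99).
#' @return list with `shared` (subset of the first set, plus match ids per
#'   other set) and `per_genome` (the input sets).
#' @export
shared_specific_orfs <- function(specific_sets, min_identity = 0.99) {
  stopifnot(length(specific_sets) >= 2L)
  s1 <- specific_sets[[1L]]
  if (nrow(s1) == 0L)
    return(list(shared = s1, per_genome = specific_sets))
  match_cols <- list()
  keep <- rep(TRUE, nrow(s1))
  for (k in seq_along(specific_sets)[-1L]) {
    sk <- specific_sets[[k]]
    idm <- matrix(0, nrow(s1), max(1L, nrow(sk)))
    for (i in seq_len(nrow(s1))) for (j in seq_len(nrow(sk)))
      idm[i, j] <- orf_identity(s1$seq[i], sk$seq[j])
    best1 <- apply(idm, 1L, which.max)
    bestk <- apply(idm, 2L, which.max)
    ok <- vapply(seq_len(nrow(s1)), function(i) {
      j <- best1[i]
      nrow(sk) > 0L && idm[i, j] >= min_identity && bestk[j] == i
    }, NA)
    keep <- keep & ok
    match_cols[[paste0("match_", k)]] <-
      ifelse(ok, sk$id[best1], NA_character_)
  }
  shared <- s1
  for (nm in names(match_cols)) shared[[nm]] <- match_cols[[nm]]
  shared <- shared[keep, , drop = FALSE]
  rownames(shared) <- NULL
  list(shared = shared, per_genome = specific_sets)
}
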