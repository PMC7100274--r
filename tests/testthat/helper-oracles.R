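# independent oracles and small fixture builders used across the suite

rnd_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

rc <- function(x) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(x)))

# brute-force SSR scanner: try every motif at every position
brute_ssrs <- function(s, min_total_len = 12,
                       min_copies = c(12, 6, 4, 3, 3, 3)) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  out <- list()
  for (m in 1:6) {
    i <- 1L
    while (i + 2L * m - 1L <= n) {
      if (i > m && ch[i] == ch[i - m]) { i <- i + 1L; next }
      motif <- paste(ch[i:(i + m - 1L)], collapse = "")
      prim <- TRUE
      for (d in seq_len(m - 1L)) {
        if (m %% d == 0L &&
            motif == strrep(substr(motif, 1, d), m / d)) prim <- FALSE
      }
      if (!prim || grepl("N", motif)) { i <- i + 1L; next }
      j <- i + m
      while (j <= n && ch[j] == ch[j - m]) j <- j + 1L
      run <- j - i
      if (run >= min_total_len && run %/% m >= min_copies[m])
        out[[length(out) + 1L]] <- data.frame(
          start = i - 1L, end = i - 1L + run, motif_len = m,
          stringsAsFactors = FALSE)
      i <- i + 1L
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      motif_len = integer()))
  unique(do.call(rbind, out))
}

# exhaustive six-frame ORF enumeration on a circular sequence
brute_orfs <- function(s, min_len = 300, circular = TRUE) {
  L <- nchar(s)
  scan <- function(seq, strand) {
    S <- if (circular) paste0(seq, seq) else seq
    ch <- strsplit(S, "")[[1]]
    res <- list()
    for (start in seq_len(min(L, nchar(S) - 2L))) {
      if (paste(ch[start:(start + 2L)], collapse = "") != "ATG") next
      # extend codon by codon to the first stop
      p <- start
      found <- FALSE
      while (p + 2L <= nchar(S)) {
        cod <- paste(ch[p:(p + 2L)], collapse = "")
        if (cod %in% c("TAA", "TAG", "TGA")) { found <- TRUE; break }
        p <- p + 3L
      }
      if (!found) next
      nt <- p + 3L - start
      if (nt <= min_len || nt > L) next
      res[[length(res) + 1L]] <- data.frame(start_s = start - 1L, nt = nt,
                                            strand = strand)
    }
    if (length(res) == 0L) return(NULL)
    df <- do.call(rbind, res)
    # longest ORF per stop: nested ATGs share the stop's circular position
    o <- order(-df$nt)
    df <- df[o, , drop = FALSE]
    stop_key <- (df$start_s + df$nt) %% L
    df <- df[!duplicated(stop_key), , drop = FALSE]
    df
  }
  fw <- scan(s, "+")
  rv <- scan(rc(s), "-")
  if (!is.null(rv)) rv$start_s <- (L - (rv$start_s + rv$nt)) %% L
  out <- rbind(fw, rv)
  if (is.null(out)) return(data.frame(start = integer(), nt = integer(),
                                      strand = character()))
  data.frame(start = out$start_s, nt = out$nt, strand = out$strand,
             stringsAsFactors = FALSE)
}

# exhaustive Fitch small parsimony: minimize changes over all internal
# state assignments (feasible for <= 6 leaves)
brute_fitch <- function(tree, mat) {
  if (!ape::is.rooted(tree))
    tree <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  states <- c("A", "C", "G", "T")
  total <- 0
  for (site in seq_len(ncol(mat))) {
    tipst <- mat[tree$tip.label, site]
    best <- Inf
    grid <- expand.grid(rep(list(states), nnode), stringsAsFactors = FALSE)
    for (g in seq_len(nrow(grid))) {
      assign_ <- unlist(grid[g, ])
      cost <- 0
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1L]; chd <- tree$edge[e, 2L]
        sp <- assign_[p - ntip]
        sc <- if (chd <= ntip) tipst[chd] else assign_[chd - ntip]
        if (sc %in% states && sp != sc) cost <- cost + 1
      }
      best <- min(best, cost)
    }
    total <- total + best
  }
  total
}

# small annotated genome builder
toy_genome <- function(id, seq, genes = NULL, circular = TRUE) {
  g <- if (is.null(genes)) mitocompare:::empty_genes() else genes
  circular_genome(id, seq, circular = circular, genes = g)
}

gene_row <- function(name, start, end, part = NA_character_, strand = "+",
                     kind = "protein") {
  data.frame(name = name, part = part, start = start, end = end,
             strand = strand, kind = kind, stringsAsFactors = FALSE)
}

# shared full-scale quartet for planted-recovery checks (built once)
quartet_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_quartet(sim_config(seed = 20240301))
    cache
  }
})
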