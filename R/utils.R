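#' @useDynLib mitocompare, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames rbinom runif
#' @importFrom utils head tail write.table read.table
NULL

# reverse complement of a plain character string over {A,C,G,T,N}
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# total length of the union of [start, end) intervals
interval_union_len <- function(start, end) {
  if (length(start) == 0L) return(0L)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  tot <- 0L; cs <- start[1L]; ce <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= ce) {
      ce <- max(ce, end[i])
    } else {
      tot <- tot + (ce - cs); cs <- start[i]; ce <- end[i]
    }
  }
  tot + (ce - cs)
}

# merge [start, end) intervals closer than `gap`; returns two-column matrix
merge_intervals <- function(start, end, gap = 0L) {
  if (length(start) == 0L) return(cbind(start = integer(), end = integer()))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]; out <- list()
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me + gap) {
      me <- max(me, end[i])
    } else {
      out[[length(out) + 1L]] <- c(ms, me); ms <- start[i]; me <- end[i]
    }
  }
  out[[length(out) + 1L]] <- c(ms, me)
  mat <- do.call(rbind, out)
  colnames(mat) <- c("start", "end")
  mat
}

# overlap in bp of [a1,a2) with [b1,b2)
overlap_len <- function(a1, a2, b1, b2) pmax(0L, pmin(a2, b2) - pmax(a1, b1))

# split an annotated gene label into base name + part suffix.
# Trailing "-D<k>" marks an extra gene copy; trailing a-e letters after a
# digit mark trans-spliced exon groups ("nad2ab" -> nad2, parts "ab").
split_gene_name <- function(x) {
  part <- rep(NA_character_, length(x))
  base <- x
  has_d <- grepl("-D[0-9]+$", base)
  part[has_d] <- sub("^.*-(D[0-9]+)$", "\\1", base[has_d])
  base[has_d] <- sub("-D[0-9]+$", "", base[has_d])
  has_p <- grepl("^.*[0-9][a-e]+$", base) & !grepl("^trn", base)
  p2 <- sub("^.*[0-9]([a-e]+)$", "\\1", base[has_p])
  part[has_p] <- ifelse(is.na(part[has_p]), p2, paste0(p2, part[has_p]))
  base[has_p] <- sub("([0-9])[a-e]+$", "\\1", base[has_p])
  data.frame(base = base, part = part, stringsAsFactors = FALSE)
}

# empty gene feature table
empty_genes <- function() {
  data.frame(name = character(), part = character(), start = integer(),
             end = integer(), strand = character(), kind = character(),
             stringsAsFactors = FALSE)
}

gene_kind_from_name <- function(name) {
  ifelse(grepl("^trn", name), "tRNA",
         ifelse(grepl("^rrn", name), "rRNA",
                ifelse(grepl("^orf", name, ignore.case = TRUE), "orf",
                       "protein")))
}
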