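#' Construct a circular genome object
#'
#' The central container of the package: a DNA sequence with circular
#' topology and an attached gene-feature table.  All coordinates in the
#' package are 0-based, half-open, on the forward strand; conversion to the
#' 1-based closed convention of GenBank/GFF3 happens only at I/O boundaries.
#'
#' @param id genome identifier.
#' @param seq DNA string; lowercase is uppercased, IUPAC ambiguity codes
#'   other than N are converted to N with a warning.
#' @param circular logical topology flag.
#' @param genes gene feature table with columns `name`, `part`, `start`,
#'   `end`, `strand`, `kind` (0-based half-open coordinates).
#' @return an object of class `CircularGenome`.
#' @export
circular_genome <- function(id, seq, circular = TRUE, genes = empty_genes()) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) == 0L) stop("genome '", id, "': empty sequence")
  bad <- gsub("[ACGTN]", "", seq)
  if (nchar(bad) > 0L) {
    iupac <- "RYSWKMBDHV"
    if (nchar(gsub(paste0("[", iupac, "]"), "", bad)) > 0L)
      stop("genome '", id, "': non-DNA characters in sequence: ",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
    warning("genome '", id, "': IUPAC ambiguity codes converted to N")
    seq <- chartr(iupac, strrep("N", nchar(iupac)), seq)
  }
  stopifnot(is.data.frame(genes))
  if (nrow(genes) > 0L) {
    stopifnot(all(genes$start >= 0L), all(genes$start < nchar(seq)),
              all(genes$end > genes$start))
  }
  structure(list(id = id, seq = seq, circular = circular, genes = genes),
            class = "CircularGenome")
}

#' @export
print.CircularGenome <- function(x, ...) {
  cat(sprintf("CircularGenome '%s': %s bp, %s, %d gene features, GC %.2f%%\n",
              x$id, format(genome_length(x), big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$genes), 100 * gc_content(x)))
  invisible(x)
}

#' Genome length in bp
#' @param genome a `CircularGenome`.
#' @export
genome_length <- function(genome) nchar(genome$seq)

#' GC content of a genome
#'
#' Fraction (G + C) / (A + C + G + T); N positions are excluded from the
#' denominator.  Returns `NA` for an all-N sequence.
#'
#' @param genome a `CircularGenome` or a plain DNA string.
#' @return fraction in \[0, 1\].
#' @export
gc_content <- function(genome) {
  s <- if (inherits(genome, "CircularGenome")) genome$seq else toupper(genome)
  counts <- table(strsplit(s, "")[[1]])
  gc <- sum(counts[names(counts) %in% c("G", "C")])
  acgt <- sum(counts[names(counts) %in% c("A", "C", "G", "T")])
  if (acgt == 0L) return(NA_real_)
  gc / acgt
}

#' Rotate a circular genome to a new origin
#'
#' The sequence is rotated so that position `new_origin` becomes position 0;
#' feature coordinates are remapped.  A feature that comes to span the new
#' origin keeps its start in \[0, length) and an `end` beyond the genome
#' length to denote the wrap.
#'
#' @param genome a circular `CircularGenome`.
#' @param new_origin 0-based position that becomes the new origin.
#' @export
rotate_genome <- function(genome, new_origin) {
  if (!genome$circular) stop("cannot rotate a linear genome")
  L <- genome_length(genome)
  o <- as.integer(new_origin) %% L
  if (o == 0L) return(genome)
  seq <- paste0(substr(genome$seq, o + 1L, L), substr(genome$seq, 1L, o))
  genes <- genome$genes
  if (nrow(genes) > 0L) {
    len <- genes$end - genes$start
    genes$start <- (genes$start - o) %% L
    genes$end <- genes$start + len
  }
  g <- circular_genome(genome$id, seq, TRUE, genes)
  attr(g, "rotation") <- (attr(genome, "rotation") %||% 0L) + o
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# extract the sequence of a (possibly origin-wrapping) interval
genome_subseq <- function(genome, start, end) {
  L <- genome_length(genome)
  if (end <= L) return(substr(genome$seq, start + 1L, end))
  paste0(substr(genome$seq, start + 1L, L), substr(genome$seq, 1L, end - L))
}

#' Read genomes from a FASTA file
#'
#' @param path FASTA file (may contain several records).
#' @param circular topology assigned to every record (FASTA carries none).
#' @return list of `CircularGenome`, in file order, without annotations.
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i)
    circular_genome(ids[i], as.character(set[[i]]), circular = circular))
}

#' Write genomes to a FASTA file
#' @param genomes a `CircularGenome` or list of them.
#' @param path output path.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "CircularGenome")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "seq"))
  names(set) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# ---- GenBank flat file ------------------------------------------------------

# parse a GenBank location string into (start0, end0, strand, origin_span)
parse_gb_location <- function(loc, L) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",")[[1]]
  segs <- lapply(parts, function(p) {
    p <- gsub("complement\\(|\\)", "", p)
    nums <- as.numeric(strsplit(p, "\\.\\.")[[1]])
    if (length(nums) == 1L) nums <- c(nums, nums)
    nums
  })
  s <- vapply(segs, `[`, 0, 1L); e <- vapply(segs, `[`, 0, 2L)
  # origin-spanning join: last segment wraps to the sequence start
  wraps <- length(s) > 1L && s[1L] > e[length(e)]
  if (wraps) {
    total <- sum(e - s + 1)
    list(start = s[1L] - 1, end = s[1L] - 1 + total, strand = strand,
         wraps = TRUE)
  } else {
    list(start = min(s) - 1, end = max(e), strand = strand, wraps = FALSE)
  }
}

#' Read an annotated genome from a GenBank flat file
#'
#' Parses the LOCUS line (length, topology), the feature table (gene, CDS,
#' tRNA and rRNA features with `/gene` or `/product` qualifiers, including
#' `join()` and `complement()` locations) and the ORIGIN sequence block.
#' Gene labels are split into base name and part suffix.  If any feature
#' spans the origin the genome is rotated so that none does; the applied
#' rotation is stored in the `"rotation"` attribute.
#'
#' @param path GenBank flat file.
#' @return a `CircularGenome`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("not a GenBank file (no LOCUS line): ", path)
  toks <- strsplit(trimws(locus[1L]), "\\s+")[[1]]
  id <- toks[2L]
  circular <- any(tolower(toks) == "circular")

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) stop("GenBank file has no ORIGIN block: ", path)
  seq_lines <- lines[(ori[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  L <- nchar(seq)

  fstart <- grep("^FEATURES", lines)
  feats <- empty_genes(); wraps_any <- FALSE
  if (length(fstart) > 0L) {
    block <- lines[(fstart[1L] + 1L):(ori[1L] - 1L)]
    keyline <- grepl("^ {5}\\S", block)
    idx <- which(keyline)
    rows <- list()
    for (i in seq_along(idx)) {
      ln <- block[idx[i]]
      key <- sub("^\\s+", "", substr(ln, 1, 20))
      key <- strsplit(key, "\\s+")[[1]][1]
      to <- if (i < length(idx)) idx[i + 1L] - 1L else length(block)
      body <- block[idx[i]:to]
      if (!key %in% c("gene", "CDS", "tRNA", "rRNA")) next
      # location: continuation lines before the first qualifier
      qual <- grep("^\\s+/", body)
      locend <- if (length(qual)) qual[1L] - 1L else length(body)
      loc <- paste(trimws(c(sub("^\\s*\\S+\\s+", "", body[1L]),
                            if (locend >= 2L) trimws(body[2:locend]))),
                   collapse = "")
      gq <- grep('^\\s+/gene="', body, value = TRUE)
      lq <- grep('^\\s+/label="', body, value = TRUE)
      name <- if (length(gq)) sub('.*/gene="([^"]*)".*', "\\1", gq[1L])
              else if (length(lq)) sub('.*/label="([^"]*)".*', "\\1", lq[1L])
              else NA_character_
      p <- parse_gb_location(loc, L)
      if (p$start < 0 || p$start >= L)
        stop("feature outside sequence bounds in ", path)
      wraps_any <- wraps_any || p$wraps
      rows[[length(rows) + 1L]] <-
        data.frame(key = key, name = name, start = as.integer(p$start),
                   end = as.integer(p$end), strand = p$strand,
                   stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      tab <- do.call(rbind, rows)
      # prefer CDS/tRNA/rRNA rows; drop plain `gene` rows duplicating them
      spec <- tab[tab$key != "gene", , drop = FALSE]
      gen <- tab[tab$key == "gene", , drop = FALSE]
      if (nrow(gen) > 0L && nrow(spec) > 0L) {
        dup <- vapply(seq_len(nrow(gen)), function(i) {
          any(spec$name == gen$name[i] &
                overlap_len(spec$start, spec$end, gen$start[i], gen$end[i]) > 0L)
        }, NA)
        gen <- gen[!dup, , drop = FALSE]
      }
      tab <- rbind(spec, gen)
      nm <- split_gene_name(ifelse(is.na(tab$name), "unknown", tab$name))
      kind <- ifelse(tab$key == "tRNA", "tRNA",
                     ifelse(tab$key == "rRNA", "rRNA",
                            gene_kind_from_name(nm$base)))
      feats <- data.frame(name = nm$base, part = nm$part, start = tab$start,
                          end = tab$end, strand = tab$strand, kind = kind,
                          stringsAsFactors = FALSE)
      feats <- feats[order(feats$start), , drop = FALSE]
      rownames(feats) <- NULL
    }
  }
  if (wraps_any && circular) {
    # rotate so no feature spans the origin
    w <- feats$end > L
    g <- circular_genome(id, seq, circular, feats[!w, , drop = FALSE])
    off <- min(feats$start[w])
    g$genes <- feats
    g <- rotate_genome(g, off)
    return(g)
  }
  circular_genome(id, seq, circular, feats)
}

# ---- GFF3 / BED -------------------------------------------------------------

#' Write gene features to GFF3
#' @param genome a `CircularGenome`.
#' @param path output path.
#' @export
write_gff3 <- function(genome, path) {
  g <- genome$genes
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", genome$id,
                     genome_length(genome)), con)
  if (nrow(g) > 0L) {
    type <- c(protein = "gene", tRNA = "tRNA", rRNA = "rRNA", orf = "ORF")[g$kind]
    lab <- ifelse(is.na(g$part), g$name, paste0(g$name, ifelse(
      grepl("^D", g$part), paste0("-", g$part), g$part)))
    writeLines(sprintf("%s\tmitocompare\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                       genome$id, type, g$start + 1L, g$end, g$strand,
                       paste0("feat", seq_len(nrow(g))), lab), con)
  }
  invisible(path)
}

#' Read gene features from GFF3 into a genome
#' @param genome a `CircularGenome` (annotations replaced).
#' @param path GFF3 file written by [write_gff3()] or compatible.
#' @export
read_gff3 <- function(genome, path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) { genome$genes <- empty_genes(); return(genome) }
  f <- read.table(text = lines, sep = "\t", quote = "",
                  stringsAsFactors = FALSE)
  lab <- sub(".*Name=([^;]*).*", "\\1", f$V9)
  nm <- split_gene_name(lab)
  kind <- c(gene = "protein", tRNA = "tRNA", rRNA = "rRNA", ORF = "orf")[f$V3]
  kind[is.na(kind)] <- "protein"
  genome$genes <- data.frame(name = nm$base, part = nm$part,
                             start = f$V4 - 1L, end = f$V5,
                             strand = f$V7, kind = unname(kind),
                             stringsAsFactors = FALSE)
  genome
}

#' Write intervals to BED (0-based half-open)
#' @param df data.frame with columns `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param chrom chromosome/genome id for column 1.
#' @param path output path.
#' @export
write_bed <- function(df, chrom, path) {
  n <- nrow(df)
  out <- data.frame(chrom = rep(chrom, n), start = df$start, end = df$end,
                    name = if ("name" %in% names(df)) df$name else ".",
                    score = if ("score" %in% names(df)) df$score else 0L,
                    strand = if ("strand" %in% names(df)) df$strand else ".")
  out <- out[order(out$start, out$end), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
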