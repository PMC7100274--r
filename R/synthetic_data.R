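SENSE_CODONS <- setdiff(
  as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"), paste0),
                  c("T", "C", "A", "G"), paste0)),
  c("TAA", "TAG", "TGA"))

random_seq <- function(n, gc = 0.40) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# random CDS of `len` nt (multiple of 3) incl. ATG start and TAA stop
random_cds <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  paste(c("ATG", sample(SENSE_CODONS, len / 3L - 2L, replace = TRUE), "TAA"),
        collapse = "")
}

set_codon <- function(cds, pos, codon) {
  # pos = 1-based first nucleotide of the codon
  paste0(substr(cds, 1L, pos - 1L), codon, substr(cds, pos + 3L, nchar(cds)))
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

# substitute a codon into a different sense codon (third base first)
mutate_codon <- function(codon) {
  for (p in c(3L, 2L, 1L)) {
    for (b in c("A", "C", "G", "T")) {
      cand <- codon
      substr(cand, p, p) <- b
      if (cand != codon && !cand %in% c("TAA", "TAG", "TGA")) return(cand)
    }
  }
  codon
}

# ---- built-in gene inventory ------------------------------------------------

# 13 conserved cluster layouts plus standalone genes; lengths in nt (CDS
# lengths include the stop codon), tRNA 75 nt, rRNAs as annotated lengths
mito_inventory <- function() {
  g <- function(name, len, part = NA_character_, kind = "protein")
    list(name = name, len = len, part = part, kind = kind)
  t_ <- function(name) g(name, 75, kind = "tRNA")
  r_ <- function(name, len) g(name, len, kind = "rRNA")
  clusters <- list(
    list(g("mat-R", 1980), g("nad1", 387, "a")),
    list(g("cob", 1182), g("rps14", 303), g("rpl5", 555), g("nad1", 192, "b")),
    list(t_("trnM"), r_("rrn26", 3500)),
    list(g("nad3", 357), g("rps12", 378)),
    list(r_("rrn18", 1900), r_("rrn5", 120)),
    list(g("cox1", 1584), g("rps10", 231, "a"), g("rps10", 150, "b")),
    list(g("rps19", 282), g("rps3", 900, "a"), g("rps3", 777, "b"),
         g("rpl16", 540), g("cox2", 450, "a"), g("cox2", 333, "b")),
    list(t_("trnS"), t_("trnD")),
    list(t_("trnC"), t_("trnN"), t_("trnY"), g("nad2", 249, "c"),
         g("nad2", 210, "d"), g("nad2", 168, "e")),
    list(g("nad2", 600, "a"), g("nad2", 240, "b"), g("sdh3", 327)),
    list(g("nad6", 618), g("rps4", 1086)),
    list(t_("trnP"), t_("trnF"), t_("trnS"), t_("trnE")),
    list(g("nad9", 573), t_("trnP"), t_("trnW")))
  standalone <- list(
    g("atp1", 1530), g("atp4", 600), g("atp6", 1161), g("atp9", 225),
    g("ccmB", 621), g("ccmC", 753), g("ccmFC", 1329), g("ccmFN", 1740),
    g("cox3", 798), g("nad4", 1488), g("nad4L", 303), g("nad5", 2010),
    g("nad7", 1185), g("rps13", 351),
    g("nad3", 357, "D2"), g("sdh3", 327, "D2"), g("sdh3", 327, "D3"))
  list(clusters = clusters, standalone = standalone)
}

# maintainer-state codons planted in candidate genes (CDS coordinates)
planted_codons <- function() list(
  atp6 = c("58" = "TAT", "91" = "ATG", "253" = "TTG", "418" = "TCA",
           "766" = "TCT", "1156" = "TCT"),
  nad2 = c("880" = "GGG", "1276" = "GGT"),
  sdh3 = c("100" = "CAT"),
  cox2 = c("199" = "ATT", "769" = "ACC", "772" = "GGG"))

# CMS gene-edit plans; positions are 1-based maintainer-CDS coordinates
cms_gene_edits <- function(cultivar) {
  sub <- function(gene, pos, codon)
    data.frame(gene = gene, type = "substitution", pos = pos, len = 3L,
               new = codon, stringsAsFactors = FALSE)
  del <- function(gene, pos, len)
    data.frame(gene = gene, type = "deletion", pos = pos, len = len,
               new = NA_character_, stringsAsFactors = FALSE)
  ins <- function(gene, pos, seq)
    data.frame(gene = gene, type = "insertion", pos = pos,
               len = nchar(seq), new = seq, stringsAsFactors = FALSE)
  shared <- rbind(sub("nad2", 1276, "GGC"), sub("sdh3", 100, "CAC"),
                  sub("cox2", 199, "ATC"))
  if (cultivar == "a") {
    priv <- c("atp1", "atp9", "ccmB", "ccmFN", "cox1", "cox3", "mat-R",
              "nad1", "nad4", "nad6", "rpl5", "rps10", "rps13", "rps4")
    rbind(
      sub("atp6", 58, "TCT"), sub("atp6", 91, "ACG"), sub("atp6", 253, "CTG"),
      sub("atp6", 418, "CCA"), sub("atp6", 766, "TCC"),
      sub("atp6", 1156, "TAT"),
      del("nad2", 456, 90L), sub("nad2", 880, "GGA"),
      del("sdh3", 277, 15L),
      sub("cox2", 769, "AGC"), sub("cox2", 772, "ACG"),
      shared,
      do.call(rbind, lapply(priv, function(g)
        sub(g, 73, NA_character_))))   # NA codon: mutate whatever is there
  } else {
    rbind(
      sub("atp6", 766, "TCC"),
      del("nad2", 456, 3L),
      del("sdh3", 274, 3L),
      ins("cox2", 383, paste(sample(SENSE_CODONS, 11, replace = TRUE),
                             collapse = "")),
      shared,
      sub("ccmC", 73, NA_character_), sub("rps3", 73, NA_character_))
  }
}

#' Simulation configuration
#'
#' Defaults emulate the observed structure of tobacco maintainer/CMS
#' mitochondrial genome pairs: a ~430 kb maintainer at GC 0.40 carrying the
#' conserved gene-cluster layout, dispersed repeat families in three size
#' classes, and an SSR complement; CMS derivation with inversions,
#' translocations, a combined event, >= 3 kb deletions, a shared ~41 kb
#' CMS-specific insertion carrying 16 specific ORFs, private insertions
#' with a large palindrome, and codon-level candidate-gene edits.  The net
#' CMS expansion falls in the 30-60 kb band.
#'
#' @param seed RNG seed (mandatory; every output is reproducible).
#' @param maintainer_length maintainer genome size in bp.
#' @param gc target GC fraction of the whole genome.
#' @param repeats planted dispersed-repeat families per size class:
#'   list(n, len = c(lo, hi), mut = substitution rate of the second copy).
#' @param ssr_plan named counts of planted SSRs per motif class.
#' @param cms CMS derivation plan (counts, length ranges, region length,
#'   specific-ORF amino-acid lengths).
#' @param cultivar_snp_rate background substitution rate between the two
#'   cultivars' maintainers (outside gene features).
#' @param reference_snp_rate substitution rate of the phylogeny reference
#'   relative to the first maintainer.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       maintainer_length = 430000,
                       gc = 0.40,
                       repeats = list(
                         large = list(n = 2, len = c(600, 4000), mut = 0.02),
                         intermediate = list(n = 10, len = c(60, 400),
                                             mut = 0.02),
                         small = list(n = 15, len = c(30, 45), mut = 0)),
                       ssr_plan = c(monomer = 3, dimer = 3, trimer = 3,
                                    tetramer = 9, pentamer = 6, hexamer = 10),
                       cms = list(
                         n_inversions = 2, inversion_len = c(5000, 15000),
                         n_translocations = 2, n_transinv = 1,
                         translocation_len = c(4000, 12000),
                         n_deletions = 3, deletion_len = c(2300, 2800),
                         region_length = 41147,
                         target_expansion = 40000,
                         specific_orf_aa = c(100, 103, 107, 110, 115, 115,
                                             121, 127, 133, 139, 145, 152,
                                             160, 168, 177, 185),
                         palindrome_arm = c(a = 5778, b = 1491)),
                       cultivar_snp_rate = 0.002,
                       reference_snp_rate = 0.003) {
  stopifnot(!missing(seed))
  cfg <- list(seed = as.integer(seed), maintainer_length = maintainer_length,
              gc = gc, repeats = repeats, ssr_plan = ssr_plan, cms = cms,
              cultivar_snp_rate = cultivar_snp_rate,
              reference_snp_rate = reference_snp_rate)
  class(cfg) <- "sim_config"
  cfg
}

# ---- maintainer generation --------------------------------------------------

#' Generate a synthetic maintainer genome with planted truth
#'
#' @param config a [sim_config()].
#' @param id genome identifier.
#' @return list with `genome` (a `CircularGenome`) and `truth` (planted
#'   feature coordinates: genes, clusters, repeats, SSRs, gene sequences).
#' @export
generate_maintainer <- function(config, id = "M1") {
  set.seed(config$seed)
  inv <- mito_inventory()
  pc <- planted_codons()

  # full CDS per gene (parts share one CDS, split later)
  gene_lens <- list()
  collect <- function(items) for (it in items) {
    gene_lens[[it$name]] <<- c(gene_lens[[it$name]] %||% integer(),
                               setNames(it$len, ifelse(is.na(it$part), "",
                                                       it$part)))
  }
  for (cl in inv$clusters) collect(cl)
  collect(Filter(function(x) is.na(x$part) || !grepl("^D", x$part),
                 inv$standalone))
  gene_seqs <- list()
  for (nm in names(gene_lens)) {
    # canonical part order (a, b, c, ...) so CDS coordinates match the
    # part-suffix concatenation used everywhere else
    lens <- gene_lens[[nm]][order(names(gene_lens[[nm]]))]
    kinds <- vapply(c(inv$clusters, list(inv$standalone)), function(items) {
      k <- vapply(items, function(it)
        if (it$name == nm) it$kind else NA_character_, "")
      k <- k[!is.na(k)]
      if (length(k)) k[1L] else NA_character_
    }, "")
    kind <- kinds[!is.na(kinds)][1L]
    parts <- names(lens)
    letters_only <- parts[parts != ""]
    total <- sum(lens)
    s <- if (kind == "protein") random_cds(total) else
      random_seq(total, gc = 0.45)
    if (nm %in% names(pc)) {
      for (p in names(pc[[nm]]))
        s <- set_codon(s, as.integer(p), pc[[nm]][[p]])
    }
    gene_seqs[[nm]] <- list(seq = s, lens = lens, kind = kind)
  }

  feat_row <- function(name, part, start, end, strand, kind)
    data.frame(name = name, part = part, start = start, end = end,
               strand = strand, kind = kind, stringsAsFactors = FALSE)

  # build elements: each is list(seq, feats (relative), type, meta)
  elements <- list()
  part_offsets <- lapply(gene_seqs, function(gs) {
    offs <- cumsum(c(0L, gs$lens[-length(gs$lens)]))
    names(offs) <- names(gs$lens)
    offs
  })
  part_seq <- function(nm, part) {
    gs <- gene_seqs[[nm]]
    key <- if (is.na(part)) "" else part
    idx <- match(key, names(gs$lens))
    off <- part_offsets[[nm]][[idx]]
    substr(gs$seq, off + 1L, off + gs$lens[[idx]])
  }
  for (ci in seq_along(inv$clusters)) {
    cl <- inv$clusters[[ci]]
    seqs <- character(0); feats <- empty_genes(); pos <- 0L
    for (k in seq_along(cl)) {
      it <- cl[[k]]
      # rpl16 overlaps the preceding rps3 part by 108 bp
      gap <- if (it$name == "rpl16") -108L else
        if (k == 1L) 0L else sample(100:800, 1L)
      pos <- pos + gap
      s <- part_seq(it$name, it$part)
      if (gap < 0L) {
        seqs <- c(seqs, substr(s, -gap + 1L, nchar(s)))
      } else {
        seqs <- c(seqs, random_seq(gap, config$gc), s)
      }
      feats <- rbind(feats, feat_row(it$name, it$part, pos,
                                     pos + nchar(s), "+", it$kind))
      pos <- pos + nchar(s)
    }
    elements[[length(elements) + 1L]] <-
      list(seq = paste(seqs, collapse = ""), feats = feats,
           type = "cluster", meta = list(index = ci))
  }
  for (it in inv$standalone) {
    s <- if (!is.na(it$part) && grepl("^D", it$part))
      gene_seqs[[it$name]]$seq else part_seq(it$name, it$part)
    elements[[length(elements) + 1L]] <-
      list(seq = s, feats = feat_row(it$name, it$part, 0L, nchar(s), "+",
                                     it$kind),
           type = "gene", meta = list(copy = it$part))
  }
  # dispersed repeat families (two copies each)
  rep_meta <- list()
  for (cls in names(config$repeats)) {
    plan <- config$repeats[[cls]]
    for (i in seq_len(plan$n)) {
      len <- sample(plan$len[1]:plan$len[2], 1L)
      src <- random_seq(len, config$gc)
      orient <- if (runif(1) < 0.5) "DR" else "IR"
      copy2 <- mutate_seq(src, plan$mut)
      if (orient == "IR") copy2 <- revcomp(copy2)
      fam <- sprintf("%s_%d", cls, i)
      elements[[length(elements) + 1L]] <-
        list(seq = src, feats = empty_genes(), type = "repeat",
             meta = list(family = fam, copy = 1L, class = cls,
                         orientation = orient))
      elements[[length(elements) + 1L]] <-
        list(seq = copy2, feats = empty_genes(), type = "repeat",
             meta = list(family = fam, copy = 2L, class = cls,
                         orientation = orient))
    }
  }
  # SSRs
  ssr_sizes <- c(monomer = 1L, dimer = 2L, trimer = 3L, tetramer = 4L,
                 pentamer = 5L, hexamer = 6L)
  min_cp <- c(12L, 6L, 4L, 3L, 3L, 3L)
  used_motifs <- character(0)
  for (cls in names(config$ssr_plan)) {
    m <- ssr_sizes[[cls]]
    for (i in seq_len(config$ssr_plan[[cls]])) {
      repeat {
        motif <- paste(sample(c("A", "C", "G", "T"), m, replace = TRUE),
                       collapse = "")
        can <- canonical_motif(motif)
        prim <- m == 1L ||
          !any(vapply(seq_len(m - 1L)[m %% seq_len(m - 1L) == 0L],
                      function(d) motif ==
                        strrep(substr(motif, 1L, d), m / d), NA))
        if (prim && !can %in% used_motifs) break
      }
      used_motifs <- c(used_motifs, can)
      # one copy above the detection minimum: a boundary base can be
      # phase-absorbed by the flanking sequence
      copies <- min_cp[m] + 1L
      run <- strrep(motif, copies)
      elements[[length(elements) + 1L]] <-
        list(seq = run, feats = empty_genes(), type = "ssr",
             meta = list(motif = can, motif_len = m,
                         copies = nchar(run) / m))
    }
  }

  # layout: shuffled elements separated by >= 2.5 kb background gaps
  elements <- elements[sample(seq_along(elements))]
  elen <- vapply(elements, function(e) nchar(e$seq), 0L)
  L <- config$maintainer_length
  free <- L - sum(elen)
  ngap <- length(elements) + 1L
  if (free < 2500L * ngap)
    stop("infeasible packing: ", sum(elen), " bp of features + ",
         2500L * ngap, " bp of minimum spacing exceed the ", L,
         " bp genome")
  w <- runif(ngap)
  extra <- floor((free - 2500L * ngap) * w / sum(w))
  gaps <- 2500L + extra
  gaps[1L] <- gaps[1L] + (free - sum(gaps))
  # background GC adjusted so the whole genome hits the target
  el_gc <- sum(vapply(elements, function(e) {
    tb <- table(strsplit(e$seq, "")[[1]])
    sum(tb[names(tb) %in% c("G", "C")])
  }, 0))
  bg_gc <- max(0.05, min(0.95, (L * config$gc - el_gc) / free))

  seqs <- character(0); pos <- 0L
  genes <- empty_genes()
  truth_rep <- list(); truth_ssr <- list(); truth_cluster <- list()
  for (i in seq_along(elements)) {
    gseq <- random_seq(gaps[i], bg_gc)
    seqs <- c(seqs, gseq); pos <- pos + gaps[i]
    e <- elements[[i]]
    seqs <- c(seqs, e$seq)
    if (nrow(e$feats) > 0L) {
      f <- e$feats; f$start <- f$start + pos; f$end <- f$end + pos
      genes <- rbind(genes, f)
    }
    if (e$type == "repeat")
      truth_rep[[length(truth_rep) + 1L]] <-
        data.frame(family = e$meta$family, copy = e$meta$copy,
                   class = e$meta$class, orientation = e$meta$orientation,
                   start = pos, end = pos + nchar(e$seq),
                   stringsAsFactors = FALSE)
    if (e$type == "ssr")
      truth_ssr[[length(truth_ssr) + 1L]] <-
        data.frame(motif = e$meta$motif, motif_len = e$meta$motif_len,
                   copies = e$meta$copies, start = pos,
                   end = pos + nchar(e$seq), stringsAsFactors = FALSE)
    if (e$type == "cluster")
      truth_cluster[[length(truth_cluster) + 1L]] <-
        data.frame(index = e$meta$index, start = pos,
                   end = pos + nchar(e$seq), stringsAsFactors = FALSE)
    pos <- pos + nchar(e$seq)
  }
  seqs <- c(seqs, random_seq(gaps[ngap], bg_gc))
  seq <- paste(seqs, collapse = "")
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genome <- circular_genome(id, seq, TRUE, genes)

  reps <- do.call(rbind, truth_rep)
  # pair table (copy 1 interval first)
  pair_rows <- lapply(split(reps, reps$family), function(fm) {
    fm <- fm[order(fm$copy), ]
    data.frame(family = fm$family[1L], class = fm$class[1L],
               orientation = fm$orientation[1L],
               start1 = min(fm$start[1L], fm$start[2L]),
               end1 = min(fm$end[1L], fm$end[2L]),
               start2 = max(fm$start[1L], fm$start[2L]),
               end2 = max(fm$end[1L], fm$end[2L]),
               stringsAsFactors = FALSE)
  })
  sig13 <- vapply(mito_inventory()$clusters, function(cl) {
    base <- vapply(cl, `[[`, "", "name")
    base <- base[c(TRUE, base[-1L] != base[-length(base)])]
    paste(canonical_signature(base), collapse = "-")
  }, "")
  truth <- list(genes = genes,
                repeats = do.call(rbind, pair_rows),
                ssrs = do.call(rbind, truth_ssr),
                clusters = do.call(rbind, truth_cluster),
                cluster_signatures = sig13,
                gene_seqs = gene_seqs)
  list(genome = genome, truth = truth)
}

# ---- structural editing -----------------------------------------------------

# protected intervals (no breakpoints allowed inside, with margin)
protected_intervals <- function(truth, margin = 150L) {
  iv <- rbind(
    cbind(truth$genes$start, truth$genes$end),
    if (!is.null(truth$repeats))
      cbind(c(truth$repeats$start1, truth$repeats$start2),
            c(truth$repeats$end1, truth$repeats$end2)),
    if (!is.null(truth$ssrs)) cbind(truth$ssrs$start, truth$ssrs$end),
    if (!is.null(truth$clusters))
      cbind(truth$clusters$start, truth$clusters$end))
  iv[, 1L] <- iv[, 1L] - margin; iv[, 2L] <- iv[, 2L] + margin
  iv
}

in_any <- function(p, iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(FALSE)
  any(p >= iv[, 1L] & p < iv[, 2L])
}

# pick a position allowed as a breakpoint: outside protected intervals,
# outside already-taken edit intervals, >= min_sep from taken breakpoints
pick_point <- function(L, protected, taken_bp, taken_iv = NULL,
                       min_sep = 3200L, tries = 1000L) {
  for (t in seq_len(tries)) {
    p <- sample.int(L - 1L, 1L)
    if (in_any(p, protected)) next
    if (!is.null(taken_iv) && nrow(taken_iv) > 0L &&
        any(p >= taken_iv[, 1L] - min_sep & p < taken_iv[, 2L] + min_sep))
      next
    if (length(taken_bp) && min(abs(taken_bp - p)) < min_sep) next
    return(p)
  }
  stop("could not place a breakpoint (infeasible packing)")
}

pick_interval <- function(L, len_range, protected, taken_bp,
                          taken_iv = NULL, min_sep = 3200L, tries = 1000L,
                          content_free = FALSE) {
  for (t in seq_len(tries)) {
    len <- sample(len_range[1]:len_range[2], 1L)
    s <- sample.int(L - len - 1L, 1L); e <- s + len
    if (in_any(s, protected) || in_any(e, protected)) next
    if (content_free &&
        any(pmin(e, protected[, 2L]) - pmax(s, protected[, 1L]) > 0L)) next
    if (!is.null(taken_iv) && nrow(taken_iv) > 0L &&
        any(pmin(e + min_sep, taken_iv[, 2L] + min_sep) -
              pmax(s - min_sep, taken_iv[, 1L] - min_sep) > 0L)) next
    if (length(taken_bp) && (min(abs(taken_bp - s)) < min_sep ||
                             min(abs(taken_bp - e)) < min_sep)) next
    return(c(s, e))
  }
  stop("could not place an edit interval (infeasible packing)")
}

# apply structural edits; returns new genome, chunk map and truth blocks.
# struct: data.frame(type, start, end, target, rev); insertions: list of
# list(point, seq, feats (relative data.frame), label)
assemble_edited <- function(genome, struct, insertions, new_id) {
  L <- genome_length(genome)
  bp <- sort(unique(c(0L, L, struct$start, struct$end,
                      struct$target[!is.na(struct$target)],
                      vapply(insertions, `[[`, 0L, "point"))))
  pieces <- data.frame(m_start = bp[-length(bp)], m_end = bp[-1L])
  piece_role <- rep("normal", nrow(pieces))
  piece_edit <- rep(NA_integer_, nrow(pieces))
  for (i in seq_len(nrow(struct))) {
    sel <- pieces$m_start >= struct$start[i] & pieces$m_end <= struct$end[i]
    piece_role[sel] <- struct$type[i]
    piece_edit[sel] <- i
  }
  out <- list()  # each: list(m_start, m_end, rev, seq, label)
  emit_piece <- function(i, rev = FALSE) {
    s <- substr(genome$seq, pieces$m_start[i] + 1L, pieces$m_end[i])
    list(m_start = pieces$m_start[i], m_end = pieces$m_end[i], rev = rev,
         seq = if (rev) revcomp(s) else s, label = piece_role[i],
         edit = piece_edit[i])
  }
  ins_at <- function(p) {
    for (ins in insertions) if (ins$point == p)
      out[[length(out) + 1L]] <<-
        list(m_start = NA_integer_, m_end = NA_integer_, rev = FALSE,
             seq = ins$seq, label = paste0("ins:", ins$label),
             edit = NA_integer_, feats = ins$feats)
    for (i in which(!is.na(struct$target)))
      if (struct$target[i] == p) {
        idx <- which(piece_edit == i)
        if (isTRUE(struct$rev[i])) idx <- rev(idx)
        for (k in idx) out[[length(out) + 1L]] <<-
            emit_piece(k, rev = isTRUE(struct$rev[i]))
      }
  }
  ins_at(0L)
  for (i in seq_len(nrow(pieces))) {
    if (piece_role[i] == "del") { ins_at(pieces$m_end[i]); next }
    if (piece_role[i] %in% c("trans", "transinv")) {
      ins_at(pieces$m_end[i]); next   # emitted at target
    }
    rev <- piece_role[i] == "inv"
    out[[length(out) + 1L]] <- emit_piece(i, rev = rev)
    ins_at(pieces$m_end[i])
  }
  # materialize
  pos <- 0L; chunks <- list(); seqs <- character(length(out))
  for (k in seq_along(out)) {
    o <- out[[k]]
    seqs[k] <- o$seq
    chunks[[k]] <- list(m_start = o$m_start, m_end = o$m_end, rev = o$rev,
                        out_start = pos, out_end = pos + nchar(o$seq),
                        label = o$label, edit = o$edit,
                        feats = o$feats %||% NULL)
    pos <- pos + nchar(o$seq)
  }
  seq <- paste(seqs, collapse = "")
  # remap features
  genes <- empty_genes()
  for (ck in chunks) {
    if (is.na(ck$m_start)) {
      if (!is.null(ck$feats) && nrow(ck$feats) > 0L) {
        f <- ck$feats
        f$start <- f$start + ck$out_start; f$end <- f$end + ck$out_start
        genes <- rbind(genes, f)
      }
      next
    }
    g <- genome$genes
    sel <- g$start >= ck$m_start & g$end <= ck$m_end
    if (!any(sel)) next
    f <- g[sel, , drop = FALSE]
    if (ck$rev) {
      ns <- ck$out_start + (ck$m_end - f$end)
      f$end <- ns + (f$end - f$start); f$start <- ns
      f$strand <- ifelse(f$strand == "+", "-", "+")
    } else {
      delta <- ck$out_start - ck$m_start
      f$start <- f$start + delta; f$end <- f$end + delta
    }
    genes <- rbind(genes, f)
  }
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  g2 <- circular_genome(new_id, seq, TRUE, genes)
  # truth blocks (maintainer-derived chunks with expected class)
  cls_map <- c(normal = "collinearity", inv = "inversion",
               trans = "translocation", transinv = "trans_inv")
  tb <- list()
  for (ck in chunks) {
    if (is.na(ck$m_start)) next
    lab <- if (ck$label %in% names(cls_map)) cls_map[[ck$label]] else
      "collinearity"
    tb[[length(tb) + 1L]] <-
      data.frame(m_start = ck$m_start, m_end = ck$m_end,
                 out_start = ck$out_start, out_end = ck$out_end,
                 orientation = if (ck$rev) "reverse" else "forward",
                 class = lab, stringsAsFactors = FALSE)
  }
  list(genome = g2, chunks = chunks, blocks = do.call(rbind, tb))
}

# map a maintainer interval through the chunk table; returns
# c(start, end, rev) or NA when deleted/split
map_interval <- function(chunks, s, e) {
  for (ck in chunks) {
    if (is.na(ck$m_start)) next
    if (s >= ck$m_start && e <= ck$m_end) {
      if (ck$rev) {
        ns <- ck$out_start + (ck$m_end - e)
        return(c(ns, ns + (e - s), 1L))
      }
      return(c(s + ck$out_start - ck$m_start,
               e + ck$out_start - ck$m_start, 0L))
    }
  }
  c(NA_integer_, NA_integer_, NA_integer_)
}

remap_truth_intervals <- function(truth, chunks) {
  # repeats: both copies remapped; an inversion of exactly one copy flips
  # DR <-> IR; copies are re-ordered so interval 1 starts first
  rp <- truth$repeats
  if (!is.null(rp) && nrow(rp) > 0L) {
    keep <- rep(TRUE, nrow(rp))
    for (i in seq_len(nrow(rp))) {
      m1 <- map_interval(chunks, rp$start1[i], rp$end1[i])
      m2 <- map_interval(chunks, rp$start2[i], rp$end2[i])
      if (is.na(m1[1L]) || is.na(m2[1L])) { keep[i] <- FALSE; next }
      if (xor(m1[3L] == 1L, m2[3L] == 1L))
        rp$orientation[i] <- if (rp$orientation[i] == "DR") "IR" else "DR"
      if (m1[1L] <= m2[1L]) {
        rp$start1[i] <- m1[1L]; rp$end1[i] <- m1[2L]
        rp$start2[i] <- m2[1L]; rp$end2[i] <- m2[2L]
      } else {
        rp$start1[i] <- m2[1L]; rp$end1[i] <- m2[2L]
        rp$start2[i] <- m1[1L]; rp$end2[i] <- m1[2L]
      }
    }
    truth$repeats <- rp[keep, , drop = FALSE]
  }
  ss <- truth$ssrs
  if (!is.null(ss) && nrow(ss) > 0L) {
    keep <- rep(TRUE, nrow(ss))
    for (i in seq_len(nrow(ss))) {
      m <- map_interval(chunks, ss$start[i], ss$end[i])
      if (is.na(m[1L])) { keep[i] <- FALSE; next }
      ss$start[i] <- m[1L]; ss$end[i] <- m[2L]
      if (m[3L] == 1L) ss$motif[i] <- canonical_motif(revcomp(ss$motif[i]))
    }
    truth$ssrs <- ss[keep, , drop = FALSE]
  }
  cl <- truth$clusters
  if (!is.null(cl) && nrow(cl) > 0L) {
    keep <- rep(TRUE, nrow(cl))
    for (i in seq_len(nrow(cl))) {
      m <- map_interval(chunks, cl$start[i], cl$end[i])
      if (is.na(m[1L])) { keep[i] <- FALSE; next }
      cl$start[i] <- m[1L]; cl$end[i] <- m[2L]
    }
    truth$clusters <- cl[keep, , drop = FALSE]
  }
  truth
}

# ---- gene edits -------------------------------------------------------------

# replace [start, end) of the genome sequence, shifting feature coordinates
splice_genome <- function(genome, start, end, newseq) {
  delta <- nchar(newseq) - (end - start)
  seq <- paste0(substr(genome$seq, 1L, start), newseq,
                substr(genome$seq, end + 1L, genome_length(genome)))
  g <- genome$genes
  cover <- g$start <= start & g$end >= end
  after <- g$start >= end
  g$start[after] <- g$start[after] + delta
  g$end[after | cover] <- g$end[after | cover] + delta
  genome$genes <- g
  genome$seq <- seq
  genome
}

# apply CDS-coordinate edits to one gene copy of a genome; the sequence of
# applied (position, delta) splices is attached as attr "edit_shifts"
apply_gene_edits <- function(genome, edits, maintainer_cds) {
  shifts <- list()
  for (gene in unique(edits$gene)) {
    ed <- edits[edits$gene == gene, , drop = FALSE]
    g <- genome$genes
    lab <- ifelse(!is.na(g$part) & grepl("^D", g$part), g$part, "main")
    sel <- which(g$name == gene & lab == "main")
    if (length(sel) == 0L) next
    feats <- g[sel, , drop = FALSE]
    pk <- ifelse(is.na(feats$part), "", sub("D[0-9]+$", "", feats$part))
    ordp <- order(pk, feats$start)
    feats <- feats[ordp, , drop = FALSE]
    offs <- cumsum(c(0L, feats$end - feats$start))
    # per-part new sequences
    cds <- maintainer_cds[[gene]]$seq
    ed <- ed[order(-ed$pos), , drop = FALSE]
    part_edits <- vector("list", nrow(feats))
    for (r in seq_len(nrow(ed))) {
      part <- max(which(offs[-length(offs)] < ed$pos[r]))
      part_edits[[part]] <- rbind(part_edits[[part]], ed[r, , drop = FALSE])
    }
    # process parts in genome order, descending, to keep coordinates valid
    proc <- order(-feats$start)
    for (p in proc) {
      pe <- part_edits[[p]]
      if (is.null(pe)) next
      s <- substr(cds, offs[p] + 1L, offs[p + 1L])
      for (r in seq_len(nrow(pe))) {
        pos <- pe$pos[r] - offs[p]
        if (pe$type[r] == "substitution") {
          newc <- pe$new[r]
          if (is.na(newc)) newc <- mutate_codon(substr(s, pos, pos + 2L))
          s <- paste0(substr(s, 1L, pos - 1L), newc,
                      substr(s, pos + 3L, nchar(s)))
        } else if (pe$type[r] == "deletion") {
          s <- paste0(substr(s, 1L, pos - 1L),
                      substr(s, pos + pe$len[r], nchar(s)))
        } else {
          s <- paste0(substr(s, 1L, pos - 1L), pe$new[r],
                      substr(s, pos, nchar(s)))
        }
      }
      ns <- if (feats$strand[p] == "-") revcomp(s) else s
      shifts[[length(shifts) + 1L]] <-
        c(pos = feats$start[p],
          delta = nchar(ns) - (feats$end[p] - feats$start[p]))
      genome <- splice_genome(genome, feats$start[p], feats$end[p], ns)
    }
  }
  attr(genome, "edit_shifts") <- shifts
  genome
}

# push truth interval coordinates through a sequence of splice shifts
shift_positions <- function(x, shifts) {
  for (sh in shifts) if (sh[["delta"]] != 0)
    x <- ifelse(x > sh[["pos"]], x + sh[["delta"]], x)
  x
}

# ---- CMS derivation ---------------------------------------------------------

# build the shared CMS-specific region (sanitized, with planted ORFs)
build_shared_region <- function(config) {
  aa <- config$cms$specific_orf_aa
  orf_lens <- (aa + 1L) * 3L
  strands <- rep(c("+", "-"), length.out = length(aa))
  orf_seqs <- vapply(orf_lens, random_cds, "")
  total_orf <- sum(orf_lens)
  nsp <- length(aa) + 1L
  free <- config$cms$region_length - total_orf
  w <- runif(nsp)
  sp <- floor((free - 200L * nsp) * w / sum(w)) + 200L
  sp[1L] <- sp[1L] + (free - sum(sp))
  seqs <- character(0); pos <- 0L; rows <- list()
  for (i in seq_along(aa)) {
    seqs <- c(seqs, random_seq(sp[i], 0.40)); pos <- pos + sp[i]
    s <- if (strands[i] == "-") revcomp(orf_seqs[i]) else orf_seqs[i]
    seqs <- c(seqs, s)
    rows[[i]] <- data.frame(aa = aa[i], start = pos, end = pos + nchar(s),
                            strand = strands[i], seq = orf_seqs[i],
                            stringsAsFactors = FALSE)
    pos <- pos + nchar(s)
  }
  seqs <- c(seqs, random_seq(sp[nsp], 0.40))
  region <- paste(seqs, collapse = "")
  orfs <- do.call(rbind, rows)
  region <- sanitize_chance_orfs(region, cbind(orfs$start, orfs$end))
  list(seq = region, orfs = orfs)
}

# break chance ORFs (> 300 nt) outside the protected intervals by planting
# an in-frame stop codon
sanitize_chance_orfs <- function(seq, protected, min_len = 300L) {
  for (iter in 1:50) {
    g <- circular_genome("tmp", seq, circular = FALSE)
    orfs <- find_orfs(g, min_len = min_len)
    planted <- vapply(seq_len(nrow(orfs)), function(i)
      any(orfs$start[i] >= protected[, 1L] - 3L &
            orfs$end[i] <= protected[, 2L] + 3L), logical(1))
    bad <- orfs[!planted, , drop = FALSE]
    if (nrow(bad) == 0L) return(seq)
    for (i in seq_len(nrow(bad))) {
      ncod <- bad$nt_length[i] / 3L
      done <- FALSE
      mid <- ceiling(ncod / 2)
      for (ci in unique(c(seq(mid, ncod - 1L), seq(mid - 1L, 1L)))) {
        if (bad$strand[i] == "+") {
          p0 <- bad$start[i] + 3L * ci          # 0-based codon start
        } else {
          p0 <- bad$end[i] - 3L * (ci + 1L)
        }
        if (in_any(p0, protected) || in_any(p0 + 2L, protected)) next
        stopc <- if (bad$strand[i] == "+") "TAA" else "TTA"
        substr(seq, p0 + 1L, p0 + 3L) <- stopc
        done <- TRUE
        break
      }
      if (!done) stop("could not sanitize a chance ORF in a planted region")
    }
  }
  stop("ORF sanitation did not converge")
}

#' Derive a CMS genome from a maintainer
#'
#' Applies, in order: inversions, translocations (plain and inverted),
#' deletions (>= 3 kb, including planted gene-copy losses), non-homologous
#' insertions (the shared CMS-specific region carrying the specific ORFs, a
#' private insertion carrying a large palindrome and a private SSR), and
#' codon-level candidate-gene edits.  Every edit is recorded in the truth
#' table together with the expected rearrangement class of each conserved
#' segment.
#'
#' @param maintainer output of [generate_maintainer()] (list with `genome`
#'   and `truth`).
#' @param config a [sim_config()].
#' @param cultivar `"a"` or `"b"` (chooses the gene-edit preset).
#' @param shared shared cytoplasm material from `build_shared_region`
#'   (internal; built automatically when NULL).
#' @param id genome identifier.
#' @param seed RNG seed for the private edits.
#' @return list with `genome` and `truth`.
#' @export
derive_cms <- function(maintainer, config, cultivar = c("a", "b"),
                       shared = NULL, id = "S1", seed = config$seed + 303L) {
  cultivar <- match.arg(cultivar)
  set.seed(seed)
  if (is.null(shared)) shared <- build_shared_region(config)
  mg <- maintainer$genome; mt <- maintainer$truth
  L <- genome_length(mg)
  prot <- protected_intervals(mt)
  cms <- config$cms

  struct <- data.frame(type = character(), start = integer(),
                       end = integer(), target = integer(), rev = logical(),
                       stringsAsFactors = FALSE)
  taken_bp <- integer(0)
  taken_iv <- matrix(integer(0), ncol = 2L)
  add_edit <- function(type, iv, target = NA_integer_, rev = FALSE) {
    struct <<- rbind(struct, data.frame(type = type, start = iv[1L],
                                        end = iv[2L], target = target,
                                        rev = rev, stringsAsFactors = FALSE))
    taken_bp <<- c(taken_bp, iv, if (!is.na(target)) target)
    taken_iv <<- rbind(taken_iv, iv)
  }
  # gene-copy losses first (their positions are fixed by the layout)
  doomed <- if (cultivar == "a") {
    list(c("nad3", "D2"), c("sdh3", "D2"), c("sdh3", "D3"))
  } else {
    list(c("nad3", "D2"), c("cob", "D2"), c("rpl5", "D2"), c("rps14", "D2"))
  }
  g <- mg$genes
  for (d in doomed) {
    sel <- which(g$name == d[1L] & !is.na(g$part) & g$part == d[2L])
    if (length(sel) == 0L) next
    iv <- c(g$start[sel[1L]] - 1600L, g$end[sel[1L]] + 1600L)
    iv[2L] <- max(iv[2L], iv[1L] + 3300L)
    add_edit("del", iv)
  }
  for (i in seq_len(cms$n_inversions))
    add_edit("inv", pick_interval(L, cms$inversion_len, prot, taken_bp,
                                  taken_iv))
  pick_target <- function(iv) {
    repeat {
      tg <- pick_point(L, prot, taken_bp, taken_iv)
      if (abs(tg - iv[1L]) >= 30000L && abs(tg - iv[2L]) >= 30000L)
        return(tg)
    }
  }
  for (i in seq_len(cms$n_translocations)) {
    iv <- pick_interval(L, cms$translocation_len, prot, taken_bp, taken_iv)
    add_edit("trans", iv, target = pick_target(iv), rev = FALSE)
  }
  for (i in seq_len(cms$n_transinv)) {
    iv <- pick_interval(L, cms$translocation_len, prot, taken_bp, taken_iv)
    add_edit("transinv", iv, target = pick_target(iv), rev = TRUE)
  }
  for (i in seq_len(cms$n_deletions))
    add_edit("del", pick_interval(L, cms$deletion_len, prot, taken_bp,
                                  taken_iv, content_free = TRUE))
  deleted_total <- sum(struct$end[struct$type == "del"] -
                         struct$start[struct$type == "del"])

  # insertions: shared region + private palindrome/SSR insert (+ new copies)
  insertions <- list()
  p_region <- pick_point(L, prot, taken_bp, taken_iv)
  taken_bp <- c(taken_bp, p_region)
  insertions[[1L]] <- list(point = p_region, seq = shared$seq,
                           feats = NULL, label = "region1")
  gained_bp <- 0L
  if (cultivar == "b") {
    for (gn in list(c("atp9", "D2"), c("atp9", "D3"), c("mat-R", "D2"))) {
      cds <- mt$gene_seqs[[gn[1L]]]$seq
      p <- pick_point(L, prot, taken_bp, taken_iv)
      taken_bp <- c(taken_bp, p)
      fl <- 1200L
      insertions[[length(insertions) + 1L]] <-
        list(point = p,
             seq = paste0(random_seq(fl, 0.40), cds, random_seq(fl, 0.40)),
             feats = data.frame(name = gn[1L], part = gn[2L], start = fl,
                                end = fl + nchar(cds), strand = "+",
                                kind = "protein", stringsAsFactors = FALSE),
             label = paste0("copy:", gn[1L], "-", gn[2L]))
      gained_bp <- gained_bp + nchar(cds) + 2L * fl
    }
  }
  # private insertion sized so the net expansion hits the configured target
  arm_len <- cms$palindrome_arm[[cultivar]]
  arm <- random_seq(arm_len, 0.40)
  ssr_gain <- if (cultivar == "a") strrep("CTTA", 4L) else
    strrep("CTCCAA", 3L)
  target_net <- cms$target_expansion %||% 40000L
  filler <- max(600L, target_net + deleted_total - cms$region_length -
                  gained_bp - 2L * arm_len - nchar(ssr_gain) - 1000L)
  priv <- paste0(random_seq(500, 0.40), arm, revcomp(arm),
                 random_seq(500, 0.40), ssr_gain,
                 random_seq(filler, 0.40))
  p_priv <- pick_point(L, prot, taken_bp, taken_iv)
  taken_bp <- c(taken_bp, p_priv)
  insertions[[length(insertions) + 1L]] <-
    list(point = p_priv, seq = priv, feats = NULL, label = "private")

  asm <- assemble_edited(mg, struct, insertions, id)
  truth <- remap_truth_intervals(mt, asm$chunks)
  truth$blocks <- asm$blocks
  truth$struct <- struct
  # locate the inserted regions in the CMS genome
  reg <- NULL; privs <- NULL
  for (ck in asm$chunks) {
    if (identical(ck$label, "ins:region1"))
      reg <- c(ck$out_start, ck$out_end)
    if (identical(ck$label, "ins:private"))
      privs <- c(ck$out_start, ck$out_end)
  }
  truth$region1 <- reg
  truth$private_insert <- privs
  truth$palindrome_arm <- arm_len
  truth$ssr_gain <- canonical_motif(if (cultivar == "a") "CTTA" else "CTCCAA")
  truth$specific_orfs <- shared$orfs
  truth$specific_orfs$start <- shared$orfs$start + reg[1L]
  truth$specific_orfs$end <- shared$orfs$end + reg[1L]

  edits <- cms_gene_edits(cultivar)
  genome <- apply_gene_edits(asm$genome, edits, mt$gene_seqs)
  # lift every truth coordinate through the gene-edit indels
  sh <- attr(genome, "edit_shifts")
  lift <- function(x) as.integer(shift_positions(x, sh))
  truth$region1 <- lift(truth$region1)
  truth$private_insert <- lift(truth$private_insert)
  for (cc in c("start", "end"))
    truth$specific_orfs[[cc]] <- lift(truth$specific_orfs[[cc]])
  if (!is.null(truth$repeats) && nrow(truth$repeats) > 0L)
    for (cc in c("start1", "end1", "start2", "end2"))
      truth$repeats[[cc]] <- lift(truth$repeats[[cc]])
  if (!is.null(truth$ssrs) && nrow(truth$ssrs) > 0L)
    for (cc in c("start", "end")) truth$ssrs[[cc]] <- lift(truth$ssrs[[cc]])
  if (!is.null(truth$clusters) && nrow(truth$clusters) > 0L)
    for (cc in c("start", "end"))
      truth$clusters[[cc]] <- lift(truth$clusters[[cc]])
  for (cc in c("out_start", "out_end"))
    truth$blocks[[cc]] <- lift(truth$blocks[[cc]])
  truth$gene_edits <- edits
  list(genome = genome, truth = truth)
}

# maintainer of the second cultivar: background SNPs outside features plus
# planted copy-number differences
derive_maintainer_b <- function(maintainer, config, id = "M2",
                                seed = config$seed + 202L) {
  set.seed(seed)
  mg <- maintainer$genome; mt <- maintainer$truth
  L <- genome_length(mg)
  prot <- protected_intervals(mt, margin = 10L)
  # SNPs
  ch <- strsplit(mg$seq, "")[[1]]
  n_snp <- rpois(1L, config$cultivar_snp_rate * L)
  pos <- sample.int(L, n_snp)
  ok <- !vapply(pos, in_any, NA, iv = prot)
  pos <- pos[ok]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  g1 <- mg; g1$seq <- paste(ch, collapse = ""); g1$id <- id
  # structural copy-number differences
  prot2 <- protected_intervals(mt)
  struct <- data.frame(type = character(), start = integer(),
                       end = integer(), target = integer(), rev = logical())
  taken <- integer(0)
  taken_iv <- matrix(integer(0), ncol = 2L)
  g <- g1$genes
  for (d in list(c("sdh3", "D2"), c("sdh3", "D3"))) {
    sel <- which(g$name == d[1L] & !is.na(g$part) & g$part == d[2L])
    iv <- c(g$start[sel[1L]] - 1600L, g$end[sel[1L]] + 1600L)
    iv[2L] <- max(iv[2L], iv[1L] + 3300L)
    struct <- rbind(struct, data.frame(type = "del", start = iv[1L],
                                       end = iv[2L], target = NA_integer_,
                                       rev = FALSE))
    taken <- c(taken, iv)
    taken_iv <- rbind(taken_iv, iv)
  }
  insertions <- list()
  for (gn in list(c("cob", "D2"), c("rpl5", "D2"), c("rps14", "D2"))) {
    cds <- mt$gene_seqs[[gn[1L]]]$seq
    p <- pick_point(L, prot2, taken, taken_iv); taken <- c(taken, p)
    fl <- 1200L
    insertions[[length(insertions) + 1L]] <-
      list(point = p,
           seq = paste0(random_seq(fl, 0.40), cds, random_seq(fl, 0.40)),
           feats = data.frame(name = gn[1L], part = gn[2L], start = fl,
                              end = fl + nchar(cds), strand = "+",
                              kind = "protein", stringsAsFactors = FALSE),
           label = paste0("copy:", gn[1L], "-", gn[2L]))
  }
  asm <- assemble_edited(g1, struct, insertions, id)
  truth <- remap_truth_intervals(mt, asm$chunks)
  truth$gene_seqs <- mt$gene_seqs
  truth$cluster_signatures <- mt$cluster_signatures
  truth$genes <- asm$genome$genes
  truth$snp_positions <- sort(pos)
  list(genome = asm$genome, truth = truth)
}

#' Generate a two-cultivar maintainer/CMS quartet with planted truth
#'
#' Two maintainer genomes diverged by background SNPs (outside gene
#' features) and planted copy-number differences, each with a derived CMS
#' genome.  The two CMS genomes share the planted CMS-specific region, its
#' 16 specific ORFs, and the shared candidate-gene edits (common cytoplasm
#' origin), plus private structural edits, palindromes and SSR gains.  A
#' reference genome for SNP phylogenies is derived from the first
#' maintainer by additional background substitutions.
#'
#' @param config a [sim_config()].
#' @return list with `genomes` (M1, S1, M2, S2), `reference` and `truth`.
#' @export
generate_quartet <- function(config) {
  m_a <- generate_maintainer(config, id = "M1")
  set.seed(config$seed + 101L)
  shared <- build_shared_region(config)
  m_b <- derive_maintainer_b(m_a, config, id = "M2",
                             seed = config$seed + 202L)
  cms_a <- derive_cms(m_a, config, "a", shared, id = "S1",
                      seed = config$seed + 303L)
  cms_b <- derive_cms(m_b, config, "b", shared, id = "S2",
                      seed = config$seed + 404L)
  # phylogeny reference: first maintainer plus background SNPs
  set.seed(config$seed + 505L)
  ch <- strsplit(m_a$genome$seq, "")[[1]]
  n_snp <- rpois(1L, config$reference_snp_rate * length(ch))
  pos <- sample.int(length(ch), n_snp)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  reference <- circular_genome("REF", paste(ch, collapse = ""), TRUE)

  expansion <- c(genome_length(cms_a$genome) - genome_length(m_a$genome),
                 genome_length(cms_b$genome) - genome_length(m_b$genome))
  copy_expect <- rbind(
    nad3 = c(2, 1, 2, 1), sdh3 = c(3, 1, 1, 1), cob = c(1, 1, 2, 1),
    rpl5 = c(1, 1, 2, 1), rps14 = c(1, 1, 2, 1), atp9 = c(1, 1, 1, 3),
    `mat-R` = c(1, 1, 1, 2))
  colnames(copy_expect) <- c("M1", "S1", "M2", "S2")
  list(genomes = list(M1 = m_a$genome, S1 = cms_a$genome,
                      M2 = m_b$genome, S2 = cms_b$genome),
       reference = reference,
       truth = list(maintainer_a = m_a$truth, maintainer_b = m_b$truth,
                    cms_a = cms_a$truth, cms_b = cms_b$truth,
                    shared_orf_count = length(config$cms$specific_orf_aa),
                    shared_orf_aa = config$cms$specific_orf_aa,
                    region_length = config$cms$region_length,
                    expansion = expansion,
                    copy_numbers = copy_expect,
                    candidate_genes = c("atp6", "cox2", "nad2", "sdh3"),
                    cluster_signatures = m_a$truth$cluster_signatures,
                    config = config))
}
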