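#' Run the full comparative pipeline and write a report bundle
#'
#' Orchestrates every analysis stage over a set of maintainer/CMS genome
#' pairs: per-genome summary features, repeat and SSR landscape, synteny
#' blocks with rearrangement classes and aligned fractions, conserved gene
#' clusters mapped to block context, gene overlaps, CMS-specific ORF
#' screening with cross-line intersection, candidate-gene polymorphism
#' calling with cross-cultivar intersection, CMS-specific regions, and the
#' two phylogenies (candidate-gene MP tree, SNP NJ tree when a reference is
#' given).  All tables are written as TSV, intervals additionally as BED,
#' and trees as newick.
#'
#' @param pairs list of pairs, each `list(maintainer =, cms =)` of
#'   `CircularGenome`s.
#' @param out_dir output directory (created when missing).
#' @param reference optional reference genome for the SNP phylogeny.
#' @param min_block synteny block granularity (bp).
#' @param candidate_genes gene names for the gene-concatenation tree;
#'   `NULL` uses the cross-cultivar polymorphism intersection.
#' @param n_boot bootstrap replicates for tree supports.
#' @param seed seed for the bootstrap resampling.
#' @return (invisibly) a list with every computed result.
#' @export
run_pipeline <- function(pairs, out_dir, reference = NULL, min_block = 3000,
                         candidate_genes = NULL, n_boot = 100, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- unlist(lapply(pairs, function(p) list(p$maintainer, p$cms)),
                    recursive = FALSE)
  ids <- vapply(genomes, `[[`, "", "id")
  names(genomes) <- ids
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  res <- list()

  # per-genome repeat landscape + summary features (Table 1 analogue)
  repeats <- lapply(genomes, find_dispersed_repeats)
  ssrs <- lapply(genomes, find_ssrs)
  summaries <- lapply(ids, function(id)
    summarize_repeats(genomes[[id]], repeats[[id]], ssrs[[id]]))
  names(summaries) <- ids
  feat <- do.call(rbind, lapply(ids, function(id) {
    g <- genomes[[id]]
    cds <- g$genes[g$genes$kind == "protein", , drop = FALSE]
    sm <- summaries[[id]]
    data.frame(genome = id, length_bp = genome_length(g),
               gc_percent = round(100 * gc_content(g), 2),
               protein_genes = length(unique(cds$name)),
               coding_bp = interval_union_len(cds$start, cds$end),
               coding_percent = round(100 * interval_union_len(cds$start,
                                                               cds$end) /
                                        genome_length(g), 2),
               repeat_bp = sm$total_repeat_bp,
               repeat_percent = round(100 * sm$repeat_fraction, 2),
               n_repeats = nrow(repeats[[id]]), n_ssrs = nrow(ssrs[[id]]),
               gene_features = nrow(g$genes), stringsAsFactors = FALSE)
  }))
  tsv(feat, "summary_features.tsv"); res$summary_features <- feat
  for (id in ids) {
    if (nrow(repeats[[id]]) > 0L)
      write_bed(data.frame(start = repeats[[id]]$start1,
                           end = repeats[[id]]$end1,
                           name = repeats[[id]]$orientation),
                id, file.path(out_dir, paste0(id, "_repeats.bed")))
  }
  tsv(do.call(rbind, lapply(ids, function(id)
    if (nrow(ssrs[[id]])) cbind(genome = id, ssrs[[id]]) else NULL)),
    "ssrs.tsv")
  res$repeats <- repeats; res$ssrs <- ssrs

  # copy numbers (Table 2 analogue)
  cn <- copy_numbers(genomes)
  tsv(data.frame(gene = rownames(cn), cn, check.names = FALSE),
      "copy_numbers.tsv")
  res$copy_numbers <- cn

  # synteny per pair (a side = CMS)
  blocks <- list()
  for (p in pairs) {
    b <- build_synteny_blocks(p$cms, p$maintainer, min_block = min_block)
    b <- classify_blocks(b)
    blocks[[p$cms$id]] <- b
  }
  bl_tab <- do.call(rbind, lapply(names(blocks), function(id) {
    b <- blocks[[id]]
    if (nrow(b) == 0L) return(NULL)
    data.frame(cms = id, maintainer = attr(b, "b_id"),
               cms_start = b$a_start, cms_end = b$a_end,
               m_start = b$b_start, m_end = b$b_end,
               orientation = b$orientation,
               identity = round(b$identity, 4),
               class = b$rearrangement_class, stringsAsFactors = FALSE)
  }))
  tsv(bl_tab, "synteny_blocks.tsv")
  af <- do.call(rbind, lapply(names(blocks), function(id)
    data.frame(cms = id,
               cms_aligned_percent = round(aligned_fraction(blocks[[id]],
                                                            "a"), 2),
               maintainer_aligned_percent =
                 round(aligned_fraction(blocks[[id]], "b"), 2))))
  tsv(af, "aligned_fractions.tsv")
  res$blocks <- blocks; res$aligned_fractions <- af

  # conserved gene clusters (Table 3 analogue)
  cons <- conserved_clusters(genomes)
  cons <- map_clusters_to_blocks(cons, blocks)
  tsv(data.frame(
    signature = vapply(cons, `[[`, "", "signature_string"),
    do.call(rbind, lapply(cons, function(cc)
      as.data.frame(lapply(cc$block_context, function(x)
        x %||% NA_character_), optional = TRUE))),
    check.names = FALSE), "gene_clusters.tsv")
  res$conserved_clusters <- cons
  ov <- do.call(rbind, lapply(ids, function(id) {
    o <- gene_overlaps(genomes[[id]])
    if (nrow(o)) cbind(genome = id, o) else NULL
  }))
  tsv(ov, "gene_overlaps.tsv"); res$gene_overlaps <- ov

  # CMS-specific ORFs
  specific <- lapply(pairs, function(p)
    screen_specific_orfs(p$cms, p$maintainer))
  names(specific) <- vapply(pairs, function(p) p$cms$id, "")
  res$specific_orfs <- specific
  if (length(specific) >= 2L) {
    sh <- shared_specific_orfs(specific)
    tsv(sh$shared[, setdiff(names(sh$shared), "seq")], "specific_orfs.tsv")
    res$shared_orfs <- sh
  } else {
    tsv(specific[[1L]][, setdiff(names(specific[[1L]]), "seq")],
        "specific_orfs.tsv")
  }

  # candidate genes (Table 4 analogue)
  polys <- lapply(pairs, function(p)
    call_polymorphisms(p$maintainer, p$cms))
  names(polys) <- names(specific)
  poly_sets <- lapply(polys, function(px)
    unique(vapply(Filter(function(r) nrow(r$events) > 0L, px),
                  `[[`, "", "gene")))
  res$polymorphic_genes <- poly_sets
  cand <- candidate_genes %||%
    (if (length(poly_sets) >= 2L) intersect_candidates(poly_sets)
     else poly_sets[[1L]])
  res$candidate_genes <- cand
  ev <- do.call(rbind, lapply(names(polys), function(id)
    do.call(rbind, lapply(polys[[id]], function(r)
      if (nrow(r$events)) cbind(cms = id, gene = r$gene,
                                length_a = r$length_a,
                                length_b = r$length_b, r$events)
      else NULL))))
  tsv(ev, "polymorphisms.tsv"); res$polymorphisms <- polys

  # CMS-specific regions
  regions <- find_unique_regions(lapply(pairs, `[[`, "cms"),
                                 lapply(pairs, `[[`, "maintainer"),
                                 min_block = min_block)
  if (length(regions)) {
    rg <- do.call(rbind, lapply(regions, function(r)
      data.frame(genome = r$genome_id, start = r$start, end = r$end,
                 length = r$length, stringsAsFactors = FALSE)))
    tsv(rg, "cms_regions.tsv")
    write_bed(rg, rg$genome[1L], file.path(out_dir, "cms_regions.bed"))
  }
  res$cms_regions <- regions

  # phylogenies
  if (length(cand) > 0L && length(genomes) >= 3L) {
    gm <- gene_concat_matrix(genomes, cand)
    tree <- bootstrap_support(gm, "mp", n_reps = n_boot, seed = seed)
    ape::write.tree(tree, file.path(out_dir, "candidate_gene_mp.nwk"))
    res$gene_tree <- tree
  }
  if (!is.null(reference) && length(genomes) >= 3L) {
    sm <- snp_matrix(genomes, reference)
    tree <- bootstrap_support(sm, "nj", n_reps = n_boot, seed = seed)
    ape::write.tree(tree, file.path(out_dir, "snp_nj.nwk"))
    res$snp_tree <- tree
    res$snp_matrix <- sm
  }

  meta <- list(package = "mitocompare",
               version = as.character(utils::packageVersion("mitocompare")),
               date = format(Sys.time(), "%Y-%m-%d"),
               parameters = list(min_block = min_block, n_boot = n_boot,
                                 seed = seed,
                                 repeat_min_identity = 0.90,
                                 orf_min_len = 300,
                                 orf_specificity_threshold = 0.99))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
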