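#' Character matrix container
#'
#' Aligned per-taxon character strings over {A,C,G,T,-,?} used for tree
#' building.
#'
#' @param mat character matrix (taxa x sites) with taxon rownames.
#' @param source `"snp_concat"` or `"gene_concat"`.
#' @param positions optional site positions in the reference.
#' @export
character_matrix <- function(mat, source = c("snp_concat", "gene_concat"),
                             positions = NULL) {
  source <- match.arg(source)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  structure(list(taxa = rownames(mat), mat = mat, source = source,
                 positions = positions), class = "CharacterMatrix")
}

#' @export
print.CharacterMatrix <- function(x, ...) {
  cat(sprintf("CharacterMatrix (%s): %d taxa x %d sites\n", x$source,
              length(x$taxa), ncol(x$mat)))
  invisible(x)
}

# reference-anchored allele track of one sample (NA where uncovered)
allele_track <- function(reference, sample, min_identity = 0.70,
                         min_len = 100) {
  hits <- anchored_align(reference$seq, sample$seq,
                         min_identity = min_identity, min_len = min_len)
  track <- rep(NA_character_, genome_length(reference))
  if (nrow(hits) == 0L) return(track)
  hits <- hits[order(-hits$score), , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    qa <- strsplit(hits$aln_q[i], "")[[1]]
    sa <- strsplit(hits$aln_s[i], "")[[1]]
    qgap <- qa == "-"
    qpos <- hits$q_start[i] + cumsum(!qgap)
    qpos <- qpos[!qgap]; al <- sa[!qgap]
    new <- is.na(track[qpos])
    track[qpos[new]] <- al[new]
  }
  track
}

#' SNP matrix of samples against a reference genome
#'
#' Each sample is aligned to the reference; for every reference position
#' covered in all samples where at least one sample differs from the
#' reference, one column of per-sample alleles is emitted, in reference
#' order.  Deletions yield "-".  Samples with less than `min_cov` alignable
#' fraction are excluded with a warning.
#'
#' @param samples list of `CircularGenome`s.
#' @param reference reference `CircularGenome`.
#' @param include_reference add the reference as a taxon.
#' @param min_cov minimum alignable fraction (default 0.1).
#' @param ... passed to the aligner.
#' @return a [character_matrix()] with `source = "snp_concat"`.
#' @export
snp_matrix <- function(samples, reference, include_reference = FALSE,
                       min_cov = 0.10, ...) {
  ids <- vapply(samples, `[[`, "", "id")
  tracks <- lapply(samples, allele_track, reference = reference, ...)
  cov <- vapply(tracks, function(t) mean(!is.na(t)), 0)
  if (any(cov < min_cov)) {
    warning("excluding samples with <", round(100 * min_cov),
            "% alignable fraction: ", paste(ids[cov < min_cov],
                                            collapse = ", "))
    tracks <- tracks[cov >= min_cov]; ids <- ids[cov >= min_cov]
  }
  refc <- strsplit(reference$seq, "")[[1]]
  tm <- do.call(rbind, tracks)
  covered <- colSums(is.na(tm)) == 0L
  variant <- covered & colSums(tm != rep(refc, each = nrow(tm)),
                               na.rm = TRUE) > 0L
  mat <- tm[, variant, drop = FALSE]
  if (include_reference) {
    mat <- rbind(mat, refc[variant]); ids <- c(ids, reference$id)
  }
  rownames(mat) <- ids
  character_matrix(mat, "snp_concat", positions = which(variant) - 1L)
}

#' Candidate-gene concatenation matrix
#'
#' For each listed gene, every taxon's coding sequence is globally aligned
#' to the first taxon's copy; alignment columns anchored on the first
#' taxon's positions are concatenated across genes.
#'
#' @param genomes list of annotated `CircularGenome`s.
#' @param genes base gene names to concatenate.
#' @return a [character_matrix()] with `source = "gene_concat"`.
#' @export
gene_concat_matrix <- function(genomes, genes) {
  ids <- vapply(genomes, `[[`, "", "id")
  cols <- list()
  for (gene in genes) {
    ref_cds <- gene_cds(genomes[[1L]], gene)
    if (is.null(ref_cds)) next
    block <- matrix(NA_character_, length(genomes), nchar(ref_cds))
    block[1L, ] <- strsplit(ref_cds, "")[[1]]
    for (t in seq_along(genomes)[-1L]) {
      cds <- gene_cds(genomes[[t]], gene)
      if (is.null(cds)) next
      g <- global_align(ref_cds, cds)
      qa <- strsplit(g$aln_a, "")[[1]]; sa <- strsplit(g$aln_b, "")[[1]]
      qgap <- qa == "-"
      qpos <- cumsum(!qgap)[!qgap]
      block[t, qpos] <- sa[!qgap]
    }
    keep <- colSums(is.na(block)) == 0L
    cols[[gene]] <- block[, keep, drop = FALSE]
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- ids
  character_matrix(mat, "gene_concat")
}

# ---- Fitch parsimony --------------------------------------------------------

state_bits <- function(ch) {
  b <- c(A = 1L, C = 2L, G = 4L, T = 8L)[ch]
  b[is.na(b)] <- 15L   # '-', '?', 'N' treated as missing (union state)
  b
}

#' Fitch parsimony score of a tree
#'
#' Sum over sites of the minimum number of state changes (Fitch small
#' parsimony); gaps and ambiguity are treated as missing.
#'
#' @param tree an `ape` "phylo" tree whose tips equal the matrix taxa.
#' @param cmat a [character_matrix()].
#' @param weights optional per-site weights.
#' @return integer (or weighted) parsimony score.
#' @export
parsimony_score <- function(tree, cmat, weights = NULL) {
  cost <- fitch_cost_vector(tree, cmat)
  if (is.null(weights)) sum(cost) else sum(cost * weights)
}

# per-site Fitch cost vector
fitch_cost_vector <- function(tree, cmat) {
  mat <- cmat$mat
  if (!setequal(tree$tip.label, rownames(mat)))
    stop("tree leaves do not match matrix taxa")
  if (ncol(mat) == 0L) return(numeric(0))
  if (!ape::is.rooted(tree))
    tree <- ape::root(tree, outgroup = tree$tip.label[1L],
                      resolve.root = TRUE)
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  S <- matrix(0L, nnode, ncol(mat))
  for (i in seq_len(ntip))
    S[i, ] <- state_bits(mat[tree$tip.label[i], ])
  cost <- numeric(ncol(mat))
  done <- logical(nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    if (!done[p]) { S[p, ] <- S[ch, ]; done[p] <- TRUE; next }
    inter <- bitwAnd(S[p, ], S[ch, ])
    empty <- inter == 0L
    cost[empty] <- cost[empty] + 1
    S[p, ] <- ifelse(empty, bitwOr(S[p, ], S[ch, ]), inter)
  }
  cost
}

# ---- topology enumeration ---------------------------------------------------

# enumerate all unrooted binary topologies on the given labels as edge lists
# (tips 1..n positive, internal nodes negative); returns list of matrices
enumerate_edge_lists <- function(n) {
  trees <- list(rbind(c(-1L, 1L), c(-1L, 2L), c(-1L, 3L)))
  if (n < 4L) return(trees)
  for (t in 4:n) {
    nxt <- list()
    for (tr in trees) {
      newint <- min(c(tr[tr < 0L], 0L)) - 1L
      for (e in seq_len(nrow(tr))) {
        tr2 <- tr
        u <- tr[e, 1L]; v <- tr[e, 2L]
        tr2[e, ] <- c(u, newint)
        tr2 <- rbind(tr2, c(newint, v), c(newint, t))
        nxt[[length(nxt) + 1L]] <- tr2
      }
    }
    trees <- nxt
  }
  trees
}

# convert an edge list over labels to an ape phylo via canonical newick
edge_list_to_newick <- function(el, labels) {
  adj <- split(c(el[, 2L], el[, 1L]), c(el[, 1L], el[, 2L]))
  build <- function(node, parent) {
    if (node > 0L) return(labels[node])
    kids <- setdiff(adj[[as.character(node)]], parent)
    subs <- sort(vapply(kids, build, "", parent = node))
    paste0("(", paste(subs, collapse = ","), ")")
  }
  root <- el[1L, 1L]   # an internal node
  kids <- adj[[as.character(root)]]
  subs <- sort(vapply(kids, build, "", parent = root))
  paste0("(", paste(subs, collapse = ","), ");")
}

enumerate_topologies <- function(labels) {
  els <- enumerate_edge_lists(length(labels))
  nwk <- vapply(els, edge_list_to_newick, "", labels = labels)
  lapply(nwk, function(x) ape::read.tree(text = x))
}

# canonical split keys (smaller side, sorted labels) of a tree's internal
# edges, for bipartition comparison
split_keys <- function(tree) {
  labels <- sort(tree$tip.label)
  bp <- ape::prop.part(ape::unroot(tree))
  keys <- character(0)
  for (p in bp) {
    side <- sort(attr(bp, "labels")[p])
    if (length(side) <= 1L || length(side) >= length(labels) - 1L) next
    other <- setdiff(labels, side)
    pick <- if (length(side) < length(other) ||
                (length(side) == length(other) &&
                 paste(side, collapse = ",") < paste(other, collapse = ",")))
      side else other
    keys <- c(keys, paste(pick, collapse = ","))
  }
  unique(keys)
}

#' Maximum parsimony tree
#'
#' Exhaustive search over all unrooted binary topologies up to
#' `exhaustive_cap` taxa; stepwise addition with NNI hill climbing beyond.
#' Ties are resolved deterministically (first in canonical newick order);
#' the number of co-optimal topologies is attached as attribute `"ties"`.
#'
#' @param cmat a [character_matrix()] with >= 3 taxa.
#' @param exhaustive_cap largest taxon count searched exhaustively.
#' @return an `ape` "phylo" tree with attributes `"score"` and `"ties"`.
#' @export
build_mp_tree <- function(cmat, exhaustive_cap = 8) {
  taxa <- cmat$taxa
  if (length(taxa) < 3L) stop("tree building needs >= 3 taxa")
  if (length(taxa) <= exhaustive_cap) {
    tops <- enumerate_topologies(taxa)
    ord <- order(vapply(tops, function(t) ape::write.tree(t), ""))
    tops <- tops[ord]
    scores <- vapply(tops, parsimony_score, 0, cmat = cmat)
    best <- which(scores == min(scores))
    tree <- tops[[best[1L]]]
    attr(tree, "score") <- min(scores)
    attr(tree, "ties") <- length(best)
    return(tree)
  }
  # heuristic: stepwise addition then NNI
  sub <- character_matrix(cmat$mat[taxa[1:3], , drop = FALSE], cmat$source)
  tree <- enumerate_topologies(taxa[1:3])[[1L]]
  for (t in taxa[-(1:3)]) {
    cand <- list()
    sub <- character_matrix(cmat$mat[c(tree$tip.label, t), , drop = FALSE],
                            cmat$source)
    for (e in seq_len(nrow(tree$edge))) {
      tr2 <- ape::bind.tree(tree,
                            ape::read.tree(text = paste0("(", t, ");")),
                            where = tree$edge[e, 2L])
      cand[[length(cand) + 1L]] <- ape::unroot(tr2)
    }
    sc <- vapply(cand, parsimony_score, 0, cmat = sub)
    tree <- cand[[which.min(sc)]]
  }
  # NNI improvement
  repeat {
    sc0 <- parsimony_score(tree, cmat)
    nb <- nni_neighbours(tree)
    scs <- vapply(nb, parsimony_score, 0, cmat = cmat)
    if (length(scs) == 0L || min(scs) >= sc0) break
    tree <- nb[[which.min(scs)]]
  }
  attr(tree, "score") <- parsimony_score(tree, cmat)
  attr(tree, "ties") <- NA_integer_
  tree
}

# all NNI neighbours of an unrooted tree
nni_neighbours <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  out <- list()
  internal <- tree$edge[tree$edge[, 2L] > ntip, , drop = FALSE]
  for (e in seq_len(nrow(internal))) {
    # swap subtrees across the internal edge: re-derive via newick surgery
    # using ape's rNNI-free approach: collapse and re-expand is complex, so
    # regenerate neighbours by moving one child of v to u
    u <- internal[e, 1L]; v <- internal[e, 2L]
    kids_v <- tree$edge[tree$edge[, 1L] == v, 2L]
    kids_u <- setdiff(tree$edge[tree$edge[, 1L] == u, 2L], v)
    for (a in kids_v) for (b in kids_u) {
      tr2 <- tree
      tr2$edge[tr2$edge[, 1L] == v & tr2$edge[, 2L] == a, 1L] <- u
      tr2$edge[tr2$edge[, 1L] == u & tr2$edge[, 2L] == b, 1L] <- v
      out[[length(out) + 1L]] <- tr2
    }
  }
  out
}

#' Neighbor-joining tree from p-distances
#'
#' Pairwise p-distance (mismatches over comparable sites, gaps/missing
#' excluded) followed by canonical neighbor joining; negative branch
#' lengths are clamped to zero.
#'
#' @param cmat a [character_matrix()] with >= 3 taxa.
#' @return an `ape` "phylo" tree with branch lengths.
#' @export
nj_tree <- function(cmat) {
  mat <- cmat$mat
  n <- nrow(mat)
  if (n < 3L) stop("tree building needs >= 3 taxa")
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- mat[i, ] %in% c("A", "C", "G", "T") &
      mat[j, ] %in% c("A", "C", "G", "T")
    if (!any(ok)) stop("taxa pair with zero comparable sites: ",
                       rownames(mat)[i], " / ", rownames(mat)[j])
    d[i, j] <- d[j, i] <- sum(mat[i, ok] != mat[j, ok]) / sum(ok)
  }
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Bootstrap support for a tree
#'
#' Sites are resampled with replacement `n_reps` times; the support of each
#' internal bipartition of the primary tree is the percentage of replicates
#' whose (strict consensus of co-optimal, for MP) tree(s) contain it.
#'
#' @param cmat a [character_matrix()].
#' @param method `"mp"` or `"nj"`.
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed RNG seed (resampling is fully reproducible).
#' @return the primary tree with `node.label` set to supports in \[0, 100\].
#' @export
bootstrap_support <- function(cmat, method = c("mp", "nj"), n_reps = 1000,
                              seed = 1) {
  method <- match.arg(method)
  stopifnot(n_reps >= 1)
  set.seed(seed)
  nsite <- ncol(cmat$mat)
  primary <- if (method == "mp") build_mp_tree(cmat) else nj_tree(cmat)
  keys <- split_keys(primary)
  counts <- setNames(numeric(length(keys)), keys)
  if (nsite > 0L && length(keys) > 0L) {
    if (method == "mp" && length(cmat$taxa) <= 8L) {
      tops <- enumerate_topologies(cmat$taxa)
      persite <- t(vapply(tops, fitch_cost_vector, numeric(nsite),
                          cmat = cmat))           # topologies x sites
      haskey <- vapply(tops, function(t)
        keys %in% split_keys(t), logical(length(keys)))
      haskey <- matrix(haskey, nrow = length(keys)) # keys x topologies
      for (r in seq_len(n_reps)) {
        w <- tabulate(sample.int(nsite, nsite, replace = TRUE), nsite)
        sc <- as.vector(persite %*% w)
        mins <- which(sc == min(sc))
        ok <- apply(haskey[, mins, drop = FALSE], 1L, all)
        counts[ok] <- counts[ok] + 1
      }
    } else {
      for (r in seq_len(n_reps)) {
        idx <- sample.int(nsite, nsite, replace = TRUE)
        sub <- character_matrix(cmat$mat[, idx, drop = FALSE], cmat$source)
        tr <- if (method == "mp") build_mp_tree(sub) else nj_tree(sub)
        ok <- keys %in% split_keys(tr)
        counts[ok] <- counts[ok] + 1
      }
    }
  }
  support <- round(100 * counts / n_reps)
  # attach supports to internal nodes by matching bipartitions
  primary$node.label <- rep("", primary$Nnode)
  ntip <- length(primary$tip.label)
  for (nd in seq_len(primary$Nnode)) {
    tips <- ape::extract.clade(primary, ntip + nd)$tip.label
    side <- sort(tips); other <- sort(setdiff(primary$tip.label, side))
    if (length(side) <= 1L || length(other) <= 1L) next
    pick <- if (length(side) < length(other) ||
                (length(side) == length(other) &&
                 paste(side, collapse = ",") < paste(other, collapse = ",")))
      side else other
    key <- paste(pick, collapse = ",")
    if (key %in% names(support))
      primary$node.label[nd] <- as.character(support[key])
  }
  primary
}

#' Do two taxon groups form separate clades?
#'
#' TRUE when some internal bipartition of the (unrooted) tree separates
#' `group` from the remaining taxa exactly.
#'
#' @param tree an `ape` "phylo".
#' @param group character vector of tip labels.
#' @export
separates_groups <- function(tree, group) {
  side <- sort(intersect(tree$tip.label, group))
  other <- sort(setdiff(tree$tip.label, group))
  pick <- if (length(side) < length(other) ||
              (length(side) == length(other) &&
               paste(side, collapse = ",") < paste(other, collapse = ",")))
    side else other
  paste(pick, collapse = ",") %in% split_keys(tree)
}
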