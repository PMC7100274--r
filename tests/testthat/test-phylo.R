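cmat <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, function(x) strsplit(x[[2]], "")[[1]]))
  rownames(m) <- vapply(rows, `[[`, "", 1)
  character_matrix(m, "gene_concat")
}

test_that("Fitch scores match hand-worked quartet cases", {
  m <- cmat(list("a1", "A"), list("a2", "A"), list("c1", "C"),
            list("c2", "C"))
  t_good <- ape::read.tree(text = "((a1,a2),(c1,c2));")
  t_bad <- ape::read.tree(text = "((a1,c1),(a2,c2));")
  expect_equal(parsimony_score(t_good, m), 1)
  expect_equal(parsimony_score(t_bad, m), 2)
  const <- cmat(list("a1", "G"), list("a2", "G"), list("c1", "G"),
                list("c2", "G"))
  expect_equal(parsimony_score(t_good, const), 0)
  expect_error(parsimony_score(t_good, cmat(list("x", "A"), list("y", "C"),
                                            list("z", "G"), list("w", "T"))),
               "taxa")
})

test_that("Fitch scores match exhaustive ancestral-state enumeration", {
  set.seed(81)
  taxa <- paste0("t", 1:5)
  for (rep in 1:5) {
    m <- matrix(sample(c("A", "C", "G", "T", "-"), 5 * 12, TRUE,
                       prob = c(rep(0.23, 4), 0.08)), 5, 12,
                dimnames = list(taxa, NULL))
    cm <- character_matrix(m, "gene_concat")
    tr <- ape::rtree(5, tip.label = sample(taxa))
    expect_equal(parsimony_score(tr, cm), brute_fitch(tr, m))
  }
})

test_that("Fitch scores agree with phangorn on random matrices", {
  skip_if_not_installed("phangorn")
  set.seed(82)
  taxa <- paste0("t", 1:6)
  for (rep in 1:5) {
    m <- matrix(sample(c("A", "C", "G", "T"), 6 * 30, TRUE), 6, 30,
                dimnames = list(taxa, NULL))
    cm <- character_matrix(m, "gene_concat")
    dat <- phangorn::phyDat(m, type = "DNA")
    tr <- ape::unroot(ape::rtree(6, tip.label = sample(taxa)))
    expect_equal(parsimony_score(tr, cm),
                 as.numeric(phangorn::parsimony(tr, dat)))
  }
})

test_that("exhaustive MP search finds the minimal topology", {
  skip_if_not_installed("phangorn")
  set.seed(83)
  # single informative split -> ((A,B),(C,D))
  m <- cmat(list("A", "AAAAA"), list("B", "AAAAA"), list("C", "CCAAA"),
            list("D", "CCAAA"))
  tr <- build_mp_tree(m)
  expect_true(separates_groups(tr, c("A", "B")))
  expect_equal(attr(tr, "score"), 2)

  # 3:1 conflicting characters: the majority split wins
  m2 <- cmat(list("A", "CCCA"), list("B", "CCCG"), list("C", "AAAA"),
             list("D", "AAAG"))
  tr2 <- build_mp_tree(m2)
  expect_true(separates_groups(tr2, c("A", "B")))

  # the returned score equals the minimum over all topologies (phangorn)
  for (n in c(5, 7)) {
    taxa <- paste0("t", seq_len(n))
    mm <- matrix(sample(c("A", "C", "G", "T"), n * 40, TRUE), n, 40,
                 dimnames = list(taxa, NULL))
    cm <- character_matrix(mm, "gene_concat")
    tr <- build_mp_tree(cm)
    dat <- phangorn::phyDat(mm, type = "DNA")
    all_sc <- vapply(phangorn::allTrees(n, tip.label = taxa),
                     function(t) as.numeric(phangorn::parsimony(t, dat)), 0)
    expect_equal(attr(tr, "score"), min(all_sc))
  }
})

test_that("MP recovers the generating topology of simulated characters", {
  set.seed(84)
  # simulate 200 sites on ((t1,t2),(t3,t4),(t5,t6)) with clade-specific
  # substitutions
  base <- sample(c("A", "C", "G", "T"), 200, TRUE)
  mut <- function(x, p) {
    hit <- runif(length(x)) < p
    x[hit] <- vapply(x[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    x
  }
  anc12 <- mut(base, 0.08); anc34 <- mut(base, 0.08); anc56 <- mut(base, 0.08)
  m <- rbind(t1 = mut(anc12, 0.02), t2 = mut(anc12, 0.02),
             t3 = mut(anc34, 0.02), t4 = mut(anc34, 0.02),
             t5 = mut(anc56, 0.02), t6 = mut(anc56, 0.02))
  tr <- build_mp_tree(character_matrix(m, "gene_concat"))
  expect_true(separates_groups(tr, c("t1", "t2")))
  expect_true(separates_groups(tr, c("t3", "t4")))
  expect_true(separates_groups(tr, c("t5", "t6")))
})

test_that("NJ recovers additive structure and is label-invariant", {
  set.seed(85)
  # disjoint private variant blocks make p-distances additive on a
  # caterpillar tree
  n <- 200
  base <- sample(c("A", "C", "G", "T"), n, TRUE)
  flip <- function(x, idx) {
    x[idx] <- vapply(x[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    x
  }
  ab <- flip(base, 111:130)      # internal branch of clade (A,B)
  de <- flip(base, 131:160)      # internal branch of clade (D,E)
  m <- rbind(A = flip(ab, 1:10), B = flip(ab, 11:20),
             C = flip(base, 21:40), D = flip(de, 41:70),
             E = flip(de, 71:110))
  cm <- character_matrix(m, "gene_concat")
  tr <- nj_tree(cm)
  expect_true(all(tr$edge.length >= 0))
  expect_true(separates_groups(tr, c("A", "B")))
  expect_true(separates_groups(tr, c("D", "E")))
  # permuting taxa leaves the unrooted topology unchanged
  perm <- m[sample(rownames(m)), ]
  tr2 <- nj_tree(character_matrix(perm, "gene_concat"))
  expect_equal(sort(mitocompare:::split_keys(tr)),
               sort(mitocompare:::split_keys(tr2)))
  expect_error(nj_tree(character_matrix(
    rbind(A = c("A", "-"), B = c("-", "A"), C = c("A", "A")),
    "gene_concat")), "comparable")
})

test_that("three identical taxa give a zero-length star", {
  m <- cmat(list("A", "ACGT"), list("B", "ACGT"), list("C", "ACGT"))
  tr <- nj_tree(m)
  expect_equal(sum(tr$edge.length), 0)
})

test_that("bootstrap supports reflect signal strength", {
  set.seed(86)
  # one perfectly supported split
  m <- cmat(list("A", strrep("A", 20)), list("B", strrep("A", 20)),
            list("C", strrep("C", 20)), list("D", strrep("C", 20)))
  tr <- bootstrap_support(m, "mp", n_reps = 100, seed = 3)
  expect_true(any(tr$node.label == "100"))

  # all-constant matrix: no supported internal structure
  mc <- cmat(list("A", strrep("G", 20)), list("B", strrep("G", 20)),
             list("C", strrep("G", 20)), list("D", strrep("G", 20)))
  trc <- bootstrap_support(mc, "mp", n_reps = 100, seed = 3)
  sup <- suppressWarnings(as.numeric(trc$node.label))
  expect_true(all(is.na(sup) | sup == 0))

  # 50/50 conflicting signal: support near 50 at 1000 replicates
  half <- cmat(list("A", paste0(strrep("A", 50), strrep("G", 50))),
               list("B", paste0(strrep("A", 50), strrep("C", 50))),
               list("C", paste0(strrep("T", 50), strrep("G", 50))),
               list("D", paste0(strrep("T", 50), strrep("C", 50))))
  trh <- bootstrap_support(half, "mp", n_reps = 1000, seed = 3)
  sup <- as.numeric(trh$node.label[trh$node.label != ""])
  expect_true(all(sup >= 30 & sup <= 65))
})

test_that("bootstrap is reproducible for a fixed seed", {
  set.seed(87)
  m <- cmat(list("A", rnd_seq(60)), list("B", rnd_seq(60)),
            list("C", rnd_seq(60)), list("D", rnd_seq(60)))
  t1 <- bootstrap_support(m, "nj", n_reps = 50, seed = 11)
  t2 <- bootstrap_support(m, "nj", n_reps = 50, seed = 11)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("SNP matrices collect variant columns against the reference", {
  set.seed(88)
  ref <- toy_genome("REF", rnd_seq(20000))
  same <- toy_genome("S0", ref$seq)
  expect_equal(ncol(snp_matrix(list(same), ref)$mat), 0L)

  mutate_at <- function(seq, pos) {
    for (p in pos) {
      old <- substr(seq, p, p)
      substr(seq, p, p) <- c(A = "C", C = "G", G = "T", T = "A")[old]
    }
    seq
  }
  one <- toy_genome("S1", mutate_at(ref$seq, 5000))
  m1 <- snp_matrix(list(one), ref)
  expect_equal(ncol(m1$mat), 1L)
  expect_equal(m1$positions, 4999L)

  # four samples with 50 planted SNPs each, partially shared
  pools <- list(seq(1000, 10800, by = 200),
                seq(5000, 14800, by = 200),
                seq(9000, 18800, by = 200),
                seq(1100, 10900, by = 200))
  samples <- lapply(seq_along(pools), function(i)
    toy_genome(paste0("P", i), mutate_at(ref$seq, pools[[i]])))
  ms <- snp_matrix(samples, ref)
  expect_equal(ncol(ms$mat), length(unique(unlist(pools))))
})
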