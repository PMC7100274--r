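test_that("cluster detection respects the gap threshold and circularity", {
  set.seed(41)
  g <- toy_genome("g", rnd_seq(10000),
                  rbind(gene_row("nad9", 0, 100),
                        gene_row("trnP", 150, 250, kind = "tRNA"),
                        gene_row("trnW", 450, 550, kind = "tRNA"),
                        gene_row("atp6", 6000, 7000)))
  cl <- detect_clusters(g, max_gap = 2000)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$signature, "nad9-trnP-trnW")

  # two genes 5 kb apart do not cluster
  g2 <- toy_genome("g2", rnd_seq(12000),
                   rbind(gene_row("a", 0, 100), gene_row("b", 5100, 5200)))
  expect_length(detect_clusters(g2, max_gap = 2000), 0L)

  # a run spanning the origin is found once
  g3 <- toy_genome("g3", rnd_seq(10000),
                   rbind(gene_row("cob", 9500, 9900),
                         gene_row("rps14", 200, 400),
                         gene_row("atp1", 4000, 5000)))
  cl3 <- detect_clusters(g3, max_gap = 2000)
  expect_length(cl3, 1L)
  expect_equal(cl3[[1]]$members, c("cob", "rps14"))
})

test_that("conserved clusters normalize parts and orientation", {
  set.seed(42)
  mk <- function(id, genes) toy_genome(id, rnd_seq(8000), genes)
  g1 <- mk("g1", rbind(gene_row("nad2", 100, 400, "a"),
                       gene_row("nad2", 500, 800, "b"),
                       gene_row("sdh3", 900, 1200)))
  g2 <- mk("g2", rbind(gene_row("sdh3", 100, 400),
                       gene_row("nad2", 500, 800, "d"),
                       gene_row("nad2", 900, 1200, "e")))
  cc <- conserved_clusters(list(g1, g2))
  expect_length(cc, 1L)
  expect_equal(cc[[1]]$signature_string, "nad2-sdh3")
})

test_that("clusters absent from one genome are not conserved", {
  set.seed(43)
  mk <- function(id, genes) toy_genome(id, rnd_seq(8000), genes)
  shared <- rbind(gene_row("cox1", 100, 600),
                  gene_row("rps10", 700, 900))
  private <- rbind(gene_row("nad6", 3000, 3500),
                   gene_row("rps4", 3600, 4000))
  g1 <- mk("g1", rbind(shared, private))
  g2 <- mk("g2", rbind(shared, private))
  g3 <- mk("g3", shared)
  cc <- conserved_clusters(list(g1, g2, g3))
  expect_equal(vapply(cc, `[[`, "", "signature_string"), "cox1-rps10")
})

test_that("planted shared clusters are recovered exactly", {
  set.seed(44)
  sh <- list(c("mat-R", "nad1"), c("trnM", "rrn26"), c("nad3", "rps12"),
             c("rrn18", "rrn5"), c("nad9", "trnP", "trnW"))
  mk <- function(id, extra) {
    rows <- list(); pos <- 100
    names_ <- c(sh, extra)
    for (cl in names_[sample(length(names_))]) {
      for (nm in cl) {
        rows[[length(rows) + 1L]] <- gene_row(nm, pos, pos + 200)
        pos <- pos + 300
      }
      pos <- pos + 3000
    }
    toy_genome(id, rnd_seq(pos + 100), do.call(rbind, rows))
  }
  gs <- list(mk("a", list(c("atp1", "atp4"))),
             mk("b", list(c("cox2", "cox3"))),
             mk("c", list()), mk("d", list()))
  cc <- conserved_clusters(gs)
  expect_setequal(
    vapply(cc, `[[`, "", "signature_string"),
    vapply(sh, function(x) paste(mitocompare:::canonical_signature(x),
                                 collapse = "-"), ""))
})

test_that("signature normalization equals its reversal", {
  set.seed(45)
  for (i in 1:20) {
    sig <- sample(letters, sample(2:6, 1))
    expect_equal(mitocompare:::canonical_signature(sig),
                 mitocompare:::canonical_signature(rev(sig)))
  }
})

test_that("cluster-to-block mapping uses majority overlap", {
  blocks <- data.frame(a_start = c(0L, 5000L), a_end = c(5000L, 10000L),
                       b_start = c(0L, 5000L), b_end = c(5000L, 10000L),
                       orientation = c("forward", "reverse"),
                       identity = 1, matches = 1L, columns = 1L, score = 1,
                       rearrangement_class = c("collinearity", "inversion"),
                       stringsAsFactors = FALSE)
  cc <- list(list(signature = c("a", "b"), signature_string = "a-b",
                  instances = list(G = list(genome_id = "G", start = 1000,
                                            end = 2000)),
                  block_context = NULL),
             list(signature = c("c", "d"), signature_string = "c-d",
                  instances = list(G = list(genome_id = "G", start = 6000,
                                            end = 7000)),
                  block_context = NULL),
             list(signature = c("e", "f"), signature_string = "e-f",
                  instances = list(G = list(genome_id = "G", start = 3600,
                                            end = 5600)),  # 70 % in block 1
                  block_context = NULL))
  out <- map_clusters_to_blocks(cc, list(G = blocks))
  expect_equal(out[[1]]$block_context$G, "collinearity")
  expect_equal(out[[2]]$block_context$G, "inversion")
  expect_equal(out[[3]]$block_context$G, "collinearity")
})

test_that("gene overlaps report pairwise overlap lengths", {
  g <- toy_genome("ov", rnd_seq(2000),
                  rbind(gene_row("rps3", 0, 500, "b"),
                        gene_row("rpl16", 392, 900),
                        gene_row("cox2", 1500, 1800)))
  ov <- gene_overlaps(g)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$overlap_bp, 108L)
  expect_setequal(c(ov$gene_a, ov$gene_b), c("rps3", "rpl16"))
  g2 <- toy_genome("no", rnd_seq(1000),
                   rbind(gene_row("a", 0, 100), gene_row("b", 200, 300)))
  expect_equal(nrow(gene_overlaps(g2)), 0L)
})
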