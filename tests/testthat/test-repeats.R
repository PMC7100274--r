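test_that("repeat size classes honor the 50/500 boundaries", {
  expect_equal(classify_repeat_size(c(49, 50, 500, 501)),
               c("small", "intermediate", "intermediate", "large"))
  expect_error(classify_repeat_size(0))
})

test_that("planted direct and inverted repeats are found and classified", {
  set.seed(3)
  x <- rnd_seq(600)
  g_dr <- toy_genome("dr", paste0(rnd_seq(2000), x, rnd_seq(3000), x,
                                  rnd_seq(2000)))
  r <- find_dispersed_repeats(g_dr)
  expect_equal(nrow(r), 1L)
  expect_equal(r$orientation, "DR")
  expect_equal(r$size_class, "large")
  expect_equal(r$identity, 1.0)
  expect_lt(abs(r$start1 - 2000), 10)

  g_ir <- toy_genome("ir", paste0(rnd_seq(2000), x, rnd_seq(3000), rc(x),
                                  rnd_seq(2000)))
  r2 <- find_dispersed_repeats(g_ir)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$orientation, "IR")
  expect_false(r2$palindromic)
})

test_that("mutated copies report identity matching the DP oracle", {
  set.seed(8)
  x <- rnd_seq(600)
  ch <- strsplit(x, "")[[1]]
  mut <- sample(600, 30)   # 5% substitutions
  for (i in mut) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  x2 <- paste(ch, collapse = "")
  g <- toy_genome("m", paste0(rnd_seq(2000), x, rnd_seq(3000), x2,
                              rnd_seq(2000)))
  r <- find_dispersed_repeats(g)
  expect_equal(nrow(r), 1L)
  expect_equal(r$orientation, "DR")
  expect_gte(r$identity, 0.93)
  expect_lte(r$identity, 0.97)
  # oracle re-validation on the reported substrings
  sw <- local_align(substr(g$seq, r$start1 + 1, r$end1),
                    substr(g$seq, r$start2 + 1, r$end2))
  expect_lt(abs(sw$identity - r$identity), 0.01)
})

test_that("repeat identity threshold is strict", {
  set.seed(9)
  x <- rnd_seq(400)
  g <- toy_genome("s", paste0(rnd_seq(1500), x, rnd_seq(1500), x,
                              rnd_seq(1000)))
  expect_equal(nrow(find_dispersed_repeats(g, min_identity = 0.90)), 1L)
  # an exact copy has identity 1.0, never "more than" 1.0
  expect_equal(nrow(find_dispersed_repeats(g, min_identity = 1.0)), 0L)
})

test_that("repeat discovery is invariant under genome rotation", {
  set.seed(12)
  x <- rnd_seq(300)
  g <- toy_genome("rot", paste0(rnd_seq(1000), x, rnd_seq(2000), x,
                                rnd_seq(1000)))
  r1 <- find_dispersed_repeats(g)
  r2 <- find_dispersed_repeats(rotate_genome(g, 4300))
  expect_equal(nrow(r1), nrow(r2))
  expect_equal(sort(r1$end1 - r1$start1), sort(r2$end1 - r2$start1))
  expect_equal(r1$orientation, r2$orientation)
})

test_that("palindromes require contiguity and match small-case enumeration", {
  set.seed(4)
  x <- rnd_seq(1491)
  g <- toy_genome("pal", paste0(rnd_seq(2000), x, rc(x), rnd_seq(2000)))
  p <- find_palindromes(g, min_len = 100)
  expect_equal(nrow(p), 1L)
  # flanking bases may extend the arms by chance complementarity
  expect_true(p$arm >= 1491L && p$arm <= 1496L)
  expect_lte(abs(p$start1 - 2000L), 5L)
  expect_true(p$palindromic)

  # same arms 10 kb apart: an IR but not a palindrome at spacer 0
  g2 <- toy_genome("far", paste0(rnd_seq(2000), x, rnd_seq(10000), rc(x),
                                 rnd_seq(2000)))
  expect_equal(nrow(find_palindromes(g2, min_len = 100)), 0L)
  r <- find_dispersed_repeats(g2)
  expect_true(any(r$orientation == "IR" & !r$palindromic))

  g3 <- toy_genome("tiny", "ACGCGT")
  p3 <- find_palindromes(g3, min_len = 3)
  expect_true(any(p3$arm == 3 & p3$start1 == 0))
})

test_that("SSR detection canonicalizes motifs and enforces thresholds", {
  s1 <- find_ssrs(paste0("GGTT", strrep("AC", 6), "GGTT"))
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$motif, "AC")
  expect_equal(s1$motif_class, "dimer")
  expect_gte(s1$copies, 6)

  set.seed(21)
  emb <- paste0(rnd_seq(300), strrep("CTTA", 4), rnd_seq(300))
  s2 <- find_ssrs(emb)
  tet <- s2[s2$motif_class == "tetramer", ]
  expect_equal(nrow(tet), 1L)
  expect_equal(tet$motif, mitocompare:::canonical_motif("CTTA"))

  expect_equal(nrow(find_ssrs("GCGCAAAAAAGCGC")), 0L)  # 6 < 12 copies
})

test_that("SSR detection matches the brute-force scanner on random input", {
  set.seed(31)
  for (i in 1:6) {
    s <- paste0(rnd_seq(600), strrep("TCA", 5), rnd_seq(600),
                strrep("A", 13), rnd_seq(600))
    mine <- find_ssrs(s)
    ref <- brute_ssrs(s)
    # every brute-force run is recovered (up to overlap resolution)
    for (j in seq_len(nrow(ref))) {
      expect_true(any(mitocompare:::overlap_len(
        mine$start, mine$end, ref$start[j], ref$end[j]) >=
          0.8 * (ref$end[j] - ref$start[j])))
    }
    expect_lte(nrow(mine), nrow(ref) + 1L)
  }
})

test_that("repeat summaries count planted features and union footprints", {
  set.seed(14)
  x <- rnd_seq(600); y <- rnd_seq(100)
  g <- toy_genome("sum", paste0(rnd_seq(1500), x, rnd_seq(1500), x,
                                rnd_seq(1500), y, rnd_seq(1500), rc(y),
                                rnd_seq(500), strrep("TGCAA", 4),
                                rnd_seq(500)))
  sm <- summarize_repeats(g)
  expect_equal(unname(sm$counts_by_size["large"]), 1L)
  expect_equal(unname(sm$counts_by_size["intermediate"]), 1L)
  expect_equal(unname(sm$counts_by_orientation["DR"]), 1L)
  expect_equal(unname(sm$counts_by_orientation["IR"]), 1L)
  expect_equal(sm$ssr_count, 1L)
  expect_equal(sm$repeat_fraction, sm$total_repeat_bp / genome_length(g))

  # overlapping intervals are counted once: 600 + 600 overlapping by 100
  fake <- data.frame(start1 = 0L, end1 = 600L, start2 = 500L, end2 = 1100L,
                     orientation = "DR", identity = 1, length = 600L,
                     size_class = "large", palindromic = FALSE)
  sm2 <- summarize_repeats(g, repeats = fake,
                           ssrs = find_ssrs("ACGT"))
  expect_equal(sm2$total_repeat_bp, 1100L)
})

test_that("repeat-free random genomes have zero repeat fraction", {
  set.seed(15)
  g <- toy_genome("bare", rnd_seq(8000))
  sm <- summarize_repeats(g, ssrs = find_ssrs(g))
  expect_equal(unname(sm$counts_by_orientation[c("DR", "IR")]), c(0L, 0L))
})

test_that("aligned fraction to a reference reflects planted content", {
  set.seed(16)
  g <- toy_genome("q", rnd_seq(20000))
  expect_equal(fraction_aligned_to(g, g), 100)
  expect_equal(fraction_aligned_to(g, rnd_seq(20000)), 0)
  ref <- rnd_seq(30000)
  g2 <- toy_genome("q2", paste0(rnd_seq(22500), substr(ref, 1001, 6000),
                                rnd_seq(22500)))   # 5 kb of 50 kb = 10%
  expect_lt(abs(fraction_aligned_to(g2, ref) - 10), 0.5)
})
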