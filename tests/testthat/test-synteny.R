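test_that("identical genomes give one collinear block covering everything", {
  set.seed(2)
  a <- toy_genome("A", rnd_seq(20000))
  b <- toy_genome("B", a$seq)
  bl <- classify_blocks(build_synteny_blocks(a, b))
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$rearrangement_class, "collinearity")
  expect_equal(aligned_fraction(bl, "a"), 100)
  expect_equal(aligned_fraction(bl, "b"), 100)
})

test_that("a planted internal inversion yields a reverse middle block", {
  set.seed(6)
  a <- toy_genome("A", rnd_seq(40000))
  b <- toy_genome("B", paste0(substr(a$seq, 1, 15000),
                              rc(substr(a$seq, 15001, 25000)),
                              substr(a$seq, 25001, 40000)))
  bl <- classify_blocks(build_synteny_blocks(b, a))
  expect_equal(nrow(bl), 3L)
  expect_equal(sum(bl$orientation == "reverse"), 1L)
  mid <- bl[bl$orientation == "reverse", ]
  expect_equal(mid$rearrangement_class, "inversion")
  expect_equal(bl$rearrangement_class[bl$orientation == "forward"],
               rep("collinearity", 2))
})

test_that("planted rearrangements are recovered with accurate breakpoints", {
  set.seed(61)
  L <- 100000
  a <- rnd_seq(L)
  # truth plan on a: inversion [20k,28k); translocations [50k,56k)->80k and
  # [60k,66k)->10k; deletion [40k,44k)
  seg <- function(s, e) substr(a, s + 1, e)
  b <- paste0(
    seg(0, 10000), seg(60000, 66000), seg(10000, 20000),
    rc(seg(20000, 28000)), seg(28000, 40000), seg(44000, 50000),
    seg(56000, 60000), seg(66000, 80000), seg(50000, 56000),
    seg(80000, L))
  ga <- toy_genome("A", a); gb <- toy_genome("B", b)
  bl <- classify_blocks(build_synteny_blocks(gb, ga))
  # conserved sequence is everything except the 4 kb deletion
  expect_gte(aligned_fraction(bl, "a"), 95)
  expect_gte(aligned_fraction(bl, "b") * nchar(b) / 100, 0.95 * (L - 4000))
  expect_equal(sum(bl$orientation == "reverse"), 1L)
  inv <- bl[bl$orientation == "reverse", ]
  expect_lte(abs(inv$b_start - 20000), 50)
  expect_lte(abs(inv$b_end - 28000), 50)
  expect_equal(inv$rearrangement_class, "inversion")
  expect_equal(sum(bl$rearrangement_class == "translocation"), 2L)
  tr <- bl[bl$rearrangement_class == "translocation", ]
  expect_true(any(abs(tr$b_start - 50000) <= 50))
  expect_true(any(abs(tr$b_start - 60000) <= 50))
})

test_that("every block receives exactly one class", {
  set.seed(62)
  a <- toy_genome("A", rnd_seq(30000))
  b <- toy_genome("B", paste0(substr(a$seq, 20001, 30000),
                              substr(a$seq, 1, 20000)))
  bl <- classify_blocks(build_synteny_blocks(b, a))
  expect_true(all(bl$rearrangement_class %in%
                    c("collinearity", "translocation", "inversion",
                      "trans_inv")))
  expect_equal(sum(table(bl$rearrangement_class)), nrow(bl))
  # a pure rotation of a circular genome stays collinear
  expect_true(all(bl$rearrangement_class == "collinearity"))
})

test_that("classification is invariant under rotation of either genome", {
  set.seed(63)
  a <- toy_genome("A", rnd_seq(40000))
  b <- toy_genome("B", paste0(substr(a$seq, 1, 12000),
                              rc(substr(a$seq, 12001, 20000)),
                              substr(a$seq, 20001, 40000)))
  base <- classify_blocks(build_synteny_blocks(b, a))
  rot <- classify_blocks(build_synteny_blocks(rotate_genome(b, 31000), a))
  # the rotation cut may split a collinear block in two; the classes of the
  # underlying regions are unchanged
  for (bl in list(base, rot)) {
    expect_equal(sum(bl$orientation == "reverse"), 1L)
    expect_equal(bl$rearrangement_class[bl$orientation == "reverse"],
                 "inversion")
    expect_true(all(bl$rearrangement_class[bl$orientation == "forward"] ==
                      "collinearity"))
  }
  expect_equal(aligned_fraction(base, "b"), aligned_fraction(rot, "b"),
               tolerance = 0.001)
})

test_that("unique regions require length, non-synteny and sharing", {
  set.seed(64)
  m1 <- toy_genome("M1", rnd_seq(60000))
  shared_ins <- rnd_seq(10000)
  priv1 <- rnd_seq(5000); priv2 <- rnd_seq(5000)
  c1 <- toy_genome("S1", paste0(substr(m1$seq, 1, 20000), shared_ins,
                                substr(m1$seq, 20001, 40000), priv1,
                                substr(m1$seq, 40001, 60000)))
  m2 <- toy_genome("M2", m1$seq)
  c2 <- toy_genome("S2", paste0(substr(m2$seq, 1, 30000), priv2,
                                substr(m2$seq, 30001, 50000), shared_ins,
                                substr(m2$seq, 50001, 60000)))
  # single pair: both insertions are unique regions
  r1 <- find_unique_regions(list(c1), list(m1))
  expect_equal(length(r1), 2L)
  # identical pair: nothing unique
  expect_equal(length(find_unique_regions(list(m2), list(m1))), 0L)
  # two CMS lines: only the shared insertion survives
  rs <- find_unique_regions(list(c1, c2), list(m1, m2))
  expect_equal(length(rs), 1L)
  expect_lte(abs(rs[[1]]$length - 10000), 300)
  expect_lte(abs(rs[[1]]$start - 20000), 150)
})

test_that("region annotation uses the 1 bp overlap rule", {
  set.seed(65)
  genes <- rbind(gene_row("atp6", 1000, 1900),
                 gene_row("cox1", 4999, 5600),   # overlaps region by 1 bp
                 gene_row("nad4", 8000, 8900))   # outside
  g <- toy_genome("G", rnd_seq(10000), genes)
  region <- list(genome_id = "G", start = 500, end = 5000, length = 4500)
  orfs <- data.frame(id = "orf100", start = 2000, end = 2303, strand = "+",
                     frame = 0L, nt_length = 303L, aa_length = 100L,
                     seq = "x", stringsAsFactors = FALSE)
  ann <- annotate_region(region, g, orfs = orfs)
  expect_equal(sort(ann$contained$genes$name), c("atp6", "cox1"))
  expect_equal(nrow(ann$contained$orfs), 1L)
  expect_equal(ann$contained$orfs$rel_start, 1500L)
  empty <- annotate_region(list(genome_id = "G", start = 9000, end = 9500,
                                length = 500), g, orfs = orfs)
  expect_equal(nrow(empty$contained$genes), 0L)
  expect_equal(nrow(empty$contained$orfs), 0L)
})
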