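test_that("ORF prediction handles minimal, reverse and boundary cases", {
  g <- toy_genome("o", "ATGAAATAA", circular = FALSE)
  o <- find_orfs(g, min_len = 0)
  expect_equal(nrow(o), 1L)
  expect_equal(o$nt_length, 9L)
  expect_equal(o$aa_length, 2L)
  expect_equal(o$strand, "+")

  # reverse-strand ORF reported on forward coordinates
  set.seed(51)
  orf <- paste(c("ATG", sample(mitocompare:::SENSE_CODONS, 40, TRUE), "TAA"),
               collapse = "")
  # "TTA" reads as an in-frame TAA stop on the reverse strand, preventing
  # upstream extension of the planted frame
  s <- paste0(rnd_seq(200), rc(orf), "TTA", rnd_seq(197))
  g2 <- toy_genome("o2", s, circular = FALSE)
  o2 <- find_orfs(g2, min_len = 100)
  o2 <- o2[o2$nt_length == nchar(orf), ]
  expect_equal(o2$strand, "-")
  expect_equal(o2$start, 200L)
  expect_equal(substr(g2$seq, o2$start + 1, o2$end), rc(orf))

  # an ORF of exactly 300 nt is excluded (strict > 300)
  orf300 <- paste(c("ATG", sample(mitocompare:::SENSE_CODONS, 98, TRUE),
                    "TAA"), collapse = "")
  g3 <- toy_genome("o3", paste0(rnd_seq(90), orf300, rnd_seq(90)),
                   circular = FALSE)
  expect_false(any(find_orfs(g3, min_len = 300)$nt_length == 300))
  expect_true(any(find_orfs(g3, min_len = 299)$nt_length == 300))
})

test_that("ORFs spanning the origin are found once with correct length", {
  set.seed(52)
  orf <- paste(c("ATG", sample(mitocompare:::SENSE_CODONS, 120, TRUE),
                 "TAA"), collapse = "")
  body <- rnd_seq(2000)
  # place the ORF so it wraps: last 150 bases at the genome start
  s <- paste0(substr(orf, nchar(orf) - 149, nchar(orf)), body,
              substr(orf, 1, nchar(orf) - 150))
  g <- toy_genome("c", s, circular = TRUE)
  o <- find_orfs(g, min_len = 300)
  hit <- o[o$nt_length == nchar(orf), ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 2150L)
  expect_gt(hit$end, genome_length(g))   # wraps
  expect_equal(hit$seq, orf)
})

test_that("ORF prediction matches exhaustive enumeration on random circles", {
  set.seed(53)
  for (i in 1:3) {
    s <- rnd_seq(3000)
    g <- toy_genome("r", s, circular = TRUE)
    mine <- find_orfs(g, min_len = 150)
    ref <- brute_orfs(s, min_len = 150, circular = TRUE)
    key <- function(d, nt) paste(d, nt)
    expect_setequal(key(mine$start, mine$nt_length),
                    key(ref$start, ref$nt))
  }
})

test_that("every predicted ORF translates cleanly", {
  set.seed(54)
  g <- toy_genome("t", rnd_seq(6000))
  o <- find_orfs(g, min_len = 150)
  for (i in seq_len(nrow(o))) {
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(o$seq[i])))
    expect_equal(nchar(aa), o$aa_length[i] + 1L)
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
    expect_equal(o$aa_length[i], o$nt_length[i] / 3 - 1)
  }
})

test_that("ORF ids follow the orf<aa> convention with letter suffixes", {
  expect_equal(name_orf(91), "orf91")
  expect_equal(name_orf(115, c("orf91", "orf115")), "orf115b")
  expect_equal(name_orf(115, c("orf115", "orf115b")), "orf115c")
})

test_that("specificity screen drops ORFs with a maintainer home", {
  set.seed(55)
  m <- rnd_seq(20000)
  orf_novel <- paste(c("ATG", sample(mitocompare:::SENSE_CODONS, 110, TRUE),
                       "TAA"), collapse = "")
  # CMS genome: maintainer backbone + a novel ORF insertion
  cms <- toy_genome("S", paste0(substr(m, 1, 10000), rnd_seq(300), orf_novel,
                                rnd_seq(300), substr(m, 10001, 20000)))
  mg <- toy_genome("M", m)
  sp <- screen_specific_orfs(cms, mg, min_len = 300)
  expect_true(any(sp$nt_length == nchar(orf_novel)))
  # every ORF fully shared with the maintainer is excluded
  verbatim <- find_orfs(cms, min_len = 300)
  shared_ids <- verbatim$id[verbatim$start > 11000]
  expect_false(any(sp$id %in% shared_ids & sp$start > 11000))
})

test_that("the 0.99 specificity boundary is strict", {
  set.seed(56)
  core <- paste(c("ATG", sample(mitocompare:::SENSE_CODONS, 98, TRUE),
                  "TAA"), collapse = "")   # 303 nt
  # maintainer carries a copy with 2 mismatches -> identity ~ 301/303 > 0.99
  core_mut <- core
  substr(core_mut, 150, 150) <- if (substr(core, 150, 150) == "A") "C" else "A"
  substr(core_mut, 160, 160) <- if (substr(core, 160, 160) == "A") "C" else "A"
  m <- paste0(rnd_seq(5000), core_mut, rnd_seq(5000))
  cms <- toy_genome("S", paste0(rnd_seq(4000), core, rnd_seq(4000)))
  sp <- screen_specific_orfs(cms, toy_genome("M", m), min_len = 300)
  expect_false(any(sp$nt_length == 303 &
                     abs(sp$start - 4000) < 50))   # 0.9934 >= 0.99: excluded
})

test_that("raising the similarity threshold never shrinks the specific set", {
  set.seed(57)
  m <- rnd_seq(15000)
  cms <- toy_genome("S", paste0(substr(m, 1, 8000), rnd_seq(2000),
                                substr(m, 8001, 15000)))
  mg <- toy_genome("M", m)
  orfs <- find_orfs(cms, min_len = 150)
  sizes <- vapply(c(0.90, 0.95, 0.99, 1.0), function(th)
    nrow(screen_specific_orfs(cms, mg, min_len = 150, sim_threshold = th,
                              orfs = orfs)), 0L)
  expect_true(all(diff(sizes) >= 0))
})

test_that("shared specific ORFs require reciprocal near-identity", {
  set.seed(58)
  mkorf <- function(n) paste(c("ATG", sample(mitocompare:::SENSE_CODONS, n,
                                             TRUE), "TAA"), collapse = "")
  shared <- mkorf(120); p1 <- mkorf(130); p2 <- mkorf(140)
  row <- function(id, seq) data.frame(id = id, start = 0L,
                                      end = nchar(seq), strand = "+",
                                      frame = 0L, nt_length = nchar(seq),
                                      aa_length = nchar(seq) / 3 - 1,
                                      seq = seq, stringsAsFactors = FALSE)
  s1 <- rbind(row("orf121", shared), row("orf131", p1))
  s2 <- rbind(row("orf121", shared), row("orf141", p2))
  sh <- shared_specific_orfs(list(s1, s2))
  expect_equal(sh$shared$id, "orf121")
  expect_equal(sh$shared$match_2, "orf121")
})
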