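test_that("substitution classification follows the standard genetic code", {
  expect_equal(classify_substitution("TAT", "TCT"), "nonsynonymous")  # Y->S
  expect_equal(classify_substitution("TCT", "TCC"), "synonymous")     # S->S
  expect_error(classify_substitution("ATG", "ATG"), "identical")
  expect_equal(classify_substitution("ANG", "ACG"), "unclassified")
})

test_that("classification agrees with independent translation on all pairs", {
  codons <- mitocompare:::SENSE_CODONS
  set.seed(71)
  pick <- sample(length(codons), 40)
  for (i in pick) for (j in sample(length(codons), 8)) {
    if (codons[i] == codons[j]) next
    aa_i <- seqinr::translate(strsplit(codons[i], "")[[1]])
    aa_j <- seqinr::translate(strsplit(codons[j], "")[[1]])
    expect_equal(classify_substitution(codons[i], codons[j]),
                 if (aa_i == aa_j) "synonymous" else "nonsynonymous")
  }
})

test_that("gene comparison reports codon-resolved events", {
  set.seed(72)
  cds <- paste(c("ATG", sample(mitocompare:::SENSE_CODONS, 200, TRUE),
                 "TAA"), collapse = "")
  # identical -> no events
  r0 <- compare_gene(cds, cds, gene = "x")
  expect_equal(nrow(r0$events), 0L)
  expect_equal(r0$length_a, r0$length_b)

  # one substitution at codon start 301 (codon 101)
  cds2 <- mitocompare:::set_codon(cds, 301, "TCT")
  cds1 <- mitocompare:::set_codon(cds, 301, "TAT")
  r1 <- compare_gene(cds1, cds2, gene = "x")
  expect_equal(nrow(r1$events), 1L)
  expect_equal(r1$events$position, 301)
  expect_equal(r1$events$codon_before, "tAt")
  expect_equal(r1$events$codon_after, "tCt")
  expect_equal(r1$events$synonymy, "nonsynonymous")

  # 90 bp deletion
  cds3 <- paste0(substr(cds, 1, 150), substr(cds, 241, nchar(cds)))
  r2 <- compare_gene(cds, cds3, gene = "x")
  del <- r2$events[r2$events$type == "deletion", ]
  expect_equal(nrow(del), 1L)
  expect_equal(del$length, 90L)
  expect_equal(r2$length_a - r2$length_b, 90L)
})

test_that("gene comparison is anti-symmetric", {
  set.seed(73)
  cds <- paste(c("ATG", sample(mitocompare:::SENSE_CODONS, 100, TRUE),
                 "TAA"), collapse = "")
  cds_del <- paste0(substr(cds, 1, 90), substr(cds, 121, nchar(cds)))
  f <- compare_gene(cds, cds_del)
  b <- compare_gene(cds_del, cds)
  expect_equal(f$length_a - f$length_b, -(b$length_a - b$length_b))
  expect_equal(f$events$type, "deletion")
  expect_equal(b$events$type, "insertion")
  expect_equal(f$events$length, b$events$length)
})

test_that("self-comparison of random CDSs is always empty", {
  set.seed(74)
  for (i in 1:5) {
    cds <- paste(c("ATG", sample(mitocompare:::SENSE_CODONS,
                                 sample(50:300, 1), TRUE), "TAA"),
                 collapse = "")
    expect_equal(nrow(compare_gene(cds, cds)$events), 0L)
  }
})

test_that("homolog matching pairs copies and reports singletons", {
  set.seed(75)
  cds <- paste(c("ATG", sample(mitocompare:::SENSE_CODONS, 80, TRUE), "TAA"),
               collapse = "")
  cdsB <- paste(c("ATG", sample(mitocompare:::SENSE_CODONS, 60, TRUE), "TAA"),
                collapse = "")
  L1 <- nchar(cds)
  gA <- toy_genome("A", paste0(rnd_seq(500), cds, rnd_seq(2500), cds,
                               rnd_seq(500), cdsB, rnd_seq(500)),
                   rbind(gene_row("nad3", 500, 500 + L1),
                         gene_row("nad3", 3000 + L1, 3000 + 2 * L1,
                                  part = "D2"),
                         gene_row("atp6", 3500 + 2 * L1,
                                  3500 + 2 * L1 + nchar(cdsB))))
  gB <- toy_genome("B", paste0(rnd_seq(800), cds, rnd_seq(800)),
                   gene_row("nad3", 800, 800 + L1))
  hm <- match_homologs(gA, gB)
  expect_equal(nrow(hm$pairs), 1L)
  expect_equal(hm$pairs$gene, "nad3")
  expect_equal(nrow(hm$a_only), 2L)       # nad3 extra copy + atp6
  expect_setequal(hm$a_only$gene, c("nad3", "atp6"))
  expect_equal(nrow(hm$b_only), 0L)
})

test_that("copy numbers merge exon parts and count D-labelled copies", {
  set.seed(76)
  gA <- toy_genome("A", rnd_seq(5000),
                   rbind(gene_row("nad2", 100, 400, "a"),
                         gene_row("nad2", 600, 900, "b"),
                         gene_row("atp9", 1500, 1725),
                         gene_row("atp9", 2000, 2225, "D2"),
                         gene_row("atp9", 2500, 2725, "D3")))
  gB <- toy_genome("B", rnd_seq(5000),
                   rbind(gene_row("nad2", 100, 400, "a"),
                         gene_row("atp9", 1500, 1725)))
  cn <- copy_numbers(list(gA, gB))
  expect_equal(unname(cn["nad2", ]), c(1L, 1L))    # parts are not copies
  expect_equal(unname(cn["atp9", ]), c(3L, 1L))    # D labels are
})

test_that("candidate intersection is plain set logic", {
  expect_equal(intersect_candidates(list(c("atp6", "cox2", "nad2", "rps4"),
                                         c("nad2", "atp6", "sdh3"))),
               c("atp6", "nad2"))
  expect_equal(intersect_candidates(list("a", "b")), character(0))
  expect_equal(intersect_candidates(list(c("x", "y"), c("y", "x"))),
               c("x", "y"))
})

test_that("edits on a reverse-strand gene round-trip through the genome", {
  set.seed(77)
  cds <- paste(c("ATG", sample(mitocompare:::SENSE_CODONS, 100, TRUE),
                 "TAA"), collapse = "")
  cds <- mitocompare:::set_codon(cds, 151, "TCT")
  L1 <- nchar(cds)
  g <- toy_genome("G", paste0(rnd_seq(1000), rc(cds), rnd_seq(1000)),
                  gene_row("atp6", 1000, 1000 + L1, strand = "-"))
  edits <- data.frame(gene = "atp6", type = "substitution", pos = 151L,
                      len = 3L, new = "TAT", stringsAsFactors = FALSE)
  g2 <- mitocompare:::apply_gene_edits(g, edits,
                                       list(atp6 = list(seq = cds)))
  rec <- compare_gene(cds, mitocompare:::gene_cds(g2, "atp6"), gene = "atp6")
  expect_equal(rec$events$position, 151)
  expect_equal(rec$events$codon_before, "tCt")
  expect_equal(rec$events$codon_after, "tAt")
})
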