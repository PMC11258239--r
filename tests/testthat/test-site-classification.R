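test_that("the coverage/mQv filter applies its thresholds at the boundary", {
  g <- read_genome(c(c1 = strrep("AT", 10)))
  sites <- make_sites("c1", c(1L, 3L, 5L), "+",
                      coverage = c(14L, 15L, 30L), mqv = c(30, 26, 25))
  f <- filter_sites(sites, 15, 25)
  # coverage >= 15 is inclusive; mQv > 25 is strict: (30, 25) fails
  expect_equal(f$pos, 3L)
  expect_equal(unname(attr(f, "removed")), c(1L, 1L))

  relaxed <- filter_sites(make_sites("c1", 7L, "+", coverage = 5L, mqv = 21), 5, 20)
  expect_equal(nrow(relaxed), 1L)

  expect_equal(nrow(filter_sites(sites[0, ], 15, 25)), 0L)
})

test_that("sites without an mQv pass or fail according to policy", {
  s <- make_sites("c1", 1L, "+", coverage = 20L, mqv = NA_real_)
  expect_equal(nrow(filter_sites(s, 15, 25, "pass")), 1L)
  expect_equal(nrow(filter_sites(s, 15, 25, "fail")), 0L)
})

test_that("ApT symmetry classification follows the dinucleotide pairing", {
  g <- read_genome(c(c1 = "AATT"))
  # plus A at 2 and minus A at 3 oppose each other in the central ApT
  both <- make_sites("c1", c(2L, 3L), c("+", "-"))
  sym <- classify_symmetry(filter_sites(both), g)
  expect_equal(sym$fraction_symmetric, 1)
  expect_equal(sym$pairs$class, "symmetric")

  one <- classify_symmetry(filter_sites(make_sites("c1", 2L, "+")), g)
  expect_equal(one$fraction_symmetric, 0)
  expect_equal(one$pairs$class, "hemi-watson")

  g2 <- read_genome(c(c1 = "AAAA"))
  non <- classify_symmetry(filter_sites(make_sites("c1", 3L, "+")), g2)
  expect_equal(non$sites$symmetry, "non-ApT")
  expect_equal(nrow(non$pairs), 0L)
})

test_that("symmetry classes partition the filtered sites exactly", {
  sim <- simulate_methylome("symmetric_clustered", seed = 9, contig_len = 5e4,
                            n_genes = 20, n_repeats = 5, with_5mc = FALSE)
  f <- filter_sites(sim$sites)
  sym <- classify_symmetry(f, sim$genome)
  counts <- table(sym$sites$symmetry)
  expect_equal(sum(counts), nrow(f))
  expect_equal(sym$n_symmetric_sites + sum(counts[c("hemi-watson", "hemi-crick")],
                                           na.rm = TRUE) +
                 sum(counts["non-ApT"], na.rm = TRUE), nrow(f))
})

test_that("context summaries center the site and measure the ApT fraction", {
  g <- read_genome(c(c1 = "GGGGGGATGGGGGGG"))
  s <- make_sites("c1", c(7L, 7L, 7L), "+")
  ms <- summarize_contexts(s, g)
  expect_equal(substr(ms$consensus, 7, 8), "AT")
  expect_equal(ms$apt_fraction, 1)
  expect_true(all(abs(colSums(ms$pfm) - 1) < 1e-12))

  # a minus-strand site whose reverse-complemented window equals the plus one
  g2 <- read_genome(c(c1 = "GGGGGGATGGGGGGCCCCCCATCCCCCCC"))
  s2 <- make_sites("c1", c(7L, 22L), c("+", "-"))
  ms2 <- summarize_contexts(s2, g2)
  expect_equal(ms2$pfm, summarize_contexts(make_sites("c1", c(7L, 7L), "+"), g2)$pfm)
})

test_that("the ApT fraction counts the +1 column", {
  set.seed(1)
  n <- 100
  seqs <- vapply(seq_len(n), function(i) {
    nxt <- if (i <= 97) "T" else "G"
    paste0("GGGGGGA", nxt, "GGGGG")
  }, "")
  g <- read_genome(stats::setNames(seqs, paste0("c", seq_len(n))))
  s <- make_sites(paste0("c", seq_len(n)), rep(7L, n), "+")
  ms <- summarize_contexts(s, g)
  expect_equal(ms$apt_fraction, 0.97)
})

test_that("sites too close to contig ends are skipped and counted", {
  g <- read_genome(c(c1 = "ATATATATATATATAT"))
  s <- make_sites("c1", c(1L, 7L), "+")
  ms <- summarize_contexts(s, g)
  expect_equal(ms$n_skipped, 1L)
  expect_equal(ms$n_sites, 1L)
  expect_error(summarize_contexts(make_sites("c1", 1L, "+"), g), "no usable sites")
})

test_that("the global 6mA level is a percentage of adenines on both strands", {
  g <- read_genome(c(c1 = "AATT"))
  expect_equal(global_6ma_level(make_sites("c1", 2L, "+"), g), 25)
  expect_equal(global_6ma_level(make_sites("c1", integer(), "+"), g), 0)
  all4 <- make_sites("c1", c(1L, 2L, 3L, 4L), c("+", "+", "-", "-"))
  expect_equal(global_6ma_level(all4, g), 100)
  expect_error(global_6ma_level(all4, read_genome(c(c1 = "GGCC"))), "no adenines")
})

test_that("the isoschizomer digest cuts by methylation state at GATC centers", {
  g <- read_genome(c(c1 = "NNGATCNN"))
  meth <- make_sites("c1", 4L, "+")
  none <- meth[0, ]
  # center cut between A and T of the 8-mer: fragments {4, 4}
  expect_equal(sort(digest_insilico(g, meth, "DpnI")$length), c(4L, 4L))
  expect_equal(digest_insilico(g, meth, "DpnII")$length, 8L)
  expect_equal(digest_insilico(g, none, "DpnI")$length, 8L)
  expect_equal(sort(digest_insilico(g, none, "DpnII")$length), c(4L, 4L))

  g2 <- read_genome(c(c1 = "AAAATTTT"))
  expect_equal(digest_insilico(g2, none, "DpnI")$length, 8L)
})

test_that("a minus-strand call on the GATC adenine also marks it methylated", {
  g <- read_genome(c(c1 = "NNGATCNN"))
  minus <- make_sites("c1", 5L, "-")  # T on plus = A on minus
  expect_equal(sort(digest_insilico(g, minus, "DpnI")$length), c(4L, 4L))
})

test_that("telomeric repeat runs are found on both strands with a unit minimum", {
  g <- read_genome(c(c1 = paste0("TTAGGGTTAGGG", strrep("C", 20), "CCCTAACCCTAA")))
  tel <- find_telomere_repeats(g)
  plus <- tel[tel$strand == "+", ]
  minus <- tel[tel$strand == "-", ]
  expect_equal(c(plus$start, plus$end), c(1L, 12L))
  expect_equal(plus$dist_to_end, 0L)
  expect_equal(c(minus$start, minus$end), c(33L, 44L))
  expect_equal(minus$dist_to_end, 0L)

  single <- find_telomere_repeats(read_genome(c(c1 = "TTAGGGCCCCCC")))
  expect_equal(nrow(single), 0L)
})
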