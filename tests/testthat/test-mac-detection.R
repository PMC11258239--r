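test_that("motif tracks enumerate AT occurrences and flag methylated ones", {
  g <- read_genome(c(c1 = "ATATAT"))
  tr <- motif_track(g, make_sites("c1", integer(), "+"))
  expect_equal(tr$start, c(1L, 3L, 5L))
  expect_false(any(tr$methylated))

  g2 <- read_genome(c(c1 = "AATT"))
  tr2 <- motif_track(g2, make_sites("c1", c(2L, 3L), c("+", "-")))
  expect_equal(tr2$start, 2L)
  expect_true(tr2$methylated)

  g3 <- read_genome(c(c1 = "GGCC"))
  expect_equal(nrow(motif_track(g3, make_sites("c1", integer(), "+"))), 0L)

  expect_error(motif_track(g, make_sites("c1", integer(), "+"), motif = "AX"),
               "ACGT")
})

test_that("clustering at a distance follows the worked chain example", {
  tr <- make_track(c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  # d = 1: the double gap breaks the chain; trailing methylated is a singleton
  cl1 <- cluster_at_distance(tr, 1)
  expect_equal(nrow(cl1), 1L)
  expect_equal(cl1$n_methylated, 2L)
  expect_equal(cl1$n_spanned, 3L)
  expect_equal(cl1$start, 1L)
  expect_equal(cl1$end, 6L)  # start of occurrence 3 (= 5) + motif len - 1

  # d = 2: one chain over all six occurrences
  cl2 <- cluster_at_distance(tr, 2)
  expect_equal(nrow(cl2), 1L)
  expect_equal(cl2$n_methylated, 3L)
  expect_equal(cl2$n_spanned, 6L)
  expect_equal(cl2$density, 0.5)

  expect_equal(nrow(cluster_at_distance(make_track(rep(FALSE, 5)), 3)), 0L)
  expect_error(cluster_at_distance(tr, 0), "d must be")
})

test_that("the distance scan scores recall x purity and breaks ties small", {
  tr <- make_track(c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  sc <- scan_distances(tr, 1:5)
  expect_equal(sc$table$recall[1], 2 / 3)
  expect_equal(sc$table$purity[1], 2 / 3)
  expect_equal(sc$table$score[1], 4 / 9)
  expect_equal(sc$table$recall[2], 1)
  expect_equal(sc$table$purity[2], 1 / 2)
  expect_equal(sc$table$score[2], 1 / 2)
  expect_equal(sc$d_star, 2L)

  dense <- scan_distances(make_track(c(TRUE, TRUE, TRUE)), 1:5)
  expect_true(all(dense$table$score == 1))
  expect_equal(dense$d_star, 1L)

  far <- make_track(c(TRUE, rep(FALSE, 41), TRUE))
  sc_far <- scan_distances(far, 1:40)
  expect_true(all(sc_far$table$n_clusters == 0))
  expect_true(all(sc_far$table$recall == 0))

  expect_error(scan_distances(make_track(c(FALSE, FALSE))), "nothing to cluster")
})

test_that("clustering matches brute-force enumeration on random tracks", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(5:200, 1)
    flags <- stats::runif(n) < stats::runif(1, 0.05, 0.6)
    tr <- make_track(flags)
    prev_recall <- -1
    for (d in 1:40) {
      got <- cluster_at_distance(tr, d)
      ora <- brute_force_clusters(flags, d)
      expect_equal(nrow(got), length(ora))
      if (length(ora) > 0) {
        starts <- tr$start[vapply(ora, function(v) v[1], 0L)]
        expect_equal(got$start, starts)
        expect_equal(got$n_methylated, lengths(ora))
      }
      if (sum(flags) > 0) {
        recall <- sum(got$n_methylated) / sum(flags)
        expect_gte(recall, prev_recall)
        prev_recall <- recall
      }
    }
  }
})

test_that("clusters nest as the distance grows (before the size filter)", {
  set.seed(7)
  for (i in 1:10) {
    flags <- stats::runif(80) < 0.3
    if (!any(flags)) next
    tr <- make_track(flags)
    for (d1 in c(1, 3, 7)) {
      c1 <- cluster_at_distance(tr, d1, min_methylated = 1)
      c2 <- cluster_at_distance(tr, d1 + sample(1:5, 1), min_methylated = 1)
      for (k in seq_len(nrow(c1))) {
        container <- c2$start <= c1$start[k] & c2$end >= c1$end[k]
        expect_equal(sum(container), 1L)
      }
    }
  }
})

test_that("detect_macs composes the scan and annotates the size range", {
  g <- read_genome(c(c1 = paste0(strrep("AT", 6), "GG")))
  sites <- make_sites("c1", c(1L, 5L, 11L), "+")
  res <- detect_macs(g, sites)
  expect_equal(res$scan$d_star, 2L)
  expect_equal(nrow(res$macs), 1L)
  expect_equal(res$macs$density, 0.5)
  expect_false(res$macs$in_size_range)  # 12 bp, below 50
  expect_equal(fraction_sites_in_macs(sites, res$macs), 1)
})

test_that("MACs are assigned to genes by strand-oriented TSS windows", {
  genes <- tibble::tibble(
    gene_id = c("gp", "gm"), contig = "c1", strand = c("+", "-"),
    start = c(1000L, 100L), end = c(2000L, 800L),
    tss = c(1000L, 800L), tts = c(2000L, 100L)
  )
  macs <- tibble::tibble(contig = "c1", start = 950L, end = 1099L,
                         n_methylated = 5L, n_spanned = 8L,
                         density = 5 / 8, size = 150L)
  asn <- assign_macs_to_genes(macs, genes)
  # plus gene window [850, 1400] overlaps; minus gene window [400, 950] just touches
  expect_true(asn$has_mac[asn$gene_id == "gp"])
  expect_true(asn$has_mac[asn$gene_id == "gm"])

  # a minus gene with TSS 800 and a MAC fully beyond its window
  macs2 <- tibble::tibble(contig = "c1", start = 960L, end = 1099L,
                          n_methylated = 5L, n_spanned = 8L,
                          density = 5 / 8, size = 140L)
  asn2 <- assign_macs_to_genes(macs2, genes)
  expect_false(asn2$has_mac[asn2$gene_id == "gm"])

  # the >= 10 methylated-motif rule used for dense-gene selection
  asn3 <- assign_macs_to_genes(macs, genes, min_sites = 10)
  expect_false(any(asn3$has_mac))
})
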