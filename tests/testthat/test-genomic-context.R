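make_gene <- function(id, contig, strand, start, end, exons = NULL) {
  tibble::tibble(
    gene_id = id, contig = contig, strand = strand,
    start = start, end = end,
    tss = if (strand == "+") start else end,
    tts = if (strand == "+") end else start,
    exons = list(exons %||% tibble::tibble(start = start, end = end)),
    utr5 = list(tibble::tibble(start = integer(), end = integer())),
    utr3 = list(tibble::tibble(start = integer(), end = integer()))
  )
}

test_that("the feature partition labels every base once with promoter truncation", {
  set.seed(3)
  g <- read_genome(c(c1 = paste(sample(c("A", "C", "G", "T"), 1000, TRUE),
                                collapse = "")))
  genes <- make_gene("g1", "c1", "+", 301L, 600L)
  p <- partition_features(g, genes)
  bases <- stats::setNames(p$summary$bases, p$summary$class)
  # promoter would be 600 bp but only 300 bp exist upstream
  expect_equal(unname(bases["exon"]), 300L)
  expect_equal(unname(bases["promoter"]), 300L)
  expect_equal(unname(bases["intergenic"]), 400L)
  expect_equal(sum(p$summary$bases), 1000L)

  # gene starting at the contig edge has a zero-length promoter
  p0 <- partition_features(g, make_gene("g1", "c1", "+", 1L, 300L))
  expect_equal(p0$summary$bases[p0$summary$class == "promoter"], 0L)

  # repeats lose to exons by precedence
  pr <- partition_features(g, genes,
                           repeats = tibble::tibble(contig = "c1",
                                                    start = 500L, end = 700L))
  basesr <- stats::setNames(pr$summary$bases, pr$summary$class)
  expect_equal(unname(basesr["exon"]), 300L)
  expect_equal(unname(basesr["repeat"]), 100L)  # only the part outside the gene
  expect_equal(sum(pr$summary$bases), 1000L)
})

test_that("partition completeness holds on a simulated genome", {
  sim <- simulate_methylome("symmetric_clustered", seed = 5, contig_len = 5e4,
                            n_genes = 20, n_repeats = 5, with_5mc = FALSE)
  p <- partition_features(sim$genome, sim$genes, sim$repeats)
  expect_identical(sum(p$summary$bases), genome_length(sim$genome))
})

test_that("enrichment is the composition-aware observed/expected ratio", {
  # 400 bp of pure A; a 40 bp single-exon gene at the start (promoter len 0)
  g <- read_genome(c(c1 = strrep("A", 400)))
  genes <- make_gene("g1", "c1", "+", 1L, 40L)
  p <- partition_features(g, genes)
  sites <- make_sites("c1", c(5L, 10L, 15L, 20L, 101L, 120L, 140L, 160L, 180L, 200L),
                      "+")
  e <- feature_enrichment(sites, p, g)
  ex <- e[e$class == "exon", ]
  expect_equal(ex$observed, 4)
  expect_equal(ex$expected, 1)  # 10 sites x 40/400 eligible adenines
  expect_equal(ex$log2fc, 2)
  # conservation: observed and expected both sum to the total sites
  expect_equal(sum(e$observed), 10)
  expect_equal(sum(e$expected), 10, tolerance = 1e-9)
  # classes with no eligible bases are undefined, not infinite
  expect_true(all(is.na(e$log2fc[e$eligible == 0])))
  expect_error(feature_enrichment(sites[0, ], p, g), "no sites")
})

test_that("uniformly planted sites show no feature enrichment", {
  sim <- simulate_methylome("symmetric_clustered", seed = 13, contig_len = 2e5,
                            n_genes = 80, n_repeats = 20, with_5mc = FALSE)
  g <- sim$genome
  p <- partition_features(g, sim$genes, sim$repeats)
  set.seed(99)
  s <- strsplit(as.character(g$seq[[1]]), "")[[1]]
  ad_plus <- which(s == "A"); ad_minus <- which(s == "T")
  all_ad <- tibble::tibble(
    pos = c(ad_plus, ad_minus),
    strand = rep(c("+", "-"), c(length(ad_plus), length(ad_minus)))
  )
  pick <- all_ad[sample.int(nrow(all_ad), 10000), ]
  sites <- make_sites("contig_1", pick$pos, pick$strand)
  e <- feature_enrichment(sites, p, g)
  e <- e[e$eligible > 500, ]  # classes large enough for the binomial bound
  expect_true(all(abs(e$log2fc) < 0.1))
})

test_that("metagene profiles scale bodies, keep flanks, and flip minus genes", {
  # sites only in the first 10% of a 1000 bp gene
  genes <- tibble::tibble(contig = "c1", start = 1001L, end = 2000L, strand = "+")
  sites <- make_sites("c1", seq(1001L, 1100L, by = 10L), "+")
  prof <- metagene_profile(sites, genes, n_body_bins = 20, n_flank_bins = 5)
  body <- prof$value[prof$section == "body"]
  expect_true(all(body[1:2] > 0))
  expect_true(all(body[3:20] == 0))
  expect_true(all(prof$value[prof$section != "body"] == 0))

  # a minus-strand mirror gene with mirrored sites contributes identically
  genes2 <- tibble::tibble(contig = "c1", start = 3001L, end = 4000L, strand = "-")
  sites2 <- make_sites("c1", seq(3901L, 4000L, by = 10L), "+")
  prof2 <- metagene_profile(sites2, genes2, n_body_bins = 20, n_flank_bins = 5)
  expect_equal(prof2$value, prof$value)

  # elements shorter than the body bin count are skipped and counted
  short <- tibble::tibble(contig = "c1", start = 1L, end = 10L, strand = "+")
  expect_error(metagene_profile(sites, short, n_body_bins = 20, n_flank_bins = 5),
               "shorter")
  both <- dplyr::bind_rows(genes, short)
  prof3 <- metagene_profile(sites, both, n_body_bins = 20, n_flank_bins = 5)
  expect_equal(attr(prof3, "n_skipped"), 1L)
})

test_that("uniform random sites give a flat metagene profile", {
  sim <- sym_fixture()
  set.seed(123)
  g <- sim$genome
  s <- strsplit(as.character(g$seq[[1]]), "")[[1]]
  ad <- which(s == "A" | s == "T")
  pos <- sample(ad, 10000)
  sites <- make_sites("contig_1", pos, ifelse(s[pos] == "A", "+", "-"))
  prof <- metagene_profile(sites, sim$genes[, c("contig", "start", "end", "strand")])
  m <- mean(prof$value)
  expect_true(all(abs(prof$value - m) / m < 0.5))
})

test_that("TSS-window counts use closed strand-oriented bounds", {
  genes <- dplyr::bind_rows(
    make_gene("gp", "c1", "+", 1000L, 2000L)[, 1:7],
    make_gene("gq", "c1", "+", 5000L, 6000L)[, 1:7]
  )
  sites <- make_sites("c1", c(900L, 1500L, 850L), "+")
  tc <- tss_window_counts(sites, genes)
  # window [850, 1400]: 900 and the boundary site 850 count; 1500 does not
  expect_equal(tc$n_sites[tc$gene_id == "gp"], 2L)
  expect_equal(tc$n_sites[tc$gene_id == "gq"], 0L)
  expect_equal(tc$n_macs, c(0L, 0L))
})
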