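test_that("expression stratification ranks, quartiles, and extracts sets", {
  ex <- tibble::tibble(gene_id = paste0("g", 1:8), abundance = 8:1)
  st <- stratify_expression(ex, n_top = 2)
  expect_equal(st$gene_id[st$quartile == "Q1"], c("g1", "g2"))
  expect_equal(st$gene_id[st$top_set], c("g1", "g2"))
  expect_equal(st$gene_id[st$bottom_set], c("g7", "g8"))

  silent <- tibble::tibble(gene_id = paste0("g", 1:8), abundance = 0)
  st0 <- stratify_expression(silent, 2)
  expect_true(all(st0$silent))
  # degenerate ties broken by gene id, deterministically
  expect_equal(st0$gene_id, sort(silent$gene_id))

  expect_warning(stratify_expression(ex, n_top = 10), "truncated")
})

test_that("stratification is invariant to monotone abundance transforms", {
  set.seed(8)
  ex <- tibble::tibble(gene_id = sprintf("g%03d", 1:100),
                       abundance = stats::rlnorm(100))
  a <- stratify_expression(ex, 10)
  b <- stratify_expression(dplyr::mutate(ex, abundance = abundance^3), 10)
  expect_equal(a$gene_id, b$gene_id)
  expect_equal(a$quartile, b$quartile)
})

test_that("per-stratum summaries join counts and report MAC proportions", {
  ex <- tibble::tibble(gene_id = sprintf("g%02d", 1:40),
                       abundance = 40:1)
  st <- stratify_expression(ex, 10)
  counts <- tibble::tibble(gene_id = ex$gene_id, n_sites = 3L,
                           n_macs = rep(c(1L, 0L), c(10, 30)))
  ms <- methylation_by_stratum(st, counts)
  expect_equal(ms$median, rep(3, 6))       # identical distributions everywhere
  expect_equal(ms$prop_with_mac[ms$stratum == "top"], 1)
  expect_equal(ms$prop_with_mac[ms$stratum == "bottom"], 0)

  none <- dplyr::mutate(counts, n_macs = 0L)
  ms0 <- methylation_by_stratum(st, none)
  expect_true(all(ms0$prop_with_mac == 0))
})

test_that("MAC-bearing proportions by stratum follow the planting design", {
  sim <- sym_fixture()
  run <- sym_run()
  st <- stratify_expression(sim$expression, 50)
  asn <- assign_macs_to_genes(run$macs$macs, sim$genes)
  ms <- methylation_by_stratum(st, dplyr::mutate(asn, n_sites = 0L))
  # clusters are planted preferentially into highly expressed genes
  expect_gt(ms$prop_with_mac[ms$stratum == "Q1"],
            ms$prop_with_mac[ms$stratum == "Q4"])
  expect_gt(ms$prop_with_mac[ms$stratum == "top"], 0.4)
})

test_that("MAC gain and loss labels are presence-based per gene", {
  genes <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"), contig = "c1", strand = "+",
    start = c(1000L, 3000L, 5000L, 7000L), end = c(1999L, 3999L, 5999L, 7999L),
    tss = c(1000L, 3000L, 5000L, 7000L), tts = c(1999L, 3999L, 5999L, 7999L)
  )
  mac <- function(st) tibble::tibble(contig = "c1", start = st, end = st + 99L,
                                     n_methylated = 5L, n_spanned = 8L,
                                     density = 5 / 8, size = 100L)
  macs_a <- dplyr::bind_rows(mac(1000L), mac(3000L), mac(3100L))
  macs_b <- dplyr::bind_rows(mac(3050L), mac(5000L))
  gl <- mac_gain_loss(macs_a, macs_b, genes)
  expect_equal(gl$status[gl$gene_id == "a"], "gained")
  expect_equal(gl$status[gl$gene_id == "b"], "stable")  # shifted but present
  expect_equal(gl$status[gl$gene_id == "c"], "lost")
  expect_equal(gl$status[gl$gene_id == "d"], "none")

  same <- mac_gain_loss(macs_a, macs_a, genes)
  expect_true(all(same$status %in% c("stable", "none")))
  expect_equal(sum(same$status == "gained"), 0L)
})

test_that("ratio shifts match sites across conditions and run Welch's test", {
  genes <- tibble::tibble(
    gene_id = c("u1", "d1"), contig = "c1", strand = "+",
    start = c(1000L, 5000L), end = c(1999L, 5999L),
    tss = c(1000L, 5000L), tts = c(1999L, 5999L)
  )
  pos_u <- seq(1000L, 1090L, 10L); pos_d <- seq(5000L, 5090L, 10L)
  a <- make_sites("c1", c(pos_u, pos_d), "+", coverage = 20L,
                  n_meth = c(rep(20L, 10), rep(10L, 10)))
  b <- make_sites("c1", c(pos_u, pos_d), "+", coverage = 20L, n_meth = 10L)
  rs <- ratio_shift_test(a, b, genes, list(up = "u1", down = "d1"))
  expect_equal(rs$per_set$mean_fold, c(2, 1))
  expect_true(rs$test$p < 1e-6)  # constant folds 2 vs 1

  # identical distributions: t = 0, p = 1
  rs0 <- ratio_shift_test(a, a, genes, list(up = "u1", down = "d1"))
  expect_equal(rs0$per_set$mean_fold, c(1, 1))
  expect_equal(rs0$test$t, 0)
  expect_equal(rs0$test$p, 1)

  # a site present in one condition only is excluded and counted
  a2 <- a[-1, ]
  rs2 <- ratio_shift_test(a2, b, genes, list(up = "u1", down = "d1"))
  expect_equal(rs2$per_set$n[1], 9L)
  expect_equal(rs2$per_set$n_unmatched[1], 1L)

  # sets with fewer than two matched sites yield a missing test
  rs3 <- ratio_shift_test(a[1, ], b, genes, list(up = "u1", down = "d1"))
  expect_true(is.na(rs3$test$p))
})

test_that("the Welch test agrees with the closed form", {
  set.seed(11)
  for (i in 1:20) {
    x <- stats::rnorm(sample(5:40, 1), sd = stats::runif(1, 0.5, 2))
    y <- stats::rnorm(sample(5:40, 1), mean = stats::runif(1, -1, 1))
    got <- sixmac:::welch_test(x, y)
    ora <- welch_oracle(x, y)
    expect_equal(got$t, ora$t, tolerance = 1e-10)
    expect_equal(got$df, ora$df, tolerance = 1e-10)
    expect_equal(got$p, ora$p, tolerance = 1e-10)
  }
})

test_that("term enrichment reproduces exact hypergeometric probabilities", {
  bg <- paste0("g", 1:10)
  sel <- bg[1:5]
  ann <- tibble::tibble(gene_id = bg[1:5], term = "T1")
  te <- term_enrichment(sel, bg, ann)
  expect_equal(te$p, 1 / choose(10, 5))
  expect_true(te$significant)

  # equal frequency in selection and background is not enriched
  ann2 <- tibble::tibble(gene_id = bg[c(1, 2, 6, 7)], term = "T2")
  te2 <- term_enrichment(sel, bg, ann2)
  expect_gte(te2$p, 0.5)

  # a term absent from the selection has p = 1 one-sided
  ann3 <- tibble::tibble(gene_id = bg[6:8], term = "T3")
  expect_equal(term_enrichment(sel, bg, ann3)$p, 1)

  expect_error(term_enrichment(character(), bg, ann), "empty")
  expect_error(term_enrichment("zz", bg, ann), "subset")
})

test_that("Fisher p-values equal exhaustive enumeration on small tables", {
  # enumeration oracle: P(X >= k) over all ways to choose the selection
  enum_p <- function(k, K, N, n) {
    total <- choose(N, n)
    sum(vapply(k:min(K, n), function(j) {
      choose(K, j) * choose(N - K, n - j)
    }, 0)) / total
  }
  bg <- paste0("g", 1:12)
  set.seed(2)
  for (i in 1:25) {
    n <- sample(1:11, 1)
    K <- sample(1:12, 1)
    sel <- sample(bg, n)
    with_term <- sample(bg, K)
    ann <- tibble::tibble(gene_id = with_term, term = "T")
    te <- term_enrichment(sel, bg, ann)
    k <- length(intersect(sel, with_term))
    if (nrow(te) == 1) {
      expect_equal(te$p, enum_p(k, K, 12, n), tolerance = 1e-12)
    }
  }
})
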