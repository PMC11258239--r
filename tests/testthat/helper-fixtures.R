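# Shared builders and oracles for the test suite. All fixtures are generated
# in code; nothing is read from disk.

# quick site-table builder; defaults give fully methylated, high-quality calls
make_sites <- function(contig, pos, strand, coverage = 20L, n_meth = coverage,
                       mqv = 30) {
  n <- length(pos)
  tibble::tibble(
    contig = rep_len(contig, n), pos = as.integer(pos),
    strand = rep_len(strand, n),
    coverage = as.integer(rep_len(coverage, n)),
    n_meth = as.integer(rep_len(n_meth, n)),
    mqv = rep_len(mqv, n)
  ) |> dplyr::mutate(ratio = n_meth / coverage)
}

# construct a motif_track directly from a methylation flag pattern;
# occurrence starts default to 1, 3, 5, ... as for a tandem AT array
make_track <- function(flags, starts = NULL, contig = "c1") {
  if (is.null(starts)) starts <- 2L * seq_along(flags) - 1L
  tr <- tibble::tibble(contig = contig, start = as.integer(starts),
                       methylated = as.logical(flags))
  tr <- structure(tr, class = c("motif_track", class(tr)))
  attr(tr, "motif") <- "AT"
  tr
}

# independent brute-force chain enumeration: walk methylated occurrences and
# chain while at most d unmethylated occurrences intervene
brute_force_clusters <- function(flags, d, min_methylated = 2) {
  meth <- which(flags)
  chains <- list()
  cur <- integer()
  for (m in meth) {
    if (length(cur) == 0 || m - cur[length(cur)] - 1 <= d) {
      cur <- c(cur, m)
    } else {
      chains[[length(chains) + 1]] <- cur
      cur <- m
    }
  }
  if (length(cur)) chains[[length(chains) + 1]] <- cur
  chains[lengths(chains) >= min_methylated]
}

# closed-form Welch statistic, df and two-sided p (independent of stats::t.test)
welch_oracle <- function(x, y) {
  m1 <- mean(x); m2 <- mean(y)
  v1 <- sum((x - m1)^2) / (length(x) - 1)
  v2 <- sum((y - m2)^2) / (length(y) - 1)
  se2 <- v1 / length(x) + v2 / length(y)
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (length(x)^2 * (length(x) - 1)) +
                 v2^2 / (length(y)^2 * (length(y) - 1)))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# memoised study-scale fixtures shared across acceptance tests
.fixture_cache <- new.env(parent = emptyenv())

sym_fixture <- function() {
  if (is.null(.fixture_cache$sym)) {
    .fixture_cache$sym <- simulate_methylome("symmetric_clustered", seed = 4242,
                                             with_5mc = FALSE)
  }
  .fixture_cache$sym
}

asym_fixture <- function() {
  if (is.null(.fixture_cache$asym)) {
    .fixture_cache$asym <- simulate_methylome("asymmetric_scattered", seed = 2424,
                                              with_5mc = FALSE)
  }
  .fixture_cache$asym
}

sym_run <- function() {
  if (is.null(.fixture_cache$sym_run)) {
    sim <- sym_fixture()
    .fixture_cache$sym_run <- characterize_methylome(sim$genome, sim$genes,
                                                     sim$sites,
                                                     expression = sim$expression)
  }
  .fixture_cache$sym_run
}
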