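#' Parameters for a synthetic 6mA regime
#'
#' Bundles the statistical structure of one methylation regime. Two presets
#' reflect the two extremes observed in Mucorales methylomes:
#' `"symmetric_clustered"` (high global level, ~92% of sites in symmetric ApT
#' pairs, concentrated in clusters of 50-500 bp starting within 150 bp
#' downstream of the TSS of preferentially highly expressed genes, per-site
#' ratio near 1) and `"asymmetric_scattered"` (low global level, ~0.3%
#' symmetric, sites scattered over adenines with an AAA_CA-biased flanking
#' context, ratio near 0.5).
#'
#' The generator targets the post-filter methylation level: it knows the
#' downstream filter policy (`filter_min_coverage`, `filter_min_mqv`) and
#' plants proportionally more sites so that the sites surviving the coverage/
#' quality filter hit `level_pct` in expectation. Coverage and mQv are drawn
#' once per adenine locus and shared by the two strands of an ApT pair, as in
#' real data where local sequencing depth is shared, so filtering removes
#' whole pairs and preserves the symmetric fraction.
#'
#' @param mode `"symmetric_clustered"` or `"asymmetric_scattered"`.
#' @param level_pct Target post-filter global 6mA level, percent of adenines.
#' @param symmetric_fraction Target fraction of sites in symmetric ApT pairs.
#' @param in_cluster_fraction Target fraction of sites inside clusters
#'   (symmetric mode only).
#' @param cluster_size_range Cluster span range in bp.
#' @param cluster_offset_range Cluster start offset downstream of the TSS, bp.
#' @param max_internal_gap Maximum unmethylated AT motifs between consecutive
#'   methylated motifs within a planted cluster.
#' @param internal_gap_probs Probabilities of internal gaps `0:max_internal_gap`.
#'   The default makes clusters dense runs in which most consecutive
#'   methylated motifs are adjacent, mirroring the near-saturated clusters of
#'   the high-6mA regime; dense clusters are also robust to coverage dropout,
#'   since losing one locus opens a gap of only one motif.
#' @param min_cluster_motifs Minimum methylated motifs for a planted cluster;
#'   genes whose drawn span holds fewer AT motifs are skipped. Keeps planted
#'   clusters large enough to be recoverable under coverage dropout.
#' @param plant_prob Named per-quartile probability that a gene receives a
#'   cluster (Q1 = most expressed).
#' @param ratio_shape Beta(a, b) parameters of the per-site methylation ratio.
#' @param coverage_mean,coverage_dispersion Negative binomial coverage model
#'   (mean and size).
#' @param mqv_mean,mqv_sd Normal model of the modification quality value.
#' @param context_pwm For the asymmetric mode, a 4 x 6 matrix (rows A,C,G,T;
#'   columns -3,-2,-1,+1,+2,+3) of flanking-base weights used to place sites.
#' @param filter_min_coverage,filter_min_mqv The filter policy the generator
#'   compensates for.
#' @return A list of class `regime_params`.
#' @export
regime_params <- function(mode = c("symmetric_clustered", "asymmetric_scattered"),
                          level_pct = NULL,
                          symmetric_fraction = NULL,
                          in_cluster_fraction = 0.92,
                          cluster_size_range = c(50, 500),
                          cluster_offset_range = c(0, 150),
                          max_internal_gap = 1,
                          internal_gap_probs = c(0.85, 0.15),
                          min_cluster_motifs = 5,
                          plant_prob = c(Q1 = 0.7, Q2 = 0.5, Q3 = 0.3, Q4 = 0.1),
                          ratio_shape = NULL,
                          coverage_mean = 30, coverage_dispersion = 5,
                          mqv_mean = 40, mqv_sd = 4,
                          context_pwm = NULL,
                          filter_min_coverage = 15, filter_min_mqv = 25) {
  mode <- match.arg(mode)
  if (is.null(level_pct)) {
    level_pct <- if (mode == "symmetric_clustered") 1.1 else 0.26
  }
  if (is.null(symmetric_fraction)) {
    symmetric_fraction <- if (mode == "symmetric_clustered") 0.92 else 0.003
  }
  if (is.null(ratio_shape)) {
    ratio_shape <- if (mode == "symmetric_clustered") c(60, 2) else c(20, 20)
  }
  if (is.null(context_pwm)) context_pwm <- default_context_pwm()
  stopifnot(level_pct > 0, symmetric_fraction >= 0, symmetric_fraction <= 1,
            in_cluster_fraction >= 0, in_cluster_fraction <= 1)
  structure(
    list(mode = mode, level_pct = level_pct,
         symmetric_fraction = symmetric_fraction,
         in_cluster_fraction = in_cluster_fraction,
         cluster_size_range = cluster_size_range,
         cluster_offset_range = cluster_offset_range,
         max_internal_gap = max_internal_gap,
         internal_gap_probs = internal_gap_probs,
         min_cluster_motifs = min_cluster_motifs,
         plant_prob = plant_prob, ratio_shape = ratio_shape,
         coverage_mean = coverage_mean, coverage_dispersion = coverage_dispersion,
         mqv_mean = mqv_mean, mqv_sd = mqv_sd,
         context_pwm = context_pwm,
         filter_min_coverage = filter_min_coverage,
         filter_min_mqv = filter_min_mqv),
    class = "regime_params"
  )
}

# Flanking-base weights for the asymmetric mode: favors an AAA_CA-like
# context (A-rich 5' flank, C/G-biased +1) while remaining degenerate enough
# to yield IUPAC-degenerate consensus codes.
default_context_pwm <- function() {
  m <- cbind(
    `-3` = c(0.55, 0.15, 0.20, 0.10),
    `-2` = c(0.60, 0.13, 0.17, 0.10),
    `-1` = c(0.60, 0.12, 0.18, 0.10),
    `+1` = c(0.20, 0.60, 0.15, 0.05),
    `+2` = c(0.50, 0.20, 0.20, 0.10),
    `+3` = c(0.25, 0.25, 0.25, 0.25)
  )
  rownames(m) <- c("A", "C", "G", "T")
  m
}

# probability a locus survives the (coverage, mQv) filter
filter_pass_prob <- function(params) {
  p_cov <- stats::pnbinom(params$filter_min_coverage - 1,
                          size = params$coverage_dispersion,
                          mu = params$coverage_mean, lower.tail = FALSE)
  # mQv is rounded from a normal; > threshold with continuity correction
  p_mqv <- stats::pnorm(params$filter_min_mqv + 0.5, params$mqv_mean,
                        params$mqv_sd, lower.tail = FALSE)
  p_cov * p_mqv
}

#' Generate a synthetic genome with gene models and repeats
#'
#' Bases are i.i.d. at the requested GC content. Genes (1-5 exons, random
#' strand) are laid out left to right with random intergenic gaps; repeats
#' are interspersed in gaps that can hold them. The layout is checked for
#' feasibility before any sequence is drawn, and the whole construction is
#' deterministic under the seed.
#'
#' @param n_contigs Number of contigs.
#' @param contig_len Length of each contig in bp.
#' @param n_genes,n_repeats Total genes and repeats, split evenly over contigs.
#' @param gc GC content in (0, 1).
#' @param seed Integer seed (mandatory).
#' @return List with `genome` (a `genome_index`), `genes` (gene models
#'   tibble), `repeats` (tibble), and `layout_truth` (per-gene layout).
#' @export
simulate_genome <- function(n_contigs = 1, contig_len = 5e5, n_genes = 200,
                            n_repeats = 50, gc = 0.4, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  gene_len_range <- c(1200L, 2200L)
  gap_range <- c(300L, 700L)
  repeat_len_range <- c(200L, 800L)
  need <- n_genes / n_contigs * (mean(gene_len_range) + mean(gap_range))
  if (need > 0.97 * contig_len) {
    stop("infeasible layout: ", n_genes, " genes do not fit in ",
         n_contigs, " x ", contig_len, " bp")
  }

  contig_names <- sprintf("contig_%d", seq_len(n_contigs))
  genes_per <- diff(round(seq(0, n_genes, length.out = n_contigs + 1)))
  reps_per <- diff(round(seq(0, n_repeats, length.out = n_contigs + 1)))

  all_genes <- list(); all_reps <- list(); seqs <- character(n_contigs)
  gid <- 0L
  for (ci in seq_len(n_contigs)) {
    ct <- contig_names[ci]
    # gene layout
    pos <- sample(gap_range[1]:gap_range[2], 1)
    g_start <- integer(); g_end <- integer()
    for (k in seq_len(genes_per[ci])) {
      len <- sample(gene_len_range[1]:gene_len_range[2], 1)
      if (pos + len - 1 > contig_len - gap_range[1]) {
        stop("infeasible layout on ", ct, ": gene ", k, " of ", genes_per[ci],
             " does not fit")
      }
      g_start <- c(g_start, pos); g_end <- c(g_end, pos + len - 1L)
      pos <- pos + len + sample(gap_range[1]:gap_range[2], 1)
    }
    ng <- length(g_start)
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    ids <- sprintf("gene_%04d", gid + seq_len(ng))
    gid <- gid + ng

    # exon structure
    exons <- vector("list", ng)
    for (k in seq_len(ng)) {
      len <- g_end[k] - g_start[k] + 1L
      n_ex <- sample(1:5, 1)
      intr <- if (n_ex > 1) sample(50:150, n_ex - 1, replace = TRUE) else integer()
      ex_total <- len - sum(intr)
      if (ex_total < 100L * n_ex) { n_ex <- 1L; intr <- integer(); ex_total <- len }
      w <- stats::runif(n_ex)
      ex_len <- floor(w / sum(w) * (ex_total - 100L * n_ex)) + 100L
      ex_len[n_ex] <- ex_total - sum(ex_len[-n_ex])
      starts <- g_start[k] + cumsum(c(0L, utils::head(ex_len, -1) + intr))
      exons[[k]] <- tibble::tibble(start = as.integer(starts),
                                   end = as.integer(starts + ex_len - 1L))
    }

    genes <- tibble::tibble(
      gene_id = ids, contig = ct, strand = strand,
      start = g_start, end = g_end,
      tss = ifelse(strand == "+", g_start, g_end),
      tts = ifelse(strand == "+", g_end, g_start),
      exons = exons,
      utr5 = replicate(ng, tibble::tibble(start = integer(), end = integer()),
                       simplify = FALSE),
      utr3 = replicate(ng, tibble::tibble(start = integer(), end = integer()),
                       simplify = FALSE)
    )
    all_genes[[ci]] <- genes

    # repeats in gaps that can hold them
    gap_lo <- c(1L, g_end + 1L)
    gap_hi <- c(g_start - 1L, contig_len)
    gap_len <- gap_hi - gap_lo + 1L
    ok <- which(gap_len >= repeat_len_range[1] + 100L)
    chosen <- if (length(ok) >= reps_per[ci]) sample(ok, reps_per[ci]) else ok
    reps <- purrr::map(chosen, function(gk) {
      rl <- min(sample(repeat_len_range[1]:repeat_len_range[2], 1), gap_len[gk] - 50L)
      rs <- gap_lo[gk] + sample.int(gap_len[gk] - rl + 1L, 1) - 1L
      tibble::tibble(contig = ct, start = as.integer(rs),
                     end = as.integer(rs + rl - 1L))
    }) |> dplyr::bind_rows()
    if (nrow(reps) > 0) reps$name <- sprintf("repeat_%s_%d", ct, seq_len(nrow(reps)))
    all_reps[[ci]] <- reps

    # sequence: i.i.d. bases at the requested GC
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs[ci] <- paste(sample(names(p), contig_len, replace = TRUE, prob = p),
                      collapse = "")
  }
  names(seqs) <- contig_names
  genes <- dplyr::bind_rows(all_genes)
  list(
    genome = read_genome(seqs),
    genes = genes,
    repeats = dplyr::bind_rows(all_reps),
    layout_truth = genes[, c("gene_id", "contig", "strand", "start", "end", "tss")]
  )
}

#' Simulate a per-gene expression table
#'
#' Log-normal FPKM values with a configurable fraction of silent
#' (zero-abundance) genes.
#'
#' @param genes Gene models tibble.
#' @param seed Integer seed.
#' @param meanlog,sdlog Log-normal parameters.
#' @param frac_silent Fraction of genes set to zero abundance.
#' @return Tibble `gene_id`, `abundance`.
#' @export
simulate_expression <- function(genes, seed, meanlog = 2, sdlog = 1.5,
                                frac_silent = 0.05) {
  set.seed(seed)
  n <- nrow(genes)
  ab <- stats::rlnorm(n, meanlog, sdlog)
  ab[sample.int(n, round(frac_silent * n))] <- 0
  tibble::tibble(gene_id = genes$gene_id, abundance = ab)
}

# AT occurrence starts per contig (non-overlapping, left-to-right)
at_starts <- function(genome) {
  out <- lapply(genome$contigs$contig, function(ct) {
    m <- gregexpr("AT", as.character(genome$seq[[ct]]), fixed = TRUE)[[1]]
    if (m[1] == -1) integer() else as.integer(m)
  })
  names(out) <- genome$contigs$contig
  out
}

# draw locus-level coverage and mQv
draw_locus_depth <- function(n, params) {
  list(
    coverage = pmax(1L, stats::rnbinom(n, size = params$coverage_dispersion,
                                       mu = params$coverage_mean)),
    mqv = round(stats::rnorm(n, params$mqv_mean, params$mqv_sd))
  )
}

#' Plant 6mA sites on a genome under a regime
#'
#' Symmetric/clustered mode: genes are selected with per-expression-quartile
#' probabilities and receive one cluster of fully symmetric methylated ApT
#' pairs starting within `cluster_offset_range` bp downstream of the TSS,
#' spanning a random size in `cluster_size_range`, with at most
#' `max_internal_gap` unmethylated AT motifs between consecutive methylated
#' ones; asymmetric background sites at non-ApT adenines make up the
#' remaining `1 - in_cluster_fraction` of sites. Planting stops when the site
#' budget implied by `level_pct` is met; if the per-quartile selection cannot
#' meet it, further genes are drafted, and an error reports the achievable
#' maximum if the whole gene set is insufficient.
#'
#' Asymmetric/scattered mode: single-strand sites are drawn over adenines
#' with flanking-context weights (`context_pwm`) favoring the AAA_CA-like
#' pattern, plus the small number of symmetric ApT pairs implied by
#' `symmetric_fraction`.
#'
#' @param genome A `genome_index`.
#' @param genes Gene models tibble.
#' @param expression Expression tibble (`gene_id`, `abundance`).
#' @param params A `regime_params`.
#' @param seed Integer seed.
#' @return List with `sites` (canonical site tibble, unfiltered) and `truth`
#'   (planted clusters with planted and detectable spans, per-site flags,
#'   parameters, and expected recovery statistics).
#' @export
plant_6ma <- function(genome, genes, expression, params, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  p_pass <- filter_pass_prob(params)
  n_post <- round(params$level_pct / 100 * genome$n_adenines)
  n_pre <- round(n_post / p_pass)
  if (n_post > genome$n_adenines) {
    stop("target level ", params$level_pct, "% exceeds the adenine content; ",
         "achievable maximum is 100%")
  }
  occs <- at_starts(genome)

  if (params$mode == "symmetric_clustered") {
    res <- plant_symmetric(genome, genes, expression, params, n_pre, occs)
  } else {
    res <- plant_asymmetric(genome, params, n_pre, occs)
  }
  sites <- res$sites

  # locus-level depth: one coverage/mQv draw per (contig, locus) shared by
  # both strands of a pair
  locus <- paste(sites$contig, sites$locus)
  ul <- !duplicated(locus)
  depth <- draw_locus_depth(sum(ul), params)
  li <- match(locus, locus[ul])
  sites$coverage <- depth$coverage[li]
  sites$mqv <- depth$mqv[li]
  ratio <- stats::rbeta(nrow(sites), params$ratio_shape[1], params$ratio_shape[2])
  sites$n_meth <- pmax(1L, as.integer(round(sites$coverage * ratio)))
  sites$ratio <- sites$n_meth / sites$coverage
  sites$passes_filter <- sites$coverage >= params$filter_min_coverage &
    sites$mqv > params$filter_min_mqv

  out_sites <- dplyr::arrange(
    sites[, c("contig", "pos", "strand", "coverage", "n_meth", "mqv", "ratio")],
    .data$contig, .data$pos, .data$strand
  )

  clusters <- res$clusters
  if (!is.null(clusters) && nrow(clusters) > 0) {
    # detectable span: restricted to motif loci predicted to survive the filter
    det <- sites[sites$in_cluster & sites$passes_filter & sites$strand == "+", ]
    spans <- det |>
      dplyr::group_by(.data$cluster_id) |>
      dplyr::summarize(det_start = min(.data$pos), det_end = max(.data$pos) + 1L,
                       n_detectable = dplyr::n(), .groups = "drop")
    clusters <- dplyr::left_join(clusters, spans, by = "cluster_id")
    clusters$n_detectable[is.na(clusters$n_detectable)] <- 0L
  }

  truth <- list(
    params = params,
    n_planted = nrow(sites),
    n_expected_post_filter = n_post,
    pass_prob = p_pass,
    clusters = clusters,
    site_truth = sites[, c("contig", "pos", "strand", "in_cluster",
                           "cluster_id", "symmetric", "passes_filter")],
    planted_symmetric_fraction = mean(sites$symmetric),
    planted_in_cluster_fraction = mean(sites$in_cluster)
  )
  list(sites = out_sites, truth = truth)
}

# --- symmetric/clustered planting ------------------------------------------

plant_symmetric <- function(genome, genes, expression, params, n_pre, occs) {
  f_cl <- params$in_cluster_fraction
  n_cluster_target <- round(f_cl * n_pre)

  strata <- stratify_expression(expression,
                                n_top = max(1, min(400, nrow(expression) %/% 2)))
  prob <- params$plant_prob[strata$quartile]
  selected <- strata$gene_id[stats::runif(nrow(strata)) < prob]
  reserve <- setdiff(strata$gene_id, selected)
  order_sel <- sample(selected)
  order_res <- sample(reserve)
  queue <- c(order_sel, order_res)
  n_primary <- length(order_sel)

  glook <- genes[match(queue, genes$gene_id), ]
  lens <- stats::setNames(genome$contigs$length, genome$contigs$contig)

  rows <- list(); cl_rows <- list()
  total <- 0L; cl_id <- 0L; n_used <- 0L
  for (i in seq_len(nrow(glook))) {
    if (total >= n_cluster_target) break
    g <- glook[i, ]
    off <- sample(params$cluster_offset_range[1]:params$cluster_offset_range[2], 1)
    span <- sample(params$cluster_size_range[1]:params$cluster_size_range[2], 1)
    if (g$strand == "+") {
      lo <- g$tss + off; hi <- min(lens[[g$contig]] - 1L, g$tss + off + span - 1L)
    } else {
      hi <- g$tss - off - 1L; lo <- max(1L, g$tss - off - span)
    }
    oc <- occs[[g$contig]]
    oc <- oc[oc >= lo & oc + 1L <= hi]
    if (length(oc) < 2) next
    # walk: methylate, then skip a random internal gap of unmethylated motifs
    take <- integer(); j <- 1L
    while (j <= length(oc)) {
      take <- c(take, j)
      j <- j + 1L + sample(0:params$max_internal_gap, 1,
                           prob = params$internal_gap_probs)
    }
    if (length(take) < max(2, params$min_cluster_motifs)) next
    pos_w <- oc[take]
    cl_id <- cl_id + 1L
    n_new <- 2L * length(take)
    rows[[cl_id]] <- tibble::tibble(
      contig = g$contig,
      pos = c(pos_w, pos_w + 1L),
      strand = rep(c("+", "-"), each = length(take)),
      locus = rep(pos_w, 2L),
      in_cluster = TRUE, cluster_id = cl_id, symmetric = TRUE
    )
    cl_rows[[cl_id]] <- tibble::tibble(
      cluster_id = cl_id, gene_id = g$gene_id, contig = g$contig,
      start = min(pos_w), end = max(pos_w) + 1L,
      n_motifs = length(take), n_sites = n_new,
      primary_selection = i <= n_primary
    )
    total <- total + n_new
    n_used <- n_used + 1L
  }
  if (total < 0.9 * n_cluster_target) {
    stop("target level unreachable: planted ", total, " cluster sites of ",
         n_cluster_target, " needed; achievable maximum level is about ",
         signif(params$level_pct * total / n_cluster_target, 3), "%")
  }
  clusters <- dplyr::bind_rows(cl_rows)
  site_rows <- dplyr::bind_rows(rows)

  # asymmetric background at non-ApT adenines outside cluster spans
  n_bg <- round(total * (1 - f_cl) / f_cl)
  bg <- sample_background(genome, n_bg, clusters)
  site_rows <- dplyr::bind_rows(site_rows, bg)
  list(sites = site_rows, clusters = clusters)
}

# sample n background adenines: outside cluster spans, not part of an ApT
sample_background <- function(genome, n, clusters, exclude = NULL) {
  if (n <= 0) {
    return(tibble::tibble(contig = character(), pos = integer(),
                          strand = character(), locus = integer(),
                          in_cluster = logical(), cluster_id = integer(),
                          symmetric = logical()))
  }
  cand <- purrr::map(genome$contigs$contig, function(ct) {
    s <- strsplit(as.character(genome$seq[[ct]]), "")[[1]]
    L <- length(s)
    nxt <- c(s[-1], "N"); prv <- c("N", s[-L])
    plus <- which(s == "A" & nxt != "T")
    minus <- which(s == "T" & prv != "A")
    cl <- clusters[clusters$contig == ct, , drop = FALSE]
    in_span <- function(p) {
      if (nrow(cl) == 0) return(rep(FALSE, length(p)))
      IRanges::overlapsAny(IRanges::IRanges(p, p),
                           IRanges::IRanges(cl$start, cl$end))
    }
    plus <- plus[!in_span(plus)]
    minus <- minus[!in_span(minus)]
    tibble::tibble(
      contig = ct,
      pos = c(plus, minus),
      strand = rep(c("+", "-"), c(length(plus), length(minus)))
    )
  }) |> dplyr::bind_rows()
  if (!is.null(exclude)) {
    cand <- dplyr::anti_join(cand, exclude, by = c("contig", "pos", "strand"))
  }
  if (nrow(cand) < n) stop("not enough background adenines available")
  pick <- cand[sample.int(nrow(cand), n), ]
  pick$locus <- pick$pos
  pick$in_cluster <- FALSE
  pick$cluster_id <- NA_integer_
  pick$symmetric <- FALSE
  pick
}

# --- asymmetric/scattered planting -----------------------------------------

plant_asymmetric <- function(genome, params, n_pre, occs) {
  n_pairs <- round(params$symmetric_fraction * n_pre / 2)
  n_single <- n_pre - 2L * n_pairs

  # symmetric pairs at random ApT occurrences
  pair_rows <- NULL
  if (n_pairs > 0) {
    all_occ <- purrr::imap(occs, function(v, ct) {
      tibble::tibble(contig = ct, start = v)
    }) |> dplyr::bind_rows()
    pk <- all_occ[sample.int(nrow(all_occ), n_pairs), ]
    pair_rows <- tibble::tibble(
      contig = rep(pk$contig, 2L),
      pos = c(pk$start, pk$start + 1L),
      strand = rep(c("+", "-"), each = n_pairs),
      locus = rep(pk$start, 2L),
      in_cluster = FALSE, cluster_id = NA_integer_, symmetric = TRUE
    )
  }

  # context-weighted single-strand sites
  pwm <- params$context_pwm
  singles <- purrr::map(genome$contigs$contig, function(ct) {
    s <- strsplit(as.character(genome$seq[[ct]]), "")[[1]]
    L <- length(s)
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    weight_at <- function(p, strand) {
      w <- rep(1, length(p))
      for (k in seq_len(6)) {
        off <- c(-3, -2, -1, 1, 2, 3)[k]
        b <- if (strand == "+") s[p + off] else comp[s[p - off]]
        wk <- pwm[, k][b]
        wk[is.na(wk)] <- 0
        w <- w * wk
      }
      w
    }
    plus <- which(s == "A"); plus <- plus[plus > 3 & plus <= L - 3]
    minus <- which(s == "T"); minus <- minus[minus > 3 & minus <= L - 3]
    tibble::tibble(
      contig = ct,
      pos = c(plus, minus),
      strand = rep(c("+", "-"), c(length(plus), length(minus))),
      w = c(weight_at(plus, "+"), weight_at(minus, "-"))
    )
  }) |> dplyr::bind_rows()
  if (!is.null(pair_rows)) {
    singles <- dplyr::anti_join(singles, pair_rows,
                                by = c("contig", "pos", "strand"))
  }
  if (nrow(singles) < n_single) {
    stop("target level unreachable: only ", nrow(singles),
         " candidate adenines for ", n_single, " sites")
  }
  pk <- singles[sample.int(nrow(singles), n_single, prob = singles$w), ]
  single_rows <- tibble::tibble(
    contig = pk$contig, pos = pk$pos, strand = pk$strand, locus = pk$pos,
    in_cluster = FALSE, cluster_id = NA_integer_, symmetric = FALSE
  )
  list(sites = dplyr::bind_rows(pair_rows, single_rows), clusters = NULL)
}

# --- 5mC and expression -----------------------------------------------------

#' Plant 5mC methylation and couple it to expression
#'
#' Repeats receive high CG methylation (and moderate CHH, low CHG), emulating
#' repeat-targeted cytosine methylation; gene bodies receive methylation that
#' increases as expression decreases (the most expressed genes are nearly
#' unmethylated); the intergenic background is near zero. Read counts are
#' binomial at the planted per-site level under a negative binomial coverage
#' model.
#'
#' @param genome A `genome_index`.
#' @param genes Gene models tibble.
#' @param repeats Repeat tibble.
#' @param expression Expression tibble (`gene_id`, `abundance`); generated
#'   with [simulate_expression()] if NULL.
#' @param seed Integer seed.
#' @param repeat_levels Named levels for repeats, per context.
#' @param gene_max_levels Named maximum gene-body levels, per context (scaled
#'   by the gene's expression rank percentile, 0 for the most expressed).
#' @param background_level Level outside repeats and genes.
#' @param coverage_mean,coverage_dispersion Coverage model.
#' @return List with `cytosines` (CX-style tibble), `expression`, and `truth`
#'   (per-element planted levels).
#' @export
plant_5mc <- function(genome, genes, repeats, expression = NULL, seed,
                      repeat_levels = c(CG = 0.8, CHG = 0.1, CHH = 0.3),
                      gene_max_levels = c(CG = 0.4, CHG = 0.05, CHH = 0.15),
                      background_level = 0.01,
                      coverage_mean = 30, coverage_dispersion = 5) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  if (is.null(expression)) expression <- simulate_expression(genes, seed = seed + 1L)
  # expression rank percentile: 0 = most expressed -> unmethylated
  ord <- order(-expression$abundance, expression$gene_id)
  pct <- stats::setNames((seq_along(ord) - 1) / max(1, length(ord) - 1),
                         expression$gene_id[ord])

  rows <- purrr::map(genome$contigs$contig, function(ct) {
    s <- strsplit(as.character(genome$seq[[ct]]), "")[[1]]
    L <- length(s)
    ctx_p <- context_of(s, "+"); ctx_m <- context_of(s, "-")
    tab <- dplyr::bind_rows(
      tibble::tibble(pos = which(!is.na(ctx_p)), strand = "+",
                     context = ctx_p[!is.na(ctx_p)]),
      tibble::tibble(pos = which(!is.na(ctx_m)), strand = "-",
                     context = ctx_m[!is.na(ctx_m)])
    )
    tab$contig <- ct

    # region labels: repeat > gene > background
    region <- rep.int(0L, L)  # 0 background, -1 repeat, k = gene row
    gsub <- which(genes$contig == ct)
    for (k in gsub) region[genes$start[k]:genes$end[k]] <- k
    rsub <- repeats[repeats$contig == ct, , drop = FALSE]
    if (nrow(rsub) > 0) {
      for (k in seq_len(nrow(rsub))) region[rsub$start[k]:rsub$end[k]] <- -1L
    }
    r <- region[tab$pos]
    lev <- rep(background_level, nrow(tab))
    is_rep <- r == -1L
    lev[is_rep] <- repeat_levels[tab$context[is_rep]]
    is_gene <- r > 0L
    gp <- pct[genes$gene_id[r[is_gene]]]
    lev[is_gene] <- gene_max_levels[tab$context[is_gene]] * gp
    tab$level <- lev
    tab
  }) |> dplyr::bind_rows()

  cov <- pmax(1L, stats::rnbinom(nrow(rows), size = coverage_dispersion,
                                 mu = coverage_mean))
  n_meth <- stats::rbinom(nrow(rows), cov, rows$level)
  cyt <- tibble::tibble(
    contig = rows$contig, pos = rows$pos, strand = rows$strand,
    n_meth = as.integer(n_meth), n_unmeth = as.integer(cov - n_meth),
    context = rows$context
  )
  truth <- list(
    repeat_levels = repeat_levels, gene_max_levels = gene_max_levels,
    background_level = background_level,
    gene_percentile = tibble::tibble(gene_id = names(pct), percentile = unname(pct))
  )
  list(cytosines = cyt, expression = expression, truth = truth)
}

#' Simulate a complete synthetic methylome
#'
#' Orchestrates genome, expression, 6mA and 5mC generation under one seed and
#' returns every object the characterization pipeline consumes, plus the
#' truth bundle. The two regimes emulate the two extremes of Mucorales
#' methylomes (see [regime_params()]).
#'
#' @param regime `"symmetric_clustered"` or `"asymmetric_scattered"`.
#' @param seed Integer seed (all stages derive their streams from it).
#' @param contig_len,n_contigs,n_genes,n_repeats,gc Genome geometry.
#' @param params Optional `regime_params` override.
#' @param with_5mc Also simulate a bisulfite report (default TRUE).
#' @return List: `genome`, `genes`, `repeats`, `expression`, `sites`,
#'   `cytosines` (or NULL), `truth`.
#' @export
simulate_methylome <- function(regime = c("symmetric_clustered", "asymmetric_scattered"),
                               seed, contig_len = 5e5, n_contigs = 1,
                               n_genes = 200, n_repeats = 50, gc = 0.4,
                               params = NULL, with_5mc = TRUE) {
  regime <- match.arg(regime)
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(params)) params <- regime_params(regime)
  base <- simulate_genome(n_contigs, contig_len, n_genes, n_repeats, gc,
                          seed = seed)
  expression <- simulate_expression(base$genes, seed = seed + 1L)
  ma <- plant_6ma(base$genome, base$genes, expression, params, seed = seed + 2L)
  mc <- if (with_5mc) {
    plant_5mc(base$genome, base$genes, base$repeats, expression, seed = seed + 3L)
  }
  list(
    genome = base$genome, genes = base$genes, repeats = base$repeats,
    expression = expression, sites = ma$sites,
    cytosines = if (with_5mc) mc$cytosines else NULL,
    truth = list(regime = regime, seed = seed, sixma = ma$truth,
                 fivemc = if (with_5mc) mc$truth else NULL)
  )
}

#' Write a simulated methylome to disk in standard formats
#'
#' Emits FASTA, GFF3, repeat BED, the canonical 6mA site table, a CX-style
#' bisulfite report, the expression TSV, and the truth bundle as JSON.
#'
#' @param sim Output of [simulate_methylome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome$seq, file.path(dir, "genome.fa"))
  write_gff3(sim$genes, file.path(dir, "genes.gff3"))
  readr::write_tsv(
    tibble::tibble(chrom = sim$repeats$contig, start = sim$repeats$start - 1L,
                   end = sim$repeats$end, name = sim$repeats$name),
    file.path(dir, "repeats.bed"), col_names = FALSE, progress = FALSE
  )
  write_site_calls(sim$sites, file.path(dir, "sites_6ma.tsv"))
  if (!is.null(sim$cytosines)) {
    write_cx_report(sim$cytosines, file.path(dir, "cx_report.tsv"))
  }
  readr::write_tsv(sim$expression, file.path(dir, "expression.tsv"),
                   progress = FALSE)
  truth <- sim$truth
  truth$sixma$params$context_pwm <- NULL  # matrices serialize poorly; in params elsewhere
  jsonlite::write_json(
    list(regime = truth$regime, seed = truth$seed,
         n_planted = truth$sixma$n_planted,
         planted_symmetric_fraction = truth$sixma$planted_symmetric_fraction,
         planted_in_cluster_fraction = truth$sixma$planted_in_cluster_fraction),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  if (!is.null(truth$sixma$clusters)) {
    readr::write_tsv(truth$sixma$clusters, file.path(dir, "truth_clusters.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(truth$sixma$site_truth, file.path(dir, "truth_sites.tsv"),
                   progress = FALSE)
  invisible(dir)
}

# minimal GFF3 writer for gene/mRNA/exon models
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gl <- sprintf("%s\tsixmac\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  g$contig, g$start, g$end, g$strand, g$gene_id)
    ml <- sprintf("%s\tsixmac\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                  g$contig, g$start, g$end, g$strand, g$gene_id, g$gene_id)
    ex <- g$exons[[1]]
    el <- sprintf("%s\tsixmac\texon\t%d\t%d\t.\t%s\t.\tID=%s.t1.exon%d;Parent=%s.t1",
                  g$contig, ex$start, ex$end, g$strand, g$gene_id,
                  seq_len(nrow(ex)), g$gene_id)
    lines <- c(lines, gl, ml, el)
  }
  writeLines(lines, path)
  invisible(path)
}
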