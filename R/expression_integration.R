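#' Stratify genes by expression level
#'
#' Ranks genes by abundance (FPKM/TPM, highest first; ties broken
#' deterministically by gene id) and assigns rank-based quartiles, Q1 being
#' the most highly expressed. Zero-abundance genes are flagged silent and sort
#' last, so they fall into Q4 whenever they are no more than a quartile of the
#' genes. The top-`n` and bottom-`n` sets (default 400) are extracted for
#' top/bottom-set association analyses.
#'
#' @param expression Tibble with `gene_id` and `abundance`.
#' @param n_top Size of the top/bottom sets (default 400).
#' @return Tibble `gene_id`, `abundance`, `rank`, `quartile` (`Q1`..`Q4`),
#'   `silent`, `top_set`, `bottom_set`.
#' @export
stratify_expression <- function(expression, n_top = 400) {
  n <- nrow(expression)
  if (n == 0) stop("empty expression table")
  if (n < 2 * n_top) {
    warning("fewer genes (", n, ") than 2 * n_top; sets truncated")
    n_top <- n %/% 2
  }
  ord <- order(-expression$abundance, expression$gene_id)
  out <- expression[ord, c("gene_id", "abundance")]
  out$rank <- seq_len(n)
  out$quartile <- paste0("Q", ceiling(out$rank / n * 4))
  out$silent <- out$abundance == 0
  out$top_set <- out$rank <= n_top
  out$bottom_set <- out$rank > n - n_top
  tibble::as_tibble(out)
}

#' Summarize methylation features by expression stratum
#'
#' Joins per-gene methylation counts (e.g. from [tss_window_counts()],
#' optionally with a `has_mac` or `n_macs` column) to expression strata and
#' summarizes the site-count distribution per quartile and for the top/bottom
#' sets: median, quartiles, 10th/90th percentiles, and the proportion of
#' genes carrying at least one MAC.
#'
#' @param strata Output of [stratify_expression()].
#' @param counts Tibble with `gene_id`, `n_sites` and optionally `n_macs` or
#'   `has_mac`.
#' @return Tibble with one row per stratum (`Q1`..`Q4`, `top`, `bottom`).
#' @export
methylation_by_stratum <- function(strata, counts) {
  missed <- mean(!strata$gene_id %in% counts$gene_id)
  if (missed > 0.05) {
    warning(sprintf("%.1f%% of genes missing from the counts table", 100 * missed))
  }
  joined <- dplyr::left_join(strata, counts, by = "gene_id")
  joined$n_sites[is.na(joined$n_sites)] <- 0L
  if (!"has_mac" %in% names(joined)) {
    joined$has_mac <- if ("n_macs" %in% names(joined)) {
      !is.na(joined$n_macs) & joined$n_macs > 0
    } else {
      NA
    }
  }
  summarize_one <- function(sub, label) {
    q <- stats::quantile(sub$n_sites, c(.1, .25, .5, .75, .9), names = FALSE)
    tibble::tibble(
      stratum = label, n_genes = nrow(sub),
      p10 = q[1], q25 = q[2], median = q[3], q75 = q[4], p90 = q[5],
      mean_sites = mean(sub$n_sites),
      prop_with_mac = mean(sub$has_mac)
    )
  }
  strata_list <- c(
    stats::setNames(lapply(paste0("Q", 1:4), function(q) joined[joined$quartile == q, ]),
                    paste0("Q", 1:4)),
    list(top = joined[joined$top_set, ], bottom = joined[joined$bottom_set, ])
  )
  purrr::imap(strata_list, summarize_one) |> dplyr::bind_rows()
}

#' Label per-gene MAC gain and loss between two conditions
#'
#' Presence-based comparison of the MAC sets of two conditions on the same
#' genome: a gene gains when a MAC overlaps its TSS window in condition A but
#' not in B, loses in the converse case, is stable when both, none when
#' neither. Shifted-but-overlapping MACs within the window count as stable.
#'
#' @param macs_a,macs_b MAC tibbles for conditions A (treatment) and B
#'   (control).
#' @param genes Gene models tibble.
#' @param window TSS window (default `c(-150, 400)`).
#' @param min_sites Minimum methylated motifs for a MAC to count.
#' @param de Optional tibble `gene_id`, `direction` (e.g. up/down/not-DE) to
#'   join on.
#' @return Tibble `gene_id`, `in_a`, `in_b`, `status` plus any DE columns.
#' @export
mac_gain_loss <- function(macs_a, macs_b, genes, window = c(-150, 400),
                          min_sites = 1, de = NULL) {
  a <- assign_macs_to_genes(macs_a, genes, window, min_sites)
  b <- assign_macs_to_genes(macs_b, genes, window, min_sites)
  out <- tibble::tibble(
    gene_id = a$gene_id,
    in_a = a$has_mac,
    in_b = b$has_mac,
    status = dplyr::case_when(
      a$has_mac & !b$has_mac ~ "gained",
      !a$has_mac & b$has_mac ~ "lost",
      a$has_mac & b$has_mac ~ "stable",
      TRUE ~ "none"
    )
  )
  if (!is.null(de)) out <- dplyr::left_join(out, de, by = "gene_id")
  out
}

# Welch two-sample t statistic pieces, delegating to stats::t.test
welch_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    return(tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_,
                          n_x = length(x), n_y = length(y)))
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    # degenerate case t.test refuses: constant samples
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(tibble::tibble(t = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
                          df = length(x) + length(y) - 2,
                          p = if (same) 1 else 0,
                          n_x = length(x), n_y = length(y)))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, n_x = length(x), n_y = length(y))
}

#' Per-site methylation-ratio shifts between conditions, with Welch's test
#'
#' Matches sites present in both conditions by (contig, position, strand)
#' within the TSS windows of each differential-expression gene set and
#' computes the per-site fold ratio `ratio_A / ratio_B`; a fold ratio above 1
#' means more methylation in the treatment (A). The fold-ratio distributions
#' of the up- and down-regulated sets are compared with a two-tailed Welch
#' test. Sites with a zero control ratio (fold undefined) and sites present
#' in only one condition are excluded and counted.
#'
#' The alternative per-gene reading (`per = "gene"`) compares the
#' site-count fold change per gene instead of the per-site ratio fold.
#'
#' @param sites_a,sites_b Filtered site tibbles for treatment and control.
#' @param genes Gene models tibble.
#' @param gene_sets Named list of gene-id vectors, typically
#'   `list(up = ..., down = ...)`.
#' @param window TSS window (default `c(-150, 400)`).
#' @param per `"site"` (default) or `"gene"`.
#' @return Object of class `ratio_shift`: list with `per_set` (tibble of set,
#'   n sites/genes matched, mean fold), `folds` (per-observation tibble),
#'   `test` (Welch t, df, p between the first two sets), counts of unmatched
#'   sites. `tidy()` returns `per_set`; `glance()` the test row.
#' @export
ratio_shift_test <- function(sites_a, sites_b, genes, gene_sets,
                             window = c(-150, 400), per = c("site", "gene")) {
  per <- match.arg(per)
  stopifnot(is.list(gene_sets), length(gene_sets) >= 1)
  w <- tss_windows(genes, window)

  fold_for_set <- function(set_genes) {
    ws <- w[w$gene_id %in% set_genes, , drop = FALSE]
    if (nrow(ws) == 0) {
      return(list(folds = numeric(), n_unmatched = 0L))
    }
    wg <- GenomicRanges::GRanges(ws$contig, IRanges::IRanges(pmax(1L, ws$win_start), ws$win_end))
    pick <- function(sites) {
      sg <- GenomicRanges::GRanges(sites$contig, IRanges::IRanges(sites$pos, sites$pos))
      sites[IRanges::overlapsAny(sg, wg), , drop = FALSE]
    }
    if (per == "site") {
      a <- pick(sites_a); b <- pick(sites_b)
      m <- dplyr::inner_join(
        a[, c("contig", "pos", "strand", "ratio")],
        b[, c("contig", "pos", "strand", "ratio")],
        by = c("contig", "pos", "strand"), suffix = c("_a", "_b")
      )
      n_unmatched <- nrow(a) + nrow(b) - 2L * nrow(m)
      ok <- m$ratio_b > 0
      list(folds = m$ratio_a[ok] / m$ratio_b[ok],
           n_unmatched = n_unmatched + sum(!ok))
    } else {
      ca <- tss_window_counts(sites_a, genes[genes$gene_id %in% set_genes, ], window = window)
      cb <- tss_window_counts(sites_b, genes[genes$gene_id %in% set_genes, ], window = window)
      ok <- cb$n_sites > 0
      list(folds = ca$n_sites[ok] / cb$n_sites[ok], n_unmatched = sum(!ok))
    }
  }

  res <- purrr::map(gene_sets, fold_for_set)
  per_set <- purrr::imap(res, function(r, nm) {
    tibble::tibble(set = nm, n = length(r$folds),
                   mean_fold = ifelse(length(r$folds) > 0, mean(r$folds), NA_real_),
                   n_unmatched = r$n_unmatched)
  }) |> dplyr::bind_rows()
  folds <- purrr::imap(res, function(r, nm) {
    tibble::tibble(set = nm, fold = r$folds)
  }) |> dplyr::bind_rows()
  test <- if (length(res) >= 2) {
    welch_test(res[[1]]$folds, res[[2]]$folds)
  } else {
    tibble::tibble(t = NA_real_, df = NA_real_, p = NA_real_, n_x = NA, n_y = NA)
  }
  structure(list(per_set = per_set, folds = folds, test = test, per = per),
            class = "ratio_shift")
}

#' @export
print.ratio_shift <- function(x, ...) {
  cat("<ratio_shift> per-", x$per, " fold ratios\n", sep = "")
  print(x$per_set)
  cat(sprintf("Welch test (set 1 vs set 2): t = %.4f, df = %.2f, p = %.4g\n",
              x$test$t, x$test$df, x$test$p))
  invisible(x)
}

#' @export
tidy.ratio_shift <- function(x, ...) x$per_set

#' @export
glance.ratio_shift <- function(x, ...) x$test

#' Annotation-term enrichment in a gene selection (Fisher's exact test)
#'
#' One-sided (enrichment) Fisher exact test per term via the hypergeometric
#' tail: the probability of observing at least as many term-carrying genes in
#' the selection, given the term's background frequency. A p-value below
#' `alpha` (default 0.05) flags the term; no multiple-testing correction is
#' applied by default, with Benjamini-Hochberg available.
#'
#' @param selected Character vector of selected gene ids (must be a subset of
#'   the background).
#' @param background Character vector of background gene ids.
#' @param annotations Tibble `gene_id`, `term` (flat labels, one row per
#'   gene-term pair).
#' @param alpha Significance cutoff (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Tibble per term: counts of the 2x2 table, `p`, `p_adj`,
#'   `significant`.
#' @export
term_enrichment <- function(selected, background, annotations, alpha = 0.05,
                            p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  selected <- unique(selected)
  background <- unique(background)
  if (length(selected) == 0) stop("empty gene selection")
  if (!all(selected %in% background)) {
    stop("selected genes must be a subset of the background")
  }
  ann <- annotations[annotations$gene_id %in% background, , drop = FALSE]
  n_sel <- length(selected)
  n_bg <- length(background)
  terms <- split(ann$gene_id, ann$term)
  rows <- purrr::imap(terms, function(genes, term) {
    genes <- unique(genes)
    k <- sum(genes %in% selected)       # selected with term
    K <- length(genes)                  # background with term
    p <- stats::phyper(k - 1, K, n_bg - K, n_sel, lower.tail = FALSE)
    tibble::tibble(
      term = term,
      selected_with = k, selected_without = n_sel - k,
      background_with = K - k, background_without = (n_bg - K) - (n_sel - k),
      p = p
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- if (p_adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$significant <- out$p_adj < alpha
  dplyr::arrange(out, .data$p)
}
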