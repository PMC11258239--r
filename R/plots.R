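#' Plot a MAC distance scan
#'
#' Recall, purity and their product (the score) against the relative
#' distance, with the selected distance marked.
#'
#' @param object A `mac_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mac_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(object$table, c("recall", "purity", "score"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$d, .data$value, color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$d_star, linetype = "dashed") +
    ggplot2::labs(x = "relative distance d (unmethylated motifs allowed)",
                  y = NULL,
                  title = sprintf("MAC distance scan (d* = %d)", object$d_star)) +
    ggplot2::theme_minimal()
}

#' Plot a metagene profile
#'
#' @param object A `metagene_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  geo <- attr(object, "geometry")
  b0 <- geo$n_flank_bins + 0.5
  b1 <- geo$n_flank_bins + geo$n_body_bins + 0.5
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$bin, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(b0, b1), linetype = "dotted") +
    ggplot2::labs(x = "bin (upstream flank | scaled body | downstream flank)",
                  y = if (geo$value == "frequency") "sites per bp" else "weighted level") +
    ggplot2::theme_minimal()
}

#' Plot feature enrichment as log2 observed/expected
#'
#' @param object A `feature_enrichment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.feature_enrichment <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[!is.na(d$log2fc) & is.finite(d$log2fc), ]
  ggplot2::ggplot(d, ggplot2::aes(.data$class, .data$log2fc)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "log2(observed / expected)") +
    ggplot2::theme_minimal()
}

#' Plot per-position base frequencies of a motif summary
#'
#' @param object A `motif_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.motif_summary <- function(object, ...) {
  d <- tidy.motif_summary(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$offset, .data$frequency,
                                  color = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "offset from methylated adenine (nt)",
                  y = "base frequency",
                  title = paste("consensus:", object$consensus)) +
    ggplot2::theme_minimal()
}

#' Plot Watson vs Crick methylation ratios of ApT pairs
#'
#' Symmetric pairs accumulate in the top-right corner; hemimethylated pairs
#' lie on the axes.
#'
#' @param object An `apt_symmetry`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.apt_symmetry <- function(object, ...) {
  d <- object$pairs
  d$watson_ratio[is.na(d$watson_ratio)] <- 0
  d$crick_ratio[is.na(d$crick_ratio)] <- 0
  ggplot2::ggplot(d, ggplot2::aes(.data$crick_ratio, .data$watson_ratio)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Crick methylation ratio", y = "Watson methylation ratio",
                  title = sprintf("%.1f%% of sites symmetric",
                                  100 * object$fraction_symmetric)) +
    ggplot2::theme_minimal()
}
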