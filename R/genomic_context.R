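FEATURE_CLASSES <- c("exon", "utr5", "utr3", "intron", "repeat", "promoter", "intergenic")

#' Partition every genomic base into one feature class
#'
#' Labels each base of the genome with exactly one of exon, 5'UTR, 3'UTR,
#' intron, repeat, promoter, or intergenic. Promoters are the 600 bp upstream
#' of each TSS (strand-aware, truncated at contig edges); everything not
#' covered by genes, repeats or promoters is intergenic. Overlaps are resolved
#' by the precedence exon > UTR > intron > repeat > promoter > intergenic
#' (gene structure is given priority over repeats).
#'
#' @param genome A `genome_index`.
#' @param genes Gene models tibble.
#' @param repeats Optional repeat tibble (`contig`, `start`, `end`).
#' @param promoter_len Promoter length in bp upstream of the TSS (default 600).
#' @return Object of class `feature_partition`: list with `labels` (per-contig
#'   integer vector indexing `classes`), `classes`, and `summary` (tibble
#'   `class`, `bases`).
#' @export
partition_features <- function(genome, genes, repeats = NULL, promoter_len = 600) {
  classes <- FEATURE_CLASSES
  code <- stats::setNames(seq_along(classes), classes)
  lens <- stats::setNames(genome$contigs$length, genome$contigs$contig)
  labels <- lapply(lens, function(L) rep.int(code[["intergenic"]], L))

  paint <- function(labels, contig, start, end, cls) {
    for (k in seq_along(contig)) {
      s <- max(1L, start[k]); e <- min(lens[[contig[k]]], end[k])
      if (s <= e) labels[[contig[k]]][s:e] <- code[[cls]]
    }
    labels
  }

  # ascending precedence: later paints win
  prom_start <- ifelse(genes$strand == "+", genes$tss - promoter_len, genes$tss + 1L)
  prom_end <- ifelse(genes$strand == "+", genes$tss - 1L, genes$tss + promoter_len)
  labels <- paint(labels, genes$contig, prom_start, prom_end, "promoter")
  if (!is.null(repeats) && nrow(repeats) > 0) {
    labels <- paint(labels, repeats$contig, repeats$start, repeats$end, "repeat")
  }
  labels <- paint(labels, genes$contig, genes$start, genes$end, "intron")
  for (i in seq_len(nrow(genes))) {
    ct <- genes$contig[i]
    u5 <- genes$utr5[[i]]; u3 <- genes$utr3[[i]]
    if (!is.null(u5) && nrow(u5)) labels <- paint(labels, rep(ct, nrow(u5)), u5$start, u5$end, "utr5")
    if (!is.null(u3) && nrow(u3)) labels <- paint(labels, rep(ct, nrow(u3)), u3$start, u3$end, "utr3")
  }
  # exon painted last: highest precedence. Note that in annotations where
  # exons cover the UTRs (the usual GFF3 layout) the UTR classes stay empty;
  # UTR features disjoint from exons are labeled as such.
  for (i in seq_len(nrow(genes))) {
    ct <- genes$contig[i]
    ex <- genes$exons[[i]]
    labels <- paint(labels, rep(ct, nrow(ex)), ex$start, ex$end, "exon")
  }

  # overlapping genes are resolved by paint order; report them
  gr <- GenomicRanges::GRanges(genes$contig, IRanges::IRanges(genes$start, genes$end))
  n_over <- sum(GenomicRanges::countOverlaps(gr, gr) > 1)
  if (n_over > 0) warning(n_over, " genes overlap another gene; resolved by precedence")

  summary <- tibble::tibble(
    class = classes,
    bases = vapply(seq_along(classes), function(k) {
      sum(vapply(labels, function(v) sum(v == k), 0L))
    }, 0L)
  )
  structure(list(labels = labels, classes = classes, summary = summary),
            class = "feature_partition")
}

#' @export
print.feature_partition <- function(x, ...) {
  cat("<feature_partition> over", sum(x$summary$bases), "bp\n")
  print(x$summary)
  invisible(x)
}

# class label at given positions
partition_label <- function(partition, contig, pos) {
  out <- integer(length(pos))
  for (ct in unique(contig)) {
    idx <- which(contig == ct)
    out[idx] <- partition$labels[[ct]][pos[idx]]
  }
  partition$classes[out]
}

#' Export a feature partition as per-class BED intervals
#' @param partition A `feature_partition`.
#' @return Tibble `contig`, `start`, `end`, `class` (1-based inclusive runs).
#' @export
partition_intervals <- function(partition) {
  purrr::imap(partition$labels, function(v, ct) {
    r <- rle(v)
    e <- cumsum(r$lengths)
    tibble::tibble(contig = ct, start = e - r$lengths + 1L, end = e,
                   class = partition$classes[r$values])
  }) |> dplyr::bind_rows()
}

# per-class eligible base counts, composition-aware
eligible_counts <- function(partition, genome, base = "A", context = NULL) {
  counts <- stats::setNames(numeric(length(partition$classes)), partition$classes)
  for (ct in names(partition$labels)) {
    s <- strsplit(as.character(genome$seq[[ct]]), "")[[1]]
    lab <- partition$labels[[ct]]
    if (base == "A") {
      elig <- s == "A" | s == "T"  # adenines on both strands
      tab <- tabulate(lab[elig], nbins = length(partition$classes))
      counts <- counts + tab
    } else {
      ctx_plus <- context_of(s, "+")
      ctx_minus <- context_of(s, "-")
      for (strand_ctx in list(ctx_plus, ctx_minus)) {
        elig <- if (is.null(context)) !is.na(strand_ctx) else !is.na(strand_ctx) & strand_ctx == context
        counts <- counts + tabulate(lab[elig], nbins = length(partition$classes))
      }
    }
  }
  counts
}

#' Observed/expected methylation enrichment over feature classes
#'
#' The expected count in a class is the total number of sites scaled by the
#' class's share of eligible bases (adenines on both strands for 6mA;
#' context-matching cytosines for 5mC), i.e. a base-composition-aware null.
#' Results are reported as log2(observed/expected).
#'
#' @param sites Site tibble (6mA) or cytosine tibble (5mC).
#' @param partition A `feature_partition`.
#' @param genome A `genome_index`.
#' @param base `"A"` for 6mA (default) or `"C"` for 5mC.
#' @param context For `base = "C"`, restrict the eligible null to one of
#'   `"CG"`, `"CHG"`, `"CHH"` (NULL = all cytosines).
#' @return Object of class `feature_enrichment`: tibble `class`, `observed`,
#'   `expected`, `eligible`, `log2fc` (NA where no eligible bases).
#' @export
feature_enrichment <- function(sites, partition, genome, base = c("A", "C"),
                               context = NULL) {
  base <- match.arg(base)
  if (nrow(sites) == 0) stop("no sites: enrichment is undefined")
  lab <- partition_label(partition, sites$contig, sites$pos)
  observed <- vapply(partition$classes, function(cl) sum(lab == cl), 0)
  eligible <- eligible_counts(partition, genome, base, context)
  expected <- nrow(sites) * eligible / sum(eligible)
  out <- tibble::tibble(
    class = partition$classes,
    observed = unname(observed),
    expected = unname(expected),
    eligible = unname(eligible),
    log2fc = ifelse(eligible > 0, log2(observed / expected), NA_real_)
  )
  structure(out, class = c("feature_enrichment", class(out)))
}

#' @export
tidy.feature_enrichment <- function(x, ...) tibble::as_tibble(x)

#' Scaled metagene profile of site frequency or methylation level
#'
#' Each element's body is rescaled to a common length and divided into
#' `n_body_bins` equal bins; flanks of `flank_len` bp are taken unscaled and
#' divided into `n_flank_bins` bins each. Minus-strand elements are
#' orientation-flipped before averaging, so bin 1 is always the far upstream
#' flank. For `value = "frequency"` the per-bin value is the site count per bp
#' averaged over elements; for `value = "level"` it is the read-pooled
#' weighted methylation level per bin (requires `n_meth`/`n_unmeth` columns).
#'
#' @param sites Site tibble (needs `contig`, `pos`; for `"level"` also
#'   `n_meth` and `n_unmeth`).
#' @param elements Tibble `contig`, `start`, `end`, `strand`.
#' @param body_len Common body length in bp the bodies are scaled to.
#' @param flank_len Flank length in bp.
#' @param n_body_bins,n_flank_bins Bin counts.
#' @param value `"frequency"` or `"level"`.
#' @return Object of class `metagene_profile`: tibble `bin`, `section`
#'   (`upstream`/`body`/`downstream`), `value`, `n`; attributes record the
#'   geometry and `n_elements` used / `n_skipped` (shorter than the body bin
#'   count).
#' @export
metagene_profile <- function(sites, elements, body_len = 1500, flank_len = 500,
                             n_body_bins = 60, n_flank_bins = 20,
                             value = c("frequency", "level")) {
  value <- match.arg(value)
  if (nrow(elements) == 0) stop("empty element set")
  n_bins <- n_body_bins + 2L * n_flank_bins
  el <- elements
  el_len <- el$end - el$start + 1L
  usable <- el_len >= n_body_bins
  n_skipped <- sum(!usable)
  el <- el[usable, , drop = FALSE]
  el_len <- el_len[usable]
  if (nrow(el) == 0) stop("all elements shorter than the body bin count")

  acc_num <- matrix(0, nrow(el), n_bins)
  acc_den <- matrix(0, nrow(el), n_bins)
  flank_bin_bp <- flank_len / n_flank_bins

  site_split <- split(seq_len(nrow(sites)), sites$contig)
  for (i in seq_len(nrow(el))) {
    idx <- site_split[[el$contig[i]]]
    if (is.null(idx)) idx <- integer()
    pos <- sites$pos[idx]
    lo <- el$start[i] - flank_len
    hi <- el$end[i] + flank_len
    sel <- idx[pos >= lo & pos <= hi]
    pos <- sites$pos[sel]
    # signed offset in the element's orientation; 0 = first body base
    off <- if (el$strand[i] == "-") el$end[i] - pos else pos - el$start[i]
    blen <- el_len[i]
    bin <- integer(length(off))
    up <- off < 0
    dn <- off >= blen
    bd <- !up & !dn
    bin[up] <- pmin(n_flank_bins, 1L + ((off[up] + flank_len) %/% flank_bin_bp))
    bin[bd] <- n_flank_bins + 1L + floor(off[bd] / blen * n_body_bins)
    bin[bd] <- pmin(bin[bd], n_flank_bins + n_body_bins)
    bin[dn] <- n_flank_bins + n_body_bins +
      pmin(n_flank_bins, 1L + ((off[dn] - blen) %/% flank_bin_bp))

    if (value == "frequency") {
      cnt <- tabulate(bin, nbins = n_bins)
      bin_bp <- c(rep(flank_bin_bp, n_flank_bins),
                  rep(blen / n_body_bins, n_body_bins),
                  rep(flank_bin_bp, n_flank_bins))
      acc_num[i, ] <- cnt / bin_bp
      acc_den[i, ] <- 1
    } else {
      m <- sites$n_meth[sel]; u <- sites$n_unmeth[sel]
      acc_num[i, ] <- vapply(seq_len(n_bins), function(b) sum(m[bin == b]), 0)
      acc_den[i, ] <- vapply(seq_len(n_bins), function(b) sum(m[bin == b] + u[bin == b]), 0)
    }
  }

  val <- if (value == "frequency") {
    colMeans(acc_num)
  } else {
    num <- colSums(acc_num); den <- colSums(acc_den)
    ifelse(den > 0, num / den, NA_real_)
  }
  n_col <- if (value == "frequency") rep(nrow(el), n_bins) else colSums(acc_den > 0)
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    section = rep(c("upstream", "body", "downstream"),
                  c(n_flank_bins, n_body_bins, n_flank_bins)),
    value = val,
    n = n_col
  )
  structure(out, class = c("metagene_profile", class(out)),
            geometry = list(body_len = body_len, flank_len = flank_len,
                            n_body_bins = n_body_bins, n_flank_bins = n_flank_bins,
                            value = value),
            n_elements = nrow(el), n_skipped = n_skipped)
}

#' Count 6mA sites and MACs in TSS windows
#'
#' Counts, for each gene, the filtered 6mA sites and (optionally) MACs inside
#' the strand-oriented window around the TSS (default -150/+400 bp, closed at
#' both ends).
#'
#' @param sites Filtered site tibble.
#' @param genes Gene models tibble.
#' @param macs Optional MAC tibble.
#' @param window Offsets from the TSS, gene orientation.
#' @return Tibble `gene_id`, `n_sites`, `n_macs`.
#' @export
tss_window_counts <- function(sites, genes, macs = NULL, window = c(-150, 400)) {
  w <- tss_windows(genes, window)
  wg <- GenomicRanges::GRanges(w$contig, IRanges::IRanges(pmax(1L, w$win_start), w$win_end))
  sg <- GenomicRanges::GRanges(sites$contig, IRanges::IRanges(sites$pos, sites$pos))
  n_sites <- GenomicRanges::countOverlaps(wg, sg)
  n_macs <- if (!is.null(macs) && nrow(macs) > 0) {
    mg <- GenomicRanges::GRanges(macs$contig, IRanges::IRanges(macs$start, macs$end))
    GenomicRanges::countOverlaps(wg, mg)
  } else {
    integer(nrow(w))
  }
  tibble::tibble(gene_id = w$gene_id, n_sites = as.integer(n_sites),
                 n_macs = as.integer(n_macs))
}
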