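#' Build a motif occurrence track for MAC detection
#'
#' Enumerates plus-strand occurrences of the motif (default `"AT"`, whose
#' reverse complement is itself, so a single scan covers both strands) on each
#' contig, left to right without overlap, and flags an occurrence as
#' methylated when any filtered 6mA site falls on an adenine within its span
#' (for AT: the plus-strand site at the A, or the minus-strand site at the T).
#'
#' @param genome A `genome_index`.
#' @param sites Filtered site tibble.
#' @param motif Motif string over ACGT (default `"AT"`).
#' @return Object of class `motif_track`: tibble `contig`, `start`,
#'   `methylated`, with attribute `motif`.
#' @export
motif_track <- function(genome, sites, motif = "AT") {
  if (!grepl("^[ACGT]+$", motif)) stop("motif must be over ACGT")
  mlen <- nchar(motif)
  occ <- purrr::map(genome$contigs$contig, function(ct) {
    s <- as.character(genome$seq[[ct]])
    m <- gregexpr(motif, s, fixed = TRUE)[[1]]  # non-overlapping, left-to-right
    if (m[1] == -1) return(tibble::tibble(contig = character(), start = integer()))
    tibble::tibble(contig = ct, start = as.integer(m))
  })
  occ <- dplyr::bind_rows(occ)
  # a site marks the occurrence whose span [start, start+mlen-1] contains it
  site_key <- unique(unlist(lapply(0:(mlen - 1L), function(off) {
    paste(sites$contig, sites$pos - off)
  })))
  occ$methylated <- if (nrow(occ)) paste(occ$contig, occ$start) %in% site_key else logical()
  out <- structure(occ, class = c("motif_track", class(occ)))
  attr(out, "motif") <- motif
  out
}

#' Cluster methylated motifs at a fixed relative distance
#'
#' Clusters are maximal chains of methylated motif occurrences in which
#' consecutive methylated occurrences are separated by at most `d`
#' unmethylated occurrences (the relative distance is counted in motif
#' occurrences, not base pairs). Chains with fewer than `min_methylated`
#' methylated motifs are discarded. Clusters never span contig boundaries.
#'
#' @param track A `motif_track`.
#' @param d Relative distance, an integer >= 1.
#' @param min_methylated Minimum methylated motifs per cluster (default 2; a
#'   single methylated motif is not a cluster).
#' @return Tibble of MACs: `contig`, `start`, `end` (1-based inclusive span
#'   from the first to the last methylated motif), `n_methylated`,
#'   `n_spanned` (all motif occurrences inside the span), `density`
#'   (`n_methylated / n_spanned`), `size` (bp).
#' @export
cluster_at_distance <- function(track, d, min_methylated = 2) {
  if (d < 1) stop("relative distance d must be >= 1")
  mlen <- nchar(attr(track, "motif") %||% "AT")
  per_contig <- split(seq_len(nrow(track)), track$contig)
  res <- purrr::map(per_contig, function(ix) {
    meth_idx <- which(track$methylated[ix])  # indices into the contig's occurrences
    if (length(meth_idx) < min_methylated) return(NULL)
    gaps <- diff(meth_idx) - 1L           # unmethylated occurrences between
    brk <- c(0L, cumsum(gaps > d))
    starts <- track$start[ix]
    chains <- unname(split(meth_idx, brk))
    chains <- chains[lengths(chains) >= min_methylated]
    if (length(chains) == 0) return(NULL)
    first <- vapply(chains, function(v) v[1], 0L)
    last <- vapply(chains, function(v) v[length(v)], 0L)
    tibble::tibble(
      contig = track$contig[ix[1]],
      start = starts[first],
      end = starts[last] + mlen - 1L,
      n_methylated = lengths(chains),
      n_spanned = last - first + 1L
    )
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(contig = character(), start = integer(), end = integer(),
                          n_methylated = integer(), n_spanned = integer())
  }
  out$density <- out$n_methylated / out$n_spanned
  out$size <- out$end - out$start + 1L
  dplyr::arrange(out, .data$contig, .data$start)
}

#' Scan relative distances and score each clustering
#'
#' For each relative distance `d` the clustering is scored as
#' `recall(d) * purity(d)`, a density-times-efficiency criterion:
#' recall is the fraction of methylated motifs genome-wide recovered into
#' clusters (efficiency of capture), and purity is the fraction of motif
#' occurrences inside cluster spans that are methylated (within-cluster
#' modification density). Recall is non-decreasing and purity non-increasing
#' in `d`, so their product has an interior optimum. The optimal distance
#' `d_star` is the smallest `d` attaining the maximal score.
#'
#' @param track A `motif_track`.
#' @param d_range Distances to evaluate (default `1:40`).
#' @param min_methylated Minimum methylated motifs per cluster.
#' @return Object of class `mac_scan`: list with `table` (tibble `d`,
#'   `n_clusters`, `recall`, `purity`, `score`), `d_star`, `min_methylated`.
#'   `tidy()` returns the table; `glance()` the selected distance and score.
#' @export
scan_distances <- function(track, d_range = 1:40, min_methylated = 2) {
  n_meth_total <- sum(track$methylated)
  if (n_meth_total == 0) stop("nothing to cluster: track has no methylated motifs")
  rows <- purrr::map(sort(unique(as.integer(d_range))), function(d) {
    cl <- cluster_at_distance(track, d, min_methylated)
    n_in <- sum(cl$n_methylated)
    spanned <- sum(cl$n_spanned)
    recall <- n_in / n_meth_total
    purity <- if (spanned > 0) n_in / spanned else NA_real_
    tibble::tibble(d = d, n_clusters = nrow(cl), recall = recall,
                   purity = purity, score = ifelse(spanned > 0, recall * purity, 0))
  })
  tab <- dplyr::bind_rows(rows)
  d_star <- tab$d[which.max(tab$score)]  # which.max -> first (smallest d) on ties
  structure(list(table = tab, d_star = d_star, min_methylated = min_methylated),
            class = "mac_scan")
}

#' @export
print.mac_scan <- function(x, ...) {
  best <- x$table[x$table$d == x$d_star, ]
  cat(sprintf("<mac_scan> d* = %d (score %.4f, recall %.4f, purity %.4f, %d clusters)\n",
              x$d_star, best$score, best$recall, best$purity, best$n_clusters))
  invisible(x)
}

#' @export
tidy.mac_scan <- function(x, ...) x$table

#' @export
glance.mac_scan <- function(x, ...) {
  best <- x$table[x$table$d == x$d_star, ]
  tibble::tibble(d_star = x$d_star, score = best$score, recall = best$recall,
                 purity = best$purity, n_clusters = best$n_clusters)
}

#' Detect methylated adenine clusters (MACs)
#'
#' Convenience composition: builds the motif track, scans relative distances
#' 1..40 for the best density-times-efficiency score, and re-clusters at the
#' selected distance. The conventional 50-500 bp size range is annotated
#' (`in_size_range`) but not enforced, since it is an observed property of
#' MACs rather than a definition.
#'
#' @param genome A `genome_index`.
#' @param sites Filtered site tibble.
#' @param motif Motif (default `"AT"`).
#' @param d_range Distances to scan (default `1:40`).
#' @param min_methylated Minimum methylated motifs per cluster (default 2).
#' @param size_range Annotated size range in bp (default `c(50, 500)`).
#' @return Object of class `mac_result`: list with `macs` (MAC tibble plus
#'   `in_size_range`), `scan` (`mac_scan`), `track` (`motif_track`).
#' @export
detect_macs <- function(genome, sites, motif = "AT", d_range = 1:40,
                        min_methylated = 2, size_range = c(50, 500)) {
  track <- motif_track(genome, sites, motif)
  scan <- scan_distances(track, d_range, min_methylated)
  macs <- cluster_at_distance(track, scan$d_star, min_methylated)
  macs$in_size_range <- macs$size >= size_range[1] & macs$size <= size_range[2]
  structure(list(macs = macs, scan = scan, track = track), class = "mac_result")
}

#' @export
print.mac_result <- function(x, ...) {
  cat("<mac_result> ", nrow(x$macs), " MACs at d* = ", x$scan$d_star, "; ",
      sum(x$macs$in_size_range), " within 50-500 bp\n", sep = "")
  invisible(x)
}

#' @export
glance.mac_result <- function(x, ...) {
  dplyr::bind_cols(
    glance.mac_scan(x$scan),
    tibble::tibble(n_macs = nrow(x$macs),
                   median_size = stats::median(x$macs$size))
  )
}

#' Fraction of 6mA sites inside MAC spans
#'
#' @param sites Filtered site tibble.
#' @param macs MAC tibble (from [detect_macs()]`$macs`).
#' @return Fraction of sites whose position falls inside a MAC span.
#' @export
fraction_sites_in_macs <- function(sites, macs) {
  if (nrow(sites) == 0) return(NA_real_)
  if (nrow(macs) == 0) return(0)
  s <- GenomicRanges::GRanges(sites$contig, IRanges::IRanges(sites$pos, sites$pos))
  m <- GenomicRanges::GRanges(macs$contig, IRanges::IRanges(macs$start, macs$end))
  mean(IRanges::overlapsAny(s, m))
}

# Strand-oriented TSS window in forward coordinates, closed on both ends.
tss_windows <- function(genes, window = c(-150, 400)) {
  up <- abs(window[1]); down <- window[2]
  tibble::tibble(
    gene_id = genes$gene_id,
    contig = genes$contig,
    win_start = ifelse(genes$strand == "+", genes$tss - up, genes$tss - down),
    win_end = ifelse(genes$strand == "+", genes$tss + down, genes$tss + up)
  )
}

#' Assign MACs to genes by TSS-window overlap
#'
#' A MAC is assigned to a gene when its span overlaps the strand-oriented
#' window around the gene's TSS (default -150 bp to +400 bp, closed at both
#' ends; for minus-strand genes the window is flipped to forward
#' coordinates). `min_sites` controls which MACs count: 1 for general
#' MAC-gene association, 10 for the stricter selection used when picking
#' densely methylated genes for term enrichment.
#'
#' @param macs MAC tibble.
#' @param genes Gene models tibble (see [read_gene_models()]).
#' @param window Numeric length-2: offsets from the TSS in the gene's
#'   orientation.
#' @param min_sites Minimum methylated motifs for a MAC to count.
#' @return Tibble `gene_id`, `n_macs`, `has_mac`.
#' @export
assign_macs_to_genes <- function(macs, genes, window = c(-150, 400), min_sites = 1) {
  w <- tss_windows(genes, window)
  macs_use <- macs[macs$n_methylated >= min_sites, , drop = FALSE]
  n <- integer(nrow(w))
  if (nrow(macs_use) > 0) {
    wg <- GenomicRanges::GRanges(w$contig, IRanges::IRanges(pmax(1L, w$win_start), w$win_end))
    mg <- GenomicRanges::GRanges(macs_use$contig, IRanges::IRanges(macs_use$start, macs_use$end))
    n <- GenomicRanges::countOverlaps(wg, mg)
  }
  tibble::tibble(gene_id = w$gene_id, n_macs = as.integer(n), has_mac = n > 0)
}
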