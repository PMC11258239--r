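#' Filter 6mA site calls by coverage and modification quality
#'
#' The default policy keeps sites with at least 15x coverage and a
#' modification quality value (mQv) strictly greater than 25. For low-coverage
#' samples a relaxed policy of 5x coverage and mQv > 20 is conventional; pass
#' `min_coverage = 5, min_mqv = 20`. Sites without an mQv (e.g. simulated
#' calls) pass the quality check by default.
#'
#' @param sites Site tibble (see [read_site_calls()]).
#' @param min_coverage Minimum coverage, inclusive.
#' @param min_mqv mQv threshold; the comparison is strict (`mqv > min_mqv`).
#' @param mqv_missing `"pass"` (default) or `"fail"`: what to do with sites
#'   lacking an mQv.
#' @return Filtered tibble with attribute `removed` (named counts by reason).
#' @export
filter_sites <- function(sites, min_coverage = 15, min_mqv = 25,
                         mqv_missing = c("pass", "fail")) {
  mqv_missing <- match.arg(mqv_missing)
  stopifnot(min_coverage >= 1)
  cov_ok <- sites$coverage >= min_coverage
  mqv_ok <- ifelse(is.na(sites$mqv), mqv_missing == "pass", sites$mqv > min_mqv)
  keep <- cov_ok & mqv_ok
  out <- sites[keep, , drop = FALSE]
  attr(out, "removed") <- c(
    low_coverage = sum(!cov_ok),
    low_mqv = sum(cov_ok & !mqv_ok)
  )
  out
}

#' Classify strand symmetry of 6mA sites at ApT dinucleotides
#'
#' The dinucleotide 5'-AT-3' places an adenine on each strand (its reverse
#' complement is again AT), so both can be methylated. For every ApT whose
#' plus-strand A sits at position `i`, the Watson site is the plus-strand call
#' at `i` and the Crick site is the minus-strand call at `i + 1`. A pair with
#' both adenines called methylated (after filtering) is symmetric; one-sided
#' pairs are hemimethylated; methylated adenines not part of any ApT are
#' asymmetric by construction.
#'
#' @param sites Filtered site tibble.
#' @param genome A `genome_index`.
#' @return Object of class `apt_symmetry`: list with `sites` (input plus a
#'   `symmetry` column: `"symmetric"`, `"hemi-watson"`, `"hemi-crick"`,
#'   `"non-ApT"`), `pairs` (one row per ApT with at least one methylated
#'   adenine: `contig`, `pos` of the plus-strand A, `watson_ratio`,
#'   `crick_ratio`, `class`), and summary counts. `glance()` returns the
#'   symmetric and ApT site fractions.
#' @export
classify_symmetry <- function(sites, genome) {
  n <- nrow(sites)
  if (n == 0) stop("no sites to classify")
  base_next <- genome_base(genome, sites$contig, sites$pos + 1L)
  base_prev <- genome_base(genome, sites$contig, sites$pos - 1L)
  # anchor = position of the plus-strand A of the ApT the site belongs to
  anchor <- rep(NA_integer_, n)
  plus <- sites$strand == "+"
  at_plus <- plus & !is.na(base_next) & base_next == "T"
  at_minus <- !plus & !is.na(base_prev) & base_prev == "A"
  anchor[at_plus] <- sites$pos[at_plus]
  anchor[at_minus] <- sites$pos[at_minus] - 1L

  key <- ifelse(is.na(anchor), NA, paste(sites$contig, anchor))
  in_apt <- !is.na(anchor)
  watson_present <- key %in% key[in_apt & plus]
  crick_present <- key %in% key[in_apt & !plus]

  symmetry <- dplyr::case_when(
    !in_apt ~ "non-ApT",
    watson_present & crick_present ~ "symmetric",
    plus ~ "hemi-watson",
    TRUE ~ "hemi-crick"
  )
  out_sites <- dplyr::mutate(sites, symmetry = symmetry)

  ap <- tibble::tibble(
    contig = sites$contig[in_apt],
    pos = anchor[in_apt],
    strand = sites$strand[in_apt],
    ratio = sites$ratio[in_apt]
  )
  pairs <- ap |>
    tidyr::pivot_wider(names_from = "strand", values_from = "ratio") |>
    dplyr::rename(watson_ratio = dplyr::any_of("+"), crick_ratio = dplyr::any_of("-"))
  if (!"watson_ratio" %in% names(pairs)) pairs$watson_ratio <- NA_real_
  if (!"crick_ratio" %in% names(pairs)) pairs$crick_ratio <- NA_real_
  pairs$class <- dplyr::case_when(
    !is.na(pairs$watson_ratio) & !is.na(pairs$crick_ratio) ~ "symmetric",
    !is.na(pairs$watson_ratio) ~ "hemi-watson",
    TRUE ~ "hemi-crick"
  )
  pairs <- dplyr::arrange(pairs, .data$contig, .data$pos)

  structure(
    list(
      sites = out_sites,
      pairs = pairs,
      n_sites = n,
      n_symmetric_sites = sum(symmetry == "symmetric"),
      n_apt_sites = sum(in_apt),
      fraction_symmetric = sum(symmetry == "symmetric") / n,
      fraction_apt = sum(in_apt) / n
    ),
    class = "apt_symmetry"
  )
}

#' @export
print.apt_symmetry <- function(x, ...) {
  cat("<apt_symmetry> ", x$n_sites, " sites: ",
      sprintf("%.2f%% symmetric, %.2f%% in ApT context\n",
              100 * x$fraction_symmetric, 100 * x$fraction_apt), sep = "")
  print(table(x$sites$symmetry))
  invisible(x)
}

#' @export
glance.apt_symmetry <- function(x, ...) {
  tibble::tibble(
    n_sites = x$n_sites,
    n_symmetric_sites = x$n_symmetric_sites,
    fraction_symmetric = x$fraction_symmetric,
    fraction_apt = x$fraction_apt
  )
}

#' @export
tidy.apt_symmetry <- function(x, ...) x$pairs

# IUPAC code for a set of bases
iupac_code <- local({
  codes <- c(A = "A", C = "C", G = "G", T = "T",
             AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
             ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  function(bases) {
    key <- paste(sort(unique(bases)), collapse = "")
    if (key == "") "N" else codes[[key]]
  }
})

#' Summarize the sequence context of methylated sites
#'
#' Extracts the window of `flank` nucleotides on each side of every site (13
#' columns for the default `flank = 6`), reverse-complementing minus-strand
#' windows so the methylated adenine is always the central column. Returns the
#' column-normalized position frequency matrix, an IUPAC consensus (a base
#' enters a column's code when its frequency is at least `consensus_min`), and
#' the fraction of sites followed by T (i.e. in ApT dinucleotides).
#'
#' @param sites Filtered site tibble.
#' @param genome A `genome_index`.
#' @param flank Flank width in nt (default 6).
#' @param consensus_min Per-column frequency needed for a base to enter the
#'   IUPAC code (default 0.25).
#' @return Object of class `motif_summary`: `pfm` (4 x (2*flank+1) matrix),
#'   `consensus`, `apt_fraction`, `n_sites`, `n_skipped` (sites too close to a
#'   contig end to extract a full window).
#' @export
summarize_contexts <- function(sites, genome, flank = 6, consensus_min = 0.25) {
  lens <- stats::setNames(genome$contigs$length, genome$contigs$contig)
  usable <- sites$pos > flank & sites$pos + flank <= lens[sites$contig]
  n_skipped <- sum(!usable)
  s <- sites[usable, , drop = FALSE]
  if (nrow(s) == 0) stop("no usable sites (all within ", flank, " bp of a contig end)")

  win_chr <- character(nrow(s))
  for (ct in unique(s$contig)) {
    idx <- which(s$contig == ct)
    str <- as.character(genome$seq[[ct]])
    win_chr[idx] <- substring(str, s$pos[idx] - flank, s$pos[idx] + flank)
  }
  win <- Biostrings::DNAStringSet(win_chr)
  minus <- s$strand == "-"
  if (any(minus)) win[minus] <- Biostrings::reverseComplement(win[minus])
  cm <- Biostrings::consensusMatrix(win, baseOnly = TRUE)[c("A", "C", "G", "T"), , drop = FALSE]
  pfm <- sweep(cm, 2, colSums(cm), "/")
  colnames(pfm) <- as.character(seq_len(ncol(pfm)) - flank - 1L)

  consensus <- paste(vapply(seq_len(ncol(pfm)), function(j) {
    iupac_code(rownames(pfm)[pfm[, j] >= consensus_min])
  }, ""), collapse = "")

  structure(
    list(pfm = pfm, consensus = consensus,
         apt_fraction = unname(pfm["T", as.character(1)]),
         n_sites = nrow(s), n_skipped = n_skipped, flank = flank),
    class = "motif_summary"
  )
}

#' @export
print.motif_summary <- function(x, ...) {
  cat("<motif_summary> ", x$n_sites, " sites (", x$n_skipped, " skipped)\n",
      "consensus: ", x$consensus, "\n",
      sprintf("ApT fraction: %.4f\n", x$apt_fraction), sep = "")
  invisible(x)
}

#' @export
tidy.motif_summary <- function(x, ...) {
  tibble::as_tibble(as.table(x$pfm), .name_repair = "minimal") |>
    stats::setNames(c("base", "offset", "frequency")) |>
    dplyr::mutate(offset = as.integer(as.character(.data$offset)))
}

#' @export
glance.motif_summary <- function(x, ...) {
  tibble::tibble(consensus = x$consensus, apt_fraction = x$apt_fraction,
                 n_sites = x$n_sites, n_skipped = x$n_skipped)
}

#' Genomic 6mA level
#'
#' Percentage of adenines (counted on both strands: plus-strand A plus
#' plus-strand T) that carry a filtered 6mA call.
#'
#' @param sites Filtered site tibble.
#' @param genome A `genome_index`.
#' @return A single percentage.
#' @export
global_6ma_level <- function(sites, genome) {
  if (genome$n_adenines == 0) stop("genome contains no adenines")
  100 * nrow(sites) / genome$n_adenines
}

#' In-silico isoschizomer digestion at GATC
#'
#' Partitions GATC occurrences into methylated (the adenine of GATC carries a
#' filtered 6mA call on either strand) and unmethylated, then cuts: DpnI at
#' methylated GATC only, DpnII at unmethylated GATC only. The cut is placed
#' at the palindromic center of GATC (between A and T, the blunt cut DpnI
#' makes), which keeps the fragment-length multiset invariant under reverse
#' complementation of the genome. GATC is palindromic, so one plus-strand
#' scan covers both strands.
#'
#' @param genome A `genome_index`.
#' @param sites Filtered site tibble.
#' @param enzyme `"DpnI"` or `"DpnII"`.
#' @return Tibble of fragments: `contig`, `start`, `end`, `length`.
#' @export
digest_insilico <- function(genome, sites, enzyme = c("DpnI", "DpnII")) {
  enzyme <- match.arg(enzyme)
  site_key <- paste(sites$contig, sites$pos, sites$strand)
  out <- purrr::map(genome$contigs$contig, function(ct) {
    len <- genome$contigs$length[genome$contigs$contig == ct]
    m <- Biostrings::matchPattern("GATC", genome$seq[[ct]])
    gstart <- BiocGenerics::start(m)
    # plus-strand A of GATC at gstart+1; minus-strand A opposite the T at gstart+2
    methylated <- paste(ct, gstart + 1L, "+") %in% site_key |
      paste(ct, gstart + 2L, "-") %in% site_key
    cut_at <- if (enzyme == "DpnI") gstart[methylated] else gstart[!methylated]
    bounds <- c(0L, sort(cut_at) + 1L, len)  # center cut: between A and T
    tibble::tibble(
      contig = ct,
      start = utils::head(bounds, -1) + 1L,
      end = utils::tail(bounds, -1),
      length = diff(bounds)
    )
  })
  dplyr::bind_rows(out)
}

#' Find putative telomeric repeat runs
#'
#' Searches each contig for maximal tandem runs of at least `min_units` copies
#' of the repeat unit on the plus strand, and of its reverse complement
#' (reported as minus-strand hits).
#'
#' @param genome A `genome_index`.
#' @param unit Repeat unit (default `"TTAGGG"`).
#' @param min_units Minimum tandem copies (default 2).
#' @return Tibble: `contig`, `start`, `end`, `strand`, `n_units`,
#'   `dist_to_end` (bp from the nearer contig end).
#' @export
find_telomere_repeats <- function(genome, unit = "TTAGGG", min_units = 2) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(unit)))
  scan_one <- function(ct, pattern, strand) {
    s <- as.character(genome$seq[[ct]])
    len <- nchar(s)
    rx <- sprintf("(?:%s){%d,}", pattern, min_units)
    m <- gregexpr(rx, s)[[1]]
    if (m[1] == -1) return(NULL)
    start <- as.integer(m)
    end <- start + attr(m, "match.length") - 1L
    tibble::tibble(
      contig = ct, start = start, end = end, strand = strand,
      n_units = (end - start + 1L) %/% nchar(pattern),
      dist_to_end = pmin(start - 1L, len - end)
    )
  }
  res <- purrr::map(genome$contigs$contig, function(ct) {
    dplyr::bind_rows(scan_one(ct, unit, "+"), scan_one(ct, rc, "-"))
  })
  dplyr::bind_rows(res)
}
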