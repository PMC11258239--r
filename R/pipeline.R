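#' Characterize a dual methylome end to end
#'
#' Runs the full analysis narrative on one sample: 6mA site filtering,
#' ApT symmetry classification, flanking-context summarization, global
#' level, MAC distance scan and clustering, feature-partition enrichment,
#' gene metagene profile, TSS-window counts, weighted 5mC levels by context,
#' and expression-stratified association. Stages that need missing inputs
#' (expression, bisulfite) are skipped with an explicit notice in the
#' report. Any stage error aborts with the stage name.
#'
#' @param genome A `genome_index`.
#' @param genes Gene models tibble.
#' @param sites Unfiltered 6mA site tibble.
#' @param repeats Optional repeat tibble.
#' @param cytosines Optional CX-style cytosine tibble.
#' @param expression Optional expression tibble.
#' @param config Named list of stage parameters; see Details. Unset entries
#'   fall back to defaults: filter (15x, mQv > 25), MAC scan over d = 1..40
#'   with a 2-motif minimum, TSS window -150/+400, promoter 600 bp, gene
#'   metagene 1.5 kb body + 0.5 kb flanks in 60 + 2x20 bins.
#' @param out_dir Optional directory; when given, all tables, the resolved
#'   configuration and a text report are written there.
#' @return Object of class `methylome_characterization`: list of stage
#'   results (`filtered_sites`, `symmetry`, `motif`, `global_level`, `macs`,
#'   `enrichment`, `metagene`, `tss_counts`, `weighted_5mc`, `strata`,
#'   `association`, `partition`, `config`, `notices`). `glance()` returns the
#'   headline statistics.
#' @export
characterize_methylome <- function(genome, genes, sites, repeats = NULL,
                                   cytosines = NULL, expression = NULL,
                                   config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(list(
    min_coverage = 15, min_mqv = 25, mqv_missing = "pass",
    motif = "AT", d_range = 1:40, min_methylated = 2,
    mac_size_range = c(50, 500),
    tss_window = c(-150, 400), promoter_len = 600,
    metagene_body = 1500, metagene_flank = 500,
    metagene_body_bins = 60, metagene_flank_bins = 20,
    n_top = 400
  ), config)
  notices <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  filtered <- stage("filter", filter_sites(sites, cfg$min_coverage, cfg$min_mqv,
                                           cfg$mqv_missing))
  symmetry <- stage("symmetry", classify_symmetry(filtered, genome))
  motif <- stage("motif", summarize_contexts(filtered, genome))
  level <- stage("global_level", global_6ma_level(filtered, genome))
  macs <- stage("mac_detection",
                detect_macs(genome, filtered, cfg$motif, cfg$d_range,
                            cfg$min_methylated, cfg$mac_size_range))
  partition <- stage("partition",
                     partition_features(genome, genes, repeats, cfg$promoter_len))
  enrich <- stage("enrichment",
                  feature_enrichment(filtered, partition, genome, base = "A"))
  metagene <- stage("metagene", metagene_profile(
    filtered, genes[, c("contig", "start", "end", "strand")],
    cfg$metagene_body, cfg$metagene_flank,
    cfg$metagene_body_bins, cfg$metagene_flank_bins
  ))
  tss_counts <- stage("tss_counts",
                      tss_window_counts(filtered, genes, macs$macs, cfg$tss_window))

  weighted <- NULL
  if (!is.null(cytosines)) {
    weighted <- stage("weighted_5mc", weighted_methylation(cytosines))
  } else {
    notices <- c(notices, "no bisulfite data: 5mC sections skipped")
  }

  strata <- NULL; association <- NULL
  if (!is.null(expression)) {
    strata <- stage("stratify", stratify_expression(expression,
                                                    min(cfg$n_top, nrow(expression) %/% 2)))
    association <- stage("association", methylation_by_stratum(strata, tss_counts))
  } else {
    notices <- c(notices, "no expression data: stratified association skipped")
  }

  res <- structure(
    list(filtered_sites = filtered, symmetry = symmetry, motif = motif,
         global_level = level, macs = macs, partition = partition,
         enrichment = enrich, metagene = metagene, tss_counts = tss_counts,
         weighted_5mc = weighted, strata = strata, association = association,
         config = cfg, notices = notices,
         genome_contigs = genome$contigs[, c("contig", "length")]),
    class = "methylome_characterization"
  )
  if (!is.null(out_dir)) write_characterization(res, out_dir)
  res
}

#' @export
print.methylome_characterization <- function(x, ...) {
  cat("<methylome_characterization>\n")
  print(glance.methylome_characterization(x))
  for (n in x$notices) cat("note:", n, "\n")
  invisible(x)
}

#' @export
glance.methylome_characterization <- function(x, ...) {
  cg_level <- if (!is.null(x$weighted_5mc)) {
    x$weighted_5mc$level[x$weighted_5mc$context == "CG"]
  } else {
    NA_real_
  }
  tibble::tibble(
    n_sites = nrow(x$filtered_sites),
    global_level_pct = x$global_level,
    fraction_symmetric = x$symmetry$fraction_symmetric,
    fraction_apt = x$symmetry$fraction_apt,
    consensus = x$motif$consensus,
    d_star = x$macs$scan$d_star,
    n_macs = nrow(x$macs$macs),
    fraction_in_macs = fraction_sites_in_macs(x$filtered_sites, x$macs$macs),
    weighted_cg_level = cg_level
  )
}

write_characterization <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) readr::write_tsv(x, file.path(out_dir, name), progress = FALSE)
  w(res$filtered_sites, "sites_filtered.tsv")
  w(res$symmetry$pairs, "symmetry_pairs.tsv")
  w(res$macs$scan$table, "mac_scan.tsv")
  write_macs_bed(res$macs$macs, file.path(out_dir, "macs.bed"))
  w(tibble::as_tibble(res$enrichment), "feature_enrichment.tsv")
  w(tibble::as_tibble(res$metagene), "metagene_profile.tsv")
  w(res$tss_counts, "tss_window_counts.tsv")
  pfm <- tibble::as_tibble(res$motif$pfm, rownames = "base")
  w(pfm, "motif_pfm.tsv")
  if (!is.null(res$weighted_5mc)) w(res$weighted_5mc, "weighted_5mc.tsv")
  if (!is.null(res$association)) w(res$association, "stratum_association.tsv")
  cfg <- res$config
  cfg$d_range <- paste(range(cfg$d_range), collapse = "..")
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  g <- glance.methylome_characterization(res)
  rep_lines <- c(
    "methylome characterization report",
    sprintf("filtered sites: %d (policy: >=%dx coverage, mQv > %d)",
            g$n_sites, res$config$min_coverage, res$config$min_mqv),
    sprintf("global 6mA level: %.4f%% of adenines", g$global_level_pct),
    sprintf("symmetric site fraction: %.4f; ApT site fraction: %.4f",
            g$fraction_symmetric, g$fraction_apt),
    sprintf("context consensus: %s", g$consensus),
    sprintf("MACs: %d at d* = %d; %.4f of sites inside MACs",
            g$n_macs, g$d_star, g$fraction_in_macs),
    if (!is.null(res$weighted_5mc)) {
      sprintf("weighted 5mC level (CG): %.4f", g$weighted_cg_level)
    },
    res$notices
  )
  writeLines(rep_lines[!is.na(rep_lines)], file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Compare two methylome characterizations on the same genome
#'
#' Computes per-gene MAC gain/loss between the two conditions and, when
#' differential-expression gene sets are given, per-site methylation-ratio
#' shifts with a Welch test between the up- and down-regulated sets.
#'
#' @param run_a,run_b `methylome_characterization` objects for treatment and
#'   control, produced on the same genome and annotation.
#' @param genome A `genome_index` (for identity checking).
#' @param genes Gene models tibble.
#' @param deg Optional tibble `gene_id`, `direction` with values `"up"` /
#'   `"down"` (others ignored).
#' @param window TSS window.
#' @return List of class `methylome_comparison`: `gain_loss`, `ratio_shift`
#'   (or NULL), `n_gained`, `n_lost`.
#' @export
compare_methylomes <- function(run_a, run_b, genome, genes, deg = NULL,
                               window = c(-150, 400)) {
  ref <- genome$contigs[, c("contig", "length")]
  if (!identical(run_a$genome_contigs, ref) ||
      !identical(run_b$genome_contigs, ref)) {
    stop("runs were not produced on the same genome (contig names/lengths differ)")
  }
  gl <- mac_gain_loss(run_a$macs$macs, run_b$macs$macs, genes, window,
                      de = deg)
  shift <- NULL
  if (!is.null(deg)) {
    sets <- list(up = deg$gene_id[deg$direction == "up"],
                 down = deg$gene_id[deg$direction == "down"])
    shift <- ratio_shift_test(run_a$filtered_sites, run_b$filtered_sites,
                              genes, sets, window)
  }
  structure(
    list(gain_loss = gl, ratio_shift = shift,
         n_gained = sum(gl$status == "gained"),
         n_lost = sum(gl$status == "lost")),
    class = "methylome_comparison"
  )
}

#' @export
print.methylome_comparison <- function(x, ...) {
  cat("<methylome_comparison> ", x$n_gained, " genes gained a MAC, ",
      x$n_lost, " lost\n", sep = "")
  if (!is.null(x$ratio_shift)) print(x$ratio_shift)
  invisible(x)
}
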