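# Per-position cytosine context over one strand of a contig.
# `s` is the plus-strand sequence as a character vector of single bases.
# Returns a character vector (length of the contig) with CG/CHG/CHH at
# cytosine positions of the requested strand and NA elsewhere; cytosines
# within 2 bp of the contig end on their strand are NA (context truncated).
context_of <- function(s, strand) {
  L <- length(s)
  out <- rep(NA_character_, L)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  if (strand == "+") {
    idx <- which(s == "C")
    idx <- idx[idx <= L - 2L]
    if (length(idx) == 0) return(out)
    b1 <- s[idx + 1L]; b2 <- s[idx + 2L]
  } else {
    idx <- which(s == "G")  # C on the minus strand
    idx <- idx[idx >= 3L]
    if (length(idx) == 0) return(out)
    b1 <- comp[s[idx - 1L]]; b2 <- comp[s[idx - 2L]]
  }
  out[idx] <- ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH"))
  out[idx][b1 == "N" | (b1 != "G" & b2 == "N")] <- NA_character_
  out
}

#' Assign the CG/CHG/CHH context of cytosines
#'
#' On the cytosine's own strand, the next two bases classify the context: CG
#' when +1 is G; CHG when +1 is H (A, C or T) and +2 is G; CHH otherwise
#' (H = A, C or T). Cytosines within 2 bp of the contig end on their strand
#' have a truncated context and return NA.
#'
#' @param genome A `genome_index`.
#' @param contig,pos,strand Parallel vectors identifying cytosines (plus
#'   strand base C for `"+"`, G for `"-"`).
#' @return Character vector of contexts (`"CG"`, `"CHG"`, `"CHH"`, or NA).
#' @export
assign_cytosine_context <- function(genome, contig, pos, strand) {
  stopifnot(length(contig) == length(pos), length(pos) == length(strand))
  base <- genome_base(genome, contig, pos)
  is_c <- (strand == "+" & base == "C") | (strand == "-" & base == "G")
  if (any(!is_c, na.rm = TRUE) || anyNA(is_c)) {
    stop("position(s) are not cytosines on the stated strand")
  }
  out <- rep(NA_character_, length(pos))
  for (ct in unique(contig)) {
    idx <- which(contig == ct)
    s <- strsplit(as.character(genome$seq[[ct]]), "")[[1]]
    ctx_p <- context_of(s, "+")
    ctx_m <- context_of(s, "-")
    p <- pos[idx]
    out[idx] <- ifelse(strand[idx] == "+", ctx_p[p], ctx_m[p])
  }
  out
}

#' Weighted methylation level by cytosine context
#'
#' The weighted level pools reads before dividing: total methylated reads over
#' total (methylated + unmethylated) reads, per context and overall. When all
#' sites share identical coverage this equals the arithmetic mean of the
#' per-site ratios. Computed over all covered cytosines by default; filtering
#' to "methylated sites" before pooling would inflate the level and is left
#' to [filter_cytosines()] for site counting.
#'
#' @param cytosines Cytosine tibble (see [read_cx_report()]).
#' @param regions Optional tibble `contig`, `start`, `end`: restrict to these
#'   intervals.
#' @param by_context Also report per-context levels (default TRUE).
#' @return Tibble `context`, `n_sites`, `meth_reads`, `total_reads`, `level`
#'   (NA when a context has zero reads in the subset). The `"all"` row pools
#'   every context.
#' @export
weighted_methylation <- function(cytosines, regions = NULL, by_context = TRUE) {
  cx <- cytosines
  if (!is.null(regions)) {
    if (nrow(regions) == 0) stop("empty region set")
    cg <- GenomicRanges::GRanges(cx$contig, IRanges::IRanges(cx$pos, cx$pos))
    rg <- GenomicRanges::GRanges(regions$contig, IRanges::IRanges(regions$start, regions$end))
    cx <- cx[IRanges::overlapsAny(cg, rg), , drop = FALSE]
  }
  level_row <- function(sub, label) {
    m <- sum(sub$n_meth); u <- sum(sub$n_unmeth)
    tibble::tibble(context = label, n_sites = nrow(sub), meth_reads = m,
                   total_reads = m + u,
                   level = ifelse(m + u > 0, m / (m + u), NA_real_))
  }
  out <- level_row(cx, "all")
  if (by_context) {
    per <- purrr::map(c("CG", "CHG", "CHH"), function(k) {
      level_row(cx[cx$context == k, , drop = FALSE], k)
    })
    out <- dplyr::bind_rows(per, out)
  }
  out
}

#' Filter cytosines to "methylated sites"
#'
#' Keeps cytosines with coverage (methylated + unmethylated reads) of at least
#' `min_coverage` and methylation ratio of at least `min_ratio`; both bounds
#' inclusive. This defines the methylated-site set used for per-gene site
#' counting and association analyses; weighted levels should be computed from
#' the unfiltered calls.
#'
#' @param cytosines Cytosine tibble.
#' @param min_coverage Minimum reads (default 5).
#' @param min_ratio Minimum methylation ratio (default 0.10).
#' @return Filtered tibble.
#' @export
filter_cytosines <- function(cytosines, min_coverage = 5, min_ratio = 0.10) {
  cov <- cytosines$n_meth + cytosines$n_unmeth
  ratio <- ifelse(cov > 0, cytosines$n_meth / cov, 0)
  cytosines[cov >= min_coverage & ratio >= min_ratio, , drop = FALSE]
}

#' Per-context 5mC metaplot over genomic elements
#'
#' Computes a scaled metagene profile of the weighted methylation level
#' (reads pooled within each bin) separately for the CG, CHG and CHH
#' contexts. Default geometry matches transposon-style metaplots: bodies
#' scaled to 3 kb with 3 kb unscaled flanks.
#'
#' @param cytosines Cytosine tibble.
#' @param elements Tibble `contig`, `start`, `end`, `strand`.
#' @param body_len,flank_len,n_body_bins,n_flank_bins Profile geometry.
#' @return Tibble with one `metagene_profile` per context stacked long:
#'   columns `context`, `bin`, `section`, `value`, `n`.
#' @export
element_metaplot <- function(cytosines, elements, body_len = 3000,
                             flank_len = 3000, n_body_bins = 60,
                             n_flank_bins = 60) {
  if (nrow(elements) == 0) stop("empty element set")
  purrr::map(c("CG", "CHG", "CHH"), function(k) {
    sub <- cytosines[cytosines$context == k, , drop = FALSE]
    prof <- metagene_profile(sub, elements, body_len, flank_len,
                             n_body_bins, n_flank_bins, value = "level")
    dplyr::mutate(tibble::as_tibble(prof), context = k, .before = 1)
  }) |> dplyr::bind_rows()
}
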