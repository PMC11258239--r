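#' Load a genome from FASTA into an indexed object
#'
#' Reads a FASTA file (or accepts a [Biostrings::DNAStringSet] directly),
#' uppercases the sequence, records any soft-masked (lowercase) intervals as a
#' mask track, and precomputes per-contig base counts. The total adenine count
#' over both strands (plus-strand A plus plus-strand T) is the denominator of
#' the genomic 6mA level.
#'
#' All coordinates in this package are 1-based and inclusive, the convention of
#' Biostrings/GenomicRanges; conversions to 0-based half-open happen only when
#' writing BED.
#'
#' @param x Path to a FASTA file, a named character vector of sequences, or a
#'   `DNAStringSet`.
#' @return An object of class `genome_index`: a list with elements `seq`
#'   (uppercase `DNAStringSet`), `contigs` (tibble with `contig`, `length`,
#'   and base counts `A`, `C`, `G`, `T`, `N`), `mask` (per-contig tibble of
#'   soft-masked intervals) and `n_adenines` (A on both strands).
#' @export
#' @examples
#' g <- read_genome(c(chr1 = "AATTGCGC"))
#' g$n_adenines
read_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    raw_chr <- as.character(x)
  } else if (is.character(x) && length(x) == 1 && file.exists(x) &&
             !grepl("^[ACGTNacgtn]+$", x)) {
    # BStringSet preserves case, so soft-masking survives the read
    seqs_raw <- Biostrings::readBStringSet(x, format = "fasta")
    if (length(seqs_raw) == 0) stop("no records in FASTA file ", x)
    raw_chr <- as.character(seqs_raw)
    # keep only the first whitespace-delimited token of each header
    names(raw_chr) <- sub("\\s.*$", "", names(seqs_raw))
  } else if (is.character(x)) {
    raw_chr <- x
    if (is.null(names(raw_chr))) names(raw_chr) <- paste0("contig", seq_along(raw_chr))
  } else {
    stop("`x` must be a FASTA path, named character vector, or DNAStringSet")
  }
  if (length(raw_chr) == 0) stop("no records")
  nm <- names(raw_chr)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) stop("all contigs must be named")
  if (anyDuplicated(nm)) {
    stop("duplicate contig names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  mask <- purrr::map(raw_chr, function(s) {
    m <- gregexpr("[acgtn]+", s)[[1]]
    if (m[1] == -1) {
      return(tibble::tibble(start = integer(), end = integer()))
    }
    tibble::tibble(start = as.integer(m), end = as.integer(m) + attr(m, "match.length") - 1L)
  })
  names(mask) <- nm

  up <- toupper(raw_chr)
  bad <- regexpr("[^ACGTN]", up)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("invalid character '%s' in contig %s at position %d",
                 substring(up[i], bad[i], bad[i]), nm[i], bad[i]))
  }
  seqs <- Biostrings::DNAStringSet(up)
  names(seqs) <- nm

  af <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  contigs <- tibble::tibble(
    contig = nm,
    length = Biostrings::width(seqs),
    A = as.integer(af[, "A"]), C = as.integer(af[, "C"]),
    G = as.integer(af[, "G"]), T = as.integer(af[, "T"]),
    N = as.integer(af[, "other"])
  )
  structure(
    list(seq = seqs, contigs = contigs, mask = mask,
         n_adenines = sum(contigs$A) + sum(contigs$T)),
    class = "genome_index"
  )
}

#' @export
print.genome_index <- function(x, ...) {
  cat("<genome_index> ", nrow(x$contigs), " contig(s), ",
      format(sum(x$contigs$length), big.mark = ","), " bp, ",
      format(x$n_adenines, big.mark = ","), " adenines (both strands)\n", sep = "")
  print(x$contigs, ...)
  invisible(x)
}

#' Total genome length
#' @param genome A `genome_index`.
#' @return Integer total length in bp.
#' @export
genome_length <- function(genome) sum(genome$contigs$length)

# Vectorized single-base lookup on the plus strand (1-based positions).
# Positions outside [1, contig length] return NA.
genome_base <- function(genome, contig, pos) {
  stopifnot(length(contig) == length(pos))
  out <- rep(NA_character_, length(pos))
  lens <- stats::setNames(genome$contigs$length, genome$contigs$contig)
  for (ct in unique(contig)) {
    idx <- which(contig == ct)
    if (!ct %in% names(lens)) stop("unknown contig: ", ct)
    s <- as.character(genome$seq[[ct]])
    p <- pos[idx]
    ok <- !is.na(p) & p >= 1 & p <= lens[[ct]]
    out[idx[ok]] <- substring(s, p[ok], p[ok])
  }
  out
}

check_contigs_known <- function(genome, contig, what = "record") {
  unknown <- setdiff(unique(contig), genome$contigs$contig)
  if (length(unknown) > 0) {
    stop(what, " on unknown contig(s): ", paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

#' Load gene models from GFF3
#'
#' Parses a GFF3 file with `gene`/`mRNA`/`exon` features (1-based inclusive
#' coordinates, the GFF3 convention) and derives one model per gene: span,
#' strand, TSS/TTS and ordered exon intervals from the gene's first mRNA.
#' UTR features (`five_prime_UTR`/`three_prime_UTR`) are kept when present.
#'
#' @param path Path to a GFF3 file.
#' @param genome A `genome_index`; used to validate contigs and bounds.
#' @return A tibble with one row per gene: `gene_id`, `contig`, `strand`,
#'   `start`, `end`, `tss`, `tts`, and list-columns `exons`, `utr5`, `utr3`
#'   (tibbles of `start`/`end`).
#' @export
read_gene_models <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  get_id <- function(i) as.character(md$ID[i])
  get_parent <- function(i) {
    p <- md$Parent[i]
    vapply(as.list(p), function(v) if (length(v)) as.character(v)[1] else NA_character_, "")
  }

  gi <- which(type == "gene")
  if (length(gi) == 0) stop("no gene features in ", path)
  genes <- tibble::tibble(
    gene_id = get_id(gi),
    contig = as.character(GenomicRanges::seqnames(gr)[gi]),
    strand = as.character(BiocGenerics::strand(gr)[gi]),
    start = GenomicRanges::start(gr)[gi],
    end = GenomicRanges::end(gr)[gi]
  )
  if (any(!genes$strand %in% c("+", "-"))) stop("genes must be stranded (+/-)")
  check_contigs_known(genome, genes$contig, "gene")
  lens <- stats::setNames(genome$contigs$length, genome$contigs$contig)
  over <- genes$end > lens[genes$contig] | genes$start < 1
  if (any(over)) {
    stop("gene(s) beyond contig bounds: ", paste(genes$gene_id[over], collapse = ", "))
  }

  mi <- which(type == "mRNA")
  mrna <- tibble::tibble(mrna_id = get_id(mi), gene_id = get_parent(mi))
  # first mRNA per gene, in file order
  mrna <- mrna[!duplicated(mrna$gene_id), , drop = FALSE]

  sub_features <- function(ftype) {
    xi <- which(type == ftype)
    tibble::tibble(
      parent = get_parent(xi),
      start = GenomicRanges::start(gr)[xi],
      end = GenomicRanges::end(gr)[xi]
    )
  }
  exons <- sub_features("exon")
  utr5 <- sub_features("five_prime_UTR")
  utr3 <- sub_features("three_prime_UTR")

  collect <- function(tab, mrna_id) {
    sub <- tab[!is.na(tab$parent) & tab$parent == mrna_id, c("start", "end")]
    sub[order(sub$start), , drop = FALSE]
  }

  genes$exons <- vector("list", nrow(genes))
  genes$utr5 <- vector("list", nrow(genes))
  genes$utr3 <- vector("list", nrow(genes))
  keep <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    mid <- mrna$mrna_id[match(genes$gene_id[i], mrna$gene_id)]
    ex <- if (is.na(mid)) exons[0, c("start", "end")] else collect(exons, mid)
    if (nrow(ex) == 0) {
      warning("gene ", genes$gene_id[i], " has no exons; skipped")
      next
    }
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      stop("overlapping exons in gene ", genes$gene_id[i])
    }
    genes$exons[[i]] <- tibble::as_tibble(ex)
    genes$utr5[[i]] <- tibble::as_tibble(if (is.na(mid)) utr5[0, c("start", "end")] else collect(utr5, mid))
    genes$utr3[[i]] <- tibble::as_tibble(if (is.na(mid)) utr3[0, c("start", "end")] else collect(utr3, mid))
    keep[i] <- TRUE
  }
  genes <- genes[keep, , drop = FALSE]
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tts <- ifelse(genes$strand == "+", genes$end, genes$start)
  dplyr::relocate(tibble::as_tibble(genes), "gene_id", "contig", "strand",
                  "start", "end", "tss", "tts")
}

#' Load repeat intervals from BED
#'
#' @param path Path to a BED file (0-based half-open, converted to 1-based
#'   inclusive on load).
#' @param genome A `genome_index`.
#' @return Tibble with `contig`, `start`, `end` (1-based inclusive) and `name`.
#' @export
read_repeats <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- tibble::tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  )
  check_contigs_known(genome, out$contig, "repeat")
  out
}

SITE_TABLE_HEADER <- "# sixmac 6mA site table v1"

#' Load per-site 6mA modification calls
#'
#' Accepts either the canonical tab-delimited site table (columns `contig`,
#' `pos` (1-based), `strand`, `coverage`, and `n_meth` or `frac`, optional
#' `mqv`) or the base-modification GFF dialect (`modified_base` rows carrying
#' `coverage`, `frac`/`frequency` and `identificationQv` attributes).
#' Fractional inputs are converted to integer methylated-read counts with
#' round-half-even rounding of `coverage * frac`. Rows whose reference base on
#' the stated strand is not adenine are rejected and counted; more than 1%
#' rejected rows aborts, since that usually signals a coordinate-convention
#' mismatch.
#'
#' @param path Path to the table.
#' @param genome A `genome_index`.
#' @param format `"auto"` (default), `"tsv"`, or `"gff"`.
#' @return Tibble of sites: `contig`, `pos`, `strand`, `coverage`, `n_meth`,
#'   `mqv`, `ratio`; attribute `n_rejected` counts non-adenine rows dropped.
#' @export
read_site_calls <- function(path, genome, format = c("auto", "tsv", "gff")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 5)
    format <- if (any(grepl("^##gff-version", first)) ||
                  any(grepl("\tmodified_base\t", first))) "gff" else "tsv"
  }
  if (format == "gff") {
    gr <- rtracklayer::import(path, format = "gff3")
    md <- S4Vectors::mcols(gr)
    num_attr <- function(x) suppressWarnings(as.numeric(as.character(x)))
    cov <- num_attr(md$coverage)
    frac <- if (!is.null(md$frac)) num_attr(md$frac) else num_attr(md$frequency)
    mqv <- if (!is.null(md$identificationQv)) num_attr(md$identificationQv) else NA_real_
    tab <- tibble::tibble(
      contig = as.character(GenomicRanges::seqnames(gr)),
      pos = GenomicRanges::start(gr),
      strand = as.character(BiocGenerics::strand(gr)),
      coverage = cov,
      n_meth = round(cov * frac),
      mqv = mqv
    )
  } else {
    tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
    req <- c("contig", "pos", "strand", "coverage")
    if (!all(req %in% names(tab))) {
      stop("site table must have columns ", paste(req, collapse = ", "),
           " plus n_meth or frac")
    }
    if ("n_meth" %in% names(tab)) {
      tab$n_meth <- as.numeric(tab$n_meth)
    } else if ("frac" %in% names(tab)) {
      # round() is round-half-even in R, which is what we want here
      tab$n_meth <- round(as.numeric(tab$coverage) * as.numeric(tab$frac))
    } else {
      stop("site table needs a n_meth or frac column")
    }
    if (!"mqv" %in% names(tab)) tab$mqv <- NA_real_
    tab <- tab[, c("contig", "pos", "strand", "coverage", "n_meth", "mqv")]
  }
  bad_row <- !tab$strand %in% c("+", "-") | is.na(tab$pos) | is.na(tab$coverage) |
    is.na(tab$n_meth) | tab$n_meth < 0 | tab$n_meth > tab$coverage
  if (any(bad_row)) {
    stop("malformed site row(s) at line(s): ",
         paste(utils::head(which(bad_row), 5), collapse = ", "))
  }
  check_contigs_known(genome, tab$contig, "site")
  validate_sites(tab, genome)
}

# Shared validation: reference base must be adenine on the stated strand.
validate_sites <- function(tab, genome) {
  base <- genome_base(genome, tab$contig, tab$pos)
  ok <- (tab$strand == "+" & base == "A") | (tab$strand == "-" & base == "T")
  ok[is.na(ok)] <- FALSE
  n_rej <- sum(!ok)
  # a handful of bad rows is tolerated (and counted) even in tiny tables;
  # a systematic excess signals an off-by-one coordinate convention
  if (n_rej > max(10, 0.01 * nrow(tab))) {
    stop(n_rej, " of ", nrow(tab), " site rows are not at an adenine on the ",
         "stated strand (>1%); check the coordinate convention of the input")
  }
  out <- tibble::as_tibble(tab[ok, , drop = FALSE])
  out$pos <- as.integer(out$pos)
  out$coverage <- as.integer(out$coverage)
  out$n_meth <- as.integer(out$n_meth)
  out$ratio <- out$n_meth / out$coverage
  out <- dplyr::arrange(out, .data$contig, .data$pos, .data$strand)
  attr(out, "n_rejected") <- n_rej
  out
}

#' Write the canonical 6mA site table
#'
#' @param sites Site tibble as returned by [read_site_calls()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_calls <- function(sites, path) {
  readr::write_lines(SITE_TABLE_HEADER, path)
  readr::write_tsv(
    sites[, c("contig", "pos", "strand", "coverage", "n_meth", "mqv")],
    path, append = TRUE, col_names = TRUE, progress = FALSE
  )
  invisible(path)
}

#' Load a CX-style per-cytosine bisulfite report
#'
#' Expects tab-delimited rows `contig`, `pos` (1-based), `strand`, `n_meth`,
#' `n_unmeth`, `context` with no header (the Bismark CX-report layout; a
#' seventh trinucleotide column is ignored). The context label is re-derived
#' from the genome and compared to the file's label; a mismatch rate above 1%
#' aborts.
#'
#' @param path Path to the report.
#' @param genome A `genome_index`.
#' @return Tibble `contig`, `pos`, `strand`, `n_meth`, `n_unmeth`, `context`
#'   (re-derived), with attribute `n_context_mismatch`.
#' @export
read_cx_report <- function(path, genome) {
  tab <- readr::read_tsv(
    path,
    col_names = c("contig", "pos", "strand", "n_meth", "n_unmeth", "context"),
    col_types = readr::cols_only(
      contig = "c", pos = "i", strand = "c",
      n_meth = "i", n_unmeth = "i", context = "c"
    ),
    comment = "#", show_col_types = FALSE, progress = FALSE
  )
  if (any(tab$n_meth < 0 | tab$n_unmeth < 0, na.rm = TRUE)) {
    stop("negative counts in CX report")
  }
  check_contigs_known(genome, tab$contig, "cytosine")
  base <- genome_base(genome, tab$contig, tab$pos)
  is_c <- (tab$strand == "+" & base == "C") | (tab$strand == "-" & base == "G")
  if (any(!is_c)) {
    stop(sum(!is_c), " CX row(s) are not at a cytosine on the stated strand")
  }
  derived <- assign_cytosine_context(genome, tab$contig, tab$pos, tab$strand)
  mism <- !is.na(derived) & derived != tab$context
  if (mean(mism) > 0.01) {
    stop(sum(mism), " of ", nrow(tab),
         " CX rows disagree with the genome-derived context (>1%)")
  }
  out <- tab
  out$context <- derived
  out <- out[!is.na(out$context), , drop = FALSE]
  attr(out, "n_context_mismatch") <- sum(mism)
  out
}

#' Write a CX-style bisulfite report
#' @param cytosines Tibble as from [read_cx_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(cytosines, path) {
  readr::write_tsv(
    cytosines[, c("contig", "pos", "strand", "n_meth", "n_unmeth", "context")],
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Load a per-gene expression table
#'
#' @param path Tab-delimited file with columns `gene_id`, `abundance`
#'   (FPKM/TPM) and optionally `log2fc`, `pvalue`.
#' @return Tibble with those columns.
#' @export
read_expression <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "abundance") %in% names(tab))) {
    stop("expression table must have gene_id and abundance columns")
  }
  if (any(tab$abundance < 0, na.rm = TRUE)) stop("negative abundance values")
  tibble::as_tibble(tab)
}

#' Write MACs as BED
#'
#' Converts from internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention. The score column holds the number of methylated
#' motifs.
#'
#' @param macs MAC tibble from [detect_macs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_macs_bed <- function(macs, path) {
  bed <- tibble::tibble(
    chrom = macs$contig,
    start = macs$start - 1L,
    end = macs$end,
    name = paste0("MAC_", seq_len(nrow(macs))),
    score = macs$n_methylated,
    strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
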