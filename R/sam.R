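#' Read single-end alignments from a SAM file
#'
#' Converts the SAM to BAM on the fly (Rsamtools) and loads the alignment
#' fields the pipeline consumes.  Unmapped records are dropped.
#'
#' @param path Path to a SAM file with a valid header (`@SQ` lines for every
#'   reference used).
#' @return A tibble with one row per mapped record: `qname`, `flag`, `chrom`,
#'   `pos` (1-based leftmost aligned position, as in SAM) and `cigar`.
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  tibble::tibble(
    qname = S4Vectors::mcols(ga)$qname,
    flag = S4Vectors::mcols(ga)$flag,
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    pos = BiocGenerics::start(ga),
    cigar = GenomicAlignments::cigar(ga)
  )
}

#' Write alignments to a SAM file
#'
#' Emits single-end SAM records with filler sequence and base qualities (the
#' pipeline only consumes coordinates and CIGAR strings).
#'
#' @param alignments Tibble with columns `qname`, `flag`, `chrom`, `pos`
#'   (1-based), `cigar`.
#' @param path Output path.
#' @param chrom_lengths Named integer vector (or two-column data frame
#'   `chrom`/`length`) giving reference lengths for the `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, chrom_lengths) {
  if (is.data.frame(chrom_lengths)) {
    chrom_lengths <- stats::setNames(chrom_lengths$length, chrom_lengths$chrom)
  }
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(alignments$cigar)
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths), as.integer(chrom_lengths))
  )
  body <- sprintf(
    "%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s",
    alignments$qname, as.integer(alignments$flag), alignments$chrom,
    as.integer(alignments$pos), alignments$cigar,
    strrep("A", qw), strrep("I", qw)
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}

# Normalise input: accept a SAM path or an alignment tibble.
as_alignments <- function(x) {
  if (is.character(x) && length(x) == 1) {
    return(read_sam(x))
  }
  tibble::as_tibble(x)
}

# Split-read gap decomposition.  For every N operation of every alignment,
# returns the gap interval (0-based half-open on the reference) and the
# overhang: the smaller of the two sums of M lengths between this gap and the
# previous/next gap (or read end).  Insertions and deletions neither add to
# nor reset the overhang.  Records whose CIGARs contain operations other than
# M/I/D/S/N are dropped with a warning.
cigar_gaps <- function(alignments) {
  cig <- alignments$cigar
  ok <- !grepl("[^0-9MIDSN]", cig)
  if (any(!ok)) {
    warning(sum(!ok), " record(s) skipped: unsupported CIGAR operation")
    alignments <- alignments[ok, , drop = FALSE]
    cig <- cig[ok]
  }
  has_gap <- grepl("N", cig, fixed = TRUE)
  if (!any(has_gap)) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), overhang = integer()))
  }
  aln <- alignments[has_gap, , drop = FALSE]
  # fast path: plain single-gap reads (xM yN zM), the overwhelming majority
  simple <- stringr::str_match(aln$cigar, "^(\\d+)M(\\d+)N(\\d+)M$")
  is_simple <- !is.na(simple[, 1])
  simple_gaps <- if (any(is_simple)) {
    m1 <- as.integer(simple[is_simple, 2])
    gapw <- as.integer(simple[is_simple, 3])
    m2 <- as.integer(simple[is_simple, 4])
    tibble::tibble(
      chrom = aln$chrom[is_simple],
      start = aln$pos[is_simple] - 1L + m1,
      end = aln$pos[is_simple] - 1L + m1 + gapw,
      overhang = pmin(m1, m2)
    )
  } else {
    NULL
  }
  aln <- aln[!is_simple, , drop = FALSE]
  if (nrow(aln) == 0) {
    return(simple_gaps)
  }
  ops <- GenomicAlignments::explodeCigarOps(aln$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(aln$cigar)
  flat <- tibble::tibble(
    read = rep(seq_along(ops), lengths(ops)),
    op = unlist(ops),
    len = unlist(lens)
  ) |>
    dplyr::group_by(.data$read) |>
    dplyr::mutate(
      # chunk s (0-based) holds the M ops between gap s and gap s + 1
      seg = cumsum(.data$op == "N"),
      ref_adv = ifelse(.data$op %in% c("M", "D", "N"), .data$len, 0L),
      ref_off = cumsum(.data$ref_adv) - .data$ref_adv
    ) |>
    dplyr::ungroup()
  m_sums <- flat |>
    dplyr::filter(.data$op == "M") |>
    dplyr::group_by(.data$read, .data$seg) |>
    dplyr::summarise(m = sum(.data$len), .groups = "drop")
  gaps <- flat |>
    dplyr::filter(.data$op == "N") |>
    dplyr::mutate(left_seg = .data$seg - 1L) |>
    dplyr::left_join(dplyr::rename(m_sums, m_left = "m"),
                     by = c("read", left_seg = "seg")) |>
    dplyr::left_join(dplyr::rename(m_sums, m_right = "m"),
                     by = c("read", "seg")) |>
    tidyr::replace_na(list(m_left = 0L, m_right = 0L))
  dplyr::bind_rows(
    simple_gaps,
    tibble::tibble(
      chrom = aln$chrom[gaps$read],
      start = aln$pos[gaps$read] - 1L + gaps$ref_off,
      end = aln$pos[gaps$read] - 1L + gaps$ref_off + gaps$len,
      overhang = as.integer(pmin(gaps$m_left, gaps$m_right))
    )
  )
}
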