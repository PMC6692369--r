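#' Build an annotation object from an exon table
#'
#' The annotation is the central gene model used throughout the package:
#' genes, transcripts, exons and the introns derived from them.  All internal
#' coordinates are 0-based half-open (`[start, end)`); GTF input/output
#' converts from/to the 1-based inclusive convention at the boundary.
#'
#' @param exons A data frame with columns `gene_id`, `transcript_id`,
#'   `chrom`, `start`, `end`, `strand` (one row per exon, 0-based half-open).
#' @return An object of class `annotation`: a list of tibbles `exons`,
#'   `transcripts`, `genes`, `introns` and `intron_transcripts` (the
#'   intron-to-transcript back-map).
#' @details Exons of a transcript must be non-overlapping, lie on a single
#'   chromosome and strand, and have `end > start`.  Introns are the gaps
#'   between consecutive exons of any transcript, deduplicated over
#'   transcripts; each intron gets a stable id `chrom:start-end(strand)` and
#'   a length `L = end - start` in nucleotides.
#' @examples
#' exons <- tibble::tibble(
#'   gene_id = "g1", transcript_id = "g1.t1", chrom = "chr1",
#'   start = c(0, 200), end = c(100, 300), strand = "+"
#' )
#' ann <- as_annotation(exons)
#' ann$introns
#' @export
as_annotation <- function(exons) {
  required <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(exons))
  if (length(missing) > 0) {
    stop("exon table lacks column(s): ", paste(missing, collapse = ", "))
  }
  exons <- tibble::as_tibble(exons)[required]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$end <= exons$start) || any(exons$start < 0)) {
    stop("invalid exon interval: require 0 <= start < end")
  }
  if (!all(exons$strand %in% c("+", "-"))) {
    stop("exon strand must be '+' or '-'")
  }
  exons <- dplyr::arrange(exons, .data$gene_id, .data$transcript_id, .data$start)
  if (nrow(exons) == 0) {
    intr <- derive_introns_from_exons(exons)
    span0 <- tibble::tibble(chrom = character(), start = integer(),
                            end = integer(), strand = character())
    return(structure(
      list(exons = exons,
           transcripts = tibble::add_column(span0, transcript_id = character(),
                                            gene_id = character(), .before = 1),
           genes = tibble::add_column(span0, gene_id = character(), .before = 1),
           introns = intr$introns,
           intron_transcripts = intr$intron_transcripts),
      class = "annotation"
    ))
  }

  # per-transcript invariants: single chrom/strand, non-overlapping exons
  tx_check <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      n_chrom = dplyr::n_distinct(.data$chrom),
      n_strand = dplyr::n_distinct(.data$strand),
      n_gene = dplyr::n_distinct(.data$gene_id),
      overlapping = any(.data$start[-1] < .data$end[-dplyr::n()]) && dplyr::n() > 1,
      .groups = "drop"
    )
  bad <- tx_check$transcript_id[tx_check$n_chrom > 1 | tx_check$n_strand > 1 |
                                  tx_check$n_gene > 1]
  if (length(bad) > 0) {
    stop("transcript(s) span multiple chromosomes/strands/genes: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  ovl <- tx_check$transcript_id[tx_check$overlapping]
  if (length(ovl) > 0) {
    stop("transcript(s) with overlapping exons: ",
         paste(utils::head(ovl, 5), collapse = ", "))
  }

  transcripts <- exons |>
    dplyr::group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    dplyr::select("transcript_id", "gene_id", "chrom", "start", "end", "strand")

  genes <- transcripts |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    dplyr::select("gene_id", "chrom", "start", "end", "strand")

  intr <- derive_introns_from_exons(exons)
  structure(
    list(
      exons = exons,
      transcripts = transcripts,
      genes = genes,
      introns = intr$introns,
      intron_transcripts = intr$intron_transcripts
    ),
    class = "annotation"
  )
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf(
    "<annotation> %d gene(s), %d transcript(s), %d exon(s), %d derived intron(s)\n",
    nrow(x$genes), nrow(x$transcripts), nrow(x$exons), nrow(x$introns)
  ))
  invisible(x)
}

# Gaps between consecutive exons of each transcript, deduplicated over
# transcripts.  Returns the intron table plus the intron -> transcript map.
derive_introns_from_exons <- function(exons) {
  gaps <- exons |>
    dplyr::arrange(.data$transcript_id, .data$start) |>
    dplyr::group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) |>
    dplyr::reframe(
      gap_start = .data$end[-dplyr::n()],
      gap_end = .data$start[-1]
    ) |>
    dplyr::rename(start = "gap_start", end = "gap_end") |>
    dplyr::filter(.data$end > .data$start)  # touching exons leave no intron
  if (nrow(gaps) == 0) {
    introns <- tibble::tibble(
      intron_id = character(), gene_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character(), length = integer()
    )
    map <- tibble::tibble(intron_id = character(), transcript_id = character())
    return(list(introns = introns, intron_transcripts = map))
  }
  gaps$intron_id <- interval_id(gaps$chrom, gaps$start, gaps$end, gaps$strand)
  introns <- gaps |>
    dplyr::distinct(.data$intron_id, .data$gene_id, .data$chrom, .data$start,
                    .data$end, .data$strand) |>
    dplyr::mutate(length = .data$end - .data$start) |>
    dplyr::arrange(.data$gene_id, .data$start, .data$end)
  map <- gaps |>
    dplyr::distinct(.data$intron_id, .data$transcript_id)
  list(introns = introns, intron_transcripts = map)
}

interval_id <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d(%s)", chrom, start, end, strand)
}

#' Derive the intron set of an annotation
#'
#' Recomputes introns (gaps between consecutive exons of any transcript) from
#' the exon table.  `as_annotation()` already stores this set; the function is
#' exposed so intron derivation can be applied to a bare exon table.
#'
#' @param x An `annotation` object or an exon data frame as accepted by
#'   [as_annotation()].
#' @return A tibble of introns: `intron_id`, `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `length`.
#' @export
derive_introns <- function(x) {
  if (inherits(x, "annotation")) {
    return(x$introns)
  }
  derive_introns_from_exons(tibble::as_tibble(x))$introns
}

#' Does a transcript's genomic span fully subsume an interval?
#'
#' A transcript subsumes an interval when the interval lies entirely within
#' the transcript's genomic span (first exon start to last exon end).  This
#' is the containment predicate used by the neighbour-junction rules.
#'
#' @param transcript A one-row data frame (or list) with `chrom`, `start`,
#'   `end` giving the transcript span.
#' @param interval A one-row data frame (or list) with `chrom`, `start`, `end`.
#' @return `TRUE` or `FALSE`; intervals on a different chromosome give `FALSE`.
#' @export
transcript_subsumes <- function(transcript, interval) {
  isTRUE(transcript$chrom == interval$chrom &&
           transcript$start <= interval$start &&
           transcript$end >= interval$end)
}

# Vectorised per-junction summary of "all transcripts containing this exact
# interval": tightest enclosing span over those transcripts.  Junctions
# contained in no transcript (novel) get an infinitely permissive span so the
# subsumption conditions hold vacuously.
containing_span_summary <- function(ids, annotation) {
  tx <- annotation$intron_transcripts |>
    dplyr::inner_join(annotation$transcripts, by = "transcript_id") |>
    dplyr::group_by(.data$intron_id) |>
    dplyr::summarise(
      tx_max_start = max(.data$start),
      tx_min_end = min(.data$end),
      .groups = "drop"
    )
  out <- tibble::tibble(intron_id = ids) |>
    dplyr::left_join(tx, by = "intron_id")
  out$tx_max_start[is.na(out$tx_max_start)] <- -Inf
  out$tx_min_end[is.na(out$tx_min_end)] <- Inf
  out
}
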