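#' Extract junction reads from alignments
#'
#' Decomposes split alignments (CIGAR `N` gaps) into junction observations,
#' applies the status-specific minimum-overhang filter and tallies reads per
#' junction.  A junction is *annotated* when its gap interval exactly matches
#' a derived intron of the annotation, *novel* otherwise; novel junctions are
#' assigned to the gene whose span contains the whole gap (smallest gene span
#' wins ties).  Gaps outside any gene span are discarded (a message reports
#' how many).
#'
#' @param alignments Alignment tibble from [read_sam()] /
#'   [simulate_alignments()], or a path to a SAM file.
#' @param annotation An `annotation` object.
#' @param min_overhang_annotated,min_overhang_novel Minimum aligned overhang
#'   (nt of the flanking matched blocks, shorter side) required to count a
#'   read towards an annotated / novel junction.  Defaults 3 and 6.
#' @return A tibble with one row per junction: `junction_id`, `gene_id`,
#'   `chrom`, `start`, `end` (0-based half-open intronic gap), `strand`
#'   (from the matched intron, `*` for novel), `status`, `count`.  Reads with
#'   several gaps contribute one observation per gap.
#' @export
extract_junction_reads <- function(alignments, annotation,
                                   min_overhang_annotated = 3,
                                   min_overhang_novel = 6) {
  alignments <- as_alignments(alignments)
  gaps <- cigar_gaps(alignments)
  if (nrow(gaps) == 0) {
    return(empty_junction_tbl())
  }
  intr <- annotation$introns |>
    dplyr::select("intron_id", "chrom", "start", "end",
                  intron_strand = "strand", intron_gene = "gene_id")
  gaps <- dplyr::left_join(gaps, intr, by = c("chrom", "start", "end"))
  gaps$status <- ifelse(is.na(gaps$intron_id), "novel", "annotated")

  # novel gaps: gene whose span contains both endpoints; smallest span on ties
  novel <- gaps[gaps$status == "novel", , drop = FALSE]
  if (nrow(novel) > 0) {
    genes <- annotation$genes |>
      dplyr::select("chrom", gene_id2 = "gene_id",
                    g_start = "start", g_end = "end")
    novel <- novel |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      dplyr::left_join(genes, by = "chrom",
                       relationship = "many-to-many") |>
      dplyr::filter(is.na(.data$g_start) |
                      (.data$g_start <= .data$start & .data$g_end >= .data$end)) |>
      dplyr::group_by(.data$.row) |>
      dplyr::slice_min(.data$g_end - .data$g_start, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    novel <- novel[!is.na(novel$g_start), , drop = FALSE]
    n_orphan <- sum(gaps$status == "novel") - nrow(novel)
    if (n_orphan > 0) {
      message(n_orphan, " junction observation(s) outside any gene span discarded")
    }
    novel <- novel |>
      dplyr::mutate(intron_gene = .data$gene_id2, intron_strand = "*") |>
      dplyr::select(dplyr::all_of(names(gaps)))
    gaps <- dplyr::bind_rows(gaps[gaps$status == "annotated", , drop = FALSE], novel)
  }

  min_oh <- ifelse(gaps$status == "annotated",
                   min_overhang_annotated, min_overhang_novel)
  gaps <- gaps[gaps$overhang >= min_oh, , drop = FALSE]
  if (nrow(gaps) == 0) {
    return(empty_junction_tbl())
  }
  gaps |>
    dplyr::mutate(
      junction_id = ifelse(.data$status == "annotated", .data$intron_id,
                           interval_id(.data$chrom, .data$start, .data$end, "*"))
    ) |>
    dplyr::count(.data$junction_id, gene_id = .data$intron_gene, .data$chrom,
                 .data$start, .data$end, strand = .data$intron_strand,
                 .data$status, name = "count") |>
    dplyr::arrange(.data$gene_id, .data$start, .data$end)
}

empty_junction_tbl <- function() {
  tibble::tibble(
    junction_id = character(), gene_id = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    status = character(), count = integer()
  )
}

#' Merge per-condition junction counts into a two-condition table
#'
#' @param counts_a,counts_b Junction count tibbles from
#'   [extract_junction_reads()] for conditions A and B.
#' @return A tibble with one row per junction observed in either condition,
#'   with `count_A` and `count_B` (0 where unobserved).
#' @export
build_junction_table <- function(counts_a, counts_b) {
  keys <- c("junction_id", "gene_id", "chrom", "start", "end", "strand", "status")
  dplyr::full_join(
    dplyr::rename(counts_a, count_A = "count"),
    dplyr::rename(counts_b, count_B = "count"),
    by = keys
  ) |>
    tidyr::replace_na(list(count_A = 0L, count_B = 0L)) |>
    dplyr::arrange(.data$gene_id, .data$start, .data$end)
}

#' Segment layout of an intron set
#'
#' Each intron is split into `max(2, floor(L / 500))` equal-width segments
#' (the last segment absorbs the remainder), the units over which intron
#' retention is measured so that localised coverage spikes (unannotated
#' exons, repeats) cannot dominate the intron-level value.
#'
#' @param introns Intron tibble (e.g. `annotation$introns`) with `intron_id`,
#'   `start`, `end`.
#' @param segment_width Target segment width in nt (default 500).
#' @return A tibble with one row per segment: `intron_id`, `segment`,
#'   `seg_start`, `seg_end`, `seg_length`.
#' @export
intron_segments <- function(introns, segment_width = 500) {
  n_seg <- pmax(2L, (introns$end - introns$start) %/% as.integer(segment_width))
  width <- (introns$end - introns$start) %/% n_seg
  out <- tibble::tibble(
    intron_id = rep(introns$intron_id, n_seg),
    istart = rep(introns$start, n_seg),
    iend = rep(introns$end, n_seg),
    w = rep(width, n_seg),
    n = rep(n_seg, n_seg)
  ) |>
    dplyr::group_by(.data$intron_id) |>
    dplyr::mutate(segment = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      seg_start = .data$istart + (.data$segment - 1L) * .data$w,
      seg_end = ifelse(.data$segment == .data$n, .data$iend,
                       .data$istart + .data$segment * .data$w),
      seg_length = .data$seg_end - .data$seg_start
    ) |>
    dplyr::select("intron_id", "segment", "seg_start", "seg_end", "seg_length")
  out
}

#' Count strictly intronic reads per intron segment
#'
#' A read is strictly intronic for an intron when its alignment has no `N`
#' gap and its full aligned reference span lies inside the intron interval.
#' Each qualifying read is assigned to the segment containing its aligned
#' midpoint, so a read is never counted in two segments of the same intron.
#' Reads straddling an exon boundary are simply not strictly intronic.
#'
#' @inheritParams extract_junction_reads
#' @param segment_width Passed to [intron_segments()].
#' @return A tibble with one row per (intron, segment), including zero-count
#'   segments: `intron_id`, `segment`, `seg_start`, `seg_end`, `seg_length`,
#'   `count`.
#' @export
count_strictly_intronic <- function(alignments, annotation, segment_width = 500) {
  alignments <- as_alignments(alignments)
  segs <- intron_segments(annotation$introns, segment_width)
  no_gap <- alignments[!grepl("N", alignments$cigar, fixed = TRUE), , drop = FALSE]
  no_gap <- no_gap[!grepl("[^0-9MIDSN]", no_gap$cigar), , drop = FALSE]
  if (nrow(no_gap) > 0) {
    w <- GenomicAlignments::cigarWidthAlongReferenceSpace(no_gap$cigar)
    reads <- tibble::tibble(
      chrom = no_gap$chrom,
      r_start = no_gap$pos - 1L,
      r_end = no_gap$pos - 1L + w
    )
    intr <- annotation$introns |>
      dplyr::select("intron_id", "chrom", i_start = "start", i_end = "end")
    hits <- dplyr::inner_join(reads, intr, by = "chrom",
                              relationship = "many-to-many") |>
      dplyr::filter(.data$r_start >= .data$i_start, .data$r_end <= .data$i_end) |>
      dplyr::mutate(mid = .data$r_start + (.data$r_end - .data$r_start - 1L) %/% 2L)
    seg_of <- segs |>
      dplyr::select("intron_id", "segment", "seg_start", "seg_end")
    hit_counts <- hits |>
      dplyr::inner_join(seg_of, by = "intron_id",
                        relationship = "many-to-many") |>
      dplyr::filter(.data$mid >= .data$seg_start, .data$mid < .data$seg_end) |>
      dplyr::count(.data$intron_id, .data$segment, name = "count")
  } else {
    hit_counts <- tibble::tibble(intron_id = character(), segment = integer(),
                                 count = integer())
  }
  segs |>
    dplyr::left_join(hit_counts, by = c("intron_id", "segment")) |>
    tidyr::replace_na(list(count = 0L))
}

#' Classify a junction's splice-site motif
#'
#' @param strand Junction strand, `+` or `-`.
#' @param donor_dinucleotide,acceptor_dinucleotide The two genomic
#'   dinucleotides at the left and right ends of the intronic gap (always as
#'   read on the forward genomic strand); `NA` when no sequence is available.
#' @return `"canonical"` for GT..AG on `+` (equivalently CT..AC read on the
#'   forward strand for `-` introns), `"unknown"` when dinucleotides are
#'   missing, `"non_canonical"` otherwise.  Vectorised.
#' @export
classify_motif <- function(strand, donor_dinucleotide, acceptor_dinucleotide) {
  donor <- toupper(donor_dinucleotide)
  acceptor <- toupper(acceptor_dinucleotide)
  out <- ifelse(
    (strand == "+" & donor == "GT" & acceptor == "AG") |
      (strand == "-" & donor == "CT" & acceptor == "AC"),
    "canonical", "non_canonical"
  )
  out[is.na(donor) | is.na(acceptor)] <- "unknown"
  out
}
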