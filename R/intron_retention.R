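#' Normalise strictly intronic segment counts to library depth
#'
#' Scales raw per-segment intronic counts by the total number of strictly
#' intronic reads in the experiment, reported per million for readability.
#' The scale cancels in all IR ratios (numerator and denominator of an IR
#' value share the condition's total), so normalisation matters only for
#' cross-condition readability of the density columns.
#'
#' @param segment_counts Segment count tibble from
#'   [count_strictly_intronic()].
#' @param total Total strictly intronic reads of the condition; defaults to
#'   the sum of `count`.
#' @return `segment_counts` with `norm_cpm` (counts per million intronic
#'   reads) added; `NA` when the total is zero.
#' @export
normalize_intronic <- function(segment_counts, total = NULL) {
  if (is.null(total)) {
    total <- sum(segment_counts$count)
  }
  segment_counts$norm_cpm <- if (total > 0) {
    segment_counts$count / total * 1e6
  } else {
    NA_real_
  }
  segment_counts
}

#' Per-intron IR values, fold changes and differential-IR tests
#'
#' The IR of a segment is the ratio of its intronic read density to the
#' pooled density of the intron's neighbour introns, per condition:
#' `((count + pc) / seg_length) / ((neighbour_sum + pc) / neighbour_length)`
#' with a Haldane pseudocount `pc` stabilising zero counts.  (Totals-based
#' library normalisation cancels in this within-condition ratio.)  The
#' intron's robust IR is the median over its `max(2, floor(L/500))` segments,
#' so a coverage spike confined to a minority of segments cannot move it.
#' `fold_change` is `max(robust_A, robust_B) / min(robust_A, robust_B)`, and
#' `p_ir` is the two-sided Fisher p for the raw-count table (intron segment
#' sum, neighbour sum) x (condition A, B).
#'
#' @param seg_counts_a,seg_counts_b Segment counts per condition from
#'   [count_strictly_intronic()].
#' @param annotation An `annotation` object.
#' @param neighbours Optional neighbour-intron edges from
#'   [neighbour_introns()]; computed from `annotation` when omitted.
#' @param pseudocount Haldane pseudocount added to each segment count and to
#'   the neighbour sum (default 0.5).
#' @param length_normalize Divide counts by span length before taking the
#'   ratio (default `TRUE`); `FALSE` gives the literal ratio of read counts.
#' @return A tibble, one row per intron: `intron_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `length`, `n_segments`, raw sums and neighbour
#'   sums per condition, `robust_ir_A`, `robust_ir_B`, `fold_change`, `p_ir`,
#'   `ir_reason` (`"ok"` or `"no_neighbour"`).
#' @export
ir_table <- function(seg_counts_a, seg_counts_b, annotation, neighbours = NULL,
                     pseudocount = 0.5, length_normalize = TRUE) {
  if (is.null(neighbours)) {
    neighbours <- neighbour_introns(annotation)
  }
  intr <- annotation$introns
  per_intron <- function(segs, cond) {
    segs |>
      dplyr::group_by(.data$intron_id) |>
      dplyr::summarise(!!paste0("intron_", cond) := sum(.data$count),
                       .groups = "drop")
  }
  tot_a <- per_intron(seg_counts_a, "A")
  tot_b <- per_intron(seg_counts_b, "B")
  totals <- intr |>
    dplyr::select("intron_id", "length") |>
    dplyr::left_join(tot_a, by = "intron_id") |>
    dplyr::left_join(tot_b, by = "intron_id") |>
    tidyr::replace_na(list(intron_A = 0L, intron_B = 0L))

  nb <- neighbours |>
    dplyr::inner_join(totals, by = c(neighbour_intron_id = "intron_id")) |>
    dplyr::group_by(.data$intron_id) |>
    dplyr::summarise(
      neighbour_A = sum(.data$intron_A),
      neighbour_B = sum(.data$intron_B),
      neighbour_length = sum(.data$length),
      .groups = "drop"
    )

  segs <- dplyr::bind_rows(
    dplyr::mutate(seg_counts_a, condition = "A"),
    dplyr::mutate(seg_counts_b, condition = "B")
  ) |>
    dplyr::inner_join(nb, by = "intron_id") |>
    dplyr::mutate(
      nb_count = ifelse(.data$condition == "A", .data$neighbour_A,
                        .data$neighbour_B),
      ir = if (length_normalize) {
        ((.data$count + pseudocount) / .data$seg_length) /
          ((.data$nb_count + pseudocount) / .data$neighbour_length)
      } else {
        (.data$count + pseudocount) / (.data$nb_count + pseudocount)
      }
    )
  robust <- segs |>
    dplyr::group_by(.data$intron_id, .data$condition) |>
    dplyr::summarise(robust_ir = stats::median(.data$ir),
                     n_segments = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "robust_ir",
                       names_prefix = "robust_ir_")

  out <- intr |>
    dplyr::left_join(totals |> dplyr::select(-"length"), by = "intron_id") |>
    dplyr::left_join(nb, by = "intron_id") |>
    dplyr::left_join(robust, by = "intron_id")
  out$n_segments <- pmax(2L, out$length %/% 500L)
  out |>
    dplyr::mutate(
      ir_reason = ifelse(is.na(.data$neighbour_length), "no_neighbour", "ok"),
      fold_change = ifelse(
        .data$ir_reason == "ok",
        pmax(.data$robust_ir_A, .data$robust_ir_B) /
          pmin(.data$robust_ir_A, .data$robust_ir_B),
        NA_real_
      ),
      p_ir = ifelse(
        .data$ir_reason == "ok",
        fisher_two_sided(.data$intron_A, .data$neighbour_A,
                         .data$intron_B, .data$neighbour_B),
        NA_real_
      )
    )
}

#' Call differentially retained introns
#'
#' An intron is called retained when two lines of evidence agree: (i) its
#' own junction (the junction exactly matching the intron boundaries) is
#' differentially used at the p-value threshold *and* has no competing
#' junction — so the junction-usage change cannot be explained by a
#' competing splice site; and (ii) the intronic coverage shows at least
#' `ir_fold` fold change in robust IR with a differential-IR p-value below
#' `ir_p`.
#'
#' @param ir_records IR tibble from [ir_table()].
#' @param calls Classified calls from [call_differential()] then
#'   [classify_events()] (needs `n_competitors`).
#' @param ir_fold Minimum IR fold change (default 2).
#' @param ir_p Differential-IR p-value threshold (default 0.001).
#' @param p_threshold Junction-usage p-value threshold; defaults to the
#'   threshold stored in `calls`.
#' @return `ir_records` with `junction_p`, `n_competitors`, `retained`,
#'   `direction` (`"up_in_A"`/`"up_in_B"`) and `reason` columns added.
#' @export
call_retention <- function(ir_records, calls, ir_fold = 2, ir_p = 0.001,
                           p_threshold = NULL) {
  if (!"n_competitors" %in% names(calls)) {
    stop("`calls` lacks `n_competitors`; run classify_events() first")
  }
  if (is.null(p_threshold)) {
    thr <- attr(calls, "thresholds")
    p_threshold <- if (is.null(thr)) 0.001 else thr$p
  }
  supp <- calls |>
    dplyr::select("junction_id", junction_p = "p_value",
                  "n_competitors")
  out <- ir_records |>
    dplyr::left_join(supp, by = c(intron_id = "junction_id")) |>
    dplyr::mutate(
      retained = !is.na(.data$junction_p) &
        .data$junction_p < p_threshold &
        .data$n_competitors == 0 &
        .data$ir_reason == "ok" &
        .data$fold_change >= ir_fold &
        .data$p_ir < ir_p,
      direction = dplyr::if_else(
        .data$retained & .data$robust_ir_B >= .data$robust_ir_A,
        "up_in_B",
        dplyr::if_else(.data$retained, "up_in_A", NA_character_)
      ),
      reason = dplyr::case_when(
        retained ~ "called",
        is.na(.data$junction_p) ~ "no_supporting_junction",
        .data$ir_reason != "ok" ~ .data$ir_reason,
        .data$junction_p >= p_threshold ~ "junction_p",
        .data$n_competitors > 0 ~ "has_competitor",
        .data$fold_change < ir_fold ~ "fold_change",
        TRUE ~ "p_ir"
      )
    )
  attr(out, "thresholds") <- list(junction_p = p_threshold, ir_fold = ir_fold,
                                  ir_p = ir_p)
  out
}
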