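#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, at fixed
#' margins, of all tables whose probability does not exceed that of the
#' observed table (the conventional probability-mass ordering).  Degenerate
#' tables with a zero row or column margin carry no evidence and return 1.
#'
#' @param a,b,c,d Non-negative integer cells.  Rows are (junction count,
#'   neighbour-sum count) and columns the two conditions, i.e. the table is
#'   `rbind(c(a, c), c(b, d))` with `a`,`b` from condition A and `c`,`d` from
#'   condition B.  Vectorised over the four arguments.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
fisher_two_sided <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.integer(a), n); b <- rep_len(as.integer(b), n)
  c <- rep_len(as.integer(c), n); d <- rep_len(as.integer(d), n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) {
    stop("Fisher table cells must be non-negative")
  }
  vapply(seq_len(n), function(i) {
    if ((a[i] + b[i]) == 0 || (c[i] + d[i]) == 0 ||
        (a[i] + c[i]) == 0 || (b[i] + d[i]) == 0) {
      return(1)
    }
    stats::fisher.test(matrix(c(a[i], b[i], c[i], d[i]), nrow = 2))$p.value
  }, numeric(1))
}

#' Percent spliced in (PSI) from junction and boundary-sharing neighbour counts
#'
#' PSI is the mean of the junction's share of read evidence at each of its
#' two boundaries: `mean(J / (J_sameStart + J), J / (J_sameEnd + J))`, where
#' `J_sameStart` / `J_sameEnd` sum the counts of neighbour junctions sharing
#' the junction's start / end coordinate.  A term whose denominator is zero
#' is dropped; when both are zero the PSI is undefined (`NA`).
#'
#' @param j Junction read count.
#' @param same_start,same_end Summed counts of neighbours sharing the
#'   junction's start / end boundary.  All vectorised.
#' @return Numeric vector of PSI values in `[0, 1]`, `NA` where undefined.
#' @export
psi <- function(j, same_start, same_end) {
  t1 <- ifelse(j + same_start > 0, j / (j + same_start), NA_real_)
  t2 <- ifelse(j + same_end > 0, j / (j + same_end), NA_real_)
  out <- rowMeans(cbind(t1, t2), na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Call differentially used junctions between two conditions
#'
#' For each junction, tests the 2x2 table (junction count, summed neighbour
#' count) x (condition A, condition B) with Fisher's exact test, computes PSI
#' per condition from the boundary-sharing neighbours, and flags a junction
#' as differential when `p < p_threshold`, `|dPSI| > dpsi_threshold` and the
#' larger of the two junction counts is at least `min_reads` (strict
#' inequalities for p and dPSI, as the thresholds are exclusive).  Junctions
#' with undefined PSI in either condition are kept with `differential =
#' FALSE` and a `reason` code.
#'
#' @param junction_table Two-condition junction tibble from
#'   [build_junction_table()].
#' @param neighbours Neighbour edge tibble from [neighbour_junctions()].
#' @param p_threshold,dpsi_threshold,min_reads Calling thresholds; defaults
#'   0.001, 0.15 and 7.
#' @return A tibble (one row per junction) with `p_value`, `psi_A`, `psi_B`,
#'   `dpsi`, `max_reads`, `neighbour_A`, `neighbour_B`, `differential`,
#'   `reason`, plus the junction columns.  A Benjamini-Hochberg adjusted
#'   p-value column `p_adj` is included for reporting only; it plays no part
#'   in the calls.  Thresholds are stored in the `"thresholds"` attribute.
#' @export
call_differential <- function(junction_table, neighbours,
                              p_threshold = 0.001, dpsi_threshold = 0.15,
                              min_reads = 7) {
  jt <- junction_table
  if (nrow(jt) == 0) {
    out <- dplyr::mutate(jt, p_value = numeric(0), p_adj = numeric(0),
                         psi_A = numeric(0), psi_B = numeric(0),
                         dpsi = numeric(0), max_reads = integer(0),
                         neighbour_A = integer(0), neighbour_B = integer(0),
                         differential = logical(0), reason = character(0))
    attr(out, "thresholds") <- list(p = p_threshold, dpsi = dpsi_threshold,
                                    min_reads = min_reads)
    return(out)
  }
  counts <- jt |> dplyr::select("junction_id", "count_A", "count_B")
  nb_sums <- neighbours |>
    dplyr::inner_join(counts, by = c(neighbour_id = "junction_id")) |>
    dplyr::group_by(.data$junction_id) |>
    dplyr::summarise(
      neighbour_A = sum(.data$count_A),
      neighbour_B = sum(.data$count_B),
      ss_A = sum(.data$count_A[.data$shares_start]),
      ss_B = sum(.data$count_B[.data$shares_start]),
      se_A = sum(.data$count_A[.data$shares_end]),
      se_B = sum(.data$count_B[.data$shares_end]),
      .groups = "drop"
    )
  out <- jt |>
    dplyr::left_join(nb_sums, by = "junction_id") |>
    tidyr::replace_na(list(neighbour_A = 0L, neighbour_B = 0L,
                           ss_A = 0L, ss_B = 0L, se_A = 0L, se_B = 0L)) |>
    dplyr::mutate(
      p_value = fisher_two_sided(.data$count_A, .data$neighbour_A,
                                 .data$count_B, .data$neighbour_B),
      p_adj = stats::p.adjust(.data$p_value, method = "BH"),
      psi_A = psi(.data$count_A, .data$ss_A, .data$se_A),
      psi_B = psi(.data$count_B, .data$ss_B, .data$se_B),
      dpsi = abs(.data$psi_A - .data$psi_B),
      max_reads = pmax(.data$count_A, .data$count_B),
      differential = !is.na(.data$dpsi) &
        .data$p_value < p_threshold &
        .data$dpsi > dpsi_threshold &
        .data$max_reads >= min_reads,
      reason = dplyr::case_when(
        is.na(.data$dpsi) ~ "undefined_psi",
        differential ~ "called",
        .data$p_value >= p_threshold ~ "p_value",
        .data$dpsi <= dpsi_threshold ~ "dpsi",
        TRUE ~ "min_reads"
      )
    ) |>
    dplyr::select(-"ss_A", -"ss_B", -"se_A", -"se_B")
  attr(out, "thresholds") <- list(p = p_threshold, dpsi = dpsi_threshold,
                                  min_reads = min_reads)
  out
}

#' Classify called junctions into splicing competition types
#'
#' Builds the boundary-sharing closure around each junction
#' ([competing_junctions()]) and assigns a category: `no_competitor` (no
#' other junction shares a boundary chain — the profile of a retained
#' constitutive intron), `Alt3SS` / `Alt5SS` (exactly one competitor sharing
#' the donor-side / acceptor-side boundary, strand-aware: on `+` the interval
#' start is the donor side, mirrored on `-`), `CEx` (a three-junction closure
#' of two inclusion junctions plus the spanning skip junction), `complex`
#' otherwise.
#'
#' @param calls Calls tibble from [call_differential()] (any junction tibble
#'   with `junction_id`, `gene_id`, `chrom`, `start`, `end`, `strand` works).
#' @param max_dist Search window around each junction (default 5000 nt).
#' @return `calls` with `category` and `n_competitors` columns added.
#' @export
classify_events <- function(calls, max_dist = 5000) {
  comp <- competing_junctions(calls, max_dist = max_dist)
  coords <- calls |> dplyr::select("junction_id", "start", "end")
  cat_of <- function(jid, strand) {
    members <- comp$competitor_id[comp$junction_id == jid]
    if (length(members) == 0) {
      return("no_competitor")
    }
    self <- coords[coords$junction_id == jid, ]
    if (length(members) == 1) {
      other <- coords[coords$junction_id == members, ]
      share_start <- other$start == self$start
      share_end <- other$end == self$end
      # on '+' the interval start is the donor (5'SS) side
      donor_side <- if (strand == "-") share_end else share_start
      return(if (donor_side) "Alt3SS" else "Alt5SS")
    }
    if (length(members) == 2) {
      trio <- coords[coords$junction_id %in% c(jid, members), ]
      if (is_cassette_trio(trio)) {
        return("CEx")
      }
    }
    "complex"
  }
  strand_eff <- ifelse(calls$strand %in% c("+", "-"), calls$strand, "+")
  calls$category <- vapply(seq_len(nrow(calls)), function(i) {
    cat_of(calls$junction_id[i], strand_eff[i])
  }, character(1))
  n_comp <- comp |> dplyr::count(.data$junction_id, name = "n_competitors")
  calls |>
    dplyr::left_join(n_comp, by = "junction_id") |>
    tidyr::replace_na(list(n_competitors = 0L))
}

# A cassette-exon closure: junctions {(d, a1), (d2, a), (d, a)} where the
# skip junction (d, a) spans both inclusion junctions and a1 <= d2.
is_cassette_trio <- function(trio) {
  if (nrow(trio) != 3) {
    return(FALSE)
  }
  for (k in 1:3) {
    skip <- trio[k, ]
    inc <- trio[-k, ]
    inc1 <- inc[inc$start == skip$start & inc$end < skip$end, ]
    inc2 <- inc[inc$end == skip$end & inc$start > skip$start, ]
    if (nrow(inc1) == 1 && nrow(inc2) == 1 && inc1$end <= inc2$start) {
      return(TRUE)
    }
  }
  FALSE
}
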