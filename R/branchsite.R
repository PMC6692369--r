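#' Assign one branch site per intron from candidate records
#'
#' When several candidate branch sites fall in the same intron, the one with
#' the highest lariat-mismatch support (number of sequenced lariat reads with
#' the reverse-transcription mismatch at the BS adenosine) is kept.  Ties are
#' broken deterministically: first the candidate closest to the 3' splice
#' site, then the lowest genomic coordinate.
#'
#' @param bs_records Tibble of candidates: `intron_id`, `bs_pos` (0-based
#'   genomic position of the BS adenosine), `lariat_mismatch_count`,
#'   optionally `confidence`.
#' @param introns Intron tibble (`annotation$introns`); used for strand-aware
#'   distance to the 3'SS and to check candidates lie inside their intron.
#' @return One row per intron with at least one candidate, with a
#'   `bs_distance` column (see [ss5_bs_distance()]) joined on.
#' @export
assign_branch_sites <- function(bs_records, introns) {
  if (nrow(bs_records) == 0) {
    return(dplyr::mutate(bs_records, bs_distance = integer(0)))
  }
  x <- bs_records |>
    dplyr::inner_join(
      introns |> dplyr::select("intron_id", "start", "end", "strand", "length"),
      by = "intron_id"
    )
  if (any(x$bs_pos < x$start | x$bs_pos >= x$end)) {
    stop("branch-site candidate outside its intron")
  }
  x |>
    dplyr::mutate(
      dist3ss = ifelse(.data$strand == "+", .data$end - 1L - .data$bs_pos,
                       .data$bs_pos - .data$start),
      bs_distance = ss5_bs_distance(.data$strand, .data$start, .data$end,
                                    .data$bs_pos)
    ) |>
    dplyr::group_by(.data$intron_id) |>
    dplyr::arrange(dplyr::desc(.data$lariat_mismatch_count), .data$dist3ss,
                   .data$bs_pos, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-"dist3ss", -"start", -"end", -"strand")
}

#' Distance from the 5' splice site to the branch-site adenosine
#'
#' The number of intron nucleotides strictly 5' of the BS adenosine, measured
#' from the intron's transcriptional 5' end: on `+`, `bs_pos - start`; on
#' `-`, `end - 1 - bs_pos`.  A BS at the first intron base has distance 0.
#'
#' @param strand Intron strand (`+`/`-`).
#' @param start,end Intron interval (0-based half-open).
#' @param bs_pos 0-based genomic position of the BS adenosine.  Vectorised.
#' @return Integer distances (nt).  Errors when a BS lies outside its intron.
#' @export
ss5_bs_distance <- function(strand, start, end, bs_pos) {
  if (any(bs_pos < start | bs_pos >= end)) {
    stop("branch site outside intron")
  }
  as.integer(ifelse(strand == "+", bs_pos - start, end - 1L - bs_pos))
}

#' Length-matched background sample of introns
#'
#' Draws, for each retained intron, `oversampling` background introns with
#' replacement from the background introns falling in the same length decile
#' (deciles of the retained length distribution), so the background carries
#' the retained set's length distribution.  An empty decile falls back to the
#' nearest non-empty one with a warning.
#'
#' @param background Tibble of background introns with a `length` column.
#' @param retained_lengths Lengths (nt) of the retained introns.
#' @param oversampling Background draws per retained intron (default 5).
#' @param seed Optional integer seed for reproducible sampling.
#' @return A tibble of sampled background rows,
#'   `oversampling * length(retained_lengths)` of them.
#' @export
length_matched_sample <- function(background, retained_lengths,
                                  oversampling = 5, seed = NULL) {
  if (nrow(background) == 0 || length(retained_lengths) == 0) {
    stop("background and retained set must be non-empty")
  }
  if (!is.null(seed)) {
    withr::local_seed(seed)
  }
  breaks <- unique(stats::quantile(retained_lengths, probs = seq(0, 1, 0.1)))
  breaks[1] <- -Inf
  breaks[length(breaks)] <- Inf
  if (length(breaks) < 2) {
    breaks <- c(-Inf, Inf)
  }
  bg_bin <- cut(background$length, breaks, labels = FALSE)
  ret_bin <- cut(retained_lengths, breaks, labels = FALSE)
  occupied <- sort(unique(bg_bin))
  rows <- unlist(lapply(seq_along(retained_lengths), function(i) {
    b <- ret_bin[i]
    pool <- which(bg_bin == b)
    if (length(pool) == 0) {
      nearest <- occupied[which.min(abs(occupied - b))]
      warning("empty length bin ", b, "; falling back to bin ", nearest)
      pool <- which(bg_bin == nearest)
    }
    pool[sample.int(length(pool), oversampling, replace = TRUE)]
  }))
  background[rows, , drop = FALSE]
}

#' Two-sample two-sided Kolmogorov-Smirnov test
#'
#' `D` is the supremum of the absolute difference between the two empirical
#' CDFs; the p-value is the asymptotic two-sample Kolmogorov approximation
#' (appropriate for the sample sizes this package compares; ties in the data
#' make it approximate).
#'
#' @param x,y Numeric samples, both non-empty.
#' @return A one-row tibble: `statistic` (D), `p_value`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty")
  }
  kt <- suppressWarnings(stats::ks.test(x, y, alternative = "two.sided",
                                        exact = FALSE))
  tibble::tibble(statistic = unname(kt$statistic),
                 p_value = kt$p.value,
                 n_x = length(x), n_y = length(y))
}

#' Compare 5'SS-BS distances of retained introns against a matched background
#'
#' Assigns one branch site per intron ([assign_branch_sites()]), computes
#' 5'SS-BS distances, draws a length-matched background sample
#' ([length_matched_sample()]) and applies the two-sided two-sample
#' Kolmogorov-Smirnov test.  High- and moderate-confidence branch-site
#' records are pooled.
#'
#' @param introns Intron tibble (`annotation$introns`).
#' @param bs_records Branch-site candidate tibble (see
#'   [assign_branch_sites()]).
#' @param retained_ids Intron ids of the retained set.
#' @param oversampling Background draws per retained intron (default 5).
#' @param length_cap Restrict the comparison to introns at most this long in
#'   nt (default 250, the short-intron regime); `Inf` disables.
#' @param seed Optional seed for the background sampling.
#' @return A `bs_distance_test` object: list with `distances` (tibble:
#'   `group` in retained/background, `intron_id`, `length`, `distance`),
#'   `ks` (tibble from [ks_two_sample()]) and `oversampling`.  Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
bs_distance_test <- function(introns, bs_records, retained_ids,
                             oversampling = 5, length_cap = 250, seed = NULL) {
  assigned <- assign_branch_sites(bs_records, introns) |>
    dplyr::filter(.data$length <= length_cap)
  retained <- assigned |> dplyr::filter(.data$intron_id %in% retained_ids)
  background <- assigned |> dplyr::filter(!.data$intron_id %in% retained_ids)
  if (nrow(retained) == 0) {
    stop("no retained intron with a branch-site assignment under the length cap")
  }
  sampled <- length_matched_sample(background, retained$length,
                                   oversampling = oversampling, seed = seed)
  distances <- dplyr::bind_rows(
    retained |> dplyr::mutate(group = "retained"),
    sampled |> dplyr::mutate(group = "background")
  ) |>
    dplyr::select("group", "intron_id", "length", distance = "bs_distance")
  ks <- ks_two_sample(distances$distance[distances$group == "retained"],
                      distances$distance[distances$group == "background"])
  structure(
    list(distances = distances, ks = ks, oversampling = oversampling),
    class = "bs_distance_test"
  )
}

#' @export
print.bs_distance_test <- function(x, ...) {
  n_ret <- sum(x$distances$group == "retained")
  n_bg <- sum(x$distances$group == "background")
  cat(sprintf(
    "<bs_distance_test> %d retained vs %d matched background introns\n  KS D = %.3f, p = %.3g\n",
    n_ret, n_bg, x$ks$statistic, x$ks$p_value
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.bs_distance_test <- function(x, ...) {
  x$distances
}

#' @exportS3Method generics::glance
glance.bs_distance_test <- function(x, ...) {
  tibble::tibble(
    ks_D = x$ks$statistic,
    ks_p = x$ks$p_value,
    n_retained = sum(x$distances$group == "retained"),
    n_background = sum(x$distances$group == "background"),
    oversampling = x$oversampling
  )
}
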