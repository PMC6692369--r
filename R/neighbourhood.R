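#' Neighbour junctions for count normalisation
#'
#' For each junction J, the neighbours N are the other junctions of the same
#' gene satisfying all of: (i) every known transcript containing N (i.e.
#' whose intron set includes N's exact interval) fully subsumes J within its
#' genomic span; (ii) every transcript containing J fully subsumes N; and
#' (iii) the minimum genomic gap between the two intervals is at most
#' `max_dist`.  Novel junctions are contained in no transcript, so (i)/(ii)
#' hold vacuously on their side.  Neighbour counts are the denominator of the
#' junction-usage Fisher test and (restricted to boundary-sharing neighbours)
#' of PSI.
#'
#' @param junctions Junction tibble (from [extract_junction_reads()] or
#'   [build_junction_table()]); needs `junction_id`, `gene_id`, `chrom`,
#'   `start`, `end`.
#' @param annotation An `annotation` object.
#' @param max_dist Maximum interval gap in nt (default 5000).
#' @return An edge tibble: `junction_id`, `neighbour_id`, `shares_start`,
#'   `shares_end`, `gap`.  Junctions with no qualifying neighbour are absent.
#' @export
neighbour_junctions <- function(junctions, annotation, max_dist = 5000) {
  if (nrow(junctions) == 0) {
    return(tibble::tibble(junction_id = character(), neighbour_id = character(),
                          shares_start = logical(), shares_end = logical(),
                          gap = integer()))
  }
  spans <- containing_span_summary(junctions$junction_id, annotation)
  j <- junctions |>
    dplyr::select("junction_id", "gene_id", "start", "end") |>
    dplyr::mutate(tx_max_start = spans$tx_max_start,
                  tx_min_end = spans$tx_min_end)
  pairs <- dplyr::inner_join(
    j,
    dplyr::rename_with(j, ~ paste0("nb_", .x)),
    by = c(gene_id = "nb_gene_id"),
    relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$junction_id != .data$nb_junction_id) |>
    dplyr::mutate(
      gap = pmax(0L, pmax(.data$start, .data$nb_start) -
                   pmin(.data$end, .data$nb_end))
    ) |>
    dplyr::filter(
      .data$gap <= max_dist,
      # (i) transcripts containing the neighbour subsume the junction
      .data$nb_tx_max_start <= .data$start, .data$nb_tx_min_end >= .data$end,
      # (ii) transcripts containing the junction subsume the neighbour
      .data$tx_max_start <= .data$nb_start, .data$tx_min_end >= .data$nb_end
    )
  pairs |>
    dplyr::transmute(
      junction_id = .data$junction_id,
      neighbour_id = .data$nb_junction_id,
      shares_start = .data$start == .data$nb_start,
      shares_end = .data$end == .data$nb_end,
      gap = .data$gap
    )
}

#' Competing junctions by greedy boundary-sharing closure
#'
#' Starting from each junction, repeatedly adds any detected junction of the
#' same gene, within `max_dist` of the seed, that shares a start or end
#' coordinate with a current member, until a fixed point.  The competitors of
#' a junction are the closure minus the junction itself; they represent
#' splice sites competing for the same boundaries (the basis of the
#' event-type classification).
#'
#' @inheritParams neighbour_junctions
#' @return An edge tibble `junction_id`, `competitor_id` (absent rows mean no
#'   competitor).
#' @export
competing_junctions <- function(junctions, max_dist = 5000) {
  out <- vector("list", nrow(junctions))
  by_gene <- split(seq_len(nrow(junctions)), junctions$gene_id)
  for (idx in by_gene) {
    g <- junctions[idx, , drop = FALSE]
    for (k in seq_along(idx)) {
      seed <- g[k, ]
      gapd <- pmax(0L, pmax(seed$start, g$start) - pmin(seed$end, g$end))
      cand <- g[gapd <= max_dist, , drop = FALSE]
      members <- seed$junction_id
      repeat {
        sel <- cand$junction_id %in% members
        starts <- cand$start[sel]
        ends <- cand$end[sel]
        grow <- cand$junction_id[cand$start %in% starts | cand$end %in% ends]
        new_members <- union(members, grow)
        if (length(new_members) == length(members)) break
        members <- new_members
      }
      comp <- setdiff(members, seed$junction_id)
      if (length(comp) > 0) {
        out[[idx[k]]] <- tibble::tibble(junction_id = seed$junction_id,
                                        competitor_id = comp)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(junction_id = character(), competitor_id = character())
  }
  res
}

#' Neighbour introns for intron-retention normalisation
#'
#' Introns whose exact-match junctions would qualify as neighbour junctions
#' of the intron's own junction, under the same subsumption/distance rules as
#' [neighbour_junctions()].  Their strictly intronic read counts form the
#' denominator of the IR ratio, absorbing gene-expression shifts between
#' conditions.
#'
#' @param annotation An `annotation` object.
#' @param max_dist Maximum interval gap in nt (default 5000).
#' @return An edge tibble `intron_id`, `neighbour_intron_id`.
#' @export
neighbour_introns <- function(annotation, max_dist = 5000) {
  pseudo <- annotation$introns |>
    dplyr::transmute(
      junction_id = .data$intron_id, gene_id = .data$gene_id,
      chrom = .data$chrom, start = .data$start, end = .data$end
    )
  neighbour_junctions(pseudo, annotation, max_dist = max_dist) |>
    dplyr::transmute(intron_id = .data$junction_id,
                     neighbour_intron_id = .data$neighbour_id)
}
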