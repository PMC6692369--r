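#' Run the full junction-centric splicing analysis
#'
#' Orchestrates the pipeline end to end: obtain inputs (either simulated
#' from a [sim_config()] or read from files), extract junction and strictly
#' intronic reads per condition, build neighbour sets, call differential
#' junction usage, classify competition types, quantify and call intron
#' retention, compare 5'SS-BS distances of retained vs length-matched
#' background introns, and tabulate event summaries.
#'
#' @param x Either a [sim_config()] (simulation mode) or a named list of
#'   input paths with elements `gtf`, `sam_a`, `sam_b` and optionally
#'   `branch_sites` (a TSV with columns `intron_id`, `chrom`, `bs_pos`,
#'   `lariat_mismatch_count`, `confidence`).
#' @param seed Seed driving all randomness (simulation and background
#'   sampling); defaults to `x$seed` in simulation mode, 1 otherwise.
#' @param p_threshold,dpsi_threshold,min_reads Junction-call thresholds
#'   (defaults 0.001, 0.15, 7; see [call_differential()]).
#' @param neighbour_dist Neighbour/competitor search distance in nt
#'   (default 5000).
#' @param ir_fold,ir_p Intron-retention thresholds (defaults 2 and 0.001).
#' @param oversampling,bs_length_cap Distance-analysis parameters
#'   (defaults 5 and 250; see [bs_distance_test()]).
#' @return A `splice_pipeline` object: list with `junctions`, `calls`, `ir`,
#'   `bs` (a [bs_distance_test()] result or `NULL` when not computable),
#'   `summary`, `introns`, `seed` and `thresholds`.  Supports `tidy()`
#'   (the calls), `glance()` and `autoplot()`.
#' @export
run_pipeline <- function(x, seed = NULL,
                         p_threshold = 0.001, dpsi_threshold = 0.15,
                         min_reads = 7, neighbour_dist = 5000,
                         ir_fold = 2, ir_p = 0.001,
                         oversampling = 5, bs_length_cap = 250) {
  if (inherits(x, "sim_config")) {
    if (is.null(seed)) {
      seed <- x$seed
    }
    annotation <- simulate_annotation(x, seed = seed)
    aln_a <- simulate_alignments(annotation, x, "A", seed = seed + 1)
    aln_b <- simulate_alignments(annotation, x, "B", seed = seed + 2)
    bs_records <- simulate_branch_sites(annotation, seed = seed + 3)
  } else if (is.list(x)) {
    missing <- setdiff(c("gtf", "sam_a", "sam_b"), names(x))
    if (length(missing) > 0) {
      stop("configuration error: missing input key(s): ",
           paste(missing, collapse = ", "))
    }
    if (is.null(seed)) {
      seed <- 1
    }
    annotation <- read_gtf(x$gtf)
    aln_a <- read_sam(x$sam_a)
    aln_b <- read_sam(x$sam_b)
    bs_records <- if (!is.null(x$branch_sites)) {
      readr::read_tsv(x$branch_sites, show_col_types = FALSE)
    } else {
      NULL
    }
  } else {
    stop("configuration error: `x` must be a sim_config or a list of input paths")
  }

  jc_a <- extract_junction_reads(aln_a, annotation)
  jc_b <- extract_junction_reads(aln_b, annotation)
  junctions <- build_junction_table(jc_a, jc_b)
  nb <- neighbour_junctions(junctions, annotation, max_dist = neighbour_dist)
  calls <- call_differential(junctions, nb, p_threshold = p_threshold,
                             dpsi_threshold = dpsi_threshold,
                             min_reads = min_reads) |>
    classify_events(max_dist = neighbour_dist)

  seg_a <- count_strictly_intronic(aln_a, annotation)
  seg_b <- count_strictly_intronic(aln_b, annotation)
  nbi <- neighbour_introns(annotation, max_dist = neighbour_dist)
  ir <- ir_table(seg_a, seg_b, annotation, neighbours = nbi) |>
    call_retention(calls, ir_fold = ir_fold, ir_p = ir_p,
                   p_threshold = p_threshold)

  bs <- NULL
  if (!is.null(bs_records) && nrow(bs_records) > 0 && any(ir$retained)) {
    bs <- tryCatch(
      bs_distance_test(annotation$introns, bs_records,
                       retained_ids = ir$intron_id[ir$retained],
                       oversampling = oversampling,
                       length_cap = bs_length_cap, seed = seed + 4),
      error = function(e) NULL
    )
  }

  structure(
    list(
      junctions = junctions,
      calls = calls,
      ir = ir,
      bs = bs,
      summary = summarize_events(calls, ir),
      introns = annotation$introns,
      seed = seed,
      thresholds = list(p = p_threshold, dpsi = dpsi_threshold,
                        min_reads = min_reads, neighbour_dist = neighbour_dist,
                        ir_fold = ir_fold, ir_p = ir_p,
                        oversampling = oversampling,
                        bs_length_cap = bs_length_cap)
    ),
    class = "splice_pipeline"
  )
}

#' Summarise called events and retained-intron length classes
#'
#' Collapses differential junctions into events (one event per connected
#' component of the boundary-sharing competitor graph, labelled by its
#' members' category) and tallies event-type proportions, plus the intron
#' length-class distribution (<200, 200-1k, 1-5k, >5k nt) of the retained
#' introns.
#'
#' @param calls Classified calls (from [call_differential()] +
#'   [classify_events()]).
#' @param ir_records Retention calls (from [call_retention()]).
#' @return A tibble with columns `section` (`event_type` or
#'   `retained_length_class`), `label`, `n` and `prop`.
#' @export
summarize_events <- function(calls, ir_records) {
  diff <- calls[calls$differential, , drop = FALSE]
  as_categories <- c("Alt3SS", "Alt5SS", "CEx", "complex")
  event_labels <- character(0)
  if (nrow(diff) > 0) {
    comp <- competing_junctions(diff)
    groups <- stats::setNames(seq_len(nrow(diff)), diff$junction_id)
    for (i in seq_len(nrow(comp))) {
      a <- unname(groups[comp$junction_id[i]])
      b <- unname(groups[comp$competitor_id[i]])
      if (!is.na(a) && !is.na(b) && a != b) {
        groups[groups == b] <- a
      }
    }
    by_event <- split(diff$category, groups[diff$junction_id])
    event_labels <- vapply(by_event, function(cats) {
      cats <- cats[cats %in% as_categories]
      if (length(cats) == 0) "no_competitor" else names(which.max(table(cats)))
    }, character(1))
    event_labels <- event_labels[event_labels %in% as_categories]
  }
  retained <- ir_records[ir_records$retained, , drop = FALSE]
  ev <- c(event_labels, rep("RI", nrow(retained)))
  ev_counts <- table(factor(ev, levels = c(as_categories, "RI")))
  ev_tbl <- tibble::tibble(
    section = "event_type",
    label = names(ev_counts),
    n = as.integer(ev_counts),
    prop = if (sum(ev_counts) > 0) as.numeric(ev_counts) / sum(ev_counts) else 0
  )
  classes <- cut(retained$length,
                 breaks = c(-Inf, 200, 1000, 5000, Inf),
                 labels = c("<200", "200-1kb", "1-5kb", ">5kb"),
                 right = FALSE)
  cl_counts <- table(classes)
  cl_tbl <- tibble::tibble(
    section = "retained_length_class",
    label = names(cl_counts),
    n = as.integer(cl_counts),
    prop = if (sum(cl_counts) > 0) as.numeric(cl_counts) / sum(cl_counts) else 0
  )
  dplyr::bind_rows(ev_tbl, cl_tbl)
}

#' @export
print.splice_pipeline <- function(x, ...) {
  cat(sprintf(
    "<splice_pipeline> %d junction(s), %d differential, %d retained intron(s) [seed %d]\n",
    nrow(x$junctions), sum(x$calls$differential), sum(x$ir$retained), x$seed
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.splice_pipeline <- function(x, ...) {
  tibble::as_tibble(x$calls)
}

#' @exportS3Method generics::glance
glance.splice_pipeline <- function(x, ...) {
  tibble::tibble(
    n_junctions = nrow(x$junctions),
    n_differential = sum(x$calls$differential),
    n_retained = sum(x$ir$retained),
    ks_p = if (is.null(x$bs)) NA_real_ else x$bs$ks$p_value,
    seed = x$seed
  )
}

#' Write all pipeline result tables to TSV files
#'
#' @param result A `splice_pipeline` object from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
export_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    junctions = file.path(dir, "junctions.tsv"),
    calls = file.path(dir, "calls.tsv"),
    ir = file.path(dir, "intron_retention.tsv"),
    summary = file.path(dir, "summary.tsv")
  )
  readr::write_tsv(result$junctions, files[["junctions"]])
  readr::write_tsv(result$calls, files[["calls"]])
  readr::write_tsv(result$ir, files[["ir"]])
  readr::write_tsv(result$summary, files[["summary"]])
  if (!is.null(result$bs)) {
    files <- c(files, bs_distances = file.path(dir, "bs_distances.tsv"))
    readr::write_tsv(result$bs$distances, files[["bs_distances"]])
  }
  invisible(files)
}
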