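#' Configuration for the synthetic splicing dataset
#'
#' Defines the study conditions the generator emulates: a mix of splicing
#' event templates (cassette exons, alternative 5'/3' splice sites, retained
#' introns, constitutive genes), condition-dependent PSI and intron-retention
#' effects, Poisson junction-read depth and short constitutive introns, so
#' every downstream stage of the pipeline can be exercised without external
#' data.
#'
#' @param n_genes Number of genes (one event template each).
#' @param event_mix Named proportions over `CEx`, `Alt5SS`, `Alt3SS`, `RI`,
#'   `constitutive`; must sum to 1.
#' @param psi_a,psi_b PSI of the first isoform (cassette inclusion /
#'   proximal splice site) in conditions A and B, in `[0, 1]`.
#' @param depth Mean junction-spanning reads per junction at isoform
#'   fraction 1.
#' @param read_length Read length in nt (>= 2).
#' @param exon_length,cassette_length Constitutive and cassette exon widths;
#'   both must be at least `read_length` so junction reads always fit.
#' @param alt_shift Offset (nt) between alternative splice sites.
#' @param ri_intron_length Length of the retained-intron target (a short
#'   constitutive intron, default 200 nt).
#' @param ri_junction_frac Named scale (`A`, `B`) on the RI target junction's
#'   read depth.  The defaults follow mass balance with `ir_fold`: when a
#'   fraction `u` of a gene's transcripts retain the intron, strictly
#'   intronic density scales with `u` and junction output with `1 - u`, so an
#'   intronic fold of 4 from a baseline retention of 0.2 (condition A) gives
#'   junction fractions 0.8 and 0.2.
#' @param ir_fold Fold increase of strictly intronic read density in the RI
#'   target intron in condition B relative to A.
#' @param intronic_density Baseline strictly intronic reads per nt in every
#'   intron and condition (pre-mRNA background).
#' @param intron_length_classes Data frame with `min`, `max`, `weight` rows
#'   defining the mixture from which non-RI intron lengths are drawn;
#'   defaults to short (70-200 nt, 30%), mid (200-1000 nt, 45%) and long
#'   (1000-5000 nt, 25%) classes.
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 60,
                       event_mix = c(CEx = 0.25, Alt5SS = 0.15, Alt3SS = 0.15,
                                     RI = 0.20, constitutive = 0.25),
                       psi_a = 0.75, psi_b = 0.25,
                       depth = 100, read_length = 50,
                       exon_length = 300, cassette_length = 150,
                       alt_shift = 60, ri_intron_length = 150,
                       ri_junction_frac = c(A = 0.8, B = 0.2),
                       ir_fold = 4, intronic_density = 0.2,
                       intron_length_classes = NULL,
                       seed = 1) {
  if (is.null(intron_length_classes)) {
    intron_length_classes <- tibble::tibble(
      min = c(70L, 200L, 1000L), max = c(200L, 1000L, 5000L),
      weight = c(0.30, 0.45, 0.25)
    )
  }
  types <- c("CEx", "Alt5SS", "Alt3SS", "RI", "constitutive")
  if (!setequal(names(event_mix), types)) {
    stop("event_mix must be named over: ", paste(types, collapse = ", "))
  }
  if (abs(sum(event_mix) - 1) > 1e-8) {
    stop("event_mix proportions must sum to 1")
  }
  if (psi_a < 0 || psi_a > 1 || psi_b < 0 || psi_b > 1) {
    stop("PSI values must lie in [0, 1]")
  }
  if (depth <= 0) {
    stop("depth must be positive")
  }
  if (read_length < 2) {
    stop("read_length must be at least 2")
  }
  if (exon_length < read_length || cassette_length < read_length) {
    stop("exon widths must be at least read_length")
  }
  if (abs(sum(intron_length_classes$weight) - 1) > 1e-8) {
    stop("intron length class weights must sum to 1")
  }
  structure(
    list(n_genes = n_genes, event_mix = event_mix[types],
         psi_a = psi_a, psi_b = psi_b, depth = depth,
         read_length = read_length, exon_length = exon_length,
         cassette_length = cassette_length, alt_shift = alt_shift,
         ri_intron_length = ri_intron_length,
         ri_junction_frac = ri_junction_frac, ir_fold = ir_fold,
         intronic_density = intronic_density,
         intron_length_classes = intron_length_classes, seed = seed),
    class = "sim_config"
  )
}

# Deterministic largest-remainder allocation of genes to event types.
allocate_events <- function(event_mix, n_genes) {
  target <- event_mix * n_genes
  counts <- floor(target)
  short <- n_genes - sum(counts)
  if (short > 0) {
    extra <- order(target - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  rep(names(event_mix), counts)
}

draw_intron_length <- function(n, classes) {
  cls <- sample.int(nrow(classes), n, replace = TRUE, prob = classes$weight)
  lo <- classes$min[cls]
  hi <- classes$max[cls]
  as.integer(lo + floor(stats::runif(n) * (hi - lo)))
}

#' Simulate a multi-gene annotation with known splicing events
#'
#' Generates one gene per event template, each on its own synthetic
#' chromosome: cassette-exon genes carry an inclusion and a skipping
#' transcript; alternative splice-site genes carry two transcripts sharing
#' one boundary of the variable intron (strand-aware, so the labelled event
#' type matches the donor/acceptor classification); retained-intron genes
#' carry a short constitutive target intron between two neighbour introns;
#' constitutive genes provide pure neighbour context.
#'
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$seed`.  The result is deterministic
#'   given the seed.
#' @return An `annotation` object.  The generating truth is attached as
#'   attribute `"sim_truth"` (see [sim_truth()]) and the synthetic chromosome
#'   lengths as attribute `"chrom_lengths"`.
#' @export
simulate_annotation <- function(config, seed = config$seed) {
  withr::local_seed(seed)
  n <- config$n_genes
  if (n == 0) {
    empty <- tibble::tibble(gene_id = character(), transcript_id = character(),
                            chrom = character(), start = integer(),
                            end = integer(), strand = character())
    ann <- as_annotation(empty[0, ])
    attr(ann, "sim_truth") <- tibble::tibble()
    attr(ann, "chrom_lengths") <- tibble::tibble(chrom = character(),
                                                 length = integer())
    return(ann)
  }
  types <- allocate_events(config$event_mix, n)
  E <- as.integer(config$exon_length)
  Cx <- as.integer(config$cassette_length)
  S <- as.integer(config$alt_shift)
  origin <- 100L

  exon_rows <- vector("list", n)
  truth_rows <- vector("list", n)
  chrom_rows <- vector("list", n)

  for (i in seq_len(n)) {
    gid <- sprintf("g%04d", i)
    chrom <- sprintf("chr_%s", gid)
    strand <- if (i %% 3 == 0) "-" else "+"
    type <- types[i]
    mk <- function(tx, s, e) {
      tibble::tibble(gene_id = gid, transcript_id = paste0(gid, ".", tx),
                     chrom = chrom, start = as.integer(s), end = as.integer(e),
                     strand = strand)
    }
    if (type == "constitutive") {
      l <- draw_intron_length(3, config$intron_length_classes)
      b <- origin + cumsum(c(0L, E + l[1], E + l[2], E + l[3]))
      ex <- mk("t1", b, b + E)
      jt <- tibble::tibble(intron_id = interval_id(chrom, b[-4] + E, b[-1], strand),
                           frac_A = 1, frac_B = 1, ri_target = FALSE)
      target <- NA_character_
    } else if (type == "CEx") {
      l <- draw_intron_length(2, config$intron_length_classes)
      e1 <- c(origin, origin + E)
      e2 <- c(e1[2] + l[1], e1[2] + l[1] + Cx)
      e3 <- c(e2[2] + l[2], e2[2] + l[2] + E)
      ex <- dplyr::bind_rows(
        mk("inc", c(e1[1], e2[1], e3[1]), c(e1[2], e2[2], e3[2])),
        mk("skip", c(e1[1], e3[1]), c(e1[2], e3[2]))
      )
      inc1 <- interval_id(chrom, e1[2], e2[1], strand)
      inc2 <- interval_id(chrom, e2[2], e3[1], strand)
      skip <- interval_id(chrom, e1[2], e3[1], strand)
      jt <- tibble::tibble(
        intron_id = c(inc1, inc2, skip),
        frac_A = c(config$psi_a, config$psi_a, 1 - config$psi_a),
        frac_B = c(config$psi_b, config$psi_b, 1 - config$psi_b),
        ri_target = FALSE
      )
      target <- skip
    } else if (type %in% c("Alt5SS", "Alt3SS")) {
      l <- draw_intron_length(1, config$intron_length_classes)
      # donor side is the interval start on '+', the interval end on '-';
      # Alt5SS keeps a common acceptor, Alt3SS a common donor
      share_end <- (type == "Alt5SS") == (strand == "+")
      if (share_end) {
        # exon1 differs (two donors), common exon2
        s2 <- origin + E + S + l
        ex <- dplyr::bind_rows(
          mk("t1", c(origin, s2), c(origin + E, s2 + E)),
          mk("t2", c(origin, s2), c(origin + E + S, s2 + E))
        )
        j1 <- interval_id(chrom, origin + E, s2, strand)
        j2 <- interval_id(chrom, origin + E + S, s2, strand)
      } else {
        # common exon1, two acceptors on exon2
        a1 <- origin + E + l
        ex <- dplyr::bind_rows(
          mk("t1", c(origin, a1), c(origin + E, a1 + E + S)),
          mk("t2", c(origin, a1 + S), c(origin + E, a1 + S + E))
        )
        j1 <- interval_id(chrom, origin + E, a1, strand)
        j2 <- interval_id(chrom, origin + E, a1 + S, strand)
      }
      jt <- tibble::tibble(
        intron_id = c(j1, j2),
        frac_A = c(config$psi_a, 1 - config$psi_a),
        frac_B = c(config$psi_b, 1 - config$psi_b),
        ri_target = FALSE
      )
      target <- j1
    } else { # RI
      l <- as.integer(250 + floor(stats::runif(2) * 350)) # neighbour introns
      ri_l <- as.integer(config$ri_intron_length)
      b <- origin + cumsum(c(0L, E + l[1], E + ri_l, E + l[2]))
      ex <- mk("t1", b, b + E)
      ids <- interval_id(chrom, b[-4] + E, b[-1], strand)
      jt <- tibble::tibble(
        intron_id = ids,
        frac_A = c(1, config$ri_junction_frac[["A"]], 1),
        frac_B = c(1, config$ri_junction_frac[["B"]], 1),
        ri_target = c(FALSE, TRUE, FALSE)
      )
      target <- ids[2]
    }
    exon_rows[[i]] <- ex
    truth_rows[[i]] <- dplyr::mutate(jt, gene_id = gid, event_type = type,
                                     target = .data$intron_id == target)
    chrom_rows[[i]] <- tibble::tibble(chrom = chrom,
                                      length = max(ex$end) + 200L)
  }

  ann <- as_annotation(dplyr::bind_rows(exon_rows))
  attr(ann, "sim_truth") <- dplyr::bind_rows(truth_rows)
  attr(ann, "chrom_lengths") <- dplyr::bind_rows(chrom_rows)
  ann
}

#' Generating truth of a simulated annotation
#'
#' @param annotation An annotation produced by [simulate_annotation()].
#' @return A tibble with one row per derived intron/junction: `gene_id`,
#'   `event_type`, `intron_id`, the generating isoform fractions `frac_A` /
#'   `frac_B`, whether the intron is the RI target (`ri_target`) and whether
#'   it is the event's measurement junction (`target`, e.g. the skip junction
#'   of a cassette event).
#' @export
sim_truth <- function(annotation) {
  truth <- attr(annotation, "sim_truth")
  if (is.null(truth)) {
    stop("annotation carries no simulation truth (not simulated?)")
  }
  truth
}

#' Synthetic chromosome lengths of a simulated annotation
#'
#' @param annotation An annotation produced by [simulate_annotation()].
#' @return Tibble `chrom`, `length`, suitable for [write_sam()].
#' @export
chrom_lengths <- function(annotation) {
  cl <- attr(annotation, "chrom_lengths")
  if (is.null(cl)) {
    cl <- annotation$genes |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(length = max(.data$end) + 200L, .groups = "drop")
  }
  cl
}

#' Simulate aligned single-end reads for one condition
#'
#' Junction reads per junction are Poisson with mean `depth` times the
#' junction's isoform fraction in the condition; each read's overhang (its
#' aligned block upstream of the gap) is uniform over `1 .. read_length - 1`,
#' so the downstream overhang filter is exercised on both sides.  Strictly
#' intronic reads per intron are Poisson with mean `intronic_density * L`
#' (times `ir_fold` for the RI target intron in condition B), placed
#' uniformly inside the intron; introns shorter than the read length get
#' none.  CIGAR strings use M/N only and records are single-end.
#'
#' @param annotation Simulated annotation (carries the generating truth).
#' @param config The [sim_config()] used to build it.
#' @param condition `"A"` or `"B"`.
#' @param seed Seed; defaults to `config$seed` offset by the condition so
#'   the two libraries are independent but reproducible.
#' @return An alignment tibble (`qname`, `flag`, `chrom`, `pos`, `cigar`)
#'   as consumed by [extract_junction_reads()], [count_strictly_intronic()]
#'   and [write_sam()].
#' @export
simulate_alignments <- function(annotation, config,
                                condition = c("A", "B"), seed = NULL) {
  condition <- match.arg(condition)
  if (is.null(seed)) {
    seed <- config$seed + match(condition, c("A", "B"))
  }
  withr::local_seed(seed)
  rl <- as.integer(config$read_length)
  truth <- sim_truth(annotation)
  intr <- annotation$introns |>
    dplyr::inner_join(truth |> dplyr::select("intron_id", "frac_A", "frac_B",
                                             "ri_target"),
                      by = "intron_id")
  frac <- if (condition == "A") intr$frac_A else intr$frac_B

  # junction-spanning reads
  n_j <- stats::rpois(nrow(intr), config$depth * frac)
  jr <- tibble::tibble(
    chrom = rep(intr$chrom, n_j),
    strand = rep(intr$strand, n_j),
    j_start = rep(intr$start, n_j),
    gap = rep(intr$length, n_j)
  )
  if (nrow(jr) > 0) {
    oh <- 1L + as.integer(floor(stats::runif(nrow(jr)) * (rl - 1L)))
    jr <- jr |>
      dplyr::mutate(
        pos = .data$j_start - oh + 1L,
        cigar = sprintf("%dM%dN%dM", oh, .data$gap, rl - oh)
      )
  } else {
    jr$pos <- integer(0)
    jr$cigar <- character(0)
  }

  # strictly intronic reads
  dens <- config$intronic_density *
    ifelse(intr$ri_target & condition == "B", config$ir_fold, 1)
  mean_ir <- ifelse(intr$length >= rl, dens * intr$length, 0)
  n_i <- stats::rpois(nrow(intr), mean_ir)
  ir <- tibble::tibble(
    chrom = rep(intr$chrom, n_i),
    strand = rep(intr$strand, n_i),
    i_start = rep(intr$start, n_i),
    room = rep(intr$length - rl, n_i)
  )
  if (nrow(ir) > 0) {
    off <- as.integer(floor(stats::runif(nrow(ir)) * (ir$room + 1L)))
    ir <- ir |>
      dplyr::mutate(pos = .data$i_start + off + 1L, cigar = sprintf("%dM", rl))
  } else {
    ir$pos <- integer(0)
    ir$cigar <- character(0)
  }

  out <- dplyr::bind_rows(
    dplyr::select(jr, "chrom", "strand", "pos", "cigar"),
    dplyr::select(ir, "chrom", "strand", "pos", "cigar")
  )
  out |>
    dplyr::mutate(
      qname = sprintf("%s_%s_%06d", condition, .data$chrom,
                      dplyr::row_number()),
      flag = ifelse(.data$strand == "-", 16L, 0L)
    ) |>
    dplyr::select("qname", "flag", "chrom", "pos", "cigar")
}

#' Branch-site detection model
#'
#' Length-dependent detection of branch sites by lariat sequencing: a
#' logistic curve in log intron length fitted through the detection rates of
#' introns around 100 nt and 250 nt, emulating the weaker detection of
#' branch sites in short introns.
#'
#' @param overall_rate Target overall fraction of introns with a BS
#'   annotation (default 0.58; informational — the curve is set by the two
#'   short-intron rates and the intron length mix determines the realised
#'   overall fraction).
#' @param short_rate_250,short_rate_100 Detection rates for introns of
#'   roughly 250 and 100 nt (defaults 0.45 and 0.27).
#' @param bs_offset_range Range (nt) upstream of the 3'SS where the BS
#'   adenosine is placed, default 18-44.
#' @return A `bs_detection_model` list with the fitted logistic coefficients.
#' @export
bs_detection_model <- function(overall_rate = 0.58, short_rate_250 = 0.45,
                               short_rate_100 = 0.27,
                               bs_offset_range = c(18L, 44L)) {
  stopifnot(overall_rate >= 0, overall_rate <= 1,
            short_rate_250 >= 0, short_rate_250 <= 1,
            short_rate_100 >= 0, short_rate_100 <= 1)
  clamp <- function(p) pmin(pmax(p, 1e-9), 1 - 1e-9)
  if (abs(short_rate_250 - short_rate_100) < 1e-12) {
    a <- stats::qlogis(clamp(short_rate_250))
    b <- 0
  } else {
    b <- (stats::qlogis(clamp(short_rate_250)) - stats::qlogis(clamp(short_rate_100))) /
      (log(250) - log(100))
    a <- stats::qlogis(clamp(short_rate_100)) - b * log(100)
  }
  structure(
    list(overall_rate = overall_rate, short_rate_250 = short_rate_250,
         short_rate_100 = short_rate_100, bs_offset_range = bs_offset_range,
         a = a, b = b),
    class = "bs_detection_model"
  )
}

#' Detection probability of a branch site given intron length
#'
#' @param model A [bs_detection_model()].
#' @param length Intron length(s) in nt.
#' @return Probabilities in `[0, 1]`.
#' @export
bs_detection_prob <- function(model, length) {
  p <- stats::plogis(model$a + model$b * log(length))
  # degenerate rates (0 or 1) round back to exactly 0/1
  p[p < 1e-8] <- 0
  p[p > 1 - 1e-8] <- 1
  p
}

#' Simulate a branch-site table for an annotation
#'
#' Each intron receives a branch-site annotation with the length-dependent
#' probability of the detection model; the BS adenosine is placed uniformly
#' within the model's offset range upstream of the 3'SS (strand-aware).
#' Lariat-mismatch support counts are positive integers, and a second,
#' independently placed candidate is occasionally emitted to exercise the
#' per-intron tie-breaking of [assign_branch_sites()].
#'
#' @param annotation An `annotation` object.
#' @param model A [bs_detection_model()].
#' @param seed Integer seed.
#' @param second_candidate_prob Probability of emitting a second candidate
#'   for a detected intron (default 0.15).
#' @return A tibble: `intron_id`, `chrom`, `bs_pos` (0-based),
#'   `lariat_mismatch_count`, `confidence` (`high`/`moderate`).
#' @export
simulate_branch_sites <- function(annotation, model = bs_detection_model(),
                                  seed = 1, second_candidate_prob = 0.15) {
  withr::local_seed(seed)
  intr <- annotation$introns
  empty <- tibble::tibble(intron_id = character(), chrom = character(),
                          bs_pos = integer(), lariat_mismatch_count = integer(),
                          confidence = character())
  if (nrow(intr) == 0) {
    return(empty)
  }
  o_min <- as.integer(model$bs_offset_range[1])
  o_max <- as.integer(model$bs_offset_range[2])
  p <- bs_detection_prob(model, intr$length)
  detected <- stats::runif(nrow(intr)) < p
  detected <- detected & intr$length >= o_min + 2L
  if (!any(detected)) {
    return(empty)
  }
  base <- intr[detected, , drop = FALSE]
  draw <- function(rows, n_extra = 0) {
    hi <- pmin(o_max, rows$length - 2L)
    d <- o_min + as.integer(floor(stats::runif(nrow(rows)) * (hi - o_min + 1L)))
    tibble::tibble(
      intron_id = rows$intron_id,
      chrom = rows$chrom,
      bs_pos = as.integer(ifelse(rows$strand == "+", rows$end - 1L - d,
                                 rows$start + d)),
      lariat_mismatch_count = 1L + stats::rpois(nrow(rows), 1.5),
      confidence = sample(c("high", "moderate"), nrow(rows), replace = TRUE,
                          prob = c(0.7, 0.3))
    )
  }
  first <- draw(base)
  again <- stats::runif(nrow(base)) < second_candidate_prob
  out <- dplyr::bind_rows(first, if (any(again)) draw(base[again, , drop = FALSE]))
  dplyr::arrange(out, .data$intron_id, .data$bs_pos)
}
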