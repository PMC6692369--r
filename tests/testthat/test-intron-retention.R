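# Fixture: one gene, main intron [100, 2100) (L = 2000, 4 segments of 500)
# flanked by intron [2200, 2700) (L = 500); the two are mutual neighbours.
ir_fixture_annotation <- function() {
  as_annotation(tibble::tibble(
    gene_id = "g", transcript_id = "g.t1", chrom = "c",
    start = c(0, 2100, 2700), end = c(100, 2200, 2800), strand = "+"
  ))
}

# Segment-count table for the fixture with given per-segment counts.
ir_fixture_counts <- function(ann, main, nb) {
  segs <- intron_segments(ann$introns)
  main_id <- ann$introns$intron_id[ann$introns$length == 2000]
  nb_id <- ann$introns$intron_id[ann$introns$length == 500]
  segs$count <- 0L
  segs$count[segs$intron_id == main_id] <- as.integer(main)
  segs$count[segs$intron_id == nb_id] <- as.integer(nb)
  segs
}

test_that("normalisation reports counts per million and cancels in ratios", {
  sc <- tibble::tibble(intron_id = "i", segment = 1L, seg_start = 0L,
                       seg_end = 100L, seg_length = 100L, count = 10L)
  expect_equal(normalize_intronic(sc, total = 1e6)$norm_cpm, 10)
  expect_true(is.na(normalize_intronic(sc, total = 0)$norm_cpm))
  # doubling counts and total leaves densities unchanged
  sc2 <- dplyr::mutate(sc, count = count * 2L)
  expect_equal(normalize_intronic(sc, total = 500)$norm_cpm,
               normalize_intronic(sc2, total = 1000)$norm_cpm)
})

test_that("equal intron and neighbour densities give IR 1 and fold 1", {
  ann <- ir_fixture_annotation()
  # density 0.1/nt everywhere: 50 per 500 nt main segment, 25 per 250 nt
  # neighbour segment
  a <- ir_fixture_counts(ann, main = rep(50, 4), nb = 25)
  ir <- ir_table(a, a, ann, pseudocount = 0)
  main <- ir[ir$length == 2000, ]
  expect_equal(main$robust_ir_A, 1)
  expect_equal(main$robust_ir_B, 1)
  expect_equal(main$fold_change, 1)
  expect_equal(main$p_ir, 1)
  expect_equal(main$n_segments, 4L)
})

test_that("robust IR is the segment median and ignores a confined spike", {
  ann <- ir_fixture_annotation()
  base <- ir_fixture_counts(ann, main = c(5, 5, 5, 5), nb = 20)
  spiked <- ir_fixture_counts(ann, main = c(5, 5, 500, 5), nb = 20)
  ir_base <- ir_table(base, base, ann)
  ir_spiked <- ir_table(spiked, spiked, ann)
  expect_identical(ir_spiked$robust_ir_A[ir_spiked$length == 2000],
                   ir_base$robust_ir_A[ir_base$length == 2000])

  # counts (2, 4, 6, 8) against a neighbour sum of 20 reads over 500 nt:
  # segment IR = ((c + 0.5)/500) / ((20.5)/500) with the Haldane pseudocount
  graded <- ir_fixture_counts(ann, main = c(2, 4, 6, 8), nb = 10)
  ir <- ir_table(graded, graded, ann)
  expect_equal(ir$robust_ir_A[ir$length == 2000],
               mean(c(4.5, 6.5)) / 20.5, tolerance = 1e-12)
})

test_that("IR is scale-invariant up to the pseudocount at moderate counts", {
  ann <- ir_fixture_annotation()
  a <- ir_fixture_counts(ann, main = c(10, 12, 14, 16), nb = 30)
  b3 <- ir_fixture_counts(ann, main = 3 * c(10, 12, 14, 16), nb = 90)
  ir1 <- ir_table(a, a, ann)
  ir3 <- ir_table(a, b3, ann)
  main1 <- ir1[ir1$length == 2000, ]
  main3 <- ir3[ir3$length == 2000, ]
  expect_lt(abs(main3$robust_ir_B / main3$robust_ir_A - 1), 0.05)
  expect_lt(abs(main3$fold_change - 1), 0.05)
  expect_equal(main1$robust_ir_A, main3$robust_ir_A)
})

test_that("differential IR reports the fold change and the Fisher p on raw sums", {
  ann <- ir_fixture_annotation()
  a <- ir_fixture_counts(ann, main = c(2, 3, 2, 3), nb = 500)
  b <- ir_fixture_counts(ann, main = c(20, 20, 20, 20), nb = 500)
  ir <- ir_table(a, b, ann, pseudocount = 0)
  main <- ir[ir$length == 2000, ]
  # densities: A 0.005/nt vs neighbour 1/nt; B 0.04 vs 1 -> fold 8
  expect_equal(main$fold_change, 8, tolerance = 1e-12)
  expect_equal(main$p_ir, fisher_oracle(10, 1000, 80, 1000), tolerance = 1e-9)
  expect_equal(main$intron_A, 10L)
  expect_equal(main$intron_B, 80L)

  # fold is symmetric in the two conditions
  ir_rev <- ir_table(b, a, ann, pseudocount = 0)
  expect_equal(ir_rev$fold_change[ir_rev$length == 2000], 8, tolerance = 1e-12)
})

test_that("an intron with no qualifying neighbours is excluded with a reason", {
  solo <- as_annotation(tibble::tibble(
    gene_id = "g", transcript_id = "t", chrom = "c",
    start = c(0, 700), end = c(100, 800), strand = "+"
  ))
  segs <- intron_segments(solo$introns)
  segs$count <- 10L
  ir <- ir_table(segs, segs, solo)
  expect_equal(ir$ir_reason, "no_neighbour")
  expect_true(is.na(ir$fold_change))
  expect_true(is.na(ir$p_ir))
})

test_that("retention needs junction evidence, no competitor, fold and p thresholds", {
  ann <- ir_fixture_annotation()
  a <- ir_fixture_counts(ann, main = c(8, 8, 8, 8), nb = 300)
  b <- ir_fixture_counts(ann, main = c(40, 40, 40, 40), nb = 300)
  ir <- ir_table(a, b, ann)
  main_id <- ann$introns$intron_id[ann$introns$length == 2000]
  nb_id <- ann$introns$intron_id[ann$introns$length == 500]
  mk_calls <- function(p, n_comp) {
    calls <- tibble::tibble(junction_id = c(main_id, nb_id),
                            p_value = c(p, 0.9),
                            n_competitors = c(n_comp, 0L))
    attr(calls, "thresholds") <- list(p = 0.001, dpsi = 0.15, min_reads = 7)
    calls
  }
  ret <- call_retention(ir, mk_calls(1e-5, 0L))
  main <- ret[ret$intron_id == main_id, ]
  expect_true(main$retained)
  expect_equal(main$direction, "up_in_B")
  expect_equal(main$reason, "called")
  # neighbour intron lacks junction support at the p threshold
  expect_false(ret$retained[ret$intron_id == nb_id])

  # a competing junction reroutes the interpretation to alternative splicing
  ret2 <- call_retention(ir, mk_calls(1e-5, 1L))
  expect_false(ret2$retained[ret2$intron_id == main_id])
  expect_equal(ret2$reason[ret2$intron_id == main_id], "has_competitor")

  # junction p above threshold
  ret3 <- call_retention(ir, mk_calls(0.01, 0L))
  expect_equal(ret3$reason[ret3$intron_id == main_id], "junction_p")

  # insufficient fold change (1.5x) with everything else in place
  weak_b <- ir_fixture_counts(ann, main = c(12, 12, 12, 12), nb = 300)
  ir_weak <- ir_table(a, weak_b, ann)
  ret4 <- call_retention(ir_weak, mk_calls(1e-5, 0L))
  main4 <- ret4[ret4$intron_id == main_id, ]
  expect_lt(main4$fold_change, 2)
  expect_false(main4$retained)
  expect_equal(main4$reason, "fold_change")
})
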