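test_that("branch-site assignment keeps the best-supported candidate, deterministically", {
  introns <- tibble::tibble(
    intron_id = "i1", gene_id = "g", chrom = "c",
    start = 1000L, end = 1120L, strand = "+", length = 120L
  )
  two <- tibble::tibble(
    intron_id = "i1", chrom = "c", bs_pos = c(1090L, 1095L),
    lariat_mismatch_count = c(3L, 7L), confidence = "high"
  )
  expect_equal(assign_branch_sites(two, introns)$bs_pos, 1095L)
  # a single candidate is returned as-is
  expect_equal(assign_branch_sites(two[1, ], introns)$bs_pos, 1090L)
  # tie on lariat support: the candidate nearer the 3'SS wins
  tie <- dplyr::mutate(two, lariat_mismatch_count = 5L)
  expect_equal(assign_branch_sites(tie, introns)$bs_pos, 1095L)
  # on '-' the 3'SS is the interval start, mirroring the tie-break
  introns_m <- dplyr::mutate(introns, strand = "-")
  expect_equal(assign_branch_sites(tie, introns_m)$bs_pos, 1090L)
  # input order does not matter
  expect_equal(assign_branch_sites(two[2:1, ], introns),
               assign_branch_sites(two, introns))
  # candidates outside the intron are an error
  bad <- dplyr::mutate(two, bs_pos = c(990L, 1095L))
  expect_error(assign_branch_sites(bad, introns), "outside")
})

test_that("5'SS-BS distances are strand-aware intron offsets", {
  expect_equal(ss5_bs_distance("+", 1000L, 1120L, 1096L), 96L)
  expect_equal(ss5_bs_distance("+", 1000L, 1120L, 1000L), 0L)
  # '-' mirror of the first case: 96 nt from the transcriptional 5' end
  expect_equal(ss5_bs_distance("-", 1000L, 1120L, 1023L), 96L)
  expect_error(ss5_bs_distance("+", 1000L, 1120L, 1120L), "outside")
})

test_that("length-matched sampling draws oversampling x retained from matching deciles", {
  set.seed(42)
  bg <- tibble::tibble(intron_id = sprintf("b%03d", 1:500),
                       length = round(stats::runif(500, 70, 250)))
  ret_len <- round(stats::runif(40, 90, 220))
  smp <- length_matched_sample(bg, ret_len, oversampling = 5, seed = 3)
  expect_equal(nrow(smp), 200L)
  # deterministic under the seed
  expect_equal(length_matched_sample(bg, ret_len, oversampling = 5, seed = 3),
               smp)
  # background identical to the retained set: sampled lengths are a multiset
  # drawn from the retained lengths
  self_bg <- tibble::tibble(intron_id = sprintf("r%02d", seq_along(ret_len)),
                            length = ret_len)
  smp1 <- length_matched_sample(self_bg, ret_len, oversampling = 1, seed = 4)
  expect_equal(nrow(smp1), length(ret_len))
  expect_true(all(smp1$length %in% ret_len))
  expect_error(length_matched_sample(bg[0, ], ret_len), "non-empty")
})

test_that("the KS statistic equals the brute-force ECDF supremum", {
  same <- ks_two_sample(1:10, 1:10)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(ks_two_sample(1:5, 101:105)$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), 1:6)$statistic, 0.5)
  expect_equal(ks_two_sample(c(1, 2, 3), 1:6)$statistic,
               ks_D_oracle(c(1, 2, 3), 1:6))
  set.seed(8)
  for (k in 1:10) {
    x <- stats::rnorm(25 + k)
    y <- stats::rnorm(40, mean = k / 10)
    expect_equal(ks_two_sample(x, y)$statistic, ks_D_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("the distance comparison pools confidences and matches lengths", {
  set.seed(11)
  n <- 120
  introns <- tibble::tibble(
    intron_id = sprintf("i%03d", 1:n), gene_id = "g", chrom = "c",
    start = seq(0L, by = 1000L, length.out = n)
  ) |>
    dplyr::mutate(length = as.integer(round(stats::runif(n, 80, 240))),
                  end = start + length, strand = "+")
  bs <- tibble::tibble(
    intron_id = introns$intron_id, chrom = "c",
    bs_pos = introns$end - 1L - sample(18:40, n, replace = TRUE),
    lariat_mismatch_count = 1L + stats::rpois(n, 2),
    confidence = sample(c("high", "moderate"), n, replace = TRUE)
  )
  ret <- introns$intron_id[1:20]
  out <- bs_distance_test(introns, bs, ret, oversampling = 5, seed = 5)
  g <- glance(out)
  expect_equal(g$n_retained, 20L)
  expect_equal(g$n_background, 100L)
  expect_true(g$ks_p >= 0 && g$ks_p <= 1)
  expect_setequal(unique(tidy(out)$group), c("retained", "background"))
})

test_that("B-complex geometry arithmetic reproduces the span bookkeeping", {
  m <- geometry_model()
  expect_equal(extended_span_nt(m), 21)
  expect_equal(min_span_nt(m), 52)
  expect_equal(extended_span_nt(geometry_model(gap_nm = 0)), 0)
  expect_equal(extended_span_nt(geometry_model(gap_nm = 7)), 10)
  expect_equal(min_span_nt(geometry_model(helix_5ss_nt = 10, helix_bs_nt = 10,
                                          gap_nm = 7)), 30)
  expect_equal(min_span_nt(geometry_model(helix_5ss_nt = 0, helix_bs_nt = 0,
                                          gap_nm = 0)), 0)
  expect_error(geometry_model(rise_nm_per_nt = 0), "positive")
})

test_that("construct distances conserve the BS-to-3'SS block and are affine in length", {
  expect_equal(construct_distance(120, 96, 80), 56)
  expect_equal(construct_distance(120, 96, 120), 96)
  expect_equal(construct_distance(211, 151, 116), 56)
  expect_equal(construct_distance(120, 96, c(150, 90, 80, 70)),
               c(126, 66, 56, 46))
  # affine with slope 1 in the new intron length
  lens <- seq(30, 300, by = 10)
  d <- construct_distance(120, 96, lens)
  expect_true(all(diff(d) == 10))
  expect_error(construct_distance(120, 96, 20), "impossible")
})
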