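test_that("two-sided Fisher p matches exhaustive hypergeometric enumeration", {
  expect_equal(fisher_two_sided(5, 5, 5, 5), 1)
  expect_equal(fisher_two_sided(0, 10, 10, 0), fisher_oracle(0, 10, 10, 0),
               tolerance = 1e-10)
  expect_equal(fisher_two_sided(10, 100, 50, 100), fisher_oracle(10, 100, 50, 100),
               tolerance = 1e-10)
  # degenerate margins carry no evidence
  expect_equal(fisher_two_sided(0, 0, 5, 7), 1)
  expect_equal(fisher_two_sided(0, 5, 0, 7), 1)
  expect_equal(fisher_two_sided(0, 0, 0, 0), 1)
  expect_error(fisher_two_sided(-1, 1, 1, 1), "non-negative")
})

test_that("PSI follows the two-boundary mean with zero-denominator terms dropped", {
  expect_equal(psi(7, 7, 7), 0.5)
  expect_equal(psi(10, 0, 0), 1)
  expect_equal(psi(6, 2, 4), mean(c(6 / 8, 6 / 10)), tolerance = 1e-12)
  expect_equal(psi(6, 2, 4), 0.675, tolerance = 1e-12)
  # one dropped term: J = 0 with an empty same-start side
  expect_equal(psi(0, 0, 10), 0)
  # both terms undefined
  expect_true(is.na(psi(0, 0, 0)))
  # vectorised, bounded, monotone in J at fixed neighbour sums
  j <- 0:60
  vals <- psi(j, 20, 35)
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(diff(vals) >= 0))
})

# A hand-built two-condition junction table exercising each calling gate.
# Junction j1 carries the signal; nb_s / nb_e share its start / end with
# identical counts (so PSI = J / (J + S)), and nb_bulk shares no boundary
# (it feeds the Fisher denominator but not PSI).
make_call_fixture <- function(j, s, bulk = c(0L, 0L)) {
  jt <- tibble::tibble(
    junction_id = c("j1", "nb_s", "nb_e", "nb_bulk"),
    gene_id = "g", chrom = "c",
    start = c(100L, 100L, 40L, 700L), end = c(300L, 500L, 300L, 900L),
    strand = "+", status = "annotated",
    count_A = c(j[1], s[1], s[1], bulk[1]),
    count_B = c(j[2], s[2], s[2], bulk[2])
  )
  nb <- tibble::tibble(
    junction_id = "j1",
    neighbour_id = c("nb_s", "nb_e", "nb_bulk"),
    shares_start = c(TRUE, FALSE, FALSE),
    shares_end = c(FALSE, TRUE, FALSE),
    gap = c(0L, 0L, 200L)
  )
  list(jt = jt, nb = nb)
}

test_that("differential calls require all three thresholds, strictly", {
  # strong signal: passes everything (PSI 0.2 -> 0.6)
  fx <- make_call_fixture(j = c(20L, 60L), s = c(80L, 40L))
  calls <- call_differential(fx$jt, fx$nb)
  j1 <- calls[calls$junction_id == "j1", ]
  expect_equal(j1$psi_A, 0.2)
  expect_equal(j1$psi_B, 0.6)
  expect_true(j1$p_value < 0.001)
  expect_true(j1$differential)
  expect_equal(j1$reason, "called")

  # dPSI exactly at the threshold is not called (strict inequality)
  fx <- make_call_fixture(j = c(150L, 300L), s = c(850L, 700L))
  calls <- call_differential(fx$jt, fx$nb)
  j1 <- calls[calls$junction_id == "j1", ]
  expect_equal(j1$dpsi, 0.15, tolerance = 1e-12)
  expect_true(j1$p_value < 0.001)
  expect_false(j1$differential)
  expect_equal(j1$reason, "dpsi")

  # fewer than 7 reads in both conditions blocks the call even at tiny p
  fx <- make_call_fixture(j = c(6L, 0L), s = c(18L, 3L),
                          bulk = c(2000L, 60000L))
  calls <- call_differential(fx$jt, fx$nb)
  j1 <- calls[calls$junction_id == "j1", ]
  expect_true(j1$p_value < 0.001)
  expect_true(j1$dpsi > 0.15)
  expect_false(j1$differential)
  expect_equal(j1$reason, "min_reads")

  # junction never observed and no boundary-sharing neighbours: PSI undefined
  fx <- make_call_fixture(j = c(0L, 0L), s = c(0L, 0L), bulk = c(50L, 50L))
  fx$nb <- fx$nb[fx$nb$neighbour_id == "nb_bulk", ]
  calls <- call_differential(fx$jt, fx$nb)
  j1 <- calls[calls$junction_id == "j1", ]
  expect_true(is.na(j1$dpsi))
  expect_false(j1$differential)
  expect_equal(j1$reason, "undefined_psi")

  expect_equal(nrow(call_differential(fx$jt[0, ], fx$nb[0, ])), 0L)
})

test_that("PSI of a cassette skip junction recovers the generating value", {
  # deterministic counts at the generator's expectations: inclusion 75,
  # skip 25 in A; mirrored in B
  cx <- toy_cassette()
  ids <- cx$introns$intron_id
  skip <- ids[cx$introns$start == 200 & cx$introns$end == 700]
  inc <- setdiff(ids, skip)
  jt <- cx$introns |>
    dplyr::transmute(junction_id = intron_id, gene_id, chrom, start, end,
                     strand, status = "annotated",
                     count_A = ifelse(intron_id == skip, 25L, 75L),
                     count_B = ifelse(intron_id == skip, 75L, 25L))
  nb <- neighbour_junctions(jt, cx)
  calls <- call_differential(jt, nb)
  sk <- calls[calls$junction_id == skip, ]
  expect_equal(sk$psi_A, 0.25)
  expect_equal(sk$psi_B, 0.75)
  expect_equal(sk$dpsi, 0.5)
  expect_true(sk$differential)
})

test_that("event classification is strand-aware and recognises cassette trios", {
  base <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g2", "g3", "g3", "g3", "g4"),
    chrom = "c", status = "annotated",
    junction_id = c("a1", "a2", "b1", "b2", "c1", "c2", "c3", "d1"),
    start = c(100L, 100L, 1000L, 1000L, 2000L, 2200L, 2000L, 5000L),
    end = c(200L, 300L, 1100L, 1200L, 2100L, 2300L, 2300L, 5100L),
    strand = c("+", "+", "-", "-", "+", "+", "+", "+")
  )
  out <- classify_events(base)
  got <- stats::setNames(out$category, out$junction_id)
  # '+' junctions sharing a start share the donor: alternative acceptors
  expect_equal(unname(got[c("a1", "a2")]), c("Alt3SS", "Alt3SS"))
  # on '-' the interval start is the acceptor side: alternative donors
  expect_equal(unname(got[c("b1", "b2")]), c("Alt5SS", "Alt5SS"))
  # cassette trio from any seed
  expect_equal(unname(got[c("c1", "c2", "c3")]), rep("CEx", 3))
  expect_equal(unname(got["d1"]), "no_competitor")
  expect_equal(out$n_competitors[out$junction_id == "d1"], 0L)

  # four chained junctions are complex
  four <- tibble::tibble(
    gene_id = "g", chrom = "c", status = "annotated",
    junction_id = c("x1", "x2", "x3", "x4"),
    start = c(100L, 100L, 250L, 250L),
    end = c(200L, 300L, 300L, 500L),
    strand = "+"
  )
  expect_true(all(classify_events(four)$category == "complex"))
})
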