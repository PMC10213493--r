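test_that("call metrics partition to one and count a worked example", {
  truth <- matrix(rep(0L, 10), 10, 1)
  est <- matrix(c(rep(0L, 8), 1L, NA), 10, 1)
  m <- call_metrics(est, truth)
  expect_equal(unname(m$per_sample$correct), 0.8)
  expect_equal(unname(m$per_sample$miscall), 0.1)
  expect_equal(unname(m$per_sample$missing), 0.1)
  expect_equal(unname(m$per_sample$accuracy), 8 / 9)
  expect_equal(m$per_sample$correct + m$per_sample$miscall +
                 m$per_sample$missing, 1, tolerance = 1e-12)
  ident <- call_metrics(truth, truth)
  expect_equal(unname(ident$mean["correct"]), 1)
  allmiss <- call_metrics(matrix(NA_integer_, 10, 1), truth)
  expect_equal(unname(allmiss$per_sample$missing), 1)
  expect_true(is.na(allmiss$per_sample$accuracy))
  expect_error(call_metrics(est, truth[1:5, , drop = FALSE]), "dimensions")
})

test_that("breakpoints fall at marker midpoints and double crossovers are detected", {
  est <- matrix(c(0L, 0L, 1L, 1L), 4, 1)
  bp <- breakpoints_and_segments(est, c(1e6, 2e6, 3e6, 4e6))
  expect_equal(bp$n_breakpoints, 1L)
  expect_equal(bp$segments$end[1], 2.5e6)
  expect_equal(nrow(bp$segments), 2)

  est2 <- matrix(c(0L, 1L, 0L), 3, 1)
  bp2 <- breakpoints_and_segments(est2, c(1e6, 1.4e6, 1.8e6))
  expect_equal(bp2$n_double_crossovers, 1L)
  expect_equal(unname(bp2$dxo_bins["0-1Mb"]), 1L)
  expect_equal(unname(bp2$dxo_bins["1-2Mb"]), 0L)

  # constant genotype: no breakpoints, one terminal segment
  bp3 <- breakpoints_and_segments(matrix(2L, 5, 1), 1:5 * 1e6)
  expect_equal(bp3$n_breakpoints, 0L)
  expect_equal(nrow(bp3$segments), 1)
  # breakpoints = segments - 1 per sample
  set.seed(3)
  est4 <- matrix(sample(c(0:2, NA), 60, TRUE, prob = c(.3, .3, .3, .1)), 30, 2)
  bp4 <- breakpoints_and_segments(est4, sort(sample.int(5e7, 30)))
  expect_equal(sum(bp4$n_breakpoints), nrow(bp4$segments) - 2)
  # segments span first to last nonmissing position per sample
  for (i in 1:2) {
    s <- bp4$segments[bp4$segments$sample == i, ]
    expect_equal(sum(s$length_bp), s$end[nrow(s)] - s$start[1])
  }
})

test_that("missing calls split genotype segments only at nonmissing switches", {
  est <- matrix(c(0L, NA, 0L, NA, 2L), 5, 1)
  bp <- breakpoints_and_segments(est, 1:5 * 1e6)
  expect_equal(bp$n_breakpoints, 1L)          # 0 -> 2 across the NA
  expect_equal(bp$segments$end[1], 4e6)       # midpoint of markers 3 and 5
})

test_that("segregation distortion is chi-square over n, summed per chromosome", {
  est <- matrix(c(rep(0L, 4)), 1, 4)
  sd1 <- segregation_distortion(est)
  expect_equal(unname(sd1$per_marker), 3)       # chi2 = 12, n = 4
  perfect <- matrix(c(0L, 1L, 1L, 2L), 1, 4)
  expect_equal(unname(segregation_distortion(perfect)$per_marker), 0)
  # relabel invariance 0 <-> 2
  set.seed(8)
  g <- matrix(sample(0:2, 40, TRUE), 2, 20)
  expect_equal(segregation_distortion(g)$per_marker,
               segregation_distortion(2L - g)$per_marker)
  # scaling identity: chi2 = n * sum((obs_frac - exp_frac)^2 / exp_frac),
  # so the level chi2/n equals the pure fraction mismatch term
  counts <- c(10, 14, 6)
  n <- sum(counts)
  frac <- counts / n
  expf <- c(.25, .5, .25)
  lvl <- segregation_distortion(matrix(rep(0:2, counts), 1))$per_marker
  expect_equal(unname(lvl), sum((frac - expf)^2 / expf), tolerance = 1e-12)
  # chromosome level sums markers
  two <- rbind(rep(0L, 4), rep(0L, 4))
  sd2 <- segregation_distortion(two, chrom = c("c1", "c1"))
  expect_equal(unname(sd2$per_chrom["c1"]), 6)
})

test_that("the Poisson double-crossover formula reproduces the F2 expectation", {
  e <- expected_double_crossovers(map_cM_per_Mb = 4, window_Mb = 1,
                                  gametes = 1628)
  expect_equal(e$probability, 1 - exp(-0.04) * 1.04, tolerance = 1e-15)
  expect_equal(round(100 * e$probability, 2), 0.08)
  expect_lt(e$expectation, 2)
  expect_gt(e$expectation, 1)
  expect_equal(expected_double_crossovers(4, 0, 10)$probability, 0)
})

test_that("masking respects the strict depth and marker filters and concordance is high on clean data", {
  set.seed(37)
  # GBS-like regime: low depth so only a small reliable subset is masked,
  # dense map (0.5 cM spacing) so neighbors can recover the masked cells
  sim <- simulate_cross(scenario = "homoP2_F2", n_offspring = 40,
                        n_markers = 400, offspring_depth = 2.5,
                        bias_fraction = 0, mismap_fraction = 0, seed = 41)
  calls_masked <- NULL
  est_fn <- function(d) {
    calls_masked <<- d
    two_round_estimate(d, mating_design("homoP2_F2"), model_params(400))
  }
  res <- mask_and_concordance(sim$ds, est_fn)
  expect_gt(res$concordance, 0.95)
  expect_gt(res$n_masked, 0)
  # masked cells had > 6 reads before masking and are zeroed after
  oc <- which(sim$ds$roles == "offspring")
  zeroed <- (sim$ds$y_ref + sim$ds$y_alt)[, oc] > 0 &
    (calls_masked$y_ref + calls_masked$y_alt)[, oc] == 0
  expect_true(all((sim$ds$y_ref + sim$ds$y_alt)[, oc][zeroed] > 6))

  # a cell with exactly 6 reads is never masked
  naive <- naive_calls(sim$ds)[, oc]
  depth6 <- (sim$ds$y_ref + sim$ds$y_alt)[, oc] == 6 & !is.na(naive)
  expect_true(all((calls_masked$y_ref + calls_masked$y_alt)[, oc][depth6] ==
                    (sim$ds$y_ref + sim$ds$y_alt)[, oc][depth6]))
})

test_that("markers failing the MAF filter are excluded from masking", {
  # construct: marker 1 MAF ~ 0.1 (excluded), marker 2 MAF 0.5 (maskable)
  nr <- 20
  yr <- rbind(c(9L, 0L, rep(9L, nr - 2), 9L, 9L),
              c(9L, 0L, rep(c(9L, 0L), (nr) / 2)))
  ya <- rbind(c(0L, 9L, rep(0L, nr - 2), 0L, 0L),
              c(0L, 9L, rep(c(0L, 9L), (nr) / 2)))
  ds <- tiny_dataset(yr, ya, pos = c(1e6, 2e6))
  got_mask <- NULL
  est_fn <- function(d) {
    got_mask <<- d
    # dummy estimate: echo naive calls
    structure(list(offspring_geno = naive_calls(d)[, -(1:2)]),
              class = "hc_estimate")
  }
  res <- mask_and_concordance(ds, est_fn)
  oc <- 3:(nr + 2)
  expect_true(all((got_mask$y_ref + got_mask$y_alt)[1, oc] ==
                    (ds$y_ref + ds$y_alt)[1, oc]))  # marker 1 untouched
  expect_gt(sum((got_mask$y_ref + got_mask$y_alt)[2, oc] == 0), 0)
})
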