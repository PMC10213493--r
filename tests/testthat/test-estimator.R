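design_f2 <- mating_design("homoP2_F2")

test_that("a forward pass with deep unambiguous reads attains the exhaustive maximum", {
  set.seed(21)
  # founders opposite homozygotes, one offspring clearly het then hom-ref
  yr <- cbind(c(25L, 25L), c(0L, 0L), c(12L, 30L))
  ya <- cbind(c(0L, 0L), c(25L, 25L), c(13L, 0L))
  ds <- tiny_dataset(yr, ya, pos = c(1e6, 2e6))
  p <- model_params(2)
  sp <- state_space(design_f2)
  v <- viterbi_pass(ds, sp, p, design = design_f2)
  got <- pass_log_prob(ds, design_f2, p, v)
  want <- brute_force_max(ds, design_f2, p)
  expect_equal(got, want, tolerance = 1e-9)
  # implied genotypes: het at marker 1, hom-ref at marker 2
  g <- sp$geno[cbind(v$hap[, 1], v$combo)]
  expect_equal(g, c(1L, 0L))
})

test_that("the forward pass never exceeds the exhaustive maximum and attains it on most random instances", {
  set.seed(42)
  sp <- state_space(design_f2)
  n <- 60
  hit <- 0
  for (r in seq_len(n)) {
    inst <- random_tiny_instance()
    v <- viterbi_pass(inst$ds, sp, inst$params, design = design_f2)
    got <- pass_log_prob(inst$ds, design_f2, inst$params, v)
    want <- brute_force_max(inst$ds, design_f2, inst$params)
    expect_lte(got, want + 1e-9)
    # the haplotype paths are always conditionally optimal given the
    # returned founder sequence
    cond <- brute_force_max(inst$ds, design_f2, inst$params,
                            fixed_combo = v$combo)
    expect_equal(got, cond, tolerance = 1e-9)
    if (want - got <= 1e-9) hit <- hit + 1
  }
  expect_gte(hit / n, 0.95)
})

test_that("all-zero reads still yield an admissible decoding with everything masked", {
  yr <- matrix(0L, 4, 4)
  ya <- matrix(0L, 4, 4)
  ds <- tiny_dataset(yr, ya)
  set.seed(1)
  est <- two_round_estimate(ds, design_f2, model_params(4))
  expect_true(all(est$offspring_geno_raw %in% 0:2))
  expect_true(all(is.na(est$offspring_geno)))  # nothing can clear p_call=0.9
})

test_that("genotype posteriors sum to one and are decisive on deep concordant reads", {
  set.seed(4)
  sim <- simulate_cross(scenario = "homoP2_F2", n_offspring = 6,
                        n_markers = 40, offspring_depth = 20,
                        bias_fraction = 0, mismap_fraction = 0, seed = 12)
  est <- two_round_estimate(sim$ds, design_f2, model_params(40))
  sums <- apply(est$posterior, c(1, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-10)
  # a deep hom-ref cell surrounded by concordant markers
  oc <- which(sim$ds$roles == "offspring")
  cell <- which(sim$truth$offspring_geno == 0 &
                  sim$ds$y_ref[, oc] >= 25, arr.ind = TRUE)
  cell <- cell[cell[, 1] %in% 5:35, , drop = FALSE]
  expect_gt(nrow(cell), 0)
  m <- cell[1, 1]; i <- cell[1, 2]
  expect_gt(est$posterior[m, 1, i], 0.999)
})

test_that("a single-marker chromosome reduces to the prior-weighted emission", {
  yr <- cbind(8L, 0L, 2L)
  ya <- cbind(0L, 8L, 1L)
  ds <- tiny_dataset(yr, ya, pos = 5e5)
  p <- model_params(1)
  set.seed(2)
  est <- two_round_estimate(ds, design_f2, p)
  sp <- state_space(design_f2)
  l <- offspring_emission(2, 1, sp, p, 1)[, est$combo]
  post_manual <- vapply(0:2, function(x)
    sum((1 / 4) * l * (sp$geno[, est$combo] == x)), 0)
  post_manual <- post_manual / sum(post_manual)
  expect_equal(est$posterior[1, , 1], post_manual, tolerance = 1e-10)
})

test_that("genotype calling applies the posterior threshold", {
  post <- array(0, c(2, 3, 1))
  post[1, , 1] <- c(0.95, 0.04, 0.01)
  post[2, , 1] <- c(0.89, 0.10, 0.01)
  geno_raw <- matrix(0L, 2, 1)
  called <- call_genotypes(post, geno_raw, p_call = 0.9)
  expect_equal(called$geno[, 1], c(0L, NA))
  expect_equal(called$marginal[, 1], c(0.95, 0.89))
  none <- call_genotypes(post, geno_raw, p_call = 0)
  expect_false(anyNA(none$geno))
})

test_that("relabeling alleles and founders mirrors the output", {
  set.seed(33)
  sim <- simulate_cross(scenario = "homoP2_F2", n_offspring = 8,
                        n_markers = 30, offspring_depth = 8,
                        bias_fraction = 0, mismap_fraction = 0, seed = 44)
  p <- model_params(30)
  set.seed(7)
  a <- two_round_estimate(sim$ds, design_f2, p)
  swapped <- hc_dataset(sim$ds$marker_ids, sim$ds$chrom, sim$ds$pos,
                        sim$ds$alt, sim$ds$ref, sim$ds$y_alt, sim$ds$y_ref,
                        sim$ds$samples, sim$ds$roles)
  set.seed(7)
  b <- two_round_estimate(swapped, design_f2, p)
  expect_equal(b$offspring_geno_raw, 2L - a$offspring_geno_raw)
  expect_equal(is.na(b$offspring_geno), is.na(a$offspring_geno))
})

test_that("when both rounds agree the merged result matches a single pass", {
  set.seed(13)
  sim <- simulate_cross(scenario = "homoP2_F2", n_offspring = 5,
                        n_markers = 20, offspring_depth = 20,
                        bias_fraction = 0, mismap_fraction = 0, seed = 5)
  p <- model_params(20)
  sp <- state_space(design_f2)
  set.seed(3)
  fwd <- viterbi_pass(sim$ds, sp, p, design = design_f2)
  set.seed(3)
  est <- two_round_estimate(sim$ds, design_f2, p)
  # deep unbiased reads leave no ambiguity: merged == forward
  expect_equal(est$combo, fwd$combo)
  g_fwd <- matrix(sp$geno[cbind(as.vector(fwd$hap),
                                rep(fwd$combo, times = ncol(fwd$hap)))],
                  20, 5)
  expect_equal(est$offspring_geno_raw, g_fwd)
})

test_that("two-round merging does not hurt accuracy relative to forward-only", {
  set.seed(99)
  sp <- state_space(design_f2)
  diffs <- replicate(20, {
    sim <- simulate_cross(scenario = "homoP2_F2", n_offspring = 12,
                          n_markers = 60, offspring_depth = 1.5,
                          bias_fraction = 0.4, seed = sample.int(1e6, 1))
    p <- model_params(60)
    est <- two_round_estimate(sim$ds, design_f2, p)
    fwd <- viterbi_pass(sim$ds, sp, p, design = design_f2)
    g_fwd <- matrix(sp$geno[cbind(as.vector(fwd$hap),
                                  rep(fwd$combo, times = ncol(fwd$hap)))],
                    60, 12)
    mean(est$offspring_geno_raw == sim$truth$offspring_geno) -
      mean(g_fwd == sim$truth$offspring_geno)
  })
  # paired across seeds: merging must not be significantly worse
  tt <- stats::t.test(diffs, alternative = "less")
  expect_gt(tt$p.value, 0.01)
})

test_that("correct call rate does not degrade with depth on unbiased data", {
  set.seed(55)
  rates <- sapply(c(0.5, 3, 20), function(dp) {
    mean(replicate(5, {
      sim <- simulate_cross(scenario = "homoP2_F2", n_offspring = 15,
                            n_markers = 50, offspring_depth = dp,
                            bias_fraction = 0, mismap_fraction = 0,
                            seed = sample.int(1e6, 1))
      est <- two_round_estimate(sim$ds, design_f2, model_params(50))
      mean(!is.na(est$offspring_geno) &
             est$offspring_geno == sim$truth$offspring_geno)
    }))
  })
  expect_true(all(diff(rates) > -0.01))
})

test_that("outbred F1 and 8-way RIL designs decode with high accuracy over called genotypes", {
  sim <- simulate_cross(scenario = "hetP2_F1", n_offspring = 15,
                        n_markers = 80, offspring_depth = 4,
                        bias_fraction = 0, mismap_fraction = 0, seed = 2)
  set.seed(2)
  est <- two_round_estimate(sim$ds, mating_design("hetP2_F1"),
                            model_params(80))
  mF1 <- call_metrics(est$offspring_geno, sim$truth$offspring_geno)
  expect_gt(unname(mF1$mean["accuracy"]), 0.9)

  sim2 <- simulate_cross(scenario = "homoP8_RIL", n_offspring = 8,
                         n_markers = 60, offspring_depth = 4,
                         bias_fraction = 0, mismap_fraction = 0, seed = 3)
  set.seed(3)
  est2 <- two_round_estimate(sim2$ds, mating_design("homoP8_RIL"),
                             model_params(60))
  mRIL <- call_metrics(est2$offspring_geno, sim2$truth$offspring_geno)
  expect_gt(unname(mRIL$mean["accuracy"]), 0.95)
  # founder genotypes are recovered essentially perfectly at 5x nonzero
  expect_gt(mean(est2$founder_geno == sim2$truth$founder_geno), 0.98)
  expect_gt(mean(est$founder_geno == sim$truth$founder_geno), 0.9)
})
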