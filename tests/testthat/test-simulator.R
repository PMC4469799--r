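test_that("scenario definitions constrain the effect draws", {
  # (a): no pleiotropy at all
  ea <- draw_effects(sim_params(scenario = "a", seed = 2))
  expect_identical(ea$alpha, rep(0, 25))
  expect_identical(ea$confounder_path, rep(0, 25))

  # (b): balanced about zero (law of large numbers on one big draw)
  eb <- draw_effects(sim_params(n_variants = 1e5, scenario = "b", seed = 3))
  mc_se <- sd(eb$alpha) / sqrt(1e5)
  expect_lt(abs(mean(eb$alpha)), 3 * mc_se)
  expect_true(all(eb$alpha >= -0.1 & eb$alpha <= 0.1))

  # (c): positive direct effects drawn independently of the gammas
  ec <- draw_effects(sim_params(n_variants = 1e5, scenario = "c", seed = 4))
  expect_true(all(ec$alpha >= 0))
  expect_lt(abs(cor(ec$alpha, ec$gamma)), 3 / sqrt(1e5))
  expect_identical(ec$confounder_path, rep(0, 1e5))

  # (d): per-variant confounder path 2.5 x alpha
  ed <- draw_effects(sim_params(scenario = "d", seed = 5))
  expect_identical(ed$confounder_path, 2.5 * ed$alpha)
  expect_true(all(ed$gamma > 0))
})

test_that("cohorts follow the structural equations", {
  p <- sim_params(n_variants = 5L, n_per_sample = 4000L, beta = 0.3,
                  scenario = "d", seed = 6)
  e <- draw_effects(p)
  ch <- simulate_cohort(p, e, "exposure")
  expect_true(all(ch$genotypes %in% 0:2))
  # the structural equations hold exactly, row by row
  expect_equal(ch$exposure,
               as.vector(ch$genotypes %*% e$gamma) + ch$confounder + ch$eps_x)
  expect_equal(ch$outcome,
               as.vector(ch$genotypes %*% e$alpha) + p$beta * ch$exposure +
                 ch$confounder + ch$eps_y)

  # null effects: the exposure is confounder plus noise only
  p0 <- sim_params(n_variants = 5L, n_per_sample = 2000L, strength = 0,
                   scenario = "a", seed = 7)
  e0 <- draw_effects(p0)
  ch0 <- simulate_cohort(p0, e0, "exposure")
  expect_equal(ch0$exposure - ch0$confounder, ch0$eps_x)
  expect_equal(var(ch0$exposure), var(ch0$confounder) + 1, tolerance = 0.15)

  # allele frequency 0.5 gives mean genotype near 1
  ph <- sim_params(n_variants = 3L, n_per_sample = 5000L,
                   maf_range = c(0.5, 0.5), seed = 8)
  gh <- simulate_cohort(ph, draw_effects(ph), "exposure")$genotypes
  expect_equal(unname(colMeans(gh)), rep(1, 3), tolerance = 0.05)
})

test_that("summaries are consistent for the generating parameters at large N", {
  p <- sim_params(n_variants = 10L, n_per_sample = 20000L, beta = 0.05,
                  scenario = "a", strength = 1.25, seed = 9)
  e <- draw_effects(p)
  d <- simulate_mr_data(p)
  expect_false(is_oriented(d))
  expect_identical(d$eaf, e$maf)
  # each exposure association within 4 reported SEs of its true gamma
  expect_true(all(abs(d$beta_exposure - e$gamma) < 4 * d$se_exposure))
  # end-to-end: IVW recovers the causal effect within its own uncertainty
  f <- ivw(suppressWarnings(orient(d)))
  expect_lt(abs(f$slope - 0.05), 4 * f$slope_se)
})

test_that("monomorphic variants are reported as simulation failures", {
  ch <- structure(list(genotypes = matrix(2L, 20, 2),
                       exposure = rnorm(20), outcome = rnorm(20)),
                  class = "mr_cohort")
  expect_error(summarize_cohorts(ch, ch, eaf = c(0.5, 0.5)), "monomorphic")
})

test_that("strength calibration hits the target mean F", {
  p <- sim_params(n_variants = 25L, n_per_sample = 250L, seed = 10)
  expect_equal(calibrate_strength(1, p), 0)    # null instruments
  m <- calibrate_strength(10.4, p)
  expect_gt(m, 0)
  # pilot simulation close to the target
  fs <- vapply(1:40, function(r) {
    pr <- p; pr$strength <- m; pr$seed <- derive_seed(10, paste0("pil", r))
    mean_f_statistic(simulate_mr_data(pr))
  }, numeric(1))
  expect_equal(mean(fs), 10.4, tolerance = 0.05 * 10.4)
  # doubling N at fixed strength roughly doubles mean F - 1
  p2 <- p; p2$n_per_sample <- 500L
  fs2 <- vapply(1:40, function(r) {
    pr <- p2; pr$strength <- m; pr$seed <- derive_seed(10, paste0("pil", r))
    mean_f_statistic(simulate_mr_data(pr))
  }, numeric(1))
  expect_equal(mean(fs2 - 1) / mean(fs - 1), 2, tolerance = 0.12)
  # an absurd target is refused
  expect_error(calibrate_strength(1e6, p), "unattainable")
})

test_that("theoretical IVW bias matches its defining sum", {
  gamma <- c(0.5, 1, 1.5); w <- c(2, 1, 0.5)
  expect_equal(theoretical_bias(gamma, rep(0, 3), w), 0)
  expect_equal(theoretical_bias(gamma, 0.3 * gamma, w), 0.3)
  set.seed(1)
  a <- rnorm(3)
  expect_equal(theoretical_bias(gamma, a, w),
               sum(gamma * w * a) / sum(gamma^2 * w))
  expect_error(theoretical_bias(c(0, 0), c(1, 1), c(1, 1)), "undefined")
})

test_that("directional pleiotropy under InSIDE biases IVW upward at the null", {
  # mean IVW estimate strictly positive in scenario (c) with beta = 0
  cell <- run_cell(sim_params(scenario = "c", strength = 1.25, seed = 12),
                   n_reps = 150)
  expect_gt(cell$ivw_mean_estimate,
            3 * cell$ivw_sd_estimate / sqrt(cell$n_reps))
  # and the sign agrees with the theoretical bias of the drawn effects
  e <- draw_effects(sim_params(scenario = "c", seed = 12))
  expect_gt(theoretical_bias(e$gamma, e$alpha, rep(1, 25)), 0)
})
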