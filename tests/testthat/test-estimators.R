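test_that("Wald ratio estimates match direct substitution and elementwise oracle", {
  d <- mr_data("v1", 0.5, 0.05, 1.0, 0.2)
  r <- ratio_estimates(d)
  expect_equal(r$estimate, 2.0)
  expect_equal(r$se, 0.4)
  expect_equal(r$weight, 0.5^2 / 0.2^2)

  d0 <- mr_data("v1", 0.3, 0.05, 0.0, 0.2)
  expect_equal(ratio_estimates(d0)$estimate, 0)

  d5 <- random_dataset(5, seed = 11)
  r5 <- ratio_estimates(d5)
  # independent elementwise recomputation
  expect_equal(r5$estimate, d5$beta_outcome / d5$beta_exposure)
  expect_equal(r5$se, d5$se_outcome / abs(d5$beta_exposure))
  expect_equal(r5$weight, d5$beta_exposure^2 / d5$se_outcome^2)

  dz <- mr_data(c("ok", "zero"), c(0.2, 0), c(1, 1), c(0.1, 0.1), c(1, 1))
  expect_error(ratio_estimates(dz), "zero")
})

test_that("IVW slope equals the closed-form weighted average of ratio estimates", {
  # exact proportionality
  d <- mr_data(paste0("v", 1:3), c(0.1, 0.2, 0.3), rep(0.01, 3),
               c(0.05, 0.10, 0.15), c(1, 1, 1))
  f <- ivw(d)
  expect_equal(f$slope, 0.5)
  expect_equal(sum(f$weights * residuals(f)^2), 0, tolerance = 1e-24)

  for (s in 1:10) {
    dd <- random_dataset(10, seed = s)
    w <- dd$beta_exposure^2 / dd$se_outcome^2
    b <- dd$beta_outcome / dd$beta_exposure
    oracle <- sum(w * b) / sum(w)      # term-by-term weighted average
    expect_equal(ivw(dd)$slope, oracle, tolerance = 1e-10)
  }
})

test_that("IVW inference matches weighted regression through the origin (lm oracle)", {
  d <- random_dataset(12, seed = 42)
  f <- ivw(d)
  lmfit <- lm(beta_outcome ~ 0 + beta_exposure, data = as.data.frame(d),
              weights = 1 / d$se_outcome^2)
  sm <- summary(lmfit)$coefficients
  expect_equal(f$slope, unname(coef(lmfit)[1]), tolerance = 1e-12)
  expect_equal(f$slope_se, unname(sm[1, 2]), tolerance = 1e-12)
  expect_equal(f$slope_p, unname(sm[1, 4]), tolerance = 1e-12)
  expect_equal(f$df, 11L)
  expect_true(f$slope_ci_lower < f$slope && f$slope < f$slope_ci_upper)
})

test_that("MR-Egger matches the weighted least-squares normal equations and lm", {
  d <- random_dataset(8, seed = 9, oriented = TRUE)
  f <- mr_egger(d)
  # independent 2x2 normal-equations solve
  X <- cbind(1, d$beta_exposure)
  W <- diag(1 / d$se_outcome^2)
  ab <- solve(t(X) %*% W %*% X, t(X) %*% W %*% d$beta_outcome)
  expect_equal(f$intercept, ab[1, 1], tolerance = 1e-12)
  expect_equal(f$slope, ab[2, 1], tolerance = 1e-12)
  lmfit <- lm(beta_outcome ~ beta_exposure, data = as.data.frame(d),
              weights = 1 / d$se_outcome^2)
  sm <- summary(lmfit)$coefficients
  expect_equal(f$intercept_se, sm[1, 2], tolerance = 1e-12)
  expect_equal(f$slope_se, sm[2, 2], tolerance = 1e-12)
  expect_equal(f$intercept_p, sm[1, 4], tolerance = 1e-12)
  expect_equal(f$slope_p, sm[2, 4], tolerance = 1e-12)
  expect_equal(f$df, 6L)
})

test_that("exact affine data recovers intercept and slope to machine precision", {
  d <- affine_dataset(a = 0.1, b = 2)
  f <- mr_egger(d)
  expect_equal(f$intercept, 0.1, tolerance = 1e-12)
  expect_equal(f$slope, 2, tolerance = 1e-12)
})

test_that("MR-Egger with a constrained intercept reproduces the IVW fit", {
  for (s in c(2, 7, 13)) {
    d <- orient(random_dataset(9, seed = s))
    fc <- mr_egger(d, constrain_intercept = TRUE)
    fi <- ivw(d)
    expect_identical(fc$slope, fi$slope)
    expect_identical(fc$slope_se, fi$slope_se)
    expect_identical(fc$method, "IVW")
    expect_null(fc$intercept)
  }
})

test_that("estimator preconditions are enforced", {
  d1 <- mr_data("only", 0.3, 0.02, 0.1, 0.05)
  expect_error(ivw(d1), "at least 2")
  expect_error(mr_fit(d1, "ivw", se_model = "fixed"), NA)  # J = 1 allowed
  d2 <- random_dataset(4, seed = 1)            # unoriented
  expect_error(mr_egger(d2), "orient")
  d3 <- orient(random_dataset(2, seed = 1))
  expect_error(mr_egger(d3), "at least 3")
  expect_error(ivw(random_dataset(5), ci_level = 1.2), "ci_level")
})

test_that("Cochran's Q matches hand expansion and summation oracle", {
  # identical ratio estimates: zero dispersion
  d <- affine_dataset(a = 0, b = 1.5, J = 5)
  h <- cochran_q(d)
  expect_equal(h$q_statistic, 0, tolerance = 1e-20)
  expect_equal(h$p_value, 1)

  # two variants with equal weights w: Q = w (b1 - b2)^2 / 2
  d2 <- mr_data(c("p", "q"), c(0.5, 0.5), c(0.01, 0.01),
                c(0.2, 0.4), c(0.1, 0.1))
  w <- 0.5^2 / 0.1^2
  b <- c(0.2, 0.4) / 0.5
  expect_equal(cochran_q(d2)$q_statistic, w * (b[1] - b[2])^2 / 2,
               tolerance = 1e-12)
  expect_equal(cochran_q(d2)$df, 1L)

  # random data: term-by-term recomputation
  dr <- random_dataset(11, seed = 77)
  wr <- dr$beta_exposure^2 / dr$se_outcome^2
  br <- dr$beta_outcome / dr$beta_exposure
  pooled <- sum(wr * br) / sum(wr)
  q_oracle <- sum(wr * (br - pooled)^2)
  hr <- cochran_q(dr)
  expect_equal(hr$q_statistic, q_oracle, tolerance = 1e-10)
  expect_equal(hr$p_value, pchisq(q_oracle, 10, lower.tail = FALSE))

  expect_error(cochran_q(mr_data("x", 1, 1, 1, 1)), "at least 2")
})

test_that("MAF correction applies the Hardy-Weinberg genotype scale", {
  d <- mr_data("m", 1, 0.1, 0.5, 0.1, eaf = 0.5)
  expect_equal(maf_corrected_strength(d), sqrt(0.5))
  d2 <- mr_data("m", 1, 0.1, 0.5, 0.1, eaf = 1e-9)
  expect_lt(maf_corrected_strength(d2), 1e-4)   # vanishes with rare alleles
  d3 <- mr_data("m", 0.2, 0.1, 0.5, 0.1, eaf = 0.3)
  expect_equal(maf_corrected_strength(d3), 0.1296148, tolerance = 1e-6)
  d4 <- mr_data(c("has", "lacks"), c(1, 1), c(1, 1), c(1, 1), c(1, 1),
                eaf = c(0.2, NA))
  expect_error(maf_corrected_strength(d4), "lacks")
  expect_error(maf_corrected_strength(random_dataset(3)), "frequency missing")
})

test_that("mean F statistic averages the squared exposure t-ratios", {
  d1 <- mr_data("s", 0.3, 0.1, 0, 1)
  expect_equal(mean_f_statistic(d1), 9)
  d2 <- mr_data(c("a", "b"), c(0.2, 0.4), c(0.1, 0.1), c(0, 0), c(1, 1))
  expect_equal(mean_f_statistic(d2), 10)       # (4 + 16) / 2
  dr <- random_dataset(9, seed = 5)
  expect_equal(mean_f_statistic(dr),
               mean((dr$beta_exposure / dr$se_exposure)^2))
})

test_that("fixed se model gives identical point estimates and known-variance SEs", {
  d <- orient(random_dataset(10, seed = 21))
  for (method in c("ivw", "egger")) {
    fr <- mr_fit(d, method)
    ff <- mr_fit(d, method, se_model = "fixed")
    expect_equal(fr$slope, ff$slope)
    w <- 1 / d$se_outcome^2
    if (method == "ivw") {
      expect_equal(ff$slope_se, sqrt(1 / sum(w * d$beta_exposure^2)))
    } else {
      X <- cbind(1, d$beta_exposure)
      V <- solve(t(X) %*% diag(w) %*% X)
      expect_equal(ff$slope_se, sqrt(V[2, 2]), tolerance = 1e-12)
      expect_equal(ff$intercept_se, sqrt(V[1, 1]), tolerance = 1e-12)
    }
    expect_equal(ff$slope_p, 2 * pnorm(-abs(ff$slope / ff$slope_se)))
  }
})

test_that("fit methods expose coefficients, intervals, predictions and residuals", {
  d <- orient(random_dataset(8, seed = 31))
  f <- mr_egger(d)
  expect_named(coef(f), c("intercept", "slope"))
  ci <- confint(f, "slope")
  expect_equal(unname(ci[1, ]), c(f$slope_ci_lower, f$slope_ci_upper))
  expect_equal(predict(f, c(0, 1)),
               c(f$intercept, f$intercept + f$slope))
  expect_equal(fitted(f) + residuals(f), d$beta_outcome)
  expect_output(print(summary(f)), "MR-Egger")
  fi <- ivw(d)
  expect_named(coef(fi), "slope")
  expect_equal(predict(fi, 2), 2 * fi$slope)
  sims <- simulate(fi, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(8L, 3L))
})
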