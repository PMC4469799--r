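#' Derive a reproducible sub-seed from a parent seed and a label
#'
#' A small FNV-1a-style hash of `paste(seed, key)` reduced modulo 2^31 - 1.
#' Used throughout the simulator and study driver so that the two samples of
#' a two-sample design, the replicates of a Monte Carlo cell, and the cells
#' of a grid each get stable, order-independent random streams from one
#' parent seed.
#'
#' @param seed integer parent seed.
#' @param key character label of the stream.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  h <- 2166136261
  for (b in utf8ToInt(paste0(format(seed, scientific = FALSE), "/", key))) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(max(1, h %% 2147483646))
}

#' Pleiotropy scenario specification
#'
#' The four patterns of direct (pleiotropic) variant--outcome effects used in
#' the simulation study. With pleiotropy scale `c`:
#' * `"a"` — no pleiotropy: all direct effects are zero (all instruments
#'   valid; InSIDE trivially satisfied).
#' * `"b"` — balanced pleiotropy: direct effects uniform on `[-c, c]`,
#'   independent of instrument strength (InSIDE satisfied).
#' * `"c"` — directional pleiotropy: direct effects uniform on `[0, c]`,
#'   drawn independently of instrument strength (InSIDE satisfied).
#' * `"d"` — directional pleiotropy violating InSIDE: as `"c"`, but each
#'   variant additionally affects the shared confounder with coefficient
#'   2.5 times its direct effect, which correlates the effective direct
#'   effects with the effective instrument strengths.
#'
#' @param label one of `"a"`, `"b"`, `"c"`, `"d"`.
#' @return A list of class `"scenario_spec"` with `label`,
#'   `alpha_distribution` (one of `"degenerate-zero"`, `"uniform-symmetric"`,
#'   `"uniform-positive"`) and `confounder_multiplier` (0, or 2.5 for
#'   `"d"`).
#' @export
scenario_spec <- function(label = c("a", "b", "c", "d")) {
  label <- match.arg(label)
  structure(list(
    label = label,
    alpha_distribution = switch(label,
                                a = "degenerate-zero",
                                b = "uniform-symmetric",
                                c = "uniform-positive",
                                d = "uniform-positive"),
    confounder_multiplier = if (label == "d") 2.5 else 0
  ), class = "scenario_spec")
}

#' Simulation parameters for the two-sample generative model
#'
#' Full specification of the linear structural model used by the simulator.
#' For individual `i` with genotypes `G_ij` (counts of the effect allele,
#' drawn as Binomial(2, p_j) under Hardy--Weinberg equilibrium):
#'
#' ```
#' X_i = sum_j gamma_j G_ij + U_i + e_Xi        (exposure)
#' Y_i = sum_j alpha_j G_ij + beta X_i + U_i + e_Yi   (outcome)
#' ```
#'
#' where `U_i` is an unobserved confounder entering both equations with unit
#' coefficient, `e_Xi`, `e_Yi` are independent standard normal errors, and
#' under scenario `"d"` each variant also feeds the confounder:
#' `U_i = sum_j 2.5 alpha_j G_ij + standard normal`. The two-sample design
#' estimates variant--exposure associations in one cohort of `n_per_sample`
#' individuals and variant--outcome associations in an independent cohort of
#' the same size.
#'
#' @param n_variants number of genetic variants J (default 25).
#' @param n_per_sample size N of each of the two non-overlapping samples.
#' @param beta true causal effect of the exposure on the outcome.
#' @param scenario pleiotropy scenario label or a [scenario_spec()].
#' @param pleiotropy_scale scale `c` of the direct effects (default 0.1).
#' @param maf_range range of the uniform law for per-variant minor allele
#'   frequencies (default `c(0.1, 0.5)`).
#' @param gamma_range range of the uniform base law for instrument effects
#'   before scaling (default `c(0.5, 1.5)`; all positive).
#' @param strength scalar multiplier applied to the drawn instrument
#'   effects; calibrate with [calibrate_strength()] to hit a target mean F
#'   statistic.
#' @param seed integer seed; every stream the simulator uses is derived from
#'   it via [derive_seed()].
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(n_variants = 25L, n_per_sample = 250L, beta = 0,
                       scenario = "a", pleiotropy_scale = 0.1,
                       maf_range = c(0.1, 0.5), gamma_range = c(0.5, 1.5),
                       strength = 1, seed = 1L) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  stopifnot(inherits(scenario, "scenario_spec"))
  n_variants <- as.integer(n_variants)
  n_per_sample <- as.integer(n_per_sample)
  if (n_variants < 1L) stop("n_variants must be >= 1")
  if (n_per_sample < 10L) stop("n_per_sample must be >= 10")
  stopifnot(length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            length(gamma_range) == 2L, gamma_range[1] > 0,
            gamma_range[1] <= gamma_range[2],
            is.numeric(pleiotropy_scale), pleiotropy_scale >= 0,
            is.numeric(strength), strength >= 0, is.numeric(beta))
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  structure(list(n_variants = n_variants, n_per_sample = n_per_sample,
                 beta = beta, scenario = scenario,
                 pleiotropy_scale = pleiotropy_scale,
                 maf_range = maf_range, gamma_range = gamma_range,
                 strength = strength, seed = seed),
            class = "sim_params")
}

#' Draw per-variant effect parameters for one simulated dataset
#'
#' Draws minor allele frequencies, instrument effects on the exposure
#' (`gamma`, all positive) and direct effects on the outcome (`alpha`)
#' according to the scenario, plus the per-variant confounder-path
#' coefficients (`2.5 * alpha` under scenario `"d"`, zero otherwise). The
#' `alpha` draws are independent of the `gamma` draws in scenarios
#' `"b"`/`"c"` (the InSIDE condition); scenario `"d"` violates InSIDE via
#' the confounder path, not by correlating the draws.
#'
#' @param params a [sim_params()] object.
#' @return A list with numeric vectors `maf`, `gamma`, `alpha`,
#'   `confounder_path`, each of length `n_variants`.
#' @export
draw_effects <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(derive_seed(params$seed, "effects"))
  J <- params$n_variants
  maf <- stats::runif(J, params$maf_range[1], params$maf_range[2])
  gamma <- params$strength *
    stats::runif(J, params$gamma_range[1], params$gamma_range[2])
  cc <- params$pleiotropy_scale
  alpha <- switch(params$scenario$alpha_distribution,
                  "degenerate-zero" = rep(0, J),
                  "uniform-symmetric" = stats::runif(J, -cc, cc),
                  "uniform-positive" = stats::runif(J, 0, cc))
  list(maf = maf, gamma = gamma, alpha = alpha,
       confounder_path = params$scenario$confounder_multiplier * alpha)
}

#' Simulate one cohort of individual-level data
#'
#' Generates genotypes, confounder, exposure and outcome for one sample
#' under the structural model of [sim_params()]. The `"exposure"` and
#' `"outcome"` samples use independent random streams derived from the
#' parent seed, giving the non-overlapping two-sample design.
#'
#' @param params a [sim_params()] object.
#' @param effects effect vectors from [draw_effects()].
#' @param which_sample `"exposure"` or `"outcome"` — selects the random
#'   stream.
#' @return A list of class `"mr_cohort"` with `genotypes` (N x J integer
#'   matrix of allele counts), `exposure`, `outcome`, `confounder`, `eps_x`,
#'   `eps_y`.
#' @export
simulate_cohort <- function(params, effects,
                            which_sample = c("exposure", "outcome")) {
  stopifnot(inherits(params, "sim_params"))
  which_sample <- match.arg(which_sample)
  set.seed(derive_seed(params$seed, paste0("cohort/", which_sample)))
  N <- params$n_per_sample; J <- params$n_variants
  G <- matrix(stats::rbinom(N * J, 2L, rep(effects$maf, each = N)), N, J)
  u_noise <- stats::rnorm(N)
  U <- as.vector(G %*% effects$confounder_path) + u_noise
  eps_x <- stats::rnorm(N)
  X <- as.vector(G %*% effects$gamma) + U + eps_x
  eps_y <- stats::rnorm(N)
  Y <- as.vector(G %*% effects$alpha) + params$beta * X + U + eps_y
  structure(list(genotypes = G, exposure = X, outcome = Y, confounder = U,
                 eps_x = eps_x, eps_y = eps_y),
            class = "mr_cohort")
}

# closed-form univariate least squares of y on each genotype column:
# returns slope and its standard error per column
univariate_assoc <- function(G, y) {
  N <- nrow(G)
  gbar <- colMeans(G)
  sxx <- colSums(G * G) - N * gbar^2
  if (any(sxx == 0))
    stop("monomorphic simulated variant (no genotype variation); ",
         "increase n_per_sample or the minor allele frequency range")
  yc <- y - mean(y)
  sxy <- as.vector(crossprod(G, yc))
  slope <- sxy / sxx
  rss <- sum(yc^2) - slope^2 * sxx
  se <- sqrt(pmax(rss, 0) / (N - 2) / sxx)
  list(beta = slope, se = se)
}

#' Summarize two simulated cohorts into per-variant association statistics
#'
#' Runs, for each variant, the simple univariate regression of the exposure
#' on genotype in the exposure cohort and of the outcome on genotype in the
#' outcome cohort, exactly as GWAS summary statistics are produced, and
#' packs the estimates and standard errors into an (unoriented) [mr_data]
#' object. The `eaf` column is set to the simulated allele frequencies.
#'
#' @param exposure_cohort,outcome_cohort [simulate_cohort()] outputs sharing
#'   the same number of variants.
#' @param eaf the allele frequencies used to generate the genotypes.
#' @return An [mr_data] object with variants `snp_1 ... snp_J`.
#' @export
summarize_cohorts <- function(exposure_cohort, outcome_cohort, eaf) {
  stopifnot(inherits(exposure_cohort, "mr_cohort"),
            inherits(outcome_cohort, "mr_cohort"))
  J <- ncol(exposure_cohort$genotypes)
  if (ncol(outcome_cohort$genotypes) != J)
    stop("the two cohorts must share the same variants")
  ax <- univariate_assoc(exposure_cohort$genotypes, exposure_cohort$exposure)
  ay <- univariate_assoc(outcome_cohort$genotypes, outcome_cohort$outcome)
  mr_data(paste0("snp_", seq_len(J)),
          beta_exposure = ax$beta, se_exposure = ax$se,
          beta_outcome = ay$beta, se_outcome = ay$se,
          eaf = eaf)
}

#' Simulate a complete two-sample summary dataset
#'
#' Convenience wrapper: [draw_effects()], two independent
#' [simulate_cohort()] calls, and [summarize_cohorts()]. The drawn effects
#' are attached as attribute `"effects"` for diagnostics such as
#' [theoretical_bias()].
#'
#' @param params a [sim_params()] object.
#' @return An unoriented [mr_data] object.
#' @export
simulate_mr_data <- function(params) {
  effects <- draw_effects(params)
  ex <- simulate_cohort(params, effects, "exposure")
  out <- simulate_cohort(params, effects, "outcome")
  d <- summarize_cohorts(ex, out, eaf = effects$maf)
  attr(d, "effects") <- effects
  attr(d, "params") <- params
  d
}

#' Expected mean F statistic under the generative model
#'
#' Analytic approximation used by [calibrate_strength()]. For variant `j`
#' with effect `gamma_j` and genotype variance `v_j = 2 p_j (1 - p_j)`, the
#' expected F statistic of the univariate exposure regression is
#' approximately `1 + N gamma_j^2 v_j / (var(X) - gamma_j^2 v_j)`. The
#' expectation over the gamma and MAF laws is computed by quadrature on a
#' midpoint grid, with `var(X)` approximated by its expectation
#' `J E[gamma^2 v] + var(U) + var(e_X)` for the base (non-confounded)
#' model.
#'
#' @param params a [sim_params()] object (its `strength`, laws, `n_variants`
#'   and `n_per_sample` are used).
#' @param grid_points number of quadrature points per dimension.
#' @return The approximate expected mean F statistic.
#' @export
expected_mean_f <- function(params, grid_points = 201L) {
  stopifnot(inherits(params, "sim_params"))
  mid <- function(r) {
    if (r[1] == r[2]) return(r[1])
    r[1] + (r[2] - r[1]) * (seq_len(grid_points) - 0.5) / grid_points
  }
  g0 <- mid(params$gamma_range) * params$strength
  p <- mid(params$maf_range)
  v <- 2 * p * (1 - p)
  x <- outer(g0^2, v)                      # gamma^2 * genotype variance
  S <- params$n_variants * mean(x) + 2     # E var(X): genetics + U + e_X
  1 + params$n_per_sample * mean(x / pmax(S - x, .Machine$double.eps))
}

#' Calibrate instrument strength to a target mean F statistic
#'
#' Finds the scalar multiplier for the instrument-effect law such that the
#' expected mean F statistic of the simulated exposure regressions equals
#' `target_mean_f` at the sample size and variant count in `params`.
#' Root-finding on the analytic approximation of [expected_mean_f()]; when
#' `pilot_reps > 0` the result is verified by a pilot simulation and a
#' warning is raised if the pilot mean F deviates from the target by more
#' than `pilot_tol` (a proportion, default 5%).
#'
#' @param target_mean_f desired mean F statistic, must exceed 1.
#' @param params a [sim_params()] object giving the laws, J and N.
#' @param pilot_reps number of pilot datasets for verification (0 to skip).
#' @param pilot_tol relative tolerance for the pilot check.
#' @return The strength multiplier (a single positive number).
#' @export
calibrate_strength <- function(target_mean_f, params, pilot_reps = 0L,
                               pilot_tol = 0.05) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.numeric(target_mean_f) || target_mean_f < 1)
    stop("target_mean_f must be >= 1 (F tends to 1 as instruments vanish)")
  if (target_mean_f == 1) return(0)
  f_at <- function(m) {
    p <- params; p$strength <- m
    expected_mean_f(p)
  }
  upper <- 1
  while (f_at(upper) < target_mean_f && upper < 1e4) upper <- upper * 2
  if (f_at(upper) < target_mean_f)
    stop("target mean F ", target_mean_f, " is unattainable at N = ",
         params$n_per_sample, ", J = ", params$n_variants,
         " (supremum ~", format(f_at(upper), digits = 4), ")")
  m <- stats::uniroot(function(m) f_at(m) - target_mean_f,
                      lower = 0, upper = upper, tol = 1e-8)$root
  if (pilot_reps > 0L) {
    fs <- vapply(seq_len(pilot_reps), function(r) {
      p <- params
      p$strength <- m
      p$seed <- derive_seed(params$seed, paste0("calibration-pilot/", r))
      mean_f_statistic(simulate_mr_data(p))
    }, numeric(1))
    if (abs(mean(fs) - target_mean_f) > pilot_tol * target_mean_f)
      warning("pilot mean F ", format(mean(fs), digits = 4),
              " deviates from target ", target_mean_f, " by more than ",
              100 * pilot_tol, "%")
  }
  m
}

#' Asymptotic IVW bias for known effect parameters
#'
#' The inverse-variance weighted estimator converges to
#' `beta + Bias(alpha, gamma)` with
#' `Bias = sum_j gamma_j w_j alpha_j / sum_j gamma_j^2 w_j`, where `w_j` are
#' the inverse-variance weights. This returns the bias term for known
#' per-variant effects — zero when all direct effects vanish, and exactly
#' `k` when `alpha_j = k gamma_j` (proportional pleiotropy shifts the slope
#' by `k`).
#'
#' @param gamma instrument effects on the exposure (not all zero).
#' @param alpha direct effects on the outcome.
#' @param weights inverse-variance weights (e.g. `1 / se_outcome^2`).
#' @return The bias term (a single number).
#' @export
theoretical_bias <- function(gamma, alpha, weights) {
  stopifnot(length(gamma) == length(alpha), length(gamma) == length(weights))
  if (all(gamma == 0)) stop("bias undefined when all gamma are zero")
  sum(gamma * weights * alpha) / sum(gamma^2 * weights)
}
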