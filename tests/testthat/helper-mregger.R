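# Shared fixtures and a memoized Monte Carlo cache.
# All datasets are generated in code; nothing is read from disk.

# a random but reproducible summary dataset
random_dataset <- function(J = 10L, seed = 1L, eaf = FALSE,
                           oriented = FALSE) {
  set.seed(seed)
  gamma <- runif(J, 0.1, 1)
  if (!oriented) gamma <- gamma * sample(c(-1, 1), J, replace = TRUE)
  d <- mr_data(paste0("v", seq_len(J)),
               beta_exposure = gamma,
               se_exposure = runif(J, 0.01, 0.1),
               beta_outcome = 0.3 * gamma + rnorm(J, sd = 0.05),
               se_outcome = runif(J, 0.05, 0.2),
               eaf = if (eaf) runif(J, 0.05, 0.95) else NULL)
  if (oriented) attr(d, "oriented") <- TRUE
  d
}

# exact affine dataset: beta_outcome = a + b * beta_exposure, zero noise
affine_dataset <- function(a = 0.1, b = 2, J = 6L) {
  gamma <- seq(0.1, 1, length.out = J)
  mr_data(paste0("v", seq_len(J)), gamma, rep(0.02, J),
          a + b * gamma, rep(0.1, J), oriented = TRUE)
}

# Monte Carlo study cells used by several test files; computed once per run.
# Study conditions: J = 25 variants, two-sample design, instruments
# calibrated so the expected mean F is 10.4 at N = 250 (mean F then scales
# with N), pleiotropy scale 0.1, 2000 replicates.
.mc_cache <- new.env(parent = emptyenv())

mc_master_seed <- 20150606L

mc_strength <- function() {
  if (is.null(.mc_cache$strength))
    .mc_cache$strength <- calibrate_strength(
      10.4, sim_params(n_variants = 25L, n_per_sample = 250L,
                       scenario = "a", seed = mc_master_seed))
  .mc_cache$strength
}

mc_cell <- function(scenario, beta = 0, n = 250L, n_reps = 2000L) {
  key <- sprintf("%s/%s/%d/%d", scenario, format(beta), n, n_reps)
  if (is.null(.mc_cache[[key]])) {
    p <- sim_params(n_variants = 25L, n_per_sample = n, beta = beta,
                    scenario = scenario, pleiotropy_scale = 0.1,
                    strength = mc_strength(),
                    seed = derive_seed(mc_master_seed, key))
    .mc_cache[[key]] <- run_cell(p, n_reps = n_reps)
  }
  .mc_cache[[key]]
}

# 3 Monte Carlo standard errors of an empirical proportion
mc_se3 <- function(rate, n_reps) 3 * sqrt(rate * (1 - rate) / n_reps)
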