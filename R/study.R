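#' Monte Carlo performance of IVW and MR-Egger for one parameter setting
#'
#' Simulates `n_reps` independent two-sample summary datasets under
#' `params`, fits the IVW and MR-Egger estimators to each (after canonical
#' orientation), and aggregates: the mean F statistic of the instruments,
#' mean and standard deviation of each slope estimate, mean standard errors,
#' and the proportion of replicates rejecting (i) the causal null
#' `slope = 0` for each method and (ii) the no-directional-pleiotropy null
#' `intercept = 0` (the MR-Egger test), all by two-sided t-tests at
#' `alpha_level` with the regression-output degrees of freedom.
#'
#' Replicates that fail to simulate (e.g. a monomorphic variant at a tiny
#' sample size) are rerun with a fresh derived sub-seed, up to `max_retries`
#' times each; the count of retried replicates is reported in the
#' `n_retried` column.
#'
#' @param params a [sim_params()] object; its `seed` is the cell seed from
#'   which every replicate's seed is derived.
#' @param n_reps number of Monte Carlo replicates (>= 1).
#' @param alpha_level two-sided significance level for all rejection
#'   decisions.
#' @param se_model standard-error convention passed to the estimators.
#' @param max_retries maximum reruns per replicate on simulation failure.
#' @return A one-row data frame (a performance-table row) with columns
#'   `scenario`, `beta`, `n_per_sample`, `n_variants`, `n_reps`, `mean_f`,
#'   `ivw_mean_estimate`, `ivw_sd_estimate`, `ivw_mean_se`,
#'   `ivw_reject_causal`, `egger_mean_estimate`, `egger_sd_estimate`,
#'   `egger_mean_se`, `egger_reject_causal`, `egger_reject_intercept`,
#'   `n_retried`.
#' @export
run_cell <- function(params, n_reps, alpha_level = 0.05,
                     se_model = c("regression-output", "fixed"),
                     max_retries = 5L) {
  stopifnot(inherits(params, "sim_params"))
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (!is.numeric(alpha_level) || alpha_level <= 0 || alpha_level > 1)
    stop("alpha_level must lie in (0, 1]")
  se_model <- match.arg(se_model)
  rec <- matrix(NA_real_, n_reps, 8L)
  colnames(rec) <- c("mean_f", "ivw_est", "ivw_se", "ivw_rej",
                     "egger_est", "egger_se", "egger_rej", "egger_int_rej")
  n_retried <- 0L
  for (r in seq_len(n_reps)) {
    d <- NULL
    for (attempt in 0:max_retries) {
      p <- params
      p$seed <- derive_seed(params$seed,
                            if (attempt == 0L) paste0("rep/", r)
                            else paste0("rep/", r, "/retry/", attempt))
      d <- tryCatch(simulate_mr_data(p), error = function(e) NULL)
      if (!is.null(d)) break
    }
    if (is.null(d))
      stop("replicate ", r, " failed after ", max_retries, " retries")
    if (attempt > 0L) n_retried <- n_retried + 1L
    d <- suppressWarnings(orient(d))
    fi <- ivw(d, se_model = se_model)
    fe <- mr_egger(d, se_model = se_model)
    rec[r, ] <- c(mean_f_statistic(d),
                  fi$slope, fi$slope_se,
                  two_sided_reject(fi$slope, fi$slope_se,
                                   fi$df, alpha_level, se_model),
                  fe$slope, fe$slope_se,
                  two_sided_reject(fe$slope, fe$slope_se,
                                   fe$df, alpha_level, se_model),
                  two_sided_reject(fe$intercept, fe$intercept_se,
                                   fe$df, alpha_level, se_model))
  }
  data.frame(scenario = params$scenario$label, beta = params$beta,
             n_per_sample = params$n_per_sample,
             n_variants = params$n_variants, n_reps = n_reps,
             mean_f = mean(rec[, "mean_f"]),
             ivw_mean_estimate = mean(rec[, "ivw_est"]),
             ivw_sd_estimate = stats::sd(rec[, "ivw_est"]),
             ivw_mean_se = mean(rec[, "ivw_se"]),
             ivw_reject_causal = mean(rec[, "ivw_rej"]),
             egger_mean_estimate = mean(rec[, "egger_est"]),
             egger_sd_estimate = stats::sd(rec[, "egger_est"]),
             egger_mean_se = mean(rec[, "egger_se"]),
             egger_reject_causal = mean(rec[, "egger_rej"]),
             egger_reject_intercept = mean(rec[, "egger_int_rej"]),
             n_retried = n_retried,
             stringsAsFactors = FALSE)
}

# two-sided test of estimate = 0 at the estimator's reference distribution;
# rejection uses p <= alpha so alpha = 1 always rejects
two_sided_reject <- function(estimate, se, df, alpha, se_model) {
  p <- if (se_model == "regression-output")
    2 * stats::pt(-abs(estimate / se), df = df)
  else 2 * stats::pnorm(-abs(estimate / se))
  as.numeric(p <= alpha)
}

#' Monte Carlo performance over a grid of scenarios and sample sizes
#'
#' Sweeps the Cartesian product of pleiotropy scenarios, true causal
#' effects, per-sample sizes and variant counts, running [run_cell()] for
#' each cell. A single instrument-strength multiplier is shared by all
#' cells, either given directly via `strength` or calibrated once with
#' [calibrate_strength()] so that the expected mean F equals
#' `target_mean_f` at the reference design (`calibrate_n`, `calibrate_j`);
#' mean F then scales with N and falls with J across the grid, as in the
#' classic two-sample simulation design. Each cell's seed is a stable hash
#' of the master seed and the cell coordinates, so results are independent
#' of grid order.
#'
#' @param scenarios character vector of scenario labels.
#' @param betas numeric vector of true causal effects.
#' @param sample_sizes integer vector of per-sample sizes N.
#' @param variant_counts integer vector of variant counts J.
#' @param n_reps Monte Carlo replicates per cell.
#' @param seed master seed.
#' @param alpha_level significance level for rejection decisions.
#' @param target_mean_f,calibrate_n,calibrate_j calibration target and
#'   reference design, used when `strength` is `NULL`.
#' @param strength optional fixed multiplier, bypassing calibration.
#' @param se_model standard-error convention.
#' @param pleiotropy_scale scale of the direct effects.
#' @param verbose print a progress line per cell.
#' @return A data frame with one [run_cell()] row per grid cell.
#' @export
run_grid <- function(scenarios = c("a", "b", "c", "d"), betas = 0,
                     sample_sizes = c(250L, 500L, 750L, 1000L),
                     variant_counts = 25L, n_reps = 1000L, seed = 1L,
                     alpha_level = 0.05, target_mean_f = 10.4,
                     calibrate_n = 250L, calibrate_j = 25L, strength = NULL,
                     se_model = "regression-output", pleiotropy_scale = 0.1,
                     verbose = FALSE) {
  if (!length(scenarios) || !length(betas) || !length(sample_sizes) ||
      !length(variant_counts)) stop("empty grid")
  if (is.null(strength)) {
    strength <- calibrate_strength(
      target_mean_f,
      sim_params(n_variants = calibrate_j, n_per_sample = calibrate_n,
                 scenario = "a", pleiotropy_scale = pleiotropy_scale,
                 seed = seed))
  }
  grid <- expand.grid(scenario = scenarios, beta = betas,
                      n_per_sample = sample_sizes, n_variants = variant_counts,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    key <- sprintf("cell/%s/%s/%d/%d", g$scenario,
                   format(g$beta, scientific = FALSE),
                   as.integer(g$n_per_sample), as.integer(g$n_variants))
    p <- sim_params(n_variants = g$n_variants, n_per_sample = g$n_per_sample,
                    beta = g$beta, scenario = g$scenario,
                    pleiotropy_scale = pleiotropy_scale,
                    strength = strength, seed = derive_seed(seed, key))
    if (verbose)
      message("cell ", i, "/", nrow(grid), ": ", key)
    run_cell(p, n_reps = n_reps, alpha_level = alpha_level,
             se_model = se_model)
  })
  out <- do.call(rbind, rows)
  attr(out, "strength") <- strength
  attr(out, "seed") <- seed
  out
}
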