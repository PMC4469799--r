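#' Full summary-data MR analysis of one dataset
#'
#' The standard analysis protocol in one call: canonically [orient()] the
#' data, compute per-variant Wald [ratio_estimates()], the [ivw()] and (when
#' J >= 3) [mr_egger()] fits, [cochran_q()] heterogeneity and the
#' [mean_f_statistic()]. With J = 2 the IVW fit is still reported and
#' MR-Egger is skipped with a notice.
#'
#' @param dataset an [mr_data] object (orientation is applied internally).
#' @param se_model,ci_level passed to the estimators.
#' @param seed optional integer recorded in the output for provenance (the
#'   analysis itself is deterministic).
#' @return A list of class `"mr_report"` with elements `ivw`, `egger`
#'   (`NULL` if skipped), `heterogeneity`, `mean_f`, `ratio`, `n_variants`,
#'   `n_flipped`, plus provenance fields `seed`, `config_hash`, `version`.
#' @export
mr_report <- function(dataset, se_model = c("regression-output", "fixed"),
                      ci_level = 0.95, seed = NULL) {
  stopifnot(inherits(dataset, "mr_data"))
  se_model <- match.arg(se_model)
  oriented <- suppressWarnings(orient(dataset))
  J <- nrow(oriented)
  egger_fit <- NULL
  if (J >= 3L) {
    egger_fit <- mr_egger(oriented, se_model = se_model, ci_level = ci_level)
  } else {
    message("MR-Egger skipped: needs at least 3 variants (J = ", J, ")")
  }
  out <- list(
    ivw = if (J >= 2L) ivw(oriented, se_model = se_model,
                           ci_level = ci_level) else NULL,
    egger = egger_fit,
    heterogeneity = if (J >= 2L) cochran_q(oriented) else NULL,
    mean_f = mean_f_statistic(oriented),
    ratio = ratio_estimates(oriented),
    n_variants = J,
    n_flipped = attr(oriented, "n_flipped"),
    seed = seed,
    config_hash = config_hash(list(se_model = se_model,
                                   ci_level = ci_level)),
    version = as.character(utils::packageVersion("mregger"))
  )
  class(out) <- "mr_report"
  out
}

#' @export
print.mr_report <- function(x, digits = 4, ...) {
  cat("Summary-data MR analysis of ", x$n_variants, " variant(s) (",
      x$n_flipped, " reoriented)\n", sep = "")
  cat("Mean instrument F statistic: ", format(x$mean_f, digits = digits),
      "\n\n", sep = "")
  if (!is.null(x$ivw)) print(x$ivw, digits = digits)
  if (!is.null(x$egger)) print(x$egger, digits = digits)
  if (!is.null(x$heterogeneity)) print(x$heterogeneity, digits = digits)
  invisible(x)
}

fit_record <- function(fit) {
  if (is.null(fit)) return(NULL)
  list(method = fit$method, slope = fit$slope, slope_se = fit$slope_se,
       slope_p = fit$slope_p, slope_ci_lower = fit$slope_ci_lower,
       slope_ci_upper = fit$slope_ci_upper, ci_level = fit$ci_level,
       intercept = fit$intercept, intercept_se = fit$intercept_se,
       intercept_p = fit$intercept_p, df = fit$df,
       n_variants = fit$n_variants, se_model = fit$se_model)
}

#' Write an analysis report to JSON and TSV
#'
#' Serializes an [mr_report()] both as a JSON record and as a flat
#' tab-delimited table with one row per method. Both artifacts embed the
#' seed, a hash of the estimator configuration, and the package version.
#'
#' @param report an `"mr_report"` object.
#' @param json_path,tsv_path output paths; either may be `NULL` to skip.
#' @return The report, invisibly.
#' @export
write_mr_report <- function(report, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(report, "mr_report"))
  rec <- list(
    version = report$version, seed = report$seed,
    config_hash = report$config_hash, n_variants = report$n_variants,
    n_flipped = report$n_flipped, mean_f = report$mean_f,
    cochran_q = if (!is.null(report$heterogeneity))
      unclass(report$heterogeneity),
    ivw = fit_record(report$ivw), egger = fit_record(report$egger)
  )
  if (!is.null(json_path))
    jsonlite::write_json(rec, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(tsv_path)) {
    rows <- lapply(Filter(Negate(is.null),
                          list(report$ivw, report$egger)), function(f)
      data.frame(method = f$method, slope = f$slope, slope_se = f$slope_se,
                 slope_p = f$slope_p, ci_lower = f$slope_ci_lower,
                 ci_upper = f$slope_ci_upper,
                 intercept = if (is.null(f$intercept)) NA else f$intercept,
                 intercept_se = if (is.null(f$intercept_se)) NA
                                else f$intercept_se,
                 intercept_p = if (is.null(f$intercept_p)) NA
                               else f$intercept_p,
                 df = f$df, n_variants = f$n_variants,
                 q_statistic = report$heterogeneity$q_statistic,
                 q_p_value = report$heterogeneity$p_value,
                 mean_f = report$mean_f,
                 seed = if (is.null(report$seed)) NA else report$seed,
                 config_hash = report$config_hash,
                 version = report$version,
                 stringsAsFactors = FALSE))
    utils::write.table(do.call(rbind, rows), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}

# stable FNV-1a hex hash of a deparsed configuration list
config_hash <- function(config) {
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' Read simulation parameters from a YAML configuration file
#'
#' Keys mirror the arguments of [sim_params()] (`n_variants`,
#' `n_per_sample`, `beta`, `scenario`, `pleiotropy_scale`, `maf_range`,
#' `gamma_range`, `strength`, `seed`); absent keys take the defaults.
#'
#' @param path path to a YAML file.
#' @return A [sim_params()] object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  known <- names(formals(sim_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(sim_params, cfg)
}

#' Generate reference fixture datasets
#'
#' Writes small synthetic summary datasets of documented structure for
#' examples and testing:
#' * `fixture_continuous_180.tsv` — 180 variants, homogeneous
#'   valid-instrument construction (generating slope 0.6), emulating a
#'   continuous-outcome analysis at GWAS scale;
#' * `fixture_pleiotropic_29.tsv` — 29 variants with directional pleiotropy
#'   injected (positive direct effects), emulating a binary-outcome analysis
#'   where the MR-Egger intercept should flag bias;
#' * `fixture_affine_exact.tsv` — 4 variants with outcome associations lying
#'   exactly on `0.1 + 0.5 * gamma` and no noise, for hand-checkable exact
#'   recovery;
#' * `fixture_params.json` — the generating parameters of every file.
#'
#' All fixtures are synthetic; none contains data from any real cohort.
#'
#' @param out_dir output directory, created if needed.
#' @param seed integer seed for the random fixtures.
#' @return Character vector of the files written, invisibly.
#' @export
generate_fixtures <- function(out_dir, seed = 20150606L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  gen <- list(seed = seed,
              version = as.character(utils::packageVersion("mregger")))

  # (i) 180-variant homogeneous continuous-outcome fixture, slope 0.6
  set.seed(derive_seed(seed, "fixture/continuous"))
  J <- 180L; slope <- 0.6
  eaf <- stats::runif(J, 0.1, 0.5)
  gamma <- stats::runif(J, 0.02, 0.08)
  se_x <- stats::runif(J, 0.003, 0.006)
  se_y <- stats::runif(J, 0.02, 0.05)
  d1 <- mr_data(sprintf("rs%05d", seq_len(J)),
                beta_exposure = gamma + stats::rnorm(J, sd = se_x),
                se_exposure = se_x,
                beta_outcome = slope * gamma + stats::rnorm(J, sd = se_y),
                se_outcome = se_y, eaf = eaf)
  f1 <- file.path(out_dir, "fixture_continuous_180.tsv")
  write_mr_data(d1, f1); files <- c(files, f1)
  gen$fixture_continuous_180 <- list(n_variants = J, true_slope = slope,
                                     intercept = 0, model = "valid instruments")

  # (ii) 29-variant fixture with directional pleiotropy injected
  set.seed(derive_seed(seed, "fixture/pleiotropic"))
  J <- 29L; slope <- 0.05; pleio <- 0.015
  eaf <- stats::runif(J, 0.1, 0.5)
  gamma <- stats::runif(J, 0.3, 1.2)
  se_x <- stats::runif(J, 0.02, 0.05)
  se_y <- stats::runif(J, 0.008, 0.02)
  alpha <- stats::runif(J, 0, 2 * pleio)     # positive direct effects
  d2 <- mr_data(sprintf("bp%02d", seq_len(J)),
                beta_exposure = gamma + stats::rnorm(J, sd = se_x),
                se_exposure = se_x,
                beta_outcome = alpha + slope * gamma +
                  stats::rnorm(J, sd = se_y),
                se_outcome = se_y, eaf = eaf)
  f2 <- file.path(out_dir, "fixture_pleiotropic_29.tsv")
  write_mr_data(d2, f2); files <- c(files, f2)
  gen$fixture_pleiotropic_29 <- list(n_variants = J, true_slope = slope,
                                     mean_direct_effect = pleio,
                                     model = "directional pleiotropy")

  # (iii) tiny exact affine fixture: outcome = 0.1 + 0.5 * exposure
  gamma <- c(0.2, 0.4, 0.6, 0.8)
  d3 <- mr_data(paste0("toy", 1:4),
                beta_exposure = gamma, se_exposure = rep(0.05, 4),
                beta_outcome = 0.1 + 0.5 * gamma, se_outcome = rep(0.1, 4),
                eaf = rep(0.3, 4))
  f3 <- file.path(out_dir, "fixture_affine_exact.tsv")
  write_mr_data(d3, f3); files <- c(files, f3)
  gen$fixture_affine_exact <- list(n_variants = 4L, intercept = 0.1,
                                   slope = 0.5, model = "exact affine")

  fp <- file.path(out_dir, "fixture_params.json")
  jsonlite::write_json(gen, fp, auto_unbox = TRUE, digits = NA)
  files <- c(files, fp)
  invisible(files)
}
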