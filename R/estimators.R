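#' Fit a summary-data Mendelian randomization model
#'
#' The workhorse behind [ivw()] and [mr_egger()]. Both estimators are weighted
#' linear regressions of the gene--outcome associations (Gamma-hat) on the
#' gene--exposure associations (gamma-hat), weighted by the inverse variance
#' of the gene--outcome associations (`1 / se_outcome^2`):
#'
#' * **IVW** constrains the intercept to zero; its slope equals the
#'   inverse-variance weighted average of the per-variant Wald ratio
#'   estimates and assumes all variants are valid instruments.
#' * **MR-Egger** leaves the intercept free; the intercept estimates the
#'   average directional pleiotropic effect across variants (the MR-Egger
#'   test is the test of intercept = 0), and the slope remains a consistent
#'   causal-effect estimate under the InSIDE assumption.
#'
#' The weighted least-squares solution is computed in closed form from the
#' normal equations; it is numerically identical to
#' `lm(beta_outcome ~ beta_exposure, weights = 1/se_outcome^2)`.
#'
#' @param dataset an [mr_data] object. MR-Egger additionally requires the
#'   dataset to be canonically [orient()]ed, because the intercept is not
#'   invariant to allele recoding.
#' @param method `"ivw"` or `"egger"`.
#' @param se_model how standard errors are formed:
#'   * `"regression-output"` (default): SE and p-values taken directly from
#'     the weighted-regression output, i.e. the residual standard error is
#'     estimated and inference uses a t reference distribution with J-1 (IVW)
#'     or J-2 (Egger) residual degrees of freedom;
#'   * `"fixed"`: known-variance fixed-effect meta-analysis convention — the
#'     residual variance is fixed at 1 and inference uses the normal
#'     distribution. Point estimates are identical under both.
#' @param ci_level confidence level for the slope interval (default 0.95).
#' @param constrain_intercept for `method = "egger"` only: force the
#'   intercept to zero, which reproduces the IVW fit exactly (the IVW
#'   estimator is the intercept-constrained special case).
#'
#' @return An object of class `"mr_fit"`: a list with elements `method`,
#'   `slope`, `slope_se`, `slope_p`, `slope_ci_lower`, `slope_ci_upper`,
#'   `ci_level`, `intercept`, `intercept_se`, `intercept_p` (`NULL` for IVW),
#'   `df`, `n_variants`, `se_model`, `weights`, `fitted`, `residuals`,
#'   `sigma` (square root of the estimated residual variance of the weighted
#'   regression) and the `data` used.
#' @seealso [ivw()], [mr_egger()], [cochran_q()], [ratio_estimates()]
#' @export
mr_fit <- function(dataset, method = c("ivw", "egger"),
                   se_model = c("regression-output", "fixed"),
                   ci_level = 0.95, constrain_intercept = FALSE) {
  stopifnot(inherits(dataset, "mr_data"))
  method <- match.arg(method)
  se_model <- match.arg(se_model)
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1)
    stop("ci_level must lie strictly in (0, 1)")
  J <- nrow(dataset)
  if (any(dataset$se_outcome <= 0)) stop("se_outcome must be positive")
  with_intercept <- method == "egger" && !constrain_intercept
  if (method == "egger") {
    if (!is_oriented(dataset))
      stop("mr_egger requires a canonically oriented dataset; call orient() ",
           "first (Egger results are not invariant to allele coding)")
    if (!constrain_intercept && J < 3L)
      stop("MR-Egger needs at least 3 variants (J - 2 residual df)")
  }
  if (!with_intercept && se_model == "regression-output" && J < 2L)
    stop("IVW with se_model = 'regression-output' needs at least 2 variants ",
         "(no residual degrees of freedom otherwise)")

  x <- dataset$beta_exposure
  y <- dataset$beta_outcome
  w <- 1 / dataset$se_outcome^2

  if (with_intercept) {
    sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
    sxx <- sum(w * x^2); sxy <- sum(w * x * y)
    det <- sw * sxx - sx^2
    if (det <= 0) stop("degenerate design: no spread in beta_exposure")
    slope <- (sw * sxy - sx * sy) / det
    intercept <- (sy - slope * sx) / sw
    fitted <- intercept + slope * x
    df <- J - 2L
    var_slope_unit <- sw / det       # variance factors at unit residual var
    var_intercept_unit <- sxx / det
  } else {
    sxx <- sum(w * x^2)
    if (sxx <= 0) stop("all beta_exposure are zero; IVW slope undefined")
    slope <- sum(w * x * y) / sxx
    intercept <- NULL
    fitted <- slope * x
    df <- J - 1L
    var_slope_unit <- 1 / sxx
    var_intercept_unit <- NULL
  }
  resid <- y - fitted
  rss_w <- sum(w * resid^2)
  if (se_model == "regression-output") {
    sigma2 <- rss_w / df
    qfun <- function(p) stats::qt(p, df = df)
    pfun <- function(t) 2 * stats::pt(-abs(t), df = df)
  } else {
    sigma2 <- 1
    qfun <- stats::qnorm
    pfun <- function(t) 2 * stats::pnorm(-abs(t))
  }
  slope_se <- sqrt(sigma2 * var_slope_unit)
  slope_p <- pfun(slope / slope_se)
  crit <- qfun(1 - (1 - ci_level) / 2)
  out <- list(
    method = if (with_intercept) "MR-Egger" else "IVW",
    slope = slope, slope_se = slope_se, slope_p = slope_p,
    slope_ci_lower = slope - crit * slope_se,
    slope_ci_upper = slope + crit * slope_se,
    ci_level = ci_level,
    intercept = NULL, intercept_se = NULL, intercept_p = NULL,
    df = df, n_variants = J, se_model = se_model,
    weights = w, fitted = fitted, residuals = resid,
    sigma = sqrt(rss_w / df), data = dataset
  )
  if (with_intercept) {
    out$intercept <- intercept
    out$intercept_se <- sqrt(sigma2 * var_intercept_unit)
    out$intercept_p <- pfun(intercept / out$intercept_se)
  }
  class(out) <- "mr_fit"
  out
}

#' Inverse-variance weighted (IVW) estimator
#'
#' Weighted regression of the gene--outcome on the gene--exposure
#' associations through the origin, with weights `1 / se_outcome^2`. The
#' slope equals the inverse-variance weighted average of the per-variant
#' Wald ratio estimates and is the standard summary-data Mendelian
#' randomization estimate, consistent when all variants are valid
#' instruments. Invariant to allele orientation.
#'
#' @inheritParams mr_fit
#' @return An `"mr_fit"` object; see [mr_fit()].
#' @examples
#' d <- mr_data(paste0("v", 1:3), c(0.1, 0.2, 0.3), rep(0.01, 3),
#'              c(0.05, 0.10, 0.15), rep(0.02, 3))
#' ivw(d)$slope   # exactly 0.5
#' @export
ivw <- function(dataset, se_model = c("regression-output", "fixed"),
                ci_level = 0.95) {
  mr_fit(dataset, method = "ivw", se_model = se_model, ci_level = ci_level)
}

#' MR-Egger regression
#'
#' The same weighted regression as [ivw()] but with the intercept left
#' unconstrained. The intercept estimates the average pleiotropic (direct)
#' effect of the variants on the outcome — a nonzero intercept (the MR-Egger
#' test, `intercept_p`) indicates directional pleiotropy, the analogue of
#' small-study bias in a meta-analysis funnel plot. Under the InSIDE
#' assumption (instrument strength independent of direct effect) the slope is
#' a consistent estimate of the causal effect even when every variant is an
#' invalid instrument.
#'
#' @inheritParams mr_fit
#' @return An `"mr_fit"` object; see [mr_fit()].
#' @export
mr_egger <- function(dataset, se_model = c("regression-output", "fixed"),
                     ci_level = 0.95, constrain_intercept = FALSE) {
  mr_fit(dataset, method = "egger", se_model = se_model, ci_level = ci_level,
         constrain_intercept = constrain_intercept)
}

#' Per-variant Wald ratio estimates
#'
#' The causal effect estimated from each variant alone: the ratio of its
#' outcome association to its exposure association, with the first-order
#' (delta-method) standard error `se_outcome / |beta_exposure|` that ignores
#' uncertainty in the exposure association. The accompanying weight
#' `beta_exposure^2 / se_outcome^2` is the inverse of that variance — the
#' fixed-effect meta-analysis weight under which the weighted mean of the
#' ratio estimates equals the IVW slope.
#'
#' @param dataset an [mr_data] object with all `beta_exposure != 0`.
#' @return A data frame with columns `variant_id`, `estimate`, `se`,
#'   `weight`.
#' @export
ratio_estimates <- function(dataset) {
  stopifnot(inherits(dataset, "mr_data"))
  zero <- dataset$beta_exposure == 0
  if (any(zero))
    stop("ratio estimate undefined (zero beta_exposure) for variant(s): ",
         paste(dataset$variant_id[zero], collapse = ", "))
  data.frame(variant_id = dataset$variant_id,
             estimate = dataset$beta_outcome / dataset$beta_exposure,
             se = dataset$se_outcome / abs(dataset$beta_exposure),
             weight = dataset$beta_exposure^2 / dataset$se_outcome^2,
             stringsAsFactors = FALSE)
}

#' Cochran's Q heterogeneity test
#'
#' Tests whether the per-variant Wald ratio estimates are mutually
#' compatible: `Q = sum_j w_j (b_j - b_IVW)^2` with first-order weights
#' `w_j = beta_exposure^2 / se_outcome^2`, referred to a chi-square
#' distribution with J-1 degrees of freedom. Substantial heterogeneity
#' indicates that different variants identify different effects, casting
#' doubt on the instrumental-variable assumptions (the summary-data analogue
#' of an over-identification test).
#'
#' @param dataset an [mr_data] object with J >= 2 and all
#'   `beta_exposure != 0`.
#' @return An object of class `"mr_heterogeneity"`: list with `q_statistic`,
#'   `df`, `p_value`.
#' @export
cochran_q <- function(dataset) {
  stopifnot(inherits(dataset, "mr_data"))
  if (nrow(dataset) < 2L) stop("Cochran's Q needs at least 2 variants")
  r <- ratio_estimates(dataset)
  pooled <- sum(r$weight * r$estimate) / sum(r$weight)  # = IVW slope
  q <- sum(r$weight * (r$estimate - pooled)^2)
  df <- nrow(dataset) - 1L
  structure(list(q_statistic = q, df = df,
                 p_value = stats::pchisq(q, df = df, lower.tail = FALSE)),
            class = "mr_heterogeneity")
}

#' @export
print.mr_heterogeneity <- function(x, digits = 4, ...) {
  cat("Cochran's Q test for heterogeneity of Wald ratio estimates\n")
  cat("  Q = ", format(x$q_statistic, digits = digits),
      " on ", x$df, " df, p = ", format.pval(x$p_value, digits = digits),
      "\n", sep = "")
  invisible(x)
}

#' MAF-corrected instrument strength
#'
#' Rescales each gene--exposure association by the standard deviation of its
#' genotype under Hardy--Weinberg equilibrium,
#' `gamma_C = gamma * sqrt(2 p (1 - p))` with `p` the effect-allele
#' frequency. When the outcome associations are estimated on common samples,
#' these corrected associations are proportional to `1 / se_outcome`, so
#' ranking or plotting variants by `gamma_C` is equivalent (up to a constant)
#' to the inverse-variance weighting used in the regressions; the corrected
#' value is the conventional funnel-plot instrument-strength axis.
#'
#' @param dataset an [mr_data] object with `eaf` available for every variant.
#' @return Numeric vector of corrected exposure associations, one per
#'   variant.
#' @export
maf_corrected_strength <- function(dataset) {
  stopifnot(inherits(dataset, "mr_data"))
  if (is.null(dataset$eaf) || anyNA(dataset$eaf)) {
    missing_ids <- if (is.null(dataset$eaf)) dataset$variant_id
                   else dataset$variant_id[is.na(dataset$eaf)]
    stop("effect-allele frequency missing for variant(s): ",
         paste(missing_ids, collapse = ", "))
  }
  dataset$beta_exposure * sqrt(2 * dataset$eaf * (1 - dataset$eaf))
}

#' Mean F statistic of the instruments
#'
#' Average of the per-variant squared t-ratios
#' `(beta_exposure / se_exposure)^2`, the usual indicator of aggregate
#' instrument strength (values near 1 indicate instruments no stronger than
#' noise; weak instruments bias two-sample estimates toward the null).
#'
#' @param dataset an [mr_data] object with positive `se_exposure`.
#' @return A single number.
#' @export
mean_f_statistic <- function(dataset) {
  stopifnot(inherits(dataset, "mr_data"))
  if (is.null(dataset$se_exposure) || anyNA(dataset$se_exposure) ||
      any(dataset$se_exposure <= 0))
    stop("se_exposure must be present and positive for every variant")
  mean((dataset$beta_exposure / dataset$se_exposure)^2)
}
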