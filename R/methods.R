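#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(x$method, " estimate (", x$n_variants, " variants, se model: ",
      x$se_model, ")\n", sep = "")
  cat("  slope: ", format(x$slope, digits = digits),
      " (SE ", format(x$slope_se, digits = digits),
      ", p = ", format.pval(x$slope_p, digits = digits), ")\n", sep = "")
  cat("  ", round(100 * x$ci_level), "% CI: [",
      format(x$slope_ci_lower, digits = digits), ", ",
      format(x$slope_ci_upper, digits = digits), "]\n", sep = "")
  if (!is.null(x$intercept))
    cat("  intercept: ", format(x$intercept, digits = digits),
        " (SE ", format(x$intercept_se, digits = digits),
        ", MR-Egger test p = ", format.pval(x$intercept_p, digits = digits),
        ")\n", sep = "")
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  if (is.null(object$intercept)) c(slope = object$slope)
  else c(intercept = object$intercept, slope = object$slope)
}

#' @export
confint.mr_fit <- function(object, parm = "slope", level = NULL, ...) {
  if (is.null(level)) level <- object$ci_level
  crit <- if (object$se_model == "regression-output")
    stats::qt(1 - (1 - level) / 2, df = object$df)
  else stats::qnorm(1 - (1 - level) / 2)
  parm <- match.arg(parm, c("slope", "intercept"), several.ok = TRUE)
  out <- t(vapply(parm, function(p) {
    est <- object[[p]]; se <- object[[paste0(p, "_se")]]
    if (is.null(est)) stop("no '", p, "' term in an ", object$method, " fit")
    c(est - crit * se, est + crit * se)
  }, numeric(2)))
  colnames(out) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                                trim = TRUE), "%")
  out
}

#' @export
summary.mr_fit <- function(object, ...) {
  terms <- if (is.null(object$intercept)) "slope"
           else c("intercept", "slope")
  tab <- do.call(rbind, lapply(terms, function(p)
    c(Estimate = object[[p]], `Std. Error` = object[[paste0(p, "_se")]],
      `t value` = object[[p]] / object[[paste0(p, "_se")]],
      `Pr(>|t|)` = object[[paste0(p, "_p")]])))
  rownames(tab) <- terms
  structure(list(fit = object, coefficients = tab),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  cat(f$method, " regression of outcome on exposure associations\n",
      "weights: inverse variance of outcome associations; se model: ",
      f$se_model, "\n\n", sep = "")
  stats::printCoefmat(x$coefficients, digits = digits,
                      P.values = TRUE, has.Pvalue = TRUE)
  cat("\nResidual df: ", f$df, " from ", f$n_variants, " variants",
      if (f$se_model == "regression-output")
        paste0("; residual sd (weighted): ", format(f$sigma, digits = digits)),
      "\n", sep = "")
  invisible(x)
}

#' @export
fitted.mr_fit <- function(object, ...) object$fitted

#' @export
residuals.mr_fit <- function(object, ...) object$residuals

#' Predicted gene--outcome association at given instrument strengths
#'
#' @param object an `"mr_fit"` object.
#' @param newdata optional data frame with a `beta_exposure` column (or a
#'   numeric vector of exposure associations); defaults to the fitted data.
#' @param ... unused.
#' @return Numeric vector of predicted outcome associations
#'   (`intercept + slope * beta_exposure`; intercept 0 for IVW).
#' @export
predict.mr_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$beta_exposure
  else if (is.numeric(newdata)) newdata
  else newdata$beta_exposure
  a <- if (is.null(object$intercept)) 0 else object$intercept
  a + object$slope * x
}

#' Parametric simulation of outcome associations from a fitted model
#'
#' Draws new gene--outcome association vectors from the fitted regression
#' line, with independent normal errors whose standard deviations are the
#' observed `se_outcome` values. Useful for quick parametric-bootstrap
#' checks of downstream summaries.
#'
#' @param object an `"mr_fit"` object.
#' @param nsim number of simulated replicates.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A data frame with `nsim` columns, each a simulated
#'   `beta_outcome` vector.
#' @export
simulate.mr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  J <- object$n_variants
  out <- as.data.frame(vapply(seq_len(nsim), function(i)
    object$fitted + stats::rnorm(J, sd = object$data$se_outcome),
    numeric(J)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.mr_fit <- function(x, ...) {
  show_ivw <- x$method == "IVW"
  mr_scatter(x$data,
             ivw_fit = if (show_ivw) x else NULL,
             egger_fit = if (!show_ivw) x else NULL,
             show_ivw = show_ivw, show_egger = !show_ivw, ...)
}
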