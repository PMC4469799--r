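#' Scatter plot of outcome against exposure associations
#'
#' Plots the per-variant gene--outcome associations (Gamma-hat) against the
#' gene--exposure associations (gamma-hat), with the IVW estimate drawn as a
#' red line through the origin, the MR-Egger fit as a blue line with free
#' intercept, and optionally the true slope as a dotted line. The lines use
#' the exact numeric estimates from [ivw()] and [mr_egger()] — the plot
#' never recomputes statistics.
#'
#' @param dataset an [mr_data] object; must be oriented if the Egger line is
#'   requested.
#' @param ivw_fit,egger_fit optional precomputed `"mr_fit"` objects; fitted
#'   on the fly when `NULL` and requested.
#' @param show_ivw,show_egger draw the respective fitted lines.
#' @param true_slope optional known causal effect, drawn dotted through the
#'   origin.
#' @param se_model passed to the estimators when fitting on the fly.
#' @param file optional output path; the device is chosen by extension
#'   (`.png` or `.pdf`). When `NULL`, draws on the current device.
#' @param col_ivw,col_egger,col_true line colours.
#' @param ... further arguments to [graphics::plot()].
#' @return Invisibly, a list with the plotted `points` (data frame of
#'   `beta_exposure`, `beta_outcome`), and `ivw`, `egger`, `true` line
#'   coefficients (`c(intercept, slope)` or `NULL`), so tests and callers
#'   can read back exactly what was drawn.
#' @export
mr_scatter <- function(dataset, ivw_fit = NULL, egger_fit = NULL,
                       show_ivw = TRUE, show_egger = TRUE, true_slope = NULL,
                       se_model = "regression-output", file = NULL,
                       col_ivw = "red", col_egger = "blue",
                       col_true = "black", ...) {
  stopifnot(inherits(dataset, "mr_data"))
  if (nrow(dataset) < 1L) stop("empty dataset")
  if (show_egger && !is_oriented(dataset))
    stop("the Egger line requires an oriented dataset; call orient() first")
  if (show_ivw && is.null(ivw_fit))
    ivw_fit <- ivw(dataset, se_model = se_model)
  if (show_egger && is.null(egger_fit))
    egger_fit <- mr_egger(dataset, se_model = se_model)
  close_dev <- open_plot_device(file)
  on.exit(close_dev())
  graphics::plot(dataset$beta_exposure, dataset$beta_outcome,
                 xlab = "Genetic association with exposure",
                 ylab = "Genetic association with outcome",
                 pch = 19, ...)
  if (!is.null(true_slope))
    graphics::abline(a = 0, b = true_slope, lty = 3, col = col_true)
  if (show_ivw)
    graphics::abline(a = 0, b = ivw_fit$slope, col = col_ivw)
  if (show_egger)
    graphics::abline(a = egger_fit$intercept, b = egger_fit$slope,
                     col = col_egger)
  invisible(list(
    points = data.frame(beta_exposure = dataset$beta_exposure,
                        beta_outcome = dataset$beta_outcome),
    ivw = if (show_ivw) c(intercept = 0, slope = ivw_fit$slope),
    egger = if (show_egger) c(intercept = egger_fit$intercept,
                              slope = egger_fit$slope),
    true = if (!is.null(true_slope)) c(intercept = 0, slope = true_slope)
  ))
}

#' Funnel plot of instrument strength against per-variant causal estimates
#'
#' The meta-analysis funnel adapted to Mendelian randomization: each
#' variant's Wald ratio estimate on the horizontal axis against its
#' instrument strength on the vertical axis — the MAF-corrected association
#' `gamma * sqrt(2p(1-p))` when `maf_correct = TRUE` (requires `eaf`), or
#' the raw exposure association otherwise. Weak instruments sit low, and
#' asymmetry of the low points about the pooled estimate indicates
#' directional pleiotropy, exactly as small-study bias shows in a
#' meta-analysis funnel. Vertical reference lines mark the IVW (red) and,
#' when the dataset is oriented and large enough, the MR-Egger (blue) slope
#' estimates.
#'
#' @param dataset an [mr_data] object with all `beta_exposure != 0`.
#' @param maf_correct use MAF-corrected instrument strength on the vertical
#'   axis.
#' @param show_ivw,show_egger draw the reference lines.
#' @param se_model,file,col_ivw,col_egger as in [mr_scatter()].
#' @param ... further arguments to [graphics::plot()].
#' @return Invisibly, a list with `points` (data frame `estimate`,
#'   `strength`), and the `ivw`/`egger` reference-line abscissae (`NULL`
#'   when not drawn).
#' @export
mr_funnel <- function(dataset, maf_correct = FALSE, show_ivw = TRUE,
                      show_egger = TRUE, se_model = "regression-output",
                      file = NULL, col_ivw = "red", col_egger = "blue", ...) {
  stopifnot(inherits(dataset, "mr_data"))
  r <- ratio_estimates(dataset)   # errors on zero beta_exposure
  strength <- if (maf_correct) maf_corrected_strength(dataset)
              else dataset$beta_exposure
  J <- nrow(dataset)
  ivw_at <- NULL
  if (show_ivw) {
    # point estimates agree across se models; "fixed" admits J = 1
    ivw_at <- ivw(dataset, se_model = "fixed")$slope
  }
  egger_at <- NULL
  if (show_egger && J >= 3L && is_oriented(dataset))
    egger_at <- mr_egger(dataset, se_model = se_model)$slope
  close_dev <- open_plot_device(file)
  on.exit(close_dev())
  graphics::plot(r$estimate, strength,
                 xlab = "Per-variant causal estimate (Wald ratio)",
                 ylab = if (maf_correct)
                   "MAF-corrected association with exposure"
                 else "Genetic association with exposure",
                 pch = 19, ...)
  if (!is.null(ivw_at)) graphics::abline(v = ivw_at, col = col_ivw)
  if (!is.null(egger_at)) graphics::abline(v = egger_at, col = col_egger)
  invisible(list(points = data.frame(estimate = r$estimate,
                                     strength = strength),
                 ivw = ivw_at, egger = egger_at))
}

# open a device chosen by file extension; returns a closer function
open_plot_device <- function(file) {
  if (is.null(file)) return(function() invisible())
  if (grepl("\\.png$", file, ignore.case = TRUE))
    grDevices::png(file, width = 7, height = 7, units = "in", res = 150)
  else if (grepl("\\.pdf$", file, ignore.case = TRUE))
    grDevices::pdf(file, width = 7, height = 7)
  else stop("unsupported plot file type (use .png or .pdf): ", file)
  function() grDevices::dev.off()
}
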