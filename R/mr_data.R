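#' Construct a summary-data Mendelian randomization dataset
#'
#' Bundles per-variant GWAS-style summary statistics — the association of each
#' genetic variant with the exposure (gamma-hat, with its standard error) and
#' with the outcome (Gamma-hat, with its standard error) — into the container
#' that all estimators in this package consume. The two sets of associations
#' are typically estimated in non-overlapping samples (two-sample design).
#'
#' @param variant_id character vector of unique variant labels (e.g. rsIDs).
#' @param beta_exposure per-allele association of each variant with the
#'   exposure.
#' @param se_exposure standard error of `beta_exposure`; strictly positive.
#' @param beta_outcome per-allele association of each variant with the
#'   outcome.
#' @param se_outcome standard error of `beta_outcome`; strictly positive.
#'   These define the inverse-variance weights used by [ivw()] and
#'   [mr_egger()].
#' @param eaf optional effect-allele frequency, strictly in (0, 1); `NA`
#'   allowed per variant. Needed only for MAF-corrected instrument strength
#'   ([maf_corrected_strength()]) and MAF-corrected funnel plots.
#' @param oriented logical; declare the dataset already canonically oriented
#'   (all `beta_exposure >= 0`). Normally left `FALSE` and set by [orient()].
#'
#' @return A data frame of class `"mr_data"` with one row per variant and an
#'   `"oriented"` attribute.
#' @seealso [orient()], [ivw()], [mr_egger()], [read_mr_data()]
#' @examples
#' d <- mr_data(paste0("rs", 1:3),
#'              beta_exposure = c(0.1, -0.2, 0.3), se_exposure = rep(0.02, 3),
#'              beta_outcome  = c(0.05, -0.11, 0.16), se_outcome = rep(0.04, 3))
#' orient(d)
#' @export
mr_data <- function(variant_id, beta_exposure, se_exposure,
                    beta_outcome, se_outcome, eaf = NULL,
                    oriented = FALSE) {
  variant_id <- as.character(variant_id)
  J <- length(variant_id)
  if (J < 1L) stop("an mr_data object needs at least one variant")
  if (anyDuplicated(variant_id))
    stop("duplicate variant_id: ",
         paste(unique(variant_id[duplicated(variant_id)]), collapse = ", "))
  num <- list(beta_exposure = beta_exposure, se_exposure = se_exposure,
              beta_outcome = beta_outcome, se_outcome = se_outcome)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != J)
      stop("'", nm, "' must be numeric of length ", J)
    if (anyNA(v) || any(!is.finite(v)))
      stop("'", nm, "' contains missing or non-finite values")
  }
  if (any(se_exposure <= 0)) stop("se_exposure must be strictly positive")
  if (any(se_outcome <= 0)) stop("se_outcome must be strictly positive")
  d <- data.frame(variant_id = variant_id,
                  beta_exposure = as.numeric(beta_exposure),
                  se_exposure = as.numeric(se_exposure),
                  beta_outcome = as.numeric(beta_outcome),
                  se_outcome = as.numeric(se_outcome),
                  stringsAsFactors = FALSE)
  if (!is.null(eaf)) {
    if (!is.numeric(eaf) || length(eaf) != J)
      stop("'eaf' must be numeric of length ", J)
    bad <- !is.na(eaf) & (eaf <= 0 | eaf >= 1)
    if (any(bad))
      stop("eaf must lie strictly in (0, 1); offending variants: ",
           paste(variant_id[bad], collapse = ", "))
    d$eaf <- as.numeric(eaf)
  }
  oriented <- isTRUE(oriented)
  if (oriented && any(d$beta_exposure < 0))
    stop("cannot mark as oriented: some beta_exposure are negative")
  structure(d, class = c("mr_data", "data.frame"), oriented = oriented)
}

#' Test or query orientation state
#' @param x an object.
#' @return `is_oriented()` returns the `"oriented"` attribute (FALSE if
#'   absent).
#' @rdname orient
#' @export
is_oriented <- function(x) isTRUE(attr(x, "oriented"))

#' Canonically orient a summary dataset
#'
#' Recodes every variant so that its association with the exposure is
#' non-negative: rows with `beta_exposure < 0` have both `beta_exposure` and
#' `beta_outcome` sign-flipped (this is a relabelling of the effect allele;
#' standard errors are unchanged). MR-Egger regression requires this
#' canonical orientation because its intercept is not invariant to allele
#' recoding; the IVW estimate, Cochran's Q and the mean F statistic are.
#'
#' A variant with `beta_exposure` exactly zero carries no orientation
#' information; it is left as-is with a warning.
#'
#' @param dataset an [mr_data] object.
#' @return The dataset with flips applied, row order preserved, and the
#'   `"oriented"` attribute set. Idempotent.
#' @export
orient <- function(dataset) {
  stopifnot(inherits(dataset, "mr_data"))
  if (is_oriented(dataset)) return(dataset)
  if (any(dataset$beta_exposure == 0))
    warning("variant(s) with beta_exposure == 0 left unflipped: ",
            paste(dataset$variant_id[dataset$beta_exposure == 0],
                  collapse = ", "))
  flip <- dataset$beta_exposure < 0
  dataset$beta_exposure[flip] <- -dataset$beta_exposure[flip]
  dataset$beta_outcome[flip] <- -dataset$beta_outcome[flip]
  attr(dataset, "oriented") <- TRUE
  attr(dataset, "n_flipped") <- sum(flip)
  dataset
}

#' @export
`[.mr_data` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("variant_id", "beta_exposure", "se_exposure",
                                  "beta_outcome", "se_outcome") %in% names(out))) {
    class(out) <- c("mr_data", "data.frame")
    attr(out, "oriented") <- attr(x, "oriented")
  }
  out
}

#' @export
print.mr_data <- function(x, ...) {
  cat("Summary-data MR dataset: ", nrow(x), " variant(s), ",
      if (is_oriented(x)) "oriented" else "unoriented",
      if (is.null(x$eaf)) ", no eaf\n" else ", with eaf\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE, ...)
  if (nrow(x) > 10L) cat("... ", nrow(x) - 10L, " more variant(s)\n", sep = "")
  invisible(x)
}

required_columns <- c("variant_id", "beta_exposure", "se_exposure",
                      "beta_outcome", "se_outcome")

#' Read and write summary datasets as delimited text
#'
#' `read_mr_data()` reads a TSV or CSV file (dialect auto-detected from the
#' extension: `.csv` comma, anything else tab) with header columns
#' `variant_id, beta_exposure, se_exposure, beta_outcome, se_outcome` and an
#' optional `eaf` column, in any column order. Malformed rows are reported
#' with their line numbers. `write_mr_data()` writes the canonical
#' tab-delimited form (UTF-8, Unix newlines, C locale decimal point).
#'
#' @param path file path.
#' @return `read_mr_data()` returns an [mr_data] object (unoriented);
#'   `write_mr_data()` returns `path` invisibly.
#' @export
read_mr_data <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE,
                           check.names = TRUE)
  missing_cols <- setdiff(required_columns, names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  # data line numbers: header is line 1
  line_no <- seq_len(nrow(raw)) + 1L
  to_num <- function(col, allow_na = FALSE) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(v) & !(allow_na & (is.na(raw[[col]]) | raw[[col]] == ""
                                    | toupper(raw[[col]]) == "NA"))
    if (any(bad))
      stop("non-numeric '", col, "' on line(s): ",
           paste(line_no[bad], collapse = ", "))
    v
  }
  be <- to_num("beta_exposure"); se_x <- to_num("se_exposure")
  bo <- to_num("beta_outcome");  se_y <- to_num("se_outcome")
  bad_se <- se_x <= 0 | se_y <= 0
  if (any(bad_se))
    stop("non-positive standard error on line(s): ",
         paste(line_no[bad_se], collapse = ", "))
  if (anyDuplicated(raw$variant_id))
    stop("duplicate variant_id in file: ",
         paste(unique(raw$variant_id[duplicated(raw$variant_id)]),
               collapse = ", "))
  eaf <- if ("eaf" %in% names(raw)) to_num("eaf", allow_na = TRUE) else NULL
  mr_data(raw$variant_id, be, se_x, bo, se_y, eaf = eaf)
}

#' @param dataset an [mr_data] object.
#' @rdname read_mr_data
#' @export
write_mr_data <- function(dataset, path) {
  stopifnot(inherits(dataset, "mr_data"))
  utils::write.table(as.data.frame(dataset), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8",
                     eol = "\n")
  invisible(path)
}
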