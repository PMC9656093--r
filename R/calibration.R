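# Calibration-line fitting and the R-squared filter.

#' Fit a per-glycan calibration line
#'
#' Ordinary least squares of expression level (pmol) on serum volume (uL),
#' over the individual replicate points (not per-volume means). R-squared is
#' \code{1 - SS_res / SS_tot}; in the degenerate case SS_tot = 0 (constant
#' response) it is reported as 1 when the residuals are also 0 (a perfect
#' constant) and 0 otherwise.
#'
#' @param volume serum volumes in uL (>= 2 distinct values).
#' @param pmol expression levels in pmol.
#' @return A \code{calibration_fit}: list with slope \code{a} (pmol/uL),
#'   intercept \code{b} (pmol), \code{r_squared}, \code{se_slope}, \code{n}
#'   and the \code{points} used.
#' @examples
#' fit_calibration(c(2, 4, 6, 8, 10), c(2, 4, 6, 8, 10))  # a=1, b=0, R2=1
#' @export
fit_calibration <- function(volume, pmol) {
  ok <- !is.na(volume) & !is.na(pmol)
  volume <- volume[ok]; pmol <- pmol[ok]
  if (length(unique(volume)) < 2L)
    stop("calibration requires at least 2 distinct volumes")
  fit <- stats::lm(pmol ~ volume)
  a <- unname(stats::coef(fit)[2L])
  b <- unname(stats::coef(fit)[1L])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((pmol - mean(pmol))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else
    if (isTRUE(all.equal(ss_res, 0))) 1 else 0
  se <- tryCatch(suppressWarnings(
    summary(fit)$coefficients["volume", "Std. Error"]),
    error = function(e) NA_real_)
  structure(list(a = a, b = b, r_squared = max(0, min(1, r2)),
                 se_slope = unname(se), n = length(pmol),
                 points = data.frame(volume = volume, pmol = pmol)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("calibration fit: y = %.4f x %+.4f  (R2 = %.4f, n = %d)\n",
              x$a, x$b, x$r_squared, x$n))
  invisible(x)
}

#' Filter calibration fits by R-squared
#'
#' Keeps fits whose R-squared is at or above the threshold (inclusive;
#' default 0.8), selecting glycans with a concentration-linear response.
#'
#' @param fits data.frame of fits with an \code{r_squared} column (as built
#'   by [run_calibration()]), or a list of \code{calibration_fit} objects.
#' @param threshold R-squared cutoff in [0, 1].
#' @return The subset passing the filter, order preserved.
#' @export
rcut_filter <- function(fits, threshold = 0.8) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (is.data.frame(fits)) {
    out <- fits[!is.na(fits$r_squared) & fits$r_squared >= threshold, ,
                drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    fits[vapply(fits, function(f)
      !is.na(f$r_squared) && f$r_squared >= threshold, logical(1))]
  }
}
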