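#' Bundled SEC molecular-weight standards
#'
#' The five purified calibration proteins spanning the working range of a
#' Superdex 200 column: Ferritin (440 kDa), aldolase (158 kDa), conalbumin
#' (75 kDa), ovalbumin (43 kDa) and ribonuclease A (13.7 kDa). The elution
#' positions shipped here are nominal example positions on the 24-fraction
#' axis; replace them with the positions measured on your own column run.
#'
#' @return Data frame with columns \code{name}, \code{mw} (kDa) and
#'   \code{elution_position} (collected fraction index, 1 elutes first).
#' @export
calibration_standards <- function() {
  data.frame(
    name = c("Ferritin", "Aldolase", "Conalbumin", "Ovalbumin",
             "Ribonuclease A"),
    mw = c(440, 158, 75, 43, 13.7),
    elution_position = c(2, 8, 12, 16, 22)
  )
}

#' Fit a log-linear SEC molecular-weight calibration
#'
#' Ordinary least squares of log10(MW) on elution position, the standard SEC
#' calibration form: larger species elute earlier, so the slope must be
#' negative.
#'
#' @param standards data frame with columns \code{mw} (kDa, > 0) and
#'   \code{elution_position}; at least two standards with distinct positions,
#'   and MW strictly decreasing with position.
#' @return An object of class \code{mw_calibration}: list with \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{valid_range} (kDa) and the
#'   input \code{standards}.
#' @examples
#' cal <- fit_calibration(calibration_standards())
#' predict_mw(cal, 12)
#' @export
fit_calibration <- function(standards) {
  req <- c("mw", "elution_position")
  if (!is.data.frame(standards) || !all(req %in% names(standards))) {
    secmap_stop("secmap_calibration_error",
                "standards must have columns 'mw' and 'elution_position'")
  }
  standards <- standards[order(standards$elution_position), , drop = FALSE]
  if (nrow(standards) < 2L ||
      length(unique(standards$elution_position)) < 2L) {
    secmap_stop("secmap_calibration_error",
                "need at least 2 standards with distinct elution positions")
  }
  if (any(standards$mw <= 0)) {
    secmap_stop("secmap_calibration_error", "standard MWs must be > 0")
  }
  if (is.unsorted(rev(standards$mw), strictly = TRUE)) {
    secmap_stop("secmap_calibration_error",
                "MW must decrease strictly with elution position")
  }
  fit <- stats::lm(log10(mw) ~ elution_position, data = standards)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0) {
    secmap_stop("secmap_calibration_error",
                "calibration slope must be negative (SEC monotonicity)")
  }
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are fine here
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = r2,
         valid_range = range(standards$mw),
         standards = standards),
    class = "mw_calibration"
  )
}

#' Predict MW from elution position on a fitted calibration
#' @param calibration an [fit_calibration()] object.
#' @param position elution position(s) on the collected-fraction axis.
#' @return Numeric MW in kDa.
#' @export
predict_mw <- function(calibration, position) {
  stopifnot(inherits(calibration, "mw_calibration"))
  10^(calibration$intercept + calibration$slope * position)
}

#' Predict elution position from MW on a fitted calibration
#'
#' MWs outside the calibration's valid range are extrapolated with a warning
#' and the returned position clamped to the terminal fractions [1, 24].
#' @param calibration an [fit_calibration()] object.
#' @param mw molecular weight(s) in kDa, > 0.
#' @return Numeric elution position(s).
#' @export
predict_position <- function(calibration, mw) {
  stopifnot(inherits(calibration, "mw_calibration"))
  if (any(mw <= 0)) {
    secmap_stop("secmap_calibration_error", "mw must be > 0")
  }
  oor <- mw < calibration$valid_range[1L] | mw > calibration$valid_range[2L]
  if (any(oor)) {
    warning(sprintf(
      "%d MW value(s) outside the calibrated range [%g, %g] kDa; clamped",
      sum(oor), calibration$valid_range[1L], calibration$valid_range[2L]),
      call. = FALSE)
  }
  pos <- (log10(mw) - calibration$intercept) / calibration$slope
  pmin(pmax(pos, 1), 24)
}

#' @export
print.mw_calibration <- function(x, ...) {
  cat(sprintf(
    "SEC MW calibration: log10(MW) = %.4f %+.4f * position (R^2 = %.4f)\n",
    x$intercept, x$slope, x$r_squared))
  cat(sprintf("valid range: %g-%g kDa, %d standards\n",
              x$valid_range[1L], x$valid_range[2L], nrow(x$standards)))
  invisible(x)
}
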