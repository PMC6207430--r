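#' Doubling time from a growth curve
#'
#' Estimates the exponential-phase doubling time. Exactly exponential
#' curves (log-linear residuals at machine precision) return the global
#' log2-linear slope's reciprocal. Otherwise a self-starting logistic model
#' is fitted to the full curve and the doubling time is `ln(2) * scal`;
#' this averages over the whole sigmoid, so additive plate-reader noise on
#' low-OD readings does not inflate the estimate the way a short
#' sliding-window maximum does. If the logistic fit fails to converge, a
#' sliding-window log-linear maximum-slope fit (`window` points above
#' `od_floor`) is used as fallback. All routes are invariant to rescaling
#' the OD readings by a constant.
#'
#' @param g data.frame with `time` (minutes, strictly increasing) and
#'   `od600`.
#' @param window number of points per fallback fit window (default 5).
#' @param od_floor OD600 below which readings are ignored (default 0.02).
#' @return doubling time in minutes.
#' @export
doubling_time <- function(g, window = 5L, od_floor = 0.02) {
  stopifnot(all(c("time", "od600") %in% names(g)), nrow(g) >= 4L,
            all(diff(g$time) > 0))
  gg <- g[g$od600 > od_floor, , drop = FALSE]
  if (nrow(gg) < window)
    stop("fewer than ", window, " readings above the OD floor")
  if (max(gg$od600) < 2 * gg$od600[1L])
    stop("curve shows no positive growth ",
         "(less than one doubling above the OD floor)")
  y <- log2(gg$od600)
  glob <- stats::lm(y ~ gg$time)
  if (max(abs(stats::resid(glob))) < 1e-9) {
    sl <- stats::coef(glob)[[2L]]
    if (sl <= 0) stop("no positive growth in the log-linear fit")
    return(1 / sl)
  }
  SSlogis <- stats::SSlogis
  fit <- tryCatch(stats::nls(od600 ~ SSlogis(time, Asym, xmid, scal),
                             data = g),
                  error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    if (cf[["scal"]] > 0 && cf[["Asym"]] > 0)
      return(log(2) * cf[["scal"]])
  }
  slopes <- vapply(seq_len(nrow(gg) - window + 1L), function(i) {
    idx <- i:(i + window - 1L)
    stats::coef(stats::lm(y[idx] ~ gg$time[idx]))[[2L]]
  }, numeric(1L))
  smax <- max(slopes)
  if (!is.finite(smax) || smax <= 0)
    stop("no window shows positive growth")
  1 / smax
}

#' Maximum OD600 of a growth curve
#'
#' @param g data.frame with `od600`.
#' @param smooth odd rolling-mean width, 0/1 for none (default).
#' @return maximum (optionally smoothed) OD600.
#' @export
max_od <- function(g, smooth = 0L) {
  stopifnot("od600" %in% names(g), nrow(g) >= 1L)
  od <- g$od600
  if (smooth > 1L) {
    od <- stats::filter(od, rep(1 / smooth, smooth), sides = 2L)
    od <- od[!is.na(od)]
  }
  max(od)
}

#' Percent change relative to a reference
#'
#' @param reference positive reference value.
#' @param value new value.
#' @return `100 * (value - reference) / reference`.
#' @export
pct_change <- function(reference, value) {
  if (reference <= 0) stop("reference must be positive")
  100 * (value - reference) / reference
}

#' Segmented western-blot calibration curve
#'
#' Antibody response is sublinear at low load, so the calibration is
#' segmented: one linear fit over the 1-10 ng standards, another over the
#' 10-100 ng standards, and below the 1 ng standard a line through the
#' 1 ng point and a blank of intensity zero.
#'
#' @param standards data.frame with `amount` (ng; must include the 1-10 and
#'   10-100 ranges) and `intensity` (nonnegative arbitrary units).
#' @return list of class `calibration_curve`.
#' @export
calibration_curve <- function(standards) {
  stopifnot(all(c("amount", "intensity") %in% names(standards)),
            all(standards$intensity >= 0))
  standards <- standards[order(standards$amount), , drop = FALSE]
  low <- standards[standards$amount >= 1 & standards$amount <= 10, ]
  high <- standards[standards$amount >= 10, ]
  if (nrow(low) < 2L || nrow(high) < 2L)
    stop("need at least two standards in each of the 1-10 and 10-100 ng ranges")
  fit_low <- stats::lm(intensity ~ amount, data = low)
  fit_high <- stats::lm(intensity ~ amount, data = high)
  i1 <- standards$intensity[standards$amount == min(low$amount)][1L]
  structure(list(standards = standards,
                 fit_low = fit_low, fit_high = fit_high,
                 low_range = range(low$intensity),
                 amount_at_low_min = min(low$amount),
                 intensity_at_low_min = i1),
            class = "calibration_curve")
}

invert_fit <- function(fit, intensity) {
  cf <- stats::coef(fit)
  if (cf[[2L]] == 0) stop("calibration segment has zero slope")
  (intensity - cf[[1L]]) / cf[[2L]]
}

#' Quantify a blot band against the segmented calibration
#'
#' The segment is chosen by the observed intensity: below the lowest
#' standard's intensity, the blank-anchored line; within the low-range
#' intensities, the 1-10 ng fit; above, the 10-100 ng fit (extrapolated
#' beyond the top standard, as done for the study's brightest sample).
#'
#' @param cal a `calibration_curve`.
#' @param intensity nonnegative band intensity.
#' @return estimated amount in ng.
#' @export
quantify_blot <- function(cal, intensity) {
  if (intensity < 0) stop("intensity must be nonnegative")
  if (intensity < cal$intensity_at_low_min)
    return(intensity / cal$intensity_at_low_min * cal$amount_at_low_min)
  if (intensity <= cal$low_range[2L])
    return(invert_fit(cal$fit_low, intensity))
  invert_fit(cal$fit_high, intensity)
}

#' Conjugation percent transfer from patch plating
#'
#' @param n_grown patched colonies that grew under double selection.
#' @param n_picked colonies picked (default 86, as in the assay).
#' @return percent transfer.
#' @export
conjugation_pct <- function(n_grown, n_picked = 86L) {
  if (n_grown < 0L || n_grown > n_picked)
    stop("n_grown must lie in [0, n_picked]")
  100 * n_grown / n_picked
}

#' PFU/mL from plaque counts
#'
#' @param plaques plaque count on the plate.
#' @param dilution fold dilution of the plated phage stock.
#' @param volume_ml plated volume in mL.
#' @return titer in PFU/mL.
#' @export
pfu_per_ml <- function(plaques, dilution = 1, volume_ml = 1) {
  if (plaques < 0 || dilution <= 0 || volume_ml <= 0)
    stop("invalid plaque count, dilution or volume")
  plaques * dilution / volume_ml
}

#' Relative phage titer
#'
#' @param pfu_test titer on the test strain (PFU/mL).
#' @param pfu_ref titer on the reference strain (PFU/mL, > 0).
#' @return ratio test/reference.
#' @export
relative_titer <- function(pfu_test, pfu_ref) {
  if (pfu_ref <= 0) stop("reference titer must be positive")
  pfu_test / pfu_ref
}
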