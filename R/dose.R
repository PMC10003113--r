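# Exposure-dose arithmetic, molar conversions for the crocin/crocetin
# system, conversion-balance checking, and absorption-spectrum summary.

#' Molar masses of the apocarotenoid pair (g/mol)
#' @export
MOLAR_MASS <- c(crocin = 976.97, crocetin = 328.41)

#' Cumulative blue-light dose
#'
#' @param per_exposure dose of one exposure, J/cm^2 (>= 0).
#' @param n number of exposure iterations (non-negative integer).
#' @return cumulative dose in J/cm^2.
#' @export
cumulative_dose <- function(per_exposure, n) {
  check_scalar(per_exposure, "per_exposure", lo = 0)
  check_scalar(n, "n", lo = 0)
  if (n != round(n)) stop("'n' must be an integer count", call. = FALSE)
  per_exposure * n
}

#' Molar content of a compound from its mass fraction
#'
#' molar content (mmol/kg) = mass fraction x 1e6 / molar mass (g/mol).
#'
#' @param mass_fraction w/w fraction in [0, 1].
#' @param molar_mass g/mol (> 0).
#' @return molar content in mmol/kg.
#' @export
molar_content <- function(mass_fraction, molar_mass) {
  check_scalar(mass_fraction, "mass_fraction", 0, 1)
  if (molar_mass <= 0) stop("molar mass must be positive", call. = FALSE)
  mass_fraction * 1e6 / molar_mass
}

#' Check molar balance of a conversion time course
#'
#' For a 1:1 hydrolysis, crocin(t) + crocetin(t) should equal crocin(0).
#' Reports the per-time balance ratio, the completion time (first time
#' crocin falls below \code{completion_tol} of its initial value), and
#' whether the product has plateaued.
#'
#' @param series data.frame with time_h, crocin_mM, crocetin_mM (molar
#'   units on a common time grid).
#' @param completion_tol completion threshold as a fraction of initial
#'   crocin (default 0.01: "fully converted").
#' @param plateau_tol maximum relative drift of the fitted crocetin trend
#'   over the last fifth of the series still counted as a plateau (a fitted
#'   slope is used so measurement noise does not mask a plateau).
#' @param c0 initial crocin concentration; by default estimated as the mean
#'   substrate level over the pre-conversion window.
#' @return list: balance (vector), mean_balance, completion_time_h
#'   (\code{NA} if not reached), plateaued (logical).
#' @export
conversion_balance <- function(series, completion_tol = 0.01,
                               plateau_tol = 0.05, c0 = NULL) {
  if (is.null(c0)) {
    # average the substrate over the pre-conversion window (product still
    # below 0.2% of its maximum) to damp measurement noise in the baseline
    ord <- order(series$time_h)
    pre <- series$crocetin_mM[ord] < 0.002 * max(series$crocetin_mM, 0)
    c0 <- if (any(pre)) mean(series$crocin_mM[ord][pre])
          else series$crocin_mM[ord][1]
  }
  if (is.na(c0) || c0 <= 0)
    stop("initial crocin concentration must be positive", call. = FALSE)
  balance <- (series$crocin_mM + series$crocetin_mM) / c0
  done <- series$time_h[series$crocin_mM < completion_tol * c0]
  tail_n <- max(3L, ceiling(nrow(series) / 5))
  ord <- order(series$time_h)
  tail_t <- utils::tail(series$time_h[ord], tail_n)
  tail_v <- utils::tail(series$crocetin_mM[ord], tail_n)
  drift <- unname(stats::coef(stats::lm(tail_v ~ tail_t))[2]) *
    diff(range(tail_t))
  plateaued <- abs(drift) <= plateau_tol * max(mean(tail_v), 1e-12)
  list(balance = balance, mean_balance = mean(balance),
       completion_time_h = if (length(done)) min(done) else NA_real_,
       plateaued = plateaued)
}

#' Summarize an absorption spectrum
#'
#' Reports the wavelength of maximal absorbance and the fraction of the
#' integrated absorbance lying in the blue band (400-490 nm), integrating
#' by the trapezoidal rule with interpolated band edges.
#'
#' @param wavelength_nm monotone wavelength grid covering 400-490 nm.
#' @param absorbance absorbance values (same length).
#' @param band blue-light band, nm.
#' @return list: lambda_max_nm, blue_fraction, total_integral.
#' @export
spectrum_summary <- function(wavelength_nm, absorbance,
                             band = c(400, 490)) {
  if (is.unsorted(wavelength_nm))
    stop("wavelength grid must be increasing", call. = FALSE)
  if (min(wavelength_nm) > band[1] || max(wavelength_nm) < band[2])
    stop("spectrum does not cover the blue band", call. = FALSE)
  if (all(absorbance == 0)) stop("no absorbance", call. = FALSE)
  lambda_max <- wavelength_nm[which.max(absorbance)]
  total <- pracma::trapz(wavelength_nm, absorbance)
  # clip the grid to the band, interpolating the edge values
  inside <- wavelength_nm >= band[1] & wavelength_nm <= band[2]
  wl <- c(band[1], wavelength_nm[inside], band[2])
  ab <- c(stats::approx(wavelength_nm, absorbance, xout = band[1])$y,
          absorbance[inside],
          stats::approx(wavelength_nm, absorbance, xout = band[2])$y)
  keep <- !duplicated(wl)
  blue <- pracma::trapz(wl[keep], ab[keep])
  list(lambda_max_nm = lambda_max, blue_fraction = blue / total,
       total_integral = total)
}
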