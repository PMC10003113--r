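# Synthetic crocin-consumption / crocetin-appearance curves: skin microbiota
# hydrolyze the glycosylated crocin to crocetin with 1:1 stoichiometry, so
# crocetin formed equals crocin consumed at every time point. The curve is a
# lag-clamped logistic: flat until the lag ends (culture adaptation), then a
# sigmoidal conversion approaching completion.

#' Generate a synthetic conversion time course
#'
#' The noise-free truth satisfies exact molar balance:
#' crocin(t) + crocetin(t) = crocin(0) at every t.
#'
#' @param c0 initial crocin concentration, mmol/L. The default 1.79 mmol/L
#'   corresponds to a culture carrying 10\% of a 50 g/L extract solution
#'   titrated at 35\% w/w crocin (molar mass 976.97 g/mol).
#' @param seed mandatory integer seed.
#' @param lag lag time before conversion starts, hours (default 66).
#' @param rate logistic rate constant, 1/h (default 0.064: conversion is
#'   essentially complete ~210 h).
#' @param t_mid logistic midpoint, hours.
#' @param times observation times, hours.
#' @param cv multiplicative measurement noise (coefficient of variation;
#'   0 disables).
#' @return data.frame: time_h, crocin_mM, crocetin_mM (noisy measurements)
#'   plus crocin_true_mM, crocetin_true_mM.
#' @export
gen_conversion_curve <- function(c0 = 1.79, seed = 1L, lag = 66,
                                 rate = 0.064, t_mid = 138,
                                 times = seq(0, 260, by = 6), cv = 0.05) {
  if (c0 < 0) stop("initial concentration must be >= 0", call. = FALSE)
  if (lag < 0) stop("lag must be >= 0", call. = FALSE)
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  s <- function(t) 1 / (1 + exp(-rate * (t - t_mid)))
  s0 <- s(lag)
  frac <- base::pmax(0, (s(times) - s0) / (1 - s0))
  crocetin <- c0 * frac
  crocin <- c0 - crocetin
  with_seed(seed, {
    noisy_crocin <- crocin
    noisy_crocetin <- crocetin
    if (cv > 0) {
      noisy_crocin <- base::pmax(crocin *
        (1 + stats::rnorm(length(times), 0, cv)), 0)
      noisy_crocetin <- base::pmax(crocetin *
        (1 + stats::rnorm(length(times), 0, cv)), 0)
    }
    data.frame(time_h = times, crocin_mM = noisy_crocin,
               crocetin_mM = noisy_crocetin, crocin_true_mM = crocin,
               crocetin_true_mM = crocetin)
  })
}
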