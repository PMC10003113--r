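# Synthetic melatonin release series from the cyclized co-culture design:
# an 8 h day phase followed by a 16 h night phase, sampled 30 min before
# night onset and 2, 5 and 8 h after it, over days D0..D2. Night induction
# is a raised-cosine bump scaled by (1 - s), where s in [0, 1] is the
# blue-light suppression; s = 0 reproduces the unstressed profile and s = 1
# removes the night induction entirely.

#' Sampling schedule of the cyclized co-culture
#'
#' @param n_days number of cycled days (default 3: D0, D1, D2).
#' @param day_length day-phase length in hours (default 8).
#' @param night_length night-phase length in hours (default 16).
#' @param offsets sampling offsets relative to night onset, hours.
#' @return list describing the schedule.
#' @export
melatonin_schedule <- function(n_days = 3L, day_length = 8,
                               night_length = 16,
                               offsets = c(-0.5, 2, 5, 8)) {
  list(n_days = n_days, day_length = day_length,
       night_length = night_length, offsets = offsets,
       cycle = day_length + night_length)
}

# raised-cosine night bump, normalized so that the mean over the night
# sampling offsets equals 1 (the induction statistic then recovers the
# amplitude exactly at zero noise)
night_bump <- function(offset, schedule) {
  u <- offset / schedule$night_length
  raw <- ifelse(offset >= 0 & offset <= schedule$night_length,
                0.5 * (1 - cos(2 * pi * u)), 0)
  night_off <- schedule$offsets[schedule$offsets >= 0]
  norm <- mean(0.5 * (1 - cos(2 * pi * night_off / schedule$night_length)))
  raw / norm
}

#' Generate synthetic melatonin release series
#'
#' @param suppression s in [0, 1]: 0 = full night induction, 1 = none.
#' @param seed mandatory integer seed.
#' @param n_replicates biological replicates.
#' @param baseline day-phase release level (assay units).
#' @param amplitude night induction amplitude (assay units); the mean rise
#'   of the night samples over baseline at s = 0.
#' @param noise Gaussian noise sd per sample (assay units; >= 0).
#' @param schedule from \code{\link{melatonin_schedule}}.
#' @param condition label stored with the series.
#' @return data.frame: condition, replicate, day, offset_h, time_h, phase,
#'   value (>= 0).
#' @export
gen_melatonin_series <- function(suppression, seed, n_replicates = 6L,
                                 baseline = 10, amplitude = 20, noise = 2,
                                 schedule = melatonin_schedule(),
                                 condition = "untreated") {
  check_scalar(suppression, "suppression", 0, 1)
  if (amplitude < 0) stop("negative amplitude", call. = FALSE)
  if (noise < 0) stop("noise must be >= 0", call. = FALSE)
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        day = seq_len(schedule$n_days) - 1L,
                        offset_h = schedule$offsets)
    grid$time_h <- grid$day * schedule$cycle + schedule$day_length +
      grid$offset_h
    grid$phase <- ifelse(grid$offset_h < 0, "day", "night")
    mu <- baseline + amplitude * (1 - suppression) *
      night_bump(grid$offset_h, schedule)
    grid$value <- base::pmax(mu + stats::rnorm(nrow(grid), 0, noise), 0)
    grid$condition <- condition
    grid[order(grid$replicate, grid$time_h),
         c("condition", "replicate", "day", "offset_h", "time_h", "phase",
           "value")]
  })
}
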