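# Phase alignment and night-induction analysis of melatonin series from the
# cyclized co-culture, plus condition comparisons through the statistical
# ladder (Kruskal-Wallis omnibus with pairwise Mann-Whitney against the
# blue-light control, or the parametric route when normality passes).

#' Label raw timestamps with day index and night-onset offset
#'
#' @param series data.frame with a \code{time_h} column (hours since the
#'   start of cycling) and any other columns.
#' @param schedule from \code{\link{melatonin_schedule}}.
#' @param tol matching tolerance in hours.
#' @return the input with \code{day}, \code{offset_h} and \code{phase}
#'   columns (re)computed; rows keep their input order.
#' @export
phase_align <- function(series, schedule = melatonin_schedule(), tol = 0.25) {
  if (nrow(series) == 0) {
    series$day <- integer(0); series$offset_h <- numeric(0)
    series$phase <- character(0)
    return(series)
  }
  if (is.null(series$time_h)) stop("series lacks a time_h column",
                                   call. = FALSE)
  sched_times <- expand.grid(day = seq_len(schedule$n_days) - 1L,
                             offset_h = schedule$offsets)
  sched_times$t <- sched_times$day * schedule$cycle + schedule$day_length +
    sched_times$offset_h
  idx <- vapply(series$time_h, function(t) {
    d <- abs(sched_times$t - t)
    k <- which.min(d)
    if (d[k] > tol) NA_integer_ else k
  }, integer(1))
  if (anyNA(idx)) {
    bad <- unique(series$time_h[is.na(idx)])
    stop("timestamps outside the sampling schedule: ",
         paste(signif(bad, 6), collapse = ", "), call. = FALSE)
  }
  series$day <- sched_times$day[idx]
  series$offset_h <- sched_times$offset_h[idx]
  series$phase <- ifelse(series$offset_h < 0, "day", "night")
  series
}

#' Night-phase induction per replicate
#'
#' Induction = mean of the night samples minus the pre-night baseline
#' sample, within each replicate. With the generator's normalized night
#' bump, its expectation is amplitude x (1 - suppression).
#'
#' @param series labeled series (needs replicate, day, offset_h, value).
#' @param day_index analysis day (default 1, the window where induction is
#'   established).
#' @return data.frame: replicate, baseline, night_mean, induction.
#' @export
night_induction <- function(series, day_index = 1L) {
  d <- series[series$day == day_index, ]
  if (nrow(d) == 0) stop("no samples on the requested day", call. = FALSE)
  out <- do.call(rbind, lapply(split(d, d$replicate), function(g) {
    base <- g$value[g$offset_h < 0]
    night <- g$value[g$offset_h >= 0]
    if (length(base) == 0) stop("missing pre-night baseline sample",
                                call. = FALSE)
    data.frame(replicate = g$replicate[1], baseline = mean(base),
               night_mean = mean(night),
               induction = mean(night) - mean(base))
  }))
  rownames(out) <- NULL
  out
}

#' Estimate the suppression parameter from a series
#'
#' @param series labeled series for one condition.
#' @param amplitude generator amplitude (assay units).
#' @param day_index analysis day.
#' @return estimated s (can fall slightly outside [0, 1] under noise).
#' @export
estimate_suppression <- function(series, amplitude, day_index = 1L) {
  ind <- night_induction(series, day_index)
  1 - mean(ind$induction) / amplitude
}

#' Compare melatonin conditions on one day
#'
#' Computes per-replicate night inductions and routes the groups through the
#' statistical ladder (see \code{\link{compare_groups}}) against the
#' reference condition.
#'
#' @param series labeled series with a \code{condition} column (>= 2
#'   conditions, >= 3 replicates each).
#' @param reference reference condition label (the blue-light control).
#' @param day_index analysis day.
#' @param gate \code{"auto"} (Shapiro-Wilk), \code{"parametric"} or
#'   \code{"nonparametric"}.
#' @return data.frame of comparison results (one row per non-reference
#'   condition).
#' @export
compare_conditions <- function(series, reference, day_index = 1L,
                               gate = "nonparametric") {
  conds <- unique(series$condition)
  if (length(conds) < 2) stop("need at least two conditions", call. = FALSE)
  if (!reference %in% conds)
    stop("reference condition not present", call. = FALSE)
  ind <- lapply(split(series, series$condition), night_induction,
                day_index = day_index)
  values <- unlist(lapply(ind, `[[`, "induction"))
  groups <- rep(names(ind), vapply(ind, nrow, integer(1)))
  if (min(table(groups)) < 3)
    stop("need >= 3 replicates per condition", call. = FALSE)
  compare_groups(values, groups, reference = reference, design = "unpaired",
                 gate = gate)
}
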