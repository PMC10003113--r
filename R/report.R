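# Rendering of per-experiment report tables in the layout of the network
# and cell-spreading summary tables: one row per metric, one column per
# condition, cells carrying the condition mean and, for non-reference
# conditions, the percent-change annotation with its significance flag.

#' Render a metrics-by-condition report table
#'
#' @param metric_means data.frame with columns \code{metric},
#'   \code{condition}, \code{value} (condition mean per metric).
#' @param comparisons data.frame as returned by
#'   \code{\link{compare_groups}}, with an additional \code{metric} column;
#'   may be empty for a values-only table.
#' @param reference reference condition label; must appear in
#'   \code{metric_means}.
#' @return data.frame: one row per metric, one character column per
#'   condition, cells \code{"<value>"} or \code{"<value> (<+/-X% flag> vs
#'   <reference>)"}.
#' @export
render_report <- function(metric_means, comparisons = NULL, reference) {
  conds <- unique(metric_means$condition)
  if (!reference %in% conds)
    stop("reference condition missing from the table", call. = FALSE)
  metrics <- unique(metric_means$metric)
  out <- data.frame(metric = metrics, stringsAsFactors = FALSE)
  for (cond in conds) {
    cells <- character(length(metrics))
    for (i in seq_along(metrics)) {
      v <- metric_means$value[metric_means$metric == metrics[i] &
                                metric_means$condition == cond]
      cell <- sprintf("%.10g", v)
      if (!is.null(comparisons) && nrow(comparisons) > 0 &&
          cond != reference) {
        cmp <- comparisons[comparisons$metric == metrics[i] &
                             comparisons$group == cond, ]
        if (nrow(cmp) == 1) {
          cell <- sprintf("%s (%+d%% %s vs %s)", cell,
                          as.integer(cmp$effect_pct_rounded), cmp$flag,
                          cmp$reference)
        }
      }
      cells[i] <- cell
    }
    out[[cond]] <- cells
  }
  out
}

#' Parse a rendered report back into values and annotations
#'
#' Inverse of \code{\link{render_report}}: recovers the numeric condition
#' means (exactly, at the rendered precision) and the percent annotations.
#'
#' @param report data.frame from \code{\link{render_report}}.
#' @return data.frame: metric, condition, value, effect_pct_rounded
#'   (\code{NA} where no annotation), flag.
#' @export
parse_report <- function(report) {
  conds <- setdiff(names(report), "metric")
  out <- NULL
  for (cond in conds) {
    for (i in seq_len(nrow(report))) {
      cell <- report[[cond]][i]
      m <- regmatches(cell,
                      regexec("^([-0-9.eE+]+)( \\(([+-][0-9]+)% (\\S+) vs (.+)\\))?$",
                              cell))[[1]]
      out <- rbind(out, data.frame(
        metric = report$metric[i], condition = cond,
        value = as.numeric(m[2]),
        effect_pct_rounded = if (m[4] == "") NA_real_ else as.numeric(m[4]),
        flag = if (m[5] == "") NA_character_ else m[5],
        stringsAsFactors = FALSE))
    }
  }
  out
}
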