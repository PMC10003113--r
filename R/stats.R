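# The statistical decision ladder: Shapiro-Wilk normality gate, then either
# the parametric route (unpaired t-test for two groups; one-way ANOVA
# followed by Dunnett's multiple comparison against the reference with a
# single pooled variance) or the nonparametric route (Kruskal-Wallis
# omnibus with pairwise Mann-Whitney U against the reference; Wilcoxon
# signed-rank for paired designs). Effects are reported as percent change
# versus the reference, with the #/*/**/*** significance flags.

#' Signed percent change versus a reference mean
#'
#' @param treated treated-group mean.
#' @param reference reference-group mean (non-zero).
#' @return list: raw (exact percent), rounded (nearest integer, half away
#'   from zero).
#' @export
percent_change <- function(treated, reference) {
  if (reference == 0) stop("reference mean must be non-zero", call. = FALSE)
  raw <- 100 * (treated - reference) / reference
  list(raw = raw, rounded = round_half_away(raw))
}

# nearest integer, ties away from zero (round() would go to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Significance flag for a p-value
#'
#' Most significant applicable threshold: p < 0.001 "***", p < 0.01 "**",
#' p < 0.05 "*", p < 0.1 "#" (trend), otherwise "ns".
#'
#' @param p p-value in [0, 1].
#' @return character flag.
#' @export
significance_flag <- function(p) {
  if (is.na(p) || p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
  if (p < 0.001) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else if (p < 0.1) "#"
  else "ns"
}

#' Normality gate (Shapiro-Wilk on every group)
#'
#' @param groups list of numeric vectors, one per group (each n >= 3,
#'   non-degenerate).
#' @param alpha gate level (default 0.05).
#' @return \code{"parametric"} if every group passes Shapiro-Wilk at
#'   \code{alpha}, else \code{"nonparametric"}.
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  if (any(vapply(groups, length, integer(1)) < 3))
    stop("every group needs n >= 3 for the normality gate", call. = FALSE)
  if (any(vapply(groups, function(g) stats::var(g) == 0, logical(1))))
    stop("degenerate (constant) group", call. = FALSE)
  p <- vapply(groups, function(g) stats::shapiro.test(g)$p.value, numeric(1))
  if (all(p >= alpha)) "parametric" else "nonparametric"
}

# cache of Monte-Carlo Dunnett null distributions, keyed by the design
.dunnett_cache <- new.env(parent = emptyenv())

#' Monte-Carlo null distribution of the Dunnett max-|t| statistic
#'
#' Simulates the joint null of the k treatment-vs-control t statistics that
#' share the control mean and a single pooled variance, and returns the
#' distribution of their maximum absolute value. 50,000 seeded draws give a
#' critical-value Monte-Carlo error well below the reporting resolution;
#' the distribution is cached per design.
#'
#' @param n vector of group sizes, reference first.
#' @param draws number of Monte-Carlo draws.
#' @return numeric vector of max-|t| draws.
#' @export
dunnett_null <- function(n, draws = 50000L) {
  key <- paste(c(n, draws), collapse = "-")
  if (!is.null(.dunnett_cache[[key]])) return(.dunnett_cache[[key]])
  k <- length(n) - 1L
  df <- sum(n) - length(n)
  null_max <- with_seed(20259L + length(n), {
    z <- matrix(stats::rnorm(draws * (k + 1L)), draws, k + 1L)
    z <- sweep(z, 2L, sqrt(n), "/")
    s <- sqrt(stats::rchisq(draws, df) / df)
    tmat <- (z[, -1L, drop = FALSE] - z[, 1L]) /
      (s * matrix(sqrt(1 / n[-1L] + 1 / n[1L]), draws, k, byrow = TRUE))
    apply(abs(tmat), 1L, max)
  })
  .dunnett_cache[[key]] <- null_max
  null_max
}

#' Dunnett's multiple comparison versus a reference group
#'
#' Treatment-vs-control t statistics with a single pooled variance;
#' single-step adjusted p-values come from the Monte-Carlo max-|t| null of
#' \code{\link{dunnett_null}}.
#'
#' @param groups named list of numeric vectors (one per group).
#' @param reference name of the reference (control) group.
#' @return data.frame: group, statistic, adjusted p.
#' @export
dunnett_test <- function(groups, reference) {
  labs <- names(groups)
  others <- setdiff(labs, reference)
  n <- vapply(groups, length, integer(1))
  means <- vapply(groups, mean, numeric(1))
  df <- sum(n) - length(n)
  pooled <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1))) / df
  null_max <- dunnett_null(c(n[reference], n[others]))
  out <- lapply(others, function(g) {
    tstat <- (means[g] - means[reference]) /
      sqrt(pooled * (1 / n[g] + 1 / n[reference]))
    p <- (1 + sum(null_max >= abs(tstat))) / (length(null_max) + 1)
    data.frame(group = g, statistic = tstat, p = p)
  })
  do.call(rbind, out)
}

#' Compare groups through the statistical decision ladder
#'
#' Routing: the Shapiro-Wilk gate picks the route (unless forced);
#' parametric data use an unpaired t-test (two groups) or one-way ANOVA
#' followed by Dunnett versus the reference with a single pooled variance
#' (more than two); nonparametric unpaired data use Kruskal-Wallis followed
#' by pairwise Mann-Whitney U versus the reference; nonparametric paired
#' data use the Wilcoxon signed-rank test. Pairwise p-values are reported
#' regardless of the omnibus outcome, as in the source tables.
#'
#' @param values numeric vector of all observations.
#' @param groups group label per observation.
#' @param reference reference group label (untreated or stress control).
#' @param design \code{"unpaired"} or \code{"paired"} (paired data must be
#'   ordered identically within each group).
#' @param gate \code{"auto"} (Shapiro-Wilk), or force \code{"parametric"} /
#'   \code{"nonparametric"}.
#' @return data.frame: one row per non-reference group with the group
#'   means, effect percent (raw and rounded), test name, omnibus and
#'   pairwise p-values, and significance flag.
#' @export
compare_groups <- function(values, groups, reference,
                           design = c("unpaired", "paired"),
                           gate = "auto") {
  design <- match.arg(design)
  gate <- match.arg(gate, c("auto", "parametric", "nonparametric"))
  gl <- split(values, groups)
  if (length(gl) < 2) stop("need at least two groups", call. = FALSE)
  if (!reference %in% names(gl))
    stop("reference group not present", call. = FALSE)
  route <- if (gate == "auto") normality_gate(gl) else gate
  others <- setdiff(names(gl), reference)
  two <- length(gl) == 2L

  omnibus_p <- NA_real_
  if (route == "parametric" && design == "unpaired") {
    if (two) {
      test_name <- "unpaired t-test"
      rows <- lapply(others, function(g) {
        p <- stats::t.test(gl[[g]], gl[[reference]],
                           var.equal = TRUE)$p.value
        data.frame(group = g, p = p)
      })
      rows <- do.call(rbind, rows)
    } else {
      test_name <- "one-way ANOVA + Dunnett"
      fit <- stats::aov(values ~ factor(groups))
      omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
      rows <- dunnett_test(gl, reference)[, c("group", "p")]
    }
  } else if (route == "parametric" && design == "paired") {
    test_name <- "paired t-test"
    rows <- do.call(rbind, lapply(others, function(g)
      data.frame(group = g,
                 p = stats::t.test(gl[[g]], gl[[reference]],
                                   paired = TRUE)$p.value)))
  } else if (design == "unpaired") {
    test_name <- if (two) "Mann-Whitney U"
                 else "Kruskal-Wallis + Mann-Whitney U"
    if (!two)
      omnibus_p <- stats::kruskal.test(values, factor(groups))$p.value
    rows <- do.call(rbind, lapply(others, function(g) {
      p <- suppressWarnings(
        stats::wilcox.test(gl[[g]], gl[[reference]])$p.value)
      data.frame(group = g, p = p)
    }))
  } else {
    test_name <- "Wilcoxon signed-rank"
    rows <- do.call(rbind, lapply(others, function(g) {
      p <- suppressWarnings(
        stats::wilcox.test(gl[[g]], gl[[reference]],
                           paired = TRUE)$p.value)
      if (is.nan(p)) p <- 1  # all differences zero: no evidence
      data.frame(group = g, p = p)
    }))
  }
  ref_mean <- mean(gl[[reference]])
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    g <- rows$group[i]
    eff <- percent_change(mean(gl[[g]]), ref_mean)
    data.frame(group = g, reference = reference,
               group_mean = mean(gl[[g]]), reference_mean = ref_mean,
               effect_pct = eff$raw, effect_pct_rounded = eff$rounded,
               test = test_name, design = design, route = route,
               omnibus_p = omnibus_p, p = rows$p[i],
               flag = significance_flag(rows$p[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
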