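# Lactation statistics: stage summaries (mean, n-1 SD, CV%), the grand
# summary across the 17 stage means, Pearson correlation with the Guilford
# strength classification, and the standard group-test battery
# (one-way ANOVA, Levene, per-group K-S normality, Tukey HSD).

#' Per-stage summary of a quantity
#'
#' Arithmetic mean, sample standard deviation (n-1 denominator) and
#' coefficient of variation CV = 100 * sd / mean.
#'
#' @param values numeric vector (n >= 1).
#' @param stage_label the stage the values belong to.
#' @return Object of class `stage_summary`: `stage_label`, `n`, `mean`,
#'   `sd`, `cv`. `cv` is `NA` (flagged via the `cv_defined` field) when the
#'   mean is 0; `sd` is `NA` for n = 1.
#' @export
#' @examples
#' summarize_stage(c(19.2, 20.1, 20.5), "7 days")
summarize_stage <- function(values, stage_label) {
  if (length(values) < 1 || any(!is.finite(values))) {
    stop("summarize_stage needs at least one finite value", call. = FALSE)
  }
  m <- mean(values)
  s <- if (length(values) > 1) stats::sd(values) else NA_real_
  cv_defined <- is.finite(s) && m > 0
  cv <- if (cv_defined) 100 * s / m else if (identical(s, 0)) 0 else NA_real_
  structure(list(stage_label = stage_label, n = length(values),
                 mean = m, sd = s, cv = cv, cv_defined = cv_defined),
            class = "stage_summary")
}

#' @export
print.stage_summary <- function(x, digits = 4, ...) {
  cat(x$stage_label, ": n=", x$n, "  ", signif(x$mean, digits), " +/- ",
      signif(x$sd, digits), "  CV ", signif(x$cv, digits), "%\n", sep = "")
  invisible(x)
}

#' Grand summary across the 17 stage means
#'
#' Unweighted arithmetic mean and sample SD (n-1) across one mean per
#' lactation stage — the "average content" row of a stage table.
#'
#' @param stage_means numeric vector, one value per stage (17 under the
#'   default schedule).
#' @param allow_partial allow fewer stages.
#' @param n_stages expected number of stages.
#' @return Named numeric `c(mean = , sd = )`.
#' @export
grand_summary <- function(stage_means, allow_partial = FALSE, n_stages = 17) {
  if (!allow_partial && length(stage_means) != n_stages) {
    stop("expected one mean per stage (", n_stages, "); got ",
         length(stage_means), " (use allow_partial = TRUE to override)",
         call. = FALSE)
  }
  c(mean = mean(stage_means), sd = stats::sd(stage_means))
}

#' Guilford strength classification of a correlation
#'
#' |r| < 0.2 negligible; 0.2-0.4 low; 0.4-0.7 moderate; 0.7-0.9 high;
#' >= 0.9 very high. Band boundaries are inclusive on the lower edge.
#'
#' @param r correlation coefficient(s) in \[-1, 1\].
#' @return Character vector of class labels.
#' @export
guilford_class <- function(r) {
  a <- abs(r)
  if (any(a > 1, na.rm = TRUE)) stop("|r| must be <= 1", call. = FALSE)
  cut(a, breaks = c(-Inf, 0.2, 0.4, 0.7, 0.9, Inf), right = FALSE,
      labels = c("negligible", "low", "moderate", "high", "very high")) |>
    as.character()
}

#' Pearson correlation with Guilford interpretation
#'
#' @param x,y numeric vectors of equal length, n >= 3, both with nonzero
#'   variance.
#' @return Object of class `correlation_result`: `r`, `n`, `p_value`
#'   (two-sided, from the t transform), `guilford_class`, `direction`.
#' @export
#' @examples
#' correlate(1:10, (1:10) + rnorm(10))
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("correlation needs at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  structure(list(r = r, n = n, p_value = p,
                 guilford_class = guilford_class(r),
                 direction = if (r >= 0) "positive" else "negative"),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, digits = 3, ...) {
  cat("r = ", signif(x$r, digits), " (n = ", x$n, ", p = ",
      signif(x$p_value, digits), "): ", x$guilford_class, " ",
      x$direction, " correlation\n", sep = "")
  invisible(x)
}

#' Standard group-test battery across lactation stages
#'
#' One-way ANOVA (F, p), Levene's homogeneity test (mean-centred absolute
#' deviations), a per-group Kolmogorov-Smirnov normality check (parameters
#' estimated from the data, so the p-values are approximate and flagged as
#' such), and Tukey's HSD pairwise table at `alpha`.
#'
#' @param groups named list mapping stage label to numeric vector. Groups
#'   with fewer than 2 values are excluded with a warning.
#' @param alpha significance level for the Tukey intervals.
#' @return Object of class `stage_test_report`: `anova` (`f`, `p`, `df`),
#'   `levene` (`f`, `p`), `ks` (per-group data frame, approximate),
#'   `tukey` (pairwise data frame), `alpha`.
#' @export
stage_group_tests <- function(groups, alpha = 0.05) {
  sizes <- vapply(groups, length, 0L)
  if (any(sizes < 2)) {
    warning("excluding group(s) with n < 2: ",
            paste(names(groups)[sizes < 2], collapse = ", "), call. = FALSE)
    groups <- groups[sizes >= 2]
  }
  if (length(groups) < 2) stop("need at least 2 groups with n >= 2", call. = FALSE)
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 0L)))
  )
  fit <- stats::aov(value ~ group, data = dat)
  an <- stats::anova(fit)
  # Levene, original (mean-centred) form: ANOVA on |x - group mean|
  dat$z <- abs(dat$value - stats::ave(dat$value, dat$group))
  lev <- stats::anova(stats::aov(z ~ group, data = dat))
  ks <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    p <- if (stats::sd(x) == 0) NA_real_ else {
      suppressWarnings(stats::ks.test((x - mean(x)) / stats::sd(x), "pnorm")$p.value)
    }
    data.frame(group = g, n = length(x), ks_p_approx = p)
  }))
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL)
  f <- an$`F value`[1]
  if (!is.finite(f)) f <- 0  # zero residual variance with zero between-group variance
  structure(list(anova = list(f = f, p = an$`Pr(>F)`[1],
                              df = unname(an$Df)),
                 levene = list(f = lev$`F value`[1], p = lev$`Pr(>F)`[1]),
                 ks = ks, tukey = tukey, alpha = alpha),
            class = "stage_test_report")
}

#' @export
print.stage_test_report <- function(x, digits = 4, ...) {
  cat("One-way ANOVA: F =", signif(x$anova$f, digits), ", p =",
      signif(x$anova$p, digits), "\n")
  cat("Levene (mean-centred): F =", signif(x$levene$f, digits), ", p =",
      signif(x$levene$p, digits), "\n")
  cat("K-S normality p (approximate, estimated parameters):\n")
  print(x$ks)
  cat("Tukey HSD at alpha =", x$alpha, ":",
      sum(x$tukey$significant), "/", nrow(x$tukey),
      "pairs significant\n")
  invisible(x)
}

# ---- quantity selectors -----------------------------------------------------

#' Quantity selectors for per-sample analyses
#'
#' Functions of a [milk_sample()] returning one number, for use with
#' [lactation_trend()], [sample_matrix()] and the stage summaries:
#' a single congener's concentration, a group sum, or a composition field.
#'
#' @param congener IUPAC number.
#' @param basis,units concentration basis and units.
#' @param bound censoring bound for substitution.
#' @param log return the natural log of the concentration (`NA` for
#'   non-positive values).
#' @return A function `milk_sample -> numeric(1)`.
#' @export
#' @examples
#' q <- q_congener(153)
#' @name quantity
q_congener <- function(congener, basis = "lipid", units = "ng_per_g",
                       bound = "middle", log = FALSE) {
  force(congener)
  function(sample) {
    v <- .from_pg(.concentrations_on(sample, as.integer(congener), bound, basis),
                  units)
    v <- unname(v)
    if (log) { if (v <= 0) NA_real_ else base::log(v) } else v
  }
}

#' @rdname quantity
#' @param group congener group for [sum_group()].
#' @export
q_group_sum <- function(group, basis = "lipid", units = "ng_per_g",
                        bound = "middle", log = FALSE) {
  force(group)
  function(sample) {
    v <- sum_group(sample, group, bound = bound, basis = basis, units = units)
    if (log) { if (v <= 0) NA_real_ else base::log(v) } else v
  }
}

#' @rdname quantity
#' @param field composition field: `"lipid_pct"`, `"dry_matter_pct"`,
#'   `"protein_pct"` or `"lactose_pct"`.
#' @export
q_composition <- function(field = c("lipid_pct", "dry_matter_pct",
                                    "protein_pct", "lactose_pct")) {
  field <- match.arg(field)
  function(sample) sample$composition[[field]]
}

#' Correlation of a quantity with lactation duration
#'
#' Pearson correlation of days postpartum against a per-sample quantity
#' over all supplied samples.
#'
#' @param samples list of [milk_sample()] objects.
#' @param quantity a selector function (see [q_congener()]).
#' @return A [correlate()] result.
#' @export
lactation_trend <- function(samples, quantity) {
  days <- vapply(samples, `[[`, 0, "stage_days")
  vals <- vapply(samples, quantity, 0)
  correlate(days, vals)
}

#' Sample-by-congener concentration matrix
#'
#' @param samples list of [milk_sample()] objects.
#' @param congeners columns (IUPAC numbers); default all registry congeners.
#' @param basis,units,bound,log as in [q_congener()].
#' @return Numeric matrix, rows named by sample id, columns `pcb_<n>`.
#' @export
sample_matrix <- function(samples, congeners = congener_registry()$congener,
                          basis = "lipid", units = "ng_per_g",
                          bound = "middle", log = TRUE) {
  rows <- lapply(samples, function(s) {
    v <- .from_pg(.concentrations_on(s, as.integer(congeners), bound, basis),
                  units)
    if (log) v <- base::log(ifelse(v > 0, v, NA_real_))
    v
  })
  m <- do.call(rbind, rows)
  dimnames(m) <- list(vapply(samples, `[[`, "", "sample_id"),
                      paste0("pcb_", congeners))
  m
}

#' Stage-wise summaries of a quantity over a sample set
#'
#' Groups samples by stage label and applies [summarize_stage()], producing
#' a stage table (one row per stage, in schedule order).
#'
#' @param samples list of [milk_sample()] objects.
#' @param quantity a selector function.
#' @param schedule the [stage_schedule()] fixing row order.
#' @return Data frame `stage_label`, `n`, `mean`, `sd`, `cv`.
#' @export
stage_table <- function(samples, quantity, schedule = stage_schedule()) {
  labs <- vapply(samples, `[[`, "", "stage_label")
  vals <- vapply(samples, quantity, 0)
  out <- lapply(schedule$labels, function(lb) {
    v <- vals[labs == lb & is.finite(vals)]
    if (!length(v)) return(NULL)
    s <- summarize_stage(v, lb)
    data.frame(stage_label = lb, n = s$n, mean = s$mean, sd = s$sd, cv = s$cv)
  })
  do.call(rbind, out)
}
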