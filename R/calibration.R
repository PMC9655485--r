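# Calibration-curve quality control: ordinary least squares fit of
# instrument response on nominal concentration, and the LOD/LOQ estimates
# 3.3 * s_intercept / slope and 10 * s_intercept / slope.

#' Fit a calibration curve
#'
#' Ordinary least squares of instrument response on nominal concentration.
#' `sd_intercept` is the OLS standard error of the intercept estimate.
#'
#' @param concentration nominal concentrations (>= 3 points, at least two
#'   distinct levels; replicate levels are allowed).
#' @param response instrument responses, same length.
#' @return Object of class `calibration_curve`: `slope`, `intercept`,
#'   `sd_intercept`, `n`, and the fitted `lm` as `fit`.
#' @export
#' @examples
#' cc <- fit_calibration(c(1, 2, 3, 4), c(3.1, 5.0, 6.9, 9.1))
#' lod_loq(cc)
fit_calibration <- function(concentration, response) {
  stopifnot(length(concentration) == length(response))
  if (length(concentration) < 3) {
    stop("calibration needs at least 3 points", call. = FALSE)
  }
  if (length(unique(concentration)) < 2) {
    stop("singular design: all concentrations identical", call. = FALSE)
  }
  fit <- stats::lm(response ~ concentration)
  # summary() warns on an exactly collinear fit; the zero SE is legitimate
  co <- suppressWarnings(summary(fit)$coefficients)
  se_int <- co["(Intercept)", "Std. Error"]
  if (!is.finite(se_int)) se_int <- 0  # exact fit with zero residual df
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 sd_intercept = se_int,
                 n = length(concentration), fit = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Calibration curve: response =", signif(x$slope, 5), "* conc +",
      signif(x$intercept, 5), " (n =", x$n,
      ", sd(intercept) =", signif(x$sd_intercept, 5), ")\n")
  invisible(x)
}

#' Detection and quantification limits from a calibration curve
#'
#' LOD = 3.3 * sd(intercept) / slope; LOQ = 10 * sd(intercept) / slope.
#' The LOQ/LOD ratio is therefore fixed at 10/3.3 for every curve.
#'
#' @param curve a [fit_calibration()] result.
#' @return Named numeric vector `c(lod = , loq = )` in concentration units.
#' @export
lod_loq <- function(curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(curve$slope) || curve$slope <= 0) {
    stop("unusable calibration curve: slope must be > 0", call. = FALSE)
  }
  c(lod = 3.3 * curve$sd_intercept / curve$slope,
    loq = 10 * curve$sd_intercept / curve$slope)
}

#' Per-congener LOD/LOQ table from a calibration-points CSV
#'
#' Reads columns `congener`, `concentration`, `response`, fits one curve per
#' congener and returns the limits in the same units as `concentration`.
#'
#' @param path CSV of calibration points.
#' @return Data frame with columns `congener`, `slope`, `sd_intercept`,
#'   `lod`, `loq`.
#' @export
lod_loq_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("congener", "concentration", "response"), names(df))
  if (length(missing)) {
    stop("calibration CSV lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(df, df$congener), function(d) {
    cc <- fit_calibration(d$concentration, d$response)
    ll <- lod_loq(cc)
    data.frame(congener = d$congener[1], slope = cc$slope,
               sd_intercept = cc$sd_intercept,
               lod = ll[["lod"]], loq = ll[["loq"]])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
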