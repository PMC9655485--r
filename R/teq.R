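# TEQ engine: basis conversion, censoring-bound substitution, the
# TEF-weighted toxic-equivalent sum TEQ = sum_i c_i * TEF_i over the
# dioxin-like congeners, and regulatory group sums.

.BOUNDS <- c("lower", "middle", "upper")

#' Convert a concentration between wet-weight and lipid basis
#'
#' Lipid-basis concentration = wet-weight concentration / (lipid fraction);
#' the inverse in the other direction; identity when the bases match.
#'
#' @param value concentration(s) >= 0.
#' @param from,to `"wet_weight"` or `"lipid"`.
#' @param lipid_pct lipid percentage of the sample, in (0, 100\] when an
#'   actual conversion is requested.
#' @return Converted concentration(s), same units as the input.
#' @export
#' @examples
#' convert_basis(0.5, "wet_weight", "lipid", lipid_pct = 4)  # 12.5
convert_basis <- function(value, from, to, lipid_pct = NULL) {
  from <- match.arg(from, .BASES)
  to <- match.arg(to, .BASES)
  if (any(value < 0, na.rm = TRUE)) stop("concentration must be >= 0", call. = FALSE)
  if (from == to) return(value)
  if (is.null(lipid_pct) || any(!is.finite(lipid_pct)) ||
      any(lipid_pct <= 0) || any(lipid_pct > 100)) {
    stop("basis conversion needs lipid_pct in (0, 100]; ",
         "a zero-lipid sample is degenerate", call. = FALSE)
  }
  frac <- lipid_pct / 100
  if (from == "wet_weight") value / frac else value * frac
}

#' Substitute censored measurements under a bound strategy
#'
#' Detected values pass through. A value below the LOD is replaced by 0
#' (`lower`), LOD/2 (`middle`) or LOD (`upper`); below the LOQ likewise
#' with the LOQ.
#'
#' @param m measurement data frame (pg/g, see [congener_measurement()]).
#' @param bound `"lower"`, `"middle"` or `"upper"`.
#' @return Numeric vector of substituted concentrations (pg/g, sample basis).
#' @export
substitute_censored <- function(m, bound = c("middle", "lower", "upper")) {
  bound <- match.arg(bound)
  limit <- ifelse(m$censor == "below_lod", m$lod,
                  ifelse(m$censor == "below_loq", m$loq, NA_real_))
  cens <- m$censor != "detected"
  if (any(cens & is.na(limit))) {
    stop("censored measurement lacks its limit (congener ",
         paste(m$congener[cens & is.na(limit)], collapse = ", "), ")",
         call. = FALSE)
  }
  out <- m$value
  out[cens] <- switch(bound,
                      lower = 0,
                      middle = limit[cens] / 2,
                      upper = limit[cens])
  out
}

# substituted concentrations of selected congeners on the requested basis,
# pg/g; absent congeners contribute 0 (warning unless bound == "lower")
.concentrations_on <- function(sample, congeners, bound, basis) {
  m <- sample$measurements
  vals <- substitute_censored(m, bound)
  vals <- vapply(seq_along(vals), function(i) {
    convert_basis(vals[i], m$basis[i], basis,
                  lipid_pct = sample$composition$lipid_pct)
  }, numeric(1))
  idx <- match(congeners, m$congener)
  out <- ifelse(is.na(idx), 0, vals[idx])
  absent <- congeners[is.na(idx)]
  if (length(absent) && bound != "lower") {
    warning("sample ", sample$sample_id, ": congener(s) ",
            paste(absent, collapse = ", "),
            " not reported and no limit available; contributing 0 under ",
            bound, " bound", call. = FALSE)
  }
  stats::setNames(out, congeners)
}

#' Compute the toxic equivalent (TEQ) of a sample
#'
#' TEQ = sum over dioxin-like congeners of concentration x TEF, in
#' pg-TEQ/g on the requested basis. Censored values are substituted per the
#' bound strategy; congeners absent from the sample contribute 0 (with a
#' warning unless `bound = "lower"`, since no limit is available for them).
#'
#' @param sample a [milk_sample()].
#' @param scheme a [tef_scheme()].
#' @param bound censoring bound; `"upper"` is the conservative regulatory
#'   convention and the default here.
#' @param basis output basis.
#' @return Object of class `teq_result`: `teq` (pg-TEQ/g), `basis`, `bound`,
#'   `per_congener` (named contributions summing to `teq`).
#' @export
#' @examples
#' s <- milk_sample("s1", "m1", 7, milk_composition(4, 12, 1.2, 6),
#'                  congener_measurement(126, 1, "wet_weight", "pg_per_g"))
#' compute_teq(s, bound = "lower")$teq  # 0.1
compute_teq <- function(sample, scheme = tef_scheme(),
                        bound = c("upper", "middle", "lower"),
                        basis = c("wet_weight", "lipid")) {
  bound <- match.arg(bound)
  basis <- match.arg(basis)
  stopifnot(inherits(sample, "milk_sample"))
  dl <- dl_congeners()
  conc <- .concentrations_on(sample, dl, bound, basis)
  contrib <- conc * tef_for(scheme, dl)
  structure(list(teq = sum(contrib), basis = basis, bound = bound,
                 per_congener = contrib, scheme = scheme$name,
                 sample_id = sample$sample_id),
            class = "teq_result")
}

#' @export
print.teq_result <- function(x, digits = 4, ...) {
  cat("TEQ ", signif(x$teq, digits), " pg-TEQ/g (", x$basis, ", ", x$bound,
      " bound, scheme ", x$scheme, ")\n", sep = "")
  top <- sort(x$per_congener, decreasing = TRUE)[1:3]
  cat("  top contributors:",
      paste0("PCB ", names(top), " (", signif(top, digits), ")", collapse = ", "),
      "\n")
  invisible(x)
}

#' Sum of a congener group's concentrations
#'
#' Arithmetic sum of the (censoring-substituted) concentrations of the
#' congeners of one group, on the requested basis. Used for the regulatory
#' sums: total ndl indicators, total non-ortho, total mono-ortho.
#'
#' @param sample a [milk_sample()].
#' @param group `"ndl_indicator"`, `"non_ortho"` or `"mono_ortho"`.
#' @param bound censoring bound (default `"middle"`, the trend-statistics
#'   convention).
#' @param basis output basis.
#' @param units output units.
#' @return Scalar concentration in `units`.
#' @export
sum_group <- function(sample, group = c("ndl_indicator", "non_ortho", "mono_ortho"),
                      bound = c("middle", "lower", "upper"),
                      basis = c("lipid", "wet_weight"),
                      units = c("ng_per_g", "pg_per_g")) {
  group <- match.arg(group)
  bound <- match.arg(bound)
  basis <- match.arg(basis)
  units <- match.arg(units)
  reg <- congener_registry()
  ids <- reg$congener[reg$group == group]
  total <- sum(.concentrations_on(sample, ids, bound, basis))
  .from_pg(total, units)
}
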