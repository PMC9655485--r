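# Infant risk assessment: daily/weekly pg-TEQ intake per kg body weight,
# tolerable-weekly-intake comparison, and screening against the EU maximum
# levels for foods for infants and young children.

#' Intake scenario for an infant
#'
#' @param sex `"male"` or `"female"`.
#' @param milk_volume_ml_per_day daily milk consumption; the default range
#'   \[478, 1356\] mL brackets reported consumption, mean 798 mL.
#' @param body_weight_kg infant body weight (> 0).
#' @param milk_density_g_per_ml density converting mL to g (default 1.0,
#'   configurable to 1.03).
#' @param stage_days optional days postpartum the scenario refers to.
#' @param volume_bounds allowed volume range.
#' @return Object of class `intake_scenario`.
#' @export
intake_scenario <- function(sex, milk_volume_ml_per_day, body_weight_kg,
                            milk_density_g_per_ml = 1.0, stage_days = NULL,
                            volume_bounds = c(478, 1356)) {
  .check_code(sex, "sex")
  if (milk_volume_ml_per_day < volume_bounds[1] ||
      milk_volume_ml_per_day > volume_bounds[2]) {
    stop("milk volume ", milk_volume_ml_per_day, " mL outside configured bounds [",
         volume_bounds[1], ", ", volume_bounds[2], "]", call. = FALSE)
  }
  if (!is.finite(body_weight_kg) || body_weight_kg <= 0) {
    stop("body weight must be > 0", call. = FALSE)
  }
  structure(list(sex = sex, milk_volume_ml_per_day = milk_volume_ml_per_day,
                 body_weight_kg = body_weight_kg,
                 milk_density_g_per_ml = milk_density_g_per_ml,
                 stage_days = stage_days),
            class = "intake_scenario")
}

#' Risk thresholds
#'
#' Defaults: tolerable weekly intake (TWI) 2 pg-TEQ/kg bw/week (the legacy
#' value 14 is kept for comparison); EU maximum levels for foods for
#' infants and young children: 0.1 pg-TEQ/g w.w. for dl-PCBs and
#' 1 ng/g w.w. for the ndl indicator sum.
#'
#' @param twi_pg_teq_per_kg_week,twi_legacy,max_dl_teq_pg_per_g_ww,max_ndl_ng_per_g_ww
#'   all > 0.
#' @return Object of class `risk_thresholds`.
#' @export
risk_thresholds <- function(twi_pg_teq_per_kg_week = 2, twi_legacy = 14,
                            max_dl_teq_pg_per_g_ww = 0.1,
                            max_ndl_ng_per_g_ww = 1.0) {
  v <- c(twi_pg_teq_per_kg_week, twi_legacy, max_dl_teq_pg_per_g_ww,
         max_ndl_ng_per_g_ww)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("all thresholds must be > 0", call. = FALSE)
  }
  structure(list(twi_pg_teq_per_kg_week = twi_pg_teq_per_kg_week,
                 twi_legacy = twi_legacy,
                 max_dl_teq_pg_per_g_ww = max_dl_teq_pg_per_g_ww,
                 max_ndl_ng_per_g_ww = max_ndl_ng_per_g_ww),
            class = "risk_thresholds")
}

#' Daily and weekly infant TEQ intake
#'
#' daily = TEQ (pg/g w.w.) x volume (mL) x density (g/mL) / body weight (kg);
#' weekly = 7 x daily; compared against the tolerable weekly intake.
#'
#' @param teq_ww wet-weight TEQ of the milk, pg-TEQ/g.
#' @param scenario an [intake_scenario()].
#' @param thresholds a [risk_thresholds()].
#' @return Object of class `intake_result`: `daily_pg_teq_per_kg`,
#'   `weekly_pg_teq_per_kg`, `twi_fraction`, `exceeds_twi`, plus the
#'   scenario.
#' @export
#' @examples
#' sc <- intake_scenario("female", 798, 4)
#' daily_intake(0.1, sc)
daily_intake <- function(teq_ww, scenario, thresholds = risk_thresholds()) {
  stopifnot(inherits(scenario, "intake_scenario"))
  if (!is.finite(teq_ww) || teq_ww < 0) stop("teq_ww must be >= 0", call. = FALSE)
  daily <- teq_ww * scenario$milk_volume_ml_per_day *
    scenario$milk_density_g_per_ml / scenario$body_weight_kg
  weekly <- 7 * daily
  frac <- weekly / thresholds$twi_pg_teq_per_kg_week
  structure(list(daily_pg_teq_per_kg = daily,
                 weekly_pg_teq_per_kg = weekly,
                 twi_fraction = frac,
                 exceeds_twi = frac > 1,
                 scenario = scenario),
            class = "intake_result")
}

#' @export
print.intake_result <- function(x, digits = 4, ...) {
  cat("Intake: ", signif(x$daily_pg_teq_per_kg, digits),
      " pg-TEQ/kg bw/day = ", signif(x$weekly_pg_teq_per_kg, digits),
      " pg-TEQ/kg bw/week (", signif(100 * x$twi_fraction, digits),
      "% of TWI", if (x$exceeds_twi) ", EXCEEDED" else "", ")\n", sep = "")
  invisible(x)
}

#' Sex-specific default milk volumes
#'
#' Splits an overall mean daily volume into female and male means given the
#' male-female consumption gap and the male share of infants, so that the
#' share-weighted mean reproduces the overall mean:
#' female = overall - male_fraction x gap; male = female + gap.
#'
#' @param overall_mean_ml overall mean daily volume (default 798 mL).
#' @param sex_gap_ml male minus female mean (default 76 mL).
#' @param male_fraction proportion of male infants in \[0, 1\]
#'   (default 0.625).
#' @return Named numeric `c(female = , male = )` in mL.
#' @export
#' @examples
#' default_sex_volumes()  # female 750.5, male 826.5
default_sex_volumes <- function(overall_mean_ml = 798, sex_gap_ml = 76,
                                male_fraction = 0.625) {
  if (male_fraction < 0 || male_fraction > 1) {
    stop("male_fraction must lie in [0, 1]", call. = FALSE)
  }
  female <- overall_mean_ml - male_fraction * sex_gap_ml
  if (female < 0 || female + sex_gap_ml < 0) {
    stop("sex gap produces a negative volume", call. = FALSE)
  }
  c(female = female, male = female + sex_gap_ml)
}

#' Screen a sample against EU maximum levels
#'
#' Computes the dl-PCB TEQ (pg-TEQ/g w.w.) and the ndl indicator sum
#' (ng/g w.w.) on the wet-weight basis and compares them to the maximum
#' levels. A value exactly at the level complies (<= convention).
#'
#' @param sample a [milk_sample()].
#' @param thresholds a [risk_thresholds()].
#' @param bound censoring bound; `"upper"` is the conservative convention
#'   for limit checks.
#' @param scheme a [tef_scheme()].
#' @return Object of class `compliance_result`: `dl_teq_ww`, `ndl_sum_ww`,
#'   `dl_fraction_of_limit`, `ndl_fraction_of_limit`, `compliant_dl`,
#'   `compliant_ndl`.
#' @export
compliance_check <- function(sample, thresholds = risk_thresholds(),
                             bound = "upper", scheme = tef_scheme()) {
  dl <- compute_teq(sample, scheme = scheme, bound = bound,
                    basis = "wet_weight")$teq
  ndl <- sum_group(sample, "ndl_indicator", bound = bound,
                   basis = "wet_weight", units = "ng_per_g")
  dl_frac <- dl / thresholds$max_dl_teq_pg_per_g_ww
  ndl_frac <- ndl / thresholds$max_ndl_ng_per_g_ww
  structure(list(sample_id = sample$sample_id,
                 dl_teq_ww = dl, ndl_sum_ww = ndl,
                 dl_fraction_of_limit = dl_frac,
                 ndl_fraction_of_limit = ndl_frac,
                 compliant_dl = dl_frac <= 1,
                 compliant_ndl = ndl_frac <= 1),
            class = "compliance_result")
}

#' @export
print.compliance_result <- function(x, digits = 4, ...) {
  cat("Sample ", x$sample_id, ": dl-TEQ ", signif(x$dl_teq_ww, digits),
      " pg-TEQ/g w.w. (", signif(100 * x$dl_fraction_of_limit, digits),
      "% of limit, ", if (x$compliant_dl) "compliant" else "NON-COMPLIANT",
      ")\n", sep = "")
  cat("  ndl sum ", signif(x$ndl_sum_ww, digits), " ng/g w.w. (",
      signif(100 * x$ndl_fraction_of_limit, digits), "% of limit, ",
      if (x$compliant_ndl) "compliant" else "NON-COMPLIANT", ")\n", sep = "")
  invisible(x)
}

#' Growth model for infant body weight
#'
#' Piecewise-linear monthly weight gain from birth weight: `gain_0_6`
#' kg/month for the first six months, `gain_after` thereafter; months are
#' `month_length_days`-day ramps (default 30, so 30 days after birth adds
#' exactly one month's gain). `mode = "none"` holds weight constant.
#'
#' @param mode `"linear"` or `"none"`.
#' @param gain_0_6,gain_after kg/month, >= 0.
#' @param month_length_days days per growth month.
#' @return Object of class `growth_model`.
#' @export
growth_model <- function(mode = c("linear", "none"), gain_0_6 = 0.6,
                         gain_after = 0.4, month_length_days = 30) {
  mode <- match.arg(mode)
  if (gain_0_6 < 0 || gain_after < 0) stop("gains must be >= 0", call. = FALSE)
  structure(list(mode = mode, gain_0_6 = gain_0_6, gain_after = gain_after,
                 month_length_days = month_length_days),
            class = "growth_model")
}

#' Infant body weight at a lactation stage
#'
#' @param stage_days days postpartum (>= 0).
#' @param birth_weight_kg birth weight, within the [infant_profile()]
#'   bounds.
#' @param growth a [growth_model()].
#' @return Body weight in kg.
#' @export
#' @examples
#' infant_weight_at(30, 3.0)  # 3.6 under the default 0.6 kg/month ramp
infant_weight_at <- function(stage_days, birth_weight_kg,
                             growth = growth_model()) {
  if (any(stage_days < 0)) stop("stage_days must be >= 0", call. = FALSE)
  if (any(birth_weight_kg < 1.5 | birth_weight_kg > 6)) {
    stop("birth_weight_kg outside plausibility bounds [1.5, 6]", call. = FALSE)
  }
  if (growth$mode == "none") return(birth_weight_kg + 0 * stage_days)
  months <- stage_days / growth$month_length_days
  birth_weight_kg + growth$gain_0_6 * pmin(months, 6) +
    growth$gain_after * pmax(months - 6, 0)
}
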