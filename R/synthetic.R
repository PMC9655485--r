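# Seeded generator of mother/infant/milk cohorts with the statistical
# structure the analysis assumes: log-normal lipid-basis concentrations
# with exponential stage decline, between-mother variation, multiplicative
# covariate effects (fish consumption, smoking, urban residence),
# stage-trending composition, and censoring near the LOD. The embedded
# truth (the config) supports parameter-recovery tests.

#' Marginal distributions of the questionnaire covariates
#'
#' Sampling probabilities for each categorical covariate, matching the
#' cohort margins: 62.5% male infants, 75% never-smokers, 83.3% urban
#' residence, 62.5% primiparous, and near-universal fish consumption.
#'
#' @return Named list; each element is a named probability vector over the
#'   corresponding codebook.
#' @export
covariate_marginals <- function() {
  list(
    age_band = c("<18" = 0.042, "18-22" = 0, "23-27" = 0.25,
                 "28-32" = 0.375, "33-36" = 0.333),
    weight_before_band = c("<55" = 0.25, "56-60" = 0.125,
                           "61-65" = 0.208, ">65" = 0.417),
    weight_after_band = c("55-60" = 0.208, "61-65" = 0.208,
                          "66-70" = 0.25, ">70" = 0.334),
    residence = c(city_gt_5000 = 0.833, town_lt_5000 = 0.042, country = 0.125),
    education = c(primary = 0.042, secondary = 0, higher = 0.958),
    parity = c(`1` = 0.625, `2` = 0.25, `3` = 0.125),
    delivery = c(natural = 0.5, c_section = 0.5),
    smoking = c(never = 0.75, quit_before_pregnancy = 0.167,
                up_to_one_pack = 0.042, more_than_one_pack = 0.042),
    sex = c(male = 0.625, female = 0.375),
    birth_weight_band = c("2.4-2.8" = 0.042, "2.9-3.2" = 0.458,
                          "3.3-3.6" = 0.458, "3.7-4.0" = 0, ">4.0" = 0.042),
    fish = c(never = 0.041, rarely = 0.3, weekly = 0.4,
             twice_weekly_plus = 0.2, daily = 0.059),
    dairy = c(never = 0.02, rarely = 0.08, weekly = 0.2,
              twice_weekly_plus = 0.3, daily = 0.4),
    poultry = c(never = 0.02, rarely = 0.08, weekly = 0.2,
                twice_weekly_plus = 0.7, daily = 0),
    beef = c(never = 0.1, rarely = 0.35, weekly = 0.35,
             twice_weekly_plus = 0.15, daily = 0.05),
    pork = c(never = 0.1, rarely = 0.3, weekly = 0.35,
             twice_weekly_plus = 0.2, daily = 0.05),
    eggs = c(never = 0.02, rarely = 0.18, weekly = 0.35,
             twice_weekly_plus = 0.3, daily = 0.15),
    vegetables = c(never = 0, rarely = 0.05, weekly = 0.05,
                   twice_weekly_plus = 0.1, daily = 0.8),
    fruit = c(never = 0, rarely = 0.05, weekly = 0.1,
              twice_weekly_plus = 0.15, daily = 0.7),
    whole_grains = c(never = 0.1, rarely = 0.5, weekly = 0.25,
                     twice_weekly_plus = 0.108, daily = 0.042)
  )
}

# default day-7 lipid-basis geometric means (ng/g lipid); group sums match
# the day-7 stage table: ndl ~20, non-ortho ~3.8, mono-ortho ~14.9
.default_baselines <- function() {
  c(`28` = 2.5, `52` = 2.0, `101` = 1.5, `138` = 5.0, `153` = 6.0, `180` = 3.0,
    `77` = 0.5, `81` = 0.3, `126` = 1.0, `169` = 2.0,
    `105` = 3.0, `114` = 0.7, `118` = 7.0, `123` = 0.5,
    `156` = 1.5, `157` = 1.0, `167` = 0.8, `189` = 0.35)
}

# target pooled log-scale correlations with lactation day; ndl values from
# the reported trend range (-0.448 for 52 ... -0.280 for 153, ~none for
# 101), dl values within the reported -0.533..-0.19 span with 169 declining
# fastest among the non-ortho group
.default_trend_targets <- function() {
  c(`28` = -0.35, `52` = -0.448, `101` = -0.10, `138` = -0.33,
    `153` = -0.280, `180` = -0.30,
    `77` = -0.35, `81` = -0.30, `126` = -0.40, `169` = -0.533,
    `105` = -0.40, `114` = -0.35, `118` = -0.30, `123` = -0.25,
    `156` = -0.35, `157` = -0.30, `167` = -0.25, `189` = -0.19)
}

# qualitative covariate findings encoded as log-scale coefficients per unit
# of the numeric covariate code: fish raises 77/81/118/189, smoking raises
# 156/118/189, urban residence raises 123/167
.default_covariate_effects <- function() {
  data.frame(
    covariate = c("fish", "fish", "fish", "fish",
                  "smoking", "smoking", "smoking",
                  "city", "city"),
    congener = c(77L, 81L, 118L, 189L, 156L, 118L, 189L, 123L, 167L),
    beta = c(0.35, 0.35, 0.35, 0.35, 0.30, 0.30, 0.30, 0.40, 0.40)
  )
}

.marginal_code_var <- function(marginals, covariate) {
  switch(covariate,
         fish = , smoking = {
           p <- marginals[[covariate]]
           codes <- seq_along(p) - 1
           sum(p * codes^2) - sum(p * codes)^2
         },
         city = {
           p <- marginals$residence[["city_gt_5000"]]
           p * (1 - p)
         },
         stop("unknown effect covariate: ", covariate, call. = FALSE))
}

.marginal_code_mean <- function(marginals, covariate) {
  switch(covariate,
         fish = , smoking = {
           p <- marginals[[covariate]]
           sum(p * (seq_along(p) - 1))
         },
         city = marginals$residence[["city_gt_5000"]])
}

# per-stage effective draw day and number of averaged aliquots: weekly
# stages are single collections; monthly stages pool four weekly aliquots
# drawn over the preceding three weeks
.stage_design <- function(schedule) {
  k <- length(schedule$labels)
  draws <- c(rep(1L, 5), rep(4L, k - 5))
  d <- schedule$rep_days
  eff <- ifelse(draws == 4, d - 10.5, d)
  data.frame(stage_label = schedule$labels, rep_day = d,
             n_draws = draws, eff_day = eff)
}

#' Synthetic cohort generator configuration
#'
#' The stated world of the generator: `n_mothers` mothers each sampled at
#' the 17-stage schedule; lipid-basis log-concentration =
#' log(baseline) + decline x day + covariate effects + mother effect +
#' noise; wet-weight value = lipid value x lipid fraction; censoring at a
#' configurable wet-weight LOD. Default decline slopes are derived from
#' `trend_targets` (the pooled log-scale day correlations the cohort should
#' exhibit) via the closed form in [implied_trend_r()].
#'
#' @param n_mothers cohort size (default 96).
#' @param schedule a [stage_schedule()].
#' @param baseline named day-7 lipid-basis geometric means, ng/g lipid.
#' @param trend_targets named target correlations (negative); used to derive
#'   `decline` when the latter is `NULL`.
#' @param decline named per-day log-scale slopes; overrides
#'   `trend_targets` when supplied.
#' @param mother_sd between-mother log-scale SD.
#' @param noise_sd within-sample (per aliquot) log-scale SD.
#' @param covariate_effects data frame `covariate` (`"fish"`, `"smoking"`,
#'   `"city"`), `congener`, `beta` (log-scale per unit code).
#' @param censor_at_lod flag values below the LOD/LOQ.
#' @param lod_ww_pg_per_g wet-weight LOD in pg/g (default 0.1 pg/g =
#'   0.1 ng/kg); LOQ = LOD x 10/3.3.
#' @param dropout_prob per-(mother, stage) probability of a missing sample.
#' @param marginals covariate sampling marginals ([covariate_marginals()]).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_mothers = 96, schedule = stage_schedule(),
                             baseline = .default_baselines(),
                             trend_targets = .default_trend_targets(),
                             decline = NULL,
                             mother_sd = 0.30, noise_sd = 0.35,
                             covariate_effects = .default_covariate_effects(),
                             censor_at_lod = TRUE, lod_ww_pg_per_g = 0.1,
                             dropout_prob = 0,
                             marginals = covariate_marginals()) {
  stopifnot(n_mothers >= 1, all(baseline > 0), mother_sd >= 0, noise_sd >= 0,
            dropout_prob >= 0, dropout_prob < 1)
  if (!all(names(trend_targets) %in% names(baseline))) {
    stop("trend_targets must cover a subset of baseline congeners", call. = FALSE)
  }
  if (nrow(covariate_effects)) {
    congener_group(covariate_effects$congener)
    for (cv in unique(covariate_effects$covariate)) .marginal_code_var(marginals, cv)
  }
  cfg <- structure(list(n_mothers = n_mothers, schedule = schedule,
                        baseline = baseline, trend_targets = trend_targets,
                        decline = decline, mother_sd = mother_sd,
                        noise_sd = noise_sd,
                        covariate_effects = covariate_effects,
                        censor_at_lod = censor_at_lod,
                        lod_ww_pg_per_g = lod_ww_pg_per_g,
                        dropout_prob = dropout_prob,
                        marginals = marginals),
                   class = "generator_config")
  if (is.null(decline)) cfg$decline <- .slopes_for_targets(cfg)
  if (any(cfg$decline > 0)) {
    stop("decline slopes must be <= 0", call. = FALSE)
  }
  cfg
}

# residual (non-day) log-scale variance of one congener: between-mother +
# average per-sample noise (aliquot averaging shrinks it) + covariate spread
.residual_var <- function(cfg, congener) {
  des <- .stage_design(cfg$schedule)
  noise_mean <- mean(cfg$noise_sd^2 / des$n_draws)
  eff <- cfg$covariate_effects
  eff <- eff[eff$congener == as.integer(congener), , drop = FALSE]
  cov_var <- 0
  if (nrow(eff)) {
    cov_var <- sum(vapply(seq_len(nrow(eff)), function(i) {
      eff$beta[i]^2 * .marginal_code_var(cfg$marginals, eff$covariate[i])
    }, 0))
  }
  cfg$mother_sd^2 + noise_mean + cov_var
}

# invert the implied-r closed form: slope = r/sqrt(1-r^2) * sigma/sd(day)
.slopes_for_targets <- function(cfg) {
  des <- .stage_design(cfg$schedule)
  sd_day <- stats::sd(des$eff_day) * sqrt((nrow(des) - 1) / nrow(des))
  vapply(names(cfg$trend_targets), function(cg) {
    r <- cfg$trend_targets[[cg]]
    sigma <- sqrt(.residual_var(cfg, cg))
    r / sqrt(1 - r^2) * sigma / sd_day
  }, 0)
}

#' Closed-form lactation-trend correlation implied by a generator config
#'
#' The pooled Pearson correlation between collection day and log
#' lipid-basis concentration implied by the generative model:
#' r = slope x sd(day) / sqrt(slope^2 var(day) + sigma^2), where sigma^2
#' collects between-mother variance, the average per-sample noise variance
#' (aliquot averaging included via the delta method), and the variance
#' contributed by covariate effects. Days enter through the per-stage
#' effective draw days of the complete schedule.
#'
#' @param config a [generator_config()].
#' @param congener IUPAC number(s); default all configured congeners.
#' @return Named numeric vector of implied correlations.
#' @export
implied_trend_r <- function(config, congener = names(config$decline)) {
  des <- .stage_design(config$schedule)
  v_day <- stats::var(des$eff_day) * (nrow(des) - 1) / nrow(des)
  vapply(as.character(congener), function(cg) {
    s <- config$decline[[cg]]
    sigma2 <- .residual_var(config, cg)
    s * sqrt(v_day) / sqrt(s^2 * v_day + sigma2)
  }, 0)
}

.sample_code <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic cohort
#'
#' @param config a [generator_config()].
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @return Object of class `synthetic_dataset`: `mothers`, `infants`,
#'   `samples` (list of [milk_sample()]), and `truth` (the config).
#' @export
#' @examples
#' ds <- generate(generator_config(n_mothers = 4), seed = 1)
#' length(ds$samples)
generate <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  mg <- config$marginals
  n <- config$n_mothers
  ids <- sprintf("M%03d", seq_len(n))

  foods <- codebooks()$food
  ff <- vapply(foods, function(f) .sample_code(n, mg[[f]]), character(n))
  if (n == 1) ff <- matrix(ff, nrow = 1, dimnames = list(NULL, foods))
  mothers <- lapply(seq_len(n), function(i) {
    maternal_profile(ids[i],
                     .sample_code(1, mg$age_band),
                     .sample_code(1, mg$weight_before_band),
                     .sample_code(1, mg$weight_after_band),
                     .sample_code(1, mg$residence),
                     .sample_code(1, mg$education),
                     as.integer(.sample_code(1, mg$parity)),
                     .sample_code(1, mg$delivery),
                     .sample_code(1, mg$smoking),
                     food_frequency = stats::setNames(ff[i, ], foods))
  })
  bands <- vapply(seq_len(n), function(i) .sample_code(1, mg$birth_weight_band), "")
  bw_range <- list("2.4-2.8" = c(2.4, 2.8), "2.9-3.2" = c(2.9, 3.2),
                   "3.3-3.6" = c(3.3, 3.6), "3.7-4.0" = c(3.7, 4.0),
                   ">4.0" = c(4.0, 4.4))
  infants <- lapply(seq_len(n), function(i) {
    rg <- bw_range[[bands[i]]]
    infant_profile(ids[i], .sample_code(1, mg$sex),
                   stats::runif(1, rg[1], rg[2]))
  })

  # numeric covariate codes feeding the concentration model
  code <- data.frame(
    fish = frequency_code(ff[, "fish"]),
    smoking = match(vapply(mothers, `[[`, "", "smoking"),
                    codebooks()$smoking) - 1L,
    city = as.integer(vapply(mothers, `[[`, "", "residence") == "city_gt_5000")
  )

  des <- .stage_design(config$schedule)
  congeners <- as.integer(names(config$baseline))
  u <- matrix(stats::rnorm(n * length(congeners), 0, config$mother_sd),
              n, length(congeners))  # mother-level congener effects

  eff <- config$covariate_effects
  cov_shift <- matrix(0, n, length(congeners))
  if (nrow(eff)) {
    for (i in seq_len(nrow(eff))) {
      j <- match(eff$congener[i], congeners)
      cv <- eff$covariate[i]
      centred <- code[[cv]] - .marginal_code_mean(config$marginals, cv)
      cov_shift[, j] <- cov_shift[, j] + eff$beta[i] * centred
    }
  }

  loq_pg <- config$lod_ww_pg_per_g * 10 / 3.3
  samples <- list()
  for (i in seq_len(n)) {
    keep <- stats::runif(nrow(des)) >= config$dropout_prob
    for (k in which(keep)) {
      d <- des$rep_day[k]
      nd <- des$n_draws[k]
      draw_days <- if (nd == 1) d else d - c(21, 14, 7, 0)
      # composition at the collection day
      lipid <- max(0.8, min(8, 4.6 - 0.00567 * (d - 7) + stats::rnorm(1, 0, 0.6)))
      protein <- max(0.3, min(3, 1.49 - 0.00165 * (d - 7) + stats::rnorm(1, 0, 0.1)))
      lactose <- max(3, min(9, 7.0 - 0.0005 * (d - 7) + stats::rnorm(1, 0, 0.45)))
      dry <- lipid + protein + lactose + max(0.05, 0.25 + stats::rnorm(1, 0, 0.1))
      comp <- milk_composition(lipid, dry, protein, lactose)

      # lipid-basis concentration: average the aliquot draws
      conc_lip <- vapply(seq_along(congeners), function(j) {
        cg <- as.character(congeners[j])
        mu <- log(config$baseline[[cg]]) + config$decline[[cg]] * draw_days +
          u[i, j] + cov_shift[i, j]
        mean(exp(mu + stats::rnorm(nd, 0, config$noise_sd)))
      }, 0)  # ng/g lipid
      conc_ww_pg <- conc_lip * 1000 * lipid / 100  # pg/g wet weight

      censor <- rep("detected", length(congeners))
      if (config$censor_at_lod) {
        censor[conc_ww_pg < loq_pg] <- "below_loq"
        censor[conc_ww_pg < config$lod_ww_pg_per_g] <- "below_lod"
      }
      meas <- data.frame(congener = congeners, value = conc_ww_pg,
                         basis = "wet_weight", units_in = "pg_per_g",
                         censor = censor,
                         lod = config$lod_ww_pg_per_g, loq = loq_pg)
      sid <- sprintf("%s_S%02d", ids[i], k)
      samples[[sid]] <- milk_sample(sid, ids[i], d, comp, meas,
                                    schedule = config$schedule)
    }
  }
  structure(list(mothers = mothers, infants = infants,
                 samples = unname(samples), truth = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic cohort:", length(x$mothers), "mothers,",
      length(x$samples), "milk samples,",
      length(x$truth$baseline), "congeners\n")
  invisible(x)
}

#' Per-sample covariate frame for ordination
#'
#' Expands mother-level covariates to one row per milk sample: collection
#' day, numeric fish and smoking codes, urban-residence dummy, parity, and
#' infant birth weight.
#'
#' @param dataset a [generate()] result.
#' @return Data frame aligned with `dataset$samples`.
#' @export
covariate_frame <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  mid <- vapply(dataset$samples, `[[`, "", "mother_id")
  mothers <- stats::setNames(dataset$mothers,
                             vapply(dataset$mothers, `[[`, "", "mother_id"))
  infants <- stats::setNames(dataset$infants,
                             vapply(dataset$infants, `[[`, "", "mother_id"))
  data.frame(
    sample_id = vapply(dataset$samples, `[[`, "", "sample_id"),
    days = vapply(dataset$samples, `[[`, 0, "stage_days"),
    fish = vapply(mid, function(m) frequency_code(mothers[[m]]$food_frequency[["fish"]]), 0L),
    smoking = vapply(mid, function(m) match(mothers[[m]]$smoking, codebooks()$smoking) - 1L, 0L),
    city = vapply(mid, function(m) as.integer(mothers[[m]]$residence == "city_gt_5000"), 0L),
    parity = vapply(mid, function(m) mothers[[m]]$parity, 0L),
    birth_weight_kg = vapply(mid, function(m) infants[[m]]$birth_weight_kg, 0),
    row.names = NULL
  )
}

#' Printed stage-summary fixture
#'
#' The 17 published per-stage rows (n, mean, SD, CV; ng/g lipid) for the
#' three regulatory group sums, packaged for reproduction tests: the
#' grand ("average content") row recomputes from these means as
#' 13.78 +/- 4.76 (ndl), 1.55 +/- 0.98 (non-ortho) and 5.89 +/- 4.09
#' (mono-ortho).
#'
#' @return Data frame `stage_label`, `n`, `group`, `mean`, `sd`, `cv`
#'   (17 rows per group).
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_stage_summaries.csv",
                      package = "milkteq", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}
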