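test_that("generation is fully deterministic under a seed", {
  cfg <- generator_config(n_mothers = 4)
  a <- generate(cfg, seed = 123)
  b <- generate(cfg, seed = 123)
  expect_identical(a$samples, b$samples)
  expect_identical(a$mothers, b$mothers)
  expect_identical(a$infants, b$infants)
  c_ <- generate(cfg, seed = 124)
  expect_false(identical(a$samples, c_$samples))
})

test_that("zero slopes and zero noise give stage-constant congeners", {
  base_ <- milkteq:::.default_baselines()
  cfg <- generator_config(
    n_mothers = 3,
    decline = stats::setNames(rep(0, length(base_)), names(base_)),
    noise_sd = 0, censor_at_lod = FALSE)
  ds <- generate(cfg, seed = 2)
  Y <- sample_matrix(ds$samples, basis = "lipid", log = FALSE)
  mid <- vapply(ds$samples, `[[`, "", "mother_id")
  for (m in unique(mid)) {
    block <- Y[mid == m, , drop = FALSE]
    expect_equal(apply(block, 2, stats::sd), rep(0, ncol(block)),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  # mother effects still differ between mothers
  expect_gt(stats::sd(Y[, "pcb_153"]), 0)
})

test_that("wet-weight and lipid-basis values are consistent by construction", {
  ds <- generate(generator_config(n_mothers = 3), seed = 5)
  for (s in ds$samples[c(1, 20, 40)]) {
    ww <- milkteq:::.concentrations_on(s, ndl_congeners(), "lower", "wet_weight")
    lp <- milkteq:::.concentrations_on(s, ndl_congeners(), "lower", "lipid")
    expect_equal(convert_basis(ww, "wet_weight", "lipid",
                               s$composition$lipid_pct),
                 lp, tolerance = 1e-12)
  }
})

test_that("censoring fraction grows monotonically with the LOD", {
  frac <- vapply(c(0.1, 50, 500, 5000), function(lod) {
    ds <- generate(generator_config(n_mothers = 5, lod_ww_pg_per_g = lod),
                   seed = 77)
    cens <- unlist(lapply(ds$samples,
                          function(s) s$measurements$censor != "detected"))
    mean(cens)
  }, 0)
  expect_true(all(diff(frac) >= 0))
  expect_lt(frac[1], 0.05)
  expect_gt(frac[4], 0.5)
})

test_that("dropout thins the per-mother panels", {
  cfg <- generator_config(n_mothers = 10, dropout_prob = 0.4)
  ds <- generate(cfg, seed = 6)
  expect_lt(length(ds$samples), 10 * 17)
  full <- generate(generator_config(n_mothers = 10), seed = 6)
  expect_equal(length(full$samples), 170)
})

test_that("implied trend correlations follow the closed form", {
  cfg <- generator_config()
  # defaults are parameterised by the targets, so the closed form returns them
  imp <- implied_trend_r(cfg, names(cfg$trend_targets))
  expect_equal(imp, cfg$trend_targets, tolerance = 1e-10)
  # doubling the noise attenuates every implied correlation
  noisy <- generator_config(noise_sd = 0.7, decline = cfg$decline)
  expect_true(all(abs(implied_trend_r(noisy)) < abs(imp)))
  expect_true(all(implied_trend_r(noisy) < 0))
})

test_that("cohort margins match the configured marginals", {
  ds <- generate(generator_config(n_mothers = 400), seed = 9)
  smoking <- vapply(ds$mothers, `[[`, "", "smoking")
  expect_equal(mean(smoking == "never"), 0.75, tolerance = 0.08)
  sex <- vapply(ds$infants, `[[`, "", "sex")
  expect_equal(mean(sex == "male"), 0.625, tolerance = 0.08)
  res <- vapply(ds$mothers, `[[`, "", "residence")
  expect_equal(mean(res == "city_gt_5000"), 0.833, tolerance = 0.08)
  p <- covariate_marginals()
  expect_true(all(abs(vapply(p, sum, 0) - 1) < 0.011))
})

test_that("covariate_frame aligns sample rows with mother covariates", {
  ds <- generate(generator_config(n_mothers = 4), seed = 10)
  cf <- covariate_frame(ds)
  expect_equal(nrow(cf), length(ds$samples))
  i <- 30
  s <- ds$samples[[i]]
  m <- Filter(function(m) m$mother_id == s$mother_id, ds$mothers)[[1]]
  expect_equal(cf$days[i], s$stage_days)
  expect_equal(cf$fish[i], frequency_code(m$food_frequency[["fish"]]))
  expect_equal(cf$city[i], as.integer(m$residence == "city_gt_5000"))
})

test_that("the printed stage-summary fixture is intact", {
  f <- table2_fixture()
  expect_equal(nrow(f), 51)
  expect_equal(unname(table(f$group)), rep(17L, 3), ignore_attr = TRUE)
  r7 <- f[f$stage_label == "7 days" & f$group == "ndl_indicator", ]
  expect_equal(r7$n, 26)
  expect_equal(r7$mean, 19.83)
  expect_equal(r7$sd, 1.26)
  expect_equal(r7$cv, 6.35)
  expect_equal(f$mean[f$stage_label == ">1 year of feeding" &
                        f$group == "ndl_indicator"], 0.343)
  # stage labels match the schedule
  expect_setequal(unique(f$stage_label), stage_labels())
})
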