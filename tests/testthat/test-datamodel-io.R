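test_that("congener registry has the three disjoint groups", {
  reg <- congener_registry()
  expect_setequal(reg$congener[reg$group == "non_ortho"], c(77, 81, 126, 169))
  expect_setequal(reg$congener[reg$group == "mono_ortho"],
                  c(105, 114, 118, 123, 156, 157, 167, 189))
  expect_setequal(reg$congener[reg$group == "ndl_indicator"],
                  c(28, 52, 101, 138, 153, 180))
  expect_false(anyDuplicated(reg$congener) > 0)
  expect_error(congener_group(135), "unknown congener")
})

test_that("stage_label_for maps the schedule correctly", {
  expect_equal(stage_label_for(7), "7 days")
  expect_equal(stage_label_for(1), "<7 days")
  expect_equal(stage_label_for(400), ">1 year of feeding")
  expect_equal(stage_label_for(c(6, 13, 28, 60, 61)),
               c("<7 days", "7 days", "28 days", "28 days", "2 months"))
  expect_error(stage_label_for(0), "must be >= 1")
  expect_error(stage_label_for(-3), "must be >= 1")
})

test_that("stage_label_for is monotone and surjective over [1, 450]", {
  labs <- stage_label_for(1:450)
  idx <- match(labs, stage_labels())
  expect_true(all(diff(idx) >= 0))
  expect_setequal(unique(labs), stage_labels())
  expect_length(stage_labels(), 17)
})

test_that("milk_composition enforces the dry-matter balance", {
  expect_s3_class(milk_composition(4.6, 12.9, 1.49, 6.5), "milk_composition")
  expect_error(milk_composition(8, 10, 2, 6), "exceeds dry matter")
  expect_error(milk_composition(-1, 12, 1, 6), "\\[0, 100\\]")
  expect_error(milk_composition(4, 120, 1, 6), "\\[0, 100\\]")
})

test_that("measurement validation catches bad rows", {
  expect_error(congener_measurement(126, -0.1, units = "pg_per_g"),
               "negative concentration")
  expect_error(congener_measurement(126, NA, censor = "below_lod"),
               "lacks its LOD")
  m <- congener_measurement(126, 5, censor = "below_lod", lod = 0.1,
                            units = "pg_per_g")
  expect_equal(m$value, 0.1)  # censored value stores the limit
  expect_error(
    congener_measurement(126, 1, lod = 0.5, loq = 0.1, units = "pg_per_g"),
    "loq >= lod")
})

test_that("milk_sample enforces uniqueness and label consistency", {
  meas <- rbind(congener_measurement(126, 1, units = "pg_per_g"),
                congener_measurement(126, 2, units = "pg_per_g"))
  expect_error(milk_sample("s", "m", 7, default_comp(), meas),
               "duplicate congener")
  expect_error(
    milk_sample("s", "m", 7, default_comp(),
                congener_measurement(126, 1, units = "pg_per_g"),
                stage_label = "14 days"),
    "inconsistent")
  s <- make_sample(`126` = 1, `153` = 3, `28` = 2)
  expect_equal(nrow(s$measurements), 3)
  expect_equal(s$stage_label, "7 days")
})

test_that("concentrations are normalised to pg/g on ingestion", {
  m <- congener_measurement(153, 0.5, units = "ng_per_g")
  expect_equal(m$value, 500)
  expect_equal(m$units_in, "ng_per_g")
  m2 <- congener_measurement(153, 500, units = "pg_per_g")
  expect_equal(m$value, m2$value)
})

test_that("long CSV read parses samples and reports schema errors", {
  csv <- file.path(tempdir(), "long.csv")
  writeLines(c(
    "sample_id,mother_id,stage_days,lipid_pct,dry_matter_pct,protein_pct,lactose_pct,congener,value,basis,units,censor,lod,loq",
    "a,m1,7,4,12,1.2,6,126,1.0,wet_weight,pg_per_g,detected,,",
    "a,m1,7,4,12,1.2,6,153,3.0,wet_weight,pg_per_g,detected,,",
    "a,m1,7,4,12,1.2,6,28,2.0,wet_weight,pg_per_g,detected,,"), csv)
  s <- suppressMessages(read_samples(csv))
  expect_length(s, 1)
  expect_equal(nrow(s[[1]]$measurements), 3)
  expect_setequal(s[[1]]$measurements$congener, c(126, 153, 28))

  writeLines(c("sample_id,congener,value", "a,126,1"), csv)
  expect_error(suppressMessages(read_samples(csv)), "required column")

  writeLines(c(
    "sample_id,mother_id,stage_days,lipid_pct,dry_matter_pct,protein_pct,lactose_pct,congener,value",
    "bad,m1,7,4,12,1.2,6,126,-0.1"), csv)
  expect_error(suppressMessages(read_samples(csv)), "bad")
  expect_warning(
    expect_length(suppressMessages(read_samples(csv, strict = FALSE)), 0),
    "rejected")
})

test_that("wide layout is accepted via the dialect", {
  csv <- file.path(tempdir(), "wide.csv")
  writeLines(c(
    "sample_id,mother_id,stage_days,lipid_pct,dry_matter_pct,protein_pct,lactose_pct,pcb_126,pcb_153",
    "w1,m1,14,4,12,1.2,6,0.8,2.5"), csv)
  s <- suppressMessages(
    read_samples(csv, sample_dialect("wide", basis = "wet_weight",
                                     units = "pg_per_g")))
  expect_length(s, 1)
  expect_setequal(s[[1]]$measurements$congener, c(126, 153))
  expect_equal(sort(s[[1]]$measurements$value), c(0.8, 2.5))
})

test_that("write/read round trip is lossless on generated fixtures", {
  ds <- generate(generator_config(n_mothers = 3), seed = 42)
  csv <- file.path(tempdir(), "rt.csv")
  write_samples(ds$samples, csv)
  back <- suppressMessages(read_samples(csv))
  expect_length(back, length(ds$samples))
  for (i in seq_along(back)) {
    a <- ds$samples[[i]]; b <- back[[i]]
    expect_identical(a$sample_id, b$sample_id)
    expect_identical(a$mother_id, b$mother_id)
    expect_identical(a$stage_days, b$stage_days)
    expect_identical(a$stage_label, b$stage_label)
    expect_identical(unclass(a$composition), unclass(b$composition))
    expect_identical(a$measurements$value, b$measurements$value)
    expect_identical(a$measurements$censor, b$measurements$censor)
    expect_identical(a$measurements$lod, b$measurements$lod)
    expect_identical(a$measurements$loq, b$measurements$loq)
  }
})

test_that("covariate table round trips through CSV", {
  ds <- generate(generator_config(n_mothers = 4), seed = 7)
  csv <- file.path(tempdir(), "cov.csv")
  write_covariates(ds$mothers, ds$infants, csv)
  back <- suppressMessages(read_covariates(csv))
  expect_length(back$mothers, 4)
  expect_identical(back$mothers[[2]]$smoking, ds$mothers[[2]]$smoking)
  expect_identical(back$mothers[[3]]$food_frequency[["fish"]],
                   ds$mothers[[3]]$food_frequency[["fish"]])
  expect_equal(back$infants[[1]]$birth_weight_kg,
               ds$infants[[1]]$birth_weight_kg)
})

test_that("profiles validate against the codebooks", {
  expect_error(maternal_profile("m", "40+", "<55", "55-60", "city_gt_5000",
                                "higher", 1, "natural", "never"),
               "age_band")
  expect_error(infant_profile("m", "male", 7), "plausibility")
  expect_error(infant_profile("m", "other", 3), "sex")
  p <- maternal_profile("m", "28-32", "<55", "55-60", "country", "higher",
                        2, "c_section", "never",
                        food_frequency = c(fish = "weekly"))
  expect_s3_class(p, "maternal_profile")
  expect_equal(frequency_code(c("never", "daily", "weekly")), c(0L, 4L, 2L))
})
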