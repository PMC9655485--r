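test_that("convert_basis follows the lipid-fraction rule", {
  expect_equal(convert_basis(0.5, "wet_weight", "lipid", 4), 12.5)
  expect_equal(convert_basis(3.7, "wet_weight", "wet_weight"), 3.7)
  x <- c(0.2, 1.7, 9.4)
  round_trip <- convert_basis(convert_basis(x, "wet_weight", "lipid", 3.3),
                              "lipid", "wet_weight", 3.3)
  expect_equal(round_trip, x, tolerance = 1e-12)
  expect_error(convert_basis(1, "wet_weight", "lipid", 0), "degenerate")
  expect_error(convert_basis(-1, "wet_weight", "lipid", 4), ">= 0")
})

test_that("substitute_censored implements the three bounds", {
  m <- rbind(
    congener_measurement(126, NA, censor = "below_lod", lod = 0.1,
                         units = "pg_per_g"),
    congener_measurement(153, NA, censor = "below_loq", lod = 0.1, loq = 0.3,
                         units = "pg_per_g"),
    congener_measurement(28, 3.2, units = "pg_per_g"))
  expect_equal(substitute_censored(m, "upper"), c(0.1, 0.3, 3.2))
  expect_equal(substitute_censored(m, "lower"), c(0, 0, 3.2))
  expect_equal(substitute_censored(m, "middle"), c(0.05, 0.15, 3.2))
  bad <- m
  bad$lod[1] <- NA
  expect_error(substitute_censored(bad, "upper"), "lacks its limit")
})

test_that("compute_teq reproduces hand-weighted sums", {
  s <- make_sample(`126` = 1)
  expect_equal(compute_teq(s, bound = "lower")$teq, 0.1)
  s2 <- make_sample(`77` = 10, `126` = 2)
  r <- compute_teq(s2, bound = "lower")
  expect_equal(r$teq, 10 * 1e-4 + 2 * 0.1)
  expect_equal(sum(r$per_congener), r$teq)
  s0 <- make_sample(`126` = 0, `77` = 0)
  expect_equal(compute_teq(s0, bound = "lower")$teq, 0)
})

test_that("single-congener unit samples return the TEF exactly", {
  scheme <- tef_scheme()
  for (cg in dl_congeners()) {
    s <- make_sample(stats::setNames(1, cg))
    expect_identical(compute_teq(s, scheme, bound = "lower")$teq,
                     unname(scheme$tef[as.character(cg)]))
  }
})

test_that("TEQ is homogeneous and commutes with basis conversion", {
  withr::with_seed(11, {
    vals <- stats::setNames(stats::runif(12, 0, 10), dl_congeners())
    s1 <- make_sample(vals, lipid = 3.2)
    s2 <- make_sample(vals * 4.5, lipid = 3.2)
    expect_equal(compute_teq(s2, bound = "lower")$teq,
                 4.5 * compute_teq(s1, bound = "lower")$teq)
    # converting the result equals computing on the other basis
    t_wet <- compute_teq(s1, bound = "lower", basis = "wet_weight")$teq
    t_lip <- compute_teq(s1, bound = "lower", basis = "lipid")$teq
    expect_equal(convert_basis(t_wet, "wet_weight", "lipid", 3.2), t_lip)
  })
})

test_that("absent congeners warn except under the lower bound", {
  s <- make_sample(`126` = 1)
  expect_warning(compute_teq(s, bound = "upper"), "not reported")
  expect_silent(r <- compute_teq(s, bound = "lower"))
  expect_equal(sum(r$per_congener != 0), 1)
  expect_error(tef_scheme(tef = c(`153` = 0.1)), "no TEF")
  expect_error(tef_scheme(tef = c(`126` = 0.1)), "missing")
})

test_that("sum_group is linear and counts each congener once", {
  six <- stats::setNames(rep(1000, 6), ndl_congeners())  # 1 ng/g each, pg/g
  s <- make_sample(six, basis = "lipid")
  expect_equal(sum_group(s, "ndl_indicator", basis = "lipid"), 6)
  a <- make_sample(`28` = 100, `52` = 200)
  b <- make_sample(`28` = 300, `52` = 50)
  merged <- make_sample(`28` = 400, `52` = 250)
  expect_equal(
    sum_group(merged, "ndl_indicator", bound = "lower", basis = "wet_weight"),
    sum_group(a, "ndl_indicator", bound = "lower", basis = "wet_weight") +
      sum_group(b, "ndl_indicator", bound = "lower", basis = "wet_weight"))
})

test_that("lower vs upper group sums differ by the censored limits", {
  lod <- c(`28` = 0.1, `52` = 0.25)
  meas <- rbind(
    congener_measurement(28, NA, censor = "below_lod", lod = lod[["28"]],
                         units = "pg_per_g"),
    congener_measurement(52, NA, censor = "below_lod", lod = lod[["52"]],
                         units = "pg_per_g"),
    congener_measurement(153, 4, units = "pg_per_g"))
  s <- milk_sample("c1", "m1", 7, default_comp(), meas)
  up <- suppressWarnings(
    sum_group(s, "ndl_indicator", bound = "upper", basis = "wet_weight",
              units = "pg_per_g"))
  lo <- sum_group(s, "ndl_indicator", bound = "lower", basis = "wet_weight",
                  units = "pg_per_g")
  expect_equal(up - lo, sum(lod))
})

test_that("bound ordering holds on random censored samples", {
  withr::with_seed(99, {
    for (i in 1:50) {
      s <- random_censored_sample(i)
      teqs <- vapply(c("lower", "middle", "upper"), function(b)
        compute_teq(s, bound = b)$teq, 0)
      expect_true(teqs[1] <= teqs[2] && teqs[2] <= teqs[3])
    }
  })
})
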