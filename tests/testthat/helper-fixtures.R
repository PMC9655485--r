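# In-code fixtures shared across the suite.

default_comp <- function(lipid = 4) {
  milk_composition(lipid, 12, 1.2, 6)
}

# one sample with measurements given as congener = value (pg/g) pairs
make_sample <- function(..., basis = "wet_weight", lipid = 4, stage_days = 7,
                        sample_id = "s1", mother_id = "m1") {
  vals <- c(...)
  meas <- do.call(rbind, lapply(names(vals), function(cg) {
    congener_measurement(as.integer(cg), vals[[cg]], basis = basis,
                         units = "pg_per_g")
  }))
  milk_sample(sample_id, mother_id, stage_days, default_comp(lipid), meas)
}

# a sample over all 18 registry congeners with random values and random
# censoring (value field carries the limit for censored rows)
random_censored_sample <- function(id) {
  congeners <- congener_registry()$congener
  n <- length(congeners)
  censor <- sample(c("detected", "below_loq", "below_lod"), n,
                   replace = TRUE, prob = c(0.6, 0.2, 0.2))
  lod <- stats::runif(n, 0.01, 0.2)
  meas <- data.frame(congener = congeners,
                     value = stats::runif(n, 0, 5),
                     basis = "wet_weight", units_in = "pg_per_g",
                     censor = censor, lod = lod, loq = lod * 10 / 3.3)
  milk_sample(paste0("rc", id), "m1", sample(1:400, 1), default_comp(), meas)
}
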