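# Domain types: milk composition, congener measurements, milk samples,
# maternal and infant profiles. Concentrations are normalised to pg/g at
# construction; the original units are retained in `units_in`.

.BASES <- c("wet_weight", "lipid")
.UNITS <- c("ng_per_g", "pg_per_g")
.CENSOR <- c("detected", "below_loq", "below_lod")

.to_pg <- function(value, units) {
  value * ifelse(units == "ng_per_g", 1000, 1)
}
.from_pg <- function(value, units) {
  value / ifelse(units == "ng_per_g", 1000, 1)
}

#' Milk composition of one sample
#'
#' Percentages of lipid, dry matter, protein and lactose in whole milk.
#' Lipid, protein and lactose are components of dry matter, so their sum
#' may not exceed the dry-matter percentage by more than `tol`.
#'
#' @param lipid_pct,dry_matter_pct,protein_pct,lactose_pct percentages in
#'   \[0, 100\].
#' @param tol slack (percentage points) allowed on the dry-matter balance.
#' @return An object of class `milk_composition`.
#' @export
#' @examples
#' milk_composition(4.6, 12.9, 1.49, 6.5)
milk_composition <- function(lipid_pct, dry_matter_pct, protein_pct,
                             lactose_pct, tol = 0.5) {
  vals <- c(lipid = lipid_pct, dry_matter = dry_matter_pct,
            protein = protein_pct, lactose = lactose_pct)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 100)) {
    stop("composition percentages must lie in [0, 100]", call. = FALSE)
  }
  if (lipid_pct + protein_pct + lactose_pct > dry_matter_pct + tol) {
    stop("lipid + protein + lactose (",
         round(lipid_pct + protein_pct + lactose_pct, 2),
         "%) exceeds dry matter (", round(dry_matter_pct, 2),
         "%) beyond tolerance", call. = FALSE)
  }
  structure(list(lipid_pct = lipid_pct, dry_matter_pct = dry_matter_pct,
                 protein_pct = protein_pct, lactose_pct = lactose_pct),
            class = "milk_composition")
}

#' A single congener concentration measurement
#'
#' One concentration value with its congener, basis (per gram whole milk or
#' per gram milk fat), censoring state and detection/quantification limits.
#' Values are stored in pg/g; `units_in` records the unit the value was
#' supplied in. For a censored measurement (`below_lod`, `below_loq`) the
#' `value` field stores the applicable limit, not a measurement.
#'
#' @param congener IUPAC number (must be in [congener_registry()]).
#' @param value concentration >= 0 in `units`; ignored (and replaced by the
#'   applicable limit) when `censor != "detected"`.
#' @param basis `"wet_weight"` or `"lipid"`.
#' @param units `"ng_per_g"` or `"pg_per_g"` (units of `value`, `lod`, `loq`).
#' @param censor `"detected"`, `"below_loq"` or `"below_lod"`.
#' @param lod,loq detection / quantification limits in `units`; required for
#'   censored measurements; `loq >= lod >= 0`.
#' @return A one-row data frame with columns `congener`, `value`, `basis`,
#'   `units_in`, `censor`, `lod`, `loq` (`value`/`lod`/`loq` in pg/g).
#' @export
#' @examples
#' congener_measurement(126, 0.5, "wet_weight", "pg_per_g")
congener_measurement <- function(congener, value, basis = "wet_weight",
                                 units = "ng_per_g", censor = "detected",
                                 lod = NA_real_, loq = NA_real_) {
  df <- data.frame(congener = as.integer(congener), value = as.numeric(value),
                   basis = basis, units_in = units, censor = censor,
                   lod = .to_pg(as.numeric(lod), units),
                   loq = .to_pg(as.numeric(loq), units))
  df$value <- .to_pg(df$value, units)
  validate_measurements(df)
}

#' Validate a measurement table
#'
#' Checks the invariants of a measurement data frame (columns as produced by
#' [congener_measurement()], values already in pg/g) and returns it. For
#' censored rows the `value` column is set to the applicable limit.
#'
#' @param df measurement data frame.
#' @return The validated data frame.
#' @export
validate_measurements <- function(df) {
  req <- c("congener", "value", "basis", "units_in", "censor", "lod", "loq")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("measurement table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  congener_group(df$congener)  # errors on unknown congener
  if (any(!df$basis %in% .BASES)) stop("basis must be wet_weight or lipid", call. = FALSE)
  if (any(!df$units_in %in% .UNITS)) stop("units must be ng_per_g or pg_per_g", call. = FALSE)
  if (any(!df$censor %in% .CENSOR)) {
    stop("censor must be one of detected/below_loq/below_lod", call. = FALSE)
  }
  bad <- !is.na(df$value) & df$value < 0
  if (any(bad)) {
    stop("negative concentration for congener(s) ",
         paste(df$congener[bad], collapse = ", "), call. = FALSE)
  }
  lim <- !is.na(df$lod) & !is.na(df$loq)
  if (any(lim & (df$loq < df$lod | df$lod < 0))) {
    stop("limits must satisfy loq >= lod >= 0", call. = FALSE)
  }
  need <- df$censor == "below_lod"
  if (any(need & is.na(df$lod))) {
    stop("below_lod measurement lacks its LOD (congener ",
         paste(df$congener[need & is.na(df$lod)], collapse = ", "), ")",
         call. = FALSE)
  }
  df$value[need] <- df$lod[need]
  need <- df$censor == "below_loq"
  if (any(need & is.na(df$loq))) {
    stop("below_loq measurement lacks its LOQ (congener ",
         paste(df$congener[need & is.na(df$loq)], collapse = ", "), ")",
         call. = FALSE)
  }
  df$value[need] <- df$loq[need]
  if (any(!is.finite(df$value))) {
    stop("missing concentration for detected congener(s) ",
         paste(df$congener[!is.finite(df$value)], collapse = ", "),
         call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' A milk sample: one collection event
#'
#' @param sample_id,mother_id identifiers.
#' @param stage_days days postpartum at collection (>= 1).
#' @param composition a [milk_composition()].
#' @param measurements a measurement data frame (see
#'   [congener_measurement()]); at most one row per congener.
#' @param stage_label optional; if supplied it must agree with
#'   `stage_label_for(stage_days, schedule)`.
#' @param schedule the [stage_schedule()] used to derive/check the label.
#' @return An object of class `milk_sample`.
#' @export
milk_sample <- function(sample_id, mother_id, stage_days, composition,
                        measurements, stage_label = NULL,
                        schedule = stage_schedule()) {
  if (!inherits(composition, "milk_composition")) {
    stop("composition must be a milk_composition", call. = FALSE)
  }
  if (!is.finite(stage_days) || stage_days < 1) {
    stop("stage_days must be >= 1 (sample ", sample_id, ")", call. = FALSE)
  }
  measurements <- validate_measurements(measurements)
  if (anyDuplicated(measurements$congener)) {
    stop("duplicate congener measurement in sample ", sample_id, call. = FALSE)
  }
  derived <- stage_label_for(stage_days, schedule)
  if (!is.null(stage_label) && !identical(stage_label, derived)) {
    stop("stage_label '", stage_label, "' inconsistent with stage_days ",
         stage_days, " ('", derived, "') in sample ", sample_id, call. = FALSE)
  }
  structure(list(sample_id = as.character(sample_id),
                 mother_id = as.character(mother_id),
                 stage_days = as.numeric(stage_days),
                 stage_label = derived,
                 composition = composition,
                 measurements = measurements),
            class = "milk_sample")
}

#' @export
print.milk_sample <- function(x, ...) {
  cat("Milk sample", x$sample_id, "(mother", x$mother_id, ") day",
      x$stage_days, "->", x$stage_label, "\n")
  cat("  lipid", x$composition$lipid_pct, "% |",
      nrow(x$measurements), "congener measurement(s)\n")
  invisible(x)
}

#' Categorical codebooks for the questionnaire
#'
#' Levels for every categorical field of the maternal and infant profiles,
#' and the ordered food-frequency scale
#' (never < rarely < weekly < twice_weekly_plus < daily).
#'
#' @return Named list of character vectors.
#' @export
codebooks <- function() {
  list(
    age_band = c("<18", "18-22", "23-27", "28-32", "33-36"),
    weight_before_band = c("<55", "56-60", "61-65", ">65"),
    weight_after_band = c("55-60", "61-65", "66-70", ">70"),
    residence = c("city_gt_5000", "town_lt_5000", "country"),
    education = c("primary", "secondary", "higher"),
    delivery = c("natural", "c_section"),
    smoking = c("never", "quit_before_pregnancy", "up_to_one_pack",
                "more_than_one_pack"),
    sex = c("male", "female"),
    birth_weight_band = c("2.4-2.8", "2.9-3.2", "3.3-3.6", "3.7-4.0", ">4.0"),
    frequency = c("never", "rarely", "weekly", "twice_weekly_plus", "daily"),
    food = c("fish", "dairy", "beef", "pork", "poultry", "eggs",
             "vegetables", "fruit", "whole_grains")
  )
}

.check_code <- function(value, field, books = codebooks()) {
  if (!value %in% books[[field]]) {
    stop("invalid ", field, " code '", value, "'; expected one of: ",
         paste(books[[field]], collapse = ", "), call. = FALSE)
  }
  value
}

#' Maternal questionnaire profile
#'
#' Questionnaire bands are stored as categorical codes, never imputed to
#' point values. `food_frequency` is a named character vector over the food
#' categories using the ordered frequency scale (see [codebooks()]).
#'
#' @param mother_id identifier.
#' @param age_band,weight_before_band,weight_after_band,residence,education,delivery,smoking
#'   categorical codes per [codebooks()].
#' @param parity positive integer number of childbirths.
#' @param food_frequency named character vector, names from the `food`
#'   codebook, values from the `frequency` codebook.
#' @return Object of class `maternal_profile`.
#' @export
maternal_profile <- function(mother_id, age_band, weight_before_band,
                             weight_after_band, residence, education,
                             parity, delivery, smoking,
                             food_frequency = character(0)) {
  books <- codebooks()
  for (f in c("age_band", "weight_before_band", "weight_after_band",
              "residence", "education", "delivery", "smoking")) {
    .check_code(get(f), f, books)
  }
  if (!is.finite(parity) || parity < 1 || parity != round(parity)) {
    stop("parity must be a positive integer", call. = FALSE)
  }
  if (length(food_frequency)) {
    bad <- setdiff(names(food_frequency), books$food)
    if (length(bad)) stop("unknown food category: ", paste(bad, collapse = ", "), call. = FALSE)
    bad <- setdiff(food_frequency, books$frequency)
    if (length(bad)) stop("unknown frequency code: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(mother_id = as.character(mother_id), age_band = age_band,
                 weight_before_band = weight_before_band,
                 weight_after_band = weight_after_band, residence = residence,
                 education = education, parity = as.integer(parity),
                 delivery = delivery, smoking = smoking,
                 food_frequency = food_frequency),
            class = "maternal_profile")
}

#' Infant profile
#'
#' @param mother_id identifier linking to the mother.
#' @param sex `"male"` or `"female"`.
#' @param birth_weight_kg birth weight in kg, within \[1.5, 6\].
#' @return Object of class `infant_profile`.
#' @export
infant_profile <- function(mother_id, sex, birth_weight_kg) {
  .check_code(sex, "sex")
  if (!is.finite(birth_weight_kg) || birth_weight_kg < 1.5 || birth_weight_kg > 6) {
    stop("birth_weight_kg outside plausibility bounds [1.5, 6]", call. = FALSE)
  }
  structure(list(mother_id = as.character(mother_id), sex = sex,
                 birth_weight_kg = birth_weight_kg),
            class = "infant_profile")
}

#' Ordinal codes for the frequency scale
#'
#' Maps frequency labels to integer codes 0 (never) .. 4 (daily), the
#' numeric treatment used for ordinal food-frequency responses in
#' ordination.
#'
#' @param x character vector of frequency labels.
#' @return Integer vector.
#' @export
frequency_code <- function(x) {
  idx <- match(x, codebooks()$frequency)
  if (anyNA(idx)) stop("unknown frequency code(s)", call. = FALSE)
  idx - 1L
}
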