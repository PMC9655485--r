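# CSV readers/writers. The canonical interchange layout is long format:
# one row per (sample, congener) carrying the sample's composition and the
# measurement fields. A wide per-sample layout (one congener column per
# "pcb_<n>") is accepted via the dialect config.

#' Table dialect for sample CSV files
#'
#' @param layout `"long"` (canonical) or `"wide"`.
#' @param basis,units defaults applied when the file lacks the columns
#'   (wide layout always uses them).
#' @return Object of class `sample_dialect`.
#' @export
sample_dialect <- function(layout = c("long", "wide"),
                           basis = "wet_weight", units = "ng_per_g") {
  layout <- match.arg(layout)
  structure(list(layout = layout, basis = basis, units = units),
            class = "sample_dialect")
}

.comp_cols <- c("lipid_pct", "dry_matter_pct", "protein_pct", "lactose_pct")

.num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read milk samples from CSV
#'
#' Long format requires columns `sample_id`, `mother_id`, `stage_days`,
#' `lipid_pct`, `dry_matter_pct`, `protein_pct`, `lactose_pct`, `congener`,
#' `value`, and optionally `basis`, `units`, `censor`, `lod`, `loq`
#' (defaults from the dialect; censored rows need their limit). Wide format
#' has one row per sample with congener columns named `pcb_<iupac>`.
#'
#' Rows violating the domain invariants abort the read with a diagnostic
#' naming the offending sample unless `strict = FALSE`, in which case the
#' offending samples are dropped with a warning.
#'
#' @param path CSV file.
#' @param dialect a [sample_dialect()].
#' @param strict abort on first invalid sample (default) or drop and warn.
#' @param schedule [stage_schedule()] for label validation.
#' @return List of [milk_sample()] objects.
#' @export
read_samples <- function(path, dialect = sample_dialect(), strict = TRUE,
                         schedule = stage_schedule()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (dialect$layout == "wide") df <- .wide_to_long(df, dialect)
  req <- c("sample_id", "mother_id", "stage_days", .comp_cols,
           "congener", "value")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("sample CSV lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$basis)) df$basis <- dialect$basis
  if (is.null(df$units)) df$units <- dialect$units
  if (is.null(df$censor)) df$censor <- "detected"
  if (is.null(df$lod)) df$lod <- NA_real_
  if (is.null(df$loq)) df$loq <- NA_real_

  samples <- list()
  bad <- character(0)
  for (sid in unique(df$sample_id)) {
    rows <- df[df$sample_id == sid, , drop = FALSE]
    res <- tryCatch({
      meas <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
        congener_measurement(rows$congener[i], .num_or_na(rows$value[i]),
                             basis = rows$basis[i], units = rows$units[i],
                             censor = rows$censor[i],
                             lod = .num_or_na(rows$lod[i]),
                             loq = .num_or_na(rows$loq[i]))
      }))
      milk_sample(sid, rows$mother_id[1], .num_or_na(rows$stage_days[1]),
                  milk_composition(.num_or_na(rows$lipid_pct[1]),
                                   .num_or_na(rows$dry_matter_pct[1]),
                                   .num_or_na(rows$protein_pct[1]),
                                   .num_or_na(rows$lactose_pct[1])),
                  meas, schedule = schedule)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- paste0("sample '", sid, "': ", conditionMessage(res))
      if (strict) stop("invalid row(s) in ", path, " -- ", msg, call. = FALSE)
      bad <- c(bad, msg)
    } else {
      samples[[sid]] <- res
    }
  }
  if (length(bad)) {
    warning(length(bad), " sample(s) rejected:\n  ",
            paste(bad, collapse = "\n  "), call. = FALSE)
  }
  message("read ", nrow(df), " measurement rows -> ", length(samples),
          " samples (", length(bad), " rejected) from ", path)
  unname(samples)
}

.wide_to_long <- function(df, dialect) {
  pcb_cols <- grep("^pcb_[0-9]+$", names(df), value = TRUE)
  if (!length(pcb_cols)) {
    stop("wide layout declared but no pcb_<iupac> columns found", call. = FALSE)
  }
  base <- df[setdiff(names(df), pcb_cols)]
  out <- do.call(rbind, lapply(pcb_cols, function(cc) {
    d <- base
    d$congener <- as.integer(sub("^pcb_", "", cc))
    d$value <- df[[cc]]
    d
  }))
  out[!is.na(out$value), , drop = FALSE]
}

# %.17g round-trips IEEE doubles exactly through text
.fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

#' Write milk samples to long-format CSV
#'
#' Values are written in pg/g (the internal unit) with full precision, so
#' `write_samples()` then [read_samples()] reproduces the object graph
#' field-for-field.
#'
#' @param samples list of [milk_sample()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  rows <- do.call(rbind, lapply(samples, function(s) {
    m <- s$measurements
    data.frame(sample_id = s$sample_id, mother_id = s$mother_id,
               stage_days = .fmt_num(s$stage_days),
               lipid_pct = .fmt_num(s$composition$lipid_pct),
               dry_matter_pct = .fmt_num(s$composition$dry_matter_pct),
               protein_pct = .fmt_num(s$composition$protein_pct),
               lactose_pct = .fmt_num(s$composition$lactose_pct),
               congener = m$congener, value = .fmt_num(m$value),
               basis = m$basis, units = "pg_per_g",
               censor = m$censor, lod = .fmt_num(m$lod),
               loq = .fmt_num(m$loq))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read / write the maternal-infant covariate table
#'
#' One row per mother: the questionnaire bands, infant sex and birth weight,
#' and food-frequency columns `ff_<food>`.
#'
#' @param path CSV file.
#' @return `read_covariates`: list with elements `mothers` (list of
#'   [maternal_profile()]) and `infants` (list of [infant_profile()]).
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("mother_id", "age_band", "weight_before_band", "weight_after_band",
           "residence", "education", "parity", "delivery", "smoking",
           "sex", "birth_weight_kg")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("covariate CSV lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ff_cols <- grep("^ff_", names(df), value = TRUE)
  mothers <- lapply(seq_len(nrow(df)), function(i) {
    ff <- unlist(df[i, ff_cols, drop = FALSE])
    names(ff) <- sub("^ff_", "", names(ff))
    maternal_profile(df$mother_id[i], df$age_band[i],
                     df$weight_before_band[i], df$weight_after_band[i],
                     df$residence[i], df$education[i], df$parity[i],
                     df$delivery[i], df$smoking[i], food_frequency = ff)
  })
  infants <- lapply(seq_len(nrow(df)), function(i) {
    infant_profile(df$mother_id[i], df$sex[i], df$birth_weight_kg[i])
  })
  message("read ", nrow(df), " mother/infant rows from ", path)
  list(mothers = mothers, infants = infants)
}

#' @rdname read_covariates
#' @param mothers,infants lists of profiles (parallel, matched on
#'   `mother_id`).
#' @export
write_covariates <- function(mothers, infants, path) {
  inf_by_id <- stats::setNames(infants, vapply(infants, `[[`, "", "mother_id"))
  foods <- codebooks()$food
  rows <- do.call(rbind, lapply(mothers, function(m) {
    i <- inf_by_id[[m$mother_id]]
    ff <- stats::setNames(rep(NA_character_, length(foods)), foods)
    ff[names(m$food_frequency)] <- m$food_frequency
    d <- data.frame(mother_id = m$mother_id, age_band = m$age_band,
                    weight_before_band = m$weight_before_band,
                    weight_after_band = m$weight_after_band,
                    residence = m$residence, education = m$education,
                    parity = m$parity, delivery = m$delivery,
                    smoking = m$smoking, sex = i$sex,
                    birth_weight_kg = .fmt_num(i$birth_weight_kg))
    d[paste0("ff_", foods)] <- as.list(ff)
    d
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a JSON run configuration
#'
#' Keys select the TEF scheme, censoring bound, schedule mapping and intake
#' parameters; unknown keys are kept verbatim so callers can nest their own
#' sections.
#'
#' @param path JSON file.
#' @return Named list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  message("config ", path, ": ", length(cfg), " top-level keys")
  cfg
}
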