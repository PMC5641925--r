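#' @importFrom stats coef lm median poly ptukey rnorm runif sd setNames var
#'   vcov aov kruskal.test cor.test logLik AIC TukeyHSD residuals fitted
#'   dbinom
#' @importFrom utils read.csv write.csv head
NULL

#' Controlled vocabulary of longitudinal variables
#'
#' Each measurement in a long table carries a variable token whose suffix
#' encodes its unit, so unit mismatches surface at parse time rather than
#' deep inside a model fit.
#'
#' @return Character vector of recognized variable tokens.
#' @export
variable_vocabulary <- function() {
  c(
    "bw_g",                # body weight, g
    "food_g_day",          # daily food intake, g/day
    "tg_mM",               # plasma triglyceride, mmol/L
    "tc_mM",               # plasma total cholesterol, mmol/L
    "hdlc_mM",             # HDL cholesterol, mmol/L
    "nonhdlc_mM",          # non-HDL cholesterol, mmol/L
    "glucose_mM",          # whole-blood glucose, mmol/L
    "insulin_ngml",        # plasma insulin, ng/mL
    "egp_umol_kg_min",     # endogenous glucose production
    "mcr_ml_kg_min",       # glucose metabolic clearance rate
    "is_overall",          # overall insulin sensitivity index
    "is_peripheral",       # peripheral insulin sensitivity index
    "is_hepatic",          # hepatic insulin sensitivity index
    "vldl_tg_umol_kg_h",   # VLDL-TG secretion rate
    "fecal_ns_umol_day",   # fecal neutral sterol excretion
    "fecal_ba_umol_day",   # fecal bile acid excretion
    "liver_tg_umol_g",     # hepatic triglyceride content
    "liver_tc_umol_g"      # hepatic total cholesterol content
  )
}

#' Study-wide configuration constants
#'
#' Physiological constants and tracer doses used throughout the pipeline.
#' Blood volume and hematocrit define the theoretical plasma volume used to
#' convert a plasma TG accumulation slope into a secretion flux; the
#' D2-glucose dose is the intraperitoneal bolus per gram body weight.
#'
#' @param seed Integer seed recorded in the configuration.
#' @param blood_ml_per_kg Assumed blood volume, mL per kg body weight.
#' @param hematocrit Hematocrit fraction in (0, 1).
#' @param d2glucose_mg_per_g D2-glucose dose, mg per g body weight.
#' @param glucose_mw Molar mass of glucose, g/mol.
#' @param alpha Significance level for nested model selection.
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1L,
                         blood_ml_per_kg = 75,
                         hematocrit = 0.45,
                         d2glucose_mg_per_g = 0.1,
                         glucose_mw = 180.16,
                         alpha = 0.05) {
  stopifnot(hematocrit > 0, hematocrit < 1,
            blood_ml_per_kg > 0, d2glucose_mg_per_g > 0,
            glucose_mw > 0, alpha >= 0, alpha <= 1)
  structure(
    list(seed = as.integer(seed),
         blood_ml_per_kg = blood_ml_per_kg,
         hematocrit = hematocrit,
         d2glucose_mg_per_g = d2glucose_mg_per_g,
         glucose_mw = glucose_mw,
         alpha = alpha,
         fragments = list(
           `c16:0` = list(formula = "C17H34O2", n_units = 8L, shift = 1L),
           `c18:0` = list(formula = "C19H38O2", n_units = 9L, shift = 1L),
           `c18:1` = list(formula = "C19H36O2", n_units = 9L, shift = 1L),
           glucose = list(formula = "C16H22O11", n_labels = 1L, shift = 2L)
         )),
    class = "study_config")
}

#' Assemble a validated long-format measurement table
#'
#' The canonical container for longitudinal data: one row per
#' (animal, week, variable) measurement. Values must be finite, variables
#' must come from [variable_vocabulary()] (or an extended vocabulary), weeks
#' may not exceed the animal's cohort span by more than one week, and the
#' (animal, week, variable) key must be unique.
#'
#' @param animal_id Character animal identifiers.
#' @param cohort_weeks Integer cohort termination week (4, 9, 13 or 28 in
#'   the default design; any positive value is accepted).
#' @param week Numeric weeks on diet, >= 0.
#' @param variable Variable tokens.
#' @param value Numeric measurement values in the token's units.
#' @param dropout Logical; animal was terminated prematurely.
#' @param vocabulary Accepted variable tokens.
#' @return A tibble of class `long_records`.
#' @export
long_records <- function(animal_id, cohort_weeks, week, variable, value,
                         dropout = FALSE,
                         vocabulary = variable_vocabulary()) {
  x <- tibble::tibble(
    animal_id = as.character(animal_id),
    cohort_weeks = as.numeric(cohort_weeks),
    week = as.numeric(week),
    variable = as.character(variable),
    value = as.numeric(value),
    dropout = as.logical(dropout))
  validate_long_records(x, vocabulary = vocabulary)
}

validate_long_records <- function(x, vocabulary = variable_vocabulary()) {
  bad_var <- !(x$variable %in% vocabulary)
  if (any(bad_var)) {
    stop("unknown variable token(s) at row(s) ",
         paste(head(which(bad_var), 5L), collapse = ", "), ": ",
         paste(unique(x$variable[bad_var]), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x$value))) {
    stop("non-finite value(s) at row(s) ",
         paste(head(which(!is.finite(x$value)), 5L), collapse = ", "),
         call. = FALSE)
  }
  if (any(x$week < 0)) stop("negative week(s)", call. = FALSE)
  over <- x$week > x$cohort_weeks + 1
  if (any(over)) {
    stop("week exceeds cohort span + 1 at row(s) ",
         paste(head(which(over), 5L), collapse = ", "), call. = FALSE)
  }
  key <- paste(x$animal_id, x$week, x$variable, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (animal, week, variable) at row(s) ",
         paste(head(which(duplicated(key)), 5L), collapse = ", "),
         call. = FALSE)
  }
  class(x) <- c("long_records", class(x))
  x
}

#' Read a long-format measurement table from CSV
#'
#' Expects columns `animal_id, cohort_weeks, week, variable, value` and an
#' optional `dropout` column; every row is validated against the variable
#' vocabulary and the uniqueness/unit invariants. Malformed numeric fields
#' and unknown tokens are hard errors naming the offending row.
#'
#' @param path Path to a CSV file with a header row.
#' @param vocabulary Accepted variable tokens.
#' @return A `long_records` tibble.
#' @export
read_long_table <- function(path, vocabulary = variable_vocabulary()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("animal_id", "cohort_weeks", "week", "variable", "value")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("cohort_weeks", "week", "value")) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(num) & !is.na(raw[[col]]) & nzchar(raw[[col]])
    if (any(bad)) {
      stop("cannot parse '", raw[[col]][which(bad)[1L]], "' as number in ",
           "column '", col, "' at data line ", which(bad)[1L], call. = FALSE)
    }
    raw[[col]] <- num
  }
  dropout <- if ("dropout" %in% names(raw)) {
    as.logical(toupper(raw$dropout) %in% c("TRUE", "T", "1"))
  } else FALSE
  long_records(raw$animal_id, raw$cohort_weeks, raw$week, raw$variable,
               raw$value, dropout, vocabulary = vocabulary)
}

#' Write a long-format measurement table to CSV
#'
#' Round-trips exactly through [read_long_table()]: full-precision values,
#' RFC-4180 quoting, UTF-8.
#'
#' @param records A `long_records` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(records, path) {
  out <- as.data.frame(records)
  out$value <- format(out$value, digits = 17, scientific = FALSE, trim = TRUE)
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Non-HDL cholesterol by subtraction
#'
#' Non-HDL-c = total cholesterol minus HDL cholesterol. Assay noise can
#' make the difference slightly negative; such values are returned as-is
#' with a warning rather than clipped.
#'
#' @param tc Total cholesterol, mM.
#' @param hdlc HDL cholesterol, mM.
#' @return Non-HDL cholesterol, mM.
#' @export
non_hdl_c <- function(tc, hdlc) {
  stopifnot(all(tc >= 0), all(hdlc >= 0))
  out <- tc - hdlc
  if (any(out < 0)) {
    warning("negative non-HDL-c value(s); kept as-is (assay noise)",
            call. = FALSE)
  }
  out
}

#' Theoretical plasma volume from body weight
#'
#' Plasma volume = body weight x blood volume per kg x (1 - hematocrit);
#' with the default 75 mL/kg blood volume and hematocrit 0.45 this is
#' 41.25 mL plasma per kg body weight.
#'
#' @param body_weight_g Body weight in grams, > 0.
#' @param blood_ml_per_kg Blood volume assumption, mL/kg.
#' @param hematocrit Hematocrit fraction.
#' @return Plasma volume in mL.
#' @export
theoretical_plasma_volume <- function(body_weight_g, blood_ml_per_kg = 75,
                                      hematocrit = 0.45) {
  if (any(body_weight_g <= 0)) {
    stop("body weight must be positive", call. = FALSE)
  }
  stopifnot(hematocrit > 0, hematocrit < 1)
  body_weight_g / 1000 * blood_ml_per_kg * (1 - hematocrit)
}
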