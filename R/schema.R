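# Covariate schema: the typed description of the baseline covariates the
# emulated trial adjusts for, mirroring the annual-health-checkup covariate
# set (demographics, diagnosis/medication flags, lifestyle questionnaire
# items, laboratory values, comorbidity index).

#' Construct a covariate schema
#'
#' A covariate schema lists every baseline covariate with its measurement
#' kind. Kinds are `binary` (stored 0/1), `categorical` (stored as a factor
#' with the declared levels) or `continuous`.
#'
#' @param name Character vector of unique covariate names.
#' @param kind Character vector, one of `"binary"`, `"categorical"`,
#'   `"continuous"` per covariate.
#' @param levels List of character vectors; `NULL` entries for non-categorical
#'   covariates, at least two levels for categorical ones.
#' @param units Character vector of measurement units (may be `""`).
#' @return An object of class `covariate_schema`: a data frame with columns
#'   `name`, `kind`, `levels` (list column) and `units`.
#' @export
covariate_schema <- function(name, kind, levels = NULL, units = NULL) {
  n <- length(name)
  if (is.null(levels)) levels <- vector("list", n)
  if (is.null(units)) units <- rep("", n)
  stopifnot(length(kind) == n, length(levels) == n, length(units) == n)
  if (anyDuplicated(name)) stop("covariate names must be unique")
  if (!all(kind %in% c("binary", "categorical", "continuous"))) {
    stop("kind must be one of 'binary', 'categorical', 'continuous'")
  }
  bad <- kind == "categorical" & vapply(levels, length, 1L) < 2L
  if (any(bad)) {
    stop("categorical covariates need >= 2 levels: ",
         paste(name[bad], collapse = ", "))
  }
  out <- data.frame(name = name, kind = kind, units = units,
                    stringsAsFactors = FALSE)
  out$levels <- levels
  class(out) <- c("covariate_schema", "data.frame")
  out
}

#' Default baseline-covariate schema of the emulated hypertension trial
#'
#' The covariate set assessed at eligibility evaluation: sex; diagnosis of
#' (or medication for) hypertension, diabetes and dyslipidemia in the past
#' 12 months; smoking; drinking status (three analysis levels: everyday,
#' sometimes, rarely-or-never); lifestyle questionnaire items (weight change
#' since age 20, intention to improve lifestyle habits, sweat-inducing
#' exercise, daily walking, eating speed, late dinner, breakfast skipping,
#' restful sleep); and the continuous measurements age, BMI, triglycerides,
#' HDL and LDL cholesterol, diastolic and systolic blood pressure, GOT, GPT,
#' Gamma-GTP, HbA1c, Charlson comorbidity index, and days since the last
#' checkup (negative: the checkup precedes time zero).
#'
#' @return A [covariate_schema] describing the full baseline covariate set.
#' @export
default_schema <- function() {
  covariate_schema(
    name = c(
      "sex_male", "dx_hypertension", "dx_diabetes", "dx_dyslipidemia",
      "smoking", "drinking", "weight_change", "intention",
      "exercise_sweat", "walking", "eating_speed", "late_dinner",
      "skip_breakfast", "sleep_rest",
      "age", "bmi", "triglycerides", "hdl", "ldl",
      "dbp_baseline", "sbp_baseline", "got", "gpt", "ggtp",
      "hba1c", "cci", "days_since_checkup"
    ),
    kind = c(
      "binary", "binary", "binary", "binary",
      "binary", "categorical", "binary", "binary",
      "binary", "binary", "categorical", "binary",
      "binary", "binary",
      rep("continuous", 13)
    ),
    levels = c(
      vector("list", 5),
      list(c("everyday", "sometimes", "rare_never")),
      vector("list", 4),
      list(c("fast", "normal", "slow")),
      vector("list", 3),
      vector("list", 13)
    ),
    units = c(
      rep("", 14),
      "years", "kg/m2", "mg/dL", "mg/dL", "mg/dL",
      "mmHg", "mmHg", "U/L", "U/L", "U/L",
      "%", "index", "days"
    )
  )
}

#' @method print covariate_schema
#' @export
print.covariate_schema <- function(x, ...) {
  cat("Covariate schema:", nrow(x), "covariates\n")
  for (i in seq_len(nrow(x))) {
    lv <- if (x$kind[i] == "categorical") {
      paste0(" {", paste(x$levels[[i]], collapse = ", "), "}")
    } else ""
    cat(sprintf("  %-20s %-11s%s\n", x$name[i], x$kind[i], lv))
  }
  invisible(x)
}

#' Write / read a covariate schema as JSON
#'
#' @param schema A [covariate_schema].
#' @param path File path.
#' @return `read_schema_json()` returns a [covariate_schema];
#'   `write_schema_json()` returns `path` invisibly.
#' @export
write_schema_json <- function(schema, path) {
  entries <- lapply(seq_len(nrow(schema)), function(i) {
    e <- list(name = schema$name[i], kind = schema$kind[i],
              units = schema$units[i])
    if (schema$kind[i] == "categorical") e$levels <- schema$levels[[i]]
    e
  })
  jsonlite::write_json(list(covariates = entries), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_schema_json
#' @export
read_schema_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  e <- raw$covariates
  covariate_schema(
    name = vapply(e, `[[`, "", "name"),
    kind = vapply(e, `[[`, "", "kind"),
    levels = lapply(e, function(x) {
      if (is.null(x$levels)) NULL else unlist(x$levels)
    }),
    units = vapply(e, function(x) x$units %||% "", "")
  )
}

# Expand a cohort's covariate columns into a numeric matrix: binary as 0/1,
# categorical as one indicator per non-reference level, continuous as is.
# Used by the ensemble, the propensity diagnostic and z-score importance.
schema_model_matrix <- function(data, schema, full_dummies = FALSE) {
  cols <- list()
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    x <- data[[nm]]
    if (is.null(x)) stop("covariate missing from data: ", nm)
    if (schema$kind[i] == "categorical") {
      lv <- schema$levels[[i]]
      x <- factor(as.character(x), levels = lv)
      keep <- if (full_dummies) lv else lv[-1]
      for (l in keep) cols[[paste0(nm, "=", l)]] <- as.numeric(x == l)
    } else {
      cols[[nm]] <- as.numeric(x)
    }
  }
  do.call(cbind, cols)
}
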