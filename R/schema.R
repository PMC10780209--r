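#' Declare the variable schema for a cohort
#'
#' Every analysis starts from a schema: one row per clinical variable, giving
#' its name, its kind, and (for categorical variables) the severity ordering
#' used to aggregate multiple within-hour records. Kinds follow the usual ICU
#' chart structure:
#'
#' * `"continuous"` — vitals and labs; multiple records within an hour are
#'   averaged, IQR outlier fences and min–max scaling apply.
#' * `"categorical"` — ordinal scales (e.g. consciousness level); within an
#'   hour the *worst* category is kept, where "worst" is the first element of
#'   `severity_order`. Categories are coded as their severity rank
#'   (1 = worst) and treated as ordinal thereafter.
#' * `"medication"` — drug/treatment events; an hour is coded 1 if any record
#'   exists and 0 otherwise. Hours without a record keep value 0 but
#'   observation mask 0.
#'
#' Fitted statistics (IQR fences, min–max range, training mean, median/IQR
#' for external rescaling) live in dedicated columns, `NA` until
#' [fit_preprocessor()] fills them from training data only.
#'
#' @param name Character vector of variable names.
#' @param kind Character vector, one of `"continuous"`, `"categorical"`,
#'   `"medication"`; recycled if length 1.
#' @param severity_order List of character vectors (worst category first),
#'   one per variable; must be non-`NULL` exactly for categorical variables.
#' @return A tibble of class `icu_schema` with one row per variable.
#' @examples
#' variable_schema(
#'   name = c("hr", "consciousness", "vasopressor"),
#'   kind = c("continuous", "categorical", "medication"),
#'   severity_order = list(NULL, c("coma", "stupor", "drowsy", "alert"), NULL)
#' )
#' @export
variable_schema <- function(name, kind, severity_order = NULL) {
  kind <- rep_len(kind, length(name))
  bad <- setdiff(kind, c("continuous", "categorical", "medication"))
  if (length(bad) > 0) {
    abort(paste0("unknown variable kind: ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(name)) abort("duplicated variable names in schema")
  if (is.null(severity_order)) severity_order <- vector("list", length(name))
  if (length(severity_order) != length(name)) {
    abort("severity_order must have one entry per variable")
  }
  has_order <- !vapply(severity_order, is.null, logical(1))
  if (!all(has_order == (kind == "categorical"))) {
    abort("severity_order must be present iff kind is 'categorical'")
  }
  out <- tibble::tibble(
    name = as.character(name),
    kind = kind,
    severity_order = severity_order,
    fence_low = NA_real_, fence_high = NA_real_,
    scale_min = NA_real_, scale_max = NA_real_,
    train_mean = NA_real_,
    train_median = NA_real_, train_iqr = NA_real_
  )
  class(out) <- c("icu_schema", class(out))
  out
}

#' Validate a long-format clinical event table against a schema
#'
#' Checks the structural invariants expected by [resample_hourly()]: the
#' required columns are present, every variable name appears in the schema,
#' and all timestamps are finite and non-negative (hours since ICU
#' admission).
#'
#' @param events A data frame with columns `patient_id`, `time_hours`,
#'   `variable`, `value`.
#' @param schema An [variable_schema()] tibble.
#' @return `events` as a tibble, invisibly checked.
#' @export
check_events <- function(events, schema) {
  events <- tibble::as_tibble(events)
  need <- c("patient_id", "time_hours", "variable", "value")
  miss <- setdiff(need, names(events))
  if (length(miss) > 0) {
    abort(paste0("event table missing columns: ", paste(miss, collapse = ", ")))
  }
  unknown <- setdiff(unique(events$variable), schema$name)
  if (length(unknown) > 0) {
    abort(paste0("variables not in schema: ", paste(unknown, collapse = ", ")),
          class = "icugrud_schema_error")
  }
  t <- events$time_hours
  if (any(!is.finite(t)) || any(t < 0)) {
    abort("time_hours must be finite and non-negative",
          class = "icugrud_input_error")
  }
  events
}

#' Convert recorded values to numeric severity-aware codes
#'
#' Continuous and medication values must parse as numbers; categorical values
#' may be given either as category labels or as numeric severity ranks and
#' are coded 1 (worst) .. K (best) per the schema's `severity_order`.
#'
#' @inheritParams check_events
#' @return `events` with a numeric `value` column.
#' @export
encode_events <- function(events, schema) {
  events <- check_events(events, schema)
  val <- events$value
  out <- suppressWarnings(as.numeric(val))
  cat_vars <- schema$name[schema$kind == "categorical"]
  for (v in cat_vars) {
    ord <- schema$severity_order[[match(v, schema$name)]]
    idx <- which(events$variable == v & is.na(out))
    if (length(idx) > 0) {
      code <- match(as.character(val[idx]), ord)
      if (anyNA(code)) {
        abort(paste0("unknown category for variable '", v, "'"),
              class = "icugrud_schema_error")
      }
      out[idx] <- code
    }
  }
  if (anyNA(out)) abort("non-numeric value for non-categorical variable",
                        class = "icugrud_input_error")
  events$value <- out
  events
}
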