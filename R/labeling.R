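#' Apply cohort inclusion rules
#'
#' Internal-cohort policy excludes patients who already had the event (e.g.
#' a pressure ulcer) before ICU admission — their outcome is not a
#' within-stay prediction target. The external-validation policy additionally
#' requires adult patients (age >= 18) with at least 48 h of records after
#' admission; a missing age under that policy excludes the patient (logged).
#'
#' @param outcomes Tibble with columns `patient_id`, `pu_time` (hours since
#'   admission of the first event record, `NA` if none), `pre_admission_pu`
#'   (logical), `age` (years), `stay_hours`.
#' @param policy `"internal"` or `"external"`.
#' @return The retained rows of `outcomes`.
#' @export
apply_cohort_filters <- function(outcomes, policy = c("internal", "external")) {
  policy <- match.arg(policy)
  out <- tibble::as_tibble(outcomes)
  keep <- !isTRUE_vec(out$pre_admission_pu)
  if (policy == "external") {
    no_age <- is.na(out$age)
    if (any(no_age & keep)) {
      inform(paste0(sum(no_age & keep), " patient(s) excluded: missing age"))
    }
    keep <- keep & !no_age & out$age >= 18 & out$stay_hours >= 48
  }
  out[keep, , drop = FALSE]
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Per-timestep labels for on-time and in-advance prediction
#'
#' The model emits a risk every hour; labels define what "correct" means at
#' each hour for a prediction horizon `h`. A patient without the event gets
#' all-zero labels over the full stay. A patient whose event occurs at hour
#' `pu_time` has the sequence truncated at the occurrence (post-event hours
#' carry no prediction task) and hours `max(1, pu_time - h) .. pu_time`
#' labelled 1: the model is asked to fire from `h` hours before the event.
#' With `pu_time = 60` and `h = 24` the first positive label is hour 36; with
#' `h = 0` only the occurrence hour is positive. If `pu_time <= h`, every
#' retained hour is positive. Fractional event times are floored to the
#' containing hour.
#'
#' @param pu_time Event hour since admission (`NA`/`NULL` for controls).
#' @param n_hours Stay length in whole hours (grid rows).
#' @param horizon Lead time `h` in hours (0 = on-time).
#' @return Integer 0/1 vector of length `n_hours` (controls) or
#'   `floor(pu_time)` (event patients).
#' @export
make_labels <- function(pu_time, n_hours, horizon = 0) {
  stopifnot(n_hours >= 1, horizon >= 0)
  if (is.null(pu_time) || is.na(pu_time)) {
    return(integer(n_hours))
  }
  pu <- max(1L, as.integer(floor(pu_time)))
  if (pu > n_hours) {
    abort("pu_time exceeds the stay length", class = "icugrud_input_error")
  }
  y <- integer(pu)
  y[max(1L, pu - as.integer(horizon)):pu] <- 1L
  y
}

#' Attach labels (and event-time truncation) to grids
#'
#' Joins outcomes onto grids, truncates event patients' matrices at the
#' occurrence hour, and adds the label vector for the requested horizon.
#'
#' @param grids An `icu_grids` tibble.
#' @param outcomes Outcome tibble (see [apply_cohort_filters()]).
#' @param horizon Lead time in hours.
#' @return `icu_grids` restricted to patients present in `outcomes`, with
#'   list-column `y` and logical column `is_case`.
#' @export
attach_labels <- function(grids, outcomes, horizon = 0) {
  schema <- attr(grids, "schema")
  scaled <- attr(grids, "scaled")
  idx <- match(grids$patient_id, outcomes$patient_id)
  grids <- grids[!is.na(idx), , drop = FALSE]
  oc <- outcomes[idx[!is.na(idx)], , drop = FALSE]
  grids$y <- purrr::map2(oc$pu_time, grids$n_hours, make_labels,
                         horizon = horizon)
  grids$is_case <- !is.na(oc$pu_time)
  len <- lengths(grids$y)
  trunc_mat <- function(mat, n) mat[seq_len(n), , drop = FALSE]
  for (col in intersect(c("values", "mask", "delta", "x"), names(grids))) {
    grids[[col]] <- purrr::map2(grids[[col]], len, trunc_mat)
  }
  grids$n_hours <- as.integer(len)
  grids <- new_icu_grids(grids, schema)
  attr(grids, "scaled") <- scaled
  attr(grids, "horizon") <- horizon
  grids
}
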