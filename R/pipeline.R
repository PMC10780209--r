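#' Prepare a simulated (or read-in) cohort for model fitting
#'
#' Wires the standard pipeline end to end: cohort filters, hourly
#' resampling, a seeded patient-level train/model-selection split,
#' preprocessing statistics fitted on the training split only and applied
#' everywhere, in-advance labels, and delta matrices. This is the function
#' the command-line tool, the examples and most tests build on.
#'
#' @param events Long event table.
#' @param outcomes Outcome table.
#' @param schema An [variable_schema()].
#' @param horizon Label lead time in hours (training labels).
#' @param policy Cohort policy, `"internal"` or `"external"`.
#' @param props Split proportions, e.g. `c(train = 0.8, valid = 0.2)`;
#'   use `c(train = 1)` to keep one split (external application).
#' @param spec Optional pre-fitted schema (external cohorts are processed
#'   with the internal statistics; when given, nothing is fitted here).
#' @param rescale_map Optional `icu_rescale` map applied to raw grids
#'   before the internal statistics.
#' @param seed Split seed.
#' @return List with one labeled, preprocessed `icu_grids` per split, the
#'   fitted `spec`, and the filtered `outcomes`.
#' @export
prepare_cohort <- function(events, outcomes, schema, horizon = 48,
                           policy = "internal",
                           props = c(train = 0.8, valid = 0.2),
                           spec = NULL, rescale_map = NULL, seed = 1L) {
  outcomes <- apply_cohort_filters(outcomes, policy)
  grids <- resample_hourly(events, schema,
                           outcomes[, c("patient_id", "stay_hours")])
  if (!is.null(rescale_map)) grids <- apply_rescale(grids, rescale_map)
  ids <- split_patients(grids$patient_id, props, seed = seed)
  splits <- purrr::map(ids, function(i) grids[grids$patient_id %in% i, ])
  if (is.null(spec)) spec <- fit_preprocessor(splits[[1]])
  splits <- purrr::map(splits, function(g) {
    g <- apply_preprocessor(g, spec, fill = TRUE)
    attach_labels(g, outcomes, horizon = horizon)
  })
  c(splits, list(spec = spec, outcomes = outcomes))
}
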