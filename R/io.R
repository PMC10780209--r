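#' Read / write the long-format event table
#'
#' Delimited text with header `patient_id,time_hours,variable,value`;
#' `value` may hold category labels for categorical variables.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_events <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(), time_hours = readr::col_double(),
    variable = readr::col_character(), value = readr::col_character()))
}

#' @rdname read_events
#' @param events Event tibble.
#' @export
write_events <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}

#' Read / write the outcome table
#'
#' Columns: `patient_id`, `pu_time` (hours, empty for controls),
#' `pre_admission_pu`, `age`, `stay_hours`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_outcomes <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(), pu_time = readr::col_double(),
    pre_admission_pu = readr::col_logical(), age = readr::col_double(),
    stay_hours = readr::col_double()))
}

#' @rdname read_outcomes
#' @param outcomes Outcome tibble.
#' @export
write_outcomes <- function(outcomes, path) {
  readr::write_csv(outcomes, path)
  invisible(path)
}

#' Read / write the variable schema with fitted statistics
#'
#' JSON so that an external site can apply byte-identical transforms.
#'
#' @param path File path.
#' @export
write_schema <- function(schema, path) {
  jsonlite::write_json(list(
    name = schema$name, kind = schema$kind,
    severity_order = schema$severity_order,
    stats = as.list(schema[, c("fence_low", "fence_high", "scale_min",
                               "scale_max", "train_mean", "train_median",
                               "train_iqr")])
  ), path, digits = NA, auto_unbox = FALSE, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_schema
#' @param schema An `icu_schema` tibble.
#' @export
read_schema <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sev <- purrr::map(j$severity_order, function(x) {
    if (length(x) == 0) NULL else as.character(x)
  })
  out <- variable_schema(j$name, j$kind, sev)
  num <- function(x) ifelse(vapply(x, is.null, logical(1)) | is.na(unlist2(x)),
                            NA_real_, unlist2(x))
  for (s in names(j$stats)) out[[s]] <- num(j$stats[[s]])
  out
}

unlist2 <- function(x) {
  x <- purrr::map(x, function(v) if (is.null(v)) NA_real_ else v)
  vapply(x, as.numeric, numeric(1))
}

#' Read / write per-patient grids as a long columnar text table
#'
#' One row per patient-hour-variable with the (scaled or raw) value, mask
#' and delta embedded, plus the label if present.
#'
#' @param grids An `icu_grids` tibble.
#' @param path File path.
#' @export
write_grids <- function(grids, path) {
  schema <- attr(grids, "schema")
  long <- purrr::pmap(
    list(grids$patient_id, grids$values, grids$mask,
         if ("delta" %in% names(grids)) grids$delta else
           purrr::map(grids$mask, compute_delta),
         if ("y" %in% names(grids)) grids$y else
           purrr::map(grids$n_hours, function(n) rep(NA_integer_, n))),
    function(id, v, m, d, y) {
      tibble::tibble(
        patient_id = id,
        hour = rep(seq_len(nrow(v)), ncol(v)),
        variable = rep(schema$name, each = nrow(v)),
        value = as.vector(v), mask = as.vector(m), delta = as.vector(d),
        label = rep(y, ncol(v)))
    })
  readr::write_csv(dplyr::bind_rows(long), path)
  invisible(path)
}

#' @rdname write_grids
#' @param schema The schema the grids were built with.
#' @param scaled Whether the stored values are already min-max scaled.
#' @export
read_grids <- function(path, schema, scaled = TRUE) {
  long <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(), hour = readr::col_integer(),
    variable = readr::col_character(), value = readr::col_double(),
    mask = readr::col_double(), delta = readr::col_double(),
    label = readr::col_integer()))
  per <- split(long, factor(long$patient_id, unique(long$patient_id)))
  D <- nrow(schema)
  out <- tibble::tibble(
    patient_id = names(per),
    n_hours = unname(purrr::map_int(per, function(p) max(p$hour))),
    values = unname(purrr::map(per, function(p) {
      matrix(p$value[order(match(p$variable, schema$name), p$hour)],
             ncol = D, dimnames = list(NULL, schema$name))
    })),
    mask = unname(purrr::map(per, function(p) {
      matrix(p$mask[order(match(p$variable, schema$name), p$hour)],
             ncol = D, dimnames = list(NULL, schema$name))
    })),
    delta = unname(purrr::map(per, function(p) {
      matrix(p$delta[order(match(p$variable, schema$name), p$hour)],
             ncol = D, dimnames = list(NULL, schema$name))
    }))
  )
  y <- purrr::map(per, function(p) p$label[p$variable == schema$name[1]])
  if (!all(is.na(unlist(y)))) {
    out$y <- unname(purrr::map(y, as.integer))
    out$is_case <- purrr::map_lgl(out$y, function(v) any(v == 1L))
  }
  g <- new_icu_grids(out, schema)
  attr(g, "scaled") <- scaled
  g
}

#' Save / load a self-contained model checkpoint
#'
#' A single JSON archive holding every trainable parameter, the model
#' configuration, and the fitted preprocessing statistics, so that
#' inference elsewhere needs nothing but this file and raw data.
#'
#' @param fit A `grud_fit`.
#' @param path File path.
#' @export
write_checkpoint <- function(fit, path) {
  jsonlite::write_json(list(
    theta = fit$theta, D = fit$D, H = fit$H, variant = fit$variant,
    lambda = fit$lambda, w_pos = fit$w_pos,
    config = fit$config, best_epoch = fit$best_epoch,
    best_val_auroc = fit$best_val_auroc,
    history = fit$history,
    schema = list(name = fit$spec$name, kind = fit$spec$kind,
                  severity_order = fit$spec$severity_order,
                  stats = as.list(fit$spec[, c("fence_low", "fence_high",
                                               "scale_min", "scale_max",
                                               "train_mean", "train_median",
                                               "train_iqr")])),
    config_hash = fit_hash(fit)
  ), path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sev <- purrr::map(j$schema$severity_order, function(x) {
    if (length(x) == 0) NULL else as.character(x)
  })
  spec <- variable_schema(j$schema$name, j$schema$kind, sev)
  for (s in names(j$schema$stats)) spec[[s]] <- unlist2(j$schema$stats[[s]])
  structure(list(
    theta = as.numeric(j$theta), D = j$D, H = j$H, variant = j$variant,
    flags = variant_flags(j$variant), lambda = j$lambda, w_pos = j$w_pos,
    spec = spec, config = j$config,
    history = tibble::as_tibble(j$history),
    best_epoch = j$best_epoch, best_val_auroc = j$best_val_auroc
  ), class = "grud_fit")
}

fit_hash <- function(fit) {
  rlang::hash(list(fit$theta, fit$D, fit$H, fit$variant, fit$lambda,
                   fit$w_pos, fit$config))
}

#' Reproducibility manifest for a pipeline run
#'
#' Stamps a run with its configuration, seed, and a content hash; two runs
#' of the same configuration and seed produce identical manifests, so any
#' artifact can be checked against (and rebuilt from) its manifest alone.
#'
#' @param subcommand Pipeline stage name.
#' @param config Named list of settings.
#' @param seed Integer seed.
#' @param path Optional path to also write the manifest as JSON.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(subcommand, config, seed, path = NULL) {
  config <- config[order(names(config))]
  man <- list(subcommand = subcommand, config = config, seed = seed,
              package = "icugrud",
              version = as.character(utils::packageVersion("icugrud")),
              hash = rlang::hash(list(subcommand, config, seed)))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
    return(invisible(man))
  }
  man
}
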