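#' Resample long-format events onto hourly per-patient grids
#'
#' Builds, for every patient, a `T x D` value matrix covering each whole hour
#' of the ICU stay (hour `t` spans `[t-1, t)` hours since admission) together
#' with a binary observation mask. Within-hour aggregation is type-specific:
#' continuous variables take the mean of all in-hour records, categorical
#' variables keep the worst category (first in `severity_order`, i.e. the
#' lowest severity code), and medications are binarised to 1 when any record
#' exists. Hours with no record are missing (`NA`, mask 0); medication hours
#' without a record are 0 with mask 0.
#'
#' @param events Long event table (`patient_id`, `time_hours`, `variable`,
#'   `value`); values may be category labels for categorical variables.
#' @param schema A [variable_schema()].
#' @param stay_hours Data frame (`patient_id`, `stay_hours`) giving each
#'   stay's length; grids have `floor(stay_hours)` rows (minimum 1).
#' @return A nested tibble of class `icu_grids` with list-columns `values`
#'   and `mask` (`T x D` matrices, columns in schema order) plus `n_hours`.
#'   The schema travels along as attribute `schema`.
#' @export
resample_hourly <- function(events, schema, stay_hours) {
  events <- encode_events(events, schema)
  stays <- tibble::as_tibble(stay_hours)
  if (!all(c("patient_id", "stay_hours") %in% names(stays))) {
    abort("stay_hours needs columns patient_id, stay_hours")
  }
  kind <- setNames(schema$kind, schema$name)
  ev <- events |>
    dplyr::mutate(hour = floor(.data$time_hours) + 1) |>
    dplyr::group_by(.data$patient_id, .data$variable, .data$hour) |>
    dplyr::summarise(
      cell = switch(kind[[.data$variable[1]]],
        continuous = mean(.data$value),
        categorical = min(.data$value),  # rank 1 = worst
        medication = 1
      ),
      .groups = "drop"
    )
  ev_split <- split(ev, factor(ev$patient_id, levels = stays$patient_id))
  D <- nrow(schema)
  med <- schema$kind == "medication"
  grids <- purrr::map2(ev_split, pmax(1L, floor(stays$stay_hours)), function(e, Th) {
    vals <- matrix(NA_real_, Th, D, dimnames = list(NULL, schema$name))
    mask <- matrix(0, Th, D, dimnames = list(NULL, schema$name))
    if (nrow(e) > 0) {
      keep <- e$hour <= Th
      i <- e$hour[keep]
      j <- match(e$variable[keep], schema$name)
      vals[cbind(i, j)] <- e$cell[keep]
      mask[cbind(i, j)] <- 1
    }
    vals[, med][is.na(vals[, med])] <- 0  # unobserved medication hours are 0
    list(values = vals, mask = mask)
  })
  out <- tibble::tibble(
    patient_id = stays$patient_id,
    n_hours = pmax(1L, as.integer(floor(stays$stay_hours))),
    values = purrr::map(grids, "values"),
    mask = purrr::map(grids, "mask")
  )
  new_icu_grids(out, schema)
}

new_icu_grids <- function(x, schema) {
  attr(x, "schema") <- schema
  class(x) <- unique(c("icu_grids", class(x)))
  x
}

#' @export
`[.icu_grids` <- function(x, ...) {
  out <- NextMethod()
  for (a in c("schema", "scaled", "horizon")) attr(out, a) <- attr(x, a)
  class(out) <- unique(c("icu_grids", class(out)))
  out
}

#' @export
print.icu_grids <- function(x, ...) {
  schema <- attr(x, "schema")
  cat("<icu_grids> ", nrow(x), " patients, ", nrow(schema), " variables, ",
      sum(x$n_hours), " patient-hours\n", sep = "")
  NextMethod()
}

#' Extract all observed values of one variable across training grids
#' @noRd
observed_values <- function(grids, var) {
  schema <- attr(grids, "schema")
  j <- match(var, schema$name)
  unlist(purrr::map2(grids$values, grids$mask, function(v, m) v[m[, j] == 1, j]),
         use.names = FALSE)
}

#' Fit Tukey IQR outlier fences for one variable
#'
#' Fences are `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`, with quartiles computed by
#' linear interpolation between order statistics (R's default type-7
#' quantile). Values later falling outside the fences are treated as
#' recording errors and converted to missing. A zero-spread variable yields
#' equal fences (a no-op filter, flagged with a message).
#'
#' @param values Numeric vector of observed training values (at least 4).
#' @return Named numeric `c(fence_low, fence_high)`.
#' @export
fit_iqr_fences <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4) abort("need at least 4 observed training values")
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  if (iqr == 0) inform("zero IQR: fences coincide, filter is a no-op")
  c(fence_low = q[1] - 1.5 * iqr, fence_high = q[2] + 1.5 * iqr)
}

#' Fit min-max range for one variable
#' @param values Numeric vector of observed training values (post-fencing).
#' @return Named numeric `c(scale_min, scale_max)`.
#' @export
fit_minmax <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("no observed training values")
  c(scale_min = min(values), scale_max = max(values))
}

#' Fit the full preprocessing statistics on training grids
#'
#' Learns, per variable and on *training* patients only: IQR outlier fences
#' (continuous variables only — ordinal codes and binary medications have no
#' meaningful fences), the min–max range on fenced values, the training mean
#' of scaled observed values (the fallback used by forward-then-mean filling
#' and by GRU-D), and the median/IQR of raw fenced values used when rescaling
#' an external cohort. Validation and test rows must never enter here; the
#' fitted schema is then applied unchanged everywhere.
#'
#' @param grids Training `icu_grids` from [resample_hourly()].
#' @return The schema with all statistics columns filled.
#' @export
fit_preprocessor <- function(grids) {
  schema <- attr(grids, "schema")
  for (i in seq_len(nrow(schema))) {
    if (schema$kind[i] == "medication") {
      # binary presence channel: 0 hours are real values, not missing
      schema$fence_low[i] <- -Inf; schema$fence_high[i] <- Inf
      schema$scale_min[i] <- 0; schema$scale_max[i] <- 1
      v_all <- unlist(purrr::map(grids$values, function(m) m[, i]),
                      use.names = FALSE)
      schema$train_median[i] <- median(v_all)
      schema$train_iqr[i] <- unname(diff(quantile(v_all, c(0.25, 0.75),
                                                  type = 7)))
      schema$train_mean[i] <- mean(scale_values(v_all, 0, 1))
      next
    }
    v <- observed_values(grids, schema$name[i])
    if (schema$kind[i] == "continuous" && length(v) >= 4) {
      f <- fit_iqr_fences(v)
      schema$fence_low[i] <- f[1]; schema$fence_high[i] <- f[2]
      v <- v[v >= f[1] & v <= f[2]]
    } else {
      schema$fence_low[i] <- -Inf; schema$fence_high[i] <- Inf
    }
    if (length(v) == 0) abort(paste0("no in-fence values for ", schema$name[i]))
    mm <- fit_minmax(v)
    schema$scale_min[i] <- mm[1]; schema$scale_max[i] <- mm[2]
    schema$train_median[i] <- median(v)
    schema$train_iqr[i] <- unname(diff(quantile(v, c(0.25, 0.75), type = 7)))
    sc <- scale_values(v, mm[1], mm[2])
    schema$train_mean[i] <- mean(sc)
  }
  schema
}

scale_values <- function(x, lo, hi) {
  if (hi == lo) return(rep(0, length(x)))
  2 * (x - lo) / (hi - lo) - 1
}

#' Convert out-of-fence observed values to missing
#'
#' Cells outside the fitted fences become `NA` with mask 0; the grid shape
#' is preserved (the hour is kept, not dropped) so temporal alignment and the
#' delta recurrence are unaffected. In-fence cells are untouched and the
#' observed count never increases.
#'
#' @param grids An `icu_grids` tibble.
#' @param spec Fitted schema from [fit_preprocessor()].
#' @return Filtered `icu_grids`.
#' @export
apply_iqr_filter <- function(grids, spec) {
  lo <- spec$fence_low; hi <- spec$fence_high
  stopifnot(!anyNA(lo), !anyNA(hi))
  if (isTRUE(attr(grids, "scaled"))) {
    # fences are learned in raw units; on an already-scaled grid apply them
    # in scaled space so the filter commutes with scaling (idempotence)
    rng <- ifelse(spec$scale_max == spec$scale_min, 1,
                  spec$scale_max - spec$scale_min)
    lo <- ifelse(is.finite(lo), 2 * (lo - spec$scale_min) / rng - 1, lo)
    hi <- ifelse(is.finite(hi), 2 * (hi - spec$scale_min) / rng - 1, hi)
  }
  out <- purrr::map2(grids$values, grids$mask, function(v, m) {
    bad <- m == 1 & (sweep(v, 2, lo, "<") | sweep(v, 2, hi, ">"))
    bad[is.na(bad)] <- FALSE
    v[bad] <- NA_real_
    m[bad] <- 0
    list(v = v, m = m)
  })
  grids$values <- purrr::map(out, "v")
  grids$mask <- purrr::map(out, "m")
  new_icu_grids(grids, spec)
}

#' Min-max scale grids to the training range
#'
#' Applies `x' = 2 (x - min) / (max - min) - 1` per variable with the
#' *training* range, so training min maps to -1 and training max to +1.
#' Non-training values may fall outside `[-1, 1]` and are deliberately not
#' clipped: an out-of-range reading is signal. A degenerate variable
#' (`max == min`) maps to constant 0 with a warning.
#'
#' @inheritParams apply_iqr_filter
#' @return Scaled `icu_grids` (attribute `scaled` set to `TRUE`).
#' @export
minmax_scale <- function(grids, spec) {
  if (isTRUE(attr(grids, "scaled"))) return(grids)
  lo <- spec$scale_min; hi <- spec$scale_max
  stopifnot(!anyNA(lo), !anyNA(hi))
  if (any(hi == lo)) warn("degenerate variable(s) mapped to constant 0")
  rng <- ifelse(hi == lo, 1, hi - lo)
  off <- ifelse(hi == lo, 0, 1)
  grids$values <- purrr::map(grids$values, function(v) {
    sweep(sweep(v, 2, lo, "-"), 2, rng / 2, "/") - off
  })
  grids <- new_icu_grids(grids, spec)
  attr(grids, "scaled") <- TRUE
  grids
}

#' Invert the min-max scaling (for reporting in clinical units)
#' @inheritParams apply_iqr_filter
#' @return Unscaled `icu_grids`.
#' @export
minmax_unscale <- function(grids, spec) {
  lo <- spec$scale_min; hi <- spec$scale_max
  rng <- ifelse(hi == lo, 0, hi - lo)
  grids$values <- purrr::map(grids$values, function(v) {
    sweep(sweep(v + 1, 2, rng / 2, "*"), 2, lo, "+")
  })
  attr(grids, "scaled") <- NULL
  grids
}

#' Hours since each variable was last observed
#'
#' The delta matrix of the decay mechanism: `delta[1, d] = 0` and for `t > 1`
#' `delta[t, d] = 1 + delta[t-1, d]` if the variable was missing at `t - 1`,
#' else 1. A never-observed variable keeps accumulating from admission.
#'
#' @param mask Binary `T x D` matrix (1 = observed).
#' @return Non-negative `T x D` matrix of hours.
#' @export
compute_delta <- function(mask) {
  T_ <- nrow(mask); D <- ncol(mask)
  delta <- matrix(0, T_, D, dimnames = dimnames(mask))
  if (T_ > 1) {
    for (t in 2:T_) {
      delta[t, ] <- 1 + ifelse(mask[t - 1, ] == 0, delta[t - 1, ], 0)
    }
  }
  delta
}

#' Attach delta matrices to grids
#' @inheritParams apply_iqr_filter
#' @return `icu_grids` with a `delta` list-column.
#' @export
add_delta <- function(grids) {
  grids$delta <- purrr::map(grids$mask, compute_delta)
  grids
}

#' Forward-fill then mean-fill missing cells
#'
#' The baseline imputation used by models without an internal imputation
#' mechanism: each missing cell takes the most recent earlier observation of
#' its variable; cells before the first observation take the training mean
#' (in scaled space). The mask is left unchanged so decay models can still
#' tell imputed cells apart. Grids must already be scaled.
#'
#' @inheritParams apply_iqr_filter
#' @return `icu_grids` with a complete `x` list-column.
#' @export
forward_then_mean_fill <- function(grids, spec) {
  stopifnot(isTRUE(attr(grids, "scaled")), !anyNA(spec$train_mean))
  mu <- spec$train_mean
  grids$x <- purrr::map(grids$values, function(v) {
    for (j in seq_len(ncol(v))) {
      col <- v[, j]
      obs <- !is.na(col)
      if (any(obs)) {
        idx <- cummax(ifelse(obs, seq_along(col), 0L))
        col <- ifelse(idx > 0, col[pmax(idx, 1L)], mu[j])
      } else {
        col <- rep(mu[j], length(col))
      }
      v[, j] <- col
    }
    v
  })
  grids
}

#' Run the fitted preprocessing chain on any cohort split
#'
#' Applies, in order: IQR outlier filtering, min–max scaling, delta
#' computation, and (optionally) forward-then-mean filling — all with
#' statistics fitted on the training split.
#'
#' @inheritParams apply_iqr_filter
#' @param fill Whether to add the filled `x` matrix for non-decay models.
#' @return Preprocessed `icu_grids`.
#' @export
apply_preprocessor <- function(grids, spec, fill = TRUE) {
  grids <- apply_iqr_filter(grids, spec)
  grids <- minmax_scale(grids, spec)
  grids <- add_delta(grids)
  if (fill) grids <- forward_then_mean_fill(grids, spec)
  grids
}

#' Fit an external-cohort rescaling map
#'
#' External sites chart the same physiology on different devices, units and
#' populations, so raw distributions shift. Per variable this learns the
#' affine map sending the *external training* median/IQR onto the internal
#' training median/IQR (robust to heavy missingness); a zero external IQR
#' degenerates to a pure median shift. Medications are binary and left
#' unmapped. Internal min–max scaling is applied after the map as usual.
#'
#' @param external_train Raw (unscaled, unfiltered) external training
#'   `icu_grids`.
#' @param spec Internal fitted schema.
#' @return Tibble (`name`, `slope`, `shift`) of class `icu_rescale`.
#' @export
fit_rescale <- function(external_train, spec) {
  maps <- purrr::map_dfr(seq_len(nrow(spec)), function(i) {
    if (spec$kind[i] == "medication") {
      return(tibble::tibble(name = spec$name[i], slope = 1, shift = 0))
    }
    # raw external units: the internal fences do not apply until after the
    # map; median/IQR are robust to the outliers the fences would catch
    v <- observed_values(external_train, spec$name[i])
    if (length(v) == 0) {
      inform(paste0("variable absent in external cohort: ", spec$name[i]))
      return(tibble::tibble(name = spec$name[i], slope = 1, shift = 0))
    }
    med_e <- median(v)
    iqr_e <- unname(diff(quantile(v, c(0.25, 0.75), type = 7)))
    slope <- if (iqr_e == 0) 1 else spec$train_iqr[i] / iqr_e
    tibble::tibble(name = spec$name[i], slope = slope,
                   shift = spec$train_median[i] - slope * med_e)
  })
  class(maps) <- c("icu_rescale", class(maps))
  maps
}

#' Apply a fitted external rescaling map to raw grids
#'
#' @param grids Raw external `icu_grids`.
#' @param rescale_map From [fit_rescale()].
#' @return `icu_grids` with observed values affinely mapped; downstream
#'   preprocessing ([apply_preprocessor()]) then proceeds with the internal
#'   statistics.
#' @export
apply_rescale <- function(grids, rescale_map) {
  schema <- attr(grids, "schema")
  a <- rescale_map$slope[match(schema$name, rescale_map$name)]
  b <- rescale_map$shift[match(schema$name, rescale_map$name)]
  grids$values <- purrr::map(grids$values, function(v) {
    sweep(sweep(v, 2, a, "*"), 2, b, "+")
  })
  grids
}
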