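#' Seeded patient-level split
#'
#' @param ids Character vector of patient ids.
#' @param props Proportions, e.g. `c(train = 0.8, valid = 0.2)`; the first
#'   `length(props) - 1` splits get `round(prop * n)` patients each and the
#'   last takes the remainder.
#' @param seed Integer seed.
#' @return Named list of id vectors.
#' @export
split_patients <- function(ids, props = c(train = 0.8, valid = 0.2),
                           seed = 1L) {
  stopifnot(abs(sum(props) - 1) < 1e-8)
  set.seed(seed)
  ids <- sample(ids)
  k <- length(props)
  sizes <- round(props[-k] * length(ids))
  sizes <- c(sizes, length(ids) - sum(sizes))
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  out <- purrr::map2(starts, ends, function(a, b) sort(ids[seq(a, b)]))
  names(out) <- names(props) %||% paste0("split", seq_len(k))
  out
}

#' AUROC/AUPRC at on-time and in-advance horizons
#'
#' For each horizon `h`, the positive pool holds each event patient's risk
#' `h` hours before the occurrence (patients whose event falls within the
#' first `h` hours are skipped and counted); the negative pool holds one
#' risk per control patient, at an hour drawn (seeded) from the empirical
#' distribution of the positive evaluation hours restricted to hours the
#' control actually has — time-matching the negatives so stay length cannot
#' masquerade as risk.
#'
#' @param scored `icu_grids` truncated at the event (labels from
#'   [attach_labels()] at any horizon), with a `risk` list-column from
#'   [predict.grud_fit()] (or any scorer).
#' @param horizons Lead times in hours.
#' @param seed Seed for the negative draws.
#' @return An `icu_eval` tibble: one row per horizon with `auroc`, `auprc`,
#'   `n_pos`, `n_neg`, `n_skipped`, and the sampling descriptor.
#' @export
evaluate_horizons <- function(scored, horizons = c(0, 12, 24, 48),
                              seed = 1L) {
  if (!"risk" %in% names(scored)) abort("scored grids need a 'risk' list-column")
  if (!"is_case" %in% names(scored)) abort("scored grids need labels: attach_labels()")
  set.seed(seed)
  cases <- scored[scored$is_case, , drop = FALSE]
  ctrls <- scored[!scored$is_case, , drop = FALSE]
  rows <- purrr::map(horizons, function(h) {
    t_pos <- cases$n_hours - h           # event hour is the last grid row
    ok <- t_pos >= 1
    if (!any(ok)) {
      inform(sprintf("horizon %d h: no eligible event patients", h))
      return(NULL)
    }
    pos <- purrr::map2_dbl(cases$risk[ok], t_pos[ok], function(p, t) p[t])
    pool <- t_pos[ok]
    neg <- purrr::map2_dbl(ctrls$risk, ctrls$n_hours, function(p, Tc) {
      cand <- pool[pool <= Tc]
      if (length(cand) == 0) return(NA_real_)
      p[cand[sample.int(length(cand), 1)]]
    })
    neg <- neg[!is.na(neg)]
    tibble::tibble(
      horizon = h,
      auroc = auroc(c(pos, neg), rep(1:0, c(length(pos), length(neg)))),
      auprc = auprc(c(pos, neg), rep(1:0, c(length(pos), length(neg)))),
      n_pos = length(pos), n_neg = length(neg),
      n_skipped = sum(!ok),
      sampling = "one time-matched draw per control", seed = seed
    )
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  class(out) <- c("icu_eval", class(out))
  out
}

#' Mask selected variables out of a cohort
#'
#' Removes the named variables' observations entirely (value missing, mask
#' 0, delta recomputed; medication channels revert to "no record"), leaving
#' the model's imputation path to stand in for them — the semantics used by
#' the Shapley attribution, where a coalition "without" a variable still
#' sees its imputed estimate, so importance credits the observations, not
#' the imputation.
#'
#' @param grids Preprocessed `icu_grids`.
#' @param drop Character vector of variable names to remove.
#' @param spec Fitted schema (to rebuild the filled `x`, if present).
#' @return `icu_grids` with those variables unobserved.
#' @export
mask_out_variables <- function(grids, drop, spec = attr(grids, "schema")) {
  if (length(drop) == 0) return(grids)
  j <- match(drop, spec$name)
  stopifnot(!anyNA(j))
  med <- spec$kind[j] == "medication"
  rng <- spec$scale_max[j] - spec$scale_min[j]
  scaled_zero <- ifelse(rng == 0, 0, -2 * spec$scale_min[j] / rng - 1)
  grids$values <- purrr::map(grids$values, function(v) {
    v[, j] <- NA_real_
    if (any(med)) v[, j[med]] <- scaled_zero[med]
    v
  })
  grids$mask <- purrr::map(grids$mask, function(m) { m[, j] <- 0; m })
  grids$delta <- purrr::map(grids$mask, compute_delta)
  if ("x" %in% names(grids)) grids <- forward_then_mean_fill(grids, spec)
  grids
}

#' Rank variables by sampling-based Shapley importance
#'
#' Estimates each variable's Shapley value for the model's discriminative
#' performance: over seeded random permutations of the variables, the
#' marginal change in pooled AUROC (risk vs label over every timestep of
#' `grids`) when the variable's observations are added to the coalition.
#' Variables outside a coalition are fully masked, so missing data are
#' attributed to the imputation path rather than to the variable itself.
#'
#' @param fit A `grud_fit`.
#' @param grids Labeled, preprocessed evaluation `icu_grids` (a modest
#'   subsample keeps this fast).
#' @param k Number of top variables to return (clamped to `D`).
#' @param n_perm Number of sampled permutations.
#' @param seed Integer seed.
#' @return Tibble (`variable`, `importance`) sorted descending, top `k`.
#' @export
rank_variables <- function(fit, grids, k = 10, n_perm = 16, seed = 1L) {
  spec <- fit$spec
  D <- nrow(spec)
  k <- max(0L, min(as.integer(k), D))
  if (k == 0L) {
    return(tibble::tibble(variable = character(), importance = numeric()))
  }
  set.seed(seed)
  y <- unlist(grids$y, use.names = FALSE)
  value_of <- memoise_coalition(function(keep) {
    g <- mask_out_variables(grids, setdiff(spec$name, keep), spec)
    sc <- predict(fit, g)
    auroc(unlist(sc$risk, use.names = FALSE), y)
  })
  contrib <- matrix(0, n_perm, D, dimnames = list(NULL, spec$name))
  for (pm in seq_len(n_perm)) {
    ord <- sample(spec$name)
    prev <- value_of(character())
    for (i in seq_along(ord)) {
      cur <- value_of(ord[seq_len(i)])
      contrib[pm, ord[i]] <- cur - prev
      prev <- cur
    }
  }
  tibble::tibble(variable = spec$name,
                 importance = colMeans(contrib)[spec$name]) |>
    dplyr::arrange(dplyr::desc(.data$importance)) |>
    head(k)
}

# Coalition values recur across permutations; cache on the sorted name set.
memoise_coalition <- function(f) {
  cache <- new.env(parent = emptyenv())
  function(keep) {
    key <- paste0("s:", paste(sort(keep), collapse = "|"))
    if (is.null(cache[[key]])) cache[[key]] <- f(keep)
    cache[[key]]
  }
}

#' Fine-tune a fitted model on an external cohort
#'
#' Implements the external-site adaptation protocol: a seeded patient-level
#' 10/10/80 split of the external cohort into fine-tuning, model-selection
#' and validation sets; the optimiser restarts from the checkpoint at a
#' reduced learning rate; performance is reported on the 80% validation
#' split only.
#'
#' @param fit Pre-trained `grud_fit`.
#' @param external Labeled, preprocessed external `icu_grids` (already
#'   rescaled if desired).
#' @param seed Integer seed (split + optimiser).
#' @param lr_factor Learning-rate reduction vs the original fit.
#' @param epochs,patience Fine-tuning schedule.
#' @param horizons Horizons for the validation report.
#' @return List with `fit` (fine-tuned), `report` (`icu_eval` on the 80%
#'   split), and `split` (the id lists).
#' @export
finetune <- function(fit, external, seed = 1L, lr_factor = 0.1,
                     epochs = 20, patience = 3,
                     horizons = c(0, 12, 24, 48)) {
  split <- split_patients(external$patient_id,
                          c(train = 0.1, select = 0.1, valid = 0.8),
                          seed = seed)
  if (any(lengths(split) < 10)) {
    abort("external cohort too small: need >= 10 patients per split")
  }
  pick <- function(ids) external[external$patient_id %in% ids, , drop = FALSE]
  new_fit <- train_grud(
    pick(split$train), pick(split$select),
    variant = fit$variant, H = fit$H, lambda = fit$lambda,
    w_pos = fit$w_pos, lr = fit$config$lr * lr_factor,
    batch_size = fit$config$batch_size, epochs = epochs,
    patience = patience, theta = fit$theta, seed = seed
  )
  scored <- predict(new_fit, pick(split$valid))
  list(fit = new_fit, report = evaluate_horizons(scored, horizons, seed = seed),
       split = split)
}
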