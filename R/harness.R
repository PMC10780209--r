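#' Simulation settings for the model-ordering benchmark
#'
#' The regime in which decay-based imputation should matter most, used by
#' [compare_models()]: every lab-like variable near the top of its
#' realistic missingness range (up to 80%), the sedation-style scale half
#' missing, and state-dependent (informative) missingness — deteriorating
#' patients are measured more often, as in real ICUs where clinicians
#' order labs because a patient looks worse. Under missingness this heavy
#' a forward-then-mean-filled series is stale most of the time, which is
#' precisely the failure mode the decay mechanism addresses.
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
ordering_benchmark_config <- function(n_patients = 2000, seed = 1L) {
  vars <- default_sim_variables()
  vars$miss_prob <- c(0.006, 0.006, 0.006,
                      0.80, 0.72, 0.65, 0.60, 0.55, 0.50,
                      0.50, 0, 0)
  sim_config(n_patients = n_patients, variables = vars,
             informative_missingness = TRUE, seed = seed)
}

#' Train and evaluate several model variants on one simulated cohort
#'
#' The comparison harness: simulates a cohort, runs the shared
#' preprocessing pipeline, trains each requested variant with identical
#' budgets, and reports horizon AUROC/AUPRC for each — the synthetic
#' counterpart of a model-comparison table on real ICU data. Variants
#' whose engine needs complete inputs (`gru`, `rnn`, `lr`) consume the
#' forward-then-mean-filled grids; decay variants consume raw values with
#' mask and delta.
#'
#' @param cfg A [sim_config()], e.g. [ordering_benchmark_config()].
#' @param variants Character vector from `"grudpp"`, `"grud"`,
#'   `"grud_trainable"`, `"gru"`, `"rnn"`, `"lr"`.
#' @param horizons Evaluation lead times (hours).
#' @param train_horizon Label lead time used for training.
#' @param H,epochs,patience,batch_size,lr Training budget, shared by all
#'   recurrent variants.
#' @param seed Seed for simulation, splits, training and evaluation.
#' @return List with `report` (tibble: `model`, `horizon`, `auroc`,
#'   `auprc`, `n_pos`, `n_neg`), `fits` (named list of fitted models), and
#'   `prep` (the preprocessed splits).
#' @export
compare_models <- function(cfg,
                           variants = c("grudpp", "grud", "gru"),
                           horizons = c(0, 12, 24, 48),
                           train_horizon = 48,
                           H = 32, epochs = 30, patience = 8,
                           batch_size = 32, lr = 1e-3,
                           seed = cfg$seed) {
  sim <- simulate_cohort(cfg)
  prep <- prepare_cohort(sim$events, sim$outcomes, sim$schema,
                         horizon = train_horizon, seed = seed)
  fits <- list()
  rows <- purrr::map(variants, function(variant) {
    if (variant == "lr") {
      fit <- fit_baseline_lr(prep$train)
    } else {
      fit <- train_grud(prep$train, prep$valid, variant = variant, H = H,
                        epochs = epochs, patience = patience,
                        batch_size = batch_size, lr = lr, seed = seed)
    }
    fits[[variant]] <<- fit
    scored <- predict(fit, prep$valid)
    rep <- evaluate_horizons(scored, horizons, seed = seed)
    dplyr::mutate(tibble::as_tibble(rep), model = variant,
                  .before = 1)
  })
  list(report = dplyr::bind_rows(rows), fits = fits, prep = prep)
}

#' Simulate an external-site cohort with shifted units and scales
#'
#' Emulates the distribution shift between hospitals: the same physiology
#' charted with different devices, units and measurement habits. Each
#' continuous variable's centre is displaced by `shift` of its internal
#' spread and its spread multiplied by `scale_factor`; ordinal and
#' medication channels are left alone (category codes travel unchanged
#' between sites).
#'
#' @param cfg Internal-site [sim_config()]; the external cohort shares its
#'   dynamics but gets its own `n_patients` and `seed`.
#' @param n_patients External cohort size.
#' @param seed External cohort seed.
#' @param shift Centre displacement in units of each variable's scale.
#' @param scale_factor Spread multiplier.
#' @return An `icu_sim` for the external site.
#' @export
simulate_external_cohort <- function(cfg, n_patients = 500, seed = 99L,
                                     shift = 2, scale_factor = 2.5) {
  vars <- cfg$variables
  cont <- vars$kind == "continuous"
  vars$center[cont] <- vars$center[cont] + shift * vars$scale[cont]
  vars$scale[cont] <- scale_factor * vars$scale[cont]
  ext_cfg <- cfg
  ext_cfg$variables <- vars
  ext_cfg$n_patients <- n_patients
  ext_cfg$seed <- as.integer(seed)
  simulate_cohort(ext_cfg)
}

#' Zero-shot vs rescaled vs fine-tuned external validation
#'
#' The external-portability experiment: train on an internal cohort, then
#' apply the model to a unit-shifted external cohort three ways — as-is
#' (zero-shot), after median/IQR rescaling onto the internal training
#' distribution, and after fine-tuning on 10% of the external patients —
#' always evaluating on the same 80% external validation split.
#'
#' @param cfg Internal [sim_config()].
#' @param n_external External cohort size.
#' @param train_horizon Label lead time for training.
#' @param H,epochs,patience Training budget.
#' @param seed Seed for everything downstream of the configs.
#' @param variant Model variant to carry through the experiment.
#' @return List with `fit` (internal), `reports` (named list of `icu_eval`
#'   for `zero_shot`, `rescaled`, `finetuned`), and `split`.
#' @export
external_validation <- function(cfg, n_external = 500, train_horizon = 48,
                                H = 32, epochs = 30, patience = 8,
                                seed = cfg$seed, variant = "grudpp") {
  sim <- simulate_cohort(cfg)
  prep <- prepare_cohort(sim$events, sim$outcomes, sim$schema,
                         horizon = train_horizon, seed = seed)
  fit <- train_grud(prep$train, prep$valid, variant = variant, H = H,
                    epochs = epochs, patience = patience, seed = seed)

  ext <- simulate_external_cohort(cfg, n_patients = n_external,
                                  seed = seed + 71L)
  ext_out <- apply_cohort_filters(ext$outcomes, "external")
  raw <- resample_hourly(ext$events, ext$schema,
                         ext_out[, c("patient_id", "stay_hours")])
  split <- split_patients(raw$patient_id,
                          c(train = 0.1, select = 0.1, valid = 0.8),
                          seed = seed)
  prep_ext <- function(grids) {
    g <- apply_preprocessor(grids, prep$spec, fill = TRUE)
    attach_labels(g, ext_out, horizon = train_horizon)
  }
  # zero-shot: internal statistics applied directly to raw external data
  zero <- prep_ext(raw)
  # rescaled: median/IQR map fitted on the external *training* portion only
  rmap <- fit_rescale(raw[raw$patient_id %in% split$train, ], prep$spec)
  resc <- prep_ext(apply_rescale(raw, rmap))
  eval_on <- function(g) {
    evaluate_horizons(predict(fit, g[g$patient_id %in% split$valid, ]),
                      seed = seed)
  }
  # fine-tuning starts from the rescaled cohort: rescaling needs no labels,
  # so a deploying site would always apply it before spending labels on
  # fine-tuning
  ft <- finetune(fit, resc, seed = seed, epochs = epochs,
                 patience = patience)
  list(fit = fit,
       reports = list(zero_shot = eval_on(zero),
                      rescaled = eval_on(resc),
                      finetuned = ft$report),
       split = split)
}
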