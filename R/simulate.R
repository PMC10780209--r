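#' Default variable profile for the synthetic ICU cohort
#'
#' Twelve variables mirroring the mix of a real ICU chart: three vital-like
#' continuous signals measured almost every hour (0.6% missing), six
#' lab-like continuous signals with 30–80% missingness (the two worst,
#' lactate-like and pH-like, at 80% and 72%), one ordinal consciousness
#' scale, and two binary medication channels whose presence depends on how
#' sick the patient is. `loading` is how strongly each observable reflects
#' the latent illness state (labs are deliberately the most informative, as
#' lactate and pH are clinically); `center`/`scale` put values on plausible
#' clinical units so scaling and fencing are exercised realistically.
#'
#' @return Tibble with columns `name`, `kind`, `severity_order`, `loading`,
#'   `noise_sd`, `center`, `scale`, `miss_prob`.
#' @export
default_sim_variables <- function() {
  tibble::tibble(
    name = c("heart_rate", "sbp", "dbp",
             "lactate", "ph", "creatinine", "wbc", "albumin", "glucose",
             "consciousness", "sedative", "vasopressor"),
    kind = c(rep("continuous", 9), "categorical", "medication", "medication"),
    severity_order = c(rep(list(NULL), 9),
                       list(c("coma", "stupor", "drowsy", "alert")),
                       list(NULL), list(NULL)),
    loading = c(0.25, -0.25, -0.2, 1.2, -1.0, 0.8, 0.6, -0.6, 0.4,
                -0.6, 0.6, 0.6),
    noise_sd = c(1, 1, 1, 0.45, 0.45, 0.55, 0.65, 0.65, 0.9, 0.8, 0, 0),
    center = c(85, 120, 65, 1.8, 7.38, 1.1, 9, 3.6, 130, 0, 0, 0),
    scale = c(12, 18, 12, 1.1, 0.05, 0.6, 3, 0.5, 35, 1, 1, 1),
    miss_prob = c(0.006, 0.006, 0.006, 0.80, 0.72, 0.50, 0.40, 0.35, 0.30,
                  0.30, 0, 0)
  )
}

#' Configuration of the synthetic ICU cohort generator
#'
#' The generator emulates the statistical regime the prediction method
#' assumes: hourly multivariate series driven by a latent AR(1) illness
#' state, per-variable missing rates spanning 0.6% (vitals) to 80% (labs),
#' roughly 4% of patients experiencing the event, and a deterministic
#' deterioration drift over the `onset_lead` hours before each event so that
#' in-advance prediction is learnable.
#'
#' @param n_patients Cohort size.
#' @param variables Variable profile tibble; see [default_sim_variables()].
#' @param rho AR(1) coefficient of the latent state (stationary unit
#'   variance; innovation sd is `sqrt(1 - rho^2)`).
#' @param stay_meanlog,stay_sdlog Log-normal stay-length parameters (hours);
#'   defaults centre the stay near 3 days.
#' @param stay_range Stays are clamped to this range (hours).
#' @param hazard_slope Slope of the per-hour logistic event hazard in the
#'   latent state; the intercept is calibrated so the expected fraction of
#'   event patients matches `prevalence`.
#' @param hazard_time Additional hazard slope per *day* of stay, reflecting
#'   cumulative immobility (pressure-injury risk accumulates with time in
#'   bed); shifts events away from the first hours of the stay.
#' @param prevalence Target fraction of patients with the event.
#' @param onset_lead Hours of pre-event drift `L`; the latent state ramps up
#'   by `drift_max` linearly over the `L` hours before the event.
#' @param drift_max Size of the deterioration drift at the event hour, in
#'   latent-state standard deviations.
#' @param pre_admission_frac Fraction flagged as having the condition before
#'   admission (excluded by the internal cohort policy).
#' @param informative_missingness If `TRUE`, sicker hours are measured more
#'   often (missingness depends on the latent state) instead of the default
#'   missing-completely-at-random cells.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 500,
                       variables = default_sim_variables(),
                       rho = 0.85,
                       stay_meanlog = log(72), stay_sdlog = 0.45,
                       stay_range = c(12, 240),
                       hazard_slope = 1.5,
                       hazard_time = 0.3,
                       prevalence = 0.04,
                       onset_lead = 72,
                       drift_max = 1.2,
                       pre_admission_frac = 0.02,
                       informative_missingness = FALSE,
                       seed = 1L) {
  stopifnot(abs(rho) < 1, prevalence > 0, prevalence < 1,
            all(variables$miss_prob >= 0 & variables$miss_prob < 1))
  structure(list(
    n_patients = n_patients, variables = variables, rho = rho,
    stay_meanlog = stay_meanlog, stay_sdlog = stay_sdlog,
    stay_range = stay_range, hazard_slope = hazard_slope,
    hazard_time = hazard_time,
    prevalence = prevalence, onset_lead = onset_lead, drift_max = drift_max,
    pre_admission_frac = pre_admission_frac,
    informative_missingness = informative_missingness,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate an ICU-like cohort
#'
#' Per patient: a stay length is drawn, a latent illness state `z_t` follows
#' a stationary AR(1), the event hour is drawn from a per-hour logistic
#' hazard in `z_t` (intercept calibrated against the realised latent paths
#' so the expected prevalence hits the target), a deterministic drift is
#' added to `z` over the `onset_lead` hours preceding the event, observables
#' are linear loadings of `z` plus noise mapped onto clinical units, and
#' each non-medication cell is hidden with its variable's missing
#' probability. The emitted long-format event table and outcome table are
#' exactly what [resample_hourly()] and [apply_cohort_filters()] consume;
#' the complete pre-masking values and latent states are returned as ground
#' truth for imputation scoring.
#'
#' @param cfg A [sim_config()].
#' @return List of class `icu_sim` with `events`, `outcomes`, `schema`,
#'   `truth` (per patient: `z`, `values` complete raw matrix, `mask`), and
#'   `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  vars <- cfg$variables
  D <- nrow(vars)
  set.seed(cfg$seed)

  n <- cfg$n_patients
  stays <- pmin(cfg$stay_range[2],
                pmax(cfg$stay_range[1], round(rlnorm(n, cfg$stay_meanlog,
                                                     cfg$stay_sdlog))))
  sig <- sqrt(1 - cfg$rho^2)
  zs <- lapply(stays, function(Th) {
    e <- rnorm(Th)
    z <- numeric(Th)
    z[1] <- e[1]
    for (t in seq_len(Th)[-1]) z[t] <- cfg$rho * z[t - 1] + sig * e[t]
    z
  })

  a <- calibrate_hazard(zs, cfg$hazard_slope, cfg$hazard_time,
                        cfg$prevalence)

  is_med <- vars$kind == "medication"
  is_cat <- vars$kind == "categorical"
  cont_j <- which(!is_med & !is_cat)

  truth <- vector("list", n)
  ev_chunks <- vector("list", n)
  pu_time <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    z <- zs[[i]]
    Th <- stays[i]
    haz <- plogis(a + cfg$hazard_slope * z +
                    cfg$hazard_time * (seq_len(Th) - 1) / 24)
    u <- runif(Th)
    hit <- which(u < haz)
    if (length(hit) > 0) {
      pu <- hit[1]
      pu_time[i] <- pu
      w0 <- pu - cfg$onset_lead
      ramp <- pmax(0, (seq_len(Th) - w0) / cfg$onset_lead)
      z <- z + cfg$drift_max * pmin(1, ramp) * (seq_len(Th) <= pu)
    }
    vals <- matrix(NA_real_, Th, D, dimnames = list(NULL, vars$name))
    for (j in cont_j) {
      vals[, j] <- vars$center[j] +
        vars$scale[j] * (vars$loading[j] * z + rnorm(Th, sd = vars$noise_sd[j]))
    }
    for (j in which(is_cat)) {
      s <- -vars$loading[j] * z + rnorm(Th, sd = vars$noise_sd[j])
      K <- length(vars$severity_order[[j]])
      vals[, j] <- pmin(K, pmax(1, K - findInterval(s, c(0.5, 1.2, 2))))
    }
    for (j in which(is_med)) {
      vals[, j] <- rbinom(Th, 1, plogis(-2.6 + vars$loading[j] * z))
    }
    pi_d <- vars$miss_prob
    if (cfg$informative_missingness) {
      pmat <- plogis(outer(-0.5 * z, qlogis(pmin(pmax(pi_d, 1e-6), 1 - 1e-6)),
                           "+"))
      pmat[, pi_d == 0] <- 0
      hidden <- matrix(runif(Th * D), Th, D) < pmat
    } else {
      hidden <- sweep(matrix(runif(Th * D), Th, D), 2, pi_d, "<")
    }
    hidden[, is_med] <- FALSE  # medication channels are presence/absence
    mask <- 1 - hidden
    mask[, is_med] <- vals[, is_med]  # a record exists only when given
    dimnames(mask) <- dimnames(vals)
    truth[[i]] <- list(z = z, values = vals, mask = mask)

    obs <- which(mask == 1, arr.ind = TRUE)
    if (nrow(obs) > 0) {
      jj <- obs[, 2]
      v <- vals[obs]
      lab <- as.character(v)
      ci <- which(is_cat[jj])
      if (length(ci) > 0) {
        lab[ci] <- purrr::map2_chr(jj[ci], v[ci], function(j, code) {
          vars$severity_order[[j]][code]
        })
      }
      ev_chunks[[i]] <- tibble::tibble(
        patient_id = sprintf("p%04d", i),
        time_hours = obs[, 1] - 1 + runif(nrow(obs)),
        variable = vars$name[jj],
        value = lab
      )
    }
  }

  outcomes <- tibble::tibble(
    patient_id = sprintf("p%04d", seq_len(n)),
    pu_time = pu_time,
    pre_admission_pu = runif(n) < cfg$pre_admission_frac,
    age = pmin(95, pmax(16, round(rnorm(n, 65, 15)))),
    stay_hours = as.numeric(stays)
  )
  names(truth) <- outcomes$patient_id

  schema <- variable_schema(vars$name, vars$kind, vars$severity_order)
  structure(list(
    events = dplyr::bind_rows(ev_chunks),
    outcomes = outcomes,
    schema = schema,
    truth = truth,
    config = cfg
  ), class = "icu_sim")
}

# Hazard intercept such that, conditional on the realised latent paths, the
# expected fraction of event patients equals the target prevalence.
calibrate_hazard <- function(zs, slope, slope_time, prevalence) {
  f <- function(a) {
    mean(vapply(zs, function(z) {
      eta <- a + slope * z + slope_time * (seq_along(z) - 1) / 24
      1 - exp(sum(log1p(-plogis(eta))))
    }, numeric(1))) - prevalence
  }
  lo <- -30; hi <- 5
  if (f(hi) < 0) {
    abort(sprintf(
      "target prevalence %.3f infeasible: attainable at most %.3f",
      prevalence, f(hi) + prevalence), class = "icugrud_config_error")
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' @export
print.icu_sim <- function(x, ...) {
  cat("<icu_sim> ", x$config$n_patients, " patients, ",
      nrow(x$config$variables), " variables, prevalence ",
      sprintf("%.3f", mean(!is.na(x$outcomes$pu_time))), "\n", sep = "")
  invisible(x)
}

#' Hide a fraction of observed cells for imputation evaluation
#'
#' Selects a seeded random subset of currently observed non-medication cells,
#' hides them (value `NA`, mask 0, delta recomputed), and returns both the
#' re-masked grids and the evaluation masks. The held-out cells are disjoint
#' from the cells the model sees, so the model's imputation estimates at
#' those cells are genuine predictions.
#'
#' @param grids Preprocessed `icu_grids`.
#' @param frac Fraction of observed cells to hide.
#' @param seed Integer seed.
#' @return List with `grids` (re-masked) and `eval_mask` (list of binary
#'   matrices marking hidden cells).
#' @export
remask_grids <- function(grids, frac = 0.1, seed = 1L) {
  set.seed(seed)
  schema <- attr(grids, "schema")
  med <- schema$kind == "medication"
  held <- purrr::map(grids$mask, function(m) {
    sel <- m == 1 & matrix(runif(length(m)) < frac, nrow(m))
    sel[, med] <- FALSE
    sel * 1
  })
  grids$values <- purrr::map2(grids$values, held, function(v, h) {
    v[h == 1] <- NA_real_; v
  })
  grids$mask <- purrr::map2(grids$mask, held, function(m, h) m * (1 - h))
  grids$delta <- purrr::map(grids$mask, compute_delta)
  list(grids = grids, eval_mask = held)
}

#' Root-mean-square error of imputation estimates on held-out cells
#'
#' @param estimates List of `T x D` matrices of model imputation estimates
#'   (scaled space), aligned with `reference`.
#' @param reference List of `T x D` matrices holding the true values at the
#'   held-out cells (e.g. the pre-remasking grid values).
#' @param eval_mask List of binary matrices from [remask_grids()].
#' @return RMSE (scalar); errors if no cell is held out.
#' @export
imputation_score <- function(estimates, reference, eval_mask) {
  sq <- purrr::pmap(list(estimates, reference, eval_mask), function(e, r, h) {
    (e[h == 1] - r[h == 1])^2
  })
  sq <- unlist(sq, use.names = FALSE)
  if (length(sq) == 0) abort("no held-out cells to score")
  sqrt(mean(sq))
}
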