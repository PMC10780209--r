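test_that("the generator honours missingness settings", {
  vars <- default_sim_variables()
  # no missingness: every non-medication cell observed
  vars0 <- vars; vars0$miss_prob[] <- 0
  sim0 <- simulate_cohort(sim_config(n_patients = 20, variables = vars0,
                                     seed = 2))
  med <- vars0$kind == "medication"
  for (tr in sim0$truth) {
    expect_true(all(tr$mask[, !med] == 1))
  }
  # an 80%-missing lab attains its rate to within +/- 0.03
  sim <- simulate_cohort(sim_config(n_patients = 500, seed = 3))
  rate <- function(v) {
    obs <- vapply(sim$truth, function(tr) sum(tr$mask[, v]), numeric(1))
    tot <- vapply(sim$truth, function(tr) nrow(tr$mask), numeric(1))
    1 - sum(obs) / sum(tot)
  }
  expect_lt(abs(rate("lactate") - 0.80), 0.03)
  expect_lt(abs(rate("ph") - 0.72), 0.03)
  expect_lt(rate("heart_rate"), 0.02)
})

test_that("the cohort is byte-identical under a fixed seed", {
  cfg <- sim_config(n_patients = 25, seed = 17)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$outcomes, s2$outcomes)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cohort(sim_config(n_patients = 25, seed = 18))
  expect_false(identical(s1$events, s3$events))
})

test_that("event prevalence concentrates on its target", {
  cfg <- sim_config(n_patients = 1000, prevalence = 0.04, seed = 5)
  sim <- simulate_cohort(cfg)
  prev <- mean(!is.na(sim$outcomes$pu_time))
  se <- sqrt(0.04 * 0.96 / 1000)
  expect_lt(abs(prev - 0.04), 3 * se)
  # an unreachable target is refused with the attained prevalence
  # one-hour stays cannot reach 99.9% prevalence under any intercept
  expect_error(simulate_cohort(sim_config(n_patients = 30, prevalence = 0.999,
                                          stay_range = c(1, 1), seed = 5)),
               class = "icugrud_config_error")
})

test_that("a deterioration signature precedes the event", {
  sim <- simulate_cohort(sim_config(n_patients = 800, seed = 8))
  oc <- sim$outcomes
  L <- sim$config$onset_lead
  pre_event <- c(); control_win <- c()
  for (i in seq_len(nrow(oc))) {
    tr <- sim$truth[[oc$patient_id[i]]]
    if (!is.na(oc$pu_time[i])) {
      w <- max(1, oc$pu_time[i] - L):oc$pu_time[i]
      pre_event <- c(pre_event, mean(tr$z[w]))
    } else if (length(tr$z) > L) {
      w <- (length(tr$z) - L):length(tr$z)
      control_win <- c(control_win, mean(tr$z[w]))
    }
  }
  tt <- t.test(pre_event, control_win)
  expect_gt(mean(pre_event) - mean(control_win), 0.5)
  expect_lt(tt$p.value, 1e-6)
})

test_that("latent dynamics recover the configured autocorrelation", {
  cfg <- sim_config(n_patients = 300, seed = 13)
  sim <- simulate_cohort(cfg)
  # controls only: the event drift inflates autocorrelation
  zs <- purrr::map(sim$truth[is.na(sim$outcomes$pu_time)], "z")
  # Marriott-Pope small-sample bias correction: E[rho_hat] ~ rho - (1+3rho)/T
  zs <- zs[lengths(zs) > 30]
  ac <- purrr::map_dbl(zs, function(z) {
    stats::cor(z[-1], z[-length(z)]) + (1 + 3 * cfg$rho) / length(z)
  })
  expect_lt(abs(mean(ac) - cfg$rho), 0.05)
})

test_that("imputation scoring behaves at its anchors", {
  p <- small_prep()
  spec <- p$spec
  prep <- p$valid
  rem <- remask_grids(prep, frac = 0.2, seed = 23)
  # score on the lab channels: vitals here are noise-dominated (loading
  # 0.25 vs noise 1), so even a perfect imputer can barely beat the mean
  # on them, whereas lab values are strongly predictable from the state
  labs <- c("lactate", "ph", "creatinine", "wbc", "albumin", "glucose")
  lab_only <- function(h) {
    h[, setdiff(colnames(h), labs)] <- 0
    h
  }
  held <- sum(unlist(purrr::map(rem$eval_mask, sum)))
  expect_gt(held, 0)
  # held-out cells really are hidden from the model's view
  for (i in seq_len(nrow(prep))) {
    h <- rem$eval_mask[[i]] == 1
    expect_true(all(rem$grids$mask[[i]][h] == 0))
    expect_true(all(is.na(rem$grids$values[[i]][h])))
  }
  # the truth itself scores zero
  expect_equal(imputation_score(prep$values, prep$values, rem$eval_mask), 0)
  lab_mask <- purrr::map(rem$eval_mask, lab_only)
  # a constant-mean imputer scores about one (scaled) SD of the truth
  obs <- unlist(purrr::map2(prep$values, lab_mask, function(v, h) v[h == 1]))
  mean_imp <- purrr::map(prep$values, function(v) {
    matrix(rep(spec$train_mean, each = nrow(v)), nrow(v))
  })
  rmse_mean <- imputation_score(mean_imp, prep$values, lab_mask)
  expect_lt(abs(rmse_mean - stats::sd(obs)), 0.25 * stats::sd(obs))
  # a reconstruction-weighted GRU-D++ head beats the constant-mean imputer
  # on the held-out lab cells
  fit <- cached("imp_fit", {
    train_grud(p$train, p$valid, variant = "grudpp", H = 32, lambda = 1,
               epochs = 25, patience = 99, seed = 42)
  })
  sc <- predict(fit, rem$grids, type = "imputation")
  rmse_model <- imputation_score(sc$imputed, prep$values, lab_mask)
  expect_lt(rmse_model, rmse_mean)
  expect_error(imputation_score(prep$values, prep$values,
                                purrr::map(rem$eval_mask, function(m) m * 0)),
               "no held-out")
})
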