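test_that("hourly resampling aggregates by variable kind", {
  schema <- tiny_schema()
  events <- tibble::tibble(
    patient_id = "a",
    time_hours = c(2.1, 2.9, 6.5, 0.5, 3.2, 3.7),
    variable = c("hr", "hr", "vaso", "lact", "gcs", "gcs"),
    value = c("4.0", "6.0", "1", "2.5", "drowsy", "coma")
  )
  g <- resample_hourly(events, schema,
                       tibble::tibble(patient_id = "a", stay_hours = 8))
  v <- g$values[[1]]; m <- g$mask[[1]]
  expect_equal(nrow(v), 8)
  # continuous: mean of the two in-hour samples
  expect_equal(unname(v[3, "hr"]), 5.0)
  expect_equal(unname(m[3, "hr"]), 1)
  # categorical: worst category (severity code 1 = coma)
  expect_equal(unname(v[4, "gcs"]), 1)
  # medication: binarised; hours without a record are 0 with mask 0
  expect_equal(unname(v[7, "vaso"]), 1)
  expect_equal(unname(m[7, "vaso"]), 1)
  expect_equal(unname(v[8, "vaso"]), 0)
  expect_equal(unname(m[8, "vaso"]), 0)
  # unsampled continuous hours are missing
  expect_true(is.na(v[5, "hr"]))
  expect_equal(unname(m[5, "hr"]), 0)
})

test_that("resampling validates schema membership and timestamps", {
  schema <- tiny_schema()
  stays <- tibble::tibble(patient_id = "a", stay_hours = 4)
  bad_var <- tibble::tibble(patient_id = "a", time_hours = 1,
                            variable = "unknown", value = "1")
  expect_error(resample_hourly(bad_var, schema, stays),
               class = "icugrud_schema_error")
  bad_time <- tibble::tibble(patient_id = "a", time_hours = -2,
                             variable = "hr", value = "1")
  expect_error(resample_hourly(bad_time, schema, stays),
               class = "icugrud_input_error")
})

test_that("IQR fences match the brute-force quartile oracle", {
  x <- as.numeric(1:100)
  f <- fit_iqr_fences(x)
  expect_equal(unname(f), oracle_fences(x))
  # zero-spread: fences coincide, only different values would be discarded
  expect_message(f5 <- fit_iqr_fences(rep(5, 10)), "no-op")
  expect_equal(unname(f5), c(5, 5))
  # a gross outlier falls outside the upper fence
  y <- c(0, 0, 0, 0, 1000)
  fy <- fit_iqr_fences(y)
  expect_gt(1000, fy["fence_high"])
  expect_equal(unname(fy), oracle_fences(y))
  # random instances
  for (s in 1:25) {
    set.seed(s)
    z <- rnorm(sample(4:60, 1))
    expect_equal(unname(fit_iqr_fences(z)), oracle_fences(z))
  }
  expect_error(fit_iqr_fences(c(1, 2, 3)), "at least 4")
})

test_that("IQR filtering converts out-of-fence cells to missing, cellwise", {
  schema <- variable_schema(paste0("v", 1:5), "continuous")
  set.seed(7)
  g <- random_grid(20, 5, seed = 7)
  grids <- as_grids(g$values, g$mask, schema)
  attr(grids, "scaled") <- NULL          # raw-unit grid, raw-unit fences
  spec <- schema
  spec$fence_low <- rep(-1, 5); spec$fence_high <- rep(1, 5)
  out <- apply_iqr_filter(grids, spec)
  vo <- out$values[[1]]; mo <- out$mask[[1]]
  for (t in 1:20) for (d in 1:5) {
    x <- g$values[t, d]
    if (!is.na(x) && (x < -1 || x > 1)) {
      expect_true(is.na(vo[t, d])); expect_equal(mo[t, d], 0)
    } else {
      expect_equal(vo[t, d], x); expect_equal(mo[t, d], g$mask[t, d])
    }
  }
  # observed count never increases; a clean grid is untouched
  expect_lte(sum(mo), sum(g$mask))
  spec$fence_low <- rep(-Inf, 5); spec$fence_high <- rep(Inf, 5)
  same <- apply_iqr_filter(grids, spec)   # no fences bind: identity
  expect_equal(same$values[[1]], g$values)
})

test_that("min-max scaling maps the training range onto [-1, 1] exactly", {
  x <- c(3, 9, 6, 4.5)
  mm <- fit_minmax(x)
  sc <- icugrud:::scale_values(x, mm[1], mm[2])
  expect_equal(sc[which.min(x)], -1)
  expect_equal(sc[which.max(x)], 1)
  expect_equal(unname(icugrud:::scale_values(mean(range(x)), mm[1], mm[2])),
               0)
  # affine round trip on a random grid
  schema <- variable_schema(paste0("v", 1:4), "continuous")
  g <- random_grid(15, 4, seed = 3)
  grids <- as_grids(g$values * 10 + 2, g$mask, schema)
  spec <- schema
  spec$scale_min <- rep(-20, 4); spec$scale_max <- rep(30, 4)
  spec$fence_low <- rep(-Inf, 4); spec$fence_high <- rep(Inf, 4)
  attr(grids, "scaled") <- NULL
  scaled <- minmax_scale(grids, spec)
  back <- minmax_unscale(scaled, spec)
  expect_equal(back$values[[1]], grids$values[[1]], tolerance = 1e-10)
  # degenerate variable maps to constant 0 with a warning
  spec$scale_max[2] <- spec$scale_min[2] <- 1
  attr(grids, "scaled") <- NULL
  expect_warning(z <- minmax_scale(grids, spec), "degenerate")
})

test_that("delta recurrence matches the per-column scan oracle", {
  m_full <- matrix(1, 6, 1)
  expect_equal(compute_delta(m_full)[, 1], c(0, 1, 1, 1, 1, 1))
  m <- matrix(0, 6, 1); m[c(1, 4), 1] <- 1
  expect_equal(compute_delta(m)[, 1], c(0, 1, 2, 3, 1, 2))
  for (s in 1:100) {
    set.seed(s)
    mk <- matrix(rbinom(30 * 8, 1, runif(1, 0.1, 0.9)), 30, 8)
    expect_equal(compute_delta(mk), oracle_delta(mk))
  }
})

test_that("forward-then-mean fill matches the two-pass oracle", {
  schema <- variable_schema(c("a", "b"), "continuous")
  v <- cbind(c(2, NA, NA), c(NA, NA, 3))
  m <- 1 * !is.na(v)
  grids <- as_grids(v, m, schema)
  spec <- schema
  spec$train_mean <- c(0.5, 0.5)
  filled <- forward_then_mean_fill(grids, spec)
  expect_equal(unname(filled$x[[1]]), cbind(c(2, 2, 2), c(0.5, 0.5, 3)))
  expect_equal(filled$mask[[1]], m)  # mask unchanged
  for (s in 1:100) {
    set.seed(s)
    g <- random_grid(sample(5:50, 1), sample(2:10, 1),
                     p_obs = runif(1, 0.1, 0.9), seed = s)
    schema_s <- variable_schema(paste0("v", seq_len(ncol(g$values))),
                                "continuous")
    spec_s <- schema_s
    spec_s$train_mean <- rnorm(ncol(g$values))
    gr <- as_grids(g$values, g$mask, schema_s)
    filled_s <- forward_then_mean_fill(gr, spec_s)
    expect_equal(unname(filled_s$x[[1]]),
                 oracle_fill(g$values, spec_s$train_mean))
    expect_false(anyNA(filled_s$x[[1]]))
  }
})

test_that("preprocessing is idempotent and fits on training data only", {
  sim <- simulate_cohort(sim_config(n_patients = 40, seed = 5))
  grids <- resample_hourly(sim$events, sim$schema,
                           sim$outcomes[, c("patient_id", "stay_hours")])
  train <- grids[1:30, ]; valid <- grids[31:40, ]
  spec <- fit_preprocessor(train)
  once <- apply_preprocessor(valid, spec, fill = TRUE)
  twice <- forward_then_mean_fill(
    minmax_scale(apply_iqr_filter(once, spec), spec), spec)
  expect_equal(twice$values, once$values)
  expect_equal(twice$mask, once$mask)
  expect_equal(twice$x, once$x)
  # perturbing validation data must not change fitted statistics
  valid2 <- valid
  valid2$values <- purrr::map(valid2$values, function(v) v * 3 + 10)
  spec2 <- fit_preprocessor(train)
  expect_identical(spec, spec2)
})

test_that("external rescaling maps median/IQR onto the internal cohort", {
  schema <- variable_schema(c("a", "b"), "continuous")
  set.seed(11)
  v <- matrix(runif(200, 3, 7), 100, 2)  # no Tukey outliers: fences inert
  grids <- as_grids(v, matrix(1, 100, 2), schema)
  attr(grids, "scaled") <- NULL
  spec <- fit_preprocessor(grids)

  # identical distribution: identity map
  map_id <- fit_rescale(grids, spec)
  expect_equal(map_id$slope, c(1, 1), tolerance = 1e-9)
  expect_equal(map_id$shift, c(0, 0), tolerance = 1e-9)

  # exact affine shift: closed-form inversion recovers internal stats
  ext <- grids
  ext$values <- purrr::map(ext$values, function(x) x * 2 + 10)
  map_aff <- fit_rescale(ext, spec)
  mapped <- apply_rescale(ext, map_aff)
  for (j in 1:2) {
    mv <- mapped$values[[1]][, j]
    expect_equal(median(mv), spec$train_median[j], tolerance = 1e-9)
    expect_equal(unname(diff(quantile(mv, c(0.25, 0.75)))),
                 spec$train_iqr[j], tolerance = 1e-9)
  }

  # constant external variable: pure shift onto the internal median
  ext2 <- grids
  ext2$values <- purrr::map(ext2$values, function(x) { x[, 1] <- 7; x })
  map_c <- fit_rescale(ext2, spec)
  expect_equal(map_c$slope[1], 1)
  expect_equal(map_c$shift[1], spec$train_median[1] - 7)
})
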