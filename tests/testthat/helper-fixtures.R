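# Shared fixtures, built in code. Heavy objects are created lazily and
# cached for the whole run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

tiny_schema <- function() {
  variable_schema(
    name = c("hr", "lact", "gcs", "vaso"),
    kind = c("continuous", "continuous", "categorical", "medication"),
    severity_order = list(NULL, NULL, c("coma", "drowsy", "alert"), NULL)
  )
}

# A random small grid (values/mask/delta) in scaled space.
random_grid <- function(T_ = 20, D = 5, p_obs = 0.6, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(T_ * D, 1, p_obs), T_, D)
  v <- matrix(rnorm(T_ * D), T_, D)
  v[m == 0] <- NA
  list(values = v, mask = m, delta = compute_delta(m))
}

# Wrap matrices into a one-patient icu_grids tibble with a generic schema.
as_grids <- function(values, mask, schema = NULL, y = NULL) {
  D <- ncol(values)
  if (is.null(schema)) {
    schema <- variable_schema(paste0("v", seq_len(D)), "continuous")
  }
  dlt <- compute_delta(mask)
  g <- tibble::tibble(
    patient_id = "p1", n_hours = nrow(values),
    values = list(values), mask = list(mask),
    delta = list(dlt)
  )
  if (!is.null(y)) {
    g$y <- list(as.integer(y))
    g$is_case <- any(y == 1)
  }
  g <- icugrud:::new_icu_grids(g, schema)
  attr(g, "scaled") <- TRUE
  g
}

# Small fully prepared cohort used across model/evaluation tests.
small_prep <- function() {
  cached("small_prep", {
    sim <- simulate_cohort(sim_config(n_patients = 150, seed = 42))
    prepare_cohort(sim$events, sim$outcomes, sim$schema,
                   horizon = 24, seed = 42)
  })
}

# A quickly trained GRU-D++ fit on the small cohort.
small_fit <- function() {
  cached("small_fit", {
    p <- small_prep()
    train_grud(p$train, p$valid, variant = "grudpp", H = 16,
               epochs = 12, patience = 12, seed = 42)
  })
}

# Independent reference implementations (oracles) ------------------------

# Quartiles by linear interpolation between order statistics, written
# directly from the definition (type-7 plotting positions).
oracle_quartile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_fences <- function(x) {
  q1 <- oracle_quartile(x, 0.25); q3 <- oracle_quartile(x, 0.75)
  c(q1 - 1.5 * (q3 - q1), q3 + 1.5 * (q3 - q1))
}

# Per-column scan for the hours-since-last-observation matrix.
oracle_delta <- function(mask) {
  out <- matrix(0, nrow(mask), ncol(mask))
  for (d in seq_len(ncol(mask))) {
    for (t in seq_len(nrow(mask))) {
      if (t == 1) out[t, d] <- 0
      else if (mask[t - 1, d] == 1) out[t, d] <- 1
      else out[t, d] <- 1 + out[t - 1, d]
    }
  }
  out
}

# Two-pass fill: carry last observation forward, then constant-fill.
oracle_fill <- function(values, mu) {
  for (d in seq_len(ncol(values))) {
    last <- NA_real_
    for (t in seq_len(nrow(values))) {
      if (!is.na(values[t, d])) last <- values[t, d]
      else values[t, d] <- if (is.na(last)) mu[d] else last
    }
  }
  values
}

# O(n^2) pairwise concordance.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# Precision-recall area by explicit threshold sweep over distinct scores.
oracle_auprc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  rec_prev <- 0; area <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel]) / sum(sel)
    rec <- sum(labels[sel]) / sum(labels)
    area <- area + (rec - rec_prev) * prec
    rec_prev <- rec
  }
  area
}

# Plain GRU forward in R, same gate convention as the compiled cell.
oracle_gru <- function(X, theta, D, H) {
  blk <- function(nm) icugrud:::param_block(theta, D, H, nm)
  Wz <- blk("Wz"); Uz <- blk("Uz"); bz <- blk("bz")
  Wr <- blk("Wr"); Ur <- blk("Ur"); br <- blk("br")
  Wc <- blk("Wc"); Uc <- blk("Uc"); bc <- blk("bc")
  w_out <- blk("w_out"); b_out <- blk("b_out"); h <- blk("h0")
  p <- numeric(nrow(X)); hs <- matrix(0, nrow(X), H)
  for (t in seq_len(nrow(X))) {
    x <- X[t, ]
    z <- plogis(Wz %*% x + Uz %*% h + bz)
    r <- plogis(Wr %*% x + Ur %*% h + br)
    c_ <- tanh(Wc %*% x + Uc %*% (r * h) + bc)
    h <- (1 - z) * h + z * c_
    hs[t, ] <- h
    p[t] <- plogis(sum(w_out * h) + b_out)
  }
  list(p = p, h = hs)
}
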