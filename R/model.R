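#' Assemble compiled-engine inputs from labeled grids
#' @noRd
model_inputs <- function(grids, flags, need_y = TRUE) {
  if (!"delta" %in% names(grids)) grids <- add_delta(grids)
  xs <- if (flags$impute == 0L) {
    if (!"x" %in% names(grids)) {
      abort("this variant needs pre-filled inputs: run forward_then_mean_fill()")
    }
    grids$x
  } else {
    grids$values
  }
  ys <- if (need_y) {
    if (!"y" %in% names(grids)) abort("grids carry no labels: run attach_labels()")
    purrr::map(grids$y, as.numeric)
  } else {
    purrr::map(grids$n_hours, numeric)
  }
  list(xs = purrr::map(xs, function(v) unname(as.matrix(v))),
       ms = purrr::map(grids$mask, function(v) unname(as.matrix(v))),
       dls = purrr::map(grids$delta, function(v) unname(as.matrix(v))),
       ys = ys)
}

xemp_for <- function(spec, flags, D) {
  if (flags$impute == 1L) {
    if (anyNA(spec$train_mean)) abort("GRU-D needs fitted training means")
    spec$train_mean
  } else {
    numeric(D)
  }
}

#' Per-timestep risk and imputation estimates for one sequence
#'
#' Thin wrapper over the compiled cell, mostly useful for testing and for
#' hand-rolled inference; [predict.grud_fit()] is the user-facing route.
#'
#' @param values `T x D` matrix (`NA` = missing) — or a complete matrix for
#'   the `gru`/`rnn` variants.
#' @param mask,delta Binary observation mask and hours-since-observation.
#' @param theta Flat parameter vector.
#' @param D,H Dimensions.
#' @param variant See [variant_flags()].
#' @param xemp Frozen empirical means (GRU-D fallback), scaled space.
#' @param lambda Reconstruction weight (controls whether the head runs).
#' @return List with `p` (length-`T` risks), `h` (`T x H` hidden states),
#'   `r` (`T x D` imputation estimates, empty when the variant has no head)
#'   and `xhat` (`T x D` imputed inputs).
#' @export
grud_forward <- function(values, mask, delta, theta, D, H,
                         variant = "grudpp", xemp = numeric(D),
                         lambda = variant_flags(variant)$lambda) {
  fl <- variant_flags(variant)
  out <- cpp_seq_forward(unname(as.matrix(values)), unname(as.matrix(mask)),
                         unname(as.matrix(delta)), theta, D, H, fl, xemp,
                         lambda)
  out$p <- as.numeric(out$p)
  out
}

#' Joint classification + reconstruction loss and its gradient
#'
#' The training objective: per patient, positive-class-weighted binary
#' cross-entropy of the hourly risks averaged over timesteps, plus
#' `lambda` times the masked mean squared error between the imputation
#' head's estimates and the observed values; both averaged over patients.
#' The gradient is computed by analytic backpropagation through time in
#' compiled code.
#'
#' @param grids Labeled, preprocessed `icu_grids`.
#' @param theta Flat parameter vector.
#' @param D,H Dimensions.
#' @param variant See [variant_flags()].
#' @param spec Fitted schema (for the GRU-D empirical-mean fallback).
#' @param lambda Reconstruction weight (`lambda = 0` recovers pure
#'   classification).
#' @param w_pos Positive-class weight (>= 1).
#' @return List with scalar `loss` and the flat `grad` vector.
#' @export
grud_loss_grad <- function(grids, theta, D, H, variant = "grudpp",
                           spec = attr(grids, "schema"),
                           lambda = variant_flags(variant)$lambda,
                           w_pos = 1) {
  fl <- variant_flags(variant)
  inp <- model_inputs(grids, fl)
  out <- cpp_batch_loss_grad(inp$xs, inp$ms, inp$dls, inp$ys, theta, D, H,
                             fl, xemp_for(spec, fl, D), lambda, w_pos)
  out$grad <- as.numeric(out$grad)
  out
}

#' Train a recurrent in-advance risk model
#'
#' Mini-batch Adam on the joint loss with early stopping on model-selection
#' AUROC (risk vs label pooled over every timestep of the model-selection
#' split). The run is bit-reproducible from `seed`: parameter
#' initialisation, batch shuffling and nothing else consume randomness.
#'
#' @param train,valid Labeled, preprocessed `icu_grids` (disjoint patients).
#'   Pass `valid = NULL` to train for a fixed number of epochs.
#' @param variant Model variant; see [variant_flags()].
#' @param H Hidden size.
#' @param lambda Reconstruction weight; default per variant.
#' @param w_pos Positive-timestep class weight; `NULL` (default) uses
#'   1 / (prevalence of positive timesteps in `train`), the usual inverse
#'   frequency weighting, floored at 1.
#' @param lr,batch_size,epochs,patience Optimiser settings.
#' @param theta Optional warm-start parameter vector (used by [finetune()]).
#' @param seed Integer seed.
#' @param verbose Print per-epoch progress.
#' @return A `grud_fit` object: parameters at the best epoch, dimensions,
#'   variant, fitted schema, optimiser config, and per-epoch `history`.
#' @export
train_grud <- function(train, valid = NULL, variant = "grudpp",
                       H = 64, lambda = variant_flags(variant)$lambda,
                       w_pos = NULL, lr = 1e-3, batch_size = 32,
                       epochs = 50, patience = 5, theta = NULL,
                       seed = 1L, verbose = FALSE) {
  if (nrow(train) == 0) abort("empty training split")
  fl <- variant_flags(variant)
  spec <- attr(train, "schema")
  D <- nrow(spec)
  if (is.null(w_pos)) {
    ypos <- sum(purrr::map_dbl(train$y, sum))
    ytot <- sum(lengths(train$y))
    w_pos <- max(1, ytot / max(ypos, 1))
  }
  set.seed(seed)
  if (is.null(theta)) theta <- grud_init_params(D, H, seed = seed)
  stopifnot(length(theta) == n_params(D, H))

  inp <- model_inputs(train, fl)
  vinp <- if (!is.null(valid)) model_inputs(valid, fl)
  xemp <- xemp_for(spec, fl, D)

  m <- numeric(length(theta)); v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0
  n <- length(inp$xs)
  history <- vector("list", epochs)
  best <- list(auroc = -Inf, theta = theta, epoch = 0L)
  wait <- 0L

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      lg <- cpp_batch_loss_grad(inp$xs[b], inp$ms[b], inp$dls[b], inp$ys[b],
                                theta, D, H, fl, xemp, lambda, w_pos)
      if (!is.finite(lg$loss)) {
        abort(sprintf("non-finite loss at epoch %d", ep))
      }
      step <- step + 1
      g <- as.numeric(lg$grad)
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mhat <- m / (1 - b1^step)
      vhat <- v / (1 - b2^step)
      theta <- theta - lr * mhat / (sqrt(vhat) + eps)
      ep_loss <- ep_loss + lg$loss * length(b)
    }
    ep_loss <- ep_loss / n
    val_auroc <- NA_real_
    if (!is.null(vinp)) {
      sc <- pooled_scores(vinp, theta, D, H, fl, xemp, lambda)
      val_auroc <- tryCatch(auroc(sc$p, sc$y), icugrud_metric_error =
                              function(e) NA_real_)
      if (!is.na(val_auroc) && val_auroc > best$auroc) {
        best <- list(auroc = val_auroc, theta = theta, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    history[[ep]] <- tibble::tibble(epoch = ep, train_loss = ep_loss,
                                    val_auroc = val_auroc)
    if (verbose) {
      message(sprintf("epoch %d  loss %.4f  val auroc %s", ep, ep_loss,
                      ifelse(is.na(val_auroc), "-", sprintf("%.4f", val_auroc))))
    }
    if (!is.null(vinp) && wait >= patience) break
  }

  if (is.null(vinp) || !is.finite(best$auroc)) {
    best <- list(auroc = NA_real_, theta = theta,
                 epoch = length(purrr::compact(history)))
  }
  structure(list(
    theta = best$theta, D = D, H = H, variant = variant, flags = fl,
    lambda = lambda, w_pos = w_pos, spec = spec,
    config = list(lr = lr, batch_size = batch_size, epochs = epochs,
                  patience = patience, seed = seed),
    history = dplyr::bind_rows(purrr::compact(history)),
    best_epoch = best$epoch, best_val_auroc = best$auroc
  ), class = "grud_fit")
}

pooled_scores <- function(inp, theta, D, H, fl, xemp, lambda) {
  out <- purrr::pmap(list(inp$xs, inp$ms, inp$dls), function(x, mk, dl) {
    as.numeric(cpp_seq_forward(x, mk, dl, theta, D, H, fl, xemp, lambda)$p)
  })
  list(p = unlist(out, use.names = FALSE),
       y = unlist(inp$ys, use.names = FALSE))
}

#' @export
print.grud_fit <- function(x, ...) {
  cat("<grud_fit> variant ", x$variant, ", D=", x$D, ", H=", x$H,
      ", ", length(x$theta), " parameters\n", sep = "")
  if (!is.na(x$best_val_auroc)) {
    cat("best epoch ", x$best_epoch, " (model-selection AUROC ",
        sprintf("%.4f", x$best_val_auroc), ")\n", sep = "")
  }
  invisible(x)
}

#' Hourly risk (and imputation) predictions for a cohort
#'
#' @param object A `grud_fit`.
#' @param grids Preprocessed `icu_grids` (same schema/statistics as
#'   training).
#' @param type `"risk"` adds a `risk` list-column of per-hour event
#'   probabilities; `"imputation"` also adds the head's `T x D` estimates.
#' @param ... Unused.
#' @return `grids` with prediction list-columns.
#' @export
predict.grud_fit <- function(object, grids, type = c("risk", "imputation"),
                             ...) {
  type <- match.arg(type)
  fl <- object$flags
  inp <- model_inputs(grids, fl, need_y = FALSE)
  xemp <- xemp_for(object$spec, fl, object$D)
  lam <- if (type == "imputation") max(object$lambda, 1e-12) else object$lambda
  out <- purrr::pmap(list(inp$xs, inp$ms, inp$dls), function(x, mk, dl) {
    cpp_seq_forward(x, mk, dl, object$theta, object$D, object$H, fl, xemp, lam)
  })
  grids$risk <- purrr::map(out, function(o) as.numeric(o$p))
  if (type == "imputation") grids$imputed <- purrr::map(out, "r")
  grids
}
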