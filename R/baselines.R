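#' Single-hour logistic-regression baseline
#'
#' The classical comparator: each patient-hour is one independent row of
#' the filled (forward-then-mean) design matrix and a plain logistic
#' regression predicts the hour's label. No temporal information crosses
#' hours, which is exactly the handicap the recurrent models remove.
#' (Tree and boosting baselines would slot in the same way but are not
#' shipped: no such engine is available to this package's dependencies.)
#'
#' @param train Labeled, preprocessed `icu_grids` with a filled `x` column.
#' @return An `hourly_baseline` object with a [predict()] method that adds
#'   a `risk` list-column, so [evaluate_horizons()] applies unchanged.
#' @export
fit_baseline_lr <- function(train) {
  if (is.null(train$x)) abort("baseline needs filled inputs (x)")
  X <- do.call(rbind, train$x)
  y <- unlist(train$y, use.names = FALSE)
  df <- as.data.frame(X)
  names(df) <- make.names(colnames(X))
  df$.y <- y
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  structure(list(glm = fit, vars = names(df)[names(df) != ".y"]),
            class = "hourly_baseline")
}

#' @export
predict.hourly_baseline <- function(object, grids, ...) {
  grids$risk <- purrr::map(grids$x, function(v) {
    df <- as.data.frame(v)
    names(df) <- make.names(colnames(v))
    unname(predict(object$glm, newdata = df, type = "response"))
  })
  grids
}
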