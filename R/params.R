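# Parameter vector layout; must mirror Params::walk()/pack() in src/grud.cpp.

grud_param_layout <- function(D, H) {
  tibble::tibble(
    name = c("Wz", "Uz", "Vz", "bz", "Wr", "Ur", "Vr", "br",
             "Wc", "Uc", "Vc", "bc", "w_gx", "b_gx", "W_gh", "b_gh",
             "x_tilde", "x_init", "W_imp", "b_imp", "w_out", "b_out", "h0"),
    rows = c(H, H, H, H, H, H, H, H, H, H, H, H, D, D, H, H,
             D, D, D, D, H, 1, H),
    cols = c(D, H, D, 1, D, H, D, 1, D, H, D, 1, 1, 1, D, 1,
             1, 1, H, 1, 1, 1, 1)
  ) |>
    dplyr::mutate(size = .data$rows * .data$cols,
                  offset = cumsum(.data$size) - .data$size)
}

n_params <- function(D, H) sum(grud_param_layout(D, H)$size)

#' Extract one named parameter block from a flat parameter vector
#' @noRd
param_block <- function(theta, D, H, name) {
  lay <- grud_param_layout(D, H)
  i <- match(name, lay$name)
  v <- theta[lay$offset[i] + seq_len(lay$size[i])]
  if (lay$cols[i] > 1) matrix(v, lay$rows[i], lay$cols[i]) else v
}

#' Overwrite one named block in a flat parameter vector
#' @noRd
set_param_block <- function(theta, D, H, name, value) {
  lay <- grud_param_layout(D, H)
  i <- match(name, lay$name)
  theta[lay$offset[i] + seq_len(lay$size[i])] <- as.numeric(value)
  theta
}

#' Initialise the trainable parameters of a recurrent risk model
#'
#' Gate weights are drawn uniformly in `[-1/sqrt(H), 1/sqrt(H)]`; the
#' trainable fallback `x_tilde`, last-observation seed `x_init`, biases and
#' the initial hidden state start at 0 (the centre of the scaled value
#' space). Input-decay rates start at a gentle 0.05/hour (observation
#' half-life around 14 h) and hidden-decay weights near zero, so decay is
#' active but mild before training.
#'
#' @param D Number of input variables.
#' @param H Hidden size.
#' @param seed Integer seed for the draws.
#' @return Numeric parameter vector (flat, fixed layout).
#' @export
grud_init_params <- function(D, H, seed = 1L) {
  set.seed(seed)
  lay <- grud_param_layout(D, H)
  theta <- numeric(sum(lay$size))
  s <- 1 / sqrt(H)
  for (nm in c("Wz", "Uz", "Vz", "Wr", "Ur", "Vr", "Wc", "Uc", "Vc",
               "W_imp", "w_out")) {
    i <- match(nm, lay$name)
    theta[lay$offset[i] + seq_len(lay$size[i])] <- runif(lay$size[i], -s, s)
  }
  theta <- set_param_block(theta, D, H, "w_gx", rep(0.05, D))
  i <- match("W_gh", lay$name)
  theta[lay$offset[i] + seq_len(lay$size[i])] <- runif(lay$size[i], -0.01, 0.01)
  theta
}

#' Flags selecting a model variant in the compiled engine
#'
#' @param variant One of `"grudpp"` (decay + mask input + hidden-state
#'   imputation head), `"grud"` (decay + mask input + frozen empirical-mean
#'   fallback), `"grud_trainable"` (decay + mask input + trainable static
#'   fallback), `"gru"` (plain GRU on pre-filled inputs), `"rnn"` (simple
#'   tanh RNN on pre-filled inputs).
#' @return List of integer flags (`cell`, `decay`, `mask_in`, `impute`) and
#'   the default reconstruction weight `lambda`.
#' @export
variant_flags <- function(variant = c("grudpp", "grud", "grud_trainable",
                                      "gru", "rnn")) {
  variant <- match.arg(variant)
  switch(variant,
    grudpp = list(cell = 0L, decay = 1L, mask_in = 1L, impute = 2L, lambda = 0.1),
    grud = list(cell = 0L, decay = 1L, mask_in = 1L, impute = 1L, lambda = 0),
    grud_trainable = list(cell = 0L, decay = 1L, mask_in = 1L, impute = 3L,
                          lambda = 0.1),
    gru = list(cell = 0L, decay = 0L, mask_in = 0L, impute = 0L, lambda = 0),
    rnn = list(cell = 1L, decay = 0L, mask_in = 0L, impute = 0L, lambda = 0)
  )
}
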