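#' Logistic sigmoid transfer function
#'
#' The transfer function used by the ANN rate law, `1 / (1 + exp(-x))`.
#' Kept as a single exported function so an alternative sigmoid can be
#' swapped in through the `transfer` argument of [ann_rate()].
#'
#' @param x numeric.
#' @return numeric in (0, 1).
#' @export
sigmoid_logistic <- function(x) 1 / (1 + exp(-x))

#' ANN rate law: right-hand side of the recurrent-network ODE system
#'
#' `dX_i/dt = v_i * f(sum_j w_ij X_j - theta_i) - k_i X_i`, with `f` a
#' sigmoid transfer function.  The production term of each gene is bounded
#' in (0, v_i) for every finite state.
#'
#' @param state numeric concentration vector of length N, finite.
#' @param params an [ann_params()].
#' @param transfer the sigmoid transfer function (default
#'   [sigmoid_logistic()]).
#' @return rate vector dX/dt of length N.
#' @export
ann_rate <- function(state, params, transfer = sigmoid_logistic) {
  stopifnot(inherits(params, "ann_params"))
  n <- length(params$v)
  if (length(state) != n) stop("state length must equal N", call. = FALSE)
  if (!all(is.finite(state))) stop("state entries must be finite",
                                   call. = FALSE)
  as.numeric(params$v * transfer(params$w %*% state - params$theta) -
               params$k * state)
}

#' S-system rate law: difference of two power-law products
#'
#' `dX_i/dt = alpha_i prod_j X_j^g_ij - beta_i prod_j X_j^h_ij`.  A
#' non-positive concentration raised to a negative kinetic order is the
#' S-system singularity: it raises a condition of class
#' `grn_singularity_error`.
#'
#' @param state numeric concentration vector of length N.
#' @param params an [ss_params()].
#' @return rate vector dX/dt of length N.
#' @export
ss_rate <- function(state, params) {
  stopifnot(inherits(params, "ss_params"))
  n <- length(params$alpha)
  if (length(state) != n) stop("state length must equal N", call. = FALSE)
  bad_g <- params$g < 0 & matrix(state <= 0, n, n, byrow = TRUE)
  bad_h <- params$h < 0 & matrix(state <= 0, n, n, byrow = TRUE)
  if (any(bad_g) || any(bad_h)) {
    stop(structure(class = c("grn_singularity_error", "error", "condition"),
                   list(message = paste("S-system singularity: non-positive",
                                        "concentration with negative kinetic",
                                        "order"),
                        call = sys.call())))
  }
  xc <- pmax(state, 1e-12)
  pow <- function(M) apply(M, 1, function(e) prod(xc^e))
  as.numeric(params$alpha * pow(params$g) - params$beta * pow(params$h))
}

#' GRLOT rate law: product of Hill-type regulatory factors
#'
#' `dX_i/dt = v_i * prod(inhibitor factors) * prod(activator factors) -
#' k_i X_i`, with activator factor `X^n / (X^n + K^n)` and inhibitor factor
#' `K^n / (X^n + K^n)`.  Each factor lies in (0, 1); a gene with no
#' regulators has production exactly `v_i`.
#'
#' @param state numeric concentration vector of length N, entries >= 0
#'   (negative concentrations with non-integer exponents are a domain error).
#' @param params a [grlot_params()].
#' @return rate vector dX/dt of length N.
#' @export
grlot_rate <- function(state, params) {
  stopifnot(inherits(params, "grlot_params"))
  n <- length(params$v)
  if (length(state) != n) stop("state length must equal N", call. = FALSE)
  reg <- params$regulators
  if (nrow(reg)) {
    noninteger <- abs(reg$n - round(reg$n)) > 0
    if (any(state[reg$source] < 0 & noninteger)) {
      stop("negative concentration with non-integer Hill exponent",
           call. = FALSE)
    }
  }
  production <- params$v
  for (r in seq_len(nrow(reg))) {
    x <- max(state[reg$source[r]], 0)
    ratio <- (x / reg$K[r])^reg$n[r]
    f <- if (reg$role[r] == "activator") {
      if (is.infinite(ratio)) 1 else ratio / (1 + ratio)
    } else {
      if (is.infinite(ratio)) 0 else 1 / (1 + ratio)
    }
    production[reg$target[r]] <- production[reg$target[r]] * f
  }
  as.numeric(production - params$k * state)
}

#' Evaluate a model's rate law at a state
#'
#' Dispatches to [ann_rate()], [ss_rate()] or [grlot_rate()] according to
#' the model's method tag.
#'
#' @param model a [grn_model()].
#' @param state concentration vector.
#' @return rate vector dX/dt.
#' @export
model_rate <- function(model, state) {
  switch(model$method,
         ANN = ann_rate(state, model$params),
         SS = ss_rate(state, model$params),
         GRLOT = grlot_rate(state, model$params))
}
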