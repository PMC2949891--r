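# Canonical flat parameter layout shared with the compiled kernels.
#
# theta_full slot order:
#   ANN   : v(1..n), theta(1..n), k(1..n), w column-major (n x n)
#   SS    : alpha(1..n), beta(1..n), g col-major, h col-major
#   GRLOT : v(1..n), k(1..n), n_reg(1..R), K_reg(1..R); regulators ordered by
#           (target, source), identical to the topology's edge order.
#
# The free (searched) parameters are a documented canonical subsequence of
# theta_full, grouped per gene in ascending gene order:
#   ANN   : v_i, theta_i, k_i, then w_ij for incoming edges (ascending j)
#   SS    : alpha_i, beta_i, h_ii, then g_ij for incoming edges (ascending j)
#   GRLOT : v_i, k_i, then (n, K) per incoming edge (ascending source)
# Masked entries are structurally fixed at zero and never searched; this is
# also the vector order used by the inferential-power correlation.

# Search intervals per parameter class; the Hill-exponent interval depends on
# the regulator role (activator vs inhibitor), and half-saturation constants
# get a positive floor so the rate law stays finite.
default_bound_table <- function() {
  list(ANN = list(v = c(0, 3), theta = c(0, 7), k = c(0, 2), w = c(-15, 15)),
       SS = list(alpha = c(0, 15), beta = c(0, 15), g = c(-3, 3), h = c(-3, 3)),
       GRLOT = list(v = c(0, 3), k = c(0, 2), n_act = c(0, 7),
                    n_inh = c(-5, 5), K = c(1e-3, 40)))
}

grlot_descriptors <- function(topology) {
  e <- topology$edges
  list(target = as.integer(e$to), source = as.integer(e$from),
       role = as.numeric(e$sign))
}

#' Free-parameter layout of a method under a topology
#'
#' Internal bookkeeping describing how a model's parameters map onto the
#' flat vector used by the integrator and by the evolutionary algorithm.
#'
#' @param method one of `"ANN"`, `"SS"`, `"GRLOT"`.
#' @param topology a [grn_topology()].
#' @return list with the flat template, free-slot indices, per-gene slices,
#'   bounds and parameter names.
#' @keywords internal
param_layout <- function(method, topology) {
  check_method(method)
  n <- topology$n_genes
  bt <- default_bound_table()[[method]]
  idx <- integer(0); lower <- numeric(0); upper <- numeric(0)
  nm <- character(0); node <- integer(0)

  add <- function(slot, lo, hi, name, gene) {
    idx <<- c(idx, slot); lower <<- c(lower, lo); upper <<- c(upper, hi)
    nm <<- c(nm, name); node <<- c(node, gene)
  }

  if (method == "ANN") {
    template <- numeric(3 * n + n * n)
    for (i in seq_len(n)) {
      add(i, bt$v[1], bt$v[2], paste0("v", i), i)
      add(n + i, bt$theta[1], bt$theta[2], paste0("theta", i), i)
      add(2 * n + i, bt$k[1], bt$k[2], paste0("k", i), i)
      reg <- regulators_of(topology, i)
      for (j in reg$from) {
        add(3 * n + (j - 1) * n + i, bt$w[1], bt$w[2],
            paste0("w", i, ".", j), i)
      }
    }
  } else if (method == "SS") {
    template <- numeric(2 * n + 2 * n * n)
    for (i in seq_len(n)) {
      add(i, bt$alpha[1], bt$alpha[2], paste0("alpha", i), i)
      add(n + i, bt$beta[1], bt$beta[2], paste0("beta", i), i)
      add(2 * n + n * n + (i - 1) * n + i, bt$h[1], bt$h[2],
          paste0("h", i, ".", i), i)
      reg <- regulators_of(topology, i)
      for (j in reg$from) {
        add(2 * n + (j - 1) * n + i, bt$g[1], bt$g[2],
            paste0("g", i, ".", j), i)
      }
    }
  } else {
    e <- topology$edges
    R <- nrow(e)
    template <- numeric(2 * n + 2 * R)
    for (i in seq_len(n)) {
      add(i, bt$v[1], bt$v[2], paste0("v", i), i)
      add(n + i, bt$k[1], bt$k[2], paste0("k", i), i)
      rows <- which(e$to == i)
      for (r in rows) {
        nb <- if (e$sign[r] > 0) bt$n_act else bt$n_inh
        add(2 * n + r, nb[1], nb[2], paste0("n", i, ".", e$from[r]), i)
        add(2 * n + R + r, bt$K[1], bt$K[2], paste0("K", i, ".", e$from[r]), i)
      }
    }
  }
  node_slices <- split(seq_along(idx), node)
  list(method = method, n = n, template = template, idx = idx,
       lower = lower, upper = upper, names = nm,
       node_slices = node_slices,
       desc = if (method == "GRLOT") grlot_descriptors(topology)
              else list(target = integer(0), source = integer(0),
                        role = numeric(0)))
}

# Flat vector from a model's parameter containers.
theta_from_model <- function(model) {
  n <- model$topology$n_genes
  p <- model$params
  if (model$method == "ANN") {
    c(p$v, p$theta, p$k, as.numeric(p$w))
  } else if (model$method == "SS") {
    c(p$alpha, p$beta, as.numeric(p$g), as.numeric(p$h))
  } else {
    e <- model$topology$edges
    reg <- p$regulators
    if (nrow(reg) != nrow(e)) {
      stop("GRLOT model must define one regulator per topology edge",
           call. = FALSE)
    }
    key_e <- paste(e$to, e$from)
    key_r <- paste(reg$target, reg$source)
    ord <- match(key_e, key_r)
    if (anyNA(ord)) stop("GRLOT regulators do not cover the topology edges",
                         call. = FALSE)
    # role carries the sign: the functional form is fixed by the edge sign,
    # the stored exponent is the (positive) magnitude
    c(p$v, p$k, reg$n[ord], reg$K[ord])
  }
}

# Model from a flat vector (no range validation: used on EA candidates).
model_from_theta <- function(method, topology, theta) {
  n <- topology$n_genes
  if (method == "ANN") {
    params <- structure(list(v = theta[1:n], theta = theta[(n + 1):(2 * n)],
                             k = theta[(2 * n + 1):(3 * n)],
                             w = matrix(theta[-(1:(3 * n))], n, n)),
                        class = "ann_params")
  } else if (method == "SS") {
    params <- structure(list(alpha = theta[1:n], beta = theta[(n + 1):(2 * n)],
                             g = matrix(theta[2 * n + 1:(n * n)], n, n),
                             h = matrix(theta[2 * n + n * n + 1:(n * n)], n, n)),
                        class = "ss_params")
  } else {
    e <- topology$edges
    R <- nrow(e)
    reg <- data.frame(target = e$to, source = e$from,
                      role = ifelse(e$sign > 0, "activator", "inhibitor"),
                      n = if (R) theta[2 * n + seq_len(R)] else numeric(0),
                      K = if (R) theta[2 * n + R + seq_len(R)] else numeric(0))
    params <- structure(list(v = theta[1:n], k = theta[(n + 1):(2 * n)],
                             regulators = reg),
                        class = "grlot_params")
  }
  structure(list(method = method, topology = topology, params = params),
            class = "grn_model")
}

#' Canonical free-parameter vector of a model
#'
#' Concatenation of all unmasked parameters in the documented per-gene order
#' (see [param_layout()]); this is the vector compared by [p_inf()].
#'
#' @param model a [grn_model()].
#' @return named numeric vector.
#' @export
model_free_vector <- function(model) {
  lay <- param_layout(model$method, model$topology)
  th <- theta_from_model(model)
  stats::setNames(th[lay$idx], lay$names)
}

#' Rebuild a model from its canonical free-parameter vector
#'
#' @param method method tag.
#' @param topology a [grn_topology()].
#' @param w numeric vector in the canonical order of [model_free_vector()].
#' @return a `grn_model`.
#' @export
model_from_free_vector <- function(method, topology, w) {
  lay <- param_layout(method, topology)
  if (length(w) != length(lay$idx)) {
    stop("free vector length does not match layout", call. = FALSE)
  }
  th <- lay$template
  th[lay$idx] <- w
  model_from_theta(method, topology, th)
}
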