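#' ANN (recurrent-network) rate-law parameters
#'
#' Houses the maximal expression rates v, connection weights w, external
#' inputs theta and first-order degradation rates k of the recurrent-network
#' formalism dX_i/dt = v_i f(sum_j w_ij X_j - theta_i) - k_i X_i.
#'
#' @param v numeric vector of maximal expression rates (concentration/time),
#'   length N, entries >= 0.
#' @param w N x N numeric matrix of connection weights; `w[i, j]` is the
#'   influence of gene j on gene i (positive activating, negative inhibiting).
#' @param theta numeric vector of external inputs (dimensionless), >= 0.
#' @param k numeric vector of degradation rates (1/time), > 0.
#' @return object of class `ann_params`.
#' @export
ann_params <- function(v, w, theta, k) {
  n <- length(v)
  w <- as.matrix(w)
  stopifnot(length(theta) == n, length(k) == n, all(dim(w) == c(n, n)))
  if (any(v < 0)) stop("v entries must be >= 0", call. = FALSE)
  if (any(theta < 0)) stop("theta entries must be >= 0", call. = FALSE)
  if (any(k <= 0)) stop("k entries must be > 0", call. = FALSE)
  structure(list(v = as.numeric(v), w = unname(w * 1),
                 theta = as.numeric(theta), k = as.numeric(k)),
            class = "ann_params")
}

#' S-system rate-law parameters
#'
#' Power-law kinetics dX_i/dt = alpha_i prod_j X_j^g_ij -
#' beta_i prod_j X_j^h_ij.  The kinetic orders g (production) and h
#' (degradation) may be any reals; their signs encode activation/inhibition.
#'
#' @param alpha numeric vector of activation rate constants, >= 0.
#' @param beta numeric vector of degradation rate constants, > 0.
#' @param g,h N x N numeric matrices of kinetic orders; `g[i, j]` is the
#'   order of gene j in the production term of gene i.
#' @return object of class `ss_params`.
#' @export
ss_params <- function(alpha, beta, g, h) {
  n <- length(alpha)
  g <- as.matrix(g); h <- as.matrix(h)
  stopifnot(length(beta) == n, all(dim(g) == c(n, n)), all(dim(h) == c(n, n)))
  if (any(alpha < 0)) stop("alpha entries must be >= 0", call. = FALSE)
  if (any(beta <= 0)) stop("beta entries must be > 0", call. = FALSE)
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 g = unname(g * 1), h = unname(h * 1)),
            class = "ss_params")
}

#' GRLOT (general rate law of transcription) parameters
#'
#' Hill-type kinetics: production of gene i is v_i times a product of
#' activator factors X^n/(X^n + K^n) and inhibitor factors K^n/(X^n + K^n),
#' minus first-order decay k_i X_i.
#'
#' @param v numeric vector of maximal expression rates, >= 0.
#' @param k numeric vector of degradation rates, > 0.
#' @param regulators data frame with one row per regulatory input and
#'   columns `target`, `source` (gene indices), `role` (`"activator"` or
#'   `"inhibitor"`), `n` (Hill exponent) and `K` (half-saturation
#'   concentration, > 0).
#' @return object of class `grlot_params`.
#' @export
grlot_params <- function(v, k, regulators = NULL) {
  n <- length(v)
  stopifnot(length(k) == n)
  if (any(v < 0)) stop("v entries must be >= 0", call. = FALSE)
  if (any(k <= 0)) stop("k entries must be > 0", call. = FALSE)
  if (is.null(regulators) || nrow(regulators) == 0L) {
    regulators <- data.frame(target = integer(), source = integer(),
                             role = character(), n = numeric(), K = numeric())
  } else {
    regulators <- as.data.frame(regulators)
    stopifnot(all(c("target", "source", "role", "n", "K") %in%
                    names(regulators)))
    if (!all(regulators$role %in% c("activator", "inhibitor"))) {
      stop("role must be 'activator' or 'inhibitor'", call. = FALSE)
    }
    if (any(regulators$K <= 0)) stop("K must be > 0 for every regulator",
                                     call. = FALSE)
    regulators$target <- as.integer(regulators$target)
    regulators$source <- as.integer(regulators$source)
    regulators <- regulators[order(regulators$target, regulators$source),
                             c("target", "source", "role", "n", "K")]
    rownames(regulators) <- NULL
  }
  structure(list(v = as.numeric(v), k = as.numeric(k),
                 regulators = regulators),
            class = "grlot_params")
}

params_method <- function(params) {
  switch(class(params)[1],
         ann_params = "ANN", ss_params = "SS", grlot_params = "GRLOT",
         stop("unknown parameter class", call. = FALSE))
}

#' Dynamic GRN model: a topology plus one method's parameter set
#'
#' @param method one of `"ANN"`, `"SS"`, `"GRLOT"`.
#' @param topology a [grn_topology()].
#' @param params the matching parameter container ([ann_params()],
#'   [ss_params()] or [grlot_params()]).  Entries outside the topology mask
#'   must be exactly zero (ANN w, SS g), and GRLOT regulators must match the
#'   topology's edges with consistent signs.
#' @return object of class `grn_model`.
#' @export
grn_model <- function(method, topology, params) {
  check_method(method)
  stopifnot(inherits(topology, "grn_topology"))
  if (params_method(params) != method) {
    stop("params class does not match method tag", call. = FALSE)
  }
  n <- topology$n_genes
  mask <- adjacency_mask(topology)
  if (method == "ANN") {
    if (length(params$v) != n) stop("params dimensions must match n_genes",
                                    call. = FALSE)
    if (any(params$w[mask == 0L] != 0)) {
      stop("ANN w entries outside the topology mask must be exactly 0",
           call. = FALSE)
    }
  } else if (method == "SS") {
    if (length(params$alpha) != n) stop("params dimensions must match n_genes",
                                        call. = FALSE)
    offdiag <- row(params$g) != col(params$g)
    if (any(params$g[mask == 0L] != 0)) {
      stop("SS g entries outside the topology mask must be exactly 0",
           call. = FALSE)
    }
    if (any(params$h[offdiag & mask == 0L] != 0)) {
      stop("SS h entries outside the mask must be exactly 0", call. = FALSE)
    }
  } else {
    if (length(params$v) != n) stop("params dimensions must match n_genes",
                                    call. = FALSE)
    reg <- params$regulators
    if (nrow(reg)) {
      sgn <- mask[cbind(reg$target, reg$source)]
      if (any(sgn == 0L)) {
        stop("every GRLOT regulator must match a topology edge", call. = FALSE)
      }
      want <- ifelse(sgn > 0, "activator", "inhibitor")
      if (any(want != reg$role)) {
        stop("GRLOT regulator roles must be consistent with edge signs",
             call. = FALSE)
      }
    }
  }
  structure(list(method = method, topology = topology, params = params),
            class = "grn_model")
}

#' @export
print.grn_model <- function(x, ...) {
  cat("Dynamic GRN model (", x$method, "), ", x$topology$n_genes,
      " genes, ", nrow(x$topology$edges), " edges, ",
      n_free_parameters(x$method, x$topology), " free parameters\n", sep = "")
  invisible(x)
}

#' Fully dense parameter count of a method
#'
#' Number of parameters each formalism uses for an N-gene network when every
#' possible interaction is present: ANN N(N+3), S-system N(2N+2), GRLOT
#' N(2N+1).  Masked (topology-restricted) counts are available through
#' [n_free_parameters()].
#'
#' @param method one of `"ANN"`, `"SS"`, `"GRLOT"`.
#' @param n_genes positive integer.
#' @return integer parameter count.
#' @export
count_parameters <- function(method, n_genes) {
  check_method(method)
  stopifnot(is.numeric(n_genes), length(n_genes) == 1L, n_genes >= 1)
  n <- as.integer(n_genes)
  switch(method,
         ANN = n * (n + 3L),
         SS = n * (2L * n + 2L),
         GRLOT = n * (2L * n + 1L))
}

#' Number of free (searched) parameters under a topology mask
#'
#' Counts the parameters actually estimated during reverse engineering:
#' per-gene baseline parameters plus one (ANN, SS) or two (GRLOT) parameters
#' per incoming edge.  For the S-system the degradation-order matrix h is
#' restricted to its diagonal.
#'
#' @param method one of `"ANN"`, `"SS"`, `"GRLOT"`.
#' @param topology a [grn_topology()].
#' @return integer count.
#' @export
n_free_parameters <- function(method, topology) {
  length(param_layout(method, topology)$idx)
}
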