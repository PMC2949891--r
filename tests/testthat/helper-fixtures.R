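# Shared fixtures built in code.

# one-gene ANN model: production v*f(-theta), first-order decay
one_gene_ann <- function(v = 1, theta = 2, k = 0.3) {
  topo <- grn_topology(1)
  grn_model("ANN", topo, ann_params(v = v, w = matrix(0, 1, 1),
                                    theta = theta, k = k))
}

# one-gene pure-decay model expressed as an S-system (alpha = 0)
one_gene_decay <- function(k = 0.3) {
  topo <- grn_topology(1)
  grn_model("SS", topo, ss_params(alpha = 0, beta = k,
                                  g = matrix(0, 1, 1), h = matrix(1, 1, 1)))
}

# two-gene cascade (X1 -> X2) reference models with known parameters,
# used by the parameter-recovery property tests
two_gene_topology <- function() {
  grn_topology(2, data.frame(from = 1, to = 2, sign = 1L))
}

two_gene_model <- function(method) {
  topo <- two_gene_topology()
  switch(method,
    ANN = grn_model("ANN", topo,
                    ann_params(v = c(1, 1), theta = c(4, 4), k = c(0.3, 0.3),
                               w = matrix(c(0, 5, 0, 0), 2, 2))),
    SS = grn_model("SS", topo,
                   ss_params(alpha = c(0, 1), beta = c(0.3, 0.3),
                             g = matrix(c(0, 2, 0, 0), 2, 2),
                             h = diag(2))),
    GRLOT = grn_model("GRLOT", topo,
                      grlot_params(v = c(0, 1), k = c(0.3, 0.3),
                                   regulators = data.frame(
                                     target = 2, source = 1,
                                     role = "activator", n = 1.5,
                                     K = 0.8))))
}

# small time-series set built from plain matrices
make_ts <- function(states_list, times = NULL) {
  p <- nrow(states_list[[1]])
  if (is.null(times)) times <- seq(0, 1, length.out = p)
  trs <- lapply(seq_along(states_list), function(i) {
    list(label = as.character(i), times = times,
         states = as.matrix(states_list[[i]]), ok = TRUE)
  })
  timeseries_set(trs, t_end = max(times), n_points = p)
}

# brute-force double-loop implementations of the fit metrics, kept
# deliberately independent of the package's vectorized versions
brute_p_fit <- function(observed, predicted) {
  total <- 0
  count <- 0
  for (i in seq_along(observed$trajectories)) {
    X <- observed$trajectories[[i]]$states
    Xhat <- predicted$trajectories[[i]]$states
    for (t in seq_len(nrow(X))) {
      for (k in seq_len(ncol(X))) {
        total <- total + (X[t, k] - Xhat[t, k])^2
        count <- count + 1
      }
    }
  }
  1 / (1 + total / count)
}

brute_relative_difference <- function(observed, predicted) {
  total <- 0
  for (i in seq_along(observed$trajectories)) {
    X <- observed$trajectories[[i]]$states
    Xhat <- predicted$trajectories[[i]]$states
    for (t in seq_len(nrow(X))) {
      for (k in seq_len(ncol(X))) {
        total <- total + ((X[t, k] - Xhat[t, k]) / X[t, k])^2
      }
    }
  }
  total
}

brute_p_inf <- function(a, b) {
  n <- length(a)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  0.5 * (1 + num / den)
}
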