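# Two-phase reverse engineering: per-gene node models fitted against the
# observed trajectories of the remaining genes (bottom-up), then a fully
# coupled network model seeded with the assembled node fits (top-down).

ts_cpp_data <- function(data) {
  ok <- vapply(data$trajectories, function(tr) isTRUE(tr$ok), logical(1))
  if (!any(ok)) stop("no successfully integrated trajectories in data",
                     call. = FALSE)
  trs <- data$trajectories[ok]
  list(times = lapply(trs, function(tr) as.numeric(tr$times)),
       states = lapply(trs, function(tr) unname(as.matrix(tr$states))))
}

fit_objective <- function(method, topology, scope, data,
                          settings = integration_settings(),
                          idx_free, template) {
  code <- method_code(method)
  n <- topology$n_genes
  desc <- if (method == "GRLOT") grlot_descriptors(topology)
          else list(target = integer(0), source = integer(0),
                    role = numeric(0))
  cd <- ts_cpp_data(data)
  force(idx_free); force(template)
  function(pop) {
    cpp_batch_objective(pop, template, idx_free, code, n,
                        desc$target, desc$source, desc$role, scope,
                        cd$times, cd$states, settings$rtol, settings$atol,
                        settings$blowup, ea_sentinel())
  }
}

# Derivative-free local refinement of an EA solution: Nelder-Mead on the
# same objective, clamped to the bounds box.  Off by default (the
# replication pipeline is EA-only); the scaled-down configurations enable
# it to supply the final decimals a full-scale EA budget would buy.
polish_solution <- function(obj, par, lower, upper, maxit, rounds = 3L) {
  f1 <- function(x) {
    obj(matrix(pmin(pmax(x, lower), upper), 1))
  }
  best_par <- par
  best_val <- f1(par)
  for (round in seq_len(rounds)) {
    r <- tryCatch(stats::optim(best_par, f1, method = "Nelder-Mead",
                               control = list(maxit = maxit,
                                              reltol = 1e-12)),
                  error = function(e) NULL)
    if (is.null(r)) break
    p <- pmin(pmax(r$par, lower), upper)
    v <- f1(p)
    if (v < best_val * (1 - 1e-6)) {
      # restarting the collapsed simplex from the improved point often
      # continues the descent on higher-dimensional objectives
      best_par <- p
      best_val <- v
    } else {
      if (v < best_val) { best_par <- p; best_val <- v }
      break
    }
  }
  list(par = best_par, value = best_val)
}

new_fit_result <- function(scope, gene, method, par, value, history,
                           repeats, repeat_values, seed) {
  structure(list(scope = scope, gene = gene, method = method, par = par,
                 objective = value, history = history, repeats = repeats,
                 repeat_values = repeat_values, seed = seed),
            class = "grn_fit_result")
}

#' @export
print.grn_fit_result <- function(x, ...) {
  cat("Fit result (", x$scope,
      if (!is.na(x$gene)) paste0(" gene ", x$gene), ", ", x$method,
      "): objective ", format(x$objective, digits = 6), " over ",
      x$repeats, " repeat(s)\n", sep = "")
  invisible(x)
}

#' Fit a single-gene node model (bottom-up phase)
#'
#' Estimates the parameters of gene `gene`'s rate equation by minimizing
#' the sum of squared deviations between its observed trajectory and the
#' trajectory obtained by integrating that single equation with the other
#' genes' concentrations supplied from the data via piecewise-linear
#' interpolation.  Multi-trajectory data sums the objective over
#' trajectories; the optimization is repeated `config$repeats` times and
#' the best run kept.
#'
#' @param gene gene index in `1:N`.
#' @param data a [timeseries_set()] containing all N genes.
#' @param method method tag for the fitted model.
#' @param topology the fixed regulatory structure searched within.
#' @param config an [ea_config()].
#' @param settings integration tolerances used for candidate evaluation.
#' @param polish if `TRUE`, each restart's best vector is refined by a
#'   bounded Nelder-Mead local search on the same objective before the
#'   best-of-restarts selection.  Off by default: the replication pipeline
#'   is EA-only.
#' @return a `grn_fit_result` with the node parameter vector in canonical
#'   order.
#' @export
fit_node_model <- function(gene, data, method, topology,
                           config = ea_config(),
                           settings = integration_settings(),
                           polish = FALSE) {
  lay <- param_layout(method, topology)
  slice <- lay$node_slices[[as.character(gene)]]
  if (is.null(slice)) stop("gene index out of range", call. = FALSE)
  obj <- fit_objective(method, topology, scope = gene, data, settings,
                       idx_free = lay$idx[slice], template = lay$template)
  best <- NULL
  vals <- numeric(config$repeats)
  for (r in seq_len(config$repeats)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 1000L * gene + r)
    run <- ea_optimize(obj, lay$lower[slice], lay$upper[slice], cfg)
    if (polish) {
      ref <- polish_solution(obj, run$par, lay$lower[slice],
                             lay$upper[slice], maxit = 2000)
      run$par <- ref$par
      run$value <- ref$value
    }
    vals[r] <- run$value
    if (is.null(best) || run$value < best$value) best <- run
  }
  new_fit_result("node", gene, method,
                 stats::setNames(best$par, lay$names[slice]),
                 best$value, best$history, config$repeats, vals,
                 config$seed)
}

#' Assemble node fits into a network model
#'
#' Concatenates the fittest node parameter vectors (one per gene, same
#' method) into a full network parameter set.  The assembled model's
#' node-wise residuals equal those of its parts, but its coupled network
#' dynamics can differ substantially -- the error-propagation effect that
#' motivates the seeded top-down phase.
#'
#' @param node_results list of N node `grn_fit_result`s, genes 1..N.
#' @param topology the shared [grn_topology()].
#' @return a [grn_model()].
#' @export
assemble_network <- function(node_results, topology) {
  n <- topology$n_genes
  if (length(node_results) != n) {
    stop("need exactly one node result per gene", call. = FALSE)
  }
  genes <- vapply(node_results, function(f) f$gene, numeric(1))
  methods <- vapply(node_results, function(f) f$method, character(1))
  if (!identical(sort(genes), as.numeric(seq_len(n)))) {
    stop("node results must cover genes 1..N exactly once", call. = FALSE)
  }
  if (length(unique(methods)) != 1L) {
    stop("mixed methods cannot be assembled", call. = FALSE)
  }
  ord <- order(genes)
  W <- unlist(lapply(node_results[ord], function(f) f$par))
  model_from_free_vector(methods[1], topology, as.numeric(W))
}

#' Fit a full network model (top-down phase)
#'
#' Minimizes the summed squared deviation over all genes and sampling
#' points between the data and the trajectory of the fully coupled system
#' integrated from each trajectory's initial state.  If `seeds` are given
#' (assembled node models), they and mutated copies form part of the
#' initial population.  The best of `config$repeats` independent runs is
#' returned.
#'
#' @param data a [timeseries_set()].
#' @param method method tag.
#' @param topology the fixed regulatory structure.
#' @param config an [ea_config()].
#' @param seeds optional list of [grn_model()]s (or a matrix of canonical
#'   free vectors) used to seed the initial population.
#' @param settings integration tolerances for candidate evaluation.
#' @param polish if `TRUE`, refine each restart's best vector with a
#'   bounded Nelder-Mead local search (see [fit_node_model()]).
#' @return a `grn_fit_result`; its `$model` field holds the fitted
#'   [grn_model()].
#' @export
fit_network_model <- function(data, method, topology, config = ea_config(),
                              seeds = NULL,
                              settings = integration_settings(),
                              polish = FALSE) {
  lay <- param_layout(method, topology)
  obj <- fit_objective(method, topology, scope = 0L, data, settings,
                       idx_free = lay$idx, template = lay$template)
  seed_mat <- NULL
  if (!is.null(seeds)) {
    if (is.matrix(seeds)) {
      seed_mat <- seeds
    } else {
      if (inherits(seeds, "grn_model")) seeds <- list(seeds)
      for (s in seeds) {
        if (s$method != method) stop("seed model method mismatch",
                                     call. = FALSE)
      }
      seed_mat <- do.call(rbind, lapply(seeds, model_free_vector))
    }
  }
  best <- NULL
  vals <- numeric(config$repeats)
  for (r in seq_len(config$repeats)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 900000L + r)
    run <- ea_optimize(obj, lay$lower, lay$upper, cfg, seeds = seed_mat)
    if (polish) {
      ref <- polish_solution(obj, run$par, lay$lower, lay$upper,
                             maxit = 5000)
      run$par <- ref$par
      run$value <- ref$value
    }
    vals[r] <- run$value
    if (is.null(best) || run$value < best$value) best <- run
  }
  res <- new_fit_result("network", NA_real_, method,
                        stats::setNames(best$par, lay$names),
                        best$value, best$history, config$repeats, vals,
                        config$seed)
  res$model <- model_from_free_vector(method, topology,
                                      as.numeric(best$par))
  res
}

#' Two-phase reverse engineering (node phase, assembly, network phase)
#'
#' Runs [fit_node_model()] for every gene, assembles the best node models
#' into a network model, then runs [fit_network_model()] with that model
#' seeding the initial population.  Returns the network fit together with
#' the node-phase provenance.
#'
#' @param data a [timeseries_set()].
#' @param method method tag.
#' @param topology the fixed regulatory structure.
#' @param config an [ea_config()].
#' @param settings integration tolerances for candidate evaluation.
#' @param polish if `TRUE`, both phases refine each restart's best vector
#'   with a bounded local search (see [fit_node_model()]).
#' @return a `grn_fit_result` with fields `$model`, `$node_fits` and
#'   `$assembled`.
#' @export
two_phase_fit <- function(data, method, topology, config = ea_config(),
                          settings = integration_settings(),
                          polish = FALSE) {
  n <- topology$n_genes
  node_fits <- lapply(seq_len(n), function(g) {
    fit_node_model(g, data, method, topology, config, settings,
                   polish = polish)
  })
  assembled <- assemble_network(node_fits, topology)
  net <- fit_network_model(data, method, topology, config,
                           seeds = list(assembled), settings,
                           polish = polish)
  net$node_fits <- node_fits
  net$assembled <- assembled
  net
}
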