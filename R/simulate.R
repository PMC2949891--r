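#' Integration settings for trajectory generation
#'
#' Defaults reproduce the study conditions: 200 evenly spaced samples over
#' 20 time units (about six degradation time-constants at k = 0.3, covering
#' the transient and the approach to steady state), adaptive Runge-Kutta
#' 4(5) with rtol 1e-6 / atol 1e-8, and a blow-up guard at |X| = 1e6 beyond
#' which integration is flagged as failed rather than aborted.
#'
#' @param t_end simulated time horizon (> 0).
#' @param n_points number of evenly spaced samples (>= 2).
#' @param rtol,atol relative/absolute integration tolerances.
#' @param blowup blow-up threshold on |X|.
#' @return object of class `integration_settings`.
#' @export
integration_settings <- function(t_end = 20, n_points = 200, rtol = 1e-6,
                                 atol = 1e-8, blowup = 1e6) {
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0",
                                             call. = FALSE)
  if (!is.numeric(n_points) || n_points < 2) stop("n_points must be >= 2",
                                                  call. = FALSE)
  if (rtol <= 0 || atol <= 0 || blowup <= 0) {
    stop("tolerances and blow-up threshold must be > 0", call. = FALSE)
  }
  structure(list(t_end = t_end, n_points = as.integer(n_points),
                 rtol = rtol, atol = atol, blowup = blowup),
            class = "integration_settings")
}

settings_times <- function(settings) {
  seq(0, settings$t_end, length.out = settings$n_points)
}

#' Time-series set container
#'
#' One or more trajectories sharing a common time grid; the product of the
#' data-generation stage and the input to inference and evaluation.
#'
#' @param trajectories list of trajectories, each a list with fields
#'   `label`, `times`, `states` (p x N matrix) and `ok` (logical
#'   integration-success flag).
#' @param t_end,n_points sampling metadata.
#' @param gene_names optional character vector of gene names.
#' @return object of class `grn_ts_set`.
#' @export
timeseries_set <- function(trajectories, t_end, n_points, gene_names = NULL) {
  stopifnot(length(trajectories) >= 1L)
  p <- length(trajectories[[1]]$times)
  for (tr in trajectories) {
    if (length(tr$times) != p ||
        any(abs(tr$times - trajectories[[1]]$times) > 1e-12)) {
      stop("every trajectory in a set must share the same time grid",
           call. = FALSE)
    }
  }
  n <- ncol(trajectories[[1]]$states)
  if (is.null(gene_names)) gene_names <- paste0("X", seq_len(n))
  structure(list(trajectories = trajectories, t_end = t_end,
                 n_points = as.integer(n_points), n_genes = n,
                 gene_names = gene_names),
            class = "grn_ts_set")
}

#' @export
print.grn_ts_set <- function(x, ...) {
  ok <- vapply(x$trajectories, function(tr) isTRUE(tr$ok), logical(1))
  cat("Time-series set:", length(x$trajectories), "trajectories x",
      x$n_points, "points x", x$n_genes, "genes",
      if (all(ok)) "" else sprintf("(%d failed)", sum(!ok)), "\n")
  invisible(x)
}

# model pieces needed by the compiled integrator
model_cpp_args <- function(model) {
  lay_desc <- if (model$method == "GRLOT") {
    grlot_descriptors(model$topology)
  } else {
    list(target = integer(0), source = integer(0), role = numeric(0))
  }
  list(code = method_code(model$method), n = model$topology$n_genes,
       theta = theta_from_model(model), desc = lay_desc)
}

#' Integrate a dynamic GRN model over an even time grid
#'
#' Adaptive Dormand-Prince 4(5) integration of the model's rate law,
#' sampled on `n_points` evenly spaced times.  Integration failures
#' (step-size collapse, non-finite state, blow-up beyond the threshold, or
#' an S-system singularity) are returned as a flagged trajectory
#' (`ok = FALSE`, remaining rows filled with the blow-up value), not as an
#' exception.
#'
#' @param model a [grn_model()].
#' @param x0 initial concentration vector of length N.
#' @param settings an [integration_settings()].
#' @param label optional trajectory label.
#' @return a trajectory: list with `label`, `times`, `states`, `ok`,
#'   `filled`.
#' @export
integrate_model <- function(model, x0, settings = integration_settings(),
                            label = NA_character_) {
  stopifnot(inherits(model, "grn_model"),
            inherits(settings, "integration_settings"))
  n <- model$topology$n_genes
  if (length(x0) != n) stop("x0 length must equal n_genes", call. = FALSE)
  a <- model_cpp_args(model)
  times <- settings_times(settings)
  res <- cpp_integrate(a$code, a$n, a$theta, a$desc$target, a$desc$source,
                       a$desc$role, as.numeric(x0), times,
                       settings$rtol, settings$atol, settings$blowup)
  states <- res$states
  colnames(states) <- paste0("X", seq_len(n))
  list(label = label, times = times, states = states, ok = res$ok,
       filled = res$filled)
}

# optional observational-noise hook: multiplicative Gaussian, seedable;
# the replicated study's data are noise-free, so noise_sd defaults to 0
apply_noise <- function(ts, noise_sd, noise_seed) {
  if (noise_sd <= 0) return(ts)
  if (!is.null(noise_seed)) set.seed(noise_seed)
  ts$trajectories <- lapply(ts$trajectories, function(tr) {
    tr$states <- tr$states *
      matrix(rnorm(length(tr$states), 1, noise_sd), nrow(tr$states))
    tr
  })
  ts
}

#' Generate the sparse training dataset (starting set 1 only)
#'
#' @param model a 5-gene [grn_model()] (or supply `x0` for other sizes).
#' @param settings an [integration_settings()].
#' @param x0 optional initial state overriding starting set 1.
#' @param noise_sd multiplicative Gaussian observational-noise standard
#'   deviation; 0 (the default) reproduces the study's noise-free data.
#' @param noise_seed seed for the noise draw (ignored when `noise_sd` is
#'   0).
#' @return a [timeseries_set()] with exactly one trajectory.
#' @export
generate_sparse <- function(model, settings = integration_settings(),
                            x0 = NULL, noise_sd = 0, noise_seed = NULL) {
  if (is.null(x0)) {
    if (model$topology$n_genes != 5L) {
      stop("starting sets are defined for 5-gene models; supply x0",
           call. = FALSE)
    }
    x0 <- starting_sets()[1, ]
  }
  tr <- integrate_model(model, x0, settings, label = "1")
  apply_noise(timeseries_set(list(tr), settings$t_end, settings$n_points),
              noise_sd, noise_seed)
}

#' Generate the detailed training dataset (starting sets 1-5)
#'
#' @param model a 5-gene [grn_model()].
#' @param settings an [integration_settings()].
#' @param noise_sd,noise_seed observational-noise hook (see
#'   [generate_sparse()]); off by default.
#' @return a [timeseries_set()] with five trajectories in starting-set
#'   order.
#' @export
generate_detailed <- function(model, settings = integration_settings(),
                              noise_sd = 0, noise_seed = NULL) {
  if (model$topology$n_genes != 5L) {
    stop("detailed datasets are defined for 5-gene models", call. = FALSE)
  }
  ss <- starting_sets()
  trs <- lapply(1:5, function(i) {
    integrate_model(model, ss[i, ], settings, label = as.character(i))
  })
  apply_noise(timeseries_set(trs, settings$t_end, settings$n_points),
              noise_sd, noise_seed)
}

#' Input-perturbed model variants for validation
#'
#' Gene X1 has no regulators in the case-study models, so its degradation
#' rate acts as the network input: lowering k_1 (beta_1 for the S-system)
#' to 0.1 raises the X1 level (increased input), raising it to 0.5 lowers
#' it (decreased input).
#'
#' @param model a [grn_model()] whose gene X1 has no incoming edges.
#' @return named list of two models, `increased` (k1 = 0.1) and
#'   `decreased` (k1 = 0.5).
#' @export
perturb_input <- function(model) {
  if (nrow(regulators_of(model$topology, 1L)) > 0L) {
    stop("perturb_input requires gene X1 to have no regulators",
         call. = FALSE)
  }
  set_k1 <- function(m, value) {
    if (m$method == "SS") m$params$beta[1] <- value else m$params$k[1] <- value
    m
  }
  list(increased = set_k1(model, 0.1), decreased = set_k1(model, 0.5))
}

#' Perturb one gene's initial concentration
#'
#' @param x0 initial concentration vector.
#' @param gene gene index.
#' @param factor positive multiplier (the study protocol uses 3, 12, 48).
#' @return the perturbed vector.
#' @export
perturb_initial <- function(x0, gene, factor) {
  if (gene < 1 || gene > length(x0)) stop("gene index out of range",
                                          call. = FALSE)
  if (factor <= 0) stop("factor must be positive", call. = FALSE)
  x0[gene] <- x0[gene] * factor
  x0
}

#' Write a time-series set as CSV
#'
#' Dialect: header `series_id,time,<gene names>`, UTF-8, `.` decimal
#' separator.  An optional JSON metadata sidecar records the sampling
#' parameters.
#'
#' @param ts a [timeseries_set()].
#' @param path output CSV path.
#' @param meta optional named list written as a JSON sidecar at
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
ts_write_csv <- function(ts, path, meta = NULL) {
  rows <- do.call(rbind, lapply(ts$trajectories, function(tr) {
    data.frame(series_id = tr$label, time = tr$times, tr$states,
               check.names = FALSE)
  }))
  names(rows) <- c("series_id", "time", ts$gene_names)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta)) {
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
               paste0(path, ".json"))
  }
  invisible(path)
}

#' Read a time-series set from CSV
#'
#' @param path CSV in the dialect of [ts_write_csv()].
#' @return a [timeseries_set()].
#' @export
ts_read_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("series_id", "time") %in% names(d))) {
    stop("format error: expected columns series_id, time, X1..XN",
         call. = FALSE)
  }
  genes <- setdiff(names(d), c("series_id", "time"))
  trs <- lapply(split(d, d$series_id), function(chunk) {
    states <- as.matrix(chunk[, genes, drop = FALSE])
    rownames(states) <- NULL
    list(label = as.character(chunk$series_id[1]), times = chunk$time,
         states = states, ok = TRUE)
  })
  trs <- trs[order(names(trs))]
  timeseries_set(unname(trs), t_end = max(d$time),
                 n_points = length(trs[[1]]$times), gene_names = genes)
}
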