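# Reference case-study networks.
#
# Cases A-C are five-gene networks with printed parameters for all three
# methods; every constructed model uses a uniform degradation rate of 0.3
# (beta_i for the S-system, whose h matrix is 1 on the diagonal and 0
# elsewhere) so that regulation is confined to the expression process.
# Case D (three genes, ANN) and case E (five genes, S-system) have fixed
# topologies but literature parameter values that must be supplied by the
# caller; they refuse to run rather than guess.

case_ids <- function() c("A", "B", "C", "D", "E", "F")

cantone_genes <- function() c("CBF1", "GAL4", "SWI5", "GAL80", "ASH1")

case_topology <- function(case_id) {
  cascade <- data.frame(from = 1:4, to = 2:5, sign = 1L)
  branched <- data.frame(from = c(1, 2, 2, 3, 4), to = c(2, 3, 4, 5, 5),
                         sign = 1L)
  switch(case_id,
    A = grn_topology(5, cascade),
    B = grn_topology(5, branched),
    C = grn_topology(5, rbind(branched,
                              data.frame(from = c(3, 5), to = c(2, 2),
                                         sign = c(1L, -1L)))),
    D = grn_topology(3, data.frame(from = c(1, 2, 2, 3),
                                   to = c(2, 3, 1, 1),
                                   sign = c(1L, 1L, 1L, -1L))),
    # Five-gene power-law benchmark topology (production edges); which
    # degradation orders are regulated is left to the case-E configuration.
    E = grn_topology(5, data.frame(from = c(3, 5, 1, 2, 5, 3, 5, 4),
                                   to = c(1, 1, 2, 3, 3, 4, 4, 5),
                                   sign = c(1L, -1L, 1L, 1L, -1L, 1L, -1L,
                                            1L))),
    # Synthetic-yeast network: genes CBF1, GAL4, SWI5, GAL80, ASH1
    F = grn_topology(5, data.frame(from = c(3, 5, 1, 2, 4, 3, 3),
                                   to = c(1, 1, 2, 3, 3, 4, 5),
                                   sign = c(1L, -1L, 1L, 1L, -1L, 1L, 1L))),
    stop("unknown case id: ", case_id, call. = FALSE))
}

# Printed parameter tables for cases A-C.  Edge-value vectors follow the
# topology's canonical (target, source) edge order.
case_abc_tables <- function() {
  list(
    A = list(
      ANN = list(v = rep(1, 5), theta = rep(4, 5), k = rep(0.3, 5),
                 w = c(5, 5, 5, 5)),
      SS = list(alpha = c(0, 1, 1, 1, 1), beta = rep(0.3, 5),
                g = c(2, 2, 2, 2)),
      GRLOT = list(v = c(0, 1, 1, 1, 1), k = rep(0.3, 5),
                   n = c(1.5, 1.5, 1.5, 1.5), K = c(1.1, 1.1, 1.1, 1.1))),
    B = list(
      # edges in (to, from) order: (2,1) (3,2) (4,2) (5,3) (5,4)
      ANN = list(v = rep(1, 5), theta = rep(4.5, 5), k = rep(0.3, 5),
                 w = c(7, 6, 4, 4, 6)),
      SS = list(alpha = c(0, 1, 1, 1, 1), beta = rep(0.3, 5),
                g = c(1.5, 2, 3, 2, 3)),
      GRLOT = list(v = c(0, 1, 1, 1, 1), k = rep(0.3, 5),
                   n = c(1.5, 2.5, 1.5, 1.5, 2.5),
                   K = c(0.8, 0.5, 0.8, 0.8, 0.5))),
    C = list(
      # edges in (to, from) order: (2,1) (2,3) (2,5) (3,2) (4,2) (5,3) (5,4)
      ANN = list(v = rep(1, 5), theta = rep(4.5, 5), k = rep(0.3, 5),
                 w = c(7, 7, -8, 6, 4, 4, 6)),
      SS = list(alpha = c(0, 1, 1, 1, 1), beta = rep(0.3, 5),
                g = c(1.5, 0.6, -0.3, 2, 3, 2, 3)),
      GRLOT = list(v = c(0, 1, 1, 1, 1), k = rep(0.3, 5),
                   n = c(1.5, 3.5, 1.5, 2.5, 1.5, 1.5, 2.5),
                   K = c(0.8, 0.1, 2.0, 0.5, 0.8, 0.8, 0.5))))
}

#' Build a reference case-study model
#'
#' Constructs the dynamic GRN model for one of the case studies.  Cases
#' `"A"`, `"B"`, `"C"` have printed parameters for all three methods.
#' Cases `"D"` (ANN only) and `"E"` (S-system only) have fixed topologies
#' but require the literature parameter values to be supplied through
#' `config`; other (case, method) combinations are unsupported.
#'
#' @param case_id one of `"A"` to `"E"`.
#' @param method one of `"ANN"`, `"SS"`, `"GRLOT"`.
#' @param config for cases D/E, a named list of parameter values: case D
#'   takes `v`, `theta`, `k` (length 3) and `w` (per-edge weights); case E
#'   takes `alpha`, `beta` (length 5) and `g`, `h` (5 x 5 matrices).
#' @return a [grn_model()].
#' @export
build_case <- function(case_id, method, config = NULL) {
  check_method(method)
  if (!case_id %in% c("A", "B", "C", "D", "E")) {
    stop("unknown case id: ", case_id, call. = FALSE)
  }
  topo <- case_topology(case_id)
  if (case_id %in% c("A", "B", "C")) {
    tab <- case_abc_tables()[[case_id]][[method]]
    e <- topo$edges
    n <- topo$n_genes
    if (method == "ANN") {
      w <- matrix(0, n, n)
      w[cbind(e$to, e$from)] <- tab$w
      params <- ann_params(v = tab$v, w = w, theta = tab$theta, k = tab$k)
    } else if (method == "SS") {
      g <- matrix(0, n, n)
      g[cbind(e$to, e$from)] <- tab$g
      params <- ss_params(alpha = tab$alpha, beta = tab$beta, g = g,
                          h = diag(n))
    } else {
      reg <- data.frame(target = e$to, source = e$from,
                        role = ifelse(e$sign > 0, "activator", "inhibitor"),
                        n = tab$n, K = tab$K)
      params <- grlot_params(v = tab$v, k = tab$k, regulators = reg)
    }
    return(grn_model(method, topo, params))
  }
  if (case_id == "D" && method != "ANN") {
    stop("unsupported combination: case D is defined for the ANN method only",
         call. = FALSE)
  }
  if (case_id == "E" && method != "SS") {
    stop("unsupported combination: case E is defined for the SS method only",
         call. = FALSE)
  }
  if (is.null(config)) {
    stop("literature parameters required: case ", case_id, " ships as a ",
         "topology-complete, parameter-open definition; supply `config`",
         call. = FALSE)
  }
  n <- topo$n_genes
  if (case_id == "D") {
    stopifnot(all(c("v", "theta", "k", "w") %in% names(config)))
    w <- matrix(0, n, n)
    w[cbind(topo$edges$to, topo$edges$from)] <- config$w
    params <- ann_params(v = config$v, w = w, theta = config$theta,
                         k = config$k)
  } else {
    stopifnot(all(c("alpha", "beta", "g", "h") %in% names(config)))
    params <- ss_params(alpha = config$alpha, beta = config$beta,
                        g = config$g, h = config$h)
  }
  grn_model(method, topo, params)
}

#' The five initial-condition starting sets
#'
#' The printed initial concentration vectors used to simulate the five-gene
#' reference models; set 1 generates the sparse datasets, sets 1-5 the
#' detailed datasets.
#'
#' @return a 5 x 5 numeric matrix, one starting set per row.
#' @export
starting_sets <- function() {
  m <- rbind(c(0.8, 0.1, 0.1, 0.1, 0.1),
             c(0.8, 0.1, 0.1, 0.3, 0.5),
             c(0.5, 0.5, 0.2, 0.1, 0.1),
             c(0.4, 0.8, 0.2, 0.2, 0.2),
             c(0.5, 0.2, 0.8, 0.8, 0.2))
  dimnames(m) <- list(paste0("set", 1:5), paste0("X", 1:5))
  m
}

#' The two case-D model variants differing only in theta_1
#'
#' Returns two ANN models on the three-gene feedback topology of case D
#' sharing all parameters except the external input of gene X1, which is
#' 3.0 (non-oscillatory regime) and 1.0 (oscillatory regime) respectively.
#'
#' @param config the case-D parameter configuration (see [build_case()]);
#'   its `theta[1]` entry is overridden by each variant.
#' @return named list with models `theta1_3.0` and `theta1_1.0`.
#' @export
case_d_variants <- function(config = NULL) {
  if (is.null(config)) {
    stop("literature parameters required: supply the case-D ANN parameters",
         call. = FALSE)
  }
  build <- function(th1) {
    cfg <- config
    cfg$theta[1] <- th1
    build_case("D", "ANN", cfg)
  }
  list("theta1_3.0" = build(3.0), "theta1_1.0" = build(1.0))
}

#' Load a switch-on/switch-off yeast time series
#'
#' Reads a CSV with a `time` column (minutes) and the five expression
#' columns CBF1, GAL4, SWI5, GAL80, ASH1, restricts it to the first 100
#' minutes while excluding the first 10-minute interval (retaining
#' 10 < t <= 100), and returns it as a one-trajectory time-series set with
#' the gene order fixed as listed.
#'
#' @param path CSV file path.
#' @param series `"switch-on"` or `"switch-off"` (used as the trajectory
#'   label).
#' @return a [timeseries_set()].
#' @export
load_cantone_series <- function(path, series = c("switch-on", "switch-off")) {
  series <- match.arg(series)
  d <- tryCatch(utils::read.csv(path), error = function(e) {
    stop("format error: cannot read '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  genes <- cantone_genes()
  need <- c("time", genes)
  if (nrow(d) == 0L) stop("format error: empty time-series file",
                          call. = FALSE)
  if (!all(need %in% names(d))) {
    stop("format error: missing columns ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  if (any(diff(d$time) <= 0)) {
    stop("format error: time column must be strictly increasing",
         call. = FALSE)
  }
  keep <- d$time > 10 & d$time <= 100
  if (!any(keep)) stop("format error: no samples in the (10, 100] minute window",
                       call. = FALSE)
  d <- d[keep, , drop = FALSE]
  states <- as.matrix(d[, genes])
  dimnames(states) <- list(NULL, genes)
  traj <- list(label = series, times = d$time, states = states, ok = TRUE)
  timeseries_set(list(traj), t_end = max(d$time), n_points = nrow(d),
                 gene_names = genes)
}
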