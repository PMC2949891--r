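#' Evolutionary-algorithm configuration
#'
#' Study-replication defaults: population 500, 300 generations, BLX-alpha
#' crossover at rate 0.6 (alpha = 0.5), creep mutation at rate 0.1 per
#' vector position (additive Gaussian with scale 5% of each parameter's
#' bound width, clipped to bounds), roulette-wheel selection over a linear
#' rank-based fitness assignment (selection pressure 1.8), one elite clone
#' per generation, and five independent repeats per optimization.
#'
#' @param pop_size population size.
#' @param generations number of generations.
#' @param crossover_rate probability a mating pair undergoes BLX-alpha
#'   crossover.
#' @param blx_alpha BLX spread parameter.
#' @param mutation_rate per-position creep-mutation probability.
#' @param creep_scale creep standard deviation as a fraction of the bound
#'   width.
#' @param selection_scheme `"rank_positional"` (roulette weights equal to
#'   the rank positions themselves, best = pop_size .. worst = 1; the
#'   default) or `"rank_linear"` (linear ranking controlled by
#'   `selection_pressure`).
#' @param selection_pressure linear-ranking selection pressure in (1, 2];
#'   used only by the `"rank_linear"` scheme.
#' @param elitism number of best individuals cloned into the next
#'   generation.
#' @param repeats independent optimization restarts (best-of is kept).
#' @param seed integer random seed for reproducibility.
#' @param seed_fraction fraction of the initial population built from seed
#'   individuals (and mutated copies) in the seeded top-down phase.
#' @return object of class `ea_config`.
#' @export
ea_config <- function(pop_size = 500, generations = 300,
                      crossover_rate = 0.6, blx_alpha = 0.5,
                      mutation_rate = 0.1, creep_scale = 0.05,
                      selection_scheme = c("rank_positional", "rank_linear"),
                      selection_pressure = 1.8, elitism = 1L,
                      repeats = 5, seed = 1L, seed_fraction = 0.1) {
  selection_scheme <- match.arg(selection_scheme)
  stopifnot(pop_size >= 4, generations >= 1, crossover_rate >= 0,
            crossover_rate <= 1, mutation_rate >= 0, mutation_rate <= 1,
            selection_pressure > 1, selection_pressure <= 2,
            repeats >= 1, seed_fraction >= 0, seed_fraction <= 1)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate, blx_alpha = blx_alpha,
                 mutation_rate = mutation_rate, creep_scale = creep_scale,
                 selection_scheme = selection_scheme,
                 selection_pressure = selection_pressure,
                 elitism = as.integer(elitism),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 seed_fraction = seed_fraction),
            class = "ea_config")
}

#' Default parameter search bounds for a method under a topology
#'
#' The searched intervals: ANN w in [-15, 15], v in [0, 3], theta in
#' [0, 7], k in [0, 2]; S-system g, h in [-3, 3], alpha, beta in [0, 15];
#' GRLOT Hill exponents in [0, 7] (activator role) or [-5, 5] (inhibitor
#' role), K in [0.001, 40], k in [0, 2], v in [0, 3].
#'
#' @param method method tag.
#' @param topology a [grn_topology()].
#' @return list with numeric vectors `lower`, `upper` and `names`, aligned
#'   with the canonical free-parameter order.
#' @export
parameter_bounds <- function(method, topology) {
  lay <- param_layout(method, topology)
  list(lower = lay$lower, upper = lay$upper, names = lay$names)
}

# worst-fitness sentinel assigned to failed/non-finite candidates
ea_sentinel <- function() 1e12

# derive a bounded positive sub-seed from a base seed and stream index
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 7919) %% 2147483629 + 1)
}

#' Real-coded evolutionary minimizer
#'
#' Minimizes `objective` over a box.  Per generation: linear rank-based
#' fitness assignment, roulette-wheel selection over the rank scores,
#' BLX-alpha crossover, additive creep mutation, clipping to bounds and
#' elitist cloning of the best individual.  The best-so-far objective value
#' is non-increasing across generations, and runs are fully reproducible
#' under a fixed seed.
#'
#' @param objective function taking a population matrix (individuals in
#'   rows) and returning a numeric vector of non-negative objective values;
#'   evaluation failures must be mapped to a finite worst-fitness sentinel,
#'   not raised.
#' @param lower,upper bound vectors (non-degenerate box).
#' @param config an [ea_config()].
#' @param seeds optional matrix of seed individuals injected into the
#'   initial population (with mutated copies), up to
#'   `config$seed_fraction` of the population.
#' @return list with `par`, `value`, `history` (best objective per
#'   generation) and `evaluations`.
#' @export
ea_optimize <- function(objective, lower, upper, config = ea_config(),
                        seeds = NULL) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  d <- length(lower)
  np <- config$pop_size
  width <- upper - lower
  set.seed(config$seed)

  clip <- function(m) {
    m <- pmax(m, matrix(lower, nrow(m), d, byrow = TRUE))
    pmin(m, matrix(upper, nrow(m), d, byrow = TRUE))
  }
  mutate <- function(m, rate) {
    hit <- matrix(runif(length(m)) < rate, nrow(m), d)
    # creep steps: Gaussian with a log-uniform scale mixture spanning three
    # decades below creep_scale, so the operator both explores (occasional
    # near-full-scale steps) and refines (frequent tiny adjustments)
    scale <- 10^-runif(length(m), 0, 3)
    step <- matrix(rnorm(length(m), 0, 1) * scale, nrow(m), d) *
      matrix(config$creep_scale * width, nrow(m), d, byrow = TRUE)
    clip(m + hit * step)
  }

  pop <- matrix(runif(np * d), np, d) *
    matrix(width, np, d, byrow = TRUE) +
    matrix(lower, np, d, byrow = TRUE)
  if (!is.null(seeds) && nrow(seeds) > 0) {
    seeds <- clip(matrix(as.numeric(seeds), ncol = d))
    n_seeded <- min(max(nrow(seeds), ceiling(config$seed_fraction * np)), np)
    block <- seeds[rep_len(seq_len(nrow(seeds)), n_seeded), , drop = FALSE]
    if (n_seeded > nrow(seeds)) {
      extra <- seq(nrow(seeds) + 1, n_seeded)
      block[extra, ] <- mutate(block[extra, , drop = FALSE],
                               rate = config$mutation_rate)
    }
    pop[seq_len(n_seeded), ] <- block
  }

  fit <- as.numeric(objective(pop))
  if (length(fit) != np) stop("objective must return one value per row",
                              call. = FALSE)
  if (!any(is.finite(fit))) {
    stop("objective is non-finite on every initial individual",
         call. = FALSE)
  }
  fit[!is.finite(fit)] <- ea_sentinel()
  evals <- np
  best_i <- which.min(fit)
  best_par <- pop[best_i, ]
  best_val <- fit[best_i]
  history <- numeric(config$generations)

  sp <- config$selection_pressure
  rank_scores <- if (config$selection_scheme == "rank_positional") {
    # roulette proportional to the rank position itself: the best of np
    # individuals gets weight np, the worst weight 1
    seq(np, 1)
  } else if (np > 1) {
    # linear ranking: best position gets score sp, worst 2 - sp
    sp - (2 * (sp - 1)) * (0:(np - 1)) / (np - 1)
  } else {
    1
  }

  for (gen in seq_len(config$generations)) {
    ord <- order(fit)                       # best first
    prob <- numeric(np)
    prob[ord] <- rank_scores
    parents <- pop[sample.int(np, np, replace = TRUE, prob = prob), ,
                   drop = FALSE]

    offspring <- parents
    half <- np %/% 2
    do_x <- runif(half) < config$crossover_rate
    for (pair in which(do_x)) {
      i1 <- 2 * pair - 1; i2 <- 2 * pair
      p1 <- parents[i1, ]; p2 <- parents[i2, ]
      lo <- pmin(p1, p2); hi <- pmax(p1, p2)
      span <- hi - lo
      a <- config$blx_alpha
      offspring[i1, ] <- lo - a * span + runif(d) * (1 + 2 * a) * span
      offspring[i2, ] <- lo - a * span + runif(d) * (1 + 2 * a) * span
    }
    offspring <- mutate(offspring, config$mutation_rate)
    for (e in seq_len(min(config$elitism, np))) {
      offspring[e, ] <- best_par            # elitist clone(s)
    }

    fit <- as.numeric(objective(offspring))
    fit[!is.finite(fit)] <- ea_sentinel()
    evals <- evals + np
    pop <- offspring
    gi <- which.min(fit)
    if (fit[gi] < best_val) {
      best_val <- fit[gi]
      best_par <- pop[gi, ]
    }
    history[gen] <- best_val
  }
  list(par = best_par, value = best_val, history = history,
       evaluations = evals)
}
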