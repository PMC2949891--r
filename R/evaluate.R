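# Verification / validation measures: predictive power on training data
# (P_ver) and on perturbed unseen data (P_val), inferential power (P_inf,
# parameter-vector correlation), a relative-difference score for comparing
# simulated expression models, and the qualitative feature comparison
# (Q_com).

#' Predictive power of one dataset against another
#'
#' `P_fit = 1 / (1 + E)` with `E` the mean squared deviation over all
#' sampling points and genes; multi-trajectory sets pool every point into
#' one error term.  1 is perfect accordance.
#'
#' @param observed,predicted [timeseries_set()]s of matching shape (same
#'   number of trajectories, points and genes).
#' @return numeric in (0, 1].
#' @export
p_fit <- function(observed, predicted) {
  ob <- observed$trajectories
  pr <- predicted$trajectories
  if (length(ob) != length(pr)) stop("shape mismatch: trajectory count",
                                     call. = FALSE)
  sq <- 0
  npts <- 0
  for (i in seq_along(ob)) {
    X <- as.matrix(ob[[i]]$states)
    Xhat <- as.matrix(pr[[i]]$states)
    if (!all(dim(X) == dim(Xhat))) stop("shape mismatch: trajectory ", i,
                                        call. = FALSE)
    sq <- sq + sum((X - Xhat)^2)
    npts <- npts + length(X)
  }
  1 / (1 + sq / npts)
}

#' Inferential power: correlation of parameter vectors
#'
#' `P_inf = 0.5 * (1 + r)` with `r` the Pearson product-moment correlation
#' between the reference and recovered parameter vectors in the same
#' canonical order (see [model_free_vector()]).  Only meaningful when both
#' models use the same method.
#'
#' @param w_ref,w_hat numeric vectors of equal length >= 2; must not be
#'   constant.
#' @return numeric in [0, 1].
#' @export
p_inf <- function(w_ref, w_hat) {
  w_ref <- as.numeric(w_ref)
  w_hat <- as.numeric(w_hat)
  if (length(w_ref) != length(w_hat) || length(w_ref) < 2) {
    stop("parameter vectors must have equal length >= 2", call. = FALSE)
  }
  if (stats::sd(w_ref) == 0 || stats::sd(w_hat) == 0) {
    stop("undefined correlation: zero-variance parameter vector",
         call. = FALSE)
  }
  0.5 * (1 + stats::cor(w_ref, w_hat))
}

# simulate `model` from each trajectory's initial state on that
# trajectory's grid; failed integrations yield sentinel-filled trajectories
simulate_like <- function(model, data, settings) {
  trs <- lapply(data$trajectories, function(tr) {
    s <- integration_settings(t_end = max(tr$times),
                              n_points = length(tr$times),
                              rtol = settings$rtol, atol = settings$atol,
                              blowup = settings$blowup)
    integrate_model(model, as.numeric(tr$states[1, ]), s, label = tr$label)
  })
  timeseries_set(trs, data$t_end, data$n_points, data$gene_names)
}

#' Verify a model against its training data (P_ver)
#'
#' Simulates the model from each training trajectory's initial state on the
#' training grid and scores the result with [p_fit()].  Integration
#' failures contribute sentinel (blow-up-filled) trajectories, so a failing
#' model scores close to 0; the result carries a `failed` attribute.
#'
#' @param model a [grn_model()].
#' @param training the [timeseries_set()] the model was fitted to.
#' @param settings integration tolerances.
#' @return `P_ver` in (0, 1], with attribute `failed` (number of failed
#'   trajectories).
#' @export
verify_model <- function(model, training,
                         settings = integration_settings()) {
  sim <- simulate_like(model, training, settings)
  val <- p_fit(training, sim)
  attr(val, "failed") <- sum(!vapply(sim$trajectories,
                                     function(tr) isTRUE(tr$ok),
                                     logical(1)))
  val
}

#' Validate a model on perturbed-input data (P_val)
#'
#' Builds the two input-perturbed variants of the reference model
#' (degradation of gene X1 set to 0.1 and 0.5), simulates each to create
#' unseen validation data, applies the identical perturbations to the
#' inferred model, and scores each condition with [p_fit()].  `P_val` is
#' the arithmetic mean of the increased-input and decreased-input scores;
#' both conditions are also reported separately.
#'
#' @param inferred the reverse-engineered [grn_model()].
#' @param reference the data-generating [grn_model()] (same topology and
#'   gene order).
#' @param settings an [integration_settings()] defining the validation
#'   grid.
#' @param x0_sets matrix of initial states (one per row) from which the
#'   validation data are simulated; defaults to the training starting sets
#'   via `starting_sets()[1, , drop = FALSE]`.
#' @return list with `p_val`, `per_condition` (named numeric), and
#'   `failed` counts.
#' @export
validate_model <- function(inferred, reference,
                           settings = integration_settings(),
                           x0_sets = NULL) {
  if (inferred$topology$n_genes != reference$topology$n_genes) {
    stop("models must share gene order and dimension", call. = FALSE)
  }
  if (is.null(x0_sets)) x0_sets <- starting_sets()[1, , drop = FALSE]
  ref_var <- perturb_input(reference)
  inf_var <- perturb_input(inferred)
  score_condition <- function(cond) {
    unseen <- lapply(seq_len(nrow(x0_sets)), function(i) {
      integrate_model(ref_var[[cond]], x0_sets[i, ], settings,
                      label = as.character(i))
    })
    pred <- lapply(seq_len(nrow(x0_sets)), function(i) {
      integrate_model(inf_var[[cond]], x0_sets[i, ], settings,
                      label = as.character(i))
    })
    obs_set <- timeseries_set(unseen, settings$t_end, settings$n_points)
    prd_set <- timeseries_set(pred, settings$t_end, settings$n_points)
    list(p = p_fit(obs_set, prd_set),
         failed = sum(!vapply(c(unseen, pred),
                              function(tr) isTRUE(tr$ok), logical(1))))
  }
  inc <- score_condition("increased")
  dec <- score_condition("decreased")
  per <- c(increased = inc$p, decreased = dec$p)
  list(p_val = mean(per), per_condition = per,
       failed = c(increased = inc$failed, decreased = dec$failed))
}

#' Relative-difference score between two expression datasets
#'
#' `sum_t sum_k ((X_kt - Xhat_kt) / X_kt)^2`: a scale-invariant squared
#' relative error used when comparing simulated expression models under
#' initial-value perturbations.
#'
#' @param observed,predicted [timeseries_set()]s of matching shape;
#'   `observed` must be strictly non-zero everywhere (it is the
#'   denominator).
#' @return non-negative real.
#' @export
relative_difference <- function(observed, predicted) {
  ob <- observed$trajectories
  pr <- predicted$trajectories
  if (length(ob) != length(pr)) stop("shape mismatch: trajectory count",
                                     call. = FALSE)
  total <- 0
  for (i in seq_along(ob)) {
    X <- as.matrix(ob[[i]]$states)
    Xhat <- as.matrix(pr[[i]]$states)
    if (!all(dim(X) == dim(Xhat))) stop("shape mismatch: trajectory ", i,
                                        call. = FALSE)
    zero <- which(X == 0, arr.ind = TRUE)
    if (nrow(zero)) {
      stop("division error: observed value is zero at (t = ", zero[1, 1],
           ", gene = ", zero[1, 2], ") of trajectory ", i, call. = FALSE)
    }
    total <- total + sum(((X - Xhat) / X)^2)
  }
  total
}

# per-method signed signal strength of edge (from -> to):
#   ANN w_ij; SS g_ij; GRLOT Hill exponent with the role carrying the sign
signal_strength <- function(model, from, to) {
  p <- model$params
  if (model$method == "ANN") return(p$w[to, from])
  if (model$method == "SS") return(p$g[to, from])
  reg <- p$regulators
  r <- which(reg$target == to & reg$source == from)
  if (!length(r)) return(0)
  s <- if (reg$role[r] == "activator") 1 else -1
  s * reg$n[r]
}

degradation_rates <- function(model) {
  if (model$method == "SS") model$params$beta else model$params$k
}

# > 20% difference between two signals (qualitative asymmetry rule)
asym <- function(a, b) {
  m <- max(abs(a), abs(b))
  m > 0 && abs(abs(a) - abs(b)) / m > 0.2
}

#' Qualitative network-feature flags (Q_com)
#'
#' Evaluates the case-relevant feature subset of a model's parameter
#' matrix: uniform degradation (all degradation rates in [0.2, 0.4]);
#' constant signal propagation (case A cascade: strongest/weakest signal
#' ratio < 2); asymmetric signal branching (X2->X3 vs X2->X4) and
#' asymmetric co-regulation (X3->X5 vs X4->X5), both at the > 20%
#' difference threshold (cases B, C); positive feedback X3->X2 and
#' negative feedback X5->X2 (case C).  Signal strength per method: ANN
#' |w_ij|, S-system |g_ij|, GRLOT Hill exponent with the role carrying the
#' sign.
#'
#' @param model a 5-gene [grn_model()] (any method).
#' @param case_id `"A"`, `"B"` or `"C"`.
#' @return named logical vector of feature flags, with the signal values
#'   used attached as attribute `signals`.
#' @export
qcom_features <- function(model, case_id) {
  if (!case_id %in% c("A", "B", "C")) {
    stop("unknown case for qualitative comparison: ", case_id,
         call. = FALSE)
  }
  k <- degradation_rates(model)
  flags <- c(uniform_degradation = all(k >= 0.2 & k <= 0.4))
  sig <- list()
  if (case_id == "A") {
    s <- vapply(1:4, function(i) signal_strength(model, i, i + 1),
                numeric(1))
    sig$cascade <- s
    flags["constant_signal_propagation"] <-
      all(s != 0) && max(abs(s)) / min(abs(s)) < 2
  } else {
    branch <- c(signal_strength(model, 2, 3), signal_strength(model, 2, 4))
    coreg <- c(signal_strength(model, 3, 5), signal_strength(model, 4, 5))
    sig$branching <- branch
    sig$co_regulation <- coreg
    flags["asymmetric_signal_branching"] <- asym(branch[1], branch[2])
    flags["asymmetric_co_regulation"] <- asym(coreg[1], coreg[2])
    if (case_id == "C") {
      sig$feedback <- c(pos = signal_strength(model, 3, 2),
                        neg = signal_strength(model, 5, 2))
      flags["positive_feedback"] <- sig$feedback[["pos"]] > 0
      flags["negative_feedback"] <- sig$feedback[["neg"]] < 0
    }
  }
  attr(flags, "signals") <- sig
  flags
}

#' Interpretation band of a P_fit value
#'
#' Narrative quality bands: below 0.9 "very poor" (dynamics bear no
#' relation to the original model); 0.95-0.99 "same range, patterns may
#' differ"; above 0.99 "converging"; above 0.999 "highly accurate".  The
#' 0.9-0.95 gap carries the interpolated label "poor".
#'
#' @param value a P_fit value in (0, 1].
#' @return character band label.
#' @export
classify_pfit <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, value > 0, value <= 1)
  if (value < 0.9) return("very poor")
  if (value < 0.95) return("poor")
  if (value < 0.99) return("same range, patterns may differ")
  if (value < 0.999) return("converging")
  "highly accurate"
}

#' Full evaluation report for one (reference, inferred) model pair
#'
#' Computes P_ver on the training data, P_val and the per-condition scores
#' via the input-perturbation protocol, Delta P_fit = P_val - P_ver,
#' inferential power P_inf when (and only when) the two models share a
#' method, and the qualitative feature flags for cases A-C.
#'
#' @param inferred the reverse-engineered [grn_model()].
#' @param reference the data-generating [grn_model()].
#' @param training the training [timeseries_set()].
#' @param case_id optional case id enabling the Q_com flags.
#' @param settings an [integration_settings()].
#' @param x0_sets validation initial states (defaults to the initial rows
#'   of the training trajectories).
#' @return object of class `grn_eval_report`.
#' @export
evaluation_report <- function(inferred, reference, training,
                              case_id = NULL,
                              settings = integration_settings(),
                              x0_sets = NULL) {
  if (is.null(x0_sets)) {
    x0_sets <- do.call(rbind, lapply(training$trajectories,
                                     function(tr) tr$states[1, ]))
  }
  p_ver <- verify_model(inferred, training, settings)
  val <- validate_model(inferred, reference, settings, x0_sets)
  within <- identical(inferred$method, reference$method)
  pinf <- if (within) {
    p_inf(model_free_vector(reference), model_free_vector(inferred))
  } else {
    NA_real_
  }
  qcom <- if (!is.null(case_id) && case_id %in% c("A", "B", "C")) {
    qcom_features(inferred, case_id)
  } else {
    NULL
  }
  structure(list(p_ver = as.numeric(p_ver), p_val = val$p_val,
                 delta_p_fit = val$p_val - as.numeric(p_ver),
                 p_inf = pinf,
                 p_inf_note = if (within) "within-method"
                              else "cross-method (qualitative only)",
                 per_condition = val$per_condition, qcom = qcom,
                 case_id = case_id,
                 gen_method = reference$method,
                 infer_method = inferred$method),
            class = "grn_eval_report")
}

#' @export
print.grn_eval_report <- function(x, ...) {
  cat(sprintf("Evaluation (%s data -> %s model%s)\n", x$gen_method,
              x$infer_method,
              if (!is.null(x$case_id)) paste0(", case ", x$case_id) else ""))
  cat(sprintf("  P_ver = %.4f (%s)\n", x$p_ver, classify_pfit(x$p_ver)))
  cat(sprintf("  P_val = %.4f  [increased %.4f, decreased %.4f]\n",
              x$p_val, x$per_condition[["increased"]],
              x$per_condition[["decreased"]]))
  cat(sprintf("  dP_fit = %+.4f\n", x$delta_p_fit))
  if (!is.na(x$p_inf)) {
    cat(sprintf("  P_inf = %.4f\n", x$p_inf))
  } else {
    cat("  P_inf: ", x$p_inf_note, "\n", sep = "")
  }
  if (!is.null(x$qcom)) {
    cat("  Q_com:", paste(names(x$qcom)[x$qcom], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flatten an evaluation report to a one-row data frame
#'
#' @param x a `grn_eval_report`.
#' @param ... unused.
#' @return one-row data frame in the study-table column layout.
#' @export
as.data.frame.grn_eval_report <- function(x, ...) {
  data.frame(case = if (is.null(x$case_id)) NA_character_ else x$case_id,
             gen_method = x$gen_method, infer_method = x$infer_method,
             p_inf = x$p_inf, p_ver = x$p_ver, p_val = x$p_val,
             delta_p_fit = x$delta_p_fit,
             p_val_increased = x$per_condition[["increased"]],
             p_val_decreased = x$per_condition[["decreased"]],
             stringsAsFactors = FALSE)
}
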