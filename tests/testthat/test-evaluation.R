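test_that("p_fit matches the brute-force double loop and hand values", {
  # hand example: X = (1, 2), Xhat = (1, 1) -> E = 0.5, P_fit = 2/3
  o <- make_ts(list(matrix(c(1, 2), 2, 1)))
  h <- make_ts(list(matrix(c(1, 1), 2, 1)))
  expect_equal(p_fit(o, h), 2 / 3)

  # identical sets score exactly 1
  expect_equal(p_fit(o, o), 1)

  # E = 1/P_fit - 1 round-trip identity
  pf <- p_fit(o, h)
  expect_equal(1 / pf - 1, 0.5)

  # oracle equivalence on random multi-trajectory sets
  set.seed(7)
  for (i in 1:10) {
    p <- sample(3:8, 1); n <- sample(2:5, 1); m <- sample(1:3, 1)
    obs <- make_ts(lapply(1:m, function(j) matrix(runif(p * n), p, n)))
    prd <- make_ts(lapply(1:m, function(j) matrix(runif(p * n), p, n)))
    expect_equal(p_fit(obs, prd), brute_p_fit(obs, prd))
  }

  expect_error(p_fit(o, make_ts(list(matrix(1, 1, 1)))), "mismatch")
})

test_that("p_inf matches Pearson-based oracle and its identities", {
  expect_equal(p_inf(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(p_inf(c(1, -2, 3), -c(1, -2, 3)), 0)

  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(sample(3:20, 1))
    b <- rnorm(length(a))
    expect_equal(p_inf(a, b), brute_p_inf(a, b))
    # invariance under positive affine rescaling
    expect_equal(p_inf(a, 2.5 * a + 1), 1)
  }

  expect_error(p_inf(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(p_inf(1, 1), "length")
})

test_that("relative difference matches its oracle and is scale invariant", {
  o <- make_ts(list(matrix(2, 1, 1)))
  h <- make_ts(list(matrix(1, 1, 1)))
  expect_equal(relative_difference(o, h), 0.25)
  expect_equal(relative_difference(o, o), 0)

  set.seed(9)
  for (i in 1:5) {
    obs <- make_ts(list(matrix(runif(12, 0.5, 2), 4, 3)))
    prd <- make_ts(list(matrix(runif(12, 0.5, 2), 4, 3)))
    expect_equal(relative_difference(obs, prd),
                 brute_relative_difference(obs, prd))
    # doubling both series leaves the score unchanged
    obs2 <- obs; prd2 <- prd
    obs2$trajectories[[1]]$states <- obs$trajectories[[1]]$states * 2
    prd2$trajectories[[1]]$states <- prd$trajectories[[1]]$states * 2
    expect_equal(relative_difference(obs2, prd2),
                 relative_difference(obs, prd))
  }

  zero <- make_ts(list(matrix(c(0, 1), 2, 1)))
  pred <- make_ts(list(matrix(c(1, 1), 2, 1)))
  expect_error(relative_difference(zero, pred), "division error")
})

test_that("verification scores a generator model as near-perfect", {
  m <- build_case("A", "ANN")
  d <- generate_sparse(m)
  expect_gt(as.numeric(verify_model(m, d)), 0.9999)

  # the zero-influence model (all free parameters 0, frozen states) scores
  # far below the generator; expected value computed by an oracle run
  null_model <- model_from_free_vector("ANN", m$topology, rep(0, 19))
  p_null <- as.numeric(verify_model(null_model, d))
  expect_equal(p_null, 0.913874, tolerance = 1e-4)
  expect_lt(p_null, 0.95)
})

test_that("validation of the reference against itself is perfect", {
  m <- build_case("A", "GRLOT")
  val <- validate_model(m, m)
  expect_equal(val$p_val, 1, tolerance = 1e-9)
  expect_equal(unname(val$per_condition), c(1, 1), tolerance = 1e-9)
  rep <- evaluation_report(m, m, generate_sparse(m), case_id = "A")
  expect_equal(rep$delta_p_fit, 0, tolerance = 1e-6)
  expect_equal(rep$p_inf, 1)
})

test_that("delta P_fit identity holds on every report", {
  m <- build_case("A", "SS")
  # a deliberately imperfect model: nudge one kinetic order
  m2 <- m
  m2$params$g[3, 2] <- 1.8
  rep <- evaluation_report(m2, m, generate_sparse(m), case_id = "A")
  expect_equal(rep$delta_p_fit, rep$p_val - rep$p_ver)
  # Table arithmetic of the printed sparse ANN case A row
  expect_equal(0.9972 - 0.9996, -0.0024)
})

test_that("cross-method pairs report P_inf as not computable", {
  ref <- build_case("A", "SS")
  inf <- build_case("A", "ANN")
  rep <- evaluation_report(inf, ref, generate_sparse(ref), case_id = "A")
  expect_true(is.na(rep$p_inf))
  expect_match(rep$p_inf_note, "qualitative")
})

test_that("Q_com reproduces the designed feature lists of the references", {
  expected <- list(
    A = c(uniform_degradation = TRUE, constant_signal_propagation = TRUE),
    B = c(uniform_degradation = TRUE, asymmetric_signal_branching = TRUE,
          asymmetric_co_regulation = TRUE),
    C = c(uniform_degradation = TRUE, asymmetric_signal_branching = TRUE,
          asymmetric_co_regulation = TRUE, positive_feedback = TRUE,
          negative_feedback = TRUE))
  for (case in names(expected)) {
    for (method in c("ANN", "SS", "GRLOT")) {
      flags <- qcom_features(build_case(case, method), case)
      expect_equal(flags[names(expected[[case]])], expected[[case]],
                   info = paste(case, method),
                   ignore_attr = TRUE)
      expect_named(flags, names(expected[[case]]))
    }
  }
})

test_that("Q_com thresholds act on degradation and signal values", {
  m <- build_case("A", "ANN")
  expect_true(qcom_features(m, "A")[["uniform_degradation"]])
  m$params$k[5] <- 0.5
  expect_false(qcom_features(m, "A")[["uniform_degradation"]])

  # constant propagation fails once one cascade weight doubles
  m2 <- build_case("A", "ANN")
  m2$params$w[3, 2] <- 10.5
  expect_false(qcom_features(m2, "A")[["constant_signal_propagation"]])

  # feedback sign flips flip the flags
  m3 <- build_case("C", "ANN")
  m3$params$w[2, 3] <- -1
  f <- qcom_features(m3, "C")
  expect_false(f[["positive_feedback"]])
  expect_true(f[["negative_feedback"]])

  expect_error(qcom_features(m, "D"), "unknown case")
})

test_that("P_fit interpretation bands follow the narrative thresholds", {
  expect_equal(classify_pfit(0.9999), "highly accurate")
  expect_equal(classify_pfit(0.85), "very poor")
  expect_equal(classify_pfit(0.97), "same range, patterns may differ")
  expect_equal(classify_pfit(0.992), "converging")
  expect_equal(classify_pfit(0.93), "poor")
})
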