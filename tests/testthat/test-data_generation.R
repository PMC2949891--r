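test_that("single-gene closed forms are reproduced by the integrator", {
  # pure decay: X(t) = 0.8 exp(-0.3 t)
  m <- one_gene_decay(k = 0.3)
  st <- integration_settings(t_end = 10, n_points = 101)
  tr <- integrate_model(m, 0.8, st)
  expect_true(tr$ok)
  expect_lt(max(abs(tr$states[, 1] - 0.8 * exp(-0.3 * tr$times))), 1e-5)

  # ANN steady state: X* = v f(-theta) / k
  ma <- one_gene_ann(v = 1, theta = 2, k = 0.3)
  xstar <- 1 * sigmoid_logistic(-2) / 0.3
  tr2 <- integrate_model(ma, 0.05, integration_settings(t_end = 60,
                                                        n_points = 200))
  expect_lt(abs(tr2$states[200, 1] - xstar), 1e-4)
})

test_that("compiled integrator agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  st <- integration_settings(t_end = 20, n_points = 50)
  x0 <- starting_sets()[2, ]
  for (method in c("ANN", "SS", "GRLOT")) {
    m <- build_case("C", method)
    tr <- integrate_model(m, x0, st)
    ref <- deSolve::ode(y = unname(x0), times = tr$times,
                        func = function(t, y, p) list(model_rate(m, y)),
                        parms = NULL, method = "lsoda",
                        rtol = 1e-9, atol = 1e-10)
    expect_true(tr$ok, info = method)
    expect_lt(max(abs(tr$states - ref[, -1])), 1e-4, label = method)
  }
})

test_that("sparse and detailed datasets follow the study design", {
  m <- build_case("A", "ANN")
  sp <- generate_sparse(m)
  expect_length(sp$trajectories, 1)
  expect_equal(dim(sp$trajectories[[1]]$states), c(200, 5))
  expect_equal(unname(sp$trajectories[[1]]$states[1, ]),
               c(0.8, 0.1, 0.1, 0.1, 0.1))

  de <- generate_detailed(m)
  expect_length(de$trajectories, 5)
  expect_equal(unname(de$trajectories[[5]]$states[1, ]),
               c(0.5, 0.2, 0.8, 0.8, 0.2))
  # detailed restricted to trajectory 1 equals the sparse set
  expect_identical(de$trajectories[[1]]$states, sp$trajectories[[1]]$states)

  # determinism: identical settings give bitwise-identical output
  sp2 <- generate_sparse(m)
  expect_identical(sp$trajectories[[1]]$states, sp2$trajectories[[1]]$states)
})

test_that("halving tolerances leaves case trajectories stable", {
  for (method in c("ANN", "SS", "GRLOT")) {
    m <- build_case("B", method)
    t1 <- generate_sparse(m)$trajectories[[1]]$states
    t2 <- generate_sparse(m, integration_settings(rtol = 5e-7,
                                                  atol = 5e-9))$trajectories[[1]]$states
    expect_lt(max(abs(t1 - t2)), 1e-5, label = method)
  }
})

test_that("ANN/GRLOT trajectories from positive starts stay non-negative", {
  for (method in c("ANN", "GRLOT")) {
    for (case in c("A", "B", "C")) {
      de <- generate_detailed(build_case(case, method))
      for (tr in de$trajectories) {
        expect_true(all(tr$states > -1e-8),
                    info = paste(case, method, tr$label))
      }
    }
  }
})

test_that("integration failure is a flagged result, not an exception", {
  # an S-system pushed into its singularity regime: strong negative
  # exponent on a decaying species with unbounded production growth
  topo <- grn_topology(2, data.frame(from = c(2, 1), to = c(1, 1),
                                     sign = c(-1L, 1L)))
  p <- ss_params(alpha = c(5, 0), beta = c(0.1, 10),
                 g = matrix(c(2, 0, -3, 0), 2, 2), h = diag(c(1, 1)))
  m <- grn_model("SS", topo, p)
  tr <- integrate_model(m, c(1, 0.5), integration_settings(t_end = 50))
  expect_false(tr$ok)
  expect_lt(tr$filled, 200)
  expect_true(all(is.finite(tr$states)))
})

test_that("input and initial-value perturbations modify what they claim", {
  m <- build_case("A", "ANN")
  pr <- perturb_input(m)
  expect_equal(pr$increased$params$k[1], 0.1)
  expect_equal(pr$decreased$params$k[1], 0.5)
  expect_equal(pr$increased$params$k[-1], m$params$k[-1])

  ms <- build_case("A", "SS")
  prs <- perturb_input(ms)
  expect_equal(prs$increased$params$beta[1], 0.1)
  expect_equal(prs$increased$params$k, NULL)

  # double application is idempotent on the {0.1, 0.5} values
  pr2 <- perturb_input(pr$increased)
  expect_equal(pr2$increased$params$k[1], 0.1)
  expect_equal(pr2$decreased$params$k[1], 0.5)

  # initial-value perturbation: one entry multiplied, others unchanged
  x0 <- c(0.0045, 0.03, 0.01, 0.02, 0.01)
  expect_equal(perturb_initial(x0, 1, 3)[1], 0.0135)
  expect_equal(perturb_initial(x0, 1, 48)[1], 0.216)
  expect_equal(perturb_initial(x0, 1, 1), x0)
  expect_equal(perturb_initial(x0, 2, 12)[-2], x0[-2])
  expect_error(perturb_initial(x0, 9, 3), "out of range")
})

test_that("the observational-noise hook defaults off and is seedable", {
  m <- build_case("A", "GRLOT")
  st <- integration_settings(n_points = 30)
  clean <- generate_sparse(m, st)
  clean2 <- generate_sparse(m, st, noise_sd = 0, noise_seed = 1)
  expect_identical(clean$trajectories[[1]]$states,
                   clean2$trajectories[[1]]$states)
  noisy1 <- generate_sparse(m, st, noise_sd = 0.05, noise_seed = 7)
  noisy2 <- generate_sparse(m, st, noise_sd = 0.05, noise_seed = 7)
  expect_identical(noisy1$trajectories[[1]]$states,
                   noisy2$trajectories[[1]]$states)
  expect_false(identical(noisy1$trajectories[[1]]$states,
                         clean$trajectories[[1]]$states))
  # multiplicative: relative deviations are noise-scale, not absolute
  rel <- noisy1$trajectories[[1]]$states / clean$trajectories[[1]]$states
  expect_lt(max(abs(rel - 1)), 0.05 * 5)
})

test_that("time-series CSV dialect round-trips", {
  m <- build_case("B", "GRLOT")
  de <- generate_detailed(m, integration_settings(n_points = 40))
  tmp <- withr::local_tempfile(fileext = ".csv")
  ts_write_csv(de, tmp, meta = list(case = "B", method = "GRLOT"))
  back <- ts_read_csv(tmp)
  expect_length(back$trajectories, 5)
  for (i in 1:5) {
    expect_equal(back$trajectories[[i]]$states,
                 unname(de$trajectories[[i]]$states) |>
                   `colnames<-`(de$gene_names),
                 tolerance = 1e-6)
  }
  expect_true(file.exists(paste0(tmp, ".json")))
})
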