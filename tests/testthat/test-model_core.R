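test_that("topology constructor enforces its invariants", {
  topo <- grn_topology(5, data.frame(from = c(1, 2), to = c(2, 2),
                                     sign = c("activating", "inhibiting")))
  expect_s3_class(topo, "grn_topology")
  expect_equal(topo$edges$sign, c(1L, -1L))
  expect_error(grn_topology(0), "positive integer")
  expect_error(grn_topology(3, data.frame(from = 1, to = 4, sign = 1)),
               "indices")
  expect_error(grn_topology(3, data.frame(from = c(1, 1), to = c(2, 2),
                                          sign = c(1, -1))),
               "at most one edge")
  # self-edges permitted
  expect_silent(grn_topology(2, data.frame(from = 1, to = 1, sign = 1)))
})

test_that("ANN rate law evaluates the sigmoid-sum form", {
  # a symmetric sigmoid at zero input gives production v/2
  p <- ann_params(v = 1, w = matrix(0, 1, 1), theta = 0, k = 0.3)
  expect_equal(ann_rate(0.7, p) + 0.3 * 0.7, 0.5)

  # case A gene X2 at starting set 1: w21*X1 - theta = 5*0.8 - 4 = 0
  m <- build_case("A", "ANN")
  r <- ann_rate(c(0.8, 0.1, 0.1, 0.1, 0.1), m$params)
  expect_equal(r[2], 1.0 * 0.5 - 0.3 * 0.1)

  # saturation: strongly negative input drives production to 0
  p2 <- ann_params(v = 2, w = matrix(-50, 1, 1), theta = 5, k = 0.3)
  expect_equal(ann_rate(3, p2), -0.3 * 3, tolerance = 1e-10)

  expect_error(ann_rate(c(1, 2), p), "length")
  expect_error(ann_rate(NaN, p), "finite")
})

test_that("ANN and GRLOT production terms stay inside (0, v)", {
  set.seed(42)
  mA <- build_case("B", "ANN")
  mG <- build_case("B", "GRLOT")
  for (i in 1:50) {
    x <- runif(5, 0, 1.5)   # physiological range; keeps f away from
                            # floating-point saturation at exactly 1
    prod_ann <- ann_rate(x, mA$params) + mA$params$k * x
    expect_true(all(prod_ann > 0 & prod_ann < pmax(mA$params$v, 1e-300)))
    prod_grlot <- grlot_rate(x, mG$params) + mG$params$k * x
    active <- mG$params$v > 0
    expect_true(all(prod_grlot[active] > 0 &
                      prod_grlot[active] < mG$params$v[active]))
  }
})

test_that("S-system rate law reduces correctly and flags singularities", {
  # case A values: g zero, h diagonal 1 -> dX/dt = alpha - beta * X
  m <- build_case("A", "SS")
  p <- m$params
  r <- ss_rate(rep(1, 5), p)
  expect_equal(r, p$alpha - p$beta)

  # all exponents zero: constant rates alpha - beta
  p0 <- ss_params(alpha = c(1, 2), beta = c(0.3, 0.5),
                  g = matrix(0, 2, 2), h = matrix(0, 2, 2))
  expect_equal(ss_rate(c(7, 9), p0), c(0.7, 1.5))

  # case C: X5 = 0 with g_25 = -0.3 is the singularity regime
  mc <- build_case("C", "SS")
  expect_error(ss_rate(c(1, 1, 1, 1, 0), mc$params),
               class = "grn_singularity_error")
})

test_that("GRLOT factors behave like complementary Hill forms", {
  # half-saturation: activator factor is exactly 0.5 at X = K, any n
  for (n in c(0.5, 1, 1.5, 4)) {
    p <- grlot_params(v = c(0, 1), k = c(0.3, 0.3),
                      regulators = data.frame(target = 2, source = 1,
                                              role = "activator",
                                              n = n, K = 1.1))
    r <- grlot_rate(c(1.1, 0.2), p)
    expect_equal(r[2] + 0.3 * 0.2, 0.5)
    # inhibitor at I = Ki is also 0.5 (the forms are complements)
    p$regulators$role <- "inhibitor"
    r2 <- grlot_rate(c(1.1, 0.2), p)
    expect_equal(r2[2] + 0.3 * 0.2, 0.5)
  }

  # activator + inhibitor factors at the same (X, n, K) sum to 1
  set.seed(1)
  for (i in 1:20) {
    x <- runif(1, 0, 4); n <- runif(1, 0.2, 5); K <- runif(1, 0.1, 3)
    act <- x^n / (x^n + K^n)
    inh <- K^n / (x^n + K^n)
    expect_equal(act + inh, 1)
  }

  # case A gene X2 at X1 = K = 1.1: production = 0.5 * v
  m <- build_case("A", "GRLOT")
  r <- grlot_rate(c(1.1, 0.1, 0.1, 0.1, 0.1), m$params)
  expect_equal(r[2], 0.5 * 1.0 - 0.3 * 0.1)

  # no regulators: production is exactly v (gene X1 here has v = 0)
  expect_equal(r[1], 0 - 0.3 * 1.1)
})

test_that("parameter counts match the method formulas", {
  expect_identical(count_parameters("ANN", 5), 40L)
  expect_identical(count_parameters("SS", 5), 60L)
  expect_identical(count_parameters("GRLOT", 1), 3L)
  expect_error(count_parameters("HILL", 3), "unknown method")

  # ANN and SS dense formulas agree with explicit field enumeration
  for (n in 1:6) {
    dense <- grn_topology(n, expand.grid(from = 1:n, to = 1:n, sign = 1L))
    expect_equal(count_parameters("ANN", n),
                 3 * n + n^2)  # v, theta, k + w matrix
    expect_equal(count_parameters("SS", n),
                 2 * n + 2 * n^2)  # alpha, beta + g, h matrices
    expect_identical(n_free_parameters("ANN", dense),
                     as.integer(3 * n + n^2))
  }
})

test_that("masked free-parameter counts follow the topology", {
  topo <- case_topology_fixture <- build_case("A", "ANN")$topology
  # 5 genes x (v, theta, k) + 4 cascade weights
  expect_identical(n_free_parameters("ANN", topo), 19L)
  # 5 genes x (alpha, beta, h_ii) + 4 g entries
  expect_identical(n_free_parameters("SS", topo), 19L)
  # 5 genes x (v, k) + 4 x (n, K)
  expect_identical(n_free_parameters("GRLOT", topo), 18L)
})

test_that("model constructor rejects mask and dimension violations", {
  topo <- grn_topology(2, data.frame(from = 1, to = 2, sign = 1L))
  w_bad <- matrix(c(0, 5, 1, 0), 2, 2)  # w[1,2] outside the mask
  expect_error(grn_model("ANN", topo,
                         ann_params(v = c(1, 1), w = w_bad,
                                    theta = c(1, 1), k = c(0.3, 0.3))),
               "mask")
  reg_bad <- data.frame(target = 2, source = 1, role = "inhibitor",
                        n = 1, K = 1)
  expect_error(grn_model("GRLOT", topo,
                         grlot_params(v = c(1, 1), k = c(0.3, 0.3),
                                      regulators = reg_bad)),
               "consistent")
})

test_that("model JSON serialization round-trips at full precision", {
  for (method in c("ANN", "SS", "GRLOT")) {
    m <- two_gene_model(method)
    # perturb to awkward floats
    if (method == "ANN") m$params$w[2, 1] <- 5 + pi * 1e-8
    m2 <- model_from_json(model_to_json(m))
    expect_identical(model_free_vector(m), model_free_vector(m2))
    expect_identical(m2$topology$edges, m$topology$edges)
  }
})

test_that("free-vector packing and unpacking are inverse operations", {
  for (method in c("ANN", "SS", "GRLOT")) {
    m <- build_case("C", method)
    w <- model_free_vector(m)
    m2 <- model_from_free_vector(method, m$topology, as.numeric(w))
    expect_equal(model_free_vector(m2), w)
  }
})
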