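test_that("Lotka-Volterra right-hand side and equilibrium", {
  p <- lv_demo()
  # exponential prey growth without predator; exponential predator decay
  expect_equal(lv_rhs(c(2, 0), p), c(2, 0))
  expect_equal(lv_rhs(c(0, 3), p), c(0, -1.5))

  eq <- lv_interior_equilibrium(p)
  expect_equal(unname(eq), c(5, 5))
  # the equilibrium zeroes the rhs to machine precision
  resid <- lv_rhs(eq, p)
  scale <- c(p$a * eq[[1]], p$c * eq[[2]])
  expect_true(all(abs(resid) <= 8 * .Machine$double.eps * scale))

  # closed-form proportionality: doubling c doubles x*, leaves y* unchanged
  p2 <- lv_params(p$a, p$b, 2 * p$c, p$d)
  eq2 <- lv_interior_equilibrium(p2)
  expect_equal(eq2[["x"]], 2 * eq[["x"]])
  expect_equal(eq2[["y"]], eq[["y"]])
})

test_that("L-V conserved quantity: closed form, extremum at equilibrium", {
  p <- lv_demo()
  expect_equal(lv_invariant(c(5, 5), p), 0.5 + 1 - 1.5 * log(5))
  # gradient of H vanishes at the interior equilibrium
  eq <- lv_interior_equilibrium(p)
  h <- 1e-7
  for (e in list(c(h, 0), c(0, h))) {
    g <- (lv_invariant(eq + e, p) - lv_invariant(eq - e, p)) / (2 * h)
    expect_lt(abs(g), 1e-6)
  }
  expect_error(lv_invariant(c(0, 1), p), class = "immunecol_validation_error")
  expect_error(lv_params(a = 0, b = 1, c = 1, d = 1),
               class = "immunecol_validation_error")
})

test_that("Allee/injury rhs: boundary equilibria and sign structure", {
  p <- allee_demo()
  expect_equal(allee_rhs(c(p$L, 0), p), c(0, 0))
  expect_equal(allee_rhs(c(p$K, 0), p), c(0, 0))
  # below the Allee threshold the prey declines
  expect_lt(allee_rhs(c(p$L / 2, 0), p)[1], 0)
  # between L and K it grows
  expect_gt(allee_rhs(c((p$L + p$K) / 2, 0), p)[1], 0)
  # at g = d the capture reward vanishes: dy/dt = -c*y for any x
  pg <- allee_params(p$a, p$K, p$L, p$c, d = 0.3, g = 0.3, response = p$response)
  for (x in c(0, 1, 5, 20)) {
    expect_equal(allee_rhs(c(x, 2), pg)[2], -pg$c * 2)
  }
  expect_error(allee_params(1, K = 5, L = 5, c = 1, d = 1,
                            response = functional_response(1)),
               class = "immunecol_validation_error")
})

test_that("Allee interior equilibrium: closed form, NONE cases, rhs residual", {
  fr <- functional_response(0.1)
  p <- allee_params(a = 0.01, K = 10, L = 1, c = 0.25, d = 0.5, g = 0,
                    response = fr)
  eq <- allee_interior_equilibrium(p)
  expect_equal(unname(eq), c(5, 2))

  # g >= d: predator cannot profit from capture
  expect_null(allee_interior_equilibrium(
    allee_params(0.01, 10, 1, 0.25, d = 0.3, g = 0.3, response = fr)))
  # x* beyond K: nullclines do not intersect at positive y
  expect_null(allee_interior_equilibrium(allee_demo(c = 0.6)))
  # x* below L
  expect_null(allee_interior_equilibrium(allee_demo(c = 0.025)))

  # saturating and sigmoidal responses: root search, residual within 1e-10
  for (resp in list(functional_response(0.2, 1, 0.5),
                    functional_response(0.05, 2, 0.3))) {
    ps <- allee_params(a = 0.01, K = 10, L = 1, c = 0.25, d = 0.5, g = 0.05,
                       response = resp)
    eqs <- allee_interior_equilibrium(ps)
    if (!is.null(eqs)) {
      r <- allee_rhs(eqs, ps)
      scale <- max(abs(c(ps$a * eqs[1] * ps$K^2, ps$c * eqs[2])))
      expect_lt(max(abs(r)) / scale, 1e-10)
    }
  }
})

test_that("tumor-immune rhs implements the mechanism couplings", {
  p <- ti_demo()
  # no cancer: no kills, APCs decay, effectors decay once APCs drain
  d0 <- ti_rhs(c(0, 2, 3), p)
  expect_equal(d0, c(0, -p$mu_A * 2, p$rho * 2 - p$mu_E * 3))
  # tumor at capacity with no immune compartments is an equilibrium
  expect_equal(ti_rhs(c(p$K_C, 0, 0), p), c(0, 0, 0))
  # killing couples into APC stimulation
  base <- ti_rhs(c(10, 1, 0), p)
  kick <- ti_rhs(c(10, 1, 2), p)
  kill <- eval_response(10, p$response) * 2
  expect_equal(kick[2] - base[2], p$s * kill)
})

test_that("QSS reduction: d_eff closed form, algebraic identity, prey preserved", {
  p <- ti_params(r = 1, K_C = 20, response = functional_response(0.1),
                 s = 0.3, mu_A = 3, rho = 2, mu_E = 0.2, g = 0.05)
  red <- qss_reduce(p)
  expect_equal(red$d_eff, 0.2)

  set.seed(5)
  for (k in 1:20) {
    C <- runif(1, 0, 25); E <- runif(1, 0, 10)
    A <- ti_apc_qss(p, C, E)
    full <- ti_rhs(c(C, A, E), p)
    rr <- reduced_rhs(c(C, E), red)
    # reduced effector equation equals full one with A at its QSS
    expect_equal(rr[2], full[3], tolerance = 1e-12)
    # prey equation is preserved exactly
    expect_identical(rr[1], full[1])
    # APC derivative vanishes at the QSS
    expect_equal(full[2], 0, tolerance = 1e-12)
  }
})

test_that("reduced module classification splits on d_eff vs g", {
  mk <- function(g) ti_params(r = 1, K_C = 20, response = functional_response(0.1),
                              s = 0.3, mu_A = 3, rho = 2, mu_E = 0.2, g = g)
  expect_identical(classify_reduced_module(mk(0.05)), "PREDATOR_PREY")
  expect_identical(classify_reduced_module(mk(0.9)), "COMPETITION")
  expect_identical(classify_reduced_module(mk(0.2)), "BOUNDARY")
})

test_that("competition-side reduced systems never oscillate", {
  batt <- parameter_battery(31, "ti", 40)
  comp <- Filter(function(p) classify_reduced_module(p) == "COMPETITION", batt)
  expect_gt(length(comp), 5)
  for (p in comp) {
    red <- qss_reduce(p)
    tr <- simulate_model("ti-reduced", red, c(0.5 * p$K_C, 0.05 * p$K_C),
                         t_end = 400, n_out = 4000)
    v <- detect_oscillation(tr)
    expect_false(v$label == "SUSTAINED")
    # effectors decline monotonically once past any initial transient:
    # with d_eff < g every capture is a net loss, dE/dt < 0 throughout
    E <- tr$states[, "E"]
    expect_true(all(diff(E) <= 1e-10))
  }
})
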