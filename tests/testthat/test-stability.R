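test_that("finite-difference Jacobian matches closed forms", {
  p <- lv_demo()
  J <- pp_jacobian("lv", c(5, 5), p)
  expect_equal(unclass(J), matrix(c(0, 0.5, -1, 0), 2, 2,
                                  dimnames = list(c("x", "y"), c("x", "y"))),
               tolerance = 1e-8)
  # against the analytic L-V Jacobian at random positive states
  set.seed(3)
  for (k in 1:20) {
    s <- 10^runif(2, -1, 1.5)
    Ja <- matrix(c(p$a - p$b * s[2], p$d * p$b * s[2],
                   -p$b * s[1], p$d * p$b * s[1] - p$c), 2, 2)
    expect_equal(unclass(pp_jacobian("lv", s, p)), Ja, tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
  # prey self-limitation at carrying capacity
  pa <- allee_demo()
  expect_lt(pp_jacobian("allee", c(pa$K, 0), pa)[1, 1], 0)
})

test_that("eigenvalue classification covers all stability labels", {
  expect_identical(classify_stability(c(-1, -2)), "STABLE_NODE")
  expect_identical(classify_stability(c(-1 + 2i, -1 - 2i)), "STABLE_FOCUS")
  expect_identical(classify_stability(c(2, 1)), "UNSTABLE_NODE")
  expect_identical(classify_stability(c(0.1 + 2i, 0.1 - 2i)), "UNSTABLE_FOCUS")
  expect_identical(classify_stability(c(-1, 2)), "SADDLE")
  expect_identical(classify_stability(c(1i, -1i)), "MARGINAL")
  expect_identical(classify_stability(c(-1, 1e-12)), "MARGINAL")
  expect_error(classify_stability(numeric(0)),
               class = "immunecol_validation_error")
})

test_that("equilibrium enumeration: counts, residuals, labels", {
  # L-V: origin saddle plus marginal center
  eq_lv <- find_equilibria("lv", lv_demo())
  expect_length(eq_lv, 2)
  expect_identical(eq_lv[[2]]$stability, "MARGINAL")
  # Allee with L > 0, d > g and interior root in (L, K): exactly 4
  eq_al <- find_equilibria("allee", allee_demo(c = 0.4))
  expect_length(eq_al, 4)
  for (e in eq_al) expect_lt(max(abs(e$rhs)), 1e-8)
  # origin is a stable node (Allee effect), K prey-only is invadable here
  expect_identical(eq_al[[1]]$stability, "STABLE_NODE")
  expect_identical(eq_al[[3]]$stability, "SADDLE")
  # escape regime: no interior equilibrium
  expect_length(find_equilibria("allee", allee_demo(c = 0.6)), 3)
  # TI model: extinction, tumor-at-capacity, coexistence
  eq_ti <- find_equilibria("ti", ti_demo())
  expect_length(eq_ti, 3)
  for (e in eq_ti) expect_lt(max(abs(e$rhs)), 1e-8)
})

test_that("stability labels agree with the perturbation oracle", {
  batt <- parameter_battery(7, "allee", 25)
  n <- 0
  for (p in batt) {
    for (e in find_equilibria("allee", p)) {
      if (e$stability == "MARGINAL" ||
          min(abs(Re(e$eigenvalues))) <= 1e-7) next
      v <- perturbation_oracle("allee", e$state, p, max(Re(e$eigenvalues)))
      expected <- if (startsWith(e$stability, "STABLE")) "STABLE" else "UNSTABLE"
      expect_identical(v, expected)
      n <- n + 1
    }
  }
  expect_gt(n, 50)
})

test_that("regime classifier reproduces the four worked outcomes", {
  want <- c("0.025" = "ELIMINATION", "0.26" = "OSCILLATION",
            "0.4" = "COEXISTENCE", "0.6" = "ESCAPE")
  for (cc in names(want)) {
    r <- classify_regime(allee_demo(c = as.numeric(cc)))
    expect_identical(r$label, want[[cc]])
  }
  # analytic-only mode and simulation-only mode agree on the clear-cut cases
  for (cc in c(0.025, 0.4, 0.6)) {
    ra <- classify_regime(allee_demo(c = cc), method = "analytic")
    rs <- classify_regime(allee_demo(c = cc), method = "simulation")
    expect_identical(ra$label, rs$label)
  }
  expect_error(classify_regime(
    allee_params(0.01, 10, 1, 0.25, 0.5, 0,
                 response = functional_response(0.1, 1, 0.5))),
    class = "immunecol_validation_error")
})

test_that("escape verdict implies predator extinction and prey at K", {
  p <- allee_demo(c = 0.6)
  r <- classify_regime(p)
  expect_identical(r$label, "ESCAPE")
  tr <- simulate_model("allee", p, c(7.5, 0.5), t_end = 1000)
  fin <- tr$states[nrow(tr$states), ]
  expect_identical(fin[["y"]], 0)
  expect_equal(fin[["x"]], p$K, tolerance = 1e-3)
})

test_that("regime classification is invariant to time rescaling", {
  # multiplying a, c and d (hence b*d) by a common factor rescales time only
  for (cc in c(0.025, 0.26, 0.4, 0.6)) {
    p <- allee_demo(c = cc)
    lab1 <- classify_regime(p)$label
    k <- 3
    p2 <- allee_params(a = k * p$a, K = p$K, L = p$L, c = k * p$c,
                       d = k * p$d, g = k * p$g, response = p$response)
    expect_identical(classify_regime(p2)$label, lab1)
  }
})

test_that("regime map rows follow the immunoediting sequence", {
  base <- allee_demo()
  m <- regime_map(base, inefficiency = seq(0.5, 14.5, length.out = 8),
                  ratio = c(0.1, 0.3))
  chk <- check_regime_sequence(m)
  expect_true(chk$ok)
  # extreme cells: very efficient predator eliminates, very inefficient escapes
  g <- m$grid
  first <- g[g$inefficiency == min(g$inefficiency), ]
  last <- g[g$inefficiency == max(g$inefficiency), ]
  expect_true(all(first$regime == "ELIMINATION"))
  expect_true(all(last$regime == "ESCAPE"))
  # the immunoediting relabeling
  expect_identical(unique(first$immunoediting_phase), "elimination")
  expect_identical(unique(last$immunoediting_phase), "escape")
  expect_setequal(immunoediting_phase(c("ELIMINATION", "OSCILLATION",
                                        "COEXISTENCE", "ESCAPE")),
                  c("elimination", "transitional oscillation", "equilibrium",
                    "escape"))
  # writer: long CSV plus JSON summary
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_regime_map(m, csv, js)
  back <- read.csv(csv)
  expect_identical(names(back),
                   c("inefficiency", "ratio", "regime", "immunoediting_phase"))
  expect_identical(nrow(back), nrow(m$grid))
  meta <- jsonlite::fromJSON(js)
  expect_identical(meta$n_cells, nrow(m$grid))
})
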