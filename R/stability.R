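#' Finite-difference Jacobian of a model's right-hand side
#'
#' Central differences with per-coordinate step `step * max(1, |state_j|)`;
#' entry `(i, j)` is the local effect of compartment `j`'s density on
#' compartment `i`'s total growth rate.  When a coordinate sits within one
#' step of zero (boundary equilibria) a forward difference is used so the
#' right-hand side is never evaluated at negative densities.
#'
#' @param model model id (see [simulate_model()]).
#' @param state evaluation state (typically an equilibrium), finite.
#' @param params matching parameter object.
#' @param step base finite-difference step.
#' @return square numeric matrix with compartment dimnames.
#' @export
pp_jacobian <- function(model, state, params, step = 1e-6) {
  model <- normalize_model(model)
  params <- check_model_params(model, params)
  info <- model_info(model)
  d <- length(info$compartments)
  if (length(state) != d || any(!is.finite(state)))
    abort_validation(sprintf("state must be %d finite densities", d))
  state <- as.numeric(state)
  J <- matrix(0, d, d, dimnames = list(info$compartments, info$compartments))
  for (j in seq_len(d)) {
    h <- step * max(1, abs(state[j]))
    e <- numeric(d); e[j] <- h
    if (state[j] - h >= 0) {
      J[, j] <- (info$rhs(state + e, params) - info$rhs(state - e, params)) / (2 * h)
    } else {
      J[, j] <- (info$rhs(state + e, params) - info$rhs(state, params)) / h
    }
  }
  J
}

#' Classify linear stability from eigenvalues
#'
#' Signs of real parts under tolerance `tol`: all below `-tol` gives a stable
#' node (real spectrum) or stable focus (complex pair); all above `tol` the
#' unstable counterparts; real parts on both sides give a saddle; any real
#' part within `±tol` of zero is marginal (e.g. the neutrally stable
#' Lotka-Volterra center, eigenvalues `±i sqrt(ac)`).
#'
#' @param eigenvalues numeric or complex eigenvalues of a real matrix.
#' @param tol zero tolerance on real parts.
#' @return one of `"STABLE_NODE"`, `"STABLE_FOCUS"`, `"UNSTABLE_NODE"`,
#'   `"UNSTABLE_FOCUS"`, `"SADDLE"`, `"MARGINAL"`.
#' @export
classify_stability <- function(eigenvalues, tol = 1e-8) {
  if (length(eigenvalues) == 0) abort_validation("no eigenvalues supplied")
  re <- Re(eigenvalues); im <- Im(eigenvalues)
  if (any(abs(re) <= tol)) return("MARGINAL")
  focus <- any(abs(im) > tol)
  if (all(re < -tol)) return(if (focus) "STABLE_FOCUS" else "STABLE_NODE")
  if (all(re > tol)) return(if (focus) "UNSTABLE_FOCUS" else "UNSTABLE_NODE")
  "SADDLE"
}

equilibrium_report <- function(model, state, params, tol = 1e-8) {
  info <- model_info(normalize_model(model))
  J <- pp_jacobian(model, state, params)
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(state = stats::setNames(as.numeric(state), info$compartments),
                 jacobian = J, eigenvalues = ev,
                 stability = classify_stability(ev, tol),
                 rhs = info$rhs(as.numeric(state), params)),
            class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat(sprintf("  (%s)  %s  eig: %s\n",
              paste(sprintf("%s = %.6g", names(x$state), x$state), collapse = ", "),
              x$stability,
              paste(format(zapsmall(x$eigenvalues, 10), digits = 4), collapse = ", ")))
  invisible(x)
}

#' Find and classify the equilibria of a model
#'
#' Enumerates boundary equilibria (extinction states, prey-only states at the
#' Allee threshold and carrying capacity, tumor-at-capacity) plus the interior
#' coexistence equilibrium from the closed forms / root searches of the models
#' module, and annotates each with its Jacobian eigenvalues and stability
#' label.
#'
#' @param model model id.
#' @param params matching parameter object.
#' @param tol zero tolerance passed to [classify_stability()].
#' @return list of `equilibrium_report` objects (class `equilibria_report`).
#' @export
find_equilibria <- function(model, params, tol = 1e-8) {
  model <- normalize_model(model)
  params <- check_model_params(model, params)
  states <- switch(model,
    lv = {
      s <- list(c(0, 0), lv_interior_equilibrium(params))
      s
    },
    allee = {
      s <- list(c(0, 0))
      if (params$L > 0) s <- c(s, list(c(params$L, 0)))
      s <- c(s, list(c(params$K, 0)))
      eq <- allee_interior_equilibrium(params)
      if (!is.null(eq)) s <- c(s, list(eq))
      s
    },
    ti = {
      s <- list(c(0, 0, 0), c(params$K_C, 0, 0))
      red <- reduced_interior_equilibrium(qss_reduce(params))
      if (!is.null(red)) {
        A <- ti_apc_qss(params, red[["C"]], red[["E"]])
        s <- c(s, list(c(red[["C"]], A, red[["E"]])))
      }
      s
    },
    ti_reduced = {
      s <- list(c(0, 0), c(params$K_C, 0))
      eq <- reduced_interior_equilibrium(params)
      if (!is.null(eq)) s <- c(s, list(eq))
      s
    })
  structure(lapply(states, equilibrium_report, model = model, params = params,
                   tol = tol),
            class = "equilibria_report")
}

#' @export
print.equilibria_report <- function(x, ...) {
  cat(sprintf("<equilibria_report> %d equilibria\n", length(x)))
  for (e in x) print(e)
  invisible(x)
}

# analytic regime candidate for a Type I Allee/injury model
analytic_regime <- function(p) {
  if (p$d <= p$g) return(list(label = "ESCAPE", x_star = Inf))
  xs <- p$c / ((p$d - p$g) * p$response$b)
  label <-
    if (xs >= p$K) "ESCAPE"
    else if (xs <= p$L) "ELIMINATION"
    else if (xs > (p$L + p$K) / 2) "COEXISTENCE"
    else "OSCILLATION_OR_ELIMINATION"
  list(label = label, x_star = xs)
}

# simulation-only regime verdict
simulate_regime <- function(p, init, t_end, burn_in, amp_floor, rtol, atol,
                            ext_floor, n_out) {
  traj <- simulate_model("allee", p, init, t_end, n_out = n_out,
                         rtol = rtol, atol = atol, ext_floor = ext_floor)
  fin <- traj$states[nrow(traj$states), ]
  x_end <- fin[[1]]; y_end <- fin[[2]]
  K <- p$K
  label <- if (x_end <= 0) {
    "ELIMINATION"
  } else if (y_end <= 0) {
    if (abs(x_end - K) / K < 1e-3) "ESCAPE" else "UNDETERMINED"
  } else {
    osc <- detect_oscillation(traj, burn_in = burn_in, amp_floor = amp_floor)
    eqm <- allee_interior_equilibrium(p)
    near_eq <- !is.null(eqm) &&
      max(abs(fin - eqm) / pmax(abs(eqm), 1e-12)) < 1e-2
    near_K <- abs(x_end - K) / K < 1e-3 && y_end < 0.01 * K &&
      allee_rhs(fin, p)[2] < 0
    if (osc$label == "SUSTAINED") "OSCILLATION"
    else if (osc$label == "DAMPED" || near_eq) "COEXISTENCE"
    else if (near_K) "ESCAPE"
    else "UNDETERMINED"
  }
  list(label = label, trajectory = traj)
}

#' Classify the dynamical regime of the Allee/injury model
#'
#' Two-stage classifier of the four qualitative outcomes of the generalized
#' predator-prey model, which parallel the phases of cancer immunoediting:
#' `ELIMINATION` (efficient predator drives the prey extinct), `OSCILLATION`
#' (sustained predator-prey cycling, the transitional regime), `COEXISTENCE`
#' (stable interior equilibrium — the "equilibrium" phase) and `ESCAPE`
#' (inefficient predator goes extinct, prey grows to carrying capacity).
#'
#' The analytic stage (Type I responses: the nullcline geometry is explicit)
#' places the predator nullcline `x* = c/((d-g) b)` relative to the Allee
#' threshold `L`, the prey-nullcline hump `(L+K)/2` and the carrying capacity
#' `K`: `x* >= K` (or `d <= g`) is escape, `x* <= L` elimination, a stable
#' interior equilibrium right of the hump is a coexistence candidate, and an
#' unstable one left of the hump cycles or crashes (resolved by simulation —
#' the internal oscillation/elimination bifurcation boundary is not known in
#' closed form).  The simulation stage always runs from `init` and confirms
#' the candidate via extinction detection and [detect_oscillation()];
#' disagreement yields `UNDETERMINED`, a first-class outcome for cells near
#' regime boundaries at finite integration time.
#'
#' @param p an [allee_params()] with a Type I response (other responses are
#'   allowed only with `method = "simulation"`).
#' @param init initial state; default `(0.75 K, 0.05 K)` — a prey population
#'   above its Allee threshold facing a small immune infiltrate.
#' @param t_end simulation horizon; default `2000 + 100/min(c, a K^2)` scales
#'   with the slowest rate in the system.
#' @param method `"both"` (default), `"analytic"` or `"simulation"`.
#' @param burn_in,amp_floor oscillation-detection options (see
#'   [detect_oscillation()]); the classifier burns in half the run so limit
#'   cycles are settled before peak amplitudes are compared.
#' @param rtol,atol,ext_floor solver options for the classification runs.
#' @return An object of class `regime`: list with `label` (one of
#'   `"ELIMINATION"`, `"OSCILLATION"`, `"COEXISTENCE"`, `"ESCAPE"`,
#'   `"UNDETERMINED"`), `analytic` (candidate label, possibly
#'   `"OSCILLATION_OR_ELIMINATION"`, or `NA`), `simulation` (simulation
#'   verdict or `NA`) and `x_star` (predator nullcline prey density).
#' @examples
#' base <- function(c) allee_params(a = 0.01, K = 10, L = 1, c = c, d = 0.5,
#'                                  g = 0, response = functional_response(0.1))
#' classify_regime(base(0.6))$label   # ESCAPE: x* = 12 > K
#' @export
classify_regime <- function(p, init = NULL, t_end = NULL,
                            method = c("both", "analytic", "simulation"),
                            burn_in = 0.5, amp_floor = 1e-4,
                            rtol = 1e-8, atol = 1e-11, ext_floor = 1e-9) {
  stopifnot(inherits(p, "allee_params"))
  method <- match.arg(method)
  type1 <- classify_response(p$response) == "TYPE_I"
  if (!type1 && method != "simulation")
    abort_validation("analytic regime classification requires a Type I response; use method = 'simulation'")
  ana <- if (type1) analytic_regime(p) else list(label = NA_character_, x_star = NA_real_)

  if (method == "analytic") {
    label <- if (ana$label == "OSCILLATION_OR_ELIMINATION") "UNDETERMINED" else ana$label
    return(structure(list(label = label, analytic = ana$label,
                          simulation = NA_character_, x_star = ana$x_star,
                          params = p), class = "regime"))
  }

  if (is.null(init)) init <- c(0.75 * p$K, 0.05 * p$K)
  if (is.null(t_end)) t_end <- 2000 + 100 / min(p$c, p$a * p$K^2)
  n_out <- as.integer(min(40000, max(2000, ceiling(t_end / 0.5))))
  sim <- simulate_regime(p, init, t_end, burn_in, amp_floor, rtol, atol,
                         ext_floor, n_out)

  label <- if (method == "simulation") {
    sim$label
  } else if (ana$label == "OSCILLATION_OR_ELIMINATION") {
    if (sim$label %in% c("OSCILLATION", "ELIMINATION")) sim$label else "UNDETERMINED"
  } else if (identical(sim$label, ana$label)) {
    ana$label
  } else {
    "UNDETERMINED"
  }
  structure(list(label = label, analytic = ana$label, simulation = sim$label,
                 x_star = ana$x_star, params = p),
            class = "regime")
}

#' @export
print.regime <- function(x, ...) {
  cat(sprintf("<regime> %s (analytic: %s, simulation: %s, x* = %.4g)\n",
              x$label, x$analytic, x$simulation, x$x_star))
  invisible(x)
}

#' Perturbation test of an equilibrium's stability
#'
#' Simulation-based stability check, independent of the eigenvalue route:
#' the equilibrium is displaced by about 0.1% (plus a small absolute offset
#' so boundary equilibria are displaced in every coordinate) and integrated
#' for `horizon` e-folding times of the dominant eigenvalue's real part.
#' The displacement is kept small so the linear regime governs the early
#' growth before any nonlinear saturation (limit cycles, neighboring
#' equilibria).  Verdict: `"STABLE"` when the final distance from the
#' equilibrium falls below `1/3` of the initial displacement; otherwise
#' `"UNSTABLE"` when the distance exceeds `3` times the displacement at any
#' sample (transient non-normal growth followed by decay still counts as
#' stable, because the final-distance test is applied first); otherwise
#' `"INCONCLUSIVE"` — expected near marginal equilibria.
#'
#' @param model model id.
#' @param state equilibrium state.
#' @param params matching parameter object.
#' @param re_dominant real part of the dominant (largest real part)
#'   eigenvalue, used only to set the horizon; pass the value from an
#'   [find_equilibria()] report.
#' @param horizon number of e-folding times to integrate.
#' @param t_max cap on the integration time.
#' @return `"STABLE"`, `"UNSTABLE"` or `"INCONCLUSIVE"`.
#' @export
perturbation_oracle <- function(model, state, params, re_dominant,
                                horizon = 8, t_max = 1e5) {
  state <- as.numeric(state)
  if (abs(re_dominant) <= 0) return("INCONCLUSIVE")
  T <- min(horizon / abs(re_dominant), t_max)
  delta <- 0.001 * (abs(state) + 0.01 * max(1, max(abs(state))))
  init <- state + delta
  tr <- simulate_model(model, params, init, t_end = T, n_out = 400,
                       ext_floor = 0)
  d0 <- sqrt(sum(delta^2))
  dist <- sqrt(rowSums((tr$states - rep(state, each = nrow(tr$states)))^2))
  if (dist[length(dist)] < d0 / 3) "STABLE"
  else if (max(dist) > 3 * d0) "UNSTABLE"
  else "INCONCLUSIVE"
}

#' Immunoediting phase names for regime labels
#'
#' Maps the ecological regime labels to the immunoediting vocabulary:
#' elimination, transitional oscillation, equilibrium, escape.
#'
#' @param labels character vector of regime labels.
#' @return character vector of phase names.
#' @export
immunoediting_phase <- function(labels) {
  map <- c(ELIMINATION = "elimination",
           OSCILLATION = "transitional oscillation",
           COEXISTENCE = "equilibrium",
           ESCAPE = "escape",
           UNDETERMINED = "undetermined")
  unname(map[labels])
}

#' Regime map over predator inefficiency and L/K
#'
#' Classifies a grid of Allee/injury parameter sets obtained from a base set
#' by varying the predator death rate `c` (via the inefficiency axis
#' `c/(d b)`) and the Allee threshold `L` (via the ratio axis `L/K`), holding
#' `a`, `K`, `b`, `d`, `g` fixed.  Scanning inefficiency from low to high at
#' fixed `L/K` traverses the regimes in the fixed order elimination,
#' oscillation, coexistence, escape — the predictable sequence that parallels
#' the elimination / (transitional oscillation) / equilibrium / escape phases
#' of immunoediting as immune efficiency degrades.
#'
#' @param p_base an [allee_params()] fixing `a`, `K`, `b`, `d`, `g` (its `c`
#'   and `L` are overridden cell by cell).
#' @param inefficiency strictly increasing values of `c/(d b)`.
#' @param ratio strictly increasing values of `L/K`, each in `[0, 1)`.
#' @param ... passed to [classify_regime()].
#' @return An object of class `regime_map`: list with `grid` (long-format
#'   data frame with columns `inefficiency`, `ratio`, `regime`,
#'   `immunoediting_phase`), the axis vectors, `base` and a label `counts`
#'   table.
#' @export
regime_map <- function(p_base, inefficiency, ratio, ...) {
  stopifnot(inherits(p_base, "allee_params"))
  if (any(diff(inefficiency) <= 0) || any(diff(ratio) <= 0))
    abort_validation("grids must be strictly increasing")
  if (any(ratio < 0) || any(ratio >= 1))
    abort_validation("'ratio' values (L/K) must lie in [0, 1)")
  b <- p_base$response$b
  cells <- expand.grid(inefficiency = inefficiency, ratio = ratio,
                       KEEP.OUT.ATTRS = FALSE)
  labels <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    p <- allee_params(a = p_base$a, K = p_base$K,
                      L = cells$ratio[i] * p_base$K,
                      c = cells$inefficiency[i] * p_base$d * b,
                      d = p_base$d, g = p_base$g, response = p_base$response)
    labels[i] <- classify_regime(p, ...)$label
  }
  grid <- data.frame(cells, regime = labels,
                     immunoediting_phase = immunoediting_phase(labels))
  structure(list(grid = grid, inefficiency = inefficiency, ratio = ratio,
                 base = p_base, counts = table(labels)),
            class = "regime_map")
}

#' @export
print.regime_map <- function(x, ...) {
  cat(sprintf("<regime_map> %d x %d cells over inefficiency [%g, %g], L/K [%g, %g]\n",
              length(x$inefficiency), length(x$ratio),
              min(x$inefficiency), max(x$inefficiency),
              min(x$ratio), max(x$ratio)))
  print(x$counts)
  invisible(x)
}

#' @export
plot.regime_map <- function(x, ...) {
  lv <- c("ELIMINATION", "OSCILLATION", "COEXISTENCE", "ESCAPE", "UNDETERMINED")
  z <- matrix(match(x$grid$regime, lv), nrow = length(x$inefficiency))
  graphics::image(x$inefficiency, x$ratio, z, zlim = c(1, 5),
                  col = c("#b2182b", "#fdae61", "#74add1", "#1a9850", "grey80"),
                  xlab = "predator inefficiency c/(db)", ylab = "L/K", ...)
  graphics::legend("topright", legend = tolower(lv), bty = "n",
                   fill = c("#b2182b", "#fdae61", "#74add1", "#1a9850", "grey80"))
  invisible(x)
}

#' Check the regime ordering along each map row
#'
#' For each fixed `L/K` row, scanning inefficiency low to high, the distinct
#' determinate labels must form an ordered subsequence of
#' (ELIMINATION, OSCILLATION, COEXISTENCE, ESCAPE); `UNDETERMINED` cells are
#' skipped.
#'
#' @param map a `regime_map`.
#' @return list with `ok` (logical) and `violations` (data frame of offending
#'   rows, possibly empty).
#' @export
check_regime_sequence <- function(map) {
  stopifnot(inherits(map, "regime_map"))
  order_ref <- c(ELIMINATION = 1, OSCILLATION = 2, COEXISTENCE = 3, ESCAPE = 4)
  bad <- list()
  for (r in map$ratio) {
    row <- map$grid[map$grid$ratio == r, ]
    row <- row[order(row$inefficiency), ]
    lab <- row$regime[row$regime != "UNDETERMINED"]
    lab <- lab[c(TRUE, lab[-1] != lab[-length(lab)])]  # collapse runs
    idx <- order_ref[lab]
    if (any(diff(idx) <= 0))
      bad[[length(bad) + 1]] <- data.frame(ratio = r,
                                           sequence = paste(lab, collapse = " > "))
  }
  list(ok = length(bad) == 0,
       violations = if (length(bad)) do.call(rbind, bad) else
         data.frame(ratio = numeric(0), sequence = character(0)))
}

#' Write a regime map to CSV (and optional JSON summary)
#'
#' Long-format CSV with columns `inefficiency,ratio,regime,immunoediting_phase`
#' and, if `json` is given, a JSON summary with the grid metadata and
#' per-label counts.
#'
#' @param map a `regime_map`.
#' @param csv CSV output path.
#' @param json optional JSON summary path.
#' @return `csv`, invisibly.
#' @export
write_regime_map <- function(map, csv, json = NULL) {
  stopifnot(inherits(map, "regime_map"))
  utils::write.csv(map$grid, csv, row.names = FALSE, quote = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(list(
      inefficiency = map$inefficiency, ratio = map$ratio,
      n_cells = nrow(map$grid),
      counts = as.list(stats::setNames(as.integer(map$counts),
                                       names(map$counts)))),
      json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(csv)
}
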