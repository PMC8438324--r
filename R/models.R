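#' Lotka-Volterra parameters
#'
#' The four-parameter classic predator-prey model
#' \deqn{x' = a x - b x y, \qquad y' = -c y + d (b x y),}
#' with `x` prey (tumor cells), `y` predator (cytotoxic cells), `a` the prey
#' per-capita birth rate, `b` the predator-prey encounter probability (`b*x`
#' is a Type I functional response), `c` the predator per-capita death rate,
#' and `d` the conversion efficiency of consumed prey into new predators.
#'
#' @param a prey per-capita birth rate, `> 0` (per time).
#' @param b encounter probability, `> 0` (per predator density per time).
#' @param c predator per-capita death rate, `> 0` (per time).
#' @param d conversion efficiency, `> 0` (dimensionless).
#' @return An object of class `lv_params`.
#' @examples
#' p <- lv_params(a = 1, b = 0.2, c = 0.5, d = 0.5)
#' lv_interior_equilibrium(p)   # x* = c/(d*b) = 5, y* = a/b = 5
#' @export
lv_params <- function(a, b, c, d) {
  structure(list(a = chk_num(a, "a", 0, strict = TRUE),
                 b = chk_num(b, "b", 0, strict = TRUE),
                 c = chk_num(c, "c", 0, strict = TRUE),
                 d = chk_num(d, "d", 0, strict = TRUE)),
            class = "lv_params")
}

#' Lotka-Volterra right-hand side
#'
#' @param state numeric `c(x, y)`, nonnegative densities.
#' @param p an [lv_params()] object.
#' @return derivatives `c(dx/dt, dy/dt)`.
#' @export
lv_rhs <- function(state, p) {
  x <- state[[1]]; y <- state[[2]]
  c(x * (p$a - p$b * y), y * (p$d * p$b * x - p$c))
}

#' Interior equilibrium of the Lotka-Volterra model
#'
#' The coexistence point `(x*, y*) = (c/(d*b), a/b)`, a neutrally stable
#' center: orbits around it are closed and populations oscillate perpetually.
#'
#' @inheritParams lv_rhs
#' @return named numeric `c(x, y)`.
#' @export
lv_interior_equilibrium <- function(p) {
  c(x = p$c / (p$d * p$b), y = p$a / p$b)
}

#' Conserved quantity of the Lotka-Volterra model
#'
#' \deqn{H(x, y) = d b x - c \ln x + b y - a \ln y} is constant along exact
#' L-V trajectories (its level sets are the closed orbits), with a minimum at
#' the interior equilibrium.  Its numerical drift measures integration error.
#'
#' @param state numeric `c(x, y)`, strictly positive.
#' @inheritParams lv_rhs
#' @return scalar `H`.
#' @export
lv_invariant <- function(state, p) {
  x <- state[[1]]; y <- state[[2]]
  if (x <= 0 || y <= 0)
    abort_validation("lv_invariant requires strictly positive densities")
  p$d * p$b * x - p$c * log(x) + p$b * y - p$a * log(y)
}

#' Allee/injury predator-prey parameters
#'
#' The generalized model
#' \deqn{x' = a x (x - L)(K - x) - f(x) y, \qquad
#'       y' = (d - g) f(x) y - c y,}
#' where prey growth is cubic with carrying capacity `K` and an Allee
#' extinction threshold `L` (populations starting below `L` collapse in the
#' absence of predators), `f` is a [functional_response()], `d` is biomass
#' conversion per capture and `g` the probability of lethal injury to the
#' predator per capture (interference cost: for effector cells, exhaustion or
#' inhibition incurred while killing).  If `g >= d` the predator gains no net
#' fitness from capture and cannot persist.
#'
#' @param a prey growth scaling, `> 0` (per time per density^2).
#' @param K carrying capacity, `> 0`.
#' @param L Allee extinction threshold, `0 <= L < K`.
#' @param c predator per-capita death rate, `> 0`.
#' @param d biomass conversion rate, `>= 0`.
#' @param g probability of lethal injury per capture, `>= 0`.
#' @param response a [functional_response()] (or `list(b, alpha, h)`).
#' @return An object of class `allee_params`.
#' @export
allee_params <- function(a, K, L, c, d, g = 0, response) {
  a <- chk_num(a, "a", 0, strict = TRUE)
  K <- chk_num(K, "K", 0, strict = TRUE)
  L <- chk_num(L, "L", 0)
  if (L >= K) abort_validation(sprintf("'L' must be < K (got L = %g, K = %g)", L, K))
  structure(list(a = a, K = K, L = L,
                 c = chk_num(c, "c", 0, strict = TRUE),
                 d = chk_num(d, "d", 0),
                 g = chk_num(g, "g", 0),
                 response = as_response(response)),
            class = "allee_params")
}

#' Allee/injury model right-hand side
#'
#' @param state numeric `c(x, y)`, nonnegative.
#' @param p an [allee_params()] object.
#' @return derivatives `c(dx/dt, dy/dt)`.
#' @export
allee_rhs <- function(state, p) {
  x <- state[[1]]; y <- state[[2]]
  f <- eval_response(x, p$response)
  c(p$a * x * (x - p$L) * (p$K - x) - f * y,
    (p$d - p$g) * f * y - p$c * y)
}

#' Interior equilibrium of the Allee/injury model
#'
#' Solves the predator nullcline `(d - g) f(x*) = c` (prey density at which
#' the predator's capture reward balances its death rate) and evaluates the
#' prey nullcline `y* = a x* (x* - L)(K - x*) / f(x*)`.  Since `f` is
#' nondecreasing the root is unique when it exists.  Returns `NULL` when no
#' interior equilibrium with positive predator density exists: `d <= g`
#' (capture is not profitable), no root of the predator nullcline on
#' `(0, x_max]`, or a root outside `(L, K)` (where `y*` would be `<= 0`).
#'
#' @param p an [allee_params()] object.
#' @param x_max upper bracket for the root search (default `10 * K`).
#' @return named numeric `c(x, y)`, or `NULL`.
#' @export
allee_interior_equilibrium <- function(p, x_max = 10 * p$K) {
  if (p$d <= p$g) return(NULL)
  r <- p$response
  if (r$b == 0) return(NULL)
  gfun <- function(x) (p$d - p$g) * eval_response(x, r) - p$c
  if (classify_response(r) == "TYPE_I") {
    xs <- p$c / ((p$d - p$g) * r$b)
  } else {
    lo <- 1e-12
    if (gfun(x_max) < 0) return(NULL)   # predator never profitable up to x_max
    if (gfun(lo) > 0) return(NULL)      # nullcline root at ~0, below L anyway
    xs <- stats::uniroot(gfun, c(lo, x_max),
                         tol = 1e-12 * max(1, p$K))$root
    # polish: f monotone, Newton step improves the bracketed root
    fp <- (p$d - p$g) * response_slope(xs, r)
    if (is.finite(fp) && fp > 0) xs <- xs - gfun(xs) / fp
  }
  if (!is.finite(xs) || xs <= p$L || xs >= p$K) return(NULL)
  ys <- p$a * xs * (xs - p$L) * (p$K - xs) / eval_response(xs, r)
  if (!is.finite(ys) || ys <= 0) return(NULL)
  c(x = xs, y = ys)
}

#' Minimal tumor-immune model parameters
#'
#' A minimally sufficient three-compartment model of tumor-immune
#' interactions, with cancer cells `C`, antigen-presenting cells `A`, and
#' activated effector (cytotoxic) cells `E`:
#' \deqn{C' = r C (1 - C/K_C) - f(C) E}
#' \deqn{A' = s f(C) E - \mu_A A}
#' \deqn{E' = \rho A - \mu_E E - g f(C) E}
#' Cancer grows logistically up to `K_C`; effectors kill cancer cells at
#' per-effector rate `f(C)`; killing stimulates APCs (rate `s` per unit kill
#' rate); effectors are recruited by APCs (rate `rho` per APC), decay at
#' `mu_E` in the absence of stimulation, and are exhausted/tolerized at rate
#' `g` per unit kill rate.  There is no direct conversion of killed cancer
#' cells into effectors — effector growth is routed through the APC
#' compartment, which is the immunological replacement for the ecological
#' "biomass conversion".
#'
#' An optional Allee threshold `allee_L` replaces the logistic growth with the
#' cubic form `r*C*(C - allee_L)*(K_C - C)` (note `r` then carries units of
#' per time per density^2).
#'
#' @param r cancer per-capita growth rate, `> 0`.
#' @param K_C cancer carrying capacity, `> 0`.
#' @param response a [functional_response()]: per-effector kill rate vs `C`.
#' @param s APC stimulation per unit kill rate, `>= 0`.
#' @param mu_A APC decay rate, `> 0`.
#' @param rho effector recruitment rate per APC, `>= 0`.
#' @param mu_E effector decay rate, `> 0`.
#' @param g effector exhaustion rate per unit kill rate, `>= 0`.
#' @param allee_L optional cancer Allee threshold (`NULL` for logistic growth).
#' @return An object of class `ti_params`.
#' @export
ti_params <- function(r, K_C, response, s, mu_A, rho, mu_E, g = 0, allee_L = NULL) {
  K_C <- chk_num(K_C, "K_C", 0, strict = TRUE)
  if (!is.null(allee_L)) {
    allee_L <- chk_num(allee_L, "allee_L", 0)
    if (allee_L >= K_C) abort_validation("'allee_L' must be < K_C")
  }
  structure(list(r = chk_num(r, "r", 0, strict = TRUE), K_C = K_C,
                 response = as_response(response),
                 s = chk_num(s, "s", 0),
                 mu_A = chk_num(mu_A, "mu_A", 0, strict = TRUE),
                 rho = chk_num(rho, "rho", 0),
                 mu_E = chk_num(mu_E, "mu_E", 0, strict = TRUE),
                 g = chk_num(g, "g", 0),
                 allee_L = allee_L),
            class = "ti_params")
}

ti_growth <- function(C, p) {
  if (is.null(p$allee_L)) p$r * C * (1 - C / p$K_C)
  else p$r * C * (C - p$allee_L) * (p$K_C - C)
}

#' Minimal tumor-immune model right-hand side
#'
#' @param state numeric `c(C, A, E)`, nonnegative.
#' @param p a [ti_params()] object.
#' @return derivatives `c(dC/dt, dA/dt, dE/dt)`.
#' @export
ti_rhs <- function(state, p) {
  C <- state[[1]]; A <- state[[2]]; E <- state[[3]]
  kill <- eval_response(C, p$response) * E
  c(ti_growth(C, p) - kill,
    p$s * kill - p$mu_A * A,
    p$rho * A - p$mu_E * E - p$g * kill)
}

#' Quasi-steady-state reduction of the tumor-immune model
#'
#' When APC turnover is fast relative to the cell populations (`mu_A` large),
#' the APC compartment tracks its quasi-steady state
#' `A*(C, E) = s f(C) E / mu_A`, and the three-compartment model reduces to a
#' predator-prey-like two-compartment system
#' \deqn{C' = r C (1 - C/K_C) - f(C) E, \qquad
#'       E' = (d_{eff} - g) f(C) E - \mu_E E,}
#' with effective conversion efficiency `d_eff = rho * s / mu_A`.  The prey
#' equation is preserved exactly; the effector equation takes the same
#' algebraic form as the predator equation of the Allee/injury model, so the
#' reduced system inherits all of its machinery.  The indirect stimulation of
#' effectors by cancer cells (via APCs) appears as the `d_eff` "conversion"
#' term even though no prey biomass is consumed.
#'
#' @param p a [ti_params()] object.
#' @return An object of class `ti_reduced_params` with fields
#'   `r, K_C, allee_L, response, d_eff, g, mu_E`.
#' @seealso [classify_reduced_module()], [qss_convergence()]
#' @export
qss_reduce <- function(p) {
  stopifnot(inherits(p, "ti_params"))
  structure(list(r = p$r, K_C = p$K_C, allee_L = p$allee_L,
                 response = p$response,
                 d_eff = p$rho * p$s / p$mu_A, g = p$g, mu_E = p$mu_E),
            class = "ti_reduced_params")
}

#' Right-hand side of the QSS-reduced tumor-immune model
#'
#' @param state numeric `c(C, E)`, nonnegative.
#' @param p a `ti_reduced_params` object from [qss_reduce()].
#' @return derivatives `c(dC/dt, dE/dt)`.
#' @export
reduced_rhs <- function(state, p) {
  C <- state[[1]]; E <- state[[2]]
  f <- eval_response(C, p$response)
  c(ti_growth(C, p) - f * E,
    (p$d_eff - p$g) * f * E - p$mu_E * E)
}

#' APC quasi-steady state
#'
#' `A*(C, E) = s f(C) E / mu_A`, the APC density the fast compartment relaxes
#' to for given cancer and effector densities.
#'
#' @param p a [ti_params()] object.
#' @param C,E cancer and effector densities.
#' @return APC density.
#' @export
ti_apc_qss <- function(p, C, E) p$s * eval_response(C, p$response) * E / p$mu_A

#' Interior equilibrium of the QSS-reduced tumor-immune model
#'
#' Solves `(d_eff - g) f(C*) = mu_E` and `E* = growth(C*)/f(C*)`.  Returns
#' `NULL` when no coexistence equilibrium with `0 < C* < K_C` and `E* > 0`
#' exists (in particular whenever `d_eff <= g`, the competition side).
#'
#' @param p a `ti_reduced_params` object (a [ti_params()] is reduced first).
#' @return named numeric `c(C, E)` or `NULL`.
#' @export
reduced_interior_equilibrium <- function(p) {
  if (inherits(p, "ti_params")) p <- qss_reduce(p)
  if (p$d_eff <= p$g) return(NULL)
  r <- p$response
  if (r$b == 0) return(NULL)
  gfun <- function(C) (p$d_eff - p$g) * eval_response(C, r) - p$mu_E
  if (classify_response(r) == "TYPE_I") {
    Cs <- p$mu_E / ((p$d_eff - p$g) * r$b)
  } else {
    hi <- 10 * p$K_C
    if (gfun(hi) < 0 || gfun(1e-12) > 0) return(NULL)
    Cs <- stats::uniroot(gfun, c(1e-12, hi), tol = 1e-12 * max(1, p$K_C))$root
  }
  if (!is.finite(Cs) || Cs <= 0 || Cs >= p$K_C) return(NULL)
  if (!is.null(p$allee_L) && Cs <= p$allee_L) return(NULL)
  Es <- ti_growth(Cs, p) / eval_response(Cs, r)
  if (!is.finite(Es) || Es <= 0) return(NULL)
  c(C = Cs, E = Es)
}

#' Classify the reduced tumor-immune community module
#'
#' The QSS-reduced system is predator-prey when the indirect positive effect
#' of cancer cells on effectors (through APC stimulation, `d_eff`) exceeds the
#' direct harm per capture (`g`, exhaustion/interference); it is competition
#' when the direct harm dominates, in which case sustained oscillations are
#' impossible.
#'
#' @param p a [ti_params()] or `ti_reduced_params` object.
#' @param tol equality tolerance for the boundary case.
#' @return one of `"PREDATOR_PREY"`, `"COMPETITION"`, `"BOUNDARY"`.
#' @export
classify_reduced_module <- function(p, tol = 1e-12) {
  if (inherits(p, "ti_params")) p <- qss_reduce(p)
  diff <- p$d_eff - p$g
  if (abs(diff) <= tol) "BOUNDARY" else if (diff > 0) "PREDATOR_PREY" else "COMPETITION"
}

# ---- model registry --------------------------------------------------------

normalize_model <- function(model) {
  m <- gsub("-", "_", tolower(model))
  if (!m %in% c("lv", "allee", "ti", "ti_reduced"))
    abort_validation(sprintf("unknown model id '%s' (use lv, allee, ti, ti-reduced)", model))
  m
}

model_info <- function(model) {
  switch(normalize_model(model),
    lv = list(compartments = c("x", "y"), rhs = lv_rhs, class = "lv_params"),
    allee = list(compartments = c("x", "y"), rhs = allee_rhs, class = "allee_params"),
    ti = list(compartments = c("C", "A", "E"), rhs = ti_rhs, class = "ti_params"),
    ti_reduced = list(compartments = c("C", "E"), rhs = reduced_rhs,
                      class = "ti_reduced_params"))
}

check_model_params <- function(model, params) {
  info <- model_info(model)
  if (inherits(params, "ti_params") && normalize_model(model) == "ti_reduced")
    params <- qss_reduce(params)
  if (!inherits(params, info$class))
    abort_validation(sprintf("model '%s' needs parameters of class '%s'",
                             model, info$class))
  params
}
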