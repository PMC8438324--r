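#' Convergence of the full tumor-immune model to its QSS reduction
#'
#' Integrates the full three-compartment model and the QSS-reduced
#' two-compartment model from matched initial conditions and measures the
#' sup-norm gap between their `(C, E)` trajectories, as the APC time scale is
#' accelerated.  For each multiplier `m`, `mu_A` and `s` are both scaled by
#' `m`, which leaves the effective conversion efficiency
#' `d_eff = rho s / mu_A` (and the reduced model) unchanged while making the
#' APC compartment relax `m` times faster.  The full model's APC compartment
#' starts at its quasi-steady state [ti_apc_qss()] for the given `(C0, E0)`.
#' As `m` grows the gap shrinks toward zero, which is the time-scale
#' separation argument for folding fast intermediaries (APCs, cytokines) into
#' the two-compartment predator-prey abstraction.
#'
#' @param p a [ti_params()] object (the `m = 1` baseline).
#' @param multipliers APC-rate multipliers, e.g. `c(10, 100, 1000)`.
#' @param init initial `c(C, E)`; default `(0.75 K_C, 0.05 K_C)`.
#' @param t_end comparison horizon.
#' @param n_out output samples per trajectory.
#' @param rtol,atol solver tolerances.
#' @return named numeric vector of relative sup-norm gaps
#'   `max_t |full - reduced| / max_t |reduced|`, one per multiplier.
#' @export
qss_convergence <- function(p, multipliers = c(10, 100, 1000), init = NULL,
                            t_end = 200, n_out = 2000,
                            rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(p, "ti_params"))
  if (is.null(init)) init <- c(0.75 * p$K_C, 0.05 * p$K_C)
  red <- qss_reduce(p)
  tr_red <- simulate_model("ti_reduced", red, init, t_end, n_out = n_out,
                           rtol = rtol, atol = atol)
  scale <- max(abs(tr_red$states))
  gaps <- vapply(multipliers, function(m) {
    pm <- ti_params(r = p$r, K_C = p$K_C, response = p$response,
                    s = p$s * m, mu_A = p$mu_A * m, rho = p$rho,
                    mu_E = p$mu_E, g = p$g, allee_L = p$allee_L)
    A0 <- ti_apc_qss(pm, init[1], init[2])
    tr_full <- simulate_model("ti", pm, c(init[1], A0, init[2]), t_end,
                              n_out = n_out, rtol = rtol, atol = atol)
    max(abs(tr_full$states[, c("C", "E")] - tr_red$states)) / scale
  }, numeric(1))
  stats::setNames(gaps, paste0("x", multipliers))
}
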