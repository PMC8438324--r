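#' Seeded random parameter battery
#'
#' Draws `n` random, invariant-satisfying parameter sets for a model,
#' reproducibly from `seed` (the global RNG state is restored afterwards).
#' Rates are drawn log-uniformly within documented ranges:
#'
#' * `"lv"`: `a`, `b`, `c`, `d` log-uniform in `[1e-2, 1e1]`.
#' * `"allee"`: `K` log-uniform in `[1, 100]`; the per-capita growth scale
#'   `a K^2` log-uniform in `[0.1, 10]` (so `a = u/K^2`); `L` uniform in
#'   `[0.05 K, 0.5 K]` (bounded away from 0 so the extinction threshold is a
#'   real threshold); `d` log-uniform in `[0.1, 1]`; `g = 0` with probability
#'   1/2, else uniform in `[0, 0.5 d]`; a Type I response with `b` log-uniform
#'   in `[0.05, 0.5]`; `c` set via a predator-nullcline ratio
#'   `x*/K = c/((d-g) b K)` log-uniform in `[0.05, 2]`, so the battery spans
#'   all four dynamical regimes.
#' * `"ti"`: `r` log-uniform in `[0.1, 2]`; `K_C` in `[10, 100]`; Type I
#'   response `b` in `[0.01, 0.5]`; `mu_A` in `[0.5, 5]`; `s`, `rho` in
#'   `[0.1, 1]`; `mu_E` in `[0.02, 0.5]`; `g = d_eff * u` with `u` log-uniform
#'   in `[0.1, 10]`, so predator-prey (`d_eff > g`) and competition
#'   (`d_eff < g`) modules each occur about half the time.
#'
#' @param seed integer RNG seed.
#' @param model model id (`"lv"`, `"allee"`, `"ti"`).
#' @param n number of parameter sets, `>= 1`.
#' @return list of `n` parameter objects.
#' @export
parameter_battery <- function(seed, model, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    abort_validation("'n' must be >= 1")
  n <- as.integer(n)
  model <- normalize_model(model)
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  }
  set.seed(seed)
  rlu <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  draw <- switch(model,
    lv = function() lv_params(a = rlu(1e-2, 1e1), b = rlu(1e-2, 1e1),
                              c = rlu(1e-2, 1e1), d = rlu(1e-2, 1e1)),
    allee = function() {
      K <- rlu(1, 100)
      a <- rlu(0.1, 10) / K^2
      L <- stats::runif(1, 0.05, 0.5) * K
      d <- rlu(0.1, 1)
      g <- if (stats::runif(1) < 0.5) 0 else stats::runif(1, 0, 0.5) * d
      b <- rlu(0.05, 0.5)
      xr <- rlu(0.05, 2)
      allee_params(a = a, K = K, L = L, c = (d - g) * b * xr * K, d = d, g = g,
                   response = functional_response(b))
    },
    ti = function() {
      mu_A <- rlu(0.5, 5); s <- rlu(0.1, 1); rho <- rlu(0.1, 1)
      d_eff <- rho * s / mu_A
      ti_params(r = rlu(0.1, 2), K_C = rlu(10, 100),
                response = functional_response(rlu(0.01, 0.5)),
                s = s, mu_A = mu_A, rho = rho, mu_E = rlu(0.02, 0.5),
                g = d_eff * rlu(0.1, 10))
    },
    ti_reduced = abort_validation("draw a 'ti' battery and qss_reduce() it"))
  replicate(n, draw(), simplify = FALSE)
}
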