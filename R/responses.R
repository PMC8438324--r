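#' Generalized functional response
#'
#' Construct the parameter set of the generalized per-predator kill-rate curve
#' \deqn{f(x) = \frac{b x^\alpha}{1 + b h x^\alpha},}
#' where `x` is prey (target-cell) density.  `b` is the predator's encounter
#' probability per unit prey density per unit time; `alpha` scales the
#' encounter rate, allowing for an attraction effect (`alpha > 1`, e.g. a
#' chemo-attractant guiding immune cells to targets) or a dilution effect
#' (`alpha < 1`, safety in numbers); `h` is the handling time spent capturing
#' and consuming one prey — immunologically, the time an effector cell spends
#' at the immunological synapse.
#'
#' For `h > 0` the response saturates at `1/h` as `x` grows; for `h = 0` and
#' `alpha = 1` it reduces to the linear (Holling Type I) form `b*x`.
#'
#' @param b encounter probability, `>= 0`.
#' @param alpha encounter-rate scaling exponent, `> 0`.
#' @param h handling time per captured prey, `>= 0`.
#' @return An object of class `functional_response`.
#' @seealso [eval_response()], [classify_response()], [response_slope()]
#' @examples
#' fr <- functional_response(b = 1, alpha = 1, h = 2)
#' eval_response(10, fr)        # 10/21
#' classify_response(fr)        # "TYPE_II"
#' @export
functional_response <- function(b, alpha = 1, h = 0) {
  b <- chk_num(b, "b", lower = 0)
  alpha <- chk_num(alpha, "alpha", lower = 0, strict = TRUE)
  h <- chk_num(h, "h", lower = 0)
  structure(list(b = b, alpha = alpha, h = h), class = "functional_response")
}

#' @export
print.functional_response <- function(x, ...) {
  cat(sprintf("Functional response f(x) = b*x^a/(1 + b*h*x^a): b = %g, alpha = %g, h = %g  [%s]\n",
              x$b, x$alpha, x$h, classify_response(x)))
  invisible(x)
}

as_response <- function(p) {
  if (inherits(p, "functional_response")) return(p)
  if (is.list(p)) return(do.call(functional_response, p))
  abort_validation("'response' must be a functional_response or a list(b, alpha, h)")
}

#' Evaluate the functional response
#'
#' Per-predator kill rate `f(x) = b x^alpha / (1 + b h x^alpha)` at prey
#' density `x`.  Vectorized over `x`.  `f(0) = 0` for any valid parameters,
#' and for `h > 0` the supremum over `x` is `1/h`.
#'
#' @param x prey density (vector), nonnegative.
#' @param p a [functional_response()].
#' @return kill rate per predator, same length as `x`.
#' @export
eval_response <- function(x, p) {
  p <- as_response(p)
  if (!is.numeric(x) || any(!is.finite(x)))
    abort_validation("'x' must be finite numeric")
  if (any(x < 0)) abort_validation("prey density 'x' must be nonnegative")
  xa <- x^p$alpha # 0^alpha = 0 for alpha > 0
  p$b * xa / (1 + p$b * p$h * xa)
}

#' Classify a functional response into Holling types
#'
#' `TYPE_I` when `h = 0` and `alpha = 1` (linear: no synapse time, no
#' attraction/dilution); `TYPE_II` when `h > 0` and `0 < alpha <= 1`
#' (saturating); `TYPE_III` when `h > 0` and `alpha > 1` (sigmoidal,
#' accelerating then decelerating).  Combinations outside these three
#' conditions (e.g. `h = 0` with `alpha != 1`) are labelled `GENERALIZED`,
#' since the classical taxonomy is not exhaustive.
#'
#' @param p a [functional_response()].
#' @return one of `"TYPE_I"`, `"TYPE_II"`, `"TYPE_III"`, `"GENERALIZED"`.
#' @export
classify_response <- function(p) {
  p <- as_response(p)
  if (p$h == 0 && p$alpha == 1) return("TYPE_I")
  if (p$h > 0 && p$alpha <= 1) return("TYPE_II")
  if (p$h > 0 && p$alpha > 1) return("TYPE_III")
  "GENERALIZED"
}

#' Slope of the functional response
#'
#' Analytic derivative
#' \deqn{f'(x) = \frac{\alpha b x^{\alpha-1}}{(1 + b h x^\alpha)^2}.}
#' Used for Jacobians and inflection checks.  At `x = 0` the slope is `b` for
#' `alpha = 1`, `0` for `alpha > 1`, and unbounded for `alpha < 1` (a domain
#' error).
#'
#' @inheritParams eval_response
#' @return derivative `df/dx`, same length as `x`.
#' @export
response_slope <- function(x, p) {
  p <- as_response(p)
  if (!is.numeric(x) || any(!is.finite(x)))
    abort_validation("'x' must be finite numeric")
  if (any(x < 0)) abort_validation("prey density 'x' must be nonnegative")
  if (p$alpha < 1 && any(x == 0))
    abort_validation("slope is unbounded at x = 0 when alpha < 1")
  xa <- x^p$alpha
  num <- p$alpha * p$b * x^(p$alpha - 1)
  num[x == 0 & p$alpha > 1] <- 0
  if (p$alpha == 1) num[] <- p$b
  num / (1 + p$b * p$h * xa)^2
}
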