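#' Integrate a model's ODEs
#'
#' Adaptive-step integration (via [deSolve::ode()], `lsoda`/`lsodar`) of any
#' registered model, sampled on a uniform output grid.  A compartment whose
#' density falls below the extinction floor while declining is clamped to
#' exactly zero for the remainder of the run.  This prevents the "atto-fox"
#' artifact of continuous-density models, where a population at physically
#' meaningless densities (far below one cell) later revives and corrupts
#' regime classification.  Crossings of the floor from below (e.g. an APC
#' compartment growing from zero) do not trigger the clamp.
#'
#' @param model model id: `"lv"`, `"allee"`, `"ti"`, or `"ti-reduced"`.
#' @param params matching parameter object ([lv_params()], [allee_params()],
#'   [ti_params()], or [qss_reduce()] output; a `ti_params` is reduced
#'   automatically for `"ti-reduced"`).
#' @param init nonnegative initial state, in the model's compartment order.
#' @param t_end end time, `> 0`.
#' @param t_start start time.
#' @param n_out number of uniform output samples.
#' @param rtol,atol solver relative/absolute tolerances.
#' @param ext_floor extinction floor (`0` disables clamping).
#' @param ... passed on to [deSolve::ode()].
#' @return An object of class `pp_trajectory`: list with `times`, `states`
#'   (matrix, one column per compartment), `model`, `params`, `extinct`
#'   (named vector of extinction times, `NA` if never extinct) and `opts`.
#' @examples
#' p <- lv_params(1, 0.2, 0.5, 0.5)
#' tr <- simulate_model("lv", p, c(2, 2), t_end = 50)
#' conservation_drift(tr, p)
#' @export
simulate_model <- function(model, params, init, t_end, t_start = 0,
                           n_out = 2000, rtol = 1e-9, atol = 1e-12,
                           ext_floor = 1e-9, ...) {
  model <- normalize_model(model)
  params <- check_model_params(model, params)
  info <- model_info(model)
  d <- length(info$compartments)
  if (length(init) != d)
    abort_validation(sprintf("model '%s' needs %d initial densities", model, d))
  if (any(!is.finite(init)) || any(init < 0))
    abort_validation("initial state must be finite and nonnegative")
  chk_num(t_end, "t_end", t_start, strict = TRUE)
  if (rtol <= 0 || atol <= 0) abort_validation("tolerances must be positive")
  n_out <- max(2L, as.integer(n_out))

  init <- stats::setNames(as.numeric(init), info$compartments)
  times <- seq(t_start, t_end, length.out = n_out)
  dead <- rep(FALSE, d)
  death_t <- rep(NA_real_, d)

  derivs <- function(t, y, parms) {
    y[dead] <- 0
    dy <- info$rhs(pmax(y, 0), params)
    dy[dead] <- 0
    list(dy)
  }

  if (ext_floor > 0) {
    rootfun <- function(t, y, parms) y - ext_floor
    eventfun <- function(t, y, parms) {
      y[dead] <- 0
      dy <- info$rhs(pmax(y, 0), params)
      hit <- !dead & (y <= ext_floor * (1 + 1e-8)) & (dy <= 0)
      if (any(hit)) {
        dead[hit] <<- TRUE
        death_t[hit] <<- t
        y[hit] <- 0
      }
      y
    }
    out <- try(deSolve::ode(y = init, times = times, func = derivs, parms = NULL,
                            method = "lsodar", rtol = rtol, atol = atol,
                            rootfunc = rootfun,
                            events = list(func = eventfun, root = TRUE), ...),
               silent = TRUE)
  } else {
    out <- try(deSolve::ode(y = init, times = times, func = derivs, parms = NULL,
                            method = "lsoda", rtol = rtol, atol = atol, ...),
               silent = TRUE)
  }
  if (inherits(out, "try-error"))
    abort_numerical(paste("ODE integration failed:", attr(out, "condition")$message))
  out <- unclass(out)
  if (nrow(out) < n_out)
    abort_numerical(sprintf(
      "ODE integration stopped early at t = %g (of %g); solver diagnostic follows the deSolve warning",
      out[nrow(out), 1], t_end))
  states <- out[, -1, drop = FALSE]
  if (any(!is.finite(states)))
    abort_numerical("non-finite state encountered during integration")
  colnames(states) <- info$compartments
  # exact zeros after a clamp; tiny solver negatives are floored
  states[states < 0] <- 0
  for (j in seq_len(d)) if (!is.na(death_t[j])) {
    states[out[, 1] >= death_t[j], j] <- 0
  }
  structure(list(model = model, times = out[, 1], states = states,
                 params = params,
                 extinct = stats::setNames(death_t, info$compartments),
                 opts = list(rtol = rtol, atol = atol, ext_floor = ext_floor,
                             n_out = n_out)),
            class = "pp_trajectory")
}

#' @export
print.pp_trajectory <- function(x, ...) {
  cat(sprintf("<pp_trajectory> model '%s', t in [%g, %g], %d samples\n",
              x$model, min(x$times), max(x$times), length(x$times)))
  fin <- x$states[nrow(x$states), ]
  cat("  final state:", paste(sprintf("%s = %.6g", colnames(x$states), fin),
                              collapse = ", "), "\n")
  ext <- x$extinct[!is.na(x$extinct)]
  if (length(ext))
    cat("  extinctions:", paste(sprintf("%s at t = %.6g", names(ext), ext),
                                collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.pp_trajectory <- function(x, ...) {
  data.frame(t = x$times, x$states, check.names = FALSE)
}

#' @export
plot.pp_trajectory <- function(x, log = "", xlab = "time", ylab = "density", ...) {
  graphics::matplot(x$times, x$states, type = "l", lty = 1, log = log,
                    xlab = xlab, ylab = ylab, ...)
  graphics::legend("topright", legend = colnames(x$states),
                   col = seq_len(ncol(x$states)), lty = 1, bty = "n")
  invisible(x)
}

# peaks/troughs: indices of strict local extrema
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[v[i] > v[i - 1] & v[i] > v[i + 1]]
}

#' Detect oscillations in a trajectory
#'
#' Scans the prey (first, or `series`-th) compartment after discarding a
#' burn-in fraction.  Strict local maxima are assigned an amplitude relative
#' to their neighboring troughs, and peaks below the amplitude floor are
#' ignored (numerical ripple on a plateau is not an oscillation).  Verdicts:
#' `SUSTAINED` if at least 4 retained peaks remain and the last-to-first
#' amplitude ratio lies within `ratio_window`; `DAMPED` if at least 3 peaks
#' with monotonically shrinking amplitudes end below half the first; `NONE`
#' otherwise.
#'
#' @param traj a `pp_trajectory`.
#' @param series column index of the series to scan (default 1, the prey).
#' @param burn_in fraction of the trajectory discarded before peak detection.
#' @param amp_floor minimum absolute peak amplitude.
#' @param ratio_window sustained-oscillation window for the last/first
#'   amplitude ratio.
#' @return An object of class `oscillation_verdict`: list with `label`
#'   (`"SUSTAINED"`, `"DAMPED"` or `"NONE"`), `peak_times`, `peak_amplitudes`.
#' @export
detect_oscillation <- function(traj, series = 1, burn_in = 0.25,
                               amp_floor = 1e-4, ratio_window = c(0.9, 1.1)) {
  stopifnot(inherits(traj, "pp_trajectory"))
  t <- traj$times
  keep <- t >= t[1] + burn_in * (t[length(t)] - t[1])
  t <- t[keep]
  v <- traj$states[keep, series]
  if (length(t) < 3 || (t[length(t)] - t[1]) < 10)
    abort_validation("trajectory must cover >= 10 time units after burn-in")
  pk <- local_maxima(v)
  tr <- local_maxima(-v)
  amps <- vapply(pk, function(i) {
    prev <- tr[tr < i]; nxt <- tr[tr > i]
    ref <- c(if (length(prev)) v[prev[length(prev)]], if (length(nxt)) v[nxt[1]])
    if (!length(ref)) ref <- min(v)
    v[i] - mean(ref)
  }, numeric(1))
  sel <- amps > amp_floor
  pk <- pk[sel]; amps <- amps[sel]
  label <- "NONE"
  if (length(pk) >= 4) {
    ratio <- amps[length(amps)] / amps[1]
    if (ratio >= ratio_window[1] && ratio <= ratio_window[2]) label <- "SUSTAINED"
  }
  if (label == "NONE" && length(pk) >= 3 &&
      all(diff(amps) < 0) && amps[length(amps)] < 0.5 * amps[1]) {
    label <- "DAMPED"
  }
  structure(list(label = label, peak_times = t[pk], peak_amplitudes = amps),
            class = "oscillation_verdict")
}

#' @export
print.oscillation_verdict <- function(x, ...) {
  cat(sprintf("<oscillation_verdict> %s (%d peaks)\n", x$label,
              length(x$peak_times)))
  invisible(x)
}

#' Conservation drift of a Lotka-Volterra trajectory
#'
#' Worst-case relative drift `max_t |H(t) - H(0)| / |H(0)|` of the conserved
#' quantity [lv_invariant()] along the samples of an L-V trajectory.  For the
#' exact flow the drift is zero; for a numerical trajectory it quantifies
#' integration error and shrinks as solver tolerances are tightened.
#'
#' @param traj a `pp_trajectory` from the `"lv"` model, strictly positive.
#' @param p the [lv_params()] used.
#' @return scalar relative drift (0 for a single-sample trajectory).
#' @export
conservation_drift <- function(traj, p) {
  stopifnot(inherits(traj, "pp_trajectory"))
  if (traj$model != "lv")
    abort_validation("conservation_drift is defined for 'lv' trajectories only")
  if (any(traj$states <= 0))
    abort_validation("conservation_drift requires strictly positive densities")
  H <- apply(traj$states, 1, lv_invariant, p = p)
  if (length(H) < 2) return(0)
  max(abs(H - H[1])) / abs(H[1])
}

#' Write / read a trajectory as CSV
#'
#' Plain CSV with header `t,<compartment names>`, one row per sample, values
#' at 12 significant digits (enough headroom below the package's conservation
#' tolerances).  A leading `# model=<id>` comment line carries the model id so
#' the file round-trips through [read_trajectory()].
#'
#' @param traj a `pp_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "pp_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# model=%s", traj$model), con)
  writeLines(paste(c("t", colnames(traj$states)), collapse = ","), con)
  m <- cbind(traj$times, traj$states)
  writeLines(apply(m, 1, function(r)
    paste(formatC(r, digits = 12, format = "g"), collapse = ",")), con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  first <- readLines(path, n = 1)
  model <- if (grepl("^# model=", first)) sub("^# model=", "", first) else NA_character_
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  states <- as.matrix(df[, -1, drop = FALSE])
  structure(list(model = model, times = df[[1]], states = states,
                 params = NULL, extinct = NULL, opts = NULL),
            class = "pp_trajectory")
}
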