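# Internal helpers: condition classes and argument checking.

abort_validation <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("immunecol_validation_error", "error", "condition"),
                      call = call))
}

abort_numerical <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("immunecol_numerical_error", "error", "condition"),
                      call = call))
}

# scalar finite numeric check
chk_num <- function(x, name, lower = -Inf, strict = FALSE, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation(sprintf("'%s' must be a finite numeric scalar", name))
  if (strict && x <= lower)
    abort_validation(sprintf("'%s' must be > %g (got %g)", name, lower, x))
  if (!strict && x < lower)
    abort_validation(sprintf("'%s' must be >= %g (got %g)", name, lower, x))
  if (x > upper)
    abort_validation(sprintf("'%s' must be <= %g (got %g)", name, upper, x))
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
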