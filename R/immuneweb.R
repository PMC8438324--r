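#' Interaction-coefficient matrix of a model at a state
#'
#' The matrix of local interaction coefficients `a_ij = d(dN_i/dt)/dN_j`: the
#' effect of changing the density of cell type `j` (column) on the growth
#' rate of cell type `i` (row), evaluated at the supplied state (typically an
#' equilibrium or a reference state).  This is the Jacobian of the total
#' growth rates; for positive densities its off-diagonal signs coincide with
#' those of the per-capita formulation, and unlike the per-capita form it is
#' well defined at zero densities.  Signs can change with density, so the
#' classification is deliberately state-dependent.
#'
#' @inheritParams pp_jacobian
#' @return An object of class `interaction_matrix` (a matrix with labelled
#'   rows/columns).
#' @seealso [sign_pattern()], [classify_web()]
#' @export
interaction_matrix <- function(model, state, params, step = 1e-6) {
  J <- pp_jacobian(model, state, params, step = step)
  structure(J, class = c("interaction_matrix", class(J)),
            state = stats::setNames(as.numeric(state), rownames(J)))
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("<interaction_matrix> a_ij = effect of column type on row type's growth rate\n")
  print(unclass(x)[,], ...)
  invisible(x)
}

#' Sign pattern of an interaction matrix
#'
#' Entrywise sign over `{+, -, 0}`, with `|a_ij| <= eps` treated as zero.
#'
#' @param M an [interaction_matrix()] (or plain square matrix).
#' @param eps magnitude below which a coefficient counts as no interaction.
#' @return character matrix over `"+"`, `"-"`, `"0"`.
#' @export
sign_pattern <- function(M, eps = 1e-9) {
  m <- unclass(M)
  if (!is.matrix(m) || nrow(m) != ncol(m) || any(!is.finite(m)))
    abort_validation("'M' must be a finite square matrix")
  out <- ifelse(abs(m) <= eps, "0", ifelse(m > 0, "+", "-"))
  dimnames(out) <- dimnames(m)
  out
}

#' Classify a pairwise community module from effect signs
#'
#' Given the signs of the two reciprocal interaction coefficients
#' `(s_ij, s_ji)`: `(+,-)` or `(-,+)` is predator-prey (the type receiving
#' the `+` is the predator); `(-,-)` competition; `(+,+)` mutualism; a `+`
#' paired with `0` commensalism; a `-` paired with `0` amensalism; `(0,0)`
#' neutral.
#'
#' @param s_ij,s_ji signs in `{"+", "-", "0"}`.
#' @return one of `"PREDATOR_PREY"`, `"COMPETITION"`, `"MUTUALISM"`,
#'   `"COMMENSALISM"`, `"AMENSALISM"`, `"NEUTRAL"`.
#' @export
classify_pair <- function(s_ij, s_ji) {
  ok <- c("+", "-", "0")
  if (!(s_ij %in% ok) || !(s_ji %in% ok))
    abort_validation("signs must be one of '+', '-', '0'")
  np <- sum(c(s_ij, s_ji) == "+")
  nm <- sum(c(s_ij, s_ji) == "-")
  if (np == 1 && nm == 1) "PREDATOR_PREY"
  else if (nm == 2) "COMPETITION"
  else if (np == 2) "MUTUALISM"
  else if (np == 1) "COMMENSALISM"
  else if (nm == 1) "AMENSALISM"
  else "NEUTRAL"
}

#' Classify every pairwise module of an interaction matrix
#'
#' Applies [classify_pair()] to the off-diagonal sign pair of every unordered
#' compartment pair.  Diagonal (self-regulation) entries never affect the
#' labels.  For predator-prey pairs the `predator` column names the type
#' whose growth rate benefits.
#'
#' @param M an [interaction_matrix()].
#' @param eps zero threshold (see [sign_pattern()]).
#' @return An object of class `immune_web`: data frame with columns `i`, `j`,
#'   `a_ij`, `a_ji`, `s_ij`, `s_ji`, `module`, `predator`.
#' @export
classify_web <- function(M, eps = 1e-9) {
  s <- sign_pattern(M, eps)
  m <- unclass(M)
  lab <- rownames(m) %||% paste0("V", seq_len(nrow(m)))
  idx <- utils::combn(nrow(m), 2)
  rows <- lapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    module <- classify_pair(s[i, j], s[j, i])
    predator <- if (module == "PREDATOR_PREY") {
      if (s[i, j] == "+") lab[i] else lab[j]
    } else NA_character_
    data.frame(i = lab[i], j = lab[j], a_ij = m[i, j], a_ji = m[j, i],
               s_ij = s[i, j], s_ji = s[j, i], module = module,
               predator = predator)
  })
  structure(do.call(rbind, rows), class = c("immune_web", "data.frame"))
}

#' @export
print.immune_web <- function(x, ...) {
  cat("<immune_web> pairwise community modules\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an immune-web report as JSON
#'
#' One JSON entry per pair: the two compartment labels, the module, and the
#' two interaction coefficients.
#'
#' @param web an `immune_web` from [classify_web()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_web_report <- function(web, path) {
  stopifnot(inherits(web, "immune_web"))
  entries <- lapply(seq_len(nrow(web)), function(k) list(
    pair = c(web$i[k], web$j[k]),
    module = web$module[k],
    a_ij = web$a_ij[k], a_ji = web$a_ji[k]))
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
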