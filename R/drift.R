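# Replicator drift factors for the CMC construction game.
#
# Two variants are carried side by side:
#   mode = "printed"  evaluates the drift-factor formulas exactly as typeset
#                     in the published replicator systems (the expressions in
#                     square brackets multiplying the state variables);
#   mode = "derived"  recomputes each factor as e1 - e2 from the payoff
#                     cells, i.e. the textbook replicator construction.
# The two disagree by known closed forms (see cmc_drift_discrepancy); the
# printed variant is the default because it is the system the published
# simulations integrated.

# Returns a vectorised function(x, y, z) -> matrix (length(x) rows, d cols)
# of drift factors. Constants are resolved once, so the per-step cost inside
# the integration loop is a handful of elementwise operations.
.factor_fun <- function(params, mode = c("printed", "derived")) {
  mode <- match.arg(mode)
  model <- .cmc_model(params)
  p <- unclass(params)
  if (mode == "printed") {
    if (model == "two") {
      function(x, y, z = NULL) with(p, cbind(
        x = (xi - 1) * (I + U) + y * pi * (1 - xi) * Tp + pi * Sl + xi * Tp,
        y = pi * Sp + (1 + v) * R + (xi - 1) * Tp + (1 - eps) * xi * U +
          (1 - eps) * (1 - xi) * U * x + (1 - x) * v * D))
    } else {
      function(x, y, z) with(p, cbind(
        x = (xi - 1) * (I + U) + y * pi * (1 - xi) * Tp +
          z * pi * (1 - xi) * Tg + pi * Sl + xi * Tp + xi * Tg +
          (1 - xi) * phi * F,
        y = pi * Sp + (1 + v) * R + (xi - 1) * Tp + (1 - eps) * xi * U +
          (1 - eps) * (1 - xi) * U * x + (1 - z) * v * D,
        z = A * (phi - v + phi * v) * (x * y - x - y) + (xi - 1) * Tg -
          (1 - phi) * F + A))
    }
  } else if (model == "two") {
    cEA <- .payoff_cell_two("efficient", "active", p)
    cEP <- .payoff_cell_two("efficient", "passive", p)
    cIA <- .payoff_cell_two("inefficient", "active", p)
    cIP <- .payoff_cell_two("inefficient", "passive", p)
    dxA <- cEA[["LH"]] - cIA[["LH"]]; dxP <- cEP[["LH"]] - cIP[["LH"]]
    dyE <- cEA[["PHI"]] - cEP[["PHI"]]; dyI <- cIA[["PHI"]] - cIP[["PHI"]]
    function(x, y, z = NULL) cbind(
      x = y * dxA + (1 - y) * dxP,
      y = x * dyE + (1 - x) * dyI)
  } else {
    cell <- function(a, b, c) .payoff_cell_three(a, b, c, p)
    # payoff advantage of the aggressive strategy in every co-player cell
    dx <- outer(c(active = 1, passive = 2), c(adequate = 1, prudent = 2),
                Vectorize(function(b, g) {
                  b <- c("active", "passive")[b]
                  g <- c("adequate", "prudent")[g]
                  cell("efficient", b, g)[["LH"]] -
                    cell("inefficient", b, g)[["LH"]]
                }))
    dy <- outer(1:2, 1:2, Vectorize(function(l, g) {
      l <- c("efficient", "inefficient")[l]
      g <- c("adequate", "prudent")[g]
      cell(l, "active", g)[["PHI"]] - cell(l, "passive", g)[["PHI"]]
    }))
    dz <- outer(1:2, 1:2, Vectorize(function(l, b) {
      l <- c("efficient", "inefficient")[l]
      b <- c("active", "passive")[b]
      cell(l, b, "adequate")[["GD"]] - cell(l, b, "prudent")[["GD"]]
    }))
    function(x, y, z) cbind(
      x = y * z * dx[1, 1] + y * (1 - z) * dx[1, 2] +
        (1 - y) * z * dx[2, 1] + (1 - y) * (1 - z) * dx[2, 2],
      y = x * z * dy[1, 1] + x * (1 - z) * dy[1, 2] +
        (1 - x) * z * dy[2, 1] + (1 - x) * (1 - z) * dy[2, 2],
      z = x * y * dz[1, 1] + x * (1 - y) * dz[1, 2] +
        (1 - x) * y * dz[2, 1] + (1 - x) * (1 - y) * dz[2, 2])
  }
}

#' Replicator drift at a game state
#'
#' Evaluates the per-role drift factors (the bracketed payoff-difference
#' expressions multiplying the state variables in the replicator system) and
#' the resulting drifts at a state.
#'
#' @inheritParams cmc_expected_payoffs
#' @param mode `"printed"` evaluates the drift factors exactly as typeset in
#'   the published replicator systems; `"derived"` recomputes them as
#'   `e1 - e2` from the payoff cells. The two differ by known closed forms
#'   (see [cmc_drift_discrepancy()]).
#' @param form `"replicator"` gives the standard replicator drift
#'   `p * (1 - p) * f`; `"linear"` gives the literal stochastic-recursion
#'   reading `p * f`.
#' @return An object of class `cmc_drift`: list with named numeric vectors
#'   `factors` and `drifts`, plus `mode` and `form`.
#' @examples
#' cmc_drift(c(0.5, 0.5), cmc_baseline("two"))
#' @export
cmc_drift <- function(state, params, mode = c("printed", "derived"),
                      form = c("replicator", "linear")) {
  .check_params(params)
  mode <- match.arg(mode)
  form <- match.arg(form)
  model <- .cmc_model(params)
  state <- .check_state(state, model)
  f <- drop(.factor_fun(params, mode)(state[1L], state[2L],
                                      if (model == "three") state[3L]))
  names(f) <- names(state)
  drifts <- if (form == "replicator") state * (1 - state) * f else state * f
  structure(list(factors = f, drifts = drifts, mode = mode, form = form),
            class = "cmc_drift")
}

#' @export
print.cmc_drift <- function(x, ...) {
  cat("CMC replicator drift (mode = ", x$mode, ", form = ", x$form, ")\n",
      sep = "")
  cat("  factors:", paste(sprintf("%s = %g", names(x$factors), x$factors),
                          collapse = ", "), "\n")
  cat("  drifts: ", paste(sprintf("%s = %g", names(x$drifts), x$drifts),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Printed-minus-derived drift factor discrepancy
#'
#' Audit of the typeset replicator systems against the payoff-matrix
#' derivation: returns, per role, the printed drift factor minus the factor
#' derived as `e1 - e2` from the payoff cells. For the two-subject game the
#' x-component equals `xi * Tp * (1 - pi)` identically and the y-component is
#' zero; for the tripartite game the z-component equals
#' `(xi - 1) * Tg * (1 - x) * (1 - y)`.
#'
#' @inheritParams cmc_drift
#' @return Named numeric vector of per-role factor differences.
#' @examples
#' cmc_drift_discrepancy(c(0.2, 0.8), cmc_baseline("two"))  # c(3, 0)
#' @export
cmc_drift_discrepancy <- function(state, params) {
  printed <- cmc_drift(state, params, mode = "printed")$factors
  derived <- cmc_drift(state, params, mode = "derived")$factors
  printed - derived
}
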