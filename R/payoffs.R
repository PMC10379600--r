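# Pure-strategy payoffs and expected payoffs for the CMC construction game.
#
# Two-subject cells follow the 2x2 payoff matrix of the lead hospital (LH,
# strategies efficient/inefficient construction) and the primary healthcare
# institutions (PHI, active/passive participation). Tripartite cells are read
# term-by-term from the expectation expressions of the three roles (see the
# methods vignette for why those, and not the tabulated matrix, are canonical
# where the two disagree).

.payoff_cell_two <- function(lh, phi_s, p) {
  with(p, {
    if (lh == "efficient") {
      if (phi_s == "active")
        c(LH = -I - U + (1 + pi) * Sl + (1 + pi) * Tp,
          PHI = -Tp + (1 + pi) * Sp + (1 + v) * R + U - (1 - v) * D)
      else
        c(LH = -I - U + (1 + pi) * Sl + (1 + pi) * xi * Tp,
          PHI = -xi * Tp + Sp + eps * U - (1 - v) * D)
    } else {
      if (phi_s == "active")
        c(LH = -xi * (I + U) + Sl + Tp,
          PHI = -Tp + (1 + pi) * Sp + (1 + v) * R + xi * U - (1 - v) * D)
      else
        c(LH = -xi * (I + U) + Sl + xi * Tp,
          PHI = -xi * Tp + Sp + eps * xi * U - D)
    }
  })
}

.payoff_cell_three <- function(lh, phi_s, gd, p) {
  eff <- lh == "efficient"
  act <- phi_s == "active"
  ade <- gd == "adequate"
  with(p, {
    lh_pay <- if (eff) {
      base <- -I - U + (1 + pi) * Sl + (1 + pi) * (if (act) Tp else xi * Tp)
      if (ade) base + Tg + F
      # asymmetric as printed: prudent support yields xi*Tg to an efficient
      # lead hospital when the institutions are active, but Tg when passive
      else if (act) base + xi * Tg + phi * F
      else base + Tg + phi * F
    } else {
      base <- -xi * (I + U) + Sl + (if (act) Tp else xi * Tp)
      if (ade) base + Tg + xi * F
      else if (act) base + xi * Tg + phi * xi * F
      else base + Tg + phi * xi * F
    }
    phi_pay <- if (act) {
      -Tp + (1 + pi) * Sp + (1 + v) * R + (if (eff) U else xi * U) -
        (1 - v) * D
    } else {
      base <- -xi * Tp + Sp + eps * (if (eff) U else xi * U)
      # the attendance-loss reduction for passive institutions follows the
      # government's support strategy (z), not the lead hospital's
      if (ade) base - (1 - v) * D else base - D
    }
    gd_pay <- if (ade) {
      if (!eff && !act) -Tg - F + A else -Tg - F + (1 + v) * A
    } else {
      if (!eff && !act) -Tg - phi * F
      else -xi * Tg - phi * F + phi * (1 + v) * A
    }
    c(LH = lh_pay, PHI = phi_pay, GD = gd_pay)
  })
}

#' Pure-strategy payoffs of the CMC construction game
#'
#' Evaluates the payoff cell for a pure-strategy profile: the lead hospital's
#' and primary institutions' payoffs in the two-subject game, plus the
#' government departments' payoff in the tripartite game.
#'
#' @param params a [cmc_params] object; its `model` attribute selects the
#'   game.
#' @param lh lead-hospital strategy, `"efficient"` or `"inefficient"`
#'   construction.
#' @param phi primary-healthcare-institution strategy, `"active"` or
#'   `"passive"` participation.
#' @param gd government strategy, `"adequate"` or `"prudent"` support.
#'   Must be `NULL` for the two-subject game and supplied for the tripartite
#'   game.
#' @return Named numeric vector of payoffs (`LH`, `PHI`[, `GD`]).
#' @examples
#' cmc_payoff(cmc_baseline("two"), "efficient", "active")      # c(8, -12)
#' cmc_payoff(cmc_baseline("three"), "efficient", "active", "adequate")
#' @export
cmc_payoff <- function(params,
                       lh = c("efficient", "inefficient"),
                       phi = c("active", "passive"),
                       gd = NULL) {
  .check_params(params)
  lh <- match.arg(lh)
  phi <- match.arg(phi)
  model <- .cmc_model(params)
  if (model == "two") {
    if (!is.null(gd))
      stop("'gd' must be absent for the two-subject game", call. = FALSE)
    .payoff_cell_two(lh, phi, params)
  } else {
    if (is.null(gd))
      stop("'gd' is required for the tripartite game", call. = FALSE)
    gd <- match.arg(gd, c("adequate", "prudent"))
    .payoff_cell_three(lh, phi, gd, params)
  }
}

# All pure-profile payoffs as a data.frame, one row per cell.
.payoff_table <- function(params) {
  model <- .cmc_model(params)
  lhs <- c("efficient", "inefficient")
  phis <- c("active", "passive")
  if (model == "two") {
    grid <- expand.grid(lh = lhs, phi = phis, stringsAsFactors = FALSE)
    pay <- t(mapply(function(a, b) .payoff_cell_two(a, b, params),
                    grid$lh, grid$phi))
  } else {
    grid <- expand.grid(lh = lhs, phi = phis, gd = c("adequate", "prudent"),
                        stringsAsFactors = FALSE)
    pay <- t(mapply(function(a, b, c) .payoff_cell_three(a, b, c, params),
                    grid$lh, grid$phi, grid$gd))
  }
  cbind(grid, as.data.frame(pay, row.names = seq_len(nrow(grid))))
}

#' Expected payoffs of a role at a mixed-strategy state
#'
#' Computes a role's expected payoff under its aggressive strategy (`e1`:
#' efficient construction / active participation / adequate support), under
#' its passive strategy (`e2`), and the population mean
#' `p * e1 + (1 - p) * e2` where `p` is the role's own mixing probability.
#' Expectations are taken over the co-players' mixing probabilities.
#'
#' @param state numeric vector `c(x, y)` or `c(x, y, z)` of strategy
#'   probabilities in `[0, 1]` (x: lead hospital efficient construction,
#'   y: primary institutions active participation, z: government adequate
#'   support).
#' @param params a [cmc_params] object.
#' @param role `"LH"`, `"PHI"`, or `"GD"` (tripartite only).
#' @return A list with components `e1`, `e2`, `mean`, `role`.
#' @examples
#' cmc_expected_payoffs(c(1, 1), cmc_baseline("two"), "LH")
#' @export
cmc_expected_payoffs <- function(state, params, role = c("LH", "PHI", "GD")) {
  .check_params(params)
  model <- .cmc_model(params)
  role <- match.arg(role)
  state <- .check_state(state, model)
  i <- .role_index(role, model)
  tab <- .payoff_table(params)
  strat_cols <- c("lh", "phi", if (model == "three") "gd")
  aggressive <- c(lh = "efficient", phi = "active", gd = "adequate")
  own <- strat_cols[i]
  others <- setdiff(strat_cols, own)
  probs <- c(lh = state[["x"]], phi = state[["y"]],
             gd = if (model == "three") state[["z"]] else NA_real_)
  weight <- rep(1, nrow(tab))
  for (o in others) {
    w <- ifelse(tab[[o]] == aggressive[[o]], probs[[o]], 1 - probs[[o]])
    weight <- weight * w
  }
  e1 <- sum(weight[tab[[own]] == aggressive[[own]]] *
              tab[[role]][tab[[own]] == aggressive[[own]]])
  e2 <- sum(weight[tab[[own]] != aggressive[[own]]] *
              tab[[role]][tab[[own]] != aggressive[[own]]])
  p <- state[[i]]
  list(e1 = e1, e2 = e2, mean = p * e1 + (1 - p) * e2, role = role)
}
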