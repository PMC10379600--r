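# The user-facing model object: a validated parameterisation of the CMC
# construction game, with methods for inspection, equilibrium analysis and
# simulation.

#' Construct a CMC evolutionary game model
#'
#' Bundles a validated parameter set into a model object for the two-subject
#' game (lead hospital vs. primary healthcare institutions) or the tripartite
#' game (adding government departments). The object supports `print()`,
#' `summary()` (payoff matrix and vertex stability), `coef()`, `simulate()`
#' and, through the returned trajectories, `plot()`.
#'
#' @param params a [cmc_params] object, or a named list/values forwarded to
#'   [cmc_params()].
#' @param model game variant, `"two"` or `"three"`; ignored when `params` is
#'   already validated.
#' @return An object of class `cmc_game`.
#' @examples
#' g <- cmc_game(cmc_baseline("two"))
#' summary(g)
#' tr <- simulate(g, seed = 1, sigma = 0, steps = 2000)
#' terminal(tr)
#' @export
cmc_game <- function(params, model = c("two", "three")) {
  if (!inherits(params, "cmc_params"))
    params <- cmc_params(params, model = match.arg(model))
  structure(list(params = params, model = .cmc_model(params)),
            class = "cmc_game")
}

#' @export
print.cmc_game <- function(x, ...) {
  cat("Evolutionary game model of CMC construction\n")
  cat("  players: lead hospital, primary healthcare institutions",
      if (x$model == "three") ", government departments", "\n", sep = "")
  print(x$params)
  invisible(x)
}

#' @export
coef.cmc_game <- function(object, ...) {
  unlist(unclass(object$params))
}

#' Vertex equilibrium stability of the replicator system
#'
#' Classifies every pure-strategy vertex of the state hypercube by the signs
#' of the drift factors evaluated there: a vertex is `stable` when, for every
#' role, the drift pushes the role's probability back toward its vertex value
#' (factor `> 0` at `p = 1`, factor `< 0` at `p = 0`); `unstable` when every
#' role is pushed away; `saddle` when the signs are mixed. A vertex with any
#' drift factor exactly zero is flagged `degenerate` and not classified.
#'
#' @param params a [cmc_params] object or a `cmc_game`.
#' @param mode drift variant, see [cmc_drift()].
#' @return A data frame of class `cmc_stability` with one row per vertex:
#'   the vertex coordinates, each role's drift factor, and `classification`.
#' @examples
#' cmc_vertex_stability(cmc_baseline("two"))
#' @export
cmc_vertex_stability <- function(params, mode = c("printed", "derived")) {
  if (inherits(params, "cmc_game")) params <- params$params
  .check_params(params)
  mode <- match.arg(mode)
  model <- .cmc_model(params)
  d <- if (model == "two") 2L else 3L
  vertices <- as.matrix(expand.grid(rep(list(c(0, 1)), d)))
  colnames(vertices) <- c("x", "y", "z")[seq_len(d)]
  fac <- .factor_fun(params, mode)
  f <- fac(vertices[, 1L], vertices[, 2L], if (d == 3L) vertices[, 3L])
  toward <- (vertices == 1 & f > 0) | (vertices == 0 & f < 0)
  res <- data.frame(vertices)
  colnames(f) <- paste0("f_", colnames(vertices))
  res <- cbind(res, f)
  cls <- character(nrow(res))
  for (i in seq_len(nrow(res))) {
    if (any(f[i, ] == 0)) cls[i] <- "degenerate"
    else if (all(toward[i, ])) cls[i] <- "stable"
    else if (!any(toward[i, ])) cls[i] <- "unstable"
    else cls[i] <- "saddle"
  }
  res$classification <- cls
  structure(res, class = c("cmc_stability", "data.frame"),
            mode = mode, model = model)
}

#' @export
summary.cmc_game <- function(object, mode = c("printed", "derived"), ...) {
  mode <- match.arg(mode)
  structure(list(model = object$model,
                 params = object$params,
                 payoffs = .payoff_table(object$params),
                 stability = cmc_vertex_stability(object$params, mode)),
            class = "summary.cmc_game")
}

#' @export
print.summary.cmc_game <- function(x, ...) {
  cat("Evolutionary game model of CMC construction (",
      if (x$model == "two") "two-subject" else "tripartite", ")\n\n",
      sep = "")
  cat("Pure-strategy payoffs:\n")
  print(x$payoffs, row.names = FALSE)
  cat("\nVertex stability (drift-factor signs, mode = ",
      attr(x$stability, "mode"), "):\n", sep = "")
  print(as.data.frame(x$stability), row.names = FALSE)
  stable <- x$stability$classification == "stable"
  if (any(stable)) {
    d <- if (x$model == "two") 2L else 3L
    labs <- apply(x$stability[stable, seq_len(d), drop = FALSE], 1,
                  function(v) paste0("(", paste(v, collapse = ","), ")"))
    cat("\nEvolutionarily stable profile(s): ", paste(labs, collapse = " "),
        "\n", sep = "")
  } else cat("\nNo stable vertex.\n")
  invisible(x)
}

#' Simulate trajectories from a CMC game model
#'
#' Method for [stats::simulate()]: runs `nsim` stochastic (or, with
#' `sigma = 0`, deterministic) trajectories of the game system.
#'
#' @param object a `cmc_game`.
#' @param nsim number of replicate trajectories.
#' @param seed base seed; replicate `r` uses `seed + r` when `nsim > 1`.
#' @param state0 initial state; default maximal uncertainty
#'   `(0.5, 0.5[, 0.5])`.
#' @param ... settings forwarded to [cmc_settings()] (`sigma`, `h`, `steps`,
#'   `mode`, `form`, `noise`).
#' @return A `cmc_trajectory` when `nsim = 1`, otherwise a [cmc_ensemble()]
#'   summary.
#' @export
simulate.cmc_game <- function(object, nsim = 1, seed = NULL,
                              state0 = NULL, ...) {
  d <- if (object$model == "two") 2L else 3L
  if (is.null(state0)) state0 <- rep(0.5, d)
  if (nsim == 1) {
    settings <- cmc_settings(seed = seed, ...)
    cmc_simulate(state0, object$params, settings)
  } else {
    if (is.null(seed)) seed <- sample.int(.Machine$integer.max - nsim, 1L)
    cmc_ensemble(state0, object$params, cmc_settings(...),
                 replicates = nsim, base_seed = seed)
  }
}
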