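# Deterministic and stochastic integration of the replicator systems.
#
# The stochastic systems are nonlinear Ito SDEs with multiplicative noise
# sigma * p * dW per role; they are discretised with the fixed-step forward
# Euler (Euler-Maruyama) scheme
#   p[n+1] = p[n] + drift(p[n]) * h + sigma * p[n] * dW[n],
# each component clamped to [0, 1] after every step (boundaries are
# absorbing under multiplicative noise). sigma = 0 reproduces the
# deterministic explicit-Euler integrator exactly.

#' Simulation settings for the CMC game systems
#'
#' @param sigma random disturbance intensity `sigma >= 0` of the
#'   multiplicative Gaussian white noise.
#' @param h step size (time units), `> 0`.
#' @param steps number of steps `N >= 1`; the horizon is `T = N * h`.
#' @param seed integer seed for the Brownian increments, or `NULL` to draw
#'   one (the drawn seed is recorded on the trajectory).
#' @param mode drift variant, see [cmc_drift()].
#' @param form drift form, see [cmc_drift()].
#' @param noise `"independent"` gives each role its own Brownian stream;
#'   `"shared"` applies one common stream to every role.
#' @return A validated list of class `cmc_settings`.
#' @export
cmc_settings <- function(sigma = 0.05, h = 0.01, steps = 10000L,
                         seed = NULL,
                         mode = c("printed", "derived"),
                         form = c("replicator", "linear"),
                         noise = c("independent", "shared")) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("sigma must be a single number >= 0", call. = FALSE)
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop("h must be a single number > 0", call. = FALSE)
  if (!is.numeric(steps) || length(steps) != 1L || steps < 1 ||
      steps != round(steps))
    stop("steps must be a positive integer", call. = FALSE)
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed))
      stop("seed must be a single integer or NULL", call. = FALSE)
    seed <- as.integer(seed)
  }
  structure(list(sigma = as.numeric(sigma), h = as.numeric(h),
                 steps = as.integer(steps), seed = seed,
                 mode = match.arg(mode), form = match.arg(form),
                 noise = match.arg(noise)),
            class = "cmc_settings")
}

.check_settings <- function(settings) {
  if (!inherits(settings, "cmc_settings"))
    stop("'settings' must be built by cmc_settings()", call. = FALSE)
  settings
}

# evaluate code under a given RNG seed without disturbing the caller's RNG
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Seeded Brownian increments
#'
#' Draws the per-step Brownian increments `delta_omega ~ N(0, h)` used by the
#' forward Euler scheme: `roles * steps` independent normal deviates with
#' mean 0 and variance `h`. The same seed reproduces the same increments
#' bit for bit.
#'
#' @param steps number of time steps.
#' @param h step size, `> 0` (the increment variance).
#' @param seed integer seed.
#' @param roles number of independent streams (one per game role, or 1 for a
#'   shared stream).
#' @return A list of class `cmc_noise` with `increments` (a `roles x steps`
#'   matrix, drawn column by column), `seed`, and `h`.
#' @examples
#' w <- cmc_brownian(100, h = 0.01, seed = 1, roles = 2)
#' dim(w$increments)
#' @export
cmc_brownian <- function(steps, h, seed, roles = 1L) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop("h must be > 0", call. = FALSE)
  if (!is.numeric(steps) || steps < 1 || steps != round(steps))
    stop("steps must be a positive integer", call. = FALSE)
  inc <- .with_seed(seed,
                    matrix(stats::rnorm(roles * steps, 0, sqrt(h)),
                           nrow = roles, ncol = steps))
  structure(list(increments = inc, seed = as.integer(seed), h = h),
            class = "cmc_noise")
}

# Core engine: steps `reps` replicates in lockstep. state0 is the common
# start, seeds has one entry per replicate (ignored when sigma == 0 and kept
# only for bookkeeping). Returns array [steps + 1, reps, d].
.sim_paths <- function(state0, params, settings, seeds) {
  model <- .cmc_model(params)
  d <- if (model == "two") 2L else 3L
  reps <- length(seeds)
  h <- settings$h
  steps <- settings$steps
  sigma <- settings$sigma
  replicator <- settings$form == "replicator"
  fac <- .factor_fun(params, settings$mode)
  if (sigma > 0) {
    nstreams <- if (settings$noise == "independent") d else 1L
    dw <- array(0, dim = c(steps, reps, d))
    for (r in seq_len(reps)) {
      inc <- cmc_brownian(steps, h, seeds[r], roles = nstreams)$increments
      for (j in seq_len(d)) dw[, r, j] <- inc[min(j, nstreams), ]
    }
  }
  X <- matrix(rep(state0, each = reps), nrow = reps, ncol = d)
  paths <- array(NA_real_, dim = c(steps + 1L, reps, d))
  paths[1L, , ] <- X
  for (n in seq_len(steps)) {
    f <- fac(X[, 1L], X[, 2L], if (d == 3L) X[, 3L])
    drift <- if (replicator) X * (1 - X) * f else X * f
    X <- if (sigma > 0) X + drift * h + sigma * X * dw[n, , ]
         else X + drift * h
    X[X < 0] <- 0
    X[X > 1] <- 1
    if (anyNA(X) || any(is.infinite(X)))
      stop("non-finite state encountered at step ", n, call. = FALSE)
    paths[n + 1L, , ] <- X
  }
  paths
}

.new_trajectory <- function(path, model, settings, seed, state0) {
  steps <- nrow(path) - 1L
  df <- data.frame(step = 0:steps, t = (0:steps) * settings$h,
                   x = path[, 1L], y = path[, 2L])
  if (model == "three") df$z <- path[, 3L]
  structure(df,
            class = c("cmc_trajectory", "data.frame"),
            model = model, settings = settings, seed = seed,
            state0 = state0,
            terminal = stats::setNames(path[steps + 1L, ],
                                       c("x", "y", "z")[seq_len(ncol(path))]))
}

#' Simulate the stochastic CMC game system
#'
#' Integrates the (stochastic) replicator system with the fixed-step forward
#' Euler (Euler-Maruyama) scheme: per role,
#' `p[n+1] = p[n] + drift(p[n]) * h + sigma * p[n] * dw[n]`, with every
#' component clamped to `[0, 1]` after each step. With `sigma = 0` the result
#' is identical to [cmc_integrate()].
#'
#' @param state0 initial state `c(x, y[, z])`.
#' @param params a [cmc_params] object.
#' @param settings a [cmc_settings] object.
#' @return A `cmc_trajectory`: a data frame with columns `step`, `t`, `x`,
#'   `y`[, `z`], carrying the settings, seed, and terminal state as
#'   attributes.
#' @examples
#' tr <- cmc_simulate(c(0.5, 0.5), cmc_baseline("two"),
#'                    cmc_settings(sigma = 0.05, steps = 2000, seed = 1))
#' terminal(tr)
#' @export
cmc_simulate <- function(state0, params, settings = cmc_settings()) {
  .check_params(params)
  .check_settings(settings)
  model <- .cmc_model(params)
  state0 <- .check_state(state0, model)
  seed <- settings$seed
  if (is.null(seed) && settings$sigma > 0)
    seed <- sample.int(.Machine$integer.max, 1L)
  path <- .sim_paths(state0, params, settings,
                     seeds = if (is.null(seed)) 0L else seed)
  .new_trajectory(path[, 1L, , drop = TRUE], model, settings, seed, state0)
}

#' Deterministic integration of the replicator system
#'
#' Fixed-step explicit Euler solution of the deterministic (`sigma = 0`)
#' replicator system, matching the drift treatment of the stochastic scheme.
#'
#' @inheritParams cmc_simulate
#' @param mode,form,h,steps see [cmc_settings()].
#' @return A `cmc_trajectory` (see [cmc_simulate()]).
#' @examples
#' tr <- cmc_integrate(c(0.5, 0.5), cmc_baseline("two"))
#' round(terminal(tr), 3)
#' @export
cmc_integrate <- function(state0, params, h = 0.01, steps = 10000L,
                          mode = c("printed", "derived"),
                          form = c("replicator", "linear")) {
  settings <- cmc_settings(sigma = 0, h = h, steps = steps,
                           mode = match.arg(mode), form = match.arg(form))
  cmc_simulate(state0, params, settings)
}

#' Terminal state of a trajectory
#'
#' @param x a `cmc_trajectory`.
#' @return Named numeric vector, the last state of the trajectory.
#' @export
terminal <- function(x) {
  stopifnot(inherits(x, "cmc_trajectory"))
  attr(x, "terminal")
}

#' @export
print.cmc_trajectory <- function(x, ...) {
  s <- attr(x, "settings")
  cat("CMC game trajectory (", attr(x, "model"), "-subject model)\n",
      sep = "")
  cat(sprintf("  sigma = %g, h = %g, steps = %d, mode = %s, form = %s\n",
              s$sigma, s$h, s$steps, s$mode, s$form))
  if (!is.null(attr(x, "seed"))) cat("  seed =", attr(x, "seed"), "\n")
  cat("  start:   ", paste(sprintf("%.3f", attr(x, "state0")),
                           collapse = ", "), "\n")
  cat("  terminal:", paste(sprintf("%.3f", terminal(x)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Plot a simulated trajectory
#'
#' Draws the strategy probabilities of every role against time.
#'
#' @param x a `cmc_trajectory`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.cmc_trajectory <- function(x, ...) {
  cols <- intersect(c("x", "y", "z"), names(x))
  labs <- c(x = "lead hospital (x)", y = "primary institutions (y)",
            z = "government (z)")[cols]
  graphics::matplot(x$t, as.matrix(as.data.frame(x)[cols]), type = "l",
                    lty = 1, lwd = 1.5, col = seq_along(cols),
                    xlab = "time", ylab = "strategy probability",
                    ylim = c(0, 1), ...)
  graphics::legend("bottomright", legend = labs, col = seq_along(cols),
                   lty = 1, lwd = 1.5, bty = "n")
  invisible(x)
}
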