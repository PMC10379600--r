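# Seeded Monte Carlo ensembles of the stochastic game system and
# convergence classification of trajectories.

# Classify a single path (matrix [steps+1, d]) against the vertices of the
# hypercube. Classification works on rolling means over a `window` fraction
# of the horizon rather than raw states: under multiplicative noise the state
# keeps being kicked off a vertex by ~sigma*sqrt(h) per step even when the
# system has settled, so raw excursions would spuriously fail a sustained
# band while window means are stable (for sigma = 0 the two readings agree).
# Converged to a vertex when the final window mean is within `tol` of it
# componentwise. Convergence time is the first raw entry into the tol-ball
# after the point from which every later window mean stays within `tol`; the
# fluctuation measure is the maximum raw deviation after that time.
.classify_path <- function(path, times, tol = 0.05, window = 0.1) {
  n <- nrow(path)
  d <- ncol(path)
  W <- max(1L, ceiling(window * (n - 1L)))
  cs <- rbind(0, apply(path, 2, cumsum))
  nw <- n - W + 1L
  win_mean <- (cs[(W + 1L):(n + 1L), , drop = FALSE] -
                 cs[1:nw, , drop = FALSE]) / W
  final_mean <- win_mean[nw, ]
  vert <- round(final_mean)
  if (max(abs(final_mean - vert)) > tol)
    return(list(label = "non-converged", vertex = rep(NA_real_, d),
                time = NA_real_, fluctuation = NA_real_))
  maxdev_w <- apply(abs(sweep(win_mean, 2, vert)), 1, max)
  ok <- rev(cumprod(rev(maxdev_w <= tol))) == 1
  first <- which(ok)[1L]
  raw_dev <- apply(abs(sweep(path, 2, vert)), 1, max)
  # convergence time: first raw entry into the tol-ball once the window-mean
  # condition holds for good
  entry <- which(raw_dev[first:n] <= tol)
  first <- if (length(entry) > 0L) first + entry[1L] - 1L else first
  list(label = paste0("(", paste(vert, collapse = ","), ")"),
       vertex = vert, time = times[first],
       fluctuation = max(raw_dev[first:n]))
}

.vertex_labels <- function(d) {
  grid <- expand.grid(rep(list(c(0, 1)), d))
  apply(grid, 1, function(v) paste0("(", paste(v, collapse = ","), ")"))
}

#' Run a seeded ensemble of stochastic game simulations
#'
#' Simulates `replicates` trajectories from a common initial state;
#' replicate `r` uses seed `base_seed + r`, so each replicate is bit-for-bit
#' identical to a single [cmc_simulate()] run with that seed, and the whole
#' ensemble is reproducible from `base_seed`.
#'
#' @inheritParams cmc_simulate
#' @param replicates number of replicate trajectories, `>= 1`.
#' @param base_seed integer; replicate `r` is seeded with `base_seed + r`.
#' @param tol vertex-convergence tolerance for classification.
#' @return An object of class `cmc_ensemble`: list with `mean_path` (the
#'   per-step mean state over replicates, as a data frame), `mean_terminal`,
#'   `convergence_fraction` (named fractions per vertex label, plus
#'   `non-converged` when present; sums to 1), `replicates`, `seeds`, and
#'   the per-replicate `terminals` and `classifications`.
#' @examples
#' es <- cmc_ensemble(c(0.5, 0.5), cmc_baseline("two"),
#'                    cmc_settings(sigma = 0.05, steps = 2000),
#'                    replicates = 5, base_seed = 1)
#' es$convergence_fraction
#' @export
cmc_ensemble <- function(state0, params, settings = cmc_settings(),
                         replicates, base_seed, tol = 0.05) {
  .check_params(params)
  .check_settings(settings)
  model <- .cmc_model(params)
  state0 <- .check_state(state0, model)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  seeds <- as.integer(base_seed) + seq_len(replicates)
  paths <- .sim_paths(state0, params, settings, seeds)
  d <- dim(paths)[3L]
  times <- (0:settings$steps) * settings$h
  cls <- lapply(seq_len(replicates),
                function(r) .classify_path(paths[, r, , drop = TRUE],
                                           times, tol = tol))
  labels <- vapply(cls, `[[`, "", "label")
  counts <- table(factor(labels, levels = c(.vertex_labels(d),
                                            "non-converged")))
  frac <- counts[counts > 0] / replicates
  mean_path <- apply(paths, c(1L, 3L), mean)
  colnames(mean_path) <- c("x", "y", "z")[seq_len(d)]
  terminals <- matrix(paths[settings$steps + 1L, , ], ncol = d,
                      dimnames = list(NULL, colnames(mean_path)))
  structure(list(mean_path = data.frame(step = 0:settings$steps, t = times,
                                        mean_path),
                 mean_terminal = colMeans(terminals),
                 convergence_fraction = stats::setNames(as.numeric(frac),
                                                        names(frac)),
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed),
                 seeds = seeds,
                 terminals = terminals,
                 classifications = labels,
                 settings = settings, model = model, state0 = state0),
            class = "cmc_ensemble")
}

#' @export
print.cmc_ensemble <- function(x, ...) {
  cat("CMC stochastic game ensemble: ", x$replicates, " replicates (",
      x$model, "-subject model, sigma = ", x$settings$sigma, ")\n", sep = "")
  cat("  base seed:", x$base_seed, "\n")
  cat("  mean terminal:", paste(sprintf("%s = %.3f", names(x$mean_terminal),
                                        x$mean_terminal), collapse = ", "),
      "\n")
  cat("  convergence fractions:\n")
  for (l in names(x$convergence_fraction))
    cat(sprintf("    %-15s %.2f\n", l, x$convergence_fraction[[l]]))
  invisible(x)
}

#' Write an ensemble summary to JSON
#'
#' @param x a `cmc_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_json <- function(x, path) {
  stopifnot(inherits(x, "cmc_ensemble"))
  jsonlite::write_json(
    list(replicates = x$replicates,
         base_seed = x$base_seed,
         convergence_fraction = as.list(x$convergence_fraction),
         mean_terminal = as.list(x$mean_terminal)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
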