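# Declarative parameter-sweep scenarios: the seven preset experiments of the
# simulation analysis (figures 2-8 style sweeps) and a generic sweep runner
# with convergence classification.

.scenario_presets <- list(
  fig2 = list(model = "two", varied = "Tp", grid = c(5, 10, 15, 20, 25)),
  fig3 = list(model = "two", varied = "pi",
              grid = c(0.1, 0.3, 0.5, 0.7, 0.9)),
  fig4 = list(model = "two", varied = "xi",
              grid = c(0.1, 0.3, 0.5, 0.7, 0.9)),
  # the delivered-resources grid is not printed in the source analysis;
  # {1,3,5,7,9} brackets the baseline U = 5 symmetrically
  fig5 = list(model = "two", varied = "U", grid = c(1, 3, 5, 7, 9)),
  fig6 = list(model = "three", varied = "Tp+Tg",
              grid = c(5, 10, 15, 20, 25)),
  fig7 = list(model = "three", varied = "v",
              grid = c(0.1, 0.3, 0.5, 0.7, 0.9)),
  fig8 = list(model = "three", varied = "phi",
              grid = c(0.1, 0.3, 0.5, 0.7, 0.9))
)

#' Build a preset sweep scenario
#'
#' Returns the declarative specification of one of the seven preset
#' parameter sweeps: `fig2` (authority ceded by primary institutions, `Tp`),
#' `fig3` (information-construction integration coefficient, `pi`), `fig4`
#' (information-integration intensity, `xi`), `fig5` (delivered medical
#' resources, `U`), `fig6` (combined ceded authority `Tp + Tg`, allocated
#' by `split`), `fig7` (policy effect coefficient, `v`), `fig8` (government
#' support intensity, `phi`). All non-varied parameters sit at the
#' [cmc_baseline()] values.
#'
#' @param name one of `"fig2"` ... `"fig8"`.
#' @param sigma,h,steps,mode,form simulation settings, see [cmc_settings()].
#' @param seed base seed for replicate noise streams.
#' @param replicates replicate trajectories per grid value (only one is run
#'   when `sigma = 0`).
#' @param state0 initial state; default `(0.5, 0.5[, 0.5])`.
#' @param split for the composite `Tp+Tg` sweep: fraction of the total
#'   allocated to `Tp` (default `2/3`, the baseline `Tp:Tg = 12:6` ratio).
#' @return An object of class `cmc_sweep_spec`.
#' @examples
#' cmc_scenario("fig4", sigma = 0)
#' @export
cmc_scenario <- function(name, sigma = 0.05, h = 0.01, steps = 10000L,
                         seed = 1L, replicates = 5L, state0 = NULL,
                         mode = c("printed", "derived"),
                         form = c("replicator", "linear"),
                         split = 2 / 3) {
  if (!name %in% names(.scenario_presets))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(.scenario_presets), collapse = ", "), call. = FALSE)
  preset <- .scenario_presets[[name]]
  d <- if (preset$model == "two") 2L else 3L
  if (is.null(state0)) state0 <- rep(0.5, d)
  settings <- cmc_settings(sigma = sigma, h = h, steps = steps, seed = seed,
                           mode = match.arg(mode), form = match.arg(form))
  structure(list(name = name, model = preset$model, varied = preset$varied,
                 grid = preset$grid,
                 split = if (preset$varied == "Tp+Tg") split,
                 baseline = cmc_baseline(preset$model),
                 state0 = .check_state(state0, preset$model),
                 sim = settings,
                 replicates = if (sigma > 0) as.integer(replicates) else 1L),
            class = "cmc_sweep_spec")
}

#' @export
print.cmc_sweep_spec <- function(x, ...) {
  cat("CMC sweep scenario '", x$name, "' (", x$model, "-subject model)\n",
      sep = "")
  cat("  varied:", x$varied, "over {", paste(x$grid, collapse = ", "), "}\n")
  if (!is.null(x$split))
    cat(sprintf("  composite split: Tp = %.3g, Tg = %.3g of the total\n",
                x$split, 1 - x$split))
  cat(sprintf("  sigma = %g, h = %g, steps = %d, replicates = %d, seed = %d\n",
              x$sim$sigma, x$sim$h, x$sim$steps, x$replicates, x$sim$seed))
  invisible(x)
}

# parameter set at one grid value of the sweep
.sweep_params <- function(spec, value) {
  vals <- unclass(spec$baseline)
  if (identical(spec$varied, "Tp+Tg")) {
    vals$Tp <- spec$split * value
    vals$Tg <- (1 - spec$split) * value
  } else {
    vals[[spec$varied]] <- value
  }
  cmc_params(vals, model = spec$model)
}

#' Run a parameter sweep
#'
#' Simulates every grid value of a sweep scenario (with `replicates` noisy
#' replicates each when `sigma > 0`) and classifies each trajectory's
#' convergence to a vertex of the strategy hypercube. Replicate `r` at grid
#' index `g` is seeded with `seed + (g - 1) * replicates + r`, so the whole
#' sweep is reproducible from the scenario's base seed.
#'
#' @param spec a `cmc_sweep_spec` from [cmc_scenario()].
#' @param tol vertex-convergence tolerance (classification requires the
#'   final 10% of the horizon to stay within `tol` of a vertex).
#' @param keep_paths keep the full trajectories (memory-heavy for long
#'   sweeps); otherwise only terminals and classifications are retained.
#' @return An object of class `cmc_sweep`: list with the `spec` and a
#'   `records` data frame (columns `scenario`, `grid_value`, `replicate`,
#'   `seed`, `terminal_x`, `terminal_y`, `terminal_z`, `classification`,
#'   `convergence_time`, `fluctuation`).
#' @examples
#' sw <- cmc_run_sweep(cmc_scenario("fig4", sigma = 0, steps = 2000))
#' sw$records[, c("grid_value", "terminal_x", "classification")]
#' @export
cmc_run_sweep <- function(spec, tol = 0.05, keep_paths = FALSE) {
  if (!inherits(spec, "cmc_sweep_spec"))
    stop("'spec' must come from cmc_scenario()", call. = FALSE)
  reps <- spec$replicates
  d <- if (spec$model == "two") 2L else 3L
  times <- (0:spec$sim$steps) * spec$sim$h
  rows <- list()
  paths_kept <- if (keep_paths) list()
  for (g in seq_along(spec$grid)) {
    value <- spec$grid[g]
    params <- tryCatch(.sweep_params(spec, value),
                       error = function(e)
                         stop("sweep '", spec$name, "' at ", spec$varied,
                              " = ", value, ": ", conditionMessage(e),
                              call. = FALSE))
    seeds <- spec$sim$seed + (g - 1L) * reps + seq_len(reps)
    paths <- .sim_paths(spec$state0, params, spec$sim, seeds)
    if (keep_paths) paths_kept[[as.character(value)]] <- paths
    for (r in seq_len(reps)) {
      cl <- .classify_path(paths[, r, , drop = TRUE], times, tol = tol)
      term <- paths[spec$sim$steps + 1L, r, ]
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = spec$name, grid_value = value, replicate = r,
        seed = seeds[r],
        terminal_x = term[1L], terminal_y = term[2L],
        terminal_z = if (d == 3L) term[3L] else NA_real_,
        classification = cl$label,
        convergence_time = cl$time, fluctuation = cl$fluctuation)
    }
  }
  structure(list(spec = spec, records = do.call(rbind, rows),
                 paths = paths_kept),
            class = "cmc_sweep")
}

#' @export
print.cmc_sweep <- function(x, ...) {
  cat("CMC sweep '", x$spec$name, "': ", x$spec$varied, " over {",
      paste(x$spec$grid, collapse = ", "), "}\n", sep = "")
  print(x$records[, setdiff(names(x$records), "fluctuation")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Scan a sweep for the threshold grid value of a role
#'
#' Runs the sweep deterministically-minded (meant for `sigma = 0` specs) and
#' returns the smallest grid value whose mean terminal probability for the
#' role exceeds 0.9 (`target = "reaches_one"`), or the largest whose mean
#' terminal falls below 0.1 (`target = "reaches_zero"`). When the qualifying
#' grid values are not a contiguous run at the corresponding end of the grid
#' the result is flagged non-monotone; the extreme value is still reported.
#'
#' @param spec a `cmc_sweep_spec`; `sigma = 0` is recommended so the scan is
#'   deterministic.
#' @param role `"LH"`, `"PHI"`, or `"GD"`.
#' @param target `"reaches_one"` or `"reaches_zero"`.
#' @return List with `value` (the threshold grid value, or `NA` when no grid
#'   value qualifies), `monotone`, and the per-grid mean `terminals`.
#' @examples
#' cmc_threshold_scan(cmc_scenario("fig4", sigma = 0, steps = 2000),
#'                    role = "LH", target = "reaches_one")
#' @export
cmc_threshold_scan <- function(spec, role = c("LH", "PHI", "GD"),
                               target = c("reaches_one", "reaches_zero")) {
  role <- match.arg(role)
  target <- match.arg(target)
  i <- .role_index(role, spec$model)
  sw <- cmc_run_sweep(spec)
  col <- c("terminal_x", "terminal_y", "terminal_z")[i]
  term <- tapply(sw$records[[col]], sw$records$grid_value, mean)
  term <- term[as.character(spec$grid)]  # grid order
  qual <- if (target == "reaches_one") term > 0.9 else term < 0.1
  idx <- unname(which(qual))
  if (length(idx) == 0L)
    return(list(value = NA_real_, monotone = TRUE,
                terminals = stats::setNames(as.numeric(term), spec$grid)))
  monotone <- if (target == "reaches_one")
    identical(idx, seq.int(min(idx), length(spec$grid)))
  else identical(idx, seq_len(max(idx)))
  value <- if (target == "reaches_one") spec$grid[min(idx)]
  else spec$grid[max(idx)]
  list(value = value, monotone = monotone,
       terminals = stats::setNames(as.numeric(term), spec$grid))
}

#' Write sweep records to CSV and a JSON summary
#'
#' @param x a `cmc_sweep`.
#' @param csv path for the per-record CSV (17-significant-digit floats);
#'   `NULL` to skip.
#' @param json path for the per-grid-value JSON summary; `NULL` to skip.
#' @return Invisibly, the list of paths written.
#' @export
write_sweep <- function(x, csv = NULL, json = NULL) {
  stopifnot(inherits(x, "cmc_sweep"))
  if (!is.null(csv)) {
    rec <- x$records
    # classification labels contain commas, so that field is quoted
    lines <- c(
      paste("scenario", "grid_value", "replicate", "seed", "terminal_x",
            "terminal_y", "terminal_z", "classification",
            "convergence_time", sep = ","),
      paste(rec$scenario, .fmt17(rec$grid_value), rec$replicate, rec$seed,
            .fmt17(rec$terminal_x), .fmt17(rec$terminal_y),
            .fmt17(rec$terminal_z),
            paste0('"', rec$classification, '"'),
            .fmt17(rec$convergence_time), sep = ","))
    writeLines(lines, csv)
  }
  if (!is.null(json)) {
    per_value <- lapply(split(x$records, x$records$grid_value), function(df) {
      list(classification = as.list(table(df$classification) / nrow(df)),
           mean_terminal = list(
             x = mean(df$terminal_x), y = mean(df$terminal_y),
             z = if (all(is.na(df$terminal_z))) NULL
                 else mean(df$terminal_z)))
    })
    jsonlite::write_json(
      list(scenario = x$spec$name, varied = x$spec$varied,
           grid = x$spec$grid, replicates = x$spec$replicates,
           base_seed = x$spec$sim$seed, sigma = x$spec$sim$sigma,
           results = per_value),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(csv = csv, json = json))
}
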