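# Configuration files, trajectory CSV round-trips, and run manifests.
#
# Config files are a flat `key = value` dialect (one assignment per line,
# `#` comments): parameter keys exactly the canonical symbols of
# cmc_params(), plus optional simulation-setting keys sigma, h, steps, seed,
# mode, form, noise. Unknown keys are rejected.

.setting_keys <- c("sigma", "h", "steps", "seed", "mode", "form", "noise")

# 17 significant digits: enough for bit-faithful double round-trips
.fmt17 <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) "" else sprintf("%.17g", v), "")
  out
}

.parse_flat_file <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("cannot parse config line (expected 'key = value'): '", ln, "'",
           call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (is.na(num)) val else num
  }
  out
}

#' Read a CMC game configuration file
#'
#' Parses a flat `key = value` configuration file into a validated parameter
#' set and simulation settings. Parameter keys are the canonical symbols of
#' [cmc_params()]; the optional keys `sigma`, `h`, `steps`, `seed`, `mode`,
#' `form`, `noise` override the [cmc_settings()] defaults. Unknown keys are
#' an error.
#'
#' @param path path to the configuration file.
#' @param model game variant the parameters must validate for.
#' @return List with `params` (a [cmc_params]) and `settings`
#'   (a [cmc_settings]).
#' @examples
#' cfg <- system.file("extdata", "baseline_two.toml", package = "cmcgame")
#' read_cmc_config(cfg, model = "two")$params
#' @export
read_cmc_config <- function(path, model = c("two", "three")) {
  model <- match.arg(model)
  raw <- .parse_flat_file(path)
  unknown <- setdiff(names(raw), c(.cmc_symbols("three"), .setting_keys))
  if (length(unknown) > 0L)
    stop("unknown key(s) in ", path, ": ", paste(unknown, collapse = ", "),
         call. = FALSE)
  par_raw <- raw[intersect(names(raw), .cmc_symbols("three"))]
  set_raw <- raw[intersect(names(raw), .setting_keys)]
  params <- cmc_params(par_raw, model = model)
  settings <- do.call(cmc_settings, set_raw)
  list(params = params, settings = settings)
}

#' Write a CMC game configuration file
#'
#' Inverse of [read_cmc_config()]: serialises a parameter set (and
#' optionally simulation settings) as flat `key = value` lines with
#' 17-significant-digit floats, so a reload reproduces the object exactly.
#'
#' @param params a [cmc_params] object.
#' @param path output file path.
#' @param settings optional [cmc_settings] to include.
#' @return `path`, invisibly.
#' @export
write_cmc_config <- function(params, path, settings = NULL) {
  .check_params(params)
  lines <- c(paste("# CMC game parameters (model:", .cmc_model(params), ")"),
             sprintf("%s = %s", names(params), .fmt17(unlist(params))))
  if (!is.null(settings)) {
    .check_settings(settings)
    lines <- c(lines, "",
               sprintf("sigma = %s", .fmt17(settings$sigma)),
               sprintf("h = %s", .fmt17(settings$h)),
               sprintf("steps = %d", settings$steps),
               if (!is.null(settings$seed))
                 sprintf("seed = %d", settings$seed),
               sprintf('mode = "%s"', settings$mode),
               sprintf('form = "%s"', settings$form),
               sprintf('noise = "%s"', settings$noise))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' One row per step with header `step,t,x,y,z`; the `z` column is empty for
#' two-subject trajectories. Floats carry 17 significant digits so that
#' re-parsing reproduces the doubles bit for bit.
#'
#' @param x a `cmc_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(x, path) {
  stopifnot(inherits(x, "cmc_trajectory"))
  df <- as.data.frame(x)
  z <- if ("z" %in% names(df)) .fmt17(df$z) else rep("", nrow(df))
  lines <- c("step,t,x,y,z",
             paste(df$step, .fmt17(df$t), .fmt17(df$x), .fmt17(df$y), z,
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path input file path.
#' @return A data frame with columns `step`, `t`, `x`, `y`[, `z`].
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(step = "integer",
                                             t = "numeric", x = "numeric",
                                             y = "numeric", z = "numeric"))
  if (all(is.na(df$z))) df$z <- NULL
  df
}

#' Write a run manifest
#'
#' Serialises everything needed to reproduce a run bit for bit: command
#' name, resolved argument vector, parameters, settings, seeds, package
#' version, and a timestamp. [cmc_replay()] re-executes a manifest.
#'
#' @param path output JSON path.
#' @param command command name.
#' @param argv resolved CLI argument vector (character).
#' @param params a [cmc_params] or `NULL`.
#' @param settings a [cmc_settings] or `NULL`.
#' @param seeds integer vector of seeds in use.
#' @param outputs character vector of output files the run wrote.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, argv = character(),
                           params = NULL, settings = NULL,
                           seeds = integer(), outputs = character()) {
  jsonlite::write_json(
    list(command = command,
         argv = as.list(argv),
         params = if (!is.null(params)) as.list(unclass(params)),
         model = if (!is.null(params)) .cmc_model(params),
         settings = if (!is.null(settings)) unclass(settings),
         seeds = seeds,
         outputs = as.list(outputs),
         package_version = as.character(utils::packageVersion("cmcgame")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Re-execute a run manifest
#'
#' Re-runs the CLI command recorded in a manifest; for `sigma = 0` and
#' seeded stochastic runs the outputs are reproduced bit for bit.
#'
#' @param manifest path to a manifest JSON written by the CLI.
#' @param outdir directory for the reproduced outputs; defaults to the
#'   manifest's own directory (overwriting the originals).
#' @return Exit status of the replayed command (0 on success).
#' @export
cmc_replay <- function(manifest, outdir = NULL) {
  m <- jsonlite::read_json(manifest)
  argv <- unlist(m$argv)
  if (!is.null(outdir)) {
    i <- which(argv == "--out")
    if (length(i) == 1L)
      argv[i + 1L] <- file.path(outdir, basename(argv[i + 1L]))
  }
  cmc_cli(c(m$command, argv))
}
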