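#' @keywords internal
"_PACKAGE"

# Canonical parameter symbols. Greek letters are case-normalised to ASCII
# config keys: pi (integration coefficient), eps (absorption ratio),
# xi (integration intensity), phi (government support intensity).
.cmc_symbols <- function(model = c("two", "three")) {
  model <- match.arg(model)
  two <- c("I", "U", "Sl", "Tp", "R", "Sp", "D", "v", "pi", "eps", "xi")
  if (model == "two") two else c(two, "Tg", "F", "A", "phi")
}

# symbols constrained to [0, 1]; all others must be strictly positive
.cmc_unit_symbols <- c("v", "pi", "eps", "xi", "phi")

.cmc_param_labels <- c(
  I   = "information integration cost of the lead hospital",
  U   = "medical resources delivered by the lead hospital",
  Sl  = "medical service capacity of the lead hospital",
  Tp  = "information and management authority ceded by primary institutions",
  R   = "performance allocation to primary institutions",
  Sp  = "medical service capacity of primary institutions",
  D   = "loss of primary institutions from decreased attendance",
  v   = "policy effect coefficient of CMC construction",
  pi  = "integration coefficient of CMC information construction",
  eps = "absorption ratio of delivered resources (passive participation)",
  xi  = "intensity factor of information integration",
  Tg  = "portion of authority ceded by government departments",
  F   = "government construction funds",
  A   = "political gains from CMC construction",
  phi = "intensity of government support"
)

#' Validate a county-medical-community game parameter set
#'
#' Builds a validated parameter set for the two-subject game (lead hospital
#' of the CMC vs. primary healthcare institutions) or the tripartite game
#' (adding government departments). Cost/benefit magnitudes (`I`, `U`, `Sl`,
#' `Tp`, `R`, `Sp`, `D`, and for the tripartite game `Tg`, `F`, `A`) must be
#' strictly positive; the dimensionless coefficients `v`, `pi`, `eps`, `xi`
#' (and `phi`) must lie in `[0, 1]`.
#'
#' @param ... named parameter values, or a single named list of them.
#' @param model `"two"` for the two-subject game, `"three"` for the
#'   tripartite game with government departments.
#' @return An object of class `cmc_params`: a named list of the validated
#'   values with a `model` attribute.
#' @examples
#' p <- cmc_params(I = 26, U = 5, Sl = 14, Tp = 12, R = 3, Sp = 2, D = 25,
#'                 v = 0.5, pi = 0.5, eps = 0.5, xi = 0.5, model = "two")
#' p
#' @seealso [cmc_baseline()] for the reference parameterisations.
#' @export
cmc_params <- function(..., model = c("two", "three")) {
  model <- match.arg(model)
  raw <- list(...)
  if (length(raw) == 1L && is.list(raw[[1L]]) &&
      (is.null(names(raw)) || names(raw)[1L] == ""))
    raw <- raw[[1L]]
  syms <- .cmc_symbols(model)
  nm <- names(raw)
  if (is.null(nm) || any(nm == ""))
    stop("all parameters must be named", call. = FALSE)
  unknown <- setdiff(nm, .cmc_symbols("three"))
  if (length(unknown) > 0L)
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(syms, nm)
  if (length(missing) > 0L)
    stop("missing parameter(s) for model '", model, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  # two-subject operations ignore the tripartite extras if supplied
  vals <- raw[syms]
  for (s in syms) {
    val <- vals[[s]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop("parameter '", s, "' must be a single finite number",
           call. = FALSE)
    if (s %in% .cmc_unit_symbols) {
      if (val < 0 || val > 1)
        stop("parameter '", s, "' = ", val,
             " violates its range 0 <= ", s, " <= 1", call. = FALSE)
    } else if (val <= 0) {
      stop("parameter '", s, "' = ", val, " violates its range ", s, " > 0",
           call. = FALSE)
    }
    vals[[s]] <- as.numeric(val)
  }
  structure(vals, model = model, class = "cmc_params")
}

#' Baseline parameterisations of the CMC construction game
#'
#' The reference numerical parameterisation used throughout the simulation
#' analysis: `I = 26`, `U = 5`, `Sl = 14`, `Tp = 12`, `R = 3`, `Sp = 2`,
#' `D = 25`, `v = pi = eps = xi = 0.5`, with `Tg = 6`, `F = 6`, `A = 10`,
#' `phi = 0.5` added for the tripartite game.
#'
#' @inheritParams cmc_params
#' @return A validated [cmc_params] object.
#' @examples
#' cmc_baseline("three")
#' @export
cmc_baseline <- function(model = c("two", "three")) {
  model <- match.arg(model)
  vals <- list(I = 26, U = 5, Sl = 14, Tp = 12, R = 3, Sp = 2, D = 25,
               v = 0.5, pi = 0.5, eps = 0.5, xi = 0.5)
  if (model == "three")
    vals <- c(vals, list(Tg = 6, F = 6, A = 10, phi = 0.5))
  cmc_params(vals, model = model)
}

.cmc_model <- function(params) attr(params, "model")

.check_params <- function(params, model = NULL) {
  if (!inherits(params, "cmc_params"))
    stop("'params' must be a cmc_params object (see cmc_params())",
         call. = FALSE)
  if (!is.null(model) && !identical(.cmc_model(params), model))
    stop("this operation needs a parameter set validated for model '",
         model, "', got '", .cmc_model(params), "'", call. = FALSE)
  invisible(params)
}

#' @export
print.cmc_params <- function(x, ...) {
  model <- .cmc_model(x)
  cat("CMC game parameters (",
      if (model == "two") "two-subject" else "tripartite", " model)\n",
      sep = "")
  w <- max(nchar(names(x)))
  for (s in names(x))
    cat(sprintf("  %-*s = %-8g %s\n", w, s, x[[s]], .cmc_param_labels[[s]]))
  invisible(x)
}

# -- game state --------------------------------------------------------------

# A game state is a named numeric vector c(x =, y =[, z =]) of strategy
# probabilities: x lead hospital efficient construction, y primary
# institutions active participation, z government adequate support.
.check_state <- function(state, model) {
  d <- if (model == "two") 2L else 3L
  if (!is.numeric(state) || length(state) != d)
    stop("state must be a numeric vector of length ", d, " for model '",
         model, "'", call. = FALSE)
  if (any(!is.finite(state)) || any(state < 0) || any(state > 1))
    stop("state components must lie in [0, 1]", call. = FALSE)
  names(state) <- c("x", "y", "z")[seq_len(d)]
  state
}

.role_index <- function(role, model) {
  roles <- if (model == "two") c("LH", "PHI") else c("LH", "PHI", "GD")
  i <- match(role, roles)
  if (is.na(i))
    stop("role must be one of ", paste(roles, collapse = ", "),
         " for model '", model, "'", call. = FALSE)
  i
}
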