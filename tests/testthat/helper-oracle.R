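# Independent oracles, written directly from the game's payoff matrix and
# expectation expressions, deliberately not sharing code with the package.

# pure-strategy payoffs, two-subject game (literal matrix transcription)
oracle_pay2 <- function(lh, phi, p) {
  if (lh == "E" && phi == "A")
    c(-p$I - p$U + (1 + p$pi) * p$Sl + (1 + p$pi) * p$Tp,
      -p$Tp + (1 + p$pi) * p$Sp + (1 + p$v) * p$R + p$U - (1 - p$v) * p$D)
  else if (lh == "E" && phi == "P")
    c(-p$I - p$U + (1 + p$pi) * p$Sl + (1 + p$pi) * p$xi * p$Tp,
      -p$xi * p$Tp + p$Sp + p$eps * p$U - (1 - p$v) * p$D)
  else if (lh == "I" && phi == "A")
    c(-p$xi * (p$I + p$U) + p$Sl + p$Tp,
      -p$Tp + (1 + p$pi) * p$Sp + (1 + p$v) * p$R + p$xi * p$U -
        (1 - p$v) * p$D)
  else
    c(-p$xi * (p$I + p$U) + p$Sl + p$xi * p$Tp,
      -p$xi * p$Tp + p$Sp + p$eps * p$xi * p$U - p$D)
}

# pure-strategy payoffs, tripartite game, transcribed term-by-term from the
# three roles' expectation expressions
oracle_pay3 <- function(lh, phi, gd, p) {
  lh_pay <- if (lh == "E") {
    s <- -p$I - p$U + (1 + p$pi) * p$Sl
    if (phi == "A" && gd == "Ad") s + (1 + p$pi) * p$Tp + p$Tg + p$F
    else if (phi == "A") s + (1 + p$pi) * p$Tp + p$xi * p$Tg + p$phi * p$F
    else if (gd == "Ad") s + (1 + p$pi) * p$xi * p$Tp + p$Tg + p$F
    else s + (1 + p$pi) * p$xi * p$Tp + p$Tg + p$phi * p$F
  } else {
    s <- -p$xi * (p$I + p$U) + p$Sl
    if (phi == "A" && gd == "Ad") s + p$Tp + p$Tg + p$xi * p$F
    else if (phi == "A") s + p$Tp + p$xi * p$Tg + p$phi * p$xi * p$F
    else if (gd == "Ad") s + p$xi * p$Tp + p$Tg + p$xi * p$F
    else s + p$xi * p$Tp + p$Tg + p$phi * p$xi * p$F
  }
  phi_pay <- if (phi == "A") {
    -p$Tp + (1 + p$pi) * p$Sp + (1 + p$v) * p$R +
      (if (lh == "E") p$U else p$xi * p$U) - (1 - p$v) * p$D
  } else {
    s <- -p$xi * p$Tp + p$Sp + p$eps * (if (lh == "E") p$U else p$xi * p$U)
    if (gd == "Ad") s - (1 - p$v) * p$D else s - p$D
  }
  gd_pay <- if (gd == "Ad") {
    if (lh == "I" && phi == "P") -p$Tg - p$F + p$A
    else -p$Tg - p$F + (1 + p$v) * p$A
  } else {
    if (lh == "I" && phi == "P") -p$Tg - p$phi * p$F
    else -p$xi * p$Tg - p$phi * p$F + p$phi * (1 + p$v) * p$A
  }
  c(lh_pay, phi_pay, gd_pay)
}

# brute-force payoff advantage e1 - e2 of a role's aggressive strategy,
# enumerating every pure profile weighted by the co-players' probabilities
oracle_e_diff <- function(state, p, role, model) {
  if (model == "two") {
    x <- state[1]; y <- state[2]
    if (role == "LH") {
      wts <- c(A = y, P = 1 - y)
      sum(vapply(names(wts), function(b)
        wts[[b]] * (oracle_pay2("E", b, p)[1] - oracle_pay2("I", b, p)[1]),
        0))
    } else {
      wts <- c(E = x, I = 1 - x)
      sum(vapply(names(wts), function(l)
        wts[[l]] * (oracle_pay2(l, "A", p)[2] - oracle_pay2(l, "P", p)[2]),
        0))
    }
  } else {
    x <- state[1]; y <- state[2]; z <- state[3]
    wl <- c(E = x, I = 1 - x)
    wp <- c(A = y, P = 1 - y)
    wg <- c(Ad = z, Pr = 1 - z)
    tot <- 0
    if (role == "LH") {
      for (b in names(wp)) for (g in names(wg))
        tot <- tot + wp[[b]] * wg[[g]] *
          (oracle_pay3("E", b, g, p)[1] - oracle_pay3("I", b, g, p)[1])
    } else if (role == "PHI") {
      for (l in names(wl)) for (g in names(wg))
        tot <- tot + wl[[l]] * wg[[g]] *
          (oracle_pay3(l, "A", g, p)[2] - oracle_pay3(l, "P", g, p)[2])
    } else {
      for (l in names(wl)) for (b in names(wp))
        tot <- tot + wl[[l]] * wp[[b]] *
          (oracle_pay3(l, b, "Ad", p)[3] - oracle_pay3(l, b, "Pr", p)[3])
    }
    tot
  }
}

# random valid parameter draws within the stated ranges
random_params <- function(model = "two") {
  vals <- list(I = runif(1, 1, 40), U = runif(1, 0.5, 12),
               Sl = runif(1, 1, 25), Tp = runif(1, 1, 30),
               R = runif(1, 0.5, 8), Sp = runif(1, 0.5, 8),
               D = runif(1, 1, 40), v = runif(1), pi = runif(1),
               eps = runif(1), xi = runif(1))
  if (model == "three")
    vals <- c(vals, list(Tg = runif(1, 0.5, 15), F = runif(1, 0.5, 15),
                         A = runif(1, 1, 20), phi = runif(1)))
  cmc_params(vals, model = model)
}

roles_for <- function(model) {
  if (model == "two") c("LH", "PHI") else c("LH", "PHI", "GD")
}

state_grid <- function(model, n = 5) {
  g <- seq(0, 1, length.out = n)
  d <- if (model == "two") 2 else 3
  m <- as.matrix(expand.grid(rep(list(g), d)))
  dimnames(m) <- NULL
  m
}
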