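test_that("two-subject payoff cells match hand-evaluated matrix entries", {
  p <- cmc_baseline("two")
  expect_equal(cmc_payoff(p, "efficient", "active"),
               c(LH = 8, PHI = -12))
  expect_equal(cmc_payoff(p, "inefficient", "passive"),
               c(LH = 4.5, PHI = -27.75))
  expect_error(cmc_payoff(p, "efficient", "active", gd = "adequate"),
               "absent")
})

test_that("lead-hospital payoff is strategy-invariant at pi = 0, xi = 1", {
  # the efficient and inefficient cells coincide symbolically there
  vals <- unclass(cmc_baseline("two"))
  vals$pi <- 0; vals$xi <- 1
  p <- cmc_params(vals, model = "two")
  expect_equal(cmc_payoff(p, "efficient", "active")[["LH"]],
               cmc_payoff(p, "inefficient", "active")[["LH"]])
})

test_that("tripartite payoff cells match the expectation-expression terms", {
  p <- cmc_baseline("three")
  expect_equal(cmc_payoff(p, "efficient", "active", "adequate"),
               c(LH = 20, PHI = -12, GD = 3))
  expect_equal(
    cmc_payoff(p, "inefficient", "passive", "adequate")[["GD"]], -2)
  expect_error(cmc_payoff(p, "efficient", "active"), "required")

  # at phi = 1 the prudent-support government payoff with both partners
  # aggressive collapses to -xi*Tg - F + (1+v)*A
  vals <- unclass(p); vals$phi <- 1
  p1 <- cmc_params(vals, model = "three")
  expect_equal(cmc_payoff(p1, "efficient", "active", "prudent")[["GD"]],
               -p1$xi * p1$Tg - p1$F + (1 + p1$v) * p1$A)
})

test_that("payoffs are affine in each magnitude parameter", {
  # doubling a magnitude parameter moves the payoff by exactly its
  # symbolic coefficient: pay(2s) - pay(s) == pay(3s) - pay(2s)
  set.seed(11)
  for (model in c("two", "three")) {
    p <- random_params(model)
    syms <- c("I", "U", "Sl", "Tp", "R", "Sp", "D",
              if (model == "three") c("Tg", "F", "A"))
    profile <- if (model == "two") list("inefficient", "passive")
               else list("inefficient", "passive", "prudent")
    for (sym in syms) {
      scale_pay <- function(k) {
        vals <- unclass(p); vals[[sym]] <- k * vals[[sym]]
        do.call(cmc_payoff, c(list(cmc_params(vals, model = model)),
                              profile))
      }
      d1 <- scale_pay(2) - scale_pay(1)
      d2 <- scale_pay(3) - scale_pay(2)
      expect_equal(d1, d2, tolerance = 1e-12,
                   label = paste("affine in", sym, model))
    }
  }
})

test_that("expected payoffs reduce to payoff cells at pure co-player states", {
  p <- cmc_baseline("two")
  expect_equal(cmc_expected_payoffs(c(0.3, 1), p, "LH")$e1, 8)
  expect_equal(cmc_expected_payoffs(c(0.3, 0), p, "LH")$e1, -1)
})

test_that("mean expected payoff obeys p*e1 + (1-p)*e2 and pins to e1 at p=1", {
  set.seed(21)
  for (model in c("two", "three")) {
    for (rep in 1:25) {
      p <- random_params(model)
      st <- runif(if (model == "two") 2 else 3)
      for (role in roles_for(model)) {
        ep <- cmc_expected_payoffs(st, p, role)
        own <- st[match(role, roles_for(model))]
        expect_equal(ep$mean, own * ep$e1 + (1 - own) * ep$e2,
                     tolerance = 1e-12)
      }
      st[1] <- 1
      ep <- cmc_expected_payoffs(st, p, "LH")
      expect_identical(ep$mean, ep$e1)
    }
  }
})

test_that("payoff advantage matches brute-force enumeration over pure profiles", {
  # oracle equivalence: e1 - e2 against an independent enumeration of all
  # pure profiles weighted by co-player probabilities, 200 random draws
  set.seed(31)
  for (rep in 1:200) {
    model <- if (rep %% 2 == 0) "two" else "three"
    p <- random_params(model)
    grid <- state_grid(model, n = 5)
    worst <- 0
    for (i in seq_len(nrow(grid))) {
      st <- grid[i, ]
      for (role in roles_for(model)) {
        ep <- cmc_expected_payoffs(st, p, role)
        worst <- max(worst,
                     abs(ep$e1 - ep$e2 - oracle_e_diff(st, p, role, model)))
      }
    }
    expect_lt(worst, 1e-12)
  }
})
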