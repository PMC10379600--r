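test_that("Brownian increments follow N(0, h) and honour the seed contract", {
  w <- cmc_brownian(100000, h = 0.01, seed = 7, roles = 1)
  inc <- as.numeric(w$increments)
  expect_lt(abs(mean(inc)), 4 * sqrt(0.01 / 100000))
  expect_lt(abs(var(inc) - 0.01) / 0.01, 0.01)

  w2 <- cmc_brownian(100000, h = 0.01, seed = 7, roles = 1)
  expect_identical(w$increments, w2$increments)
  w3 <- cmc_brownian(100000, h = 0.01, seed = 8, roles = 1)
  expect_false(identical(w$increments, w3$increments))
  expect_error(cmc_brownian(10, h = 0, seed = 1), "h")
})

test_that("increment generation does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(cmc_brownian(10, h = 0.01, seed = 1))
  expect_identical(runif(1), a)
})

test_that("zero noise reproduces the deterministic integrator exactly", {
  p <- cmc_baseline("two")
  det <- cmc_integrate(c(0.5, 0.5), p, steps = 2000)
  sto <- cmc_simulate(c(0.5, 0.5), p,
                      cmc_settings(sigma = 0, steps = 2000, seed = 3))
  expect_identical(det$x, sto$x)
  expect_identical(det$y, sto$y)
})

test_that("seeded stochastic runs are bit-reproducible and seed-sensitive", {
  p <- cmc_baseline("three")
  s <- cmc_settings(sigma = 0.1, steps = 1000, seed = 17)
  t1 <- cmc_simulate(c(0.5, 0.5, 0.5), p, s)
  t2 <- cmc_simulate(c(0.5, 0.5, 0.5), p, s)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  s2 <- cmc_settings(sigma = 0.1, steps = 1000, seed = 18)
  t3 <- cmc_simulate(c(0.5, 0.5, 0.5), p, s2)
  expect_false(identical(t1$x, t3$x))
})

test_that("the x = 0 boundary is absorbing under multiplicative noise", {
  p <- cmc_baseline("two")
  tr <- cmc_simulate(c(0, 0.5), p,
                     cmc_settings(sigma = 0.5, steps = 500, seed = 5))
  expect_true(all(tr$x == 0))
})

test_that("states stay inside the unit cube for all noise intensities", {
  set.seed(61)
  for (sigma in c(0, 0.05, 0.2, 1.0)) {
    model <- sample(c("two", "three"), 1)
    p <- random_params(model)
    d <- if (model == "two") 2 else 3
    tr <- cmc_simulate(runif(d), p,
                       cmc_settings(sigma = sigma, steps = 1000,
                                    seed = sample.int(1000, 1)))
    m <- as.matrix(as.data.frame(tr)[, -(1:2)])
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("stochastic runs stay near the deterministic attractor at small noise", {
  # moderate disturbance of the (1,1) attractor: terminal within 0.1 of the
  # vertex for at least 90% of 50 seeded replicates
  p <- cmc_baseline("two")
  es <- cmc_ensemble(c(0.5, 0.5), p,
                     cmc_settings(sigma = 0.05, h = 0.01, steps = 20000),
                     replicates = 50, base_seed = 100)
  near <- rowSums(abs(sweep(es$terminals, 2, c(1, 1))) <= 0.1) == 2
  expect_gte(mean(near), 0.9)
})

test_that("ensemble replicates reproduce single seeded runs and their mean", {
  p <- cmc_baseline("two")
  s <- cmc_settings(sigma = 0.05, steps = 500)
  es <- cmc_ensemble(c(0.5, 0.5), p, s, replicates = 1, base_seed = 7)
  single <- cmc_simulate(c(0.5, 0.5), p,
                         cmc_settings(sigma = 0.05, steps = 500, seed = 8))
  expect_identical(es$mean_path$x, single$x)
  expect_identical(es$mean_path$y, single$y)
  expect_identical(unname(es$terminals[1, ]), unname(terminal(single)))

  # sigma = 0: identical replicates concentrate all mass on one vertex
  es0 <- cmc_ensemble(c(0.5, 0.5), p, cmc_settings(sigma = 0, steps = 5000),
                      replicates = 5, base_seed = 1)
  expect_identical(es0$convergence_fraction, c("(1,1)" = 1))
})

test_that("tripartite ensemble concentrates on the all-aggressive vertex", {
  p <- cmc_baseline("three")
  es <- cmc_ensemble(c(0.5, 0.5, 0.5), p,
                     cmc_settings(sigma = 0.05, steps = 10000),
                     replicates = 50, base_seed = 100)
  expect_identical(names(which.max(es$convergence_fraction)), "(1,1,1)")
})

test_that("ensemble mean terminals approach the deterministic limit as noise shrinks", {
  p <- cmc_baseline("two")
  det <- terminal(cmc_integrate(c(0.5, 0.5), p, steps = 4000))
  gaps <- vapply(c(0.2, 0.1, 0.05, 0.025), function(s) {
    es <- cmc_ensemble(c(0.5, 0.5), p,
                       cmc_settings(sigma = s, steps = 4000),
                       replicates = 30, base_seed = 500)
    max(abs(es$mean_terminal - det))
  }, 0)
  expect_true(all(diff(gaps) <= 0.05))
})

test_that("shared-noise streams apply one increment to every role", {
  p <- cmc_baseline("two")
  s <- cmc_settings(sigma = 0.3, steps = 5, seed = 4, noise = "shared")
  tr <- cmc_simulate(c(0.5, 0.5), p, s)
  w <- cmc_brownian(5, h = 0.01, seed = 4, roles = 1)
  d <- cmc_drift(c(0.5, 0.5), p)
  step1 <- c(0.5, 0.5) + d$drifts * 0.01 + 0.3 * c(0.5, 0.5) *
    w$increments[1, 1]
  expect_equal(c(tr$x[2], tr$y[2]), unname(step1))
})
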