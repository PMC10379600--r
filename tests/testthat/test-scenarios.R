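# frozen reference table for the preset experiments
.expected_presets <- list(
  fig2 = list(model = "two", varied = "Tp", grid = c(5, 10, 15, 20, 25)),
  fig3 = list(model = "two", varied = "pi",
              grid = c(0.1, 0.3, 0.5, 0.7, 0.9)),
  fig4 = list(model = "two", varied = "xi",
              grid = c(0.1, 0.3, 0.5, 0.7, 0.9)),
  fig5 = list(model = "two", varied = "U", grid = c(1, 3, 5, 7, 9)),
  fig6 = list(model = "three", varied = "Tp+Tg", grid = c(5, 10, 15, 20, 25)),
  fig7 = list(model = "three", varied = "v", grid = c(0.1, 0.3, 0.5, 0.7, 0.9)),
  fig8 = list(model = "three", varied = "phi",
              grid = c(0.1, 0.3, 0.5, 0.7, 0.9))
)

.frozen_baseline <- list(I = 26, U = 5, Sl = 14, Tp = 12, R = 3, Sp = 2,
                         D = 25, v = 0.5, pi = 0.5, eps = 0.5, xi = 0.5,
                         Tg = 6, F = 6, A = 10, phi = 0.5)

test_that("every preset carries the frozen baselines and grids", {
  for (name in names(.expected_presets)) {
    sc <- cmc_scenario(name)
    exp <- .expected_presets[[name]]
    expect_identical(sc$model, exp$model, label = name)
    expect_identical(sc$varied, exp$varied, label = name)
    expect_equal(sc$grid, exp$grid, label = name)
    syms <- names(unclass(sc$baseline))
    expect_identical(unclass(sc$baseline)[syms],
                     .frozen_baseline[syms], label = name)
  }
  expect_error(cmc_scenario("fig9"), "unknown scenario")
})

test_that("the composite authority sweep splits 2:1 between Tp and Tg", {
  sc <- cmc_scenario("fig6")
  p <- cmcgame:::.sweep_params(sc, 18)
  expect_equal(p$Tp, 12)
  expect_equal(p$Tg, 6)
  expect_equal(p$Tp / p$Tg, unclass(sc$baseline)$Tp / unclass(sc$baseline)$Tg)
})

test_that("deterministic sweep outcomes match the expected attractors", {
  sw2 <- cmc_run_sweep(cmc_scenario("fig2", sigma = 0))
  expect_identical(
    sw2$records$classification[sw2$records$grid_value == 5], "(0,1)")

  sw4 <- cmc_run_sweep(cmc_scenario("fig4", sigma = 0))
  expect_identical(
    sw4$records$classification[sw4$records$grid_value == 0.9], "(1,1)")

  sw8 <- cmc_run_sweep(cmc_scenario("fig8", sigma = 0))
  expect_lt(sw8$records$terminal_z[sw8$records$grid_value == 0.9], 0.5)
})

test_that("threshold scans recover the integration-intensity bracket", {
  sc <- cmc_scenario("fig4", sigma = 0)
  up <- cmc_threshold_scan(sc, role = "LH", target = "reaches_one")
  expect_equal(up$value, 0.5)
  expect_true(up$monotone)
  down <- cmc_threshold_scan(sc, role = "LH", target = "reaches_zero")
  expect_equal(down$value, 0.3)
  expect_true(down$monotone)
})

test_that("primary institutions participate at every integration coefficient", {
  sc <- cmc_scenario("fig3", sigma = 0)
  res <- cmc_threshold_scan(sc, role = "PHI", target = "reaches_one")
  expect_equal(res$value, 0.1)
  expect_true(all(res$terminals > 0.9))
})

test_that("deterministic sweeps are exactly rerun-stable and monotone", {
  sc <- cmc_scenario("fig4", sigma = 0)
  a <- cmc_run_sweep(sc)
  b <- cmc_run_sweep(sc)
  expect_identical(a$records, b$records)
  expect_true(all(diff(a$records$terminal_x) >= 0))

  sw8 <- cmc_run_sweep(cmc_scenario("fig8", sigma = 0))
  expect_true(all(diff(sw8$records$terminal_z) <= 0))
})

test_that("out-of-range grid values are rejected with the grid annotation", {
  sc <- cmc_scenario("fig3", sigma = 0)
  sc$grid <- c(0.5, 1.5)
  expect_error(cmc_run_sweep(sc), "pi = 1.5")
})

test_that("sweep export round-trips records and writes a JSON summary", {
  sw <- cmc_run_sweep(cmc_scenario("fig4", sigma = 0, steps = 2000))
  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  write_sweep(sw, csv = csv, json = json)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(sw$records))
  expect_identical(back$terminal_x, sw$records$terminal_x)
  js <- jsonlite::read_json(json)
  expect_identical(js$scenario, "fig4")
  expect_equal(length(js$results), 5)
})
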