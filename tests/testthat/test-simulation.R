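test_that("synthetic populations match their generating models", {
  pop <- generate_population(population_model("exponential"), seed = 2)
  expect_equal(attr(pop, "N"), 1000L)
  expect_true(all(pop$x >= 0))
  expect_equal(unname(attr(pop, "Nh")), c(500L, 500L))

  popu <- generate_population(population_model("uniform"), seed = 3)
  expect_true(all(popu$x >= 17 & popu$x <= 24))
  # rho = 0: y is pure standard-normal noise
  expect_equal(median(popu$y), 0, tolerance = 0.15)
  expect_equal(abs(cor(popu$y, popu$x)), 0, tolerance = 0.1)

  # reproducibility
  expect_identical(generate_population(population_model("gamma"), seed = 9)$x,
                   generate_population(population_model("gamma"), seed = 9)$x)
  expect_error(population_model("gamma", params = c(shape = -1)), "invalid")
  expect_error(population_model("weibull"))
})

test_that("percent relative efficiency follows its definition", {
  expect_equal(pre(2, 1), 200)
  expect_equal(pre(1.7, 1.7), 100)
  expect_equal(pre(1, 4), 25)
  expect_error(pre(1, 0), "positive")
})

test_that("Monte Carlo tables are reproducible and baseline-normalised", {
  pop <- generate_population(population_model("gamma"), seed = 12)
  d <- design_spec(attr(pop, "Nh"), mh = 60, nh = 20)
  ests <- c("baseline", "ratio", "exp_ratio", "E6")
  a <- run_monte_carlo(pop, d, estimators = ests, U = 50, master_seed = 77)
  b <- run_monte_carlo(pop, d, estimators = ests, U = 50, master_seed = 77)
  expect_identical(a$mse, b$mse)
  expect_equal(a$pre[a$estimator == "baseline"], 100)
  expect_true(all(a$mse >= 0))
  # registry-order independence of the replication streams
  c2 <- run_monte_carlo(pop, d, estimators = rev(ests), U = 50, master_seed = 77)
  expect_equal(sort(c2$mse), sort(a$mse))
  # a different master seed moves the estimates
  expect_false(identical(
    run_monte_carlo(pop, d, estimators = "baseline", U = 50, master_seed = 78)$mse,
    a$mse[a$estimator == "baseline"]))
})

test_that("a census design removes all sampling variability", {
  pop <- generate_population(population_model("uniform"), seed = 5, L = 2)
  Nh <- attr(pop, "Nh")
  d <- design_spec(Nh, mh = Nh, nh = Nh - 1L)
  res <- run_monte_carlo(pop, d, estimators = "baseline", U = 20,
                         master_seed = 1)
  # nh = Nh - 1 still pins the stratum median to within the middle pair;
  # the empirical MSE must be far below the theoretical SRS variance
  strat_med <- sum(Nh / sum(Nh) * tapply(pop$y, pop$stratum, median))
  expect_lt(res$mse, 0.01)
  expect_equal(res$pre, 100)
})

test_that("per-design constants are computed once from the population", {
  pop <- generate_population(population_model("gamma"), seed = 30)
  designs <- allocate(2, L = 2, Nh = attr(pop, "Nh"))[1:2]
  res <- run_monte_carlo(pop, designs, estimators = c("baseline", "D1"),
                         U = 30, master_seed = 4)
  expect_equal(nrow(res), 4L)
  expect_setequal(unique(res$m), c(200L, 300L))
})
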