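# samples with exactly controlled phase medians: odd-length vectors whose
# middle order statistic is the target
vec_med <- function(m, n = 5) m + seq(-(n - 1) / 2, (n - 1) / 2)

one_stratum <- function(My = 10, Mx2 = 4, Mx1 = 5) {
  fake_sample(`1` = list(x1 = vec_med(Mx1), y2 = vec_med(My), x2 = vec_med(Mx2)))
}

test_that("baseline is the weighted stratum median", {
  d1 <- unit_design()
  expect_equal(estimate_baseline(one_stratum(), d1)$estimate, 10)
  s2 <- fake_sample(`1` = list(x1 = 1:3, y2 = vec_med(10), x2 = 1:3),
                    `2` = list(x1 = 1:3, y2 = vec_med(20), x2 = 1:3))
  expect_equal(estimate_baseline(s2, unit_design(2))$estimate, 15)
  expect_equal(estimate_baseline(fake_sample(`1` = list(x1 = 1:3, y2 = c(3, 1, 2), x2 = 1:3)),
                                 d1)$estimate, 2)
  expect_equal(sample_median(c(1, 2, 3, 4)), 2.5)
  expect_equal(sample_median(7), 7)
})

test_that("ratio estimator honours both orientations", {
  s <- one_stratum()  # My=10, Mx_hat=4, Mx_acute=5
  d <- unit_design()
  expect_equal(estimate_ratio(s, d)$estimate, 10 * 5 / 4)
  expect_equal(estimate_ratio(s, d, "as_printed")$estimate, 10 * 4 / 5)
  # collapses to baseline when the phase medians coincide
  s0 <- one_stratum(Mx2 = 5, Mx1 = 5)
  expect_equal(estimate_ratio(s0, d)$estimate, 10)
  # invariant under x -> c x
  sc <- fake_sample(`1` = list(x1 = 3 * vec_med(5), y2 = vec_med(10),
                               x2 = 3 * vec_med(4)))
  expect_equal(estimate_ratio(sc, d)$estimate, estimate_ratio(s, d)$estimate)
})

test_that("difference estimators follow the printed brackets", {
  s <- one_stratum()
  d <- unit_design()
  expect_equal(estimate_difference(s, d, "D1", list(d1 = 2))$estimate,
               10 + 2 * (5 - 4))
  expect_equal(estimate_difference(s, d, "D2", list(d2 = 1, d3 = 0))$estimate, 10)
  expect_equal(estimate_difference(s, d, "D3", list(d4 = 2, d5 = 3))$estimate,
               (2 * 10 + 3 * 1) * 5 / 4)
  expect_equal(estimate_difference(s, d, "D4", list(d6 = 2, d7 = 3))$estimate,
               (2 * 10 + 3 * 1) * 1 / 9)
  # no difference term when the phase medians agree
  s0 <- one_stratum(Mx2 = 5, Mx1 = 5)
  expect_equal(estimate_difference(s0, d, "D1", list(d1 = 77))$estimate, 10)
  expect_error(estimate_difference(s, d, "D2", list(d2 = 1)), "missing constants")
})

test_that("exponential estimators follow the printed exponents", {
  s <- fake_sample(`1` = list(x1 = vec_med(6), y2 = vec_med(10), x2 = vec_med(4)))
  d <- unit_design()
  expect_equal(estimate_exponential(s, d, "ratio")$estimate, 10 * exp(0.2))
  expect_equal(estimate_exponential(s, d, "product")$estimate, 10 * exp(-0.2))
  # exp(a) exp(-a) = 1: ratio * product = baseline^2 for a single stratum
  expect_equal(estimate_exponential(s, d, "ratio")$estimate *
                 estimate_exponential(s, d, "product")$estimate, 100)
  s0 <- one_stratum(Mx2 = 5, Mx1 = 5)
  expect_equal(estimate_exponential(s0, d, "ratio")$estimate, 10)
})

test_that("proposed family reduces and limits correctly", {
  d <- unit_design()
  s <- one_stratum()  # Mx_hat=4, Mx_acute=5
  # symmetric spec cancels exactly
  sym <- transform_spec(1, 0, 1, 0, Mx = 4.5)
  expect_equal(estimate_proposed(s, d, sym)$estimate, 10)
  # k2 -> 0 leaves the first exponent only: 10 exp((4-5)/9)
  lim <- transform_spec(1, 0, 1, 1e14, Mx = 4.5)
  expect_equal(estimate_proposed(s, d, lim)$estimate, 10 * exp(-1 / 9),
               tolerance = 1e-10)
  # any spec collapses to baseline when the phase medians coincide
  s0 <- one_stratum(Mx2 = 5, Mx1 = 5)
  set.seed(42)
  for (i in 1:20) {
    sp <- transform_spec(runif(1, 0.1, 5), runif(1, 0, 5),
                         runif(1, 0.1, 5), runif(1, 0, 5), Mx = runif(1, 1, 9))
    expect_equal(estimate_proposed(s0, d, sp)$estimate, 10)
  }
})

test_that("catalogue variants reproduce the hand-coded closed forms", {
  set.seed(8)
  pop <- generate_population(population_model("exponential"), seed = 21, L = 2)
  d <- design_spec(attr(pop, "Nh"), mh = 60, nh = 20)
  smp <- draw_two_phase_sample(pop, d, seed = 9)
  med <- stratum_sample_medians(smp)
  aux <- split(pop$x, pop$stratum)
  tr <- build_transforms(aux, variants = c(1, 6))
  # hand-coded variant formulas, written directly from the published rows
  hand <- function(h, t1, t2, t4) {
    a <- med$Mx_hat[h]; b <- med$Mx_acute[h]
    med$My_hat[h] *
      exp(t1 * (a - b) / (t1 * (b + a) + 2 * t2)) *
      exp((b - a) / ((b + a) + 2 * t4))
  }
  qs <- lapply(aux, quantile_summary)
  e1_hand <- sum(d$Wh * sapply(1:2, function(h)
    hand(h, qs[[h]]$QD, qs[[h]]$MAD, qs[[h]]$max - qs[[h]]$min)))
  e6_hand <- sum(d$Wh * sapply(1:2, function(h)
    hand(h, qs[[h]]$QA, qs[[h]]$sigma, qs[[h]]$QD)))
  expect_equal(estimate_proposed(smp, d, tr$E1, "E1")$estimate, e1_hand)
  expect_equal(estimate_proposed(smp, d, tr$E6, "E6")$estimate, e6_hand)
})

test_that("estimates are y-scale equivariant and permutation invariant", {
  pop <- generate_population(population_model("gamma"), seed = 5, L = 2)
  d <- design_spec(attr(pop, "Nh"), mh = 40, nh = 15)
  smp <- draw_two_phase_sample(pop, d, seed = 2)
  ests <- c("baseline", "ratio", "exp_ratio", "exp_product", "E2")
  fit <- twophase_median(smp, d, estimators = ests, pop = pop)
  # scale y by c > 0
  smp_c <- smp
  for (h in seq_along(smp_c)) smp_c[[h]]$y2 <- 3 * smp_c[[h]]$y2
  fit_c <- twophase_median(smp_c, d, estimators = ests, pop = pop)
  expect_equal(coef(fit_c), 3 * coef(fit))
  # permute within strata
  smp_p <- smp
  for (h in seq_along(smp_p)) {
    o1 <- sample(seq_along(smp_p[[h]]$x1))
    o2 <- sample(seq_along(smp_p[[h]]$y2))
    smp_p[[h]]$x1 <- smp_p[[h]]$x1[o1]
    smp_p[[h]]$y2 <- smp_p[[h]]$y2[o2]
    smp_p[[h]]$x2 <- smp_p[[h]]$x2[o2]
  }
  fit_p <- twophase_median(smp_p, d, estimators = ests, pop = pop)
  expect_equal(coef(fit_p), coef(fit))
})
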