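test_that("sample quantiles follow the interpolation convention", {
  v <- c(2, 4, 6, 8, 10, 12, 14, 16, 18)
  expect_equal(sample_quantile(v, 0.5), 10)
  expect_equal(sample_quantile(v, 0.25), 6)   # position 1 + 0.25*8 = 3
  expect_equal(sample_quantile(rep(7, 3), 0.3), 7)
  # monotone in p
  ps <- sort(runif(20, 0.01, 0.99))
  expect_true(all(diff(sample_quantile(v, ps)) >= 0))
  expect_error(sample_quantile(numeric(0), 0.5), "no data")
  expect_error(sample_quantile(c(1, NA), 0.5), "non-finite")
  expect_error(sample_quantile(v, 0), "inside")
})

test_that("quantile summary matches hand-computed values on the toy set", {
  s <- quantile_summary(c(2, 4, 6, 8, 10, 12, 14, 16, 18))
  expect_equal(s$Q1, 6)
  expect_equal(s$Q3, 14)
  expect_equal(s$IQR, 8)
  expect_equal(s$QD, 4)
  expect_equal(s$QA, 10)
  expect_equal(s$TM, 10)
  expect_equal(s$MR, 10)
  expect_equal(s$DM, 10)
  expect_equal(s$MAD, 4)
  expect_equal(s$PM, sqrt(84))
  expect_equal(s$Sk, 0)
})

test_that("degenerate and tiny inputs are handled", {
  s <- quantile_summary(rep(5, 7))
  expect_equal(c(s$median, s$QA, s$TM, s$DM, s$MR), rep(5, 5))
  expect_equal(c(s$IQR, s$QD, s$MAD, s$sigma), rep(0, 4))
  expect_true(is.na(s$Sk))  # skewness undefined at zero spread
  expect_equal(quantile_summary(c(1, 2, 3, 4, 5))$MAD, 1)
  expect_true(is.na(quantile_summary(c(-3, -1, 2, 5))$PM))  # Q1*Q3 < 0
  expect_true(is.na(quantile_summary(7)$sigma))
})

test_that("all summary fields agree with the sort-based oracle", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(3:200, 1)
    v <- switch(1 + i %% 3,
                rnorm(n, sd = 10), rexp(n) * 50, runif(n, -5, 5))
    s <- quantile_summary(v)
    b <- brute_summary(v)
    for (f in names(b)) expect_equal(s[[f]], b[[f]], tolerance = 1e-12)
  }
})

test_that("location/scale measures have the right equivariance", {
  set.seed(7)
  v <- rexp(37) * 10
  a <- 3.7; b <- -12
  s0 <- quantile_summary(v)
  s1 <- quantile_summary(a * v + b)
  for (f in c("median", "QA", "TM", "DM", "MR")) {
    expect_equal(s1[[f]], a * s0[[f]] + b, tolerance = 1e-12)
  }
  for (f in c("IQR", "QD", "MAD", "sigma")) {
    expect_equal(s1[[f]], a * s0[[f]], tolerance = 1e-12)
  }
  expect_equal(s1$Sk, s0$Sk, tolerance = 1e-12)
  expect_equal(quantile_summary(-v)$Sk, -s0$Sk, tolerance = 1e-12)
})

test_that("shrink factors follow the k-definition", {
  expect_equal(transform_spec(1, 0, 1, 1, Mx = 5)$k1, 1)
  s <- quantile_summary(c(2, 4, 6, 8, 10, 12, 14, 16, 18))
  tr <- make_transform(s, Mx = 10, variant_id = 1)
  expect_equal(tr$k1, 40 / 44)               # QD*Mx/(QD*Mx + MAD)
  expect_equal(tr$k2, 10 / 26)               # Mx/(Mx + (max - min))
  expect_lt(transform_spec(1, 0, 1, 1e12, Mx = 5)$k2, 1e-10)
  # k increasing in t1*Mx, decreasing in t2
  k <- function(t1, t2, Mx) transform_spec(t1, t2, 1, 1, Mx)$k1
  expect_true(k(2, 1, 5) > k(1, 1, 5))
  expect_true(k(1, 2, 5) < k(1, 1, 5))
  expect_error(transform_spec(1, -5, 1, 1, Mx = 5), "degenerate transform")
  expect_error(make_transform(s, Mx = -1, variant_id = 1), "positive")
})

test_that("the transformation catalogue fills the printed rows", {
  set.seed(11)
  v <- rexp(60) * 8 + 1
  s <- quantile_summary(v)
  Mx <- s$median
  rows <- list(
    `1` = c(s$QD, s$MAD, 1, s$max - s$min),
    `2` = c(s$TM, s$MR, 1, s$IQR),
    `3` = c(s$DM, s$MAD, 1, s$QD),
    `4` = c(s$Sk, 1, 1, s$Q3 - s$Q2),
    `6` = c(s$QA, s$sigma, 1, s$QD),
    `7` = c(s$median, s$IQR, 1, s$MAD),
    `8` = c(s$Q1 * s$Q3, s$max * s$min, 1, s$IQR)
  )
  for (id in names(rows)) {
    tr <- make_transform(s, Mx, as.integer(id))
    expect_equal(c(tr$t1, tr$t2, tr$t3, tr$t4), rows[[id]],
                 info = paste("variant", id))
  }
  t5 <- make_transform(s, Mx, 5)
  expect_equal(c(t5$t1, t5$t2, t5$t4),
               log(c(s$Q3 + 1, s$Q1 + 1, s$MR + 1)))
  t5m <- make_transform(s, Mx, 5, e5_log_shift = "minus1")
  expect_equal(t5m$t1, log(s$Q3 - 1))
  expect_error(make_transform(quantile_summary(c(0.1, 0.2, 0.3, 0.4)),
                              Mx = 0.25, variant_id = 5,
                              e5_log_shift = "minus1"),
               "variant 5")
})
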