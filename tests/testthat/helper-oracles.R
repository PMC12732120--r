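# Brute-force oracles and generators shared across the suite.

# Sort-based quantile oracle: linear interpolation at position 1 + p(n-1),
# written independently of stats::quantile.
brute_quantile <- function(values, p) {
  s <- sort(values)
  n <- length(s)
  pos <- 1 + p * (n - 1)
  lo <- floor(pos)
  hi <- ceiling(pos)
  s[lo] + (pos - lo) * (s[hi] - s[lo])
}

brute_median <- function(values) {
  s <- sort(values)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# every quantile-summary field from first principles
brute_summary <- function(v) {
  n <- length(v)
  q1 <- brute_quantile(v, 0.25); q2 <- brute_median(v); q3 <- brute_quantile(v, 0.75)
  dec <- sapply(1:9 / 10, function(p) brute_quantile(v, p))
  mu <- sum(v) / n
  sg <- sqrt(sum((v - mu)^2) / n)
  list(
    Q1 = q1, Q2 = q2, Q3 = q3, deciles = dec,
    IQR = q3 - q1, QD = (q3 - q1) / 2, QA = (q1 + q3) / 2,
    TM = (q1 + 2 * q2 + q3) / 4, DM = sum(dec) / 9,
    MAD = brute_median(abs(v - q2)), MR = (max(v) + min(v)) / 2,
    sigma = sg,
    Sk = if (sg > 0) sum((v - mu)^3) / n / sg^3 else NA_real_,
    PM = if (q1 * q3 >= 0) sqrt(q1 * q3) else NA_real_
  )
}

# random single- or multi-stratum moment model with a valid design
random_moments <- function(L = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Nh <- sample(50:400, L, replace = TRUE)
  mh <- pmax(4L, floor(Nh * runif(L, 0.2, 0.8)))
  nh <- pmax(2L, floor(mh * runif(L, 0.2, 0.8)))
  nh <- pmin(nh, mh - 1L)
  d <- design_spec(Nh, mh, nh)
  moment_model(
    My = runif(L, 1, 100), Mx = runif(L, 1, 100),
    CMy = runif(L, 0.1, 2), CMx = runif(L, 0.1, 2),
    rho = runif(L, -0.9, 0.9),
    theta1 = d$theta1, theta3 = d$theta3, Wh = d$Wh
  )
}

# hand-built two-phase sample object with prescribed values (for estimator
# formula tests that need exact control over the phase medians)
fake_sample <- function(...) {
  strata <- list(...)
  structure(strata, class = "twophase_sample")
}

# single-stratum design with weight 1 (sizes only need to satisfy nh < mh <= Nh)
unit_design <- function(L = 1) design_spec(rep(100L, L), rep(20L, L), rep(10L, L))
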