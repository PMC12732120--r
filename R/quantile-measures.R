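#' Sample quantile
#'
#' Computes the p-th sample quantile under a stated convention. The default
#' convention is linear interpolation at position \eqn{1 + p(n-1)} on the
#' sorted data (the widely used "type 7" rule), which is what every quantile
#' measure in this package is built on.
#'
#' @param values numeric vector, nonempty and finite.
#' @param p probability in (0, 1); may be a vector.
#' @param convention quantile convention; `"type7"` (linear interpolation,
#'   default) or an integer 1..9 passed through to [stats::quantile()].
#' @return the quantile(s), unnamed.
#' @export
#' @examples
#' sample_quantile(c(2, 4, 6, 8, 10, 12, 14, 16, 18), 0.25)  # 6
sample_quantile <- function(values, p, convention = "type7") {
  check_numeric(values, "values")
  if (!is.numeric(p) || length(p) < 1L || any(!is.finite(p)) ||
      any(p <= 0) || any(p >= 1)) {
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  }
  type <- if (identical(convention, "type7")) 7L else as.integer(convention)
  unname(stats::quantile(values, probs = p, type = type, names = FALSE))
}

#' Sample median
#'
#' Order-statistic median: middle order statistic for odd n, mean of the two
#' central order statistics for even n.
#'
#' @param values numeric vector, nonempty and finite.
#' @return the sample median.
#' @export
sample_median <- function(values) {
  check_numeric(values, "values")
  stats::median(values)
}

#' Quantile and robust location/scale summary
#'
#' Computes the full catalogue of quantile-based measures used to build the
#' transformation constants of the proposed estimator family: quartiles,
#' deciles, interquartile range (IQR), quartile deviation (QD = IQR/2),
#' quartile average (QA), quartile-weighted trimmed mean
#' (TM = (Q1 + 2 Q2 + Q3)/4), decile mean (DM = mean of D1..D9), unscaled
#' median absolute deviation (MAD), mid-range (MR), population standard
#' deviation (divide-by-n), population skewness (third standardized moment,
#' divide-by-n) and the product measure PM = sqrt(Q1 Q3).
#'
#' MAD carries no consistency factor: it is the raw median of absolute
#' deviations from the median. `sigma` and `Sk` are `NA` for n < 2 and `PM`
#' is `NA` when Q1*Q3 < 0 (square root undefined).
#'
#' @param values numeric vector, nonempty and finite.
#' @param convention quantile convention, see [sample_quantile()].
#' @return an object of class `"quantile_summary"`: a named list with fields
#'   `n, min, max, median, Q1, Q2, Q3, D1..D9 (vector `deciles`), IQR, QD,
#'   QA, TM, DM, MAD, MR, sigma, Sk, PM`.
#' @export
#' @examples
#' quantile_summary(c(2, 4, 6, 8, 10, 12, 14, 16, 18))
quantile_summary <- function(values, convention = "type7") {
  check_numeric(values, "values")
  n <- length(values)
  q <- sample_quantile(values, c(0.25, 0.5, 0.75), convention)
  deciles <- sample_quantile(values, seq(0.1, 0.9, by = 0.1), convention)
  med <- q[2L]
  mn <- min(values); mx <- max(values)
  xbar <- mean(values)
  sigma <- if (n >= 2L) sqrt(sum((values - xbar)^2) / n) else NA_real_
  Sk <- if (n >= 2L && is.finite(sigma) && sigma > 0) {
    sum((values - xbar)^3) / n / sigma^3
  } else NA_real_
  pm <- if (q[1L] * q[3L] >= 0) sqrt(q[1L] * q[3L]) else NA_real_
  out <- list(
    n = n, min = mn, max = mx,
    median = med, Q1 = q[1L], Q2 = med, Q3 = q[3L],
    deciles = deciles,
    IQR = q[3L] - q[1L],
    QD = (q[3L] - q[1L]) / 2,
    QA = (q[1L] + q[3L]) / 2,
    TM = (q[1L] + 2 * med + q[3L]) / 4,
    DM = mean(deciles),
    MAD = stats::median(abs(values - med)),
    MR = (mx + mn) / 2,
    sigma = sigma, Sk = Sk, PM = pm
  )
  class(out) <- "quantile_summary"
  out
}

#' @export
print.quantile_summary <- function(x, digits = 6, ...) {
  cat("Quantile summary (n = ", x$n, ")\n", sep = "")
  flat <- unlist(x[setdiff(names(x), c("n", "deciles"))])
  print(signif(flat, digits))
  cat("deciles D1..D9:\n")
  print(signif(x$deciles, digits))
  invisible(x)
}

#' Serialize a quantile summary to a one-row data frame
#'
#' Flat CSV-friendly row (deciles expanded to columns `D1`..`D9`), keyed by
#' an optional stratum label.
#'
#' @param summary a [quantile_summary()] object.
#' @param stratum optional stratum label stored in a leading column.
#' @return a one-row `data.frame`.
#' @export
as.data.frame.quantile_summary <- function(x, row.names = NULL, optional = FALSE,
                                           stratum = NULL, ...) {
  dec <- as.list(x$deciles)
  names(dec) <- paste0("D", 1:9)
  flat <- c(x[c("n", "min", "max", "median", "Q1", "Q2", "Q3")], dec,
            x[c("IQR", "QD", "QA", "TM", "DM", "MAD", "MR", "sigma", "Sk", "PM")])
  df <- as.data.frame(flat)
  if (!is.null(stratum)) df <- cbind(data.frame(stratum = stratum), df)
  df
}

#' Transformation specification for the double-exponential estimator family
#'
#' Builds the per-stratum constants \eqn{(t_{1h}, t_{2h}, t_{3h}, t_{4h},
#' V_{1h}, V_{2h})} and the derived shrink factors
#' \deqn{k_{1h} = t_{1h} M_{xh} / (t_{1h} M_{xh} + t_{2h}), \quad
#'       k_{2h} = t_{3h} M_{xh} / (t_{3h} M_{xh} + t_{4h}).}
#' The shrink factor is the first-order sensitivity of the corresponding
#' exponential term to the auxiliary median contrast; it equals 1 exactly when
#' the additive term (t2 or t4) is 0 and lies in (0, 1] for strictly positive
#' inputs.
#'
#' @param t1,t2,t3,t4 transformation constants. Signed measures (such as
#'   skewness) are admissible; a transform is degenerate only when a
#'   denominator t*Mx + t' is (numerically) zero.
#' @param Mx the (known) auxiliary median of the stratum; must be positive.
#' @param V1,V2 predetermined constants, default 1.
#' @param variant_id variant label, one of 1..8 or "custom".
#' @return an object of class `"transform_spec"`.
#' @export
transform_spec <- function(t1, t2, t3, t4, Mx, V1 = 1, V2 = 1,
                           variant_id = "custom") {
  for (nm in c("t1", "t2", "t3", "t4", "Mx", "V1", "V2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    }
  }
  if (Mx <= 0) stop("'Mx' must be positive", call. = FALSE)
  den1 <- t1 * Mx + t2
  den2 <- t3 * Mx + t4
  if (abs(den1) <= 1e-12 * max(abs(t1 * Mx), abs(t2), 1) ||
      abs(den2) <= 1e-12 * max(abs(t3 * Mx), abs(t4), 1)) {
    stop("degenerate transform: zero denominator t*Mx + t'", call. = FALSE)
  }
  out <- list(t1 = t1, t2 = t2, t3 = t3, t4 = t4, V1 = V1, V2 = V2,
              Mx = Mx, k1 = t1 * Mx / den1, k2 = t3 * Mx / den2,
              variant_id = variant_id)
  class(out) <- "transform_spec"
  out
}

#' @export
print.transform_spec <- function(x, ...) {
  cat("Transform spec [", x$variant_id, "]: t = (",
      paste(signif(c(x$t1, x$t2, x$t3, x$t4), 5), collapse = ", "),
      "), V = (", x$V1, ", ", x$V2, "), Mx = ", signif(x$Mx, 6),
      " -> k1 = ", signif(x$k1, 6), ", k2 = ", signif(x$k2, 6), "\n", sep = "")
  invisible(x)
}

# Transformation catalogue: (t1, t2, t3, t4) per variant, built from the
# auxiliary variable's quantile summary. Variant 5 mixes logarithms of the
# quartiles; two printings of its shift disagree (log(Q+1) vs log(Q-1)), so
# the domain-safe +1 shift is the default with `e5_log_shift = "minus1"`
# available for the alternative reading.
variant_t <- function(s, variant_id, e5_log_shift = "plus1") {
  stopifnot(variant_id %in% 1:8)
  switch(variant_id,
    `1` = c(s$QD, s$MAD, 1, s$max - s$min),
    `2` = c(s$TM, s$MR, 1, s$IQR),
    `3` = c(s$DM, s$MAD, 1, s$QD),
    `4` = c(s$Sk, 1, 1, s$Q3 - s$Q2),
    `5` = {
      sh <- if (identical(e5_log_shift, "minus1")) -1 else 1
      args <- c(s$Q3 + sh, s$Q1 + sh, s$MR + sh)
      if (any(args <= 0)) {
        stop("variant 5 needs Q1, Q3 and MR > ", -sh, call. = FALSE)
      }
      c(log(args[1L]), log(args[2L]), 1, log(args[3L]))
    },
    `6` = c(s$QA, s$sigma, 1, s$QD),
    `7` = c(s$median, s$IQR, 1, s$MAD),
    `8` = c(s$Q1 * s$Q3, s$max * s$min, 1, s$IQR)
  )
}

#' Instantiate a catalogue transformation
#'
#' Fills a [transform_spec()] from the quantile summary of the auxiliary
#' variable according to the eight-row transformation catalogue:
#' variant 1 uses (QD, MAD, 1, max-min); 2: (TM, MR, 1, IQR);
#' 3: (DM, MAD, 1, QD); 4: (Sk, 1, 1, Q3-Q2);
#' 5: (log(Q3+1), log(Q1+1), 1, log(MR+1)); 6: (QA, sigma, 1, QD);
#' 7: (median, IQR, 1, MAD); 8: (Q1*Q3, max*min, 1, IQR).
#'
#' @param summary a [quantile_summary()] of the stratum's auxiliary values.
#' @param Mx the stratum auxiliary median used in the shrink factors (> 0).
#' @param variant_id integer 1..8.
#' @param V1,V2 predetermined constants, default 1.
#' @param e5_log_shift `"plus1"` (default, domain-safe) or `"minus1"`;
#'   variant 5 only.
#' @return a `"transform_spec"`.
#' @export
#' @examples
#' s <- quantile_summary(c(2, 4, 6, 8, 10, 12, 14, 16, 18))
#' make_transform(s, Mx = 10, variant_id = 1)  # k1 = 40/44
make_transform <- function(summary, Mx, variant_id, V1 = 1, V2 = 1,
                           e5_log_shift = "plus1") {
  stopifnot(inherits(summary, "quantile_summary"))
  variant_id <- as.integer(variant_id)
  t <- variant_t(summary, variant_id, e5_log_shift)
  if (any(!is.finite(t))) {
    stop("degenerate transform: non-finite t-constants for variant ",
         variant_id, call. = FALSE)
  }
  transform_spec(t[1L], t[2L], t[3L], t[4L], Mx = Mx, V1 = V1, V2 = V2,
                 variant_id = variant_id)
}

check_numeric <- function(values, what) {
  if (length(values) == 0L) stop("no data in '", what, "'", call. = FALSE)
  if (!is.numeric(values)) stop("'", what, "' must be numeric", call. = FALSE)
  if (any(!is.finite(values))) {
    stop("non-finite values in '", what, "'", call. = FALSE)
  }
  invisible(TRUE)
}
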