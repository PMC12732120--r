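#' Kernel density estimate at the sample median
#'
#' Gaussian kernel density with Silverman's rule-of-thumb bandwidth
#' ([stats::bw.nrd0()]) evaluated at the sample median. This is the plug-in
#' used for the density-at-the-median terms of the first-order variance of a
#' sample median.
#'
#' @param values numeric vector (n >= 10, nonzero spread).
#' @param bw bandwidth: `"nrd0"` (default) or a positive number.
#' @param at evaluation point; default the sample median of `values`.
#' @return the density estimate (strictly positive).
#' @export
density_at_median <- function(values, bw = "nrd0", at = NULL) {
  check_numeric(values, "values")
  if (length(values) < 10L) stop("need at least 10 values", call. = FALSE)
  if (max(values) == min(values)) {
    stop("degenerate distribution: zero spread", call. = FALSE)
  }
  h <- if (identical(bw, "nrd0")) stats::bw.nrd0(values) else as.numeric(bw)
  if (!is.finite(h) || h <= 0) stop("invalid bandwidth", call. = FALSE)
  if (is.null(at)) at <- stats::median(values)
  mean(stats::dnorm((at - values) / h)) / h
}

#' Median correlation
#'
#' The dependence measure \eqn{4 P_{11} - 1}, where \eqn{P_{11}} is the
#' proportion of pairs with both coordinates at or below their respective
#' medians. It is 0 under independence and \eqn{\pm 1} under perfect
#' co-/counter-monotonicity, and is well defined even for heavy-tailed
#' variables without product moments.
#'
#' @param y,x paired numeric vectors, length >= 4.
#' @return a number in [-1, 1].
#' @export
median_correlation <- function(y, x) {
  check_numeric(y, "y")
  check_numeric(x, "x")
  if (length(y) != length(x)) stop("length mismatch", call. = FALSE)
  if (length(y) < 4L) stop("need at least 4 pairs", call. = FALSE)
  p11 <- mean(y <= stats::median(y) & x <= stats::median(x))
  4 * p11 - 1
}

new_stratum_moments <- function(df) {
  df$CMyx <- df$rho * df$CMy * df$CMx
  df$K <- df$rho * df$CMy / df$CMx
  class(df) <- c("stratum_moments", "data.frame")
  df
}

#' Per-stratum moment model from a population
#'
#' Computes, for each stratum, the quantities entering every first-order
#' bias/MSE expression: population medians \eqn{M_{yh}, M_{xh}}, kernel
#' density estimates at those medians, the median correlation
#' \eqn{\rho_{yxh} = 4P_{11h} - 1}, the median coefficients
#' \eqn{C_{Myh} = 1/(M_{yh} f_{yh}(M_{yh}))} and \eqn{C_{Mxh}} (analogous),
#' the cross coefficient \eqn{C_{Myxh} = \rho C_{My} C_{Mx}}, the ratio
#' \eqn{K_h = \rho C_{My}/C_{Mx}}, the stratum weights and the design
#' constants \eqn{\theta_{1h}, \theta_{2h}, \theta_{3h}}.
#'
#' @param pop a [stratified_population()].
#' @param design the matching [design_spec()].
#' @param bw bandwidth passed to [density_at_median()].
#' @return an object of class `"stratum_moments"`: a data frame with columns
#'   `stratum, Nh, mh, nh, Wh, theta1, theta2, theta3, My, Mx, fy, fx, rho,
#'   CMy, CMx, CMyx, K`.
#' @export
stratum_moments <- function(pop, design, bw = "nrd0") {
  stopifnot(inherits(pop, "strat_pop"), inherits(design, "design_spec"))
  ys <- split(pop$y, pop$stratum)
  xs <- split(pop$x, pop$stratum)
  L <- nrow(design)
  My <- vapply(ys, stats::median, 0)
  Mx <- vapply(xs, stats::median, 0)
  fy <- mapply(function(v, m) density_at_median(v, bw = bw, at = m), ys, My)
  fx <- mapply(function(v, m) density_at_median(v, bw = bw, at = m), xs, Mx)
  rho <- mapply(median_correlation, ys, xs)
  df <- data.frame(
    stratum = design$stratum, Nh = design$Nh, mh = design$mh, nh = design$nh,
    Wh = design$Wh, theta1 = design$theta1, theta2 = design$theta2,
    theta3 = design$theta3,
    My = unname(My), Mx = unname(Mx), fy = unname(fy), fx = unname(fx),
    rho = unname(rho),
    CMy = 1 / (unname(My) * unname(fy)), CMx = 1 / (unname(Mx) * unname(fx))
  )
  new_stratum_moments(df)
}

#' Per-stratum moment model from a printed summary table
#'
#' The fixture route: builds the same `"stratum_moments"` object from a table
#' of published per-stratum summary statistics (as supplied by
#' [real_population_fixture()]). Medians, densities at the medians, the
#' correlation and the design sizes are taken verbatim; weights, theta
#' constants and the C coefficients are derived from them.
#'
#' @param table a data frame with columns `N, m, n, Mx, My, fx, fy, rho`
#'   (one row per stratum; an optional `stratum` column supplies labels).
#' @return a `"stratum_moments"` data frame.
#' @export
stratum_moments_from_table <- function(table) {
  need <- c("N", "m", "n", "Mx", "My", "fx", "fy", "rho")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("missing fixture field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  design <- design_spec(table$N, table$m, table$n,
                        labels = if ("stratum" %in% names(table)) {
                          table$stratum
                        } else seq_len(nrow(table)))
  df <- data.frame(
    stratum = design$stratum, Nh = design$Nh, mh = design$mh, nh = design$nh,
    Wh = design$Wh, theta1 = design$theta1, theta2 = design$theta2,
    theta3 = design$theta3,
    My = table$My, Mx = table$Mx, fy = table$fy, fx = table$fx,
    rho = table$rho,
    CMy = 1 / (table$My * table$fy), CMx = 1 / (table$Mx * table$fx)
  )
  new_stratum_moments(df)
}

#' Construct a moment model directly from its components
#'
#' Mainly for theory work and property tests: builds a `"stratum_moments"`
#' object from explicitly supplied coefficients, bypassing any data.
#'
#' @param My,Mx,CMy,CMx,rho,theta1,theta3 numeric vectors (recycled), with
#'   `theta2 = theta1 - theta3` implied.
#' @param Wh stratum weights; default equal weights normalised to sum 1.
#' @return a `"stratum_moments"` data frame.
#' @export
moment_model <- function(My, Mx, CMy, CMx, rho, theta1, theta3, Wh = NULL) {
  L <- max(lengths(list(My, Mx, CMy, CMx, rho, theta1, theta3)))
  if (is.null(Wh)) Wh <- rep(1 / L, L)
  df <- data.frame(
    stratum = seq_len(L), Nh = NA_integer_, mh = NA_integer_, nh = NA_integer_,
    Wh = rep_len(Wh, L),
    theta1 = rep_len(theta1, L), theta2 = rep_len(theta1 - theta3, L),
    theta3 = rep_len(theta3, L),
    My = rep_len(My, L), Mx = rep_len(Mx, L),
    fy = 1 / (rep_len(My, L) * rep_len(CMy, L)),
    fx = 1 / (rep_len(Mx, L) * rep_len(CMx, L)),
    rho = rep_len(rho, L),
    CMy = rep_len(CMy, L), CMx = rep_len(CMx, L)
  )
  new_stratum_moments(df)
}
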