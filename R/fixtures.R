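#' Published summary statistics of the three real populations
#'
#' Per-stratum summary statistics of three published two-stratum survey
#' populations (school enrolment, registered factories/employment, and
#' household income/food expenditure), packaged exactly as printed in their
#' source: design sizes (N, m, n), auxiliary range, medians, density
#' estimates at the medians, correlation, and the quantile measures
#' (TM, DM, Sk, QA, QD, MAD, QR, MR). The values are stored verbatim,
#' including one internal oddity in Population-1 (its printed QD for
#' stratum 1 equals its printed DM, 982.650 — almost certainly a transcription
#' slip in the source, flagged via the `qd_equals_dm` attribute and not
#' corrected). `QR` is a printed range-type column its source never defines;
#' it is kept under the printed name and not mapped onto IQR.
#'
#' @param name `"Population-1"`, `"Population-2"` or `"Population-3"`.
#' @return a `data.frame` of class `"real_population_fixture"` with one row
#'   per stratum.
#' @export
real_population_fixture <- function(name = c("Population-1", "Population-2",
                                             "Population-3")) {
  name <- match.arg(name)
  path <- system.file("extdata", "real_population_summaries.csv",
                      package = "median2ph", mustWork = TRUE)
  all <- utils::read.csv(path, stringsAsFactors = FALSE)
  fix <- all[all$population == name, , drop = FALSE]
  rownames(fix) <- NULL
  attr(fix, "qd_equals_dm") <- any(fix$QD == fix$DM & fix$QD > 100)
  class(fix) <- c("real_population_fixture", "data.frame")
  fix
}

#' Moment model from a packaged fixture
#'
#' Converts a [real_population_fixture()] into the `"stratum_moments"`
#' object the theory route consumes (weights, theta constants and C
#' coefficients derived from the printed N/m/n, medians, densities and
#' correlation).
#'
#' @param fixture a `"real_population_fixture"`.
#' @return a `"stratum_moments"` data frame.
#' @export
fixture_to_moments <- function(fixture) {
  stopifnot(inherits(fixture, "real_population_fixture"))
  stratum_moments_from_table(data.frame(
    stratum = fixture$stratum, N = fixture$N, m = fixture$m, n = fixture$n,
    Mx = fixture$Mx, My = fixture$My, fx = fixture$fx, fy = fixture$fy,
    rho = fixture$rho
  ))
}
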