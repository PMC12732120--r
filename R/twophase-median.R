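#' Estimate a finite-population median from a stratified two-phase sample
#'
#' The package's main fitting function: evaluates a registry of median
#' estimators — the stratified sample median, ratio, difference (D1--D4),
#' exponential ratio/product, and the transformed double-exponential family
#' E1--E8 — on one stratified two-phase sample.
#'
#' Auxiliary transformation constants for E1--E8 are "known characteristics"
#' of the auxiliary variable: they are computed from the population when
#' `pop` is supplied (simulation mode) and from the first-phase sample
#' otherwise (real-data mode). The optimal plug-in constants of D1--D4
#' require a moment model; it is taken from `moments`, computed from `pop`,
#' or, as a last resort, estimated from the sample itself
#' ([sample_moments()]).
#'
#' @param sample a [draw_two_phase_sample()] result.
#' @param design the matching [design_spec()].
#' @param estimators registry subset (default all, [estimator_registry()]).
#' @param pop optional [stratified_population()] the sample was drawn from.
#' @param moments optional `"stratum_moments"` for the D-estimator constants
#'   (and for theoretical MSEs in `summary()`).
#' @param transforms optional named list (`E1`..`E8`) of per-stratum
#'   [transform_spec()] lists, overriding the automatic construction.
#' @param constants optional named list of D-estimator constants, overriding
#'   the optima.
#' @param ratio_orientation passed to [estimate_ratio()].
#' @return an object of class `"twophase_median"` with `print()`, `coef()`
#'   and `summary()` methods.
#' @export
#' @examples
#' pop <- generate_population(population_model("gamma"), seed = 7)
#' des <- design_spec(attr(pop, "Nh"), mh = 150, nh = 60)
#' smp <- draw_two_phase_sample(pop, des, seed = 11)
#' fit <- twophase_median(smp, des, pop = pop)
#' coef(fit)
twophase_median <- function(sample, design,
                            estimators = estimator_registry(),
                            pop = NULL, moments = NULL, transforms = NULL,
                            constants = NULL,
                            ratio_orientation = "first_over_second") {
  stopifnot(inherits(sample, "twophase_sample"), inherits(design, "design_spec"))
  bad <- setdiff(estimators, estimator_registry())
  if (length(bad)) stop("unknown estimator(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  needs_E <- grepl("^E[1-8]$", estimators)
  needs_D <- estimators %in% c("D1", "D2", "D3", "D4")
  if (any(needs_E) && is.null(transforms)) {
    aux <- aux_by_stratum(if (is.null(pop)) sample else pop)
    transforms <- build_transforms(
      aux, variants = as.integer(sub("E", "", estimators[needs_E])))
  }
  if (any(needs_D)) {
    if (is.null(moments)) {
      moments <- if (!is.null(pop)) stratum_moments(pop, design)
                 else sample_moments(sample, design)
    }
    for (est in estimators[needs_D]) {
      if (is.null(constants[[est]])) {
        constants[[est]] <- optimal_constants(moments, est)
      }
    }
  }
  est <- eval_registry(sample, design, estimators, transforms, constants,
                       ratio_orientation)
  structure(list(estimates = est, design = design,
                 medians = stratum_sample_medians(sample),
                 transforms = transforms, constants = constants,
                 moments = moments),
            class = "twophase_median")
}

#' Moment model estimated from the sample itself
#'
#' Real-data fallback for plug-in constants when no population or published
#' moment table is available: medians and the median correlation from the
#' second phase, densities at the medians by kernel estimation (y from the
#' second phase, x from the larger first phase).
#'
#' @param sample a two-phase sample.
#' @param design the matching design.
#' @return a `"stratum_moments"` data frame.
#' @export
sample_moments <- function(sample, design) {
  My <- vapply(sample, function(s) sample_median(s$y2), 0)
  Mx <- vapply(sample, function(s) sample_median(s$x1), 0)
  fy <- vapply(sample, function(s) density_at_median(s$y2), 0)
  fx <- vapply(sample, function(s) density_at_median(s$x1), 0)
  rho <- vapply(sample, function(s) median_correlation(s$y2, s$x2), 0)
  df <- data.frame(
    stratum = design$stratum, Nh = design$Nh, mh = design$mh, nh = design$nh,
    Wh = design$Wh, theta1 = design$theta1, theta2 = design$theta2,
    theta3 = design$theta3,
    My = unname(My), Mx = unname(Mx), fy = unname(fy), fx = unname(fx),
    rho = unname(rho),
    CMy = 1 / unname(My * fy), CMx = 1 / unname(Mx * fx)
  )
  new_stratum_moments(df)
}

#' @export
coef.twophase_median <- function(object, ...) object$estimates

#' @export
print.twophase_median <- function(x, digits = 6, ...) {
  cat("Two-phase median estimates (", nrow(x$design), " strata, m = ",
      sum(x$design$mh), ", n = ", sum(x$design$nh), ")\n", sep = "")
  print(signif(x$estimates, digits))
  invisible(x)
}

#' @export
summary.twophase_median <- function(object, ...) {
  tab <- data.frame(estimator = names(object$estimates),
                    estimate = unname(object$estimates), row.names = NULL)
  if (!is.null(object$moments)) {
    tab$theory_mse <- vapply(tab$estimator, function(e) {
      tryCatch(theory_for(e, object)$mse, error = function(err) NA_real_)
    }, 0)
    base <- tab$theory_mse[tab$estimator == "baseline"]
    if (length(base) == 1L && is.finite(base)) {
      tab$theory_pre <- pre(base, tab$theory_mse)
    }
  }
  structure(list(table = tab, design = object$design,
                 medians = object$medians),
            class = "summary.twophase_median")
}

theory_for <- function(est, object) {
  m <- object$moments
  switch(est,
    baseline = theory_baseline_variance(m),
    ratio = theory_existing(m, "A"),
    exp_ratio = theory_existing(m, "Re"),
    exp_product = theory_existing(m, "Pe"),
    D1 = , D2 = , D3 = , D4 = theory_existing(m, est),
    theory_proposed(m, object$transforms[[est]])
  )
}

#' @export
print.summary.twophase_median <- function(x, digits = 6, ...) {
  cat("Stratified two-phase median estimation\n")
  cat("Per-stratum sample medians:\n")
  print.data.frame(format(x$medians, digits = digits), row.names = FALSE)
  cat("\nEstimates:\n")
  tab <- x$table
  for (col in setdiff(names(tab), "estimator")) tab[[col]] <- signif(tab[[col]], digits)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}
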