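#' Per-stratum sample medians of a two-phase sample
#'
#' @param sample a [draw_two_phase_sample()] result.
#' @return a `data.frame` with one row per stratum and columns `My_hat`,
#'   `Mx_hat` (second-phase medians of y and x) and `Mx_acute` (first-phase
#'   median of x).
#' @export
stratum_sample_medians <- function(sample) {
  stopifnot(inherits(sample, "twophase_sample"))
  data.frame(
    stratum = names(sample),
    My_hat = vapply(sample, function(s) sample_median(s$y2), 0),
    Mx_hat = vapply(sample, function(s) sample_median(s$x2), 0),
    Mx_acute = vapply(sample, function(s) sample_median(s$x1), 0),
    row.names = NULL
  )
}

#' Names of the built-in estimators
#'
#' `"baseline"` is the stratified sample median; `"ratio"` the ratio
#' estimator (estimator A); `"D1"`..`"D4"` the difference-type estimators;
#' `"exp_ratio"`/`"exp_product"` the exponential ratio and product
#' estimators; `"E1"`..`"E8"` the transformed double-exponential family.
#'
#' @return character vector of registry names in canonical reporting order.
#' @export
estimator_registry <- function() {
  c("baseline", "ratio", "D1", "exp_ratio", "exp_product",
    "D2", "D3", "D4", paste0("E", 1:8))
}

new_estimate <- function(name, per_stratum, Wh, constants = list()) {
  structure(list(estimator = name, estimate = sum(Wh * per_stratum),
                 per_stratum = per_stratum, Wh = Wh, constants = constants),
            class = "estimator_estimate")
}

#' @export
print.estimator_estimate <- function(x, ...) {
  cat(format(x$estimator, width = 11), signif(x$estimate, 6), "\n")
  invisible(x)
}

#' Stratified sample median (baseline estimator)
#'
#' \eqn{\hat M_{yst} = \sum_h W_h \hat M_{yh}}.
#'
#' @param sample a two-phase sample.
#' @param design the matching [design_spec()].
#' @return an `"estimator_estimate"`.
#' @export
estimate_baseline <- function(sample, design) {
  med <- stratum_sample_medians(sample)
  new_estimate("baseline", med$My_hat, design$Wh)
}

#' Ratio estimator of the median
#'
#' Combines per-stratum sample medians with the ratio of the two phases'
#' auxiliary medians. The default orientation multiplies by
#' \eqn{\acute M_{xh} / \hat M_{xh}} (the classical two-phase form, the one
#' consistent with the first-order bias/MSE theory used here);
#' `"as_printed"` gives the transposed \eqn{\hat M_{xh} / \acute M_{xh}}
#' variant.
#'
#' @inheritParams estimate_baseline
#' @param orientation `"first_over_second"` (default) or `"as_printed"`.
#' @return an `"estimator_estimate"`.
#' @export
estimate_ratio <- function(sample, design,
                           orientation = c("first_over_second", "as_printed")) {
  orientation <- match.arg(orientation)
  med <- stratum_sample_medians(sample)
  if (orientation == "first_over_second") {
    if (any(med$Mx_hat == 0)) stop("ratio undefined: zero second-phase auxiliary median", call. = FALSE)
    terms <- med$My_hat * med$Mx_acute / med$Mx_hat
  } else {
    if (any(med$Mx_acute == 0)) stop("ratio undefined: zero first-phase auxiliary median", call. = FALSE)
    terms <- med$My_hat * med$Mx_hat / med$Mx_acute
  }
  new_estimate("ratio", terms, design$Wh, list(orientation = orientation))
}

#' Difference-type estimators of the median
#'
#' Four variants built on the auxiliary contrast
#' \eqn{\acute M_{xh} - \hat M_{xh}}:
#' D1: \eqn{\sum_h W_h[\hat M_{yh} + d_{1h}(\acute M_{xh} - \hat M_{xh})]};
#' D2: \eqn{\sum_h W_h[d_{2h}\hat M_{yh} + d_{3h}(\acute M_{xh} - \hat M_{xh})]};
#' D3 multiplies the D2-style bracket (constants \eqn{d_{4h}, d_{5h}}) by
#' \eqn{\acute M_{xh}/\hat M_{xh}}; D4 multiplies its bracket (constants
#' \eqn{d_{6h}, d_{7h}}) by
#' \eqn{(\acute M_{xh}-\hat M_{xh})/(\acute M_{xh}+\hat M_{xh})}.
#'
#' @inheritParams estimate_baseline
#' @param variant `"D1"`, `"D2"`, `"D3"` or `"D4"`.
#' @param constants named list of per-stratum constant vectors: `d1` for D1,
#'   `d2`+`d3` for D2, `d4`+`d5` for D3, `d6`+`d7` for D4 (scalars recycled).
#'   Plug-in optima come from [optimal_constants()].
#' @return an `"estimator_estimate"`.
#' @export
estimate_difference <- function(sample, design, variant = "D1", constants) {
  med <- stratum_sample_medians(sample)
  L <- nrow(med)
  need <- switch(variant, D1 = "d1", D2 = c("d2", "d3"), D3 = c("d4", "d5"),
                 D4 = c("d6", "d7"), stop("unknown variant: ", variant, call. = FALSE))
  if (missing(constants) || !all(need %in% names(constants))) {
    stop("missing constants for ", variant, ": need ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  cst <- lapply(constants[need], rep_len, L)
  diff <- med$Mx_acute - med$Mx_hat
  terms <- switch(variant,
    D1 = med$My_hat + cst$d1 * diff,
    D2 = cst$d2 * med$My_hat + cst$d3 * diff,
    D3 = {
      if (any(med$Mx_hat == 0)) stop("D3 undefined: zero second-phase auxiliary median", call. = FALSE)
      (cst$d4 * med$My_hat + cst$d5 * diff) * med$Mx_acute / med$Mx_hat
    },
    D4 = {
      s <- med$Mx_acute + med$Mx_hat
      if (any(s == 0)) stop("D4 undefined: zero auxiliary median sum", call. = FALSE)
      (cst$d6 * med$My_hat + cst$d7 * diff) * diff / s
    }
  )
  new_estimate(variant, terms, design$Wh, cst)
}

#' Exponential ratio and product estimators of the median
#'
#' \eqn{\sum_h W_h \hat M_{yh}
#'   \exp\{(\acute M_{xh} - \hat M_{xh})/(\acute M_{xh} + \hat M_{xh})\}}
#' for the ratio direction; the product direction negates the exponent.
#'
#' @inheritParams estimate_baseline
#' @param direction `"ratio"` or `"product"`.
#' @return an `"estimator_estimate"`.
#' @export
estimate_exponential <- function(sample, design,
                                 direction = c("ratio", "product")) {
  direction <- match.arg(direction)
  med <- stratum_sample_medians(sample)
  s <- med$Mx_acute + med$Mx_hat
  if (any(s == 0)) stop("exponential estimator undefined: zero auxiliary median sum", call. = FALSE)
  arg <- (med$Mx_acute - med$Mx_hat) / s
  if (direction == "product") arg <- -arg
  new_estimate(if (direction == "ratio") "exp_ratio" else "exp_product",
               med$My_hat * exp(arg), design$Wh)
}

#' Transformed double-exponential family of estimators
#'
#' The proposed family
#' \deqn{\hat E_{st} = \sum_h W_h \hat M_{yh}
#'  \exp\!\Big[\frac{V_{1h} t_{1h}(\hat M_{xh}-\acute M_{xh})}
#'                 {t_{1h}(\acute M_{xh}+\hat M_{xh})+2t_{2h}}\Big]
#'  \exp\!\Big[\frac{V_{2h} t_{3h}(\acute M_{xh}-\hat M_{xh})}
#'                 {t_{3h}(\acute M_{xh}+\hat M_{xh})+2t_{4h}}\Big],}
#' where the two exponents carry opposite signs of the auxiliary contrast and
#' the t-constants are known quantile characteristics of the auxiliary
#' variable (see [make_transform()]).
#'
#' @inheritParams estimate_baseline
#' @param spec a single [transform_spec()] (recycled over strata) or a list
#'   with one spec per stratum.
#' @param name estimator label for the result.
#' @return an `"estimator_estimate"`.
#' @export
estimate_proposed <- function(sample, design, spec, name = "proposed") {
  med <- stratum_sample_medians(sample)
  L <- nrow(med)
  if (inherits(spec, "transform_spec")) spec <- rep(list(spec), L)
  if (!is.list(spec) || length(spec) != L) {
    stop("'spec' must supply one transform_spec per stratum", call. = FALSE)
  }
  terms <- numeric(L)
  for (h in seq_len(L)) {
    sp <- spec[[h]]
    stopifnot(inherits(sp, "transform_spec"))
    s <- med$Mx_acute[h] + med$Mx_hat[h]
    den1 <- sp$t1 * s + 2 * sp$t2
    den2 <- sp$t3 * s + 2 * sp$t4
    if (abs(den1) <= 1e-12 * max(abs(sp$t1 * s), abs(2 * sp$t2), 1) ||
        abs(den2) <= 1e-12 * max(abs(sp$t3 * s), abs(2 * sp$t4), 1)) {
      stop("degenerate transform in stratum ", med$stratum[h], call. = FALSE)
    }
    d <- med$Mx_hat[h] - med$Mx_acute[h]
    terms[h] <- med$My_hat[h] *
      exp(sp$V1 * sp$t1 * d / den1) * exp(-sp$V2 * sp$t3 * d / den2)
  }
  new_estimate(name, terms, design$Wh,
               list(k1 = vapply(spec, `[[`, 0, "k1"),
                    k2 = vapply(spec, `[[`, 0, "k2")))
}

#' Build catalogue transforms per stratum
#'
#' Instantiates the transformation catalogue from the auxiliary variable.
#' In simulation mode the t-constants are "known characteristics of the
#' population": computed from the population x within each stratum. In
#' real-data mode they come from the first-phase sample instead.
#'
#' @param x_by_stratum list of numeric vectors of auxiliary values, one per
#'   stratum (population values, or phase-1 values).
#' @param variants integer vector from 1..8.
#' @param Mx optional per-stratum auxiliary medians used in the shrink
#'   factors; default is the median of each `x_by_stratum` element.
#' @param ... passed to [make_transform()] (`V1`, `V2`, `e5_log_shift`).
#' @return a named list `E1..E8` (for the requested variants), each a list of
#'   per-stratum [transform_spec()]s.
#' @export
build_transforms <- function(x_by_stratum, variants = 1:8, Mx = NULL, ...) {
  summaries <- lapply(x_by_stratum, quantile_summary)
  if (is.null(Mx)) Mx <- vapply(x_by_stratum, sample_median, 0)
  out <- lapply(variants, function(v) {
    lapply(seq_along(summaries), function(h) {
      make_transform(summaries[[h]], Mx = Mx[h], variant_id = v, ...)
    })
  })
  names(out) <- paste0("E", variants)
  out
}

# auxiliary values per stratum from a population (simulation mode) or a
# sample's first phase (real-data mode)
aux_by_stratum <- function(obj) {
  if (inherits(obj, "strat_pop")) {
    split(obj$x, obj$stratum)
  } else if (inherits(obj, "twophase_sample")) {
    lapply(obj, `[[`, "x1")
  } else {
    stop("need a strat_pop or twophase_sample", call. = FALSE)
  }
}
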