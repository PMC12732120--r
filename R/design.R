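#' Equal-frequency stratification on the auxiliary variable
#'
#' Partitions units into L strata by ranking on `x` and cutting at the
#' x-quantiles (equal-frequency). When N is not divisible by L, the extra
#' units go to the lowest-indexed strata. Ties are broken by original order,
#' so every unit in stratum i has x no larger than every unit in stratum i+1.
#'
#' @param values_x numeric auxiliary values.
#' @param L number of strata (>= 1).
#' @param method only `"equal_freq"` is provided.
#' @return integer stratum labels 1..L, one per unit.
#' @export
stratify <- function(values_x, L, method = "equal_freq") {
  check_numeric(values_x, "values_x")
  L <- as.integer(L)
  if (L < 1L) stop("'L' must be >= 1", call. = FALSE)
  if (!identical(method, "equal_freq")) {
    stop("unknown stratification method: ", method, call. = FALSE)
  }
  N <- length(values_x)
  sizes <- rep(N %/% L, L) + as.integer(seq_len(L) <= N %% L)
  if (any(sizes < 2L)) {
    stop("stratum too small: equal-frequency split of ", N, " units into ",
         L, " strata leaves a stratum with < 2 units", call. = FALSE)
  }
  labels <- integer(N)
  labels[order(values_x)] <- rep.int(seq_len(L), sizes)
  labels
}

round_half_up <- function(x) floor(x + 0.5)

#' Two-phase design specification
#'
#' Per-stratum sizes and the sampling constants of the stratified two-phase
#' SRSWOR design:
#' \deqn{\theta_{1h} = \tfrac14(1/n_h - 1/N_h), \quad
#'       \theta_{2h} = \tfrac14(1/m_h - 1/N_h), \quad
#'       \theta_{3h} = \tfrac14(1/n_h - 1/m_h),}
#' with \eqn{\theta_{3h} = \theta_{1h} - \theta_{2h}} identically. The design
#' requires \eqn{n_h < m_h \le N_h} in every stratum.
#'
#' @param Nh,mh,nh integer vectors of per-stratum population, first-phase and
#'   second-phase sizes (recycled to a common length).
#' @param labels optional stratum labels (default `1..L`).
#' @return an object of class `"design_spec"`: a `data.frame` with columns
#'   `stratum, Nh, mh, nh, Wh, theta1, theta2, theta3`.
#' @export
#' @examples
#' design_spec(Nh = 36, mh = 18, nh = 9)
design_spec <- function(Nh, mh, nh, labels = NULL) {
  L <- max(length(Nh), length(mh), length(nh))
  Nh <- as.integer(rep_len(Nh, L))
  mh <- as.integer(rep_len(mh, L))
  nh <- as.integer(rep_len(nh, L))
  if (is.null(labels)) labels <- seq_len(L)
  if (any(nh < 2L)) stop("second-phase size nh must be >= 2", call. = FALSE)
  bad <- which(!(nh < mh & mh <= Nh))
  if (length(bad)) {
    stop("design must satisfy nh < mh <= Nh; violated in stratum ",
         labels[bad[1L]], " (Nh=", Nh[bad[1L]], ", mh=", mh[bad[1L]],
         ", nh=", nh[bad[1L]], ")", call. = FALSE)
  }
  d <- data.frame(
    stratum = labels, Nh = Nh, mh = mh, nh = nh,
    Wh = Nh / sum(Nh),
    theta1 = 0.25 * (1 / nh - 1 / Nh),
    theta2 = 0.25 * (1 / mh - 1 / Nh),
    theta3 = 0.25 * (1 / nh - 1 / mh)
  )
  class(d) <- c("design_spec", "data.frame")
  d
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Two-phase design:", nrow(x), "strata, m =", sum(x$mh),
      ", n =", sum(x$nh), ", N =", sum(x$Nh), "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# (m, n) grids of the three allocation schemes
scheme_pairs <- function(scheme) {
  switch(as.character(scheme),
    "1" = {
      m <- c(300L, 500L, 800L)
      do.call(rbind, lapply(m, function(mm)
        data.frame(m = mm, n = as.integer(round_half_up(c(0.10, 0.20, 0.30, 0.40) * mm)))))
    },
    "2" = data.frame(m = c(200L, 300L, 500L, 800L), n = c(50L, 75L, 125L, 200L)),
    "3" = {
      m <- c(150L, 250L, 400L, 600L, 900L)
      do.call(rbind, lapply(m, function(mm)
        data.frame(m = mm, n = as.integer(round_half_up(c(0.10, 0.25, 0.40) * mm)))))
    },
    stop("unknown scheme: ", scheme, call. = FALSE)
  )
}

# equal allocation of a total across L strata, remainders to lowest strata
equal_alloc <- function(total, L) {
  rep(total %/% L, L) + as.integer(seq_len(L) <= total %% L)
}

#' Allocation schemes
#'
#' Expands one of the three allocation schemes into a list of
#' [design_spec()]s, one per (m, n) cell:
#' scheme 1 crosses m in \{300, 500, 800\} with n in \{0.10m, 0.20m, 0.30m,
#' 0.40m\} (rounded half up); scheme 2 uses the four pairs (200,50), (300,75),
#' (500,125), (800,200); scheme 3 crosses m in \{150, 250, 400, 600, 900\}
#' with n in \{0.10m, 0.25m, 0.40m\}. Totals are split equally across strata
#' with remainders assigned to the lowest-indexed strata; an (m, n) cell whose
#' rounded allocation violates nh < mh <= Nh raises an error naming the cell.
#'
#' @param scheme 1, 2 or 3.
#' @param L number of strata.
#' @param Nh per-stratum population sizes (length L or scalar).
#' @return a list of `design_spec`, named `"m<m>_n<n>"`.
#' @export
#' @examples
#' allocate(2, L = 2, Nh = 500)[["m200_n50"]]
allocate <- function(scheme, L, Nh) {
  L <- as.integer(L)
  Nh <- as.integer(rep_len(Nh, L))
  pairs <- scheme_pairs(scheme)
  out <- vector("list", nrow(pairs))
  names(out) <- paste0("m", pairs$m, "_n", pairs$n)
  for (i in seq_len(nrow(pairs))) {
    mh <- equal_alloc(pairs$m[i], L)
    nh <- pmax(equal_alloc(pairs$n[i], L), 2L)
    if (any(nh >= mh) || any(mh > Nh)) {
      stop("allocation (m=", pairs$m[i], ", n=", pairs$n[i],
           ") violates nh < mh <= Nh in stratum ",
           which(nh >= mh | mh > Nh)[1L], call. = FALSE)
    }
    out[[i]] <- design_spec(Nh, mh, nh)
  }
  out
}
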