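# Deterministic per-replication seed derived from (master seed, u); an LCG
# mix keeps substreams order-independent and inside the 32-bit range.
derive_seed <- function(master_seed, u = 0L) {
  as.integer((as.double(master_seed) %% 2147483647 * 48271 + u * 16807 + 1) %%
               2147483647)
}

#' Draw a stratified two-phase SRSWOR sample
#'
#' Phase 1 draws `mh` units per stratum from the `Nh` population units by
#' simple random sampling without replacement, recording the auxiliary
#' variable only. Phase 2 draws `nh` units per stratum from the phase-1 units
#' (again SRSWOR), recording both variables. The second-phase set is always a
#' subset of the first-phase set.
#'
#' @param pop a [stratified_population()].
#' @param design a [design_spec()] whose strata and `Nh` match `pop`.
#' @param seed optional integer; when supplied the draw is reproducible
#'   (the global RNG state is restored afterwards).
#' @return an object of class `"twophase_sample"`: a list with one element
#'   per stratum, each holding `x1` (phase-1 auxiliary values), `y2`, `x2`
#'   (phase-2 values) and the population row indices of both phases.
#' @export
draw_two_phase_sample <- function(pop, design, seed = NULL) {
  stopifnot(inherits(pop, "strat_pop"), inherits(design, "design_spec"))
  Nh_pop <- attr(pop, "Nh")
  if (nrow(design) != length(Nh_pop) ||
      !all(as.character(design$stratum) == names(Nh_pop)) ||
      !all(design$Nh == unname(Nh_pop))) {
    stop("design does not match population strata", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  idx_by_stratum <- split(seq_len(nrow(pop)), pop$stratum)
  out <- vector("list", nrow(design))
  names(out) <- as.character(design$stratum)
  for (h in seq_len(nrow(design))) {
    rows <- idx_by_stratum[[h]]
    i1 <- rows[sample.int(length(rows), design$mh[h])]
    i2 <- i1[sample.int(length(i1), design$nh[h])]
    out[[h]] <- list(x1 = pop$x[i1], y2 = pop$y[i2], x2 = pop$x[i2],
                     phase1 = i1, phase2 = i2)
  }
  structure(out, class = "twophase_sample", design = design)
}

#' @export
print.twophase_sample <- function(x, ...) {
  d <- attr(x, "design")
  cat("Two-phase sample:", length(x), "strata; mh =",
      paste(d$mh, collapse = "/"), ", nh =", paste(d$nh, collapse = "/"), "\n")
  invisible(x)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
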