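#' Read a YAML run configuration
#'
#' A run configuration names a mode (`simulate`, `estimate` or `theory`) and
#' its inputs: a population model (`population: gamma`, optional `rho`,
#' `params`, `N`) or a population CSV (`population_csv:`); an allocation
#' `scheme` (1/2/3) or explicit `mh`/`nh` lists; `L`; an estimator subset
#' (`estimators:`); replications `U`; `master_seed`; an optional `out` CSV
#' path; and the `mode: theory` extras `fixture:` (a packaged population
#' name) or `moments_csv:`. Unset fields fall back to documented defaults
#' (L = 2, U = 2000, all estimators, seed 1).
#'
#' @param path YAML file path.
#' @return a validated config list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$mode) || !cfg$mode %in% c("simulate", "estimate", "theory")) {
    stop("config 'mode' must be simulate, estimate or theory", call. = FALSE)
  }
  cfg$L <- if (is.null(cfg$L)) 2L else as.integer(cfg$L)
  cfg$U <- if (is.null(cfg$U)) 2000L else as.integer(cfg$U)
  if (cfg$U < 1L) stop("'U' must be >= 1", call. = FALSE)
  cfg$master_seed <- if (is.null(cfg$master_seed)) 1L else as.integer(cfg$master_seed)
  if (is.null(cfg$estimators)) cfg$estimators <- estimator_registry()
  bad <- setdiff(cfg$estimators, estimator_registry())
  if (length(bad)) stop("unknown estimator(s) in config: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (f in c("population_csv", "moments_csv")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("config file reference does not exist: ", cfg[[f]], call. = FALSE)
    }
  }
  class(cfg) <- "run_config"
  cfg
}

config_designs <- function(cfg, Nh) {
  if (!is.null(cfg$mh)) {
    list(design_spec(Nh, unlist(cfg$mh), unlist(cfg$nh)))
  } else {
    allocate(if (is.null(cfg$scheme)) 2L else cfg$scheme, cfg$L, Nh)
  }
}

#' Execute a run configuration
#'
#' Dispatches on the config `mode`: `simulate` runs [run_monte_carlo()] over
#' the configured designs; `estimate` draws one sample (or uses a population
#' CSV) and returns [twophase_median()] estimates; `theory` evaluates
#' first-order bias/MSE for every configured estimator from a moment model
#' (fixture, moments CSV or population). When the config names an `out`
#' path, the result table is also written there as CSV and a one-line log
#' with the seed is appended to `<out>.log`.
#'
#' @param cfg a `"run_config"` (or a path to one).
#' @return the mode's result table.
#' @export
run_config <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  pop <- if (!is.null(cfg$population_csv)) {
    read_population_csv(cfg$population_csv)
  } else if (!is.null(cfg$population)) {
    generate_population(
      population_model(cfg$population,
                       N = if (is.null(cfg$N)) 1000 else cfg$N,
                       rho = cfg$rho, params = unlist(cfg$params)),
      seed = cfg$master_seed, L = cfg$L)
  } else NULL

  out <- switch(cfg$mode,
    simulate = {
      if (is.null(pop)) stop("simulate mode needs a population", call. = FALSE)
      run_monte_carlo(pop, config_designs(cfg, attr(pop, "Nh")),
                      estimators = cfg$estimators, U = cfg$U,
                      master_seed = cfg$master_seed, L = cfg$L)
    },
    estimate = {
      if (is.null(pop)) stop("estimate mode needs a population", call. = FALSE)
      design <- config_designs(cfg, attr(pop, "Nh"))[[1L]]
      fit <- twophase_median(
        draw_two_phase_sample(pop, design, seed = cfg$master_seed),
        design, estimators = cfg$estimators, pop = pop)
      data.frame(estimator = names(coef(fit)), estimate = unname(coef(fit)))
    },
    theory = {
      moments <- if (!is.null(cfg$fixture)) {
        fixture_to_moments(real_population_fixture(cfg$fixture))
      } else if (!is.null(cfg$moments_csv)) {
        new_stratum_moments(utils::read.csv(cfg$moments_csv))
      } else if (!is.null(pop)) {
        stratum_moments(pop, config_designs(cfg, attr(pop, "Nh"))[[1L]])
      } else stop("theory mode needs a fixture, moments CSV or population",
                  call. = FALSE)
      theory_table(moments, cfg$estimators)
    }
  )
  if (!is.null(cfg$out)) {
    utils::write.csv(out, cfg$out, row.names = FALSE)
    cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " mode=", cfg$mode,
        " seed=", cfg$master_seed, " U=", cfg$U, " version=",
        as.character(utils::packageVersion("median2ph")), "\n",
        sep = "", file = paste0(cfg$out, ".log"), append = TRUE)
  }
  out
}

#' First-order theory table for a registry of estimators
#'
#' @param moments a `"stratum_moments"` object.
#' @param estimators registry subset; E-variants are evaluated at the shrink
#'   factors implied by `transforms` when given, otherwise skipped.
#' @param transforms optional named list `E1..E8` of per-stratum
#'   [transform_spec()]s.
#' @return a `data.frame` with columns `estimator, bias, mse, pre`.
#' @export
theory_table <- function(moments, estimators = estimator_registry(),
                         transforms = NULL) {
  map <- c(baseline = "baseline", ratio = "A", D1 = "D1", exp_ratio = "Re",
           exp_product = "Pe", D2 = "D2", D3 = "D3", D4 = "D4")
  rows <- lapply(estimators, function(e) {
    res <- if (e %in% names(map)) {
      theory_existing(moments, map[[e]])
    } else if (!is.null(transforms[[e]])) {
      theory_proposed(moments, transforms[[e]])
    } else return(NULL)
    data.frame(estimator = e, bias = res$bias, mse = res$mse)
  })
  out <- do.call(rbind, rows)
  base <- out$mse[out$estimator == "baseline"]
  if (length(base) == 1L) out$pre <- pre(base, out$mse)
  out
}

#' Render a results table as an estimator-by-population grid
#'
#' Reshapes a tidy results table (one row per population/design/estimator,
#' as produced by [run_monte_carlo()] or [theory_table()]) into the wide
#' estimator-by-column grid used in reports, in canonical estimator order,
#' with values at 6 significant digits. Returns the grid and, invisibly,
#' writes it as CSV and/or aligned text when paths are given.
#'
#' @param results a data frame with columns `estimator`, a value column, and
#'   grouping columns (`population` and/or `m`, `n`).
#' @param value which column to tabulate (default `"pre"` if present, else
#'   `"mse"`).
#' @param csv,txt optional output paths.
#' @return the wide `data.frame`.
#' @export
render_report <- function(results, value = NULL, csv = NULL, txt = NULL) {
  if (nrow(results) == 0L) stop("empty results", call. = FALSE)
  if (is.null(value)) value <- if ("pre" %in% names(results)) "pre" else "mse"
  keys <- intersect(c("population", "m", "n"), names(results))
  col <- if (length(keys)) {
    interaction(results[keys], drop = TRUE, sep = " ")
  } else factor("value")
  est <- factor(results$estimator,
                levels = intersect(estimator_registry(), results$estimator))
  wide <- tapply(results[[value]], list(est, col), function(v) v[1L])
  out <- data.frame(estimator = rownames(wide),
                    signif(wide, 6), check.names = FALSE, row.names = NULL)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  if (!is.null(txt)) {
    writeLines(utils::capture.output(print.data.frame(out, row.names = FALSE)),
               txt)
  }
  out
}
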