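#' Stratified finite population
#'
#' A unit-level finite population of size N carrying the study variable `y`,
#' the auxiliary variable `x` and a stratum label per unit. Stratum counts
#' must all be at least 2.
#'
#' @param y,x numeric vectors of equal length (finite).
#' @param stratum vector of stratum labels, same length.
#' @return an object of class `"strat_pop"`: a `data.frame` with columns
#'   `y, x, stratum` (stratum as a factor with levels in first-appearance
#'   order of the sorted labels) and attributes `N` and `Nh`.
#' @export
stratified_population <- function(y, x, stratum) {
  check_numeric(y, "y")
  check_numeric(x, "x")
  if (length(y) != length(x) || length(y) != length(stratum)) {
    stop("'y', 'x' and 'stratum' must have the same length", call. = FALSE)
  }
  stratum <- factor(stratum)
  Nh <- table(stratum)
  if (any(Nh < 2L)) {
    stop("stratum too small: ", paste(names(Nh)[Nh < 2L], collapse = ", "),
         " (need >= 2 units per stratum)", call. = FALSE)
  }
  pop <- data.frame(y = y, x = x, stratum = stratum)
  attr(pop, "N") <- length(y)
  attr(pop, "Nh") <- stats::setNames(as.integer(Nh), names(Nh))
  class(pop) <- c("strat_pop", "data.frame")
  pop
}

#' @export
print.strat_pop <- function(x, ...) {
  Nh <- attr(x, "Nh")
  cat("Stratified population: N =", attr(x, "N"), "units in", length(Nh),
      "strata\n  Nh:", paste(names(Nh), "=", Nh, collapse = ", "), "\n")
  invisible(x)
}

#' Read a population CSV
#'
#' Expects a header row `y,x,stratum`. Cells in `y` and `x` must be numeric.
#'
#' @param path path to the CSV file.
#' @return a [stratified_population()].
#' @export
read_population_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("y", "x", "stratum"), names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("y", "x")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "', row ", bad[1L],
           ": '", df[[col]][bad[1L]], "'", call. = FALSE)
    }
    if (anyNA(v)) stop("missing value in column '", col, "'", call. = FALSE)
    df[[col]] <- v
  }
  stratified_population(df$y, df$x, df$stratum)
}

#' Write a population CSV
#'
#' @param pop a [stratified_population()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(pop, path) {
  stopifnot(inherits(pop, "strat_pop"))
  utils::write.csv(data.frame(y = pop$y, x = pop$x, stratum = pop$stratum),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
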