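#' Delta notation for stable isotope ratios
#'
#' Converts a measured isotope ratio to per-mil delta notation relative to
#' an international standard (PDB for carbon, atmospheric N2 for
#' nitrogen): \eqn{\delta X = (R_{sample}/R_{standard} - 1) \times 1000}.
#'
#' @param r_sample measured isotope ratio (e.g. 13C/12C), `>= 0`.
#' @param r_standard standard ratio, `> 0`.
#' @return delta value in per mil.
#' @examples
#' delta_value(0.0111, 0.0112)  # about -8.93 permil
#' @export
delta_value <- function(r_sample, r_standard) {
  if (!is.numeric(r_sample) || !is.numeric(r_standard))
    stop_input("isotope ratios must be numeric")
  if (any(!is.finite(r_standard)) || any(r_standard <= 0))
    stop_input("r_standard must be positive and finite")
  if (any(!is.finite(r_sample)) || any(r_sample < 0))
    stop_input("r_sample must be non-negative and finite")
  (r_sample / r_standard - 1) * 1000
}

#' Validate a table of feather isotope samples
#'
#' Checks structure and flags delta values outside plausible ecological
#' ranges (delta13C in \[-40, -5\], delta15N in \[-5, 25\]).  Range
#' violations are warnings, not errors, so that extreme synthetic
#' scenarios still run.
#'
#' @param samples data frame with columns `territory_id`, `year`,
#'   `delta13C`, `delta15N` (one row per feather sample).
#' @return the validated data frame, invisibly.
#' @export
validate_samples <- function(samples) {
  check_columns(samples, c("territory_id", "year", "delta13C", "delta15N"),
                "consumer table")
  if (any(is.na(samples$territory_id)) || any(is.na(samples$year)))
    stop_input("every sample needs a territory_id and a year")
  if (any(!is.finite(samples$year)) || any(samples$year %% 1 != 0))
    stop_input("year must be an integer")
  for (col in c("delta13C", "delta15N")) {
    v <- samples[[col]]
    if (!is.numeric(v)) stop_input(sprintf("%s must be numeric", col))
    if (any(is.infinite(v))) stop_input(sprintf("%s contains infinite values", col))
  }
  out13 <- stats::na.omit(samples$delta13C)
  out15 <- stats::na.omit(samples$delta15N)
  if (any(out13 < -40 | out13 > -5))
    warning("delta13C values outside the plausible range [-40, -5] permil")
  if (any(out15 < -5 | out15 > 25))
    warning("delta15N values outside the plausible range [-5, 25] permil")
  invisible(samples)
}

#' Average sibling feathers into one observation per nest-year
#'
#' Each nest (territory) and year is one statistical observation: the
#' isotope values of sampled siblings are averaged with equal weight.
#' Missing isotope values are ignored pairwise, so a sample lacking one
#' isotope still contributes to the other's mean (a warning is issued).
#'
#' @param samples data frame of feather samples (see [validate_samples()]).
#' @return data frame with one row per (territory_id, year):
#'   `territory_id`, `year`, `mean_delta13C`, `mean_delta15N`,
#'   `n_siblings`.
#' @export
average_siblings <- function(samples) {
  if (is.null(samples) || nrow(samples) == 0) {
    return(data.frame(territory_id = character(), year = integer(),
                      mean_delta13C = numeric(), mean_delta15N = numeric(),
                      n_siblings = integer(), stringsAsFactors = FALSE))
  }
  validate_samples(samples)
  if (any(is.na(samples$delta13C)) || any(is.na(samples$delta15N)))
    warning("missing isotope values: sibling means computed pairwise")
  key <- interaction(samples$territory_id, samples$year, drop = TRUE)
  split_idx <- split(seq_len(nrow(samples)), key)
  rows <- lapply(split_idx, function(idx) {
    s <- samples[idx, , drop = FALSE]
    data.frame(territory_id = as.character(s$territory_id[1]),
               year = as.integer(s$year[1]),
               mean_delta13C = mean(s$delta13C, na.rm = TRUE),
               mean_delta15N = mean(s$delta15N, na.rm = TRUE),
               n_siblings = nrow(s), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$territory_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate several prey types into one source category
#'
#' A food category (e.g. "livestock") may pool several prey types, each
#' with its own isotope mean and SD.  Under stratified random sampling
#' with equal weight per prey type, a randomly drawn item comes from an
#' equal-probability finite mixture, so (law of total variance)
#' \deqn{\mu = \sum_k \mu_k / K, \qquad
#'       \sigma^2 = \sum_k (\sigma_k^2 + \mu_k^2)/K - \mu^2.}
#' The alternative `"stratified_mean"` form returns the variance of the
#' equally weighted *mean* of the prey types,
#' \eqn{\sum_k \sigma_k^2 / K^2}, for users who want the spread of a
#' category average rather than of a random item.
#'
#' @param mu numeric vector of component means (per mil).
#' @param sd numeric vector of component SDs, same length, `>= 0`.
#' @param variance one of `"mixture"` (default) or `"stratified_mean"`.
#' @return named list with `mu` and `sd` of the aggregated category.
#' @examples
#' aggregate_sources(c(-24, -26), c(1, 1))  # mu -25, sd sqrt(2)
#' @export
aggregate_sources <- function(mu, sd, variance = c("mixture", "stratified_mean")) {
  variance <- match.arg(variance)
  if (length(mu) < 1 || length(mu) != length(sd))
    stop_input("mu and sd must be non-empty vectors of equal length")
  if (any(!is.finite(mu)) || any(!is.finite(sd)))
    stop_input("component parameters must be finite")
  if (any(sd < 0)) stop_input("component sd must be non-negative")
  K <- length(mu)
  m <- mean(mu)
  v <- switch(variance,
              mixture = mean(sd^2 + mu^2) - m^2,
              stratified_mean = sum(sd^2) / K^2)
  v <- max(v, 0) # guard tiny negative from floating point
  list(mu = m, sd = sqrt(v))
}

#' Build a source specification table
#'
#' @param name character vector of category names.
#' @param mu13C,sd13C,mu15N,sd15N numeric vectors (per mil).
#' @return data frame of class `source_spec` with one row per category.
#' @export
source_spec <- function(name, mu13C, sd13C, mu15N, sd15N) {
  if (any(sd13C < 0) || any(sd15N < 0)) stop_input("source sd must be >= 0")
  out <- data.frame(name = as.character(name), mu13C = mu13C, sd13C = sd13C,
                    mu15N = mu15N, sd15N = sd15N, stringsAsFactors = FALSE)
  class(out) <- c("source_spec", "data.frame")
  out
}

#' Reference source geometry for the five-category vulture diet model
#'
#' Bivariate isotope distributions (mean and SD of delta13C and delta15N,
#' muscle tissue) of the five food sources used throughout: landfill,
#' livestock, wild herbivores, carnivores, birds.  Values are literature
#' compilations for the NE Iberian study system; multi-prey categories
#' were aggregated with [aggregate_sources()].
#'
#' @return a [source_spec()] table with five rows.
#' @export
default_sources <- function() {
  source_spec(
    name  = DIET_CATEGORIES,
    mu13C = c(-21.67, -25.68, -24.22, -24.60, -23.67),
    sd13C = c(1.44, 0.19, 1.17, 0.70, 0.57),
    mu15N = c(5.50, 6.07, 2.54, 9.00, 6.40),
    sd15N = c(1.74, 0.40, 1.63, 2.30, 1.07))
}

#' Trophic enrichment factor specification
#'
#' Additive consumer-minus-diet shift per isotope, with uncertainty.  The
#' default values are phylogenetically imputed feather TEFs for a
#' carnivorous accipitrid: 1.11 (SD 1.12) permil for delta13C and 3.33
#' (SD 1.18) permil for delta15N.
#'
#' @param mu13C,sd13C,mu15N,sd15N numeric scalars (per mil), SDs `>= 0`.
#' @return named list of class `tef_spec`.
#' @export
tef_spec <- function(mu13C = 1.11, sd13C = 1.12, mu15N = 3.33, sd15N = 1.18) {
  if (sd13C < 0 || sd15N < 0) stop_input("TEF sd must be >= 0")
  structure(list(mu13C = mu13C, sd13C = sd13C, mu15N = mu15N, sd15N = sd15N),
            class = "tef_spec")
}

#' @rdname tef_spec
#' @export
default_tef <- function() tef_spec()

#' Read input tables from CSV
#'
#' CSV dialect: UTF-8, comma separated, headered, "." decimal, empty
#' fields for missing values.
#'
#' `read_sources()` accepts an optional `parent_category` column: rows
#' with a non-empty `parent_category` are prey-type components and are
#' aggregated into their parent with [aggregate_sources()].
#'
#' @param path file path.
#' @param variance aggregation variance form, see [aggregate_sources()].
#' @return `read_consumers()`: a validated sample data frame;
#'   `read_sources()`: a [source_spec()] table; `read_tef()`: a
#'   [tef_spec()].
#' @name io_read
NULL

#' @rdname io_read
#' @export
read_consumers <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_samples(df)
  df
}

#' @rdname io_read
#' @export
read_sources <- function(path, variance = "mixture") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("name", "mu13C", "sd13C", "mu15N", "sd15N"), "sources table")
  if (!is.null(df$parent_category)) {
    comp <- !is.na(df$parent_category) & nzchar(df$parent_category)
    top <- df[!comp, , drop = FALSE]
    for (parent in unique(df$parent_category[comp])) {
      rows <- df[comp & df$parent_category == parent, , drop = FALSE]
      a13 <- aggregate_sources(rows$mu13C, rows$sd13C, variance)
      a15 <- aggregate_sources(rows$mu15N, rows$sd15N, variance)
      top <- rbind(top[, c("name", "mu13C", "sd13C", "mu15N", "sd15N")],
                   data.frame(name = parent, mu13C = a13$mu, sd13C = a13$sd,
                              mu15N = a15$mu, sd15N = a15$sd))
    }
    df <- top
  }
  source_spec(df$name, df$mu13C, df$sd13C, df$mu15N, df$sd15N)
}

#' @rdname io_read
#' @export
read_tef <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("isotope", "mu", "sd"), "TEF table")
  get <- function(iso, col) {
    i <- match(iso, df$isotope)
    if (is.na(i)) stop_input(sprintf("TEF table lacks isotope '%s'", iso))
    df[[col]][i]
  }
  tef_spec(mu13C = get("13C", "mu"), sd13C = get("13C", "sd"),
           mu15N = get("15N", "mu"), sd15N = get("15N", "sd"))
}
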