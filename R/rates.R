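#' Read a population denominator table
#'
#' @param path Delimited text with columns `year,sex,age_group,population`.
#' @return Tibble with those columns (`year` integer, `population` double).
#' @export
read_population <- function(path) {
  pop <- readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(), sex = readr::col_character(),
    age_group = readr::col_character(), population = readr::col_double()
  ), progress = FALSE)
  if (any(pop$population <= 0)) stop("population must be > 0", call. = FALSE)
  pop
}

#' Read a standard-population weight table
#'
#' @param path Delimited text with columns `age_group,std_weight`.
#' @return Normalized standard-population tibble (weights sum to 1).
#' @export
read_standard_population <- function(path) {
  std <- readr::read_csv(path, col_types = readr::cols(
    age_group = readr::col_character(), std_weight = readr::col_double()
  ), progress = FALSE)
  normalize_standard(std)
}

normalize_standard <- function(std) {
  if (any(std$std_weight < 0)) stop("standard weights must be >= 0", call. = FALSE)
  s <- sum(std$std_weight)
  if (s <= 0) stop("standard weights must not all be zero", call. = FALSE)
  if (abs(s - 1) > 1e-8) {
    warning("standard population weights sum to ", format(s),
            "; normalizing to 1", call. = FALSE)
    std$std_weight <- std$std_weight / s
  }
  std
}

#' WHO world standard population (2000-2025), 5-year bands
#'
#' The WHO world standard age distribution on the bands 0-4 through 80-84
#' plus an open 85+ band (the published 85-89/90-94/95-99/100+ tail is
#' collapsed into 85+), normalized to sum to 1.
#'
#' @return Standard-population tibble with columns `age_group`, `std_weight`.
#' @export
who_standard_population <- function() {
  w <- c(8.86, 8.69, 8.60, 8.47, 8.22, 7.93, 7.61, 7.15, 6.59, 6.04,
         5.37, 4.55, 3.72, 2.96, 2.21, 1.52, 0.91, 0.635)
  tibble::tibble(
    age_group = age_group_labels(default_age_breaks()),
    std_weight = w / sum(w)
  )
}

#' Convert an annual population table to person-years at a period resolution
#'
#' At `"year"` resolution this is the identity (one calendar year of exposure
#' per head). At `"month"` resolution each month of a year receives
#' `population / 12` person-years; months are treated as equal-length, leap
#' years included.
#'
#' @param pop Population tibble (`year,sex,age_group,population`).
#' @param resolution `"year"` or `"month"`.
#' @return Tibble `period,sex,age_group,person_years` with `period` labels
#'   matching [aggregate_weights()].
#' @export
person_years <- function(pop, resolution = c("year", "month")) {
  resolution <- match.arg(resolution)
  if (resolution == "year") {
    return(tibble::tibble(
      period = as.character(pop$year), sex = pop$sex,
      age_group = pop$age_group, person_years = pop$population
    ))
  }
  tidyr::expand_grid(pop, month = 1:12) |>
    dplyr::transmute(
      period = sprintf("%d-%02d", .data$year, .data$month),
      sex = .data$sex, age_group = .data$age_group,
      person_years = .data$population / 12
    )
}

#' Age- and sex-specific mortality rates per 100,000
#'
#' Joins a stratified weighted count table to person-years and computes
#' crude rates per 100,000 with a per-cell variance. The default `"poisson"`
#' variance treats the weighted count as a Poisson mean (it reduces exactly to
#' the classical estimator when all weights are 1, i.e. under the UCOD
#' scheme); `"weighted"` replaces the count with the sum of squared weights in
#' the variance numerator, the compound-Poisson variance appropriate when a
#' death contributes fractional weight.
#'
#' @param counts Weighted count table from [aggregate_weights()].
#' @param pop Person-years table from [person_years()] (or an annual
#'   population table, which is converted at year resolution). Every stratum
#'   in `counts` must be covered; a missing stratum is a hard error listing it.
#' @param variance `"poisson"` or `"weighted"`.
#' @return `counts` with added `person_years`, `rate`, `rate_var` (both per
#'   100,000 scale).
#' @export
age_specific_rates <- function(counts, pop, variance = c("poisson", "weighted")) {
  variance <- match.arg(variance)
  if (!"period" %in% names(pop)) {
    pop <- person_years(pop, "year")
  }
  out <- dplyr::left_join(counts, pop, by = c("period", "sex", "age_group"))
  bad <- is.na(out$person_years)
  if (any(bad)) {
    b <- utils::head(unique(out[bad, c("period", "sex", "age_group")]), 5)
    stop("population table missing strata: ",
         paste(b$period, b$sex, b$age_group, sep = "/", collapse = ", "),
         call. = FALSE)
  }
  zero_pop <- out$person_years <= 0
  if (any(zero_pop & out$weighted_deaths > 0)) {
    stop("nonzero deaths in a stratum with zero population", call. = FALSE)
  }
  num <- if (variance == "poisson") out$weighted_deaths else out$sum_sq_weights
  out$rate <- 1e5 * out$weighted_deaths / out$person_years
  out$rate_var <- 1e10 * num / out$person_years^2
  out
}

#' Directly age-standardized mortality rates
#'
#' Applies a fixed standard age distribution to the age-specific rates of
#' each period-sex-group-scheme stratum: `asmr = sum_a s_a * rate_a` with
#' variance `sum_a s_a^2 * var_a`. The default 95% interval is the Fay-Feuer
#' gamma interval for a weighted sum of Poisson-type counts, which stays
#' valid at low event counts; `ci = "normal"` gives the symmetric
#' `asmr +/- 1.96 * sqrt(var)` interval for cross-checking.
#'
#' @param rates Output of [age_specific_rates()].
#' @param std Standard-population tibble (`age_group,std_weight`); normalized
#'   with a warning if the weights do not sum to 1. Every standard age group
#'   must be present in `rates` (zero-filled cells are fine).
#' @param ci `"gamma"` or `"normal"`.
#' @param level Confidence level (default 0.95).
#' @return A `mc_rates` tibble: one row per `period,sex,group,scheme` with
#'   `weighted_deaths` (total), `asmr`, `asmr_var`, `ci_low`, `ci_high`, all
#'   on the per-100,000 scale.
#' @export
standardize_rates <- function(rates, std = who_standard_population(),
                              ci = c("gamma", "normal"), level = 0.95) {
  ci <- match.arg(ci)
  std <- normalize_standard(std)
  missing_groups <- setdiff(std$age_group, unique(rates$age_group))
  if (length(missing_groups)) {
    stop("age groups in the standard absent from the rate table: ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(unique(rates$age_group), std$age_group)
  if (length(extra)) {
    stop("rate table age groups missing from the standard: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  x <- dplyr::left_join(rates, std, by = "age_group")
  out <- x |>
    dplyr::group_by(.data$period, .data$sex, .data$group, .data$scheme) |>
    dplyr::summarise(
      weighted_deaths = sum(.data$weighted_deaths),
      asmr = sum(.data$std_weight * .data$rate),
      asmr_var = sum(.data$std_weight^2 * .data$rate_var),
      w_max = max(1e5 * .data$std_weight / .data$person_years),
      .groups = "drop"
    )
  alpha <- (1 - level) / 2
  if (ci == "gamma") {
    y <- out$asmr
    v <- out$asmr_var
    wm <- out$w_max
    lo <- ifelse(y > 0, qgamma(alpha, shape = y^2 / v, scale = v / y), 0)
    hi <- qgamma(1 - alpha,
                 shape = (y + wm)^2 / (v + wm^2),
                 scale = (v + wm^2) / (y + wm))
    out$ci_low <- lo
    out$ci_high <- hi
  } else {
    z <- qnorm(1 - alpha)
    out$ci_low <- pmax(0, out$asmr - z * sqrt(out$asmr_var))
    out$ci_high <- out$asmr + z * sqrt(out$asmr_var)
  }
  out$w_max <- NULL
  class(out) <- c("mc_rates", class(out))
  out
}
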