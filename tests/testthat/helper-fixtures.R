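# in-code fixture builders shared across test files

make_records <- function(ucod, part2 = vector("list", length(ucod)),
                         year = 2020L, month = 3L,
                         sex = rep("F", length(ucod)),
                         age = rep(67L, length(ucod))) {
  tibble::tibble(
    record_id = sprintf("r%03d", seq_along(ucod)),
    year = rep_len(as.integer(year), length(ucod)),
    month = rep_len(as.integer(month), length(ucod)),
    sex = sex, age = as.integer(age), ucod = ucod, part2 = part2
  )
}

# uniform population across strata of a record set
flat_population <- function(records, population = 1e5,
                            age_breaks = default_age_breaks()) {
  tidyr::expand_grid(
    year = sort(unique(records$year)),
    sex = c("M", "F"),
    age_group = multicause:::age_group_labels(age_breaks)
  ) |>
    dplyr::mutate(population = population)
}

# three coarse age bands keep simulation-heavy tests fast
coarse_breaks <- c(0L, 40L, 65L)

coarse_standard <- function() {
  tibble::tibble(
    age_group = multicause:::age_group_labels(coarse_breaks),
    std_weight = c(0.5, 0.3, 0.2)
  )
}

coarse_population <- function(years = 2019L, per_cell = 7e4) {
  tidyr::expand_grid(
    year = as.integer(years), sex = c("M", "F"),
    age_group = multicause:::age_group_labels(coarse_breaks)
  ) |>
    dplyr::mutate(population = per_cell)
}

coarse_hazards <- function(rates = c(NEOPLASMS = 120, CVD = 250, DM = 100,
                                     CD = 100, COVID19 = 0, ILL_DEFINED = 20,
                                     OTHER = 300)) {
  tidyr::expand_grid(
    group = names(rates), sex = c("M", "F"),
    age_group = multicause:::age_group_labels(coarse_breaks)
  ) |>
    dplyr::mutate(rate = unname(rates[group]))
}

coarse_sim_config <- function(years = 2019L, per_cell = 7e4, seed = 1L,
                              missing_sex_prob = 0, missing_age_prob = 0,
                              cause_hazards = coarse_hazards(),
                              competition_prob = 0, ...) {
  sim_config(
    years = years,
    population = coarse_population(years, per_cell),
    cause_hazards = cause_hazards,
    covid_multiplier = setNames(rep(0, length(years)), as.character(years)),
    competition_prob = competition_prob,
    missing_sex_prob = missing_sex_prob, missing_age_prob = missing_age_prob,
    age_breaks = coarse_breaks, seed = seed, ...
  )
}
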