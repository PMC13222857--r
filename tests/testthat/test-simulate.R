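test_that("configuration invariants are enforced by name", {
  expect_error(coarse_sim_config(competition_prob = 1.5), "probabilities")
  expect_error(coarse_sim_config(part2_lambda = c(`2019` = -1)), "part2_lambda")
  bad_haz <- coarse_hazards()
  bad_haz$rate[1] <- -5
  expect_error(coarse_sim_config(cause_hazards = bad_haz), "cause_hazards")
  bad_prof <- multicause:::default_comorbidity_profile()
  bad_prof[1, 1] <- bad_prof[1, 1] + 0.5
  expect_error(coarse_sim_config(comorbidity_profile = bad_prof), "sum to 1")
  ill_prof <- cbind(multicause:::default_comorbidity_profile() * 0.9,
                    ILL_DEFINED = rep(0.1, 7))
  expect_error(coarse_sim_config(comorbidity_profile = ill_prof), "ILL_DEFINED")
  expect_error(sim_config(covid_multiplier = c(`2019` = 1)), "covid_multiplier")
})

test_that("degenerate configurations produce the forced outputs", {
  zero <- coarse_hazards(rates = setNames(rep(0, 7), cause_groups()))
  empty <- simulate_deaths(coarse_sim_config(cause_hazards = zero))
  expect_equal(nrow(empty), 0)

  no_p2 <- simulate_deaths(coarse_sim_config(per_cell = 500, seed = 8,
                                             part2_zero_prob = c(`2019` = 1)))
  expect_true(all(lengths(no_p2$part2) == 0))
})

test_that("stratum death counts follow the configured Poisson means", {
  # one cause at 30 per 100,000 over 10^6 person-years: ~Poisson(300)
  haz <- coarse_hazards(rates = c(NEOPLASMS = 0, CVD = 0, DM = 30, CD = 0,
                                  COVID19 = 0, ILL_DEFINED = 0, OTHER = 0))
  cfg <- coarse_sim_config(per_cell = 1e6 / 6, cause_hazards = haz, seed = 13)
  deaths <- simulate_deaths(cfg)
  expect_true(all(map_cause_group(icd10_normalize(deaths$ucod)) == "DM"))
  expect_lt(abs(nrow(deaths) - 300), 3 * sqrt(300))
})

test_that("a fixed seed reproduces certificates byte-identically", {
  cfg <- coarse_sim_config(per_cell = 800, seed = 14)
  expect_identical(simulate_deaths(cfg), simulate_deaths(cfg))
  cfg2 <- coarse_sim_config(per_cell = 800, seed = 15)
  expect_false(identical(simulate_deaths(cfg), simulate_deaths(cfg2)))
})

test_that("closed-form expectations collapse across schemes when Part II is empty", {
  cfg <- coarse_sim_config(part2_zero_prob = c(`2019` = 1))
  t1 <- true_asmr(cfg, "UCOD", coarse_standard())
  t2 <- true_asmr(cfg, "MCOD_HALF", coarse_standard())
  t3 <- true_asmr(cfg, "MCOD_EQUAL", coarse_standard())
  expect_equal(t1$asmr, t2$asmr)
  expect_equal(t1$asmr, t3$asmr)
})

test_that("a pure DM-with-one-CVD-mention world splits the half weight exactly", {
  haz <- coarse_hazards(rates = c(NEOPLASMS = 0, CVD = 0, DM = 40, CD = 0,
                                  COVID19 = 0, ILL_DEFINED = 0, OTHER = 0))
  prof <- multicause:::default_comorbidity_profile()
  prof[] <- 0
  prof[, "CVD"] <- 1
  cfg <- coarse_sim_config(cause_hazards = haz, comorbidity_profile = prof,
                           part2_zero_prob = c(`2019` = 0),
                           part2_lambda = c(`2019` = 1e-9))
  tr <- true_asmr(cfg, "MCOD_HALF", coarse_standard())
  expect_equal(tr$asmr[tr$group == "DM"], rep(20, 2))
  expect_equal(tr$asmr[tr$group == "CVD"], rep(20, 2))
  tru <- true_asmr(cfg, "UCOD", coarse_standard())
  expect_equal(tru$asmr[tru$group == "DM"], rep(40, 2))
})

test_that("closed-form expectations match a large simulation through the pipeline", {
  cfg <- coarse_sim_config(per_cell = 2e5, seed = 16,
                           part2_zero_prob = c(`2019` = 0.6),
                           part2_lambda = c(`2019` = 0.9))
  deaths <- simulate_deaths(cfg)
  recs <- clean_certificates(deaths)
  py <- person_years(cfg$population, "year")
  std <- coarse_standard()
  for (sch in c("MCOD_HALF", "MCOD_EQUAL")) {
    est <- aggregate_weights(recs, sch, age_breaks = coarse_breaks) |>
      age_specific_rates(py, variance = "weighted") |>
      standardize_rates(std)
    tr <- true_asmr(cfg, sch, std)
    cmp <- dplyr::inner_join(est, tr, by = c("period", "sex", "group"),
                             suffix = c("_est", "_true"))
    z <- (cmp$asmr_est - cmp$asmr_true) / sqrt(pmax(cmp$asmr_var, 1e-12))
    z[cmp$asmr_var == 0 & cmp$asmr_est == cmp$asmr_true] <- 0
    expect_lt(max(abs(z)), 4)
  }
})

test_that("declining Part II zero-probability reproduces a completion gradient", {
  years <- 2019:2022
  cfg <- sim_config(
    years = years, population = coarse_population(years, 3e4),
    cause_hazards = coarse_hazards(),
    covid_multiplier = setNames(rep(0, 4), years),
    part2_zero_prob = setNames(c(0.667, 0.588, 0.549, 0.536), years),
    part2_lambda = setNames(rep(0.8, 4), years),
    competition_prob = 0, missing_sex_prob = 0, missing_age_prob = 0,
    age_breaks = coarse_breaks, seed = 17
  )
  tab <- tabulate_certificates(clean_certificates(simulate_deaths(cfg)))
  zero <- tab[tab$table == "part2_completion_recorded" & tab$level == "0", ]
  zero <- zero[order(zero$period), ]
  expect_equal(nrow(zero), 4)
  expect_true(all(diff(zero$pct) < 0))
  expect_lt(abs(zero$pct[1] - 66.7), 2.5)
  expect_lt(abs(zero$pct[4] - 53.6), 2.5)
})

test_that("raising competition shifts chronic deaths to COVID UCODs, totals fixed", {
  years <- 2021L
  mk <- function(p) {
    sim_config(
      years = years, population = coarse_population(years, 3e4),
      cause_hazards = coarse_hazards(rates = c(NEOPLASMS = 120, CVD = 250,
                                               DM = 100, CD = 100, COVID19 = 80,
                                               ILL_DEFINED = 20, OTHER = 300)),
      covid_multiplier = c(`2021` = 1), pandemic_years = 2021L,
      competition_prob = p, missing_sex_prob = 0, missing_age_prob = 0,
      age_breaks = coarse_breaks, seed = 18
    )
  }
  d0 <- simulate_deaths(mk(0))
  d4 <- simulate_deaths(mk(0.4))
  expect_equal(nrow(d0), nrow(d4))
  g0 <- map_cause_group(icd10_normalize(d0$ucod))
  g4 <- map_cause_group(icd10_normalize(d4$ucod))
  expect_gt(sum(g4 == "COVID19"), sum(g0 == "COVID19"))
  expect_lt(sum(g4 == "CVD"), sum(g0 == "CVD"))
  # swaps are nested: every non-swapped certificate is unchanged
  expect_equal(sum(g0 != g4), sum(g4 == "COVID19") - sum(g0 == "COVID19"))
})
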