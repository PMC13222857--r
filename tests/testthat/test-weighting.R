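test_that("cleaning flags ill-defined UCODs and drops bad Part II mentions", {
  recs <- clean_certificates(make_records(
    ucod = c("R99", "E11", "E11"),
    part2 = list(c("I10"), c("R57", "I10"), character(0))
  ))
  expect_equal(recs$excluded, c(TRUE, FALSE, FALSE))
  expect_equal(recs$part2_clean[[2]], "I10")
  expect_equal(recs$n_part2[2], 2L)
  expect_equal(recs$n_part2_clean[2], 1L)
  expect_equal(recs$part2_clean[[3]], character(0))
  # unparseable UCOD is rejected, not excluded
  bad <- clean_certificates(make_records("notacode"))
  expect_true(bad$rejected)
  expect_false(bad$excluded)
})

test_that("weight assignment follows the half-weight and equal-share rules", {
  recs <- clean_certificates(make_records("E11", list(c("I10", "J18"))))
  w <- assign_weights(recs, "MCOD_HALF")
  expect_equal(w$weight[match(c("E11", "I10", "J18"), w$code)], c(0.5, 0.25, 0.25))
  expect_equal(w$group[match(c("E11", "I10", "J18"), w$code)], c("DM", "CVD", "CD"))

  w0 <- assign_weights(clean_certificates(make_records("E11")), "MCOD_HALF")
  expect_equal(w0$weight, 1)

  req <- clean_certificates(make_records("I21", list(c("E11", "I10", "N18"))))
  weq <- assign_weights(req, "MCOD_EQUAL")
  expect_equal(weq$weight, rep(0.25, 4))

  wu <- assign_weights(req, "UCOD")
  expect_equal(nrow(wu), 1)
  expect_equal(wu$weight, 1)
})

test_that("weighting an excluded or rejected certificate is a hard error", {
  recs <- clean_certificates(make_records(c("R99", "E11"), list("I10", character(0))))
  expect_error(assign_weights(recs, "MCOD_HALF"), "ill-defined")
  rej <- clean_certificates(make_records("??"))
  expect_error(assign_weights(rej, "UCOD"), "unparseable")
})

test_that("same-group and duplicate Part II mentions accumulate", {
  recs <- clean_certificates(make_records("I21", list(c("I10", "E11"))))
  agg <- aggregate_weights(recs, "MCOD_HALF")
  cvd <- agg$weighted_deaths[agg$group == "CVD" & agg$weighted_deaths > 0]
  expect_equal(cvd, 0.75)
  solo <- clean_certificates(make_records("I21", list("I10")))
  agg1 <- aggregate_weights(solo, "MCOD_HALF")
  expect_equal(agg1$weighted_deaths[agg1$group == "CVD" & agg1$weighted_deaths > 0], 1)
  # a Part II repeat of the UCOD code is kept by default, droppable by flag
  dup <- clean_certificates(make_records("E11", list(c("E11", "I10"))))
  w_keep <- assign_weights(dup, "MCOD_HALF")
  expect_equal(sort(w_keep$weight), c(0.25, 0.25, 0.5))
  w_drop <- assign_weights(dup, "MCOD_HALF", drop_ucod_duplicates = TRUE)
  expect_equal(sort(w_drop$weight), c(0.5, 0.5))
})

test_that("single-record aggregation splits weight across group strata", {
  recs <- clean_certificates(make_records("E11", list("I10")))
  agg <- aggregate_weights(recs, "MCOD_HALF")
  nz <- agg[agg$weighted_deaths > 0, ]
  expect_setequal(nz$group, c("DM", "CVD"))
  expect_equal(nz$weighted_deaths, c(0.5, 0.5))
  expect_equal(sum(agg$weighted_deaths), 1)
  # zero strata are emitted, not dropped
  expect_true(all(cause_groups() %in% agg$group))
})

test_that("aggregation refuses missing demographics and excluded rows are dropped", {
  recs <- clean_certificates(make_records(
    c("E11", "R99"), list(character(0), character(0)),
    sex = c(NA, "F")
  ))
  expect_error(aggregate_weights(recs, "UCOD"), "impute")
  ok <- clean_certificates(make_records(c("E11", "R99")))
  agg <- aggregate_weights(ok, "UCOD")
  expect_equal(sum(agg$weighted_deaths), 1)  # the ill-defined record contributes nothing
})

test_that("weights conserve mass: per record and per stratum, all schemes", {
  cfg <- coarse_sim_config(per_cell = 4e3, seed = 301)
  recs <- clean_certificates(simulate_deaths(cfg))
  analyzed <- recs[!recs$excluded & !recs$rejected, ]
  for (sch in weight_schemes()) {
    w <- assign_weights(analyzed, sch)
    per_rec <- tapply(w$weight, w$record_id, sum)
    expect_lt(max(abs(per_rec - 1)), 1e-12)
    agg <- aggregate_weights(recs, sch, age_breaks = coarse_breaks)
    per_stratum <- agg |>
      dplyr::summarise(total = sum(weighted_deaths),
                       .by = c(period, sex, age_group))
    counts <- analyzed |>
      dplyr::count(period = as.character(year), sex,
                   age_group = age_group_label(age, coarse_breaks))
    chk <- dplyr::left_join(counts, per_stratum, by = c("period", "sex", "age_group"))
    expect_lt(max(abs(chk$total - chk$n)), 1e-9)
    # weighted deaths dominate summed squared weights
    expect_true(all(agg$weighted_deaths >= agg$sum_sq_weights - 1e-12))
  }
})

test_that("all three schemes coincide when Part II is empty", {
  cfg <- coarse_sim_config(per_cell = 2e3, seed = 77,
                           part2_zero_prob = c(`2019` = 1))
  recs <- clean_certificates(simulate_deaths(cfg))
  aggs <- lapply(weight_schemes(), function(s)
    aggregate_weights(recs, s, age_breaks = coarse_breaks)[
      c("period", "sex", "age_group", "group", "weighted_deaths")])
  expect_equal(aggs[[1]], aggs[[2]])
  expect_equal(aggs[[1]], aggs[[3]])
})

test_that("under the half-weight scheme the UCOD weight dominates any single mention", {
  cfg <- coarse_sim_config(per_cell = 2e3, seed = 99)
  recs <- clean_certificates(simulate_deaths(cfg))
  recs <- recs[!recs$excluded & !recs$rejected, ]
  w <- assign_weights(recs, "MCOD_HALF")
  mx <- tapply(w$weight[w$source == "part2"], w$record_id[w$source == "part2"], max)
  uc <- tapply(w$weight[w$source == "ucod"], w$record_id[w$source == "ucod"], max)
  expect_true(all(uc[names(mx)] >= mx))
})

test_that("aggregation matches the brute-force per-record oracle", {
  cfg <- coarse_sim_config(per_cell = 3e3, seed = 5)
  recs <- clean_certificates(simulate_deaths(cfg))
  for (sch in weight_schemes()) {
    expect_lt(compare_to_oracle(recs, sch, age_breaks = coarse_breaks), 1e-9)
  }
})

test_that("death-record files round-trip through the cc-column layout", {
  recs <- make_records(c("E11", "I21"), list(c("I10", "J18"), character(0)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_death_records(recs, path)
  back <- read_death_records(path)
  expect_equal(back$ucod, recs$ucod)
  expect_equal(back$part2, recs$part2)
  expect_equal(back$age, recs$age)
})
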