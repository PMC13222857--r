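#' Configure the synthetic death-certificate generator
#'
#' Builds and validates the full generative model behind [simulate_deaths()]:
#' a population by year, sex and 5-year age band; cause-specific annual
#' hazards (deaths per 100,000 person-years) for the seven analysis groups;
#' a zero-inflated, truncated-at-6 Poisson model for the number of Part II
#' contributing causes whose completeness drifts across years; a per-UCOD
#' comorbidity profile governing which groups appear in Part II; a
#' pandemic-period cause-competition mechanism under which a decedent with a
#' chronic (CVD or DM) underlying cause has COVID-19 recorded as the UCOD and
#' the chronic cause demoted to Part II; and small missing-completely-at-
#' random gaps in sex and age. Every piece is overridable; defaults emulate a
#' mid-sized Latin-American vital-statistics system across 2019-2022.
#'
#' @param years Calendar years to simulate.
#' @param pop_total Total population per year (both sexes); used only when
#'   `population` is not supplied.
#' @param population Optional tibble `year,sex,age_group,population`.
#' @param cause_hazards Optional tibble `group,sex,age_group,rate` (per
#'   100,000 person-years). The COVID-19 row is a reference hazard scaled by
#'   `covid_multiplier` per year.
#' @param covid_multiplier Named numeric, one entry per year, scaling the
#'   COVID-19 hazard (0 before the pandemic).
#' @param part2_zero_prob Named numeric per year: probability Part II is
#'   empty. The default declines over years, reproducing the drift towards
#'   more complete certificates.
#' @param part2_lambda Named numeric per year: Poisson mean of the nonzero
#'   Part II count, truncated to 1..6.
#' @param comorbidity_profile Matrix (UCOD group x Part II group) of
#'   categorical probabilities for each Part II mention; rows sum to 1 and
#'   must put no mass on `ILL_DEFINED` (so closed-form expectations stay
#'   exact after cleaning).
#' @param competition_prob Probability that an eligible pandemic-period
#'   chronic-UCOD decedent has the UCOD displaced by COVID-19.
#' @param pandemic_years Years in which the competition mechanism operates.
#' @param missing_sex_prob,missing_age_prob MCAR missingness probabilities.
#' @param code_lists Named list of ICD-10 codes sampled uniformly within each
#'   group.
#' @param age_breaks Age-band lower bounds.
#' @param monthly Reserved flag: months are always drawn uniformly, so annual
#'   and monthly analyses share one generator.
#' @param seed Integer seed; a fixed seed makes the output byte-identical.
#' @return A validated `mc_sim_config` list.
#' @export
sim_config <- function(years = 2019:2022,
                       pop_total = 1e6,
                       population = NULL,
                       cause_hazards = NULL,
                       covid_multiplier = NULL,
                       part2_zero_prob = NULL,
                       part2_lambda = NULL,
                       comorbidity_profile = NULL,
                       competition_prob = 0.25,
                       pandemic_years = c(2020L, 2021L),
                       missing_sex_prob = 3e-4,
                       missing_age_prob = 1.2e-3,
                       code_lists = NULL,
                       age_breaks = default_age_breaks(),
                       monthly = FALSE,
                       seed = 1L) {
  years <- as.integer(years)
  labs <- age_group_labels(age_breaks)
  if (is.null(population)) {
    population <- default_population(years, pop_total, age_breaks)
  }
  if (is.null(cause_hazards)) {
    cause_hazards <- default_cause_hazards(age_breaks)
  }
  if (is.null(covid_multiplier)) {
    covid_multiplier <- default_year_series(
      years, c(`2019` = 0, `2020` = 1, `2021` = 1.8, `2022` = 0.25), 0)
  }
  if (is.null(part2_zero_prob)) {
    part2_zero_prob <- default_year_series(
      years, c(`2019` = 0.667, `2020` = 0.588, `2021` = 0.549, `2022` = 0.536), 0.6)
  }
  if (is.null(part2_lambda)) {
    part2_lambda <- default_year_series(
      years, c(`2019` = 0.65, `2020` = 0.85, `2021` = 0.90, `2022` = 1.00), 0.8)
  }
  if (is.null(comorbidity_profile)) comorbidity_profile <- default_comorbidity_profile()
  if (is.null(code_lists)) code_lists <- default_code_lists()

  cfg <- structure(list(
    years = years, population = tibble::as_tibble(population),
    cause_hazards = tibble::as_tibble(cause_hazards),
    covid_multiplier = covid_multiplier,
    part2_zero_prob = part2_zero_prob, part2_lambda = part2_lambda,
    comorbidity_profile = comorbidity_profile,
    competition_prob = competition_prob,
    pandemic_years = as.integer(pandemic_years),
    missing_sex_prob = missing_sex_prob, missing_age_prob = missing_age_prob,
    code_lists = code_lists, age_breaks = age_breaks,
    monthly = monthly, seed = as.integer(seed)
  ), class = "mc_sim_config")
  validate_sim_config(cfg)
}

default_year_series <- function(years, known, fill) {
  out <- setNames(rep(fill, length(years)), as.character(years))
  hit <- intersect(names(out), names(known))
  out[hit] <- known[hit]
  out
}

default_population <- function(years, pop_total, age_breaks) {
  labs <- age_group_labels(age_breaks)
  # smooth young-leaning pyramid; open band smallest
  shape <- exp(-0.09 * seq_along(labs)) + 0.25
  share <- shape / sum(shape)
  tidyr::expand_grid(year = years, sex = c("M", "F")) |>
    tidyr::expand_grid(tibble::tibble(age_group = labs, share = share)) |>
    dplyr::mutate(population = .data$share * pop_total / 2, share = NULL)
}

default_cause_hazards <- function(age_breaks = default_age_breaks()) {
  labs <- age_group_labels(age_breaks)
  n <- length(age_breaks)
  mid <- c((age_breaks[-n] + age_breaks[-1] - 1) / 2, age_breaks[n] + 5)
  curves <- list(
    NEOPLASMS   = 6.0 * exp(0.070 * mid),
    CVD         = 2.5 * exp(0.090 * mid),
    DM          = 0.5 * exp(0.085 * mid),
    CD          = 40 * exp(-0.10 * mid) + 1.5 * exp(0.070 * mid),
    COVID19     = 0.8 * exp(0.060 * mid),
    ILL_DEFINED = 2.0 + 0.30 * exp(0.060 * mid),
    OTHER       = 60 * exp(-0.08 * mid) + 5.0 * exp(0.075 * mid)
  )
  purrr::imap_dfr(curves, function(r, g) {
    dplyr::bind_rows(
      tibble::tibble(group = g, sex = "M", age_group = labs, rate = 1.25 * r),
      tibble::tibble(group = g, sex = "F", age_group = labs, rate = 0.85 * r)
    )
  })
}

default_comorbidity_profile <- function() {
  g <- c("NEOPLASMS", "CVD", "DM", "CD", "COVID19", "OTHER")
  m <- rbind(
    NEOPLASMS   = c(0.15, 0.25, 0.10, 0.10, 0.00, 0.40),
    CVD         = c(0.05, 0.30, 0.20, 0.10, 0.00, 0.35),
    DM          = c(0.05, 0.45, 0.10, 0.10, 0.00, 0.30),
    CD          = c(0.05, 0.30, 0.15, 0.10, 0.00, 0.40),
    COVID19     = c(0.05, 0.30, 0.20, 0.15, 0.05, 0.25),
    ILL_DEFINED = c(0.08, 0.30, 0.12, 0.10, 0.00, 0.40),
    OTHER       = c(0.08, 0.30, 0.12, 0.10, 0.00, 0.40)
  )
  colnames(m) <- g
  m
}

default_code_lists <- function() {
  list(
    NEOPLASMS = c("C16", "C18", "C34", "C50", "C61"),
    CVD = c("I10", "I21", "I25", "I50", "I64"),
    DM = c("E10", "E11", "E14"),
    CD = c("A09", "A41", "B24", "J15", "J18"),
    COVID19 = c("U071", "U072"),
    ILL_DEFINED = c("R54", "R98", "R99"),
    OTHER = c("F03", "G30", "K70", "N18", "W19")
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  probs <- c(cfg$part2_zero_prob, cfg$competition_prob,
             cfg$missing_sex_prob, cfg$missing_age_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("sim config: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$cause_hazards$rate < 0)) {
    stop("sim config: cause_hazards rates must be >= 0", call. = FALSE)
  }
  if (any(cfg$population$population < 0)) {
    stop("sim config: population must be >= 0", call. = FALSE)
  }
  yrs <- as.character(cfg$years)
  for (f in c("covid_multiplier", "part2_zero_prob", "part2_lambda")) {
    if (!all(yrs %in% names(cfg[[f]]))) {
      stop("sim config: ", f, " must be named for every simulated year", call. = FALSE)
    }
  }
  if (any(cfg$part2_lambda <= 0)) {
    stop("sim config: part2_lambda must be > 0", call. = FALSE)
  }
  pr <- cfg$comorbidity_profile
  if (!setequal(rownames(pr), cause_groups())) {
    stop("sim config: comorbidity_profile needs one row per cause group", call. = FALSE)
  }
  if ("ILL_DEFINED" %in% colnames(pr) && any(pr[, "ILL_DEFINED"] > 0)) {
    stop("sim config: comorbidity_profile must put no mass on ILL_DEFINED",
         call. = FALSE)
  }
  if (any(abs(rowSums(pr) - 1) > 1e-8)) {
    stop("sim config: comorbidity_profile rows must sum to 1", call. = FALSE)
  }
  if (any(pr < 0)) stop("sim config: comorbidity_profile must be >= 0", call. = FALSE)
  labs <- age_group_labels(cfg$age_breaks)
  if (!setequal(unique(cfg$population$age_group), labs) ||
      !setequal(unique(cfg$cause_hazards$age_group), labs)) {
    stop("sim config: population and cause_hazards must use the configured ",
         "age bands", call. = FALSE)
  }
  cfg
}

# Part II count distribution: P(0) = pi, else Poisson(lambda) truncated to 1..6
part2_count_probs <- function(pi0, lambda) {
  p <- stats::dpois(1:6, lambda)
  c(pi0, (1 - pi0) * p / sum(p))
}

#' Simulate death certificates from a generator configuration
#'
#' Draws, per year-sex-age-cause stratum, a Poisson death count with mean
#' `hazard * population / 100000`, then fills in each certificate: a UCOD
#' code uniform over the group's code list, a Part II count from the
#' zero-inflated truncated Poisson, Part II codes from the UCOD group's
#' comorbidity profile, the pandemic cause-competition swap, and MCAR
#' missingness in sex and age. The draw is fully determined by `cfg$seed`,
#' and the competition mechanism consumes its own dedicated draws so that
#' configurations differing only in `competition_prob` produce the same
#' certificates with a nested set of swaps.
#'
#' @param cfg A [sim_config()] object.
#' @return A death-record tibble (as [read_death_records()] returns).
#' @export
simulate_deaths <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  labs <- age_group_labels(cfg$age_breaks)
  lo <- setNames(cfg$age_breaks, labs)
  n_br <- length(cfg$age_breaks)
  hi <- setNames(c(cfg$age_breaks[-1] - 1L, cfg$age_breaks[n_br] + 14L), labs)

  strata <- dplyr::inner_join(
    dplyr::filter(cfg$population, .data$year %in% cfg$years),
    cfg$cause_hazards,
    by = c("sex", "age_group"), relationship = "many-to-many"
  )
  strata$rate <- ifelse(strata$group == "COVID19",
                        strata$rate * cfg$covid_multiplier[as.character(strata$year)],
                        strata$rate)
  strata <- dplyr::arrange(strata, .data$year, .data$sex, .data$age_group, .data$group)

  rec <- NULL
  withr::with_seed(cfg$seed, {
    d <- rpois(nrow(strata), strata$rate * strata$population / 1e5)
    idx <- rep.int(seq_len(nrow(strata)), d)
    n <- length(idx)
    rec <- tibble::tibble(
      year = strata$year[idx], sex = strata$sex[idx],
      age_group = strata$age_group[idx], group = strata$group[idx]
    )
    rec$month <- sample.int(12L, n, replace = TRUE)
    rec$age <- as.integer(floor(runif(n, lo[rec$age_group], hi[rec$age_group] + 1)))
    rec$ucod <- draw_codes(rec$group, cfg$code_lists)

    # Part II counts and codes
    yr <- as.character(rec$year)
    k <- integer(n)
    for (y in as.character(cfg$years)) {
      sel <- yr == y
      if (!any(sel)) next
      k[sel] <- sample(0:6, sum(sel), replace = TRUE,
                       prob = part2_count_probs(cfg$part2_zero_prob[y],
                                                cfg$part2_lambda[y]))
    }
    ridx <- rep.int(seq_len(n), k)
    p2_group <- draw_profile_groups(rec$group[ridx], cfg$comorbidity_profile)
    p2_code <- draw_codes(p2_group, cfg$code_lists)
    part2 <- split(p2_code, factor(ridx, levels = seq_len(n)))
    rec$part2 <- unname(lapply(part2, unname))

    # pandemic cause competition: chronic UCOD displaced by COVID-19
    eligible <- which(rec$year %in% cfg$pandemic_years & rec$group %in% c("CVD", "DM"))
    u_comp <- runif(length(eligible))
    swap <- eligible[u_comp < cfg$competition_prob]
    if (length(swap)) {
      covid_codes <- cfg$code_lists$COVID19
      new_ucod <- covid_codes[sample.int(length(covid_codes), length(swap),
                                         replace = TRUE)]
      rec$part2[swap] <- purrr::map2(rec$part2[swap], rec$ucod[swap],
                                     function(v, u) c(v, u))
      rec$ucod[swap] <- new_ucod
      rec$group[swap] <- "COVID19"
    }

    # MCAR missingness
    rec$sex[runif(n) < cfg$missing_sex_prob] <- NA_character_
    rec$age[runif(n) < cfg$missing_age_prob] <- NA_integer_
  })
  tibble::tibble(
    record_id = sprintf("d%07d", seq_len(nrow(rec))),
    year = rec$year, month = rec$month, sex = rec$sex, age = rec$age,
    ucod = rec$ucod, part2 = rec$part2
  )
}

draw_codes <- function(groups, code_lists) {
  out <- character(length(groups))
  for (g in unique(groups)) {
    sel <- groups == g
    codes <- code_lists[[g]]
    out[sel] <- codes[sample.int(length(codes), sum(sel), replace = TRUE)]
  }
  out
}

draw_profile_groups <- function(ucod_groups, profile) {
  out <- character(length(ucod_groups))
  cols <- colnames(profile)
  for (g in unique(ucod_groups)) {
    sel <- ucod_groups == g
    out[sel] <- cols[sample.int(length(cols), sum(sel), replace = TRUE,
                                prob = profile[g, ])]
  }
  out
}

#' Closed-form expected age-standardized rates for a generator configuration
#'
#' Computes, without simulation, the exact expected ASMR per
#' (year, sex, cause group) under each weighting scheme implied by a
#' [sim_config()]: hazards are adjusted for the pandemic competition swap,
#' and the expected fractional weight reaching each group is integrated over
#' the Part II count distribution and the comorbidity profile. Certificates
#' with an ill-defined UCOD are excluded from the analysis, so the
#' `ILL_DEFINED` group's expected analyzed rate is 0 by construction.
#'
#' @param cfg A [sim_config()] object.
#' @param scheme One of [weight_schemes()].
#' @param std Standard population used for the expectation.
#' @return Tibble `period,sex,group,scheme,asmr` (`period` is the year as
#'   character), the oracle for parameter-recovery checks.
#' @export
true_asmr <- function(cfg, scheme = c("UCOD", "MCOD_HALF", "MCOD_EQUAL"),
                      std = who_standard_population()) {
  scheme <- match.arg(scheme)
  cfg <- validate_sim_config(cfg)
  std <- normalize_standard(std)
  groups <- cause_groups()
  profile <- cfg$comorbidity_profile[, intersect(colnames(cfg$comorbidity_profile),
                                                 groups), drop = FALSE]
  q <- matrix(0, nrow = length(groups), ncol = length(groups),
              dimnames = list(groups, groups))
  q[rownames(profile), colnames(profile)] <- profile

  out <- list()
  for (y in cfg$years) {
    ys <- as.character(y)
    pk <- part2_count_probs(cfg$part2_zero_prob[ys], cfg$part2_lambda[ys])
    kk <- 0:6
    pi0 <- pk[1]
    ek1 <- sum(pk / (kk + 1))
    ekk <- sum(pk * kk / (kk + 1))
    e2k1 <- sum(pk / (kk + 2))
    e2kk <- sum(pk * kk / (kk + 2))
    p_comp <- if (y %in% cfg$pandemic_years) cfg$competition_prob else 0

    # expected weight landing on group j per death with (original) UCOD g
    w_nc <- function(g) {
      w <- setNames(numeric(length(groups)), groups)
      if (scheme == "UCOD") {
        w[g] <- 1
      } else if (scheme == "MCOD_HALF") {
        w <- 0.5 * (1 - pi0) * q[g, ]
        w[g] <- w[g] + pi0 + 0.5 * (1 - pi0)
      } else {
        w <- ekk * q[g, ]
        w[g] <- w[g] + ek1
      }
      w
    }
    w_comp <- function(g) {
      w <- setNames(numeric(length(groups)), groups)
      if (scheme == "UCOD") {
        w["COVID19"] <- 1
      } else if (scheme == "MCOD_HALF") {
        w <- 0.5 * (ekk * q[g, ])
        w[g] <- w[g] + 0.5 * ek1
        w["COVID19"] <- w["COVID19"] + 0.5
      } else {
        w <- e2kk * q[g, ]
        w[g] <- w[g] + e2k1
        w["COVID19"] <- w["COVID19"] + e2k1
      }
      w
    }

    haz <- cfg$cause_hazards
    haz$rate_y <- ifelse(haz$group == "COVID19",
                         haz$rate * cfg$covid_multiplier[ys], haz$rate)
    for (s in unique(haz$sex)) {
      hs <- haz[haz$sex == s, ]
      wide <- tidyr::pivot_wider(hs[c("age_group", "group", "rate_y")],
                                 names_from = "group", values_from = "rate_y")
      wide <- wide[match(std$age_group, wide$age_group), ]
      rate_j <- matrix(0, nrow = nrow(wide), ncol = length(groups),
                       dimnames = list(NULL, groups))
      for (g in setdiff(groups, "ILL_DEFINED")) {
        h <- wide[[g]]
        if (is.null(h)) next
        if (g %in% c("CVD", "DM") && p_comp > 0) {
          rate_j <- rate_j + outer(h, (1 - p_comp) * w_nc(g) + p_comp * w_comp(g))
        } else {
          rate_j <- rate_j + outer(h, w_nc(g))
        }
      }
      asmr <- colSums(std$std_weight * rate_j)
      out[[length(out) + 1]] <- tibble::tibble(
        period = ys, sex = s, group = groups, scheme = scheme,
        asmr = unname(asmr)
      )
    }
  }
  dplyr::bind_rows(out)
}
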