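#' Table-1-style tabulation of decedent characteristics
#'
#' Summarizes certificates per period: counts by sex, by coarse reporting age
#' bands, by UCOD cause group, and the Part II completion distribution
#' (0, 1, 2, 3+ contributing causes) — the latter both as recorded and after
#' dropping invalid/ill-defined mentions, since completeness statistics are
#' sensitive to that cleaning.
#'
#' @param records Cleaned records ([clean_certificates()]). All records are
#'   tabulated, including ill-defined and rejected ones (they are part of the
#'   registry even though they leave the weighted analysis).
#' @param band_breaks Lower bounds of the reporting age bands.
#' @return Long tibble `table,level,period,n,pct` (`pct` within period).
#' @export
tabulate_certificates <- function(records,
                                  band_breaks = c(0L, seq(20L, 80L, 10L))) {
  recs <- records
  recs$period <- as.character(recs$year)
  one <- function(var, label) {
    recs |>
      dplyr::filter(!is.na(.data[[var]])) |>
      dplyr::count(.data$period, level = as.character(.data[[var]])) |>
      dplyr::group_by(.data$period) |>
      dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup() |>
      dplyr::mutate(table = label, .before = 1)
  }
  recs$age_band <- age_group_label(recs$age, band_breaks)
  recs$part2_recorded <- pmin(recs$n_part2, 3L)
  recs$part2_cleaned <- pmin(recs$n_part2_clean, 3L)
  recs$part2_recorded <- ifelse(recs$part2_recorded == 3L, "3+",
                                as.character(recs$part2_recorded))
  recs$part2_cleaned <- ifelse(recs$part2_cleaned == 3L, "3+",
                               as.character(recs$part2_cleaned))
  dplyr::bind_rows(
    one("sex", "sex"),
    one("age_band", "age_group"),
    one("ucod_group", "cause_group"),
    one("part2_recorded", "part2_completion_recorded"),
    one("part2_cleaned", "part2_completion_cleaned")
  )
}

#' Run the full weighted-mortality pipeline
#'
#' Orchestrates clean -> impute -> weight -> standardize -> contrast from a
#' single configuration: reads (or accepts in-memory) death records,
#' population denominators, a standard population and a cause map; imputes
#' missing sex and age; aggregates fractional cause weights under each
#' requested scheme; computes age-standardized rates; and contrasts each
#' multiple-cause scheme against the UCOD scheme. All randomness flows from
#' one master seed through fixed named streams, so a rerun with the same
#' configuration is byte-identical.
#'
#' @param config A named list (or path to a YAML/JSON file) with elements:
#'   `deaths`, `population` (tibbles or file paths), optional `standard` and
#'   `cause_map` (default WHO standard / packaged map), `schemes` (default all
#'   three), `contrasts` (default `TRUE`; requires `"UCOD"` among schemes),
#'   `period_resolution` (`"year"`/`"month"`), `age_breaks`, `variance`
#'   (`"poisson"`/`"weighted"`), `ci` (`"gamma"`/`"normal"`),
#'   `age_impute_method`, `out_dir` (optional: write tidy delimited outputs
#'   and a JSON run log), `seed`.
#' @return An `mc_pipeline` object: list with `rates`, `contrasts`,
#'   `tabulation`, `records` (cleaned, imputed) and `log`. Use [tidy()] for
#'   the contrast table and [glance()] for the accounting summary.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  cfg <- utils::modifyList(list(
    standard = NULL, cause_map = NULL, schemes = weight_schemes(),
    contrasts = TRUE, period_resolution = "year",
    age_breaks = default_age_breaks(), variance = "poisson", ci = "gamma",
    age_impute_method = "pmm", out_dir = NULL, seed = 1L
  ), config)
  if (isTRUE(cfg$contrasts) && !"UCOD" %in% cfg$schemes) {
    stop("configuration error: contrasts require the UCOD scheme", call. = FALSE)
  }
  for (f in c("deaths", "population")) {
    if (is.character(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("configuration error: ", f, " file not found: ", cfg[[f]], call. = FALSE)
    }
  }
  deaths <- if (is.character(cfg$deaths)) read_death_records(cfg$deaths) else cfg$deaths
  pop <- if (is.character(cfg$population)) read_population(cfg$population) else cfg$population
  std <- if (is.null(cfg$standard)) {
    who_standard_population()
  } else if (is.character(cfg$standard)) {
    read_standard_population(cfg$standard)
  } else cfg$standard
  map <- if (is.null(cfg$cause_map)) {
    default_cause_map()
  } else if (is.character(cfg$cause_map)) {
    read_cause_map(cfg$cause_map)
  } else validate_cause_map(cfg$cause_map)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  recs <- stage("clean", clean_certificates(deaths, map))
  n_input <- nrow(recs)
  n_rejected <- sum(recs$rejected)
  n_excluded <- sum(recs$excluded & !recs$rejected)
  analyzed <- recs[!recs$rejected & !recs$excluded, ]
  analyzed <- stage("impute", {
    a <- impute_sex(analyzed, seed = stream_seed(cfg$seed, "impute_sex"))
    imputed_sex <- attr(a, "imputed_sex")
    a <- impute_age(a, method = cfg$age_impute_method,
                    seed = stream_seed(cfg$seed, "impute_age"),
                    age_breaks = cfg$age_breaks)
    attr(a, "imputed_sex") <- imputed_sex
    a
  })

  py <- stage("person_years", person_years(pop, cfg$period_resolution))
  rates <- list()
  for (sch in cfg$schemes) {
    rates[[sch]] <- stage(paste0("rates:", sch), {
      aggregate_weights(analyzed, sch, map, cfg$period_resolution,
                        cfg$age_breaks) |>
        age_specific_rates(py, variance = cfg$variance) |>
        standardize_rates(std, ci = cfg$ci)
    })
  }
  contrasts <- NULL
  if (isTRUE(cfg$contrasts)) {
    contrasts <- dplyr::bind_rows(lapply(
      setdiff(cfg$schemes, "UCOD"),
      function(sch) stage(paste0("contrast:", sch),
                          rate_contrast(rates[[sch]], rates[["UCOD"]]))
    ))
    class(contrasts) <- c("mc_contrast", setdiff(class(contrasts), "mc_contrast"))
  }
  tabulation <- stage("tabulate", tabulate_certificates(recs))
  all_rates <- dplyr::bind_rows(rates)
  class(all_rates) <- c("mc_rates", setdiff(class(all_rates), "mc_rates"))

  log <- list(
    package_version = as.character(utils::packageVersion("multicause")),
    seed = cfg$seed,
    schemes = cfg$schemes,
    period_resolution = cfg$period_resolution,
    variance = cfg$variance, ci = cfg$ci,
    n_input = n_input, n_rejected = n_rejected,
    n_excluded_ill_defined = n_excluded,
    n_analyzed = nrow(analyzed),
    imputed_sex = attr(analyzed, "imputed_sex") %||% 0L,
    imputed_age = attr(analyzed, "imputed_age") %||% 0L
  )
  stopifnot(log$n_input == log$n_analyzed + log$n_excluded_ill_defined + log$n_rejected)

  out <- structure(list(rates = all_rates, contrasts = contrasts,
                        tabulation = tabulation, records = analyzed, log = log),
                   class = "mc_pipeline")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(all_rates, file.path(cfg$out_dir, "rates.csv"), progress = FALSE)
    if (!is.null(contrasts)) {
      readr::write_csv(contrasts, file.path(cfg$out_dir, "contrasts.csv"),
                       progress = FALSE)
    }
    readr::write_csv(tabulation, file.path(cfg$out_dir, "tabulation.csv"),
                     progress = FALSE)
    jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

# independent named randomness streams derived from one master seed
stream_seed <- function(master, name) {
  v <- utf8ToInt(name)
  h <- sum(v * seq_along(v))
  abs((as.integer(master) %% 1000003L) * 1009L + h) %% 2147483647L
}

#' @export
print.mc_pipeline <- function(x, ...) {
  cat("<mc_pipeline>\n")
  cat("  analyzed records:", x$log$n_analyzed,
      "(excluded ill-defined:", x$log$n_excluded_ill_defined,
      ", rejected:", x$log$n_rejected, ")\n")
  cat("  schemes:", paste(x$log$schemes, collapse = ", "), "\n")
  cat("  rate strata:", nrow(x$rates), "\n")
  if (!is.null(x$contrasts)) cat("  contrast strata:", nrow(x$contrasts), "\n")
  invisible(x)
}

#' @rdname run_pipeline
#' @param x An `mc_pipeline` object.
#' @param ... Unused.
#' @export
tidy.mc_pipeline <- function(x, ...) {
  if (is.null(x$contrasts)) x$rates else x$contrasts
}

#' @rdname run_pipeline
#' @export
glance.mc_pipeline <- function(x, ...) {
  tibble::as_tibble(x$log[c("n_input", "n_rejected", "n_excluded_ill_defined",
                            "n_analyzed", "imputed_sex", "imputed_age", "seed")])
}
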