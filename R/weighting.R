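#' Weighting schemes
#'
#' The three attribution schemes: `UCOD` gives the full unit weight to the
#' underlying cause; `MCOD_HALF` (the primary multiple-cause scheme) gives
#' half the weight to the underlying cause and divides the other half equally
#' among the Part II contributing causes; `MCOD_EQUAL` (the sensitivity
#' scheme) divides the unit weight equally across the underlying cause and
#' every contributing cause. Under every scheme each decedent carries total
#' weight 1, so adding mentions redistributes weight rather than inflating
#' cause-specific counts.
#'
#' @return Character vector of scheme labels.
#' @export
weight_schemes <- function() c("UCOD", "MCOD_HALF", "MCOD_EQUAL")

#' Assign fractional cause weights to cleaned certificates
#'
#' Expands each certificate into one row per weighted cause mention. With `k`
#' clean Part II mentions: `UCOD` puts weight 1 on the underlying cause;
#' `MCOD_HALF` puts 0.5 on it and `0.5/k` on each mention (1 when `k = 0`);
#' `MCOD_EQUAL` puts `1/(k+1)` on every code. Duplicate mentions, including a
#' Part II repeat of the UCOD code, each receive their own weight (by default;
#' `drop_ucod_duplicates` removes Part II mentions equal to the UCOD code
#' before weighting).
#'
#' @param records Cleaned records ([clean_certificates()]); must contain no
#'   excluded or rejected rows — attempting to weight an ill-defined
#'   certificate is a hard error, not a silent drop.
#' @param scheme One of [weight_schemes()].
#' @param map Cause-map tibble used to label each weighted code.
#' @param drop_ucod_duplicates Drop Part II codes identical to the UCOD code
#'   before weighting. Default `FALSE` (the literal reading: the certificate
#'   said it twice, it is weighted twice).
#' @return Tibble with one row per weight: `record_id`, `code`, `source`
#'   (`"ucod"`/`"part2"`), `group`, `weight`. Weights sum to 1 within each
#'   record.
#' @examples
#' recs <- clean_certificates(tibble::tibble(
#'   record_id = "d1", year = 2020L, month = 3L, sex = "F", age = 67L,
#'   ucod = "E11", part2 = list(c("I10", "J18"))
#' ))
#' assign_weights(recs, "MCOD_HALF")
#' @export
assign_weights <- function(records, scheme = c("UCOD", "MCOD_HALF", "MCOD_EQUAL"),
                           map = default_cause_map(), drop_ucod_duplicates = FALSE) {
  scheme <- match.arg(scheme)
  if (any(records$excluded)) {
    stop("cannot assign weights to certificates excluded for an ill-defined ",
         "underlying cause; filter them out first", call. = FALSE)
  }
  if (any(records$rejected)) {
    stop("cannot assign weights to certificates with an unparseable ",
         "underlying cause; filter them out first", call. = FALSE)
  }
  p2 <- records$part2_clean
  if (drop_ucod_duplicates) {
    p2 <- purrr::map2(p2, records$ucod, function(v, u) v[v != u])
  }
  k <- lengths(p2)
  w_ucod <- switch(scheme,
    UCOD = rep(1, nrow(records)),
    MCOD_HALF = ifelse(k == 0, 1, 0.5),
    MCOD_EQUAL = 1 / (k + 1)
  )
  ucod_rows <- tibble::tibble(
    record_id = records$record_id,
    code = records$ucod,
    source = "ucod",
    weight = w_ucod
  )
  if (scheme == "UCOD" || sum(k) == 0) {
    out <- ucod_rows
  } else {
    idx <- rep.int(seq_along(p2), k)
    w_p2 <- switch(scheme,
      MCOD_HALF = 0.5 / k,
      MCOD_EQUAL = 1 / (k + 1)
    )
    part2_rows <- tibble::tibble(
      record_id = records$record_id[idx],
      code = unlist(p2, use.names = FALSE),
      source = "part2",
      weight = w_p2[idx]
    )
    out <- dplyr::bind_rows(ucod_rows, part2_rows)
  }
  out$group <- map_cause_group(out$code, map)
  out[c("record_id", "code", "source", "group", "weight")]
}

#' Aggregate cause weights into stratified counts
#'
#' Runs [assign_weights()] and sums weights (and squared weights, kept for the
#' compound-Poisson variance option of the rates step) into a complete
#' stratified table: every combination of period, sex, age group and cause
#' group present in the analysis frame is emitted, zero-filled where no weight
#' landed. Excluded (ill-defined UCOD) and rejected certificates are removed
#' before aggregation and contribute to no group; a non-excluded record with
#' missing sex or age is a hard error directing the caller to imputation.
#'
#' @param records Cleaned records ([clean_certificates()]).
#' @param scheme One of [weight_schemes()].
#' @param map Cause-map tibble.
#' @param period_resolution `"year"` or `"month"`; monthly periods are labelled
#'   `"YYYY-MM"`.
#' @param age_breaks Lower bounds of the age bands (see [age_group_label()]).
#' @param drop_ucod_duplicates Passed to [assign_weights()].
#' @return A tibble with columns `period`, `sex`, `age_group`, `group`,
#'   `scheme`, `weighted_deaths`, `sum_sq_weights`. Within every
#'   period-sex-age stratum the `weighted_deaths` sum over groups equals the
#'   number of analyzed certificates.
#' @export
aggregate_weights <- function(records, scheme = c("UCOD", "MCOD_HALF", "MCOD_EQUAL"),
                              map = default_cause_map(),
                              period_resolution = c("year", "month"),
                              age_breaks = default_age_breaks(),
                              drop_ucod_duplicates = FALSE) {
  scheme <- match.arg(scheme)
  period_resolution <- match.arg(period_resolution)
  keep <- !records$excluded & !records$rejected
  recs <- records[keep, ]
  if (nrow(recs) == 0) stop("no analyzable certificates after exclusions", call. = FALSE)
  if (anyNA(recs$sex) || anyNA(recs$age)) {
    stop("records with missing sex or age cannot be aggregated; ",
         "run impute_sex()/impute_age() first", call. = FALSE)
  }
  recs$period <- period_label(recs$year, recs$month, period_resolution)
  recs$age_group <- age_group_label(recs$age, age_breaks)

  w <- assign_weights(recs, scheme, map, drop_ucod_duplicates = drop_ucod_duplicates)
  key <- recs[c("record_id", "period", "sex", "age_group")]
  w <- dplyr::left_join(w, key, by = "record_id")

  groups <- unique(c(map$group, "OTHER"))
  grid <- tidyr::expand_grid(
    period = sort(unique(recs$period)),
    sex = sort(unique(recs$sex)),
    age_group = age_group_labels(age_breaks),
    group = groups
  )
  agg <- w |>
    dplyr::group_by(.data$period, .data$sex, .data$age_group, .data$group) |>
    dplyr::summarise(
      weighted_deaths = sum(.data$weight),
      sum_sq_weights = sum(.data$weight^2),
      .groups = "drop"
    )
  out <- grid |>
    dplyr::left_join(agg, by = c("period", "sex", "age_group", "group")) |>
    dplyr::mutate(
      weighted_deaths = dplyr::coalesce(.data$weighted_deaths, 0),
      sum_sq_weights = dplyr::coalesce(.data$sum_sq_weights, 0),
      scheme = scheme,
      .before = "weighted_deaths"
    )
  out[c("period", "sex", "age_group", "group", "scheme",
        "weighted_deaths", "sum_sq_weights")]
}

period_label <- function(year, month, resolution) {
  if (resolution == "year") as.character(year) else sprintf("%d-%02d", year, month)
}
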