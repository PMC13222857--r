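#' Standardized rate differences and ratios: MCOD versus UCOD
#'
#' For each period-sex-group stratum, contrasts a multiple-cause standardized
#' rate with the matching underlying-cause rate: the rate difference
#' `rd = asmr_mcod - asmr_ucod` (per 100,000) and the rate ratio
#' `rr = asmr_mcod / asmr_ucod`. Values at the null (0 and 1) mean the
#' multiple-cause view adds nothing to the underlying-cause picture for that
#' group. CIs use the independence approximation: `var(rd) = var_m + var_u`
#' and a log-normal interval for `rr` with
#' `var(log rr) = var_m / asmr_m^2 + var_u / asmr_u^2`. The two rates are
#' computed from the same decedents, so these intervals are conservative for
#' `rd`; see [contrast_bootstrap()] for correlation-respecting intervals.
#'
#' @param mcod,ucod `mc_rates` tibbles from [standardize_rates()] under a
#'   multiple-cause scheme and the UCOD scheme, over identical strata.
#' @param level Confidence level.
#' @return A `mc_contrast` tibble: `period,sex,group,scheme`, both ASMRs,
#'   `rd,rd_low,rd_high,rr,rr_low,rr_high`. When the UCOD ASMR is 0 the
#'   ratio columns are `NA` (undefined), the difference is still reported.
#' @examples
#' # identical inputs give rd = 0, rr = 1 in every stratum
#' @export
rate_contrast <- function(mcod, ucod, level = 0.95) {
  keys <- c("period", "sex", "group")
  u <- ucod[c(keys, "asmr", "asmr_var")]
  names(u)[4:5] <- c("asmr_ucod", "var_ucod")
  x <- dplyr::inner_join(
    dplyr::rename(mcod, asmr_mcod = "asmr", var_mcod = "asmr_var"),
    u, by = keys
  )
  if (nrow(x) != nrow(mcod) || nrow(x) != nrow(ucod)) {
    stop("mcod and ucod rate tables do not cover identical strata", call. = FALSE)
  }
  z <- qnorm(1 - (1 - level) / 2)
  rd <- x$asmr_mcod - x$asmr_ucod
  rd_se <- sqrt(x$var_mcod + x$var_ucod)
  pos <- x$asmr_ucod > 0 & x$asmr_mcod > 0
  rr <- ifelse(x$asmr_ucod > 0, x$asmr_mcod / x$asmr_ucod, NA_real_)
  log_se <- ifelse(pos,
                   sqrt(x$var_mcod / x$asmr_mcod^2 + x$var_ucod / x$asmr_ucod^2),
                   NA_real_)
  out <- tibble::tibble(
    period = x$period, sex = x$sex, group = x$group, scheme = x$scheme,
    asmr_mcod = x$asmr_mcod, asmr_ucod = x$asmr_ucod,
    rd = rd, rd_low = rd - z * rd_se, rd_high = rd + z * rd_se,
    rr = rr,
    rr_low = ifelse(pos, rr * exp(-z * log_se), ifelse(is.na(rr), NA_real_, 0)),
    rr_high = ifelse(pos, rr * exp(z * log_se), NA_real_)
  )
  class(out) <- c("mc_contrast", class(out))
  out
}

#' Bootstrap confidence intervals for MCOD-vs-UCOD contrasts
#'
#' The multiple-cause and underlying-cause standardized rates come from the
#' same certificates and are strongly positively correlated, so
#' independence-based intervals for the rate difference over-cover. This
#' resamples whole certificates with replacement, recomputing both ASMRs and
#' their contrast per replicate, and returns percentile intervals that
#' respect the within-record correlation.
#'
#' @param records Cleaned, imputed records (no missing sex/age among analyzed
#'   rows); excluded/rejected rows are dropped internally.
#' @param pop Annual population table (`year,sex,age_group,population`).
#' @param std Standard-population tibble.
#' @param scheme Multiple-cause scheme to contrast against `UCOD`.
#' @param map Cause map.
#' @param period_resolution `"year"` or `"month"`.
#' @param age_breaks Age bands.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return A `mc_contrast` tibble with percentile `rd`/`rr` intervals; point
#'   estimates are from the original (unresampled) data.
#' @export
contrast_bootstrap <- function(records, pop, std = who_standard_population(),
                               scheme = c("MCOD_HALF", "MCOD_EQUAL"),
                               map = default_cause_map(),
                               period_resolution = c("year", "month"),
                               age_breaks = default_age_breaks(),
                               B = 200L, seed = 1L, level = 0.95) {
  scheme <- match.arg(scheme)
  period_resolution <- match.arg(period_resolution)
  std <- normalize_standard(std)
  recs <- records[!records$excluded & !records$rejected, ]
  if (anyNA(recs$sex) || anyNA(recs$age)) {
    stop("impute sex/age before bootstrapping", call. = FALSE)
  }
  recs$.row <- seq_len(nrow(recs))
  recs$period <- period_label(recs$year, recs$month, period_resolution)
  recs$age_group <- age_group_label(recs$age, age_breaks)
  py <- person_years(pop, period_resolution)

  # per-record scaled contributions to each (period, sex, group) ASMR
  contrib <- function(sch) {
    w <- assign_weights(recs, sch, map)
    w |>
      dplyr::left_join(recs[c("record_id", ".row", "period", "sex", "age_group")],
                       by = "record_id") |>
      dplyr::left_join(py, by = c("period", "sex", "age_group")) |>
      dplyr::left_join(std, by = "age_group") |>
      dplyr::mutate(c = 1e5 * .data$std_weight * .data$weight / .data$person_years) |>
      dplyr::group_by(.data$.row, .data$period, .data$sex, .data$group) |>
      dplyr::summarise(c = sum(.data$c), .groups = "drop")
  }
  cm <- contrib(scheme)
  cu <- contrib("UCOD")
  strata <- dplyr::distinct(dplyr::bind_rows(cm[c("period", "sex", "group")],
                                             cu[c("period", "sex", "group")]))
  strata <- dplyr::arrange(strata, .data$period, .data$sex, .data$group)
  strata$.key <- seq_len(nrow(strata))
  cm <- dplyr::left_join(cm, strata, by = c("period", "sex", "group"))
  cu <- dplyr::left_join(cu, strata, by = c("period", "sex", "group"))
  n <- nrow(recs)
  S <- nrow(strata)
  asmr_m0 <- vapply(seq_len(S), function(s) sum(cm$c[cm$.key == s]), 0)
  asmr_u0 <- vapply(seq_len(S), function(s) sum(cu$c[cu$.key == s]), 0)

  rd_draws <- matrix(NA_real_, B, S)
  rr_draws <- matrix(NA_real_, B, S)
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      freq <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
      m <- rowsum(cm$c * freq[cm$.row], cm$.key)
      u <- rowsum(cu$c * freq[cu$.row], cu$.key)
      mv <- uv <- numeric(S)
      mv[as.integer(rownames(m))] <- m
      uv[as.integer(rownames(u))] <- u
      rd_draws[b, ] <- mv - uv
      rr_draws[b, ] <- ifelse(uv > 0, mv / uv, NA_real_)
    }
  })
  alpha <- (1 - level) / 2
  out <- strata
  out$scheme <- scheme
  out$asmr_mcod <- asmr_m0
  out$asmr_ucod <- asmr_u0
  out$rd <- asmr_m0 - asmr_u0
  q <- function(x, p) if (all(is.na(x))) NA_real_ else quantile(x, p, na.rm = TRUE, names = FALSE)
  out$rd_low <- apply(rd_draws, 2, q, p = alpha)
  out$rd_high <- apply(rd_draws, 2, q, p = 1 - alpha)
  out$rr <- ifelse(asmr_u0 > 0, asmr_m0 / asmr_u0, NA_real_)
  out$rr_low <- apply(rr_draws, 2, q, p = alpha)
  out$rr_high <- apply(rr_draws, 2, q, p = 1 - alpha)
  out$.key <- NULL
  class(out) <- c("mc_contrast", class(out))
  out
}
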