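# independent per-record brute-force weighting oracle: a plain double loop
# over certificates, no shared aggregation code with aggregate_weights()

oracle_aggregate <- function(records, scheme, map = default_cause_map(),
                             age_breaks = default_age_breaks()) {
  acc <- new.env(parent = emptyenv())
  add <- function(key, w) {
    cur <- acc[[key]]
    if (is.null(cur)) cur <- c(0, 0)
    acc[[key]] <- cur + c(w, w^2)
  }
  year <- records$year
  sex <- records$sex
  ageg <- age_group_label(records$age, age_breaks)
  ucod <- records$ucod
  p2 <- records$part2_clean
  skip <- records$excluded | records$rejected
  for (i in seq_len(nrow(records))) {
    if (skip[i]) next
    stratum <- paste(year[i], sex[i], ageg[i], sep = "|")
    codes <- if (scheme == "UCOD") ucod[i] else c(ucod[i], p2[[i]])
    k <- length(p2[[i]])
    w <- switch(scheme,
      UCOD = 1,
      MCOD_HALF = if (k == 0) 1 else c(0.5, rep(0.5 / k, k)),
      MCOD_EQUAL = rep(1 / (k + 1), k + 1)
    )
    for (j in seq_along(codes)) {
      add(paste(stratum, map_cause_group(codes[j], map), sep = "|"), w[j])
    }
  }
  keys <- ls(acc)
  parts <- strsplit(keys, "|", fixed = TRUE)
  tibble::tibble(
    period = vapply(parts, `[`, "", 1),
    sex = vapply(parts, `[`, "", 2),
    age_group = vapply(parts, `[`, "", 3),
    group = vapply(parts, `[`, "", 4),
    weighted_deaths = vapply(keys, function(k) acc[[k]][1], 0),
    sum_sq_weights = vapply(keys, function(k) acc[[k]][2], 0)
  )
}

compare_to_oracle <- function(records, scheme, age_breaks = default_age_breaks()) {
  agg <- aggregate_weights(records, scheme, age_breaks = age_breaks)
  orc <- oracle_aggregate(records, scheme, age_breaks = age_breaks)
  joined <- dplyr::full_join(
    agg, orc,
    by = c("period", "sex", "age_group", "group"), suffix = c("_agg", "_orc")
  ) |>
    dplyr::mutate(dplyr::across(dplyr::starts_with(c("weighted", "sum")),
                                ~ dplyr::coalesce(.x, 0)))
  max(abs(joined$weighted_deaths_agg - joined$weighted_deaths_orc),
      abs(joined$sum_sq_weights_agg - joined$sum_sq_weights_orc))
}
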