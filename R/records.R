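#' Read death records from delimited text
#'
#' Expects one row per decedent with columns
#' `record_id,year,month,sex,age,ucod,cc1..ccN` — a variable number of
#' contributing-cause columns holding Part II mentions in certificate order
#' (blank cells ignored). Codes are kept raw here; [clean_certificates()]
#' normalizes and validates them.
#'
#' @param path Path to a UTF-8 delimited (comma) text file.
#' @return A tibble with columns `record_id`, `year`, `month`, `sex`
#'   (`"M"`/`"F"`/`NA`), `age` (integer years, `NA` allowed), `ucod`, and a
#'   list-column `part2` of character vectors.
#' @export
read_death_records <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("record_id", "year", "month", "sex", "age", "ucod")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("death-record file missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  cc_cols <- grep("^cc[0-9]+$", names(raw), value = TRUE)
  cc_cols <- cc_cols[order(as.integer(sub("^cc", "", cc_cols)))]
  cc <- as.matrix(raw[cc_cols])
  part2 <- lapply(seq_len(nrow(raw)), function(i) {
    v <- cc[i, ]
    v <- v[!is.na(v) & trimws(v) != ""]
    unname(as.character(v))
  })
  tibble::tibble(
    record_id = raw$record_id,
    year = as.integer(raw$year),
    month = as.integer(raw$month),
    sex = ifelse(raw$sex %in% c("M", "F"), raw$sex, NA_character_),
    age = suppressWarnings(as.integer(raw$age)),
    ucod = raw$ucod,
    part2 = part2
  )
}

#' Write death records as delimited text
#'
#' Inverse of [read_death_records()]: the `part2` list-column is spread into
#' `cc1..ccN` columns, where N is the longest Part II list present.
#'
#' @param records Death-record tibble with a `part2` list-column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_death_records <- function(records, path) {
  k <- max(c(0L, lengths(records$part2)))
  out <- records[c("record_id", "year", "month", "sex", "age", "ucod")]
  if (k > 0) {
    for (j in seq_len(k)) {
      out[[paste0("cc", j)]] <-
        vapply(records$part2, function(v) if (length(v) >= j) v[j] else NA_character_, "")
    }
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Default 5-year age bands
#'
#' Lower bounds of the 5-year age groups 0-4 ... 80-84 with an open-ended
#' 85+ band, matching the bands on which the packaged standard population is
#' defined.
#'
#' @return Integer vector of band lower bounds.
#' @export
default_age_breaks <- function() seq(0L, 85L, by = 5L)

#' Label ages with age-group bands
#'
#' @param age Integer ages in years.
#' @param breaks Strictly increasing lower bounds of the bands; the last band
#'   is open-ended (`"85+"` style).
#' @return Character labels, `NA` for `NA` ages.
#' @export
age_group_label <- function(age, breaks = default_age_breaks()) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("age breaks must be strictly increasing", call. = FALSE)
  }
  labs <- age_group_labels(breaks)
  idx <- findInterval(age, breaks)
  out <- rep(NA_character_, length(age))
  ok <- !is.na(age) & idx >= 1
  out[ok] <- labs[idx[ok]]
  out
}

age_group_labels <- function(breaks = default_age_breaks()) {
  n <- length(breaks)
  c(paste0(breaks[-n], "-", breaks[-1] - 1L), paste0(breaks[n], "+"))
}

#' Clean and classify death certificates
#'
#' Prepares parsed records for weighting: normalizes the underlying cause
#' (UCOD) and all Part II codes, maps the UCOD to its cause group, flags
#' records for exclusion when the UCOD is ill-defined (Chapter XVIII,
#' R00-R99 — these certificates carry no usable underlying cause and cannot
#' enter the weighting schemes), flags records whose UCOD does not parse as an
#' ICD-10 code at all, and drops invalid and ill-defined mentions from Part II
#' while preserving certificate order.
#'
#' @param records Death-record tibble as from [read_death_records()].
#' @param map Cause-map tibble.
#' @return The input with added columns `ucod` (normalized), `ucod_group`,
#'   `rejected` (unparseable UCOD), `excluded` (ill-defined UCOD),
#'   `part2_clean` (list-column), `n_part2` (raw Part II length) and
#'   `n_part2_clean`.
#' @examples
#' recs <- tibble::tibble(
#'   record_id = "d1", year = 2020L, month = 3L, sex = "F", age = 67L,
#'   ucod = "E11.9", part2 = list(c("R57", "I10"))
#' )
#' clean_certificates(recs)
#' @export
clean_certificates <- function(records, map = default_cause_map()) {
  ucod <- icd10_normalize(records$ucod)
  ucod_group <- map_cause_group(ucod, map)
  p2 <- records$part2
  n2 <- lengths(p2)
  flat <- icd10_normalize(unlist(p2, use.names = FALSE))
  grp <- map_cause_group(flat, map)
  keep <- !is.na(flat) & grp != "ILL_DEFINED"
  idx <- rep.int(seq_along(p2), n2)
  part2_clean <- split(flat[keep], factor(idx[keep], levels = seq_along(p2)))
  part2_clean <- lapply(part2_clean, unname)
  out <- records
  out$ucod <- ucod
  out$ucod_group <- ucod_group
  out$rejected <- is.na(ucod)
  out$excluded <- !is.na(ucod_group) & ucod_group == "ILL_DEFINED"
  out$part2_clean <- unname(part2_clean)
  out$n_part2 <- n2
  out$n_part2_clean <- lengths(out$part2_clean)
  out
}
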