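#' Cause-group labels used throughout the package
#'
#' The fixed set of analysis groups: the four disease groups under study
#' (neoplasms, circulatory system diseases, diabetes mellitus, communicable
#' diseases), COVID-19, ill-defined causes (ICD-10 Chapter XVIII), and a
#' residual. COVID-19 is kept out of the communicable-diseases group so that
#' pandemic-period cause competition can be observed rather than absorbed.
#'
#' @return Character vector of the seven group labels, in matching order
#'   (the residual label `"OTHER"` last).
#' @export
cause_groups <- function() {
  c("NEOPLASMS", "CVD", "DM", "CD", "COVID19", "ILL_DEFINED", "OTHER")
}

.icd_pattern <- "^[A-Z][0-9]{2}[A-Z0-9]?$"

#' Normalize raw ICD-10 code strings
#'
#' Strips dots and whitespace, upper-cases, and validates against the
#' 3-to-4-character ICD-10 shape (letter, two digits, optional alphanumeric
#' fourth character). Invalid entries become `NA` rather than errors: rejection
#' is a value, and downstream cleaning decides what to do with it.
#'
#' @param raw Character vector of raw code strings (e.g. `"e11.9"`, `"I21"`).
#' @return Character vector of the same length; normalized codes, `NA` where
#'   the input does not parse as an ICD-10 code.
#' @examples
#' icd10_normalize(c("e11.9", "I21", "XX!"))
#' @export
icd10_normalize <- function(raw) {
  x <- toupper(gsub("[.[:space:]]", "", as.character(raw)))
  x[x == ""] <- NA_character_
  ok <- !is.na(x) & grepl(.icd_pattern, x)
  ifelse(ok, x, NA_character_)
}

#' Default cause-group map
#'
#' The packaged condensed cause list: ordered inclusive code-prefix ranges,
#' first match wins, unmatched valid codes fall to `OTHER`. COVID-19
#' (U071/U072) is listed first so it is carved out of communicable diseases;
#' ill-defined causes (R00-R99) get their own group so they can be excluded
#' from weighting. The whole map is an ordinary tibble, so alternative
#' condensed-list readings are drop-in replacements (see [read_cause_map()]).
#'
#' @return A tibble with columns `group`, `range_start`, `range_end`, checked
#'   in row order.
#' @examples
#' default_cause_map()
#' @export
default_cause_map <- function() {
  map <- tibble::tribble(
    ~group,        ~range_start, ~range_end,
    "COVID19",     "U071",       "U072",
    "ILL_DEFINED", "R00",        "R99",
    "DM",          "E10",        "E14",
    "NEOPLASMS",   "C00",        "D48",
    "CVD",         "I00",        "I99",
    "CD",          "A00",        "B99",
    "CD",          "J00",        "J22"
  )
  validate_cause_map(map)
}

validate_cause_map <- function(map, file = NULL) {
  need <- c("group", "range_start", "range_end")
  if (!all(need %in% names(map))) {
    stop("cause map must have columns group, range_start, range_end", call. = FALSE)
  }
  map <- tibble::as_tibble(map)[need]
  map$range_start <- toupper(trimws(map$range_start))
  map$range_end <- toupper(trimws(map$range_end))
  bad_code <- !grepl(.icd_pattern, map$range_start) | !grepl(.icd_pattern, map$range_end)
  bad_len <- nchar(map$range_start) != nchar(map$range_end)
  bad_ord <- map$range_end < map$range_start
  bad <- which(bad_code | bad_len | bad_ord)
  if (length(bad)) {
    stop(sprintf(
      "malformed cause-map range in row %d: %s,%s,%s",
      bad[1], map$group[bad[1]], map$range_start[bad[1]], map$range_end[bad[1]]
    ), call. = FALSE)
  }
  # overlap within a group is a configuration error; across groups order resolves
  for (g in unique(map$group)) {
    rows <- map[map$group == g, ]
    if (nrow(rows) > 1) {
      o <- order(rows$range_start)
      rs <- rows$range_start[o]
      re <- rows$range_end[o]
      if (any(rs[-1] <= re[-length(re)] &
              nchar(rs[-1]) == nchar(re[-length(re)]))) {
        stop(sprintf("overlapping ranges within group %s", g), call. = FALSE)
      }
    }
  }
  map
}

#' Read a cause-group map from a delimited file
#'
#' @param path Path to a UTF-8 delimited text file with columns
#'   `group,range_start,range_end`. Rows are matched in file order, so list the
#'   most specific ranges (e.g. COVID-19) before the chapters that contain
#'   them. A range with `range_end < range_start` is a hard error naming the
#'   row.
#' @return A validated cause-map tibble, as [default_cause_map()].
#' @export
read_cause_map <- function(path) {
  map <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_cause_map(map, file = path)
}

#' Map ICD-10 codes to cause groups
#'
#' Pure, vectorized lookup: each code is compared, in map order, against the
#' inclusive prefix ranges; the first matching row's group is returned and
#' codes matching no row fall to `"OTHER"`. A 4-character range row (only
#' COVID-19 in the default map) matches on the first four characters, so a
#' bare 3-character code never matches it.
#'
#' @param codes Character vector of normalized ICD-10 codes (see
#'   [icd10_normalize()]); `NA`s map to `NA`.
#' @param map A cause-map tibble ([default_cause_map()] or [read_cause_map()]).
#' @return Character vector of group labels.
#' @examples
#' map_cause_group(c("E11", "U071", "R99", "K70"))
#' @export
map_cause_group <- function(codes, map = default_cause_map()) {
  out <- rep(NA_character_, length(codes))
  valid <- !is.na(codes)
  out[valid] <- "OTHER"
  for (i in seq_len(nrow(map))) {
    L <- nchar(map$range_start[i])
    pre <- substr(codes, 1L, L)
    hit <- valid & out == "OTHER" &
      nchar(codes) >= L & pre >= map$range_start[i] & pre <= map$range_end[i]
    out[hit] <- map$group[i]
  }
  out
}
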