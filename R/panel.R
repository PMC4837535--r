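#' Validate a resource panel
#'
#' A resource panel is a tibble with one row per geographic unit and year,
#' holding the population, land area and the amount of each of the four
#' resource indicators. Columns (units are encoded in the names):
#'
#' * `unit` — non-empty unit name, unique within each year,
#' * `year` — integer calendar year,
#' * `population_10k` — resident population in 10,000 persons (> 0),
#' * `area_10k_km2` — land area in 10,000 square kilometres (> 0),
#' * `institutions`, `personnel`, `beds`, `investment_100m_yuan` —
#'   non-negative resource amounts (counts; investment in
#'   hundred-million yuan).
#'
#' @param panel A data frame to validate.
#' @return The validated panel as a tibble, invisibly usable in a pipe.
#' @export
#' @examples
#' validate_panel(china_panel_2013())
validate_panel <- function(panel) {
  if (!is.data.frame(panel)) {
    abort_validation("`panel` must be a data frame.")
  }
  needed <- c("unit", "year", "population_10k", "area_10k_km2",
              unname(.indicator_cols))
  missing_cols <- setdiff(needed, names(panel))
  if (length(missing_cols) > 0) {
    abort_parse(c("Panel is missing required columns.",
                  x = paste("Missing:", paste(missing_cols, collapse = ", "))))
  }
  panel <- as_tibble(panel)
  if (nrow(panel) == 0) {
    abort_validation("Panel contains no rows (empty panel).")
  }
  num_cols <- setdiff(needed, "unit")
  for (cl in num_cols) {
    if (!is.numeric(panel[[cl]])) {
      abort_parse(sprintf("Column `%s` must be numeric.", cl))
    }
    if (anyNA(panel[[cl]])) {
      bad <- which(is.na(panel[[cl]]))
      abort_parse(sprintf("Column `%s` has non-numeric or missing cells (rows %s).",
                          cl, paste(head(bad, 5), collapse = ", ")))
    }
  }
  if (any(!nzchar(panel$unit) | is.na(panel$unit))) {
    abort_validation("Every `unit` name must be non-empty.")
  }
  if (any(panel$population_10k <= 0)) {
    bad <- panel$unit[panel$population_10k <= 0]
    abort_validation(sprintf("Population must be positive (violated by: %s).",
                             paste(bad, collapse = ", ")))
  }
  if (any(panel$area_10k_km2 <= 0)) {
    bad <- panel$unit[panel$area_10k_km2 <= 0]
    abort_validation(sprintf("Area must be positive (violated by: %s).",
                             paste(bad, collapse = ", ")))
  }
  for (cl in unname(.indicator_cols)) {
    if (any(panel[[cl]] < 0)) {
      bad <- panel$unit[panel[[cl]] < 0]
      abort_validation(sprintf("Resource `%s` must be non-negative (violated by: %s).",
                               cl, paste(bad, collapse = ", ")))
    }
  }
  dup <- panel %>%
    group_by(.data$year, .data$unit) %>%
    filter(n() > 1) %>%
    ungroup()
  if (nrow(dup) > 0) {
    pairs <- distinct(dup, .data$unit, .data$year)
    abort_validation(sprintf(
      "Duplicate unit-year rows: %s.",
      paste(sprintf("%s (%d)", pairs$unit, pairs$year), collapse = ", ")))
  }
  invisible(panel)
}

#' Read or write a resource panel CSV
#'
#' The on-disk schema is the column set documented in [validate_panel()],
#' UTF-8, period decimal separator, no thousands separators. `read_panel()`
#' validates on read and reports malformed cells with their row; full
#' double precision survives a write/read round trip.
#'
#' @param path Path to a panel CSV file.
#' @return `read_panel()` returns a validated panel tibble; `write_panel()`
#'   returns `panel` invisibly.
#' @export
#' @examples
#' p <- read_panel(system.file("extdata", "china_2013_panel.csv",
#'                             package = "theilequity"))
#' nrow(p)
read_panel <- function(path) {
  if (!file.exists(path)) {
    abort_parse(sprintf("Panel file not found: %s", path))
  }
  panel <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(unit = readr::col_character(),
                                            .default = readr::col_double())))
  probs <- readr::problems(panel)
  if (nrow(probs) > 0) {
    abort_parse(c("Malformed cells in panel CSV.",
                  x = paste(sprintf("row %d, col %d: expected %s, got %s",
                                    probs$row, probs$col, probs$expected,
                                    probs$actual), collapse = "; ")))
  }
  panel$year <- as.integer(panel$year)
  validate_panel(panel)
  panel
}

#' @rdname read_panel
#' @param panel A validated resource panel.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  readr::write_csv(panel, path)
  invisible(panel)
}

#' Packaged 2013 China panel and companions
#'
#' `china_panel_2013()` returns the 2013 cross-section of China's 31
#' provincial-level units (provinces, autonomous regions and
#' municipalities, excluding Hong Kong, Macao and Taiwan). Absolute
#' resource amounts are reconstructed as published per-10,000-capita
#' density times population; areas come from the published per-area
#' table. `china_partition()` returns the conventional east/central/west
#' three-region grouping of those 31 units. `china_national_totals()`
#' returns national totals and per-10,000-capita densities for 2009-2013,
#' one row per year; the national population exceeds the 31-unit sum
#' because some population (e.g. armed forces) is not attributed to any
#' provincial unit.
#'
#' @return A tibble (panel, partition or totals table respectively).
#' @export
#' @examples
#' china_panel_2013()
china_panel_2013 <- function() {
  read_panel(system.file("extdata", "china_2013_panel.csv",
                         package = "theilequity"))
}

#' @rdname china_panel_2013
#' @export
china_partition <- function() {
  read_partition(system.file("extdata", "china_regions.csv",
                             package = "theilequity"))
}

#' @rdname china_panel_2013
#' @export
china_national_totals <- function() {
  readr::read_csv(system.file("extdata", "china_national_totals.csv",
                              package = "theilequity"),
                  show_col_types = FALSE)
}

# Restrict a panel to one year, inferring the year when unique.
panel_slice <- function(panel, year = NULL) {
  validate_panel(panel)
  if (is.null(year)) {
    yrs <- unique(panel$year)
    if (length(yrs) > 1) {
      abort_validation(sprintf(
        "Panel spans several years (%s); supply `year`.",
        paste(sort(yrs), collapse = ", ")))
    }
    year <- yrs
  }
  out <- filter(panel, .data$year == !!year)
  if (nrow(out) == 0) {
    abort_validation(sprintf("Panel has no rows for year %s.", year))
  }
  out
}

match_indicator <- function(indicator) {
  if (!is.character(indicator) || length(indicator) != 1) {
    abort_validation("`indicator` must be a single indicator name.")
  }
  if (!indicator %in% names(.indicator_cols)) {
    abort_validation(c(
      sprintf("Unknown indicator `%s`.", indicator),
      i = paste("Valid indicators:", paste(names(.indicator_cols), collapse = ", "))))
  }
  .indicator_cols[[indicator]]
}
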