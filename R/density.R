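#' Density arithmetic
#'
#' `per_capita_density()` divides a resource amount by a population given
#' in 10,000-person units, yielding the amount per 10,000 persons.
#' `per_area_density()` divides by a land area in 10,000-km2 units,
#' yielding the amount per 10,000 km2. `percent_change()` returns
#' `100 * (last - first) / first`. All three are vectorized and validate
#' their denominators.
#'
#' @param amount Non-negative resource amount(s).
#' @param population Population(s) in 10,000-person units (> 0).
#' @param area Land area(s) in 10,000-km2 units (> 0).
#' @param first,last Densities (or any positive baseline and its later
#'   value); `first` must be positive.
#' @return A numeric vector.
#' @export
#' @examples
#' per_capita_density(6181891, 136072)   # beds per 10,000 persons
#' percent_change(33.10, 45.43)          # percent growth
per_capita_density <- function(amount, population) {
  if (any(!is.finite(population)) || any(population <= 0)) {
    abort_validation("`population` must be positive and finite.")
  }
  if (any(amount < 0)) abort_validation("`amount` must be non-negative.")
  amount / population
}

#' @rdname per_capita_density
#' @export
per_area_density <- function(amount, area) {
  if (any(!is.finite(area)) || any(area <= 0)) {
    abort_validation("`area` must be positive and finite.")
  }
  if (any(amount < 0)) abort_validation("`amount` must be non-negative.")
  amount / area
}

#' @rdname per_capita_density
#' @export
percent_change <- function(first, last) {
  if (any(!is.finite(first)) || any(first <= 0)) {
    abort_domain("`first` must be positive; percent change is undefined.")
  }
  100 * (last - first) / first
}

#' Per-capita and per-area density table
#'
#' One row per unit and indicator with the amount, the per-10,000-person
#' density and the per-10,000-km2 density. Densities scale linearly in
#' the amount.
#'
#' @inheritParams resource_shares
#' @param indicators Indicator names to include (default all four).
#' @return A tibble with columns `unit`, `year`, `indicator`, `amount`,
#'   `per_capita`, `per_area`.
#' @export
#' @examples
#' density_table(china_panel_2013(), indicators = "personnel")
density_table <- function(panel, year = NULL,
                          indicators = names(theil_indicators())) {
  slice <- panel_slice(panel, year)
  cols <- vapply(indicators, match_indicator, character(1))
  purrr::map_dfr(indicators, function(ind) {
    amt <- slice[[cols[[ind]]]]
    tibble(unit = slice$unit,
           year = slice$year,
           indicator = ind,
           amount = amt,
           per_capita = per_capita_density(amt, slice$population_10k),
           per_area = per_area_density(amt, slice$area_10k_km2))
  })
}

#' Ratio of the largest to the smallest density
#'
#' @param values Positive numeric vector of densities.
#' @param units Optional unit names aligned with `values`; when given,
#'   the extremal units are identified.
#' @return With `units = NULL`, a single number `max(values) /
#'   min(values)`. Otherwise a one-row tibble with columns `ratio`,
#'   `max_unit`, `max_value`, `min_unit`, `min_value`.
#' @export
#' @examples
#' extremal_ratio(c(2, 8))
#' d <- density_table(china_panel_2013(), indicators = "personnel")
#' extremal_ratio(d$per_area, d$unit)
extremal_ratio <- function(values, units = NULL) {
  if (length(values) < 1) abort_validation("`values` must be non-empty.")
  if (any(!is.finite(values)) || any(values <= 0)) {
    abort_domain("All densities must be positive; the max/min ratio is undefined.")
  }
  ratio <- max(values) / min(values)
  if (is.null(units)) return(ratio)
  if (length(units) != length(values)) {
    abort_validation("`units` must align with `values`.")
  }
  tibble(ratio = ratio,
         max_unit = units[which.max(values)], max_value = max(values),
         min_unit = units[which.min(values)], min_value = min(values))
}
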