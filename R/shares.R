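#' Build paired population and resource shares
#'
#' For one year of a panel and one indicator, computes each unit's
#' population share `p` and resource share `y`. These paired shares are
#' the sole input of the Theil index: equity means `y` tracks `p`.
#'
#' By default both vectors are normalized over the units of the slice, so
#' each sums to exactly 1. Published yearbook analyses sometimes divide
#' instead by a national reference total that exceeds the sum over units
#' (population not attributed to any unit, such as armed forces); pass
#' `population_total` and/or `resource_total` to reproduce that
#' convention, in which case the corresponding shares sum to slightly
#' less than 1 and the result carries a `reference_totals` attribute.
#'
#' @param panel A resource panel (see [validate_panel()]).
#' @param indicator One of `"institutions"`, `"personnel"`, `"beds"`,
#'   `"investment"`.
#' @param year Calendar year to slice on; may be omitted when the panel
#'   holds a single year.
#' @param population_total,resource_total Optional reference totals used
#'   as normalizing denominators instead of the slice sums. Must be at
#'   least the slice sum.
#' @return A tibble with columns `unit`, `p`, `y`, of class
#'   `"theil_shares"`, carrying `indicator` and `year` attributes.
#' @export
#' @examples
#' resource_shares(china_panel_2013(), "institutions")
resource_shares <- function(panel, indicator, year = NULL,
                            population_total = NULL, resource_total = NULL) {
  slice <- panel_slice(panel, year)
  col <- match_indicator(indicator)
  pop <- slice$population_10k
  amt <- slice[[col]]
  pop_sum <- sum(pop)
  amt_sum <- sum(amt)
  if (amt_sum <= 0) {
    abort_domain(sprintf(
      "Total %s is zero for this slice; resource shares are undefined.",
      indicator))
  }
  check_total <- function(total, sum, what) {
    if (!is.numeric(total) || length(total) != 1 || total <= 0) {
      abort_validation(sprintf("`%s_total` must be a single positive number.", what))
    }
    if (total < sum * (1 - 1e-9)) {
      abort_validation(sprintf(
        "`%s_total` (%g) is smaller than the slice sum (%g).", what, total, sum))
    }
    total
  }
  pt <- if (is.null(population_total)) pop_sum else
    check_total(population_total, pop_sum, "population")
  rt <- if (is.null(resource_total)) amt_sum else
    check_total(resource_total, amt_sum, "resource")
  out <- tibble(unit = slice$unit, p = pop / pt, y = amt / rt)
  ref <- !is.null(population_total) || !is.null(resource_total)
  structure(out,
            class = c("theil_shares", class(out)),
            indicator = indicator,
            year = unique(slice$year),
            reference_totals = if (ref)
              list(population = population_total, resource = resource_total))
}

# Minimal structural check for anything used as a share table.
check_shares <- function(shares) {
  if (!is.data.frame(shares) || !all(c("p", "y") %in% names(shares))) {
    abort_validation("`shares` must be a data frame with columns `p` and `y`.")
  }
  if (nrow(shares) == 0) {
    abort_validation("`shares` has no rows.")
  }
  if (any(shares$p < 0) || any(shares$y < 0)) {
    abort_validation("Shares must be non-negative.")
  }
  invisible(shares)
}
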