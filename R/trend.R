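#' Multi-year Theil trend table
#'
#' For every year-by-indicator slice of a panel, computes the national
#' Theil index and, when a partition is supplied, the within/between
#' decomposition, the contribution rates and one row per region holding
#' its internal Theil index `t_g` and its contribution `p_g t_g / T`.
#' A slice that fails (for instance because one indicator's total is
#' zero in one year) is dropped with a warning and recorded in the
#' `problems` attribute; the remaining slices are unaffected.
#'
#' @inheritParams resource_shares
#' @param partition Optional region partition (data frame with `unit`
#'   and `region`); without it only national rows are produced.
#' @param indicators Indicator names to include (default all four).
#' @param reference_population Optional reference population total(s)
#'   used as the denominator of the population shares instead of the
#'   slice sum (the published-yearbook convention; see
#'   [resource_shares()]). Either a single number applied to every year
#'   or a data frame with a `year` column and a `population_10k` (or
#'   `population_total`) column, such as [china_national_totals()].
#' @param epsilon Optional epsilon floor forwarded to the share
#'   computations.
#' @return A tibble of class `"theil_trend"` with columns `year`,
#'   `indicator`, `scope` (`"national"` or a region name), `theil`,
#'   `within`, `between`, `contribution_within`, `contribution_between`,
#'   `contribution`, sorted by year, indicator, scope (national first).
#'   Failed slices are listed in `attr(, "problems")`.
#' @export
#' @examples
#' theil_trend(china_panel_2013(), china_partition(),
#'             indicators = "personnel")
theil_trend <- function(panel, partition = NULL,
                        indicators = names(theil_indicators()),
                        reference_population = NULL, epsilon = NULL) {
  validate_panel(panel)
  vapply(indicators, match_indicator, character(1))
  years <- sort(unique(panel$year))

  ref_pop_for <- function(yr) {
    if (is.null(reference_population)) return(NULL)
    if (is.data.frame(reference_population)) {
      col <- intersect(c("population_10k", "population_total"),
                       names(reference_population))
      if (length(col) == 0 || !"year" %in% names(reference_population)) {
        abort_validation(
          "`reference_population` needs columns `year` and `population_10k`.")
      }
      hit <- reference_population$year == yr
      if (!any(hit)) return(NULL)
      reference_population[[col[1]]][hit][1]
    } else {
      reference_population
    }
  }

  problems <- list()
  rows <- list()
  for (yr in years) {
    for (ind in indicators) {
      res <- tryCatch({
        sh <- resource_shares(panel, ind, year = yr,
                              population_total = ref_pop_for(yr))
        if (is.null(partition)) {
          tibble(year = yr, indicator = ind, scope = "national",
                 theil = as.numeric(theil_index(sh, epsilon = epsilon)),
                 within = NA_real_, between = NA_real_,
                 contribution_within = NA_real_,
                 contribution_between = NA_real_,
                 contribution = NA_real_)
        } else {
          dec <- theil_decompose(sh, partition, epsilon = epsilon)
          bind_rows(
            tibble(year = yr, indicator = ind, scope = "national",
                   theil = dec$total, within = dec$within,
                   between = dec$between,
                   contribution_within = dec$contribution_within,
                   contribution_between = dec$contribution_between,
                   contribution = NA_real_),
            tibble(year = yr, indicator = ind, scope = dec$groups$group,
                   theil = dec$groups$t_g, within = NA_real_,
                   between = NA_real_, contribution_within = NA_real_,
                   contribution_between = NA_real_,
                   contribution = dec$groups$contribution))
        }
      }, theilequity_error = function(e) {
        problems[[length(problems) + 1]] <<-
          tibble(year = yr, indicator = ind, message = conditionMessage(e))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1]] <- res
    }
  }
  if (length(rows) == 0) {
    abort_validation("Every year-indicator slice failed; no trend rows produced.")
  }
  out <- bind_rows(rows)
  out <- out[order(out$year, match(out$indicator, indicators),
                   out$scope != "national"), ]
  if (length(problems) > 0) {
    probs <- bind_rows(problems)
    warn(sprintf("%d year-indicator slice(s) failed and were dropped; see attr(, \"problems\").",
                 nrow(probs)))
    attr(out, "problems") <- probs
  }
  class(out) <- c("theil_trend", class(out))
  out
}

#' Plot a Theil trend
#'
#' Line chart of the Theil index by year, one line per scope (national
#' plus each region), faceted by indicator.
#'
#' @param object A `"theil_trend"` tibble from [theil_trend()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.theil_trend <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$year, y = .data$theil,
                               colour = .data$scope, group = .data$scope)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$indicator), scales = "free_y") +
    ggplot2::labs(x = "year", y = "Theil index", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked contribution-rate chart for a trend
#'
#' For a trend computed with a partition, stacks each region's
#' contribution `p_g t_g / T` and the between-region contribution by
#' year, faceted by indicator — the standard way to show which part of
#' the system drives total inequality over time.
#'
#' @param trend A `"theil_trend"` tibble computed with a partition.
#' @return A ggplot object.
#' @export
plot_contributions <- function(trend) {
  if (!inherits(trend, "theil_trend")) {
    abort_validation("`trend` must come from theil_trend().")
  }
  nat <- filter(trend, .data$scope == "national",
                !is.na(.data$contribution_between))
  grp <- filter(trend, .data$scope != "national", !is.na(.data$contribution))
  if (nrow(grp) == 0) {
    abort_validation("Trend carries no regional contributions; compute it with a partition.")
  }
  df <- bind_rows(
    select(grp, "year", "indicator", component = "scope",
           contribution = "contribution"),
    tibble(year = nat$year, indicator = nat$indicator,
           component = "between regions",
           contribution = nat$contribution_between))
  df$component <- factor(df$component,
                         levels = c(unique(grp$scope), "between regions"))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$year),
                                   y = .data$contribution,
                                   fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$indicator)) +
    ggplot2::labs(x = "year", y = "share of total Theil index", fill = NULL) +
    ggplot2::theme_minimal()
}
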