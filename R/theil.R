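#' Theil index (population-weighted mean log deviation)
#'
#' Computes `T = sum_i p_i * ln(p_i / y_i)` over units, where `p_i` is a
#' unit's population share and `y_i` its resource share. This is the
#' population-weighted member of the generalized-entropy family (the mean
#' log deviation, GE(0), sometimes written Theil-L), not the
#' resource-weighted Theil-T: only this form decomposes exactly with
#' population-share weights (see [theil_decompose()]). `T` is zero when
#' allocation is exactly proportional to population and grows without an
#' upper bound as resources concentrate away from the population; smaller
#' is more equitable.
#'
#' Units with `p_i = 0` contribute zero (the continuous limit of
#' `p ln p`). A unit with `p_i > 0` but `y_i = 0` makes the index
#' undefined: by default this is an error, because silent infinities hide
#' data problems. Passing `epsilon` opts into an exploratory policy that
#' floors `y` at `epsilon` and renormalizes `y` back to its original sum;
#' the result is then flagged with an `adjusted` attribute.
#'
#' @param shares A share table: data frame with columns `p` and `y`, such
#'   as built by [resource_shares()].
#' @param epsilon Optional positive floor applied to zero resource shares
#'   (default `NULL`: zero resource with positive population is an error).
#' @return A single non-negative number. When the epsilon policy fired,
#'   it carries attribute `adjusted = TRUE`.
#' @export
#' @examples
#' theil_index(data.frame(p = c(0.5, 0.5), y = c(0.9, 0.1)))
#' theil_index(resource_shares(china_panel_2013(), "personnel"))
theil_index <- function(shares, epsilon = NULL) {
  check_shares(shares)
  p <- shares$p
  y <- apply_epsilon(shares, epsilon)
  adjusted <- !identical(y, shares$y)
  bad <- p > 0 & y == 0
  if (any(bad)) {
    who <- if ("unit" %in% names(shares)) {
      paste(shares$unit[bad], collapse = ", ")
    } else {
      paste("rows", paste(which(bad), collapse = ", "))
    }
    abort_domain(c(
      sprintf("Zero resource share with positive population share (%s); the Theil index is undefined.", who),
      i = "Pass `epsilon` to floor zero shares for exploratory use."))
  }
  pos <- p > 0
  out <- sum(p[pos] * log(p[pos] / y[pos]))
  # non-negative for normalized shares (Gibbs); absorb sub-roundoff noise
  if (out < 0 && out > -1e-12) out <- 0
  if (adjusted) attr(out, "adjusted") <- TRUE
  out
}

# Epsilon policy: floor zero y at epsilon, renormalize y to its original
# sum. Returns y unchanged when epsilon is NULL or nothing was floored.
apply_epsilon <- function(shares, epsilon) {
  y <- shares$y
  if (is.null(epsilon)) return(y)
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    abort_validation("`epsilon` must be a single positive number.")
  }
  hit <- shares$p > 0 & y < epsilon
  if (!any(hit)) return(y)
  tot <- sum(y)
  y[hit] <- epsilon
  y * tot / sum(y)
}

#' Within-group Theil index
#'
#' The Theil index of a subset of units after renormalizing both shares
#' inside the group: `t_g` is [theil_index()] applied to `p_i / p_g` and
#' `y_i / y_g` over the members, where `p_g` and `y_g` are the group's
#' share sums. Because of the internal renormalization, `t_g` does not
#' depend on how the parent shares were normalized.
#'
#' @inheritParams theil_index
#' @param members Group membership: a character vector of unit names
#'   (requires a `unit` column) or a logical/integer row index.
#' @return A single non-negative number `t_g`.
#' @export
#' @examples
#' sh <- resource_shares(china_panel_2013(), "personnel")
#' east <- china_partition()
#' theil_within(sh, east$unit[east$region == "east"])
theil_within <- function(shares, members, epsilon = NULL) {
  check_shares(shares)
  if (is.character(members)) {
    if (!"unit" %in% names(shares)) {
      abort_validation("Naming members requires a `unit` column in `shares`.")
    }
    unknown <- setdiff(members, shares$unit)
    if (length(unknown) > 0) {
      abort_validation(sprintf("Unknown unit(s): %s.",
                               paste(unknown, collapse = ", ")))
    }
    idx <- shares$unit %in% members
  } else {
    idx <- members
  }
  sub <- shares[idx, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort_validation("Empty member set.")
  }
  p_g <- sum(sub$p)
  y_g <- sum(apply_epsilon(shares, epsilon)[idx])
  if (p_g <= 0) {
    abort_domain("Group population share is zero; within-group Theil is undefined.")
  }
  if (y_g <= 0) {
    abort_domain("Group resource share is zero; within-group Theil is undefined.")
  }
  inner <- tibble(unit = if ("unit" %in% names(sub)) sub$unit else NULL,
                  p = sub$p / p_g, y = sub$y / y_g)
  theil_index(inner, epsilon = epsilon)
}

#' Decompose the Theil index into within- and between-region parts
#'
#' Splits total inequality exactly into
#' `T = T_within + T_between`, with
#' `T_within = sum_g p_g * t_g` (each group's internal Theil index
#' weighted by its population share) and
#' `T_between = sum_g p_g * ln(p_g / y_g)` (the Theil index of the
#' group-level aggregates). The identity is algebraic, so the two parts
#' always reproduce an independently computed total to floating-point
#' accuracy. Contribution rates divide each part — and each group's
#' weighted term `p_g * t_g` — by the total; when the total is zero they
#' are reported as `NA` (undefined, not 0/0).
#'
#' @inheritParams theil_index
#' @param partition A data frame with columns `unit` and `region`
#'   covering every unit of `shares` exactly once
#'   (see [validate_partition()]).
#' @return An object of class `"theil_decomposition"`: a list with
#'   `groups` (tibble: `group`, `n_units`, `p_g`, `y_g`, `t_g`,
#'   `weighted_term`, `contribution`), scalars `total`, `within`,
#'   `between`, `contribution_within`, `contribution_between`, and the
#'   `indicator`/`year` metadata carried by `shares`. Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
#' @examples
#' sh <- resource_shares(china_panel_2013(), "personnel")
#' theil_decompose(sh, china_partition())
theil_decompose <- function(shares, partition, epsilon = NULL) {
  check_shares(shares)
  if (!"unit" %in% names(shares)) {
    abort_validation("`shares` must have a `unit` column to be partitioned.")
  }
  part <- validate_partition(partition, shares$unit)
  region_levels <- unique(part$region)

  dat <- shares
  dat$y <- apply_epsilon(shares, epsilon)
  adjusted <- !identical(dat$y, shares$y)
  dat <- left_join(as_tibble(dat), part, by = "unit")

  groups <- dat %>%
    group_by(group = factor(.data$region, levels = region_levels)) %>%
    summarise(n_units = n(),
              p_g = sum(.data$p),
              y_g = sum(.data$y),
              t_g = theil_within(dat, .data$region[1] == dat$region),
              .groups = "drop") %>%
    arrange(.data$group) %>%
    mutate(group = as.character(.data$group),
           weighted_term = .data$p_g * .data$t_g)

  between <- with(groups, sum(ifelse(p_g > 0, p_g * log(p_g / y_g), 0)))
  if (between < 0 && between > -1e-12) between <- 0
  within <- sum(groups$weighted_term)
  total <- as.numeric(theil_index(dat, epsilon = NULL))

  gap <- abs(total - (within + between))
  if (gap > 1e-8 * max(1, abs(total))) {
    abort("Internal error: decomposition additivity violated.",
          class = "theilequity_error")
  }

  if (total > 0) {
    groups$contribution <- groups$weighted_term / total
    cw <- within / total
    cb <- between / total
  } else {
    groups$contribution <- NA_real_
    cw <- NA_real_
    cb <- NA_real_
  }

  structure(
    list(groups = groups,
         total = total, within = within, between = between,
         contribution_within = cw, contribution_between = cb,
         indicator = attr(shares, "indicator"),
         year = attr(shares, "year"),
         adjusted = adjusted),
    class = "theil_decomposition")
}

#' @export
print.theil_decomposition <- function(x, digits = 4, ...) {
  hdr <- "Theil index decomposition"
  meta <- c(x$indicator, x$year)
  if (length(meta) > 0) hdr <- paste0(hdr, " (", paste(meta, collapse = ", "), ")")
  cat(hdr, "\n")
  cat(sprintf("  total %.*f = within %.*f + between %.*f\n",
              digits, x$total, digits, x$within, digits, x$between))
  if (!is.na(x$contribution_within)) {
    cat(sprintf("  contribution: within %.1f%%, between %.1f%%\n",
                100 * x$contribution_within, 100 * x$contribution_between))
  } else {
    cat("  contribution rates undefined (total is zero)\n")
  }
  if (isTRUE(x$adjusted)) cat("  note: zero resource shares floored (epsilon policy)\n")
  print(x$groups, digits = digits)
  invisible(x)
}

#' Tidy a Theil decomposition
#'
#' One row per group plus `__within__`, `__between__` and `__total__`
#' summary rows, matching the package's decomposition CSV schema
#' (`group,p_g,y_g,t_g,weighted_term,contribution`).
#'
#' @param x A `"theil_decomposition"` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.theil_decomposition <- function(x, ...) {
  bind_rows(
    select(x$groups, "group", "p_g", "y_g", "t_g", "weighted_term",
           "contribution"),
    tibble(group = c("__within__", "__between__", "__total__"),
           p_g = NA_real_, y_g = NA_real_, t_g = NA_real_,
           weighted_term = c(x$within, x$between, x$total),
           contribution = c(x$contribution_within, x$contribution_between,
                            if (x$total > 0) 1 else NA_real_)))
}

#' Glance at a Theil decomposition
#'
#' @param x A `"theil_decomposition"` object.
#' @param ... Unused.
#' @return A one-row tibble with the totals, the contribution rates and
#'   the problem size.
#' @exportS3Method generics::glance
glance.theil_decomposition <- function(x, ...) {
  tibble(total = x$total, within = x$within, between = x$between,
         contribution_within = x$contribution_within,
         contribution_between = x$contribution_between,
         n_units = sum(x$groups$n_units), n_groups = nrow(x$groups),
         adjusted = isTRUE(x$adjusted))
}

#' Plot the contribution rates of a decomposition
#'
#' A bar chart of each region's contribution `p_g * t_g / T` plus the
#' between-region contribution `T_between / T`.
#'
#' @param object A `"theil_decomposition"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.theil_decomposition <- function(object, ...) {
  if (is.na(object$contribution_within)) {
    abort_domain("Contribution rates are undefined (total Theil index is zero).")
  }
  df <- bind_rows(
    tibble(component = object$groups$group,
           contribution = object$groups$contribution),
    tibble(component = "between regions",
           contribution = object$contribution_between))
  df$component <- factor(df$component, levels = df$component)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$contribution)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "share of total Theil index",
                  title = "Contribution to inequality",
                  subtitle = paste(c(object$indicator, object$year),
                                   collapse = ", ")) +
    ggplot2::theme_minimal()
}
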