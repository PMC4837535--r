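#' Read a region partition CSV
#'
#' A partition assigns every geographic unit to exactly one named region.
#' The on-disk schema is two columns, `unit,region`. Region order follows
#' first appearance in the file.
#'
#' @param path Path to a partition CSV, or the builtin name `"china3"`
#'   for the packaged east/central/west grouping.
#' @return A tibble with columns `unit` and `region`.
#' @export
#' @examples
#' read_partition("china3")
read_partition <- function(path) {
  if (identical(path, "china3")) {
    path <- system.file("extdata", "china_regions.csv", package = "theilequity")
  }
  if (!file.exists(path)) {
    abort_parse(sprintf("Partition file not found: %s", path))
  }
  part <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("unit", "region") %in% names(part))) {
    abort_parse("Partition CSV must have columns `unit,region`.")
  }
  select(part, "unit", "region")
}

#' Validate a partition against a set of units
#'
#' Checks that the partition covers every unit of the panel slice exactly
#' once and that no region is empty over those units. Units are matched by
#' name.
#'
#' @param partition A data frame with columns `unit` and `region`.
#' @param units Character vector of unit names to cover, or a panel
#'   (data frame with a `unit` column) from which they are taken.
#' @return The partition restricted to `units`, as a tibble with `region`
#'   kept in stable first-appearance order (invisibly usable in a pipe).
#' @export
#' @examples
#' validate_partition(china_partition(), china_panel_2013())
validate_partition <- function(partition, units) {
  if (!is.data.frame(partition) ||
      !all(c("unit", "region") %in% names(partition))) {
    abort_validation("`partition` must be a data frame with columns `unit` and `region`.")
  }
  if (is.data.frame(units)) units <- unique(units$unit)
  if (length(units) == 0) {
    abort_validation("No units to partition (empty slice).")
  }
  partition <- as_tibble(partition)
  dup <- partition$unit[duplicated(partition$unit)]
  if (length(dup) > 0) {
    abort_validation(sprintf("Unit assigned to more than one region: %s.",
                             paste(unique(dup), collapse = ", ")))
  }
  uncovered <- setdiff(units, partition$unit)
  if (length(uncovered) > 0) {
    abort_validation(sprintf("Partition does not cover: %s.",
                             paste(uncovered, collapse = ", ")))
  }
  out <- filter(partition, .data$unit %in% units)
  counts <- table(factor(out$region, levels = unique(partition$region)))
  empty <- names(counts)[counts == 0]
  if (length(empty) > 0) {
    abort_validation(sprintf("Region(s) with no units over this slice: %s.",
                             paste(empty, collapse = ", ")))
  }
  invisible(out)
}
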