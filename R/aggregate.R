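# Min-max normalisation and category aggregation of the ES indicators.

#' Min-max normalisation across units
#'
#' (x - min) / (max - min), computed over the non-missing values;
#' missing values stay missing. A constant vector carries no
#' between-unit contrast and is mapped to all zeros with a warning.
#'
#' @param values Numeric vector with >= 2 non-missing values.
#' @return Vector in \[0, 1\] (NA preserved).
#' @export
#' @examples
#' minmax_normalize(c(2, 4, 6))  # 0, 0.5, 1
minmax_normalize <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("min-max normalisation needs >= 2 non-missing values")
  lo <- min(values[ok]); hi <- max(values[ok])
  if (hi == lo) {
    warning("constant vector normalised to all zeros")
    values[ok] <- 0
    return(values)
  }
  (values - lo) / (hi - lo)
}

#' Normalise an ES indicator table
#'
#' Adds `norm_capacity` and `norm_flow` columns: each service's
#' capacity and flow are independently min-max normalised across the
#' units. Independent normalisation is what allows a unit's normalised
#' flow to exceed its normalised capacity.
#'
#' @param es_table Long table from [assess_ecosystem_services()].
#' @return The table with two added columns.
#' @export
normalize_es_table <- function(es_table) {
  es_table$norm_capacity <- NA_real_
  es_table$norm_flow <- NA_real_
  for (e in unique(es_table$es)) {
    k <- es_table$es == e
    es_table$norm_capacity[k] <- minmax_normalize(es_table$capacity[k])
    es_table$norm_flow[k] <- minmax_normalize(es_table$flow[k])
  }
  es_table
}

#' Aggregate one CICES category
#'
#' Plain sum of the normalised component indicators of a category
#' (three services each), per unit. A unit missing any component is
#' flagged NA and excluded pairwise downstream.
#'
#' @param normalized_table Output of [normalize_es_table()].
#' @param category One of `"regulating"`, `"provisioning"`,
#'   `"cultural"`.
#' @return data.frame with `legend_id`, `capacity`, `flow` (each in
#'   \[0, 3\]).
#' @export
aggregate_category <- function(normalized_table, category) {
  if (!category %in% unique(es_registry()$category)) {
    stop("unknown category: ", category)
  }
  t <- normalized_table[normalized_table$category == category, ]
  sum_or_na <- function(x) if (any(is.na(x))) NA_real_ else sum(x)
  cap <- tapply(t$norm_capacity, t$legend_id, sum_or_na)
  flow <- tapply(t$norm_flow, t$legend_id, sum_or_na)
  ids <- as.integer(names(cap))
  out <- data.frame(legend_id = ids, capacity = as.numeric(cap),
                    flow = as.numeric(flow))
  out[order(out$legend_id), , drop = FALSE]
}

#' Capacity-flow difference
#'
#' Aggregated capacity minus aggregated flow; negative values mean the
#' realised flow exceeds the normalised potential.
#'
#' @param aggregates data.frame with `capacity` and `flow` columns
#'   (from [aggregate_category()]).
#' @return Numeric vector of per-unit differences.
#' @export
capacity_flow_difference <- function(aggregates) {
  aggregates$capacity - aggregates$flow
}

#' Aggregated indicator table
#'
#' Per-unit normalised, category-summed capacity and flow for the
#' three CICES categories, plus the capacity-flow difference of each.
#'
#' @param es_table Long table from [assess_ecosystem_services()].
#' @return data.frame with `legend_id`, `group` and columns
#'   `<category>_capacity`, `<category>_flow`, `<category>_diff` for
#'   regulating, provisioning and cultural.
#' @export
aggregate_indicators <- function(es_table) {
  norm <- normalize_es_table(es_table)
  ids <- sort(unique(es_table$legend_id))
  out <- data.frame(legend_id = ids,
                    group = es_table$group[match(ids, es_table$legend_id)])
  for (cat in c("regulating", "provisioning", "cultural")) {
    agg <- aggregate_category(norm, cat)
    stopifnot(identical(agg$legend_id, ids))
    out[[paste0(cat, "_capacity")]] <- agg$capacity
    out[[paste0(cat, "_flow")]] <- agg$flow
    out[[paste0(cat, "_diff")]] <- capacity_flow_difference(agg)
  }
  out
}

#' Long-format radar-chart data
#'
#' Per-unit normalised capacity and flow of every service, in long
#' format suitable for stellar/radar charts.
#'
#' @inheritParams aggregate_indicators
#' @return data.frame with `legend_id`, `group`, `es`, `measure`
#'   (capacity/flow), `value`.
#' @export
radar_chart_data <- function(es_table) {
  norm <- normalize_es_table(es_table)
  long <- rbind(
    data.frame(legend_id = norm$legend_id, group = norm$group,
               es = norm$es, measure = "capacity",
               value = norm$norm_capacity),
    data.frame(legend_id = norm$legend_id, group = norm$group,
               es = norm$es, measure = "flow", value = norm$norm_flow))
  long[order(long$legend_id, long$es, long$measure), ]
}
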