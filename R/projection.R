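#' Project a fitted temperature response onto monthly climate grids
#'
#' Applies the fitted model at every grid cell for every selected month
#' and averages the monthly responses. Each month contributes one
#' evaluation temperature per cell, chosen by `policy`:
#'
#' * `"midpoint"` (default): evaluate at `(tmin + tmax) / 2`;
#' * `"min"` / `"max"`: evaluate at the monthly extreme alone;
#' * `"mean_response"`: average the responses at tmin and at tmax.
#'
#' The seasonal mean response is scaled to percent mortality (x 100,
#' capped at 100). Nodata in any used layer propagates to the output cell.
#' The months default to the October-March soybean growing season.
#'
#' @param stack A [monthly_stack()].
#' @param params A [thermal_params()] object (proportion-scale response,
#'   typically the virulence model).
#' @param months Integer months to aggregate (default `c(10:12, 1:3)`).
#' @param policy Temperature-combination policy (above).
#' @return Object of class `performance_map`: `mortality` (a
#'   [climate_grid()] of percent mortality), `params`, `months`, `policy`,
#'   and after [classify_performance()] also `classes`, `class_edges`,
#'   `class_labels`.
#' @export
project_response <- function(stack, params,
                             months = c(10:12, 1:3),
                             policy = c("midpoint", "min", "max",
                                        "mean_response")) {
  stopifnot(inherits(stack, "monthly_stack"),
            inherits(params, "thermal_params"))
  policy <- match.arg(policy)
  months <- as.integer(months)
  if (length(months) == 0L || any(months < 1L | months > 12L))
    stop("months must be a non-empty subset of 1:12", call. = FALSE)
  ref <- stack$tmin[[1]]
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  valid <- matrix(TRUE, nrow(ref$values), ncol(ref$values))
  for (mo in months) {
    tmin <- stack$tmin[[mo]]$values
    tmax <- stack$tmax[[mo]]$values
    valid <- valid & !is.na(tmin) & !is.na(tmax)
    resp <- switch(policy,
      midpoint = eval_thermal((tmin + tmax) / 2, params),
      min = eval_thermal(tmin, params),
      max = eval_thermal(tmax, params),
      mean_response = (eval_thermal(tmin, params) +
                       eval_thermal(tmax, params)) / 2)
    resp[is.na(resp)] <- 0   # masked below via `valid`
    acc <- acc + resp
  }
  mort <- pmin(acc / length(months) * 100, 100)
  mort[!valid] <- NA_real_
  structure(
    list(mortality = climate_grid(mort, ref$cellsize, ref$xllcorner,
                                  ref$yllcorner, ref$nodata),
         params = params, months = months, policy = policy),
    class = "performance_map")
}

#' @export
print.performance_map <- function(x, ...) {
  cat("performance_map:", paste(dim(x$mortality$values), collapse = " x "),
      "cells; policy", x$policy, "; months",
      paste(x$months, collapse = ","), "\n")
  v <- x$mortality$values
  cat(sprintf("  predicted mortality: %.1f-%.1f%% (median %.1f%%)\n",
              min(v, na.rm = TRUE), max(v, na.rm = TRUE),
              stats::median(v, na.rm = TRUE)))
  if (!is.null(x$classes)) {
    tab <- table(factor(x$classes$values, levels = seq_along(x$class_labels),
                        labels = x$class_labels))
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Classify predicted performance into mortality bands
#'
#' Cuts percent mortality at strictly increasing `edges` into
#' `length(edges) + 1` half-open bands `[lo, hi)`: with the default edges
#' (10, 25, 60) a cell at exactly 25% falls in the band above 25. The
#' default labels follow the four-band reading of predicted performance:
#' below 10% low, 10-25% moderate, 25-60% high, above 60% very high.
#'
#' @param map A `performance_map` from [project_response()].
#' @param edges Strictly increasing percent thresholds within (0, 100).
#' @param labels Band names, `length(edges) + 1` of them.
#' @return The map with `classes` (integer-coded [climate_grid()]),
#'   `class_edges` and `class_labels` filled in.
#' @export
classify_performance <- function(map, edges = c(10, 25, 60),
                                 labels = c("low", "moderate", "high",
                                            "very high")) {
  stopifnot(inherits(map, "performance_map"))
  if (length(edges) < 1L || is.unsorted(edges, strictly = TRUE) ||
      any(edges <= 0 | edges >= 100))
    stop("edges must be strictly increasing within (0, 100)", call. = FALSE)
  if (length(labels) != length(edges) + 1L)
    stop("need one more label than edges", call. = FALSE)
  v <- map$mortality$values
  cls <- matrix(findInterval(v, edges, left.open = FALSE) + 1L,
                nrow(v), ncol(v))
  cls[is.na(v)] <- NA_integer_
  g <- map$mortality
  map$classes <- climate_grid(cls, g$cellsize, g$xllcorner, g$yllcorner,
                              g$nodata)
  map$class_edges <- edges
  map$class_labels <- labels
  map
}

#' Summarize hourly temperatures as hours per day in bands
#'
#' For an hourly temperature series, counts how many observed hours per
#' day fall into each temperature band and averages those daily counts
#' within each calendar month. Bands are contiguous half-open intervals
#' `(lo, hi]` built from `edges` (default 15, 20, 25, 30, 35 deg C, giving
#' <=15, 15-20, ..., >35); a reading exactly on an edge counts in the band
#' below, so 15.0 deg C falls in the coldest band. Gaps in the series are
#' tolerated: per-day band counts always sum to the hours actually
#' observed that day.
#'
#' @param series Data frame with columns `timestamp` (POSIXct, `Date`, or
#'   a string parseable by [as.POSIXct()]) and `temp` (deg C).
#' @param edges Increasing band boundaries, deg C.
#' @return Data frame with one row per (month, band): columns `month`,
#'   `band`, `mean_hours_per_day`, plus `n_days` observed.
#' @export
hours_in_ranges <- function(series, edges = c(15, 20, 25, 30, 35)) {
  stopifnot(is.data.frame(series), all(c("timestamp", "temp") %in%
                                         names(series)))
  if (nrow(series) == 0L) stop("empty temperature series", call. = FALSE)
  if (is.unsorted(edges, strictly = TRUE))
    stop("edges must be strictly increasing", call. = FALSE)
  ts <- series$timestamp
  if (!inherits(ts, c("POSIXct", "POSIXt", "Date")))
    ts <- as.POSIXct(ts, tz = "UTC")
  temp <- as.numeric(series$temp)
  keep <- !is.na(ts) & is.finite(temp)
  ts <- ts[keep]; temp <- temp[keep]
  if (length(ts) == 0L) stop("no valid readings in series", call. = FALSE)

  breaks <- c(-Inf, edges, Inf)
  band_labels <- c(paste0("<=", edges[1]),
                   if (length(edges) > 1)
                     paste0(utils::head(edges, -1) , "-", edges[-1]),
                   paste0(">", edges[length(edges)]))
  band <- cut(temp, breaks = breaks, right = TRUE, labels = band_labels)
  day <- format(ts, "%Y-%m-%d")
  month <- as.integer(format(ts, "%m"))

  per_day <- as.data.frame(table(day = day, band = band),
                           stringsAsFactors = FALSE)
  per_day$month <- as.integer(format(as.Date(per_day$day), "%m"))
  agg <- stats::aggregate(Freq ~ month + band, data = per_day, FUN = mean)
  names(agg)[names(agg) == "Freq"] <- "mean_hours_per_day"
  n_days <- stats::aggregate(day ~ month,
                             data = unique(per_day[c("day", "month")]),
                             FUN = length)
  names(n_days)[2] <- "n_days"
  out <- merge(agg, n_days, by = "month")
  out$band <- factor(out$band, levels = band_labels)
  out[order(out$month, out$band), c("month", "band", "mean_hours_per_day",
                                    "n_days")]
}
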