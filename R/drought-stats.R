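#' Default run-theory threshold by resolution
#'
#' The published defaults for the drought threshold applied to the combined
#' index: 0.12 at 0.25 degree resolution and 0.17 at 1 degree. With
#' `"auto"`, the threshold is recomputed from the data as the mean over
#' pixels of each pixel's severe-drought (D2) boundary value -- the value at
#' the 10th percentile of the pixel's own index distribution.
#'
#' @param index A `grid_series` of the combined index.
#' @param threshold `NULL` (resolution default), `"auto"`, or a number in
#'   (0, 1).
#' @return A single numeric threshold.
#' @export
run_threshold <- function(index, threshold = NULL) {
  if (is.numeric(threshold)) {
    if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)", call. = FALSE)
    return(threshold)
  }
  if (identical(threshold, "auto")) {
    q10 <- index |>
      dplyr::group_by(.data$row, .data$col) |>
      dplyr::summarise(q = stats::quantile(.data$value, 0.10, na.rm = TRUE,
                                           names = FALSE), .groups = "drop")
    return(mean(q10$q, na.rm = TRUE))
  }
  defaults <- c("0.25deg" = 0.12, "1deg" = 0.17)
  res <- grid_resolution(index)
  if (!res %in% names(defaults)) {
    stop("no default threshold for resolution '", res,
         "'; supply one explicitly or use \"auto\"", call. = FALSE)
  }
  unname(defaults[res])
}

#' Extract drought events by run theory
#'
#' Decomposes each pixel's index series into maximal consecutive runs of
#' months with value strictly below the threshold. Each run is one drought
#' event with a duration (months) and a severity (the sum of index values
#' within the run; a *lower* sum per month means worse drought). Masked
#' months terminate runs -- a data gap never bridges two events.
#'
#' @param index A `grid_series` of the combined index.
#' @param threshold See [run_threshold()].
#' @return A tibble of class `drought_events`: one row per event with
#'   columns `row`, `col`, `start_year`, `start_month`, `end_year`,
#'   `end_month`, `duration`, `severity`; attribute `threshold`.
#' @export
#'
#' @examples
#' gs <- grid_series(data.frame(year = 2001, month = 1:5, row = 1, col = 1,
#'                              value = c(0.3, 0.10, 0.08, 0.11, 0.3)), "regcdi")
#' extract_runs(gs, threshold = 0.12)  # one event: duration 3, severity 0.29
extract_runs <- function(index, threshold = NULL) {
  tau <- run_threshold(index, threshold)
  events <- index |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::arrange(.data$year, .data$month, .by_group = TRUE) |>
    dplyr::group_modify(~pixel_runs(.x, tau)) |>
    dplyr::ungroup()
  structure(events, threshold = tau,
            class = c("drought_events", class(tibble::tibble())))
}

pixel_runs <- function(px, tau) {
  below <- !is.na(px$value) & px$value < tau
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (length(keep) == 0) {
    return(tibble::tibble(start_year = integer(), start_month = integer(),
                          end_year = integer(), end_month = integer(),
                          duration = integer(), severity = double()))
  }
  tibble::tibble(
    start_year = px$year[starts[keep]], start_month = px$month[starts[keep]],
    end_year = px$year[ends[keep]], end_month = px$month[ends[keep]],
    duration = r$lengths[keep],
    severity = vapply(keep, function(i) sum(px$value[starts[i]:ends[i]]), 0))
}

#' Count drought months per pixel
#'
#' `drought_months()` tallies, at each pixel, the months classified as
#' drought: `subset = "all"` counts D1-D4 (mild/moderate to exceptional),
#' `"severe"` counts D2-D4 only. `propensity()` is the drought-propensity
#' hotspot layer -- the count of D1-D4 months, optionally restricted to a
#' cropping season.
#'
#' @param classes A `drought_class_grid` from [classify_drought()].
#' @param subset `"all"` (D1-D4) or `"severe"` (D2-D4).
#' @param season Optional [season_definition()] restriction.
#' @return A tibble `row`, `col`, `months` (nonnegative integer count).
#' @export
drought_months <- function(classes, subset = c("all", "severe")) {
  subset <- match.arg(subset)
  classes |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(months = sum(is_drought_class(.data$class, subset),
                                  na.rm = TRUE), .groups = "drop")
}

#' @rdname drought_months
#' @export
propensity <- function(classes, season = NULL) {
  if (!is.null(season)) classes <- seasonal_filter(classes, season)
  drought_months(classes, "all")
}

#' Hotspot summary layers
#'
#' Assembles the per-pixel hotspot products: mean annual severity and mean
#' annual duration of run-theory drought events (sums divided by the number
#' of study years; masked where a pixel has no events), total drought
#' months (D1-D4), severe-to-exceptional months (D2-D4), propensity, and a
#' seasonal propensity column per supplied season. Lower mean severity
#' means more severe drought.
#'
#' @param index A `grid_series` of the combined index.
#' @param classes The matching `drought_class_grid`.
#' @param threshold See [run_threshold()].
#' @param seasons List of [season_definition()]s for seasonal propensity
#'   layers (default: the three cropping seasons).
#' @return A tibble of class `hotspot_stack`, one row per pixel.
#' @export
hotspot_stack <- function(index, classes, threshold = NULL,
                          seasons = list(season_definition("kharif"),
                                         season_definition("rabi"),
                                         season_definition("summer"))) {
  n_years <- length(unique(index$year))
  events <- extract_runs(index, threshold)
  pixels <- dplyr::distinct(tibble::as_tibble(index), .data$row, .data$col)
  ev <- events |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(mean_annual_severity = sum(.data$severity) / n_years,
                     mean_annual_duration = sum(.data$duration) / n_years,
                     n_events = dplyr::n(), .groups = "drop")
  out <- pixels |>
    dplyr::left_join(ev, by = c("row", "col")) |>
    dplyr::mutate(n_events = tidyr::replace_na(.data$n_events, 0L)) |>
    dplyr::left_join(dplyr::rename(drought_months(classes, "all"),
                                   total_drought_months = "months"),
                     by = c("row", "col")) |>
    dplyr::left_join(dplyr::rename(drought_months(classes, "severe"),
                                   severe_drought_months = "months"),
                     by = c("row", "col")) |>
    dplyr::left_join(dplyr::rename(propensity(classes), propensity = "months"),
                     by = c("row", "col"))
  for (s in seasons) {
    layer <- propensity(classes, s)
    names(layer)[names(layer) == "months"] <- paste0("propensity_", s$name)
    out <- dplyr::left_join(out, layer, by = c("row", "col"))
  }
  structure(out, n_years = n_years, threshold = attr(events, "threshold"),
            class = c("hotspot_stack", class(tibble::tibble())))
}
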