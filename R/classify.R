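#' Drought categories
#'
#' Ordered from most severe to wet: D4 (exceptional), D3 (extreme), D2
#' (severe), D1 (moderate), D0 (dry/abnormally dry), wet. The ordered factor
#' runs D4 < D3 < D2 < D1 < D0 < wet, so "less than or equal D1" means
#' drought of at least moderate severity.
#'
#' @format Character vector of the six class labels.
#' @export
drought_classes <- c("D4", "D3", "D2", "D1", "D0", "wet")

# default fixed-range cut points (index units = cumulative percentiles of
# the USDM convention: 2/5/10/20/30)
regcdi_breaks <- c(0.02, 0.05, 0.10, 0.20, 0.30)

#' Classify drought from index values
#'
#' `regcdi_class()` maps index values in [0, 1] to the six drought
#' categories with the fixed ranges: D4 <= 0.02 < D3 <= 0.05 < D2 <= 0.10
#' < D1 <= 0.20 < D0 <= 0.30 < wet. Intervals are lower-exclusive,
#' upper-inclusive (with D4 = [0, 0.02]), so every value maps to exactly one
#' class. `classify_drought()` applies this to a gridded index series,
#' either on the raw values (`scheme = "fixed"`) or on each pixel's own
#' empirical percentiles (`scheme = "percentile"`, the USDM percentile
#' convention: the same 2/5/10/20/30 cuts applied to the pixel's empirical
#' CDF).
#'
#' @param values Numeric vector in [0, 1] (values outside are an error:
#'   upstream contract breach).
#' @param breaks The five ascending cut points; defaults to
#'   0.02/0.05/0.10/0.20/0.30.
#' @return `regcdi_class()` an ordered factor over
#'   `D4 < D3 < D2 < D1 < D0 < wet`; `classify_drought()` a tibble of class
#'   `drought_class_grid` with columns `year`, `month`, `row`, `col`,
#'   `class` (masked cells get `NA`).
#' @export
#'
#' @examples
#' regcdi_class(c(0.01, 0.07, 0.15, 0.5))  # D4 D2 D1 wet
regcdi_class <- function(values, breaks = regcdi_breaks) {
  stopifnot(length(breaks) == 5, !is.unsorted(breaks))
  if (any(values < 0 | values > 1, na.rm = TRUE)) {
    stop("index values must lie in [0, 1]", call. = FALSE)
  }
  cut(values, breaks = c(0, breaks, 1), labels = drought_classes,
      include.lowest = TRUE, right = TRUE, ordered_result = TRUE)
}

#' @rdname regcdi_class
#' @param index A `grid_series` of a combined drought index in [0, 1].
#' @param scheme `"fixed"` (default) or `"percentile"`.
#' @export
classify_drought <- function(index, scheme = c("fixed", "percentile"),
                             breaks = regcdi_breaks) {
  scheme <- match.arg(scheme)
  out <- tibble::as_tibble(index)[c("year", "month", "row", "col", "value")]
  if (scheme == "fixed") {
    out$class <- regcdi_class(out$value, breaks)
  } else {
    out <- out |>
      dplyr::group_by(.data$row, .data$col) |>
      dplyr::mutate(.p = percentile_rank(.data$value)) |>
      dplyr::ungroup()
    out$class <- regcdi_class(out$.p, breaks)
    out$.p <- NULL
  }
  out$value <- NULL
  structure(dplyr::arrange(out, .data$year, .data$month, .data$row, .data$col),
            scheme = scheme, breaks = breaks,
            class = c("drought_class_grid", class(tibble::tibble())))
}

# empirical CDF value of each observation within its own series (ties share
# the max rank, the ecdf convention); NA stays NA
percentile_rank <- function(v) {
  n <- sum(!is.na(v))
  if (n == 0) return(v)
  stats::ecdf(v)(v)
}

#' Is a class a drought class?
#'
#' `"all"` counts the drought categories D1-D4 (D0, "abnormally dry", is not
#' drought); `"severe"` counts D2-D4 only.
#'
#' @param cls Factor/character of drought classes.
#' @param subset `"all"` or `"severe"`.
#' @return Logical vector (`NA` for masked cells).
#' @export
is_drought_class <- function(cls, subset = c("all", "severe")) {
  subset <- match.arg(subset)
  lv <- if (subset == "all") c("D1", "D2", "D3", "D4") else c("D2", "D3", "D4")
  ifelse(is.na(cls), NA, as.character(cls) %in% lv)
}
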