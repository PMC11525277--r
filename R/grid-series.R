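#' Monthly gridded series
#'
#' A `grid_series` is a long tibble with one row per pixel-month and columns
#' `year`, `month`, `row`, `col`, `value`, carrying the variable name, units
#' and resolution tag as attributes. Missing (masked) cells are stored as
#' `NA` values; every timestamp holds the full pixel grid, so the time axis
#' and the spatial grid are always rectangular. Row 1 is the northernmost
#' row; coordinates are pixel centers; the resolution tag is metadata only
#' (no reprojection is ever performed).
#'
#' @param data A data frame with columns `year`, `month`, `row`, `col`,
#'   `value`. `value` may contain `NA` for masked cells.
#' @param variable Variable label (e.g. `"lst"`, `"ssm"`).
#' @param units Units label (e.g. `"K"`, `"m3/m3"`); may be `""`.
#' @param resolution Resolution tag, e.g. `"0.25deg"` or `"1deg"`.
#'
#' @return A tibble of class `grid_series`, sorted by (year, month, row, col).
#' @export
#'
#' @examples
#' df <- expand.grid(year = 2001, month = 1:3, row = 1:2, col = 1:2)
#' df$value <- runif(nrow(df))
#' gs <- grid_series(df, variable = "ssm", units = "m3/m3")
#' grid_dim(gs)
grid_series <- function(data, variable, units = "", resolution = "0.25deg") {
  required <- c("year", "month", "row", "col", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("grid_series data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- tibble::as_tibble(data)[required]
  if (!is.numeric(x$value)) stop("`value` must be numeric", call. = FALSE)
  if (any(!x$month %in% 1:12)) stop("`month` must lie in 1..12", call. = FALSE)
  if (any(is.infinite(x$value), na.rm = TRUE)) {
    stop("unmasked values must be finite; use NA for masked cells", call. = FALSE)
  }
  x <- dplyr::arrange(x, .data$year, .data$month, .data$row, .data$col)
  if (anyDuplicated(x[c("year", "month", "row", "col")]) > 0) {
    stop("duplicate (year, month, row, col) cells", call. = FALSE)
  }
  # rectangularity: every timestamp carries the identical pixel set
  n_ts <- nrow(dplyr::distinct(x, .data$year, .data$month))
  n_px <- nrow(dplyr::distinct(x, .data$row, .data$col))
  if (nrow(x) != n_ts * n_px) {
    stop("grid is not rectangular: each timestamp must hold every pixel",
         call. = FALSE)
  }
  structure(x,
            variable = variable, units = units, resolution = resolution,
            class = c("grid_series", class(tibble::tibble())))
}

#' @export
print.grid_series <- function(x, ...) {
  ts <- grid_timestamps(x)
  cat(sprintf("<grid_series> %s [%s] %s; %d x %d pixels, %d months (%d-%02d to %d-%02d)\n",
              attr(x, "variable"), attr(x, "units"), attr(x, "resolution"),
              grid_dim(x)[1], grid_dim(x)[2], nrow(ts),
              ts$year[1], ts$month[1], ts$year[nrow(ts)], ts$month[nrow(ts)]))
  NextMethod()
}

#' Timestamps, dimensions and metadata of a grid series
#'
#' @param x A `grid_series`.
#' @return `grid_timestamps()` returns a tibble of the ordered (year, month)
#'   pairs; `grid_dim()` a length-2 integer vector (rows, cols);
#'   `grid_variable()` / `grid_resolution()` the metadata labels.
#' @export
grid_timestamps <- function(x) {
  dplyr::arrange(dplyr::distinct(x, .data$year, .data$month),
                 .data$year, .data$month)
}

#' @rdname grid_timestamps
#' @export
grid_dim <- function(x) {
  c(rows = length(unique(x$row)), cols = length(unique(x$col)))
}

#' @rdname grid_timestamps
#' @export
grid_variable <- function(x) attr(x, "variable")

#' @rdname grid_timestamps
#' @export
grid_resolution <- function(x) attr(x, "resolution")

# month index since year 0 -- for gap detection and lagging
month_index <- function(year, month) year * 12L + (month - 1L)

#' Check that grid series are co-registered
#'
#' Verifies that all supplied `grid_series` share an identical pixel grid and
#' identical timestamps. Any mismatch fails loudly; nothing is broadcast.
#'
#' @param ... Two or more `grid_series`.
#' @return Invisibly `TRUE`; otherwise an error.
#' @export
assert_conformable <- function(...) {
  xs <- list(...)
  if (length(xs) < 2) return(invisible(TRUE))
  key_cols <- c("year", "month", "row", "col")
  ref <- xs[[1]]
  for (i in seq_along(xs)[-1]) {
    cand <- xs[[i]]
    same <- nrow(cand) == nrow(ref) &&
      all(vapply(key_cols, function(k) identical(as.vector(ref[[k]]), as.vector(cand[[k]])),
                 logical(1)))
    if (!same) {
      stop("grid series are not co-registered (shape or timestamps differ)",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# join two conformable series into a tibble with value.x / value.y
gs_pair <- function(a, b) {
  assert_conformable(a, b)
  out <- a
  out$value_b <- b$value
  out
}

# rebuild a grid_series from a template, replacing values
gs_with_values <- function(template, values, variable = NULL, units = NULL) {
  out <- template[c("year", "month", "row", "col")]
  out$value <- values
  grid_series(out,
              variable = variable %||% attr(template, "variable"),
              units = units %||% attr(template, "units"),
              resolution = attr(template, "resolution"))
}

#' Cropping-season definitions
#'
#' The three cropping seasons of a monsoon agricultural calendar: `summer`
#' (pre-monsoon, March-June), `kharif` (monsoon, June-September, harvest in
#' September/October) and `rabi` (winter, October-February). Custom month
#' sets may be supplied; months must be non-empty and within 1..12.
#'
#' @param name Season name; one of `"summer"`, `"kharif"`, `"rabi"` (with
#'   default month sets) or any label when `months` is given.
#' @param months Optional integer vector of calendar months (1..12).
#' @return A list of class `season_definition` with elements `name`, `months`.
#' @export
#'
#' @examples
#' season_definition("kharif")
#' season_definition("custom", months = c(7, 8))
season_definition <- function(name, months = NULL) {
  defaults <- list(summer = 3:6, kharif = 6:9, rabi = c(10:12, 1:2))
  if (is.null(months)) {
    if (!name %in% names(defaults)) {
      stop("unknown season '", name, "'; supply `months` explicitly", call. = FALSE)
    }
    months <- defaults[[name]]
  }
  months <- as.integer(months)
  if (length(months) == 0) stop("season month set must be non-empty", call. = FALSE)
  if (any(!months %in% 1:12)) stop("season months must lie in 1..12", call. = FALSE)
  structure(list(name = name, months = sort(unique(months))),
            class = "season_definition")
}

#' @export
print.season_definition <- function(x, ...) {
  cat(sprintf("<season> %s: months %s\n", x$name, paste(x$months, collapse = ",")))
  invisible(x)
}

#' Restrict a gridded object to a cropping season
#'
#' Keeps only the rows whose calendar month belongs to the season's month
#' set. Works on any tibble with a `month` column (`grid_series`, drought
#' class grids); grid metadata is preserved.
#'
#' @param x A `grid_series` or a tibble with a `month` column.
#' @param season A [season_definition()].
#' @return Object of the same type restricted to season months.
#' @export
seasonal_filter <- function(x, season) {
  stopifnot(inherits(season, "season_definition"))
  keep <- x$month %in% season$months
  out <- x[keep, , drop = FALSE]
  attributes(out)[c("variable", "units", "resolution", "scheme")] <-
    attributes(x)[c("variable", "units", "resolution", "scheme")]
  class(out) <- class(x)
  out
}
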