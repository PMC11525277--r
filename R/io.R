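#' Read and write monthly grid stacks
#'
#' Two on-disk dialects are supported. The portable dialect is a plain-text
#' CSV with a small `#`-prefixed metadata header (variable, units,
#' resolution) followed by `year,month,row,col,value` records; masked cells
#' are written as empty fields. When the \pkg{ncdf4} package is installed a
#' CF-style NetCDF dialect (dimensions `time`, `row`, `col`; months since
#' 2000-01) is also available. `write_grid_stack()` round-trips through
#' `read_grid_stack()` exactly for CSV and to numeric storage precision for
#' NetCDF. A file whose time axis is stored out of order is reordered
#' ascending with a message.
#'
#' @param path File path. `.nc` selects the NetCDF dialect, anything else CSV.
#' @param variable Optional variable label to select/verify; for CSV the
#'   stored label must match when supplied.
#' @param series A `grid_series`.
#' @param format `"auto"` (by extension), `"csv"` or `"netcdf"`.
#' @return `read_grid_stack()` a `grid_series`; `write_grid_stack()` the path,
#'   invisibly.
#' @export
read_grid_stack <- function(path, variable = NULL, format = c("auto", "csv", "netcdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nc$", path, ignore.case = TRUE)) "netcdf" else "csv"
  }
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  if (format == "netcdf") return(read_grid_nc(path, variable))

  header <- readLines(path, n = 20L)
  header <- header[startsWith(header, "#")]
  meta <- function(key, default = "") {
    ln <- grep(paste0("^#\\s*", key, ":"), header, value = TRUE)
    if (length(ln) == 0) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", ln[1]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("year", "month", "row", "col", "value")
  if (!all(need %in% names(df))) {
    stop("'", path, "' lacks grid-stack columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  stored_var <- meta("variable", default = variable %||% "value")
  if (!is.null(variable) && !identical(stored_var, variable)) {
    stop("variable mismatch: file stores '", stored_var, "', requested '",
         variable, "'", call. = FALSE)
  }
  warn_if_unordered(df)
  grid_series(df, variable = stored_var, units = meta("units"),
              resolution = meta("resolution", "0.25deg"))
}

warn_if_unordered <- function(df) {
  mi <- month_index(df$year, df$month)
  if (is.unsorted(mi)) {
    message("time axis stored out of order; reordering ascending")
  }
  invisible(NULL)
}

#' @rdname read_grid_stack
#' @export
write_grid_stack <- function(series, path, format = c("auto", "csv", "netcdf")) {
  stopifnot(inherits(series, "grid_series"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nc$", path, ignore.case = TRUE)) "netcdf" else "csv"
  }
  if (format == "netcdf") return(write_grid_nc(series, path))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# grid_series",
               paste0("# variable: ", attr(series, "variable")),
               paste0("# units: ", attr(series, "units")),
               paste0("# resolution: ", attr(series, "resolution"))), con)
  utils::write.csv(as.data.frame(series), con, row.names = FALSE, na = "")
  invisible(path)
}

read_grid_nc <- function(path, variable = NULL) {
  if (!requireNamespace("ncdf4", quietly = TRUE)) {
    stop("the NetCDF dialect requires the 'ncdf4' package", call. = FALSE)
  }
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!"time" %in% names(nc$dim)) stop("'", path, "': no time axis", call. = FALSE)
  vars <- names(nc$var)
  vname <- variable %||% vars[1]
  if (!vname %in% vars) stop("variable '", vname, "' not in '", path, "'", call. = FALSE)
  tvals <- as.vector(nc$dim$time$vals)            # months since 2000-01
  arr <- ncdf4::ncvar_get(nc, vname, collapse_degen = FALSE)
  units <- ncdf4::ncatt_get(nc, vname, "units")$value
  res <- ncdf4::ncatt_get(nc, 0, "resolution")$value
  if (identical(units, 0)) units <- ""
  if (identical(res, 0)) res <- "0.25deg"
  ord <- order(tvals)
  if (is.unsorted(tvals)) message("time axis stored out of order; reordering ascending")
  tvals <- tvals[ord]
  arr <- arr[, , ord, drop = FALSE]               # (row, col, time)
  df <- tidyr::expand_grid(time = seq_along(tvals),
                           col = seq_len(dim(arr)[2]),
                           row = seq_len(dim(arr)[1]))
  df$year <- 2000L + tvals[df$time] %/% 12L
  df$month <- tvals[df$time] %% 12L + 1L
  df$value <- arr[cbind(df$row, df$col, df$time)]
  grid_series(df[c("year", "month", "row", "col", "value")],
              variable = vname, units = units, resolution = res)
}

write_grid_nc <- function(series, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE)) {
    stop("the NetCDF dialect requires the 'ncdf4' package", call. = FALSE)
  }
  ts <- grid_timestamps(series)
  d <- grid_dim(series)
  tvals <- month_index(ts$year, ts$month) - month_index(2000L, 1L)
  dim_r <- ncdf4::ncdim_def("row", "index", seq_len(d[1]))
  dim_c <- ncdf4::ncdim_def("col", "index", seq_len(d[2]))
  dim_t <- ncdf4::ncdim_def("time", "months since 2000-01", tvals, unlim = TRUE)
  var <- ncdf4::ncvar_def(attr(series, "variable"), attr(series, "units"),
                          list(dim_r, dim_c, dim_t), missval = -9999,
                          prec = "double")
  nc <- ncdf4::nc_create(path, list(var))
  on.exit(ncdf4::nc_close(nc))
  arr <- array(NA_real_, dim = c(d[1], d[2], nrow(ts)))
  idx <- cbind(series$row, series$col,
               match(month_index(series$year, series$month),
                     month_index(ts$year, ts$month)))
  arr[idx] <- series$value
  ncdf4::ncvar_put(nc, var, arr)
  ncdf4::ncatt_put(nc, 0, "resolution", attr(series, "resolution"))
  invisible(path)
}

#' Read a district yield table
#'
#' Reads a CSV with columns `district`, `year`, `yield` (mass/area). Rows
#' with a blank yield are kept with `yield = NA` and are excluded from any
#' downstream mean/sd computation; duplicate (district, year) keys are an
#' error.
#'
#' @param path CSV file path.
#' @return A tibble with columns `district`, `year`, `yield`.
#' @export
read_yield_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("district", "year", "yield")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("yield table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(df$yield)) {
    # blank cells read as "" force character; coerce, flagging true non-numerics
    suppressWarnings(y <- as.numeric(df$yield))
    bad <- !is.na(df$yield) & df$yield != "" & is.na(y)
    if (any(bad)) {
      stop("non-numeric yield value(s): ", paste(unique(df$yield[bad]), collapse = ", "),
           call. = FALSE)
    }
    df$yield <- y
  }
  if (anyDuplicated(df[c("district", "year")]) > 0) {
    stop("duplicate (district, year) rows in yield table", call. = FALSE)
  }
  tibble::as_tibble(df[need])
}

#' Read/write a zone (district) label map
#'
#' A zone map assigns each pixel to a district id (or `NA` background) and is
#' stored as a CSV with columns `row`, `col`, `district`.
#'
#' @param path CSV file path.
#' @param zones Tibble with columns `row`, `col`, `district`.
#' @return `read_zone_map()` a tibble; `write_zone_map()` the path, invisibly.
#' @export
read_zone_map <- function(path) {
  df <- utils::read.csv(path)
  need <- c("row", "col", "district")
  if (!all(need %in% names(df))) {
    stop("zone map lacks column(s): ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df[need])
}

#' @rdname read_zone_map
#' @export
write_zone_map <- function(zones, path) {
  utils::write.csv(as.data.frame(zones[c("row", "col", "district")]), path,
                   row.names = FALSE, na = "")
  invisible(path)
}
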