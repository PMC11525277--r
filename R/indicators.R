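#' Per-pixel climatology of a gridded series
#'
#' Computes the per-pixel minimum, mean and maximum of a monthly series over
#' its reference period, either per calendar month (the usual convention for
#' condition indices: "maximum NDVI" means the multi-year maximum for that
#' month) or over the whole series. Masked months are excluded; a pixel
#' (-month) with no unmasked observations gets `NA` statistics.
#'
#' @param x A `grid_series`.
#' @param by_month If `TRUE` (default) climatology is computed per calendar
#'   month; if `FALSE`, over the whole series.
#' @return A tibble with columns `row`, `col` (, `month`), `n`, `min`,
#'   `mean`, `max`, of class `grid_climatology`.
#' @export
#'
#' @examples
#' gs <- grid_series(data.frame(year = rep(2001:2003, each = 1), month = 6,
#'                              row = 1, col = 1, value = c(0.2, 0.4, 0.6)),
#'                   "ndvi")
#' grid_climatology(gs)
grid_climatology <- function(x, by_month = TRUE) {
  grp <- if (by_month) c("row", "col", "month") else c("row", "col")
  out <- x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      min = if (n > 0) min(.data$value, na.rm = TRUE) else NA_real_,
      mean = if (n > 0) mean(.data$value, na.rm = TRUE) else NA_real_,
      max = if (n > 0) max(.data$value, na.rm = TRUE) else NA_real_,
      .groups = "drop")
  structure(out, by_month = by_month, variable = attr(x, "variable"),
            class = c("grid_climatology", class(out)))
}

join_climatology <- function(x, clim) {
  by <- if (isTRUE(attr(clim, "by_month"))) c("row", "col", "month") else c("row", "col")
  dplyr::left_join(x, as.data.frame(clim), by = by)
}

clip01 <- function(v, clip, lo = 0, hi = 1) {
  if (clip) pmin(pmax(v, lo), hi) else v
}

#' Normalized-difference reflectance indices
#'
#' `compute_ndwi()` is the normalized difference water index
#' (NIR - SWIR)/(NIR + SWIR); `compute_ndvi()` the normalized difference
#' vegetation index (NIR - red)/(NIR + red); `compute_siwsi()` the shortwave
#' infrared water stress index (SWIR - NIR)/(SWIR + NIR), which *increases*
#' with leaf-water stress (variant 1 uses the 1628-1652 nm channel, variant 2
#' the 1230-1250 nm channel -- pass the matching band). All lie in [-1, 1]
#' where defined; a zero denominator yields a masked cell.
#'
#' @param nir,swir,red Co-registered reflectance `grid_series` (band 2 = NIR).
#' @return A `grid_series` of the index.
#' @export
#'
#' @examples
#' px <- data.frame(year = 2001, month = 1, row = 1, col = 1)
#' nir <- grid_series(cbind(px, value = 0.3), "nir")
#' swir <- grid_series(cbind(px, value = 0.1), "swir")
#' compute_ndwi(nir, swir)$value  # 0.5
compute_ndwi <- function(nir, swir) {
  p <- gs_pair(nir, swir)
  den <- p$value + p$value_b
  v <- ifelse(den == 0, NA_real_, (p$value - p$value_b) / den)
  gs_with_values(nir, v, variable = "ndwi", units = "")
}

#' @rdname compute_ndwi
#' @export
compute_ndvi <- function(nir, red) {
  p <- gs_pair(nir, red)
  den <- p$value + p$value_b
  v <- ifelse(den == 0, NA_real_, (p$value - p$value_b) / den)
  gs_with_values(nir, v, variable = "ndvi", units = "")
}

#' @rdname compute_ndwi
#' @param swir_band The SWIR reflectance band: 1628-1652 nm for SIWSI-1,
#'   1230-1250 nm for SIWSI-2.
#' @param variant Label suffix, 1 or 2.
#' @export
compute_siwsi <- function(swir_band, nir, variant = 1) {
  p <- gs_pair(swir_band, nir)
  den <- p$value + p$value_b
  v <- ifelse(den == 0, NA_real_, (p$value - p$value_b) / den)
  gs_with_values(nir, v, variable = paste0("siwsi", variant), units = "")
}

#' Condition indices relative to a pixel climatology
#'
#' `compute_vci()` is the vegetation condition index
#' 100 (NDVI - NDVI_min)/(NDVI_max - NDVI_min) in percent; `compute_tci()`
#' the temperature condition index (LST_max - LST)/(LST_max - LST_min),
#' which is 0 at the hot extreme and 1 at the cool extreme; `compute_smci()`
#' the soil moisture condition index (SSM - SSM_min)/(SSM_max - SSM_min).
#' Values outside the climatology envelope are clipped by default (set
#' `clip = FALSE` to retain them); a flat climatology (max = min) yields a
#' masked cell.
#'
#' @param ndvi,lst,ssm Input `grid_series`.
#' @param clim A [grid_climatology()] of the same variable and pixel grid.
#' @param clip Clip out-of-envelope values to the index range (default TRUE).
#' @return A `grid_series` of the index.
#' @export
compute_vci <- function(ndvi, clim, clip = TRUE) {
  j <- join_climatology(ndvi, clim)
  rng <- j$max - j$min
  v <- ifelse(is.na(rng) | rng == 0, NA_real_, 100 * (j$value - j$min) / rng)
  gs_with_values(ndvi, clip01(v, clip, 0, 100), variable = "vci", units = "%")
}

#' @rdname compute_vci
#' @export
compute_tci <- function(lst, clim, clip = TRUE) {
  j <- join_climatology(lst, clim)
  rng <- j$max - j$min
  v <- ifelse(is.na(rng) | rng == 0, NA_real_, (j$max - j$value) / rng)
  gs_with_values(lst, clip01(v, clip), variable = "tci", units = "")
}

#' @rdname compute_vci
#' @export
compute_smci <- function(ssm, clim, clip = TRUE) {
  j <- join_climatology(ssm, clim)
  rng <- j$max - j$min
  v <- ifelse(is.na(rng) | rng == 0, NA_real_, (j$value - j$min) / rng)
  gs_with_values(ssm, clip01(v, clip), variable = "smci", units = "")
}

#' Soil moisture deficit index (recursive)
#'
#' The soil-water departure SD_i is the deviation of soil moisture SW_i from
#' its per-pixel, per-calendar-month climatological mean MSW_i, scaled by the
#' dry-side range (MSW - MinSW) when SW <= MSW and by the wet-side range
#' (MaxSW - MSW) when SW > MSW, so SD lies in [-1, 1]. The index then
#' accumulates with memory 0.5: SMDI_i = 0.5 SMDI_(i-1) + SD_i / 50,
#' initialized at 0 before the first month (the 0.5 memory decays any
#' initialization within about six months). A degenerate active-branch range
#' masks the cell; the recursion re-initializes from 0 after a masked month.
#'
#' @param ssm Surface soil moisture `grid_series`.
#' @param clim A per-calendar-month [grid_climatology()] of the same series
#'   (supplies MSW, MinSW, MaxSW).
#' @return A `grid_series` of SMDI (bounded by 0.04 in magnitude at the
#'   recursion's fixed point).
#' @export
compute_smdi <- function(ssm, clim) {
  if (!isTRUE(attr(clim, "by_month"))) {
    stop("SMDI requires a per-calendar-month climatology", call. = FALSE)
  }
  j <- join_climatology(ssm, clim)
  sd_i <- smdi_departure(j$value, j$mean, j$min, j$max)
  out <- j |>
    dplyr::mutate(.sd = sd_i) |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::arrange(.data$year, .data$month, .by_group = TRUE) |>
    dplyr::mutate(value = smdi_recursion(.data$.sd)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$year, .data$month, .data$row, .data$col)
  gs_with_values(ssm, out$value, variable = "smdi", units = "")
}

# two-branch soil-water departure, SD in [-1, 1]; both branches agree (0) at
# SW = MSW
smdi_departure <- function(sw, msw, minsw, maxsw) {
  dry <- sw <= msw
  den <- ifelse(dry, msw - minsw, maxsw - msw)
  ifelse(is.na(sw) | is.na(den) | den == 0,
         ifelse(!is.na(sw) & !is.na(msw) & sw == msw, 0, NA_real_),
         (sw - msw) / den)
}

# SMDI_i = 0.5 SMDI_{i-1} + SD_i/50, SMDI_0 = 0; NA SD masks the month and
# resets the carried state to 0
smdi_recursion <- function(sd_i) {
  purrr::accumulate(sd_i, function(prev, s) {
    if (is.na(s)) return(NA_real_)
    0.5 * (if (is.na(prev)) 0 else prev) + s / 50
  }, .init = 0)[-1]
}

#' Soil water deficit index
#'
#' SWDI = (theta - theta_FC) / theta_AWC: zero at field capacity, negative in
#' deficit, and +1 when the soil holds one full available-water capacity
#' above field capacity.
#'
#' @param theta Volumetric soil water content `grid_series` (m3/m3).
#' @param soil A tibble with columns `row`, `col`, `theta_fc`, `theta_awc`
#'   (see [estimate_soil_parameters()] for a data-driven fallback).
#' @return A `grid_series` of SWDI.
#' @export
compute_swdi <- function(theta, soil) {
  need <- c("row", "col", "theta_fc", "theta_awc")
  if (!all(need %in% names(soil))) {
    stop("soil parameter grid needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(soil$theta_awc <= 0, na.rm = TRUE)) {
    stop("theta_awc must be positive", call. = FALSE)
  }
  j <- dplyr::left_join(theta, soil[need], by = c("row", "col"))
  v <- (j$value - j$theta_fc) / j$theta_awc
  gs_with_values(theta, v, variable = "swdi", units = "")
}

#' Estimate soil parameters from the soil-moisture record
#'
#' An approximation for when field capacity and available water capacity are
#' not supplied: theta_FC is taken as the per-pixel 95th percentile of the
#' observed soil moisture and theta_AWC as the 95th-minus-5th percentile
#' range. Use measured soil properties when available.
#'
#' @param theta Volumetric soil water content `grid_series`.
#' @param probs Lower/upper quantiles used as the wilting-point and
#'   field-capacity proxies.
#' @return A soil parameter tibble (`row`, `col`, `theta_fc`, `theta_awc`)
#'   with attribute `approximate = TRUE`.
#' @export
estimate_soil_parameters <- function(theta, probs = c(0.05, 0.95)) {
  out <- theta |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(
      theta_fc = stats::quantile(.data$value, probs[2], na.rm = TRUE, names = FALSE),
      theta_awc = diff(stats::quantile(.data$value, probs, na.rm = TRUE, names = FALSE)),
      .groups = "drop")
  structure(out, approximate = TRUE)
}
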