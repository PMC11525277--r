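#' Configure a synthetic study scene
#'
#' Defines a fully self-contained gridded scene with the statistical
#' structure the monitoring framework assumes: deterministic seasonal cycles
#' (a land-surface-temperature sinusoid peaking pre-monsoon, a Jun-Sep
#' monsoon precipitation pulse), AR(1) Gaussian anomalies, localized
#' multi-month drought episodes, a district tiling, and district yields
#' coupled to growing-season drought severity. During an episode, soil
#' moisture and precipitation are depressed and land surface temperature
#' elevated immediately, while the vegetation/reflectance stress signature
#' (NIR depressed, SWIR and red elevated) follows after `lead_months` --
#' soil-moisture deficit leads the canopy response.
#'
#' Defaults mirror a monsoon-regime study area at desk scale: a 5 x 6 grid
#' over 2001-2019 tiled into 30 districts, drought episodes roughly once
#' every three years, canopy lead of 1 month, and Kharif paddy yields
#' `base - beta * (district mean episode intensity over Kharif) + noise`.
#'
#' @param nrow,ncol Grid dimensions.
#' @param years Calendar years of the monthly record.
#' @param n_districts Number of districts in the rectangular zone tiling.
#' @param seed Integer seed; the scene is a deterministic function of the
#'   config.
#' @param rho AR(1) coefficient of the anomaly processes, in [0, 1).
#' @param lst_amplitude Seasonal LST amplitude (K).
#' @param monsoon_precip Mean monthly monsoon (Jun-Sep) precipitation (mm).
#' @param episodes List of episodes, each a list with elements `rows`,
#'   `cols` (pixel index vectors), `start_year`, `start_month`, `length`
#'   (months) and `intensity` in (0, 1]. `NULL` selects the default episode
#'   set; `list()` disables episodes.
#' @param lead_months Months by which soil-moisture deficit leads the
#'   vegetation/reflectance response.
#' @param yield_base,yield_beta,yield_sd Yield model: district-year yield =
#'   base - beta * mean Kharif episode intensity + N(0, sd) (kg/ha).
#' @param resolution Resolution tag attached to all series.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(nrow = 5, ncol = 6, years = 2001:2019,
                         n_districts = 30, seed = 1L, rho = 0.5,
                         lst_amplitude = 6, monsoon_precip = 280,
                         episodes = NULL, lead_months = 1,
                         yield_base = 1500, yield_beta = 600, yield_sd = 80,
                         resolution = "0.25deg") {
  if (is.null(episodes)) {
    episodes <- default_episodes(nrow, ncol, years)
  }
  cfg <- list(nrow = nrow, ncol = ncol, years = sort(years),
              n_districts = n_districts, seed = as.integer(seed), rho = rho,
              lst_amplitude = lst_amplitude, monsoon_precip = monsoon_precip,
              episodes = episodes, lead_months = lead_months,
              yield_base = yield_base, yield_beta = yield_beta,
              yield_sd = yield_sd, resolution = resolution)
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

# one multi-month episode roughly every third year, alternating between two
# sub-regions, pre-/early-monsoon onsets
default_episodes <- function(nrow, ncol, years) {
  ep_years <- years[seq(2, length(years), by = 3)]
  half_r <- max(1, nrow %/% 2)
  half_c <- max(1, ncol %/% 2)
  lapply(seq_along(ep_years), function(i) {
    west <- i %% 2 == 1
    list(rows = if (west) 1:half_r else (nrow - half_r + 1):nrow,
         cols = if (west) 1:half_c else (ncol - half_c + 1):ncol,
         start_year = ep_years[i],
         start_month = if (west) 6L else 4L,
         length = 5L + (i %% 2), intensity = 0.7 + 0.1 * (i %% 2))
  })
}

validate_scene_config <- function(cfg) {
  stopifnot(cfg$nrow >= 1, cfg$ncol >= 1, length(cfg$years) >= 1,
            cfg$rho >= 0, cfg$rho < 1)
  t0 <- month_index(cfg$years[1], 1L)
  t1 <- month_index(cfg$years[length(cfg$years)], 12L)
  for (ep in cfg$episodes) {
    stopifnot(all(ep$rows %in% seq_len(cfg$nrow)),
              all(ep$cols %in% seq_len(cfg$ncol)),
              ep$length >= 1, ep$intensity > 0, ep$intensity <= 1)
    s <- month_index(ep$start_year, ep$start_month)
    if (s < t0 || s + ep$length - 1 > t1) {
      stop("episode falls outside the scene's time range", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Ground truth of the imposed drought episodes
#'
#' The machine-readable truth table for recovery experiments: one row per
#' episode pixel-month with the imposed intensity; overlapping episodes are
#' merged per pixel-month keeping the maximum intensity.
#'
#' @param cfg A [scene_config()].
#' @return A tibble `row`, `col`, `year`, `month`, `intensity` (empty when
#'   the config has no episodes).
#' @export
truth_report <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  if (length(cfg$episodes) == 0) {
    return(tibble::tibble(row = integer(), col = integer(), year = integer(),
                          month = integer(), intensity = double()))
  }
  rows <- purrr::map_dfr(cfg$episodes, function(ep) {
    t <- month_index(ep$start_year, ep$start_month) + seq_len(ep$length) - 1L
    tidyr::expand_grid(row = ep$rows, col = ep$cols, t = t) |>
      dplyr::mutate(year = .data$t %/% 12L, month = .data$t %% 12L + 1L,
                    intensity = ep$intensity)
  })
  rows |>
    dplyr::group_by(.data$row, .data$col, .data$year, .data$month) |>
    dplyr::summarise(intensity = max(.data$intensity), .groups = "drop") |>
    dplyr::arrange(.data$row, .data$col, .data$year, .data$month)
}

# per-pixel-month episode intensity grid (0 outside episodes), optionally
# time-shifted by `shift` months (for the lagged canopy response)
episode_field <- function(cfg, frame, shift = 0L) {
  truth <- truth_report(cfg)
  if (nrow(truth) == 0) return(rep(0, nrow(frame)))
  truth$t <- month_index(truth$year, truth$month) + shift
  key <- dplyr::left_join(
    dplyr::mutate(frame, t = month_index(.data$year, .data$month)),
    truth[c("row", "col", "t", "intensity")], by = c("row", "col", "t"))
  tidyr::replace_na(key$intensity, 0)
}

#' Generate a synthetic gridded scene
#'
#' Produces co-registered monthly `grid_series` for land surface temperature
#' (K), surface soil moisture (m3/m3), precipitation (mm) and four surface
#' reflectance bands (red, NIR/band 2, and two SWIR channels), a district
#' zone map, a district-year yield table, and the episode truth table. The
#' output is a deterministic function of the config (including its seed).
#'
#' @param cfg A [scene_config()].
#' @return A list with elements `lst`, `ssm`, `precip`, `red`, `nir`,
#'   `swir5`, `swir6` (grid_series), `zones`, `yields`, `truth` (tibbles)
#'   and `config`.
#' @export
#'
#' @examples
#' sc <- generate_scene(scene_config(nrow = 2, ncol = 2, years = 2001:2004,
#'                                   n_districts = 4, seed = 42))
#' sc$lst
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  set.seed(cfg$seed)
  frame <- tidyr::expand_grid(year = cfg$years, month = 1:12,
                              row = seq_len(cfg$nrow), col = seq_len(cfg$ncol)) |>
    dplyr::arrange(.data$row, .data$col, .data$year, .data$month)
  n_px <- cfg$nrow * cfg$ncol
  n_t <- length(cfg$years) * 12L

  ar1 <- function(sd) {
    as.numeric(vapply(seq_len(n_px), function(i) {
      as.numeric(stats::filter(stats::rnorm(n_t, sd = sd * sqrt(1 - cfg$rho^2)),
                               cfg$rho, method = "recursive"))
    }, numeric(n_t)))
  }
  # monthly weights of the monsoon regime (peak Jul-Sep) and canopy greenness
  monsoon_w <- c(.04, .02, .02, .03, .10, .55, .95, 1, .90, .45, .15, .06)
  green_w <- c(.35, .3, .25, .2, .25, .45, .7, .9, 1, .95, .7, .5)

  stress_now <- episode_field(cfg, frame)                      # SSM/precip/LST
  stress_lag <- episode_field(cfg, frame, shift = cfg$lead_months)  # canopy

  m <- frame$month
  lst <- 301 + cfg$lst_amplitude * cos(2 * pi * (m - 5) / 12) +
    ar1(1.2) + 4 * stress_now
  precip_mean <- pmax(5, cfg$monsoon_precip * monsoon_w[m]) *
    (1 - 0.8 * stress_now)
  precip <- stats::rgamma(nrow(frame), shape = 4, scale = precip_mean / 4)
  ssm <- pmin(0.45, pmax(0.02,
    0.20 + 0.12 * monsoon_w[m] + 0.03 * ar1(1) - 0.15 * stress_now))
  red <- pmin(1, pmax(0, 0.07 + 0.015 * ar1(1) + 0.04 * stress_lag))
  nir <- pmin(1, pmax(0, 0.30 + 0.08 * green_w[m] + 0.02 * ar1(1) -
                           0.12 * stress_lag))
  swir5 <- pmin(1, pmax(0, 0.18 + 0.02 * ar1(1) + 0.09 * stress_lag))
  swir6 <- pmin(1, pmax(0, 0.24 + 0.02 * ar1(1) + 0.07 * stress_lag))

  mk <- function(v, variable, units) {
    grid_series(dplyr::mutate(frame, value = v), variable = variable,
                units = units, resolution = cfg$resolution)
  }
  zones <- zone_tiling(cfg$nrow, cfg$ncol, cfg$n_districts)
  yields <- scene_yields(cfg, zones)
  list(lst = mk(lst, "lst", "K"),
       ssm = mk(ssm, "ssm", "m3/m3"),
       precip = mk(precip, "precip", "mm"),
       red = mk(red, "red", ""),
       nir = mk(nir, "nir", ""),
       swir5 = mk(swir5, "swir5", ""),
       swir6 = mk(swir6, "swir6", ""),
       zones = zones, yields = yields, truth = truth_report(cfg),
       config = cfg)
}

#' Rectangular district tiling of the grid
#'
#' Assigns each pixel to one of `n_districts` zones by splitting the grid
#' into near-equal contiguous tiles (every district id then appears in the
#' yield table).
#'
#' @param nrow,ncol Grid dimensions.
#' @param n_districts Number of zones (at most `nrow * ncol`).
#' @return A tibble `row`, `col`, `district`.
#' @export
zone_tiling <- function(nrow, ncol, n_districts) {
  n_px <- nrow * ncol
  if (n_districts > n_px) {
    stop("more districts than pixels (", n_districts, " > ", n_px, ")", call. = FALSE)
  }
  grid <- tidyr::expand_grid(row = seq_len(nrow), col = seq_len(ncol))
  grid$district <- as.integer(ceiling(seq_len(n_px) / (n_px / n_districts)))
  grid
}

# district-year yields coupled to the mean Kharif episode intensity
scene_yields <- function(cfg, zones) {
  kharif <- season_definition("kharif")
  truth <- truth_report(cfg)
  base_grid <- tidyr::expand_grid(district = sort(unique(zones$district)),
                                  year = cfg$years)
  sev <- truth |>
    dplyr::filter(.data$month %in% kharif$months) |>
    dplyr::inner_join(zones, by = c("row", "col")) |>
    dplyr::group_by(.data$district, .data$year) |>
    dplyr::summarise(sum_intensity = sum(.data$intensity), .groups = "drop")
  n_kharif_px <- zones |>
    dplyr::count(.data$district, name = "n_px") |>
    dplyr::mutate(n_cells = .data$n_px * length(kharif$months))
  out <- base_grid |>
    dplyr::left_join(sev, by = c("district", "year")) |>
    dplyr::left_join(n_kharif_px, by = "district") |>
    dplyr::mutate(
      mean_sev = tidyr::replace_na(.data$sum_intensity, 0) / .data$n_cells,
      yield = cfg$yield_base - cfg$yield_beta * .data$mean_sev +
        stats::rnorm(dplyr::n(), sd = cfg$yield_sd)) |>
    dplyr::select("district", "year", "yield")
  out
}
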