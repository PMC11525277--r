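#' Standardized precipitation index
#'
#' `fit_spi()` fits, per pixel and per calendar month, a zero-inflated gamma
#' distribution to the k-month rolling precipitation accumulation:
#' H(x) = q + (1 - q) G(x), where q is the probability of a zero
#' accumulation and G the gamma CDF fitted to the nonzero accumulations by
#' Thom's approximate maximum-likelihood estimator (the standard SPI
#' convention). `compute_spi()` maps accumulations through the fitted H and
#' the standard-normal quantile function, so SPI over its own fitting period
#' is approximately mean 0, sd 1.
#'
#' A calendar-month cell whose nonzero accumulations are (near-)constant has
#' no meaningful gamma fit and is masked with a warning; an all-zero
#' accumulation series is likewise masked.
#'
#' @param precip Monthly precipitation `grid_series` (must be nonnegative).
#' @param scale_months Accumulation scale k, typically 3 or 6.
#' @param min_years Minimum number of years required for a stable fit
#'   (default 15); fewer is an error.
#' @return `fit_spi()` a tibble of class `spi_parameters` with columns `row`,
#'   `col`, `month`, `q`, `shape`, `scale`; `compute_spi()` a `grid_series`
#'   of SPI values (the first k - 1 months, lacking a full accumulation, are
#'   masked).
#' @export
#'
#' @examples
#' df <- expand.grid(year = 2001:2020, month = 1:12, row = 1, col = 1)
#' df$value <- rgamma(nrow(df), shape = 2, scale = 50)
#' pr <- grid_series(df, "precip", units = "mm")
#' pars <- fit_spi(pr, scale_months = 3)
#' spi <- compute_spi(pr, pars)
#' round(c(mean(spi$value, na.rm = TRUE), sd(spi$value, na.rm = TRUE)), 2)
fit_spi <- function(precip, scale_months = 3, min_years = 15) {
  if (any(precip$value < 0, na.rm = TRUE)) {
    stop("precipitation must be nonnegative", call. = FALSE)
  }
  n_years <- length(unique(precip$year))
  if (n_years < min_years) {
    stop("SPI fit requires >= ", min_years, " years of monthly precipitation; got ",
         n_years, call. = FALSE)
  }
  acc <- spi_accumulate(precip, scale_months)
  pars <- acc |>
    dplyr::filter(!is.na(.data$acc)) |>
    dplyr::group_by(.data$row, .data$col, .data$month) |>
    dplyr::summarise(fit = list(fit_gamma_thom(.data$acc)), .groups = "drop") |>
    tidyr::unnest_wider("fit")
  n_bad <- sum(is.na(pars$shape) & pars$q < 1)
  if (n_bad > 0) {
    warning(n_bad, " pixel-month cell(s) had a degenerate gamma fit and are masked",
            call. = FALSE)
  }
  structure(pars, scale_months = scale_months,
            class = c("spi_parameters", class(pars)))
}

# right-aligned k-month accumulation; any masked month inside the window
# masks the accumulation
spi_accumulate <- function(precip, k) {
  precip |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::arrange(.data$year, .data$month, .by_group = TRUE) |>
    dplyr::mutate(acc = zoo::rollsumr(.data$value, k, fill = NA),
                  # precip is nonnegative: snap rolling-sum FP residue to exact 0
                  acc = dplyr::if_else(abs(.data$acc) < 1e-9, 0, .data$acc)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$year, .data$month, .data$row, .data$col)
}

# Thom's approximate-ML gamma fit of the nonzero part, with the
# zero-accumulation probability q estimated empirically
fit_gamma_thom <- function(x) {
  q <- mean(x == 0)
  pos <- x[x > 0]
  if (length(pos) < 3) {
    return(list(q = q, shape = NA_real_, scale = NA_real_))
  }
  m <- mean(pos)
  a <- log(m) - mean(log(pos))
  if (!is.finite(a) || a <= 1e-12) {   # (near-)constant positive values
    return(list(q = q, shape = NA_real_, scale = NA_real_))
  }
  shape <- (1 + sqrt(1 + 4 * a / 3)) / (4 * a)
  list(q = q, shape = shape, scale = m / shape)
}

#' @rdname fit_spi
#' @param params An `spi_parameters` object from `fit_spi()`.
#' @export
compute_spi <- function(precip, params) {
  stopifnot(inherits(params, "spi_parameters"))
  k <- attr(params, "scale_months")
  acc <- spi_accumulate(precip, k)
  j <- dplyr::left_join(acc, as.data.frame(params),
                        by = c("row", "col", "month"))
  g <- ifelse(j$acc > 0 & !is.na(j$shape),
              stats::pgamma(j$acc, shape = j$shape, scale = j$scale), 0)
  h <- j$q + (1 - j$q) * g
  # guard the normal quantile against 0/1 (all-zero cells, extreme tails)
  h <- pmin(pmax(h, 1e-6), 1 - 1e-6)
  v <- ifelse(is.na(j$acc) | is.na(j$shape), NA_real_, stats::qnorm(h))
  gs_with_values(precip, v, variable = paste0("spi", k), units = "")
}
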