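#' Normalize an indicator to [0, 1] with drought-low orientation
#'
#' Rescales each pixel's series to [0, 1] by its own min-max over the study
#' period (the same window over which the entropy weights are later
#' computed). Indicators that *increase* with drought stress (SIWSI) are
#' flipped (`1 - r`) so that, after preparation, low values uniformly mean
#' drought. A pixel whose series is constant has no range and is masked.
#'
#' @param series A `grid_series`.
#' @param invert Flip the oriented values (`1 - r`); use for stress-positive
#'   indicators such as SIWSI. Default `FALSE`.
#' @return A `grid_series` with values in [0, 1] (attribute
#'   `normalized = TRUE`).
#' @export
#'
#' @examples
#' gs <- grid_series(data.frame(year = 2001, month = 1:3, row = 1, col = 1,
#'                              value = c(10, 20, 30)), "x")
#' normalize_indicator(gs)$value       # 0 0.5 1
#' normalize_indicator(gs, invert = TRUE)$value  # 1 0.5 0
normalize_indicator <- function(series, invert = FALSE) {
  out <- series |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::mutate(.lo = suppressWarnings(min(.data$value, na.rm = TRUE)),
                  .hi = suppressWarnings(max(.data$value, na.rm = TRUE)),
                  value = dplyr::if_else(
                    is.finite(.data$.lo) & .data$.hi > .data$.lo,
                    (.data$value - .data$.lo) / (.data$.hi - .data$.lo),
                    NA_real_)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$year, .data$month, .data$row, .data$col)
  v <- if (invert) 1 - out$value else out$value
  res <- gs_with_values(series, v, units = "")
  attr(res, "normalized") <- TRUE
  res
}

#' Bundle normalized indicators into a stack
#'
#' Binds co-registered normalized indicator series into one long tibble with
#' an `indicator` column, the container the entropy-weighting and
#' combination steps operate on.
#'
#' @param ... Named `grid_series` (names override each series' variable
#'   label), or a single named list of them.
#' @return A tibble of class `indicator_stack` with columns `indicator`,
#'   `year`, `month`, `row`, `col`, `value`.
#' @export
indicator_stack <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !inherits(xs[[1]], "grid_series")) {
    xs <- xs[[1]]
  }
  if (is.null(names(xs)) || any(names(xs) == "")) {
    names(xs) <- vapply(xs, grid_variable, character(1))
  }
  if (anyDuplicated(names(xs)) > 0) stop("indicator names must be unique", call. = FALSE)
  do.call(assert_conformable, unname(xs))
  out <- purrr::imap(xs, \(g, nm) dplyr::mutate(tibble::as_tibble(g), indicator = nm)) |>
    purrr::list_rbind() |>
    dplyr::select("indicator", "year", "month", "row", "col", "value")
  structure(out, resolution = attr(xs[[1]], "resolution"),
            class = c("indicator_stack", class(tibble::tibble())))
}

#' Entropy frequencies of a normalized series
#'
#' The frequency series f_j = r_j / sum(r) of a pixel's normalized indicator
#' values, the distribution whose Shannon entropy measures the indicator's
#' information content. An all-zero series has no distribution and returns
#' `NA` with a warning.
#'
#' @param r Numeric vector of normalized values in [0, 1] (one pixel, one
#'   indicator, over months).
#' @return Numeric vector summing to 1, or all-`NA`.
#' @export
entropy_frequencies <- function(r) {
  s <- sum(r)
  if (is.na(s) || s <= 0) {
    warning("all-zero (or masked) series: frequencies undefined", call. = FALSE)
    return(rep(NA_real_, length(r)))
  }
  r / s
}

#' Normalized Shannon entropy
#'
#' H = -K sum(f ln f) with K = 1/ln(n) and the convention 0 ln 0 = 0, so H
#' is 1 for a uniform distribution over n months and 0 for a one-hot
#' distribution.
#'
#' @param f Frequency vector (nonnegative, summing to 1).
#' @param n Number of months; defaults to `length(f)`.
#' @return Entropy in [0, 1].
#' @export
#'
#' @examples
#' shannon_entropy(rep(0.25, 4))        # 1
#' shannon_entropy(c(1, 0, 0, 0))       # 0
shannon_entropy <- function(f, n = length(f)) {
  if (n < 2) stop("entropy needs n >= 2 months", call. = FALSE)
  terms <- ifelse(f > 0, f * log(f), 0)
  -sum(terms) / log(n)
}

#' Weights from per-indicator entropies
#'
#' W_i = (1 - H_i) / (m - sum(H)): indicators whose normalized series are
#' less uniform (lower entropy, more information) receive more weight. When
#' every entropy equals 1 the formula is 0/0; equal weights are returned
#' with a warning.
#'
#' @param h Numeric vector of per-indicator entropies in [0, 1] (length m >= 2).
#' @return Weight vector: nonnegative, summing to 1.
#' @export
#'
#' @examples
#' entropy_weight(c(0.9, 0.8, 0.7))   # 1/6 2/6 3/6
entropy_weight <- function(h) {
  m <- length(h)
  if (m < 2) stop("need at least two indicators", call. = FALSE)
  den <- m - sum(h)
  if (!is.finite(den) || den <= .Machine$double.eps * m) {
    warning("all indicators maximally uninformative (sum H = m); using equal weights",
            call. = FALSE)
    return(rep(1 / m, m))
  }
  (1 - h) / den
}

#' Per-pixel entropy weights for an indicator stack
#'
#' At each pixel, months where every indicator is unmasked are retained, the
#' frequency distribution of each indicator's normalized series is formed,
#' its normalized Shannon entropy computed, and the entropy weights derived
#' ([entropy_weight()]). Weights are computed over the full monthly series
#' (not per season), independently at every grid location.
#'
#' @param stack An [indicator_stack()] of normalized indicators.
#' @return A tibble of class `entropy_weights` with columns `row`, `col`,
#'   `indicator`, `n` (months used), `entropy`, `weight`.
#' @export
entropy_weights <- function(stack) {
  stopifnot(inherits(stack, "indicator_stack"))
  m <- length(unique(stack$indicator))
  if (m < 2) stop("need at least two indicators", call. = FALSE)
  complete <- stack |>
    dplyr::group_by(.data$row, .data$col, .data$year, .data$month) |>
    dplyr::filter(!anyNA(.data$value)) |>
    dplyr::ungroup()
  out <- complete |>
    dplyr::group_by(.data$row, .data$col, .data$indicator) |>
    dplyr::summarise(n = dplyr::n(),
                     entropy = pixel_entropy(.data$value), .groups = "drop_last") |>
    dplyr::mutate(weight = if (anyNA(.data$entropy) || .data$n[1] < 2)
                             NA_real_ else entropy_weight(.data$entropy)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$row, .data$col, .data$indicator)
  structure(out, m = m, class = c("entropy_weights", class(tibble::tibble())))
}

pixel_entropy <- function(r) {
  if (length(r) < 2) return(NA_real_)
  s <- sum(r)
  if (s <= 0) return(NA_real_)
  shannon_entropy(r / s, n = length(r))
}

#' @export
print.entropy_weights <- function(x, ...) {
  cat(sprintf("<entropy_weights> %d indicators x %d pixels\n",
              attr(x, "m"), nrow(dplyr::distinct(x, .data$row, .data$col))))
  NextMethod()
}

#' Tidy and summarise entropy-weight objects
#'
#' `tidy()` returns the per-pixel, per-indicator weights as a plain tibble;
#' `glance()` a one-row summary with the number of indicators, pixels and
#' the spatial mean weight per indicator (wide).
#'
#' @param x An `entropy_weights` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy entropy_weights
#' @export
tidy.entropy_weights <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.entropy_weights
#' @method glance entropy_weights
#' @export
glance.entropy_weights <- function(x, ...) {
  means <- x |>
    dplyr::group_by(.data$indicator) |>
    dplyr::summarise(w = mean(.data$weight, na.rm = TRUE)) |>
    tidyr::pivot_wider(names_from = "indicator", values_from = "w",
                       names_prefix = "mean_w_")
  dplyr::bind_cols(
    tibble::tibble(m = attr(x, "m"),
                   n_pixels = nrow(dplyr::distinct(x, .data$row, .data$col)),
                   mean_entropy = mean(x$entropy, na.rm = TRUE)),
    means)
}

#' Combine normalized indicators into the regional combined drought index
#'
#' RegCDI_j = sum_i W_i r_ij at every pixel-month: the entropy-weighted
#' convex combination of the normalized, drought-low-oriented indicators.
#' RegCDI lies in [0, 1]; lower values indicate more severe drought. A
#' pixel-month with any masked constituent (or masked weights) is masked.
#'
#' @param stack An [indicator_stack()] of normalized indicators.
#' @param weights An [entropy_weights()] object whose indicator names match
#'   the stack's.
#' @return A `grid_series` with variable `"regcdi"`, carrying the indicator
#'   names in attribute `indicators`.
#' @export
combine_regcdi <- function(stack, weights) {
  stopifnot(inherits(stack, "indicator_stack"))
  if (!setequal(unique(stack$indicator), unique(weights$indicator))) {
    stop("indicator names in stack and weights differ", call. = FALSE)
  }
  j <- dplyr::left_join(tibble::as_tibble(stack),
                        weights[c("row", "col", "indicator", "weight")],
                        by = c("row", "col", "indicator"))
  out <- j |>
    dplyr::group_by(.data$year, .data$month, .data$row, .data$col) |>
    dplyr::summarise(value = sum(.data$weight * .data$value), .groups = "drop") |>
    dplyr::arrange(.data$year, .data$month, .data$row, .data$col)
  res <- grid_series(out, variable = "regcdi", units = "",
                     resolution = attr(stack, "resolution") %||% "0.25deg")
  attr(res, "indicators") <- sort(unique(stack$indicator))
  res
}

#' One-call RegCDI pipeline
#'
#' Convenience wrapper: normalizes the supplied indicator series (flipping
#' any listed in `invert`), computes per-pixel entropy weights and combines
#' them into RegCDI.
#'
#' @param ... Named raw indicator `grid_series` (e.g. `smci = , tci = ,
#'   siwsi1 = `).
#' @param invert Character vector of indicator names to orientation-flip
#'   (stress-positive indicators); default `"siwsi1"` intersected with the
#'   supplied names.
#' @return A list with elements `stack`, `weights`, `index`.
#' @export
regcdi_pipeline <- function(..., invert = "siwsi1") {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !inherits(xs[[1]], "grid_series")) {
    xs <- xs[[1]]
  }
  normed <- purrr::imap(xs, \(g, nm) normalize_indicator(g, invert = nm %in% invert))
  stack <- indicator_stack(normed)
  w <- entropy_weights(stack)
  list(stack = stack, weights = w, index = combine_regcdi(stack, w))
}
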