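#' Standardize district yields
#'
#' Adds the standardized yield z = (x - mu) / sigma per district, where mu
#' and sigma are the district's mean and standard deviation over its
#' non-missing years. Sigma uses the sample (n - 1) convention by default
#' (`sd_type = "population"` divides by n). A district with fewer than
#' `min_years` usable years, or zero spread, cannot be standardized: its z
#' is `NA` and the district is flagged with a warning.
#'
#' @param yields Tibble with columns `district`, `year`, `yield`.
#' @param min_years Minimum non-missing years per district (default 3).
#' @param sd_type `"sample"` (n - 1, default) or `"population"`.
#' @return The input with added columns `mu`, `sigma`, `z`.
#' @export
#'
#' @examples
#' y <- data.frame(district = 1, year = 2001:2003, yield = c(2, 4, 6))
#' standardize_yield(y)$z   # -1 0 1
standardize_yield <- function(yields, min_years = 3,
                              sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  out <- yields |>
    dplyr::group_by(.data$district) |>
    dplyr::mutate(
      .n = sum(!is.na(.data$yield)),
      mu = mean(.data$yield, na.rm = TRUE),
      sigma = {
        s <- stats::sd(.data$yield, na.rm = TRUE)
        if (sd_type == "population" && .data$.n[1] > 1) {
          s <- s * sqrt((.data$.n[1] - 1) / .data$.n[1])
        }
        s
      },
      z = dplyr::if_else(.data$.n >= min_years & .data$sigma > 0,
                         (.data$yield - .data$mu) / .data$sigma, NA_real_)) |>
    dplyr::ungroup()
  bad <- unique(out$district[out$.n < min_years | !(out$sigma > 0)])
  if (length(bad) > 0) {
    warning("district(s) excluded from standardization (too few years or zero spread): ",
            paste(bad, collapse = ", "), call. = FALSE)
  }
  out$.n <- NULL
  out
}

#' Seasonal drought severity per pixel-year
#'
#' The drought severity a crop experiences in a season: with
#' `mode = "season-min"` the minimum index value over the season's months in
#' each year (maximum drought severity, since low index = drought); with
#' `mode = "critical-month"` the index value at the designated critical
#' crop-growth-stage month (default August, mid-Kharif).
#'
#' @param index A `grid_series` (combined index or normalized indicator).
#' @param season A [season_definition()].
#' @param mode `"season-min"` or `"critical-month"`.
#' @param critical_month Calendar month used by `"critical-month"`.
#' @return A tibble `row`, `col`, `year`, `severity`.
#' @export
seasonal_severity <- function(index, season, mode = c("season-min", "critical-month"),
                              critical_month = 8) {
  mode <- match.arg(mode)
  x <- seasonal_filter(index, season)
  if (mode == "critical-month") {
    if (!critical_month %in% season$months) {
      stop("critical month ", critical_month, " is outside season '",
           season$name, "'", call. = FALSE)
    }
    x <- x[x$month == critical_month, , drop = FALSE]
    return(dplyr::arrange(
      dplyr::select(tibble::as_tibble(x), "row", "col", "year", severity = "value"),
      .data$row, .data$col, .data$year))
  }
  x |>
    dplyr::group_by(.data$row, .data$col, .data$year) |>
    dplyr::summarise(severity = if (all(is.na(.data$value))) NA_real_
                     else min(.data$value, na.rm = TRUE), .groups = "drop")
}

#' Pearson correlation with degenerate-input guards
#'
#' The standard product-moment correlation, returning `NA` with a warning
#' when fewer than three paired complete years remain or either series is
#' constant.
#'
#' @param a,b Numeric vectors of equal length (paired years).
#' @return Correlation in [-1, 1], or `NA`.
#' @export
pearson_correlation <- function(a, b) {
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) {
    warning("fewer than 3 paired observations: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant input: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Pixelwise correlation between seasonal severity and district yield
#'
#' Correlates each pixel's yearly seasonal severity with the yield (or
#' standardized yield) series of the district the pixel belongs to. Pixels
#' in districts with fewer than three usable years are masked.
#'
#' @param severity A [seasonal_severity()] tibble.
#' @param yields A yield table, standardized ([standardize_yield()]) when
#'   `target = "z"`.
#' @param zones Tibble `row`, `col`, `district` (background pixels `NA`).
#' @param target `"yield"` or `"z"`.
#' @return A tibble `row`, `col`, `district`, `n_years`, `pcc`, with
#'   attribute `mean_pcc` (spatial mean over defined pixels).
#' @export
correlation_map <- function(severity, yields, zones, target = c("yield", "z")) {
  target <- match.arg(target)
  if (target == "z" && !"z" %in% names(yields)) {
    yields <- standardize_yield(yields)
  }
  yields$.target <- yields[[target]]
  j <- severity |>
    dplyr::inner_join(zones, by = c("row", "col")) |>
    dplyr::inner_join(yields[c("district", "year", ".target")],
                      by = c("district", "year"))
  out <- j |>
    dplyr::group_by(.data$row, .data$col, .data$district) |>
    dplyr::summarise(
      n_years = sum(stats::complete.cases(.data$severity, .data$.target)),
      pcc = suppressWarnings(pearson_correlation(.data$severity, .data$.target)),
      .groups = "drop")
  structure(out, mean_pcc = mean(out$pcc, na.rm = TRUE), target = target)
}

#' Select one indicator per type by yield correlation
#'
#' Given the mean correlation of each candidate indicator with yield and
#' with standardized yield, picks within each indicator type (vegetation
#' condition, soil moisture, crop water stress) the indicator with the
#' highest mean of the two summaries. Ties break by the standardized-yield
#' correlation, then lexicographically (logged via message).
#'
#' @param summaries Tibble with columns `indicator`, `type`, `pcc_yield`,
#'   `pcc_z`.
#' @param types Types that must each contribute one indicator.
#' @return The winning rows, one per type (ordered as `types`).
#' @export
select_indicators <- function(summaries,
                              types = c("soil moisture", "vegetation condition",
                                        "crop water stress")) {
  missing_types <- setdiff(types, summaries$type)
  if (length(missing_types) > 0) {
    stop("no candidate indicator of type: ", paste(missing_types, collapse = ", "),
         call. = FALSE)
  }
  picks <- lapply(types, function(tp) {
    cand <- summaries[summaries$type == tp, , drop = FALSE]
    score <- (cand$pcc_yield + cand$pcc_z) / 2
    best <- which(score == max(score))
    if (length(best) > 1) {
      best <- best[cand$pcc_z[best] == max(cand$pcc_z[best])]
      if (length(best) > 1) {
        best <- best[order(cand$indicator[best])][1]
        message("tie for type '", tp, "' broken lexicographically")
      } else best <- best[1]
    }
    cand[best, , drop = FALSE]
  })
  dplyr::bind_rows(picks)
}

#' Binarize a series into drought / non-drought
#'
#' Rules: `"threshold"` -- drought when the value is strictly below `tau`
#' (an index value exactly at the threshold is not drought);
#' `"class"` -- drought when the drought class is D1-D4 (D0 is not drought);
#' `"z-negative"` -- drought when standardized yield is below zero.
#'
#' @param x Numeric values, or classes for `rule = "class"`.
#' @param rule One of `"threshold"`, `"class"`, `"z-negative"`.
#' @param tau Threshold for `rule = "threshold"`.
#' @return Logical vector: `TRUE` = drought (`NA` for masked).
#' @export
binarize <- function(x, rule = c("threshold", "class", "z-negative"), tau = NULL) {
  rule <- match.arg(rule)
  switch(rule,
         "threshold" = {
           if (is.null(tau)) stop("rule 'threshold' needs `tau`", call. = FALSE)
           x < tau
         },
         "class" = is_drought_class(x, "all"),
         "z-negative" = x < 0)
}

#' Confusion matrix between actual and predicted labels
#'
#' For logical (binary drought) vectors, tallies TP/TN/FP/FN with drought as
#' the positive class. For factors/characters, builds the k x k class-count
#' table. Pairs with a missing entry on either side are dropped.
#'
#' @param actual,predicted Logical vectors, or factors with common levels.
#' @return An object of class `confusion_matrix`: a list with `table` (2x2
#'   or k x k, rows = actual, cols = predicted) and `binary` flag.
#' @export
#'
#' @examples
#' cm <- confusion(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' accuracy(cm)
#' mcc(cm)
confusion <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have equal length", call. = FALSE)
  }
  ok <- !is.na(actual) & !is.na(predicted)
  actual <- actual[ok]; predicted <- predicted[ok]
  if (length(actual) == 0) stop("no complete pairs to tabulate", call. = FALSE)
  binary <- is.logical(actual) && is.logical(predicted)
  if (binary) {
    tab <- table(factor(actual, levels = c(TRUE, FALSE)),
                 factor(predicted, levels = c(TRUE, FALSE)),
                 dnn = c("actual", "predicted"))
  } else {
    lv <- sort(union(unique(as.character(actual)), unique(as.character(predicted))))
    tab <- table(factor(as.character(actual), levels = lv),
                 factor(as.character(predicted), levels = lv),
                 dnn = c("actual", "predicted"))
  }
  structure(list(table = tab, binary = binary), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix>", if (x$binary) "binary" else "multi-class", "\n")
  print(x$table)
  invisible(x)
}

cm_counts <- function(cm) {
  stopifnot(cm$binary)
  t <- cm$table
  list(tp = as.numeric(t["TRUE", "TRUE"]), tn = as.numeric(t["FALSE", "FALSE"]),
       fp = as.numeric(t["FALSE", "TRUE"]), fn = as.numeric(t["TRUE", "FALSE"]))
}

#' Accuracy and Matthews correlation of a confusion matrix
#'
#' `accuracy()` is 100 (TP + TN) / (TP + TN + FP + FN) percent; for a
#' multi-class table, 100 trace / total. `mcc()` (binary only) is
#' (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), the Pearson
#' correlation of the two 0/1 label vectors, in [-1, 1]; when any factor of
#' the denominator is zero the value is 0 by convention (flagged with a
#' warning).
#'
#' @param cm A [confusion()] matrix.
#' @return `accuracy()` percent in [0, 100]; `mcc()` a value in [-1, 1].
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  100 * sum(diag(cm$table)) / sum(cm$table)
}

#' @rdname accuracy
#' @export
mcc <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (!cm$binary) stop("MCC is defined for binary classification", call. = FALSE)
  k <- cm_counts(cm)
  den2 <- (k$tp + k$fp) * (k$tp + k$fn) * (k$tn + k$fp) * (k$tn + k$fn)
  if (den2 == 0) {
    warning("zero factor in MCC denominator; returning 0 by convention", call. = FALSE)
    return(0)
  }
  unname((k$tp * k$tn - k$fp * k$fn) / sqrt(den2))
}

#' Lagged early-warning skill of a predictor indicator
#'
#' Evaluates whether a (normalized, drought-low) predictor indicator at
#' month t - lag anticipates index drought at month t. The index is
#' binarized by the run threshold (value < tau); the predictor by its own
#' percentile drought classes (D1-D4 on each pixel's empirical distribution),
#' putting predictors on a common footing. All pixels and months are pooled
#' into one confusion matrix per lag (index = actual, lagged predictor =
#' predicted).
#'
#' @param index A `grid_series` combined index.
#' @param predictor A co-registered `grid_series` (e.g. normalized SMCI).
#' @param lags Integer lead times in months (default 1:3); each must be
#'   shorter than the series.
#' @param threshold See [run_threshold()].
#' @return A tibble with one row per lag: `lag`, `n`, `tp`, `tn`, `fp`,
#'   `fn`, `accuracy`, `mcc`.
#' @export
early_warning <- function(index, predictor, lags = 1:3, threshold = NULL) {
  assert_conformable(index, predictor)
  tau <- run_threshold(index, threshold)
  n_months <- nrow(grid_timestamps(index))
  if (any(lags >= n_months)) stop("lag must be shorter than the series", call. = FALSE)
  pred_classes <- classify_drought(predictor, scheme = "percentile")
  pred <- dplyr::mutate(tibble::as_tibble(pred_classes),
                        drought = binarize(.data$class, "class"),
                        t = month_index(.data$year, .data$month))
  idx <- dplyr::mutate(tibble::as_tibble(index),
                       drought = binarize(.data$value, "threshold", tau = tau),
                       t = month_index(.data$year, .data$month))
  purrr::map_dfr(lags, function(L) {
    j <- dplyr::inner_join(
      idx[c("row", "col", "t", "drought")],
      dplyr::mutate(pred[c("row", "col", "t", "drought")], t = .data$t + L),
      by = c("row", "col", "t"), suffix = c("_actual", "_pred"))
    cm <- confusion(j$drought_actual, j$drought_pred)
    k <- cm_counts(cm)
    tibble::tibble(lag = L, n = sum(cm$table),
                   tp = k$tp, tn = k$tn, fp = k$fp, fn = k$fn,
                   accuracy = accuracy(cm), mcc = suppressWarnings(mcc(cm)))
  })
}
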