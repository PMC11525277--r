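test_that("yield standardization centers and scales per district", {
  y <- data.frame(district = 1, year = 2001:2003, yield = c(2, 4, 6))
  z <- standardize_yield(y)
  expect_equal(z$z, c(-1, 0, 1))         # sample sd = 2
  expect_equal(unique(z$mu), 4)
  expect_equal(unique(z$sigma), 2)
  expect_equal(mean(z$z), 0)
  # x = mu -> 0; x = mu + sigma -> 1 by construction
  expect_equal(z$z[z$yield == unique(z$mu)], 0)

  pop <- standardize_yield(y, sd_type = "population")
  expect_equal(unique(pop$sigma), 2 * sqrt(2 / 3))

  flat <- data.frame(district = c(1, 1, 1, 2, 2, 2), year = rep(2001:2003, 2),
                     yield = c(5, 5, 5, 1, 2, 3))
  expect_warning(zf <- standardize_yield(flat), "excluded")
  expect_true(all(is.na(zf$z[zf$district == 1])))
  expect_false(anyNA(zf$z[zf$district == 2]))
})

test_that("seasonal severity takes the season minimum or the critical month", {
  v <- rep(0.9, 12); v[6:9] <- c(0.5, 0.2, 0.6, 0.3)
  gs <- gs1(v, variable = "regcdi")
  kharif <- season_definition("kharif")
  expect_equal(seasonal_severity(gs, kharif)$severity, 0.2)
  expect_equal(seasonal_severity(gs, kharif, mode = "critical-month",
                                 critical_month = 8)$severity, 0.6)
  expect_error(seasonal_severity(gs, kharif, mode = "critical-month",
                                 critical_month = 12), "outside season")
  const <- gs1(rep(0.4, 12), variable = "regcdi")
  expect_equal(seasonal_severity(const, kharif)$severity, 0.4)
})

test_that("pearson correlation matches hand values and guards degeneracy", {
  a <- c(1, 2, 3)
  expect_equal(pearson_correlation(a, a), 1)
  expect_equal(pearson_correlation(a, -a), -1)
  expect_equal(pearson_correlation(a, c(1, 3, 2)), 0.5)
  expect_warning(r <- pearson_correlation(c(1, 2), c(3, 4)), "fewer than 3")
  expect_true(is.na(r))
  expect_warning(r2 <- pearson_correlation(c(1, 1, 1), a), "constant")
  expect_true(is.na(r2))
})

test_that("correlation map recovers a perfect severity-yield coupling", {
  # severity at every pixel identical to the district z series -> PCC = 1
  years <- 2001:2008
  z_series <- c(-1.2, 0.3, 1.1, -0.5, 0.9, -1.0, 0.6, -0.2)
  sev <- tidyr::expand_grid(row = 1:2, col = 1:2, year = years) |>
    dplyr::mutate(severity = rep(z_series, 4))
  zones <- zone_tiling(2, 2, 2)
  yields <- tidyr::expand_grid(district = 1:2, year = years) |>
    dplyr::mutate(yield = 100 + 10 * rep(z_series, 2))
  cmap <- correlation_map(sev, yields, zones, target = "yield")
  expect_equal(cmap$pcc, rep(1, 4), tolerance = 1e-12)
  expect_equal(attr(cmap, "mean_pcc"), 1, tolerance = 1e-12)

  # a district with < 3 usable years is masked
  short <- yields[yields$year <= 2002 | yields$district == 2, ]
  cmap2 <- suppressWarnings(correlation_map(sev, short, zones, target = "yield"))
  expect_true(all(is.na(cmap2$pcc[cmap2$district == 1])))
  expect_false(anyNA(cmap2$pcc[cmap2$district == 2]))
})

test_that("correlation map recovers an imposed linear coupling from noise", {
  set.seed(101)
  years <- 2001:2015
  sev_vals <- runif(length(years), 0, 1)
  sev <- tidyr::expand_grid(row = 1L, col = 1L, year = years) |>
    dplyr::mutate(severity = sev_vals)
  yields <- tibble::tibble(district = 1L, year = years,
                           yield = 1000 + 400 * sev_vals + rnorm(length(years), sd = 60))
  cmap <- correlation_map(sev, yields, zone_tiling(1, 1, 1), target = "yield")
  expect_gt(cmap$pcc, 0.7)   # strong imposed coupling survives the noise
})

test_that("indicator selection picks the per-type correlation leader", {
  tab <- tibble::tribble(
    ~indicator, ~type,                  ~pcc_yield, ~pcc_z,
    "vci",      "vegetation condition", 0.01,       0.02,
    "tci",      "vegetation condition", 0.49,       0.54,
    "ndwi",     "vegetation condition", 0.20,       0.20,
    "smci",     "soil moisture",        0.33,       0.30,
    "smdi",     "soil moisture",        0.13,       0.08,
    "swdi",     "soil moisture",        0.21,       0.19,
    "siwsi1",   "crop water stress",    0.15,       0.15,
    "siwsi2",   "crop water stress",    0.02,       0.02)
  picks <- select_indicators(tab)
  expect_equal(picks$indicator, c("smci", "tci", "siwsi1"))

  tie <- tibble::tibble(indicator = c("b", "a"), type = "soil moisture",
                        pcc_yield = 0.3, pcc_z = 0.3)
  expect_message(p2 <- select_indicators(tie, types = "soil moisture"),
                 "lexicographically")
  expect_equal(p2$indicator, "a")
  expect_error(select_indicators(tab[tab$type != "soil moisture", ]),
               "no candidate indicator")
})

test_that("binarization rules use strict cuts and exclude D0", {
  expect_equal(binarize(c(-0.5, 0.2), rule = "z-negative"), c(TRUE, FALSE))
  expect_equal(binarize(c(0.12, 0.119), rule = "threshold", tau = 0.12),
               c(FALSE, TRUE))
  cls <- regcdi_class(c(0.25, 0.15, 0.01))    # D0, D1, D4
  expect_equal(binarize(cls, rule = "class"), c(FALSE, TRUE, TRUE))
  expect_error(binarize(1:3, rule = "threshold"), "tau")
})

test_that("confusion matrices tally binary agreement", {
  actual <- c(rep(TRUE, 4), rep(FALSE, 6))
  cm <- confusion(actual, actual)
  expect_equal(accuracy(cm), 100)
  expect_equal(mcc(cm), 1)
  cm_inv <- confusion(actual, !actual)
  expect_equal(accuracy(cm_inv), 0)
  expect_equal(mcc(cm_inv), -1)
  # hand-tallied mixed case
  act <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)
  pred <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  k <- regcdi:::cm_counts(confusion(act, pred))
  expect_equal(unlist(k), c(tp = 3, tn = 3, fp = 1, fn = 1))
  expect_error(confusion(c(TRUE), c(TRUE, FALSE)), "equal length")
})

test_that("accuracy and MCC reproduce their closed forms", {
  mk <- function(tp, tn, fp, fn) {
    confusion(c(rep(TRUE, tp + fn), rep(FALSE, tn + fp)),
              c(rep(TRUE, tp), rep(FALSE, fn), rep(FALSE, tn), rep(TRUE, fp)))
  }
  expect_equal(accuracy(mk(3, 5, 1, 1)), 80)
  expect_equal(accuracy(mk(2, 2, 2, 2)), 50)
  expect_equal(mcc(mk(2, 2, 2, 2)), 0)
  expect_equal(mcc(mk(6, 3, 1, 2)), 16 / sqrt(7 * 8 * 4 * 5))  # approx 0.478
  expect_warning(z <- mcc(mk(0, 5, 0, 0)), "zero factor")
  expect_equal(z, 0)
})

test_that("MCC equals the Pearson correlation of the 0/1 label vectors", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    act <- runif(n) < runif(1, 0.2, 0.8)
    pred <- runif(n) < runif(1, 0.2, 0.8)
    if (length(unique(act)) < 2 || length(unique(pred)) < 2) next
    expect_equal(mcc(confusion(act, pred)), cor(as.numeric(act), as.numeric(pred)),
                 tolerance = 1e-12)
  }
})

test_that("accuracy is invariant to relabeling and merging only helps", {
  set.seed(7)
  act <- runif(100) < 0.4
  pred <- runif(100) < 0.4
  expect_equal(accuracy(confusion(act, pred)), accuracy(confusion(!act, !pred)))
  # multi-class accuracy <= binary accuracy after merging D1-D4
  for (i in 1:10) {
    a_cls <- regcdi_class(runif(200))
    p_cls <- regcdi_class(runif(200))
    multi <- accuracy(confusion(a_cls, p_cls))
    bin <- accuracy(confusion(binarize(a_cls, "class"), binarize(p_cls, "class")))
    expect_lte(multi, bin)
  }
})

test_that("early warning scores a perfectly leading predictor at 100%", {
  set.seed(15)
  n <- 120
  v <- runif(n, 0, 1)
  idx <- gs1(v, variable = "regcdi")
  # circular shift: predictor at month t holds the index value of month t + 1,
  # with an identical value multiset, so its percentile drought classes (D1-D4,
  # the lowest 20%) coincide with the index's strict-threshold droughts at tau =
  # the index's 20th percentile
  lead1 <- gs1(v[c(2:n, 1)], variable = "pred")
  q20 <- quantile(v, 0.2, names = FALSE)
  ew <- early_warning(idx, lead1, lags = 1, threshold = q20)
  expect_equal(ew$accuracy, 100)
  expect_equal(ew$mcc, 1)
})

test_that("an independent predictor has no early-warning skill", {
  set.seed(33)
  n <- 10000
  idx_v <- runif(n)
  pred_v <- runif(n)   # independent
  # single-pixel long series
  t <- seq_len(n) - 1L
  mk <- function(v, nm) grid_series(
    data.frame(year = 2001L + t %/% 12L, month = t %% 12L + 1L,
               row = 1L, col = 1L, value = v), nm)
  ew <- early_warning(mk(idx_v, "regcdi"), mk(pred_v, "p"), lags = 1,
                      threshold = 0.3)
  expect_lt(abs(ew$mcc), 0.05)
  expect_error(early_warning(gs1(runif(5), variable = "regcdi"),
                             gs1(runif(5), variable = "p"), lags = 10,
                             threshold = 0.3), "shorter")
})
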