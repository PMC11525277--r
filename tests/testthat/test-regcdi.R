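test_that("normalization min-max rescales, flips stress-positive series, masks flats", {
  expect_equal(normalize_indicator(gs1(c(10, 20, 30)))$value, c(0, 0.5, 1))
  # stress-positive SIWSI: reflected so that low = drought
  expect_equal(normalize_indicator(gs1(c(-0.2, 0, 0.2)), invert = TRUE)$value,
               c(1, 0.5, 0))
  # idempotent (up to affine identity) on a series already spanning [0, 1]
  expect_equal(normalize_indicator(gs1(c(0, 0.25, 1)))$value, c(0, 0.25, 1))
  expect_true(all(is.na(normalize_indicator(gs1(c(0.4, 0.4, 0.4)))$value)))
})

test_that("entropy frequencies normalize to unit sum and flag all-zero series", {
  expect_equal(entropy_frequencies(rep(1, 4)), rep(0.25, 4))
  expect_equal(entropy_frequencies(c(1, 0, 0, 1)), c(0.5, 0, 0, 0.5))
  expect_equal(entropy_frequencies(c(0.2, 0.3, 0.5)), c(0.2, 0.3, 0.5))
  expect_warning(f <- entropy_frequencies(c(0, 0, 0)), "all-zero")
  expect_true(all(is.na(f)))
})

test_that("Shannon entropy hits its closed-form anchors", {
  expect_equal(shannon_entropy(rep(1 / 7, 7)), 1)
  expect_equal(shannon_entropy(c(1, 0, 0, 0)), 0)
  # direct evaluation of -(1/ln 3) sum f ln f
  f <- c(0.5, 0.25, 0.25)
  expect_equal(shannon_entropy(f, 3),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)) / log(3))
  expect_equal(round(shannon_entropy(f, 3), 4), 0.9464)
  expect_error(shannon_entropy(1, n = 1), "n >= 2")
})

test_that("entropy weights follow the direct formula with its degenerate fallback", {
  expect_equal(entropy_weight(c(0.4, 0.4, 0.4)), rep(1 / 3, 3))  # symmetry
  expect_equal(entropy_weight(c(1, 1, 0)), c(0, 0, 1))
  expect_equal(entropy_weight(c(0.9, 0.8, 0.7)), c(1, 2, 3) / 6)
  expect_warning(w <- entropy_weight(c(1, 1, 1)), "equal weights")
  expect_equal(w, rep(1 / 3, 3))
  expect_error(entropy_weight(0.5), "two indicators")
})

test_that("per-pixel stack weights satisfy the simplex contract and match the oracle", {
  set.seed(42)
  for (m in 2:4) {
    n_months <- 36
    series <- lapply(seq_len(m), function(i) {
      gs_random(2, 2, n_months, seed = 100 * m + i, variable = paste0("ind", i))
    })
    stack <- indicator_stack(series)
    w <- entropy_weights(stack)
    sums <- tapply(w$weight, paste(w$row, w$col), sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(w$weight >= 0 & w$weight <= 1))
    # brute-force oracle at one pixel
    r_mat <- sapply(series, function(g) g$value[g$row == 1 & g$col == 2])
    or <- oracle_entropy_weights(r_mat)
    got <- w[w$row == 1 & w$col == 2, ]
    expect_equal(got$entropy, or$h, tolerance = 1e-12)
    expect_equal(got$weight, or$w, tolerance = 1e-12)
  }
})

test_that("combination is the weighted dot product with convex bounds", {
  mk_const <- function(v, nm) gs1(rep(v, 3), variable = nm)
  # hand-built weights via a stack whose entropies give W = (0.2, 0.3, 0.5)
  # -> instead verify directly: combine r = (0.1, 0.4, 0.8), W = (0.2, 0.3, 0.5)
  stack <- indicator_stack(a = mk_const(0.1, "a"), b = mk_const(0.4, "b"),
                           c = mk_const(0.8, "c"))
  w <- structure(tibble::tibble(row = 1L, col = 1L, indicator = c("a", "b", "c"),
                                n = 3L, entropy = NA_real_,
                                weight = c(0.2, 0.3, 0.5)),
                 m = 3L,
                 class = c("entropy_weights", class(tibble::tibble())))
  idx <- combine_regcdi(stack, w)
  expect_equal(idx$value, rep(0.2 * 0.1 + 0.3 * 0.4 + 0.5 * 0.8, 3))  # 0.54

  ones <- indicator_stack(a = mk_const(1, "a"), b = mk_const(1, "b"),
                          c = mk_const(1, "c"))
  expect_equal(combine_regcdi(ones, w)$value, rep(1, 3))
  halves <- indicator_stack(a = mk_const(0.5, "a"), b = mk_const(0.5, "b"),
                            c = mk_const(0.5, "c"))
  expect_equal(combine_regcdi(halves, w)$value, rep(0.5, 3))

  w_bad <- w; w_bad$indicator <- c("a", "b", "zzz")
  expect_error(combine_regcdi(stack, w_bad), "differ")
})

test_that("RegCDI stays in [0,1] and ignores indicator order on random stacks", {
  for (seed in 1:5) {
    series <- lapply(1:3, function(i) {
      normalize_indicator(gs_random(3, 3, 30, seed = 10 * seed + i,
                                    variable = paste0("ind", i)))
    })
    names(series) <- paste0("ind", 1:3)
    stack <- indicator_stack(series)
    w <- entropy_weights(stack)
    idx <- combine_regcdi(stack, w)
    ok <- !is.na(idx$value)
    expect_true(all(idx$value[ok] >= -1e-12 & idx$value[ok] <= 1 + 1e-12))
    # permuted indicator order: identical index and classes
    stack_p <- indicator_stack(series[c(3, 1, 2)])
    idx_p <- combine_regcdi(stack_p, entropy_weights(stack_p))
    expect_equal(idx_p$value, idx$value, tolerance = 1e-12)
    expect_equal(classify_drought(idx_p)$class, classify_drought(idx)$class)
  }
})

test_that("a pixel-month with any masked constituent is masked in the index", {
  a <- gs1(c(0.2, 0.4, 0.6), variable = "a")
  b <- gs1(c(0.3, NA, 0.9), variable = "b")
  stack <- indicator_stack(a = a, b = b)
  w <- entropy_weights(stack)
  idx <- combine_regcdi(stack, w)
  expect_true(is.na(idx$value[2]))
  expect_false(anyNA(idx$value[-2]))
})

test_that("fixed-range classification reproduces the published category table", {
  expect_equal(as.character(regcdi_class(c(0.15, 0.01, 0.5, 0.07))),
               c("D1", "D4", "wet", "D2"))
  # boundaries are upper-inclusive
  expect_equal(as.character(regcdi_class(c(0.02, 0.05, 0.10, 0.20, 0.30))),
               c("D4", "D3", "D2", "D1", "D0"))
  expect_equal(as.character(regcdi_class(c(0, 1))), c("D4", "wet"))
  expect_error(regcdi_class(c(-0.1, 0.5)), "\\[0, 1\\]")
  expect_error(regcdi_class(1.2), "\\[0, 1\\]")
})

test_that("classification partitions [0,1] monotonically", {
  v <- seq(0, 1, length.out = 10000)
  cls <- regcdi_class(v)
  expect_false(anyNA(cls))                          # every value in exactly one class
  expect_equal(nlevels(cls), 6)
  expect_true(all(sort(unique(as.character(cls))) == sort(drought_classes)))
  expect_true(!is.unsorted(as.integer(cls)))        # severity never increases with value
})

test_that("percentile classification applies the same cuts to each pixel's own CDF", {
  # 100 distinct values at one pixel: exact empirical percentiles
  v <- (1:100) / 100
  set.seed(1)
  gs <- gs1(sample(v), variable = "regcdi", start_year = 2001)
  cls <- classify_drought(gs, scheme = "percentile")
  j <- dplyr::left_join(tibble::as_tibble(gs), tibble::as_tibble(cls),
                        by = c("year", "month", "row", "col"))
  j <- j[order(j$value), ]
  counts <- table(j$class)
  expect_equal(as.integer(counts[c("D4", "D3", "D2", "D1", "D0", "wet")]),
               c(2, 3, 5, 10, 10, 70))
  # ranking, not raw value, drives the class
  expect_equal(as.character(j$class[1]), "D4")
  expect_equal(as.character(j$class[100]), "wet")
})

test_that("tidy/glance expose weights in broom style", {
  stack <- indicator_stack(a = normalize_indicator(gs_random(2, 2, 24, 1, "a")),
                           b = normalize_indicator(gs_random(2, 2, 24, 2, "b")))
  w <- entropy_weights(stack)
  td <- tidy(w)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("row", "col", "indicator", "n", "entropy", "weight"))
  gl <- glance(w)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$m, 2L)
  expect_equal(gl$n_pixels, 4L)
})
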