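# single-pixel monthly series starting January of start_year
gs1 <- function(values, start_year = 2001, variable = "x", units = "",
                resolution = "0.25deg") {
  n <- length(values)
  t <- seq_len(n) - 1L
  grid_series(data.frame(year = start_year + t %/% 12L, month = t %% 12L + 1L,
                         row = 1L, col = 1L, value = values),
              variable = variable, units = units, resolution = resolution)
}

# small multi-pixel random series (complete grid, optional mask fraction)
gs_random <- function(nrow = 2, ncol = 2, n_months = 24, seed = 1,
                      variable = "x", mask_frac = 0) {
  set.seed(seed)
  t <- seq_len(n_months) - 1L
  df <- expand.grid(year = NA, month = NA, row = seq_len(nrow),
                    col = seq_len(ncol), t = t)
  df$year <- 2001L + df$t %/% 12L
  df$month <- df$t %% 12L + 1L
  df$value <- runif(nrow(df))
  if (mask_frac > 0) df$value[sample(nrow(df), ceiling(mask_frac * nrow(df)))] <- NA
  grid_series(df[c("year", "month", "row", "col", "value")], variable = variable)
}

# multi-year single-pixel series indexed by (year, fixed months)
gs_years <- function(values, years, month = 6, variable = "x") {
  grid_series(data.frame(year = years, month = month, row = 1L, col = 1L,
                         value = values), variable = variable)
}

# independent brute-force entropy-weight oracle: plain loops, full precision
oracle_entropy_weights <- function(r_mat) {
  n <- nrow(r_mat); m <- ncol(r_mat)
  h <- numeric(m)
  for (i in seq_len(m)) {
    f <- r_mat[, i] / sum(r_mat[, i])
    acc <- 0
    for (j in seq_len(n)) if (f[j] > 0) acc <- acc + f[j] * log(f[j])
    h[i] <- -acc / log(n)
  }
  list(h = h, w = (1 - h) / (m - sum(h)))
}

# indicator triple + pipeline from a synthetic scene
scene_pipeline <- function(cfg) {
  sc <- generate_scene(cfg)
  smci <- compute_smci(sc$ssm, grid_climatology(sc$ssm))
  tci <- compute_tci(sc$lst, grid_climatology(sc$lst))
  siwsi <- compute_siwsi(sc$swir5, sc$nir, 1)
  pipe <- regcdi_pipeline(smci = smci, tci = tci, siwsi1 = siwsi)
  smci_n <- pipe$stack[pipe$stack$indicator == "smci", ]
  pipe$smci_norm <- grid_series(
    smci_n[c("year", "month", "row", "col", "value")], "smci")
  pipe$scene <- sc
  pipe
}
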