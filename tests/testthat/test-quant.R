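test_that("an exact log-linear series is recovered perfectly", {
  r <- c(10, 100, 1000, 10000)
  curve <- qpcr_curve("X", "A:X", r, 20 + 3.3219 * log10(r))
  fit <- fit_cq_model(curve)
  expect_equal(fit$slope, 3.3219, tolerance = 1e-12)
  expect_equal(fit$intercept, 20, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
})

test_that("curve constructor enforces ordering and censoring invariants", {
  expect_error(qpcr_curve("X", "m", c(10, 5), c(20, 21)), "increasing")
  expect_error(qpcr_curve("X", "m", c(-1, 10), c(20, 21)), "positive")
  ## censored ratio below a detected one is inconsistent
  expect_error(qpcr_curve("X", "m", c(10, 100, 1000), c(20, NA, 24)),
               "censored")
  expect_error(fit_cq_model(qpcr_curve("X", "m", c(10, 100), c(20, 22))),
               "fit error")
})

test_that("fitted slopes match the closed-form OLS oracle on the Cq table", {
  curves <- load_cq_table()
  expect_length(curves, 6L)
  expect_equal(nrow(curves[["Cistanche sinensis"]]$points), 11L)
  expect_equal(range(curves[["Cistanche sinensis"]]$points$ratio),
               c(10, 20000))
  for (cv in curves) {
    fit <- fit_cq_model(cv)
    want <- oracle_ols(log10(cv$points$ratio), cv$points$cq_mean)
    expect_equal(fit$slope, unname(want["slope"]), tolerance = 1e-9)
    expect_equal(fit$intercept, unname(want["intercept"]), tolerance = 1e-9)
    expect_gt(fit$r_squared, 0.95)
    expect_gt(fit$slope, 0)
  }
})

test_that("Cq means rise with dilution within replicate noise in every row", {
  ## one printed pair (O. coerulescens 30000:1 -> 40000:1) dips by 0.22
  ## cycles, within its replicate SDs, so monotonicity is asserted up to
  ## the printed noise level
  for (cv in load_cq_table()) {
    d_cq <- diff(cv$points$cq_mean)
    tol <- cv$points$cq_sd[-1] + cv$points$cq_sd[-nrow(cv$points)]
    expect_true(all(d_cq >= -tol), label = cv$detected_species)
  }
})

test_that("efficiency follows the textbook slope identity", {
  r <- c(10, 100, 1000)
  perfect <- fit_cq_model(qpcr_curve("X", "m", r, 20 + 3.3219 * log10(r)))
  expect_equal(efficiency(perfect), 1.0, tolerance = 1e-3)
  ## steeper slopes mean lower efficiency; the limit is 0
  steep <- fit_cq_model(qpcr_curve("X", "m", r, 20 + 10 * log10(r)))
  expect_lt(efficiency(steep), efficiency(perfect))
  expect_equal(10^(1 / 1e9) - 1, 0, tolerance = 1e-8)
  ## flat series is flagged non-informative
  flat <- fit_cq_model(qpcr_curve("X", "m", r, c(20, 20, 20)))
  expect_equal(flat$slope, 0)
  expect_true(flat$noninformative)
  expect_error(efficiency(flat), "fit error")
})

test_that("LOD ratio inverts the fitted line and brackets the censoring", {
  fit <- structure(list(intercept = 20, slope = 3.3219,
                        noninformative = FALSE), class = "qpcr_fit")
  expect_equal(lod_ratio(fit, cq_cutoff = 36.6102), 1e5, tolerance = 1e-3)
  expect_warning(lod_ratio(fit, cq_cutoff = 19), "LOD ratio < 1")
  ## consistency with the printed detection boundaries: detection persisted
  ## through every detected ratio (predicted Cq there stays under the
  ## cutoff, so the LOD exceeds the last detected ratio), and censoring set
  ## in just before the fitted line crosses the cutoff (predicted Cq at the
  ## first censored ratio lies a little below 37 in every row)
  for (cv in load_cq_table()) {
    f <- fit_cq_model(cv, cq_cutoff = 37)
    expect_gt(f$lod_ratio, max(cv$points$ratio))
    pred_at_censor <- f$intercept + f$slope * log10(min(cv$censored))
    expect_gt(pred_at_censor, 34)
    expect_lt(pred_at_censor, 37)
  }
})

test_that("simulation recovers the generating parameters", {
  ## Cq = a + b log10(r) + N(0, 0.3) on the fixture's ratio grid; the mean
  ## of 200 replicate estimates must sit within 3 standard errors of truth
  a <- 22; b <- 3.4; sigma <- 0.3
  grid <- load_cq_table()[[1]]
  ratios <- c(grid$points$ratio, grid$censored)
  set.seed(2024)
  est <- t(replicate(200, {
    cq <- a + b * log10(ratios) + rnorm(length(ratios), 0, sigma)
    fit <- fit_cq_model(qpcr_curve("X", "m", ratios, cq))
    c(fit$intercept, fit$slope)
  }))
  se <- apply(est, 2, stats::sd) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, 1]) - a), 3 * se[1])
  expect_lt(abs(mean(est[, 2]) - b), 3 * se[2])
})

test_that("weighted fits honor 1/sd^2 weights", {
  r <- c(10, 100, 1000, 10000)
  cq <- c(20.1, 23.2, 26.5, 40)        # outlier at the last point
  sd <- c(0.1, 0.1, 0.1, 5)            # but with huge uncertainty
  wfit <- fit_cq_model(qpcr_curve("X", "m", r, cq, sd), weighted = TRUE)
  ufit <- fit_cq_model(qpcr_curve("X", "m", r, cq, sd), weighted = FALSE)
  expect_lt(abs(wfit$slope - 3.2), abs(ufit$slope - 3.2))
})
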