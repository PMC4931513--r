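test_that("identical channels give RWC of exactly 1", {
  set.seed(5)
  x <- matrix(runif(64, 1, 100), 8)
  res <- rwc(x, x, threshold_np = 0, threshold_marker = 0)
  expect_identical(res$rwc, 1)
  expect_identical(res$percent, 100)
  expect_equal(res$n_coloc_pixels, res$n_pixels_evaluated)
})

test_that("an empty colocalized set gives RWC of 0", {
  set.seed(6)
  x <- matrix(runif(36, 1, 10), 6)
  expect_identical(rwc(x, matrix(0, 6, 6), 0, 0)$rwc, 0)
  # nothing above the NP threshold either
  expect_identical(rwc(matrix(1, 4, 4), matrix(9, 4, 4), 5, 0)$rwc, 0)
})

test_that("a six-pixel toy case matches explicit enumeration", {
  np <- c(50, 40, 30, 20, 10, 5)
  mk <- c(45, 10, 35, 25, 50, 1)
  # ranks(np): 1..6; ranks(mk): 2,5,3,4,1,6; D = 1,3,0,0,4,0
  # A = np > 8 -> pixels 1..5; C = A & mk > 20 -> {1,3,4,5}
  # W = (6-D)/6: 5/6, 1, 1, 2/6 for pixels 1,3,4,5
  expected <- (50 * 5 / 6 + 30 * 1 + 20 * 1 + 10 * 2 / 6) /
    (50 + 40 + 30 + 20 + 10)
  expect_equal(rwc(np, mk, 8, 20)$rwc, expected, tolerance = 1e-12)
  expect_equal(naive_rwc(np, mk, 8, 20), expected, tolerance = 1e-12)
})

test_that("module RWC equals the brute-force oracle on random cells", {
  set.seed(41)
  for (i in 1:250) {
    n <- sample(4:64, 1)
    np <- round(runif(n, 0, 60))     # ties occur frequently
    mk <- round(runif(n, 0, 60))
    tn <- runif(1, 0, 30); tm <- runif(1, 0, 30)
    expect_equal(rwc(np, mk, tn, tm)$rwc, naive_rwc(np, mk, tn, tm),
                 tolerance = 1e-9)
  }
})

test_that("RWC respects the rank core's invariances", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(6:50, 1)
    np <- runif(n, 0, 100); mk <- runif(n, 0, 100)
    tn <- runif(1, 0, 50); tm <- runif(1, 0, 50)
    base <- rwc(np, mk, tn, tm)$rwc
    # monotone transform of the marker channel, threshold transformed
    expect_equal(rwc(np, mk^3, tn, tm^3)$rwc, base, tolerance = 1e-9)
    expect_equal(rwc(np, exp(mk / 20), tn, exp(tm / 20))$rwc, base,
                 tolerance = 1e-9)
    # positive linear rescaling of the NP channel
    expect_equal(rwc(np * 7.3, mk, tn * 7.3, tm)$rwc, base,
                 tolerance = 1e-9)
    expect_true(base >= 0 && base <= 1)
  }
})

test_that("auto thresholds separate modes and scale with the data", {
  set.seed(7)
  v <- matrix(c(rnorm(200, 10, 1), rnorm(200, 200, 10)), ncol = 1)
  th <- auto_threshold(v)
  expect_gt(th, 15); expect_lt(th, 195)
  expect_equal(auto_threshold(v * 2), th * 2, tolerance = 1e-9)
  expect_equal(auto_threshold(v / 2), th / 2, tolerance = 1e-9)
  # constant channel: cutoff at the constant, so nothing is above it
  cv <- matrix(5, 4, 4)
  expect_gte(auto_threshold(cv), 5)
  expect_error(auto_threshold(cv, matrix(FALSE, 4, 4)), "empty mask")
  q <- auto_threshold(matrix(1:100, 10), method = "percentile",
                      percentile = 0.9)
  expect_equal(q, as.numeric(quantile(1:100, 0.9)))
})

test_that("condition summaries aggregate per-cell percentages", {
  # one synthetic cell, marker == np: percent is exactly 100, sem NA
  x <- matrix(runif(100, 10, 50), 10)
  fld <- field_image(list(nuclei = x * 0, lamp1 = x, np = x))
  seg <- list(cell_labels = matrix(1L, 10, 10))
  rec <- data.frame(cell_id = 1L, qc_pass = TRUE)
  out <- percent_colocalized(list(fld), list(seg), list(rec))
  expect_equal(out$summary$n_cells, 1)
  expect_equal(out$summary$mean_percent, out$cells$percent)
  expect_true(is.na(out$summary$sem_percent))
  # identical cells: condition mean equals the single-cell percent
  seg2 <- list(cell_labels = matrix(rep(c(1L, 2L), each = 50), 10))
  rec2 <- data.frame(cell_id = 1:2, qc_pass = TRUE)
  out2 <- percent_colocalized(list(fld), list(seg2), list(rec2))
  expect_equal(out2$summary$mean_percent, 100)
  # zero passing cells: empty, flagged by NA summary
  rec0 <- data.frame(cell_id = 1L, qc_pass = FALSE)
  out0 <- percent_colocalized(list(fld), list(seg), list(rec0))
  expect_equal(nrow(out0$cells), 0)
  expect_true(is.na(out0$summary$mean_percent))
})

test_that("high trafficking conditions colocalize more than low ones", {
  pc <- function(f, seed) {
    cfg <- simulation_config(n_cells_per_field = 25,
                             base_in_spot_fraction = f)
    sim <- simulate_field(cfg, effect = 1, seed = seed)
    res <- analyze_field(sim$field)
    percent_colocalized(list(res$corrected), list(res$seg),
                        list(res$records))$summary$mean_percent
  }
  hi <- mean(c(pc(0.9, 61), pc(0.9, 62)))
  lo <- mean(c(pc(0.2, 61), pc(0.2, 62)))
  expect_gt(hi, lo)
})
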