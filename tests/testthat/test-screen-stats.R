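test_that("the viability rule applies both strict thresholds", {
  w <- data.frame(
    treatment_id = rep(c("a", "b", "c", "d"), each = 3),
    n_cells_analyzed = c(49, 80, 80,    # one well below 50
                         50, 50, 49,    # below both sub-rules
                         50, 50, 50,    # exactly at both boundaries
                         200, 200, 200))
  v <- viability_filter(w)
  expect_equal(v$viable[match(c("a", "b", "c", "d"), v$treatment_id)],
               c(FALSE, FALSE, TRUE, TRUE))
})

test_that("NEG normalization rescales wells and centres controls at 1", {
  w <- data.frame(plate_id = "P1", replicate_id = 1,
                  treatment_id = c("NEG", "NEG", "NEG", "t"),
                  gene = c("NEG", "NEG", "NEG", "t"), sirna_id = 0,
                  is_negative_control = c(TRUE, TRUE, TRUE, FALSE),
                  lamp1_np_ratio = c(0.8, 0.8, 0.8, 0.4),
                  n_cells_analyzed = 200)
  nz <- normalize_to_neg(w)
  expect_equal(nz$wells$normalized_ratio[4], 0.5)
  expect_equal(nz$controls$neg_mean, 1)
  set.seed(1)
  w2 <- data.frame(plate_id = rep(c("P1", "P2"), each = 6),
                   replicate_id = rep(1:2, times = 6),
                   treatment_id = rep(c("NEG", "NEG", "x"), 4),
                   gene = "g", sirna_id = 0,
                   is_negative_control = rep(c(TRUE, TRUE, FALSE), 4),
                   lamp1_np_ratio = runif(12, 0.3, 0.9),
                   n_cells_analyzed = 100)
  nz2 <- normalize_to_neg(w2)
  expect_equal(nz2$controls$neg_mean, 1, tolerance = 1e-12)
  w3 <- w2[!w2$is_negative_control, ]
  expect_error(normalize_to_neg(w3), "P1")
})

test_that("phenotype thresholds sit at mu - 2/3 sd with closed boundaries", {
  ctl <- data.frame(neg_mean = 1, neg_sd = 0.1)
  expect_equal(call_phenotype(0.65, ctl), "strong_decrease")
  expect_equal(call_phenotype(0.70, ctl), "strong_decrease")  # tie: extreme
  expect_equal(call_phenotype(0.75, ctl), "mild_decrease")
  expect_equal(call_phenotype(0.80, ctl), "mild_decrease")    # tie: mild
  expect_equal(call_phenotype(0.95, ctl), "none")
  expect_equal(call_phenotype(1.20, ctl), "mild_increase")
  expect_equal(call_phenotype(1.35, ctl), "strong_increase")
  expect_error(call_phenotype(0.5, data.frame(neg_mean = 1, neg_sd = 0)),
               "degenerate")
})

test_that("classification is invariant to global ratio rescaling", {
  genes <- paste0("G", 1:30)
  lay <- make_screen_layout(genes, n_replicates = 3, n_neg_wells = 6)
  eff <- as.list(stats::setNames(c(rep(0.5, 5), rep(1, 25)), genes))
  wt <- simulate_well_table(lay, eff, neg_cv = 0.05, seed = 3)
  base <- screen_statistics(wt)$treatments
  wt2 <- wt
  wt2$lamp1_np_ratio <- wt2$lamp1_np_ratio * 13.7
  scaled <- screen_statistics(wt2)$treatments
  expect_identical(base$phenotype, scaled$phenotype)
})

test_that("the k-of-n siRNA validation rule behaves and is monotone", {
  expect_true(validate_gene(c("strong_decrease", "mild_decrease",
                              "none"))$validated)
  expect_equal(validate_gene(c("strong_decrease", "mild_decrease",
                               "none"))$n_confirming, 2)
  expect_false(validate_gene(c("strong_decrease", "none",
                               "none"))$validated)
  v3 <- validate_gene(rep("strong_decrease", 3))
  expect_true(v3$validated); expect_equal(v3$n_confirming, 3)
  # monotone: adding a confirming siRNA never invalidates
  set.seed(2)
  pool <- c("strong_decrease", "mild_decrease", "none", "mild_increase")
  for (i in 1:25) {
    ph <- sample(pool, sample(1:4, 1), replace = TRUE)
    before <- validate_gene(ph)$validated
    after <- validate_gene(c(ph, "mild_decrease"))$validated
    expect_true(!before || after)
  }
  # increase direction counts increases
  expect_true(validate_gene(c("mild_increase", "strong_increase"),
                            direction = "increase")$validated)
})

test_that("one-tailed t-tests match the closed-form t distribution", {
  expect_equal(one_tailed_ttest(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_gt(one_tailed_ttest(c(101, 102, 103), c(1, 2, 3), "less"), 0.999)
  x <- c(4.1, 5.2, 3.8, 4.6); y <- c(5.5, 6.1, 5.9, 6.6, 5.2)
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  tstat <- (mean(x) - mean(y)) / (sp * sqrt(1 / length(x) + 1 / length(y)))
  expect_equal(one_tailed_ttest(x, y, "less"),
               pt(tstat, length(x) + length(y) - 2), tolerance = 1e-12)
  # degenerate: both constant
  expect_equal(one_tailed_ttest(c(1, 1), c(1, 1)), 0.5)
  expect_equal(one_tailed_ttest(c(0, 0), c(1, 1), "less"), 0)
  expect_equal(one_tailed_ttest(c(2, 2), c(1, 1), "less"), 1)
})

test_that("planted effects are recovered through the statistics stage", {
  genes <- paste0("G", 1:40)
  lay <- make_screen_layout(genes, n_replicates = 3, n_neg_wells = 8)
  eff <- as.list(stats::setNames(rep(1, 40), genes))
  eff$G1 <- 0.5
  wt <- simulate_well_table(lay, eff, neg_cv = 0.05, seed = 11)
  res <- screen_statistics(wt)
  g1 <- res$treatments[res$treatments$treatment_id == "G1", ]
  expect_lt(abs(g1$normalized_ratio_mean - 0.5), 0.05)
  expect_equal(g1$phenotype, "strong_decrease")
  expect_lt(g1$p_value, 0.05)
})

test_that("control readouts flag planted changes but not null draws", {
  genes <- paste0("G", 1:60)
  lay <- make_screen_layout(genes, n_replicates = 3, n_neg_wells = 10)
  eff <- as.list(stats::setNames(rep(1, 60), genes))
  wt <- simulate_well_table(lay, eff, neg_cv = 0.05, seed = 21,
                            lamp1_effects = list(G1 = 2))
  cr <- control_readouts(wt)
  expect_true(cr$lamp1_intensity_per_cell_flagged[cr$treatment_id == "G1"])
  # null treatments flagged at about the nominal rate (binomial bound)
  nulls <- cr$lamp1_intensity_per_cell_flagged[cr$treatment_id != "G1"]
  expect_lte(sum(nulls), qbinom(0.999, length(nulls), 0.05) + 1)
  # optional LysoTracker columns absent from input => absent from output
  expect_false(any(grepl("lyso", names(cr))))
})
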