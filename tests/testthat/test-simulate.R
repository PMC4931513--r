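test_that("identical seeds give bit-identical fields", {
  cfg <- simulation_config(n_cells_per_field = 12)
  a <- simulate_field(cfg, effect = 1, seed = 11)
  b <- simulate_field(cfg, effect = 1, seed = 11)
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth$cells, b$truth$cells)
  c <- simulate_field(cfg, effect = 1, seed = 12)
  expect_false(identical(a$field$channels, c$field$channels))
})

test_that("configured cell counts and roles are honoured", {
  cfg <- clean_sim_config(n_cells_per_field = 30)
  sim <- simulate_field(cfg, effect = 1, seed = 2)
  tr <- sim$truth$cells
  expect_equal(nrow(tr), 30)
  expect_equal(sum(tr$is_border | tr$is_apoptotic | tr$is_mitotic), 0)
  cfg2 <- simulation_config(n_cells_per_field = 20,
                            apoptotic_fraction = 0.1,
                            mitotic_fraction = 0.1,
                            border_cell_fraction = 0.2)
  tr2 <- simulate_field(cfg2, effect = 1, seed = 3)$truth$cells
  expect_equal(sum(tr2$is_apoptotic), 2)
  expect_equal(sum(tr2$is_mitotic), 2)
  expect_equal(sum(tr2$is_border), 4)
})

test_that("planted in-spot fraction is realized exactly pre-noise", {
  cfg <- clean_sim_config(n_cells_per_field = 30,
                          base_in_spot_fraction = 0.6)
  sim <- simulate_field(cfg, effect = 1, seed = 5)
  np <- sim$truth$prenoise$np
  spot <- sim$truth$spot_labels > 0
  cell <- sim$truth$cell_labels > 0
  expect_equal(sum(np[spot]) / sum(np[cell]), 0.6, tolerance = 1e-12)
  # after quantization to camera units the ratio moves by < 0.003
  npq <- sim$field$channels$np
  expect_equal(sum(npq[spot]) / sum(npq[cell]), 0.6, tolerance = 0.003)
})

test_that("NP mass is conserved per cell and effects clamp monotonically", {
  cfg <- clean_sim_config(n_cells_per_field = 15)
  sim <- simulate_field(cfg, effect = 1, seed = 9)
  np <- sim$truth$prenoise$np
  for (i in sim$truth$cells$cell_id) {
    m <- sim$truth$cell_labels == i
    expect_equal(sum(np[m]), sim$truth$cells$np_total[i],
                 tolerance = 1e-9)
  }
  effs <- c(0, 0.5, 1, 1.5, 2, 5)
  fs <- vapply(effs, function(e)
    simulate_field(cfg, effect = e, seed = 1)$truth$f_planted, 0)
  expect_true(all(diff(fs) >= 0))
  expect_equal(fs[1], 0)
  expect_equal(fs[length(fs)], 1)   # clamped at 1
})

test_that("truth label maps are mutually consistent", {
  cfg <- simulation_config(n_cells_per_field = 20)
  sim <- simulate_field(cfg, effect = 1, seed = 13)
  t <- sim$truth
  expect_true(all(t$cell_labels[t$nucleus_labels > 0] ==
                    t$nucleus_labels[t$nucleus_labels > 0]))
  sp <- t$spot_labels > 0
  expect_true(all(t$cell_labels[sp] == t$spot_to_cell[t$spot_labels[sp]]))
  expect_setequal(unique(as.vector(t$cell_labels[t$cell_labels > 0])),
                  t$cells$cell_id)
})

test_that("degenerate geometry raises an explicit error", {
  cfg <- simulation_config(field_shape = c(48L, 48L),
                           n_cells_per_field = 200L)
  expect_error(simulate_field(cfg, effect = 1, seed = 1), "cannot fit")
})

test_that("screen simulation emits one image set per well and field", {
  lay <- make_screen_layout(c("A", "B", "C"), n_replicates = 3,
                            n_neg_wells = 1)
  cfg <- simulation_config(n_cells_per_field = 6)
  dir <- tempfile("scr")
  scr <- simulate_screen(lay, list(A = 1, B = 1, C = 1), cfg,
                         fields_per_well = 2, seed = 4, dir = dir)
  expect_equal(nrow(scr$manifest), 4 * 3 * 2)   # (3 genes + NEG) wells
  expect_equal(nrow(scr$truth_wells), nrow(lay))
  expect_true(all(file.exists(scr$manifest$np)))
})

test_that("screen simulation validates effects and plants exact ratios", {
  lay <- make_screen_layout(c("geneA", "geneB"), n_neg_wells = 2)
  cfg <- simulation_config(n_cells_per_field = 6)
  expect_error(
    simulate_screen(lay, list(geneA = 0.5), cfg, seed = 1,
                    dir = tempfile()),
    "geneB")
  scr <- simulate_screen(lay, list(geneA = 0.5, geneB = 1), cfg, seed = 1,
                         dir = tempfile(), replicate_cv = 0, well_cv = 0)
  tw <- scr$truth_wells
  fa <- mean(tw$f_true[tw$treatment_id == "geneA"])
  fn <- mean(tw$f_true[tw$is_negative_control])
  expect_equal(fa / fn, 0.5, tolerance = 1e-12)
})

test_that("imageless well tables are deterministic and exactly scaled", {
  genes <- paste0("G", 1:348)
  lay <- make_screen_layout(genes, n_replicates = 3, n_neg_wells = 10)
  effects <- as.list(stats::setNames(rep(1, 348), genes))
  wt <- simulate_well_table(lay, effects, neg_cv = 0, seed = 1)
  expect_equal(sum(!wt$is_negative_control), 1044)  # 348 x 3 replicates
  expect_true(all(abs(wt$lamp1_np_ratio - 0.55) < 1e-12))
  wt2 <- simulate_well_table(lay, effects, neg_cv = 0, seed = 1)
  expect_identical(wt, wt2)
  wt3 <- simulate_well_table(lay, effects, neg_cv = 0.05, seed = 2)
  expect_gt(stats::sd(wt3$lamp1_np_ratio), 0)
})

test_that("layout invariants are enforced", {
  lay <- make_screen_layout(c("A", "B"), n_neg_wells = 2)
  expect_silent(hcsnano:::validate_layout(lay))
  dup <- rbind(lay, lay[1, ])
  expect_error(hcsnano:::validate_layout(dup), "unique")
  noneg <- lay[!lay$is_negative_control, ]
  expect_error(hcsnano:::validate_layout(noneg), "negative-control")
})
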