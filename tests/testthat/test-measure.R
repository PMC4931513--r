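make_toy_field <- function(np, lamp1 = np * 0, nuclei = np * 0) {
  field_image(list(nuclei = nuclei, lamp1 = lamp1, np = np))
}

test_that("hand-built fixture sums are reproduced exactly", {
  np <- matrix(0, 8, 8)
  cell <- matrix(0L, 8, 8); nucl <- matrix(0L, 8, 8)
  spot <- matrix(0L, 8, 8)
  cell[3:6, 3:6] <- 1L            # 16-px cell
  nucl[4:5, 4:5] <- 1L
  np[3:6, 3:6] <- 2.5             # sums to 40 over the cell
  spot[3, 3:6] <- 1L              # covers np values summing 10
  seg <- list(nucleus_labels = nucl, cell_labels = cell,
              spot_labels = spot, spot_to_cell = c(1L))
  rec <- measure_cells(make_toy_field(np), seg)
  expect_equal(rec$np_total_in_cell, 40)
  expect_equal(rec$np_total_in_spots, 10)
  expect_equal(rec$spot_count, 1L)
})

test_that("cells without spots have zero in-spot signal; subset sums hold", {
  cfg <- simulation_config(n_cells_per_field = 15)
  for (seed in 1:3) {
    sim <- simulate_field(cfg, effect = 1, seed = seed)
    rec <- analyze_field(sim$field)$records
    expect_true(all(rec$np_total_in_spots <= rec$np_total_in_cell + 1e-9))
    expect_true(all(rec$np_total_in_spots[rec$spot_count == 0] == 0))
    expect_true(all(rec$np_total_in_spots >= 0))
  }
})

test_that("border cells are excluded with reason border", {
  np <- matrix(1, 16, 16)
  cell <- matrix(0L, 16, 16); nucl <- matrix(0L, 16, 16)
  cell[1:4, 4:8] <- 1L            # touches row 1
  nucl[2:3, 5:7] <- 1L
  cell[8:12, 8:12] <- 2L          # interior
  nucl[9:11, 9:11] <- 2L
  seg <- list(nucleus_labels = nucl, cell_labels = cell,
              spot_labels = matrix(0L, 16, 16), spot_to_cell = integer(0))
  rec <- qc_filter_cells(measure_cells(make_toy_field(np,
                                                      nuclei = np * 50),
                                       seg),
                         qc_gates(apoptotic_area = 1,
                                  mitotic_intensity = 1e6))
  expect_equal(rec$qc_reason, c("border", "pass"))
  expect_equal(rec$qc_pass, c(FALSE, TRUE))
})

test_that("generous gates pass every interior cell", {
  cfg <- clean_sim_config(n_cells_per_field = 10)
  sim <- simulate_field(cfg, effect = 1, seed = 3)
  res <- analyze_field(sim$field,
                       analysis_params(gates = qc_gates(0, 1e9)))
  expect_equal(sum(res$records$qc_pass), nrow(res$records))
})

test_that("small nuclei and bright nuclei are gated with their reasons", {
  rec <- data.frame(cell_id = 1:3, nucleus_area = c(10, 100, 100),
                    cell_area = 100,
                    nucleus_mean_intensity = c(100, 400, 100),
                    touches_border = FALSE, qc_pass = NA,
                    qc_reason = NA_character_, np_total_in_cell = 1,
                    np_total_in_spots = 0, lamp1_mean_intensity = 1,
                    spot_count = 0L)
  out <- qc_filter_cells(rec, qc_gates(apoptotic_area = 40,
                                       mitotic_intensity = 150))
  expect_equal(out$qc_reason, c("apoptotic", "mitotic", "pass"))
})

test_that("the well ratio is the ratio of averages", {
  rec <- data.frame(np_total_in_spots = c(10, 30),
                    np_total_in_cell = c(20, 60),
                    lamp1_mean_intensity = 1, spot_count = 1L,
                    qc_pass = TRUE)
  expect_equal(well_ratio(rec)$lamp1_np_ratio, 0.5)
  rec$np_total_in_spots <- rec$np_total_in_cell
  expect_equal(well_ratio(rec)$lamp1_np_ratio, 1.0)
})

test_that("wells without usable cells are flagged, not errors", {
  wr <- well_ratio(hcsnano:::empty_cell_records())
  expect_true(is.na(wr$lamp1_np_ratio))
  expect_false(wr$ratio_defined)
  expect_equal(wr$n_cells_analyzed, 0)
  zero <- data.frame(np_total_in_spots = 0, np_total_in_cell = 0,
                     lamp1_mean_intensity = 0, spot_count = 0L,
                     qc_pass = TRUE)
  expect_false(well_ratio(zero)$ratio_defined)
})

test_that("ratio is exactly invariant to NP rescaling given fixed masks", {
  cfg <- simulation_config(n_cells_per_field = 12)
  sim <- simulate_field(cfg, effect = 1, seed = 6)
  res <- analyze_field(sim$field)
  fld2 <- res$corrected
  fld2$channels$np <- fld2$channels$np * 3.7
  rec2 <- qc_filter_cells(measure_cells(fld2, res$seg), qc_gates())
  expect_equal(well_ratio(rec2)$lamp1_np_ratio,
               well_ratio(res$records)$lamp1_np_ratio, tolerance = 1e-12)
})

test_that("pipeline ratio is nearly invariant to NP channel rescaling", {
  cfg <- clean_sim_config(n_cells_per_field = 15)
  sim <- simulate_field(cfg, effect = 1, seed = 18)
  base <- well_ratio(analyze_field(sim$field)$records)$lamp1_np_ratio
  for (c in c(0.5, 4)) {
    fld <- sim$field
    fld$channels$np <- fld$channels$np * c
    r <- well_ratio(analyze_field(fld)$records)$lamp1_np_ratio
    expect_lt(abs(r - base), 0.01)
  }
})
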