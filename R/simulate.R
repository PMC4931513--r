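#' Simulation configuration for synthetic screen fields
#'
#' Bundles the geometry, intensity and noise parameters of the synthetic
#' fluorescence-microscopy generator. The generator emulates one field of a
#' 384-well high-content screen: Hoechst-stained nuclei, punctate LAMP1
#' signal riding on a faint cytoplasmic haze, and a nanoparticle (NP)
#' channel whose per-cell signal is split between LAMP1-positive spots and
#' diffuse cytoplasm with an exactly planted in-spot fraction, plus a
#' smooth illumination gradient, Poisson shot noise and Gaussian read
#' noise. Cell radii are deliberately smaller than the default rolling-ball
#' radius so that intracellular signal survives background correction.
#'
#' @param field_shape integer (height, width) in pixels.
#' @param n_cells_per_field number of cells planted per field.
#' @param nucleus_radius_range range of nucleus semi-axes, pixels.
#' @param cell_radius_range range of cell semi-axes, pixels.
#' @param spots_per_cell_mean mean LAMP1 spot count per cell (each cell
#'   receives at least one spot so the planted in-spot fraction is always
#'   realizable).
#' @param spot_radius_range range of spot radii, pixels.
#' @param np_total_per_cell total NP intensity planted per cell (camera
#'   units, pre-noise).
#' @param base_in_spot_fraction baseline fraction \code{f0} of a cell's NP
#'   signal placed inside its LAMP1 spots (control condition).
#' @param background_gradient_amplitude peak amplitude of the smooth
#'   polynomial background surface.
#' @param noise list with \code{gaussian_sd} (read noise, camera units) and
#'   \code{poisson} (logical, shot noise on/off).
#' @param apoptotic_fraction,mitotic_fraction,border_cell_fraction fractions
#'   of planted cells rendered as small bright apoptotic nuclei, condensed
#'   bright mitotic nuclei without a cytoplasm ring, or cells overlapping
#'   the field border.
#' @param bit_depth 8 or 16; channels are quantized to this depth.
#' @param nucleus_intensity,lamp1_spot_intensity,lamp1_diffuse_intensity
#'   nominal channel intensities (camera units).
#' @param pixel_size nominal pixel size, micrometres per pixel (metadata).
#' @param seed default seed used when none is passed to the simulators.
#' @return a validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(field_shape = c(192L, 192L),
                              n_cells_per_field = 25L,
                              nucleus_radius_range = c(3.5, 5),
                              cell_radius_range = c(6, 8.5),
                              spots_per_cell_mean = 4,
                              spot_radius_range = c(0.7, 1.1),
                              np_total_per_cell = 60000,
                              base_in_spot_fraction = 0.55,
                              background_gradient_amplitude = 25,
                              noise = list(gaussian_sd = 2, poisson = TRUE),
                              apoptotic_fraction = 0.06,
                              mitotic_fraction = 0.06,
                              border_cell_fraction = 0.12,
                              bit_depth = 16L,
                              nucleus_intensity = 120,
                              lamp1_spot_intensity = 110,
                              lamp1_diffuse_intensity = 3,
                              pixel_size = 0.16,
                              seed = 1L) {
  cfg <- list(field_shape = as.integer(field_shape),
              n_cells_per_field = as.integer(n_cells_per_field),
              nucleus_radius_range = nucleus_radius_range,
              cell_radius_range = cell_radius_range,
              spots_per_cell_mean = spots_per_cell_mean,
              spot_radius_range = spot_radius_range,
              np_total_per_cell = np_total_per_cell,
              base_in_spot_fraction = base_in_spot_fraction,
              background_gradient_amplitude = background_gradient_amplitude,
              noise = noise,
              apoptotic_fraction = apoptotic_fraction,
              mitotic_fraction = mitotic_fraction,
              border_cell_fraction = border_cell_fraction,
              bit_depth = as.integer(bit_depth),
              nucleus_intensity = nucleus_intensity,
              lamp1_spot_intensity = lamp1_spot_intensity,
              lamp1_diffuse_intensity = lamp1_diffuse_intensity,
              pixel_size = pixel_size,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  fr <- c("base_in_spot_fraction", "apoptotic_fraction", "mitotic_fraction",
          "border_cell_fraction")
  for (f in fr) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a fraction in [0, 1]", f), call. = FALSE)
  }
  if (length(cfg$field_shape) != 2L || any(cfg$field_shape < 32L))
    stop("'field_shape' must be two integers >= 32", call. = FALSE)
  for (f in c("nucleus_radius_range", "cell_radius_range",
              "spot_radius_range")) {
    v <- cfg[[f]]
    if (length(v) != 2L || any(v <= 0) || v[2] < v[1])
      stop(sprintf("'%s' must be a positive increasing range", f),
           call. = FALSE)
  }
  stopifnot_scalar_number(cfg$n_cells_per_field, "n_cells_per_field", 1)
  stopifnot_scalar_number(cfg$spots_per_cell_mean, "spots_per_cell_mean", 0)
  stopifnot_scalar_number(cfg$np_total_per_cell, "np_total_per_cell", 0)
  stopifnot_scalar_number(cfg$background_gradient_amplitude,
                          "background_gradient_amplitude", 0)
  if (!cfg$bit_depth %in% c(8L, 16L))
    stop("'bit_depth' must be 8 or 16", call. = FALSE)
  if (!is.list(cfg$noise) || is.null(cfg$noise$gaussian_sd) ||
      is.null(cfg$noise$poisson))
    stop("'noise' must be list(gaussian_sd=, poisson=)", call. = FALSE)
  cfg
}

# Pixel coordinates of a filled rotated ellipse, clipped to the field.
ellipse_pixels <- function(cy, cx, a, b, theta, shape) {
  r <- ceiling(max(a, b))
  ys <- max(1L, floor(cy - r)):min(shape[1], ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(shape[2], ceiling(cx + r))
  g <- expand.grid(y = ys, x = xs)
  dy <- g$y - cy; dx <- g$x - cx
  u <- dy * cos(theta) + dx * sin(theta)
  v <- -dy * sin(theta) + dx * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  cbind(y = g$y[keep], x = g$x[keep])
}

disc_pixels <- function(cy, cx, r, shape) {
  ellipse_pixels(cy, cx, r, r, 0, shape)
}

px_index <- function(px, shape) (px[, "x"] - 1L) * shape[1] + px[, "y"]

# Rejection-sample non-overlapping cell centres; border cells are pushed
# against a field edge so their mask crosses it.
place_cells <- function(n, n_border, shape, rmax) {
  sep2 <- (2 * rmax + 1)^2
  margin <- rmax + 5
  usable <- prod(pmax(shape - 2 * margin, 1))
  if (n * sep2 * 0.9 > usable + n_border * 4 * rmax^2)
    stop("degenerate geometry: cells cannot fit in the field", call. = FALSE)
  ys <- xs <- numeric(0)
  tries <- 0L
  is_border <- rep(c(TRUE, FALSE), c(n_border, n - n_border))
  for (i in seq_len(n)) {
    repeat {
      tries <- tries + 1L
      if (tries > 20000L)
        stop("degenerate geometry: cells cannot fit in the field",
             call. = FALSE)
      if (is_border[i]) {
        edge <- sample.int(4L, 1L)
        off <- runif(1, 0.2, 0.6) * rmax
        if (edge == 1L) { y <- 1 + off; x <- runif(1, margin, shape[2] - margin) }
        else if (edge == 2L) { y <- shape[1] - off; x <- runif(1, margin, shape[2] - margin) }
        else if (edge == 3L) { x <- 1 + off; y <- runif(1, margin, shape[1] - margin) }
        else { x <- shape[2] - off; y <- runif(1, margin, shape[1] - margin) }
      } else {
        y <- runif(1, margin, shape[1] - margin)
        x <- runif(1, margin, shape[2] - margin)
      }
      if (!length(ys) || all((ys - y)^2 + (xs - x)^2 >= sep2)) break
    }
    ys <- c(ys, y); xs <- c(xs, x)
  }
  data.frame(cy = ys, cx = xs, is_border = is_border)
}

# Smooth low-order polynomial background surface scaled to [0, amplitude].
background_surface <- function(shape, amplitude) {
  if (amplitude <= 0) return(matrix(0, shape[1], shape[2]))
  yy <- matrix(seq(0, 1, length.out = shape[1]), shape[1], shape[2])
  xx <- matrix(seq(0, 1, length.out = shape[2]), shape[1], shape[2],
               byrow = TRUE)
  co <- runif(6, -1, 1)
  s <- co[1] + co[2] * xx + co[3] * yy + co[4] * xx * yy +
    co[5] * xx^2 + co[6] * yy^2
  s <- s - min(s)
  if (max(s) > 0) s <- s / max(s)
  s * amplitude
}

#' Simulate one multi-channel screen field with ground truth
#'
#' Generates a 3-channel field (\code{nuclei}, \code{lamp1}, \code{np}).
#' Each healthy cell receives a planted NP in-spot fraction
#' \code{f = clamp(f0 * effect, 0, 1)}: NP intensity totalling
#' \code{np_total_per_cell} is divided exactly so that spot pixels carry
#' fraction \code{f} and the remaining cytoplasm the rest, before
#' background and noise are applied. Apoptotic and mitotic cells carry
#' diffuse NP only and are flagged in the truth table.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param effect trafficking-effect multiplier applied to \code{f0}
#'   (1 = control; < 1 reduced lysosomal delivery).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param plate_id,well_id,field_id identifiers stamped on the field.
#' @param keep_prenoise keep pre-noise signal/background matrices in the
#'   truth object (used by tests; off for large screens).
#' @return list with \code{field} (a \code{\link{field_image}}) and
#'   \code{truth}: per-cell table, label maps (\code{nucleus_labels},
#'   \code{cell_labels}, \code{spot_labels}), \code{spot_to_cell},
#'   the background surface and pre-noise channels when requested.
#' @examples
#' cfg <- simulation_config(n_cells_per_field = 6,
#'                          apoptotic_fraction = 0, mitotic_fraction = 0,
#'                          border_cell_fraction = 0)
#' sim <- simulate_field(cfg, effect = 1, seed = 7)
#' nrow(sim$truth$cells)
#' @export
simulate_field <- function(config, effect = 1, seed = config$seed,
                           plate_id = "P1", well_id = "A01", field_id = 1L,
                           keep_prenoise = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  stopifnot_scalar_number(effect, "effect", lower = 0)
  with_seed(seed, simulate_field_impl(config, effect, plate_id, well_id,
                                      field_id, keep_prenoise))
}

simulate_field_impl <- function(cfg, effect, plate_id, well_id, field_id,
                                keep_prenoise) {
  shape <- cfg$field_shape
  n <- cfg$n_cells_per_field
  n_border <- round(cfg$border_cell_fraction * n)
  n_apop <- round(cfg$apoptotic_fraction * n)
  n_mit <- round(cfg$mitotic_fraction * n)
  if (n_apop + n_mit > n - n_border)
    stop("special-cell fractions exceed available cells", call. = FALSE)

  pos <- place_cells(n, n_border, shape, max(cfg$cell_radius_range))
  # special roles among non-border cells (border cells are QC'd anyway)
  roles <- rep("normal", n)
  nb <- which(!pos$is_border)
  if (n_apop > 0) roles[nb[seq_len(n_apop)]] <- "apoptotic"
  if (n_mit > 0) roles[nb[n_apop + seq_len(n_mit)]] <- "mitotic"

  nuc_lab <- cell_lab <- spot_lab <- matrix(0L, shape[1], shape[2])
  nuclei_ch <- lamp1_ch <- np_ch <- matrix(0, shape[1], shape[2])
  f_planted <- max(0, min(1, cfg$base_in_spot_fraction * effect))

  cells <- vector("list", n)
  spot_to_cell <- integer(0)
  spot_id <- 0L
  for (i in seq_len(n)) {
    apop <- roles[i] == "apoptotic"; mit <- roles[i] == "mitotic"
    a <- runif(1, cfg$nucleus_radius_range[1], cfg$nucleus_radius_range[2])
    b <- runif(1, cfg$nucleus_radius_range[1], cfg$nucleus_radius_range[2])
    theta <- runif(1, 0, pi)
    if (apop) { a <- a * 0.5; b <- b * 0.5 }
    if (mit) { a <- a * 0.95; b <- b * 0.95 }
    ca <- max(runif(1, cfg$cell_radius_range[1], cfg$cell_radius_range[2]),
              a + 2)
    cb <- max(runif(1, cfg$cell_radius_range[1], cfg$cell_radius_range[2]),
              b + 2)
    if (apop) { ca <- a + 1.5; cb <- b + 1.5 }
    if (mit) { ca <- a + 1; cb <- b + 1 }   # no cytoplasm ring
    nuc_px <- ellipse_pixels(pos$cy[i], pos$cx[i], a, b, theta, shape)
    cell_px <- ellipse_pixels(pos$cy[i], pos$cx[i], ca, cb, theta, shape)
    nuc_idx <- px_index(nuc_px, shape)
    cell_idx <- px_index(cell_px, shape)
    # disjoint cells are enforced by placement; keep first claim on ties
    cell_idx <- cell_idx[cell_lab[cell_idx] == 0L]
    nuc_idx <- intersect(nuc_idx, cell_idx)
    cell_lab[cell_idx] <- i
    nuc_lab[nuc_idx] <- i

    int_scale <- runif(1, 0.9, 1.1)
    nuc_int <- cfg$nucleus_intensity * int_scale *
      (if (apop) 2.2 else if (mit) 2.8 else 1)
    nuclei_ch[nuc_idx] <- nuc_int

    n_spots <- 0L; spot_idx_all <- integer(0)
    if (!apop && !mit) {
      n_spots <- 1L + stats::rpois(1, max(cfg$spots_per_cell_mean - 1, 0))
      cyto_idx <- setdiff(cell_idx, nuc_idx)
      pool <- if (length(cyto_idx)) cyto_idx else cell_idx
      centers <- pool[sample.int(length(pool), n_spots, replace = TRUE)]
      for (s in seq_len(n_spots)) {
        spot_id <- spot_id + 1L
        sy <- (centers[s] - 1L) %% shape[1] + 1L
        sx <- (centers[s] - 1L) %/% shape[1] + 1L
        sr <- runif(1, cfg$spot_radius_range[1], cfg$spot_radius_range[2])
        sp <- px_index(disc_pixels(sy, sx, sr, shape), shape)
        sp <- intersect(sp, cell_idx)            # spot within its cell
        spot_lab[sp] <- spot_id
        spot_to_cell[spot_id] <- i
        spot_idx_all <- union(spot_idx_all, sp)
      }
      lamp1_ch[cell_idx] <- cfg$lamp1_diffuse_intensity
      lamp1_ch[spot_idx_all] <- cfg$lamp1_spot_intensity * runif(1, 0.9, 1.1)
    }

    # exact NP mass split: spot pixels carry fraction f of the cell total
    A_c <- length(cell_idx); A_s <- length(spot_idx_all)
    f_cell <- if (apop || mit) NA_real_ else f_planted
    Ttot <- cfg$np_total_per_cell * (if (apop || mit) 0.3 else 1)
    if (apop || mit) {
      np_ch[cell_idx] <- Ttot / A_c
    } else {
      non_spot <- setdiff(cell_idx, spot_idx_all)
      if (A_s > 0) np_ch[spot_idx_all] <- f_cell * Ttot / A_s
      if (length(non_spot))
        np_ch[non_spot] <- (1 - f_cell) * Ttot / length(non_spot)
    }

    cells[[i]] <- data.frame(
      cell_id = i, cy = pos$cy[i], cx = pos$cx[i],
      nuc_a = a, nuc_b = b, cell_a = ca, cell_b = cb, theta = theta,
      is_apoptotic = apop, is_mitotic = mit, is_border = pos$is_border[i],
      f_cell = f_cell, np_total = Ttot, n_spots = n_spots)
  }
  cells <- do.call(rbind, cells)

  bg <- background_surface(shape, cfg$background_gradient_amplitude)
  prenoise <- if (keep_prenoise)
    list(np = np_ch, lamp1 = lamp1_ch, nuclei = nuclei_ch) else NULL
  nuclei_out <- nuclei_ch + 0.5 * bg
  lamp1_out <- lamp1_ch + bg
  np_out <- np_ch + bg
  maxv <- 2^cfg$bit_depth - 1
  finish <- function(m) {
    if (isTRUE(cfg$noise$poisson)) m <- matrix(stats::rpois(length(m), m),
                                               nrow(m), ncol(m))
    sd <- cfg$noise$gaussian_sd %||% 0
    if (sd > 0) m <- m + stats::rnorm(length(m), 0, sd)
    pmin(pmax(round(m), 0), maxv)
  }
  channels <- list(nuclei = finish(nuclei_out), lamp1 = finish(lamp1_out),
                   np = finish(np_out))
  list(field = field_image(channels, plate_id, well_id, field_id,
                           cfg$pixel_size),
       truth = list(cells = cells, nucleus_labels = nuc_lab,
                    cell_labels = cell_lab, spot_labels = spot_lab,
                    spot_to_cell = spot_to_cell, background = bg,
                    prenoise = prenoise, effect = effect,
                    f_planted = f_planted))
}

#' Build a screen plate layout
#'
#' Creates the long-format plate layout of a multi-replicate siRNA screen:
#' one row per (plate, well, replicate), mapping wells to treatments. Each
#' gene may be targeted by several independent siRNAs (validation-screen
#' style); every plate carries \code{n_neg_wells} non-targeting negative
#' control wells (\code{NEG}). The same well positions are reused across
#' replicates, mirroring replicated plates of a 384-well screen.
#'
#' @param genes character vector of gene identifiers.
#' @param sirnas_per_gene independent siRNAs per gene (1 = pooled).
#' @param n_replicates number of independent experiments.
#' @param n_neg_wells negative-control wells per plate.
#' @param plate_capacity wells available per plate (384-well default).
#' @param wells_per_treatment replicate wells per treatment within each
#'   plate (1 = one well per treatment, the primary-screen format).
#' @return data.frame with columns \code{plate_id, well_id, replicate_id,
#'   treatment_id, gene, sirna_id, is_negative_control}.
#' @export
make_screen_layout <- function(genes, sirnas_per_gene = 1L,
                               n_replicates = 3L, n_neg_wells = 10L,
                               plate_capacity = 384L,
                               wells_per_treatment = 1L) {
  stopifnot(length(genes) >= 1L, n_neg_wells >= 1L,
            wells_per_treatment >= 1L)
  trt <- expand.grid(sirna = seq_len(sirnas_per_gene), gene = genes,
                     stringsAsFactors = FALSE)
  trt$treatment_id <- if (sirnas_per_gene > 1L)
    paste0(trt$gene, "_si", trt$sirna) else as.character(trt$gene)
  if (wells_per_treatment > 1L)
    trt <- trt[rep(seq_len(nrow(trt)), each = wells_per_treatment), ]
  wells_all <- as.vector(outer(sprintf("%02d", 1:24), LETTERS[1:16],
                               function(c, r) paste0(r, c)))
  per_plate <- plate_capacity - n_neg_wells
  if (per_plate < 1L) stop("plate capacity too small", call. = FALSE)
  n_plates <- ceiling(nrow(trt) / per_plate)
  rows <- list()
  k <- 0L
  for (p in seq_len(n_plates)) {
    idx <- ((p - 1L) * per_plate + 1L):min(p * per_plate, nrow(trt))
    ids <- c(rep("NEG", n_neg_wells), trt$treatment_id[idx])
    gs <- c(rep("NEG", n_neg_wells), trt$gene[idx])
    si <- c(rep(0L, n_neg_wells), trt$sirna[idx])
    wells <- wells_all[seq_along(ids)]
    for (r in seq_len(n_replicates)) {
      k <- k + 1L
      rows[[k]] <- data.frame(plate_id = sprintf("P%02d", p),
                              well_id = wells, replicate_id = r,
                              treatment_id = ids, gene = gs, sirna_id = si,
                              is_negative_control = ids == "NEG")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

validate_layout <- function(layout) {
  need <- c("plate_id", "well_id", "replicate_id", "treatment_id", "gene",
            "sirna_id", "is_negative_control")
  miss <- setdiff(need, names(layout))
  if (length(miss))
    stop("layout is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- paste(layout$plate_id, layout$well_id, layout$replicate_id)
  if (anyDuplicated(key))
    stop("(plate_id, well_id, replicate_id) must be unique", call. = FALSE)
  for (p in unique(layout$plate_id))
    if (!any(layout$is_negative_control[layout$plate_id == p]))
      stop("plate ", p, " has no negative-control well", call. = FALSE)
  invisible(layout)
}

resolve_effects <- function(layout, effects) {
  trts <- unique(layout$treatment_id[!layout$is_negative_control])
  missing_t <- setdiff(trts, names(effects))
  if (length(missing_t))
    stop("no effect specified for treatment(s): ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  e <- unlist(effects)[as.character(layout$treatment_id)]
  e[layout$is_negative_control] <- 1.0   # NEG is the null by definition
  unname(e)
}

#' Simulate a whole screen as TIFF fields on disk
#'
#' Generates every (well, replicate, field) image set of a layout with
#' planted per-treatment trafficking effects, writing per-channel TIFFs to
#' \code{dir}. Replicate-to-replicate variability is injected as a shared
#' multiplicative offset per replicate (it cancels under per-replicate NEG
#' normalization), and per-well variability as an independent
#' multiplicative jitter on the effect.
#'
#' @param layout a layout as from \code{\link{make_screen_layout}}.
#' @param effects named list/vector mapping treatment_id to effect
#'   multiplier; negative controls are forced to 1.
#' @param config a \code{\link{simulation_config}}.
#' @param fields_per_well imaged fields per well.
#' @param seed master seed (all field seeds derive from it).
#' @param dir output directory for TIFFs.
#' @param replicate_cv,well_cv coefficients of variation of the replicate
#'   offset and per-well jitter.
#' @return list with \code{manifest} (one row per field: plate, well,
#'   replicate, field, treatment, file paths), \code{truth_wells} (planted
#'   effect and realized in-spot fraction per well) and \code{layout}.
#' @export
simulate_screen <- function(layout, effects, config = simulation_config(),
                            fields_per_well = 1L, seed = config$seed,
                            dir = tempfile("screen"), replicate_cv = 0.05,
                            well_cv = 0.05) {
  validate_layout(layout)
  eff <- resolve_effects(layout, effects)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  reps <- sort(unique(layout$replicate_id))
  rep_off <- with_seed(derive_seed(seed, "replicate-offsets"),
                       stats::setNames(pmax(1 + stats::rnorm(length(reps), 0,
                                                             replicate_cv), 0),
                                       reps))
  manifest <- list(); truth <- list()
  for (i in seq_len(nrow(layout))) {
    row <- layout[i, ]
    wseed <- derive_seed(seed, row$plate_id, row$well_id, row$replicate_id)
    jit <- with_seed(wseed, pmax(1 + stats::rnorm(1, 0, well_cv), 0))
    e_well <- eff[i] * rep_off[as.character(row$replicate_id)] * jit
    f_well <- max(0, min(1, config$base_in_spot_fraction * e_well))
    for (fd in seq_len(fields_per_well)) {
      fseed <- derive_seed(wseed, "field", fd)
      sim <- simulate_field(config, effect = e_well, seed = fseed,
                            plate_id = row$plate_id,
                            well_id = sprintf("%s_R%d", row$well_id,
                                              row$replicate_id),
                            field_id = fd, keep_prenoise = FALSE)
      paths <- write_field_tiff(sim$field, dir, config$bit_depth)
      manifest[[length(manifest) + 1L]] <- data.frame(
        plate_id = row$plate_id, well_id = row$well_id,
        replicate_id = row$replicate_id, field_id = fd,
        treatment_id = row$treatment_id, gene = row$gene,
        sirna_id = row$sirna_id,
        is_negative_control = row$is_negative_control,
        t(paths))
    }
    truth[[i]] <- data.frame(row, planted_effect = eff[i],
                             effect_realized = e_well, f_true = f_well)
  }
  manifest <- do.call(rbind, manifest); rownames(manifest) <- NULL
  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  list(manifest = manifest, truth_wells = truth, layout = layout, dir = dir)
}

#' Simulate an imageless per-well record table
#'
#' Fast screen-statistics mode: draws per-well LAMP1-associated NP ratios
#' directly as \code{baseline_ratio * effect * (1 + N(0, neg_cv))},
#' truncated to [0, 1], together with analyzed-cell counts and per-cell
#' mean LAMP1 intensities. Used to exercise the statistics layer at full
#' 348-gene scale in seconds.
#'
#' @param layout screen layout (see \code{\link{make_screen_layout}}).
#' @param effects named effects map as in \code{\link{simulate_screen}}.
#' @param neg_cv coefficient of variation of the well-to-well noise.
#' @param cells_per_well numeric \code{c(mean, sd)} of the analyzed-cell
#'   count distribution (normal, rounded, truncated at 0).
#' @param baseline_ratio control-condition raw ratio.
#' @param lamp1_effects optional named map of per-treatment multipliers on
#'   the mean LAMP1 intensity per cell (default 1 for all).
#' @param seed integer seed.
#' @return a WellRecord data.frame (layout columns plus
#'   \code{n_cells_analyzed}, \code{lamp1_np_ratio},
#'   \code{mean_lamp1_intensity_per_cell}).
#' @export
simulate_well_table <- function(layout, effects, neg_cv = 0.05,
                                cells_per_well = c(200, 30),
                                baseline_ratio = 0.55,
                                lamp1_effects = NULL, seed = 1L) {
  validate_layout(layout)
  stopifnot_scalar_number(neg_cv, "neg_cv", lower = 0)
  eff <- resolve_effects(layout, effects)
  lamp_mult <- rep(1, nrow(layout))
  if (!is.null(lamp1_effects)) {
    m <- unlist(lamp1_effects)[as.character(layout$treatment_id)]
    lamp_mult[!is.na(m)] <- m[!is.na(m)]
  }
  with_seed(seed, {
    n <- nrow(layout)
    ratio <- baseline_ratio * eff * (1 + stats::rnorm(n, 0, neg_cv))
    ratio <- pmin(pmax(ratio, 0), 1)
    cells <- pmax(round(stats::rnorm(n, cells_per_well[1],
                                     cells_per_well[2])), 0)
    lamp1 <- pmax(stats::rnorm(n, 100, 8), 0) * lamp_mult
    out <- data.frame(layout, n_cells_analyzed = cells,
                      lamp1_np_ratio = ratio,
                      mean_lamp1_intensity_per_cell = lamp1)
    rownames(out) <- NULL
    out
  })
}
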