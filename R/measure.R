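#' QC gate parameters
#'
#' Gates used to remove apoptotic, mitotic and border cells before
#' measurement aggregation. Apoptotic cells present as small condensed
#' nuclei (area below \code{apoptotic_area}); mitotic cells as bright
#' condensed chromatin (mean nucleus intensity above
#' \code{mitotic_intensity}). Defaults are calibrated on the synthetic
#' generator's geometry and intensity scales.
#'
#' @param apoptotic_area nucleus area gate, px^2.
#' @param mitotic_intensity nucleus mean-intensity gate, camera units.
#' @return list of class \code{qc_gates}.
#' @export
qc_gates <- function(apoptotic_area = 40, mitotic_intensity = 150) {
  structure(list(apoptotic_area = apoptotic_area,
                 mitotic_intensity = mitotic_intensity),
            class = "qc_gates")
}

#' Measure per-cell morphology and intensities
#'
#' Extracts one record per segmented cell: nucleus and cell areas, nucleus
#' mean intensity (raw Hoechst), border contact, total NP intensity over
#' the cell mask and over the cell's spot pixels, mean marker intensity
#' over the cell mask, and spot count. The NP and marker channels are
#' expected to be background-corrected.
#'
#' @param field a \code{\link{field_image}} with channels \code{nuclei},
#'   \code{lamp1} (or another marker) and \code{np}.
#' @param seg list with \code{nucleus_labels}, \code{cell_labels},
#'   \code{spot_labels}, \code{spot_to_cell} (as produced by the
#'   segmentation functions).
#' @param np_channel,marker_channel channel names.
#' @return data.frame with one row per cell (a CellRecord table); QC flags
#'   are unset until \code{\link{qc_filter_cells}} runs.
#' @export
measure_cells <- function(field, seg, np_channel = "np",
                          marker_channel = "lamp1") {
  np <- field$channels[[np_channel]]
  mk <- field$channels[[marker_channel]]
  nu <- field$channels[["nuclei"]]
  if (is.null(np) || is.null(mk) || is.null(nu))
    stop("field lacks required channels", call. = FALSE)
  cl <- seg$cell_labels
  if (!all(dim(cl) == dim(np)))
    stop("segmentation and channel shapes differ", call. = FALSE)
  n <- max(cl)
  if (n == 0L) return(empty_cell_records())
  nl <- seg$nucleus_labels; sl <- seg$spot_labels
  sum_by <- function(v, lab) {
    out <- numeric(n)
    t <- tapply(v[lab > 0], lab[lab > 0], sum)
    out[as.integer(names(t))] <- t
    out
  }
  count_by <- function(lab) tabulate(lab[lab > 0], nbins = n)
  cell_area <- count_by(cl)
  nuc_area <- count_by(nl)
  nuc_sum <- sum_by(nu, nl)
  np_cell <- sum_by(np, cl)
  mk_cell <- sum_by(mk, cl)
  # NP in spots, credited to the spot's cell
  np_spots <- numeric(n); spot_count <- integer(n)
  if (length(seg$spot_to_cell)) {
    sidx <- which(sl > 0)
    per_spot <- tapply(np[sidx], sl[sidx], sum)
    owners <- seg$spot_to_cell[as.integer(names(per_spot))]
    agg <- tapply(as.numeric(per_spot), owners, sum)
    np_spots[as.integer(names(agg))] <- agg
    tc <- table(seg$spot_to_cell)
    spot_count[as.integer(names(tc))] <- as.integer(tc)
  }
  # border contact: any cell-mask pixel on the outermost row/column
  edge <- matrix(FALSE, nrow(cl), ncol(cl))
  edge[1, ] <- edge[nrow(cl), ] <- TRUE
  edge[, 1] <- edge[, ncol(cl)] <- TRUE
  border_ids <- unique(cl[edge & cl > 0])
  data.frame(cell_id = seq_len(n),
             nucleus_area = nuc_area,
             cell_area = cell_area,
             nucleus_mean_intensity = ifelse(nuc_area > 0,
                                             nuc_sum / nuc_area, 0),
             touches_border = seq_len(n) %in% border_ids,
             qc_pass = NA, qc_reason = NA_character_,
             np_total_in_cell = np_cell,
             np_total_in_spots = np_spots,
             lamp1_mean_intensity = ifelse(cell_area > 0,
                                           mk_cell / cell_area, 0),
             spot_count = spot_count)
}

empty_cell_records <- function() {
  data.frame(cell_id = integer(0), nucleus_area = numeric(0),
             cell_area = numeric(0), nucleus_mean_intensity = numeric(0),
             touches_border = logical(0), qc_pass = logical(0),
             qc_reason = character(0), np_total_in_cell = numeric(0),
             np_total_in_spots = numeric(0),
             lamp1_mean_intensity = numeric(0), spot_count = integer(0))
}

#' Flag cells failing quality control
#'
#' Sets \code{qc_pass}/\code{qc_reason} on a CellRecord table: cells whose
#' mask touches the field border are removed first (reason \code{border}),
#' then cells with nucleus area below the apoptotic gate (reason
#' \code{apoptotic}), then cells with nucleus mean intensity above the
#' mitotic gate (reason \code{mitotic}); all others pass.
#'
#' @param records CellRecord data.frame from \code{\link{measure_cells}}.
#' @param gates a \code{\link{qc_gates}} object.
#' @return the records with QC columns filled.
#' @export
qc_filter_cells <- function(records, gates = qc_gates()) {
  stopifnot(inherits(gates, "qc_gates"))
  reason <- rep("pass", nrow(records))
  reason[records$nucleus_mean_intensity > gates$mitotic_intensity] <- "mitotic"
  reason[records$nucleus_area < gates$apoptotic_area] <- "apoptotic"
  reason[records$touches_border] <- "border"
  records$qc_reason <- reason
  records$qc_pass <- reason == "pass"
  records
}

#' Per-well LAMP1-associated NP ratio
#'
#' Aggregates QC-passing cells pooled over all fields of one well into the
#' screen's per-well statistic: the average over cells of total NP
#' intensity inside LAMP1 spots, divided by the average over cells of
#' total NP intensity in the cell region (a ratio of averages, equal to
#' the ratio of the two sums). Wells with no passing cells, or zero total
#' NP signal, return an \code{NA} ratio flagged \code{ratio_defined =
#' FALSE} rather than an error; the viability rule removes them downstream.
#'
#' @param records CellRecord rows (all fields of one well), QC flags set.
#' @param passing_only use only \code{qc_pass} cells (default TRUE).
#' @return one-row data.frame: \code{lamp1_np_ratio}, \code{ratio_defined},
#'   \code{n_cells_analyzed}, \code{mean_lamp1_intensity_per_cell},
#'   \code{mean_spot_count}.
#' @examples
#' rec <- data.frame(np_total_in_spots = c(10, 30),
#'                   np_total_in_cell = c(20, 60),
#'                   lamp1_mean_intensity = c(1, 1),
#'                   spot_count = c(1, 1), qc_pass = TRUE)
#' well_ratio(rec)$lamp1_np_ratio   # 40/80 = 0.5
#' @export
well_ratio <- function(records, passing_only = TRUE) {
  if (passing_only && nrow(records)) records <- records[records$qc_pass, ]
  n <- nrow(records)
  denom <- if (n) mean(records$np_total_in_cell) else 0
  num <- if (n) mean(records$np_total_in_spots) else 0
  defined <- n > 0 && denom > 0
  data.frame(lamp1_np_ratio = if (defined) num / denom else NA_real_,
             ratio_defined = defined,
             n_cells_analyzed = n,
             mean_lamp1_intensity_per_cell =
               if (n) mean(records$lamp1_mean_intensity) else NA_real_,
             mean_spot_count = if (n) mean(records$spot_count) else NA_real_)
}

#' Analysis parameter set
#'
#' Collects every tunable of the image-analysis stage with its default:
#' rolling-ball radius (10 px), nucleus segmentation, cytoplasm
#' segmentation, spot detection and QC gates.
#'
#' @param rollball_radius rolling-ball radius in pixels.
#' @param nucleus_min_area,nucleus_smooth_sigma,watershed_tolerance
#'   nucleus segmentation parameters.
#' @param cyto_threshold_factor,cyto_dilate,cyto_min_component cytoplasm
#'   mask parameters.
#' @param spot_scale,spot_contrast,spot_min_area,spot_max_area spot
#'   detection parameters.
#' @param gates a \code{\link{qc_gates}} object.
#' @return list of class \code{analysis_params}.
#' @export
analysis_params <- function(rollball_radius = 10, nucleus_min_area = 6L,
                            nucleus_smooth_sigma = 1.5,
                            watershed_tolerance = 1,
                            cyto_threshold_factor = 0.6, cyto_dilate = 0L,
                            cyto_min_component = 25L,
                            spot_scale = 3L, spot_contrast = 30,
                            spot_min_area = 1L, spot_max_area = 100L,
                            gates = qc_gates()) {
  structure(list(rollball_radius = rollball_radius,
                 nucleus_min_area = nucleus_min_area,
                 nucleus_smooth_sigma = nucleus_smooth_sigma,
                 watershed_tolerance = watershed_tolerance,
                 cyto_threshold_factor = cyto_threshold_factor,
                 cyto_dilate = cyto_dilate,
                 cyto_min_component = cyto_min_component,
                 spot_scale = spot_scale, spot_contrast = spot_contrast,
                 spot_min_area = spot_min_area,
                 spot_max_area = spot_max_area, gates = gates),
            class = "analysis_params")
}

#' Analyze one field end to end
#'
#' Runs the full per-field chain: rolling-ball background correction of
#' the marker and NP channels (the nuclei channel is used raw),
#' nucleus/cell segmentation, spot detection on the marker, measurement
#' and QC flagging.
#'
#' @param field a \code{\link{field_image}}.
#' @param params an \code{\link{analysis_params}}.
#' @return list with \code{records} (QC-flagged CellRecord table),
#'   \code{seg} (label maps) and \code{corrected} (corrected channels).
#' @export
analyze_field <- function(field, params = analysis_params()) {
  stopifnot(inherits(field, "field_image"),
            inherits(params, "analysis_params"))
  lamp1 <- subtract_background(field$channels$lamp1, params$rollball_radius)
  np <- subtract_background(field$channels$np, params$rollball_radius)
  nuc_lab <- segment_nuclei(field$channels$nuclei,
                            min_area = params$nucleus_min_area,
                            smooth_sigma = params$nucleus_smooth_sigma,
                            watershed_tolerance = params$watershed_tolerance)
  cell_lab <- segment_cells(nuc_lab, np,
                            threshold_factor = params$cyto_threshold_factor,
                            dilate_mask = params$cyto_dilate,
                            min_component = params$cyto_min_component)
  sp <- detect_spots(lamp1, cell_lab, spot_scale = params$spot_scale,
                     contrast = params$spot_contrast,
                     min_area = params$spot_min_area,
                     max_area = params$spot_max_area)
  seg <- list(nucleus_labels = nuc_lab, cell_labels = cell_lab,
              spot_labels = sp$spot_labels, spot_to_cell = sp$spot_to_cell)
  corrected <- field
  corrected$channels$lamp1 <- lamp1
  corrected$channels$np <- np
  records <- qc_filter_cells(measure_cells(corrected, seg), params$gates)
  list(records = records, seg = seg, corrected = corrected)
}
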