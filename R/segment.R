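#' Segment nuclei from the Hoechst channel
#'
#' Open equivalent of the screening software's nucleus-finding step:
#' Gaussian smoothing, global Otsu threshold, hole filling, then a
#' distance-transform watershed to split touching nuclei, with a minimum
#' object area filter. Labels are sequential integers, 0 = background.
#'
#' @param nuclei_channel numeric matrix (raw or corrected Hoechst image).
#' @param min_area discard objects smaller than this many pixels.
#' @param smooth_sigma Gaussian pre-smoothing sigma, pixels.
#' @param threshold absolute intensity threshold; default \code{NULL}
#'   computes Otsu on the smoothed image.
#' @param watershed_tolerance minimum distance-map depth between two
#'   objects for them to be split (passed to the watershed).
#' @return integer label matrix.
#' @export
segment_nuclei <- function(nuclei_channel, min_area = 6L, smooth_sigma = 1.5,
                           threshold = NULL, watershed_tolerance = 1) {
  stopifnot(is.matrix(nuclei_channel))
  img <- EBImage::Image(nuclei_channel)
  sm <- if (smooth_sigma > 0)
    EBImage::gblur(img, sigma = smooth_sigma,
                   radius = 2 * ceiling(3 * smooth_sigma) + 1) else img
  rng <- range(sm)
  if (diff(rng) <= 0) return(matrix(0L, nrow(nuclei_channel),
                                    ncol(nuclei_channel)))
  thr <- threshold %||% EBImage::otsu(sm, range = rng, levels = 256)
  mask <- EBImage::fillHull(sm > thr)
  if (!any(mask) || all(mask)) return(matrix(0L, nrow(nuclei_channel),
                                             ncol(nuclei_channel)))
  # contrast guard: on a blank (noise-only) field Otsu still splits the
  # noise distribution; demand real foreground/background separation
  fg <- mean(sm[mask]); bgv <- sm[!mask]
  if (is.null(threshold) && fg - mean(bgv) < 5 * stats::sd(bgv))
    return(matrix(0L, nrow(nuclei_channel), ncol(nuclei_channel)))
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < min_area)
  if (length(small)) lab[lab %in% small] <- 0L
  relabel_sequential(lab)
}

relabel_sequential <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(matrix(0L, nrow(lab), ncol(lab)))
  map <- integer(max(ids)); map[ids] <- seq_along(ids)
  out <- lab
  out[out > 0] <- map[out[out > 0]]
  storage.mode(out) <- "integer"
  matrix(out, nrow(lab), ncol(lab))
}

#' Segment cell bodies seeded from nuclei
#'
#' Open equivalent of the cytoplasm-finding step: a seeded watershed
#' (Voronoi region growing on the intensity landscape of a cytoplasmic
#' reference channel) assigns every above-threshold pixel to the nucleus it
#' belongs to. Exactly one cell region is produced per nucleus, regions are
#' disjoint, and each contains its seed nucleus.
#'
#' @param nucleus_labels integer label matrix from
#'   \code{\link{segment_nuclei}}.
#' @param ref_channel cytoplasmic reference image (e.g. the
#'   background-corrected NP channel, whose diffuse component fills the
#'   cell body).
#' @param smooth_sigma smoothing applied to the reference before
#'   thresholding.
#' @param threshold_factor the cytoplasm mask keeps pixels above this
#'   fraction of the estimated cytoplasm plateau intensity; for a blurred
#'   step edge a fraction near 0.5 crosses close to the true boundary.
#' @param dilate_mask radius of a final morphological dilation of the
#'   cytoplasm mask (same rationale).
#' @param min_component connected mask components smaller than this many
#'   pixels are treated as noise speckle and dropped before growing.
#' @return integer cell label matrix (same label ids as the nuclei).
#' @export
segment_cells <- function(nucleus_labels, ref_channel, smooth_sigma = 1.5,
                          threshold_factor = 0.6, dilate_mask = 0L,
                          min_component = 25L) {
  stopifnot(is.matrix(nucleus_labels), is.matrix(ref_channel),
            all(dim(nucleus_labels) == dim(ref_channel)))
  if (!any(nucleus_labels > 0))
    return(matrix(0L, nrow(nucleus_labels), ncol(nucleus_labels)))
  img <- EBImage::Image(ref_channel)
  sm <- if (smooth_sigma > 0)
    EBImage::gblur(img, sigma = smooth_sigma,
                   radius = 2 * ceiling(3 * smooth_sigma) + 1) else img
  # Otsu on a log scale: the reference channel is strongly trimodal
  # (background, diffuse cytoplasm, bright puncta) and a linear Otsu can
  # land between cytoplasm and puncta, losing the cell body. The Otsu cut
  # separates background from cell; the final threshold is a fraction of
  # the cytoplasm plateau (median above-cut intensity), which for a
  # blurred step edge crosses close to the true cell boundary.
  lg <- log1p(pmax(sm, 0))
  rng <- range(lg)
  mask <- if (diff(rng) > 0) {
    t0 <- expm1(EBImage::otsu(EBImage::Image(lg), range = rng, levels = 256))
    plateau <- stats::median(sm[sm > t0])
    sm > max(threshold_factor * plateau, t0 * 0.75)
  } else sm > -Inf
  # drop small speckle components (shot noise) before region growing
  comp <- EBImage::bwlabel(EBImage::Image(mask))
  sizes <- tabulate(comp[comp > 0])
  if (length(sizes)) {
    bad <- which(sizes < min_component)
    if (length(bad)) mask[EBImage::imageData(comp) %in% bad] <- FALSE
  }
  if (dilate_mask > 0)
    mask <- EBImage::dilate(mask,
                            EBImage::makeBrush(2L * as.integer(dilate_mask) + 1L,
                                               "disc"))
  mask <- mask | (nucleus_labels > 0)   # a cell always contains its nucleus
  lab <- EBImage::propagate(sm, seeds = EBImage::Image(nucleus_labels),
                            mask = mask)
  out <- EBImage::imageData(lab)
  storage.mode(out) <- "integer"
  matrix(out, nrow(nucleus_labels), ncol(nucleus_labels))
}

#' Detect punctate marker spots and assign them to cells
#'
#' Open equivalent of the spot-finding step: a white top-hat at the spot
#' scale enhances punctate structure, pixels above a contrast-over-local-
#' background threshold are labelled, size-filtered, and each spot is
#' assigned to the cell containing its centroid. Spot pixels are clipped to
#' their cell's mask; spots whose centroid falls outside all cells are
#' discarded.
#'
#' @param marker_channel background-corrected marker image (e.g. LAMP1).
#' @param cell_labels integer cell label matrix.
#' @param spot_scale radius of the top-hat structuring element, pixels
#'   (slightly larger than the largest expected spot).
#' @param contrast minimum top-hat amplitude (intensity units above local
#'   background) for a pixel to count as spot signal.
#' @param min_area,max_area spot size limits in pixels.
#' @return list with \code{spot_labels} (integer matrix) and
#'   \code{spot_to_cell} (integer vector indexed by spot id).
#' @export
detect_spots <- function(marker_channel, cell_labels, spot_scale = 3L,
                         contrast = 30, min_area = 1L, max_area = 100L) {
  stopifnot(is.matrix(marker_channel), is.matrix(cell_labels),
            all(dim(marker_channel) == dim(cell_labels)))
  brush <- EBImage::makeBrush(2L * as.integer(spot_scale) + 1L, "disc")
  th <- EBImage::whiteTopHat(EBImage::Image(marker_channel), brush)
  mask <- EBImage::imageData(th) > contrast
  if (!any(mask))
    return(list(spot_labels = matrix(0L, nrow(mask), ncol(mask)),
                spot_to_cell = integer(0)))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  sizes <- tabulate(lab[lab > 0])
  bad <- which(sizes < min_area | sizes > max_area)
  if (length(bad)) lab[lab %in% bad] <- 0L
  lab <- relabel_sequential(lab)
  n <- max(lab)
  if (n == 0L) return(list(spot_labels = lab, spot_to_cell = integer(0)))
  # assign by centroid, clip pixels to the assigned cell's mask
  idx <- which(lab > 0)
  ys <- (idx - 1L) %% nrow(lab) + 1L
  xs <- (idx - 1L) %/% nrow(lab) + 1L
  ids <- lab[idx]
  cy <- round(tapply(ys, ids, mean)); cx <- round(tapply(xs, ids, mean))
  owner <- cell_labels[cbind(as.integer(cy), as.integer(cx))]
  out <- matrix(0L, nrow(lab), ncol(lab))
  keep_map <- integer(n); spot_to_cell <- integer(0)
  nk <- 0L
  for (s in seq_len(n)) {
    if (owner[s] == 0L) next
    sel <- idx[ids == s]
    sel <- sel[cell_labels[sel] == owner[s]]
    if (!length(sel)) next
    nk <- nk + 1L
    out[sel] <- nk
    spot_to_cell[nk] <- owner[s]
  }
  list(spot_labels = out, spot_to_cell = spot_to_cell)
}
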