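#' Automatic intensity threshold within a mask
#'
#' Default is Otsu's method computed over the masked pixels only (256
#' histogram bins spanning the masked intensity range, making the cutoff
#' equivariant under positive rescaling); a fixed-percentile alternative
#' is available.
#'
#' @param channel numeric matrix.
#' @param mask logical matrix of the same dimension (or \code{NULL} for
#'   the whole image).
#' @param method \code{"otsu"}, \code{"percentile"} or
#'   \code{"max_fraction"} (a fixed fraction of the masked maximum, the
#'   convention of standard colocalization pipelines; it keeps moderate
#'   diffuse signal in the evaluated set where a bimodal Otsu would cut
#'   between diffuse and punctate modes).
#' @param percentile percentile used by the percentile method.
#' @param max_fraction fraction of the masked maximum used by the
#'   max_fraction method.
#' @return a single intensity cutoff.
#' @export
auto_threshold <- function(channel, mask = NULL,
                           method = c("otsu", "percentile",
                                      "max_fraction"),
                           percentile = 0.9, max_fraction = 0.15) {
  method <- match.arg(method)
  if (is.null(mask)) mask <- array(TRUE, dim(channel))
  v <- channel[mask]
  if (!length(v)) stop("empty mask", call. = FALSE)
  if (method == "percentile") return(unname(stats::quantile(v, percentile)))
  if (method == "max_fraction") return(max_fraction * max(v))
  rng <- range(v)
  if (diff(rng) <= 0) return(rng[1])   # constant channel: nothing above
  img <- EBImage::Image(matrix(v, ncol = 1))
  EBImage::otsu(img, range = rng, levels = 256)
}

#' Rank Weighted Colocalization coefficient (RWC)
#'
#' Quantifies co-occurrence of NP signal with an organelle marker inside
#' one cell. Over the n in-mask pixels, both channels are ranked by
#' descending intensity (ties get average ranks). Each pixel i receives a
#' weight \eqn{W_i = (n - D_i)/n} with \eqn{D_i} the absolute difference
#' of its two ranks, and
#' \deqn{RWC = \sum_{i \in C} I_{np}(i) W_i / \sum_{i \in A} I_{np}(i)}
#' where A is the set of NP-above-threshold pixels and C the subset also
#' above the marker threshold. RWC is the fraction of NP intensity that
#' colocalizes with the marker, discounted by rank disagreement: 1 when
#' both channels are identical, 0 when no pixel clears both thresholds.
#'
#' @param ch_np,ch_marker numeric matrices or vectors of equal length
#'   (intensities restricted to one cell).
#' @param threshold_np,threshold_marker intensity cutoffs (pixels strictly
#'   above count); defaults use \code{\link{auto_threshold}} within the
#'   mask.
#' @param mask logical array selecting the cell's pixels (default: all).
#' @return list of class \code{rwc_result}: \code{rwc}, \code{percent},
#'   \code{n_pixels_evaluated} (|A|), \code{n_coloc_pixels} (|C|).
#' @examples
#' x <- matrix(runif(64), 8)
#' rwc(x, x, threshold_np = 0, threshold_marker = 0)$rwc   # 1
#' @export
rwc <- function(ch_np, ch_marker, threshold_np = NULL,
                threshold_marker = NULL, mask = NULL) {
  if (!all(dim(as.matrix(ch_np)) == dim(as.matrix(ch_marker))))
    stop("channel shapes differ", call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, length(ch_np))
  np <- as.numeric(ch_np)[as.logical(mask)]
  mk <- as.numeric(ch_marker)[as.logical(mask)]
  if (!length(np)) stop("empty mask", call. = FALSE)
  if (is.null(threshold_np))
    threshold_np <- auto_threshold(matrix(np, ncol = 1))
  if (is.null(threshold_marker))
    threshold_marker <- auto_threshold(matrix(mk, ncol = 1))
  if (threshold_np < 0 || threshold_marker < 0)
    stop("thresholds must be >= 0", call. = FALSE)
  n <- length(np)
  A <- np > threshold_np
  C <- A & (mk > threshold_marker)
  denom <- sum(np[A])
  if (!any(A) || denom <= 0)
    return(rwc_result(0, sum(A), sum(C)))
  r_np <- rank(-np, ties.method = "average")
  r_mk <- rank(-mk, ties.method = "average")
  W <- (n - abs(r_np - r_mk)) / n
  rwc_result(sum(np[C] * W[C]) / denom, sum(A), sum(C))
}

rwc_result <- function(value, nA, nC) {
  structure(list(rwc = value, percent = 100 * value,
                 n_pixels_evaluated = as.integer(nA),
                 n_coloc_pixels = as.integer(nC)),
            class = "rwc_result")
}

#' @export
print.rwc_result <- function(x, ...) {
  cat(sprintf("RWC = %.4f (%.1f%%), |A| = %d, |C| = %d\n", x$rwc,
              x$percent, x$n_pixels_evaluated, x$n_coloc_pixels))
  invisible(x)
}

#' Per-cell colocalization percentages for a condition
#'
#' Computes the RWC of the NP channel with a marker for every QC-passing
#' cell of one condition (one or more analyzed fields), as the percentage
#' of NP signal colocalizing with the marker, and summarizes the condition
#' as mean and standard error over cells.
#'
#' @param fields list of \code{\link{field_image}} objects with
#'   background-corrected channels (e.g. \code{$corrected} from
#'   \code{\link{analyze_field}}).
#' @param segmentations matching list of segmentation results; each needs
#'   \code{cell_labels} and (for QC) the analyzed \code{records}.
#' @param records_list matching list of QC-flagged CellRecord tables.
#' @param marker_name marker channel name (e.g. \code{"lamp1"}).
#' @param threshold_method passed to \code{\link{auto_threshold}};
#'   the default fraction-of-maximum keeps diffuse NP signal in the
#'   evaluated set, so the percentage responds to the diffuse/punctate
#'   split rather than only to the brightest pixels.
#' @return list with \code{cells} (per-cell data.frame: field index, cell
#'   id, rwc, percent) and \code{summary} (n, mean percent, sem; sem is
#'   \code{NA} for n < 2). Zero passing cells give an empty table and an
#'   all-\code{NA} summary.
#' @export
percent_colocalized <- function(fields, segmentations, records_list,
                                marker_name = "lamp1",
                                threshold_method = "max_fraction") {
  stopifnot(length(fields) == length(segmentations),
            length(fields) == length(records_list))
  rows <- list()
  for (k in seq_along(fields)) {
    fld <- fields[[k]]; seg <- segmentations[[k]]
    rec <- records_list[[k]]
    pass_ids <- rec$cell_id[rec$qc_pass]
    np <- fld$channels$np; mk <- fld$channels[[marker_name]]
    if (is.null(mk)) stop("missing marker channel: ", marker_name,
                          call. = FALSE)
    for (cid in pass_ids) {
      m <- seg$cell_labels == cid
      res <- rwc(np, mk,
                 threshold_np = auto_threshold(np, m, threshold_method),
                 threshold_marker = auto_threshold(mk, m, threshold_method),
                 mask = m)
      rows[[length(rows) + 1L]] <- data.frame(field = k, cell_id = cid,
                                              rwc = res$rwc,
                                              percent = res$percent)
    }
  }
  cells <- if (length(rows)) do.call(rbind, rows) else
    data.frame(field = integer(0), cell_id = integer(0), rwc = numeric(0),
               percent = numeric(0))
  n <- nrow(cells)
  summary <- data.frame(
    n_cells = n,
    mean_percent = if (n) mean(cells$percent) else NA_real_,
    sem_percent = if (n >= 2) stats::sd(cells$percent) / sqrt(n) else NA_real_)
  list(cells = cells, summary = summary)
}
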