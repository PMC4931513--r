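#' Multi-channel fluorescence field
#'
#' A \code{field_image} bundles the co-registered 2D intensity channels of
#' one imaged field (typically \code{nuclei}, \code{lamp1} and \code{np})
#' together with its plate/well/field identifiers. Intensities are stored as
#' non-negative numeric matrices in arbitrary camera units; the nominal
#' pixel size is carried as metadata only.
#'
#' @param channels named list of numeric matrices, all the same dimension.
#' @param plate_id,well_id,field_id identifiers recorded in all outputs.
#' @param pixel_size nominal pixel size in micrometres per pixel.
#' @return an object of class \code{field_image}.
#' @examples
#' ch <- list(nuclei = matrix(0, 8, 8), lamp1 = matrix(0, 8, 8),
#'            np = matrix(0, 8, 8))
#' f <- field_image(ch, "P1", "A01", 1)
#' dim(f$channels$np)
#' @export
field_image <- function(channels, plate_id = "P1", well_id = "A01",
                        field_id = 1L, pixel_size = 0.16) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("'channels' must be a named list of matrices", call. = FALSE)
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m), TRUE)))
    stop("all channels must be numeric matrices", call. = FALSE)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all channels must share the same dimensions", call. = FALSE)
  if (any(vapply(channels, function(m) any(m < 0), TRUE)))
    stop("channel intensities must be non-negative", call. = FALSE)
  structure(list(channels = channels,
                 plate_id = as.character(plate_id),
                 well_id = as.character(well_id),
                 field_id = as.integer(field_id),
                 pixel_size = pixel_size),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("field_image %s/%s field %d: %dx%d px, channels: %s\n",
              x$plate_id, x$well_id, x$field_id, d[1], d[2],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Write a field to per-channel grayscale TIFF files
#'
#' One file per channel named \code{<plate>_<well>_<field>_<channel>.tif}.
#' Intensities are stored as unsigned integers at the requested bit depth;
#' values above the representable maximum are clipped.
#'
#' @param field a \code{field_image}.
#' @param dir output directory (created if missing).
#' @param bit_depth 8 or 16.
#' @return invisibly, the paths written (named by channel).
#' @export
write_field_tiff <- function(field, dir, bit_depth = 16L) {
  stopifnot(inherits(field, "field_image"), bit_depth %in% c(8L, 16L))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  maxv <- 2^bit_depth - 1
  paths <- character(0)
  for (ch in names(field$channels)) {
    p <- file.path(dir, sprintf("%s_%s_%d_%s.tif", field$plate_id,
                                field$well_id, field$field_id, ch))
    m <- pmin(round(field$channels[[ch]]), maxv) / maxv
    tiff::writeTIFF(m, p, bits.per.sample = bit_depth)
    paths[ch] <- p
  }
  invisible(paths)
}

#' Read a field back from per-channel TIFF files
#'
#' Inverse of \code{\link{write_field_tiff}}: reads the named channels of
#' one plate/well/field from \code{dir} and restores integer camera units.
#'
#' @param dir directory holding the TIFF files.
#' @param plate_id,well_id,field_id identifiers used in the file names.
#' @param channels channel names to read.
#' @param pixel_size metadata to attach.
#' @return a \code{field_image}.
#' @export
read_field_tiff <- function(dir, plate_id, well_id, field_id,
                            channels = c("nuclei", "lamp1", "np"),
                            pixel_size = 0.16) {
  chl <- list()
  for (ch in channels) {
    p <- file.path(dir, sprintf("%s_%s_%d_%s.tif", plate_id, well_id,
                                as.integer(field_id), ch))
    if (!file.exists(p)) stop("missing image file: ", p, call. = FALSE)
    m <- tiff::readTIFF(p, as.is = TRUE)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    storage.mode(m) <- "double"
    chl[[ch]] <- m
  }
  field_image(chl, plate_id, well_id, field_id, pixel_size)
}
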