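#' Ball structuring element for grayscale morphology
#'
#' Offsets and heights of a hemispherical (ball) structuring element of the
#' given pixel radius: support is the disc \code{dx^2 + dy^2 <= r^2}, height
#' \code{sqrt(r^2 - dx^2 - dy^2)} in intensity units.
#'
#' @param radius ball radius in pixels (>= 1).
#' @return a data.frame with columns \code{dx}, \code{dy}, \code{h}.
#' @keywords internal
ball_element <- function(radius) {
  r <- as.integer(ceiling(radius))
  off <- expand.grid(dx = -r:r, dy = -r:r)
  d2 <- off$dx^2 + off$dy^2
  keep <- d2 <= radius^2
  data.frame(dx = off$dx[keep], dy = off$dy[keep],
             h = sqrt(radius^2 - d2[keep]))
}

# Grayscale erosion/dilation with a non-flat structuring element, by
# shift-and-compare. Out-of-image neighbours are ignored (the min/max runs
# over the valid offsets only), which keeps a constant image constant.
shift_extreme <- function(img, se, op = c("erode", "dilate")) {
  op <- match.arg(op)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(if (op == "erode") Inf else -Inf, nr, nc)
  for (k in seq_len(nrow(se))) {
    dx <- se$dx[k]; dy <- se$dy[k]; h <- se$h[k]
    rs <- max(1, 1 + dx):min(nr, nr + dx)   # destination rows
    cs <- max(1, 1 + dy):min(nc, nc + dy)
    src_r <- rs - dx; src_c <- cs - dy
    if (op == "erode") {
      out[rs, cs] <- pmin(out[rs, cs], img[src_r, src_c] - h)
    } else {
      out[rs, cs] <- pmax(out[rs, cs], img[src_r, src_c] + h)
    }
  }
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the slowly varying background of a fluorescence image as the
#' grayscale opening with a ball structuring element (a ball of the given
#' radius "rolled" beneath the intensity surface; the background is the
#' upper envelope of all ball positions fitting under the image), then
#' subtracts it. Structures too sharp for the ball to enter -- nuclei,
#' punctate organelle signal, vesicular nanoparticle accumulations -- are
#' retained at their height above the local background, while smooth
#' illumination gradients are removed. The estimated background never
#' exceeds the image, and the result is clipped at zero.
#'
#' @param image non-negative numeric matrix.
#' @param radius ball radius in pixels; default 10.
#' @return matrix of the same dimension: \code{image - background}.
#' @examples
#' img <- matrix(100, 32, 32)   # flat field
#' img[16, 16] <- 300           # one sharp peak
#' cor <- subtract_background(img, radius = 10)
#' range(cor)                   # peak kept at ~200, background removed
#' @export
subtract_background <- function(image, radius = 10) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("'image' must be a numeric matrix", call. = FALSE)
  stopifnot_scalar_number(radius, "radius", lower = 1)
  if (any(image < 0)) stop("'image' must be non-negative", call. = FALSE)
  se <- ball_element(radius)
  bg <- shift_extreme(shift_extreme(image, se, "erode"), se, "dilate")
  bg <- pmin(bg, image)    # guard against numeric fuzz at edges
  pmax(image - bg, 0)
}
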