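# Independent oracles used to cross-check the package implementations.
# These are written as plain per-pixel enumerations, deliberately sharing
# no code path with the package.

# Grayscale opening with a ball structuring element, then subtraction:
# per-pixel min/max over explicitly enumerated offsets.
naive_rolling_ball_subtract <- function(img, radius = 10) {
  r <- ceiling(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  keep <- off$dy^2 + off$dx^2 <= radius^2
  dys <- off$dy[keep]; dxs <- off$dx[keep]
  hs <- sqrt(radius^2 - dys^2 - dxs^2)
  nr <- nrow(img); nc <- ncol(img)
  er <- matrix(NA_real_, nr, nc)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    yy <- y + dys; xx <- x + dxs
    ok <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
    er[y, x] <- min(img[cbind(yy[ok], xx[ok])] - hs[ok])
  }
  bg <- matrix(NA_real_, nr, nc)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    yy <- y + dys; xx <- x + dxs
    ok <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
    bg[y, x] <- max(er[cbind(yy[ok], xx[ok])] + hs[ok])
  }
  pmax(img - pmin(bg, img), 0)
}

# Brute-force RWC: ranks by explicit pairwise counting, sums enumerated.
naive_rwc <- function(np, mk, thr_np, thr_mk) {
  np <- as.numeric(np); mk <- as.numeric(mk)
  n <- length(np)
  rank_desc <- function(v)
    vapply(seq_len(n),
           function(i) sum(v > v[i]) + (sum(v == v[i]) + 1) / 2, 0)
  r1 <- rank_desc(np); r2 <- rank_desc(mk)
  A <- which(np > thr_np)
  C <- A[mk[A] > thr_mk]
  if (!length(A) || sum(np[A]) <= 0) return(0)
  tot <- 0
  for (i in C) tot <- tot + np[i] * (n - abs(r1[i] - r2[i])) / n
  tot / sum(np[A])
}

# Simulation config variants used across tests
clean_sim_config <- function(...) {
  simulation_config(apoptotic_fraction = 0, mitotic_fraction = 0,
                    border_cell_fraction = 0,
                    background_gradient_amplitude = 0,
                    noise = list(gaussian_sd = 0, poisson = FALSE), ...)
}

# Detected label corresponding to a planted cell (majority overlap of the
# truth nucleus with the detected nucleus map); NA if undetected.
matched_label <- function(truth, seg, i) {
  det <- seg$nucleus_labels[truth$nucleus_labels == i]
  det <- det[det > 0]
  if (!length(det)) return(NA_integer_)
  as.integer(names(sort(table(det), decreasing = TRUE))[1])
}
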