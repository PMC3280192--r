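# Independent reference implementations used as oracles, deliberately
# written differently from the package code paths they check.

# Brute-force colony size: scan every pixel of the image, test L1
# membership at the pixel center, threshold at 1.25 x window minimum.
brute_force_colony_size <- function(blue, cx, cy, half_diag) {
  H <- nrow(blue); W <- ncol(blue)
  xs <- matrix(rep(seq_len(W) - 1, each = H), nrow = H)
  ys <- matrix(rep(seq_len(H) - 1, times = W), nrow = H)
  member <- abs(xs + 0.5 - cx) + abs(ys + 0.5 - cy) <= half_diag
  vals <- blue[member]
  if (length(vals) == 0L) return(NA_integer_)
  sum(vals > 1.25 * min(vals))
}

# Exhaustive-scan noise band: walk candidate halfwidths upward until the
# required fraction of strains falls inside.
brute_force_noise_band <- function(rep1, rep2, coverage) {
  d <- abs(rep2 - rep1)
  for (b in sort(d)) {
    if (mean(d <= b) >= coverage) return(b)
  }
  max(d)
}

# Small anonymous catalog for capacity / shape tests.
toy_catalog <- function(n) {
  strain_catalog(sprintf("G%03d", seq_len(n)))
}

# Plate-image wrapper around a bare blue matrix with axis-aligned corners.
as_plate <- function(blue, ...) {
  H <- nrow(blue); W <- ncol(blue)
  px <- array(0L, dim = c(H, W, 3L))
  px[, , 3] <- blue
  plate_image(px, rbind(tl = c(0, 0), tr = c(W, 0),
                        bl = c(0, H), br = c(W, H)))
}
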