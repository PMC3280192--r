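#' Plate image container
#'
#' Holds the raster intensities of a photographed plate together with the
#' manually identified pixel coordinates of the four corners of the spot
#' grid. Coordinates are 0-based with x rightward and y downward; pixel
#' membership tests are evaluated at pixel centers (x + 0.5, y + 0.5).
#'
#' @param pixels H x W x C integer array of intensities (0-255).
#' @param corners 4 x 2 numeric matrix, rows `tl`, `tr`, `bl`, `br` and
#'   columns `x`, `y`, spanning the spot-grid extent.
#' @return An object of class `plate_image`.
#' @export
plate_image <- function(pixels, corners) {
  if (!is.array(pixels) || !(length(dim(pixels)) %in% c(2L, 3L))) {
    stop("pixels must be an H x W (x C) array", call. = FALSE)
  }
  if (length(dim(pixels)) == 2L) {
    pixels <- array(pixels, dim = c(dim(pixels), 1L))
  }
  corners <- as.matrix(corners)
  if (!all(dim(corners) == c(4L, 2L))) {
    stop("corners must be a 4 x 2 matrix (tl, tr, bl, br) x (x, y)",
         call. = FALSE)
  }
  if (is.null(rownames(corners))) rownames(corners) <- c("tl", "tr", "bl", "br")
  colnames(corners) <- c("x", "y")
  structure(list(pixels = pixels, corners = corners), class = "plate_image")
}

#' @export
print.plate_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("plate_image: ", d[1], " x ", d[2], " px, ", d[3], " channel(s)\n",
      sep = "")
  invisible(x)
}

#' Extract the blue channel
#'
#' Colony sizes are quantified on the blue channel of the plate photograph,
#' where yeast colonies on agar give the strongest contrast. Single-channel
#' (grayscale) images pass through unchanged with a note; RGBA images drop
#' the alpha channel.
#'
#' @param image a [plate_image()].
#' @return H x W numeric intensity matrix.
#' @export
blue_channel <- function(image) {
  stopifnot(inherits(image, "plate_image"))
  nc <- dim(image$pixels)[3]
  if (nc == 1L) {
    message("single-channel image: using intensities as-is")
    return(image$pixels[, , 1])
  }
  if (nc %in% c(3L, 4L)) {
    return(image$pixels[, , 3])
  }
  stop(sprintf("cannot extract a blue channel from a %d-channel image", nc),
       call. = FALSE)
}

#' Compute the window size of a plate grid
#'
#' The window size is the larger of the grid width divided by the number of
#' columns and the grid length divided by the number of rows, as a real
#' number (no rounding). Width and length are taken from the manually
#' identified corners (averaging the two opposite edges, which is exact for
#' an axis-aligned rectangle).
#'
#' @param corners 4 x 2 corner matrix (rows tl, tr, bl, br).
#' @param n_rows,n_cols grid dimensions.
#' @return Window size in pixels.
#' @export
window_size <- function(corners, n_rows, n_cols) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  corners <- as.matrix(corners)
  edge <- function(a, b) sqrt(sum((corners[a, ] - corners[b, ])^2))
  width <- (edge("tl", "tr") + edge("bl", "br")) / 2
  length_ <- (edge("tl", "bl") + edge("tr", "br")) / 2
  if (width <= 0 || length_ <= 0) {
    stop("degenerate corner geometry: zero width or length", call. = FALSE)
  }
  max(width / n_cols, length_ / n_rows)
}

#' Partition a plate image into diamond windows
#'
#' Lays an n_rows x n_cols lattice of window centers over the spot-grid
#' extent (bilinear interpolation between the four corners) and frames each
#' center with a diamond — an L1 ball whose diagonals equal the window
#' size. A pixel belongs to a window when the L1 distance from its center
#' to the window center is at most half the window size.
#'
#' @param image a [plate_image()].
#' @param n_rows,n_cols grid dimensions.
#' @return A tibble of windows: `row`, `col`, `cx`, `cy`, `half_diag`.
#' @export
partition_plate <- function(image, n_rows, n_cols) {
  stopifnot(inherits(image, "plate_image"))
  ws <- window_size(image$corners, n_rows, n_cols)
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  grid <- grid[order(grid$row, grid$col), ]
  uv <- cbind((grid$col - 0.5) / n_cols, (grid$row - 0.5) / n_rows)
  centers <- bilinear_centers(image$corners, uv)
  d <- dim(image$pixels)
  tol <- 1e-6  # float dust from the bilinear lattice is not a real overhang
  if (any(centers[, "x"] - ws / 2 < -tol | centers[, "x"] + ws / 2 > d[2] + tol |
          centers[, "y"] - ws / 2 < -tol | centers[, "y"] + ws / 2 > d[1] + tol)) {
    warning("some windows extend outside the image and are clipped",
            call. = FALSE)
  }
  tibble::tibble(
    row = as.integer(grid$row), col = as.integer(grid$col),
    cx = centers[, "x"], cy = centers[, "y"], half_diag = ws / 2
  )
}

# Intensities of the pixels belonging to one diamond window (clipped to the
# image), tested at pixel centers.
window_pixels <- function(blue, cx, cy, half_diag) {
  H <- nrow(blue); W <- ncol(blue)
  x0 <- max(0L, as.integer(ceiling(cx - half_diag - 0.5)))
  x1 <- min(W - 1L, as.integer(floor(cx + half_diag - 0.5)))
  y0 <- max(0L, as.integer(ceiling(cy - half_diag - 0.5)))
  y1 <- min(H - 1L, as.integer(floor(cy + half_diag - 0.5)))
  if (x1 < x0 || y1 < y0) return(numeric(0))
  dx <- abs((x0:x1) + 0.5 - cx)
  dy <- abs((y0:y1) + 0.5 - cy)
  member <- outer(dy, dx, `+`) <= half_diag
  blue[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L)][member]
}

#' Colony size from one diamond window
#'
#' Counts the pixels in the window whose intensity is strictly greater than
#' 1.25 times the minimum intensity of the window; this count is the colony
#' size. The threshold is relative to the window's own minimum, so
#' uniformly dimming a window leaves the count unchanged and a uniform
#' (empty) window always scores zero.
#'
#' @param window one row of a [partition_plate()] table (or a list with
#'   `cx`, `cy`, `half_diag`).
#' @param blue intensity matrix from [blue_channel()].
#' @return A list: `pixel_count`, `window_min`, `n_pixels` (window area in
#'   pixels; `pixel_count` is `NA` for a window empty after clipping).
#' @export
colony_size <- function(window, blue) {
  vals <- window_pixels(blue, window$cx, window$cy, window$half_diag)
  if (length(vals) == 0L) {
    return(list(pixel_count = NA_integer_, window_min = NA_real_,
                n_pixels = 0L))
  }
  m <- min(vals)
  list(pixel_count = sum(vals > 1.25 * m), window_min = m,
       n_pixels = length(vals))
}

#' Quantify every spot on a plate
#'
#' Partitions the image with the layout's grid dimensions, measures every
#' window with [colony_size()], and joins the strain identities from the
#' layout.
#'
#' @param image a [plate_image()].
#' @param layout plate layout matching the image's grid.
#' @return A tibble: `row`, `col`, `strain_id`, `is_edge`, `pixel_count`,
#'   `window_min`.
#' @export
quantify_plate <- function(image, layout) {
  n_rows <- attr(layout, "n_rows"); n_cols <- attr(layout, "n_cols")
  needed <- c("row", "col", "strain_id", "is_edge")
  if (is.null(n_rows) || is.null(n_cols) ||
      !all(needed %in% names(layout))) {
    stop("layout does not describe the partition grid (dimensions or ",
         "columns missing)", call. = FALSE)
  }
  windows <- partition_plate(image, n_rows, n_cols)
  blue <- blue_channel(image)
  counts <- integer(nrow(windows)); mins <- numeric(nrow(windows))
  cx <- windows$cx; cy <- windows$cy; hd <- windows$half_diag
  for (i in seq_len(nrow(windows))) {
    m <- colony_size(list(cx = cx[i], cy = cy[i], half_diag = hd[i]), blue)
    counts[i] <- m$pixel_count; mins[i] <- m$window_min
  }
  windows$pixel_count <- counts
  windows$window_min <- mins
  out <- dplyr::inner_join(
    layout[, c("row", "col", "strain_id", "is_edge")],
    windows[, c("row", "col", "pixel_count", "window_min")],
    by = c("row", "col")
  )
  if (nrow(out) != nrow(layout)) {
    stop("layout grid does not match the image partition", call. = FALSE)
  }
  out
}
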