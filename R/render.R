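#' Render a synthetic colony-array plate image
#'
#' Draws the plate photograph the quantification stage consumes: one filled
#' disc per spot, centred in that spot's diamond window, with radius
#' proportional to the strain's relative growth (untreated: fitness;
#' treated: fitness reduced by drug inhibition). The signal is carried on
#' the blue channel over a uniform background. Border colonies are enlarged
#' by the edge-effect boost; on treated plates, spontaneous suppressor
#' colonies (full-size discs on susceptible spots) are planted at a Poisson
#' rate. The per-spot true disc pixel counts are returned so quantification
#' can be tested against planted truth.
#'
#' @param layout plate layout (test or master grid).
#' @param truth truth table from [truth_table()].
#' @param params [sim_params()].
#' @param treated logical; `TRUE` renders the drug plate.
#' @return A list with elements `image` (a `plate_image`) and `truth_sizes`
#'   (tibble: `row`, `col`, `strain_id`, `radius_px`, `true_pixels`,
#'   `suppressor`).
#' @export
render_plate_image <- function(layout, truth, params = sim_params(),
                               treated = FALSE) {
  dims <- layout_dims(layout)
  w <- params$window_px
  if (w * sqrt(2) < 8) {
    stop("geometry too small: window diagonal under 8 pixels", call. = FALSE)
  }
  n_rows <- dims[["n_rows"]]; n_cols <- dims[["n_cols"]]
  W <- as.integer(ceiling(n_cols * w)); H <- as.integer(ceiling(n_rows * w))
  set.seed(derive_seed(params$rng_seed,
                       if (treated) "render_treated" else "render_control"))

  jit <- function() stats::runif(2, -params$corner_jitter, params$corner_jitter)
  corners <- rbind(
    tl = c(0, 0) + jit(), tr = c(n_cols * w, 0) + jit(),
    bl = c(0, n_rows * w) + jit(), br = c(n_cols * w, n_rows * w) + jit()
  )
  colnames(corners) <- c("x", "y")

  uv <- cbind((layout$col - 0.5) / n_cols, (layout$row - 0.5) / n_rows)
  centers <- bilinear_centers(corners, uv)

  score <- growth_score(truth, layout$strain_id, treated)
  score[layout$is_edge] <- score[layout$is_edge] * params$edge_boost
  radius <- params$colony_radius_frac * w * score
  # a disc centred in a diamond of half-diagonal w/2 stays inside it while
  # r <= (w/2)/sqrt(2); cap so boosted colonies never bleed into neighbours
  radius <- pmin(radius, 0.99 * (w / 2) / sqrt(2))

  suppressor <- rep(FALSE, nrow(layout))
  if (treated && params$suppressor_rate > 0) {
    n_sup <- stats::rpois(1, params$suppressor_rate)
    candidates <- which(!layout$is_edge & score < 0.5)
    if (n_sup > 0 && length(candidates) > 0) {
      picked <- sample(candidates, min(n_sup, length(candidates)))
      suppressor[picked] <- TRUE
      radius[picked] <- params$colony_radius_frac * w
    }
  }

  blue <- matrix(params$bg_level, nrow = H, ncol = W)
  true_pixels <- integer(nrow(layout))
  half_diag <- w / 2
  for (i in seq_len(nrow(layout))) {
    r <- radius[i]
    if (r <= 0) next
    cx <- centers[i, 1]; cy <- centers[i, 2]
    x0 <- max(0L, as.integer(floor(cx - r - 1))); x1 <- min(W - 1L, as.integer(ceiling(cx + r)))
    y0 <- max(0L, as.integer(floor(cy - r - 1))); y1 <- min(H - 1L, as.integer(ceiling(cy + r)))
    if (x1 < x0 || y1 < y0) next
    px <- (x0:x1) + 0.5; py <- (y0:y1) + 0.5
    dx <- px - cx; dy <- py - cy
    disc <- outer(dy^2, dx^2, `+`) <= r^2            # rows = y, cols = x
    diamond <- outer(abs(dy), abs(dx), `+`) <= half_diag
    blue[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L)][disc] <- params$fg_level
    true_pixels[i] <- sum(disc & diamond)
  }

  if (params$noise_sd > 0) {
    blue <- blue * (1 + matrix(stats::rnorm(H * W, 0, params$noise_sd), H, W))
  }
  blue <- pmin(pmax(round(blue), 0), 255)
  pixels <- array(0L, dim = c(H, W, 3L))
  pixels[, , 1] <- as.integer(round(blue * 0.30))
  pixels[, , 2] <- as.integer(round(blue * 0.55))
  pixels[, , 3] <- as.integer(blue)

  list(
    image = plate_image(pixels, corners),
    truth_sizes = tibble::tibble(
      row = layout$row, col = layout$col, strain_id = layout$strain_id,
      radius_px = radius, true_pixels = true_pixels, suppressor = suppressor
    )
  )
}

# Bilinear interpolation of points (u, v) in [0,1]^2 between four corners
# (rows tl, tr, bl, br; columns x, y).
bilinear_centers <- function(corners, uv) {
  u <- uv[, 1]; v <- uv[, 2]
  x <- (1 - u) * (1 - v) * corners["tl", "x"] + u * (1 - v) * corners["tr", "x"] +
    (1 - u) * v * corners["bl", "x"] + u * v * corners["br", "x"]
  y <- (1 - u) * (1 - v) * corners["tl", "y"] + u * (1 - v) * corners["tr", "y"] +
    (1 - u) * v * corners["bl", "y"] + u * v * corners["br", "y"]
  cbind(x = x, y = y)
}

#' Write a plate image to PNG or JPEG
#'
#' PNG output is lossless and is what exact tests rely on; JPEG mirrors the
#' capture format of gel-documentation systems (requires the EBImage
#' package).
#'
#' @param img a `plate_image`.
#' @param path output path ending in `.png`, `.jpg` or `.jpeg`.
#' @param quality JPEG quality (0-100), ignored for PNG.
#' @return `path`, invisibly.
#' @export
write_plate_image <- function(img, path, quality = 90) {
  arr <- img$pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(arr, target = path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("JPEG output requires the EBImage package", call. = FALSE)
    }
    EBImage::writeImage(EBImage::Image(aperm(arr, c(2, 1, 3)),
                                       colormode = "Color"),
                        path, quality = quality)
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read a plate image from PNG or JPEG
#'
#' @param path image path.
#' @param corners 4 x 2 matrix of grid-corner pixel coordinates (rows
#'   `tl`, `tr`, `bl`, `br`; columns x, y), as identified for the plate.
#' @return A `plate_image`.
#' @export
read_plate_image <- function(path, corners) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("JPEG input requires the EBImage package", call. = FALSE)
    }
    arr <- aperm(EBImage::imageData(EBImage::readImage(path)), c(2, 1, 3))
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  plate_image(array(as.integer(round(arr * 255)), dim = dim(arr)), corners)
}
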