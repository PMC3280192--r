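test_that("blue channel extraction follows the stated channel conventions", {
  px <- array(0L, dim = c(2, 2, 3))
  px[, , 1] <- 10L; px[, , 2] <- 20L; px[, , 3] <- 30L
  corners <- rbind(tl = c(0, 0), tr = c(2, 0), bl = c(0, 2), br = c(2, 2))
  expect_true(all(blue_channel(plate_image(px, corners)) == 30L))

  gray <- array(77L, dim = c(2, 2, 1))
  expect_message(b <- blue_channel(plate_image(gray, corners)), "single")
  expect_true(all(b == 77L))

  rgba <- array(5L, dim = c(2, 2, 4)); rgba[, , 3] <- 99L
  expect_true(all(blue_channel(plate_image(rgba, corners)) == 99L))

  two <- array(1L, dim = c(2, 2, 2))
  expect_error(blue_channel(plate_image(two, corners)), "channel")
})

test_that("window size is the larger of width/cols and length/rows", {
  corners <- function(w, h) rbind(tl = c(0, 0), tr = c(w, 0),
                                  bl = c(0, h), br = c(w, h))
  expect_equal(window_size(corners(1600, 1152), 24, 32), 50)
  expect_equal(window_size(corners(960, 1200), 24, 32), 50)
  expect_equal(window_size(corners(300, 300), 10, 10), 30)
  # no rounding: fractional sizes are preserved
  expect_equal(window_size(corners(100, 90), 3, 3), 100 / 3)
  degenerate <- rbind(tl = c(5, 5), tr = c(5, 5), bl = c(5, 5), br = c(5, 5))
  expect_error(window_size(degenerate, 2, 2), "degenerate")
})

test_that("partition produces one diamond per grid position", {
  blue <- matrix(0L, nrow = 24 * 14, ncol = 32 * 14)
  img <- as_plate(blue)
  w <- partition_plate(img, 24, 32)
  expect_equal(nrow(w), 768L)
  expect_equal(unique(w$half_diag), 7)
  # a single window spanning the whole plate overhangs the image vertically
  expect_warning(one <- partition_plate(img, 1, 1), "clipped")
  expect_equal(nrow(one), 1L)
  expect_equal(unname(c(one$cx, one$cy)),
               c(ncol(blue) / 2, nrow(blue) / 2))
})

test_that("adjacent diamonds at lattice spacing share no pixel", {
  # one bright pixel swept across the boundary between two windows must be
  # counted by exactly one of them
  win_a <- list(cx = 10, cy = 10, half_diag = 5)
  win_b <- list(cx = 20, cy = 10, half_diag = 5)
  for (x in 13:17) {
    for (y in c(8, 10, 12)) {
      blue <- matrix(10, nrow = 20, ncol = 40)
      blue[y + 1, x + 1] <- 200
      counted <- c(colony_size(win_a, blue)$pixel_count,
                   colony_size(win_b, blue)$pixel_count)
      expect_lte(sum(counted), 1L)
      in_either <- abs(x + 0.5 - 10) + abs(y + 0.5 - 10) <= 5 ||
        abs(x + 0.5 - 20) + abs(y + 0.5 - 10) <= 5
      expect_equal(sum(counted), as.integer(in_either))
    }
  }
})

test_that("colony size counts pixels strictly above 1.25 x window minimum", {
  blue <- matrix(80, nrow = 10, ncol = 10)
  win <- list(cx = 5, cy = 5, half_diag = 3)
  expect_equal(colony_size(win, blue)$pixel_count, 0L)  # uniform window

  # set all member pixels to 100, then three of them to 130:
  # threshold 125 forces a count of exactly 3
  blue2 <- matrix(100, nrow = 10, ncol = 10)
  blue2[5, 5] <- 130; blue2[5, 6] <- 130; blue2[6, 5] <- 130
  m <- colony_size(win, blue2)
  expect_equal(m$pixel_count, 3L)
  expect_equal(m$window_min, 100)

  # a window that clips to nothing is flagged missing
  off <- colony_size(list(cx = -50, cy = -50, half_diag = 2), blue)
  expect_true(is.na(off$pixel_count))
})

test_that("colony size matches the brute-force oracle on rendered plates", {
  cat_ <- toy_catalog(15)
  lay <- build_test_layout(build_master_layout(cat_))
  truth <- truth_table(cat_, resistant = "G003")
  p <- sim_params(noise_sd = 0, suppressor_rate = 0)
  r <- render_plate_image(lay, truth, p, treated = TRUE)
  blue <- blue_channel(r$image)
  wins <- partition_plate(r$image, 24, 32)
  idx <- seq(1, nrow(wins), by = 7)  # a systematic sample of windows
  for (i in idx) {
    expect_equal(
      colony_size(wins[i, ], blue)$pixel_count,
      brute_force_colony_size(blue, wins$cx[i], wins$cy[i],
                              wins$half_diag[i])
    )
  }
})

test_that("counts respond monotonically to brightening and ignore dimming", {
  blue <- matrix(100, nrow = 12, ncol = 12)
  blue[6, 6] <- 180; blue[6, 7] <- 180
  win <- list(cx = 6, cy = 6, half_diag = 4)
  base <- colony_size(win, blue)$pixel_count
  for (delta in c(10, 60, 200)) {
    brighter <- blue; brighter[7, 6] <- 100 + delta
    expect_gte(colony_size(win, brighter)$pixel_count, base)
  }
  # multiplying the whole window by k > 0 leaves the relative threshold,
  # and hence the count, unchanged
  for (k in c(0.5, 2, 3.7)) {
    expect_equal(colony_size(win, blue * k)$pixel_count, base)
  }
})

test_that("quantification is translation-equivariant and deterministic", {
  cat_ <- toy_catalog(6)
  lay <- build_test_layout(build_master_layout(cat_))
  p <- sim_params(noise_sd = 0, suppressor_rate = 0)
  truth <- truth_table(cat_, resistant = "G002")
  r <- render_plate_image(lay, truth, p, treated = TRUE)
  q1 <- quantify_plate(r$image, lay)
  q2 <- quantify_plate(r$image, lay)
  expect_identical(q1, q2)

  # embed the image at an integer offset and shift the corners to match
  off <- c(11L, 17L)  # x, y
  d <- dim(r$image$pixels)
  big <- array(0L, dim = c(d[1] + 40L, d[2] + 40L, 3L))
  big[off[2] + seq_len(d[1]), off[1] + seq_len(d[2]), ] <- r$image$pixels
  shifted <- plate_image(big, sweep(r$image$corners, 2, off, `+`))
  q3 <- quantify_plate(shifted, lay)
  expect_equal(q3$pixel_count, q1$pixel_count)

  # a blank plate yields zero everywhere
  blank <- as_plate(matrix(57L, nrow = 24 * 14, ncol = 32 * 14))
  qb <- quantify_plate(blank, lay)
  expect_true(all(qb$pixel_count == 0L))
  expect_error(quantify_plate(r$image, lay[, c("row", "col", "strain_id")]),
               "grid")
})

test_that("counts never exceed the window area", {
  set.seed(404)
  blue <- matrix(sample(0:255, 400, replace = TRUE), nrow = 20)
  for (hd in c(2, 4.5, 7)) {
    m <- colony_size(list(cx = 10, cy = 10, half_diag = hd), blue)
    expect_gte(m$pixel_count, 0L)
    expect_lte(m$pixel_count, m$n_pixels)
  }
})
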