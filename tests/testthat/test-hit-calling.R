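test_that("replicate medians are robust to a single suppressor colony", {
  expect_equal(replicate_median(c(120, 122, 125, 400)), 123.5)
  expect_equal(replicate_median(c(50, 50, 50, 50)), 50)
  expect_message(m <- replicate_median(c(10, 20, 30), "x"), "3 of 4")
  expect_equal(m, 20)
  expect_true(is.na(replicate_median(c(NA_real_, NA_real_))))
})

test_that("edge exclusion removes exactly the 108 border spots", {
  lay <- build_test_layout(build_master_layout(default_strain_catalog()))
  meas <- tibble::tibble(row = lay$row, col = lay$col, pixel_count = 1)
  kept <- exclude_edges(lay, meas)
  expect_equal(nrow(kept), 660L)
  interior_only <- meas[!lay$is_edge, ]
  expect_equal(nrow(exclude_edges(lay, interior_only)), 660L)
})

test_that("edge exclusion changes plate statistics on boosted plates", {
  cat_ <- toy_catalog(10)
  lay <- build_test_layout(build_master_layout(cat_))
  truth <- truth_table(cat_, resistant = "G001")
  p <- sim_params(rng_seed = 21, edge_boost = 2)
  r <- render_plate_image(lay, truth, p, treated = FALSE)
  q <- quantify_plate(r$image, lay)
  with_edges <- sd(q$pixel_count)
  without <- sd(exclude_edges(lay, q)$pixel_count)
  expect_false(isTRUE(all.equal(with_edges, without)))
})

test_that("scores are 100 x drug median over control median", {
  d <- tibble::tibble(strain_id = c("a", "b", "c"),
                      median_size = c(60, 120, 10))
  c_ <- tibble::tibble(strain_id = c("a", "b", "c"),
                       median_size = c(120, 120, 0))
  s <- normalize_scores(d, c_)
  expect_equal(s$score[s$strain_id == "a"], 50)
  expect_equal(s$score[s$strain_id == "b"], 100)
  expect_equal(attr(s, "excluded"), "c")  # zero control median
  s2 <- normalize_scores(c_, c_)
  expect_true(all(s2$score == 100))
  expect_error(normalize_scores(d, tibble::tibble(strain_id = "z",
                                                  median_size = 1)),
               "shared")
})

test_that("SD thresholds call the outlier in the worked example", {
  scores <- tibble::tibble(
    strain_id = sprintf("s%02d", 1:60),
    median_drug = 1, median_control = 1,
    score = c(rep(100, 59), 190)
  )
  calls <- call_hits(scores, resistant_sd = 3)
  m <- mean(scores$score); s <- sd(scores$score)
  expect_equal(m, 101.5)
  expect_equal(s, sqrt((59 * 1.5^2 + 88.5^2) / 59))
  expect_equal(calls$z[60], (190 - m) / s)
  expect_gt(calls$z[60], 3)
  expect_equal(calls$call[60], "resistant")
  expect_true(all(calls$call[1:59] == "none"))
})

test_that("borderline strains shift calls between the 3 and 2.5 SD menus", {
  base <- c(rep(95, 20), rep(100, 20), rep(105, 19))
  # search for an outlier value whose z lands strictly between 2.5 and 3
  v <- NA
  for (cand in seq(110, 200, by = 0.5)) {
    x <- c(base, cand)
    z <- (cand - mean(x)) / sd(x)
    if (z > 2.5 && z < 3) { v <- cand; break }
  }
  expect_false(is.na(v))
  scores <- tibble::tibble(strain_id = sprintf("s%02d", 1:60),
                           median_drug = 1, median_control = 1,
                           score = c(base, v))
  at3 <- call_hits(scores, resistant_sd = 3)
  at25 <- call_hits(scores, resistant_sd = 2.5)
  expect_equal(at3$call[60], "none")
  expect_equal(at25$call[60], "resistant")
})

test_that("calls are invariant under affine rescaling of the scores", {
  set.seed(77)
  scores <- tibble::tibble(strain_id = sprintf("s%03d", 1:80),
                           median_drug = 1, median_control = 1,
                           score = c(rnorm(78, 100, 8), 160, 40))
  ref <- call_hits(scores, resistant_sd = 3)
  for (k in c(0.2, 3)) {
    for (shift in c(-30, 0, 250)) {
      tr <- scores; tr$score <- k * tr$score + shift
      got <- call_hits(tr, resistant_sd = 3)
      expect_equal(got$call, ref$call)
      expect_equal(got$z, ref$z)
    }
  }
})

test_that("resistant sets nest as the threshold is relaxed", {
  set.seed(31)
  for (rep in 1:5) {
    scores <- tibble::tibble(strain_id = sprintf("s%03d", 1:100),
                             median_drug = 1, median_control = 1,
                             score = rlnorm(100, log(100), 0.3))
    r3 <- scores$strain_id[call_hits(scores, 3)$call == "resistant"]
    r25 <- scores$strain_id[call_hits(scores, 2.5)$call == "resistant"]
    r2 <- scores$strain_id[call_hits(scores, 2)$call == "resistant"]
    expect_true(all(r3 %in% r25))
    expect_true(all(r25 %in% r2))
  }
})

test_that("sensitive strains are flagged below -2.5 SD", {
  scores <- tibble::tibble(strain_id = sprintf("s%02d", 1:60),
                           median_drug = 1, median_control = 1,
                           score = c(rep(100, 59), 5))
  calls <- call_hits(scores)
  expect_equal(calls$call[60], "sensitive")
})

test_that("degenerate plates make no calls and warn", {
  scores <- tibble::tibble(strain_id = c("a", "b", "c"),
                           median_drug = 1, median_control = 1,
                           score = c(100, 100, 100))
  expect_warning(calls <- call_hits(scores), "degenerate")
  expect_true(all(calls$call == "none"))
  expect_error(call_hits(scores[1:2, ]), "at least 3")
  expect_warning(call_hits(tibble::tibble(strain_id = letters[1:4],
                                          median_drug = 1,
                                          median_control = 1,
                                          score = c(1, 2, 3, 9)),
                           resistant_sd = 4),
                 "non-standard")
})
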