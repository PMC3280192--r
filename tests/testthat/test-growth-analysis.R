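exp_curve <- function(mu, n0 = 0.05, blank = 0.08, hours = 10) {
  t <- seq(0, hours * 60, by = 10)
  tibble::tibble(time_min = t, od600 = n0 * exp(mu * t / 60) + blank)
}

test_that("mu_max recovers a pure exponential rate exactly", {
  cv <- exp_curve(0.30)
  est <- mu_max(cv, blank = 0.08)
  expect_equal(est$mu_max, 0.30, tolerance = 1e-9)
  expect_equal(est$r_squared, 1, tolerance = 1e-9)
  expect_true(est$window[["start_min"]] >= min(cv$time_min))
  expect_true(est$window[["end_min"]] <= max(cv$time_min))
})

test_that("mu_max handles flat, short and synthetic logistic curves", {
  flat <- tibble::tibble(time_min = seq(0, 600, 10), od600 = 0.09)
  expect_equal(mu_max(flat)$mu_max, 0)
  expect_error(mu_max(flat[1:3, ], window_points = 5), "at least 5")
  p <- sim_params()
  cv <- simulate_growth_curve(0.35, 0, p, noise = FALSE)
  est <- mu_max(cv, blank = p$blank_od)
  expect_equal(est$mu_max, 0.35, tolerance = 0.05)
})

test_that("subtracting the full first reading biases the estimate upward", {
  # documents why a measured media blank is preferred when available
  p <- sim_params()
  cv <- simulate_growth_curve(0.35, 0, p, noise = FALSE)
  naive <- mu_max(cv, blank = "first")$mu_max
  expect_gt(naive, 0.35)
})

test_that("mu_max never rises with drug concentration on noiseless families", {
  p <- sim_params(ic50_uM = 10, hill_h = 1.5)
  mus <- vapply(c(0, 2, 5, 10, 20, 50), function(cc) {
    mu_max(simulate_growth_curve(0.35, cc, p, noise = FALSE),
           blank = p$blank_od)$mu_max
  }, numeric(1))
  expect_true(all(diff(mus) <= 1e-12))
})

test_that("dose-response summarizes replicates with mean and SEM", {
  mk <- function(mu, cc, rep) {
    cv <- exp_curve(mu); cv$conc_uM <- cc; cv$replicate <- rep; cv
  }
  curves <- dplyr::bind_rows(
    mk(0.30, 0, 1), mk(0.32, 0, 2), mk(0.34, 0, 3),
    mk(0.10, 5, 1), mk(0.10, 5, 2), mk(0.10, 5, 3)
  )
  dr <- dose_response(curves, blank = 0.08)
  expect_equal(dr$conc_uM, c(0, 5))
  expect_equal(dr$mu_max[1], 0.32, tolerance = 1e-9)
  expect_equal(dr$se[1], sd(c(0.30, 0.32, 0.34)) / sqrt(3),
               tolerance = 1e-6)
  expect_equal(dr$se[2], 0, tolerance = 1e-9)
  expect_error(dose_response(curves[curves$conc_uM > 0, ]),
               "including 0")
})

test_that("ic_level inverts exact Hill dose-responses to machine precision", {
  cases <- expand.grid(ic50 = c(3, 10, 40), h = c(1, 1.5, 2.8),
                       level = c(0.5, 0.9))
  for (i in seq_len(nrow(cases))) {
    ic50 <- cases$ic50[i]; h <- cases$h[i]; level <- cases$level[i]
    conc <- sort(unique(c(0, ic50 * 4^seq(-2, 2.5, by = 0.5))))
    dr <- tibble::tibble(conc_uM = conc,
                         mu_max = 0.4 / (1 + (conc / ic50)^h),
                         se = 0, n = 3)
    est <- ic_level(dr, level = level)
    expect_equal(est$method, "hill_fit")
    expect_equal(est$concentration, ic50 * (level / (1 - level))^(1 / h),
                 tolerance = 1e-6)
  }
})

test_that("ic_level refuses unreachable or nonsense levels", {
  dr <- tibble::tibble(conc_uM = c(0, 1, 2, 4),
                       mu_max = 0.4 / (1 + (c(0, 1, 2, 4) / 10)),
                       se = 0, n = 1)
  expect_error(ic_level(dr, level = 0.9), "not bracketed")
  expect_error(ic_level(dr, level = 0), "strictly between")
  expect_error(ic_level(dr, level = 1.1), "strictly between")
  no_zero <- dr[dr$conc_uM > 0, ]
  expect_error(ic_level(no_zero), "zero-concentration")
})

test_that("IC90 is recovered within 10% median error from noisy panels", {
  p <- sim_params(ic50_uM = 10, hill_h = 1.5, od_noise_sd = 0.05)
  true_ic90 <- 10 * 9^(1 / 1.5)
  concs <- c(0, 1, 2, 5, 10, 20, 50, 100)
  rel_err <- vapply(1:50, function(seed) {
    curves <- dplyr::bind_rows(lapply(concs, function(cc) {
      dplyr::bind_rows(lapply(1:3, function(r) {
        pp <- p
        pp$rng_seed <- seed * 10000L + round(cc) * 10L + r
        cv <- simulate_growth_curve(0.35, cc, pp)
        cv$replicate <- r
        cv
      }))
    }))
    est <- ic_level(dose_response(curves, window_points = "auto",
                                  blank = p$blank_od), 0.9)
    abs(est$concentration - true_ic90) / true_ic90
  }, numeric(1))
  expect_lt(median(rel_err), 0.10)
})

test_that("the log-linear band fit matches windowed estimates on clean curves", {
  p <- sim_params()
  for (mu in c(0.1, 0.35)) {
    cv <- simulate_growth_curve(mu, 0, p, noise = FALSE)
    expect_equal(mu_max(cv, "auto", blank = p$blank_od)$mu_max, mu,
                 tolerance = 1e-9)
    expect_equal(mu_max(cv, 5, blank = p$blank_od)$mu_max, mu,
                 tolerance = 1e-9)
  }
  flat <- tibble::tibble(time_min = seq(0, 600, 10), od600 = 0.09)
  expect_equal(mu_max(flat, "auto")$mu_max, 0)
})

test_that("recovery fraction reports the protected growth fraction", {
  expect_equal(recovery_fraction(0.28, 0.35), 0.8)
  expect_equal(recovery_fraction(0.035, 0.35), 0.1)  # IC90, no competitor
  expect_equal(recovery_fraction(-0.01, 0.35), 0)    # clipped at zero
  expect_error(recovery_fraction(0.1, 0), "positive")
  # closed-form composite: Hill rate at the protected concentration
  p <- sim_params(ic50_uM = 10, hill_h = 1.5, ks_uM = 5)
  ic90 <- 10 * 9^(1 / 1.5)
  comp <- c(0, 1, 5, 20, 100, 500)
  rec <- recovery_fraction(
    0.35 / (1 + (apply_protection(ic90, comp, 5) / 10)^1.5), 0.35
  )
  expect_equal(rec[1], 0.1, tolerance = 1e-12)
  expect_true(all(diff(rec) > 0))
  expect_gt(rec[length(rec)], 0.95)
})

test_that("final OD reports blank-subtracted yield", {
  t <- seq(0, 600, 10)
  cv <- tibble::tibble(time_min = t,
                       od600 = c(0.1, seq(0.1, 1.0, length.out = 60)))
  expect_equal(final_od(cv), 0.9)
  mono <- tibble::tibble(time_min = t, od600 = seq(0.08, 0.8, length.out = 61))
  expect_equal(final_od(mono), max(mono$od600) - mono$od600[1])
  expect_equal(final_od(mono[0, ]), 0)
})
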