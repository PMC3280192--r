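#' Maximum specific growth rate from an OD600 time series
#'
#' The blank is subtracted (first reading, or a supplied media blank) and
#' the blanked OD floored at a small positive epsilon before logging. Only
#' readings above the instrument detection floor carry usable rate
#' information; below it the signal is dominated by measurement noise.
#'
#' With a numeric `window_points` (default 5 samples, 50 minutes at
#' 10-minute sampling), the rate is taken from sliding windows: the window
#' maximizing the least-squares slope of ln(OD) versus time minus twice
#' its standard error is selected (a lower-confidence-bound rule that
#' ignores windows whose steepness is an artefact of noise and reduces to
#' the plain maximum slope on noiseless data) and its slope reported,
#' converted to per-hour.
#'
#' With `window_points = "auto"` the slope is fit over the whole detected
#' log-linear band instead: all samples above the detection floor and, for
#' curves that saturate well clear of the floor, below a tenth of the
#' saturation plateau (the early-exponential region). Short windows track
#' the instantaneous maximum on clean curves; the band fit pools hundreds
#' of samples and is the robust choice for noisy or strongly inhibited
#' cultures, whose windowed estimates are dominated by noise.
#'
#' If no sample clears the detection floor the culture never grew
#' measurably and the rate is 0.
#'
#' @param curve growth-curve tibble with `time_min` and `od600`.
#' @param window_points sliding-window length in samples (default 5, i.e.
#'   50 minutes at 10-minute sampling).
#' @param blank `"first"` (default) subtracts the first reading, or a
#'   numeric instrument blank measured from a medium-only well. Using the
#'   measured blank is preferred when available: subtracting the first
#'   reading also removes the inoculum biomass, which steepens ln(OD) just
#'   above the detection floor and biases the windowed maximum upward.
#' @param od_floor epsilon OD applied after blank subtraction.
#' @param detection_floor blanked OD below which readings are treated as
#'   below the instrument's reliable detection range (default 0.02 OD).
#' @return A list: `mu_max` (per hour), `window` (start/end time, min),
#'   `r_squared`.
#' @export
mu_max <- function(curve, window_points = 5, blank = "first",
                   od_floor = 1e-4, detection_floor = 0.02) {
  t_min <- curve$time_min
  b <- if (identical(blank, "first")) curve$od600[1] else as.numeric(blank)
  od <- curve$od600 - b
  od <- pmax(od, od_floor)
  n <- length(od)
  if (is.numeric(window_points) && n < window_points) {
    stop(sprintf("need at least %d samples, got %d", window_points, n),
         call. = FALSE)
  }
  y <- log(od)
  t_h <- t_min / 60
  detected <- od > detection_floor
  if (identical(window_points, "auto")) {
    k_est <- max(od)
    idx <- which(detected)
    if (k_est > 10 * detection_floor) {
      idx <- which(detected & od <= 0.1 * k_est)
    }
    if (length(idx) < 3L) idx <- which(detected)
    if (length(idx) < 3L) {
      return(list(mu_max = 0, window = c(start_min = NA_real_,
                                         end_min = NA_real_),
                  r_squared = NA_real_))
    }
    tc <- t_h[idx] - mean(t_h[idx]); yc <- y[idx] - mean(y[idx])
    sxx <- sum(tc^2); sxy <- sum(tc * yc); syy <- sum(yc^2)
    return(list(
      mu_max = max(sxy / sxx, 0),
      window = c(start_min = min(t_min[idx]), end_min = max(t_min[idx])),
      r_squared = if (syy > 0) sxy^2 / (sxx * syy) else 1
    ))
  }
  best <- list(score = -Inf, slope = NA_real_, i = NA_integer_,
               r2 = NA_real_)
  for (i in seq_len(n - window_points + 1L)) {
    idx <- i:(i + window_points - 1L)
    if (!all(detected[idx])) next
    tt <- t_h[idx]; yy <- y[idx]
    tc <- tt - mean(tt); yc <- yy - mean(yy)
    sxx <- sum(tc^2); sxy <- sum(tc * yc); syy <- sum(yc^2)
    slope <- sxy / sxx
    rss <- max(syy - sxy^2 / sxx, 0)
    se <- sqrt(rss / (window_points - 2) / sxx)
    score <- slope - 2 * se
    if (score > best$score) {
      r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 1
      best <- list(score = score, slope = slope, i = i, r2 = r2)
    }
  }
  if (is.na(best$i)) {
    # growth never cleared the detection floor
    return(list(mu_max = 0, window = c(start_min = NA_real_,
                                       end_min = NA_real_),
                r_squared = NA_real_))
  }
  list(
    mu_max = max(best$slope, 0),  # a declining culture has zero growth rate
    window = c(start_min = t_min[best$i],
               end_min = t_min[best$i + window_points - 1L]),
    r_squared = best$r2
  )
}

#' Dose-response profile of growth rate versus drug concentration
#'
#' Estimates the maximum specific growth rate for each replicate curve and
#' summarizes per concentration with the mean and the standard error over
#' replicates.
#'
#' @param curves long-format growth table (`conc_uM`, `replicate`,
#'   `time_min`, `od600`; one curve per conc x replicate).
#' @param window_points,blank passed to [mu_max()].
#' @return A tibble: `conc_uM`, `mu_max`, `se`, `n`, sorted by
#'   concentration.
#' @export
dose_response <- function(curves, window_points = 5, blank = "first") {
  concs <- sort(unique(curves$conc_uM))
  if (length(concs) < 2L || !0 %in% concs) {
    stop("dose-response needs >= 2 concentrations including 0", call. = FALSE)
  }
  if (!"replicate" %in% names(curves)) curves$replicate <- 1L
  rows <- lapply(concs, function(cc) {
    sub <- curves[curves$conc_uM == cc, ]
    mus <- vapply(split(sub, sub$replicate),
                  function(s) mu_max(s[order(s$time_min), ],
                                     window_points, blank = blank)$mu_max,
                  numeric(1))
    tibble::tibble(
      conc_uM = cc, mu_max = mean(mus),
      se = if (length(mus) > 1) stats::sd(mus) / sqrt(length(mus)) else 0,
      n = length(mus)
    )
  })
  dplyr::bind_rows(rows)
}

#' Inhibitory-concentration estimate from a dose-response profile
#'
#' Fits the Hill inhibition model `mu(c) = mu0 / (1 + (c/IC50)^h)` by
#' least squares, with `mu0` fixed at the zero-concentration growth rate
#' (stabilizing small panels), and inverts it at the requested level:
#' the IC90 (level 0.9) is the concentration reducing the wild-type rate
#' by 90%. If the fit fails, monotone interpolation of rate against
#' log-concentration is used instead. Estimates outside the measured
#' concentration range are refused rather than extrapolated.
#'
#' @param dr dose-response tibble from [dose_response()].
#' @param level inhibition level in (0, 1); default 0.9.
#' @return A list: `level`, `concentration` (uM), `method` (`"hill_fit"`
#'   or `"interpolation"`), and `mu0`, `ic50`, `hill_h` when fitted.
#' @export
ic_level <- function(dr, level = 0.9) {
  if (level <= 0 || level >= 1) {
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  }
  dr <- dr[order(dr$conc_uM), ]
  mu0 <- dr$mu_max[dr$conc_uM == 0]
  if (length(mu0) != 1L || mu0 <= 0) {
    stop("dose-response must include a positive zero-concentration rate",
         call. = FALSE)
  }
  target <- (1 - level) * mu0
  if (min(dr$mu_max) > target) {
    stop(sprintf(
      "level %.2f not bracketed: smallest observed rate is %.3g (target %.3g); extend the concentration range",
      level, min(dr$mu_max), target), call. = FALSE)
  }
  pos <- dr[dr$conc_uM > 0, ]
  fit <- tryCatch({
    frac <- pmin(pmax(pos$mu_max / mu0, 1e-9), 1 - 1e-9)
    lin <- stats::lm(log(1 / frac - 1) ~ log(pos$conc_uM))
    h0 <- unname(max(stats::coef(lin)[2], 0.2))
    ic50_0 <- unname(exp(-stats::coef(lin)[1] / h0))
    minpack.lm::nlsLM(
      mu_max ~ mu0 / (1 + (conc_uM / ic50)^h),
      data = pos,
      start = list(ic50 = ic50_0, h = h0),
      lower = c(1e-9, 0.05), control = minpack.lm::nls.lm.control(maxiter = 200)
    )
  }, error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    conc <- cf[["ic50"]] * (level / (1 - level))^(1 / cf[["h"]])
    method <- "hill_fit"
  } else {
    # monotone interpolation on log10 concentration
    lx <- log10(pos$conc_uM)
    conc <- 10^stats::approx(pos$mu_max, lx, xout = target, ties = mean)$y
    method <- "interpolation"
    cf <- c(ic50 = NA_real_, h = NA_real_)
  }
  if (!is.finite(conc) || conc > max(dr$conc_uM) || conc < 0) {
    stop(sprintf(
      "estimated concentration %.3g uM lies outside the measured range [0, %.3g]; refusing to extrapolate",
      conc, max(dr$conc_uM)), call. = FALSE)
  }
  list(level = level, concentration = unname(conc), method = method,
       mu0 = mu0, ic50 = unname(cf[["ic50"]]), hill_h = unname(cf[["h"]]))
}

#' Growth-rate recovery under competitive protection
#'
#' The fraction of the untreated growth rate recovered when the drug is
#' co-administered with the carrier's natural substrate. At the drug's IC90
#' with no competitor this is 0.10 by construction; under the shared-site
#' competitive model it rises monotonically toward 1 as the competitor
#' concentration grows.
#'
#' @param mu_drug_plus_competitor growth rate with drug + competitor, /h.
#' @param mu_untreated untreated growth rate, /h (> 0).
#' @return Recovery fraction (>= 0), vectorized.
#' @export
recovery_fraction <- function(mu_drug_plus_competitor, mu_untreated) {
  if (any(mu_untreated <= 0)) {
    stop("untreated growth rate must be positive", call. = FALSE)
  }
  pmax(mu_drug_plus_competitor / mu_untreated, 0)
}

#' Final optical density of a growth curve
#'
#' Blank-subtracted OD of the last sample. Final OD broadly equates to
#' biomass yield and can reveal resistance or protection that growth rate
#' misses (a culture may grow slowly yet reach a higher yield when
#' protected).
#'
#' @param curve growth-curve tibble with `time_min` and `od600`.
#' @return Final blank-subtracted OD600 (floored at 0).
#' @export
final_od <- function(curve) {
  if (nrow(curve) == 0L) return(0)
  od <- curve$od600[order(curve$time_min)]
  max(od[length(od)] - od[1], 0)
}
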