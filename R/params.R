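#' Simulation parameters
#'
#' One object collects every tunable of the synthetic-data generators:
#' plate-image geometry and colony intensity model, the edge and suppressor
#' artefact models, the pool-competition model, and the growth-curve /
#' Hill-inhibition / competitive-protection models. Defaults reproduce the
#' study conditions where stated (10-minute OD sampling, pool sampled at the
#' exit from exponential phase) and otherwise use values typical for
#' S. cerevisiae in minimal medium; rationale for each default is given in
#' the methods vignette.
#'
#' @param rng_seed integer seed; a fixed seed gives byte-identical outputs.
#' @param window_px pixels per grid window (spot pitch) in rendered images.
#' @param corner_jitter uniform jitter (pixels) applied to plate corners.
#' @param bg_level,fg_level blue-channel background / colony intensity
#'   (0-255).
#' @param noise_sd multiplicative Gaussian intensity noise (fraction).
#' @param colony_radius_frac colony radius at relative growth 1, as a
#'   fraction of `window_px`; kept small enough that a boosted edge colony
#'   still fits inside its diamond window.
#' @param edge_boost multiplicative size boost (> 1) for border colonies,
#'   emulating reduced nutrient competition at plate edges.
#' @param suppressor_rate expected number of spontaneous suppressor colonies
#'   per treated plate (Poisson).
#' @param mu_wt wild-type maximum specific growth rate, per hour.
#' @param pool_stop_factor pool competitions are integrated until total
#'   biomass reaches this multiple of the inoculum (sampling at the exit
#'   from exponential phase).
#' @param afu_scale total arbitrary-fluorescence units distributed across
#'   strains in a pool readout.
#' @param afu_sdlog log-normal readout noise (sdlog) on pool AFU.
#' @param lag_h growth-curve lag duration, hours.
#' @param od0 inoculum OD600 above blank.
#' @param carrying_od carrying capacity (final OD600 above blank).
#' @param blank_od instrument blank OD600.
#' @param sample_min OD sampling interval, minutes.
#' @param duration_h growth-curve duration, hours; long enough (3 days)
#'   for strongly inhibited cultures to clear the detection floor.
#' @param od_noise_sd multiplicative Gaussian OD noise (fraction).
#' @param ic50_uM,hill_h Hill inhibition model: growth rate under drug is
#'   `mu0 / (1 + (conc/ic50_uM)^hill_h)`.
#' @param ks_uM competitor binding constant for the shared-carrier
#'   competitive-protection model.
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(rng_seed = 1L,
                       window_px = 14,
                       corner_jitter = 0,
                       bg_level = 40,
                       fg_level = 200,
                       noise_sd = 0.05,
                       colony_radius_frac = 0.23,
                       edge_boost = 1.3,
                       suppressor_rate = 1,
                       mu_wt = 0.35,
                       pool_stop_factor = 100,
                       afu_scale = 5e5,
                       afu_sdlog = 0.1,
                       lag_h = 2,
                       od0 = 0.01,
                       carrying_od = 0.9,
                       blank_od = 0.08,
                       sample_min = 10,
                       duration_h = 72,
                       od_noise_sd = 0,
                       ic50_uM = 10,
                       hill_h = 1.5,
                       ks_uM = 5) {
  p <- list(
    rng_seed = as.integer(rng_seed), window_px = window_px,
    corner_jitter = corner_jitter, bg_level = bg_level,
    fg_level = fg_level, noise_sd = noise_sd,
    colony_radius_frac = colony_radius_frac, edge_boost = edge_boost,
    suppressor_rate = suppressor_rate, mu_wt = mu_wt,
    pool_stop_factor = pool_stop_factor, afu_scale = afu_scale,
    afu_sdlog = afu_sdlog, lag_h = lag_h, od0 = od0,
    carrying_od = carrying_od, blank_od = blank_od,
    sample_min = sample_min, duration_h = duration_h,
    od_noise_sd = od_noise_sd, ic50_uM = ic50_uM, hill_h = hill_h,
    ks_uM = ks_uM
  )
  positive <- c("window_px", "bg_level", "fg_level", "colony_radius_frac",
                "edge_boost", "mu_wt", "pool_stop_factor", "afu_scale",
                "od0", "carrying_od", "sample_min", "duration_h",
                "ic50_uM", "hill_h", "ks_uM")
  for (nm in positive) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0) {
      stop(sprintf("sim_params: '%s' must be a positive scalar", nm),
           call. = FALSE)
    }
  }
  nonneg <- c("corner_jitter", "noise_sd", "suppressor_rate", "afu_sdlog",
              "lag_h", "blank_od", "od_noise_sd")
  for (nm in nonneg) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0) {
      stop(sprintf("sim_params: '%s' must be a non-negative scalar", nm),
           call. = FALSE)
    }
  }
  if (p$pool_stop_factor <= 1) {
    stop("sim_params: pool_stop_factor must exceed 1 (stop biomass above inoculum)",
         call. = FALSE)
  }
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (seed ", x$rng_seed, ")\n", sep = "")
  cat("  image: ", x$window_px, " px/window, bg ", x$bg_level, ", fg ",
      x$fg_level, ", noise sd ", x$noise_sd, ", edge boost ",
      x$edge_boost, ", suppressor rate ", x$suppressor_rate, "\n", sep = "")
  cat("  pool: mu_wt ", x$mu_wt, "/h, stop x", x$pool_stop_factor,
      ", AFU scale ", x$afu_scale, ", sdlog ", x$afu_sdlog, "\n", sep = "")
  cat("  growth: lag ", x$lag_h, " h, K ", x$carrying_od, " OD, sample ",
      x$sample_min, " min; Hill IC50 ", x$ic50_uM, " uM, h ", x$hill_h,
      "; Ks ", x$ks_uM, " uM\n", sep = "")
  invisible(x)
}

# Derive a reproducible child seed (kept below 2^31) for a named substream.
derive_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + offs) %% 2147483563) + 1L
}
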