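#' Simulate a deletion-pool competition
#'
#' Models the batch co-culture of all catalog strains in one vessel, with
#' and without drug. Each strain grows exponentially,
#' `n_i(t) = n_i(0) * exp(mu_i * t)`, where `mu_i` is the wild-type rate
#' scaled by the strain's relative fitness and — in the treated arm —
#' reduced by its drug inhibition. Each arm is integrated until total
#' biomass reaches the stop multiple of the inoculum (sampling at the exit
#' from exponential phase), so arms with different compositions run for
#' different times, just as fermenter runtimes differ per treatment. The
#' barcode-array readout assigns each strain `AFU = scale * p_i * eps_i`,
#' with `p_i` its final proportion and `eps_i` log-normal readout noise.
#'
#' @param catalog strain catalog.
#' @param truth truth table giving per-strain fitness and drug inhibition.
#' @param params [sim_params()]; uses `mu_wt`, `pool_stop_factor`,
#'   `afu_scale`, `afu_sdlog`, `rng_seed`.
#' @param noise logical; `FALSE` disables readout noise.
#' @return A tibble: `strain_id`, `afu_untreated`, `afu_treated`, `ratio`
#'   (`NA` when `afu_untreated` is 0), `p_untreated`, `p_treated`
#'   (noise-free final proportions), `is_transporter`.
#' @export
simulate_pool <- function(catalog, truth, params = sim_params(),
                          noise = TRUE) {
  idx <- match(catalog$strain_id, truth$strain_id)
  if (anyNA(idx)) stop("truth table must cover the catalog", call. = FALSE)
  fitness <- truth$relative_fitness[idx]
  inhibition <- truth$drug_inhibition[idx]
  mu_untreated <- params$mu_wt * fitness
  mu_treated <- mu_untreated * (1 - inhibition)
  if (all(mu_untreated <= 0)) {
    stop("stagnant pool: no strain grows in the untreated arm", call. = FALSE)
  }
  if (all(mu_treated <= 0)) {
    stop("stagnant pool: no strain grows under drug", call. = FALSE)
  }
  n <- nrow(catalog)
  n0 <- rep(1 / n, n)  # equal initial proportions, unit inoculum biomass

  p_untreated <- as.vector(pool_final_proportions(n0, mu_untreated,
                                                  params$pool_stop_factor))
  p_treated <- as.vector(pool_final_proportions(n0, mu_treated,
                                                params$pool_stop_factor))

  set.seed(derive_seed(params$rng_seed, "pool"))
  eps_u <- if (noise) stats::rlnorm(n, 0, params$afu_sdlog) else rep(1, n)
  eps_t <- if (noise) stats::rlnorm(n, 0, params$afu_sdlog) else rep(1, n)
  afu_u <- params$afu_scale * p_untreated * eps_u
  afu_t <- params$afu_scale * p_treated * eps_t

  tibble::tibble(
    strain_id = catalog$strain_id,
    afu_untreated = afu_u,
    afu_treated = afu_t,
    ratio = ifelse(afu_u > 0, afu_t / afu_u, NA_real_),
    p_untreated = p_untreated,
    p_treated = p_treated,
    is_transporter = catalog$category == "transporter_mutant"
  )
}

# Final proportions of exponentially competing strains when total biomass
# first reaches stop_factor * sum(n0): solve sum(n0 * exp(mu * t)) = stop
# for t (monotone in t), then normalize.
pool_final_proportions <- function(n0, mu, stop_factor) {
  stop_biomass <- stop_factor * sum(n0)
  total <- function(t) sum(n0 * exp(mu * t)) - stop_biomass
  t_hi <- log(stop_factor) / max(mu)  # reached if everything grew at max mu
  while (total(t_hi) < 0) t_hi <- t_hi * 2
  t_star <- stats::uniroot(total, c(0, t_hi), tol = 1e-12)$root
  nf <- n0 * exp(mu * t_star)
  p <- nf / sum(nf)
  attr(p, "t_star") <- t_star
  p
}
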