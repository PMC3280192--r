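#' Planted-truth table for synthetic screens
#'
#' The truth table assigns each strain an untreated relative fitness (about
#' 1) and a drug inhibition: the fraction of its growth rate removed by the
#' drug. A deletion that removes the drug's uptake carrier leaves the strain
#' resistant (inhibition near 0) while strains with intact uptake are
#' strongly inhibited — the premise that resistance to a cytotoxic drug
#' flags the loss of its import route.
#'
#' @param catalog strain catalog.
#' @param resistant character vector of strain ids planted as resistant.
#' @param base_inhibition drug inhibition (0..1) of non-resistant strains.
#' @param resistant_inhibition inhibition of the planted resistant strains.
#' @param fitness untreated relative fitness (scalar or per-strain vector).
#' @return A tibble with columns `strain_id`, `relative_fitness`,
#'   `drug_inhibition`, `planted_call`.
#' @export
truth_table <- function(catalog, resistant = character(),
                        base_inhibition = 0.9, resistant_inhibition = 0,
                        fitness = 1) {
  stopifnot(all(resistant %in% catalog$strain_id))
  if (any(c(base_inhibition, resistant_inhibition) < 0) ||
      any(c(base_inhibition, resistant_inhibition) > 1)) {
    stop("drug inhibition must lie in [0, 1]", call. = FALSE)
  }
  n <- nrow(catalog)
  fitness <- rep_len(fitness, n)
  inhibition <- rep(base_inhibition, n)
  inhibition[catalog$strain_id %in% resistant] <- resistant_inhibition
  call <- rep("none", n)
  call[catalog$strain_id %in% resistant] <- "resistant"
  tibble::tibble(
    strain_id = catalog$strain_id,
    relative_fitness = fitness,
    drug_inhibition = inhibition,
    planted_call = call
  )
}

# Relative growth score of a strain on a plate: fitness, reduced by drug
# inhibition on treated plates.
growth_score <- function(truth, strain_ids, treated) {
  idx <- match(strain_ids, truth$strain_id)
  if (anyNA(idx)) {
    stop("layout contains strains absent from the truth table", call. = FALSE)
  }
  s <- truth$relative_fitness[idx]
  if (treated) s <- s * (1 - truth$drug_inhibition[idx])
  s
}
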