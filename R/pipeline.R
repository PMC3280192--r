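#' Run configuration for end-to-end screens
#'
#' Builds (or reads from YAML) the single configuration object the
#' orchestration functions consume. Threshold settings outside the
#' conventional menus (resistance at 3, 2.5 or 2 SD; enrichment ratio 2 or
#' 3) are accepted with a warning.
#'
#' @param path YAML config file, or `NULL` to build from arguments.
#' @param rng_seed integer seed recorded in every output header.
#' @param drug drug name label.
#' @param drug_conc_uM drug concentration on the treated plate, uM.
#' @param resistant_strains strain ids planted resistant (synthetic truth).
#' @param base_inhibition drug inhibition of non-resistant strains.
#' @param resistant_sd robot-screen resistance threshold (SD).
#' @param band_halfwidth pool noise-band halfwidth (AFU).
#' @param ratio_threshold pool enrichment ratio threshold.
#' @param params_overrides named list overriding [sim_params()] defaults.
#' @param out_dir directory for output files, or `NULL` to skip writing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(path = NULL, rng_seed = 1L, drug = "drug",
                       drug_conc_uM = NA_real_,
                       resistant_strains = character(),
                       base_inhibition = 0.9, resistant_sd = 3,
                       band_halfwidth = 1000, ratio_threshold = 3,
                       params_overrides = list(), out_dir = NULL) {
  cfg <- list(
    rng_seed = as.integer(rng_seed), drug = drug,
    drug_conc_uM = drug_conc_uM,
    resistant_strains = as.character(resistant_strains),
    base_inhibition = base_inhibition, resistant_sd = resistant_sd,
    band_halfwidth = band_halfwidth, ratio_threshold = ratio_threshold,
    params_overrides = params_overrides, out_dir = out_dir
  )
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    for (k in names(y)) cfg[[k]] <- y[[k]]
    cfg$rng_seed <- as.integer(cfg$rng_seed)
    cfg$resistant_strains <- as.character(cfg$resistant_strains)
    if (!is.null(cfg$out_dir) && !grepl("^/", cfg$out_dir)) {
      cfg$out_dir <- file.path(dirname(normalizePath(path)), cfg$out_dir)
    }
  }
  if (!cfg$resistant_sd %in% c(3, 2.5, 2)) {
    warning("resistance threshold outside the conventional menu {3, 2.5, 2}",
            call. = FALSE)
  }
  if (!cfg$ratio_threshold %in% c(2, 3)) {
    warning("enrichment ratio outside the conventional menu {2, 3}",
            call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

config_params <- function(cfg) {
  do.call(sim_params, c(list(rng_seed = cfg$rng_seed),
                        cfg$params_overrides))
}

config_meta <- function(cfg, ...) {
  c(list(rng_seed = cfg$rng_seed, drug = cfg$drug,
         resistant_sd = cfg$resistant_sd,
         band_halfwidth = cfg$band_halfwidth,
         ratio_threshold = cfg$ratio_threshold), list(...))
}

#' Run a synthetic robot-array screen end to end
#'
#' Simulate -> quantify -> call: builds the master and 768-spot test
#' layouts, renders a control and a drug plate from the planted truth,
#' quantifies both images, and calls resistant/sensitive strains against
#' the control. Deterministic given the config seed.
#'
#' @param cfg a [run_config()] (or a YAML path accepted by it).
#' @param catalog strain catalog; defaults to the packaged 111-strain
#'   panel.
#' @return A list: `layout`, `truth`, `measurements` (drug and control),
#'   `calls`, `truth_sizes`, `report` (text lines). Tables are written to
#'   `cfg$out_dir` when set.
#' @export
run_robot_screen <- function(cfg, catalog = default_strain_catalog()) {
  if (is.character(cfg)) cfg <- run_config(path = cfg)
  params <- config_params(cfg)
  master <- build_master_layout(catalog)
  layout <- build_test_layout(master)
  truth <- truth_table(catalog, resistant = cfg$resistant_strains,
                       base_inhibition = cfg$base_inhibition)
  control <- render_plate_image(layout, truth, params, treated = FALSE)
  treated <- render_plate_image(layout, truth, params, treated = TRUE)
  meas_control <- quantify_plate(control$image, layout)
  meas_drug <- quantify_plate(treated$image, layout)
  wt <- wildtype_id(catalog)
  calls <- score_plate(meas_drug, meas_control, layout,
                       resistant_sd = cfg$resistant_sd, wildtype = wt)
  census <- attr(calls, "threshold_census")
  report <- c(
    sprintf("robot screen: drug %s, seed %d", cfg$drug, cfg$rng_seed),
    sprintf("spots measured: %d (%d interior)", nrow(layout),
            sum(!layout$is_edge)),
    sprintf("edge spots excluded: %d", sum(layout$is_edge)),
    sprintf("strains excluded (unnormalizable): %s",
            paste(attr(calls, "excluded"), collapse = ", ")),
    sprintf("resistance threshold: %s SD; sensitive: 2.5 SD",
            cfg$resistant_sd),
    sprintf("resistant calls at 3/2.5/2 SD: %d/%d/%d",
            census[["sd3"]], census[["sd2.5"]], census[["sd2"]]),
    sprintf("suppressor colonies planted: %d",
            sum(treated$truth_sizes$suppressor)),
    sprintf("resistant calls made (non-control): %d",
            sum(calls$call == "resistant" & !calls$is_control))
  )
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_with_meta(calls, file.path(cfg$out_dir, "robot_calls.tsv"),
                        config_meta(cfg, stage = "robot_screen"))
    writeLines(report, file.path(cfg$out_dir, "robot_report.txt"))
  }
  list(layout = layout, truth = truth,
       measurements = list(drug = meas_drug, control = meas_control),
       calls = calls, truth_sizes = treated$truth_sizes, report = report)
}

#' Run a synthetic pool-competition screen
#'
#' Simulates the treated and untreated pool competitions from the planted
#' truth, normalizes the AFU readouts, and calls enrichment with the
#' configured band and ratio thresholds.
#'
#' @inheritParams run_robot_screen
#' @return A list: `profiles`, `calls` (transporter-annotated), `report`.
#' @export
run_pool_screen <- function(cfg, catalog = default_strain_catalog()) {
  if (is.character(cfg)) cfg <- run_config(path = cfg)
  params <- config_params(cfg)
  truth <- truth_table(catalog, resistant = cfg$resistant_strains,
                       base_inhibition = cfg$base_inhibition)
  profiles <- simulate_pool(catalog, truth, params)
  scaled <- normalize_afu(profiles$afu_untreated, profiles$afu_treated)
  profiles$afu_untreated <- scaled[[1]]
  profiles$afu_treated <- scaled[[2]]
  calls <- call_enrichment(profiles, band_halfwidth = cfg$band_halfwidth,
                           ratio_threshold = cfg$ratio_threshold)
  calls <- annotate_transporters(calls, catalog)
  s <- attr(calls, "summary")
  report <- c(
    sprintf("pool screen: drug %s, seed %d", cfg$drug, cfg$rng_seed),
    sprintf("normalization: total_sum"),
    sprintf("band halfwidth: %s AFU; ratio threshold: %s",
            cfg$band_halfwidth, cfg$ratio_threshold),
    sprintf("enriched transporter strains: %d; other: %d",
            s[["enriched_transporter"]], s[["enriched_other"]])
  )
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_with_meta(calls, file.path(cfg$out_dir, "pool_calls.tsv"),
                        config_meta(cfg, stage = "pool_screen",
                                    normalization = "total_sum"))
    writeLines(report, file.path(cfg$out_dir, "pool_report.txt"))
  }
  list(profiles = profiles, calls = calls, report = report)
}

#' Run a synthetic growth-curve validation experiment
#'
#' Simulates replicate growth curves over a concentration series, builds
#' the dose-response profile, estimates the inhibitory concentration at
#' the requested level (default IC90), and sweeps competitor
#' concentrations at that IC to produce the protection table (growth-rate
#' recovery and final OD per competitor concentration).
#'
#' @param cfg a [run_config()].
#' @param concentrations drug concentration series, uM (must include 0).
#' @param competitor_concs competitor concentrations for the protection
#'   sweep, uM.
#' @param n_replicates replicate curves per concentration.
#' @param level inhibition level for the IC estimate.
#' @return A list: `dose_response`, `ic`, `protection` (tibble with
#'   `competitor_uM`, `mu`, `recovery`, `final_od`).
#' @export
run_validation <- function(cfg, concentrations = c(0, 1, 2, 5, 10, 20, 50, 100),
                           competitor_concs = c(0, 1, 5, 10, 50, 100, 500),
                           n_replicates = 3, level = 0.9) {
  if (is.character(cfg)) cfg <- run_config(path = cfg)
  params <- config_params(cfg)
  curves <- dplyr::bind_rows(lapply(concentrations, function(cc) {
    dplyr::bind_rows(lapply(seq_len(n_replicates), function(r) {
      p <- params
      p$rng_seed <- derive_seed(params$rng_seed, paste("rep", r, cc))
      cv <- simulate_growth_curve(params$mu_wt, cc, p)
      cv$replicate <- r
      cv
    }))
  }))
  # the simulated instrument's media blank is known, as it would be from a
  # medium-only well on a real plate
  dr <- dose_response(curves, blank = params$blank_od)
  ic <- ic_level(dr, level = level)
  mu0 <- dr$mu_max[dr$conc_uM == 0]
  prot <- dplyr::bind_rows(lapply(competitor_concs, function(comp) {
    cv <- simulate_growth_curve(params$mu_wt, ic$concentration, params,
                                competitor_uM = comp, noise = FALSE)
    est <- mu_max(cv, blank = params$blank_od)
    tibble::tibble(competitor_uM = comp, mu = est$mu_max,
                   recovery = recovery_fraction(est$mu_max, mu0),
                   final_od = final_od(cv))
  }))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_with_meta(dr, file.path(cfg$out_dir, "dose_response.tsv"),
                        config_meta(cfg, stage = "validation"))
    write_tsv_with_meta(prot, file.path(cfg$out_dir, "protection.tsv"),
                        config_meta(cfg, stage = "validation",
                                    ic_level = level,
                                    ic_concentration_uM = ic$concentration))
  }
  list(dose_response = dr, ic = ic, protection = prot)
}
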