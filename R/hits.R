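#' Median colony size across replicate spots
#'
#' Each mutant occupies four spots on the test plate; the median of the
#' replicate sizes is used, which makes the summary robust to a single
#' suppressor colony or failed spot. Missing replicates are tolerated down
#' to one, with a note.
#'
#' @param values numeric replicate measurements (NAs are missing spots).
#' @param strain_id optional label for log messages.
#' @return Median of the available replicates, or `NA` if all are missing.
#' @export
replicate_median <- function(values, strain_id = NULL) {
  ok <- values[!is.na(values)]
  if (length(ok) == 0L) return(NA_real_)
  if (length(ok) < 4L) {
    message(sprintf("strain %s: only %d of 4 replicates available",
                    if (is.null(strain_id)) "?" else strain_id, length(ok)))
  }
  stats::median(ok)
}

#' Drop edge spots from a measurement table
#'
#' Border colonies are wild-type buffer whose sizes are inflated by edge
#' effects (reduced nutrient competition), so they are excluded from all
#' medians and plate statistics.
#'
#' @param layout plate layout carrying `is_edge` flags.
#' @param measurements measurement table with `row` and `col`.
#' @return The measurements at interior positions only.
#' @export
exclude_edges <- function(layout, measurements) {
  keep <- layout[!layout$is_edge, c("row", "col")]
  dplyr::inner_join(measurements, keep, by = c("row", "col"))
}

# Per-strain replicate medians of interior spots.
strain_medians <- function(measurements) {
  sp <- split(measurements$pixel_count, measurements$strain_id)
  tibble::tibble(
    strain_id = names(sp),
    median_size = vapply(names(sp), function(s) replicate_median(sp[[s]], s),
                         numeric(1)),
    n_replicates = vapply(sp, function(v) sum(!is.na(v)), integer(1))
  )
}

#' Normalized relative-growth scores
#'
#' For every strain present on both plates, the median drug-plate size is
#' divided by the median control-plate size and multiplied by 100, so a
#' score of 100 means growth unaffected by the drug. Strains whose control
#' median is zero cannot be normalized; they are excluded from scoring and
#' listed in the `excluded` attribute of the result.
#'
#' @param drug_medians,control_medians per-strain median tables
#'   (`strain_id`, `median_size`), e.g. from interior measurements.
#' @return A tibble: `strain_id`, `median_drug`, `median_control`, `score`;
#'   attribute `excluded` names the unnormalizable or dropped strains.
#' @export
normalize_scores <- function(drug_medians, control_medians) {
  merged <- dplyr::inner_join(
    drug_medians[, c("strain_id", "median_size")],
    control_medians[, c("strain_id", "median_size")],
    by = "strain_id", suffix = c("_drug", "_control")
  )
  if (nrow(merged) == 0L) {
    stop("no strains shared between drug and control plates", call. = FALSE)
  }
  names(merged) <- c("strain_id", "median_drug", "median_control")
  bad <- is.na(merged$median_drug) | is.na(merged$median_control) |
    merged$median_control == 0
  excluded <- merged$strain_id[bad]
  out <- merged[!bad, ]
  out$score <- 100 * out$median_drug / out$median_control
  attr(out, "excluded") <- excluded
  out
}

#' Call resistant and sensitive strains from normalized scores
#'
#' Scores are standardized against the plate average and sample standard
#' deviation of all included strains. Strains scoring more than
#' `resistant_sd` standard deviations above the plate average are called
#' resistant (the standard threshold is 3 SD; 2.5 or 2 SD may be used to
#' compensate for extreme outliers), and strains more than 2.5 SD below are
#' called sensitive. Inequalities are strict.
#'
#' @param scores score table from [normalize_scores()].
#' @param resistant_sd resistance threshold in SD units: 3 (default), 2.5
#'   or 2.
#' @param sensitive_sd sensitivity threshold in SD units (default 2.5).
#' @return The score table with `z`, `call` (`resistant`/`sensitive`/
#'   `none`), `resistant_threshold_sd`, `sensitive_threshold_sd`; attribute
#'   `threshold_census` counts resistant calls at each of 3/2.5/2 SD.
#' @export
call_hits <- function(scores, resistant_sd = 3, sensitive_sd = 2.5) {
  if (!resistant_sd %in% c(3, 2.5, 2)) {
    warning("non-standard resistance threshold: ", resistant_sd, " SD",
            call. = FALSE)
  }
  if (nrow(scores) < 3L) {
    stop("need at least 3 scored strains to estimate plate statistics",
         call. = FALSE)
  }
  m <- mean(scores$score)
  s <- stats::sd(scores$score)
  out <- scores
  if (!is.finite(s) || s == 0) {
    warning("degenerate plate: score SD is zero, no calls made",
            call. = FALSE)
    out$z <- 0
    out$call <- "none"
  } else {
    out$z <- (out$score - m) / s
    out$call <- ifelse(out$z > resistant_sd, "resistant",
                       ifelse(out$z < -sensitive_sd, "sensitive", "none"))
  }
  out$resistant_threshold_sd <- resistant_sd
  out$sensitive_threshold_sd <- sensitive_sd
  attr(out, "plate_mean") <- m
  attr(out, "plate_sd") <- s
  attr(out, "threshold_census") <- c(
    sd3 = sum(out$z > 3), sd2.5 = sum(out$z > 2.5), sd2 = sum(out$z > 2)
  )
  out
}

#' Score a drug plate against its control plate
#'
#' Composite of the hit-calling steps: edge exclusion, replicate medians,
#' control normalization and SD-threshold calling.
#'
#' @param drug_meas,control_meas measurement tables from
#'   [quantify_plate()].
#' @param layout the shared plate layout.
#' @param resistant_sd resistance threshold (3, 2.5 or 2 SD).
#' @param wildtype strain id treated as the control strain; it contributes
#'   to plate statistics but is flagged `is_control` so reports can exclude
#'   it from hit lists.
#' @return Hit-call table as from [call_hits()], plus `is_control`.
#' @export
score_plate <- function(drug_meas, control_meas, layout, resistant_sd = 3,
                        wildtype = NULL) {
  d <- strain_medians(exclude_edges(layout, drug_meas))
  c_ <- strain_medians(exclude_edges(layout, control_meas))
  scores <- normalize_scores(d, c_)
  calls <- call_hits(scores, resistant_sd = resistant_sd)
  calls$is_control <- if (is.null(wildtype)) FALSE else
    calls$strain_id %in% wildtype
  for (a in c("excluded", "plate_mean", "plate_sd", "threshold_census")) {
    attr(calls, a) <- attr(scores, a) %||% attr(calls, a)
  }
  attr(calls, "excluded") <- attr(scores, "excluded")
  calls
}

`%||%` <- function(a, b) if (is.null(a)) b else a
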