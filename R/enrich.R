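#' Total-sum normalization of AFU arrays
#'
#' Scales each condition's raw AFU vector so that its total equals the mean
#' total across conditions; relative proportions within a condition are
#' unchanged. This in-repo normalization stands in for the external array
#' normalization protocol used with physical barcode arrays, and is
#' declared in the output metadata.
#'
#' @param ... two or more numeric AFU vectors sharing the strain index, or
#'   a single list of them.
#' @return A list of scaled vectors, in input order, with attribute
#'   `normalization = "total_sum"`.
#' @export
normalize_afu <- function(...) {
  arrays <- list(...)
  if (length(arrays) == 1L && is.list(arrays[[1]])) arrays <- arrays[[1]]
  lens <- lengths(arrays)
  if (length(unique(lens)) != 1L) {
    stop("AFU arrays must share the strain index", call. = FALSE)
  }
  totals <- vapply(arrays, sum, numeric(1))
  if (any(totals <= 0)) {
    stop("cannot normalize an all-zero condition", call. = FALSE)
  }
  target <- mean(totals)
  out <- Map(function(a, tot) a * target / tot, arrays, totals)
  attr(out, "normalization") <- "total_sum"
  out
}

#' Estimate the pool noise band from untreated replicates
#'
#' Two untreated replicate pools differ only by measurement noise; the band
#' halfwidth is the smallest `b` such that at least `coverage` of strains
#' satisfy `|afu_rep2 - afu_rep1| <= b` (the 98%-coverage band drawn as the
#' +/- translation of the parity line on pool scatter plots). With no
#' replicates supplied, the conventional fixed halfwidth of 1000 AFU is
#' returned.
#'
#' @param rep1,rep2 untreated replicate AFU vectors (may be `NULL`).
#' @param coverage fraction of strains the band must cover, in (0, 1].
#' @return Band halfwidth in AFU.
#' @export
estimate_noise_band <- function(rep1 = NULL, rep2 = NULL, coverage = 0.98) {
  if (coverage <= 0 || coverage > 1) {
    stop("coverage must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(rep1) || is.null(rep2)) return(1000)
  if (length(rep1) != length(rep2)) {
    stop("replicate profiles must share the strain index", call. = FALSE)
  }
  d <- sort(abs(rep2 - rep1))
  d[ceiling(coverage * length(d))]
}

#' Call enriched (resistant) strains in a treated vs untreated pool
#'
#' A strain is enriched when its treated-arm AFU exceeds its untreated-arm
#' AFU by more than the noise-band halfwidth AND its treated/untreated
#' ratio reaches the ratio threshold (the band is a noise estimate; the
#' ratio lines are effect-size thresholds; both must be cleared). Strains
#' with zero untreated AFU have no defined ratio; for them the band
#' criterion alone governs and the undefined ratio is flagged. Strains are
#' ranked by treated AFU, descending, ties broken by strain id.
#'
#' @param profiles pool profile tibble with `strain_id`, `afu_untreated`,
#'   `afu_treated`.
#' @param band_halfwidth noise-band halfwidth, AFU (default 1000).
#' @param ratio_threshold enrichment ratio threshold, conventionally 3
#'   (standard) or 2 (relaxed).
#' @return The profiles with `diff`, `ratio`, `ratio_undefined`,
#'   `enriched`, `rank_on_treated`, and the thresholds used.
#' @export
call_enrichment <- function(profiles, band_halfwidth = 1000,
                            ratio_threshold = 3) {
  if (nrow(profiles) == 0L) stop("empty profile set", call. = FALSE)
  if (!ratio_threshold %in% c(2, 3)) {
    warning("non-standard enrichment ratio threshold: ", ratio_threshold,
            call. = FALSE)
  }
  out <- profiles
  out$diff <- out$afu_treated - out$afu_untreated
  out$ratio <- ifelse(out$afu_untreated > 0,
                      out$afu_treated / out$afu_untreated, NA_real_)
  out$ratio_undefined <- out$afu_untreated == 0
  out$enriched <- ifelse(
    out$ratio_undefined,
    out$diff > band_halfwidth,
    out$diff > band_halfwidth & out$ratio >= ratio_threshold
  )
  ord <- order(-out$afu_treated, out$strain_id)
  out$rank_on_treated <- integer(nrow(out))
  out$rank_on_treated[ord] <- seq_len(nrow(out))
  out$band_halfwidth <- band_halfwidth
  out$ratio_threshold <- ratio_threshold
  out
}

#' Overlay transporter identity on enrichment calls
#'
#' Pool competitions cover the whole deletion collection; this flags which
#' called strains are transporter deletants (the stars on the scatter
#' plots) and summarizes enriched counts by class.
#'
#' @param calls enrichment-call table from [call_enrichment()].
#' @param catalog strain catalog; strains absent from the catalog are
#'   flagged `FALSE` with a warning.
#' @return Calls with `is_transporter`; attribute `summary` holds enriched
#'   counts for transporter and non-transporter strains.
#' @export
annotate_transporters <- function(calls, catalog) {
  known <- calls$strain_id %in% catalog$strain_id
  if (any(!known)) {
    warning(sum(!known), " strain(s) not in catalog; flagged as non-transporter",
            call. = FALSE)
  }
  calls$is_transporter <- calls$strain_id %in% transporter_ids(catalog)
  attr(calls, "summary") <- c(
    enriched_transporter = sum(calls$enriched & calls$is_transporter),
    enriched_other = sum(calls$enriched & !calls$is_transporter)
  )
  calls
}

#' Scatter diagnostic of a pool competition
#'
#' Treated vs untreated AFU per strain with the parity line, the +/- band
#' lines, and the enrichment-ratio lines; transporter deletants are
#' star-marked.
#'
#' @param calls annotated enrichment calls.
#' @param ratio_lines ratios to draw (default 2 and 3).
#' @return A ggplot object (requires ggplot2).
#' @export
plot_pool_scatter <- function(calls, ratio_lines = c(2, 3)) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_pool_scatter requires ggplot2", call. = FALSE)
  }
  band <- calls$band_halfwidth[1]
  p <- ggplot2::ggplot(calls, ggplot2::aes(
    x = .data[["afu_untreated"]], y = .data[["afu_treated"]]
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
    ggplot2::geom_abline(slope = 1, intercept = band, colour = "hotpink") +
    ggplot2::geom_abline(slope = 1, intercept = -band, colour = "seagreen3") +
    ggplot2::geom_point(ggplot2::aes(shape = .data[["is_transporter"]],
                                     colour = .data[["enriched"]])) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 18, `TRUE` = 8)) +
    ggplot2::labs(x = "untreated AFU", y = "treated AFU",
                  shape = "transporter", colour = "enriched")
  for (r in ratio_lines) {
    p <- p + ggplot2::geom_abline(slope = r, intercept = 0,
                                  linetype = "dashed", colour = "steelblue")
  }
  p
}
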