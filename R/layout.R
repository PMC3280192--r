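#' Build the 384-well master-plate layout
#'
#' Arrays the catalog into a 16 x 24 master plate: every border well carries
#' the wild-type control (a buffer against edge effects), and each
#' transporter strain occupies exactly two interior wells (duplicate
#' inoculation). Interior wells left over after placing the catalog are
#' filled with additional wild-type control wells, never left empty.
#'
#' @param catalog a strain catalog (see [strain_catalog()]).
#' @return A layout tibble with columns `row`, `col`, `strain_id`,
#'   `replicate_index`, `is_edge`, plus attributes `n_rows`/`n_cols`.
#' @export
build_master_layout <- function(catalog) {
  n_rows <- 16L; n_cols <- 24L
  strains <- transporter_ids(catalog)
  if (length(strains) < 1L) {
    stop("catalog must contain at least one transporter strain", call. = FALSE)
  }
  interior_capacity <- (n_rows - 2L) * (n_cols - 2L)  # 14 * 22 = 308
  if (2L * length(strains) > interior_capacity) {
    stop(sprintf(
      "catalog too large: %d strains need %d duplicate wells but the plate interior holds %d",
      length(strains), 2L * length(strains), interior_capacity), call. = FALSE)
  }
  wt <- wildtype_id(catalog)
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  grid <- grid[order(grid$row, grid$col), c("row", "col")]
  is_edge <- grid$row %in% c(1L, n_rows) | grid$col %in% c(1L, n_cols)
  assign <- rep(wt, nrow(grid))
  interior_idx <- which(!is_edge)          # row-major interior order
  duplicated_strains <- rep(strains, each = 2L)
  assign[interior_idx[seq_along(duplicated_strains)]] <- duplicated_strains
  out <- tibble::tibble(
    row = as.integer(grid$row), col = as.integer(grid$col),
    strain_id = assign, is_edge = is_edge
  )
  out$replicate_index <- stats::ave(seq_len(nrow(out)), out$strain_id,
                                    FUN = seq_along)
  out <- out[, c("row", "col", "strain_id", "replicate_index", "is_edge")]
  attr(out, "n_rows") <- n_rows
  attr(out, "n_cols") <- n_cols
  attr(out, "plate_kind") <- "master"
  out
}

#' Build the 768-spot test-plate layout
#'
#' The master plate is spotted twice onto each test plate, giving a 24 x 32
#' grid of 768 spots in which every transporter mutant appears in
#' quadruplicate (two master wells x two spotting passes). The full border
#' ring of the test plate is wild-type buffer. Each master interior well is
#' assigned to two consecutive interior test positions in row-major order;
#' interior test positions beyond those 616 are filled with wild-type
#' control spots.
#'
#' @param master a 16 x 24 master layout from [build_master_layout()].
#' @return A 768-row layout tibble (columns as in [build_master_layout()]).
#' @export
build_test_layout <- function(master) {
  if (is.null(attr(master, "n_rows")) ||
      attr(master, "n_rows") != 16L || attr(master, "n_cols") != 24L ||
      nrow(master) != 384L) {
    stop("master layout must be a 16 x 24 (384-well) plate", call. = FALSE)
  }
  n_rows <- 24L; n_cols <- 32L
  wt <- unique(master$strain_id[master$is_edge])
  if (length(wt) != 1L) {
    stop("master border must carry a single wild-type control strain",
         call. = FALSE)
  }
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  grid <- grid[order(grid$row, grid$col), c("row", "col")]
  is_edge <- grid$row %in% c(1L, n_rows) | grid$col %in% c(1L, n_cols)
  assign <- rep(wt, nrow(grid))
  interior_idx <- which(!is_edge)          # 22 * 30 = 660 positions
  src <- master[!master$is_edge, ]
  src <- src[order(src$row, src$col), ]
  spotted <- rep(src$strain_id, each = 2L)  # two spotting passes per well
  assign[interior_idx[seq_along(spotted)]] <- spotted
  out <- tibble::tibble(
    row = as.integer(grid$row), col = as.integer(grid$col),
    strain_id = assign, is_edge = is_edge
  )
  out$replicate_index <- stats::ave(seq_len(nrow(out)), out$strain_id,
                                    FUN = seq_along)
  out <- out[, c("row", "col", "strain_id", "replicate_index", "is_edge")]
  attr(out, "n_rows") <- n_rows
  attr(out, "n_cols") <- n_cols
  attr(out, "plate_kind") <- "test"
  out
}

layout_dims <- function(layout) {
  c(n_rows = attr(layout, "n_rows"), n_cols = attr(layout, "n_cols"))
}
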