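#' Strain catalog
#'
#' A catalog lists the deletion strains available for arraying and pooling:
#' transporter deletion mutants plus a single wild-type control strain (an
#' ho-locus deletion, phenotypically wild type in diploids).
#'
#' @param gene_names character vector of transporter gene names (unique,
#'   uppercase by convention).
#' @param wildtype_id strain identifier used for the wild-type control.
#' @return A tibble with columns `strain_id`, `category`
#'   (`"transporter_mutant"` or `"wildtype_control"`) and `gene_name`.
#' @examples
#' cat111 <- default_strain_catalog()
#' table(cat111$category)
#' @export
strain_catalog <- function(gene_names, wildtype_id = "WT") {
  gene_names <- as.character(gene_names)
  if (anyDuplicated(gene_names)) {
    stop("strain catalog gene names must be unique", call. = FALSE)
  }
  if (wildtype_id %in% gene_names) {
    stop("wildtype id collides with a transporter strain id", call. = FALSE)
  }
  tibble::tibble(
    strain_id = c(gene_names, wildtype_id),
    category = c(rep("transporter_mutant", length(gene_names)),
                 "wildtype_control"),
    gene_name = c(gene_names, "HO")
  )
}

#' Default 111-transporter catalog
#'
#' The packaged catalog holds 111 plasma-membrane transporter deletion
#' strains and one wild-type control. The transporter genes examined in the
#' original screen are not all individually listed in the source material;
#' this catalog combines the transporter genes that are named in the study's
#' results with additional well-characterized S. cerevisiae plasma-membrane
#' transporter genes to reach the stated panel size of 111, and is therefore
#' a synthetic stand-in for the original strain list.
#'
#' @return A 112-row strain catalog tibble (111 mutants + 1 control).
#' @export
default_strain_catalog <- function() {
  named_in_study <- c(
    "CAN1", "NRT1", "FCY2", "FEN2", "ITR1", "FUI1", "MAL11", "AGP1",
    "CTR1", "PCA1", "SNQ2", "CCH1", "MID1", "PHO89", "LEM3", "DNF2",
    "QDR2", "FET3", "FTR1", "FPS1", "HNM1", "FAT1", "PDR5", "PUG1",
    "VHT1", "YPP1", "ALR1", "STE6", "DAL5"
  )
  panel_fill <- c(
    # hexose and other sugar/carboxylate transport
    paste0("HXT", c(1:11, 13:17)), "GAL2", "STL1", "JEN1", "ADY2",
    "MAL31", "MPH2", "MPH3",
    # amino-acid permeases
    "GAP1", "PUT4", "LYP1", "ALP1", "DIP5", "GNP1", "BAP2", "BAP3",
    "TAT1", "TAT2", "MUP1", "MUP3", "MMP1", "SAM3", "AGP2", "AGP3",
    # nitrogen sources and peptides
    "DUR3", "MEP1", "MEP2", "MEP3", "PTR2", "OPT1", "OPT2",
    # nucleobases, nucleosides, vitamins
    "FCY21", "FCY22", "FUR4", "THI7", "THI72", "THI73",
    # phosphate, sulfate, metals, siderophores
    "PHO84", "PHO87", "PHO90", "PHO91", "SUL1", "SUL2",
    "ZRT1", "ZRT2", "SMF1", "SMF2", "SMF3", "CTR3",
    "SIT1", "ARN1", "ARN2", "ENB1",
    # inositol, glycerophosphoinositol, polyamines, multidrug
    "ITR2", "GIT1", "TPO1", "TPO2", "TPO3", "TPO4",
    "AQR1", "QDR1", "QDR3", "FLR1", "ATR1", "AZR1", "SGE1", "SEO1"
  )
  strain_catalog(c(named_in_study, panel_fill))
}

wildtype_id <- function(catalog) {
  id <- catalog$strain_id[catalog$category == "wildtype_control"]
  if (length(id) != 1L) {
    stop("catalog must contain exactly one wildtype_control strain",
         call. = FALSE)
  }
  id
}

transporter_ids <- function(catalog) {
  catalog$strain_id[catalog$category == "transporter_mutant"]
}
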