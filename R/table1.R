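#' Load the packaged per-drug evidence table
#'
#' The package ships the study's summary of 26 cytotoxic drugs: the pool
#' and robot screen hits (with the SD threshold each hit was qualified at),
#' indirect-effect genes, liquid-culture verification status, competitive
#' protection, and Lipinski rule-of-five pass/fail. Gene symbols are
#' normalized to uppercase; the raw printed cell text is retained in
#' `raw_*` columns. The file's checksum is verified on load.
#'
#' @param path fixture path; defaults to the packaged table.
#' @param check_integrity verify the fixture checksum (default `TRUE`).
#' @return A tibble of 26 drug records with list-columns `pool_hits`
#'   (character vectors), `robot_hits` and `indirect_hits` (tibbles with
#'   `gene`, `evidence_sd`).
#' @export
load_table1 <- function(path = NULL, check_integrity = is.null(path)) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1.tsv", package = "carrierscreen")
  }
  if (check_integrity) {
    sum_now <- unname(tools::md5sum(path))
    if (!identical(sum_now, table1_md5)) {
      stop("drug-evidence fixture failed its integrity check (md5 ",
           sum_now, ")", call. = FALSE)
    }
  }
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", fill = TRUE)
  for (nm in names(raw)) raw[[nm]][is.na(raw[[nm]])] <- ""
  tibble::tibble(
    drug = raw$drug,
    pool_hits = lapply(raw$pool_hits, parse_gene_list),
    robot_conc_uM = as.numeric(raw$robot_conc_uM),
    robot_hits = lapply(raw$robot_hits, parse_hit_list),
    indirect_hits = lapply(raw$indirect_hits, parse_hit_list),
    verification = raw$verification,
    competitor_protects = raw$competitor_protects,
    lipinski_pass = raw$lipinski_pass == "pass",
    raw_robot_hits = raw$raw_robot_hits,
    raw_indirect_hits = raw$raw_indirect_hits
  )
}

# md5 of the packaged fixture; recorded when the fixture was frozen.
table1_md5 <- "dbb2209440221d2058962738b69c4f71"

# "None", "" -> empty; "CAN1" / "A;B" -> character vector.
parse_gene_list <- function(cell) {
  cell <- trimws(cell)
  if (cell == "" || tolower(cell) == "none") return(character(0))
  trimws(strsplit(cell, ";")[[1]])
}

# "FEN2:2;SNQ2:2.5" -> tibble(gene, evidence_sd); bare genes default to the
# standard 3 SD threshold.
parse_hit_list <- function(cell) {
  genes <- parse_gene_list(cell)
  if (length(genes) == 0L) {
    return(tibble::tibble(gene = character(0), evidence_sd = numeric(0)))
  }
  parts <- strsplit(genes, ":")
  tibble::tibble(
    gene = vapply(parts, `[[`, character(1), 1L),
    evidence_sd = vapply(parts, function(p)
      if (length(p) > 1L) as.numeric(p[2]) else 3, numeric(1))
  )
}

serialize_hit_list <- function(hits) {
  if (nrow(hits) == 0L) return("")
  paste(sprintf("%s:%s", hits$gene, format(hits$evidence_sd, trim = TRUE)),
        collapse = ";")
}

#' Serialize drug records back to the fixture text format
#'
#' @param records tibble from [load_table1()] or [build_summary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_drug_records <- function(records, path) {
  out <- data.frame(
    drug = records$drug,
    pool_hits = vapply(records$pool_hits, paste, character(1),
                       collapse = ";"),
    robot_conc_uM = records$robot_conc_uM,
    robot_hits = vapply(records$robot_hits, serialize_hit_list,
                        character(1)),
    indirect_hits = vapply(records$indirect_hits, serialize_hit_list,
                           character(1)),
    verification = records$verification,
    competitor_protects = records$competitor_protects,
    lipinski_pass = ifelse(records$lipinski_pass, "pass", "fail"),
    raw_robot_hits = records$raw_robot_hits,
    raw_indirect_hits = records$raw_indirect_hits,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Does a drug record carry a direct transporter hit?
#'
#' A direct hit is a pool or robot hit; genes listed only under indirect
#' effects do not count (their deletions alter the drug's target or
#' cellular state rather than its import).
#'
#' @param record one drug record (single row of the records tibble).
#' @return Logical.
#' @export
has_direct_hit <- function(record) {
  length(record$pool_hits[[1]]) > 0L || nrow(record$robot_hits[[1]]) > 0L
}

#' Headline counts over a set of drug records
#'
#' Counts the drugs, the drugs with at least one direct (pool or robot)
#' hit, and the Lipinski passes, and assigns each drug to a category:
#' `none` (no hits at all), `indirect_only`, `single_carrier` (exactly one
#' distinct direct gene) or `multiple` (two or more).
#'
#' @param records drug records tibble.
#' @return A list: `n_drugs`, `n_with_direct_hit`, `n_lipinski_pass`,
#'   `categories` (named counts summing to `n_drugs`).
#' @export
summarize_records <- function(records) {
  n <- nrow(records)
  if (n == 0L) {
    return(list(n_drugs = 0L, n_with_direct_hit = 0L, n_lipinski_pass = 0L,
                categories = c(none = 0L, indirect_only = 0L,
                               single_carrier = 0L, multiple = 0L)))
  }
  cats <- vapply(seq_len(n), function(i) {
    rec <- records[i, ]
    direct <- unique(c(rec$pool_hits[[1]], rec$robot_hits[[1]]$gene))
    indirect <- rec$indirect_hits[[1]]$gene
    if (length(direct) == 0L && length(indirect) == 0L) "none"
    else if (length(direct) == 0L) "indirect_only"
    else if (length(direct) == 1L) "single_carrier"
    else "multiple"
  }, character(1))
  list(
    n_drugs = n,
    n_with_direct_hit = sum(vapply(seq_len(n), function(i)
      has_direct_hit(records[i, ]), logical(1))),
    n_lipinski_pass = sum(records$lipinski_pass),
    categories = c(
      none = sum(cats == "none"),
      indirect_only = sum(cats == "indirect_only"),
      single_carrier = sum(cats == "single_carrier"),
      multiple = sum(cats == "multiple")
    )
  )
}

#' Assemble drug records from new screen outputs
#'
#' Combines per-drug robot hit calls, pool enrichment calls and optional
#' validation/protection flags into records shaped like the packaged
#' evidence table. Direct versus indirect classification is never inferred:
#' genes present in the `indirect_annotation` table (expert curation:
#' gene, substrate class, mechanism note) are moved to the indirect column;
#' requesting indirect classification without an annotation table is a
#' configuration error.
#'
#' @param drug drug name.
#' @param robot_calls hit-call table from [score_plate()]/[call_hits()]
#'   (or `NULL`).
#' @param enrichment_calls enrichment table from [call_enrichment()] (or
#'   `NULL`).
#' @param robot_conc_uM drug concentration used on the robot plate.
#' @param indirect_annotation `NULL`, or a data frame with a `gene` column
#'   naming genes whose resistance is curated as indirect.
#' @param classify_indirect set `TRUE` to split hits using the annotation.
#' @param verification,competitor_protects,lipinski_pass record fields.
#' @return A one-row drug records tibble (same shape as [load_table1()]).
#' @export
build_summary <- function(drug, robot_calls = NULL, enrichment_calls = NULL,
                          robot_conc_uM = NA_real_,
                          indirect_annotation = NULL,
                          classify_indirect = !is.null(indirect_annotation),
                          verification = "not_tested",
                          competitor_protects = "not_tested",
                          lipinski_pass = NA) {
  if (classify_indirect && is.null(indirect_annotation)) {
    stop("indirect classification requested without an annotation table",
         call. = FALSE)
  }
  robot <- if (is.null(robot_calls)) {
    tibble::tibble(gene = character(0), evidence_sd = numeric(0))
  } else {
    res <- robot_calls[robot_calls$call == "resistant" &
                         !(robot_calls$is_control %||% FALSE), ]
    tibble::tibble(gene = res$strain_id,
                   evidence_sd = res$resistant_threshold_sd)
  }
  indirect <- tibble::tibble(gene = character(0), evidence_sd = numeric(0))
  if (classify_indirect && nrow(robot) > 0L) {
    move <- robot$gene %in% indirect_annotation$gene
    indirect <- robot[move, ]
    robot <- robot[!move, ]
  }
  pool <- if (is.null(enrichment_calls)) character(0) else
    sort(enrichment_calls$strain_id[enrichment_calls$enriched])
  tibble::tibble(
    drug = drug,
    pool_hits = list(pool),
    robot_conc_uM = robot_conc_uM,
    robot_hits = list(robot),
    indirect_hits = list(indirect),
    verification = verification,
    competitor_protects = competitor_protects,
    lipinski_pass = lipinski_pass,
    raw_robot_hits = "",
    raw_indirect_hits = ""
  )
}
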