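#' Aggregate connectivity records into per-drug cross-cell-line scores
#'
#' Records are mapped from perturbagen to drug (explicit map or embedded
#' DrugBank suffix, see [map_perturbagens()]); unmapped or undefined records
#' are excluded with a logged count. Within each (drug, cell line) the
#' signature scores collapse to their arithmetic mean first; the drug's
#' `mean_score` is then the arithmetic mean of its per-cell scores. Under the
#' `require_all_cells` policy (the default) a drug missing any of the cell
#' lines spanned by the records is excluded; `mean_available` averages over
#' whatever cells the drug has.
#'
#' @param records a [score_library()] result (rows may span cell lines).
#' @param drug_map optional [drug_target_table()] supplying the perturbagen
#'   map and drug names.
#' @param policy `"require_all_cells"` or `"mean_available"`.
#' @param cell_lines optional explicit cell-line universe for the
#'   `require_all_cells` policy (defaults to the cells present in `records`).
#' @return data.frame of class `drug_scores`, ordered by descending
#'   `mean_score` (ties by drug id): columns `drug_id`, `drug_name`,
#'   one `score.<cell>` column per cell line, `mean_score`, `rank`.
#' @export
aggregate_by_drug <- function(records, drug_map = NULL,
                              policy = c("require_all_cells", "mean_available"),
                              cell_lines = NULL) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(records),
            all(c("perturbagen_id", "cell_line", "c") %in% names(records)))
  ok <- !is.na(records$c)
  if (any(!ok)) sc_log("aggregate_by_drug: %d undefined record(s) dropped",
                       sum(!ok))
  records <- records[ok, , drop = FALSE]
  drug_ids <- map_perturbagens(records$perturbagen_id, drug_map)
  unmapped <- is.na(drug_ids)
  if (any(unmapped)) {
    sc_log("aggregate_by_drug: %d record(s) with unmapped perturbagen dropped",
           sum(unmapped))
  }
  records <- records[!unmapped, , drop = FALSE]
  drug_ids <- drug_ids[!unmapped]
  if (!nrow(records)) stop("no mappable connectivity records", call. = FALSE)

  cells <- sort(cell_lines %||% unique(records$cell_line))
  # signatures -> per (drug, cell) mean
  per_cell <- stats::aggregate(records$c,
                               by = list(drug_id = drug_ids,
                                         cell_line = records$cell_line),
                               FUN = mean)
  names(per_cell)[3L] <- "c"
  wide <- stats::reshape(per_cell, idvar = "drug_id", timevar = "cell_line",
                         direction = "wide", sep = ".")
  score_cols <- paste0("c.", cells)
  for (col in setdiff(score_cols, names(wide))) wide[[col]] <- NA_real_
  wide <- wide[, c("drug_id", score_cols), drop = FALSE]
  names(wide) <- c("drug_id", paste0("score.", cells))

  smat <- as.matrix(wide[, -1L, drop = FALSE])
  if (policy == "require_all_cells") {
    complete <- rowSums(is.na(smat)) == 0L
    if (any(!complete)) {
      sc_log("aggregate_by_drug: %d drug(s) missing a cell line excluded",
             sum(!complete))
    }
    wide <- wide[complete, , drop = FALSE]
    smat <- smat[complete, , drop = FALSE]
  }
  if (!nrow(wide)) stop("no drug satisfies the aggregation policy", call. = FALSE)
  wide$mean_score <- rowMeans(smat, na.rm = TRUE)

  names_map <- NULL
  if (inherits(drug_map, "drug_target_table")) {
    names_map <- stats::setNames(drug_map$drug_name, drug_map$drug_id)
    names_map <- names_map[!duplicated(names(names_map))]
  }
  wide$drug_name <- if (is.null(names_map)) wide$drug_id
                    else ifelse(is.na(names_map[wide$drug_id]),
                                wide$drug_id, names_map[wide$drug_id])

  o <- order(-wide$mean_score, wide$drug_id)
  wide <- wide[o, , drop = FALSE]
  wide$rank <- seq_len(nrow(wide))
  rownames(wide) <- NULL
  cols <- c("drug_id", "drug_name", paste0("score.", cells), "mean_score", "rank")
  structure(wide[, cols], class = c("drug_scores", "data.frame"))
}

#' @export
print.drug_scores <- function(x, ...) {
  cat(sprintf("drug_scores: %d drugs ranked by mean connectivity\n", nrow(x)))
  NextMethod()
}

#' Take the top-k ranked drugs
#'
#' @param scores a [aggregate_by_drug()] result (already ranked; ties were
#'   broken by drug id).
#' @param k number of drugs to keep (default 10).
#' @return the first `k` rows; if `k` exceeds the table, all rows with a
#'   warning.
#' @export
top_k <- function(scores, k = 10) {
  stopifnot(inherits(scores, "drug_scores"), k >= 0)
  if (k > nrow(scores)) {
    warning(sprintf("k = %d exceeds the %d ranked drugs; returning all",
                    k, nrow(scores)), call. = FALSE)
    k <- nrow(scores)
  }
  scores[seq_len(k), , drop = FALSE]
}

#' Extract the unique target proteins of the top-ranked drugs
#'
#' Takes the union of the drug-target edges of the given drugs whose
#' pharmacological action is in `actions` (antagonist/inhibitor by default,
#' i.e. targets the drugs suppress), deduplicated by gene symbol; each target
#' keeps the list of drugs that contributed it. Drugs absent from the table
#' contribute nothing (logged).
#'
#' @param top a [top_k()] result, or a character vector of drug ids.
#' @param table a [drug_target_table()].
#' @param actions pharmacological actions to keep.
#' @return data.frame of class `target_set`: `gene_symbol`, `uniprot_id`,
#'   `source_drugs` (drug ids, `;`-separated), sorted by gene symbol;
#'   attribute `size` = number of unique target proteins.
#' @export
extract_targets <- function(top, table,
                            actions = c("antagonist", "inhibitor")) {
  stopifnot(inherits(table, "drug_target_table"))
  drug_ids <- if (is.character(top)) top else top$drug_id
  bad <- setdiff(actions, DRUG_ACTIONS)
  if (length(bad)) {
    stop(sprintf("unknown action(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  absent <- setdiff(drug_ids, table$drug_id)
  if (length(absent)) {
    sc_log("extract_targets: %d drug(s) absent from the target table",
           length(absent))
  }
  rows <- table[table$drug_id %in% drug_ids & table$action %in% actions, ,
                drop = FALSE]
  if (!nrow(rows)) {
    out <- data.frame(gene_symbol = character(0), uniprot_id = character(0),
                      source_drugs = character(0), stringsAsFactors = FALSE)
    return(structure(out, size = 0L, class = c("target_set", "data.frame")))
  }
  syms <- sort(unique(rows$target_gene_symbol))
  first <- match(syms, rows$target_gene_symbol)
  out <- data.frame(
    gene_symbol = syms,
    uniprot_id = rows$target_uniprot_id[first],
    source_drugs = vapply(syms, function(s)
      paste(sort(unique(rows$drug_id[rows$target_gene_symbol == s])),
            collapse = ";"), ""),
    stringsAsFactors = FALSE)
  if ("target_protein_name" %in% names(rows)) {
    out$protein_name <- rows$target_protein_name[first]
  }
  rownames(out) <- NULL
  structure(out, size = nrow(out), class = c("target_set", "data.frame"))
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("target_set: %d unique target proteins\n", attr(x, "size")))
  NextMethod()
}
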