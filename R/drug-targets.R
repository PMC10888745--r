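#' Allowed pharmacological actions in a drug-target table
#' @export
DRUG_ACTIONS <- c("inhibitor", "antagonist", "agonist", "other")

#' Construct a drug-target table
#'
#' Rows are drug-to-protein edges with a pharmacological action drawn from a
#' closed vocabulary; an optional perturbagen-to-drug mapping table links
#' reference-library perturbagen ids to drug ids.
#'
#' @param edges data.frame with columns `drug_id`, `drug_name`,
#'   `target_gene_symbol`, `target_uniprot_id`, `action`.
#' @param perturbagen_map optional data.frame with columns `perturbagen_id`,
#'   `drug_id`.
#' @return object of class `drug_target_table` (a data.frame with the map in
#'   attribute `perturbagen_map`).
#' @export
drug_target_table <- function(edges, perturbagen_map = NULL) {
  need <- c("drug_id", "drug_name", "target_gene_symbol",
            "target_uniprot_id", "action")
  if (!is.data.frame(edges) || !all(need %in% names(edges))) {
    stop(sprintf("drug-target table needs columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  keep_cols <- c(need, intersect("target_protein_name", names(edges)))
  edges <- edges[, keep_cols, drop = FALSE]
  bad <- setdiff(unique(edges$action), DRUG_ACTIONS)
  if (length(bad)) {
    stop(sprintf("unknown action(s) %s; allowed: %s",
                 paste(sQuote(bad), collapse = ", "),
                 paste(DRUG_ACTIONS, collapse = ", ")), call. = FALSE)
  }
  key <- paste(edges$drug_id, edges$target_gene_symbol, edges$action, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- edges[duplicated(key), , drop = FALSE]
    stop(sprintf("duplicate (drug_id, target_gene_symbol, action) row(s): %s",
                 paste(unique(paste(dup$drug_id, dup$target_gene_symbol, sep = "/")),
                       collapse = ", ")), call. = FALSE)
  }
  if (!is.null(perturbagen_map)) {
    if (!all(c("perturbagen_id", "drug_id") %in% names(perturbagen_map))) {
      stop("perturbagen_map needs columns 'perturbagen_id' and 'drug_id'",
           call. = FALSE)
    }
    perturbagen_map <- perturbagen_map[, c("perturbagen_id", "drug_id")]
  }
  rownames(edges) <- NULL
  structure(edges, perturbagen_map = perturbagen_map,
            class = c("drug_target_table", "data.frame"))
}

#' @export
print.drug_target_table <- function(x, ...) {
  cat(sprintf("drug_target_table: %d edges, %d drugs, %d unique targets\n",
              nrow(x), length(unique(x$drug_id)),
              length(unique(x$target_gene_symbol))))
  NextMethod()
}

#' Read a drug-target TSV (plus optional perturbagen map)
#'
#' @param path TSV with the five columns of [drug_target_table()].
#' @param map_path optional TSV with columns `perturbagen_id`, `drug_id`.
#' @return a [drug_target_table()].
#' @export
read_drug_targets <- function(path, map_path = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  edges <- read_tsv(path)
  pmap <- NULL
  if (!is.null(map_path)) {
    if (!file.exists(map_path)) {
      stop(sprintf("file not found: %s", map_path), call. = FALSE)
    }
    pmap <- read_tsv(map_path)
  }
  drug_target_table(edges, pmap)
}

#' Write a drug-target table (and its perturbagen map) to TSV
#' @param table a [drug_target_table()].
#' @param path output TSV path.
#' @param map_path optional output path for the perturbagen map.
#' @export
write_drug_targets <- function(table, path, map_path = NULL) {
  stopifnot(inherits(table, "drug_target_table"))
  write_tsv(as.data.frame(table), path)
  pmap <- attr(table, "perturbagen_map")
  if (!is.null(map_path) && !is.null(pmap)) write_tsv(pmap, map_path)
  invisible(path)
}

#' Map perturbagen ids to drug ids
#'
#' Resolution order: (1) an explicit perturbagen map attached to `drug_map`;
#' (2) an embedded trailing DrugBank suffix — perturbagen ids of the form
#' `BRD-Kxxxxxxxx_DBnnnnn` carry their drug id after the final underscore.
#' Unresolvable ids yield `NA`.
#'
#' @param perturbagen_ids character vector.
#' @param drug_map optional [drug_target_table()] (its `perturbagen_map`
#'   attribute is consulted) or a data.frame with `perturbagen_id`/`drug_id`.
#' @return character vector of drug ids (NA where unmapped).
#' @export
map_perturbagens <- function(perturbagen_ids, drug_map = NULL) {
  out <- rep(NA_character_, length(perturbagen_ids))
  pmap <- NULL
  if (inherits(drug_map, "drug_target_table")) {
    pmap <- attr(drug_map, "perturbagen_map")
  } else if (is.data.frame(drug_map)) {
    pmap <- drug_map
  }
  if (!is.null(pmap)) {
    idx <- match(perturbagen_ids, pmap$perturbagen_id)
    out[!is.na(idx)] <- pmap$drug_id[idx[!is.na(idx)]]
  }
  # implicit mapping: trailing _DB<digits> suffix embeds the DrugBank id
  has_suffix <- grepl("_DB[0-9]+$", perturbagen_ids)
  out[is.na(out) & has_suffix] <-
    sub("^.*_(DB[0-9]+)$", "\\1", perturbagen_ids[is.na(out) & has_suffix])
  out
}
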