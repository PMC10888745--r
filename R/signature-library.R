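#' Construct a reference signature library
#'
#' A `signature_library` models an L1000-style level-5 collection: an ordered
#' list of landmark genes (978 in the emulated schema) and, per reference
#' signature, a real-valued amplitude vector over those genes plus perturbagen
#' / cell line / dose / time metadata.
#'
#' @param amplitudes numeric matrix, landmark genes in rows (rownames = gene
#'   ids), signatures in columns (colnames = signature ids).
#' @param meta data.frame with one row per signature and columns
#'   `signature_id`, `perturbagen_id`, `cell_line`, `dose`, `time`.
#' @return object of class `signature_library`: list with `genes`,
#'   `amplitudes`, `meta` (meta reordered to match the matrix columns).
#' @export
signature_library <- function(amplitudes, meta) {
  if (!is.matrix(amplitudes) || !is.numeric(amplitudes)) {
    stop("'amplitudes' must be a numeric matrix", call. = FALSE)
  }
  genes <- rownames(amplitudes)
  sig_ids <- colnames(amplitudes)
  if (is.null(genes) || is.null(sig_ids)) {
    stop("'amplitudes' must have gene rownames and signature colnames",
         call. = FALSE)
  }
  if (anyDuplicated(genes)) stop("landmark gene ids must be unique", call. = FALSE)
  if (anyDuplicated(sig_ids)) stop("signature ids must be unique", call. = FALSE)
  if (any(!is.finite(amplitudes))) {
    stop("all amplitudes must be finite", call. = FALSE)
  }
  need <- c("signature_id", "perturbagen_id", "cell_line", "dose", "time")
  if (!is.data.frame(meta) || !all(need %in% names(meta))) {
    stop(sprintf("metadata must be a data.frame with columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  missing_meta <- setdiff(sig_ids, meta$signature_id)
  if (length(missing_meta)) {
    stop(sprintf("metadata missing for signature(s): %s",
                 paste(missing_meta, collapse = ", ")), call. = FALSE)
  }
  meta <- meta[match(sig_ids, meta$signature_id), need, drop = FALSE]
  rownames(meta) <- NULL
  structure(list(genes = genes, amplitudes = amplitudes, meta = meta),
            class = "signature_library")
}

#' @export
print.signature_library <- function(x, ...) {
  cat(sprintf("signature_library: %d landmark genes x %d signatures (%d perturbagens, %d cell lines)\n",
              length(x$genes), ncol(x$amplitudes),
              length(unique(x$meta$perturbagen_id)),
              length(unique(x$meta$cell_line))))
  invisible(x)
}

#' @export
length.signature_library <- function(x) ncol(x$amplitudes)

#' Read a signature library from a matrix file plus a metadata TSV
#'
#' The matrix is genes x signatures in GCT 1.2 or TSV layout (see
#' [read_expression_gct()] for the accepted dialects); the metadata TSV has
#' one row per signature with columns `signature_id`, `perturbagen_id`,
#' `cell_line`, `dose`, `time`. Signatures present in the matrix but absent
#' from the metadata are an alignment error (listing the missing ids); extra
#' metadata rows are ignored.
#'
#' @param matrix_path path to the amplitude matrix.
#' @param meta_path path to the metadata TSV.
#' @return a [signature_library()].
#' @export
read_signature_library <- function(matrix_path, meta_path) {
  vals <- parse_gct_matrix(matrix_path)
  if (!file.exists(meta_path)) {
    stop(sprintf("file not found: %s", meta_path), call. = FALSE)
  }
  meta <- read_tsv(meta_path)
  signature_library(vals, meta)
}

#' Write a signature library as a GCT matrix plus metadata TSV
#' @param lib a [signature_library()].
#' @param matrix_path,meta_path output paths.
#' @export
write_signature_library <- function(lib, matrix_path, meta_path) {
  stopifnot(inherits(lib, "signature_library"))
  write_gct_matrix(lib$amplitudes, matrix_path)
  write_tsv(lib$meta, meta_path)
  invisible(c(matrix_path, meta_path))
}

#' Filter a signature library by cell line, dose, time, and drug approval
#'
#' Retains only signatures matching every non-NULL criterion. Dose and time
#' are compared as value-plus-unit quantities under unit normalization
#' ("uM" == "µM", "h" == "hr", case-insensitive) with relative numeric
#' tolerance 1e-9, so "10 µM" matches a stored "10.0 uM".
#' `approved_only` keeps signatures whose perturbagen maps to a drug id,
#' either through `drug_map` or through a trailing `_DBxxxxx` suffix in the
#' perturbagen id (see [map_perturbagens()]).
#'
#' @param lib a [signature_library()].
#' @param cell_line,dose,time optional filters (NULL = no constraint).
#' @param approved_only keep only perturbagens mappable to a drug id.
#' @param drug_map optional [drug_target_table()] supplying the
#'   perturbagen-to-drug mapping for `approved_only`.
#' @return the filtered [signature_library()]; an empty result is a warning,
#'   not an error.
#' @export
filter_library <- function(lib, cell_line = NULL, dose = NULL, time = NULL,
                           approved_only = FALSE, drug_map = NULL) {
  stopifnot(inherits(lib, "signature_library"))
  keep <- rep(TRUE, ncol(lib$amplitudes))
  if (!is.null(cell_line)) keep <- keep & lib$meta$cell_line %in% cell_line
  if (!is.null(dose)) {
    keep <- keep & vapply(lib$meta$dose, quantity_equal, logical(1L), b = dose)
  }
  if (!is.null(time)) {
    keep <- keep & vapply(lib$meta$time, quantity_equal, logical(1L), b = time)
  }
  if (isTRUE(approved_only)) {
    drug_ids <- map_perturbagens(lib$meta$perturbagen_id, drug_map)
    keep <- keep & !is.na(drug_ids)
  }
  if (!any(keep)) {
    warning("filter_library: no signatures match the given criteria",
            call. = FALSE)
  }
  out <- lib
  out$amplitudes <- lib$amplitudes[, keep, drop = FALSE]
  out$meta <- lib$meta[keep, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}
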