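#' Construct a validated expression matrix
#'
#' An `expression_matrix` holds a genes-by-samples table of non-negative,
#' finite intensities together with a control/treated group label and a
#' replicate index per sample. It is the input to [contrast()].
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param groups named character vector mapping every sample id to
#'   `"control"` or `"treated"`.
#' @param replicates optional named integer vector of replicate indices per
#'   sample; defaults to 1..k within each group in column order.
#' @param cell_line optional cell-line label carried through to contrasts.
#' @return an object of class `expression_matrix`: a list with elements
#'   `values`, `groups`, `replicates`, `cell_line`.
#' @examples
#' v <- matrix(c(10, 20, 11, 21, 30, 5, 32, 6), nrow = 2,
#'             dimnames = list(c("G1", "G2"), c("c1", "c2", "t1", "t2")))
#' em <- expression_matrix(v, c(c1 = "control", c2 = "control",
#'                              t1 = "treated", t2 = "treated"))
#' @export
expression_matrix <- function(values, groups, replicates = NULL,
                              cell_line = NA_character_) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("'values' must have gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop(sprintf("duplicate gene id(s): %s",
                 paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("all intensities must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  groups <- unlist(groups)
  missing <- setdiff(sample_ids, names(groups))
  if (length(missing)) {
    stop(sprintf("no group label for sample(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(groups), sample_ids)
  if (length(extra)) {
    stop(sprintf("group map names sample(s) absent from the matrix: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  groups <- groups[sample_ids]
  if (!all(groups %in% c("control", "treated"))) {
    stop("group labels must be 'control' or 'treated'", call. = FALSE)
  }
  if (!any(groups == "control") || !any(groups == "treated")) {
    stop("need at least one control and one treated sample", call. = FALSE)
  }
  if (is.null(replicates)) {
    replicates <- stats::ave(seq_along(groups), groups, FUN = seq_along)
    names(replicates) <- sample_ids
  } else {
    replicates <- as.integer(unlist(replicates)[sample_ids])
    names(replicates) <- sample_ids
  }
  structure(list(values = values, groups = groups,
                 replicates = replicates, cell_line = cell_line),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d control, %d treated)%s\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "control"), sum(x$groups == "treated"),
              if (is.na(x$cell_line)) "" else paste0(", cell line ", x$cell_line)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# ---- GCT / TSV parsing ------------------------------------------------------

# Parse a genes-x-columns numeric table from GCT 1.2 text or a plain TSV with
# a header row of column ids and gene ids in column 1. Returns a numeric
# matrix with dimnames. Used by both expression and signature-library readers.
parse_gct_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop(sprintf("empty file: %s", path), call. = FALSE)
  if (startsWith(lines[[1L]], "#1.")) {
    if (trimws(lines[[1L]]) != "#1.2") {
      stop(sprintf("unsupported GCT version line: '%s' (only #1.2 is supported)",
                   lines[[1L]]), call. = FALSE)
    }
    if (length(lines) < 3L) {
      stop("malformed GCT: missing dimension or header line", call. = FALSE)
    }
    dims <- strsplit(trimws(lines[[2L]]), "\t|[ ]+")[[1L]]
    dims <- suppressWarnings(as.integer(dims))
    if (length(dims) != 2L || any(is.na(dims))) {
      stop(sprintf("malformed GCT dimension line: '%s'", lines[[2L]]), call. = FALSE)
    }
    header <- strsplit(lines[[3L]], "\t", fixed = TRUE)[[1L]]
    if (length(header) != dims[2L] + 2L) {
      stop(sprintf("malformed GCT header line: %d column names for %d declared samples",
                   length(header) - 2L, dims[2L]), call. = FALSE)
    }
    body <- lines[-(1:3)]
    if (length(body) != dims[1L]) {
      stop(sprintf("GCT declares %d rows but contains %d data rows",
                   dims[1L], length(body)), call. = FALSE)
    }
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != dims[2L] + 2L)) {
      bad <- which(nf != dims[2L] + 2L)[1L]
      stop(sprintf("malformed GCT data row %d: %d fields, expected %d",
                   bad, nf[bad], dims[2L] + 2L), call. = FALSE)
    }
    ids <- vapply(fields, `[[`, "", 1L)
    vals <- t(vapply(fields, function(f) as.numeric(f[-(1:2)]),
                     numeric(dims[2L])))
    if (dims[2L] == 1L) vals <- matrix(vals, ncol = 1L)
    dimnames(vals) <- list(ids, header[-(1:2)])
    vals
  } else {
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    body <- lines[-1L]
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    # header may or may not name the gene-id column
    ncol_data <- unique(nf) - 1L
    if (length(unique(nf)) != 1L) {
      stop("malformed TSV: rows have differing field counts", call. = FALSE)
    }
    col_ids <- if (length(header) == ncol_data + 1L) header[-1L] else header
    if (length(col_ids) != ncol_data) {
      stop(sprintf("malformed TSV header: %d column ids for %d data columns",
                   length(col_ids), ncol_data), call. = FALSE)
    }
    ids <- vapply(fields, `[[`, "", 1L)
    vals <- t(vapply(fields, function(f) as.numeric(f[-1L]), numeric(ncol_data)))
    if (ncol_data == 1L) vals <- matrix(vals, ncol = 1L)
    dimnames(vals) <- list(ids, col_ids)
    vals
  }
}

#' Read an expression matrix from GCT 1.2 or TSV text
#'
#' Accepts the GCT 1.2 layout (`#1.2` version line, `<ngene> <nsample>`
#' dimension line, `NAME`/`Description` columns) or a plain TSV whose first
#' row holds sample ids and whose first column holds gene ids.
#'
#' @param path path to the file.
#' @param group_map named character vector mapping each sample id in the file
#'   to `"control"` or `"treated"`.
#' @inheritParams expression_matrix
#' @return an [expression_matrix()].
#' @export
read_expression_gct <- function(path, group_map, cell_line = NA_character_) {
  vals <- parse_gct_matrix(path)
  expression_matrix(vals, group_map, cell_line = cell_line)
}

#' Write an expression matrix as GCT 1.2 text
#'
#' @param mat an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_gct <- function(mat, path) {
  stopifnot(inherits(mat, "expression_matrix"))
  write_gct_matrix(mat$values, path)
}

write_gct_matrix <- function(values, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#1.2", con)
  writeLines(sprintf("%d\t%d", nrow(values), ncol(values)), con)
  writeLines(paste(c("NAME", "Description", colnames(values)), collapse = "\t"), con)
  txt <- matrix(sprintf("%.17g", values), nrow = nrow(values))
  rows <- paste(rownames(values), "na",
                apply(txt, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(rows, con)
  invisible(path)
}

#' Serialize the group labels of an expression matrix to TSV
#'
#' Two columns, `sample_id` and `group`; the companion of
#' [write_expression_gct()] so a matrix round-trips through text files.
#' @param mat an [expression_matrix()].
#' @param path output path.
#' @export
write_group_map <- function(mat, path) {
  stopifnot(inherits(mat, "expression_matrix"))
  write_tsv(data.frame(sample_id = names(mat$groups), group = unname(mat$groups)),
            path)
}

#' Read a sample-to-group TSV written by [write_group_map()]
#' @param path path to a two-column TSV (`sample_id`, `group`).
#' @return named character vector suitable for [read_expression_gct()].
#' @export
read_group_map <- function(path) {
  df <- read_tsv(path)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("group map TSV must have columns 'sample_id' and 'group'", call. = FALSE)
  }
  stats::setNames(df$group, df$sample_id)
}
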