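#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (set id -> member gene ids).
#' @param descriptions optional named character vector of set descriptions.
#' @param universe optional explicit background gene list.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("'sets' must be a named list of gene id vectors", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) stop("set ids must be unique", call. = FALSE)
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty)) {
    stop(sprintf("gene set(s) with no members: %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  }
  dup <- names(sets)[vapply(sets, anyDuplicated, integer(1L)) > 0L]
  if (length(dup)) {
    stop(sprintf("duplicate members within set(s): %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)],
                 universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, median size %g%s\n",
              length(x$sets), stats::median(lengths(x$sets)),
              if (is.null(x$universe)) ""
              else sprintf(", universe of %d genes", length(x$universe))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' Broad convention: one set per line, tab-separated
#' `set_id<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path path to the GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf("GMT line %d has no members (need id, description, >=1 gene)",
                 short[1L]), call. = FALSE)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- ids
  gene_set_collection(sets, stats::setNames(desc, ids))
}

#' Write a gene-set collection in GMT format
#' @param gsc a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(names(gsc$sets), function(id) {
    paste(c(id, gsc$descriptions[[id]] %||% "", gsc$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}
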