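#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query list is enriched for the set's
#' members against an explicit background universe, using the upper-tail
#' hypergeometric probability `P(X >= k)` (equivalently a one-sided Fisher
#' exact test on the 2x2 overlap table). The EASE variant replaces the
#' observed overlap `k` with `max(k - 1, 0)` before taking the tail, giving a
#' deliberately conservative p-value. Optionally Benjamini-Hochberg adjusted
#' p-values are appended.
#'
#' Query genes outside the universe are dropped with a logged count; each
#' set is intersected with the universe before testing.
#'
#' @param query character vector of gene ids.
#' @param sets a [gene_set_collection()].
#' @param universe background gene list; defaults to the collection's
#'   universe if it carries one.
#' @param ease use the conservative EASE overlap decrement.
#' @param bh append Benjamini-Hochberg adjusted p-values.
#' @return data.frame (class `enrichment_table`), one row per set, sorted by
#'   ascending p (ties by set id): `set_id`, `description`, `overlap_count`,
#'   `query_size`, `set_size`, `universe_size`, `p_value`, optionally
#'   `adjusted_p`, and `overlap_genes` (`;`-separated).
#' @export
ora <- function(query, sets, universe = NULL, ease = FALSE, bh = FALSE) {
  stopifnot(inherits(sets, "gene_set_collection"))
  universe <- universe %||% sets$universe
  if (is.null(universe) || !length(universe)) {
    stop("an explicit, non-empty background universe is required", call. = FALSE)
  }
  universe <- unique(universe)
  if (!length(query)) stop("empty query gene list", call. = FALSE)
  query <- unique(query)
  outside <- !(query %in% universe)
  if (any(outside)) {
    sc_log("ora: dropped %d query gene(s) outside the universe", sum(outside))
  }
  query <- query[!outside]
  if (!length(query)) {
    stop("no query gene lies in the background universe", call. = FALSE)
  }
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(sets$sets), function(id) {
    members <- intersect(sets$sets[[id]], universe)
    s <- length(members)
    ov <- intersect(query, members)
    k <- length(ov)
    kk <- if (ease) max(k - 1L, 0L) else k
    # upper tail P(X >= kk) for X ~ Hypergeom(N, s, q)
    p <- stats::phyper(kk - 1L, s, N - s, q, lower.tail = FALSE)
    data.frame(set_id = id, description = sets$descriptions[[id]] %||% "",
               overlap_count = k, query_size = q, set_size = s,
               universe_size = N, p_value = p,
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bh) {
    out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
    out <- out[, c("set_id", "description", "overlap_count", "query_size",
                   "set_size", "universe_size", "p_value", "adjusted_p",
                   "overlap_genes")]
  }
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_table", "data.frame"))
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("enrichment_table: %d sets tested, %d with p < 0.05\n",
              nrow(x), sum(x$p_value < 0.05)))
  NextMethod()
}

#' Merge DEG lists across cell lines
#'
#' Deduplicated union of the up- or down-regulated genes of several DEG
#' sets, e.g. to build one query list per direction for enrichment.
#'
#' @param degsets list of [select_degs()] results.
#' @param direction `"up"` or `"down"`.
#' @return sorted character vector of gene ids.
#' @export
merge_gene_sets <- function(degsets, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!length(degsets)) stop("need at least one DEG set", call. = FALSE)
  stopifnot(all(vapply(degsets, inherits, logical(1L), "deg_set")))
  sort(unique(unlist(lapply(degsets, `[[`, direction), use.names = FALSE)))
}
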