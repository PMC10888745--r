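#' Signed-rank profile of one reference signature
#'
#' Ranks the signature's genes by absolute amplitude, ascending (rank n =
#' largest |amplitude|), ties broken deterministically by ascending gene id,
#' and attaches the amplitude's sign. A gene with amplitude exactly 0 gets
#' signed rank 0 and never contributes to a score.
#'
#' @param amplitudes named numeric vector (gene id -> amplitude), or a
#'   [signature_library()] together with `signature_id`.
#' @param signature_id when `amplitudes` is a library, the column to use.
#' @return object of class `reference_rank_profile`: named integer vector of
#'   signed ranks with attributes `n` (number of landmark genes) and
#'   `signature_id`.
#' @examples
#' build_reference_ranks(c(A = 2, B = -1, C = 0.5))  # A:+3 B:-2 C:+1
#' @export
build_reference_ranks <- function(amplitudes, signature_id = NA_character_) {
  if (inherits(amplitudes, "signature_library")) {
    lib <- amplitudes
    if (!signature_id %in% colnames(lib$amplitudes)) {
      stop(sprintf("signature '%s' not in library", signature_id), call. = FALSE)
    }
    amplitudes <- stats::setNames(lib$amplitudes[, signature_id], lib$genes)
  }
  if (is.null(names(amplitudes)) || anyDuplicated(names(amplitudes))) {
    stop("amplitudes must be named by unique gene ids", call. = FALSE)
  }
  if (any(!is.finite(amplitudes))) stop("amplitudes must be finite", call. = FALSE)
  n <- length(amplitudes)
  a <- abs(amplitudes)
  o <- order(a, names(amplitudes))          # ties by ascending gene id
  rank_abs <- integer(n)
  rank_abs[o] <- seq_len(n)
  sr <- as.integer(sign(amplitudes)) * rank_abs
  if (all(sr == 0L)) sc_log("build_reference_ranks: all-zero amplitude vector")
  structure(stats::setNames(sr, names(amplitudes)),
            n = n, signature_id = signature_id,
            class = "reference_rank_profile")
}

#' @export
print.reference_rank_profile <- function(x, ...) {
  cat(sprintf("reference_rank_profile: %d landmark genes (%d nonzero)\n",
              attr(x, "n"), sum(unclass(x) != 0L)))
  invisible(x)
}

#' Build an ordered query signature from a contrast table
#'
#' Takes the DEGs of a contrast (per [select_degs()] thresholds), keeps those
#' present in the landmark gene space, orders them ascending by |log2fc|
#' (position m = strongest change), optionally truncates to the `m_max`
#' strongest, and attaches signed query ranks: `sign(log2fc) * position` in
#' ordered mode, or just the sign (+/-1) in unordered mode.
#'
#' @param ct a [contrast()] table.
#' @param landmark_genes character vector of reference landmark gene ids.
#' @param m_max optional cap on query size (keeps the strongest genes).
#' @param fc_cutoff,p_cutoff DEG thresholds passed to [select_degs()].
#' @param mode `"ordered"` (ranks carry magnitude order) or `"unordered"`
#'   (signs only).
#' @return object of class `query_signature`: data.frame with columns `gene`,
#'   `log2fc`, `sr` (signed query rank), ordered weakest to strongest;
#'   attributes `mode`, `m`, `n_dropped` (DEGs absent from landmarks).
#' @export
build_query <- function(ct, landmark_genes, m_max = NULL,
                        fc_cutoff = 1.5, p_cutoff = 0.05,
                        mode = c("ordered", "unordered")) {
  mode <- match.arg(mode)
  degs <- select_degs(ct, fc_cutoff = fc_cutoff, p_cutoff = p_cutoff)
  genes <- c(degs$up, degs$down)
  in_lm <- genes %in% landmark_genes
  n_dropped <- sum(!in_lm)
  if (n_dropped) {
    sc_log("build_query: dropped %d DEG(s) absent from the landmark space",
           n_dropped)
  }
  genes <- genes[in_lm]
  if (!length(genes)) {
    stop("empty query: no DEG lies in the landmark gene space", call. = FALSE)
  }
  idx <- match(genes, ct$gene)
  lfc <- ct$log2fc[idx]
  o <- order(abs(lfc), genes)               # ascending strength, ties by id
  genes <- genes[o]; lfc <- lfc[o]
  if (!is.null(m_max) && length(genes) > m_max) {
    keep <- seq.int(length(genes) - m_max + 1L, length(genes))
    genes <- genes[keep]; lfc <- lfc[keep]
  }
  m <- length(genes)
  sr <- if (mode == "ordered") as.integer(sign(lfc)) * seq_len(m)
        else as.integer(sign(lfc))
  structure(data.frame(gene = genes, log2fc = lfc, sr = sr,
                       stringsAsFactors = FALSE),
            mode = mode, m = m, n_dropped = n_dropped,
            class = c("query_signature", "data.frame"))
}

#' Assemble a query signature directly from signed ranks
#'
#' Low-level constructor used by the scoring examples and the generators:
#' genes are given weakest to strongest with their direction.
#'
#' @param genes character vector, ascending strength.
#' @param signs vector of +1/-1 per gene.
#' @param mode `"ordered"` or `"unordered"`.
#' @return a `query_signature`.
#' @export
query_signature <- function(genes, signs, mode = c("ordered", "unordered")) {
  mode <- match.arg(mode)
  if (anyDuplicated(genes)) stop("query genes must be unique", call. = FALSE)
  if (length(genes) < 1L) stop("query must contain at least one gene", call. = FALSE)
  if (length(signs) != length(genes) || any(!signs %in% c(-1, 1))) {
    stop("'signs' must be +1/-1, one per gene", call. = FALSE)
  }
  m <- length(genes)
  sr <- if (mode == "ordered") as.integer(signs) * seq_len(m)
        else as.integer(signs)
  structure(data.frame(gene = as.character(genes),
                       log2fc = as.numeric(signs) * seq_len(m), sr = sr,
                       stringsAsFactors = FALSE),
            mode = mode, m = m, n_dropped = 0L,
            class = c("query_signature", "data.frame"))
}

#' @export
print.query_signature <- function(x, ...) {
  cat(sprintf("query_signature: %d genes, %s mode (%d DEGs dropped off-landmark)\n",
              attr(x, "m"), attr(x, "mode"), attr(x, "n_dropped")))
  NextMethod()
}

#' Normalized Zhang connectivity score of a query against one reference
#'
#' The raw connection strength is the sum of products of reference and query
#' signed ranks over the query genes carried by the reference,
#' `C = sum_i sr_ref(g_i) * sr_q(g_i)`. It is normalized by its theoretical
#' maximum `C_max` — attained when the strongest query genes sit at the
#' strongest reference ranks with matching signs — giving
#' `c = C / C_max` in `[-1, 1]`: +1 is perfect mimicry, -1 perfect reversal.
#' In ordered mode `C_max = sum_{k=0}^{m_eff-1} (m_eff - k) (n - k)`; in
#' unordered mode `C_max = sum_{k=0}^{m_eff-1} (n - k)`, with `n` the number
#' of landmark genes and `m_eff` the number of query genes present in the
#' reference with nonzero rank.
#'
#' Query genes absent from the reference (or sitting on a zero amplitude)
#' are set aside first and the remaining genes re-ranked 1..m_eff in their
#' original strength order, which keeps the score within `[-1, 1]` and makes
#' it invariant to dropping a gene the reference does not carry.
#'
#' Both `C` and `C_max` are products and sums of integer ranks, so `c` is
#' exact up to the single final division.
#'
#' @param ref a [build_reference_ranks()] profile.
#' @param q a [build_query()] / [query_signature()] object.
#' @param meta optional named list (`signature_id`, `perturbagen_id`,
#'   `cell_line`) copied into the record.
#' @return a one-row data.frame (class `connectivity_record`) with columns
#'   `signature_id`, `perturbagen_id`, `cell_line`, `c`, `m_eff`.
#' @examples
#' ref <- build_reference_ranks(c(A = 5, B = -4, C = 3, D = -2, E = 1))
#' q <- query_signature(c("C", "B"), c(+1, +1))
#' zhang_score(ref, q)$c  # -5/14
#' @export
zhang_score <- function(ref, q, meta = list()) {
  stopifnot(inherits(ref, "reference_rank_profile"),
            inherits(q, "query_signature"))
  n <- attr(ref, "n")
  sr_ref <- unclass(ref)
  attributes(sr_ref) <- list(names = names(sr_ref))
  res <- zhang_score_core(sr_ref, n, q)
  structure(data.frame(
    signature_id = meta$signature_id %||% attr(ref, "signature_id"),
    perturbagen_id = meta$perturbagen_id %||% NA_character_,
    cell_line = meta$cell_line %||% NA_character_,
    c = res$c, m_eff = res$m_eff,
    stringsAsFactors = FALSE),
    class = c("connectivity_record", "data.frame"))
}

# Shared scoring core: named signed-rank vector + query -> list(c, m_eff).
# Stops with "undefined score" errors for m_eff = 0 or C_max = 0.
zhang_score_core <- function(sr_ref, n, q) {
  hit <- q$gene %in% names(sr_ref)[sr_ref != 0L]
  m_eff <- sum(hit)
  if (m_eff == 0L) {
    stop("undefined score: no query gene carries a nonzero reference rank",
         call. = FALSE)
  }
  signs <- sign(q$sr[hit])
  sr_q <- if (attr(q, "mode") == "ordered") signs * seq_len(m_eff) else signs
  Craw <- sum(as.numeric(sr_ref[q$gene[hit]]) * sr_q)
  ks <- 0:(m_eff - 1L)
  Cmax <- if (attr(q, "mode") == "ordered") sum((m_eff - ks) * (n - ks))
          else sum(n - ks)
  if (Cmax == 0) {
    stop("undefined score: degenerate reference (C_max = 0)", call. = FALSE)
  }
  list(c = Craw / Cmax, m_eff = m_eff)
}

#' Score every signature of a library against a query
#'
#' Applies [zhang_score()] to each signature, in deterministic
#' signature-id order. A signature for which the score is undefined (no
#' usable query gene, or an all-zero reference) yields a flagged record with
#' `c = NA` and the reason in `note` rather than an error.
#'
#' @param lib a [signature_library()].
#' @param q a query signature.
#' @return data.frame (class `connectivity_records`) with one row per
#'   signature: `signature_id`, `perturbagen_id`, `cell_line`, `c`, `m_eff`,
#'   `note`.
#' @export
score_library <- function(lib, q) {
  stopifnot(inherits(lib, "signature_library"))
  if (ncol(lib$amplitudes) == 0L) {
    stop("cannot score an empty signature library", call. = FALSE)
  }
  ord <- order(lib$meta$signature_id)
  nsig <- length(ord)
  cs <- numeric(nsig)
  meffs <- integer(nsig)
  notes <- character(nsig)
  n <- length(lib$genes)
  for (i in seq_len(nsig)) {
    j <- ord[i]
    a <- lib$amplitudes[, j]
    o <- order(abs(a), lib$genes)
    rank_abs <- integer(n)
    rank_abs[o] <- seq_len(n)
    sr_ref <- stats::setNames(as.integer(sign(a)) * rank_abs, lib$genes)
    rec <- tryCatch(zhang_score_core(sr_ref, n, q), error = function(e) e)
    if (inherits(rec, "error")) {
      cs[i] <- NA_real_
      notes[i] <- conditionMessage(rec)
    } else {
      cs[i] <- rec$c
      meffs[i] <- rec$m_eff
    }
  }
  out <- data.frame(signature_id = lib$meta$signature_id[ord],
                    perturbagen_id = lib$meta$perturbagen_id[ord],
                    cell_line = lib$meta$cell_line[ord],
                    c = cs, m_eff = meffs, note = notes,
                    stringsAsFactors = FALSE)
  structure(out, class = c("connectivity_records", "data.frame"))
}

#' @export
print.connectivity_records <- function(x, ...) {
  cat(sprintf("connectivity_records: %d signatures, c in [%.3f, %.3f]%s\n",
              nrow(x),
              suppressWarnings(min(x$c, na.rm = TRUE)),
              suppressWarnings(max(x$c, na.rm = TRUE)),
              if (any(is.na(x$c))) sprintf(" (%d undefined)", sum(is.na(x$c)))
              else ""))
  NextMethod()
}
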