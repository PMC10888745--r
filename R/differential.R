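#' Per-gene fold changes and p-values for one cell line
#'
#' For each gene, computes the mean intensity per group, the raw-scale fold
#' change `fc = mean_treated / mean_control`, the signed fold change
#' (`fc` when `fc >= 1`, else `-1/fc`, so down-regulation carries a negative
#' sign with magnitude >= 1), `log2fc = log2(fc)`, and a two-sided t-test
#' p-value on log2-transformed intensities (Welch by default).
#'
#' Genes with any non-positive intensity cannot be log-transformed and are
#' excluded from the table with a logged reason (no pseudocount is added);
#' they are reported in the `excluded` attribute. If both groups are exactly
#' constant the t statistic is undefined: equal means give p = 1, unequal
#' means give the smallest representable p (flagged in `excluded` as
#' `degenerate_variance`, but kept in the table).
#'
#' @param mat an [expression_matrix()].
#' @param cell_line label recorded in the output (defaults to the matrix's).
#' @param var_equal use the pooled-variance Student t-test instead of Welch.
#' @return a `contrast_table`: data.frame with columns `gene`,
#'   `mean_control`, `mean_treated`, `fc`, `signed_fc`, `log2fc`, `p_value`,
#'   `cell_line`, plus attribute `excluded` (data.frame gene/reason).
#' @examples
#' v <- matrix(c(10, 11, 9.5, 30, 29, 31), nrow = 1,
#'             dimnames = list("G1", paste0("s", 1:6)))
#' em <- expression_matrix(v, setNames(rep(c("control", "treated"), each = 3),
#'                                     paste0("s", 1:6)))
#' contrast(em)   # fc ~ 3, signed_fc ~ 3
#' @export
contrast <- function(mat, cell_line = NULL, var_equal = FALSE) {
  stopifnot(inherits(mat, "expression_matrix"))
  cell_line <- cell_line %||% mat$cell_line
  ctrl <- mat$values[, mat$groups == "control", drop = FALSE]
  trt <- mat$values[, mat$groups == "treated", drop = FALSE]
  n1 <- ncol(ctrl); n2 <- ncol(trt)
  if (n1 < 2L || n2 < 2L) {
    stop("need >= 2 replicates per group to compute a p-value", call. = FALSE)
  }

  nonpos <- rowSums(mat$values <= 0) > 0L
  excluded <- data.frame(gene = rownames(mat$values)[nonpos],
                         reason = rep("nonpositive_intensity", sum(nonpos)),
                         stringsAsFactors = FALSE)
  if (any(nonpos)) {
    sc_log("contrast: excluded %d gene(s) with non-positive intensities",
           sum(nonpos))
  }
  ctrl <- ctrl[!nonpos, , drop = FALSE]
  trt <- trt[!nonpos, , drop = FALSE]
  genes <- rownames(mat$values)[!nonpos]

  mean_control <- rowMeans(ctrl)
  mean_treated <- rowMeans(trt)
  fc <- mean_treated / mean_control
  signed_fc <- ifelse(fc >= 1, fc, -1 / fc)
  log2fc <- log2(fc)

  # Welch/Student t on log2 intensities, vectorised over genes
  lx <- log2(ctrl); ly <- log2(trt)
  m1 <- rowMeans(lx); m2 <- rowMeans(ly)
  v1 <- rowSums((lx - m1)^2) / (n1 - 1L)
  v2 <- rowSums((ly - m2)^2) / (n2 - 1L)
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2L, length(se2))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  tstat <- (m2 - m1) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)

  degen <- se2 == 0
  if (any(degen)) {
    p[degen & (m1 == m2)] <- 1
    p[degen & (m1 != m2)] <- .Machine$double.xmin
    excluded <- rbind(excluded,
                      data.frame(gene = genes[degen],
                                 reason = rep("degenerate_variance", sum(degen)),
                                 stringsAsFactors = FALSE))
    sc_log("contrast: %d gene(s) with zero within-group variance", sum(degen))
  }

  out <- data.frame(gene = genes,
                    mean_control = mean_control,
                    mean_treated = mean_treated,
                    fc = fc, signed_fc = signed_fc, log2fc = log2fc,
                    p_value = p,
                    cell_line = rep(cell_line %||% NA_character_, length(genes)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, excluded = excluded,
            class = c("contrast_table", "data.frame"))
}

#' @export
print.contrast_table <- function(x, ...) {
  cat(sprintf("contrast_table: %d genes, cell line %s (%d excluded)\n",
              nrow(x), x$cell_line[1L] %||% NA, nrow(attr(x, "excluded"))))
  NextMethod()
}

#' Select differentially expressed genes from a contrast table
#'
#' Up-regulated: `signed_fc >= fc_cutoff` and `p_value < p_cutoff`;
#' down-regulated: `signed_fc <= -fc_cutoff` and `p_value < p_cutoff`.
#' The fold-change boundary is inclusive. Optionally the p-values are
#' Benjamini-Hochberg adjusted before thresholding (off by default).
#'
#' @param ct a [contrast()] table.
#' @param fc_cutoff signed fold-change threshold, must be >= 1 (default 1.5).
#' @param p_cutoff p-value threshold (default 0.05).
#' @param adjust apply Benjamini-Hochberg correction before thresholding.
#' @return a `deg_set`: list with `cell_line`, `up`, `down`, `fc_cutoff`,
#'   `p_cutoff`.
#' @export
select_degs <- function(ct, fc_cutoff = 1.5, p_cutoff = 0.05, adjust = FALSE) {
  stopifnot(inherits(ct, "contrast_table"))
  if (fc_cutoff < 1) {
    stop("fc_cutoff must be >= 1 (signed fold changes have magnitude >= 1)",
         call. = FALSE)
  }
  p <- if (adjust) stats::p.adjust(ct$p_value, method = "BH") else ct$p_value
  up <- ct$gene[ct$signed_fc >= fc_cutoff & p < p_cutoff]
  down <- ct$gene[ct$signed_fc <= -fc_cutoff & p < p_cutoff]
  structure(list(cell_line = ct$cell_line[1L] %||% NA_character_,
                 up = up, down = down,
                 fc_cutoff = fc_cutoff, p_cutoff = p_cutoff),
            class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat(sprintf("deg_set (%s): %d up, %d down at |signed FC| >= %g, p < %g\n",
              x$cell_line, length(x$up), length(x$down),
              x$fc_cutoff, x$p_cutoff))
  invisible(x)
}

#' Partition DEGs across cell lines into Venn regions
#'
#' Assigns every gene appearing in any of the input sets (for the requested
#' direction) to exactly one region of the Venn partition: region names are
#' the sorted cell-line labels joined by `"&"` (e.g. `"A549&MCF7"` holds the
#' genes in those two sets and no other). All 2^k - 1 regions are reported,
#' empty ones as zero-length vectors.
#'
#' @param sets list of >= 2 [select_degs()] results with distinct cell lines.
#' @param direction `"up"` or `"down"`.
#' @return named list, region -> character vector of genes.
#' @export
overlap_degs <- function(sets, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(sets) < 2L) stop("need at least 2 DEG sets", call. = FALSE)
  stopifnot(all(vapply(sets, inherits, logical(1L), "deg_set")))
  labels <- vapply(sets, `[[`, "", "cell_line")
  if (anyDuplicated(labels)) {
    stop("duplicate cell_line labels across DEG sets", call. = FALSE)
  }
  members <- lapply(sets, `[[`, direction)
  names(members) <- labels
  all_genes <- unique(unlist(members, use.names = FALSE))
  # membership pattern per gene -> region key
  inset <- vapply(members, function(g) all_genes %in% g,
                  logical(length(all_genes)))
  if (length(all_genes) == 1L) inset <- matrix(inset, nrow = 1L)
  region_of <- apply(inset, 1L, function(row)
    paste(sort(labels[row]), collapse = "&"))
  # enumerate all non-empty label subsets so empty regions are explicit
  k <- length(labels)
  keys <- unlist(lapply(seq_len(k), function(sz)
    utils::combn(sort(labels), sz, FUN = paste, collapse = "&",
                 simplify = FALSE)))
  out <- stats::setNames(lapply(keys, function(key)
    if (length(all_genes)) sort(all_genes[region_of == key]) else character(0)),
    keys)
  out
}
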