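# Small in-code fixtures shared across test files.

# 2-group expression matrix from explicit per-gene replicate values.
# `control` / `treated` are lists: gene id -> numeric replicate vector.
make_expr <- function(control, treated, cell_line = "A549") {
  genes <- names(control)
  stopifnot(identical(genes, names(treated)))
  vals <- cbind(do.call(rbind, control), do.call(rbind, treated))
  r1 <- length(control[[1L]]); r2 <- length(treated[[1L]])
  ids <- c(sprintf("c%d", seq_len(r1)), sprintf("t%d", seq_len(r2)))
  colnames(vals) <- ids
  rownames(vals) <- genes
  expression_matrix(vals, setNames(rep(c("control", "treated"), c(r1, r2)), ids),
                    cell_line = cell_line)
}

# Tiny signature library: `amps` is a genes x signatures matrix (dimnames set).
make_library <- function(amps, cell_line = "A549", pert = NULL,
                         dose = "10 uM", time = "6 h") {
  sig_ids <- colnames(amps)
  meta <- data.frame(
    signature_id = sig_ids,
    perturbagen_id = pert %||% paste0("P_", sig_ids),
    cell_line = rep_len(cell_line, length(sig_ids)),
    dose = rep_len(dose, length(sig_ids)),
    time = rep_len(time, length(sig_ids)),
    stringsAsFactors = FALSE)
  signature_library(amps, meta)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

table1_targets_path <- function() {
  system.file("extdata", "table1_drug_targets.tsv", package = "sigconnect")
}

table1_drugs_path <- function() {
  system.file("extdata", "table1_drugs.tsv", package = "sigconnect")
}

# Brute-force maximum of the raw connection strength C over all placements of
# an m-gene ordered/unordered query into an n-gene reference: every injective
# assignment of query genes to reference genes, every sign pattern.
brute_force_cmax <- function(sr_ref, m, mode = "ordered") {
  n <- length(sr_ref)
  placements <- utils::combn(n, m, simplify = FALSE)
  best <- -Inf
  q_mag <- if (mode == "ordered") seq_len(m) else rep(1L, m)
  perms <- all_perms(m)
  for (pl in placements) {
    for (pm in perms) {
      refs <- sr_ref[pl[pm]]
      # optimal signs align each product to be positive
      best <- max(best, sum(abs(q_mag * refs)))
    }
  }
  best
}

all_perms <- function(m) {
  if (m == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(m - 1L)) {
    for (pos in seq_len(m)) {
      out[[length(out) + 1L]] <- append(p, m, after = pos - 1L)
    }
  }
  out
}

# Naive sum-of-products oracle for the raw strength C of a specific query
# against a specific reference (no closed forms, direct definition).
naive_C <- function(sr_ref, query_genes, query_sr) {
  total <- 0
  for (i in seq_along(query_genes)) {
    g <- query_genes[i]
    if (g %in% names(sr_ref) && sr_ref[[g]] != 0L) {
      total <- total + sr_ref[[g]] * query_sr[i]
    }
  }
  total
}
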