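#' Specification for the synthetic benchmark generators
#'
#' Bundles every tunable of the seeded generators. The defaults reproduce the
#' benchmark design the package is validated against: triplicate treated vs
#' control profiles over the 978-gene landmark space in three cancer cell
#' lines (A549, PC3, MCF7) at 10 uM / 6 h, 40 up- and 30 down-regulated genes
#' planted at fold change 2 under multiplicative log-normal noise
#' (sd 0.05 on the log scale), and a reference library of 200 decoy drugs
#' plus 5 planted mimics at template correlation 0.9.
#'
#' @param seed integer seed; every generator is a pure function of
#'   (spec, seed).
#' @param n_genes number of genes on the expression array.
#' @param n_landmark number of landmark genes in the reference space
#'   (first `n_landmark` gene ids; default 978).
#' @param replicates replicates per group (default 3).
#' @param n_up,n_down planted DEG counts.
#' @param effect_fc planted fold change (up-genes multiplied, down-genes
#'   divided by it).
#' @param noise_sd sd of the multiplicative log-normal noise (natural-log
#'   scale). At 0, an epsilon jitter of 1e-9 (relative) keeps within-group
#'   variances nonzero so t statistics stay defined.
#' @param n_drugs number of decoy drugs.
#' @param n_mimics,n_reversers planted drugs whose library signatures
#'   recapitulate (resp. invert) the planted query directions.
#' @param mimic_correlation template mixing weight rho in [0, 1]: mimic
#'   amplitude = rho * template + (1 - rho) * N(0, 1) noise.
#' @param cell_lines cell-line labels; one signature per drug per cell line.
#' @param dose,time metadata stamped on every generated signature.
#' @param target_actions action vocabulary sampled for generated drug-target
#'   edges.
#' @return object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(seed = 1L, n_genes = 978L, n_landmark = 978L,
                           replicates = 3L, n_up = 40L, n_down = 30L,
                           effect_fc = 2, noise_sd = 0.05,
                           n_drugs = 200L, n_mimics = 5L, n_reversers = 0L,
                           mimic_correlation = 0.9,
                           cell_lines = c("A549", "PC3", "MCF7"),
                           dose = "10 uM", time = "6 h",
                           target_actions = DRUG_ACTIONS) {
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               n_landmark = as.integer(n_landmark),
               replicates = as.integer(replicates),
               n_up = as.integer(n_up), n_down = as.integer(n_down),
               effect_fc = effect_fc, noise_sd = noise_sd,
               n_drugs = as.integer(n_drugs),
               n_mimics = as.integer(n_mimics),
               n_reversers = as.integer(n_reversers),
               mimic_correlation = mimic_correlation,
               cell_lines = cell_lines, dose = dose, time = time,
               target_actions = target_actions)
  if (spec$n_landmark > spec$n_genes) {
    stop("n_landmark cannot exceed n_genes", call. = FALSE)
  }
  if (spec$n_up + spec$n_down > spec$n_landmark) {
    stop("planted DEG counts exceed the landmark gene space", call. = FALSE)
  }
  if (spec$mimic_correlation < 0 || spec$mimic_correlation > 1) {
    stop("mimic_correlation must lie in [0, 1]", call. = FALSE)
  }
  if (spec$effect_fc <= 1) stop("effect_fc must exceed 1", call. = FALSE)
  if (spec$noise_sd < 0 || spec$replicates < 2L || spec$n_up < 0L ||
      spec$n_down < 0L || spec$n_drugs < 0L || spec$n_mimics < 0L ||
      spec$n_reversers < 0L) {
    stop("counts must be non-negative, noise_sd >= 0, replicates >= 2",
         call. = FALSE)
  }
  if (!all(spec$target_actions %in% DRUG_ACTIONS)) {
    stop("target_actions must come from the closed action vocabulary",
         call. = FALSE)
  }
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0("synthetic_spec: seed %d, %d genes (%d landmark), ",
                     "%d+%d planted DEGs at FC %g, noise_sd %g,\n  ",
                     "%d decoys + %d mimics + %d reversers at rho %g, ",
                     "cells %s, %s / %s\n"),
              x$seed, x$n_genes, x$n_landmark, x$n_up, x$n_down, x$effect_fc,
              x$noise_sd, x$n_drugs, x$n_mimics, x$n_reversers,
              x$mimic_correlation, paste(x$cell_lines, collapse = "/"),
              x$dose, x$time))
  invisible(x)
}

synthetic_gene_ids <- function(spec) {
  sprintf("G%05d", seq_len(spec$n_genes))
}

#' Landmark gene ids of a synthetic spec
#' @param spec a [synthetic_spec()].
#' @return character vector of the first `n_landmark` gene ids.
#' @export
landmark_genes <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  synthetic_gene_ids(spec)[seq_len(spec$n_landmark)]
}

# Planted DEG identities are drawn once per seed (stream 0) and shared by all
# cell lines, so one mimic template can correlate with every cell's query.
planted_degs <- function(spec) {
  lm <- landmark_genes(spec)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sub_seed(spec$seed, 0L))
  picked <- sample(lm, spec$n_up + spec$n_down)
  list(up = sort(picked[seq_len(spec$n_up)]),
       down = sort(picked[spec$n_up + seq_len(spec$n_down)]))
}

#' Signed direction map of the planted query
#'
#' The planted truth as a named vector of signed log2 effects
#' (+log2(effect_fc) for planted up-genes, -log2(effect_fc) for down-genes),
#' the form [gen_library()] expects for its mimic template.
#' @param spec a [synthetic_spec()].
#' @return named numeric vector over the planted genes.
#' @export
planted_truth_query <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  truth <- planted_degs(spec)
  stats::setNames(c(rep(log2(spec$effect_fc), length(truth$up)),
                    rep(-log2(spec$effect_fc), length(truth$down))),
                  c(truth$up, truth$down))
}

#' Generate a replicated treated/control expression matrix with planted DEGs
#'
#' Control intensities are log-normal baseline draws (meanlog log(100),
#' sdlog 0.8) shared by both groups; planted up-genes are multiplied and
#' planted down-genes divided by `effect_fc` in the treated group; every
#' intensity then receives multiplicative noise `exp(N(0, noise_sd^2))`.
#' Sample ids encode the cell line, group, and replicate index. Fully
#' reproducible from (spec, cell_line).
#'
#' @param spec a [synthetic_spec()].
#' @param cell_line one of `spec$cell_lines`.
#' @return list with `matrix` (an [expression_matrix()]) and `truth`
#'   (list of planted `up` / `down` gene ids).
#' @export
gen_expression <- function(spec, cell_line) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ci <- match(cell_line, spec$cell_lines)
  if (is.na(ci)) {
    stop(sprintf("unknown cell line '%s'", cell_line), call. = FALSE)
  }
  truth <- planted_degs(spec)
  genes <- synthetic_gene_ids(spec)
  r <- spec$replicates
  sd_eff <- max(spec$noise_sd, 1e-9)  # epsilon jitter at noise_sd = 0

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sub_seed(spec$seed, ci))

  baseline <- exp(stats::rnorm(spec$n_genes, log(100), 0.8))
  effect <- rep(1, spec$n_genes)
  effect[match(truth$up, genes)] <- spec$effect_fc
  effect[match(truth$down, genes)] <- 1 / spec$effect_fc

  noise <- matrix(exp(stats::rnorm(spec$n_genes * 2L * r, 0, sd_eff)),
                  nrow = spec$n_genes)
  vals <- cbind(baseline * noise[, seq_len(r), drop = FALSE],
                baseline * effect * noise[, r + seq_len(r), drop = FALSE])
  sample_ids <- c(sprintf("%s_DMSO_%d", cell_line, seq_len(r)),
                  sprintf("%s_TRT_%d", cell_line, seq_len(r)))
  dimnames(vals) <- list(genes, sample_ids)
  groups <- stats::setNames(rep(c("control", "treated"), each = r), sample_ids)
  list(matrix = expression_matrix(vals, groups, cell_line = cell_line),
       truth = truth)
}

#' Generate an L1000-style reference library with planted mimics/reversers
#'
#' Decoy signatures are i.i.d. standard-normal amplitude vectors over the
#' landmark genes. Each planted mimic mixes a direction-aligned template
#' with noise, `rho * template + (1 - rho) * N(0, 1)`, where the template
#' carries the truth query's signs scaled to amplitude 5 (so at high rho the
#' query genes occupy the top absolute ranks with matching signs); reversers
#' are identical with all template signs flipped. Every drug receives one
#' signature per cell line at the spec's dose/time; perturbagen ids embed
#' the drug id as a trailing `_DBnnnnn` suffix.
#'
#' @param spec a [synthetic_spec()].
#' @param truth_query named numeric vector of signed query directions over
#'   landmark genes (e.g. [planted_truth_query()]).
#' @return list with `library` (a [signature_library()]), and the planted
#'   drug id vectors `mimic_drugs`, `reverser_drugs`, `decoy_drugs`.
#' @export
gen_library <- function(spec, truth_query = planted_truth_query(spec)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lm <- landmark_genes(spec)
  outside <- setdiff(names(truth_query), lm)
  if (length(outside)) {
    stop(sprintf("truth query gene(s) outside the landmark space: %s",
                 paste(utils::head(outside, 5L), collapse = ", ")),
         call. = FALSE)
  }
  n <- spec$n_landmark
  rho <- spec$mimic_correlation
  template <- rep(0, n)
  names(template) <- lm
  if (length(truth_query)) {
    template[names(truth_query)] <-
      truth_query * (5 / max(abs(truth_query)))
  }

  n_total <- spec$n_drugs + spec$n_mimics + spec$n_reversers
  drug_ids <- sprintf("DB%05d", seq_len(n_total))
  kind <- rep(c("decoy", "mimic", "reverser"),
              c(spec$n_drugs, spec$n_mimics, spec$n_reversers))
  pert_ids <- sprintf("BRD-S%06d_%s", seq_len(n_total), drug_ids)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sub_seed(spec$seed, 1000L))

  ncell <- length(spec$cell_lines)
  amp <- matrix(stats::rnorm(n * n_total * ncell), nrow = n)
  sig_ids <- character(n_total * ncell)
  meta_pert <- character(n_total * ncell)
  meta_cell <- character(n_total * ncell)
  col <- 0L
  for (ci in seq_len(ncell)) {
    for (d in seq_len(n_total)) {
      col <- col + 1L
      if (kind[d] == "mimic") {
        amp[, col] <- rho * template + (1 - rho) * amp[, col]
      } else if (kind[d] == "reverser") {
        amp[, col] <- -rho * template + (1 - rho) * amp[, col]
      }
      sig_ids[col] <- sprintf("SIG_%s_%s", drug_ids[d], spec$cell_lines[ci])
      meta_pert[col] <- pert_ids[d]
      meta_cell[col] <- spec$cell_lines[ci]
    }
  }
  dimnames(amp) <- list(lm, sig_ids)
  meta <- data.frame(signature_id = sig_ids, perturbagen_id = meta_pert,
                     cell_line = meta_cell,
                     dose = rep(spec$dose, length(sig_ids)),
                     time = rep(spec$time, length(sig_ids)),
                     stringsAsFactors = FALSE)
  list(library = signature_library(amp, meta),
       mimic_drugs = drug_ids[kind == "mimic"],
       reverser_drugs = drug_ids[kind == "reverser"],
       decoy_drugs = drug_ids[kind == "decoy"])
}

#' Generate a synthetic drug-target table
#'
#' Every generated drug receives 1-5 targets drawn from a synthetic protein
#' pool, with actions sampled from the spec's action vocabulary. Planted
#' mimic and reverser drugs additionally receive one designated true target
#' (`TGT_TRUE_<drug>`, action `inhibitor`) so end-to-end recovery of planted
#' targets can be asserted. Includes the perturbagen map matching
#' [gen_library()].
#'
#' @param spec a [synthetic_spec()].
#' @return a [drug_target_table()] with attribute `true_targets` (named by
#'   planted drug id).
#' @export
gen_drug_targets <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_total <- spec$n_drugs + spec$n_mimics + spec$n_reversers
  drug_ids <- sprintf("DB%05d", seq_len(n_total))
  kind <- rep(c("decoy", "mimic", "reverser"),
              c(spec$n_drugs, spec$n_mimics, spec$n_reversers))
  pert_ids <- sprintf("BRD-S%06d_%s", seq_len(n_total), drug_ids)
  pool <- sprintf("TGT%04d", seq_len(max(50L, n_total)))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sub_seed(spec$seed, 2000L))

  rows <- lapply(seq_len(n_total), function(d) {
    k <- sample(1:5, 1L)
    tg <- sample(pool, k)
    data.frame(drug_id = drug_ids[d],
               drug_name = sprintf("drug-%s", tolower(drug_ids[d])),
               target_gene_symbol = tg,
               target_uniprot_id = sprintf("P%05d", match(tg, pool)),
               action = sample(spec$target_actions, k, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  planted <- drug_ids[kind != "decoy"]
  true_targets <- stats::setNames(sprintf("TGT_TRUE_%s", planted), planted)
  if (length(planted)) {
    edges <- rbind(edges, data.frame(
      drug_id = planted,
      drug_name = sprintf("drug-%s", tolower(planted)),
      target_gene_symbol = unname(true_targets),
      target_uniprot_id = sprintf("Q%05d", seq_along(planted)),
      action = rep("inhibitor", length(planted)),
      stringsAsFactors = FALSE))
  }
  # sampling can repeat a (drug, target, action) key; keep first occurrence
  key <- paste(edges$drug_id, edges$target_gene_symbol, edges$action, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  out <- drug_target_table(edges,
                           data.frame(perturbagen_id = pert_ids,
                                      drug_id = drug_ids,
                                      stringsAsFactors = FALSE))
  attr(out, "true_targets") <- true_targets
  out
}

#' Generate a synthetic gene-set collection
#'
#' One set per planted direction (`planted_up`, `planted_down`, holding the
#' planted DEGs) plus `n_decoy_sets` random sets drawn from the gene space,
#' in the same GMT-compatible shape [read_gmt()] produces.
#'
#' @param spec a [synthetic_spec()].
#' @param n_decoy_sets number of random background sets (default 10).
#' @return a [gene_set_collection()] with the expression gene space as its
#'   universe.
#' @export
gen_gmt <- function(spec, n_decoy_sets = 10L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  truth <- planted_degs(spec)
  genes <- synthetic_gene_ids(spec)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sub_seed(spec$seed, 3000L))

  sets <- list()
  desc <- character(0)
  if (length(truth$up)) {
    sets$planted_up <- truth$up
    desc["planted_up"] <- "planted up-regulated genes"
  }
  if (length(truth$down)) {
    sets$planted_down <- truth$down
    desc["planted_down"] <- "planted down-regulated genes"
  }
  for (i in seq_len(n_decoy_sets)) {
    id <- sprintf("decoy_set_%02d", i)
    sets[[id]] <- sort(sample(genes, sample(10:50, 1L)))
    desc[id] <- "random decoy set"
  }
  gene_set_collection(sets, desc, universe = genes)
}

#' Write every synthetic pipeline input to a directory
#'
#' Materializes the generators as the text files the readers consume: one
#' GCT + group-map TSV per cell line, the library GCT + metadata TSV, the
#' drug-target and perturbagen-map TSVs, and a GMT collection. Returns the
#' paths in the layout [run_config()] expects, so
#' `run_pipeline(run_config(simulate_inputs(spec, dir)))` is a complete
#' desk-scale run.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return named list of paths: `expression` (named by cell line), `groups`,
#'   `library_matrix`, `library_meta`, `drug_targets`, `perturbagen_map`,
#'   `gmt`.
#' @export
simulate_inputs <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_paths <- character(0)
  group_paths <- character(0)
  for (cl in spec$cell_lines) {
    ge <- gen_expression(spec, cl)
    ep <- file.path(dir, sprintf("expr_%s.gct", cl))
    gp <- file.path(dir, sprintf("groups_%s.tsv", cl))
    write_expression_gct(ge$matrix, ep)
    write_group_map(ge$matrix, gp)
    expr_paths[cl] <- ep
    group_paths[cl] <- gp
  }
  gl <- gen_library(spec)
  mp <- file.path(dir, "library.gct")
  tp <- file.path(dir, "library_meta.tsv")
  write_signature_library(gl$library, mp, tp)
  dt <- gen_drug_targets(spec)
  dp <- file.path(dir, "drug_targets.tsv")
  pp <- file.path(dir, "perturbagen_map.tsv")
  write_drug_targets(dt, dp, pp)
  gmtp <- file.path(dir, "sets.gmt")
  write_gmt(gen_gmt(spec), gmtp)
  list(expression = expr_paths, groups = group_paths,
       library_matrix = mp, library_meta = tp,
       drug_targets = dp, perturbagen_map = pp, gmt = gmtp)
}
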