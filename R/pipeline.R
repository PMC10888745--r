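#' Build and validate a pipeline run configuration
#'
#' A run configuration names every input file and threshold of the
#' end-to-end analysis. It can be given as a named list (e.g. the output of
#' [simulate_inputs()] plus options) or as the path to a YAML file holding
#' the same fields.
#'
#' Fields: `expression` (named list/vector, cell line -> GCT/TSV path),
#' `groups` (cell line -> sample-to-group TSV path), `library_matrix`,
#' `library_meta`, `drug_targets`, `perturbagen_map` (optional), `gmt`,
#' `out_dir`, and options `fc_cutoff` (1.5), `p_cutoff` (0.05), `mode`
#' ("ordered"), `m_max` (NULL), `k` (10), `policy` ("require_all_cells"),
#' `dose`/`time` library filters (NULL = no filter), `approved_only`
#' (FALSE), `ease`/`bh` enrichment flags (FALSE).
#'
#' @param x named list of fields, or path to a YAML file.
#' @param ... fields overriding those in `x`.
#' @return object of class `run_config`.
#' @export
run_config <- function(x = list(), ...) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop(sprintf("config file not found: %s", x), call. = FALSE)
    x <- yaml::read_yaml(x)
  }
  stopifnot(is.list(x))
  dots <- list(...)
  x[names(dots)] <- dots
  defaults <- list(fc_cutoff = 1.5, p_cutoff = 0.05, mode = "ordered",
                   m_max = NULL, k = 10L, policy = "require_all_cells",
                   dose = NULL, time = NULL, approved_only = FALSE,
                   ease = FALSE, bh = FALSE, out_dir = tempfile("sigconnect_run_"))
  for (f in names(defaults)) if (is.null(x[[f]])) x[[f]] <- defaults[[f]]

  need <- c("expression", "groups", "library_matrix", "library_meta",
            "drug_targets", "gmt")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop(sprintf("run_config is missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  x$expression <- unlist(x$expression)
  x$groups <- unlist(x$groups)
  if (is.null(names(x$expression)) || is.null(names(x$groups))) {
    stop("'expression' and 'groups' must be named by cell line", call. = FALSE)
  }
  if (!setequal(names(x$expression), names(x$groups))) {
    stop("'expression' and 'groups' must cover the same cell lines", call. = FALSE)
  }
  paths <- c(x$expression, x$groups, x$library_matrix, x$library_meta,
             x$drug_targets, x$perturbagen_map, x$gmt)
  absent <- paths[!file.exists(paths)]
  if (length(absent)) {
    stop(sprintf("input path(s) do not exist: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  if (x$fc_cutoff < 1 || x$p_cutoff <= 0) {
    stop("thresholds must be positive (fc_cutoff >= 1)", call. = FALSE)
  }
  x$mode <- match.arg(x$mode, c("ordered", "unordered"))
  x$policy <- match.arg(x$policy, c("require_all_cells", "mean_available"))
  structure(x, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run_config: %d cell line(s) [%s], FC >= %g, p < %g, %s mode, k = %d\n",
              length(x$expression), paste(names(x$expression), collapse = ", "),
              x$fc_cutoff, x$p_cutoff, x$mode, x$k))
  invisible(x)
}

config_fingerprint <- function(cfg) {
  # path fields are reduced to basenames so the fingerprint identifies the
  # analysis (inputs by name + parameters), not where it was staged
  flat <- unclass(cfg)
  path_fields <- c("expression", "groups", "library_matrix", "library_meta",
                   "drug_targets", "perturbagen_map", "gmt", "out_dir")
  for (f in intersect(path_fields, names(flat))) {
    flat[[f]] <- basename(flat[[f]])
  }
  flat <- flat[sort(names(flat))]
  fnv1a_hex(paste(utils::capture.output(utils::str(flat, give.attr = FALSE)),
                  collapse = "\n"))
}

run_stage <- function(name, fun) {
  tryCatch(fun(), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full signature-matching pipeline
#'
#' Executes, per the configuration: (1) per-cell-line contrast and DEG
#' selection; (2) the cross-cell Venn partition of DEGs; (3) reference
#' library loading and filtering; (4) per-cell query construction and
#' library scoring; (5) cross-cell drug aggregation and top-k ranking;
#' (6) antagonist/inhibitor target extraction; (7) over-representation
#' analysis of the merged up/down DEG lists. Each stage's table is written
#' to `out_dir` (TSV/JSON), and a machine-readable report (row counts per
#' stage, config fingerprint, package version) is written as `report.json`.
#' Identical configs and inputs give identical outputs; the report body
#' carries no timestamps.
#'
#' @param cfg a [run_config()] (or anything [run_config()] accepts).
#' @return the report, invisibly (class `run_report`).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cells <- sort(names(cfg$expression))
  outputs <- character(0)
  counts <- list()

  # stage 1: contrasts + DEG sets
  contrasts <- list(); degsets <- list()
  run_stage("contrast", function() {
    for (cl in cells) {
      gm <- read_group_map(cfg$groups[[cl]])
      em <- read_expression_gct(cfg$expression[[cl]], gm, cell_line = cl)
      ct <- contrast(em)
      contrasts[[cl]] <<- ct
      degsets[[cl]] <<- select_degs(ct, cfg$fc_cutoff, cfg$p_cutoff)
      p <- file.path(cfg$out_dir, sprintf("contrast_%s.tsv", cl))
      write_tsv(as.data.frame(ct), p)
      outputs <<- c(outputs, p)
    }
    counts$degs <<- lapply(degsets, function(d)
      list(up = length(d$up), down = length(d$down)))
  })

  # stage 2: Venn partition of DEGs across cell lines
  run_stage("overlap", function() {
    venn <- list()
    if (length(cells) >= 2L) {
      venn <- list(up = lapply(overlap_degs(degsets, "up"), as.list),
                   down = lapply(overlap_degs(degsets, "down"), as.list))
    }
    p <- file.path(cfg$out_dir, "venn_regions.json")
    jsonlite::write_json(venn, p, auto_unbox = TRUE, pretty = TRUE)
    outputs <<- c(outputs, p)
    counts$venn_regions <<- length(venn$up)
  })

  # stage 3: reference library
  drug_table <- NULL; lib <- NULL
  run_stage("library", function() {
    drug_table <<- read_drug_targets(cfg$drug_targets, cfg$perturbagen_map)
    full <- read_signature_library(cfg$library_matrix, cfg$library_meta)
    lib <<- filter_library(full, dose = cfg$dose, time = cfg$time,
                           approved_only = cfg$approved_only,
                           drug_map = drug_table)
    counts$library_signatures <<- length(lib)
  })

  # stage 4: queries + connectivity scores per cell line
  records <- list()
  run_stage("score", function() {
    for (cl in cells) {
      q <- build_query(contrasts[[cl]], lib$genes, m_max = cfg$m_max,
                       fc_cutoff = cfg$fc_cutoff, p_cutoff = cfg$p_cutoff,
                       mode = cfg$mode)
      recs <- score_library(filter_library(lib, cell_line = cl), q)
      records[[cl]] <- recs
      p <- file.path(cfg$out_dir, sprintf("scores_%s.tsv", cl))
      write_tsv(as.data.frame(recs), p)
      outputs <<- c(outputs, p)
    }
    records <<- records
    counts$scored_signatures <<- sum(vapply(records, nrow, 0L))
  })

  # stage 5: drug aggregation + ranking
  ranked <- NULL; top <- NULL
  run_stage("rank", function() {
    all_records <- do.call(rbind, lapply(records, as.data.frame))
    ranked <<- aggregate_by_drug(all_records, drug_table, policy = cfg$policy)
    top <<- top_k(ranked, cfg$k)
    p <- file.path(cfg$out_dir, "ranked_drugs.tsv")
    write_tsv(as.data.frame(ranked), p)
    outputs <<- c(outputs, p)
    counts$ranked_drugs <<- nrow(ranked)
  })

  # stage 6: target extraction
  run_stage("targets", function() {
    targets <- extract_targets(top, drug_table)
    p <- file.path(cfg$out_dir, "target_set.json")
    jsonlite::write_json(
      list(size = attr(targets, "size"), targets = as.data.frame(targets)),
      p, auto_unbox = TRUE, pretty = TRUE)
    outputs <<- c(outputs, p)
    counts$targets <<- attr(targets, "size")
  })

  # stage 7: enrichment of merged DEG lists
  run_stage("enrich", function() {
    gsc <- read_gmt(cfg$gmt)
    universe <- unique(unlist(lapply(contrasts, `[[`, "gene"),
                             use.names = FALSE))
    for (dir in c("up", "down")) {
      genes <- merge_gene_sets(degsets, dir)
      p <- file.path(cfg$out_dir, sprintf("enrichment_%s.tsv", dir))
      if (length(genes)) {
        et <- ora(genes, gsc, universe, ease = cfg$ease, bh = cfg$bh)
        write_tsv(as.data.frame(et), p)
        counts[[paste0("enriched_", dir)]] <<- sum(et$p_value < 0.05)
      } else {
        write_tsv(data.frame(set_id = character(0)), p)
        counts[[paste0("enriched_", dir)]] <<- 0L
      }
      outputs <<- c(outputs, p)
    }
  })

  report <- list(
    package = "sigconnect",
    version = as.character(utils::packageVersion("sigconnect")),
    config_fingerprint = config_fingerprint(cfg),
    parameters = list(fc_cutoff = cfg$fc_cutoff, p_cutoff = cfg$p_cutoff,
                      mode = cfg$mode, k = cfg$k, policy = cfg$policy),
    cell_lines = cells,
    counts = counts,
    outputs = basename(outputs))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(structure(report, class = "run_report"))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (sigconnect %s, config %s)\n",
              x$version, x$config_fingerprint))
  for (cl in names(x$counts$degs)) {
    cat(sprintf("  %s: %d up / %d down DEGs\n", cl,
                x$counts$degs[[cl]]$up, x$counts$degs[[cl]]$down))
  }
  cat(sprintf("  %d library signatures scored, %d drugs ranked, %d targets\n",
              x$counts$scored_signatures %||% 0L,
              x$counts$ranked_drugs %||% 0L,
              x$counts$targets %||% 0L))
  cat(sprintf("  outputs: %s\n", paste(x$outputs, collapse = ", ")))
  invisible(x)
}
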