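test_that("GCT 1.2 parsing honours the declared dimensions", {
  p <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "3\t6",
               paste(c("NAME", "Description", paste0("s", 1:6)), collapse = "\t"),
               paste(c("G1", "na", 1:6), collapse = "\t"),
               paste(c("G2", "na", 7:12), collapse = "\t"),
               paste(c("G3", "na", 13:18), collapse = "\t")), p)
  gm <- setNames(rep(c("control", "treated"), each = 3), paste0("s", 1:6))
  em <- read_expression_gct(p, gm)
  expect_equal(dim(em), c(3L, 6L))
  expect_equal(rownames(em$values), c("G1", "G2", "G3"))
  expect_equal(em$values["G2", "s4"], 10)

  # declared rows must match actual rows
  writeLines(c("#1.2", "4\t6",
               paste(c("NAME", "Description", paste0("s", 1:6)), collapse = "\t"),
               paste(c("G1", "na", 1:6), collapse = "\t")), p)
  expect_error(read_expression_gct(p, gm), "declares 4 rows")

  # malformed header names the offence
  writeLines(c("#1.2", "1\t6",
               paste(c("NAME", "Description", paste0("s", 1:5)), collapse = "\t"),
               paste(c("G1", "na", 1:6), collapse = "\t")), p)
  expect_error(read_expression_gct(p, gm), "header")
})

test_that("expression validation rejects NaN, negatives, and duplicates", {
  gm <- setNames(rep(c("control", "treated"), each = 2), paste0("s", 1:4))
  p <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "2\t4",
               paste(c("NAME", "Description", paste0("s", 1:4)), collapse = "\t"),
               paste(c("G1", "na", 1, "NaN", 3, 4), collapse = "\t"),
               paste(c("G2", "na", 1, 2, 3, 4), collapse = "\t")), p)
  expect_error(read_expression_gct(p, gm), "finite")

  writeLines(c("#1.2", "2\t4",
               paste(c("NAME", "Description", paste0("s", 1:4)), collapse = "\t"),
               paste(c("G1", "na", 1, 2, 3, 4), collapse = "\t"),
               paste(c("G1", "na", 1, 2, 3, 4), collapse = "\t")), p)
  expect_error(read_expression_gct(p, gm), "duplicate gene")

  v <- matrix(c(1, -2, 3, 4), 1, dimnames = list("G1", paste0("s", 1:4)))
  expect_error(expression_matrix(v, gm), ">= 0")
  # group map naming an absent sample is a key error
  v2 <- matrix(1:4, 1, dimnames = list("G1", paste0("s", 1:4)))
  expect_error(expression_matrix(v2, c(gm, s9 = "control")), "s9")
  expect_error(expression_matrix(v2, gm[1:3]), "no group label")
})

test_that("expression GCT round-trips exactly", {
  set.seed(42)
  v <- matrix(abs(rnorm(12, 100, 30)), 3,
              dimnames = list(c("G1", "G2", "G3"), paste0("s", 1:4)))
  gm <- setNames(rep(c("control", "treated"), each = 2), paste0("s", 1:4))
  em <- expression_matrix(v, gm)
  p <- withr::local_tempfile(fileext = ".gct")
  write_expression_gct(em, p)
  em2 <- read_expression_gct(p, gm)
  expect_identical(em2$values, em$values)
  expect_identical(em2$groups, em$groups)
})

test_that("signature library reader aligns metadata and validates shape", {
  set.seed(7)
  amps <- matrix(rnorm(978 * 50), 978,
                 dimnames = list(sprintf("L%04d", 1:978), sprintf("S%02d", 1:50)))
  lib <- make_library(amps)
  expect_equal(length(lib$genes), 978L)
  expect_equal(length(lib), 50L)

  mp <- withr::local_tempfile(fileext = ".gct")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_signature_library(lib, mp, tp)
  lib2 <- read_signature_library(mp, tp)
  expect_identical(lib2$amplitudes, lib$amplitudes)
  expect_identical(lib2$meta, lib$meta)

  # matrix declaring 978 rows but holding 977 is a format error
  lines <- readLines(mp)
  writeLines(lines[-10], mp)
  expect_error(read_signature_library(mp, tp), "declares 978 rows")

  # metadata missing one signature id names it
  write_signature_library(lib, mp, tp)
  meta <- read.delim(tp)
  write.table(meta[meta$signature_id != "S07", ], tp, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_signature_library(mp, tp), "S07")
})

test_that("filter_library matches criteria, normalizes units, is idempotent", {
  set.seed(11)
  amps <- matrix(rnorm(10 * 50), 10,
                 dimnames = list(sprintf("L%02d", 1:10), sprintf("S%02d", 1:50)))
  cells <- rep(c("A549", "PC3"), c(20, 30))
  lib <- make_library(amps, cell_line = cells,
                      dose = rep(c("10.0 uM", "1 uM"), c(40, 10)))
  f <- filter_library(lib, cell_line = "A549")
  expect_equal(length(f), 20L)
  expect_true(all(f$meta$cell_line == "A549"))

  # no criteria = identity
  expect_identical(filter_library(lib), lib)

  # "10 µM" must match stored "10.0 uM"
  fd <- filter_library(lib, dose = "10 µM")
  expect_equal(length(fd), 40L)
  ft <- filter_library(lib, time = "6 hr")
  expect_equal(length(ft), 50L)

  # idempotence
  once <- filter_library(lib, cell_line = "PC3", dose = "10 uM")
  twice <- filter_library(once, cell_line = "PC3", dose = "10 uM")
  expect_identical(twice, once)

  # empty result warns, does not error
  expect_warning(filter_library(lib, cell_line = "MCF7"), "no signatures")

  # approved_only keeps only perturbagens with a drug mapping
  lib3 <- make_library(amps, pert = c(sprintf("BRD-X%02d_DB%05d", 1:25, 1:25),
                                      sprintf("BRD-NOMAP-%02d", 26:50)))
  fa <- filter_library(lib3, approved_only = TRUE)
  expect_equal(length(fa), 25L)
})

test_that("GMT parsing and round-trip follow the Broad convention", {
  p <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc one\tG1\tG2", "S2\t\tG3\tG4\tG5"), p)
  gsc <- read_gmt(p)
  expect_equal(length(gsc), 2L)
  expect_equal(gsc$sets$S1, c("G1", "G2"))
  expect_equal(unname(gsc$descriptions["S1"]), "desc one")

  p2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gsc, p2)
  gsc2 <- read_gmt(p2)
  expect_identical(gsc2$sets, gsc$sets)

  writeLines("S1\tdesc", p)
  expect_error(read_gmt(p), "no members")
})

test_that("drug-target tables enforce the closed action vocabulary", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("drug_id", "drug_name", "target_gene_symbol",
                     "target_uniprot_id", "action", sep = "\t"),
               paste("D1", "drugone", "TP53", "P04637", "modulator", sep = "\t")),
             p)
  expect_error(read_drug_targets(p), "modulator")
  expect_error(read_drug_targets(p), "inhibitor, antagonist, agonist, other")

  writeLines(c(paste("drug_id", "drug_name", "target_gene_symbol",
                     "target_uniprot_id", "action", sep = "\t"),
               paste("D1", "drugone", "TP53", "P04637", "inhibitor", sep = "\t"),
               paste("D1", "drugone", "TP53", "P04637", "inhibitor", sep = "\t")),
             p)
  expect_error(read_drug_targets(p), "duplicate")
})

test_that("the packaged top-10 drug-target fixture has 10 drugs and 22 edges", {
  tab <- read_drug_targets(table1_targets_path())
  expect_equal(length(unique(tab$drug_id)), 10L)
  expect_equal(nrow(tab), 22L)
  expect_true(all(tab$action %in% c("inhibitor", "antagonist")))
})

test_that("perturbagen ids resolve through explicit maps then DB suffixes", {
  ids <- c("BRD-K33106058_DB00987", "BRD-XXXX", "CUSTOM-1")
  expect_equal(map_perturbagens(ids),
               c("DB00987", NA, NA))
  pmap <- data.frame(perturbagen_id = "CUSTOM-1", drug_id = "DB99999")
  expect_equal(map_perturbagens(ids, pmap),
               c("DB00987", NA, "DB99999"))
})

test_that("quantity parsing is locale-independent and accepts scientific notation", {
  q <- sigconnect:::parse_quantity("1.5e1 uM")
  expect_equal(q$value, 15)
  expect_equal(q$unit, "um")
  expect_true(sigconnect:::quantity_equal("6 h", "6.0 HR"))
  expect_false(sigconnect:::quantity_equal("6 h", "6 uM"))
})
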