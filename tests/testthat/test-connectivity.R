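test_that("reference signed ranks follow the |amplitude| order and sign", {
  sr <- build_reference_ranks(c(A = 2.0, B = -1.0, C = 0.5))
  expect_equal(unclass(sr)[c("A", "B", "C")],
               c(A = 3L, B = -2L, C = 1L), ignore_attr = TRUE)

  # |amplitude| tie broken by ascending gene id
  sr2 <- build_reference_ranks(c(B = -1.0, A = 1.0))
  expect_equal(unclass(sr2)[c("A", "B")], c(A = 1L, B = -2L),
               ignore_attr = TRUE)

  # zero amplitude gets rank 0
  sr3 <- build_reference_ranks(c(A = 1, B = 0, C = -2))
  expect_equal(unclass(sr3)[["B"]], 0L)
})

test_that("reference ranks are invariant to monotone amplitude transforms", {
  set.seed(5)
  a <- setNames(rnorm(40), sprintf("G%02d", 1:40))
  sr <- build_reference_ranks(a)
  for (f in list(function(x) 2 * x, function(x) sign(x) * abs(x)^3,
                 function(x) sign(x) * log1p(abs(x)))) {
    expect_identical(unclass(build_reference_ranks(f(a))), unclass(sr))
  }
})

test_that("query construction intersects with landmarks and orders by strength", {
  ct <- structure(data.frame(
    gene = paste0("G", 1:5),
    mean_control = rep(10, 5), mean_treated = rep(20, 5),
    fc = c(2^0.8, 2^1.2, 2^-2, 2^1.6, 2^2),
    signed_fc = c(2^0.8, 2^1.2, -2^2, 2^1.6, 2^2),
    log2fc = c(0.8, 1.2, -2, 1.6, 2),
    p_value = rep(0.01, 5),
    cell_line = "A549", stringsAsFactors = FALSE),
    excluded = data.frame(gene = character(0), reason = character(0)),
    class = c("contrast_table", "data.frame"))

  q <- build_query(ct, landmark_genes = c("G1", "G2", "G3"))
  expect_equal(attr(q, "m"), 3L)
  expect_equal(attr(q, "n_dropped"), 2L)
  expect_equal(q$gene, c("G1", "G2", "G3"))   # ascending |log2fc| 0.8 < 1.2 < 2
  expect_equal(q$sr, c(1L, 2L, -3L))

  qu <- build_query(ct, landmark_genes = c("G1", "G2", "G3"), mode = "unordered")
  expect_equal(qu$sr, c(1L, 1L, -1L))

  qm <- build_query(ct, landmark_genes = paste0("G", 1:5), m_max = 2)
  expect_equal(qm$gene, c("G3", "G5"))   # strongest two (|log2fc| = 2) survive

  expect_error(build_query(ct, landmark_genes = "L999"), "empty query")
})

test_that("the worked 5-gene example scores -5/14", {
  ref <- build_reference_ranks(c(A = 5, B = -4, C = 3, D = -2, E = 1))
  q <- query_signature(c("C", "B"), c(+1, +1))
  rec <- zhang_score(ref, q)
  expect_equal(rec$c, -5 / 14)
  expect_equal(rec$m_eff, 2L)
})

test_that("self-derived queries hit the score extremes exactly", {
  set.seed(17)
  amp <- setNames(rnorm(978), sprintf("L%04d", 1:978))
  ref <- build_reference_ranks(amp)
  sr <- unclass(ref)
  for (m in c(1, 20, 978)) {
    ord <- names(sr)[order(abs(sr))]
    top <- ord[(978 - m + 1):978]             # weakest-to-strongest top-m
    self_q <- query_signature(top, sign(sr[top]))
    expect_identical(zhang_score(ref, self_q)$c, 1)
    flip_q <- query_signature(top, -sign(sr[top]))
    expect_identical(zhang_score(ref, flip_q)$c, -1)
  }
})

test_that("closed-form C_max equals the exhaustive-enumeration maximum", {
  set.seed(23)
  for (n in 2:6) {
    amp <- setNames(rnorm(n), sprintf("g%d", seq_len(n)))
    ref <- build_reference_ranks(amp)
    sr <- unclass(ref)
    attributes(sr) <- list(names = names(sr))
    for (m in seq_len(min(3, n))) {
      for (mode in c("ordered", "unordered")) {
        brute <- brute_force_cmax(sr, m, mode)
        ks <- 0:(m - 1)
        closed <- if (mode == "ordered") sum((m - ks) * (n - ks))
                  else sum(n - ks)
        expect_equal(closed, brute,
                     info = sprintf("n=%d m=%d %s", n, m, mode))
      }
    }
  }
})

test_that("implementation scores equal the naive sum-of-products oracle", {
  set.seed(29)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    m <- sample(1:min(8, n), 1)
    amp <- setNames(rnorm(n), sprintf("g%02d", seq_len(n)))
    ref <- build_reference_ranks(amp)
    sr <- unclass(ref)
    attributes(sr) <- list(names = names(sr))
    genes <- sample(names(sr), m)
    signs <- sample(c(-1, 1), m, replace = TRUE)
    for (mode in c("ordered", "unordered")) {
      q <- query_signature(genes, signs, mode = mode)
      rec <- zhang_score(ref, q)
      q_sr <- if (mode == "ordered") signs * seq_len(m) else signs
      C <- naive_C(sr, genes, q_sr)
      ks <- 0:(m - 1)
      Cmax <- if (mode == "ordered") sum((m - ks) * (n - ks)) else sum(n - ks)
      expect_equal(rec$c, C / Cmax)
    }
  }
})

test_that("scores stay in [-1, 1] across seeded random draws", {
  set.seed(31)
  cs <- replicate(1000, {
    n <- sample(3:60, 1)
    amp <- setNames(rnorm(n), sprintf("g%02d", seq_len(n)))
    ref <- build_reference_ranks(amp)
    m <- sample(1:n, 1)
    q <- query_signature(sample(names(amp), m),
                         sample(c(-1, 1), m, replace = TRUE),
                         mode = sample(c("ordered", "unordered"), 1))
    zhang_score(ref, q)$c
  })
  expect_true(all(cs >= -1 & cs <= 1))
})

test_that("negating all query signs negates the score exactly", {
  set.seed(37)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    amp <- setNames(rnorm(n), sprintf("g%02d", seq_len(n)))
    ref <- build_reference_ranks(amp)
    m <- sample(1:n, 1)
    genes <- sample(names(amp), m)
    signs <- sample(c(-1, 1), m, replace = TRUE)
    c1 <- zhang_score(ref, query_signature(genes, signs))$c
    c2 <- zhang_score(ref, query_signature(genes, -signs))$c
    expect_identical(c2, -c1)
  }
})

test_that("query genes absent from the reference change nothing", {
  set.seed(41)
  amp <- setNames(rnorm(20), sprintf("g%02d", 1:20))
  ref <- build_reference_ranks(amp)
  genes <- c("g03", "OFFLM1", "g11", "g17", "OFFLM2")
  signs <- c(1, -1, -1, 1, 1)
  with_absent <- zhang_score(ref, query_signature(genes, signs))
  kept <- !grepl("OFFLM", genes)
  without <- zhang_score(ref, query_signature(genes[kept], signs[kept]))
  expect_identical(with_absent$c, without$c)
  expect_identical(with_absent$m_eff, without$m_eff)

  # a zero-amplitude gene behaves like an absent one
  amp2 <- c(amp, zero1 = 0)
  ref2 <- build_reference_ranks(amp2)
  q2 <- zhang_score(ref2, query_signature(c("g03", "zero1", "g11"), c(1, 1, -1)))
  q3 <- zhang_score(ref2, query_signature(c("g03", "g11"), c(1, -1)))
  expect_identical(q2$c, q3$c)
})

test_that("undefined scores raise explicit errors", {
  ref <- build_reference_ranks(c(A = 1, B = -2))
  expect_error(zhang_score(ref, query_signature("Z", 1)), "undefined score")
  ref0 <- build_reference_ranks(c(A = 0, B = 0))
  expect_error(zhang_score(ref0, query_signature("A", 1)), "undefined score")
})

test_that("score_library is deterministic and flags per-signature failures", {
  set.seed(43)
  n <- 30
  genes <- sprintf("g%02d", seq_len(n))
  amps <- matrix(rnorm(n * 4), n, dimnames = list(genes, paste0("S", 1:4)))
  # duplicate one signature under a different id; make one degenerate
  amps[, 3] <- amps[, 1]
  amps[, 4] <- 0
  lib <- make_library(amps)
  q <- query_signature(c("g05", "g10", "g20"), c(1, -1, 1))
  recs <- score_library(lib, q)
  expect_equal(nrow(recs), 4L)
  expect_equal(recs$signature_id, sort(colnames(amps)))
  expect_identical(recs$c[recs$signature_id == "S1"],
                   recs$c[recs$signature_id == "S3"])
  expect_true(is.na(recs$c[recs$signature_id == "S4"]))
  expect_match(recs$note[recs$signature_id == "S4"], "undefined")

  # a planted self-signature dominates random decoys
  target <- rnorm(n)
  amps2 <- cbind(matrix(rnorm(n * 3), n), target)
  dimnames(amps2) <- list(genes, paste0("R", 1:4))
  lib2 <- make_library(amps2)
  ref <- build_reference_ranks(setNames(target, genes))
  sr <- unclass(ref)
  ord <- names(sr)[order(abs(sr))]
  top <- ord[(n - 9):n]
  qs <- query_signature(top, sign(sr[top]))
  recs2 <- score_library(lib2, qs)
  expect_equal(recs2$signature_id[which.max(recs2$c)], "R4")
  expect_equal(max(recs2$c), 1)
})

test_that("a full-scale library scores completely", {
  set.seed(47)
  genes <- sprintf("L%04d", 1:978)
  amps <- matrix(rnorm(978 * 200), 978,
                 dimnames = list(genes, sprintf("S%03d", 1:200)))
  lib <- make_library(amps)
  q <- query_signature(sample(genes, 30), sample(c(-1, 1), 30, replace = TRUE))
  recs <- score_library(lib, q)
  expect_equal(nrow(recs), 200L)
  expect_true(all(!is.na(recs$c)))
  expect_true(all(abs(recs$c) <= 1))
})
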