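mk_cells <- function(counts, genes = NULL, mito = NULL) {
  counts <- as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (is.null(genes)) genes <- paste0("G", seq_len(nrow(counts)))
  cells <- paste0("C", seq_len(ncol(counts)))
  dimnames(counts) <- list(genes, cells)
  if (is.null(mito)) mito <- startsWith(genes, "MT-")
  structure(list(counts = counts, gene_ids = genes, cell_ids = cells,
                 mito_flag = mito), class = "SparseCellMatrix")
}

test_that("QC boundaries: expressed-gene counts, mito fraction, gene filter", {
  n_genes <- 600
  m <- matrix(0, n_genes, 4)
  m[1:499, 1] <- 1          # 499 expressed -> removed
  m[1:500, 2] <- 1          # 500 -> kept
  m[1:550, 3] <- 1          # kept, then mito check below
  m[1:550, 4] <- 1
  genes <- c(paste0("MT-", 1:5), paste0("G", 1:(n_genes - 5)))
  m[1:5, 3] <- c(30, 30, 30, 22, 0)  # 112 of 657 counts ~ 17% mito
  cells <- mk_cells(m, genes = genes)
  out <- qc_filter(cells, min_genes = 500, max_genes = 9000,
                   max_mito = 0.10, min_cells_per_gene = 1)
  expect_setequal(out$cell_ids, c("C2", "C4"))
  # gene expressed in fewer than 3 surviving cells is removed
  m2 <- matrix(5, 20, 4); m2[1, 1:2] <- 0  # gene 1 expressed in 2 cells
  out2 <- qc_filter(mk_cells(m2), min_genes = 1, min_cells_per_gene = 3)
  expect_false("G1" %in% out2$gene_ids)
  expect_null(suppressMessages(qc_filter(mk_cells(m2), min_genes = 100)))
})

test_that("normalization matches the 10k scale-factor log1p convention", {
  m <- matrix(c(2, 8, 0, 10, 0, 0), 3, 2)
  norm <- normalize_log(mk_cells(m))
  expect_equal(norm[1, 1], log(1 + 1e4 * 2 / 10))
  expect_equal(norm[3, 1], 0)
  doubled <- normalize_log(mk_cells(m * 2))
  expect_equal(as.matrix(doubled), as.matrix(norm))
  bad <- mk_cells(matrix(c(1, 0, 0, 0), 2, 2))
  expect_error(normalize_log(bad), "zero total")
})

test_that("signature score cancels exactly on a constant matrix", {
  m <- Matrix::Matrix(3, 30, 10, sparse = TRUE)
  dimnames(m) <- list(paste0("G", 1:30), paste0("C", 1:10))
  s <- score_signature(m, paste0("G", 1:5), n_bins = 3, n_ctrl = 10,
                       seed = 1)
  expect_equal(unname(s), rep(0, 10))
  expect_error(score_signature(m, c("NOPE1", "NOPE2"), seed = 1),
               "NOPE1")
})

test_that("signature score equals the brute-force oracle with the same seed", {
  set.seed(11)
  m <- Matrix::Matrix(rpois(50 * 30, 2), 50, 30, sparse = TRUE)
  dimnames(m) <- list(paste0("G", 1:50), paste0("C", 1:30))
  norm <- normalize_log(mk_cells(as.matrix(m)))
  sig <- paste0("G", c(3, 11, 25, 40))
  expect_equal(score_signature(norm, sig, n_bins = 5, n_ctrl = 20,
                               seed = 42),
               score_oracle(norm, sig, n_bins = 5, n_ctrl = 20, seed = 42))
})

test_that("classification rule satisfies its truth table exhaustively", {
  cases <- expand.grid(m1 = c(-0.4, 0, 0.5, 0.9),
                       m2 = c(-0.4, 0, 0.5, 0.9))
  out <- classify_macrophages(setNames(cases$m1, paste0("c", 1:16)),
                              setNames(cases$m2, paste0("c", 1:16)))
  expected <- ifelse(cases$m1 > cases$m2 & cases$m1 > 0, "M1-like",
                     ifelse(cases$m2 > cases$m1 & cases$m2 > 0, "M2-like",
                            "Na"))
  expect_equal(out$state, expected)
  # positive tie -> Na with the tie flag
  tie <- classify_macrophages(c(a = 0.5), c(a = 0.5))
  expect_equal(tie$state, "Na"); expect_true(tie$tie)
  expect_equal(classify_macrophages(0.5, -0.2)$state, "M1-like")
  expect_equal(classify_macrophages(-0.1, -0.3)$state, "Na")
  expect_equal(classify_macrophages(0.2, 0.4)$state, "M2-like")
})

test_that("single-marker mode assigns M2-like on marker expression", {
  m <- matrix(c(0, 5, 3, 0), 2, 2)
  norm <- normalize_log(mk_cells(m, genes = c("CD163", "OTHER")))
  out <- classify_by_marker(norm, "CD163")
  expect_equal(out$state, c("M1-like", "M2-like"))
  hi <- classify_by_marker(norm, "CD163", threshold = 100)
  expect_equal(hi$state, c("M1-like", "M1-like"))
})

test_that("sc differential expression: expression filter and null behavior", {
  set.seed(21)
  m <- matrix(rpois(200 * 60, 1.5), 200, 60)
  m[1, ] <- 0; m[1, c(1, 31)] <- 1   # ~3% expressed in each group
  norm <- normalize_log(mk_cells(m))
  groups <- rep(c("g1", "g2"), each = 30)
  out <- sc_differential_expression(norm, groups, min_frac = 0.10)
  expect_false("G1" %in% out$gene)
  expect_equal(sum(out$significant), 0)  # identical distributions
  expect_error(sc_differential_expression(norm, rep("g1", 60)), "two")
})

test_that("QC + normalization commute with cell permutation", {
  x <- gen_single_cells(n_cells = 60, n_genes = 300, n_signature = 20,
                        seed = 31)
  perm <- sample(60)
  xp <- x$cells
  xp$counts <- xp$counts[, perm]
  xp$cell_ids <- xp$cell_ids[perm]
  a <- normalize_log(qc_filter(x$cells, min_genes = 50))
  b <- normalize_log(qc_filter(xp, min_genes = 50))
  expect_equal(as.matrix(b), as.matrix(a[, colnames(b)]))
})

test_that("planted cell states are recovered end to end", {
  x <- gen_single_cells(n_cells = 400, n_genes = 800, n_signature = 60,
                        shift = 1.5, seed = 41)
  qc <- qc_filter(x$cells)
  norm <- normalize_log(qc)
  s1 <- score_signature(norm, x$signatures$m1, seed = 1)
  s2 <- score_signature(norm, x$signatures$m2, seed = 2)
  ann <- classify_macrophages(s1, s2)
  truth <- x$truth$cell_state[ann$cell_id]
  expect_gt(mean(ann$state == truth), 0.9)
  # planted markers reach significance in the state comparison
  sel <- ann$state %in% c("M1-like", "M2-like")
  de <- sc_differential_expression(norm[, sel], ann$state[sel])
  expect_gt(sum(de$significant & de$gene %in%
                  c(x$signatures$m1, x$signatures$m2)), 10)
})
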