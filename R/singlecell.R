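#' Quality-control filtering of single-cell counts
#'
#' Removes cells with fewer than `min_genes` or more than `max_genes`
#' expressed genes (strict bounds), cells whose mitochondrial count
#' fraction exceeds `max_mito`, and then genes expressed in fewer than
#' `min_cells_per_gene` surviving cells.
#'
#' @param cells a `SparseCellMatrix` of raw counts
#' @param min_genes,max_genes expressed-gene bounds (defaults 500 / 9000)
#' @param max_mito maximum mitochondrial count fraction (default 0.10)
#' @param min_cells_per_gene minimum cells per gene (default 3)
#' @return filtered `SparseCellMatrix`; `NULL` with a message if no cell
#'   survives
#' @export
qc_filter <- function(cells, min_genes = 500, max_genes = 9000,
                      max_mito = 0.10, min_cells_per_gene = 3) {
  m <- cells$counts
  n_expressed <- Matrix::colSums(m > 0)
  mito_frac <- Matrix::colSums(m[cells$mito_flag, , drop = FALSE]) /
    pmax(Matrix::colSums(m), 1)
  keep_c <- n_expressed >= min_genes & n_expressed <= max_genes &
    mito_frac <= max_mito
  if (!any(keep_c)) { message("no cell passed QC"); return(NULL) }
  m <- m[, keep_c, drop = FALSE]
  keep_g <- Matrix::rowSums(m > 0) >= min_cells_per_gene
  m <- m[keep_g, , drop = FALSE]
  structure(list(counts = m, gene_ids = cells$gene_ids[keep_g],
                 cell_ids = cells$cell_ids[keep_c],
                 mito_flag = cells$mito_flag[keep_g]),
            class = "SparseCellMatrix")
}

#' Library-size normalization and natural-log transform
#'
#' Each count is divided by its cell's total, multiplied by the scale
#' factor, and natural-log transformed as `ln(1 + x)` (so zeros stay
#' zero; a bare `ln` would be undefined at 0).
#'
#' @param cells a QC-filtered `SparseCellMatrix`
#' @param scale_factor default 10000
#' @return dgCMatrix of normalized log expression (genes x cells)
#' @export
normalize_log <- function(cells, scale_factor = 1e4) {
  tot <- Matrix::colSums(cells$counts)
  if (any(tot == 0))
    stop("cell(s) with zero total counts: ",
         paste(cells$cell_ids[tot == 0], collapse = ", "))
  norm <- cells$counts %*% Matrix::Diagonal(x = scale_factor / tot)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(cells$counts)
  as(norm, "CsparseMatrix")
}

#' Control-binned signature (module) score per cell
#'
#' All genes are binned by average expression across cells into `n_bins`
#' equal-frequency bins (ties broken by average-expression rank, then
#' lexicographic gene id). For each signature gene, `n_ctrl` control genes
#' are drawn at random from its bin (with replacement when the bin holds
#' fewer than `n_ctrl` genes). A cell's score is the mean, over signature
#' genes, of the gene's expression minus the mean expression of its
#' control draw.
#'
#' @param norm_matrix normalized log expression (genes x cells), typically
#'   restricted to the cells under study (binning then reflects that
#'   subset)
#' @param gene_list signature gene ids (order defines the random draw
#'   sequence)
#' @param n_bins number of expression bins (default 24)
#' @param n_ctrl control genes per signature gene (default 100)
#' @param seed integer seed
#' @return named numeric vector, one score per cell
#' @export
score_signature <- function(norm_matrix, gene_list, n_bins = 24,
                            n_ctrl = 100, seed = 1) {
  genes <- rownames(norm_matrix)
  sig <- intersect(gene_list, genes)
  if (!length(sig))
    stop("no signature gene present in the matrix; missing: ",
         paste(utils::head(setdiff(gene_list, genes), 10), collapse = ", "))
  avg <- Matrix::rowMeans(norm_matrix)
  ord <- order(avg, genes)  # ties: rank then lexicographic id
  bin <- integer(length(genes))
  bin[ord] <- ceiling(seq_along(genes) / (length(genes) / n_bins))
  bin[bin > n_bins] <- n_bins
  names(bin) <- genes
  sig <- gene_list[gene_list %in% genes]  # preserve input order
  set.seed(seed)
  dm <- as.matrix(norm_matrix[sig, , drop = FALSE])
  ctrl_means <- matrix(0, length(sig), ncol(norm_matrix))
  for (i in seq_along(sig)) {
    pool <- genes[bin == bin[sig[i]]]
    draw <- sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    ctrl_means[i, ] <- Matrix::colMeans(norm_matrix[draw, , drop = FALSE])
  }
  scores <- colMeans(dm - ctrl_means)
  names(scores) <- colnames(norm_matrix)
  scores
}

#' Classify macrophages from two signature scores
#'
#' M1-like when the M1 score is the larger and positive; M2-like when the
#' M2 score is the larger and positive; `Na` (unknown) when neither score
#' is positive. An exact positive tie is assigned `Na` with a `tie`
#' flag.
#'
#' @param score_m1,score_m2 named score vectors over the same cells
#' @return data.frame: cell_id, score_m1, score_m2, state
#'   (`"M1-like"`/`"M2-like"`/`"Na"`), tie
#' @export
classify_macrophages <- function(score_m1, score_m2) {
  stopifnot(length(score_m1) == length(score_m2))
  if (!is.null(names(score_m1)) && !is.null(names(score_m2)))
    stopifnot(identical(names(score_m1), names(score_m2)))
  state <- ifelse(score_m1 > score_m2 & score_m1 > 0, "M1-like",
                  ifelse(score_m2 > score_m1 & score_m2 > 0, "M2-like",
                         "Na"))
  tie <- score_m1 == score_m2 & score_m1 > 0
  data.frame(cell_id = if (is.null(names(score_m1)))
    as.character(seq_along(score_m1)) else names(score_m1),
    score_m1 = unname(score_m1), score_m2 = unname(score_m2),
    state = state, tie = tie, stringsAsFactors = FALSE)
}

#' Single-marker macrophage classification
#'
#' Assigns M2-like when the marker gene's normalized expression exceeds
#' the threshold (default: any expression), M1-like otherwise.
#'
#' @param norm_matrix normalized expression (genes x cells)
#' @param marker marker gene id (e.g. `"CD163"`)
#' @param threshold expression cutoff (strict `>`, default 0)
#' @return data.frame: cell_id, marker_expr, state
#' @export
classify_by_marker <- function(norm_matrix, marker, threshold = 0) {
  if (!marker %in% rownames(norm_matrix))
    stop("marker '", marker, "' not in matrix")
  ex <- as.numeric(norm_matrix[marker, ])
  data.frame(cell_id = colnames(norm_matrix), marker_expr = ex,
             state = ifelse(ex > threshold, "M2-like", "M1-like"),
             stringsAsFactors = FALSE)
}

#' Differential expression between two cell groups
#'
#' Pooled-variance (Student) two-sample t-tests per gene on the normalized
#' values, restricted to genes expressed in at least `min_frac` of the
#' cells of either group, with Bonferroni correction over the tested
#' genes. Significance requires adjusted p below `alpha` and an average
#' log2 fold change above `min_avg_log2fc` (one direction, as stated).
#' The average log2FC is `log2(mean(expm1(x)) + 1)` per group, differenced.
#'
#' @param norm_matrix normalized log expression (genes x cells)
#' @param groups named character/factor of length `ncol(norm_matrix)` with
#'   exactly two levels; log2FC is level 2 minus level 1 (alphabetical)
#' @param min_frac expression-fraction filter (default 0.10)
#' @param alpha adjusted-p cut (default 0.05)
#' @param min_avg_log2fc log2FC cut (default 0.75, strict `>`)
#' @return data.frame: gene, avg_log2fc, t, p, p_adj, frac_1, frac_2,
#'   significant
#' @export
sc_differential_expression <- function(norm_matrix, groups,
                                       min_frac = 0.10, alpha = 0.05,
                                       min_avg_log2fc = 0.75) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("exactly two groups required")
  i1 <- which(groups == lev[1]); i2 <- which(groups == lev[2])
  if (length(i1) < 2 || length(i2) < 2)
    stop("each group needs at least 2 cells")
  m1 <- norm_matrix[, i1, drop = FALSE]
  m2 <- norm_matrix[, i2, drop = FALSE]
  f1 <- Matrix::rowMeans(m1 > 0); f2 <- Matrix::rowMeans(m2 > 0)
  test <- f1 >= min_frac | f2 >= min_frac
  m1 <- as.matrix(m1[test, , drop = FALSE])
  m2 <- as.matrix(m2[test, , drop = FALSE])
  n1 <- ncol(m1); n2 <- ncol(m2)
  mu1 <- rowMeans(m1); mu2 <- rowMeans(m2)
  v1 <- apply(m1, 1, var); v2 <- apply(m2, 1, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, (mu2 - mu1) / se, 0)
  p <- ifelse(se > 0, 2 * pt(-abs(t), n1 + n2 - 2), 1)
  p_adj <- pmin(p * length(p), 1)  # Bonferroni over tested genes
  lfc <- log2(rowMeans(expm1(m2)) + 1) - log2(rowMeans(expm1(m1)) + 1)
  out <- data.frame(gene = rownames(norm_matrix)[test],
                    avg_log2fc = lfc, t = t, p = p, p_adj = p_adj,
                    frac_1 = f1[test], frac_2 = f2[test],
                    significant = p_adj < alpha & lfc > min_avg_log2fc,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
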