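# shared fixture builders and independent oracles

# quick FeatureTable: values is a matrix, columns split evenly over two
# conditions unless a condition vector is given
make_ft <- function(values, conds = NULL, feature_id = NULL,
                    protein_id = NULL, meta = NULL, phospho = FALSE) {
  values <- as.matrix(values)
  ns <- ncol(values)
  if (is.null(conds)) conds <- rep(c("A", "B"), each = ns / 2)
  samples <- paste0(conds, "_", stats::ave(seq_len(ns), conds,
                                           FUN = seq_along))
  if (is.null(feature_id)) feature_id <- paste0("F", seq_len(nrow(values)))
  if (is.null(protein_id)) protein_id <- feature_id
  if (!is.null(meta) && nrow(meta) == 1 && nrow(values) > 1)
    meta <- meta[rep(1, nrow(values)), , drop = FALSE]
  feature_table(values, feature_id, protein_id, samples,
                stats::setNames(conds, samples), meta,
                is_phospho_table = phospho)
}

# exhaustive two-sided Fisher p (point-probability method) by enumerating
# all 2x2 tables at the observed margins
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  as <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(as, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive upper-tail hypergeometric P(X >= q) by direct summation
hyper_enum_p <- function(q, m, N, k) {
  xs <- q:min(m, k)
  if (q > min(m, k)) return(0)
  sum(choose(m, xs) * choose(N - m, k - xs)) / choose(N, k)
}

# brute-force current-flow betweenness: per-pair reduced-Laplacian solve
# and explicit edge-current accumulation (independent of the package's
# pseudoinverse-based implementation)
cfb_oracle <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  L <- as.matrix(igraph::laplacian_matrix(g))
  score <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    b <- numeric(n); b[s] <- 1; b[t] <- -1
    phi <- numeric(n)
    phi[-n] <- solve(L[-n, -n], b[-n])
    for (v in setdiff(seq_len(n), c(s, t))) {
      thr <- 0
      for (e in seq_len(nrow(el))) {
        if (el[e, 1] == v || el[e, 2] == v)
          thr <- thr + abs(phi[el[e, 1]] - phi[el[e, 2]])
      }
      score[v] <- score[v] + thr / 2
    }
  }
  names(score) <- igraph::V(g)$name
  score
}

# brute-force control-binned signature score replicating the documented
# draw order, computed with dense loops
score_oracle <- function(norm_matrix, gene_list, n_bins, n_ctrl, seed) {
  m <- as.matrix(norm_matrix)
  genes <- rownames(m)
  avg <- rowMeans(m)
  ord <- order(avg, genes)
  bin <- integer(length(genes))
  bin[ord] <- ceiling(seq_along(genes) / (length(genes) / n_bins))
  bin[bin > n_bins] <- n_bins
  names(bin) <- genes
  sig <- gene_list[gene_list %in% genes]
  set.seed(seed)
  contrib <- matrix(0, length(sig), ncol(m))
  for (i in seq_along(sig)) {
    pool <- genes[bin == bin[sig[i]]]
    draw <- sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    for (cc in seq_len(ncol(m)))
      contrib[i, cc] <- m[sig[i], cc] - mean(m[draw, cc])
  }
  stats::setNames(colMeans(contrib), colnames(m))
}

# standard preprocessing chain used by several recovery tests
prep_chain <- function(x, seed) {
  prot <- impute_missing(log2_center(clean_proteome(x$proteome)),
                         seed = seed + 1000L)
  ph <- clean_phospho(x$phospho)
  phos <- impute_missing(log2_center(ph$analysis_set), seed = seed + 2000L)
  list(prot = prot, phos = phos, motif = ph$motif_set)
}
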