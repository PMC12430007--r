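#' Cross-dataset consensus of bulk differential-expression tables
#'
#' A gene is eligible when its expression lies above the dataset median in
#' at least `min_expr_datasets` datasets; significant in one dataset when
#' its adjusted p-value is below `fdr_max` and its abundance ratio exceeds
#' `min_ratio` (|log2FC| > log2(min_ratio)); and a consensus hit when
#' significant in at least `min_datasets` datasets (`mode = "intersect"`)
#' or in any dataset (`mode = "union"`, the two-study case).
#'
#' @param tables list of data.frames with gene, log2fc, adj_p
#' @param expr_tables list of data.frames with gene, expr (same datasets);
#'   `NULL` skips the expression prefilter
#' @param min_datasets consensus threshold (default 3)
#' @param fdr_max per-dataset adjusted-p cut (default 0.05)
#' @param min_ratio per-dataset fold-ratio cut (default 4)
#' @param min_expr_datasets datasets in which expression must be above the
#'   median (default 3)
#' @param mode `"intersect"` (default) or `"union"`
#' @return data.frame: gene, per-dataset flags `sig_1..sig_k`,
#'   n_significant_datasets, consensus, direction_consistent
#' @export
consensus_de <- function(tables, expr_tables = NULL, min_datasets = 3,
                         fdr_max = 0.05, min_ratio = 4,
                         min_expr_datasets = 3,
                         mode = c("intersect", "union")) {
  mode <- match.arg(mode)
  k <- length(tables)
  if (mode == "intersect" && k < min_datasets)
    stop("intersect mode needs at least min_datasets (", min_datasets,
         ") tables; got ", k)
  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene"))))
  lfc_min <- log2(min_ratio)
  sig <- sapply(tables, function(tb) {
    i <- match(genes, tb$gene)
    s <- tb$adj_p[i] < fdr_max & abs(tb$log2fc[i]) > lfc_min
    ifelse(is.na(s), FALSE, s)
  })
  if (is.null(dim(sig))) sig <- matrix(sig, nrow = length(genes))
  dir <- sapply(tables, function(tb) sign(tb$log2fc[match(genes, tb$gene)]))
  if (is.null(dim(dir))) dir <- matrix(dir, nrow = length(genes))
  eligible <- rep(TRUE, length(genes))
  if (!is.null(expr_tables)) {
    above <- sapply(expr_tables, function(tb) {
      i <- match(genes, tb$gene)
      a <- tb$expr[i] > median(tb$expr, na.rm = TRUE)
      ifelse(is.na(a), FALSE, a)
    })
    if (is.null(dim(above))) above <- matrix(above, nrow = length(genes))
    eligible <- rowSums(above) >= min_expr_datasets
  }
  n_sig <- rowSums(sig)
  consensus <- eligible &
    if (mode == "intersect") n_sig >= min_datasets else n_sig >= 1
  dsig <- dir * sig
  dir_cons <- apply(dsig, 1, function(r) {
    r <- r[r != 0 & !is.na(r)]
    length(r) == 0 || all(r > 0) || all(r < 0)
  })
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (j in seq_len(k)) out[[paste0("sig_", j)]] <- sig[, j]
  out$n_significant_datasets <- n_sig
  out$eligible <- eligible
  out$consensus <- consensus
  out$direction_consistent <- dir_cons
  out
}

#' Cross-dataset consensus of differential-transcript-usage gene calls
#'
#' @param gene_flags list of character vectors, one per dataset, each the
#'   genes with transcript-usage evidence after the upstream two-stage
#'   screening
#' @param min_fraction fraction of datasets required (default 0.5,
#'   "at least half", i.e. `>= ceiling(min_fraction * n)`)
#' @return character vector of retained genes
#' @export
consensus_dtu <- function(gene_flags, min_fraction = 0.5) {
  n <- length(gene_flags)
  need <- ceiling(min_fraction * n)
  counts <- base::table(unlist(lapply(gene_flags, unique)))
  sort(names(counts)[counts >= need])
}

#' Merge interaction records across sources with confidence filtering
#'
#' Source roles: `source1` (combined-score list) kept only above its
#' threshold; `source2` (physical-interaction list) kept only when a
#' confidence value is present (any value); `source3` (confidence-scored
#' list) kept only above its threshold. Survivors are unioned into
#' undirected simple edges; duplicate pairs collapse with their source
#' provenance concatenated.
#'
#' @param records data.frame node_a/node_b/source/confidence
#' @param thresholds named list, defaults `list(source1=0.7, source3=0.7)`
#'   (strict `>`)
#' @return data.frame: node_a, node_b (lexicographic order), sources
#'   (comma-joined provenance)
#' @export
merge_interactions <- function(records,
                               thresholds = list(source1 = 0.7,
                                                 source3 = 0.7)) {
  keep <- logical(nrow(records))
  s <- records$source
  keep[s == "source1"] <- !is.na(records$confidence[s == "source1"]) &
    records$confidence[s == "source1"] > thresholds$source1
  keep[s == "source2"] <- !is.na(records$confidence[s == "source2"])
  keep[s == "source3"] <- !is.na(records$confidence[s == "source3"]) &
    records$confidence[s == "source3"] > thresholds$source3
  r <- records[keep & records$node_a != records$node_b, , drop = FALSE]
  if (!nrow(r))
    return(data.frame(node_a = character(), node_b = character(),
                      sources = character()))
  a <- pmin(r$node_a, r$node_b); b <- pmax(r$node_a, r$node_b)
  key <- paste(a, b, sep = "\r")
  srcs <- vapply(split(r$source, key), function(x)
    paste(sort(unique(x)), collapse = ","), "")
  uk <- names(srcs)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  out <- data.frame(node_a = vapply(parts, `[[`, "", 1),
                    node_b = vapply(parts, `[[`, "", 2),
                    sources = unname(srcs), stringsAsFactors = FALSE)
  out[order(out$node_a, out$node_b), , drop = FALSE]
}

#' Build the integrative multi-omics network
#'
#' Keeps only edges whose both endpoints are significant in at least one
#' evidence layer, drops connected components dominated by
#' transcript-usage-only evidence (more than `dtu_max_fraction` of the
#' component's nodes carry only the `dtu` layer), and returns the largest
#' remaining connected component.
#'
#' @param edges data.frame node_a/node_b (e.g. from [merge_interactions()])
#' @param hits_by_layer named list layer -> significant gene/protein set;
#'   layers among proteome, phospho, transcript, dtu
#' @param dtu_max_fraction component drop threshold (default 0.75,
#'   strict `>`)
#' @return igraph undirected simple graph with the vertex attribute
#'   `layers` (comma-joined evidence layers); `NULL` with a message when
#'   nothing survives
#' @export
build_integrative_network <- function(edges, hits_by_layer,
                                      dtu_max_fraction = 0.75) {
  stopifnot(all(names(hits_by_layer) %in%
                  c("proteome", "phospho", "transcript", "dtu")))
  node_layers <- function(v) names(hits_by_layer)[
    vapply(hits_by_layer, function(h) v %in% h, TRUE)]
  sig_nodes <- unique(unlist(hits_by_layer))
  e <- edges[edges$node_a %in% sig_nodes & edges$node_b %in% sig_nodes, ,
             drop = FALSE]
  if (!nrow(e)) { message("integrative network is empty"); return(NULL) }
  g <- igraph::graph_from_data_frame(e[, c("node_a", "node_b")],
                                     directed = FALSE)
  g <- igraph::simplify(g)
  layers <- lapply(igraph::V(g)$name, node_layers)
  igraph::V(g)$layers <- vapply(layers, paste, "", collapse = ",")
  dtu_only <- vapply(layers, function(l) identical(l, "dtu"), TRUE)
  comp <- igraph::components(g)
  drop <- which(vapply(seq_len(comp$no), function(ci) {
    ix <- comp$membership == ci
    mean(dtu_only[ix]) > dtu_max_fraction
  }, TRUE))
  keep_v <- !(comp$membership %in% drop)
  g <- igraph::induced_subgraph(g, which(keep_v))
  if (igraph::vcount(g) == 0) {
    message("integrative network is empty after the DTU-composition filter")
    return(NULL)
  }
  comp <- igraph::components(g)
  igraph::induced_subgraph(g, which(comp$membership ==
                                      which.max(comp$csize)))
}

#' Current-flow betweenness centrality
#'
#' For every source-target pair a unit current is injected at the source
#' and extracted at the target; edge currents are obtained from the graph
#' Laplacian (random-walk/electrical formulation). A node's score is its
#' summed current throughput over all pairs, with the pair's endpoints
#' excluded; scores are unnormalized. On trees this reduces to
#' shortest-path betweenness, since all current takes the unique path.
#'
#' @param graph connected undirected igraph with at least 3 nodes
#' @return named numeric vector of node scores
#' @export
current_flow_betweenness <- function(graph) {
  if (igraph::is_directed(graph)) graph <- igraph::as_undirected(graph)
  if (!igraph::is_connected(graph))
    stop("graph is disconnected; analyze each component separately")
  n <- igraph::vcount(graph)
  if (n < 3) stop("need at least 3 nodes")
  el <- igraph::as_edgelist(graph, names = FALSE)
  m <- nrow(el)
  L <- as.matrix(igraph::laplacian_matrix(graph))
  # pseudoinverse via grounding one node (row/col removed), then re-padding
  C <- matrix(0, n, n)
  C[-1, -1] <- solve(L[-1, -1, drop = FALSE])
  # potentials difference operator on edges: F[e, v] = C[u,v] - C[w,v]
  Fm <- C[el[, 1], , drop = FALSE] - C[el[, 2], , drop = FALSE]
  # node-edge aggregation: half the absolute current of incident edges
  Ag <- Matrix::sparseMatrix(i = c(el[, 1], el[, 2]),
                             j = c(seq_len(m), seq_len(m)),
                             x = 0.5, dims = c(n, m))
  score <- numeric(n)
  for (s in seq_len(n - 1)) {
    ts <- (s + 1):n
    A <- abs(Fm[, ts, drop = FALSE] - Fm[, s])  # m x |ts| edge currents
    thr <- as.matrix(Ag %*% A)
    thr[s, ] <- 0                              # endpoints excluded
    thr[cbind(ts, seq_along(ts))] <- 0
    score <- score + rowSums(thr)
  }
  names(score) <- igraph::V(graph)$name
  score
}

#' Modularity-based module decomposition with a target average degree
#'
#' Multi-level (Louvain) modularity optimization with seeded tie-breaking.
#' The resolution parameter is tuned by bisection so the mean within-module
#' degree of the partition approaches `target_avg_degree`; modules are
#' sorted by size (descending) and those below `min_module_size` are
#' flagged sub-threshold rather than dropped.
#'
#' @param graph connected undirected igraph
#' @param target_avg_degree desired mean within-module node degree
#'   (default 10)
#' @param min_module_size flag threshold (default 10)
#' @param seed integer seed
#' @return list of class `ModulePartition`: `membership` (named integer,
#'   module ids 1.. by decreasing size), `sizes`, `sub_threshold` (logical
#'   per module), `modularity`, `resolution`, `avg_within_degree`
#' @export
detect_modules <- function(graph, target_avg_degree = 10,
                           min_module_size = 10, seed = 1) {
  stopifnot(igraph::is_connected(graph))
  avg_within <- function(memb) {
    deg <- numeric(igraph::vcount(graph))
    el <- igraph::as_edgelist(graph, names = FALSE)
    same <- memb[el[, 1]] == memb[el[, 2]]
    for (e in which(same)) {
      deg[el[e, 1]] <- deg[el[e, 1]] + 1
      deg[el[e, 2]] <- deg[el[e, 2]] + 1
    }
    mean(deg)
  }
  run <- function(res) {
    set.seed(seed)
    cl <- igraph::cluster_louvain(graph, resolution = res)
    memb <- igraph::membership(cl)
    list(memb = memb, mod = igraph::modularity(graph, memb),
         avg = avg_within(memb), res = res)
  }
  # the degree target is a density constraint on the partition: sweep the
  # resolution parameter and, among partitions whose mean within-module
  # degree reaches the target, keep the one with the highest (standard)
  # modularity. Higher resolution means smaller, sparser modules, so the
  # constraint caps how finely the graph is split. When even the whole
  # graph is sparser than the target the constraint cannot bind and the
  # best-modularity partition of the sweep is used.
  cands <- lapply(c(seq(0.25, 4, by = 0.375), 1), run)
  ok <- vapply(cands, function(r) r$avg >= target_avg_degree, TRUE)
  pool <- if (any(ok)) cands[ok] else cands
  best <- pool[[which.max(vapply(pool, `[[`, 0, "mod"))]]
  memb <- best$memb
  sizes <- sort(base::table(memb), decreasing = TRUE)
  relab <- setNames(seq_along(sizes), names(sizes))
  memb2 <- setNames(as.integer(relab[as.character(memb)]),
                    igraph::V(graph)$name)
  sizes <- as.integer(sizes)
  structure(list(membership = memb2, sizes = sizes,
                 sub_threshold = sizes < min_module_size,
                 modularity = best$mod, resolution = best$res,
                 avg_within_degree = best$avg),
            class = "ModulePartition")
}

#' @export
print.ModulePartition <- function(x, ...) {
  cat(sprintf(
    "ModulePartition: %d modules over %d nodes (modularity %.3f)\n",
    length(x$sizes), length(x$membership), x$modularity))
  cat("sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat(sprintf("resolution %.3f, mean within-module degree %.2f\n",
              x$resolution, x$avg_within_degree))
  invisible(x)
}
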