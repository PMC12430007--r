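#' @importFrom stats fisher.test
NULL

# 2x2 footprint table for one substrate set:
#   a = upregulated & recognized, b = upregulated & not,
#   c = other measured & recognized, d = other measured & not
.footprint_fisher <- function(up, measured, recognized) {
  other <- setdiff(measured, up)
  a <- length(intersect(up, recognized))
  b <- length(up) - a
  c <- length(intersect(other, recognized))
  d <- length(other) - c
  tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  ft <- fisher.test(tab, alternative = "two.sided")
  list(a = a, b = b, c = c, d = d,
       odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Kinase-activity enrichment from curated substrate sets
#'
#' For each kinase, compares the upregulated phosphosites it recognizes
#' against all other measured phosphosites it recognizes, in a 2x2 table
#' (upregulated vs other measured x recognized vs not) tested with a
#' two-sided Fisher's exact test (point-probability convention: the sum of
#' table probabilities not exceeding the observed one). A kinase is called
#' upregulated when p < 0.05; no multiple-testing correction is applied by
#' default (switchable).
#'
#' Sites are identified by [make_site_id()] strings; both site sets should
#' come from the class I (motif) set. Kinases recognizing no measured site
#' are excluded and reported in the `"excluded"` attribute.
#'
#' @param upregulated_sites character vector of upregulated site ids
#'   (subset of `measured_sites`)
#' @param measured_sites character vector of all measured site ids
#' @param ksmap curated kinase-substrate map (data.frame with kinase,
#'   protein, residue)
#' @param p_max significance cut (default 0.05)
#' @param correct apply BH correction across kinases before calling
#'   significance (default FALSE)
#' @return data.frame: kinase, a, b, c, d, odds_ratio, p, (fdr,)
#'   significant; attribute `"excluded"` lists skipped kinases
#' @export
enrich_curated_substrates <- function(upregulated_sites, measured_sites,
                                      ksmap, p_max = 0.05,
                                      correct = FALSE) {
  if (!all(upregulated_sites %in% measured_sites))
    stop("upregulated sites must be a subset of measured sites")
  ks_site <- make_site_id(ksmap$protein, ksmap$residue)
  by_kin <- split(ks_site, ksmap$kinase)
  excluded <- character()
  rows <- list()
  for (k in names(by_kin)) {
    rec <- intersect(unique(by_kin[[k]]), measured_sites)
    if (!length(rec)) { excluded <- c(excluded, k); next }
    f <- .footprint_fisher(upregulated_sites, measured_sites, rec)
    rows[[k]] <- data.frame(kinase = k, a = f$a, b = f$b, c = f$c, d = f$d,
                            odds_ratio = f$odds_ratio, p = f$p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(kinase = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), odds_ratio = numeric(),
                      p = numeric(), significant = logical())
  if (nrow(out)) {
    # upregulation call: the two-sided p must pass AND the footprint must
    # be enriched (odds ratio > 1), not depleted
    if (correct) {
      out$fdr <- bh_adjust(out$p)
      out$significant <- out$fdr < p_max & out$odds_ratio > 1
    } else {
      out$significant <- out$p < p_max & out$odds_ratio > 1
    }
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Filter site-level kinase-family predictions
#'
#' Keeps predictions with posterior probability above 0.035 whose posterior
#' also exceeds the prior, then retains per site only the three families
#' with the highest posterior (all families tied at rank three are kept,
#' for determinism).
#'
#' @param preds data.frame: protein, residue, kinase_family, posterior,
#'   prior
#' @param posterior_min posterior cut (strict `>`, default 0.035)
#' @param top_n families kept per site (default 3)
#' @return filtered data.frame
#' @export
filter_site_predictions <- function(preds, posterior_min = 0.035,
                                    top_n = 3) {
  stopifnot(all(preds$posterior >= 0 & preds$posterior <= 1),
            all(preds$prior >= 0 & preds$prior <= 1))
  keep <- preds$posterior > posterior_min & preds$posterior > preds$prior
  preds <- preds[keep, , drop = FALSE]
  if (!nrow(preds)) { rownames(preds) <- NULL; return(preds) }
  site <- make_site_id(preds$protein, preds$residue)
  sel <- unlist(lapply(split(seq_len(nrow(preds)), site), function(ix) {
    post <- preds$posterior[ix]
    if (length(ix) <= top_n) return(ix)
    cut <- sort(post, decreasing = TRUE)[top_n]
    ix[post >= cut]  # ties at rank top_n are all kept
  }), use.names = FALSE)
  out <- preds[sort(sel), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kinase-family enrichment from filtered predictions
#'
#' Same 2x2 footprint construction as the curated analysis, per predicted
#' kinase family, with BH correction across families; a family is
#' significant only with at least `min_substrates` upregulated substrates
#' and adjusted p below `fdr_max`.
#'
#' @param filtered_preds output of [filter_site_predictions()]
#' @param upregulated_sites,measured_sites site id vectors
#' @param min_substrates minimum upregulated recognized substrates
#'   (default 10)
#' @param fdr_max adjusted-p cut (default 0.05)
#' @return data.frame: family, a, b, c, d, odds_ratio, p, fdr, significant
#' @export
enrich_predicted_families <- function(filtered_preds, upregulated_sites,
                                      measured_sites, min_substrates = 10,
                                      fdr_max = 0.05) {
  if (!length(upregulated_sites) || !nrow(filtered_preds))
    return(data.frame(family = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), odds_ratio = numeric(),
                      p = numeric(), fdr = numeric(),
                      significant = logical()))
  site <- make_site_id(filtered_preds$protein, filtered_preds$residue)
  by_fam <- split(site, filtered_preds$kinase_family)
  rows <- list()
  for (fam in names(by_fam)) {
    rec <- intersect(unique(by_fam[[fam]]), measured_sites)
    if (!length(rec)) next
    f <- .footprint_fisher(upregulated_sites, measured_sites, rec)
    rows[[fam]] <- data.frame(family = fam, a = f$a, b = f$b, c = f$c,
                              d = f$d, odds_ratio = f$odds_ratio, p = f$p,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out$significant <- out$a >= min_substrates & out$fdr < fdr_max
  rownames(out) <- NULL
  out
}

#' Assemble a kinase-kinase / kinase-TF signaling network
#'
#' Directed edges kinase -> substrate protein are drawn only when the
#' target protein carries an upregulated phosphosite that the kinase
#' recognizes — through the curated map (`evidence = "curated"`) or through
#' a filtered family prediction whose family contains the kinase
#' (`evidence = "predicted"`). Node inclusion:
#' upregulated kinases always; kinases carrying targeted upregulated sites;
#' unmeasured kinases only when they bridge at least one upregulated kinase
#' to another measured kinase; TFs with upregulated substrate sites;
#' in `mode = "large"`, measured non-upregulated kinases only when they
#' connect two or more upregulated kinases.
#'
#' @param upregulated_kinases kinases inferred active (enrichment calls)
#' @param measured_kinases kinases quantified in the experiment
#' @param ksmap curated kinase-substrate map
#' @param filtered_preds filtered predictions (may be `NULL`)
#' @param families data.frame family/kinase membership (needed when
#'   predictions are used)
#' @param upregulated_sites upregulated site ids
#' @param tf_list transcription-factor symbols
#' @param mode `"focused"` (default) or `"large"`
#' @return igraph directed graph with node attributes `upregulated`,
#'   `measured`, `bridging`, `is_tf` and edge attributes `evidence`, `site`
#' @export
build_signaling_network <- function(upregulated_kinases, measured_kinases,
                                    ksmap, filtered_preds = NULL,
                                    families = NULL, upregulated_sites,
                                    tf_list = character(),
                                    mode = c("focused", "large")) {
  mode <- match.arg(mode)
  # candidate edges: kinase -> protein of a recognized upregulated site
  cur_site <- make_site_id(ksmap$protein, ksmap$residue)
  keep <- cur_site %in% upregulated_sites
  edges <- data.frame(from = ksmap$kinase[keep], to = ksmap$protein[keep],
                      evidence = "curated", site = cur_site[keep],
                      stringsAsFactors = FALSE)
  if (!is.null(filtered_preds) && nrow(filtered_preds)) {
    if (is.null(families))
      stop("families membership table required when predictions are used")
    ps <- make_site_id(filtered_preds$protein, filtered_preds$residue)
    pk <- filtered_preds[ps %in% upregulated_sites, , drop = FALSE]
    ps <- ps[ps %in% upregulated_sites]
    if (nrow(pk)) {
      fam_kin <- split(families$kinase, families$family)
      pe <- do.call(rbind, lapply(seq_len(nrow(pk)), function(i) {
        kins <- fam_kin[[pk$kinase_family[i]]]
        if (is.null(kins)) return(NULL)
        data.frame(from = kins, to = pk$protein[i], evidence = "predicted",
                   site = ps[i], stringsAsFactors = FALSE)
      }))
      if (!is.null(pe)) edges <- rbind(edges, pe)
    }
  }
  edges <- edges[!duplicated(edges[, c("from", "to", "site")]), ,
                 drop = FALSE]
  all_kin <- unique(c(ksmap$kinase, measured_kinases, upregulated_kinases,
                      if (!is.null(families)) families$kinase))
  is_kin <- function(x) x %in% all_kin
  # the network holds kinase-kinase and kinase-TF connections only
  edges <- edges[is_kin(edges$to) | edges$to %in% tf_list, , drop = FALSE]
  up_tf <- intersect(tf_list, edges$to)

  # undirected adjacency over candidate edges, for the inclusion rules
  nbrs <- function(v) unique(c(edges$to[edges$from == v],
                               edges$from[edges$to == v]))
  cand <- unique(c(edges$from, edges$to, upregulated_kinases))
  unmeasured_kin <- cand[is_kin(cand) & !(cand %in% measured_kinases)]
  bridging <- unmeasured_kin[vapply(unmeasured_kin, function(v) {
    nb <- nbrs(v)
    any(nb %in% upregulated_kinases) &&
      any(nb %in% setdiff(measured_kinases, v))
  }, TRUE)]
  sources <- union(upregulated_kinases, bridging)
  keep_node <- function(v) {
    if (v %in% sources || v %in% up_tf) return(TRUE)
    if (v %in% measured_kinases) {
      if (mode == "large")
        return(sum(nbrs(v) %in% upregulated_kinases) >= 2)
      # focused: measured kinases enter as substrates of included kinases
      return(any(edges$to == v & edges$from %in% sources))
    }
    FALSE
  }
  nodes <- cand[vapply(cand, keep_node, TRUE)]
  edges <- edges[edges$from %in% nodes & edges$to %in% nodes, ,
                 drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  igraph::V(g)$upregulated <- nodes %in% upregulated_kinases
  igraph::V(g)$measured <- nodes %in% measured_kinases |
    !is_kin(nodes)  # non-kinase substrates are measured by construction
  igraph::V(g)$bridging <- is_kin(nodes) & !(nodes %in% measured_kinases)
  igraph::V(g)$is_tf <- nodes %in% tf_list
  g
}
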