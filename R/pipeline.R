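#' Default pipeline configuration
#'
#' All thresholds default to the study's values; simulation sizes are
#' desk-scale defaults chosen so a full synthetic run completes in
#' minutes on one CPU.
#'
#' @return nested named list
#' @export
default_config <- function() {
  list(
    seed = 1,
    stages = list(simulate = TRUE, preprocess = TRUE, diffexpr = TRUE,
                  kinase = TRUE, consensus = TRUE, network = TRUE,
                  singlecell = TRUE, enrichment = TRUE),
    simulate = list(
      n_proteins = 300, sites_per_protein = 2, n_replicates = 4,
      n_kinases = 10, n_active = 3, n_substrates = 20, n_protein_de = 25,
      effect_log2 = 2, noise_sd = 0.3, missing_mid = 22.5,
      missing_slope = 1.2,
      n_datasets = 6, n_genes = 2000, frac_de = 0.05, concordance = 0.9,
      n_blocks = 4, block_size = 40, p_in = 0.3, p_out = 0.01,
      frac_fail = 0.2,
      n_cells = 600, sc_n_genes = 1500, n_signature = 100, shift = 1.5,
      nb_dispersion = 2, frac_m1 = 0.5, mito_frac_outliers = 0.05),
    thresholds = list(
      fdr_max = 0.05, abs_log2fc_min = 1.0, min_peptides = 2,
      min_measured = 2, loc_prob_min = 0.75,
      impute_shift_high = 0.5, impute_shift_low = 1.8, impute_width = 0.3,
      moderation = "on",
      kinase_p_max = 0.05, min_substrates = 10, posterior_min = 0.035,
      consensus_min_datasets = 3, min_ratio = 4, dtu_min_fraction = 0.5,
      conf_source1 = 0.7, conf_source3 = 0.7, dtu_max_fraction = 0.75,
      target_avg_degree = 10, min_module_size = 10,
      qc_min_genes = 500, qc_max_genes = 9000, qc_max_mito = 0.10,
      qc_min_cells_per_gene = 3, sc_min_frac = 0.10, sc_alpha = 0.05,
      sc_min_avg_log2fc = 0.75, n_bins = 24, n_ctrl = 100,
      ora_min_novel = 2, ora_min_hits = 5, ora_max_set_size = 300))
}

.merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(defaults))
      stop("unknown config key: ", paste0(path, k))
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]],
                                     paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate and resolve a pipeline configuration
#'
#' Reads a YAML file (or takes a list), injects defaults, rejects unknown
#' keys, and range-checks the thresholds.
#'
#' @param config YAML file path, a list, or `NULL` for pure defaults
#' @return resolved config list (class `RunConfig`)
#' @export
validate_config <- function(config = NULL) {
  user <- if (is.null(config)) list()
  else if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    out <- yaml::read_yaml(config)
    if (is.null(out)) list() else out
  } else config
  cfg <- .merge_config(default_config(), user)
  th <- cfg$thresholds
  frac_keys <- c("fdr_max", "loc_prob_min", "posterior_min",
                 "dtu_min_fraction", "dtu_max_fraction", "qc_max_mito",
                 "sc_min_frac", "sc_alpha")
  for (k in frac_keys)
    if (th[[k]] < 0 || th[[k]] > 1)
      stop("config thresholds.", k, " must lie in [0, 1]; got ", th[[k]])
  if (!th$moderation %in% c("on", "off"))
    stop("config thresholds.moderation must be 'on' or 'off'")
  for (k in c("min_peptides", "min_measured", "min_substrates",
              "consensus_min_datasets"))
    if (th[[k]] < 0) stop("config thresholds.", k, " must be >= 0")
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    stop("config seed must be an integer")
  class(cfg) <- "RunConfig"
  cfg
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Executes the stages in order (simulate, preprocess, differential
#' testing with PTM adjustment, kinase inference, bulk consensus,
#' integrative network, single cell, enrichment), writing each stage's
#' tables under `outdir` plus a JSON run report with counts, seeds,
#' thresholds and the resolved-config hash. Identical config (including
#' seed) gives byte-identical outputs.
#'
#' @param config a `RunConfig` from [validate_config()], a YAML path, or
#'   `NULL` for defaults
#' @param outdir output directory (created)
#' @return the run report (list), invisibly; also written as
#'   `report.json`
#' @export
run_pipeline <- function(config = NULL, outdir = tempfile("macsig_run_")) {
  cfg <- if (inherits(config, "RunConfig")) config else
    validate_config(config)
  st <- cfg$stages; sim <- cfg$simulate; th <- cfg$thresholds
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(stages = list(), seed = cfg$seed,
                 thresholds = th)
  tick <- function(stage) message(sprintf("[macsig] %s: %s", stage,
                                          format(Sys.time(), "%H:%M:%S")))
  need <- function(dep, stage) {
    if (!isTRUE(st[[dep]]))
      stop("stage '", stage, "' requires stage '", dep, "' to be enabled")
  }
  seed <- as.integer(cfg$seed)

  # ---- simulate -----------------------------------------------------
  if (!isTRUE(st$simulate)) stop("pipeline currently runs on synthetic ",
                                 "inputs; enable the simulate stage")
  tick("simulate")
  phx <- gen_phosphoproteome(
    n_proteins = sim$n_proteins, sites_per_protein = sim$sites_per_protein,
    n_replicates = sim$n_replicates, n_kinases = sim$n_kinases,
    n_active = sim$n_active, n_substrates = sim$n_substrates,
    n_protein_de = sim$n_protein_de, effect_log2 = sim$effect_log2,
    noise_sd = sim$noise_sd,
    missing_params = list(mid = sim$missing_mid, slope = sim$missing_slope),
    seed = seed)
  bulk <- gen_bulk_de_tables(n_datasets = sim$n_datasets,
                             n_genes = sim$n_genes, frac_de = sim$frac_de,
                             concordance = sim$concordance,
                             seed = seed + 1L)
  sc <- gen_single_cells(n_cells = sim$n_cells, n_genes = sim$sc_n_genes,
                         n_signature = sim$n_signature, shift = sim$shift,
                         nb_dispersion = sim$nb_dispersion,
                         frac_m1 = sim$frac_m1,
                         mito_frac_outliers = sim$mito_frac_outliers,
                         seed = seed + 3L)
  simdir <- file.path(outdir, "simulate")
  dir.create(simdir, showWarnings = FALSE)
  write_feature_table(phx$proteome, file.path(simdir, "proteome.tsv"))
  write_feature_table(phx$phospho, file.path(simdir, "phospho.tsv"))
  .write_tsv(phx$ksmap, file.path(simdir, "kinase_substrates.tsv"))
  write_sparse_counts(sc$cells, file.path(simdir, "cells"))
  report$stages$simulate <- list(
    n_proteins = nrow(phx$proteome$values),
    n_phosphosites = nrow(phx$phospho$values),
    n_cells = length(sc$cells$cell_ids))

  # ---- preprocess ---------------------------------------------------
  if (isTRUE(st$preprocess)) {
  need("simulate", "preprocess"); tick("preprocess")
  prot <- log2_center(clean_proteome(phx$proteome, th$min_peptides))
  prot <- impute_missing(prot, seed = seed + 10L,
                         shift_high = th$impute_shift_high,
                         shift_low = th$impute_shift_low,
                         width = th$impute_width)
  ph <- clean_phospho(phx$phospho, min_measured = th$min_measured,
                      loc_prob_min = th$loc_prob_min)
  phos <- impute_missing(log2_center(ph$analysis_set), seed = seed + 11L,
                         shift_high = th$impute_shift_high,
                         shift_low = th$impute_shift_low,
                         width = th$impute_width)
  predir <- file.path(outdir, "preprocess")
  dir.create(predir, showWarnings = FALSE)
  write_feature_table(prot, file.path(predir, "proteome_imputed.tsv"))
  write_feature_table(phos, file.path(predir, "phospho_imputed.tsv"))
  motif_ids <- ph$motif_set$feature_id
  report$stages$preprocess <- list(
    n_proteins_clean = nrow(prot$values),
    n_phospho_analysis = nrow(phos$values),
    n_phospho_motif = length(motif_ids))

  }

  # ---- diffexpr -----------------------------------------------------
  if (isTRUE(st$diffexpr)) {
  need("preprocess", "diffexpr"); tick("diffexpr")
  conds <- unique(phos$condition)
  pr_res <- moderated_ttest(prot, conds[1], conds[2], th$moderation)
  pr_res$fdr <- bh_adjust(pr_res$p)
  pr_res <- call_significant(pr_res, th$fdr_max, th$abs_log2fc_min)
  ph_res <- moderated_ttest(phos, conds[1], conds[2], th$moderation)
  ph_res$fdr <- bh_adjust(ph_res$p)
  ph_res <- call_significant(ph_res, th$fdr_max, th$abs_log2fc_min)
  ph_res <- reconcile_multiplicity(ph_res)
  adj <- adjust_ptm(ph_res, pr_res, fdr_max = th$fdr_max)
  raw_sig_sites <- unique(ph_res$site_id[ph_res$significant])
  adj <- apply_keep_rule(adj, raw_sig_sites)
  dedir <- file.path(outdir, "diffexpr")
  dir.create(dedir, showWarnings = FALSE)
  .write_tsv(pr_res, file.path(dedir, "proteome_de.tsv"))
  .write_tsv(ph_res, file.path(dedir, "phospho_de.tsv"))
  .write_tsv(adj, file.path(dedir, "phospho_adjusted.tsv"))
  report$stages$diffexpr <- list(
    n_protein_significant = sum(pr_res$significant),
    n_phospho_significant = length(raw_sig_sites),
    n_phospho_driven = sum(adj$phospho_driven & !adj$no_protein_evidence),
    n_kept_sites = length(attr(adj, "kept_sites")))

  }

  # ---- kinase -------------------------------------------------------
  if (isTRUE(st$kinase)) {
  need("diffexpr", "kinase"); tick("kinase")
  in_motif <- ph_res$feature_id %in% motif_ids
  measured <- unique(ph_res$site_id[in_motif])
  up <- unique(ph_res$site_id[in_motif & ph_res$significant &
                                ph_res$log2fc > 0])
  up <- intersect(up, c(attr(adj, "kept_sites"),
                        adj$site_id[adj$no_protein_evidence]))
  kin_en <- enrich_curated_substrates(up, measured, phx$ksmap,
                                      p_max = th$kinase_p_max)
  pred <- gen_site_predictions(phx$ksmap, seed = seed + 20L)
  fpred <- filter_site_predictions(pred$predictions,
                                   posterior_min = th$posterior_min)
  fam_en <- enrich_predicted_families(fpred, up, measured,
                                      min_substrates = th$min_substrates,
                                      fdr_max = th$fdr_max)
  up_kin <- kin_en$kinase[kin_en$significant]
  signet <- build_signaling_network(
    up_kin, measured_kinases = unique(phx$ksmap$kinase), ksmap = phx$ksmap,
    filtered_preds = fpred, families = pred$families,
    upregulated_sites = up, tf_list = character(), mode = "focused")
  kindir <- file.path(outdir, "kinase")
  dir.create(kindir, showWarnings = FALSE)
  .write_tsv(kin_en, file.path(kindir, "kinase_enrichment.tsv"))
  .write_tsv(fam_en, file.path(kindir, "family_enrichment.tsv"))
  igraph::write_graph(signet, file.path(kindir, "signaling_network.graphml"),
                      format = "graphml")
  report$stages$kinase <- list(
    n_significant_kinases = sum(kin_en$significant),
    significant_kinases = sort(up_kin),
    n_significant_families = sum(fam_en$significant),
    n_network_nodes = igraph::vcount(signet))

  }

  # ---- consensus ----------------------------------------------------
  if (isTRUE(st$consensus)) {
  need("simulate", "consensus"); tick("consensus")
  cons <- consensus_de(bulk$tables, bulk$expr,
                       min_datasets = th$consensus_min_datasets,
                       fdr_max = th$fdr_max, min_ratio = th$min_ratio)
  dtu_genes <- consensus_dtu(bulk$dtu_calls,
                             min_fraction = th$dtu_min_fraction)
  consdir <- file.path(outdir, "consensus")
  dir.create(consdir, showWarnings = FALSE)
  .write_tsv(cons, file.path(consdir, "consensus_de.tsv"))
  writeLines(dtu_genes, file.path(consdir, "consensus_dtu.txt"))
  report$stages$consensus <- list(
    n_consensus_genes = sum(cons$consensus),
    n_dtu_genes = length(dtu_genes))

  }

  # ---- network ------------------------------------------------------
  if (isTRUE(st$network)) {
  need("consensus", "network"); need("diffexpr", "network")
  tick("network")
  hits_by_layer <- list(
    proteome = pr_res$feature_id[pr_res$significant],
    phospho = unique(adj$protein_id[adj$kept]),
    transcript = cons$gene[cons$consensus],
    dtu = dtu_genes)
  n_nodes <- sim$n_blocks * sim$block_size
  set.seed(seed + 30L)
  hit_pool <- unique(unlist(hits_by_layer))
  filler <- setdiff(unique(unlist(lapply(bulk$tables, `[[`, "gene"))),
                    hit_pool)
  node_names <- sample(c(sample(hit_pool, min(length(hit_pool),
                                              round(0.8 * n_nodes))),
                         sample(filler, n_nodes)))[seq_len(n_nodes)]
  net <- gen_interaction_network(n_blocks = sim$n_blocks,
                                 block_size = sim$block_size,
                                 p_in = sim$p_in, p_out = sim$p_out,
                                 frac_fail = sim$frac_fail,
                                 node_names = node_names,
                                 seed = seed + 31L)
  edges <- merge_interactions(net$records,
                              thresholds = list(source1 = th$conf_source1,
                                                source3 = th$conf_source3))
  g <- build_integrative_network(edges, hits_by_layer,
                                 dtu_max_fraction = th$dtu_max_fraction)
  netdir <- file.path(outdir, "network")
  dir.create(netdir, showWarnings = FALSE)
  if (is.null(g)) stop("stage 'network': integrative network is empty")
  cfb <- current_flow_betweenness(g)
  part <- detect_modules(g, target_avg_degree = th$target_avg_degree,
                         min_module_size = th$min_module_size,
                         seed = seed + 32L)
  node_tab <- data.frame(node = igraph::V(g)$name,
                         layers = igraph::V(g)$layers,
                         centrality = unname(cfb[igraph::V(g)$name]),
                         module = unname(part$membership[
                           igraph::V(g)$name]),
                         stringsAsFactors = FALSE)
  .write_tsv(node_tab, file.path(netdir, "nodes.tsv"))
  igraph::write_graph(g, file.path(netdir, "integrative_network.graphml"),
                      format = "graphml")
  report$stages$network <- list(
    n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
    n_modules = length(part$sizes),
    modularity = part$modularity,
    avg_within_degree = part$avg_within_degree)

  }

  # ---- singlecell ---------------------------------------------------
  if (isTRUE(st$singlecell)) {
  need("simulate", "singlecell"); tick("singlecell")
  qc <- qc_filter(sc$cells, min_genes = th$qc_min_genes,
                  max_genes = th$qc_max_genes, max_mito = th$qc_max_mito,
                  min_cells_per_gene = th$qc_min_cells_per_gene)
  if (is.null(qc)) stop("stage 'singlecell': no cell passed QC")
  norm <- normalize_log(qc)
  s1 <- score_signature(norm, sc$signatures$m1, n_bins = th$n_bins,
                        n_ctrl = th$n_ctrl, seed = seed + 40L)
  s2 <- score_signature(norm, sc$signatures$m2, n_bins = th$n_bins,
                        n_ctrl = th$n_ctrl, seed = seed + 41L)
  ann <- classify_macrophages(s1, s2)
  truth_state <- sc$truth$cell_state[ann$cell_id]
  acc <- mean(ann$state == truth_state & ann$state != "Na") /
    max(mean(ann$state != "Na"), 1e-12)
  grp <- ann$state
  sel <- grp %in% c("M1-like", "M2-like")
  de <- if (min(base::table(factor(grp[sel],
                                   c("M1-like", "M2-like")))) >= 2) {
    sc_differential_expression(norm[, sel, drop = FALSE], grp[sel],
                               min_frac = th$sc_min_frac,
                               alpha = th$sc_alpha,
                               min_avg_log2fc = th$sc_min_avg_log2fc)
  } else {
    message("too few cells per state for differential expression")
    data.frame(gene = character(), avg_log2fc = numeric(), t = numeric(),
               p = numeric(), p_adj = numeric(), frac_1 = numeric(),
               frac_2 = numeric(), significant = logical())
  }
  scdir <- file.path(outdir, "singlecell")
  dir.create(scdir, showWarnings = FALSE)
  .write_tsv(ann, file.path(scdir, "annotation.tsv"))
  .write_tsv(de, file.path(scdir, "sc_de.tsv"))
  report$stages$singlecell <- list(
    n_cells_qc = length(qc$cell_ids),
    n_m1 = sum(ann$state == "M1-like"),
    n_m2 = sum(ann$state == "M2-like"),
    n_na = sum(ann$state == "Na"),
    state_accuracy_non_na = acc,
    n_sc_de = sum(de$significant))

  }

  # ---- enrichment ---------------------------------------------------
  if (isTRUE(st$enrichment)) {
  need("diffexpr", "enrichment"); need("network", "enrichment")
  tick("enrichment")
  # phospho ORA: hits = proteins of kept sites, background = all phospho
  # proteins in the analysis set
  bg <- unique(phos$protein_id)
  hits <- intersect(unique(adj$protein_id[adj$kept]), bg)
  psets <- gen_gene_sets(bg, n_sets = 12, size_range = c(10, 60),
                         planted = list(PLANTED_KEPT = hits),
                         seed = seed + 50L)
  ora <- hypergeometric_ora(hits, bg, psets)
  ora <- prune_and_filter(ora, min_novel = th$ora_min_novel,
                          min_hits = th$ora_min_hits,
                          max_set_size = th$ora_max_set_size,
                          fdr_max = th$fdr_max)
  # per-module ORA against the full network background
  net_bg <- igraph::V(g)$name
  nsets <- gen_gene_sets(net_bg, n_sets = 10, size_range = c(10, 50),
                         seed = seed + 51L)
  mod_rows <- list()
  for (mid in seq_along(part$sizes)) {
    mem <- names(part$membership)[part$membership == mid]
    if (length(mem) < th$min_module_size) next
    mora <- hypergeometric_ora(mem, net_bg, nsets)
    mora <- prune_and_filter(mora, min_novel = th$ora_min_novel,
                             min_hits = th$ora_min_hits,
                             max_set_size = th$ora_max_set_size,
                             fdr_max = th$fdr_max)
    mora$module <- mid
    mod_rows[[mid]] <- mora
  }
  mod_ora <- do.call(rbind, mod_rows)
  endir <- file.path(outdir, "enrichment")
  dir.create(endir, showWarnings = FALSE)
  .write_tsv(ora, file.path(endir, "phospho_ora.tsv"))
  if (!is.null(mod_ora))
    .write_tsv(mod_ora, file.path(endir, "module_ora.tsv"))
  report$stages$enrichment <- list(
    n_phospho_sets_retained = sum(ora$retained),
    n_module_sets_tested = if (is.null(mod_ora)) 0L else nrow(mod_ora))

  }

  # ---- report -------------------------------------------------------
  cfgfile <- file.path(outdir, "config_resolved.yaml")
  yaml::write_yaml(unclass(cfg), cfgfile)
  report$config_hash <- unname(tools::md5sum(cfgfile))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
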