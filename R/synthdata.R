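#' @importFrom stats rnorm runif rbinom rnbinom plogis median sd var
NULL

#' Canonical phosphosite identifier
#'
#' @param protein protein symbol(s)
#' @param residue residue string(s) such as `"S176"`
#' @return character site id(s) `"PROTEIN:S176"`
#' @export
make_site_id <- function(protein, residue) paste(protein, residue, sep = ":")

#' Generate a synthetic two-condition (phospho)proteome experiment
#'
#' Emulates a label-free two-condition experiment with biological
#' replicates: log-normal baseline intensities (log2 scale `Normal(25, 2)`
#' per protein), phosphosites nested within proteins, a set of kinases
#' whose substrate sites are shifted by `effect_log2` in the second
#' condition at the phospho level only, and a disjoint set of proteins
#' shifted at the protein level (propagating to their sites, to exercise
#' the PTM-vs-protein adjustment). Missingness is left-censoring: the
#' probability that an entry is missing is a decreasing logistic function
#' of its true log2 intensity.
#'
#' @param n_proteins number of proteins
#' @param sites_per_protein phosphosites per protein
#' @param n_replicates biological replicates per condition
#' @param n_kinases number of kinases in the curated map
#' @param n_active number of kinases with planted activity (`<= n_kinases`)
#' @param n_substrates substrate sites per kinase (disjoint across kinases,
#'   drawn from proteins without a planted protein-level effect)
#' @param n_protein_de number of proteins with a planted protein-level effect
#' @param effect_log2 planted log2 effect size (condition B minus A)
#' @param noise_sd per-measurement Gaussian noise SD on the log2 scale
#' @param missing_params `NULL` for no censoring, else
#'   `list(mid=, slope=)`: P(missing) = plogis(-slope * (x - mid)) at true
#'   log2 intensity x; `slope` must be `>= 0`
#' @param conditions two condition labels
#' @param seed integer seed; identical seed gives identical output
#' @return list with elements `proteome` and `phospho` ([feature_table()]s
#'   of raw intensities), `ksmap` (data.frame kinase/protein/residue/source),
#'   and `truth` (planted ground truth: `de_proteins`, `active_kinases`,
#'   `kinase_substrates`, `phospho_driven_sites`, `cond_b`)
#' @export
gen_phosphoproteome <- function(n_proteins = 400, sites_per_protein = 2,
                                n_replicates = 4, n_kinases = 10,
                                n_active = 3, n_substrates = 20,
                                n_protein_de = 30, effect_log2 = 2,
                                noise_sd = 0.3,
                                missing_params = list(mid = 22.5, slope = 1.2),
                                conditions = c("M1", "M2a"), seed = 1) {
  stopifnot(n_active <= n_kinases, n_replicates >= 2,
            length(conditions) == 2)
  if (!is.null(missing_params)) {
    if (!all(c("mid", "slope") %in% names(missing_params)) ||
        missing_params$slope < 0)
      stop("missing_params must be list(mid=, slope=) with slope >= 0")
  }
  if (effect_log2 == 0 && n_active > 0)
    warning("effect_log2 = 0 with planted active kinases: truth unrecoverable")
  set.seed(seed)

  proteins <- sprintf("P%04d", seq_len(n_proteins))
  kinases <- sprintf("KIN%02d", seq_len(n_kinases))
  prot_base <- rnorm(n_proteins, 25, 2)
  names(prot_base) <- proteins
  de_prots <- sample(proteins, n_protein_de)
  de_effect <- setNames(rep(effect_log2, n_protein_de), de_prots)

  # sites nested in proteins
  site_prot <- rep(proteins, each = sites_per_protein)
  n_sites <- length(site_prot)
  pos <- sample(5:900, n_sites, replace = TRUE)
  res_letter <- sample(c("S", "T", "Y"), n_sites, replace = TRUE,
                       prob = c(0.75, 0.2, 0.05))
  residue <- paste0(res_letter, pos)
  # disambiguate duplicate residues within a protein
  sid <- make_site_id(site_prot, residue)
  while (anyDuplicated(sid)) {
    d <- duplicated(sid)
    pos[d] <- pos[d] + 1L
    residue <- paste0(res_letter, pos)
    sid <- make_site_id(site_prot, residue)
  }

  # kinase substrates: disjoint, never on protein-level DE proteins so each
  # planted phospho effect has exactly one mechanism
  eligible <- which(!(site_prot %in% de_prots))
  need <- n_kinases * n_substrates
  if (length(eligible) < need)
    stop("not enough sites on non-DE proteins for the requested kinase map")
  picked <- sample(eligible, need)
  kin_of_site <- rep(NA_character_, n_sites)
  kin_of_site[picked] <- rep(kinases, each = n_substrates)
  active <- kinases[seq_len(n_active)]

  multiplicity <- sample(1:3, n_sites, replace = TRUE,
                         prob = c(0.7, 0.25, 0.05))
  locprob <- ifelse(runif(n_sites) < 0.9, runif(n_sites, 0.76, 1),
                    runif(n_sites, 0.3, 0.74))
  site_base <- prot_base[site_prot] + rnorm(n_sites, -1, 1)

  n_s <- 2 * n_replicates
  samples <- paste0(rep(conditions, each = n_replicates), "_r",
                    rep(seq_len(n_replicates), 2))
  cond_of <- setNames(rep(conditions, each = n_replicates), samples)
  is_b <- cond_of == conditions[2]

  censor <- function(true_log2) {
    if (is.null(missing_params)) return(true_log2)
    p <- plogis(-missing_params$slope * (true_log2 - missing_params$mid))
    true_log2[runif(length(true_log2)) < p] <- NA_real_
    true_log2
  }

  # proteome matrix
  prot_eff <- ifelse(proteins %in% de_prots, effect_log2, 0)
  pm <- matrix(rnorm(n_proteins * n_s, 0, noise_sd), n_proteins, n_s)
  pm <- pm + prot_base + outer(prot_eff, as.numeric(is_b))
  pm <- censor(pm)
  proteome <- feature_table(
    2^pm, proteins, proteins, samples, cond_of,
    meta = data.frame(peptide_count = sample(2:30, n_proteins, TRUE),
                      is_contaminant = FALSE, is_decoy = FALSE,
                      is_phospho = FALSE))

  # phospho matrix: protein-level effect propagates; active-kinase substrate
  # sites get the additional phospho-specific effect
  phos_eff <- prot_eff[match(site_prot, proteins)] +
    ifelse(!is.na(kin_of_site) & kin_of_site %in% active, effect_log2, 0)
  sm <- matrix(rnorm(n_sites * n_s, 0, noise_sd), n_sites, n_s)
  sm <- sm + site_base + outer(phos_eff, as.numeric(is_b))
  sm <- censor(sm)
  phospho <- feature_table(
    2^sm, paste0(sid, "|m", multiplicity), site_prot, samples, cond_of,
    meta = data.frame(peptide_count = 1L, is_contaminant = FALSE,
                      is_decoy = FALSE, multiplicity = multiplicity,
                      localization_prob = locprob, residue = residue,
                      is_phospho = TRUE),
    is_phospho_table = TRUE)

  has_kin <- !is.na(kin_of_site)
  ksmap <- data.frame(kinase = kin_of_site[has_kin],
                      protein = site_prot[has_kin],
                      residue = residue[has_kin],
                      source = "curated", stringsAsFactors = FALSE)
  truth <- list(
    de_proteins = de_effect,
    active_kinases = active,
    kinase_substrates = split(sid[has_kin], kin_of_site[has_kin]),
    phospho_driven_sites = sid[has_kin & kin_of_site %in% active],
    cond_b = conditions[2])
  list(proteome = proteome, phospho = phospho, ksmap = ksmap, truth = truth)
}

#' Generate synthetic per-dataset bulk differential-expression tables
#'
#' Emulates a panel of independently analysed bulk RNA-seq studies of the
#' same two phenotypes: a fraction of genes is truly differential, and each
#' truly differential gene reaches significance (adjusted p < 0.05 and
#' |log2FC| > 2) in each dataset independently with probability
#' `concordance`; null genes pass with a small false-positive rate. Also
#' emits per-dataset expression tables (for the above-median prefilter)
#' and per-dataset differential-transcript-usage gene calls.
#'
#' @param n_datasets number of datasets
#' @param n_genes genes per dataset
#' @param frac_de fraction of truly differential genes
#' @param concordance per-dataset probability that a true gene is called
#' @param fp_rate per-dataset false-positive probability for null genes
#' @param frac_dtu fraction of genes with planted transcript-usage changes
#' @param dtu_concordance per-dataset call probability for true DTU genes
#' @param seed integer seed
#' @return list: `tables` (each gene/log2fc/adj_p), `expr` (each gene/expr),
#'   `dtu_calls` (character vectors), `truth` (`de_genes` signed effects,
#'   `dtu_genes`)
#' @export
gen_bulk_de_tables <- function(n_datasets = 6, n_genes = 2000,
                               frac_de = 0.05, concordance = 0.9,
                               fp_rate = 0.01, frac_dtu = 0.03,
                               dtu_concordance = 0.8, seed = 1) {
  stopifnot(concordance >= 0, concordance <= 1, n_datasets >= 1)
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  n_de <- round(frac_de * n_genes)
  de_genes <- sample(genes, n_de)
  dir <- sample(c(-1, 1), n_de, replace = TRUE)
  names(dir) <- de_genes
  dtu_genes <- sample(setdiff(genes, de_genes), round(frac_dtu * n_genes))

  tables <- expr <- dtu_calls <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    is_de <- genes %in% de_genes
    called <- ifelse(is_de, runif(n_genes) < concordance,
                     runif(n_genes) < fp_rate)
    log2fc <- ifelse(called,
                     sample(c(-1, 1), n_genes, TRUE) * runif(n_genes, 2.2, 6),
                     runif(n_genes, -1.8, 1.8))
    log2fc[is_de & called] <- dir[genes[is_de & called]] *
      runif(sum(is_de & called), 2.2, 6)
    adj_p <- ifelse(called, runif(n_genes, 0, 0.049),
                    runif(n_genes, 0.06, 1))
    tables[[d]] <- data.frame(gene = genes, log2fc = log2fc, adj_p = adj_p,
                              stringsAsFactors = FALSE)
    e <- runif(n_genes)
    e[is_de] <- runif(sum(is_de), 0.55, 1)  # true genes sit in the upper half
    expr[[d]] <- data.frame(gene = genes, expr = e, stringsAsFactors = FALSE)
    hit <- runif(length(dtu_genes)) < dtu_concordance
    fp <- sample(setdiff(genes, dtu_genes), rbinom(1, n_genes, fp_rate / 2))
    dtu_calls[[d]] <- c(dtu_genes[hit], fp)
  }
  list(tables = tables, expr = expr, dtu_calls = dtu_calls,
       truth = list(de_genes = dir, dtu_genes = dtu_genes))
}

#' Generate a synthetic interaction edge list with planted modules
#'
#' Draws a stochastic-block-model graph (dense within blocks, sparse
#' between) and distributes its edges across the three interaction-source
#' roles, with confidence values drawn so that a configurable fraction of
#' records fails the downstream confidence thresholds.
#'
#' @param n_blocks number of planted modules
#' @param block_size nodes per module
#' @param p_in within-block edge probability
#' @param p_out between-block edge probability (`< p_in`)
#' @param frac_fail fraction of records drawn below the confidence cut
#'   (or, for the physical-interaction source, with absent confidence)
#' @param node_names optional node names (default `N001`, ...)
#' @param seed integer seed
#' @return list: `records` (data.frame node_a/node_b/source/confidence),
#'   `truth` (`membership` named integer vector)
#' @export
gen_interaction_network <- function(n_blocks = 4, block_size = 40,
                                    p_in = 0.3, p_out = 0.01,
                                    frac_fail = 0.2, node_names = NULL,
                                    seed = 1) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1)
  set.seed(seed)
  n <- n_blocks * block_size
  pref <- matrix(p_out, n_blocks, n_blocks); diag(pref) <- p_in
  g <- igraph::sample_sbm(n, pref.matrix = pref,
                          block.sizes = rep(block_size, n_blocks))
  if (is.null(node_names)) node_names <- sprintf("N%04d", seq_len(n))
  stopifnot(length(node_names) == n, !anyDuplicated(node_names))
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(el)
  src <- sample(c("source1", "source2", "source3"), m, replace = TRUE)
  fail <- runif(m) < frac_fail
  conf <- ifelse(fail, runif(m, 0.3, 0.7), runif(m, 0.701, 0.99))
  conf[src == "source2" & fail] <- NA_real_
  conf[src == "source2" & !fail] <- runif(sum(src == "source2" & !fail))
  records <- data.frame(node_a = node_names[el[, 1]],
                        node_b = node_names[el[, 2]],
                        source = src, confidence = conf,
                        stringsAsFactors = FALSE)
  membership <- setNames(rep(seq_len(n_blocks), each = block_size),
                         node_names)
  list(records = records, truth = list(membership = membership))
}

#' Generate synthetic single-cell macrophage counts with planted states
#'
#' Negative-binomial counts over log-normal gene baseline means and
#' log-normal per-cell library-size factors. Cells are planted as M1-like
#' or M2-like: the corresponding signature genes' means are multiplied by
#' `2^shift`. A stated fraction of cells is made to fail quality control
#' (mitochondrial-count outliers and very low library cells), to exercise
#' the filters.
#'
#' @param n_cells number of cells
#' @param n_genes number of genes (including `n_mito` mitochondrial genes)
#' @param n_signature genes per state signature (`<= n_genes / 4`)
#' @param shift planted log2 shift of signature-gene means
#' @param nb_dispersion negative-binomial size parameter
#' @param frac_m1 fraction of cells planted as M1-like
#' @param mito_frac_outliers fraction of cells with boosted mitochondrial
#'   counts (fail the >10% mito filter)
#' @param low_count_frac_outliers fraction of cells with collapsed library
#'   size (fail the minimum expressed-gene filter)
#' @param n_mito number of mitochondrial genes (named `MT-...`)
#' @param seed integer seed
#' @return list: `cells` (`SparseCellMatrix`), `signatures`
#'   (`list(m1=, m2=)` gene vectors), `truth` (`cell_state` named vector,
#'   `mito_outliers`, `low_count_outliers`)
#' @export
gen_single_cells <- function(n_cells = 800, n_genes = 1500,
                             n_signature = 100, shift = 1.5,
                             nb_dispersion = 2, frac_m1 = 0.5,
                             mito_frac_outliers = 0.05,
                             low_count_frac_outliers = 0.03,
                             n_mito = 10, seed = 1) {
  stopifnot(n_signature <= n_genes / 4, frac_m1 >= 0, frac_m1 <= 1)
  set.seed(seed)
  mito_genes <- sprintf("MT-G%02d", seq_len(n_mito))
  other <- sprintf("G%05d", seq_len(n_genes - n_mito))
  genes <- c(mito_genes, other)
  cells <- sprintf("CELL%05d", seq_len(n_cells))
  m1_sig <- other[seq_len(n_signature)]
  m2_sig <- other[n_signature + seq_len(n_signature)]

  base <- exp(rnorm(n_genes, log(1.0), 0.8))
  # mitochondrial means set so a typical cell carries ~3% mito counts
  base[seq_len(n_mito)] <- 0.03 / 0.97 * sum(base[-seq_len(n_mito)]) / n_mito

  state <- ifelse(runif(n_cells) < frac_m1, "M1-like", "M2-like")
  names(state) <- cells
  libf <- exp(rnorm(n_cells, 0, 0.25))
  mito_out <- runif(n_cells) < mito_frac_outliers
  low_out <- !mito_out & runif(n_cells) < low_count_frac_outliers
  libf[low_out] <- libf[low_out] * 0.03

  mu <- outer(base, libf)
  mu[match(m1_sig, genes), state == "M1-like"] <-
    mu[match(m1_sig, genes), state == "M1-like"] * 2^shift
  mu[match(m2_sig, genes), state == "M2-like"] <-
    mu[match(m2_sig, genes), state == "M2-like"] * 2^shift
  mu[seq_len(n_mito), mito_out] <- mu[seq_len(n_mito), mito_out] * 10

  counts <- matrix(rnbinom(length(mu), mu = mu, size = nb_dispersion),
                   n_genes, n_cells)
  sm <- as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  dimnames(sm) <- list(genes, cells)
  cellmat <- structure(list(counts = sm, gene_ids = genes, cell_ids = cells,
                            mito_flag = startsWith(genes, "MT-")),
                       class = "SparseCellMatrix")
  list(cells = cellmat,
       signatures = list(m1 = m1_sig, m2 = m2_sig),
       truth = list(cell_state = state,
                    mito_outliers = cells[mito_out],
                    low_count_outliers = cells[low_out]))
}

#' Generate synthetic kinase-family site predictions
#'
#' Builds a site-level kinase-family prediction table consistent with a
#' curated kinase-substrate map: each kinase maps to its own family, true
#' substrate sites receive a high-posterior prediction for their kinase's
#' family, and random decoy predictions (mostly failing the posterior and
#' posterior-vs-prior filters) are added.
#'
#' @param ksmap curated map (data.frame kinase/protein/residue)
#' @param n_decoys number of decoy predictions
#' @param seed integer seed
#' @return list: `predictions` (data.frame protein/residue/kinase_family/
#'   posterior/prior), `families` (data.frame family/kinase)
#' @export
gen_site_predictions <- function(ksmap, n_decoys = 200, seed = 1) {
  set.seed(seed)
  fam_of <- setNames(paste0("FAM_", unique(ksmap$kinase)),
                     unique(ksmap$kinase))
  true_pred <- data.frame(protein = ksmap$protein, residue = ksmap$residue,
                          kinase_family = fam_of[ksmap$kinase],
                          posterior = runif(nrow(ksmap), 0.06, 0.4),
                          prior = 0.01, stringsAsFactors = FALSE)
  idx <- sample(nrow(ksmap), n_decoys, replace = TRUE)
  decoy <- data.frame(protein = ksmap$protein[idx],
                      residue = ksmap$residue[idx],
                      kinase_family = sample(fam_of, n_decoys, replace = TRUE),
                      posterior = runif(n_decoys, 0, 0.035),
                      prior = 0.01, stringsAsFactors = FALSE)
  preds <- rbind(true_pred, decoy)
  preds <- preds[!duplicated(preds[, c("protein", "residue",
                                       "kinase_family")]), ]
  rownames(preds) <- NULL
  list(predictions = preds,
       families = data.frame(family = unname(fam_of),
                             kinase = names(fam_of),
                             stringsAsFactors = FALSE))
}

#' Generate a synthetic gene-set collection over a universe
#'
#' Random member sets drawn from the universe, optionally seeded with
#' "coherent" sets built around supplied groups (so that enrichment of a
#' planted structure is recoverable).
#'
#' @param universe symbols to draw from
#' @param n_sets number of random sets
#' @param size_range inclusive range of set sizes
#' @param planted optional named list of symbol groups; each becomes a set
#'   (padded with random members up to the lower size bound)
#' @param seed integer seed
#' @return a `GeneSetCollection` (named list)
#' @export
gen_gene_sets <- function(universe, n_sets = 15, size_range = c(10, 60),
                          planted = NULL, seed = 1) {
  set.seed(seed)
  sets <- list()
  for (nm in names(planted)) {
    mem <- intersect(planted[[nm]], universe)
    pad <- max(0, size_range[1] - length(mem))
    if (pad > 0)
      mem <- unique(c(mem, sample(setdiff(universe, mem), pad)))
    sets[[nm]] <- structure(mem, description = "planted")
  }
  for (i in seq_len(n_sets)) {
    sz <- sample(size_range[1]:size_range[2], 1)
    sets[[sprintf("SET%03d", i)]] <-
      structure(sample(universe, min(sz, length(universe))),
                description = "random")
  }
  structure(sets, class = "GeneSetCollection")
}
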