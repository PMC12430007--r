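#' @importFrom stats pt p.adjust
NULL

#' Two-sample (moderated) t-tests per feature
#'
#' Pooled-variance two-sample t-tests on the log2 matrix, one per feature,
#' contrasting `cond_b` minus `cond_a`. With `moderation = "on"`, sample
#' variances are shrunk toward an empirical-Bayes prior estimated from the
#' distribution of all feature variances by moment matching on the log
#' variances (Smyth 2004, as implemented in limma's `squeezeVar`), and the
#' residual degrees of freedom are augmented by the prior degrees of
#' freedom. Requires a complete (post-imputation) matrix.
#'
#' @param table log2-scale `FeatureTable` without missing values
#' @param cond_a,cond_b condition labels; log2FC is `cond_b - cond_a`
#' @param moderation `"on"` (default) or `"off"`
#' @return data.frame with one row per feature: feature_id, protein_id,
#'   log2fc, se, df, t, p, n_a, n_b (plus site_id, multiplicity,
#'   localization_prob for phospho tables)
#' @export
moderated_ttest <- function(table, cond_a, cond_b,
                            moderation = c("on", "off")) {
  moderation <- match.arg(moderation)
  if (!all(c(cond_a, cond_b) %in% table$condition))
    stop("condition(s) absent from table: ",
         paste(setdiff(c(cond_a, cond_b), table$condition), collapse = ", "))
  if (anyNA(table$values))
    stop("matrix contains missing values; impute first")
  A <- condition_matrix(table, cond_a)
  B <- condition_matrix(table, cond_b)
  na <- ncol(A); nb <- ncol(B)
  if (na < 2 || nb < 2) stop("both conditions need >= 2 samples")
  fc <- rowMeans(B) - rowMeans(A)
  va <- apply(A, 1, var); vb <- apply(B, 1, var)
  df <- na + nb - 2
  s2 <- ((na - 1) * va + (nb - 1) * vb) / df
  if (moderation == "on") {
    sq <- limma::squeezeVar(s2, df)
    s2 <- sq$var.post
    df_tot <- df + sq$df.prior  # may be infinite (near-normal reference)
  } else {
    df_tot <- df
  }
  se <- sqrt(s2 * (1 / na + 1 / nb))
  t <- ifelse(se > 0, fc / se, ifelse(fc == 0, 0, sign(fc) * Inf))
  p <- ifelse(se > 0 | fc == 0, 2 * pt(-abs(t), df_tot), 0)
  out <- data.frame(feature_id = table$feature_id,
                    protein_id = table$protein_id,
                    log2fc = fc, se = se, df = df_tot, df_res = df,
                    t = t, p = p,
                    n_a = na, n_b = nb, stringsAsFactors = FALSE)
  if (table$is_phospho_table) {
    out$site_id <- make_site_id(table$protein_id, table$meta$residue)
    out$multiplicity <- table$meta$multiplicity
    out$localization_prob <- table$meta$localization_prob
  }
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' The correction family is exactly the supplied vector: when several
#' contrasts or multiplicity classes of one omics layer are corrected
#' jointly, concatenate their p-values before calling.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`
#' @return adjusted p-values (monotone, capped at 1), same order
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1] and be non-missing")
  p.adjust(pvalues, method = "BH")
}

#' Flag significant differential results
#'
#' Significance requires an FDR strictly below `fdr_max` ("below 5%") and
#' an absolute log2 fold change of at least `abs_log2fc_min`.
#'
#' @param results data.frame with `fdr` and `log2fc` columns
#' @param fdr_max FDR cut (strict `<`, default 0.05)
#' @param abs_log2fc_min minimum |log2FC| (inclusive `>=`, default 1)
#' @return `results` with a logical `significant` column
#' @export
call_significant <- function(results, fdr_max = 0.05, abs_log2fc_min = 1.0) {
  stopifnot(!is.null(results$fdr), !is.null(results$log2fc))
  results$significant <- results$fdr < fdr_max &
    abs(results$log2fc) >= abs_log2fc_min
  results
}

#' Remove sites with discordant directions across multiplicity classes
#'
#' Singly, doubly and triply phosphorylated peptides carrying the same site
#' are analyzed as separate features; a site whose classes are
#' significantly regulated in opposite directions is uninterpretable and
#' all its entries are removed. Discordance requires both directions to be
#' significant.
#'
#' @param results data.frame with `site_id`, `multiplicity`, `log2fc`,
#'   `significant` columns
#' @return filtered data.frame
#' @export
reconcile_multiplicity <- function(results) {
  stopifnot(!is.null(results$site_id), !is.null(results$multiplicity),
            !is.null(results$significant))
  bad <- vapply(split(seq_len(nrow(results)), results$site_id), function(ix) {
    sig <- results$significant[ix]
    fc <- results$log2fc[ix]
    any(sig & fc > 0) && any(sig & fc < 0)
  }, TRUE)
  drop_sites <- names(bad)[bad]
  out <- results[!(results$site_id %in% drop_sites), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Adjust phosphopeptide fold changes for protein-level changes
#'
#' Tests whether each phosphopeptide's fold change exceeds that of its
#' parent protein, i.e. whether the observed regulation is
#' phosphorylation-driven rather than an abundance effect. The test
#' statistic is
#' `t = (log2FC_ptm - log2FC_protein) / SE` with
#' `SE = SP * sqrt(1/df_protein + 1/df_ptm)` and pooled SD
#' `SP^2 = (SE_protein^2 (df_protein - 1) + SE_ptm^2 (df_ptm - 1)) /
#' (df_protein + df_ptm - 2)`; the two-sided p-value uses
#' `df_protein + df_ptm - 2` degrees of freedom. P-values are BH-corrected
#' across all adjusted tests and `phospho_driven` flags adjusted FDR below
#' `fdr_max`.
#'
#' Sites whose protein was not quantified pass through with
#' `phospho_driven = TRUE` and `no_protein_evidence = TRUE`: absence of
#' protein evidence cannot demonstrate abundance driving.
#'
#' @param phospho data.frame of phosphopeptide results (needs feature_id,
#'   site_id, protein_id, log2fc, se, df)
#' @param protein data.frame of protein-level results (needs feature_id or
#'   protein_id, log2fc, se, df)
#' @param fdr_max significance cut on the adjusted FDR (default 0.05)
#' @return data.frame with one row per phosphopeptide: the input fields,
#'   protein-side log2fc/se/df, sp, se_adj, t_adj, p_adj, fdr_adj,
#'   phospho_driven, no_protein_evidence
#' @export
adjust_ptm <- function(phospho, protein, fdr_max = 0.05) {
  pid <- if (!is.null(protein$protein_id)) protein$protein_id else
    protein$feature_id
  idx <- match(phospho$protein_id, pid)
  have <- !is.na(idx)
  # the pooled-SD construction uses the residual df of each t-test; the
  # (possibly prior-augmented) moderated df serves only site-level p-values
  dfp_all <- if (!is.null(protein$df_res)) protein$df_res else protein$df
  dfm_all <- if (!is.null(phospho$df_res)) phospho$df_res else phospho$df
  se_p <- protein$se[idx]; df_p <- dfp_all[idx]
  fc_p <- protein$log2fc[idx]
  se_m <- phospho$se; df_m <- dfm_all
  if (any(df_p[have] < 2) || any(df_m < 2))
    stop("degrees of freedom must be >= 2 on both sides")
  sp2 <- (se_p^2 * (df_p - 1) + se_m^2 * (df_m - 1)) / (df_p + df_m - 2)
  se_adj <- sqrt(sp2) * sqrt(1 / df_p + 1 / df_m)
  t_adj <- (phospho$log2fc - fc_p) / se_adj
  p_adj <- 2 * pt(-abs(t_adj), df_p + df_m - 2)
  out <- data.frame(feature_id = phospho$feature_id,
                    site_id = phospho$site_id,
                    protein_id = phospho$protein_id,
                    log2fc_ptm = phospho$log2fc,
                    log2fc_protein = fc_p,
                    se_ptm = se_m, se_protein = se_p,
                    df_ptm = df_m, df_protein = df_p,
                    sp = sqrt(sp2), se = se_adj, t_adj = t_adj,
                    p_adj = p_adj,
                    no_protein_evidence = !have,
                    stringsAsFactors = FALSE)
  out$fdr_adj <- NA_real_
  out$fdr_adj[have] <- bh_adjust(out$p_adj[have])
  out$phospho_driven <- ifelse(have, out$fdr_adj < fdr_max, TRUE)
  out
}

#' Apply the protein-level keep rule to adjusted phosphopeptides
#'
#' For every protein with at least one phosphorylation-driven site, all of
#' that protein's sites that were significant in the raw phosphopeptide
#' comparison are kept for downstream analysis (i.e. all significant
#' phosphopeptides before the comparison to protein-level changes).
#' Proteins without any phosphorylation-driven site contribute nothing.
#'
#' @param adjusted data.frame from [adjust_ptm()]
#' @param raw_significant character vector of site ids significant in the
#'   raw phosphopeptide differential test
#' @return `adjusted` with a logical `kept` column; the kept site ids are
#'   attached as attribute `"kept_sites"`
#' @export
apply_keep_rule <- function(adjusted, raw_significant) {
  driven_prot <- unique(adjusted$protein_id[adjusted$phospho_driven])
  adjusted$kept <- adjusted$protein_id %in% driven_prot &
    adjusted$site_id %in% raw_significant
  attr(adjusted, "kept_sites") <- unique(adjusted$site_id[adjusted$kept])
  adjusted
}
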