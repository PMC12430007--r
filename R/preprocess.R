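#' Clean a proteome feature table
#'
#' Removes common contaminants (keratins etc.), decoy (reversed-sequence)
#' matches, and protein groups quantified from fewer than `min_peptides`
#' peptides.
#'
#' @param table proteome `FeatureTable`
#' @param min_peptides minimum measured peptides per protein (default 2)
#' @return filtered `FeatureTable` (possibly empty)
#' @export
clean_proteome <- function(table, min_peptides = 2) {
  stopifnot(inherits(table, "FeatureTable"), !table$is_phospho_table)
  keep <- !table$meta$is_contaminant & !table$meta$is_decoy &
    table$meta$peptide_count >= min_peptides
  ft_subset(table, keep)
}

#' Clean a phosphosite feature table
#'
#' Drops non-phosphorylated peptides (identified after enrichment),
#' contaminants and decoys, then keeps features measured in at least
#' `min_measured` replicates of at least one condition. The returned
#' `motif_set` is additionally restricted to class I sites (localization
#' probability above `loc_prob_min`), the set used for kinase-motif
#' analyses.
#'
#' @param table phospho `FeatureTable`
#' @param min_measured minimum measurements in some condition (default 2)
#' @param loc_prob_min class I localization-probability cut (default 0.75,
#'   strict `>`)
#' @return list with `analysis_set` and `motif_set` `FeatureTable`s
#' @export
clean_phospho <- function(table, min_measured = 2, loc_prob_min = 0.75) {
  stopifnot(inherits(table, "FeatureTable"), table$is_phospho_table)
  small <- names(which(base::table(table$condition) < 2))
  if (length(small))
    warning("condition(s) with <2 samples: ",
            paste(small, collapse = ", "),
            "; the min-measured rule cannot bind there")
  keep <- table$meta$is_phospho & !table$meta$is_contaminant &
    !table$meta$is_decoy
  x <- ft_subset(table, keep)
  conds <- unique(x$condition)
  meas <- sapply(conds, function(cc)
    rowSums(!is.na(x$values[, ft_cond_samples(x, cc), drop = FALSE])))
  if (is.null(dim(meas))) meas <- matrix(meas, nrow = nrow(x$values))
  x <- ft_subset(x, apply(meas >= min_measured, 1, any))
  motif <- ft_subset(x, !is.na(x$meta$localization_prob) &
                       x$meta$localization_prob > loc_prob_min)
  list(analysis_set = x, motif_set = motif)
}

#' Log2-transform and mean-center a feature table
#'
#' Each present intensity is replaced by its log2, minus the feature's mean
#' log2 over all present samples (all conditions pooled). Missing entries
#' stay missing.
#'
#' @param table `FeatureTable` of raw positive intensities
#' @return `FeatureTable` on the centered log2 scale
#' @export
log2_center <- function(table) {
  v <- table$values
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive intensity for feature '",
         table$feature_id[bad[1, 1]], "', sample '",
         table$sample_ids[bad[1, 2]], "'")
  lv <- log2(v)
  table$values <- lv - rowMeans(lv, na.rm = TRUE)
  table
}

#' Impute missing values from downshifted normal distributions
#'
#' Left-censored (missing-not-at-random) imputation in two tiers, applied
#' per condition. The reference mean and SD are, by default, the per-sample
#' (column) statistics of all present log2 intensities in that sample.
#' For a feature measured in more than 50% of a condition's replicates,
#' missing entries in that condition are drawn from
#' `Normal(mu - 0.5*sd, (0.3*sd)^2)`; for a feature measured in 50% or
#' fewer (including none), from `Normal(mu - 1.8*sd, (0.3*sd)^2)`.
#' Draws are consumed in row-major order (feature, then sample), so the
#' result is bit-identical for a given seed regardless of storage layout.
#'
#' @param table log2-transformed, centered `FeatureTable`
#' @param seed integer seed
#' @param shift_high shift (in SDs) for the >50%-measured tier (default 0.5)
#' @param shift_low shift for the <=50% tier (default 1.8)
#' @param width width of the imputation distribution in SDs (default 0.3)
#' @param reference `"sample"` (default) for per-column statistics, or
#'   `"feature"` for per-row statistics over present values
#' @return `FeatureTable` with no missing entries; present values untouched
#' @export
impute_missing <- function(table, seed, shift_high = 0.5, shift_low = 1.8,
                           width = 0.3,
                           reference = c("sample", "feature")) {
  reference <- match.arg(reference)
  v <- table$values
  conds <- unique(table$condition)
  cond_cols <- lapply(conds, function(cc)
    which(table$sample_ids %in% ft_cond_samples(table, cc)))
  names(cond_cols) <- conds
  # tier per feature x condition: fraction measured strictly above 0.5
  frac <- sapply(conds, function(cc) {
    cols <- cond_cols[[cc]]
    rowMeans(!is.na(v[, cols, drop = FALSE]))
  })
  if (is.null(dim(frac))) frac <- matrix(frac, nrow = nrow(v))
  colnames(frac) <- conds
  if (reference == "sample") {
    mu <- apply(v, 2, mean, na.rm = TRUE)
    sdev <- apply(v, 2, sd, na.rm = TRUE)
    if (any(!is.finite(mu)) || any(!is.finite(sdev)) || any(sdev == 0))
      stop("imputation reference SD not estimable for sample(s): ",
           paste(table$sample_ids[!is.finite(sdev) | sdev == 0 |
                                    !is.finite(mu)], collapse = ", "))
  }
  set.seed(seed)
  for (i in seq_len(nrow(v))) {
    if (reference == "feature") {
      mu_i <- mean(v[i, ], na.rm = TRUE)
      sd_i <- sd(v[i, ], na.rm = TRUE)
      if (!is.finite(mu_i) || !is.finite(sd_i) || sd_i == 0)
        stop("imputation reference SD not estimable for feature '",
             table$feature_id[i], "'")
    }
    for (j in seq_len(ncol(v))) {
      if (!is.na(v[i, j])) next
      cc <- table$condition[table$sample_ids[j]]
      shift <- if (frac[i, cc] > 0.5) shift_high else shift_low
      if (reference == "sample") {
        m <- mu[j]; s <- sdev[j]
      } else {
        m <- mu_i; s <- sd_i
      }
      v[i, j] <- rnorm(1, m - shift * s, width * s)
    }
  }
  table$values <- v
  table
}
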