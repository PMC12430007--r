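#' Feature-by-sample intensity table
#'
#' The shared container for label-free proteome and phosphosite intensity
#' matrices. Rows are features (protein groups, or phosphosites keyed by
#' site id and multiplicity), columns are samples. Missing values are `NA`;
#' raw (pre-log) intensities are strictly positive where present.
#'
#' @param values numeric matrix, features x samples. `NA` marks missing.
#' @param feature_id character vector of unique feature identifiers.
#' @param protein_id character vector; first protein of the mapped group.
#' @param sample_ids character vector of unique sample identifiers.
#' @param condition named character vector mapping sample id to condition
#'   label (e.g. `"M1"`, `"M2a"`, `"M2c"`).
#' @param meta data.frame of per-feature metadata. Recognised columns:
#'   `peptide_count` (integer), `multiplicity` (1/2/3, phospho only),
#'   `localization_prob` (fraction in `[0,1]`), `residue` (e.g. `"S176"`),
#'   `is_contaminant`, `is_decoy`, `is_phospho` (logicals).
#' @param is_phospho_table logical; whether this is a phosphosite table
#'   (multiplicity must then be present in `meta`).
#'
#' @return An object of class `FeatureTable`: a list with elements
#'   `values`, `feature_id`, `protein_id`, `sample_ids`, `condition`,
#'   `meta`, `is_phospho_table`.
#' @export
feature_table <- function(values, feature_id, protein_id, sample_ids,
                          condition, meta = NULL,
                          is_phospho_table = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(feature_id))
    stop("values has ", nrow(values), " rows but ", length(feature_id),
         " feature ids were given")
  if (ncol(values) != length(sample_ids))
    stop("values has ", ncol(values), " columns but ", length(sample_ids),
         " sample ids were given")
  if (anyDuplicated(feature_id))
    stop("feature ids must be unique")
  if (anyDuplicated(sample_ids))
    stop("sample ids must be unique")
  if (!all(sample_ids %in% names(condition)))
    stop("every sample needs a condition; missing: ",
         paste(setdiff(sample_ids, names(condition)), collapse = ", "))
  condition <- condition[sample_ids]
  if (is.null(meta)) meta <- data.frame(row.names = seq_along(feature_id))
  if (nrow(meta) != length(feature_id))
    stop("meta must have one row per feature")
  if (length(protein_id) != length(feature_id))
    stop("protein_id must have one entry per feature")
  for (fl in c("is_contaminant", "is_decoy", "is_phospho")) {
    if (is.null(meta[[fl]])) meta[[fl]] <- rep(FALSE, length(feature_id))
    meta[[fl]] <- as.logical(meta[[fl]])
  }
  if (is_phospho_table && is.null(meta$multiplicity))
    stop("phospho tables require a multiplicity column in meta")
  if (!is.null(meta$multiplicity) &&
      !all(is.na(meta$multiplicity) | meta$multiplicity %in% 1:3))
    stop("multiplicity must be 1, 2 or 3")
  if (!is.null(meta$localization_prob)) {
    lp <- meta$localization_prob
    if (any(!is.na(lp) & (lp < 0 | lp > 1)))
      stop("localization_prob must lie in [0, 1]")
  }
  dimnames(values) <- list(feature_id, sample_ids)
  structure(
    list(values = values,
         feature_id = as.character(feature_id),
         protein_id = as.character(protein_id),
         sample_ids = as.character(sample_ids),
         condition = condition,
         meta = meta,
         is_phospho_table = isTRUE(is_phospho_table)),
    class = "FeatureTable")
}

#' @export
print.FeatureTable <- function(x, ...) {
  cat(sprintf("FeatureTable: %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_phospho_table) "phosphosites" else "proteins"))
  tab <- table(x$condition)
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  cat(sprintf("missing entries: %d (%.1f%%)\n", sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.FeatureTable <- function(x) dim(x$values)

# row subset preserving all aligned slots
ft_subset <- function(x, keep) {
  x$values <- x$values[keep, , drop = FALSE]
  x$feature_id <- x$feature_id[keep]
  x$protein_id <- x$protein_id[keep]
  x$meta <- x$meta[keep, , drop = FALSE]
  rownames(x$meta) <- NULL
  x
}

# samples belonging to one condition
ft_cond_samples <- function(x, cond) {
  x$sample_ids[x$condition[x$sample_ids] == cond]
}

#' Extract a submatrix of samples for one condition
#'
#' @param x a `FeatureTable`
#' @param cond condition label
#' @return numeric matrix restricted to that condition's samples
#' @export
condition_matrix <- function(x, cond) {
  s <- ft_cond_samples(x, cond)
  if (!length(s)) stop("condition '", cond, "' not present in table")
  x$values[, s, drop = FALSE]
}
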