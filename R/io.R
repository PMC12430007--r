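#' @importFrom stats setNames
NULL

# intensity column header convention: intensity.<condition>.<sample_id>
.INT_PREFIX <- "intensity."

.req_cols <- function(schema) {
  base <- c("feature_id", "protein_id", "peptide_count",
            "is_contaminant", "is_decoy")
  if (schema == "phospho")
    c(base, "multiplicity", "localization_prob", "residue", "is_phospho")
  else base
}

#' Read a feature-by-sample intensity table from TSV
#'
#' Expects a header row with the metadata columns of the given schema plus
#' intensity columns named `intensity.<condition>.<sample_id>`. Intensity
#' values of 0 or empty cells are recorded as missing (`NA`): LFQ zeros are
#' non-detections, not true zero abundance.
#'
#' @param path TSV file path
#' @param schema `"proteome"` or `"phospho"`
#' @return a [feature_table()]
#' @export
read_feature_table <- function(path, schema = c("proteome", "phospho")) {
  schema <- match.arg(schema)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- .req_cols(schema)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema '", schema, "': required column missing: ",
         paste(miss, collapse = ", "))
  int_cols <- grep(paste0("^", .INT_PREFIX), names(df), value = TRUE)
  if (!length(int_cols)) stop("no intensity.<condition>.<sample> columns found")
  parts <- strsplit(sub(paste0("^", .INT_PREFIX), "", int_cols), ".",
                    fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad))
    stop("intensity column not of form intensity.<condition>.<sample>: ",
         int_cols[bad][1])
  cond <- vapply(parts, `[[`, "", 1)
  samp <- vapply(parts, function(p) paste(p[-1], collapse = "."), "")
  vals <- matrix(NA_real_, nrow(df), length(int_cols))
  for (j in seq_along(int_cols)) {
    raw <- df[[int_cols[j]]]
    empty <- is.na(raw) | raw == "" | raw == "NA"
    num <- suppressWarnings(as.numeric(raw))
    badrow <- which(!empty & is.na(num))
    if (length(badrow))
      stop("non-numeric intensity at row ", badrow[1],
           ", column ", int_cols[j], ": '", raw[badrow[1]], "'")
    num[empty | (!is.na(num) & num == 0)] <- NA_real_
    vals[, j] <- num
  }
  as_log <- function(x) as.logical(x) | x %in% c("1", "TRUE", "True", "true")
  meta <- data.frame(
    peptide_count = as.integer(df$peptide_count),
    is_contaminant = as_log(df$is_contaminant),
    is_decoy = as_log(df$is_decoy),
    stringsAsFactors = FALSE)
  if (schema == "phospho") {
    meta$multiplicity <- as.integer(df$multiplicity)
    meta$localization_prob <- as.numeric(df$localization_prob)
    meta$residue <- df$residue
    meta$is_phospho <- as_log(df$is_phospho)
  } else {
    meta$is_phospho <- FALSE
  }
  feature_table(vals, df$feature_id, df$protein_id, samp,
                setNames(cond, samp), meta,
                is_phospho_table = schema == "phospho")
}

#' Write a feature table to TSV
#'
#' Emits a deterministic column order (metadata first, then intensity
#' columns in stored sample order); missing intensities are written as
#' empty cells so that a read/write round trip is exact.
#'
#' @param x a `FeatureTable`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_feature_table <- function(x, path) {
  schema <- if (x$is_phospho_table) "phospho" else "proteome"
  meta_cols <- .req_cols(schema)
  df <- data.frame(feature_id = x$feature_id, protein_id = x$protein_id,
                   stringsAsFactors = FALSE)
  for (cl in setdiff(meta_cols, c("feature_id", "protein_id"))) {
    v <- x$meta[[cl]]
    if (is.null(v)) v <- rep(NA, length(x$feature_id))
    df[[cl]] <- v
  }
  for (j in seq_along(x$sample_ids)) {
    s <- x$sample_ids[j]
    col <- paste0(.INT_PREFIX, x$condition[s], ".", s)
    v <- x$values[, j]
    df[[col]] <- ifelse(is.na(v), "", format(v, digits = 15, trim = TRUE,
                                             scientific = FALSE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' GMT dialect: one set per line, `set_id TAB description TAB member...`.
#' Duplicate members within a set are de-duplicated; an empty file yields
#' an empty collection.
#'
#' @param path GMT file path
#' @return a named list of class `GeneSetCollection`; element names are set
#'   ids, each element a character vector of members with a `description`
#'   attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT format error at line ", i, ": fewer than 3 fields")
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (f[1] %in% names(sets)) stop("duplicate set id: ", f[1])
    sets[[f[1]]] <- structure(members, description = f[2])
  }
  structure(sets, class = "GeneSetCollection")
}

#' Write a gene-set collection to GMT
#' @param sets named list of member vectors (descriptions taken from the
#'   `description` attribute when present)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    d <- attr(sets[[i]], "description")
    if (is.null(d)) d <- ""
    paste(c(names(sets)[i], d, as.character(sets[[i]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an interaction edge list from TSV
#'
#' Two node columns (`node_a`, `node_b`) and an optional `confidence`
#' column. Self-loops are dropped. Records are tagged with the given
#' source label (the three roles are a combined-score list, a
#' physical-interaction list, and a confidence-scored list).
#'
#' @param path TSV path
#' @param source source label, e.g. `"source1"`
#' @return data.frame with columns node_a, node_b, source, confidence
#' @export
read_interactions <- function(path, source) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (!all(c("node_a", "node_b") %in% names(df)))
    stop("interaction TSV needs node_a and node_b columns")
  conf <- rep(NA_real_, nrow(df))
  if ("confidence" %in% names(df)) {
    raw <- df$confidence
    empty <- is.na(raw) | raw == "" | raw == "NA"
    conf <- suppressWarnings(as.numeric(raw))
    bad <- which(!empty & is.na(conf))
    if (length(bad))
      stop("non-numeric confidence at row ", bad[1], ": '", raw[bad[1]], "'")
    conf[empty] <- NA_real_
  }
  out <- data.frame(node_a = df$node_a, node_b = df$node_b,
                    source = source, confidence = conf,
                    stringsAsFactors = FALSE)
  out <- out[out$node_a != out$node_b, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an interaction edge list to TSV
#' @param records data.frame as returned by [read_interactions()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_interactions <- function(records, path) {
  df <- records[, c("node_a", "node_b", "confidence")]
  df$confidence <- ifelse(is.na(df$confidence), "",
                          format(df$confidence, digits = 15, trim = TRUE,
                                 scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sparse single-cell count matrix
#'
#' Expects `matrix.mtx` (MatrixMarket, genes x cells), `genes.tsv` and
#' `barcodes.tsv` in `dir`. Mitochondrial genes are flagged by name prefix.
#'
#' @param dir directory containing the three files
#' @param mito_prefix gene-name prefix marking mitochondrial genes
#' @return list of class `SparseCellMatrix` with elements `counts`
#'   (dgCMatrix, genes x cells), `gene_ids`, `cell_ids`, `mito_flag`
#' @export
read_sparse_counts <- function(dir, mito_prefix = "MT-") {
  m <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  genes <- genes[nzchar(genes)]; cells <- cells[nzchar(cells)]
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    stop("dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
         " but genes.tsv has ", length(genes), " and barcodes.tsv has ",
         length(cells), " entries")
  if (anyDuplicated(genes)) stop("gene ids must be unique")
  if (anyDuplicated(cells)) stop("cell ids must be unique")
  if (any(m@x < 0) || any(m@x != round(m@x)))
    stop("counts must be non-negative integers")
  dimnames(m) <- list(genes, cells)
  structure(list(counts = m, gene_ids = genes, cell_ids = cells,
                 mito_flag = startsWith(genes, mito_prefix)),
            class = "SparseCellMatrix")
}

#' Write a sparse single-cell count matrix
#' @param x a `SparseCellMatrix`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_sparse_counts <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(x$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @export
print.SparseCellMatrix <- function(x, ...) {
  cat(sprintf("SparseCellMatrix: %d genes x %d cells, %d mitochondrial genes\n",
              length(x$gene_ids), length(x$cell_ids), sum(x$mito_flag)))
  invisible(x)
}
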