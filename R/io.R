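# File interfaces. Matrices are genes-as-rows throughout; gene ids are
# matched as exact strings (identifier harmonization is upstream scope).

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read / write a bulk expression matrix
#'
#' Dense TSV/CSV with genes as rows: first column gene ids, header row
#' holding sample ids. Duplicate gene ids are collapsed by summation with a
#' warning; negative entries are a format error.
#'
#' @param path file path (`.csv` is comma-separated, anything else
#'   tab-separated).
#' @param bulk a [bulk_matrix].
#' @return `read_bulk` returns a [bulk_matrix]; `write_bulk` returns
#'   `path` invisibly.
#' @export
read_bulk <- function(path) {
  df <- read.table(path, sep = delim_for(path), header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("malformed bulk matrix %s: need gene id column plus at least one sample", path)
  genes <- as.character(df[[1]])
  X <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(X)) stopf("malformed bulk matrix %s: non-numeric entries", path)
  if (any(X < 0)) {
    idx <- which(X < 0, arr.ind = TRUE)[1, ]
    stopf("negative entry in %s at gene %s, sample %s", path,
          sQuote(genes[idx[1]]), sQuote(colnames(X)[idx[2]]))
  }
  X <- collapse_duplicate_genes(X, genes)
  bulk_matrix(X)
}

collapse_duplicate_genes <- function(X, genes) {
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warnf("%d duplicate gene id(s) collapsed by summation: %s",
          length(dup), paste(sQuote(utils::head(dup, 5)), collapse = ", "))
    X <- rowsum(X, group = genes, reorder = FALSE)
    genes <- rownames(X)
  }
  rownames(X) <- genes
  X
}

#' @rdname read_bulk
#' @export
write_bulk <- function(bulk, path) {
  stopifnot(inherits(bulk, "bulk_matrix"))
  df <- data.frame(gene_id = bulk$gene_ids, bulk$X, check.names = FALSE)
  colnames(df) <- c("gene_id", bulk$sample_ids)
  write.table(df, path, sep = delim_for(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read single-cell counts with labels
#'
#' Two layouts are supported: a dense TSV/CSV (genes as rows, first column
#' gene ids, header barcodes) or a MatrixMarket sparse triplet (`.mtx`
#' matrix, genes x cells, plus one-id-per-line gene and barcode files).
#' Labels come as a TSV with columns `barcode`, `cell_type` and optionally
#' `cell_state`; every barcode in the matrix must be labelled.
#'
#' @param path dense matrix file, or the `.mtx` file when `genes` and
#'   `barcodes` are given.
#' @param labels path of the label TSV.
#' @param genes,barcodes id files accompanying an `.mtx` matrix.
#' @return an [sc_counts].
#' @export
read_sc <- function(path, labels, genes = NULL, barcodes = NULL) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(genes) || is.null(barcodes)) {
      stopf("MTX input needs accompanying gene and barcode id files")
    }
    m <- as(Matrix::readMM(path), "CsparseMatrix")
    gene_ids <- readLines(genes)
    cell_ids <- readLines(barcodes)
    if (nrow(m) != length(gene_ids) || ncol(m) != length(cell_ids)) {
      stopf("MTX dimensions (%d x %d) do not match id files (%d genes, %d barcodes)",
            nrow(m), ncol(m), length(gene_ids), length(cell_ids))
    }
    dimnames(m) <- list(gene_ids, cell_ids)
    counts <- m
  } else {
    df <- read.table(path, sep = delim_for(path), header = TRUE,
                     check.names = FALSE, stringsAsFactors = FALSE)
    gene_ids <- as.character(df[[1]])
    counts <- as.matrix(df[, -1, drop = FALSE])
    if (any(counts < 0)) stopf("negative entry in single-cell matrix %s", path)
    counts <- collapse_duplicate_genes(counts, gene_ids)
    gene_ids <- rownames(counts)
    cell_ids <- colnames(counts)
  }
  lab <- read.table(labels, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  need <- c("barcode", "cell_type")
  if (!all(need %in% colnames(lab))) {
    stopf("label file %s must have columns 'barcode' and 'cell_type'", labels)
  }
  miss <- setdiff(cell_ids, lab$barcode)
  if (length(miss) > 0) {
    stopf("%d barcode(s) in the matrix are missing from the label file (e.g. %s)",
          length(miss), sQuote(miss[1]))
  }
  lab <- lab[match(cell_ids, lab$barcode), ]
  sc_counts(counts,
            cell_type_labels = lab$cell_type,
            cell_state_labels = if ("cell_state" %in% colnames(lab))
              lab$cell_state else NULL,
            gene_ids = rownames(counts), cell_ids = cell_ids)
}

#' Write a simulated dataset to disk
#'
#' Writes the pseudobulk (TSV), both single-cell halves (MatrixMarket MTX +
#' gene/barcode/label files), and the ground-truth fraction tables.
#'
#' @param dataset a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bulk(dataset$pseudobulk, file.path(dir, "pseudobulk.tsv"))
  write_fractions(dataset$true_type_fractions,
                  file.path(dir, "true_type_fractions.tsv"))
  write_fractions(dataset$true_state_fractions,
                  file.path(dir, "true_state_fractions.tsv"))
  for (half in c("sc_reference_half", "sc_simulation_half")) {
    sc <- dataset[[half]]
    stem <- file.path(dir, sub("^sc_", "", half))
    Matrix::writeMM(Matrix::Matrix(as.matrix(sc$counts), sparse = TRUE),
                    paste0(stem, ".mtx"))
    writeLines(sc$gene_ids, paste0(stem, "_genes.txt"))
    writeLines(sc$cell_ids, paste0(stem, "_barcodes.txt"))
    lab <- data.frame(barcode = sc$cell_ids, cell_type = sc$cell_type_labels,
                      cell_state = sc$cell_state_labels)
    write.table(lab, paste0(stem, "_labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

write_fractions <- function(theta, path) {
  df <- data.frame(sample_id = rownames(theta), theta, check.names = FALSE)
  colnames(df) <- c("sample_id", colnames(theta))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_fractions <- function(path) {
  df <- read.table(path, sep = delim_for(path), header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

# Provenance sidecar: every CLI output file gets <file>.prov.json recording
# input hashes, parameters and the package version.
write_provenance <- function(out_file, inputs = character(0),
                             params = list()) {
  hashes <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else {
    list()
  }
  jsonlite::write_json(
    list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         package = "cellfrac",
         version = as.character(utils::packageVersion("cellfrac")),
         inputs = hashes, params = params),
    paste0(out_file, ".prov.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_file)
}
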