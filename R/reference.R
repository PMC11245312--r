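#' Single-cell count container
#'
#' Bundles a raw (non-log) gene-by-cell count matrix with per-cell labels at
#' cell-type and, optionally, cell-state resolution. Cell states are finer
#' expression patterns within a type; every state label must map to exactly
#' one type label across all cells.
#'
#' @param counts gene x cell non-negative count matrix (base matrix or a
#'   `Matrix` sparse matrix). Raw scale, not log-transformed.
#' @param cell_type_labels character vector, one type label per cell.
#' @param cell_state_labels optional character vector, one state label per
#'   cell. When `NULL`, states default to types (one state per type).
#' @param gene_ids,cell_ids identifiers; default to dimnames of `counts`.
#' @return an object of class `sc_counts`.
#' @export
sc_counts <- function(counts, cell_type_labels, cell_state_labels = NULL,
                      gene_ids = rownames(counts),
                      cell_ids = colnames(counts)) {
  if (is.null(gene_ids)) {
    gene_ids <- paste0("g", seq_len(nrow(counts)))
  }
  if (is.null(cell_ids)) {
    cell_ids <- paste0("c", seq_len(ncol(counts)))
  }
  check_nonneg(counts, "single-cell count matrix")
  n_cells <- ncol(counts)
  cell_type_labels <- as.character(cell_type_labels)
  if (length(cell_type_labels) != n_cells) {
    stopf("cell_type_labels has length %d but there are %d cells",
          length(cell_type_labels), n_cells)
  }
  if (!is.null(cell_state_labels)) {
    cell_state_labels <- as.character(cell_state_labels)
    if (length(cell_state_labels) != n_cells) {
      stopf("cell_state_labels has length %d but there are %d cells",
            length(cell_state_labels), n_cells)
    }
    check_state_type_pairing(cell_state_labels, cell_type_labels)
  }
  structure(
    list(counts = counts, gene_ids = as.character(gene_ids),
         cell_ids = as.character(cell_ids),
         cell_type_labels = cell_type_labels,
         cell_state_labels = cell_state_labels),
    class = "sc_counts")
}

check_state_type_pairing <- function(states, types) {
  pairs <- unique(data.frame(state = states, type = types,
                             stringsAsFactors = FALSE))
  dup <- pairs$state[duplicated(pairs$state)]
  if (length(dup) > 0) {
    stopf("cell state label(s) %s appear under more than one cell type",
          paste(sQuote(unique(dup)), collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.sc_counts <- function(x, ...) {
  cat(sprintf("sc_counts: %d genes x %d cells; %d cell types",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_type_labels))))
  if (!is.null(x$cell_state_labels)) {
    cat(sprintf(", %d cell states", length(unique(x$cell_state_labels))))
  }
  cat("\n")
  invisible(x)
}

# Namespace a state label under its type so state ids are globally unique.
# A label already equal to, or prefixed by, its type is left as is.
namespace_states <- function(states, types) {
  ifelse(states == types | startsWith(states, paste0(types, ".")),
         states, paste(types, states, sep = "."))
}

#' Construct a reference profile object
#'
#' Low-level constructor; most users build references with [ref_prepare()]
#' or load them with [read_reference()]. Columns of `A` are per-state
#' probability distributions over genes (each sums to 1).
#'
#' @param A gene x state matrix of expression probabilities.
#' @param state_to_type named character vector mapping each state id to its
#'   cell-type id.
#' @param gene_ids,state_ids identifiers; default to dimnames of `A`.
#' @return an object of class `ref_profile` with fields `A`, `gene_ids`,
#'   `state_ids`, `state_to_type` and `type_ids` (types in order of first
#'   appearance among the states).
#' @export
ref_profile <- function(A, state_to_type, gene_ids = rownames(A),
                        state_ids = colnames(A)) {
  A <- as.matrix(A)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(A)))
  if (is.null(state_ids)) stopf("state ids are required (column names of A)")
  rownames(A) <- gene_ids
  colnames(A) <- state_ids
  if (!all(state_ids %in% names(state_to_type))) {
    missing <- setdiff(state_ids, names(state_to_type))
    stopf("state(s) %s have no cell-type mapping",
          paste(sQuote(missing), collapse = ", "))
  }
  extra <- setdiff(names(state_to_type), state_ids)
  if (length(extra) > 0) {
    stopf("state_to_type maps state(s) %s that are not in the matrix",
          paste(sQuote(extra), collapse = ", "))
  }
  map <- as.character(state_to_type[state_ids])
  names(map) <- state_ids
  obj <- structure(
    list(A = A, gene_ids = as.character(gene_ids),
         state_ids = as.character(state_ids),
         state_to_type = map, type_ids = unique(unname(map))),
    class = "ref_profile")
  rep <- validate_reference(obj)
  if (length(rep$violations) > 0) {
    stopf("invalid reference profile: %s",
          paste(rep$violations, collapse = "; "))
  }
  obj
}

#' @export
print.ref_profile <- function(x, ...) {
  cat(sprintf("ref_profile: %d genes, %d cell states, %d cell types\n",
              nrow(x$A), ncol(x$A), length(x$type_ids)))
  invisible(x)
}

#' Build a reference profile from labelled single-cell counts
#'
#' Pools the raw counts of all cells sharing a cell-state label and converts
#' each pooled profile to a probability distribution over genes (the maximum
#' likelihood estimate of the state's expression profile). Genes with zero
#' counts in every state are dropped and reported; a small pseudocount keeps
#' every retained gene at positive probability in every state, which
#' protects the downstream fixed-point update from zero mixture
#' denominators.
#'
#' @param sc an [sc_counts] object. If it carries no `cell_state_labels`,
#'   states default to the cell types.
#' @param pseudocount non-negative scalar added to each pooled gene count
#'   before normalization. Default `1e-8`.
#' @return a [ref_profile]. The dropped gene ids are available in
#'   `attr(ref, "dropped_genes")`.
#' @export
ref_prepare <- function(sc, pseudocount = 1e-8) {
  stopifnot(inherits(sc, "sc_counts"))
  if (pseudocount < 0) stopf("pseudocount must be non-negative")
  types <- sc$cell_type_labels
  states <- sc$cell_state_labels %||% types
  check_state_type_pairing(states, types)
  state_ids <- namespace_states(states, types)

  uniq <- !duplicated(state_ids)
  ord_states <- state_ids[uniq]
  ord_types <- types[uniq]

  # pool counts per state via a sparse cell x state indicator
  ind <- Matrix::sparseMatrix(
    i = seq_along(state_ids),
    j = match(state_ids, ord_states),
    x = 1, dims = c(length(state_ids), length(ord_states)))
  pooled <- as.matrix(sc$counts %*% ind)
  dimnames(pooled) <- list(sc$gene_ids, ord_states)

  zero_state <- colSums(pooled) == 0
  if (any(zero_state) && pseudocount == 0) {
    stopf("state(s) %s have zero total counts and pseudocount is 0",
          paste(sQuote(ord_states[zero_state]), collapse = ", "))
  }

  keep <- rowSums(pooled) > 0
  dropped <- sc$gene_ids[!keep]
  if (length(dropped) > 0) {
    message(sprintf("ref_prepare: dropped %d gene(s) with zero counts in every state",
                    length(dropped)))
    pooled <- pooled[keep, , drop = FALSE]
  }
  if (nrow(pooled) == 0) stopf("no gene has a nonzero count in any state")

  pooled <- pooled + pseudocount
  A <- sweep(pooled, 2, colSums(pooled), "/")
  ref <- ref_profile(A, state_to_type = setNames(ord_types, ord_states))
  attr(ref, "dropped_genes") <- dropped
  ref
}

#' Derive cell-state labels by within-type clustering
#'
#' Assigns cell-state labels when the source single-cell data carries only
#' cell-type labels, by partitioning the cells of each type into up to
#' `states_per_type` k-means clusters of their library-size-normalized,
#' log1p-transformed profiles. Library-size normalization removes sequencing
#' depth as a nuisance variable before clustering. Deterministic under a
#' fixed `seed`. This is generic subclustering plumbing, not a tuned
#' state-discovery method; curated state annotations are preferable when
#' available.
#'
#' @param sc an [sc_counts] object.
#' @param states_per_type positive integer; each type gets
#'   `min(states_per_type, number of its cells)` states.
#' @param seed integer seed for the clustering.
#' @return a copy of `sc` with `cell_state_labels` filled in.
#' @export
derive_cell_states <- function(sc, states_per_type, seed = 0) {
  stopifnot(inherits(sc, "sc_counts"))
  if (length(states_per_type) != 1 || states_per_type < 1) {
    stopf("states_per_type must be a single integer >= 1")
  }
  states_per_type <- as.integer(states_per_type)
  types <- sc$cell_type_labels
  if (states_per_type == 1L) {
    sc$cell_state_labels <- types
    return(sc)
  }
  labels <- character(length(types))
  type_levels <- unique(types)
  for (i in seq_along(type_levels)) {
    tp <- type_levels[i]
    cells <- which(types == tp)
    sub <- as.matrix(sc$counts[, cells, drop = FALSE])
    depth <- colSums(sub)
    depth[depth == 0] <- 1
    dat <- t(log1p(sweep(sub, 2, depth, "/") * 1e4))
    key <- apply(dat, 1, paste, collapse = "\r")
    uq <- unique(key)
    k <- min(states_per_type, length(uq))
    if (k <= 1) {
      cl <- rep(1L, length(cells))
    } else if (k == length(uq)) {
      # as many states as distinct profiles: trivial partition
      cl <- match(key, uq)
    } else {
      cl <- with_seed(seed + i, {
        kmeans(dat, centers = k, nstart = 5, iter.max = 100)$cluster
      })
    }
    labels[cells] <- paste0(tp, ".s", cl)
  }
  sc$cell_state_labels <- labels
  sc
}

#' Validate a reference profile
#'
#' Checks the structural invariants of a reference: non-negative entries,
#' columns summing to 1 (within `1e-9`), no all-zero column, and a complete
#' state-to-type mapping. Violations are reported, not raised, so the
#' function can be used to audit externally produced references. The report
#' also tallies states per type.
#'
#' @param ref a [ref_profile] (or a bare list with the same fields).
#' @return a list of class `ref_validation`: `violations` (character,
#'   empty when valid), `n_genes`, `n_states`, `n_types`,
#'   `states_per_type` (named integer vector).
#' @export
validate_reference <- function(ref) {
  v <- character(0)
  A <- ref$A
  if (any(A < 0)) v <- c(v, "negative entries in A")
  cs <- colSums(A)
  bad <- which(abs(cs - 1) > 1e-9)
  if (length(bad) > 0) {
    v <- c(v, sprintf("column(s) %s do not sum to 1 (max deviation %.3g)",
                      paste(sQuote(colnames(A)[bad]), collapse = ", "),
                      max(abs(cs - 1))))
  }
  if (any(cs == 0)) v <- c(v, "all-zero column in A")
  map <- ref$state_to_type
  unmapped <- setdiff(colnames(A), names(map))
  if (length(unmapped) > 0) {
    v <- c(v, sprintf("unmapped state(s): %s",
                      paste(sQuote(unmapped), collapse = ", ")))
  }
  per_type <- table(factor(unname(map[colnames(A)])))
  structure(
    list(violations = v, n_genes = nrow(A), n_states = ncol(A),
         n_types = length(unique(unname(map))),
         states_per_type = setNames(as.integer(per_type),
                                    names(per_type))),
    class = "ref_validation")
}

#' @export
print.ref_validation <- function(x, ...) {
  cat(sprintf("reference validation: %d genes, %d states, %d types\n",
              x$n_genes, x$n_states, x$n_types))
  if (length(x$violations) == 0) {
    cat("no violations\n")
  } else {
    cat("violations:\n")
    for (v in x$violations) cat(" -", v, "\n")
  }
  invisible(x)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Read / write a reference profile
#'
#' The on-disk format is a tab-separated gene-by-state matrix (first column
#' `gene_id`, remaining columns named by state id) plus a JSON sidecar,
#' `<path minus extension>.json`, holding the `{state_id: type_id}` map.
#' Writing and re-reading reproduces `A` to within `1e-12`.
#'
#' @param ref a [ref_profile].
#' @param path path of the TSV matrix file.
#' @return `read_reference` returns a [ref_profile]; `write_reference`
#'   returns `path` invisibly.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "ref_profile"))
  df <- data.frame(gene_id = ref$gene_ids,
                   signif(ref$A, 17), check.names = FALSE)
  colnames(df) <- c("gene_id", ref$state_ids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(ref$state_to_type), sidecar_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  side <- sidecar_path(path)
  if (!file.exists(side)) {
    stopf("reference sidecar %s not found", side)
  }
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (colnames(df)[1] != "gene_id") {
    stopf("malformed reference matrix: first column must be 'gene_id'")
  }
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- df$gene_id
  map <- jsonlite::read_json(side, simplifyVector = TRUE)
  map <- setNames(as.character(unlist(map)), names(map))
  missing <- setdiff(colnames(A), names(map))
  if (length(missing) > 0) {
    stopf("sidecar is missing state(s): %s",
          paste(sQuote(missing), collapse = ", "))
  }
  extra <- setdiff(names(map), colnames(A))
  if (length(extra) > 0) {
    stopf("sidecar maps state(s) absent from the matrix: %s",
          paste(sQuote(extra), collapse = ", "))
  }
  ref_profile(A, state_to_type = map)
}
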