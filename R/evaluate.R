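#' Score estimated against true cell-type fractions
#'
#' For each cell type, computes the Pearson correlation and RMSE across
#' samples between estimated and ground-truth fractions, plus their means
#' across types -- the standard per-type accuracy summary for deconvolution
#' benchmarks. Types and samples are matched by id; types present in only
#' one of the two matrices are reported, never silently dropped. A type
#' with zero variance in the truth has no defined correlation: it is
#' reported as `NA`, excluded from the mean, and a warning is emitted.
#'
#' @param est sample x type matrix of estimated fractions.
#' @param truth sample x type matrix of true fractions.
#' @param metadata optional named list recorded in the report (reference
#'   id, dataset id, seed, ...).
#' @return a list of class `eval_report`: `per_type_pearson`,
#'   `per_type_rmse` (named by type), `mean_pearson`, `mean_rmse`,
#'   `unmatched_types`, `n_samples`, `sample_rmse` (per-sample RMSE across
#'   types), `metadata`.
#' @export
evaluate_fractions <- function(est, truth, metadata = list()) {
  est <- as.matrix(est)
  truth <- as.matrix(truth)
  if (is.null(colnames(est)) || is.null(colnames(truth))) {
    stopf("est and truth must have type ids as column names")
  }
  unmatched <- union(setdiff(colnames(est), colnames(truth)),
                     setdiff(colnames(truth), colnames(est)))
  shared <- intersect(colnames(truth), colnames(est))
  if (length(shared) == 0) stopf("no shared cell types between est and truth")
  if (!is.null(rownames(est)) && !is.null(rownames(truth))) {
    if (!setequal(rownames(est), rownames(truth))) {
      stopf("est and truth cover different sample sets")
    }
    est <- est[rownames(truth), , drop = FALSE]
  } else if (nrow(est) != nrow(truth)) {
    stopf("est and truth have different numbers of samples")
  }
  e <- est[, shared, drop = FALSE]
  t_ <- truth[, shared, drop = FALSE]
  r <- setNames(rep(NA_real_, length(shared)), shared)
  for (k in shared) {
    if (sd(t_[, k]) == 0 || sd(e[, k]) == 0) {
      r[k] <- NA_real_
    } else {
      r[k] <- cor(e[, k], t_[, k])
    }
  }
  if (anyNA(r)) {
    warnf("type(s) %s have zero variance; correlation undefined, excluded from the mean",
          paste(sQuote(shared[is.na(r)]), collapse = ", "))
  }
  rmse <- setNames(sqrt(colMeans((e - t_)^2)), shared)
  structure(
    list(per_type_pearson = r,
         per_type_rmse = rmse,
         mean_pearson = mean(r, na.rm = TRUE),
         mean_rmse = mean(rmse),
         unmatched_types = unmatched,
         n_samples = nrow(e),
         sample_rmse = sqrt(rowMeans((e - t_)^2)),
         metadata = metadata),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d samples, %d types\n", x$n_samples,
              length(x$per_type_pearson)))
  cat(sprintf("mean Pearson r = %.4f, mean RMSE = %.4f\n",
              x$mean_pearson, x$mean_rmse))
  df <- data.frame(pearson = round(x$per_type_pearson, 4),
                   rmse = round(x$per_type_rmse, 4))
  print(df)
  if (length(x$unmatched_types) > 0) {
    cat("unmatched types:", paste(x$unmatched_types, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare candidate references on the same bulk data
#'
#' Deconvolves the same bulk matrix against each candidate reference,
#' scores each run against the ground truth with [evaluate_fractions()],
#' and ranks the references by mean per-type Pearson correlation (ties keep
#' input order). This is the core of the reference-evaluation loop:
#' reference construction involves many choices (source data, state
#' granularity, clustering), and ranking candidates on simulated truth is
#' how those choices are tuned.
#'
#' @param bulk a [bulk_matrix].
#' @param refs a list of [ref_profile] objects (optionally named).
#' @param truth sample x type matrix of true fractions.
#' @param ... passed to [run_deconv()].
#' @return a list of class `ref_comparison`: `ranking` (data.frame with
#'   reference, mean_pearson, mean_rmse, rank), `reports` (one
#'   `eval_report` per reference, input order).
#' @export
compare_references <- function(bulk, refs, truth, ...) {
  stopifnot(length(refs) >= 1)
  if (inherits(refs, "ref_profile")) refs <- list(refs)
  ids <- names(refs) %||% paste0("ref", seq_along(refs))
  ids[ids == ""] <- paste0("ref", which(ids == ""))
  reports <- vector("list", length(refs))
  for (i in seq_along(refs)) {
    res <- run_deconv(bulk, refs[[i]], ...)
    reports[[i]] <- evaluate_fractions(res$theta_type, truth,
                                       metadata = list(reference = ids[i]))
  }
  names(reports) <- ids
  scores <- vapply(reports, `[[`, numeric(1), "mean_pearson")
  ord <- order(-scores)  # stable: ties keep input order
  ranking <- data.frame(
    reference = ids[ord],
    mean_pearson = unname(scores[ord]),
    mean_rmse = unname(vapply(reports, `[[`, numeric(1), "mean_rmse")[ord]),
    rank = seq_along(ord))
  structure(list(ranking = ranking, reports = reports),
            class = "ref_comparison")
}

#' @export
print.ref_comparison <- function(x, ...) {
  cat("reference comparison (ranked by mean per-type Pearson):\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Non-negative least squares baseline
#'
#' A sanity baseline for the comparison harness: regresses each bulk column
#' on the type-pooled reference profiles under a non-negativity constraint
#' and normalizes the coefficients to fractions. Each type's profile is the
#' average of its states' probability columns. This is a signature-matrix
#' regression, not part of the Bayesian method; it exists so reference
#' comparisons have an independent yardstick.
#'
#' @param bulk a [bulk_matrix] (or gene x sample matrix).
#' @param ref a [ref_profile].
#' @return sample x type fraction matrix.
#' @export
nnls_baseline <- function(bulk, ref) {
  if (!inherits(bulk, "bulk_matrix")) bulk <- bulk_matrix(bulk)
  if (!identical(bulk$gene_ids, ref$gene_ids)) {
    shared <- intersect_genes(bulk, ref)
    bulk <- shared$bulk
    ref <- shared$ref
  }
  types <- ref$type_ids
  B <- vapply(types, function(k) {
    cols <- ref$state_ids[unname(ref$state_to_type) == k]
    rowMeans(ref$A[, cols, drop = FALSE])
  }, numeric(nrow(ref$A)))
  B <- matrix(B, nrow = nrow(ref$A), dimnames = list(ref$gene_ids, types))
  N <- ncol(bulk$X)
  out <- matrix(0, N, length(types),
                dimnames = list(bulk$sample_ids, types))
  for (n in seq_len(N)) {
    x <- bulk$X[, n]
    if (sum(x) == 0) stopf("sample %s has all-zero counts",
                           sQuote(bulk$sample_ids[n]))
    fit <- pracma::lsqnonneg(B, x / sum(x))
    co <- fit$x
    if (sum(co) == 0) co <- rep(1, length(types))
    out[n, ] <- co / sum(co)
  }
  out
}
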