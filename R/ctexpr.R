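#' Cell-type-specific expression from the compressed representation
#'
#' After deconvolution, the bulk signal of every gene in every sample can be
#' apportioned among cell types in proportion to their posterior
#' responsibility. The full gene x sample x type array is never stored:
#' [run_deconv()] keeps only the state fractions and the per-gene,
#' per-sample mixture denominator `d[g,n] = sum_s A[g,s] * theta[n,s]` (the
#' 2D scaling matrix), from which any slice is reconstructed on demand:
#'
#' `Z[g,n,k] = X[g,n] * (sum_{s in type k} A[g,s] * theta[n,s]) / d[g,n]`
#'
#' Entries with `X[g,n] = 0` are 0, and for each gene and sample the slices
#' sum over types to `X[g,n]` exactly (read conservation).
#'
#' @param result a `deconv_result` from [run_deconv()], or a `compressed_z`
#'   object (then `X` must be supplied).
#' @param type a cell-type id present in the reference.
#' @param X optional gene x sample matrix; defaults to the bulk stored in
#'   `result`.
#' @return `reconstruct_Z_ct`: a gene x sample matrix for the requested
#'   type. `get_Z_array`: a gene x sample x type array (class
#'   `ct_expression`).
#' @export
reconstruct_Z_ct <- function(result, type, X = NULL) {
  cz <- as_compressed_z(result)
  if (is.null(X)) {
    if (inherits(result, "deconv_result")) {
      X <- result$bulk$X
    } else {
      stopf("X is required when reconstructing from a bare compressed_z")
    }
  }
  if (inherits(X, "bulk_matrix")) X <- X$X
  ref <- cz$ref
  if (!type %in% ref$type_ids) {
    stopf("unknown cell type %s; available: %s", sQuote(type),
          paste(sQuote(ref$type_ids), collapse = ", "))
  }
  if (nrow(X) != nrow(cz$d) || ncol(X) != ncol(cz$d)) {
    stopf("X (%d x %d) does not match the compressed representation (%d x %d)",
          nrow(X), ncol(X), nrow(cz$d), ncol(cz$d))
  }
  states_k <- ref$state_ids[unname(ref$state_to_type) == type]
  num <- ref$A[, states_k, drop = FALSE] %*%
    t(cz$theta_state[, states_k, drop = FALSE])
  d <- cz$d
  if (any(X > 0 & d == 0)) {
    stopf("zero mixture denominator at a gene/sample with positive bulk signal")
  }
  d[d == 0] <- 1  # only where X is 0; the result there is 0 regardless
  Z <- X * num / d
  Z[X == 0] <- 0
  dimnames(Z) <- dimnames(X)
  Z
}

as_compressed_z <- function(x) {
  if (inherits(x, "deconv_result")) return(x$compressed)
  if (inherits(x, "compressed_z")) return(x)
  stopf("expected a deconv_result or compressed_z object")
}

#' @export
print.compressed_z <- function(x, ...) {
  cat(sprintf("compressed_z: scaling matrix %d genes x %d samples, %d states\n",
              nrow(x$d), ncol(x$d), ncol(x$theta_state)))
  invisible(x)
}

#' @rdname reconstruct_Z_ct
#' @export
get_Z_array <- function(result, X = NULL) {
  cz <- as_compressed_z(result)
  if (is.null(X) && inherits(result, "deconv_result")) X <- result$bulk$X
  if (inherits(X, "bulk_matrix")) X <- X$X
  types <- cz$ref$type_ids
  Z <- array(0, dim = c(nrow(X), ncol(X), length(types)),
             dimnames = list(rownames(X), colnames(X), types))
  for (k in seq_along(types)) {
    Z[, , k] <- reconstruct_Z_ct(cz, types[k], X = X)
  }
  class(Z) <- c("ct_expression", class(Z))
  Z
}

#' Re-estimate the reference from deconvolved expression
#'
#' Builds an updated, cell-type-resolution reference from the first-round
#' cell-type-specific expression. In `"pooled"` mode each type's profile is
#' the across-sample sum of its Z slice (plus pseudocount), normalized. In
#' `"per_sample_malignant"` mode the non-malignant (environment) types are
#' pooled as above, but the named malignant type gets one profile per
#' sample, reflecting that malignant expression is patient-specific while
#' the microenvironment is shared. A second deconvolution round against the
#' updated reference ([run_deconv_updated()]) does not necessarily improve
#' accuracy, so this round is optional and off by default in the pipeline.
#'
#' @param result a `deconv_result`, or a gene x sample x type
#'   `ct_expression` array from [get_Z_array()].
#' @param mode `"pooled"` (default) or `"per_sample_malignant"`.
#' @param malignant_type the malignant type id (required in
#'   `"per_sample_malignant"` mode).
#' @param pseudocount non-negative scalar added per gene before
#'   normalization (default `1e-8`).
#' @return in pooled mode, a [ref_profile] at type resolution (states =
#'   types, identity map); in per-sample mode, an object of class
#'   `updated_reference_bundle` with the pooled environment profiles and a
#'   gene x sample matrix of per-sample malignant profiles.
#' @export
update_reference <- function(result, mode = c("pooled", "per_sample_malignant"),
                             malignant_type = NULL, pseudocount = 1e-8) {
  mode <- match.arg(mode)
  Z <- if (inherits(result, "ct_expression")) result else get_Z_array(result)
  types <- dimnames(Z)[[3]]
  genes <- dimnames(Z)[[1]]
  samples <- dimnames(Z)[[2]]
  pooled <- apply(Z, c(1, 3), sum)  # gene x type total expression
  if (pseudocount == 0 && any(colSums(pooled) == 0)) {
    stopf("type(s) %s have zero total expression and pseudocount is 0",
          paste(sQuote(types[colSums(pooled) == 0]), collapse = ", "))
  }
  if (mode == "pooled") {
    P <- pooled + pseudocount
    A <- sweep(P, 2, colSums(P), "/")
    return(ref_profile(A, state_to_type = setNames(types, types),
                       gene_ids = genes, state_ids = types))
  }
  if (is.null(malignant_type) || !malignant_type %in% types) {
    stopf("per_sample_malignant mode requires malignant_type to be one of: %s",
          paste(sQuote(types), collapse = ", "))
  }
  env_types <- setdiff(types, malignant_type)
  env <- pooled[, env_types, drop = FALSE] + pseudocount
  env <- sweep(env, 2, colSums(env), "/")
  mal <- Z[, , malignant_type, drop = TRUE]
  mal <- matrix(mal, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  mal <- mal + pseudocount
  if (pseudocount == 0 && any(colSums(mal) == 0)) {
    stopf("malignant profile has zero mass in some sample and pseudocount is 0")
  }
  mal <- sweep(mal, 2, colSums(mal), "/")
  structure(list(env = env, malignant = mal,
                 malignant_type = malignant_type,
                 type_ids = types, gene_ids = genes,
                 sample_ids = samples),
            class = "updated_reference_bundle")
}

#' @export
print.updated_reference_bundle <- function(x, ...) {
  cat(sprintf(
    "updated_reference_bundle: %d genes; %d shared environment types + per-sample %s profiles (%d samples)\n",
    length(x$gene_ids), ncol(x$env), sQuote(x$malignant_type),
    length(x$sample_ids)))
  invisible(x)
}

#' Second-round deconvolution against an updated reference
#'
#' Re-runs the fixed-point estimator at cell-type resolution against the
#' reference produced by [update_reference()]. With a per-sample malignant
#' bundle, each sample is deconvolved against its own malignant column plus
#' the shared environment columns.
#'
#' @param bulk a [bulk_matrix] (or gene x sample matrix).
#' @param updated a [ref_profile] or `updated_reference_bundle` from
#'   [update_reference()].
#' @inheritParams run_deconv
#' @return a `deconv_result` at type resolution.
#' @export
run_deconv_updated <- function(bulk, updated, max_iter = 100, tol = 1e-6,
                               alpha = 1) {
  if (inherits(updated, "ref_profile")) {
    return(run_deconv(bulk, updated, max_iter = max_iter, tol = tol,
                      alpha = alpha))
  }
  stopifnot(inherits(updated, "updated_reference_bundle"))
  if (!inherits(bulk, "bulk_matrix")) bulk <- bulk_matrix(bulk)
  if (!identical(bulk$gene_ids, updated$gene_ids)) {
    stopf("bulk gene ids do not match the updated reference (reconstruct Z from the same gene-intersected bulk)")
  }
  if (!identical(bulk$sample_ids, updated$sample_ids)) {
    stopf("bulk sample ids do not match the updated reference bundle")
  }
  types <- updated$type_ids
  env_types <- colnames(updated$env)
  N <- ncol(bulk$X)
  theta <- matrix(0, nrow = N, ncol = length(types),
                  dimnames = list(bulk$sample_ids, types))
  n_iter <- integer(N)
  converged <- logical(N)
  loglik <- vector("list", N)
  for (n in seq_len(N)) {
    A_n <- cbind(updated$malignant[, n], updated$env)
    colnames(A_n) <- c(updated$malignant_type, env_types)
    A_n <- A_n[, types, drop = FALSE]  # original type order
    fit <- deconv_one(bulk$X[, n], A_n, max_iter, tol, alpha)
    theta[n, ] <- fit$theta
    n_iter[n] <- fit$n_iter
    converged[n] <- fit$converged
    loglik[[n]] <- fit$loglik
  }
  structure(
    list(theta_state = theta, theta_type = theta,
         n_iter = setNames(n_iter, bulk$sample_ids),
         converged = setNames(converged, bulk$sample_ids),
         loglik = setNames(loglik, bulk$sample_ids),
         ref = updated, bulk = bulk, compressed = NULL, alpha = alpha),
    class = "deconv_result")
}
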