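#' Bulk expression container
#'
#' A gene-by-sample matrix of non-negative, non-log expression values
#' (raw counts or linear-scale abundances such as TPM).
#'
#' @param X gene x sample non-negative matrix.
#' @param gene_ids,sample_ids identifiers; default to dimnames of `X`.
#' @return an object of class `bulk_matrix`.
#' @export
bulk_matrix <- function(X, gene_ids = rownames(X),
                        sample_ids = colnames(X)) {
  X <- as.matrix(X)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(X)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(X)))
  check_nonneg(X, "bulk matrix")
  dimnames(X) <- list(gene_ids, sample_ids)
  structure(list(X = X, gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids)),
            class = "bulk_matrix")
}

#' @export
print.bulk_matrix <- function(x, ...) {
  cat(sprintf("bulk_matrix: %d genes x %d samples\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Restrict bulk and reference to their shared genes
#'
#' Subsets both objects to the genes present in both, in the reference's
#' gene order, and re-normalizes each reference column to sum to 1 over the
#' retained genes. The number of genes dropped from each side is reported
#' with a message.
#'
#' @param bulk a [bulk_matrix].
#' @param ref a [ref_profile].
#' @return a list with elements `bulk` and `ref`.
#' @export
intersect_genes <- function(bulk, ref) {
  stopifnot(inherits(bulk, "bulk_matrix"), inherits(ref, "ref_profile"))
  shared <- ref$gene_ids[ref$gene_ids %in% bulk$gene_ids]
  if (length(shared) == 0) {
    stopf("no shared genes between bulk and reference")
  }
  n_drop_bulk <- length(bulk$gene_ids) - length(shared)
  n_drop_ref <- length(ref$gene_ids) - length(shared)
  if (n_drop_bulk + n_drop_ref > 0) {
    message(sprintf(
      "intersect_genes: %d shared genes; dropped %d from bulk, %d from reference",
      length(shared), n_drop_bulk, n_drop_ref))
  }
  X <- bulk$X[shared, , drop = FALSE]
  A <- ref$A[shared, , drop = FALSE]
  cs <- colSums(A)
  if (any(cs == 0)) {
    stopf("state(s) %s have zero total probability on the shared genes",
          paste(sQuote(colnames(A)[cs == 0]), collapse = ", "))
  }
  A <- sweep(A, 2, cs, "/")
  list(bulk = bulk_matrix(X, gene_ids = shared,
                          sample_ids = bulk$sample_ids),
       ref = ref_profile(A, state_to_type = ref$state_to_type))
}

#' One fixed-point update of the state fractions
#'
#' The derandomized Gibbs step: instead of sampling the latent assignment
#' of each gene's reads to cell states, compute its conditional mean. The
#' expected number of reads assigned to state `s` is
#' `sum_g x_g * A[g,s] * theta[s] / sum_s' A[g,s'] * theta[s']`; normalizing
#' these expected counts over states yields the updated fractions. With a
#' flat prior (`alpha = 1`) this is exactly the EM update for the
#' multinomial mixture, so the likelihood never decreases. `alpha > 1` adds
#' a symmetric Dirichlet prior (MAP-EM).
#'
#' @param x one bulk column (non-negative vector over genes).
#' @param A gene x state reference matrix, columns summing to 1.
#' @param theta current state fraction vector (on the simplex).
#' @param alpha symmetric Dirichlet concentration; `1` (default) is flat.
#' @return the updated fraction vector.
#' @export
em_step <- function(x, A, theta, alpha = 1) {
  d <- as.vector(A %*% theta)
  pos <- x > 0
  if (any(pos & d == 0)) {
    stopf("degenerate mixture: gene with positive bulk signal has zero probability under every weighted state")
  }
  n_s <- theta * as.vector(crossprod(A[pos, , drop = FALSE], x[pos] / d[pos]))
  m <- pmax(n_s + alpha - 1, 0)
  if (sum(m) == 0) m <- rep(1, length(theta))
  m / sum(m)
}

# Deconvolve a single bulk column to convergence.
deconv_one <- function(x, A, max_iter, tol, alpha) {
  S <- ncol(A)
  theta <- rep(1 / S, S)
  if (sum(x) == 0) {
    return(list(theta = theta, n_iter = 0L, converged = FALSE,
                loglik = numeric(0), zero_sample = TRUE))
  }
  ll <- numeric(max_iter + 1)
  ll[1] <- mix_loglik(x, A, theta)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    theta_new <- em_step(x, A, theta, alpha = alpha)
    ll[it + 1] <- mix_loglik(x, A, theta_new)
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(theta = theta, n_iter = it, converged = converged,
       loglik = ll[seq_len(it + 1)], zero_sample = FALSE)
}

#' Estimate cell-state and cell-type fractions in bulk samples
#'
#' Per sample, initializes the state fractions uniformly and iterates
#' [em_step()] until the largest absolute change falls below `tol` or
#' `max_iter` is reached. Samples are independent; results do not depend on
#' their order. State fractions are aggregated to type fractions by summing
#' over the states of each type. The per-iteration multinomial
#' log-likelihood is recorded per sample and is non-decreasing (EM
#' property).
#'
#' If the gene sets of `bulk` and `ref` differ, they are intersected with
#' [intersect_genes()] first. A bulk matrix whose maximum value is below 50
#' triggers a warning, as it is likely log-transformed; the model requires
#' linear-scale input.
#'
#' @param bulk a [bulk_matrix] (or a gene x sample matrix).
#' @param ref a [ref_profile].
#' @param max_iter maximum fixed-point iterations per sample (default 100).
#' @param tol convergence tolerance on `max(abs(diff(theta)))`
#'   (default `1e-6`).
#' @param alpha symmetric Dirichlet prior concentration; `1` = flat (pure
#'   maximum likelihood).
#' @return an object of class `deconv_result`: `theta_state` (sample x
#'   state), `theta_type` (sample x type), `n_iter`, `converged`, `loglik`
#'   (list of per-iteration traces), `ref`, `bulk` (gene-intersected), and
#'   `compressed` -- a `compressed_z` object holding the 2D scaling matrix
#'   from which cell-type-specific expression can be reconstructed without
#'   storing the full 3D array.
#' @export
run_deconv <- function(bulk, ref, max_iter = 100, tol = 1e-6, alpha = 1) {
  if (!inherits(bulk, "bulk_matrix")) bulk <- bulk_matrix(bulk)
  stopifnot(inherits(ref, "ref_profile"), max_iter >= 1, tol >= 0)
  if (!identical(bulk$gene_ids, ref$gene_ids)) {
    shared <- intersect_genes(bulk, ref)
    bulk <- shared$bulk
    ref <- shared$ref
  }
  X <- bulk$X
  if (max(X) < 50) {
    warnf("bulk matrix maximum is %.3g (< 50); input looks log-transformed but must be on the linear scale",
          max(X))
  }
  A <- ref$A
  N <- ncol(X)
  S <- ncol(A)
  fits <- vector("list", N)
  for (n in seq_len(N)) {
    fits[[n]] <- deconv_one(X[, n], A, max_iter, tol, alpha)
  }
  zero <- vapply(fits, `[[`, logical(1), "zero_sample")
  if (any(zero)) {
    warnf("%d sample(s) have all-zero counts; returning uniform fractions (flagged unconverged): %s",
          sum(zero), paste(bulk$sample_ids[zero], collapse = ", "))
  }
  theta_state <- matrix(unlist(lapply(fits, `[[`, "theta")),
                        nrow = N, ncol = S, byrow = TRUE)
  dimnames(theta_state) <- list(bulk$sample_ids, ref$state_ids)
  theta_type <- aggregate_states(theta_state, ref$state_to_type)
  compressed <- structure(
    list(theta_state = theta_state,
         d = A %*% t(theta_state),
         ref = ref),
    class = "compressed_z")
  structure(
    list(theta_state = theta_state,
         theta_type = theta_type,
         n_iter = setNames(vapply(fits, `[[`, integer(1), "n_iter"),
                           bulk$sample_ids),
         converged = setNames(vapply(fits, `[[`, logical(1), "converged"),
                              bulk$sample_ids),
         loglik = setNames(lapply(fits, `[[`, "loglik"), bulk$sample_ids),
         ref = ref, bulk = bulk, compressed = compressed,
         alpha = alpha),
    class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf(
    "deconv_result: %d samples, %d states -> %d types; %d/%d converged (median %d iterations)\n",
    nrow(x$theta_state), ncol(x$theta_state), ncol(x$theta_type),
    sum(x$converged), length(x$converged),
    as.integer(stats::median(x$n_iter))))
  invisible(x)
}

#' Aggregate state fractions to type fractions
#'
#' Sums the fraction columns of the states belonging to each cell type.
#' Row sums are preserved exactly (the states partition each row's mass).
#'
#' @param theta_state sample x state fraction matrix with state ids as
#'   column names.
#' @param state_to_type named character vector mapping state id to type id.
#' @return sample x type fraction matrix, types in order of first
#'   appearance.
#' @export
aggregate_states <- function(theta_state, state_to_type) {
  states <- colnames(theta_state)
  if (is.null(states)) stopf("theta_state must have state ids as colnames")
  unmapped <- setdiff(states, names(state_to_type))
  if (length(unmapped) > 0) {
    stopf("unmapped state(s): %s",
          paste(sQuote(unmapped), collapse = ", "))
  }
  map <- unname(state_to_type[states])
  type_ids <- unique(map)
  M <- 1 * outer(map, type_ids, "==")
  out <- theta_state %*% M
  dimnames(out) <- list(rownames(theta_state), type_ids)
  out
}
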