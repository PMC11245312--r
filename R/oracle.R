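#' Collapsed Gibbs sampler for the deconvolution model (testing oracle)
#'
#' Samples the posterior of the state fractions for a single bulk column of
#' integer counts under the same multinomial-mixture generative model that
#' the fixed-point estimator solves. The chain alternates (a) per-gene
#' latent assignment counts `z[g, ] ~ Multinomial(x[g], responsibility)`
#' with responsibility proportional to `A[g, ] * theta`, and (b)
#' `theta ~ Dirichlet(alpha + colSums(z))`. Sampling assignment counts per
#' gene (rather than individual reads) is statistically identical to
#' read-level sampling and keeps small instances fast.
#'
#' This is a verification device, not part of the estimation pipeline: on
#' small instances with large total counts and a flat prior, its posterior
#' mean must agree with the deterministic fixed point within Monte-Carlo
#' error, which is exactly what the package's tests assert. The
#' Monte-Carlo standard error (MCSE) is estimated by batch means, which
#' accounts for autocorrelation in the chain.
#'
#' @param x one bulk column of non-negative integer counts.
#' @param A gene x state reference matrix, columns summing to 1.
#' @param n_burnin discarded initial iterations (default 500).
#' @param n_keep retained iterations (default 2000).
#' @param alpha symmetric Dirichlet concentration over states (default 1,
#'   flat -- matching the flat-prior fixed point).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param max_size guard on `G * S * n_keep` to keep the oracle at desk
#'   scale (default 5e7).
#' @return a list: `mean` (posterior mean fractions), `mcse` (per-state
#'   Monte-Carlo standard error of the mean), `n_keep`.
#' @keywords internal
#' @export
gibbs_deconvolve <- function(x, A, n_burnin = 500, n_keep = 2000,
                             alpha = 1, seed = NULL, max_size = 5e7) {
  stopifnot(n_burnin >= 0, n_keep >= 1, alpha > 0)
  if (any(x < 0) || max(abs(x - round(x))) > 1e-8) {
    stopf("the Gibbs oracle is defined on non-negative integer counts")
  }
  x <- round(x)
  G <- nrow(A)
  S <- ncol(A)
  if (as.double(G) * S * n_keep > max_size) {
    stopf("instance too large for the oracle (G*S*n_keep = %.3g > %.3g)",
          as.double(G) * S * n_keep, max_size)
  }
  if (S == 1) {
    return(list(mean = 1, mcse = 0, n_keep = n_keep))
  }
  with_seed(seed, {
    theta <- rep(1 / S, S)
    draws <- matrix(0, nrow = n_keep, ncol = S)
    pos <- which(x > 0)
    for (it in seq_len(n_burnin + n_keep)) {
      z <- numeric(S)
      for (g in pos) {
        w <- A[g, ] * theta
        z <- z + rmultinom(1, x[g], w)[, 1]
      }
      gam <- rgamma(S, shape = alpha + z)
      theta <- gam / sum(gam)
      if (it > n_burnin) draws[it - n_burnin, ] <- theta
    }
    post_mean <- colMeans(draws)
    mcse <- apply(draws, 2, batch_means_mcse)
    list(mean = setNames(post_mean, colnames(A)),
         mcse = setNames(mcse, colnames(A)),
         n_keep = n_keep)
  })
}

# Batch-means MCSE of the mean of a (possibly autocorrelated) chain.
# Batch size n^(2/3): conservative under the autocorrelation a collapsed
# Gibbs chain shows when state profiles are correlated.
batch_means_mcse <- function(v) {
  n <- length(v)
  m <- max(1L, floor(n^(2 / 3)))
  nb <- floor(n / m)
  if (nb < 2) return(sd(v) / sqrt(n))
  bm <- colMeans(matrix(v[seq_len(nb * m)], nrow = m))
  sqrt(m * stats::var(bm) / (nb * m))
}

#' Fixed-point vs Gibbs agreement battery
#'
#' Generates random small deconvolution instances, solves each with the
#' deterministic fixed point and with the collapsed Gibbs oracle, and
#' reports the element-wise discrepancy in units of the Monte-Carlo
#' standard error. With a flat prior and large total counts the posterior
#' mean concentrates on the maximum-likelihood fractions, so the two
#' routes must agree within sampling error.
#'
#' Instances are drawn in the regime the equivalence claim covers:
#' references are well-conditioned (reciprocal condition number of the
#' state-profile Gram matrix above `min_rcond`), because nearly collinear
#' state profiles make the split of their combined fraction
#' unidentifiable -- the likelihood is flat along a ridge and neither the
#' fixed point nor the chain mean is a meaningful point estimate there;
#' and true fractions are bounded away from the simplex boundary
#' (`min_fraction`), because when the maximum-likelihood estimate of a
#' fraction is exactly 0 its posterior is approximately half-normal and
#' the posterior mean carries an `O(1/sqrt(n))` positive bias relative to
#' the MLE that no amount of sampling removes.
#'
#' @param n_instances number of random instances (default 10).
#' @param seed integer seed.
#' @param n_genes,n_states instance dimensions (kept small; the oracle is a
#'   desk-scale device).
#' @param min_rcond reciprocal-condition-number floor for the reference's
#'   Gram matrix (default 0.02); candidate references below it are
#'   redrawn.
#' @param min_fraction floor on the smallest true state fraction (default
#'   0.1); candidate fraction vectors below it are redrawn so the MLE
#'   stays in the simplex interior.
#' @param total_counts total reads per instance (default 50000). The
#'   posterior mean differs from the MLE by an `O(1/total_counts)`
#'   curvature term even at an interior optimum; counts must be large
#'   enough that this gap is negligible against the Monte-Carlo error the
#'   tolerance is expressed in.
#' @param n_burnin,n_keep Gibbs chain lengths.
#' @return a data.frame with one row per instance: instance dimensions, the
#'   maximum absolute difference between the fixed point and the Gibbs
#'   mean, the maximum of that difference divided by 3 MCSE (`max_ratio`;
#'   agreement means every value is below 1), and a pass flag.
#' @export
oracle_battery <- function(n_instances = 10, seed = 1, n_genes = 5,
                           n_states = 3, total_counts = 50000,
                           n_burnin = 2000, n_keep = 20000,
                           min_rcond = 0.02, min_fraction = 0.1) {
  rows <- vector("list", n_instances)
  for (i in seq_len(n_instances)) {
    inst <- with_seed(seed + i, {
      G <- sample(3:n_genes, 1)
      S <- sample(2:n_states, 1)
      repeat {
        A <- t(rdirichlet(S, rep(1, G)))
        if (rcond(crossprod(A)) >= min_rcond) break
      }
      repeat {
        theta_true <- rdirichlet(1, rep(2, S))[1, ]
        if (min(theta_true) >= min_fraction) break
      }
      x <- rmultinom(1, total_counts, as.vector(A %*% theta_true))[, 1]
      list(G = G, S = S, A = A, x = x)
    })
    fp <- deconv_one(inst$x, inst$A, max_iter = 10000, tol = 1e-10,
                     alpha = 1)
    gb <- gibbs_deconvolve(inst$x, inst$A, n_burnin = n_burnin,
                           n_keep = n_keep, alpha = 1, seed = seed + 1000 + i)
    diff <- abs(fp$theta - gb$mean)
    ratio <- diff / (3 * pmax(gb$mcse, .Machine$double.eps))
    rows[[i]] <- data.frame(instance = i, n_genes = inst$G,
                            n_states = inst$S,
                            total_counts = sum(inst$x),
                            max_abs_diff = max(diff),
                            max_ratio = max(ratio),
                            agrees = all(ratio < 1))
  }
  do.call(rbind, rows)
}
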