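# Shared fixtures and independent oracles for the test suite.

# The two-gene, two-state instance whose deconvolution is solvable by hand:
# A has linearly independent columns and x/sum(x) = (0.6, 0.4) lies in
# their convex hull, so the exact mixture solves A f = (0.6, 0.4), i.e.
# f = (2/3, 1/3).
hand_instance <- function() {
  A <- matrix(c(0.8, 0.2, 0.2, 0.8), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  list(A = A,
       ref = ref_profile(A, state_to_type = c(s1 = "T1", s2 = "T2")),
       x = c(g1 = 60, g2 = 40),
       theta_exact = c(2 / 3, 1 / 3))
}

# Independent grid-search oracle: exhaustive evaluation of the multinomial
# log-likelihood on a simplex lattice (S = 2 or 3). Never calls the
# package's update.
simplex_grid <- function(S, step) {
  f <- seq(0, 1, by = step)
  if (S == 2) {
    cbind(f, 1 - f)
  } else if (S == 3) {
    g <- expand.grid(f1 = f, f2 = f)
    g <- g[g$f1 + g$f2 <= 1 + 1e-12, ]
    cbind(g$f1, g$f2, pmax(0, 1 - g$f1 - g$f2))
  } else {
    stop("grid oracle supports S = 2 or 3")
  }
}

grid_mle <- function(x, A, step = 0.01) {
  grid <- simplex_grid(ncol(A), step)
  M <- A %*% t(grid)                   # gene x points mixture probs
  pos <- x > 0
  ll <- as.vector(crossprod(log(M[pos, , drop = FALSE]), x[pos]))
  grid[which.max(ll), ]
}

# Random well-posed instance: strictly positive reference columns and an
# interior fraction vector, so the MLE is unique and interior.
random_instance <- function(seed, n_genes = 10, n_states = 3,
                            total = 100000) {
  set.seed(seed)
  repeat {
    A <- matrix(rgamma(n_genes * n_states, 1), n_genes)
    A <- sweep(A, 2, colSums(A), "/")
    if (rcond(crossprod(A)) >= 0.02) break
  }
  repeat {
    theta <- rgamma(n_states, 2)
    theta <- theta / sum(theta)
    if (min(theta) >= 0.1) break
  }
  x <- as.vector(A %*% theta) * total  # noiseless expected counts
  dimnames(A) <- list(paste0("g", seq_len(n_genes)),
                      paste0("s", seq_len(n_states)))
  names(x) <- rownames(A)
  list(A = A, theta = theta, x = x)
}

# A labelled random single-cell toy for reference-module tests.
random_sc <- function(seed, n_genes = 12, cells_per_state = 4,
                      types = c("T1", "T1", "T2"),
                      states = c("a", "b", "c")) {
  set.seed(seed)
  n_states <- length(states)
  counts <- matrix(rpois(n_genes * cells_per_state * n_states, 5),
                   nrow = n_genes)
  sc_counts(counts,
            cell_type_labels = rep(types, each = cells_per_state),
            cell_state_labels = rep(states, each = cells_per_state),
            gene_ids = paste0("g", seq_len(n_genes)))
}

# fixture_small() is deterministic; cache it per test run.
cached_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- fixture_small()
    fx
  }
})
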