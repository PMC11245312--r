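# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. NULL seed leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# n draws from Dirichlet(alpha); rows are draws on the simplex.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  # guard against all-zero rows when alpha is tiny
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, ] <- 1 / k
  g / rowSums(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_nonneg <- function(m, what) {
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stopf("%s contains a negative entry at row %d, column %d",
          what, idx[1], idx[2])
  }
  invisible(TRUE)
}

# Multinomial log-likelihood (up to the constant) of one bulk column under
# mixture weights theta: sum_g x_g * log(sum_s A_gs theta_s).
mix_loglik <- function(x, A, theta) {
  d <- as.vector(A %*% theta)
  pos <- x > 0
  sum(x[pos] * log(d[pos]))
}
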