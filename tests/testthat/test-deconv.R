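test_that("em_step computes the mean read assignment, hand-checked", {
  h <- hand_instance()
  # responsibilities at uniform theta: gene1 -> 0.8/0.2, gene2 -> 0.2/0.8
  # expected counts: state1 = 60*0.8 + 40*0.2 = 56, state2 = 44
  expect_equal(em_step(h$x, h$A, c(0.5, 0.5)), c(0.56, 0.44))
  # S = 1: the only state takes everything
  expect_equal(em_step(c(3, 7), matrix(c(0.4, 0.6), 2, 1), 1), 1)
  # the exact solution is a fixed point
  expect_lt(max(abs(em_step(h$x, h$A, h$theta_exact) - h$theta_exact)),
            1e-12)
})

test_that("run_deconv recovers the algebraic solution on exact-fit data", {
  h <- hand_instance()
  res <- run_deconv(bulk_matrix(matrix(h$x, 2, 1,
                                       dimnames = list(names(h$x), "b1"))),
                    h$ref, max_iter = 10000, tol = 1e-12)
  expect_lt(max(abs(res$theta_state[1, ] - h$theta_exact)), 1e-8)
  expect_true(res$converged[1])
  # cross-check against an independent linear solve and the grid oracle
  expect_equal(unname(solve(h$A, h$x / sum(h$x))), h$theta_exact,
               tolerance = 1e-12)
  expect_lt(max(abs(grid_mle(h$x, h$A, step = 1e-3) - h$theta_exact)),
            1e-3)
})

test_that("a bulk column proportional to one reference column yields that vertex", {
  set.seed(21)
  A <- matrix(rgamma(12, 1), 4)
  A <- sweep(A, 2, colSums(A), "/")
  dimnames(A) <- list(paste0("g", 1:4), paste0("s", 1:3))
  ref <- ref_profile(A, state_to_type = setNames(paste0("T", 1:3),
                                                 colnames(A)))
  x <- matrix(A[, 2] * 5000, 4, 1, dimnames = list(rownames(A), "b"))
  res <- run_deconv(x, ref, max_iter = 5000, tol = 1e-10)
  # EM approaches simplex vertices sublinearly, so the tolerance is looser
  # than for interior optima
  expect_lt(max(abs(res$theta_state[1, ] - c(0, 1, 0))), 1e-3)
})

test_that("run_deconv matches the simplex grid-search MLE on random instances", {
  for (seed in c(101, 202, 303)) {
    inst <- random_instance(seed, n_genes = 10, n_states = 3)
    # noisy counts so the optimum is not a trivial exact fit
    set.seed(seed + 1)
    x <- rmultinom(1, 20000, inst$x / sum(inst$x))[, 1]
    names(x) <- rownames(inst$A)
    ref <- ref_profile(inst$A,
                       state_to_type = setNames(paste0("T", 1:3),
                                                colnames(inst$A)))
    res <- run_deconv(matrix(x, dimnames = list(names(x), "b")), ref,
                      max_iter = 5000, tol = 1e-10)
    oracle <- grid_mle(x, inst$A, step = 0.01)
    expect_lt(max(abs(res$theta_state[1, ] - oracle)), 0.02)
  }
})

test_that("the log-likelihood trace is non-decreasing for every sample", {
  fx <- cached_fixture()
  ref <- ref_prepare(fx$sc_reference_half)
  res <- run_deconv(fx$pseudobulk, ref)
  for (ll in res$loglik) {
    expect_gte(min(diff(ll)), -1e-7)
  }
})

test_that("fractions are scale-invariant in the bulk column", {
  inst <- random_instance(17, n_genes = 8, n_states = 3)
  ref <- ref_profile(inst$A,
                     state_to_type = setNames(paste0("T", 1:3),
                                              colnames(inst$A)))
  X1 <- matrix(inst$x, dimnames = list(names(inst$x), "b"))
  res1 <- run_deconv(X1, ref, tol = 1e-10, max_iter = 2000)
  res2 <- run_deconv(X1 * 13.7, ref, tol = 1e-10, max_iter = 2000)
  expect_lt(max(abs(res1$theta_state - res2$theta_state)), 1e-10)
})

test_that("permuting reference states permutes theta and leaves types unchanged", {
  inst <- random_instance(29, n_genes = 8, n_states = 3)
  map <- setNames(c("T1", "T1", "T2"), colnames(inst$A))
  ref <- ref_profile(inst$A, state_to_type = map)
  X <- matrix(inst$x, dimnames = list(names(inst$x), "b"))
  res <- run_deconv(X, ref, tol = 1e-10, max_iter = 2000)
  p <- c(3, 1, 2)
  ref_p <- ref_profile(inst$A[, p], state_to_type = map[p])
  res_p <- run_deconv(X, ref_p, tol = 1e-10, max_iter = 2000)
  expect_lt(max(abs(res_p$theta_state[, colnames(res$theta_state)] -
                      res$theta_state)), 1e-9)
  expect_lt(max(abs(res_p$theta_type[, colnames(res$theta_type)] -
                      res$theta_type)), 1e-9)
})

test_that("aggregate_states sums state fractions by type and preserves rows", {
  th <- matrix(c(0.2, 0.3, 0.5), 1,
               dimnames = list("b", c("s1", "s2", "s3")))
  out <- aggregate_states(th, c(s1 = "k1", s2 = "k1", s3 = "k2"))
  expect_equal(out, matrix(c(0.5, 0.5), 1,
                           dimnames = list("b", c("k1", "k2"))))
  # identity map: unchanged
  out_id <- aggregate_states(th, c(s1 = "s1", s2 = "s2", s3 = "s3"))
  expect_equal(unname(out_id), unname(th))
  # row sums preserved exactly on random input
  set.seed(4)
  th_r <- matrix(rgamma(15, 1), 5)
  th_r <- th_r / rowSums(th_r)
  colnames(th_r) <- c("s1", "s2", "s3")
  agg <- aggregate_states(th_r, c(s1 = "a", s2 = "b", s3 = "a"))
  expect_equal(rowSums(agg), rowSums(th_r))
  expect_error(aggregate_states(th, c(s1 = "k1", s2 = "k1")), "unmapped")
})

test_that("intersect_genes restricts to shared genes and renormalizes", {
  h <- hand_instance()
  bulk3 <- bulk_matrix(matrix(c(60, 40, 5), 3, 1,
                              dimnames = list(c("g1", "g2", "g9"), "b")))
  expect_message(sh <- intersect_genes(bulk3, h$ref), "dropped 1 from bulk")
  expect_equal(sh$bulk$gene_ids, c("g1", "g2"))
  expect_equal(sh$ref$A, h$ref$A)

  # reference wider than bulk: columns renormalized over retained genes
  A3 <- rbind(h$A * 0.9, g3 = c(0.1, 0.1))
  rownames(A3) <- c("g1", "g2", "g3")
  ref3 <- ref_profile(A3, state_to_type = c(s1 = "T1", s2 = "T2"))
  bulk2 <- bulk_matrix(matrix(c(60, 40), 2, 1,
                              dimnames = list(c("g1", "g2"), "b")))
  sh2 <- suppressMessages(intersect_genes(bulk2, ref3))
  expect_lt(max(abs(colSums(sh2$ref$A) - 1)), 1e-12)
  expect_equal(sh2$ref$A, h$ref$A)

  none <- bulk_matrix(matrix(1, 1, 1, dimnames = list("zz", "b")))
  expect_error(intersect_genes(none, h$ref), "no shared genes")
})

test_that("degenerate inputs are flagged, not silently absorbed", {
  h <- hand_instance()
  X <- matrix(c(60, 40, 0, 0), 2, dimnames = list(c("g1", "g2"),
                                                  c("b1", "b2")))
  expect_warning(res <- run_deconv(X, h$ref), "all-zero")
  expect_false(res$converged["b2"])
  expect_equal(unname(res$theta_state["b2", ]), c(0.5, 0.5))
  expect_true(res$converged["b1"])

  # low-magnitude input looks log-transformed
  expect_warning(run_deconv(matrix(c(3.1, 2.2), 2,
                                   dimnames = list(c("g1", "g2"), "b")),
                            h$ref),
                 "log-transformed")

  # a gene with signal but zero probability under every state
  A0 <- matrix(c(1, 0, 1, 0), 2, dimnames = list(c("g1", "g2"),
                                                 c("s1", "s2")))
  expect_error(em_step(c(10, 5), A0, c(0.5, 0.5)), "degenerate")
})
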