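#' Configuration for the pseudobulk simulator
#'
#' Defaults describe a small but realistic benchmark: sparse,
#' well-separated type profiles (Dirichlet concentration below 1 mimics the
#' marker-gene structure of real cell types), moderate within-state
#' cell-to-cell variability, and multinomial read sampling matching the
#' topic-model likelihood.
#'
#' @param n_genes number of genes.
#' @param n_types number of cell types.
#' @param states_per_type cell states per type.
#' @param n_cells_per_state cells generated per state (must be >= 2 so the
#'   held-out split is possible).
#' @param n_bulk_samples number of pseudobulk samples.
#' @param reads_per_bulk reads per pseudobulk sample.
#' @param depth_per_cell reads per single cell.
#' @param fraction_prior Dirichlet concentration for per-sample type
#'   fractions (1 = uniform over the simplex).
#' @param profile_separation per-gene Dirichlet concentration for the
#'   per-type base profiles; values below 1 give sparse, divergent
#'   profiles.
#' @param state_jitter log-normal sd of the per-state perturbation of the
#'   type base profile (states within a type are similar but distinct).
#' @param noise within-state cell-level gamma noise shape; the per-gene
#'   expression of each cell is the state profile times Gamma(noise, noise)
#'   factors (mean 1, CV `1/sqrt(noise)`), so larger is quieter.
#' @param shift_reference log-normal sd of a per-gene multiplicative factor
#'   applied to the reference half only, emulating a technical platform
#'   difference between reference and bulk; 0 (default) disables it.
#' @param overdispersion optional negative-binomial size parameter for the
#'   pseudobulk reads; `NULL` (default) uses multinomial sampling.
#' @param seed integer seed.
#' @return a validated list of class `sim_config`.
#' @export
simulate_config <- function(n_genes = 50, n_types = 3, states_per_type = 2,
                            n_cells_per_state = 20, n_bulk_samples = 20,
                            reads_per_bulk = 20000, depth_per_cell = 2000,
                            fraction_prior = 1, profile_separation = 0.3,
                            state_jitter = 0.3, noise = 10,
                            shift_reference = 0, overdispersion = NULL,
                            seed = 1) {
  cfg <- list(n_genes = n_genes, n_types = n_types,
              states_per_type = states_per_type,
              n_cells_per_state = n_cells_per_state,
              n_bulk_samples = n_bulk_samples,
              reads_per_bulk = reads_per_bulk,
              depth_per_cell = depth_per_cell,
              fraction_prior = fraction_prior,
              profile_separation = profile_separation,
              state_jitter = state_jitter, noise = noise,
              shift_reference = shift_reference,
              overdispersion = overdispersion, seed = seed)
  counts <- c("n_genes", "n_types", "states_per_type", "n_cells_per_state",
              "n_bulk_samples", "reads_per_bulk", "depth_per_cell")
  for (f in counts) {
    if (cfg[[f]] < 1) stopf("%s must be a positive count", f)
  }
  if (cfg$n_cells_per_state < 2) {
    stopf("n_cells_per_state must be >= 2 to split cells into reference and simulation halves")
  }
  if (cfg$fraction_prior <= 0) stopf("fraction_prior must be > 0")
  if (cfg$profile_separation <= 0) stopf("profile_separation must be > 0")
  if (cfg$noise <= 0) stopf("noise must be > 0")
  if (cfg$shift_reference < 0) stopf("shift_reference must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Simulate single-cell data and pseudobulk with a held-out-cells split
#'
#' Generates a complete benchmark dataset under the multinomial mixture
#' model: (1) per-type base gene-probability profiles drawn from a sparse
#' Dirichlet, perturbed log-normally into per-state profiles; (2) single
#' cells drawn per state as multinomial reads from the state profile
#' modulated by cell-level gamma noise; (3) a 50/50 split of each state's
#' cells into a reference half and a simulation half with disjoint cell
#' ids, so that no information flows from reference construction into bulk
#' simulation -- mimicking the realistic regime in which the reference
#' comes from different material than the bulk; (4) per-sample type
#' fractions drawn from a Dirichlet and divided equally among the type's
#' states; (5) pseudobulk columns drawn as multinomial reads from the
#' mixture of the simulation half's pooled (empirical) state profiles.
#' Optionally the reference half receives a per-gene multiplicative
#' log-normal shift emulating a platform difference.
#'
#' @param cfg a [simulate_config()] object (or arguments for one, passed
#'   through `...` when `cfg` is missing).
#' @param ... passed to [simulate_config()] when `cfg` is missing.
#' @return a list of class `sim_dataset`: `true_type_fractions` (sample x
#'   type), `true_state_fractions` (sample x state), `sc_reference_half`
#'   and `sc_simulation_half` ([sc_counts] with disjoint cell ids),
#'   `pseudobulk` ([bulk_matrix]), `state_profiles` (true generative gene x
#'   state probabilities), `sim_state_profiles` (simulation half's pooled
#'   empirical profiles used to draw the pseudobulk), `state_to_type`, and
#'   the `config`.
#' @export
simulate_dataset <- function(cfg = simulate_config(...), ...) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    G <- cfg$n_genes
    K <- cfg$n_types
    Spt <- cfg$states_per_type
    S <- K * Spt
    genes <- sprintf("g%04d", seq_len(G))
    types <- sprintf("T%d", seq_len(K))
    state_of <- rep(seq_len(Spt), times = K)
    type_of_state <- rep(types, each = Spt)
    states <- paste0(type_of_state, ".s", state_of)

    # generative profiles: sparse per-type base, per-state jitter
    base <- t(rdirichlet(K, rep(cfg$profile_separation, G)))  # G x K
    P <- matrix(0, G, S, dimnames = list(genes, states))
    for (s in seq_len(S)) {
      jit <- exp(rnorm(G, 0, cfg$state_jitter))
      p <- base[, match(type_of_state[s], types)] * jit
      P[, s] <- p / sum(p)
    }

    # single cells: multinomial reads from noisy state profiles
    n_cells <- cfg$n_cells_per_state * S
    counts <- matrix(0L, G, n_cells)
    cell_state <- character(n_cells)
    cell_type <- character(n_cells)
    idx <- 0L
    for (s in seq_len(S)) {
      for (cc in seq_len(cfg$n_cells_per_state)) {
        idx <- idx + 1L
        w <- P[, s] * rgamma(G, shape = cfg$noise, rate = cfg$noise)
        counts[, idx] <- rmultinom(1, cfg$depth_per_cell, w)[, 1]
        cell_state[idx] <- states[s]
        cell_type[idx] <- type_of_state[s]
      }
    }
    cell_ids <- sprintf("cell%05d", seq_len(n_cells))
    dimnames(counts) <- list(genes, cell_ids)

    # held-out split: first half of each state's cells -> reference
    half <- floor(cfg$n_cells_per_state / 2)
    in_ref <- logical(n_cells)
    for (s in seq_len(S)) {
      cells_s <- which(cell_state == states[s])
      in_ref[cells_s[seq_len(half)]] <- TRUE
    }

    ref_counts <- counts[, in_ref, drop = FALSE]
    if (cfg$shift_reference > 0) {
      shift <- exp(rnorm(G, 0, cfg$shift_reference))
      ref_counts <- ref_counts * shift
    }
    sc_ref <- sc_counts(ref_counts, cell_type[in_ref], cell_state[in_ref],
                        gene_ids = genes, cell_ids = cell_ids[in_ref])
    sc_sim <- sc_counts(counts[, !in_ref, drop = FALSE],
                        cell_type[!in_ref], cell_state[!in_ref],
                        gene_ids = genes, cell_ids = cell_ids[!in_ref])

    # empirical state profiles of the simulation half (pooled MLE)
    sim_prof <- vapply(states, function(s) {
      v <- rowSums(counts[, !in_ref & cell_state == s, drop = FALSE])
      v / sum(v)
    }, numeric(G))
    dimnames(sim_prof) <- list(genes, states)

    # per-sample fractions: Dirichlet over types, equal split over states
    theta_type <- rdirichlet(cfg$n_bulk_samples, rep(cfg$fraction_prior, K))
    theta_state <- theta_type[, match(type_of_state, types), drop = FALSE] / Spt
    samples <- sprintf("bulk%03d", seq_len(cfg$n_bulk_samples))
    dimnames(theta_type) <- list(samples, types)
    dimnames(theta_state) <- list(samples, states)

    X <- matrix(0, G, cfg$n_bulk_samples, dimnames = list(genes, samples))
    for (n in seq_len(cfg$n_bulk_samples)) {
      m <- as.vector(sim_prof %*% theta_state[n, ])
      if (is.null(cfg$overdispersion)) {
        X[, n] <- rmultinom(1, cfg$reads_per_bulk, m)[, 1]
      } else {
        X[, n] <- rnbinom(G, mu = cfg$reads_per_bulk * m,
                          size = cfg$overdispersion)
      }
    }

    structure(
      list(true_type_fractions = theta_type,
           true_state_fractions = theta_state,
           sc_reference_half = sc_ref,
           sc_simulation_half = sc_sim,
           pseudobulk = bulk_matrix(X, gene_ids = genes,
                                    sample_ids = samples),
           state_profiles = P,
           sim_state_profiles = sim_prof,
           state_to_type = setNames(type_of_state, states),
           config = cfg),
      class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "sim_dataset: %d genes, %d types x %d states, %d+%d cells (reference+simulation), %d pseudobulk samples (%g reads each)\n",
    cfg$n_genes, cfg$n_types, cfg$states_per_type,
    ncol(x$sc_reference_half$counts), ncol(x$sc_simulation_half$counts),
    cfg$n_bulk_samples, cfg$reads_per_bulk))
  invisible(x)
}

#' Deterministic small benchmark dataset
#'
#' A fixed 50-gene, 3-type (2 states each), 20-sample dataset used
#' throughout the tests and documentation. Regenerated on demand from a
#' fixed seed; no data ships with the package.
#'
#' @return a `sim_dataset` (see [simulate_dataset()]).
#' @export
fixture_small <- function() {
  simulate_dataset(simulate_config(
    n_genes = 50, n_types = 3, states_per_type = 2,
    n_cells_per_state = 20, n_bulk_samples = 20,
    reads_per_bulk = 20000, depth_per_cell = 2000, seed = 42))
}

#' Replicate pseudobulk columns at a fixed composition
#'
#' Draws repeated multinomial pseudobulk columns from a dataset's
#' simulation-half state profiles at a given state-fraction vector. Used to
#' check the generator's first moment (the expected column proportions
#' equal the profile mixture) and handy for power analyses at fixed
#' composition.
#'
#' @param dataset a `sim_dataset`.
#' @param theta_state state fraction vector (simplex over the dataset's
#'   states).
#' @param n_rep number of replicate columns.
#' @param reads reads per column (default: the dataset's
#'   `reads_per_bulk`).
#' @param seed integer seed.
#' @return a gene x `n_rep` count matrix.
#' @export
sample_pseudobulk <- function(dataset, theta_state, n_rep,
                              reads = dataset$config$reads_per_bulk,
                              seed = 1) {
  stopifnot(inherits(dataset, "sim_dataset"))
  m <- as.vector(dataset$sim_state_profiles %*% theta_state)
  with_seed(seed, {
    rmultinom(n_rep, reads, m)
  })
}
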