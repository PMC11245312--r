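---
title: "Fixed-point deconvolution of bulk expression: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed-point deconvolution of bulk expression: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellfrac)
```

## The model

Bulk RNA-seq measures a mixture: each sample's reads come from many cell
populations at unknown proportions. `cellfrac` treats deconvolution as a
multinomial mixture in the topic-model sense — reads are words, samples
are documents, cell states are topics, genes are the vocabulary. A
reference matrix $A_{G\times S}$ gives, per cell state $s$, the
probability $A_{gs}$ that a read from that state maps to gene $g$
(columns sum to 1). Each bulk column $x$ is modelled as

$$x \sim \mathrm{Multinomial}\Big(\textstyle\sum_g x_g,\;
  A\,\theta\Big), \qquad \theta \in \Delta^{S-1},$$

where $\theta$ is the vector of cell-state fractions. Cell *states* are
finer expression patterns within a cell *type*; estimation runs at state
resolution and type fractions are obtained by summing the state
fractions of each type. This hierarchy matters in tumor profiling, where
a "fibroblast" or "malignant" type is not one uniform profile.

## The fixed-point update

The Bayesian treatment of this model samples, for every gene, the latent
assignment of its $x_g$ reads to states and then resamples $\theta$ —
thousands of Gibbs iterations per sample. The key observation behind
`cellfrac` is that the per-iteration information actually used downstream
is the *mean* of that assignment distribution, which has closed form.
One update of `em_step()` computes the expected reads per state

$$n_s = \theta_s \sum_g x_g \frac{A_{gs}}{\sum_{s'} A_{gs'}\theta_{s'}}$$

and renormalizes $\theta' = n / \sum_s n_s$. This is exactly the EM
update for the multinomial mixture, so the data log-likelihood
$\sum_g x_g \log (A\theta)_g$ is non-decreasing along the iteration — a
property the test suite asserts on every fixture run with slack `1e-7`
for floating-point noise. Iterated to convergence, the update lands on
the maximum-likelihood fractions; with large read counts that is also
where the flat-prior posterior mean concentrates, so the derandomized
algorithm reproduces the sampled estimate without any Monte-Carlo error.
The optional `alpha` argument adds a symmetric Dirichlet prior (MAP-EM,
$\theta'_s \propto \max(n_s + \alpha - 1, 0)$); the default `alpha = 1`
is flat and is what the equivalence testing assumes.

Convergence uses a dual criterion: at most `max_iter = 100` iterations
per sample and a tolerance of `1e-6` on the largest absolute change in
$\theta$, both configurable. Because states of the same type have
deliberately similar profiles, the *division* of a type's fraction among
its states is often softly identified: such samples can exhaust
`max_iter` with `converged = FALSE` while the type-level sums — the
quantity of scientific interest — are stable to far better than the
tolerance. A `FALSE` flag is therefore a prompt to look at the
likelihood trace, not necessarily a failed fit. Initialization is uniform over states — the
symmetric choice; on identifiable instances the fixed point does not
depend on it. Samples are deconvolved independently, so results are
invariant to sample order, and multiplying a bulk column by any positive
constant leaves its fractions unchanged (only proportions enter). Inputs
that *look* log-transformed (maximum below 50) trigger a warning because
the model is only meaningful on the linear scale.

Degenerate inputs are flagged rather than absorbed: an all-zero bulk
column returns uniform fractions with `converged = FALSE` and a warning;
a gene with bulk signal but zero probability under every weighted state
is an error (prevented in practice by the reference pseudocount, below).

## Reference construction

`ref_prepare()` pools the raw counts of all cells sharing a state label
and normalizes each pooled profile — the maximum-likelihood profile
estimate. Two numerical choices:

* **Pseudocount** (default `1e-8` per gene) added before normalization,
  so no retained gene has probability exactly zero in any state. This
  protects the fixed-point denominator $\sum_s A_{gs}\theta_s$ from
  vanishing at genes with bulk signal. The value is small enough to be
  negligible against any real count.
* **All-zero genes are dropped**, not kept at uniform probability: they
  carry no information and inflating them distorts every column's
  normalization. Dropped ids are reported on the returned object.

State ids are namespaced as `type.state` so they are globally unique;
labels already carrying their type prefix are left alone, which keeps
the type-level and state-level code paths consistent.

When the source data has only type labels, `derive_cell_states()`
partitions each type's cells by k-means on library-size-normalized
(to 10k), `log1p`-transformed profiles. Library size is a nuisance
variable — two cells of the same state sequenced at different depths
should cluster together. This is deliberately generic subclustering
plumbing with a deterministic seed, not a tuned state-discovery method;
when curated state annotations exist they should be used instead. If a
type has no more distinct profiles than requested states, each distinct
profile becomes its own state (k-means is undefined there).

## Cell-type-specific expression and the 2D compression

Given fractions, the posterior expected contribution of type $k$ to the
bulk signal of gene $g$ in sample $n$ is

$$Z_{gnk} = X_{gn}\,
  \frac{\sum_{s \in k} A_{gs}\theta_{ns}}{d_{gn}}, \qquad
  d_{gn} = \sum_s A_{gs}\theta_{ns}.$$

The full $Z_{G\times N\times K}$ array is never stored: the result
object keeps only $\theta$ and the scaling matrix $d$ (gene × sample),
from which any type's slice is reconstructed on demand by
`reconstruct_Z_ct()`. The compression is exact — reconstruction through
the stored $d$ equals the one-shot computation from $(X, A, \theta)$ to
machine precision — and by construction $\sum_k Z_{gnk} = X_{gn}$ (read
conservation), both asserted in the tests. The axis order of
`get_Z_array()` is fixed as gene × sample × type.

## The optional update round

`update_reference()` re-estimates a type-resolution reference from
first-round $Z$: pooled mode sums each type's slice across samples
(pseudocount `1e-8`, symmetric with `ref_prepare`); the
`per_sample_malignant` mode instead gives the named malignant type one
profile per sample, since malignant expression is patient-specific while
the microenvironment is shared. The second round
(`run_deconv_updated()`) runs at type resolution; with a per-sample
bundle each sample is solved against its own malignant column plus the
shared environment columns. On exact-fit data the update reproduces the
generating profiles and the second round reproduces the first-round
fractions — a fixed point the tests verify. Empirically an updated
reference does not necessarily improve accuracy, so the round is
optional and off by default; `compare_references()` can quantify its
effect on simulated data. Pooled mode is the default because the
malignant-type treatment requires an explicit, dataset-specific choice
of which type is malignant.

## The Gibbs oracle and the regime of the equivalence claim

`gibbs_deconvolve()` is a collapsed Gibbs sampler for the same model:
per gene, assignment counts $z_{g\cdot} \sim \mathrm{Multinomial}(x_g,
\mathrm{resp}_g)$, then $\theta \sim \mathrm{Dirichlet}(\alpha + \sum_g
z_{g\cdot})$. Sampling per-gene counts rather than individual reads is
statistically identical and keeps desk-scale instances fast. It exists
to *verify* the estimator, not to run it: `oracle_battery()` draws
random small instances, solves each both ways, and requires agreement
within 3 Monte-Carlo standard errors element-wise (batch-means MCSE,
batch size $n^{2/3}$, which stays honest under chain autocorrelation).

The equivalence "fixed point = sampled posterior mean" is an asymptotic
statement, and the battery draws instances from the regime it covers:

* **Identifiable references.** Nearly collinear state profiles make the
  split of their combined fraction unidentifiable; the likelihood is
  flat along a ridge, the chain mixes pathologically slowly there, and
  no point estimate is meaningful. Instances require a reciprocal
  condition number of $A^\top A$ of at least 0.02.
* **Interior optima.** When the MLE of a fraction is exactly 0, its
  posterior is approximately half-normal and the posterior mean carries
  an $O(n^{-1/2})$ positive bias that no chain length removes. True
  fractions are therefore drawn with every component at least 0.1.
* **Large counts.** Even at an interior optimum the posterior mean
  differs from the MLE by an $O(1/n)$ curvature term; the battery uses
  50 000 reads per instance so that term is negligible against the
  Monte-Carlo error the tolerance is expressed in.

Outside this regime the two estimators genuinely differ — not because
the derandomization is wrong, but because "the" posterior summary is no
longer a single well-determined point.

## The pseudobulk simulator

`simulate_dataset()` generates the full benchmark: per-type base
profiles from a sparse Dirichlet, per-state log-normal jitter of the
base, single cells as multinomial reads from gamma-modulated state
profiles, and pseudobulk columns as multinomial reads from mixtures of
*empirical* state profiles. Its central design feature is the held-out
split: each state's cells are divided 50/50 into a reference half and a
simulation half with disjoint cell ids, and the pseudobulk is mixed
exclusively from the simulation half's pooled profiles — no information
flows from reference construction into bulk generation, which mimics
the realistic setting where the reference comes from different material
than the bulk. The optional `shift_reference` applies a per-gene
log-normal factor to the reference half only, emulating a technical
platform difference on top of the sampling-based mismatch.

Default parameters, chosen once as a realistic small benchmark:

| parameter | default | meaning |
|---|---|---|
| `profile_separation` | 0.3 | Dirichlet concentration of type base profiles; below 1 gives the sparse, marker-dominated structure real cell types show |
| `state_jitter` | 0.3 | log-normal sd between states of a type — similar but distinct profiles |
| `noise` | 10 | gamma shape of cell-level expression noise (CV ≈ 0.32 within a state) |
| `depth_per_cell` | 2000 | reads per cell, a typical shallow droplet depth |
| `fraction_prior` | 1 | uniform Dirichlet over per-sample type fractions |

Per-sample type fractions are split equally among the type's states.
Read sampling is multinomial, matching the model's likelihood; an
optional negative-binomial mode (`overdispersion`) generates off-model
bulk for robustness checks. What the simulator does **not** emulate:
ambient RNA, doublets, batch structure within the reference, platform-
specific gene-length effects, and genuinely novel cell populations
absent from the reference. Passing benchmarks here therefore shows
correctness of the estimator under (and moderately off) its model, not
performance on any particular real cohort.

The tests run the generator at three scales: the deterministic
`fixture_small()` (50 genes, 3 types × 2 states, 20 samples of 20k
reads) for fast exact checks; a 200-gene consistency run at $10^6$
reads and minimal noise, where estimated type fractions must correlate
with truth above 0.99; and the headline benchmark (1000 genes, 8 types
× 2 states, 200 cells per state, 100 samples of 100k reads, reference
shift sd 0.2), where the average per-type Pearson correlation between
estimated and true type fractions is required to reach at least 0.92 —
`scripts/acceptance.R` recomputes exactly this quantity.

## Evaluation

`evaluate_fractions()` reports, per cell type, the Pearson correlation
and RMSE across samples between estimated and true fractions, and their
means across types — correlation captures ranking fidelity per type,
RMSE absolute calibration. A type with zero variance in the truth has
no defined correlation; it is reported as `NA` and excluded from the
mean with a warning rather than being assigned a fabricated 0. Metrics
are computed on type-level fractions (passing state-level matrices
works identically if state-resolution scoring is wanted).
`compare_references()` ranks candidate references by mean per-type
correlation with ties kept in input order, and `nnls_baseline()` — a
non-negative least-squares regression on type-averaged profiles —
provides an independent yardstick from outside the Bayesian framework.

## Known limitations

* Gene identifiers are matched as exact strings; symbol/Ensembl
  harmonization is upstream scope.
* The estimator assumes every population in the bulk is represented in
  the reference; mass from missing populations is absorbed by the
  closest available profiles.
* The fixed point approaches simplex *vertices* (samples truly composed
  of a single state) sublinearly, so fractions near 0/1 converge more
  slowly than interior ones.
* Posterior uncertainty is deliberately out of scope: the method's
  point is replacing sampling with the mean. Where uncertainty matters,
  the Gibbs oracle can be run on small problems.

## A minimal session

```{r, eval = FALSE}
fx <- fixture_small()
ref <- ref_prepare(fx$sc_reference_half)
res <- run_deconv(fx$pseudobulk, ref)
evaluate_fractions(res$theta_type, fx$true_type_fractions)
Z_t1 <- reconstruct_Z_ct(res, "T1")
```
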