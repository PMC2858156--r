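---
title: "Inferring gene regulatory networks by sparse multiple regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene regulatory networks by sparse multiple regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nir)
```

## Model and assumptions

The package treats the transcriptome near its operating point as a linear
dynamical system, `dx/dt = A x + p`: `x` holds expression deviations from
the unperturbed steady state, `p` the externally applied perturbations, and
the influence matrix `A` encodes the regulatory network — `a_ij` is the
signed, directed effect of gene `j` on gene `i`, with the diagonal playing
the role of first-order self-degradation.  The linearization is trusted
only for *small* perturbations measured *after* the system has settled
("local steady-state data"), where `A x_l + p_l = 0` for every experiment
`l`.

Solving the steady-state condition row by row turns network inference into
N independent regressions.  For target gene `i` the response across the M
experiments is `y = -p_i` (the sign flip moves the perturbation to the
right-hand side, so the fitted coefficients are the `a_ij` themselves, with
recovered signs directly comparable to a generating network).  The
regressors are the N transcript profiles — including gene `i`'s own, since
the degradation term is a genuine self-influence.  Estimation is ordinary
(unweighted) least squares; measurement variances are assumed homogeneous
enough that weighting would not change the selected supports.

Sparsity enters as a hard cap `k` on the number of regulators per gene.
Exhaustive best-subset selection over `choose(N, k)` sets is infeasible
beyond toy sizes, so the search is a greedy forward beam: score all N
single-regressor models, keep the best `beam_width` (default `k`); at each
later step extend every surviving set by every unused candidate, merge
duplicate sets produced by different parents, score each once, keep the
best `beam_width`; stop at size `k` and return the minimum-RSS set.  With
`beam_width` at least the candidate count at every step, this provably
reduces to exhaustive best-subset selection (a property the test suite
exercises at small N), and its RSS can never beat the exhaustive optimum.

## The fast regression core

Scoring a candidate set `S` needs only the normal equations
`(X_S X_Sᵀ) b = X_S yᵀ`.  Both sides are extractable from quantities
computed once per data set: the Gram matrix `G = X Xᵀ` and the projection
`xty = X yᵀ` (for a canonical design — one unit perturbation per
experiment — `xty` is just a sign-flipped column selection of `X`).  Each
candidate therefore costs one `s × s` symmetric gather plus one Cholesky
solve, independent of M.  The residual sum of squares is evaluated
algebraically as `rss = y yᵀ − bᵀ xty_S` (clamped at zero against roundoff)
rather than by touching the data matrix again.  The kernel lives in
`src/nir_core.cpp` (RcppArmadillo); the dense per-subset Cholesky is the
LAPACK one behind `arma::chol`.

Numerical choices:

* **Singular candidates.** A subset whose Gram submatrix fails the Cholesky
  factorization (linearly dependent regressors, e.g. a flat expression
  profile) is reported as a `singular_candidate` and silently excluded from
  the beam — no ridge term or pseudo-inverse is substituted, because the
  model class assumes independent regressors.  If every size-k candidate is
  singular the gene is reported with an empty regulator set in the result's
  `failures` attribute; the run continues.
* **Tie-breaking.** Candidate sets with RSS equal to within 1e-12 relative
  are ordered by lexicographically smallest subset.  This makes results
  deterministic across worker counts and platforms.
* **Zero-coefficient pruning.** Coefficients smaller than 1e-8 relative to
  the gene's largest fitted coefficient are dropped from the network.  On
  noise-free data the slots beyond the true in-degree come out numerically
  zero, so the recovered in-degree equals the true one even when `k` is
  generous; on noisy data nothing is pruned in practice.
* **k versus pool size.** Requesting more regulators than there are
  candidates is an error, not a silent clamp — clamping would change the
  model class invisibly.

## Parallel execution

Genes are independent given `G`, so `run_parallel()` partitions them into
near-equal contiguous blocks, one per worker (forked processes via the
`parallel` package; a serial loop when one worker is requested or forking
is unavailable).  Workers only read shared inputs and never communicate,
and results are reassembled in gene order, so the inferred network is
bit-identical for every worker count — a property the acceptance tests
check on a 100-gene data set for 1, 2, 4 and 8 workers.  A failure inside
a worker aborts the run naming the offending gene.

## The in-silico benchmark generator

`random_network()` draws each off-diagonal influence independently with
probability `avg_in_degree / (n_genes − 1)`, magnitude uniform in
`[weight_low, weight_high]` (defaults 0.5–1) with equiprobable sign, fixes
the diagonal at −1, and rescales each row's off-diagonal entries so their
absolute sum is at most 0.9.  Strict diagonal dominance is the simplest
certifiable guarantee that `A` is invertible and the steady state stable;
the −1 diagonal pins the time/concentration scale to match unit-magnitude
perturbations.  `steady_state_data()` applies the canonical design
(experiment `l` perturbs gene `l` with magnitude 1) and solves
`X = −A⁻¹ P`, then adds Gaussian noise with standard deviation `noise_sd`
× RMS of the clean signal.  The default `noise_sd = 0.1` is a deliberate,
documented choice of a realistic microarray-scale noise level; the
benchmark literature this emulates does not pin a single value, so
absolute accuracy figures carry simulator-dependent uncertainty.

What the simulator does *not* emulate: nonlinear regulation (the data are
generated by the same linear model class the inference assumes, so accuracy
here is an upper bound on real-data behaviour), correlated or
signal-dependent noise, unobserved regulators, and imperfect knowledge of
which gene a perturbation hits.  Passing benchmarks therefore demonstrate
correctness and self-consistency of the method, not field performance.

## Identifiability and the choice of k

With noise-free canonical data and `M = N`, the representation
`y = a_i· X` is unique, so a gene is exactly recoverable if and only if its
true regulator count *including the self-term* is at most `k`.  The
generator draws off-diagonal in-degrees from a binomial with mean
`avg_in_degree`, so some genes always exceed any fixed `k`; the noise-free
recovery check consequently scores the genes that satisfy the
identifiability precondition (in 20 replicates of 50 genes at average
in-degree 3 and `k = 5`, all of them are recovered exactly, weights to
better than 1e-6 relative).  Conversely, when `k` is *below* the typical
in-degree the inferred in-degree is capped at `k` (minus the slot the
self-term almost always claims), which bounds attainable sensitivity at
roughly `E[min(in-degree, k−1)] / E[in-degree]` regardless of data quality
— at average in-degree 3 and `k = 3` this is about 0.6.  Choosing `k` at or
above the expected in-degree (the default working point is `k = 10` at
average in-degree 10) avoids the cap at the cost of a few false positives
in the surplus slots.

## Problem sizes and defaults

The shipped benchmarks run at desk scale: 10 genes × 20 replicates,
100 genes × 10 replicates and 200 genes × 5 replicates, each with one unit
single-gene perturbation per gene, `noise_sd = 0.1`, and `k = 10` (3 for
the 10-gene runs).  A 200-gene, `k = 10` inference evaluates roughly
4 million candidate regressions and takes seconds per network in the
compiled kernel.  All randomness is seeded: the topology draw uses
`sim_config$seed`, the noise draw `seed + 1000003` so the two streams are
decoupled but individually reproducible.

## Known limitations

* Steady-state only: the time-derivative term is assumed zero, so
  time-course data and transient responses are out of scope.
* One linear model per gene: saturation, combinatorial logic and hidden
  confounders are not represented.
* The sparsity bound is global; genes with true in-degree above `k` are
  systematically under-recovered (see above).
* The worker pool is single-node; distributed-memory execution is not
  provided.
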