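---
title: "Moment-ratio tests for hierarchical functional modularity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-ratio tests for hierarchical functional modularity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A *functional module* is a set `S` of observable network components that are
conditionally independent of all other components given a single scalar
*interface variable* `y`.  We work with binary interfaces, `y` in `{1, 2}`.
This is less restrictive than it sounds: the same test applies to continuous
interfaces whenever (i) only mean values carry the functional signal (as
assumed for transcription rates and instantaneous firing rates) and (ii) the
mean of any variable downstream of an interface is linear in that
interface's mean.  Probabilistic Boolean networks satisfy both conditions by
construction.

A *modularization* is a family of modules that is either *flat* (pairwise
disjoint) or *nested* (pairwise disjoint-or-contained).  One component,
`s_ref` (by convention the last), belongs to no module and anchors the
denominators below.

With all components normalized to zero mean, a module with a binary
interface forces proportionality between rows of the moment-ratio matrix

    B[k, l] = E[s_k s_l s_ref] / (E[s_k s_ref] E[s_l s_ref]),

specifically `B[k, l]` is constant over `k` in `S` for each `l` outside
`S`.  Each module thus contributes equality constraints on the vectorized
ratios `b_v`, `v = v(k, l)`; constraints from different modules that share a
ratio index merge transitively (union-find in `index_sets()`).  The result
is a partition of all `d_X0 = (d-1)(d-2)/2` ratio indices into `d_X` sets;
unconstrained indices stay as singletons.  A purely *linear* module
additionally equates all above-diagonal entries of its submatrix (addition
is commutative, so any finer structure inside a linear module is
untestable); the fully linear model equates all ratios.

## Estimators

Two estimation schemes are used, chosen by what is being tested.

**Nested/flat modularizations** (`nested_products()`): for a pair `(k, l)`
the numerator `E[s_k s_l s_d]` is estimated from the odd-numbered samples
and the denominator `E[s_k s_d] E[s_l s_d]` from products across the two
halves of the recording, `s_k^(n) s_d^(n) s_l^(n+N/2) s_d^(n+N/2)`.  Using
disjoint sample pairs for the two covariance factors makes the denominator
estimate unbiased.  Samples are consumed in acquisition order; nothing is
shuffled, so a given input file yields bit-identical results.  An odd
trailing sample is dropped with a warning.

**Single modules** (`single_module_products()`, used by the
regulatory-network pipeline): one product per sample, numerator
`E[s_k s_l]`, denominator `E[s_k s_ref]`, and the two ratios of the module
`{1, 2}` are estimated on the first and second halves of the samples
respectively.  This makes the two ratio estimates independent, which
matters for calibration (below).

**Cutoff.** Each ratio's denominator has a signal-to-noise statistic
`rho = b2 / se(b2)`.  If `|rho| < theta` (strictly), the ratio is set to 0,
its variance entry to infinity, and its covariance entries to 0; with the
convention `1/Inf = 0` it then drops out of every downstream formula.  The
default `theta = 5` guarantees finite moments of the truncated ratio for
approximately joint-normal moment estimates; the regulatory-network variant
uses `theta = 0.5` (any value below 1) because there the cutoff only guards
degenerate denominators and the `alpha_min` floor is not needed.  The
boundary is kept exactly as specified: `|rho|` equal to `theta` survives.

**Covariance.** `ratio_covariance()` applies the delta method to the
per-term product covariances, with factor
`sqrt(lambda_v lambda_w) / (n b2_v b2_w)` where `n` is the per-term count.
`lambda_v` is 1 in asymptotic mode; in corrected mode it is the polynomial
`xi_0 (1 + sum_{n=1..5} xi_n (rho/6)^(-2n))` with
`(xi_0..xi_5) = (1.367, 2.047, 4.735, -1.923, -1.231, 2.790)`, an inflation
that accounts for the heavy tails of a truncated normal ratio at finite
signal-to-noise (it tends to `xi_0 = 1.367` as `rho` grows).

## The test

The statistic `T` (in `test_statistic()`) is half the difference between
the total weighted sum of squares of the ratios and its within-set pooled
counterpart; algebraically a variance decomposition, so `T >= 0` always
(clipped at 0 against round-off).  Singleton sets cancel exactly, which is
why the shape parameter is `zeta = (d_X0 - d_X)/2`, half the number of
equality constraints.  Under the candidate, `T ~ Gamma(zeta, 1)`; p-values
are the upper gamma tail via `pgamma(..., lower.tail = FALSE)`, which is
accurate far below 1e-10.  `zeta = 0` means no constraint, `T` identically
0 and `p = 1`.

Three corrections keep the decision conservative:

* `lambda_max` — the largest eigenvalue of the ratio covariance restricted
  to constrained sets and normalized to unit diagonal — scales the whole
  covariance before `T` is computed.  Cut-off ratios and singletons
  get weight 0 in the normalization — the natural limit of `1/sqrt(Inf)` —
  and a family with no constrained set has `lambda_max = 1` (the test is
  vacuous there anyway).
* `alpha_min = 1 - erf((theta-1)/sqrt(2))^d_X0 * erf(6/sqrt(2))^d_X0`
  bounds the probability that cutoff misclassification invalidates the
  gamma null when some true correlations with `s_ref` are zero.  For
  `theta <= 1` the expression exceeds 1 and the floor is defined as 0.
* Multiple testing over `d_H` candidates divides the corrected level
  `alpha_Gamma = (alpha* - alpha_min)/(1 - alpha_min)` by `d_H`; `d_H`
  defaults to the number of candidates actually tested on the same samples.

## Candidate enumeration

`enumerate_candidates(d)` generates every nonempty laminar family of
subsets of the non-reference components with subset size at least 2 and
proper containment in the non-reference set.  Modules never contain the
reference component and never equal the full non-reference set: such a
module would impose zero testable constraints.  For `d = 5` this yields 25
candidates (26 with the fully linear model).  The canonical order — number
of modules first, then lexicographic on the sorted module lists — is fixed
so that labels `M1 ... M25` are reproducible across runs; the
data-generating structure of the default simulator corresponds to `M10`
(`{3,4}`), `M8` (`{2,3,4}`) and `M25` (both).

## The proof-of-principle simulator

`pbn_default_spec()` encodes a five-population network with two latent
interfaces: a root population `x4`; `x3` coupled to it; `y1` a noiseless AND
of `x3, x4` interfacing the module `{3,4}`; `x2` driven by `y1`; `y2` a
noisy XOR-like function of `x2, y1` interfacing `{2,3,4}`; `x1` driven by
`y2`; and the output `x5 = AND(x1, y2)` as reference component.  All
conditional probabilities use contrast 0.85/0.15 except the deterministic
AND gates.  The optimal *linear* readout of `x5` from the other populations
attains only `R^2 = 0.79` under the exact joint distribution
(`linear_r2()`), so the network is genuinely nonlinear and the fully linear
model is falsifiable.

Observables are population spike counts: 10 neurons per population firing
at 5 Hz (state 1) or 25 Hz (state 2), counted in 200 ms bins — expected
counts 10 or 50 — over 4500 bins (15 minutes).  The per-neuron point
process is not part of the model's claims; we draw population counts as
Poisson with the state-dependent mean, the same law as independent Poisson
neurons, because only the conditional mean enters the method's assumptions.
Exact moments of the counts (means, covariances, central third cross
moments for distinct triples) come from enumerating the 2^7 joint
configurations (`exact_count_moments()`), which the Monte Carlo paths are
tested against.  Under this noise model the exact minimum pairwise count
correlation is 0.40 (0.43 without count noise); single recordings scatter
around it by about ±0.02.

What the simulator does *not* emulate: temporal dependence within and
across bins (counts are i.i.d. given the states — real recordings need the
`check_autocorrelation()` gate and subsampling), non-Poisson dispersion,
rate drift, and measurement noise on the observables.  Tests passing on
this generator therefore validate the statistical machinery under the
stated conditions, not robustness to those real-data features.

`linear_surrogate()` builds the matched null: each component is permuted
independently (destroying all cross dependence), standardized to unit
variance, and mixed by the Cholesky factor of the original sample
covariance.  Without the standardization the mixed data would have
covariance `L D L'` rather than the intended `L L'`; both behaviours are
available behind the `standardize` flag, with standardization the default.
On surrogates the fully linear model is retained at nominal rates.

## Calibration and power: what the tests compute

The gamma null is *exact* only when the surviving ratio estimates are
uncorrelated; with correlated ratios the `lambda_max` scaling makes the
test conservative instead.  On any strongly coupled count network the
paired-scheme ratio estimates are substantially correlated (they share the
reference component and the sample halves), so the calibration suite uses
the estimator that is exactly in the uncorrelated regime by construction:
the disjoint-half single-module test (`single_module_test()`,
`zeta = 1/2`) on an exact flat module — a binary interface with four
conditionally independent linear readouts (interface gain 2, unit noise),
`N = 10^4` samples, 2000 replicates, compared to `Gamma(1/2, 1)` by a
Kolmogorov–Smirnov test.  Conservativeness of the full corrected pipeline
is validated separately: 500 replicate recordings of the default network,
all-26-candidate correction at overall level 0.01, observed type-I
rejection of the true modularization at or near zero.

Power is asymmetric across false candidates.  Most inconsistent
modularizations violate equalities by a large margin and are rejected in
nearly all 15-minute replicates, with rejection probability growing in the
recording length (checked at N = 500, 1500, 4500).  A few candidates
(those built from `{2,3}` or `{2,4}`) violate only one equality by a small
margin under this noise model; at 15 minutes the conservative corrections
leave them mostly unrejected.  This is a genuine power limit of the
corrected test at these settings, not a defect: their evidence grows with
`N` like every other false candidate's.

## Regulatory-network re-ranking

For expression data, every subnetwork of two transcription factors (TFs)
and two target genes (TGs) is tested for the single module containing both
TFs — the hypothesis that one regulator's influence is indirect, mediated
by a single interface.  The pipeline starts from a ranked interaction list
(absolute Pearson correlation by default, artificial p-values `rank/N`) and
re-scores edges by `p <- max(p, c * p_test)`.

Conventions, each fixed after weighing the open alternatives:

* A subnetwork is *sufficiently connected* when at least three of its four
  TF–TG edges are in the set of the `set_size` most likely interactions,
  including both edges of the *putative interface TF* — the TF owning the
  subnetwork's most likely edge (ties broken in favour of the first TF in
  label order).  `set_size` is the method's only free parameter.
* The scale `c` is the p-value at the *boundary* of the most-likely set
  (its largest member).  With this choice an irrefutable module
  (`p_test = 1`) demotes an edge exactly to the boundary of the set whose
  membership triggered the test, and never past it; missing evidence
  against a module can therefore never outweigh the evidence that made the
  subnetwork eligible.  A smaller scale (for example the best p-value in
  the set) would make the correction inoperative for rank-based p-values,
  since `c * p_test` could then never exceed any edge's own p.
* Corrections for the same edge from different subnetworks combine by
  taking the maximum — the conservative combination for the disjunction of
  the individual hypotheses.
* The two TG roles (which one is the reference) follow gene-label order;
  evaluating both roles and taking the larger p is available via
  `swap_ref` but off by default.
* `holdout_size_selection()` takes every 8th sample (indices 1, 9, 17, ...)
  as the holdout, computes corrections on the holdout only, and picks the
  `set_size` maximizing the area under the precision-recall curve against
  the gold standard.  The selection criterion on the holdout is our choice;
  only the holdout construction is fixed a priori.
* Under fully permuted data the subnetwork test is conservative rather
  than uniform: destroyed correlations drive the denominators under the
  cutoff and the p-value collapses to 1, which adds no spurious evidence.

Whether an indirect TF–TG dependency is *removable* by this test depends on
the gold-standard topology: if the target's mediating regulators include
two or more TFs that are mutually dependent (one reachable from the other,
or sharing an upstream regulator), a single interface cannot represent the
dependency and `classify_indirect()` labels it nonremovable.  The
structural rule is deliberately isolated in that one function so it can be
swapped for a different operationalization.

The planted-network property test simulates nested motifs (an upstream TF
driving a downstream TF driving three TGs with mixed readout strengths, 800
samples), where the indirect upstream edges interleave with weak direct
edges in the correlation ranking; re-ranking with `set_size` equal to the
number of plausibly connected edges strictly raises the area under the
precision-recall curve in well over 90% of replicates.  Challenge score
formulas (`overall_score()`) operate on user-supplied null-distribution
p-values; generating the null distribution itself is out of scope.

## Numerical conventions and degenerate inputs

* Cutoff boundary: strictly `|rho| < theta` zeroes a ratio; equality
  survives.  A zero-variance denominator with nonzero mean is treated as
  infinite signal-to-noise (kept); with zero mean it is cut off.
* Extended reals: `Inf` variances propagate as exact zeros wherever the
  inverse enters (statistic weights, eigenvalue normalization).
* `T` is clipped at 0; p-values never exceed 1 by construction.
* `decide()` refuses `alpha* <= alpha_min` with an actionable error rather
  than returning a vacuous decision.
* File parsers reject ragged rows, non-numeric cells, duplicate headers and
  unknown labels with located errors; numeric output uses 6 significant
  digits, p-values scientific notation.
* Enumeration is capped at 24 observable components (about 10^7 single
  modules); beyond that the hypothesis-driven workflow (test a proposed
  family and its 2^n sub-families) is the intended use.

## Problem sizes used by the test suite

Unit and property tests run at small sizes (hundreds of samples); the
calibration block uses 2000 replicates of 10^4 samples; type-I control uses
500 replicate 4500-bin recordings; estimator unbiasedness uses 10^4
replicates of 200 population-centred samples against the enumeration
oracle; the planted-network property uses 50 replicates of 800 samples.
These sizes were chosen so each property is measured with comfortable
Monte Carlo margins while the whole suite stays quick on one CPU.

## Known limitations

* Interface variables are binary (or continuous under the linearity
  conditions); interfaces with three or more effective values are outside
  the model.
* The test refutes modularizations; it does not search for modules, and it
  does not estimate interface values or rate functions.
* Near-null false candidates (violations small relative to the corrected
  variance) need longer recordings than clearly false ones — the corrected
  test trades power for validity under correlated ratios.
* The i.i.d.-sampling assumption must be checked on real recordings
  (`check_autocorrelation()` below 0.05 at the sampling lag is the working
  gate) and enforced by subsampling if violated.
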