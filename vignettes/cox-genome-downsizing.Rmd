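---
title: "Linking a mitochondrial COX mutation to genome downsizing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking a mitochondrial COX mutation to genome downsizing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Species of the carnivorous plant family Lentibulariaceae (*Pinguicula*,
*Utricularia*, *Genlisea*) carry the smallest nuclear genomes known in
flowering plants. A candidate mechanism is a pair of amino-acid replacements
in helix 3 of cytochrome *c* oxidase subunit I: the ancestral lysine–serine
(LS) configuration was replaced by cysteine–cysteine (CC) in the common
ancestor of *Utricularia* and *Genlisea*, with a later decay to
cysteine–serine (CS) in *Genlisea* section *Genlisea* and a reversal to LS
in subgenus *Tayloria*. The reactive thiol groups of the cysteines plausibly
elevate mitochondrial ROS production, DNA damage, and — through
deletion-biased repair — genome shrinkage.

`ouregime` implements the comparative machinery needed to test this
hypothesis end to end: classify and reconstruct the COX state on a dated
phylogeny, paint the reconstructed states onto branches as selective
regimes, and ask whether 1C genome size and mean chromosome size (analysed
on the log10 Mbp scale) evolve toward regime-specific optima.

## Pipeline overview

1. **COX state determination** (`classify_cox_state()`, `marginal_asr()`):
   tips are classified from the two diagnostic codons of a 237-bp COX
   fragment; internal nodes by maximum-likelihood marginal ancestral
   reconstruction under a substitution model chosen by BIC
   (`select_model_bic()`). Species without sequences can be assigned by
   taxonomic affiliation (`impute_states_by_affiliation()`), and every
   analysis can be run both with and without those imputed records
   (`run_study(variant = "both")`).
2. **Regime painting** (`paint_regimes()`): each branch carries the state of
   its tipward node, so a state change at a node affects the branch beneath
   it. This matches the node-based reconstruction that feeds the painting.
3. **Phylogenetic regression** (`fit_pgls()`, `select_error_model()`):
   log10 trait ~ COX state with LS as the reference level, under
   Brownian-motion or Ornstein–Uhlenbeck residual kernels
   (fixed-root and stationary-root variants), the error structure chosen by
   Akaike weight.
4. **Trait-evolution model comparison** (`fit_ou_models()`): the seven
   standard models BM1, BMS, OU1, OUM, OUMV, OUMA, OUMVA, differing in which
   of the optimum (theta), attraction strength (alpha) and diffusion
   variance (sigma-squared) are shared or regime-specific.
5. **Parametric bootstrap** (`parametric_bootstrap_theta()`,
   `compare_regime_optima()`): the sampling distribution of the per-regime
   optima under the selected model, with pairwise Mann–Whitney comparisons.

## The multi-regime OU model

Along a branch of length $t$ in regime $r$ the trait follows
$dx = \alpha_r(\theta_r - x)\,dt + \sigma_r\,dW$, giving the exact
transition $x_{child} \mid x_{parent} \sim N\!\big(\theta_r + (x_{parent} -
\theta_r)e^{-\alpha_r t},\; \sigma^2_r \tfrac{1 - e^{-2\alpha_r t}}{2\alpha_r}\big)$
(`branch_transition()`; the $\alpha \to 0$ Brownian limit is handled by a
series-safe branch for $\alpha t < 10^{-6}$). Units on a height-1 tree:
$\theta$ in log10 Mbp, $\alpha$ in 1/time (phylogenetic half-life
$\ln 2 / \alpha$), $\sigma^2$ in log10-Mbp$^2$/time.

The likelihood is computed two independent ways, and the package's test
suite requires them to agree to $10^{-8}$:

* an **explicit multivariate normal**: the mean accumulates piecewise
  attraction toward the painted optima along each root-to-tip path, and the
  covariance accumulates diffusion variance with attraction decay, both
  evaluated exactly piecewise-constant per painted segment (so
  regime-specific $\alpha$ in OUMA/OUMVA involves no approximation);
* **Gaussian belief propagation**: post-order elimination of node values
  using the exact branch transitions.

Fitting profiles the optima (and the root value, when separate) by GLS and
the overall $\sigma^2$ scale analytically, leaving only log-$\alpha$ values
and log $\sigma^2$-ratios for numeric search — 0 (BM1) to $2R-1$ (OUMVA)
dimensions. One-dimensional searches use a log-spaced grid plus Brent
refinement; higher dimensions use box-constrained quasi-Newton from
dispersed deterministic starts (8 by default) with a simplex fallback.
$\alpha$ is bounded in $[10^{-8}, 50/\text{tree height}]$; a fit at the
upper bound warns of a near-white-noise model.

**Root handling.** The default ties the root value to the root regime's
optimum — the smallest parameterization, giving the parameter counts
BM1 $2$, BMS $R{+}1$, OU1 $3$, OUM $R{+}2$, OUMV/OUMA $2R{+}1$, OUMVA $3R$.
A free root value and a stationary root are available as switches; the
original analysis does not state its choice, so the tied default was chosen
as the more parsimonious model and the alternatives are one argument away.

**Model weights.** AICc is the default weighting criterion because the
empirical analysis sizes (about 112 and 67 species) are small relative to
the larger models' parameter counts; plain AIC is a switch.

## Phylogenetic regression details

At fixed $\alpha$ the GLS estimates and the ML residual variance are closed
form; $\alpha$ is profiled on the log scale. Standard errors use the
small-sample corrected variance $\hat\sigma^2 n/(n-p)$ and t-tests use
$n - p$ degrees of freedom; under a true-null simulation harness the CC
contrast's type-I error at nominal 5% stays within a few points of nominal
(checked in the acceptance suite). $R^2$ is computed in the whitened space
against an intercept-only model refitted under the same fitted correlation;
because the original package's adjusted-$R^2$ convention is undocumented,
both $1-(1-R^2)(n-1)/(n-p)$ and the $(n-p-1)$ variant are reported.

## What the synthetic-data generator emulates

With no redistributable supplementary data, the package generates complete
synthetic studies (`build_synthetic_study()`) whose structure mirrors the
empirical one, and the acceptance checks score recovery against the
generator's truth ledger. Defaults, chosen once on scientific grounds:

* **Tree**: Yule, 120 tips (about the size of the study tree), scaled to
  height 1 (the published tree is relatively dated).
* **Regime history**: sequential Markov gains LS → CC → CS at rate 0.35 per
  allowed move (an optional CC → LS reversal mirrors *Tayloria*), with
  histories redrawn until the tip composition falls inside bands
  (LS 20–70%, CC 20–70%, CS 5–50%) that match the empirical composition —
  a deep CC gain spanning roughly half the species and a smaller CS clade.
  Unconstrained low-rate histories concentrate transitions near the
  present and routinely leave a regime nearly empty, which no study of
  this design would analyse.
* **Traits**: OUMA with optima at the published estimates
  (genome 597/210/51.09 Mbp; mean chromosome 55.41/12.21/2.18 Mbp, log10
  scale), attraction $\alpha = (1.5, 3, 6)$ — half-lives of roughly 0.46,
  0.23 and 0.12 tree heights, a moderate spread with the strongest pull in
  the most derived regime — and $\sigma^2 = 0.135$, giving a stationary
  within-regime spread of 0.1–0.2 log10 units, comparable to the within-genus
  spread of published genome sizes. Chromosome numbers are derived by
  rounding the genome/chromosome-size ratio so the trait table is
  internally consistent.
* **Sequences**: JC+Gamma (shape 0.5), 237 sites, with the two state codons
  overwritten per tip to encode its regime (synonymous codons randomized so
  silent variation does not leak the state); 60% of tips carry sequences,
  the rest rely on taxonomic imputation, as in the real data.

The generator does **not** emulate: polyploidy jumps or other discrete trait
shifts, measurement error in flow-cytometry values, tree estimation error or
calibration uncertainty, codon-level selection, or indels. Passing recovery
tests therefore demonstrates the estimators work under the model's own
assumptions at realistic sizes — not robustness to these violations.

## Problem sizes used by the checks

The test-suite harnesses use 250-tip trees with 100 replicates for optimum
recovery (errors measured on the log10 analysis scale), 150-tip trees with
200 replicates for regression calibration, 300-tip studies for the
seven-model selection check, and study-sized trees (112/67 species) for the
regression and funnel checks; the bootstrap runs a 20-replicate smoke
version in the tests and the full 100 replicates in
`scripts/acceptance.R`. These sizes keep every harness's Monte-Carlo error
well below the tolerances being asserted.

## Numerical choices and degenerate inputs

* Discrete-Gamma rates use 4 equal-probability categories with the
  mean-of-band convention (category rates average 1 exactly).
* Ambiguity codes enter the pruning likelihood as partial indicator
  vectors; gaps are fully missing. MAP states break exact posterior ties by
  the fixed order A < C < G < T and set a tie flag.
* Trees must be ultrametric (relative tolerance $10^{-4}$ by default —
  published dated trees carry rounding error) for trait analyses; zero-length
  internal branches are permitted with a warning. Pruning preserves
  root-to-tip depths by retaining the dropped basal path as a root edge.
* Species matching trims whitespace and unifies underscores and spaces.
* Regimes painted on fewer than two branches trigger a warning and the fit
  proceeds; covariance matrices are Cholesky-factorized and a singular
  matrix aborts with its condition estimate.
* When the analysis tree has tips without reconstructed ancestors (direct
  state-table route), internal regimes come from an equal-rates Mk
  reconstruction (`ape::ace`) with a descendant-majority fallback; in the
  sequence route, reconstructed node states are carried from the ASR tree
  to the analysis tree by matching most-recent common ancestors, and
  unmapped nodes inherit their parent's state.

## Known limitations

* Optimum recovery for a rare, single-origin regime is information-limited.
  In study-like data the CS state arises once, in a small clade (~7% of
  species); because its members share most of their history, the effective
  number of independent draws of the CS process is a handful, and the
  harness measures the attainable sampling precision of the CS optimum at
  roughly 15% on the back-transformed Mbp scale even at 300 tips (LS and CC
  sit near 5% and 10%). This is a property of the design, not of the
  estimator: reported CS optima should be read with their bootstrap
  intervals, not as point values.
* The Mann–Whitney comparison of bootstrap optimum distributions inherits
  the anticonservatism of testing resampled replicates of a single fit; the
  equal-optima null behaviour is characterized in the test suite and the
  p-values should be read as the field reads them, not as calibrated error
  rates.
* Measurement error in the traits and uncertainty in the tree and in the
  regime painting are not propagated (no SIMMAP-style averaging over
  histories).
* The BIC scan covers the JC/K2P/HKY families with and without Gamma — a
  deliberate reduction of the full 24-model scan of common software; the
  winning family for data of this kind (JC+Gamma) is contained in the set.
* The bootstrap refits use a warm start from the original estimate plus a
  few fresh starts; pathological multimodality could in principle evade
  both, which is why replicate failures are counted and reported.
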