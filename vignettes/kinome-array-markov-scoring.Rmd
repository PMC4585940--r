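---
title: "Markov scoring of kinome peptide arrays: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov scoring of kinome peptide arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinomescore)
library(dplyr)
```

## The measurement and the question

A kinome peptide array spots ~1000 short kinase-substrate peptides on a
solid support. Incubating the array with a cell lysate and radiolabeled
ATP transfers label onto every peptide that active kinases in the lysate
can phosphorylate; a phosphor-imager then yields, per spot, a foreground
density and a local background density in arbitrary units. Profiling two
genotypes — here the motivating design is wild-type versus *Tsc2*-null
mouse embryonic fibroblasts, with three technical replicates of two
biological replicates per genotype — and contrasting which substrate
groups light up gives a pathway-level picture of how a mutation rewires
kinase signaling.

The pipeline answers that question in five stages, each independently
re-runnable from files:

1. **QC** — within-condition Pearson concordance of replicates, gated at
   0.85.
2. **Calling** — per reaction, classify each peptide as significantly
   phosphorylated above background (a two-state latent classification).
3. **Markov scores** — per peptide and condition, count the reactions
   (0–6 in the default design) with a positive call.
4. **Category collapse** — per upstream-kinase signal category, the
   fraction of member peptides with score at or above a threshold
   `tau`.
5. **Differential comparison** — permutation test on the per-category
   fraction difference between the two conditions, BH-adjusted.

## The two-state calling model

Calling treats each reaction independently: no information is pooled
across replicates before scoring, so the downstream Markov score really
counts independent reactions.

Within one reaction, the corrected density of spot $p$ is
$c_p = \max(f_p - b_p, 0)$, foreground minus local background. The
corrected values of one array are modelled as a two-component Gaussian
mixture on the $\log(1+c)$ scale,

$$y_p = \log(1 + c_p), \qquad
  y_p \sim (1-\pi_1)\,\mathcal N(\mu_0, \sigma_0^2) +
  \pi_1\,\mathcal N(\mu_1, \sigma_1^2), \quad \mu_0 < \mu_1,$$

fitted by EM, and a peptide is called phosphorylated when its posterior
probability of the upper component reaches the decision threshold
(default 0.5; a posterior exactly at the threshold counts as a call, a
one-line rule that keeps the pipeline deterministic).

Two numerical choices matter and are worth stating precisely:

* **The zero atom.** Because correction floors at zero, every spot
  whose foreground does not exceed its local background lands exactly
  on $c = 0$ — routinely a third of a quiescent array. A point mass is
  not Gaussian: if the zeros enter the fit, one component collapses
  onto the atom (its variance hits any floor you set) and everything
  with $c > 0$ is called phosphorylated. Zeros are therefore
  *background by definition* — posterior 0 without reference to the
  model — and the mixture is fitted on the strictly positive corrected
  values, where it separates the background noise halo (spots whose
  foreground exceeds background by chance) from genuinely
  phosphorylated spots.
* **Determinism.** The fit is initialized at the 25th/75th percentiles
  of the data with equal weights and the pooled standard deviation, and
  stops when the relative log-likelihood change falls below $10^{-8}$
  (cap 500 iterations). The log-likelihood trace is asserted
  non-decreasing on every fit. Component standard deviations are
  floored at 0.1 log-units as a collapse safeguard; with zeros excluded
  the floor essentially never binds.

Degenerate inputs (all values identical, or fewer than 20 positive
spots) yield a single-state fallback in which every peptide is
background — an array that incorporated no signal should produce no
calls, not errors. A robust z-score rule
(`corrected > median + k * MAD`, default `k = 3`) is available as an
alternative calling method for data where a mixture is not
identifiable.

With unequal component variances the posterior is not monotone in
corrected density (the wide component can win again in the extreme
upper tail); with equal variances monotonicity is exact, and the test
suite checks precisely that. In practice the fitted upper component is
much tighter than the background one and the non-monotone region lies
far beyond the data.

## Markov scores and category fractions

The Markov score $M_p \in \{0, \dots, R\}$ counts reactions with a
positive call ($R = n_\text{bio} \times n_\text{tech} = 6$ by default).
Flagged bad spots yield `no_call` and shrink the per-peptide usable
count `n_called`; the invariant $0 \le M_p \le n_\text{called} \le R$
is enforced everywhere. Peptides with `n_called < R/2` are excluded
from category summaries — a score supported by fewer than half the
reactions is uninterpretable — and the exclusion is logged.

A category's fraction is
$f_c = |\{p \in c : M_p \ge \tau\}| / n_c$. The threshold `tau`
defaults to 4 of 6 — phosphorylated in a majority of reactions — since
the mapping from Markov scores to "counted phosphorylated" is a
reporting convention rather than a derived quantity; `tau = 1`
reproduces the alternative any-reaction reading, and both are exposed
as configuration.

## The permutation test

The observed statistic per category is $|\Delta_c|$ with
$\Delta_c = f_c^{(B)} - f_c^{(A)}$. The null distribution is built by
re-drawing category memberships uniformly over all categorized peptides
(preserving category sizes) and recomputing $|\Delta_c|$; the p-value
uses the add-one estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\}) / (1 + n_\text{perm})$, so
p-values are never zero, and BH adjustment is applied across
categories. The label permutation conditions on the observed
per-peptide call pattern, so it asks: *is this category's contrast
larger than a random group of categorized peptides of the same size
would show?*

This estimator is deliberately conservative. On a small layout the
fraction statistic is coarse (granularity $1/n_c$); whenever the
observed $\Delta_c$ is exactly 0 every permutation ties and $p = 1$.
Under a no-effect generator the p-value distribution is therefore
*valid* — $P(p \le \alpha) \le \alpha$, which the test suite verifies —
but visibly sub-uniform at desk scale: a strict Kolmogorov–Smirnov
uniformity check rejects it, and the acceptance suite records that
outcome honestly rather than switching to an anti-conservative
estimator to force uniformity.

## The synthetic-study generator

The generator exists so every stage can be validated against planted
ground truth without any data download. It emulates the two-genotype
MEF design: a 1024-peptide layout on four 16×16 blocks (the physical
grid of the original array is not published; the block convention is
ours), twelve 20-peptide signal categories (mTOR, p70S6K, AMPK,
Chk1/Chk2, PAK, PKA, PKC, CK2, GSK3, CDK, Src, CaMK2), and
knockout-side activation of the first five — the pathway set the
motivating study found elevated.

Intensities follow a multiplicative lognormal model:

$$f_{p,c,b,t} = \exp\!\big(\mu + e_p + \log m_{p,c} + B_{c,b,p} + T_{c,b,t,p}\big),$$

with baseline $\mu = \log 50$, per-peptide propensity
$e_p \sim \mathcal N(0, 0.25^2)$, activity multiplier $m$ (4 for active
peptides, 1 otherwise), biological noise
$B \sim \mathcal N(0, 0.15^2)$ drawn per spot but *shared across the
technical replicates of one lysate*, and technical noise
$T \sim \mathcal N(0, 0.08^2)$ per spot and reaction. Background is
i.i.d. lognormal $(\log 50, 0.25)$ per spot. Sharing $B$ within a
lysate is what makes technical replicates more concordant than
biological ones, reproducing the two distinct correlation levels a
replicated array study shows.

Parameter rationale, chosen once as a package default:

* A lognormal is the natural nonnegative model for phosphor-imager
  densities, which this analysis only ever reads through
  background-relative calls; any similarly heavy-tailed choice would be
  equally consistent.
* The activity multiplier 4 and 20-peptide categories are calibration
  conventions (configuration, never hard-coded).
* Baseline foreground is centred on the background distribution, so an
  inactive spot exceeds its local background only by chance — that is
  what makes "significantly more phosphorylated than background" a
  nontrivial question.
* The noise scales emulate a high-quality assay of the kind the
  motivating study reports (mean technical Pearson r ≈ 0.99, biological
  ≈ 0.94, both "well in excess" of the 0.85 gate) while keeping the
  two-state calling accurate to a few percent; a quarter of peptides
  outside planted categories are constitutively active (multiplier 4 in
  both conditions), so arrays are far from empty under the null.
* Constitutive activity is drawn from *all* peptides outside the
  planted categories, including members of unplanted categories. If
  unplanted categories could never contain active peptides their
  fractions would be identically zero and the permutation null could
  not be probed; real annotation groups always contain constitutively
  active substrates.

What the generator deliberately does **not** emulate: spatial artifacts
(scratches, gradients, edge effects), image-level segmentation error,
saturation of the phosphor-imager, or sequence-driven cross-reactivity
between categories. Passing tests therefore demonstrate that the
*computational* pipeline is correct and calibrated under its stated
noise model — not that the laboratory assay is free of spatial or
chemical artifacts.

## Reproducibility and problem sizes

Every stochastic entry point takes an explicit integer seed:
`generation_config(seed)` drives the layout draw and (offset by one)
the intensity draws, and `differential_categories(seed)` the
permutations. `run_all()` expands its single seed the same way
(simulation uses the seed, the permutation test seed + 1), so stage
reruns agree with full runs, and its manifest records configuration,
seed, package version and MD5 checksums of all inputs and outputs;
reruns are byte-identical.

The validation suite works at desk scale by design: full-size
1024-peptide studies for recovery and QC checks (20 seeds for the
concordance figure, 10 for planted-category recovery), 200 randomized
small instances per brute-force oracle, and 500 scaled-down 64-peptide
studies for null calibration. The scaled-down null probe uses a
deliberately call-discordant regime (constitutive multiplier 2 at 50%
prevalence, `baseline_log_sd = 0.1`, `sigma_bio = 0.7`,
`sigma_tech = 0.3`) chosen so the permutation statistic varies from
study to study; with well-separated defaults nearly every null study
returns $\Delta = 0$ and the calibration question is vacuous.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(outdir = "run1",
                  simulate = generation_config(seed = 7),
                  n_perm = 10000, seed = 7)
res <- run_all(cfg)
res$differential |> dplyr::arrange(q_value)
autoplot(res$differential)   # grey-scale category x condition tiles
autoplot(res$qc)             # replicate correlation heatmaps
```

## Known limitations

* The calling model is the minimal two-state realization of
  "significantly more phosphorylated than background"; the original
  array protocol's exact state analysis is not published in reusable
  form, and per-spot local correction followed by a global two-state
  fit is our interpretation. Whether the historical analysis used raw,
  corrected or log densities for its Pearson QC is equally unstated; QC
  here uses `log1p` foreground, which handles zero spots and precedes
  correction.
* Pairwise designs only: one comparison contrasts exactly two
  conditions.
* The permutation test conditions on calls; it does not propagate
  uncertainty from the mixture fit into the category p-values.
* Scale coherence of calls under a global intensity rescaling is exact
  on the log scale but only approximate through `log1p` for spots with
  corrected density near zero.
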