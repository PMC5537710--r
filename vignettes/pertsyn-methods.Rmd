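---
title: "Methods: from dose-response synergy to perturbed network connections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from dose-response synergy to perturbed network connections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pertsyn)
```

`pertsyn` chains five analyses that together take a two-drug combination
experiment from "is it synergistic?" to "which network connections did
the treatment rewire?". This vignette states each model, its
assumptions, the tunable parameters, and the numerical and design
choices made where the literature leaves room.

## 1. Median-effect synergy analysis

**Model.** Viability relative to untreated control defines the fraction
affected `fa = 1 - viability`. The median-effect equation
`fa/fu = (D/Dm)^m` (with `fu = 1 - fa`) is linear in log space:
`log10(fa/fu) = m log10(D) - m log10(Dm)`. `fit_median_effect()` runs
unweighted ordinary least squares on that plot; `m` (unitless) is the
slope, `Dm` (nM) the median-effect dose, i.e. the IC50. The linear
correlation `r` of the plot is reported as a quality flag, with a
warning below `r^2 = 0.9`, the conventional screen for this analysis.

**Assumptions.** Monotone dose-response; multiplicative (roughly
lognormal) assay noise; viability normalised to the control mean.
Viabilities are clipped to `[1e-4, 1 - 1e-4]` before the log-odds
transform so no point maps to infinity; at least 3 distinct dose levels
are required, and the informative design places doses so that `fa`
spans roughly 0.15–0.85 — outside that range the log-odds transform
amplifies noise and levers the slope.

**Combination index.** For a fixed-ratio mixture fitted on the
*total-dose* axis, the two-term (mutually exclusive) index at effect
level `fa` is `CI = sum_i (D)_i / (Dx)_i` where `(D)_i = ratio_i *
Dtot(fa)` and `(Dx)_i` comes from the single-agent fit. The two-term
form is used because the printed CI of the summary tables this package
models equals `sum(1/DRI)` to rounding; no third interaction term is
added. The dose reduction index is `DRI_i = (Dx)_i / (D)_i` and the
identity `CI = sum(1/DRI_i)` is exact by construction. The potentiation
factor `PF_i = IC50_single_i / (ratio_i * IC50_combo)` follows the
verbal definition (single-agent IC50 over that drug's dose within the
combination at the combined IC50); published PF values are not always
reconstructible from DRIs under a single definition, so PF is reported
but not used as a validation surface. Classification bands:
`CI <= 0.3` strong synergism, `(0.3, 0.9]` synergism, `(0.9, 1.1]`
additivity, `> 1.1` antagonism (the strong-synergism cutoff follows
CalcuSyn convention).

## 2. SAM differential expression

**Statistic.** For two unpaired classes,
`d_i = (mean_treat - mean_ctrl) / (s_i + s0)` with the pooled standard
error `s_i = sqrt((1/n1 + 1/n2)(SS1 + SS2)/(n1 + n2 - 2))`. The fudge
factor `s0` is chosen among percentiles of `s_i` (0 included) to
minimise the coefficient of variation of window-wise MADs of `d` across
ten `s_i`-quantile windows, the standard recipe for making the spread
of `d` independent of variance.

**Permutation null.** Group labels are permuted; when
`choose(n, n1) <= n_perm` all distinct ordered label assignments are
enumerated exactly once (identity included, the original convention),
otherwise `n_perm` assignments are sampled under the seed. The expected
order statistics `dbar_(i)` are means of sorted permuted `d`.

**Calling.** Genes are called past the first crossing of the
`|d_(i) - dbar_(i)| >= delta` band, scanning each side outward from the
centre of the quantile-quantile line; at `delta = 0` every gene is
called (boundary convention). The FDR estimate is
`pi0 * median_perm(#null beyond cuts) / #called`, with
`pi0 = min(1, 2 * Pr(d inside the null interquartile band))`.
`sam_choose_delta()` scans 200 evenly spaced deltas up to the largest
observed departure and takes the smallest delta whose *suffix-maximum*
FDR estimate (so every larger delta also qualifies) is at or below the
target — a monotonisation that cannot be gamed by a single noisy dip.
Fold changes are mean differences on the log2 scale; no fold-change
filter is applied.

## 3. Signaling pathway impact analysis

`pNDE` is the hypergeometric upper tail of the DEG count in the pathway
given the measured universe. Perturbation propagates through the signed
topology by `PF(g) = dE(g) + sum_u beta_ug PF(u)/Nds(u)`, solved as the
linear system `(I - B) PF = dE`; `Acc = PF - dE` and `tA = sum(Acc)`.
Edge weights: activation/phosphorylation/expression +1, inhibition −1;
binding/association and indirect edges default to +1 (they are treated
as live connections downstream, matching how perturbed-connection
tables report them) with a switch to 0. Nodes absent from the
expression matrix are dropped before propagation and degrees are
recomputed.

Numerical choices: a singular or near-singular `(I - B)`
(`rcond < 1e-10`, e.g. a two-node feedback loop) is damped by
`B <- 0.99 B` and re-solved, with a message; the observed `tA` and its
bootstrap null always use the same operator. `pPERT` reassigns the
observed non-zero `dE` values to random pathway positions
(`n_boot = 2000` by default, seed mandatory), median-centres the
bootstrap `tA`, and reports the two-sided exceedance fraction floored
at `1/n_boot`; exact floating-point ties are kept in the exceedance
count via a `1e-9` relative tolerance. `pG = c - c ln(c)` with
`c = pNDE * pPERT` (the Fisher-product tail), BH-adjusted across
pathways into `pGFdr` (Bonferroni available).

## 4. Module fusion and multigroup SEM

Significant pathways (`pGFdr < 0.05` by default) are fused by node/edge
union; duplicate typed edges collapse with provenance, conflicting
types for the same ordered pair are both kept. For every ordered DEG
pair, *all* minimum-hop directed paths are enumerated (edge types do
not affect path length) and the module is the union of their nodes and
edges; DEGs disconnected from every other DEG drop out.

**Path model.** Each node with module parents follows a linear
structural equation with Gaussian error and a free intercept; exogenous
nodes keep free mean and variance. The fit is equation-wise OLS — the
exact maximum-likelihood solution for acyclic modules and a
pseudo-likelihood approximation when the fused graph carries cycles
(flagged in output); whether the original multigroup analyses of this
kind fit a joint covariance ML or equation-wise models is generally not
recoverable from publications, and the equation-wise form is both
transparent and well calibrated. Intercepts are profiled out by
within-group centring, so planted or real differential-expression mean
shifts cannot leak into path coefficients.

**Standardisation.** Expression is z-scored per gene on the *combined*
sample (default `standardize = "global"`). Coefficients are then on a
standardised scale — comparable across edges, able to exceed 1 when
group variances differ — while the likelihood still sees between-group
variance differences. Z-scoring per gene *per group* (available as
`standardize = "group"`) pins each group's variance to 1 and makes the
likelihood-ratio test conservative by roughly a `(1 - rho^2)` factor
per edge, which is why it is not the default. Because a per-variable
affine map applied to both groups preserves both the free and the
constrained model family, the global-z LRT is identical to the raw-data
LRT and keeps its asymptotic chi-square calibration.

**Tests.** The free model fits coefficients per group; the constrained
model shares coefficients across groups while keeping group-specific
intercepts and error variances (profiled/iterated via reweighted least
squares). `LRT = 2(ll_free - ll_constrained)` is referred to chi-square
with one degree of freedom per constrained coefficient. Per edge, Wald
p-values per group and the difference test
`z = (b_t - b_c)/sqrt(SE_t^2 + SE_c^2)` are reported; difference
p-values are raw (as such tables conventionally print them) with a BH
column added. Nodes with more parents than `n - 1` fall back to a small
ridge penalty and lose their standard errors (flagged). Reported
`0.0000` p-values in published analogues of this table are read as
`p < 5e-5`, not exact zeros.

## 5. Methylation arm comparison

β-values (methylation fractions in `[0, 1]`) across four arms —
CTR, EV, AZA, EV+AZA — are compared by Kruskal–Wallis (tie-corrected,
via `stats::kruskal.test`) on observations pooled over the probe panel
(all probes × samples per arm), matching a joint test over a gene
panel; a per-probe mode exists behind a flag since the replication unit
is genuinely ambiguous for array designs with few samples. Dunn's post
hoc z uses pooled ranks with tie correction; the pair p-values are
BH-adjusted by default (Bonferroni available — Dunn's classic choice,
but BH matches the FDR logic used elsewhere in the pipeline). Array
preprocessing (background correction, normalisation, probe filtering)
is out of scope; inputs are assumed preprocessed.

## 6. What the synthetic data emulate — and what they do not

The generators are pure functions of a seed (bit-identical across runs)
and plant full ground truth:

- `sim_dose_response()` / `sim_combination()`: median-effect-shaped
  viability with multiplicative lognormal noise (sd 0.05 by default, a
  typical MTT replicate CV); combinations invert the CI definition so a
  chosen CI profile is the truth. Default single-agent parameters
  (`Dm = 6.3` nM, `m = 1` and `Dm = 46.7` nM, `m = 1.4`) are consistent
  with the printed IC25/IC75 working concentrations of the
  everolimus/AZA study this package models.
- `sim_expression()`: ~20k i.i.d. Gaussian background genes on the log2
  scale (default; tests use hundreds for speed), a planted 31-gene
  module (`ngfr_module_topology()`, patterned on the apoptotic
  NGFR–RAC1–MAPK10–TP53–BAX/BCL2 axis with PI3K-Akt, focal-adhesion and
  ECM neighbours) generated from linear structural equations with
  group-specific coefficients, mean-shift DEGs (2 log2 units by
  default), and n = 3/group by default as typical for array
  experiments.
- `sim_pathways()`: one host pathway containing the module plus decoy
  pathways of random signed edges, with a salted RNG stream so a shared
  base seed cannot align decoy membership with planted DEGs.
- `sim_beta()`: Beta-distributed β-values with arm means shifted −0.2
  in AZA-containing arms, emulating demethylating-agent action; 769
  probes over the module's gene panel by default.

Not emulated: probe-level microarray artifacts, batch effects,
correlated background genes, realistic methylation probe dependence,
IDAT-level preprocessing. Passing tests therefore demonstrate that the
algorithms are correct and calibrated under their stated models — not
that the models capture every property of real arrays.

## 7. Test and validation scale

The suite validates each stage against independent oracles: exhaustive
hypergeometric enumeration (universes ≤ 12), relaxed fixed-point
iteration for perturbation propagation (100 random DAGs and subcritical
cyclic graphs, agreement to 1e-8), a hand-written BFS/DFS
all-shortest-paths enumerator (50 random 30-node instances), and
closed-form standardised coefficients from the implied covariance.
Calibration runs use 20 seeds for SAM null/planted matrices
(1000 genes, n = 4/group), 200 seeds for SEM type-I and power
(n = 100/group), 100 seeds for sign-flip localisation (n = 150/group),
and 20 end-to-end pipelines (800 background genes, n = 200/group, eight
pathways) — sizes chosen to give stable Monte-Carlo estimates while
keeping the default test run in the low minutes.

One calibration limit is worth stating plainly: with n = 4/group and a
2-sigma mean shift, the non-centrality of any two-sample statistic is
about 2.8, while an FDR-0.05 threshold at 5% prevalence sits near 3.3 —
so no method can recover the large majority of planted genes under
those conditions, and SAM's measured recall there (~0.35, at realized
FDP ~0.04) reflects the information bound, not an implementation
defect. Recall rises with replication, not with tuning.

## 8. Known limitations

- The SEM stage is a pseudo-likelihood approximation on cyclic modules;
  fit indices (CFI/RMSEA) and latent variables are out of scope.
- pPERT inherits bootstrap granularity (`1/n_boot` floor); with the
  2000 default the smallest reportable value is 5e-4.
- The CI machinery covers two-drug fixed-ratio designs only; Bliss,
  ZIP, HSA and 3+-drug response surfaces are non-goals.
- KEGG XML parsing is not included; pathways enter via the GMT +
  typed-edge-list dialect documented in `read_pathways()`.
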