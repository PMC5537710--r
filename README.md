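# pertsyn

Quantifying drug-combination synergy and dissecting its transcriptional
mechanism, in one tested pipeline.

`pertsyn` is aimed at labs that screen two-drug combinations (for example
an mTOR inhibitor plus a demethylating agent in a cancer cell line) and
then ask *why* a combination is synergistic. It implements the complete
computational chain such a study needs:

1. **Median-effect synergy analysis.** Dose–response viability data are
   fit to the median-effect model `fa/fu = (D/Dm)^m`, where `fa` is the
   fraction of cells affected, `fu = 1 − fa`, `Dm` the median-effect dose
   (IC50) and `m` the sigmoidicity. For a fixed-ratio combination the
   two-term combination index at effect level `fa` is

   `CI = (D)_1/(Dx)_1 + (D)_2/(Dx)_2`,

   with `(D)_i` the dose of drug *i* inside the combination and `(Dx)_i`
   the single-agent dose giving the same effect. `CI < 1` indicates
   synergy, `= 1` additivity, `> 1` antagonism; the dose reduction index
   is `DRI_i = (Dx)_i/(D)_i`, so `CI = Σ 1/DRI_i` holds exactly.
2. **SAM differential expression.** Two-class permutation testing with
   the relative difference `d_i = (x̄_treat − x̄_ctrl)/(s_i + s0)`,
   automatic fudge-factor selection, and a delta threshold chosen to
   keep the permutation-estimated FDR below a target.
3. **Signaling pathway impact analysis (SPIA).** Per pathway, the
   hypergeometric over-representation probability `pNDE` is combined
   with the perturbation probability `pPERT` obtained by propagating the
   observed log2 fold changes over the signed, directed pathway topology
   (`PF(g) = ΔE(g) + Σ_u β_ug PF(u)/Nds(u)`) and bootstrapping the total
   accumulated perturbation `tA`. The combined `pG = c − c·ln(c)` with
   `c = pNDE·pPERT` is BH-adjusted into `pGFdr`.
4. **Module fusion + multigroup SEM.** Significant pathways are fused
   into one network; the module spanned by *all* directed shortest paths
   between differentially expressed genes is extracted; a linear
   structural-equation path model is fit per condition and coefficient
   equality is tested globally by likelihood ratio and per edge by Wald
   difference tests — yielding the list of perturbed connections.
5. **Methylation arm comparison.** Kruskal–Wallis across treatment arms
   on pooled β-values with Dunn post hoc tests and per-gene summaries.
6. **Synthetic data with planted truth.** Every input above can be
   generated with known ground truth (planted CI profiles, DEGs, module
   coefficients, demethylation shifts), so the whole chain is testable
   without any external download.

## Worked example

Fit two single agents and a 50:50 fixed-ratio combination generated
with a planted combination index of 0.25:

```r
library(pertsyn)
ev  <- sim_dose_response("EV",  m = 1.0, Dm = 6.3,  doses = 10^seq(-1, 2, 0.5),  noise_sd = 0, seed = 1)
aza <- sim_dose_response("AZA", m = 1.4, Dm = 46.7, doses = 10^seq(-0.5, 3, 0.5), noise_sd = 0, seed = 1)
f_ev  <- fit_median_effect(ev)
f_aza <- fit_median_effect(aza)
f_ev
#> Median-effect fit: EV
#>   m  = 1.0000 (slope)
#>   Dm = 6.3 nM (ED50)
#>   r  = 1.0000 (28 points)

combo <- sim_combination(list(list(m = 1.0, Dm = 6.3), list(m = 1.4, Dm = 46.7)),
                         ratio = c(0.5, 0.5), target_ci = 0.25, noise_sd = 0, seed = 2)
fa_ci_curve(fit_median_effect(combo), list(f_ev, f_aza), fa_grid = c(0.25, 0.5, 0.75))
#> Synergy report (3 effect levels):
#>    fa    ci dri_1 dri_2 pf_1 pf_2            label
#>  0.25 0.250  4.40  44.6 4.57 33.9 strong synergism
#>  0.50 0.248  4.57  33.9 4.57 33.9 strong synergism
#>  0.75 0.249  4.75  25.7 4.57 33.9 strong synergism
```

The report reads: at the 50% effect level the combination needs only
1/4.6 of the everolimus dose and 1/34 of the AZA dose that each drug
would need alone (`dri_1`, `dri_2`); the combination index 0.25
(recovering the planted value) falls in the strong-synergism band.

The expression arm runs the same way from files:

```r
run_all("expr.tsv", "groups.tsv", "pathways.gmt", "edges.tsv",
        out_dir = "out", fdr = 0.05, n_perm = 200, n_boot = 2000, seed = 1)
```

writing `sam.tsv`, `spia.tsv`, `module_edges.tsv` (the perturbed-connection
table: per-edge estimates and p-values for control, treatment and their
difference), `module_sem.json` (the global likelihood-ratio test) and a
`manifest.json` with seed and input checksums for reproducibility.

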