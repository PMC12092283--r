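---
title: "Molecular treatment effects in a repeated-biopsy trial: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular treatment effects in a repeated-biopsy trial: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddfx)
```

ddfx analyses randomized two-arm trials in which every patient contributes a
molecular profile (a bulk transcriptome of a kidney allograft biopsy, in the
motivating setting) at baseline and at two follow-up visits. The quantity of
interest throughout is the *interactive* treatment effect — the
difference-in-differences, written ΔΔ: how much more (or less) a score or a
gene changed under active treatment than it changed under placebo over the
same window. Conditioning on the placebo arm's time trend is what separates
a drug effect from regression to the mean, seasonal drift, or biopsy-protocol
effects.

## The models

**Score-level inference.** A gene-set score $Y_{ijk}$ (arm $i$, visit $j$,
patient $k$) is modelled as

$$Y_{ijk} = \mu + \mathrm{Arm}_i + \mathrm{Visit}_j +
  (\mathrm{Arm{:}Visit})_{ij} + b_k + \varepsilon_{ijk}, \qquad
  b_k \sim N(0, \sigma^2_{\mathrm{pat}}),$$

and the treatment effect is the arm-by-visit interaction. Because molecular
scores are bounded, skewed and often bimodal, the test is nonparametric: the
aligned-rank transform (ART). For each effect, the estimated cell-mean
contributions of all *other* effects are subtracted from every observation
(the alignment), the aligned values are ranked with average ties, and the
full factorial mixed model is refit by REML on the ranks; only the target
effect's F-test is interpreted, with Satterthwaite denominator degrees of
freedom. `art_anova()` additionally logs the largest off-target F on each
aligned column (`$alignment_check`) — a standard sanity check that the
alignment stripped what it was supposed to.

Pairwise comparisons among the six arm-by-visit cells use the
aligned-rank-contrast variant: the two factors are concatenated into one
six-level factor, the response is aligned and ranked for it, and all 15
pairwise contrasts are taken on that single-factor mixed fit
(`interaction_contrasts()`). Contrasts across factor combinations computed
on the *per-effect* aligned columns are known to be invalid, which is why
the concatenated-factor route is used. The three
difference-in-differences windows (baseline→week 24, week 24→week 52,
baseline→week 52) are computed as interaction contrasts on the same fit and
flagged `primary`; BH-FDR is applied within the 15-pair family and within
the 3-window family separately. Note the pairwise scale is aligned ranks,
so estimates are interpretable in rank units, not score units.

**Trajectories.** For injury-type scores the visit factor is replaced by
continuous time (weeks 0/24/52) and `fit_mixed_slopes()` fits
`score ~ arm * week` with a per-patient random intercept and slope (REML).
Per-arm slopes with 95% CIs come from the estimated marginal trends; the
arm-by-week interaction is the formal test. Random-slope fits that are
singular — common with only three time points — fall back to a random
intercept, and degenerate (e.g. noise-free) data fall back to OLS; the
downgrade is recorded in `$downgraded` rather than hidden. All mixed-model
degrees of freedom in the package are Satterthwaite; Kenward–Roger is
deliberately not used (it is slower, fragile on near-singular fits, and the
two agree closely at this design size).

**Omnibus test.** `omnibus_permanova()` asks whether a whole *category* of
scores (e.g. all rejection-activity scores) differs among groups: PERMANOVA
on Euclidean distances in score space. Permutations are free by default;
the repeated-measures structure is ignored there, which is a caveat worth
knowing — a patient-blocked mode (`strata = patient`) is provided for
sensitivity analysis. p = (1 + #{permuted F ≥ observed}) / (1 + n_perm), so
p can never be smaller than 1/(n_perm+1).

**Gene-level ΔΔ.** Genome-wide testing restricts to the most variable genes
by interquartile range (`iqr_filter()`; the kept count is dataset
configuration — there is no universal cutoff), then fits, per gene, an
ordinary least-squares model with the six arm-by-visit cell means plus a
slope for the biopsy's cortical fraction (%cortex), a tissue-composition
nuisance: medullary tissue expresses a different program, and biopsy cores
vary in how much cortex they sample. %cortex is centered so the cell means
are interpretable at the average composition. On the complete 60-sample
design the residual df is 60 − 7 = 53. The window contrast is

$$\Delta\Delta\mathrm{FC}_{b\to 24} =
 \tfrac{1}{2}(\mathrm{Felz}_{24} - \mathrm{Felz}_{0}) -
 \tfrac{1}{2}(\mathrm{Placebo}_{24} - \mathrm{Placebo}_{0}),$$

reproducing the halved convention of the motivating analysis exactly
(`scale = FALSE` gives the plain difference-in-differences; the halved form
is the default so reported numbers match that convention). The three
windows telescope: the full-period contrast equals the sum of the two
sub-windows, a property the tests assert at 1e-12.

Per-gene variances are moderated by empirical Bayes: the prior
$(d_0, s_0^2)$ is estimated by trigamma moment-matching on $\log s^2$
(`limma::fitFDist`), the posterior variance is
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, and the moderated t has
$d_0 + d$ degrees of freedom. Genes are *ranked by uncorrected p* — the
reporting convention of the motivating study for a 20-patient trial, where
FDR-significant genome-wide hits are not expected — with BH-FDR still
reported per gene. Genes whose baseline values already differ between arms
(Welch t, p < 0.05 — the test is a package choice; the threshold is the
published one) are flagged and excluded from interpretation outputs, but
never removed from fitting or hyperparameter estimation.

One calibration subtlety: patient random intercepts cancel exactly in the
within-patient ΔΔ contrast, but the per-gene OLS residual variance still
absorbs them, so under patient heterogeneity the moderated p-values are
*conservative*, not anti-conservative. The test suite checks uniformity of
null p-values under the iid-noise generator and conservativeness under the
patient-effect generator.

**Gene-set derivation.** Four selective sets are derived from a reference
cohort carrying per-sample rejection-archetype scores plus a cell panel
(NK cells, unstimulated and IFNγ-stimulated HUVECs; one log2 summary value
per gene per condition):

* activity set: top 20 genes by Spearman correlation with the
  early-rejection score;
* IFNγ-inducible set: top 100 by that correlation, kept if rho > 0.2, then
  a fivefold cell filter;
* NK-expressed set: top 100, drop genes above the panel median in either
  HUVEC condition, keep the top 20 by NK expression;
* endothelial set: top 100 by the fully-developed-rejection score, kept if
  unstimulated HUVEC expression exceeds NK expression fourfold (log2
  difference ≥ log2 4, boundary inclusive).

Three rules here are genuinely ambiguous in prose and are pinned as
follows. (1) The fivefold sentence for the IFNγ set does not say which
HUVEC condition is the numerator; the default reading is *IFNγ-inducible
and not NK-expressed* (stimulated HUVEC ≥ 5× NK **and** ≥ 5× unstimulated
HUVEC), with the alternate reading (both HUVEC conditions ≥ 5× NK) behind
`mode = "huvec_over_nk"`. (2) "unstimulated and IFNγ-stimulated HUVEC
expression >50th percentile" under negation: the default drops a gene if
*either* condition exceeds its median (conservative against endothelial
contamination); strict-AND is `exclude = "both"`. (3) All fold filters are
inclusive at the boundary, percentiles are linear-interpolation (type-7)
quantiles over the full panel, and every sort breaks ties lexicographically
by gene id — determinism is a contract, and tests assert that monotone
per-gene transforms leave every selection unchanged.

The injury ontology is mechanical: from a marker table of (gene,
cell_state, state_class), keep only injury-induced (`New`) cell states, one
set per state plus one collated union for enrichment.

**Scoring.** A gene-set score is the mean over member genes of the per-gene
log2 difference from a control reference (equivalently, log geometric mean
fold change) — the convention of the pathogenesis-based transcript-set
literature, whose defining papers give the construction rather than a
closed formula. The control is pluggable because the historical control
cohort of the motivating platform is not reproducible here; without one,
genes are centered at the cohort mean, which leaves all within-trial
contrasts unchanged (scores are then relative to the average biopsy).
Set genes missing from a matrix are dropped with a warning, not an error:
real set lists always contain platform-absent genes.

**Enrichment.** Two modes, because cutoff-based and rank-based enrichment
answer slightly different questions and the motivating analysis used the
former while discussing the latter as the alternative. `ora_hypergeometric()`
tests p < 0.05 gene lists (split by ΔΔ sign) against each library term with
a one-sided hypergeometric upper tail, BH within library.
`gsea_rank()` is a weighted Kolmogorov–Smirnov running sum on the full
ranking with a *gene-permutation* null, NES normalized by the same-sign
null mean, p from the same-sign tail with +1 smoothing. Public ontologies
are consumed only as user-supplied GMT files — shipping a snapshot of GO or
KEGG would pin an arbitrary database version; the packaged default is the
synthetic injury ontology.

## What the generator emulates, and what it does not

The synthetic module generates (i) a reference cohort in which activity
genes load on a latent early-rejection score and endothelial genes on a
fully-developed-rejection score, with loadings calibrated through the
Gaussian Spearman relation $\rho_s = \tfrac{6}{\pi}\arcsin(\rho_p/2)$;
(ii) a cell panel in which each planted class clears its filter by a
configurable log2 margin, and cross-cell-type baselines share a common
per-gene level (large fold differences between cell types are rare by
chance, as in real panels); and (iii) trials from the additive model
*baseline + patient intercept + planted arm-by-visit class effect + %cortex
slope + noise*, with injury genes following linear per-week trends.

Default study conditions: 2 arms × 10 patients × 3 visits (the 60-biopsy
design); planted ΔΔ of −1.0 log2 on both activity classes at week 24 with
partial rebound (−0.3) by week 52 and −0.5/−0.4 on the endothelial class;
injury slopes −0.01 log2/week under treatment and +0.005 under placebo
(signs mirroring the motivating trial's injury trajectories; magnitudes
chosen as a moderate effect over 52 weeks, ~0.5 log2 total); patient SD
0.5 and residual SD 0.3 log2 — typical between-patient and replicate-level
spreads for bulk microarray data; %cortex uniform on [40, 100] with a
zero cortex slope except for a 10% "medulla-sensitive" gene fraction.

Deliberately not emulated: probe-level data and normalization, batch
effects, missing visits, inter-gene correlation beyond the latent scores
(a `gene_cor` knob exists but defaults to 0 because the real correlation
structure is unknown), heavy-tailed noise, and classifier scores that
require proprietary training cohorts. Passing tests therefore demonstrate
that the *statistical machinery* is correct and calibrated under the stated
model — not that the model captures every feature of real biopsy data.

## Numerical choices and problem sizes

Seeds parameterize every stochastic step and are recorded in outputs;
identical seeds give bit-identical artifacts (pipeline result tables are
written at 10 significant digits, below which REML optimizer noise lives).
Constant genes get a Spearman correlation of 0 rather than NA. Degenerate
inputs fail loudly: constant responses, constant score matrices, empty
factorial cells and rank-deficient designs are errors, not warnings.
PERMANOVA in the bundled demo config uses 10^4 permutations (the motivating
study used 10^6; the floor of p ≈ 1e-4 is ample for a demo); tests use
what each check needs. Calibration checks use 1000 null simulations of the
full design for the ART interaction (type-I error asserted within
[0.03, 0.07] at α = 0.05), 100 seeds for slope-sign recovery, and 20 for
ΔΔ-bias recovery (bias < 5% of the planted effect); these sizes put
Monte-Carlo error comfortably below the asserted bands while keeping the
suite fast.

One property often *expected* of rank methods does not hold for ART and is
intentionally not asserted: invariance under arbitrary monotone transforms
of the response. The alignment step is linear-scale arithmetic, so only
affine invariance holds (and is tested); the pure rank-based selections in
the gene-set module are fully monotone-invariant (also tested).

## A worked run

```{r demo, eval = FALSE}
cfg <- default_config(outdir = "run", seed = 1)
cfg$simulate <- list(n_genes = 800, n_per_arm = 10, ref_samples = 300)
cfg$dge$iqr_keep <- 400
manifest <- run_pipeline(cfg)

scores <- readr::read_tsv("run/score_table.tsv")
fit <- art_anova(scores, "abmr_activity")
tidy(fit)
interaction_contrasts(fit)
autoplot(fit_mixed_slopes(scores, "aki_injury_all"))
```

## Limitations

Scores in, inference out: the package does not normalize raw arrays, does
not train classifiers, and takes archetype scores as given inputs. The
PERMANOVA default ignores patient blocking. The ART pairwise contrasts are
on the rank scale. Enrichment against public ontologies reproduces only
what the user's GMT snapshot contains. And all recovery guarantees are
statements about the generator's additive Gaussian world.
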