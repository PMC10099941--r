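---
title: "Methods: models, parameters and design choices in allohybrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in allohybrid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The experimental design

`allohybrid` analyzes the factorial design that separates the two components
of allopolyploidization: interspecific hybridization and whole-genome
duplication (WGD). Seven groups — the diploid parents `Co2` and `Cg2`
(maternal *C. orientalis*-like parent P1 and *C. grandiflora*-like parent
P2), their diploid hybrid `F2`, the autotetraploids `Co4` and `Cg4`, and
allotetraploids produced doubling-first (`Allo-d`) or hybridization-first
(`Allo-h`) — are each represented by 6 independent lines. One individual per
line is sequenced in two tissues (7 × 6 × 2 = 84 expression samples) and 6
individuals per line are phenotyped (7 × 6 × 6 = 252 plants). Hybrid state
and ploidy are pure functions of the group label, so the design embeds a
2 × 2 hybridization × WGD factorial (with `F2`/`Allo-*` hybrids and the
`*4` groups tetraploid) inside a one-way seven-group layout.

# The count model

Counts are read pairs per feature (gene or TE) per sample. Within a tissue
the model is negative binomial with a log link,

$$\log \mu_{gs} = \beta_{g,\mathrm{group}(s)} + \log(\hat N_s), \qquad
  \mathrm{Var}(y_{gs}) = \mu_{gs} + \phi_g \mu_{gs}^2,$$

where $\hat N_s$ is the TMM-effective library size (column sum × TMM
factor). This is the standard `~ 0 + group` parameterization: one abundance
per group per gene, all seven groups fitted jointly so dispersion
information is pooled across the design.

**Dispersion estimation.** The group intercepts are profiled out by a
vectorized Newton iteration (score $\sum_s (y-\mu)/(1+\phi\mu)$, expected
information $\sum_s \mu/(1+\phi\mu)$). The per-gene profile likelihood is
evaluated on a log2-spaced grid of dispersions ($2^{-14}$ to $2^4$ in half-
log2 steps) with a Cox–Reid adjustment of $-\tfrac12 \log \mathcal I$ per
group parameter, which removes most of the downward small-sample bias of
plain profile ML; the per-gene maximum is refined by quadratic
interpolation, and a maximum at the lower grid boundary is reported as
dispersion 0. The common dispersion maximizes the summed profile
likelihood. The working dispersion is the weighted combination
$(d_0\,\phi_{\text{common}} + \mathrm{df}\,\phi_g)/(d_0 + \mathrm{df})$
with prior df $d_0 = 10$ — enough shrinkage to stabilize 6-per-group
estimates without erasing genuine per-gene variation. In simulations with
known truth (42 samples, 7 groups) the median estimate for a true
dispersion of 0.1 falls within a few percent of 0.1, and Poisson data
collapse below 0.02.

**Testing.** A pairwise contrast between groups A and B is a
likelihood-ratio test of a shared abundance versus separate abundances on
the A ∪ B samples, dispersion held fixed; the statistic is referred to
$\chi^2_1$. With dispersion forced to zero this reduces exactly to the
two-group Poisson deviance test, which the test suite verifies to 1e-6.
The log2 fold-change is computed from the fitted abundances in CPM units
with the configured prior count (default 0.5) added to both sides — this
keeps genes expressed in only one group finite — and capped at ±20.

**Fold-change threshold and FDR.** A gene is differentially expressed when
FC > 2 and BH-adjusted FDR < 0.05. The fold-change condition is applied
*before* the BH step: p-values are computed for all genes, the BH
adjustment runs within the subset with |log2FC| > 1, and calls are made in
that subset (`fdr_mode = "subset_then_bh"`). The alternative order —
adjust everything, then filter by FC — is available as
`"bh_then_filter"`. The subset mode matches the described workflow but is
only trustworthy after the expression filter: among very low-count genes a
|log2FC| > 1 arises by chance and the selection correlates with small
p-values, so the subset loses its FDR guarantee. At the design's
sequencing depth (≈ 2 × 10⁷ read pairs) the `TPM > 2 in ≥ 3 samples`
filter leaves genes whose null fold-change noise almost never reaches the
threshold, and two identically distributed groups yield a median of zero
DEGs across seeds — the computable analogue of the near-absence of
diploid-vs-autotetraploid DEGs in this design.

# The ten expression categories

For each gene of a hybrid group, three contrast statuses (each
up/down/ns) form the triple (hybrid vs P1, hybrid vs P2, P1 vs P2). The
decision table is total on the 27 ordered triples and produces exactly ten
labels:

| pattern | label |
|---|---|
| (up, up, ·), (down, down, ·) | transgressive up / down |
| (ns, up, up), (ns, down, down) | complete ELD toward P1, high / low |
| (up, ns, down), (down, ns, up) | complete ELD toward P2, high / low |
| (up, down, down), (down, up, up) | additive (strict intermediate) |
| (ns, ns, ns) | no change |
| (ns, ns, up/down) | unresolved parental difference |
| remaining 12 | ambiguous |

Complete ELD means the hybrid is statistically indistinguishable from one
parent while differing from the other in the direction of the parental
difference; transgression means the hybrid exceeds both parents in the
same direction; the additive label demands significance against *both*
parents in opposite, parentally consistent directions (a strict reading of
"intermediate"). Status patterns that are internally inconsistent —
possible under test noise, e.g. the hybrid "above" the higher parent but
"equal" to the lower — are reported as ambiguous rather than silently
dropped. The table lives in a single constant
(`allohybrid:::CLASSIFICATION_TABLE`) so an alternative category scheme
can be swapped in without touching the classifier; classification depends
only on statuses, never on magnitudes, and swapping the parents maps the
ELD labels onto each other while fixing every other class (a property the
tests enumerate).

Because the categories inherit the FC > 2 threshold, recovery of a
configured ELD truth is only exact when the effect sizes clear the
threshold: an additive gene whose parents differ by just 2-fold sits
1 log2 unit from either parent — exactly at the cut — and flips between
"additive" and "ELD" with estimation noise. The recovery tests therefore
use parental |log2FC| ≥ 3, placing midparent expression 1.5 log2 units
from each parent; under those conditions the recovered complete-ELD
proportion tracks the truth within a fraction of a percentage point.

# The synthetic generator

The generator produces the full design from one `simulation_config()`:

* **Baseline abundance** per gene: log2-normal, mean 4, sd 2; a per-gene
  tissue offset (sd 1 log2 unit) makes tissue the dominant axis of
  variation, as it is in real ordinations.
* **Parental divergence**: a fraction `pi_ped` (default 0.25) of genes is
  parentally differential, with log2 fold-changes drawn from N(0, 1.5)
  truncated to |logFC| ≥ 1, split symmetrically around the baseline.
* **Hybrid modes**: `hybrid_mode_fractions` is a simplex over {additive,
  ELD_P1, ELD_P2, TRE_up, TRE_down, conserved} applied **to the parentally
  differential genes** (dominance and transgression presuppose a parental
  difference; non-PED genes are all "conserved"). Additive genes take the
  midparent log2 mean exactly; ELD genes take one parent's mean;
  transgressive genes exceed the more extreme parent by `tre_shift`
  (default 1.5 log2 units). A PED gene drawn "conserved" also takes the
  midparent value — additivity is the biological null — so "additive" vs
  "conserved" differ only as bookkeeping labels, and the defaults (17%
  additive, 3% ELD each side, ~0.01% TRE) reproduce dominance at a few
  percent of genes with transgression vanishingly rare.
* **WGD null**: by default `wgd_effect_fraction = 0`, so the expected
  expression of `Co4` equals `Co2`, `Cg4` equals `Cg2`, and both
  allotetraploids equal `F2` — relative expression is untouched by WGD.
  This is the generator's encoding of the design's central contrast, and
  it is breakable (`wgd_effect_fraction`, `wgd_logfc`) for sensitivity
  analyses.
* **Counts**: each sample's library size is lognormal (median 2 × 10⁷ read
  pairs, sd 0.15 on the log scale) and is allocated **multinomially** over
  gamma-perturbed feature weights (shape 1/φ per feature, per-gene φ
  lognormal around 0.05). Marginally each count is negative binomial with
  the configured dispersion to excellent approximation, while the sample
  total equals the drawn library size exactly — independent NB draws would
  not conserve totals, which the downsampling and TE-proportion stages
  rely on.
* **TE features**: `n_te` features with class labels drawn from
  `te_class_weights` and lognormal per-feature weights; each sample's
  expected TE read share equals its lane's `te_fraction` (defaults 5.3%,
  1.5%, 4.8% — one conspicuously low lane), with lanes assigned in a
  balanced block: lines 1–6 map to lanes 1,2,3,1,2,3, so every group ×
  tissue has two samples on each lane and the lane effect is orthogonal to
  the biology.
* **Phenotypes**: per-flower pollen viability is binomial (≥ 300 grains
  per flower, two flowers summed per individual) with beta-binomial
  overdispersion ρ = 0.02, around a group-viability map whose defaults
  (parents ≈ 0.97–0.99, synthetic groups 0.81–0.91) build in the
  hybridization × WGD interaction: WGD lowers viability in non-hybrids but
  not hybrids. Normal-seed proportions (totals Poisson, 10 fruits × ~20
  seeds) work the same way (hybrid defaults 0.57/0.70/0.78 for
  F2/Allo-d/Allo-h; non-hybrid values are the implementer's choice of the
  same order as the parents' viability). Stem length, flowering time and
  pollen count are normal around group means ordered parent < hybrid <
  parent with a tetraploid offset.

What the generator does **not** emulate: genomic position (TEs have no
loci, so no insertion-level analyses), homeolog-resolved expression (total
expression of both homeologs, as in the upstream counting), within-line
pedigree structure (a line random effect is exposed but defaults to
σ = 0 since variance components are not part of the design's defaults),
GC/length biases, and batch effects on *gene* expression (lane affects
only the TE share). Passing tests on synthetic data therefore validate
the statistical machinery and its calibration, not robustness to those
real-data artifacts.

# Statistical engines

* **One-way ANOVA / Tukey HSD**: classical decomposition via `lm`;
  pairwise comparisons from the studentized range (Tukey–Kramer when
  unbalanced); the compact letter display uses the insert-absorb
  algorithm, deterministic with groups ordered by descending mean. Letters
  are a pure function of the pairwise significance matrix (tested by brute
  force).
* **Quasi-binomial GLM**: binomial-logit fit on numerator/denominator;
  dispersion φ = Pearson χ²/df from the full model, so coefficients equal
  the plain binomial fit and SEs scale by √φ exactly. Term tests are
  type II analysis-of-deviance F-tests — each term tested against the
  model containing every term that does not contain it, F = (ΔDev/Δdf)/φ —
  matching the conventional car-style output to machine precision in the
  cross-checks. Type III is available by flag; the two differ only with
  interactions and unbalanced data. Summing the two flowers of an
  individual (rather than averaging proportions) keeps the binomial
  denominator honest.
* **Extreme ranks**: ties are broken by a seeded random permutation,
  making ranks a strict total order, so every gene contributes exactly one
  rank-1 and one rank-N extreme (the conservation identity
  Σ n_low = Σ n_high = G holds exactly) and the exchangeable-null mean per
  individual is exactly 2G/N. A "drop tied extremes" mode exists for
  sensitivity analysis; it breaks conservation by construction.
* **Leading-logFC MDS**: the distance between two samples is the RMS of
  their top-500 squared log2-CPM differences (genes re-ranked per pair,
  prior count 0.5); classical (Torgerson) scaling embeds the matrix, and
  exactly Euclidean inputs are reproduced to numerical tolerance. Axis
  signs are indeterminate.

# Numerical choices and degenerate inputs

* TMM: reference sample = upper-quartile/library-size ratio closest to
  its mean; trims 30% (M) and 5% (A); genes zero in either sample
  excluded; a sample sharing no expressed genes with the reference gets
  factor 1 with a warning; factors rescaled to geometric mean 1. Scaling
  a column only perturbs the inverse-variance weights, so factors move by
  well under 1%.
* Strict inequalities in both expression filters (`> 2`, `> 1`): a gene
  exactly at the threshold is excluded.
* Newton iterations start from `log((Σy + 0.5)/Σ N̂)`, cap steps at ±5,
  and stop at step < 1e-12; all-zero groups get log-abundance −30 (zero
  mean) rather than −∞.
* Downsampling: per-cell binomial thinning with keep probability
  `target/group-mean`, capped at 1, seeded; an all-equal design takes the
  probability-1 branch and returns the input unchanged.
* All-zero samples in TPM yield a zero column with a warning, not a
  division error; all-zero genes are flagged and excluded from testing.
* Pipeline stage seeds derive from the global seed as
  `(seed × 10007 + 101 × stage) mod (2³¹ − 1)`, so stages are individually
  reproducible and disabling one never changes another's stream.

# Scope decisions

* The spec-level command-line surface is provided as the package's
  exported functions plus `run_pipeline()` and a thin `Rscript` wrapper
  (`inst/cli/allohybrid.R`); an R analysis package's natural interface is
  its functions and this vignette.
* Group-mean downsampling is implemented as binomial thinning toward the
  smallest group-mean library size — the simplest scheme that equalizes
  average depth across groups; it is a reconstruction of that goal, not of
  a specific script.
* BH is applied per contrast (standard practice when contrasts are
  reported separately); the choice is recorded in the result's metadata.
* Mixed models with line as a random effect are out of scope; the
  fixed-effect ANOVA/GLM layer mirrors the analyses the design calls for.

# Simulation sizes used by the test suite

The acceptance-style tests run at the sizes their claims are stated for:
the null-DE property at 10,000 genes × 6 + 6 samples over 20 seeds; ELD/TRE
recovery on a 10,000-gene single-tissue design (42 samples); type-I
calibration of the quasi-binomial interaction F-test and the Tukey
family-wise error at 1000 replicates; interaction power at 200 replicates
of the full 252-plant phenotype design; the TE lane analysis at 100
replicates of a reduced (250 gene + 60 TE) matrix, which leaves the
proportion structure untouched; and the extreme-rank null at 5000 genes ×
42 individuals over 20 seeds. Unit tests use smaller fixtures chosen to
keep every oracle comparison exact.
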