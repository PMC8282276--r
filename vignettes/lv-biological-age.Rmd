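---
title: "Methods: biological-age transcriptomics of the left ventricle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biological-age transcriptomics of the left ventricle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvbioage)
```

## The problem

Chronological age (CA) is a poor clock for an organ: two donors of the same
calendar age can carry left ventricles (LV) in very different physiological
states. `lvbioage` implements a transcriptomic route to *biological age*
(BA) for bulk LV RNA-seq and the downstream analyses that BA enables:
validating the markers against a fibrosis phenotype, finding BA-related
miRNAs and the target genes they plausibly repress, assembling those into a
cardiac regulatory network, and asking how heart-enriched the regulators
are across a tissue panel.

Two BA proxies are computed per donor:

* **CDKN2A expression** — the log2 normalized expression of the
  CDKN2A/p16 senescence locus, a one-gene marker that travels well across
  cohorts;
* **AppAge** ("apparent age") — a many-gene transcriptional index defined
  below, more sensitive but cohort-dependent.

## The AppAge model

For each gene `g` passing a screen, expression is calibrated linearly on
chronological age across the cohort:

```
x_g = beta0_g + beta1_g * age + eps,  eps ~ N(0, sigma_g^2)
```

`fit_appage()` performs the per-gene least-squares fits and keeps genes
whose slope is significant at a Benjamini–Hochberg FDR (default 0.05; with
a real transcriptome this screen yields age-gene sets in the
low-thousands, in line with published transcriptional-age work). The
apparent age of sample `i` is then the precision-weighted least-squares
inversion of all retained calibrations: with `w_g = 1/sigma_g^2`,

```
AppAge_i = sum_g w_g beta1_g (x_ig - beta0_g) / sum_g w_g beta1_g^2
```

which is the unique minimizer over `a` of
`sum_g w_g (x_ig - beta0_g - beta1_g a)^2`. The test suite requires this
closed form to agree with a brute-force grid search on that objective to
within 0.01 years on every sample. Numerical guards: `sigma_g` is floored
at `1e-6` so noiseless fixtures keep finite weights; rescaling every
`sigma_g` by a common factor provably leaves AppAge unchanged (the weights
cancel), which is also tested. An optional affine rescaling to the
calibration cohort's CA mean/sd exists but is off by default — the raw
inversion is already in years and rescaling would hide calibration bias.

## Normalization

`normalize_expression()` implements counts-per-million followed by
`log2(x + 1)`. Gene length is deliberately outside the data model, so no
RPKM/TPM is attempted: every statistic in the package is rank-based
(Spearman, Mann–Whitney) and therefore invariant to any per-sample
monotone rescaling, making CPM a faithful stand-in. The pseudocount of 1
is zero-preserving and standard. Both the expression threshold and sample
fraction of `filter_low_expression()` are arguments, since low-expression
filters vary between cohorts.

## Cohort structure and the overlap statistic

`hierarchical_split()` clusters samples on the whole normalized
transcriptome with correlation distance (1 − Pearson) and average linkage
— the scale-robust default for transcriptome sample dendrograms — and cuts
at the root into the two earliest-separated branches. Both choices are
arguments.

`distribution_overlap()` quantifies how well the unsupervised split
separates an age marker: one Gaussian kernel density per group, Silverman
rule-of-thumb bandwidth, evaluated on a shared 512-point grid spanning the
pooled range padded by three bandwidths; the overlap is
`100 * sum(min(f1, f2)) * dx`. These grid constants make the statistic
bit-reproducible given the inputs. Each density integrates to 1 within
`1e-3` on its grid (tested). A degenerate (constant-within-group) marker
is an error rather than a silent zero-bandwidth density.

The estimator's accuracy is checked against the closed-form overlap of
N(0,1) and N(1,1), `100·2·Φ(−1/2) ≈ 61.7%`. The test plants the two
normals with quantile-spaced values (`qnorm((i−0.5)/n)`) rather than
random draws: at n = 200 the overlap of *random* samples fluctuates with
an sd of about 4 points, so a random-draw check would measure sampling
noise, not the estimator. With planted quantiles the observed 63.4% is
pure kernel-smoothing bias and deterministic.

## Fibrosis from H&E histology

H&E stains the extracellular matrix (ECM) light pink and myocytes dark;
`quantify_fibrosis()` turns that color contrast into an area fraction:

1. tissue vs near-white background by mean-RGB luminance (default
   threshold 0.9);
2. optical densities deconvolved with the standard Ruifrok–Johnston
   hematoxylin/eosin vectors (overridable for other stain batches);
3. Otsu threshold on the per-pixel eosin ratio `cE/(cE + cH)`; ECM pixels
   must also be brighter than `ecm_min_luminance` (default 0.5, "light
   pink vs dark");
4. a 3×3 majority vote, then a morphological opening (radius 1 px).

Two numerical choices deserve notice. First, Otsu *always* splits, even a
pure-class image; when the two candidate classes' mean ratios differ by
less than `min_separation = 0.25` the tissue is treated as single-class
and assigned by whether its mean ratio exceeds 0.5. The 0.25 default sits
between the within-class ratio spread observed under texture noise
(≈ 0.18 for bright ECM, whose optical densities are small and hence
directionally noisy) and the between-class separation (≈ 0.34). Second,
the majority vote: pixel-level classification noise is symmetric, and
without the vote, noise pinholes make the opening erode thin ECM strands
from their ragged edges (a −2 to −4 point bias at high fractions), while
hole-closing alternatives bridge adjacent strands (+4) — the majority
filter is the unbiased cleanup. Mean absolute error against ground-truth
masks is ≈ 0.7 points over ECM fractions 0.05–0.6, within the 2-point
design bound, and the estimate moves < 1 point under 2× nearest-neighbor
rescaling.

Note the estimate is *ECM area*, not collagen specifically — H&E does not
distinguish collagen within the matrix, so "fibrosis" here means matrix
expansion.

## Differential expression, DEG overlap, GSEA

`de_genes()` compares two marker bins per feature with a two-sided
Mann–Whitney test (exact p-values whenever `wilcox.test` can provide
them; the suite checks exact agreement with full enumeration of rank
splits for group sizes ≤ 8), BH-adjusts across features, and requires a
nonzero difference of group medians for a direction call.
`deg_overlap()` is direction-aware: a gene recovered with the opposite
sign counts as a miss.

`preranked_gsea()` is the classic weighted Kolmogorov–Smirnov running
sum: hits step up by `|score|^p` normalized over the set (default
`p = 1`), misses step down by `1/(N − |S|)`, ES is the maximum signed
excursion. The null permutes *set membership* (seeded), not sample
labels: it is deterministic at desk scale and is the natural null for a
pre-ranked list with no sample-level exchangeability to exploit. NES
divides ES by the mean |null ES| of matching sign; the nominal p is the
matching-sign permutation tail with the +1 correction; FDR is BH across
sets within each ES sign (simpler than the Broad NES-ratio FDR and
conservative at these set counts). The ES implementation is tested
against a hand-traced running sum and against an independent
implementation (`fgsea::calcGseaStat`) where available, and satisfies the
rank-test identities: at `p = 0` it is invariant to strictly monotone
score transforms and negates under ranking reversal.

## BIO-AGEmiRNAs and mirror targets

A miRNA is BA-related (`identify_bioage_mirnas()`) when it is (i)
differentially expressed between the biologically youngest (P20) and
oldest (P100) CDKN2A fifths and (ii) Spearman-correlated with CDKN2A
across all samples, both at BH FDR 0.05; its direction is the correlation
sign. Quintile bins are rank-based with ties broken by sample-id order
(documented because marker ties are possible) and remainders allotted to
the lowest bins; the function refuses bins not built from the marker it
is given.

`select_mirror_targets()` filters a predicted-target edge list to pairs
where the target *mirrors* its regulator across biological aging. All
three filters default on and are individually toggleable (the exact
published recipe varies, so each criterion is separable):

1. **anticorrelation** — Spearman(target, miRNA) < 0, BH-significant
   across all tested pairs;
2. **differential** — target DE between P20/P100 with direction opposite
   the miRNA's;
3. **cdkn2a** — target's CDKN2A correlation significant with sign
   opposite the miRNA's.

`build_network()` keeps targets annotated in at least one cardiac gene
set and the top-k (default 5) up- and down-regulated miRNAs by
|rho(CDKN2A)|, reporting per-miRNA coverage of the network's genes.
`compute_spm()` scores tissue specificity as the squared cosine between a
feature's mean-expression profile and each tissue's indicator vector
(`SPM_t = m_t² / Σ m_j²`), which is normalized to [0, 1], sums to 1, and
is invariant to global rescaling; pairwise Mann–Whitney tests compare the
focal tissue with every other.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` draws the study conditions every test runs under: 132
male donors with chronological ages uniform on 20–70 and a latent
biological age

```
b_i = 20 + r_i (CA_i − 20) + e_i
```

with a log-normal multiplicative aging rate `r_i` (mean 1, log-sd
`aging_rate_sd = 0.25`) anchored at age 20 — the youngest adult heart has
had no time to diverge — plus Gaussian noise (`sd = 2` years). This is
the minimal generative model in which CA and BA genuinely diverge
(Spearman ≈ 0.9) while remaining positively coupled, which is the premise
the whole analysis rests on.

Expression: age-responsive features move linearly in log2 with `b_i` at
`slope_scale = 0.035` log2 units/year jittered per gene (≈ 3.4-fold over
the 50-year range — the effect size of a strong, robustly detectable
aging gene), and counts are negative-binomial with common dispersion
0.08, typical of deeply sequenced bulk tissue. A CDKN2A-like senescence
gene gets a firmly positive slope. Planted miRNAs split 14 up / 6 down —
the structure recovery tests are read against — and each one's true
targets take the opposite slope plus a negative partial dependence
(coefficient 0.25) on the miRNA's realized standardized log2 level, so
target–miRNA anticorrelation survives conditioning on age. All of these
defaults were fixed from a power prototype before the recovery tests were
written, and not revisited.

One default deserves its rationale spelled out: `n_null_mirna = 580`, so
the 20 planted regulators are ~3.3% of a 600-feature miRNome — the
fraction reported for the LV. Beyond realism of proportion, the wide null
background keeps per-sample miRNA library sizes stable; with a narrow
miRNome the planted 14-up/6-down imbalance shifts library totals with
age and CPM normalization imprints a spurious (but real, post-
normalization) age trend on every null miRNA — a compositional artifact
any analyst of small RNA data will recognize.

Deliberately **not** emulated: read-level data, batch effects, sex
differences (the emulated cohort is male-only), GC/length biases,
correlated gene–gene noise beyond the shared latent age, miRNA target
sharing, and realistic staining variation in the histology fixture
(flat colors plus Gaussian texture; the quantifier contract is color
contrast, not stain chemistry). Passing tests therefore demonstrate the
*machinery* — calibration, inversion, filtering, scoring — under the
stated statistical structure; they do not certify performance on GTEx or
any real cohort.

Other generator fixtures: `generate_fibrosis_phenotype()` (linear in
latent BA, Gaussian noise, clipped to [0, 100]),
`generate_histology_image()` (random-walk ECM ribbons stamped 3×3 until
the mask fraction is within 0.005 of target; unreachable targets at small
sizes are an error, not a silent miss), `generate_tissue_panel()` (one
designated tissue expressing one feature at a configurable fold over an
otherwise uniform panel; 24 tissues by default), and
`generate_cardiac_sets()` (synthetic annotation mixing mirror targets
with nulls, plus a pure-null control set).

## Problem sizes and determinism

The shipped tests and the acceptance script run on: the default
132-sample cohort (≈ 1060 genes, 600 miRNAs), 20 histology images at
128 px, 20 independent cohort seeds for the miRNA-recovery averages, 400
points for the overlap check, and 100 random p-vectors for the BH check
— sizes at which every stage's behavior is already asymptotic in the
quantities tested while a full run stays in the tens of seconds. All
randomness flows from explicit integer seeds; identical seeds give
bit-identical cohorts, images, permutations and pipeline outputs
(`run_pipeline()` writes a manifest of MD5s to prove it).

## Known limitations

* AppAge is cohort-dependent by construction (calibrations are refit per
  cohort); absolute values are not comparable across studies without the
  optional rescaling, and even then only loosely.
* The CDKN2A marker inherits all caveats of single-gene markers:
  cell-composition shifts in bulk tissue can move it without any change
  in senescence burden.
* The mirror-target filters are correlational; they cannot distinguish
  direct repression from shared upstream drivers. (Experimental
  validation is out of scope here.)
* The fibrosis quantifier measures ECM area fraction under an H&E color
  model; Masson trichrome or picrosirius data need different stain
  vectors and validation.
* GSEA FDR per sign via BH on permutation p-values is conservative for
  small permutation counts; raise `n_perm` for publication-grade q
  values.
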