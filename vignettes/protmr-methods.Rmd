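---
title: "Methods: proteome-wide bidirectional MR at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide bidirectional MR at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protmr)
```

## Overview

`protmr` implements a bidirectional proteome-wide Mendelian randomization
(MR) workflow from GWAS summary statistics: plasma proteins are screened
as causal candidates for disease (forward MR, protein exposure / disease
outcome), diseases are screened as causes of protein-level changes
(reverse MR), hits are subjected to pleiotropy sensitivity analyses,
multiplicity control and replication in a second pQTL panel, and carried
into a phenome-wide scan with over-representation testing, multi-trait
colocalization, and single-cell cell-type enrichment/differential
expression. Because the biobank-scale inputs such a study consumes are
not redistributable, the package ships a synthetic summary-statistics and
single-cell generator that plants known causal structure, so every stage
can be exercised and calibrated against ground truth.

## The summary-statistics sampling model

All GWAS inputs are marginal association tables (variant, alleles, EAF,
beta, SE, p, N). The generator samples them directly in marginal-effect
space: within an LD block with correlation matrix $R$ and joint
(conditional) causal effects $\beta$, the marginal estimate is

$$\hat\beta \sim \mathrm{MVN}\!\left(R\beta,\ R/n\right), \qquad
  \mathrm{se} = 1/\sqrt{n},$$

treating each trait as variance-standardized. Disease traits are
simulated on the liability scale and their effects interpreted as
log-odds without conversion; any scale constant is absorbed into the
causal effect $\gamma$. No individual-level genotypes are generated:
summary-level sampling is exactly what two-sample MR consumes, and it
makes the instrument-validity assumptions hold by construction except
where violations (horizontal pleiotropy, reverse causation, sample
overlap) are explicitly planted.

A `truth_spec` declares: per-protein cis architecture (causal variants
inside the $\pm$1 Mb window around the encoding gene), shared trans-hub
variants affecting several proteins, per-disease liability loci (the
reverse-direction instruments), forward effects $\gamma$
(protein $\to$ disease), reverse effects $\delta$ (disease $\to$
protein), optional variants with direct disease effects that bypass the
protein (horizontal pleiotropy), two ancestries with distinct LD, and a
smaller replication pQTL panel.

### Default study conditions and why they look the way they do

The defaults emulate the structure of a proteome-wide MR study at desk
scale: a discovery pQTL cohort of 34,557 Europeans and a 2,783-sample
East Asian branch, a 1,225-sample replication panel, 19 disease
phenotypes with category labels, and a protein panel reduced to 50.
Three numeric choices deserve explanation because they are coupled:

* **Disease-GWAS sample size (50,000 EUR / 30,000 EAS).** Desk-scale
  effect sizes are necessarily much larger than real pQTL/disease
  effects, so a full-size (hundreds of thousands) outcome GWAS would
  make each protein-mediated variant signal genome-wide significant on
  its own — causal proteins' cis variants would then be selected as
  *disease* instruments and leak into the reverse direction, an artifact
  real data do not exhibit (real mediated per-variant effects sit far
  below $5\times10^{-8}$). The outcome $n$ is scaled so that mediated
  single-variant signals stay about 3 SD below the genome-wide
  threshold while aggregate MR power stays above 95%.
* **Effect sizes.** Cis effects are $|\beta| \in [0.28, 0.32]$ SD per
  allele at nine well-separated cis variants per protein, trans-hub
  effects $|\beta| \approx 0.15$, disease liability loci
  $|\beta| \approx 0.08$ log-odds, $\gamma = 0.035$, $\delta = 0.12$.
  These come from a power/separation analysis: the MR z-score scales as
  $\gamma\sqrt{n_{out}\sum\beta_x^2}$ while the per-variant mediated
  leak scales as $\gamma\beta_{x,\max}\sqrt{n_{out}}$, so the number of
  instruments (the $\sqrt{k}$ between them) is what buys simultaneous
  power and separation.
* **LD decay (AR-style, 0.3/0.25 by ancestry).** Causal variants are
  spread through their block so their marginal effects stay close to
  the joint effects. Under strong LD, clumping at $r^2 < 0.1$ retains
  weakly *correlated* instruments; the inverse-variance weights then
  understate the estimator variance slightly (a well-known LD artifact,
  visible as mild anticonservatism in null simulations with decay 0.8).
  The calibration studies in the test suite therefore use zero-decay
  blocks, where clumped instruments are exactly independent and the
  estimators' nominal distributions are exact.

The generator can also flip a random subset of allele codings (to
exercise harmonization) and sample exposure/outcome estimates with
correlated errors (participant overlap); both are off by default.

## Harmonization and instruments

Alleles are aligned to the exposure's effect allele; swapped codings
negate the outcome beta and complement the EAF. Strand is assumed
forward in both studies (allele-swap harmonization only), with optional
frequency-based strand inference. Palindromic variants (A/T, C/G) with
minor-allele frequency above 0.42 are removed as strand-ambiguous —
a conventional two-sample MR cutoff.

Instrument selection follows the standard recipe: genome-wide
significant variants ($p < 5\times10^{-8}$) are greedily LD-clumped at
$r^2 < 0.1$ within 500 kb of lead variants; "within 500 kb" is read as a
single window around each lead ($|\Delta pos| \le 500$ kb), with pairs
farther apart treated as independent regardless of $r^2$. Variants are
cis to a protein if they fall within 1 Mb of either side of the gene's
start/stop; instrument sets are built cis-only and cis+trans. Index
variants absent from the outcome study are replaced by the best proxy
(present in both studies, exposure-significant, within 500 kb,
$r^2 > 0.7$; ties by higher $r^2$, then smaller exposure p, then
lexicographic id). A proxy carries the *index* variant's exposure
effect, and its outcome effect is sign-aligned by the sign of the
index–proxy LD correlation.

## Estimators

For harmonized pairs $(\hat\beta_{Xj}, \hat\beta_{Yj})$ with outcome SE
$\sigma_{Yj}$ and weights $w_j = 1/\sigma_{Yj}^2$:

* **Wald ratio** (single instrument): $\hat\beta_Y/\hat\beta_X$ with
  first-order SE $\sigma_Y/|\hat\beta_X|$.
* **IVW**: weighted zero-intercept regression. Cochran's $Q$ is
  reported; by default the SE is inflated by $\sqrt{Q/(k-1)}$ when that
  exceeds one (multiplicative random effects), and the fixed-effect SE
  and p-value are always carried alongside so either variant can be
  used. The fixed-effect variant is the one whose null distribution is
  exact, and it is what the calibration checks test.
* **MR-Egger**: weighted regression with an unconstrained intercept
  after orienting all exposure effects non-negative; inference by
  t with $k-2$ df and the regression residual scale (the textbook
  weighted-regression form, which is exactly calibrated under the
  null). The intercept is the directional-pleiotropy balance test.
* **Weighted median**: ratios ordered, weights
  $\hat\beta_X^2/\sigma_Y^2$; the estimate interpolates where the
  standardized cumulative weight crosses 0.5. SE by parametric
  bootstrap (1000 draws, seeded).
* **Weighted mode**: normal-kernel weighted density over the ratios,
  bandwidth $\varphi \times 0.9\min(\mathrm{sd},\mathrm{mad})k^{-1/5}$,
  argmax on a 512-point grid spanning the ratios $\pm 3$ bandwidths
  (ties to the smallest ratio); bootstrap SE.

Exposure-side uncertainty enters only through the bootstrap procedures;
no weak-instrument correction is applied to IVW/Egger, matching the
estimators' standard forms. This convention is accurate when outcome
noise dominates, i.e. $\gamma^2\sigma_X^2 \ll \sigma_Y^2$; the parameter
recovery study is run in that regime (outcome $n = 5000$ against an
exposure panel of 34,557) because at comparable noise levels and large
$\gamma$ the ignored exposure variance visibly erodes CI coverage
(about 2% at $\gamma = 0.5$ with equal panel sizes).

`mr_fit()` is the model-fitting front end: it returns a classed object
with `print`, `summary` (odds ratios per 1-SD increment), `coef`,
`confint`, `plot` and `residuals` methods.

## Sensitivity analyses

**RSS outlier simulation (`presso()`).** The observed residual sum of
squares of leave-one-out IVW predictions,
$\sum_j w_j(\hat\beta_{Yj} - \hat\beta^{(-j)}\hat\beta_{Xj})^2$, is
ranked against a null distribution obtained by re-simulating outcome
effects from the leave-one-out fits with the reported outcome noise
(1000 draws by default; p-values floored at $1/(n_{sim}+1)$). Per-IV
terms give outlier p-values, Bonferroni-corrected over the number of
IVs at 0.05; flagged IVs are removed and the IVW estimate recomputed,
with a distortion test against random same-size removals.

**HEIDI-style filter (`heidi_filter()`).** The instrument with the
smallest exposure p is the reference; every other instrument's Wald
ratio is compared to the reference ratio with a delta-method variance on
both traits, removing instruments at $p < 0.01$ and repeating once. A
single-reference, single-pass rule is a deliberate simplification of
multi-SNP-reference implementations; the reference is never removed.

**Multivariable MR (`mvmr_fit()`).** Weighted least squares of outcome
z-scores on the variant-by-protein exposure z-score matrix without
intercept, for variants pre-clumped at $r^2 < 0.01$ / 500 kb and
associated with at least one protein. Because z-scores carry unit
sampling variance, the coefficient covariance is $(X'X)^{-1}$; no
estimating-equation bias correction is applied (the generator controls
the weak-instrument inputs such a correction needs), and a
rank-deficient design raises an error naming the collinear exposures.

## Multiplicity, replication, phenome scan

Significance flags use IVW as the primary method. The Bonferroni family
is defined as the *testable* exposure-outcome pairs within each
(direction, IV mode, ancestry) stratum, and the family size $m$ is
reported on every record — a reproducible, self-documenting denominator.
Benjamini–Hochberg flags are computed by the standard step-up rule on
the same family. Replication re-runs the same MR with instruments
rebuilt from the replication panel and flags nominal ($p<0.05$),
FDR and Bonferroni replication plus sign consistency; proteins missing
from the panel are marked not-assessable. The phenome-wide scan filters
disease phenotypes to those with at least 50 cases (quantitative
biomarker and medication phenotypes, used in the Asian branch, are
exempt), runs one MR per protein-phenotype cell and direction, and
classifies per-protein specificity (one disease, one category,
pleiotropic at 20/15/10/5 diseases).

Over-representation of a protein functional group $G$ in a disease
category $D$ uses the upper-tail hypergeometric probability

$$P = 1-\sum_{i=0}^{k-1}
  \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}}$$

with $N$ = (total diseases) $\times |G|$, $M$ = (diseases in $D$)
$\times |G|$, $n$ = significant signals in $G$ across categories, $k$ =
those within $D$; significance is Bonferroni-corrected for groups
$\times$ categories. Functional groups and phenotype categories are
input metadata (they come from curation, not computation).

## Multi-trait colocalization

Per variant and trait, evidence is the Wakefield approximate Bayes
factor
$\log\mathrm{ABF} = \tfrac12\log\frac{\sigma^2}{\sigma^2+W^2} +
\tfrac12 z^2\frac{W^2}{\sigma^2+W^2}$, with prior SD $W = 0.15$ for
quantitative traits (0.2 is conventional for binary log-odds;
configurable). For a trait set the algorithm enumerates: the null; every
some-but-not-all-associated subset (per-trait regional prior $10^{-4}$
per variant); the all-causal shared-variant configurations (first trait
at $10^{-4}$ per variant, each further trait at the conditional
colocalization prior, default 0.02 from the conventional
0.005/0.01/0.02 sweep); and the all-causal distinct-variant
configurations (the product of per-trait sums minus same-variant
terms). The regional probability is the posterior that all traits are
associated; the alignment probability is the shared share of the
all-causal mass; their product is the reported posterior for a single
shared causal variant, with the top shared configuration as candidate.
If a threshold (swept 0.6–0.9) fails, the trait whose removal maximizes
the remaining alignment is split off and the remainder re-evaluated —
a deterministic divisive rule that is a stated simplification of
published multi-trait clustering algorithms, with no claim of numerical
equivalence. Triads (protein, tissue RNA, disease) are simply
three-trait runs.

## Single-cell module

Nucleus counts are summed into pseudobulk profiles by donor and cell
type (zero-nuclei profiles omitted; aggregation conserves totals
exactly). Normalization uses TMM factors
(`edgeR::calcNormFactors(method = "TMM")`, trims 0.3/0.05, factors
rescaled to geometric mean 1) and
$\log_2\mathrm{CPM} = \log_2\!\big((c + 0.25) /
(L f + 0.5)\times 10^6\big)$ — note this applies the pseudocount in the
stated closed form rather than edgeR's adjusted-library-size variant;
the difference is $\mathcal{O}(p/c)$ and documented here.

A gene is **enriched** in a cell type when all of: (1) mean normalized
expression more than 4-fold higher than in the other types with
BH-adjusted one-vs-rest $p < 0.01$ (Welch t on profile-level log-CPM);
(2) at least 25% of the type's nuclei express it; (3) a single-gene
classifier separates the type's nuclei with AUC > 0.6 — realized as the
rank-based (Mann–Whitney, midrank ties) AUC, the minimal deterministic,
training-free classifier satisfying that description. Display ordering
is by top-expression cell type, then the mean Gini coefficient of
(average nuclei expression, fraction expressing) across types,
descending.

**Differential expression** per cell type fits limma-voom on the
pseudobulk counts — the mean–variance weighted linear model of
expression on disease group (DCM or HCM vs non-failing) adjusted for
age and sex — and flags genes at least 50% higher in cardiomyopathy
(log2FC $\ge \log_2 1.5$) with BH-adjusted $p < 0.01$ within the cell
type. Arms with fewer than three donors per group are not testable, and
a condition/sex-confounded design is an error, not a silent fit.

The synthetic single-cell generator plants negative-binomial counts
(dispersion 2, per-gene lognormal baselines, a per-(gene, donor)
lognormal biological factor of SD 0.15) over a donor panel of 16
non-failing, 11 DCM and 15 HCM donors — the cohort structure being
emulated — with declared enrichment and DE fold changes entering the NB
mean multiplicatively, so planted folds are recovered in pseudobulk
expectation. It does not emulate ambient RNA, doublets, batch structure,
or cell-type misassignment, so passing round-trips demonstrate the
pipeline's statistical behavior, not robustness to those artifacts.

## Numerical choices and degenerate inputs

* Correlation matrices are validated (symmetry, unit diagonal, entries
  in $[-1,1]$, PSD within $10^{-8}$); jittered matrices are projected
  back to the PSD cone by eigenvalue clipping with the unit diagonal
  restored. Sampling adds a $10^{-10}$ ridge before Cholesky.
* Two-sided normal p-values are floored at the smallest positive
  double; empirical (simulation) p-values use the $(1+\#)/(n+1)$ rule.
* Ties: proxy selection by $r^2$, then exposure p, then id; mode-grid
  argmax to the smallest ratio; clump ordering by p then id — all fixed
  so runs are bit-reproducible at a given seed.
* Bootstrap and simulation seeds are mandatory at the API and derived
  per-context from a single user seed.
* Estimators below their minimum instrument count return recorded
  not-estimable markers rather than raising; pairs with no surviving
  instruments are "not testable" and excluded from multiplicity
  denominators.

## Problem sizes used by the test and acceptance runs

All simulation-based studies below use zero-decay LD, so that clumped
instruments are exactly independent as the estimators assume. Under
visible LD, desk-scale z-scores make even weakly correlated neighbors
of causal variants genome-wide significant; the $r^2 < 0.1$ clump
filter retains them, and the resulting correlated instruments make IVW
mildly anticonservative — an independence-assumption artifact, not an
estimator defect, and one that full-scale data do not exhibit at the
same strength. Structured-LD behavior (clump windows, proxies,
HEIDI filtering) is covered by dedicated tests instead.

Estimator-oracle checks use 1000 random instrument sets of up to 10
IVs; calibration runs 1000 null replicates; parameter recovery 200
replicates per $\gamma \in \{0.1, 0.2, 0.3, 0.5\}$ with 10 instruments;
outlier handling 200 clean plus 200 contaminated replicates at 1000
null simulations each; enrichment is enumerated exhaustively for all
$N \le 60$; end-to-end discovery uses the 50-protein / 6-disease study
for 100 replicates; colocalization 200 shared and 200 distinct regions;
the single-cell round-trip 100 generated cohorts at 40 nuclei per donor
and cell type. The acceptance script recomputes the same quantities at
the sizes recorded in its output.

## Known limitations

* LD is synthetic (AR-decay blocks plus jitter); no realistic human LD
  maps, MAF spectra, or genome-wide variant counts.
* The MVMR fit omits the published estimating-equation bias correction;
  the HEIDI filter uses one reference instrument; the colocalization
  clustering is a simplified enumeration — none of these claim
  numerical equivalence with the corresponding released software.
* Disease effects are treated as log-odds throughout; no liability /
  odds-ratio conversion is attempted.
* Cross-database protein annotation (druggability, clinical evidence)
  is curation, out of scope; functional groups arrive as input TSVs.
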