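---
title: "Models and methods in immusel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in immusel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Immune genes are among the most consistent targets of positive selection in
mammals, but gene categories differ both in *function* (how directly their
products interact with pathogens) and in *selective constraint* (how much
purifying selection they experience). A higher rate of positive selection in
a category can therefore be a direct effect of function or an indirect
effect of weaker constraint. `immusel` implements a comparative pipeline for
separating these two explanations: gene-wide codon-model tests for episodic
positive selection, a within-species constraint measure (pN/pS), expression
covariates (mean expression and the tissue-specificity index tau), and a
category-level statistical layer in which constraint enters as a covariate.
A synthetic-data generator produces every input with the statistical
structure the analysis assumes, so the whole pipeline is testable without
any external data.

## Codon substitution model

The substitution process runs over the 61 sense codons of the universal
code. For codons $i \neq j$ differing at $d$ positions, the instantaneous
rate is

$$
q_{ij} =
\begin{cases}
\pi_j \,\kappa^{\mathbb{1}[\text{transition}]}\, r_{ij} & d = 1 \\
\delta\, \pi_j \, r_{ij} & d = 2 \\
\psi\, \pi_j \, r_{ij} & d = 3
\end{cases}
\qquad
r_{ij} = \begin{cases} s & \text{synonymous} \\ \omega & \text{nonsynonymous,} \end{cases}
$$

where $\kappa$ is the transition/transversion ratio, $\pi$ the sense-codon
frequencies (F3x4 from the alignment), $\omega$ the dN/dS of the site class,
$s$ its synonymous rate, and $\delta, \psi$ the double-/triple-hit
("multi-hit", MH) rates. Every class matrix is scaled by the rate of the
base model ($\omega = s = 1$, current $\delta, \psi$), so one unit of branch
length is one expected substitution per codon under the base model. Site
classes come from a discrete mixture: three $\omega$ classes (ascending,
free weights) crossed with three synonymous-rate classes constrained to
weighted mean one (the identifiability convention that makes "$\omega = 1$"
meaningful).

Three model variants mirror the standard robustness ladder for gene-wide
selection tests: `base` (the $\omega$ mixture only), `S` (adds
synonymous-rate variation across sites), and `S_MH` (adds multi-hit
substitutions). Ignoring S and MH when they are present in the data is a
well-documented source of false positive selection signals; the package's
calibration tests reproduce exactly this pattern (large base-model LRTs on
multi-hit null data, quiet `S_MH` LRTs).

## Likelihood machinery and optimization

Likelihoods are computed by Felsenstein pruning in C++ over unique site
patterns, with one symmetric eigendecomposition per mixture class (the
model is reversible, so $D_\pi^{1/2} Q D_\pi^{-1/2}$ is symmetric) and
per-node rescaling against underflow. Gap codons (`---`), `NNN` and codons
containing any ambiguous base are treated as missing data.

The gene-wide test compares the unconstrained fit (largest $\omega$ class
free) against a null capping the largest class at 1; the statistic
$2\Delta\ell$ is referred to $\chi^2_2$, which is conservative at the
boundary (the null distribution has an atom at zero). The paper-style
M1a-vs-M2a comparison and a single-$\omega$ dN/dS estimator use the same
machinery with different class structures.

Free parameters are optimized by bounded BFGS (`optim(method =
"L-BFGS-B")`) on log/logit transformed coordinates with a forward-difference
gradient. Two design choices matter for cost and robustness:

* **Weight profiling.** Mixture weights enter the likelihood only through
  the per-class site likelihoods, so they are profiled out by an inner EM
  pass at every outer evaluation. For the unconstrained fits both the
  $\omega$-class and synonymous-rate-class weights are profiled (the
  likelihood is invariant under a joint rescaling of the synonymous rates,
  the $\omega$s and the tree scale, so the mean-one normalization can be
  applied after fitting). For the constrained fit the cap
  $\omega_{\max} = 1$ is defined on the mean-one scale, which couples the
  weights to the rate matrices, so there the weights stay in the outer
  optimization.
* **Warm-start chains.** The null fit starts from the unconstrained optimum
  with the largest class capped; `S` starts from `base`, `S_MH` from `S`.
  If a null fit ends above its alternative, the alternative is refit from
  the null solution, so the reported LRT is never negative for lack of
  convergence (tiny negative values from optimizer noise are clamped at 0).
  Per-class likelihood columns are cached on their defining parameters so a
  finite-difference step recomputes only the classes the perturbed
  parameter touches.

Branch lengths keep their input proportions; a single tree-scale factor is
optimized. Full per-branch optimization would multiply the parameter count
by the number of edges for little benefit at gene scale.

Model averaging across the three variants uses Akaike weights on the
alternative fits, $w_i \propto \exp(-\Delta\mathrm{AIC}_i / 2)$, and the
averaged p-value $\sum_i w_i p_i$; genes are flagged at Benjamini–Hochberg
$q < 0.2$.

## pN/pS with the p(S+1) adjustment

Constraint within species is measured from polymorphism. Each coding
position is classified by fold degeneracy (f0/f2/f3/f4: how many of the four
nucleotides encode the same amino acid), giving synonymous and nonsynonymous
site counts $S = f_2/3 + 2f_3/3 + f_4$ and $N = f_0 + 2f_2/3 + f_3/3$.
SNPs surviving the filter cascade (biallelic; QUAL > 30; at least one
supporting read per strand; at least two reads centered on each side;
heterozygote allele balance in [0.3, 0.7]; exact one-sided Hardy–Weinberg
excess-heterozygote p > 1e-4; bounded missingness; repeat-masked;
minor-allele frequency threshold) are classified as synonymous or
nonsynonymous against the reference codon background, and

$$
pN = \frac{n_\text{nonsyn}}{N}, \qquad
pS^{+1} = \frac{n_\text{syn} + 1}{S}, \qquad
pN/pS = \frac{pN}{pS^{+1}}.
$$

The pseudo-count is applied to the synonymous *variant count*, keeping the
ratio defined for genes without synonymous polymorphism. Per-gene values are
averaged across the two study species (genes missing in either species are
dropped by default). Coverage handling follows the study design: per-sample
masks at depth below one third or above 1.5 times the sample median (halved
for males on X-linked scaffolds), excessive-coverage intervals at twice the
mean total coverage, and X-scaffold assignment by the normalized
female:male coverage ratio. Where the original workflow assigned X scaffolds
by manual inspection of coverage plots, the package uses a numeric window
(ratio in [1.7, 2.5]) so the rule is testable.

Coordinates are 0-based half-open internally; VCF positions are converted on
read and BED intervals are used natively. Stop-gain changes count as
nonsynonymous. Codons carrying more than one SNP are classified per-SNP
against the reference background.

## Expression covariates

Counts are normalized with TMM (via edgeR, the tool that defines the
procedure) and converted to FPKM by dividing CPM by the effective length in
kb (lengths of zero are remapped to 0.01). Tissue specificity is

$$
\tau = \frac{\sum_{i=1}^{N}(1 - x_i / x_{\max})}{N - 1}
$$

on untransformed per-tissue mean TMM–FPKM values ($\tau = 0$ uniform, 1
single-tissue); genes with all-zero tissue means are excluded. The mean
expression covariate is the arithmetic mean of tissue means. A log2(CPM+1)
PCA over samples serves as QC (samples should group by tissue).

## Category statistics

Covariates are transformed (square root for dN/dS; log10 for mean
expression, PPI count and sequence length; arcsine-square-root for tau) and
Z-scored. The positive-selection flag is modeled by logistic regression on
category with optional covariates, with type-3 likelihood-ratio term tests;
transformed dN/dS by OLS with type-3 F tests. Post hoc contrasts of each
category against the control use Dunnett's construction: the adjusted
p-value is $P(\max_j |T_j| \geq |t_\text{obs}|)$ under the joint
normal/t null with the correlation of the contrast estimates, evaluated by
Monte Carlo (200,000 draws, fixed seed, adjusted p accurate to about
±0.002). For pN/pS, whose distribution resists normalizing transforms, a
tie-corrected Kruskal–Wallis test with Dunn's vs-control z-tests
(BH-corrected within the comparison family) is used. Partial Spearman
correlations rank-transform all variables and correlate residuals after
regressing on the control ranks. Two-by-two contingency comparisons use the
binomial likelihood-ratio (G) test with 1 df. Missing covariates are handled
by listwise deletion per model.

## The synthetic world

`simulation_config()` fixes the study conditions; `simulate_world()` draws
one realization:

* **Trees**: pure-birth within each of two clades (15 taxa each by default)
  joined by stems; 0.5 expected substitutions per codon root-to-tip, with
  80% of the depth inside the clades.
* **Alignments**: site classes drawn from the mixture, root codon from
  $\pi$, evolution by exact $e^{Qt}$ per branch — deterministic given the
  seed, no stop codons, no gaps.
* **Variants**: a parametric stand-in (not a coalescent). Synonymous and
  nonsynonymous SNP counts are Poisson with means $\theta S$ and
  $\theta \cdot \text{target} \cdot N$, so the expected pre-pseudo-count
  pN/pS equals the target; positions are placed on the corresponding
  mutational opportunity, minor-allele counts follow the neutral $1/i$
  spectrum, and genotypes are assigned by randomly distributing allele
  copies over chromosomes.
* **Expression**: per-gene profiles with one maximal tissue and the rest at
  $1 - \tau$, so tau on noiseless means equals the target exactly;
  negative-binomial counts (dispersion 0.1 — the study reports no noise
  model, so a standard RNA-seq value is used) scaled by library size and
  effective length.
* **Coverage**: windowed negative-binomial depths with halved male depth on
  X scaffolds and a configurable spike rate for filter testing.

Per-gene positive-selection status is drawn from a logistic model with a
direct category effect plus a slope on log pN/pS (the constraint-mediated
path): `fraction_positive` sets the marginal rate per category and
`constraint_slope` (default 1.2 per log unit) the mediated share. Default
category settings — control 5%, cytokines 30%, cell-surface 20%, signaling
5% positive; pN/pS targets 0.15/0.30/0.25/0.10; tau targets
0.40/0.70/0.60/0.35 — encode the qualitative structure the analysis is
designed to detect: cytokines and cell-surface proteins less constrained
and more often under positive selection, signaling proteins more
constrained. Marginal rates and constraint levels are in the range the
rodent comparison reports; the effect decomposition (how much of the
cytokine excess is mediated by constraint) is a calibration choice made
once and flagged here.

In the fast pipeline mode (`selection_mode = "truth"`) the generator's true
per-gene status is used as the positive flag, so end-to-end tests exercise
the constraint, expression, merging and statistics stages at realistic gene
counts; `selection_mode = "codon_fit"` runs the full codon-model battery per
gene and is intended for small worlds.

## What the tests show (and what they cannot)

The test suite verifies, among other things: exact agreement of the pruning
likelihood with brute-force marginalization on small trees; exact agreement
of synonymous site counts with brute-force mutant enumeration; bounded
type-I error and real power of the gene-wide tests at the study scale
(30 taxa, 300 codons); the multi-hit false-positive pattern; recovery of
single-omega dN/dS, tau and logistic category effects; and reproduction of
the headline inference pattern (constraint attenuates the category term;
the cytokine contrast survives) in at least 80% of replicate synthetic
worlds. Replicate counts in the tests are desk-scale choices (for example
13 null genes for the type-I bound and 20 replicate worlds); the problem
dimensions match the study design. Synthetic data share the *statistical*
structure of the real inputs but none of their biological texture —
no alignment error, no annotation error, no demography or linkage, no
batch structure in expression — so green tests certify the machinery and
its calibration, not the biology of any particular data set.

## Numerical choices and limitations

* Optimizer: bounded BFGS, forward-difference gradients, box bounds on the
  transformed parameters; iteration caps are configurable (`maxit`,
  `null_maxit`), with deterministic seed-derived restarts (`n_restarts`).
* LRTs are clamped at zero; p-values from $\chi^2_2$ are conservative at
  the boundary.
* The EM weight profiles converge to 1e-8 in log-likelihood; class columns
  are cached to 14 significant digits of their defining parameters.
* Degenerate inputs: all-gap columns contribute nothing; alignments with no
  variation are flagged unidentifiable for the single-omega estimator;
  all-zero expression samples are excluded from TMM with a warning; zero
  male coverage labels a scaffold X with a warning.
* Branch-length proportions are trusted from the input trees; only a global
  scale is re-estimated.
* No branch-site tests, no site-level reporting, no synonymous-rate
  autocorrelation, no MNP decomposition, no ancestral polarization.

## Interfaces

All functionality is exposed as documented R functions; `run_pipeline()`
executes the stages in dependency order and writes TSV outputs plus a JSON
manifest with config hash, seeds and per-stage checksums (bit-identical
reruns given the same config). A thin command-line wrapper over these
functions ships in `inst/scripts/immusel.R` with subcommands `simulate`,
`run`, `select`, `pnps`, `expression` and `stats`.
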