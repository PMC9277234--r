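---
title: "Dissecting fitness alignment and conflict in legume–rhizobium symbiosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting fitness alignment and conflict in legume–rhizobium symbiosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbiopleio)
library(dplyr)
```

## The scientific question

When a locus in a microbial symbiont's genome affects fitness-related
traits of both the microbe and its host — *symbiotic pleiotropy* — the
signs of the two effects decide whether the partners' interests are aligned
(same sign: a *concordant* variant) or in conflict (opposite sign: a
*discordant* variant). symbiopleio implements the full analysis chain used
to ask this question in a panel of *Sinorhizobium meliloti* strains paired
with *Medicago truncatula* host lines:

1. **Strain means.** Rack-corrected estimated marginal means (EMMs) per
   strain for the single-strain fitness proxies — shoot biomass and leaf
   chlorophyll A for the plant; nodule number and nodule weight for the
   rhizobium — and their pairwise Pearson correlations per host line.
2. **Multi-strain relative fitness.** In a select-and-resequence
   experiment all strains compete on the same plants; strain frequencies
   are reconstructed from pooled nodule sequencing and summarised as the
   fold-change relative to the initial mean frequency.
3. **GWAS.** A kinship-corrected univariate linear mixed model per variant,
   per trait, per host (5 proxies × 2 hosts = 10 runs), yielding allelic
   effect sizes (betas).
4. **Significance.** Permutation-based family-wise thresholds per run.
5. **Pleiotropy classification.** Variants significant for ≥ 2 traits on
   the same host are classified into rhizobium-fitness vs symbiotic
   pleiotropy and labelled concordant/discordant per trait pair.
6. **Selection signatures.** Per-gene diversity and neutrality statistics
   (π, Watterson's θ, Tajima's D, Fu & Li's D\* and F\*), with focal gene
   categories compared against a resampled null of all significant genes.

Every stage is also exercised end-to-end on synthetic data with a known
ground truth, produced by the package's own generator.

## The mixed model

For one trait on one host, with one value per strain (EMMs for
single-strain proxies, median log2 fold-change for relative fitness), the
per-variant model is

$$ y = \alpha\,\mathbf{1} + x\beta + u + \varepsilon,\qquad
   u \sim N(0,\ \sigma_g^2 K),\quad \varepsilon \sim N(0,\ \sigma_e^2 I), $$

where $x$ is the haploid 0/1 genotype at the focal site and $K$ the
centered kinship matrix $K = X_c X_c^\top / L$ over all filtered sites.
The variance ratio $\lambda = \sigma_g^2/\sigma_e^2$ is estimated **once
per trait** by REML on the null (intercept-only) model, using the
eigendecomposition of $K$ to reduce the problem to a one-dimensional
optimisation (a log-spaced grid scan over $[10^{-5}, 10^5]$ followed by
Brent refinement in the bracketing interval; hitting the grid boundary is
flagged). Per site, generalized least squares in the rotated basis gives
$\hat\beta$, its standard error, and a Wald p-value against a $t_{n-2}$
reference. With $K = I$ the scan reduces exactly to ordinary least squares,
which the tests assert.

Per-site re-estimation of $\lambda$ (as some GWAS tools optionally do) is
omitted: at panel sizes of 100–1000 strains with a null-model $\lambda$,
the difference is negligible and the single estimate keeps the permutation
machinery fast and transparent.

Traits are standardized to unit variance before testing so betas are
comparable across proxies when signs are compared; raw-scale betas are
emitted alongside. Missing genotypes are mean-imputed for testing only —
sites are never dropped per strain, and the stored panel is untouched.

## Permutation thresholds

The family-wise threshold for each run permutes the trait vector across
strains (preserving the panel's LD structure and the kinship spectrum),
reruns the scan, and records the maximum $|\beta|$ and the minimum Wald p.
The threshold at level $\alpha$ is the $\lceil(1-\alpha)B\rceil$-th order
statistic of the null maxima (default $B = 1000$, $\alpha = 0.05$); a
variant is significant when its observed $|\beta|$ reaches the threshold.
Both the $|\beta|$- and p-based statistics are stored so either convention
can be audited; on balanced panels with near-constant standard errors they
select identical variant sets (asserted in the tests). By default
$\lambda$ is re-estimated for every permuted trait; a fast path reuses the
observed estimate.

A property worth knowing: with standardized traits, the max-$|\beta|$
statistic is dominated by the rarest variants (whose genotype variance is
smallest), so thresholds fall — and power rises — as the panel grows or
the MAF filter tightens. The sign-recovery tests therefore use several
hundred strains; with 100 strains the same machinery is calibrated but has
little power against effects diluted across many causal sites.

## Pool-frequency reconstruction

Given the known strain genotypes $G$ (strains × sites) and one pooled
sample with per-site depth $d_j$ and alternate-read count $a_j$, the
composition $f$ is the depth-weighted constrained least-squares solution

$$ \hat f = \arg\min_{f \ge 0,\ \sum_s f_s = 1}
   \sum_j d_j\left(\frac{a_j}{d_j} - (G^\top f)_j\right)^2 , $$

the natural estimand of likelihood-based haplotype-reconstruction methods
in a transparent convex form. It is solved by projected gradient descent
with Euclidean projection onto the simplex and a backtracking line search,
so the objective is monotone non-increasing (asserted per iteration in the
tests); convergence is declared at a gradient-mapping norm below $10^{-8}$
(at most 10 000 iterations), and the weighted residual is reported so poor
fits are visible. Sites with any missing genotype call are dropped (and
counted), as are sites with panel MAF below 0.05, which carry little
information about composition.

Relative fitness is then, per pool,
$(\hat f_{\text{final}} + \epsilon)/(f_{\text{init}} + \epsilon)$ with a
pseudo-frequency $\epsilon = 1/(2\,\tilde d)$ ($\tilde d$ the median
per-site depth) keeping log2 fold-changes finite; the per-strain summary is
the median across pools of the same host line, and the log2 fold-change is
the trait used in the relative-fitness GWAS (the log stabilizes the
variance of a ratio). Whether fold-change should be computed per pool and
then summarised, or on frequencies pooled across plants, is genuinely open;
per-pool-then-median is the default and both paths are available.

## Neutrality statistics

Per gene, on the complete-case strain subset (strains with no missing call
across the gene; a pairwise-deletion alternative was considered and
rejected as harder to verify), the package computes segregating sites $S$,
π (mean pairwise differences, reported per site and in total), Watterson's
$\theta_W = S/a_n$, Tajima's D with the 1989 variance constants, and the
outgroup-free Fu & Li D\* and F\* with the corrected (starred) constants —
the panel is a single species with no outgroup, so the starred variants are
the right choice. Genes with fewer than 4 complete sequences are skipped;
monomorphic genes report π = θ = 0 with the D-type statistics *missing*,
never zero; at $n = 2$ sequences π and $\theta_W$ coincide algebraically
and Tajima's D is exactly 0. The implementation is checked to $10^{-10}$
against a brute-force dual implementation (explicit pairwise difference
counting plus independently typed constants) on random genes.

The "focal category versus null distribution" comparison is formalized as
size-matched resampling: the null pool is all genes containing significant
variants; `reps` subsets of the focal size are drawn without replacement
and the empirical two-tailed p-value is
$(1 + \#\{|\bar{x}_{\text{null}} - \bar{x}| \ge |\bar{x}_{\text{focal}} -
\bar{x}|\})/(\text{reps}+1)$, flagged at $p < 0.1$. This makes the
focal-vs-distribution reading of the comparison explicit and exactly
reproducible under a seed.

## The synthetic-data generator

`sim_config()` fixes the study conditions; `simulate_genotypes()`,
`simulate_phenotypes()` and `simulate_pools()` generate the four inputs and
a truth ledger. What it emulates:

* **Population structure** via the Balding–Nichols model: ancestral
  frequencies uniform on (0.05, 0.95), subpopulation frequencies Beta with
  variance parameter `fst` (default 0.3, 3 subpopulations), haploid 0/1
  genotypes, 2% missing calls by default to exercise the filters. Sites
  sit on three replicons (chromosome, pSymA, pSymB, split in proportion to
  their physical sizes) and are tiled into contiguous genes with geometric
  lengths (mean 10 sites).
* **Planted pleiotropy**: each "pair" is one variant with signed effects on
  two proxies — rhizobium × plant for symbiotic pairs, rhizobium ×
  rhizobium for rhizobium-fitness pairs — same-sign for concordant,
  opposite for discordant (default 10 + 10, effect 0.8 SD). A configurable
  fraction of pairs can be private to one host line to study host overlap.
* **Replicate structure**: per host, `reps_per_strain` (default 4,
  matching a four-to-five-replicate greenhouse design) replicates per
  strain, random rack assignment with rack effects drawn once
  (`rack_sd`, default 1), residual noise `noise_sd` (default 1). The
  polygenic term has covariance proportional to the same kinship matrix
  the GWAS uses, scaled so that `h2_polygenic` is the polygenic share of
  strain-level (polygenic + one-replicate residual) variance.
* **Selection and pooling**: strain fitness
  $w_s = \exp(\text{gradient} \times \text{standardized breeding value})$
  for the relative-fitness trait; end frequencies
  $\propto f_{\text{init}} w_s$; per pool and site, depth
  $\sim\text{Poisson}(\bar d)$ and alternate reads
  $\sim\text{Binomial}(d, (G^\top f)_j)$. Initial frequencies are equal by
  default (the experiment mixed strains at nominally equal titre), with a
  Dirichlet-perturbed option. Read sampling uses the pre-masking genotype
  matrix, consistent with the reconstruction contract that drops
  missing-genotype sites.

What it does **not** emulate: coalescent ancestry or recombination (linkage
exists only through shared structure), gene gain/loss, within-nodule
bacteroid differentiation, genotype-by-genotype interaction terms, or
non-Gaussian trait noise. Passing tests on this generator demonstrate that
the estimators recover what they claim under their stated models — not
that real nodule pools or greenhouse data satisfy those models.

Default scale is 100 strains × 5000 sites so the whole pipeline runs in
under a minute; the real study's scale (191 strains, 36 526 SNPs, an
89-strain pool) is reachable by configuration.

## Numerical and design choices

* Variant filter defaults: MAF ≥ 0.05, missingness ≤ 0.2.
* EMMs come from the fixed-effect model `value ~ strain + rack` via the
  emmeans package; a mixed-model (random-rack) alternative was rejected as
  harder to verify for no practical gain at these design sizes. Rack
  confounded with strain triggers a rank warning and a pseudo-inverse fit.
* Correlation stars (*, **, ***) at p < 0.05/0.01/0.001 are reported raw,
  without multiple-testing correction across the trait-pair grid —
  deliberately mirroring the conventional presentation; treat the grid
  inferentially with care.
* Chlorophyll A is analysed untransformed by default (no transformation is
  assumed anywhere); a log flag can be applied upstream if desired.
* GWAS runs on strain means (one value per genotype), not replicate rows.
* Host lines are never pooled in any stage.
* All stochastic stages derive their seeds deterministically from the one
  configured seed; a fixed configuration reproduces byte-identical outputs,
  which the run manifest certifies with per-artifact checksums. Stage
  timings go to a separate file so manifests of identical runs compare
  equal.
* Pipeline stages communicate only through declared file artifacts
  (plain-text VCF/GFF3/CSV/TSV/JSON), so any stage can be re-implemented
  or re-run independently; fresh outputs are skipped on re-run.

## Problem sizes used by the test suite

The shipped tests run the oracle comparisons at 40 strains × 100 sites,
the calibration scans at 100 strains × 5000 sites, family-wise error over
200 null datasets of 50 strains × 200 sites at B = 500, sign recovery at
500 strains × 600 sites, pool recovery at 20–30 strains with depth 1000,
and the full default pipeline twice for determinism. These sizes were
chosen to give stable Monte-Carlo verdicts while keeping a full test run
in the minutes range on one core.

## Limitations

* The LMM assumes Gaussian traits and an additive per-allele effect;
  count-like proxies (nodule number) are treated as Gaussian after EMM
  averaging.
* Frequency reconstruction requires the strain reference panel; it does
  not discover unknown haplotypes, and near-duplicate strains make the
  problem ill-conditioned (the reported residual and convergence flag are
  the diagnostic).
* The resampling formalization of the category-vs-null comparison is a
  declared design choice; other formalizations (e.g. rank tests) could
  give different p-values for the same data.
* Balding–Nichols panels have site-frequency spectra unlike neutral
  coalescent data, so neutrality statistics on simulated panels are used
  for implementation checks (against oracles and planted contrasts), not
  as biological calibration.
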