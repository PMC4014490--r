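---
title: "Mapping gene-by-sex interaction QTL in heterogeneous stock populations"
author: "gxsmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping gene-by-sex interaction QTL in heterogeneous stock populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxsmap)
```

## The problem

Heterogeneous stock (HS) mice descend from eight inbred founder strains
through many generations of pseudo-random mating, so every chromosome is a
fine-grained mosaic of founder haplotypes. The population maps quantitative
traits at a few-Mb resolution, but two features complicate interaction
mapping: individuals are unequally related (population structure), and the
space of candidate interactions — every SNP with sex, every SNP pair — is
far too large for exhaustive testing.

`gxsmap` addresses this with a Bayesian *sparse partitioning* mapper: a
model is a partition of a small subset of the predictors (SNPs coded as
three-level factors, plus the distinguished predictor `SEX`) into disjoint
groups of one to three members. Predictors in one group interact; the group
contributes one mean per observed joint genotype level. Model space is
explored by Markov chain Monte Carlo, and the evidence of each model is
available in closed form, which is what makes the sampler verifiable
against exhaustive enumeration.

## The grouped-means model and its evidence

For a model (state) $M$ with groups $g_1, \dots, g_k$,

$$y_i = \mu + \sum_{j=1}^{k} \theta_{j,\,\ell_j(i)} + \varepsilon_i,
\qquad \varepsilon_i \sim N(0, \sigma^2),$$

where $\ell_j(i)$ is individual $i$'s joint level of group $j$'s members
(3 levels for one SNP, up to 27 for a three-SNP group; `SEX` contributes a
factor of 2). Priors: $\mu$ flat, $\theta \sim N(0, \tau^2\sigma^2)$
independently, and the scale-free prior $p(\sigma^2) \propto 1/\sigma^2$.
All three integrate analytically, so `sp_log_evidence()` is exact and
deterministic; joint levels unobserved in the data simply contribute no
term. The default $\tau^2 = 0.2$ puts a cell mean's prior spread at about
45% of the residual scale, appropriate for standardized phenotypes where
any single locus explains a few percent of variance at most. Unit tests
cross-check the evidence against dense-matrix numeric integration over
$\sigma^2$.

The prior over states is independent inclusion of each predictor at rate
$r$ (default $2/p$, so the expected model size is about two predictors),
combined with a uniform distribution over the legal partitions of the
included set. Constraints: at most 10 distinct predictors, at most 2
three-member groups, and an interaction mode — `all` (any predictors may
co-group), `snp_only` (`SEX` restricted to singleton groups, i.e. GxS
prohibited while SNP–SNP epistasis remains allowed), or `none`.

A practical note on $r$: the $2/p$ default expresses "about two causal
predictors among the full genome-wide panel" (thousands of pruned SNPs).
When the mapper is run on a deliberately reduced panel of a few dozen
markers, the same sparsity belief should be kept by passing the
genome-scale rate explicitly (`incl_rate`); rescaling it to the small panel
makes spurious inclusion — and with it spurious co-grouping — far more
likely than in a genome-wide run, because given joint inclusion of an
irrelevant pair the uniform partition prior already places substantial mass
on the co-grouped arrangement.

## The sampler

`sp_mcmc()` runs Metropolis–Hastings over states with four elementary
moves: insert an excluded predictor (into a new singleton or an existing
group), remove an included predictor, move a predictor between groups
(which merges and splits groups), and swap an included predictor for an
excluded one, proposed with weights 0.3/0.3/0.2/0.2 and uniform choices
among candidates. Insert and remove are exact reverses of one another
(insertion chooses a destination, so removing a predictor from inside a
group can be undone in one step), and move and swap are self-reverse, so
detailed balance holds; proposals violating a constraint carry zero prior
and are rejected. Evidence values are memoized per canonical state.

One recorded iteration is a *sweep* of `moves_per_iter` elementary
proposals (default: the number of predictors). A single elementary move
updates at most one predictor, so recording the chain at move granularity
would make the short conventional schedule — 2000 iterations, the first
500 discarded — almost useless as a posterior sample; with sweep recording
the same schedule mixes well. Posterior inclusion probabilities are counts
over the 1500 retained sweeps, so every reported probability is an integer
multiple of 1/1500. Pairwise (interaction) probabilities count co-grouping
and can never exceed either member's inclusion probability.

For six or fewer predictors, `sp_enumerate_posterior()` computes the exact
posterior by enumerating every legal state. The test suite requires a
50,000-iteration chain to agree with enumeration to within 0.03 in every
inclusion and pairwise probability.

## Calling and calibration

`sp_call_qtl()` reports main effects (inclusion $\ge$ 0.2), GxS (SNP–SEX
co-grouping $\ge$ 0.2) and GxG (SNP–SNP co-grouping $\ge$ 0.2). The 0.2
operating point is where posterior-probability histograms of genome-wide
runs thin out; `probability_histogram()` reproduces those summaries with a
0.05 display floor. Expected false positives at the threshold are
estimated by `permutation_fdr()`: each phenotype is permuted once (more
via `permutations`) and the mapper re-run, counting interaction
probabilities that still clear the threshold.

## The frequentist comparator

`compute_rmip()` implements bootstrap resample model averaging on
founder-ancestry dosages: each locus is an 8-column dosage block (one
column dropped for identifiability), and forward selection adds, per step,
the block that most reduces the residual sum of squares, gated by the
partial F-test p-value *Bonferroni-adjusted for the number of candidate
loci scanned at that step* being at or below 0.05. The adjustment is the
package's reading of the inclusion rule's "adjusted p-value": without it, a
scan over many loci admits a spurious locus in nearly every resample and
the conventional RMIP > 0.25 threshold (about one false positive per
genome scan) loses its meaning. Repeating the selection over 100 bootstrap
resamples gives each locus a resample model inclusion probability — a
locus selected in 70 of 100 resamples has RMIP 0.70. Peaks are local
maxima above a reporting floor (default 0.1), merged within 5 Mbp, with a
95% interval spanning the 2.5th–97.5th percentiles of the positions
selected across resamples. `single_sex_scan()` restricts the scan to one
sex so GxS candidates can be checked for sex-specific main-effect support
(`match_gxs_single_sex()`, 5 Mbp window), and `match_qtl()` matches
sparse-partitioning calls to peaks whose 95% interval, expanded by 2 Mbp,
covers the call position (greedy nearest-first, each peak used once).

## Heritability and relatedness

`kinship_allelic_corr()` builds $K = ZZ^\top/m$ from genotypes
standardized by their sample allele frequencies; `reml_h2()` maximizes the
restricted likelihood of the single-kinship mixed model over the variance
ratio $\lambda = \sigma_g^2/\sigma_e^2$ on a $\log_2$ grid from $2^{-14}$
to $2^{14}$ refined by interior optimization, after one eigendecomposition
of $K$. With $K = I$ the profile is flat in $\lambda$; the function then
reports $h^2 = 0$ with `converged = FALSE` and a warning rather than an
arbitrary number. Negative kinship eigenvalues are clipped at zero within
a $10^{-8}$ tolerance. Phenotype preprocessing uses the same fit:
`adjust_relatedness()` whitens the phenotype by the inverse square root of
the fitted covariance $\hat\sigma_g^2 K + \hat\sigma_e^2 I$ — a
generalized-least-squares rotation, chosen over BLUP residuals because it
leaves an exchangeable vector suitable for the permutation machinery.

Preprocessing order is Box-Cox normalization (profile-likelihood $\lambda$
on the grid $-2, -1.9, \dots, 2$, with a $1-\min(y)$ shift when values are
non-positive), then marginal covariate screening at $\alpha = 0.05$ with
joint removal of the significant ones, then relatedness adjustment.
Redundant markers are pruned by `prune_concordant_snps()`: within each
chromosome, greedy left-to-right clustering at 99% genotype concordance,
keeping the leftmost representative — greedy and leftmost because the
choice within a concordant cluster is statistically immaterial and this
rule is deterministic and order-stable.

## Cross-validated GxS variance

`cv_variance_explained()` measures the phenotypic variance attributable to
GxS as the difference in out-of-sample percent variance explained between
two configurations identical except for `interaction_mode`: `all` versus
`snp_only` (sex marginal only; epistasis allowed in both). Ten folds of
near-equal size; per fold, both chains are trained on the remaining nine
and scored on the held-out tenth. Prediction averages, over retained
states, each state's posterior-mean fitted values (cell means shrunk by
the conjugate prior; joint levels unseen in training fall back to the
state's intercept). Percent variance explained pools squared errors,
$100\,(1 - \sum \mathrm{SSE}/\sum \mathrm{SST})$, with SST about the
training mean — pooled rather than averaged per fold because small test
tranches make per-fold $R^2$ unstable. Values can be negative (a model can
predict worse than the training mean out of sample) and are reported
unclamped. Per-fold chain seeds derive from the fold index only, so
swapping the two configurations negates the difference exactly.

## The synthetic HS generator

`simulate_founders()` draws an 8-strain biallelic panel whose expected
population allele frequency (granular in eighths, since a random HS
chromosome is marginally a uniform draw among the founders) lies in a
configurable minor-allele-frequency window. `simulate_hs_population()`
then runs a discrete-generation random-mating pedigree — 50 generations by
default, crossovers Poisson at 0.01 per Mbp per meiosis (about 1 cM/Mb),
shared parent pairs across chromosomes so relatedness is genome-wide — and
records the true founder of origin of both homologues at every marker.
Genotypes are by construction the sum of the two inherited founder
alleles, and ancestry dosages sum to 2 everywhere; an optional symmetric
Dirichlet admixture emulates probabilistic haplotype reconstruction, and
`add_redundant_snps()` plants near-duplicate markers for the pruning
stage. `simulate_phenotype()` composes sex, additive, sex-specific,
epistatic, polygenic (multivariate normal with covariance proportional to
the allelic-correlation kinship) and noise components, and reports each
component's realized variance share as ground truth.

What the generator does not emulate: X-chromosome dosage compensation (all
chromosomes are simulated autosomally — a documented simplification, since
hemizygous male coding is a real-data concern), genotyping error beyond
the planted duplicates, mutation, and selective phenotyping. Passing tests
therefore demonstrate correctness of the machinery under a faithful but
idealized HS architecture, not robustness to every artefact of real data.

## Validation problem sizes

The end-to-end suite uses two generated populations: a marker-dense one
(n = 800, m = 2000, five 80-Mbp chromosomes, 50 generations) for kinship
and heritability recovery (true $h^2 = 0.5$, 20 phenotype draws, mean
estimate within 0.1), and a lean one (n = 1500, m = 60, three chromosomes)
for the mapping checks. A planted GxS QTL contributing 2% *pure
interaction* variance — opposite-sign slopes in the two sexes, sized on
the component orthogonal to the additive SNP and sex terms, since a
same-sign single-sex slope is mostly absorbed by main effects — must raise
the mean cross-validated difference above half a percentage point over 20
seeds, while a GxS-free generator stays within ±0.3 of zero. A planted 8%
main-effect QTL must be called by both mappers and matched in at least 90%
of seeds. Sampler-versus-enumeration agreement is checked at p = 6,
n = 300 with 50,000 iterations. Reduced chain schedules (200–400
iterations after sweep recording) are used inside cross-validation loops;
these sizes are the package's validation choices and scale up freely.

## Known limitations and open choices

* The original sparse-partitioning software's exact priors are not
  restated here; the grouped-means conjugate family was chosen for exact
  evidence and a feasible enumeration oracle. Posterior probabilities are
  comparable in spirit, not numerically identical, to other SP
  implementations.
* Whether sex should be *forced* into every model as a marginal term is
  left configurable in effect: under `snp_only` sex competes for inclusion
  like any predictor but cannot co-group. Forcing was not adopted as the
  default because inclusion of a genuine sex effect is essentially certain
  anyway at these sample sizes.
* The correlation report uses $n - 2$ degrees of freedom for the t-test of
  a Pearson correlation; published analyses occasionally print $n - 1$.
* Peak confidence intervals derive from bootstrap peak-position
  percentiles; with few distinct selected positions they can degenerate to
  a point, in which case `match_qtl()`'s window expansion still provides
  slack.
* REML reports no standard error for $h^2$; profile-likelihood intervals
  were deliberately left out of scope.
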