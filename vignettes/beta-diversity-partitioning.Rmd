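---
title: "Partitioning gut-microbiome beta diversity among feeding guild, site, and host taxonomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning gut-microbiome beta diversity among feeding guild, site, and host taxonomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamgut)
```

## The scientific question

Freshwater macroinvertebrates (mayflies, stoneflies, caddisflies, aquatic
beetles and flies, dragonflies) host gut bacterial communities whose
composition could be governed by where the host lives (the stream and its
microbial source pool), by what the host is (its taxonomic order, family,
genus), or by what the host does (its functional feeding group, FFG — the
ecological guild defined by how it acquires food: filtering collectors,
gathering collectors, scrapers, predators, shredders/detritivores). These
explanations pull in different directions: geography is a stochastic,
dispersal-driven account; taxonomy suggests phylosymbiosis; the FFG account
is deterministic and physiological, since guilds differ systematically in
gut morphology and pH.

`streamgut` implements the full analysis path for a 16S amplicon survey
designed around that question: samples of single taxa collected across
multiple stream sites, sequenced, denoised into an ASV (amplicon sequence
variant) table upstream, and analyzed here from the curated ASV table
onward. The centerpiece is a Bayesian hierarchical Beta regression that
partitions pairwise Bray-Curtis dissimilarity among the four grouping
factors in a single model.

## Pipeline stages and their settings

1. **Curation** (`curate_table`): ASVs unassigned at the domain level or
   assigned to Eukaryota are removed; then samples with fewer than 1000
   remaining reads are removed. Filtering order matters and is fixed:
   taxa first, then samples.
2. **Family-level collapse** (`collapse_to_rank`): counts are summed over
   ASVs sharing the lineage prefix down to the bacterial family. ASVs
   unassigned at the family rank are pooled per deepest assigned parent
   (`"...;O1;unclassified"`), never across parents, so unassigned reads
   from different orders are not merged.
3. **Rarefaction** (`rarefy`): subsampling without replacement
   (multivariate hypergeometric) to 1110 reads per sample, replicated 10
   times; replicate `r` uses seed `seed + r` so any replicate can be
   regenerated alone. Samples below the depth are dropped and listed.
   Whether downstream statistics use a single replicate or the replicate
   average is not dictated by the design; both paths exist, and the
   pipeline averages alpha indices and distance matrices element-wise
   across replicates (`aggregate_alpha`, `aggregate_distance`). The
   indicator screen, which needs integer counts, runs on the first
   replicate.
4. **Alpha diversity** (`alpha_diversity`): observed taxa; bias-corrected
   Chao1, `S + F1(F1 - 1) / (2 (F2 + 1))`; Shannon diversity in log base 2
   (the dialect of the QIIME lineage of tools this pipeline mirrors); and
   evenness `H / log2(S)`, reported alongside `H` because "Shannon's
   evenness" and plain "Shannon's" are both used in field summaries.
   Group differences use the Kruskal-Wallis rank-sum test — the k-group
   generalization of the Wilcoxon test, which is what a chi-square
   statistic with k - 1 degrees of freedom in a published table implies —
   with H defined as 0 and p as 1 when every value ties.
5. **Beta diversity**: Bray-Curtis dissimilarity
   (`1 - 2 sum min / sum totals`), NMDS ordination minimizing Kruskal
   stress-1 (one classical-scaling start plus random starts), one-way
   PERMANOVA with the pseudo-F on squared dissimilarities and add-one
   permutation p-values, PERMDISP (distances to group centroids in
   principal-coordinate space, with the standard imaginary-axis
   correction), and a per-taxon Kruskal-Wallis indicator screen with
   Benjamini-Hochberg control at q = 0.05.

### Degenerate and edge cases

- PERMANOVA offers exhaustive enumeration of all labeled assignments for
  small n; the sampled path uses the add-one estimator, so p is never 0.
- PERMDISP excludes singleton groups with a warning rather than producing
  astronomically large, meaningless F ratios: a one-member group has no
  dispersion, and including it yields arithmetic artifacts (the kind that
  surface as F values like 4e+30 in published genus-level tables).
  When all centroid distances vanish the result is flagged degenerate
  (`F = NaN`) instead of reporting 0/0.
- Constant-abundance taxa in the indicator screen get p = 1 by
  convention, not an error.

## The hierarchical Beta regression

Each unordered pair of samples contributes one observation: its
Bray-Curtis value `y`, plus one level per factor (host family, host genus,
FFG, stream site). The model is

    y_i ~ Beta(mu_i * phi, (1 - mu_i) * phi)
    logit(mu_i) = alpha + a_family[i] + a_genus[i] + a_ffg[i] + a_site[i]
    alpha ~ Normal(0, 1)
    a_f[j] ~ Normal(0, sigma_f)      for varying factors f
    sigma_f ~ Exponential(rate 0.5)
    phi ~ Gamma(shape 0.01, rate 0.01)

so the mean is the inferential target and `phi` a precision; the Beta
variance is `mu (1 - mu) / (1 + phi)`. The Exponential prior is
parameterized by rate (mean 2) and the Gamma by shape and rate, the
conventions of the Stan-family samplers this model class is usually fitted
with.

**Pair-to-level assignment.** A pair of samples only has a well-defined
family (or genus, FFG, site) when both members share it. We give each
factor a sentinel level `"mixed"` for non-shared pairs, estimated exactly
like any other level. This uses every pair, gives each observation one
level per factor as the formula requires, and makes each level's
posterior mean dissimilarity depend on its same-level pairs. The
alternative — dropping non-shared pairs for a given factor — is available
via `shared_only_factor` in `build_pair_observations()`. Genus labels are
qualified by family (`"family/genus"`, `"family:unknown"` when the genus
was not identified) so the genus factor is properly nested in family.
Host order is deliberately not a model term: with family and genus in the
model, order is almost entirely redundant, and the four-factor formula is
the model this package implements.

**Boundary handling.** Bray-Curtis attains 0 and 1, where the Beta density
is undefined, so every response is squeezed with the Smithson-Verkuilen
transform `y' = (y (N - 1) + 0.5) / N`, `N` being the number of pairs.

**Fixed-factor variants.** For model comparison, four variants each make
one factor "fixed": one unpooled coefficient per level with a
Normal(0, 1) prior, the other three factors remaining varying intercepts.
WAIC (`-2 (lppd - p_WAIC)`, log-sum-exp stabilized) ranks the five fits;
`SE(delta WAIC) = sqrt(n var(pointwise differences))`. `p_WAIC` uses the
population variance over draws, so duplicating draws leaves WAIC exactly
unchanged. Bayesian R-squared is computed per draw as
`var(mu) / (var(mu) + mean(mu (1 - mu) / (1 + phi)))` and its posterior SD
is reported as the spread (labeled as such; a standard error of the mean
would be far smaller).

### Why hierarchical shrinkage is the point

Partial pooling pulls sparsely observed levels toward the grand mean in
proportion to their data, which is what makes per-genus estimates usable
when many genera have a single sample pair. The same mechanism drives the
WAIC comparison: a varying factor whose true effects are negligible is
shrunk to nothing at almost no complexity cost, while a fixed factor pays
for every unpooled coefficient. That is why, when one factor dominates,
the model fixing *that* factor (and letting shrinkage silence the others)
wins the comparison.

## The sampler

The posterior is explored with an adaptive Metropolis-within-Gibbs sampler
written in C++ (Rcpp):

- **Non-centered effects**: each varying effect is `sigma_f * z`, `z`
  updated on the unit scale with a Normal(0, 1) prior.
- **Log-scale updates** for `sigma` and `phi`, with Jacobian-corrected
  densities (Exponential and Gamma priors respectively).
- **Recentering move**: `alpha -> alpha + d`, `z -> z - d / sigma_f`
  leaves every linear predictor unchanged, and the conditional of `d` is
  Gaussian, so it is an exact Gibbs step. It removes the translation
  degeneracy between the grand mean and each factor's mean effect.
- **Rescaling move**: `sigma -> sigma e^l`, `z -> z e^{-l}` leaves every
  effect unchanged; a Metropolis step along this ray (with the `e^{-Jl}`
  Jacobian) explores the scale degeneracy of the non-centered
  parameterization. Without these two moves the sampler stalls on
  exactly the directions that matter for variance partitioning.
- **Adaptation**: per-parameter proposal scales follow a Robbins-Monro
  recursion toward ~30% acceptance during warmup and are frozen at the
  end of warmup, keeping the post-warmup chain a valid fixed-kernel
  Markov chain.

Defaults mirror the analysis design: 4 chains, 2000 iterations, 1000
warmup, convergence judged by split-chain R-hat < 1.1 (rank normalization
off) and effective sample sizes from Geyer-truncated autocorrelation sums.
Constant parameters are flagged rather than given a spurious R-hat. All
chains run sequentially from one seeded RNG stream: one seed, identical
draws.

The primary correctness oracle is the reduced two-parameter model (alpha,
phi only): its posterior is integrated on a dense 350 x 350 grid and the
sampler must reproduce the posterior mean of alpha to 0.02. The secondary
oracle is simulation-based calibration on that reduced model: parameters
drawn from the priors, data from the likelihood, and the rank of the true
alpha among thinned posterior draws tested for uniformity. One numerical
caveat is documented in the test itself: Gamma(0.01, 0.01) puts most of
its mass at precisions so small that Beta draws underflow double
precision, so calibration draws restrict phi to the numerically
representable range [0.5, 2000]; within it, generator and model agree
exactly.

## The synthetic-data generator

The generator is the package's stand-in for the field study, with two
independent routes:

- `generate_metadata` + `generate_counts`: a survey design of 10 sites and
  41 samples (the field design's distribution), 7 host orders, 26
  families, 5 FFGs, ~20% of samples identified only to family. Counts
  follow a compositional log-linear model: per-ASV baseline log-abundances
  plus Normal(0, sigma) site/FFG/family/genus effects per ASV, softmax to
  a composition, lognormal library sizes clipped to the observed range
  1235..98479 reads, multinomial counts. No generative count model is
  dictated by the study design; this softmax construction is our choice,
  the minimal one that makes FFG and site signal tunable and detectable in
  Bray-Curtis space. Default tables use 300 ASVs — far below a real
  survey's ~12,000 — because family-level collapse and rarefaction make
  desk-scale tables statistically equivalent for the pipeline's purposes.
- `generate_pair_observations`: dissimilarities drawn directly from the
  Beta model with known alpha, phi, and per-factor effect scales, for
  testing the model against its own generative process. Default scales
  are (ffg 0.8, site 0.5, family 0.3, genus 0.3) on the logit scale with
  alpha 0.85 and phi 20, the regime the package's headline analyses
  emulate: mean dissimilarity ~0.7 with SD ~0.1 and guild as the dominant
  source of variation.

What the generator does **not** emulate: read-level error, chimeras,
phylogenetic structure among ASVs, overdispersion beyond multinomial
sampling, correlated effects between factors (in real data family and FFG
are partially confounded because guild membership follows taxonomy), and
unbalanced level co-occurrence. Passing tests therefore demonstrate that
the machinery is correct under its stated model, not that real gut
microbiome data meet those assumptions.

Every generator operation derives its own RNG stream from the single
config seed via fixed offsets, so metadata and counts can be regenerated
independently.

## Study-scale choices in tests and the acceptance script

Simulation sizes were chosen once as the smallest designs that identify
the quantities under test: parameter recovery uses 20 runs of 1500
observations with 21 levels per factor at 4 chains x 800/400 iterations;
model selection uses 20 runs of 600 observations with short 2-chain fits;
null calibration uses 2000 PERMANOVA simulations at n = 16 with 99
permutations and 50 indicator tables of 100 taxa x 40 samples. With
finitely many levels a sigma posterior tracks the *realized* spread of
that run's effects, which fluctuates around the population value — the
per-factor credible-interval coverage targets (17 of 20) account for
exactly this.

## Known limitations

- PERMANOVA is one-way (the design's use case); no interaction or
  strata support.
- The sampler is random-walk based; for models far larger than this
  design (hundreds of levels, many factors) a gradient-based sampler
  would mix better per iteration.
- WAIC is the only comparison criterion (no PSIS-LOO).
- The `"mixed"` sentinel construction is one defensible reading of how a
  pairwise dissimilarity maps to single factor levels; conclusions about
  level-specific means refer to same-level pairs under that construction.
- Pairwise observations are not independent (each sample appears in many
  pairs); the model, like the analysis it implements, treats them as
  exchangeable given their levels.
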