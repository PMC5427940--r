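---
title: "Modelling gene family turnover on a dated phylogeny"
author: "famturn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gene family turnover on a dated phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Comparative proteome studies summarise each gene family (a hierarchical
orthologous group, HOG) as a vector of per-species copy counts at the tips
of a dated species tree. Two complementary questions follow. Where on the
tree did gains, duplications and losses happen, and are some lineages --
here bats, and within them the echolocating Yangochiroptera versus the
non-echolocating Old World fruit bats -- gaining or losing genes faster
than the rest of the tree? And are particular functional classes of
families (olfactory receptors, immunity genes) over-represented among the
expanding or contracting ones?

`famturn` implements that analysis end to end: parsimony event mapping,
maximum-likelihood birth--death models with annotation-error correction,
simulation-based significance, term enrichment, and phylogenetically
corrected trait correlation. A bundled 18-taxon laurasiatherian chronogram
(8 bats and 10 outgroups, every root-to-tip path 80 My) and an exact
birth--death simulator make the whole pipeline testable on synthetic data
with known truth.

## The birth--death model of family size

Each gene copy independently duplicates at rate $\lambda$ and is lost at
rate $\mu$ (per gene per million years). Over a branch of duration $t$ a
single copy leaves 0 descendants with probability $\alpha$ and $k \ge 1$
descendants with probability $(1-\alpha)(1-\beta)\beta^{k-1}$, where for
$\lambda \ne \mu$

$$\alpha = \frac{\mu(E-1)}{\lambda E - \mu},\qquad
  \beta = \frac{\lambda(E-1)}{\lambda E - \mu},\qquad
  E = e^{(\lambda-\mu)t},$$

and in the critical case $\lambda = \mu$,
$\alpha = \beta = \lambda t/(1+\lambda t)$. A family of size $s$ is the sum
of $s$ independent copies, so the size transition law is the $s$-fold
convolution of that offspring law; size 0 is absorbing (a lost family is
never re-gained). Two independent implementations coexist deliberately:
the exported R functions evaluate the survivor-sum closed form in log
space, while the compiled pruning core builds each transition matrix by
truncated convolution (exact for all states below the cap, since size
paths cannot re-enter from above). The test suite requires the two routes
to agree to near machine precision.

State space is truncated at $S$ = (largest observed count) + 10 by
default. At the turnover rates relevant here (order $10^{-3}$--$10^{-4}$
per gene per My) the probability mass beyond that cap is far below the
$10^{-9}$ normalisation tolerance the tests enforce.

### Rate classes

A `rate_model` maps every branch to a rate class. Class 0 is the
background; each named clade (e.g. all bats, or Yangochiroptera and Old
World fruit bats separately) adds a class covering the clade's branches
plus its stem. With `tied = TRUE` a class has one turnover rate
($\lambda = \mu$); with `tied = FALSE` gain and loss are free. This
reproduces the usual model ladder: one/two/three rate classes, tied or
free -- up to six rate parameters for the three-class free model.

### Annotation error

Fragmented assemblies and imperfect gene annotation corrupt tip counts.
The error channel is deliberately minimal: with probability
$1-\varepsilon$ the observed count equals the true count, and with
probability $\varepsilon/2$ each it is off by one in either direction; at
true count 0 the impossible $-1$ outcome folds back onto 0. The channel
enters the likelihood as the tips' emission probabilities, so error and
rates are estimated jointly. `estimate_error()` profiles $\varepsilon$ on
a halving grid $\{0,\ \varepsilon_{\max}/2^k\}$ (default
$\varepsilon_{\max} = 0.5$) refined by golden-section search, refitting
rates at every candidate -- no prior on the error distribution. The
per-species mode starts all species at the global optimum and cycles
through species, profiling one error with the others fixed, until no
estimate moves by more than $10^{-3}$.

### Likelihood, root prior, and ascertainment

`family_log_likelihood()` runs Felsenstein pruning over the truncated
states, vectorised across families with per-family rescaling. The root
combines partials under a prior over root sizes conditional on presence;
the default is uniform over $1..S$, chosen as an uninformative reference
rather than a claim about real root-size distributions. The prior is not
innocuous: when data are generated with small geometric root sizes, the
uniform prior pulls the free gain-rate estimate down by a modest fraction
(the simulate-and-refit tests absorb this within their $\pm 25\%$
tolerance). `fit_model(root_prior = )` accepts a point mass or an
arbitrary prior vector for users who want to assert more.

Fitting analyses only families that were observed somewhere, which is an
ascertainment condition: families that went extinct everywhere are
invisible. By default `fit_model()` therefore conditions the likelihood on
non-extinction (dividing by $1 - P(\text{all tips observe } 0)$),
computed in the same pruning pass as an extra all-zero pseudo-profile.
`condition_on_observed = FALSE` restores the plain likelihood.
Families are additionally restricted to those present at the focal root
(`filter_root_families()`: presence on both sides of the root split)
before fitting, mirroring the root-presence condition of the original
analyses.

### Optimisation

Rates are optimised in log space -- Brent on $[\,10^{-8}, 1\,]$ for a
single parameter, Nelder--Mead otherwise -- from a moment-based start
(within-family cross-tip variance scales like $2\,\bar s\,\lambda\,T$
under the tied model), with `n_restarts` starts jittered by up to
$\pm 50\%$. The fit is flagged converged when the best two restarts agree
in $-\ln L$ within $10^{-4}$.

## Parsimony event mapping

Ancestral copy numbers come from Sankoff dynamic programming with linear
cost $|\Delta|$ over states $0..S$ ($S$ = family maximum + 1): every
per-copy gain or loss is weighted equally. A family's origin is fixed
beforehand to the MRCA of the species where it is observed (the HOG
definition: all genes descended from one ancestral gene, so the group's
taxonomic level is its birth); states outside the origin subtree are 0 and
the origin state is at least 1. Ties are resolved deterministically --
closest to the parent's chosen state, then the smaller count; at the
origin, the smallest minimum-cost state $\ge 1$ -- so event reports are
reproducible. Whether an ambiguous placement should instead lean rootward
is not decidable from first principles; a different convention would move
some per-branch tallies.

Per-branch summaries count families gained (origin on the branch),
families lost (parent positive, child zero), duplication and loss events
(summed positive/negative changes), and expanded/contracted family
counts. The exhaustive-enumeration test equates the Sankoff cost with the
brute-force minimum on all small instances, and the event-logged
simulator guarantees the inferred cost never exceeds the number of events
that actually occurred.

## Significance machinery

**Per-family p-values.** For each family, `family_pvalues()` simulates
`n_mc` replicate families under the fitted model and reports
$p = (1 + \#\{\ln L_{\mathrm{sim}} \le \ln L_{\mathrm{obs}}\})/(1 + n_{mc})$
-- the standard conservative Monte-Carlo estimator; its floor
$1/(1+n_{mc})$ avoids zero p-values. Root sizes for the replicates are
drawn, by default, from the model's root prior: the family and its
replicates are then exchangeable under the null, which makes the p-values
exactly calibrated -- the property the calibration test verifies
(Kolmogorov--Smirnov distance to uniform below 0.05 at 2,000 null
families). The alternative `root = "posterior"` scheme draws roots from
each family's conditional root-size posterior, concentrating the test on
deviations beyond what the family's own size explains; it is closer in
spirit to conditioning on family size but only approximately calibrated,
which is why it is not the default.

**Per-branch tests.** Given the jointly most-likely ancestral states
(max-product analogue of the pruning recursion), each branch gets an
exact two-tailed test by probability ordering: the p-value is the total
transition probability of all child states no more probable than the one
reconstructed. This is a convention -- the original tooling's internal
branch test is not documented -- but it is exact, needs no simulation,
and is monotone in the size of the jump.

**Model comparison.** `simulate_null_lrt()` builds the null distribution
of $2\Delta\ln L$ between nested models by simulating datasets under the
fitted null and refitting both models to each, with the critical value
taken as the order statistic at $\lceil 0.95\,n \rceil$ -- no asymptotic
chi-squared reference, matching the simulation-based design of the
original analysis. The calibration test checks the achieved type-I error
on held-out null batches.

## Enrichment and trait correlation

Term enrichment is a one-sided hypergeometric (Fisher) over-representation
test per term, with the population fixed to the families present at the
*parent* node of the tested branch -- only families that existed before
the branch could change along it. Expansion and contraction sets are
tested separately; under-representation is not reported. Terms absent
from the population are skipped rather than reported at $p = 1$, and the
correction burden $m$ is the number of terms actually tested (Bonferroni,
Holm and Sidak columns). The term map is taken as given -- there is no
ontology-graph propagation of annotations to ancestor terms, so results
are relative to whatever closure the map already encodes.

Phylogenetic independent contrasts follow Felsenstein's pruning:
standardized contrast $(x_i - x_j)/\sqrt{b_i + b_j}$, weighted-average
node values, and branch extension $b_i b_j/(b_i + b_j)$. The contrast
correlation is Pearson through the origin (contrast signs are arbitrary)
with a t-test on $n-1$ degrees of freedom; raw tip correlations use
Spearman's rank statistic with a seeded permutation p-value, appropriate
at 18 species where large-sample approximations are unreliable. Genome
sizes missing from the C-value database are imputed as the genus
arithmetic mean (genus = first underscore-delimited token), with a
provenance flag.

## The synthetic-study generator

`generate_study()` produces every input the pipeline consumes, under
conditions chosen to mirror the bundled laurasiatherian study: the
18-taxon chronogram; 2,000 families; a single tied turnover rate of
0.0008 changes/gene/My (the species-error-corrected global estimate);
root sizes shifted-geometric with mean 2, conditional on at least one
copy (the root draw of the original simulation tool is undocumented, so
this is a package choice -- small typical families with a long tail);
global annotation error 0.0635; a planted term ("OR-like") carried by
60% of the families that truly contract inside the bat clade versus 10%
elsewhere; and a Brownian C-value trait ($\sigma^2 = 0.005$ Gb$^2$/My
around a 2.5 Gb root -- tip standard deviation of roughly 0.6 Gb around a
mammal-scale mean) with an optional target correlation to per-tip loss
counts (default 0, matching the original finding of no association).

Count evolution is simulated *exactly* (per-copy exponential event times
down every branch), so each family carries a complete event log; planted
enrichment is defined on truly contracting families, making the
enrichment acceptance independent of reconstruction noise. The
`simulate_profiles()` matrix sampler is a second, faster simulator used
inside the significance machinery; the two routes are compared against
closed-form extinction and mean-growth identities in the tests.

What the generator does *not* emulate: orthology-inference noise beyond
the $\pm 1$ channel (no family splitting/merging), rate heterogeneity
across families, gene-tree/species-tree discordance, or ontology
structure among terms. Passing tests therefore demonstrate correctness of
the inference machinery under the stated generative model, not robustness
to every artefact of real proteome pipelines.

## Numerical choices and scales

- Transition matrices: truncated convolution in compiled code; survivor
  sum in log space (logsumexp-safe, each term a probability) in R as the
  reference; pruning re-scales per family per node.
- Optimiser tolerances: `reltol` $10^{-8}$; error search stops at
  $\Delta\varepsilon \le 10^{-3}$.
- Test problem sizes are the package's own desk-scale choices: rate
  recovery at 2,000 families with 5 restarts; p-value calibration at
  2,000 families with $n_{mc} = 300$; LRT calibration on the 8-taxon bat
  subtree with 60 families, a 5,000-simulation null batch (matching the
  original analysis' simulation count) and 500 held-out datasets;
  per-species error isolation on the 3-taxon fruit-bat subtree.
- All Monte-Carlo machinery takes explicit seeds; pipeline stages derive
  per-stage substreams from one configured seed.

## Known limitations

- No gamma (across-family) rate heterogeneity; every family in a class
  shares the class rates.
- The $\pm 1$ error channel cannot represent gross annotation failures
  (whole-family absence from an assembly).
- The uniform root prior biases free gain/loss estimates slightly when
  true root sizes are small (see above); supply `root_prior` if better
  information exists.
- Branch classes always include the clade stem; separating stem from
  crown requires manual `edge_class` editing.
- The enrichment test assumes the flat term map is already closed under
  whatever ontology semantics the user intends.
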