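# famturn

Gene family turnover on dated phylogenies: event mapping, birth–death
models with annotation-error correction, simulation-based significance,
term enrichment, and phylogenetically corrected trait correlation.

## What it is for

Comparative genomics pipelines reduce each gene family (hierarchical
orthologous group, HOG) to a vector of per-species gene copy counts at
the tips of a time-calibrated species tree. `famturn` is for the analyst
who has such a table — typically thousands of families across a modest
number of genomes — and wants to know where gains, duplications and
losses happened; whether focal lineages (here bats, and the echolocating
vs. non-echolocating bat clades) turn genes over faster than the rest of
the tree; which functional terms are enriched among expanding or
contracting families; and whether turnover tracks a species trait such
as genome size.

The package bundles an 18-taxon laurasiatherian chronogram (8 bats and
10 other mammals; every root-to-tip path is 80 My) and a full synthetic
study generator, so every stage can be exercised and tested without any
external data.

## The model

Each gene copy independently duplicates at rate λ and is lost at rate μ
(per gene per million years); family size is the sum of independent
copies and size 0 is absorbing. Over a branch of length *t* a single
copy leaves no descendants with probability α and *k* ≥ 1 descendants
with probability (1−α)(1−β)β^(k−1), where for λ ≠ μ

    α = μ(E−1)/(λE−μ),   β = λ(E−1)/(λE−μ),   E = exp((λ−μ)t)

and α = β = λt/(1+λt) when λ = μ. Branches are grouped into rate
classes (background, bats, fruit bats, …), with gain and loss either
tied (λ = μ) or free per class. Observed counts pass through a ±1
annotation-error channel with per-species probability ε, estimated by
profile likelihood. Ancestral event placement uses linear-cost Wagner
parsimony (Sankoff DP) with the family's origin fixed at the MRCA of
observed presence. Significance comes from Monte-Carlo per-family
p-values, exact per-branch transition tail tests, and a
simulation-built likelihood-ratio null; enrichment is a one-sided
hypergeometric test against the families present at the tested branch's
parent node; trait correlation uses Spearman (permutation p) and
Felsenstein's independent contrasts (correlation through the origin).

## Worked example

A synthetic study along the bundled chronogram, analysed end to end:

```r
library(famturn)
tree <- laurasiatheria_tree()
clades <- laurasiatheria_clades()
study <- generate_study(list(n_families = 500, eps = 0), seed = 11)
counts <- as_family_counts(
  study$counts_observed[rowSums(study$counts_observed) > 0, ], tree)

# 1. parsimony event mapping: busiest branches by loss events
events <- summarize_branch_events(counts, tree)
head(events[order(-events$loss_events),
            c("branch_label", "families_gained", "families_lost",
              "duplication_events", "loss_events")], 3)
#>  branch_label families_gained families_lost duplication_events loss_events
#>      F._catus               0            12                 33          42
#>   E._caballus               0            15                 63          39
#>     S._scrofa               0             6                 35          39

# 2. tied single-class birth-death fit on root-present families
root_fams <- filter_root_families(counts, tree)
fit <- fit_model(root_fams, tree, rate_model(tree, tied = TRUE),
                 n_restarts = 5, seed = 1)
fit
#> Birth-death fit: tied (lambda = mu)
#>   classes: background
#>   lambda:  0.000796
#>   mu:      0.000796
#>   -lnL:   5962.418 (498 families)
#>   restarts agree: TRUE
```

The recovered turnover rate, 0.000796 changes/gene/My, matches the
generator's truth of 0.0008 — the study was simulated under the tied
single-rate model, so no family should look non-random:

```r
pv <- family_pvalues(fit, n_mc = 500, seed = 2)
sum(pv$p_bh < 0.01)
#> [1] 0

# 3. term enrichment among families contracting inside the bat clade
bat_node <- mrca_node(tree, clades$bats)
maps <- lapply(seq_len(nrow(counts)),
               function(i) ancestral_counts(counts[i, ], tree))
names(maps) <- rownames(counts)
bat_branches <- intersect(nodes_under(tree, bat_node),
                          tree$edge[, 2])
contracted <- unique(unlist(lapply(bat_branches, function(b)
  branch_change_sets(maps, tree, b)$contracted)))
enr <- fisher_enrichment(contracted, rownames(counts), study$terms)
head(enr, 3)
#>     term  k   n   K   N            p p_bonferroni       p_holm   p_sidak
#>  OR-like 78 141 125 500 3.685959e-21 7.740514e-20 7.740514e-20 0.0000000
#>      T08 14 141  31 500 2.829143e-02 5.941200e-01 5.658286e-01 0.4526606
#>      T01 21 141  54 500 4.835346e-02 1.000000e+00 9.187158e-01 0.6468257
```

The generator plants the term `OR-like` on 60% of truly contracting
families in the bat clade versus 10% elsewhere; the test recovers it
(Bonferroni p ≈ 8 × 10⁻²⁰) while the filler terms stay at chance.

```r
# 4. phylogenetically corrected correlation of loss rate and genome size
tt <- tip_turnover(fit, events)
correlate(setNames(tt$expected_losses, tt$species), study$traits,
          use_pic = TRUE, tree = tree)[c("estimate", "p")]
#> $estimate
#> [1] 0.2224539
#> $p
#> [1] 0.3772218
```

The default generator evolves genome size independently of turnover, and
the contrast correlation is accordingly non-significant.

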