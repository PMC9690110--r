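# tipclust

Bayesian nonparametric clustering of gene-expression samples (or any
vector-variate subjects) with the **table invitation prior** (TIP) — a
distance-dependent partition prior that estimates the number of clusters
automatically, with its hyperparameters set by change-point detection on
each subject's sorted pairwise distances rather than by analyst tuning.

## The method in brief

Subjects are rows of an n × p matrix X. Pairwise distances d(i, j) become
attraction weights through an exponential-decay kernel

&nbsp;&nbsp;&nbsp;&nbsp;λ(i, j) = exp(−τ·d(i, j)),&nbsp;&nbsp; τ̂ = 1 / median{d(i, j) : i > j}.

A Gibbs sampler explores partitions: at iteration t a random host r invites
its n̂τr most similar subjects to a proposed new table, where
n̂τr ~ Poisson(first change-point position of r's sorted distances), found by
binary segmentation. Every subject i is then reassigned over tables
k = 1, …, K(t)+1 with probability

&nbsp;&nbsp;&nbsp;&nbsp;P(c_i = k) ∝ Σ_{j : c̃_j = k} λ(i, j) × p(x_i | table k),

where c̃ is the modified (invitation) partition and p(x_i | table k) is the
Normal-Inverse-Wishart posterior predictive (a multivariate Student-t) of
table k fitted on its current members with i held out. Recorded draws are
summarised by the posterior similarity matrix B̄ (entrywise mean of
co-clustering indicators) and a single consensus partition: the recorded
draw maximizing the posterior expected adjusted Rand (PEAR) index against
B̄. Baseline samplers for the Ewens-Pitman Attraction (EPA) prior — with
West's gamma posterior for the mass parameter α — and its Chinese Restaurant
Process special case are included, along with a Gaussian/inverse-Wishart
simulation generator and evaluation metrics (adjusted Rand index), a
maximum-weight spanning-tree "one-cluster" graph of B̄ for visualization,
PCA preprocessing, and a small CLI.

See the methods vignette (`vignettes/tip-clustering-methods.Rmd`) for the
model, defaults, and numerical choices.

## Worked example

```r
library(tipclust)

d <- sim_preset("sim1", seed = 1)    # 4 Gaussian clusters, sizes 20/25/30/35, p = 2
fit <- run_tip(d$X, burn_in = 1000, samples = 1000, seed = 11)
glance(fit)
#> # A tibble: 1 × 7
#>   prior     n     K  pear samples burn_in  seed
#>   <chr> <int> <int> <dbl>   <int>   <dbl> <dbl>
#> 1 tip     110     4 0.873    1000    1000    11

cons <- tip_consensus(fit)
table(consensus = cons$assignment, truth = d$labels)
#>          truth
#> consensus  1  2  3  4
#>         1  0  0  0 35
#>         2  0  0 30  0
#>         3  0 25  0  0
#>         4 20  0  0  0
adjusted_rand(cons$assignment, d$labels)
#> [1] 1
```

The consensus finds exactly the four generating clusters (K = 4; the PEAR
value 0.873 is the expected adjusted Rand of the consensus against the whole
posterior; ARI = 1 against the truth). `tidy(fit)` returns the per-subject
assignments as a tibble, `autoplot(fit)` the cluster-count trace,
`plot_psm(cons)` the similarity heatmap, and
`autoplot(one_cluster_graph(cons$Bbar))` the one-cluster network.

From a shell, the same pipeline runs as

```sh
./exec/tipclust simulate --preset sim1 --seed 1 --out sim.csv
./exec/tipclust run --input sim.csv --label-col .cluster --seed 11 --output out/
```

writing the consensus assignments, B̄, one-cluster edge list, K trace, and a
JSON run report.

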