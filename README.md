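# vamix — vector-attribute assortativity for networks

Networks often wire assortatively: edges preferentially join nodes with
similar attributes. The classic assortativity coefficient *r* handles one
scalar (or categorical) attribute per node. `vamix` is for the case where
each node carries a **vector** attribute x ∈ ℝ^q — an activity profile, a
multi-dimensional behavioral signature, a typed-degree vector — and you want
one bounded, comparable number for how assortatively the network is wired
with respect to it. It is aimed at network scientists and computational
biologists analyzing attributed graphs.

## The method

The index compares the observed mean edge similarity against a Monte-Carlo
null from graph randomization:

1. **Observed statistic.** With a pairwise similarity ξ (cosine by default),
   compute the mean similarity of connected nodes,
   ξ̄_G = (1/m) Σ_{(v,u)∈E} ξ(x_v, x_u).
2. **Null sample.** Rewire the edges B times under a null model — uniform
   G(n,m), degree-preserving edge swaps, or covariate-matched rewiring
   (e.g. preserving the distance distribution of connected nodes) — keeping
   attributes attached to their nodes; recompute the mean similarity ξ̄_i on
   each, giving the sample Ξ.
3. **Empirical test.** ξ̄_G above the upper (1 − sigLevel/2) quantile of Ξ ⇒
   positive mixing; below the lower ⇒ negative; otherwise random. A
   two-sided add-one permutation p-value is reported.
4. **Bounded effect size.** d = (ξ̄_G − mean(Ξ)) / σ_rand, with σ_rand the
   pooled edge-level similarity standard deviation under the null, mapped to
   **α = d / √(d² + ε) ∈ (−1, 1)** (ε = 1 by default).

The package also provides the scalar coefficient *r* (edge-iteration form of
the normalized endpoint covariance), the per-dimension-average baseline
r_base = mean(r_1, …, r_q), a planted-partition generator of attributed
networks with exactly computable ground-truth mixing, and an evaluation
harness (RMSE, Δe = |r_true − α| − |r_true − r_base|, estimator
bias/variance). See the methods vignette
(`vignettes/vector-assortativity.Rmd`) for conventions and design choices.

## Worked example

```r
library(vamix)

g <- exampleGraph()          # 6 nodes in two attribute "camps", 7 edges, q = 2
meanEdgeSimilarity(g)
#> [1] 0.8611154

computeVAIndex(g, B = 200, seed = 42)
#> VA-index result
#>   alpha      = 0.6518  (verdict: positive)
#>   d          = 0.8595
#>   xi_bar_G   = 0.861115   null mean = 0.521247   sigma_rand = 0.395439
#>   p-value    = 0.00995   null 95% interval = [0.304459, 0.75265]
#>   B = 200, epsilon = 1, similarity = cosine, seed = 42
```

Connected nodes are far more similar (0.861) than under random rewiring
(null mean 0.521): the observed value clears the upper end of the null 95%
interval, so the network is positively mixed (p ≈ 0.01 is the smallest
two-sided value B = 200 can resolve), with bounded effect size α ≈ 0.65.

On a planted-partition benchmark with known ground truth:

```r
cfg <- syntheticConfig(n = 100, targetM = 300, q = 4, pIn = 0.9, pOut = 0.1)
net <- generateNetwork(cfg, seed = 1)
rTrue(net)                                            # planted ground truth
#> [1] 0.8055236
computeVAIndex(net@graph, B = 200, seed = 2)@alpha    # VA-index
#> [1] 0.3901181
suppressWarnings(baselineVectorAssortativity(net@graph))  # per-dim baseline
#> [1] 0.2107629
```

Both estimators are attenuated by attribute noise, but the VA-index (0.39)
sits much closer to the planted truth (0.81) than the per-dimension baseline
(0.21), whose signal is diluted across uninformative dimensions.

## Command line

A thin Rscript wrapper exposes the same functionality:

```sh
VAMIX=$(Rscript -e 'cat(system.file("exec", "vamix", package = "vamix"))')
Rscript $VAMIX compute  --edges edges.tsv --attrs attrs.csv \
    --similarity cosine --null gnm --B 1000 --epsilon 1.0 --seed 42 \
    --out result.json
Rscript $VAMIX baseline --edges edges.tsv --attrs attrs.csv --out base.json
Rscript $VAMIX simulate --config suite.yaml --seed 7 --out records.csv
Rscript $VAMIX evaluate --records records.csv --out summary.json
```

Results go to files; logs go to stderr; every output embeds the tool
version, resolved parameters and seed. `--null covariate` matches the
distribution of a pairwise node covariate named via `--covariate-column`.

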