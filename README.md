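# grnarch

Regulatory network topology and the genetic architecture of gene expression.

## The problem

Two robust observations from bulk-tissue eQTL studies sit in tension: the
*cis* fraction of a typical gene's expression heritability,
h²cis/h², is small (median ≈ 0.2–0.3), yet individual *cis*-eQTL effects are
roughly an order of magnitude **larger** than *trans*-eQTL effects. Which
gene-regulatory-network (GRN) architectures are compatible with both?

grnarch is an R package for people who want to ask that question
quantitatively: it simulates GRNs as random directed acyclic graphs,
propagates cis-acting genetic variation through a linear structural equation
model, and decomposes every gene's genetic variance **exactly** — no
individual-level simulation needed — via the total-effects matrix

    L = (I − G)⁻¹ = Σ_t G^t     (finite: G is nilpotent on a DAG)

where `G[j, i]` is the direct effect of gene *j* on gene *i* (magnitude γ,
sign per gene). With each gene's aggregate cis input normalized to unit
variance:

* genetic variance of gene *i*: `V_G,i = (LᵀL)_ii`
* cis fraction: `L_ii² / (LᵀL)_ii = 1 / (LᵀL)_ii`
* trans contribution of regulator *j*: `B_ji² = L_ji² / (LᵀL)_ii`
* distance-resolved fractions: `B_ji²` summed over regulators at directed
  shortest-path distance *d*
* lead trans/cis effect-size ratio: `max_j |L_ji| / |L_ii|`

On top of this sit:

* two calibrated DAG generators — a reparameterized planted-partition model
  (`r` expected regulators/gene, `m` within-group edge fraction, `k` groups)
  and a modular acyclic scale-free generator with out-degree uniformity `d`
  (small `d` ⇒ hub regulators);
* closed-form expected cis fractions for the V, diamond (bi-parallel) and
  triangle (feed-forward) motifs, with an exhaustive sign-enumeration oracle
  that verifies them to 1e-12;
* motif counting, K-S distribution matching of simulated cis-fraction
  distributions against per-gene heritability tables, tail selection of
  matched networks, and OLS residualization/mediation analyses over
  parameter sweeps;
* a synthetic heritability-table generator (Beta fractions, logistic eQTL
  detection) so the whole pipeline runs without any external data.

Everything user-facing returns a tibble; matching and mediation results
support `tidy()`/`glance()`; each result type has a plot function
(`plot_cis_fraction_cdf()`, `plot_distance_profile()`, `autoplot()` on match
objects).

## A worked example

Simulate one modular scale-free GRN of 500 genes with hub regulators, and
decompose expression variance:

```r
library(grnarch)

params <- grn_params(n = 500, k = 5, r = 6, m = 0.8,
                     gamma = 0.4, p_plus = 0.8, d = 2)
grn <- assign_signs(generate_scalefree_dag(params, seed = 1),
                    params$p_plus, params$gamma, seed = 1)
grn
#> <signed_grn> 500 genes, 2978 edges, gamma = 0.4, 407 activators

eff <- total_effects(grn)
decomp <- variance_decomposition(eff)
decomp
#> # A tibble: 500 × 9
#>    gene index   v_g cis_fraction trans_fraction lead_trans_fraction lead_ratio
#>   <int> <int> <dbl>        <dbl>          <dbl>               <dbl>      <dbl>
#> 1     1    59  1.16        0.862          0.138               0.138       0.4
#> 2     2   315  2.62        0.381          0.619               0.119       0.56
#> 3     3   205  1.35        0.743          0.257               0.119       0.4
#> 4     4    50  1.16        0.862          0.138               0.138       0.4
#> # ℹ 496 more rows
```

Gene 1 is regulated only directly (its single strongest regulator carries
all of its 13.8% trans variance, effect 0.4 = γ); gene 2 sits deeper in the
network, where accumulated indirect regulation leaves only 38% of its
genetic variance in *cis*. Summarizing the whole network:

```r
summarize_grn(decomp, grn$topology, count_motifs(grn$topology),
              distance_decomposition(eff))
#>   median_cis_fraction median_lead_ratio median_ancestors median_cum2 n_ffl n_biparallel
#> 1           0.4273487           0.55104               25   0.9871367  1066         2029
```

The median gene keeps 43% of its genetic variance in *cis*, has 25 upstream
regulators, and 98.7% of its heritability is explained by regulators within
two hops — the signature of a hub-rich, motif-rich architecture.

A full experiment — sweep 500 such networks, match them against a reference
cis-fraction distribution, inspect what the matched networks look like:

```r
ref <- generate_synthetic_table(11409, 0.28, seed = 1)
sweep <- run_sweep(preset_config("scalefree", "desk", seed = 1))
match <- run_matching(sweep, ref, tail_fraction = 0.025)
glance(match)    # matched-set medians vs background
autoplot(match)  # parameter distributions, matched vs background
```

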