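# depmimic

Analysis of collective departures in socially structured animal groups.

When a wild group breaks camp, one individual initiates and the others decide
*whether* and *when* to follow. That decision reflects individual traits (age,
sex, vulnerability), social structure (who is bonded to whom) and immediate
context (who is standing where). `depmimic` implements the complete analysis
chain used to untangle these influences in small primate-style groups —
behavioural ecologists working with departure-order and group-scan data are
its audience — together with an agent-based simulator of the joining process
so that every statistic in the chain can be validated by parameter recovery.

## What it computes

**Affiliation.** From instantaneous group scans, the per-dyad grooming and
huddling rates (interactions over scans in which both individuals were
visible), combined into the dyadic composite sociability index

    DSI_xy = ( g_xy / ḡ  +  h_xy / h̄ ) / 2

where ḡ and h̄ are the group means over dyads. The group mean DSI is 1 by
construction; a right-skewed distribution (median well below 1) means
affiliation is concentrated in few dyads. Network-level structure is
summarised by Newman's weighted assortativity coefficient for age-sex
classes.

**Travel association.** The inter-departure interval of a dyad,

    IDI_xy = (1/n) Σ_i |t_xi − t_yi| / m_i ,

the mean absolute difference in departure time across the n movements both
joined, each normalised by that movement's mean pairwise difference m_i.
Dyads that habitually leave in close succession have a small IDI; the
all-dyad average within any movement is exactly 1.

**Departure order and cohesion.** Van / centre / rear position scores (the
two first and two last movers frame the centre), follower-count histograms
with a χ² test of homogeneity, joining-latency summaries, and
distance-category occupancy (five ordinal bins: 0–1, 1–3, 3–5, 5–10, >10 m).

**Inference.** Regressions of IDI on DSI and of proximity on DSI with
node-label permutation tests (individual identities shuffled within group, so
dyadic non-independence is respected), mixed/fixed-effect models of following
latency on distance category, last-follower latency on group size, and
no-intercept position-score models with multiplicity-adjusted class
contrasts; Holm correction within each model family.

**Simulation.** A Gillespie-style competing-risks simulator in which an
undeparted individual j joins with hazard

    λ_j(t) = λ0 · exp( β_N·D(t) + β_A·Σ_{k departed} w_jk − β_S·s_j(t) )

(D = number already departed; w = latent affiliation weights; s_j = scaled
rank of j's distance to the most recent departer). β_N, β_A and β_S switch on
anonymous, affiliative and spatial mimetism respectively; with all three at
zero, joining reduces to exchangeable exponential waits with known closed
forms.

## Worked example

```r
library(depmimic)

cfg <- sim_config(seed = 42)          # four groups, 31 individuals, 167 events
sim <- simulate_dataset(cfg)

groom <- dyadic_rate(sim$scans, "grooming", sim$groups)
hud   <- dyadic_rate(sim$scans, "huddling", sim$groups)
dsi   <- compute_dsi(groom, hud)
dsi_summary(dsi)
#>   group_id n_dyads mean median fraction_above_mean skewness
#> 1       G1      28    1  0.520               0.286     1.82
#> 2       G2      15    1  0.386               0.333     1.88
#> 3       G3      15    1  0.735               0.333     1.17
#> 4       G4      55    1  0.432               0.273     1.99

idi <- compute_idi(sim$events, sim$groups)
set.seed(42)
fit_idi_on_dsi(idi, dsi, n_perm = 2000)
#> <dep_model> idi_on_dsi (lm, n = 113)
#>          term   estimate      se ci_lower ci_upper   p_value
#> 1 (Intercept)  1.092e+00 0.03135  1.02955  1.15382 1.529e-60
#> 2         dsi -9.169e-02 0.01099 -0.11347 -0.06990 2.636e-13
#> ...
#> permutation p (2000 node permutations): dsi = 5e-04
```

The summary table says each group's DSI averages exactly 1 (the index's
normalisation) while the medians sit far below it — bonds are concentrated in
few dyads. The regression recovers the affiliative-mimetism signature built
into the simulation: a higher DSI predicts a *shorter* inter-departure
interval (negative coefficient), and the node-permutation p-value shows the
association is far stronger than expected from relabelling individuals.
`run_pipeline()` performs this whole chain (plus position, cohesion,
occupancy and latency-distance analyses) and writes CSV/JSON outputs and a
markdown report; `run_recovery_suite()` tabulates sign-recovery and
false-positive rates across null/affiliative/spatial scenarios.

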