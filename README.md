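# cladeshift

Birth–death diversification analysis for dated phylogenies whose tips are
higher taxa (families, superfamilies) carrying extant species-richness
counts — the setting in which questions like *"did the origin of complete
metamorphosis accelerate insect diversification?"* are asked. The package
is organised as an analysis workflow: every computation lives in exported,
tested functions, and the numbered scripts under `analysis/` run the whole
study on a synthetic dataset generated at the published scale.

## What it computes

For a *richness tree* — a rooted ultrametric chronogram (ages in Ma) joined
to a table of per-terminal species counts — `cladeshift` provides:

* **Combined likelihood.** Each diversification regime is a constant-rate
  birth–death process with net rate `r = λ − μ` and turnover `ε = μ/λ`. The
  log-likelihood sums the reconstructed-process (Nee) density of the
  observed internal splits (per branch: `log r − r(t₁−t₂) −
  log(1 − ε e^{−r t₁})`) and, for each terminal with richness `nᵢ` and stem
  age `tᵢ`, the survival-conditioned geometric mass
  `(1−β)β^{nᵢ−1}` with `β = (e^{rt}−1)/(e^{rt}−ε)`. With all terminals
  monotypic this equals the Nee crown-conditioned likelihood exactly.
* **Stepwise shift detection** (`stepwise_search`): greedy MEDUSA-style
  forward selection of rate-shift nodes, `k = 2 + 3s`, accepted at a fixed
  AIC improvement threshold (default 4), deterministic tie-breaking.
* **Single-shift placement comparison** (`placement_scan`,
  `single_shift_fit`, `lrt`): alternative named placements fit with turnover
  fixed at the homogeneous estimate and ranked by likelihood, with
  `χ² = 2 ΔlnL` tests.
* **Richness ratios** (`richness_ratio`, `ratio_timeline`): observed clade
  richness (corrected for nested shifts) over the expectation
  `e^{rt}/(1−α)` under the parental regime, with 95% bounds from the
  closed-form clade-size quantiles.
* **Ensemble robustness** (`search_ensemble`, `tally_robustness`): the
  identical search repeated over dated-tree ensembles with fixed topology,
  shifts matched by exact leafset and binned at >80% / >50% / >30% / <30%
  recovery.
* **Lineage-through-time curves** (`ltt_curve`, `ltt_envelope`) with
  ensemble quantile bands.
* **A seeded generator** (`simulate_bd`, `simulate_with_shift`,
  `collapse_to_higher_taxa`, `pseudo_posterior`, `simulate_bd_counts`) for
  multi-regime chronograms, higher-taxon collapses with truth tables, and
  pseudo-posterior age ensembles.

## Worked example

`analysis/01_simulate_study_system.R` generates a dated family-level tree
with the published crown age (474 Ma) and turnover (0.5) and a single
upshift preserving the published 3.1× net-rate contrast
(0.0104 → 0.0326 /Ma, originating 150 Ma), collapsed at 50 Ma. One run
gives 65 terminals totalling 317 species, 20 of them descending from the
shifted lineage. The remaining scripts then print:

```
uniform model: r = 0.00986 /Ma, eps = 0.789, lnL = -476.603

shift model: 1 shift(s), lnL = -444.930, k = 5, AIC = 899.860
 regime shift_node           r       eps n_edges n_terminals
      1         NA 0.009936306 0.3146149      89          45
      2         86 0.035461467 0.2642272      39          20
accepted 1 shift(s); first = node 86 (true shifted clade node 86)

best placement: true_clade; chi2 vs uniform = 55.36 (df 3, p = 5.76e-12)

  node   age observed expected ratio direction
1   86 187.5      215    8.943 24.04        up

tallied 3 clades over 100 trees; top recovery 0.99
```

Reading this: the homogeneous fit recovers the background net rate
(0.0099 vs 0.0104 simulated); the stepwise search accepts exactly one
shift, at the true node, with the clade rate 0.0355 vs 0.0326 simulated;
the placement scan prefers the true clade decisively over its parent,
children and an outgroup; the clade holds 215 species where ~9 were
expected under the background regime (a 24-fold upshift); and the shift is
recovered in 99% of a 100-sample node-age ensemble (the top robustness
class). Tables land under `results/` as TSV/JSON plus annotated NEXUS
trees.

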