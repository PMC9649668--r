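# frugnet

Habitat fragmentation reshapes the networks that link fleshy-fruited
plants to the frugivorous birds that disperse their seeds. `frugnet` is an
R package for ecologists analysing such plant-frugivore networks (PFNs)
sampled by arboreal camera traps across fragmented landscapes — for
example reservoir archipelagos, where former hilltops become land-bridge
islands spanning orders of magnitude in area.

The package covers the full analysis chain:

* **Event processing** — the five-minute independence rule (consecutive
  records of the same plant-frugivore interaction merge unless separated by
  more than five minutes, with gap-chaining), weighted network
  construction, aggregation across sites.
* **Structure** — connectance $C = L/(P \cdot B)$; Barber's bipartite
  modularity $Q = \sum_m (w_m/F - K_m D_m / F^2)$ maximised by the
  LPAwb+/DIRTLPAwb+ label-propagation algorithm; weighted nestedness
  (wNODF, 0–100); per-species normalised degree.
* **Null models** — Patefield fixed-marginal randomisation with
  $\Delta = \mathrm{Obs} - \overline{\mathrm{Null}}$ and
  $z = \Delta/\mathrm{sd}(\mathrm{Null})$ transformations and 95%
  percentile-interval significance calls.
* **Stability** — co-extinction cascades under four removal scenarios
  (random / worst-case by plant abundance / best-case reversed / size-case
  by bird body mass), with robustness $R$ the area below the secondary
  extinction curve.
* **Sampling checks** — abundance-based sample coverage
  $\hat C = 1 - (f_1/n)[(n-1)f_1/((n-1)f_1 + 2f_2)]$ over link
  frequencies, and camera-day rarefaction to a common effort.
* **Island statistics** — multiple regressions on log10 area and
  isolation, species-area vs interactions-area slope comparison,
  incidence-function connectivity indices, and a piecewise structural
  equation model summarised by Fisher's
  $C = -2\sum \ln p_i \sim \chi^2_{2k}$ with indirect effects as products
  of standardised path coefficients.
* **Synthetic data** — an archipelago generator with tunable nestedness
  and modularity, known occupancy and detection ground truth, and
  burst-structured camera streams, so the whole pipeline runs and is
  tested without external data.

## Worked example

```r
library(frugnet)

cfg <- archipelago_config(n_islands = 6, n_plants = 15, n_birds = 18,
                          camera_days_per_island = 120,
                          detection_rate_per_day = 1.5, seed = 2024)
islands <- generate_archipelago(cfg)
sys     <- generate_species_system(cfg, islands)
events  <- generate_event_log(sys$truth, islands, cfg)

indep <- filter_independent_events(events)
cat(nrow(events), "raw records ->", nrow(indep), "independent events\n")

M <- build_network(indep[indep$island_id == "I01", ], "I01")
cat("I01 network:", nrow(M), "plants x", ncol(M), "birds,",
    sum(M > 0), "links\n")
cat(sprintf("connectance = %.3f, wNODF = %.1f, Q = %.3f\n",
            connectance(M), wnodf(M), dirt_lpa_wb_plus(M, seed = 1)$Q))

ns <- null_ensemble(M, wnodf, N = 200, metric = "wnodf", seed = 9)
print(ns[, c("metric", "obs", "delta", "z", "significant")], digits = 3)

rob <- simulate_robustness(M, "random", reps = 200, seed = 4)
cat(sprintf("random-removal robustness: mean R = %.3f (sd %.3f)\n",
            rob$mean_R, rob$sd_R))
```

prints

```
4440 raw records -> 3393 independent events
I01 network: 6 plants x 10 birds, 37 links
connectance = 0.617, wNODF = 55.7, Q = 0.323
  metric  obs delta   z significant
1  wnodf 55.7 -22.9 -11        TRUE
random-removal robustness: mean R = 0.826 (sd 0.079)
```

Reading this: about a quarter of the raw records were within-burst
duplicates removed by the independence filter. Island I01's network
realises 62% of its possible links; its weighted nestedness (55.7) is far
*below* the Patefield expectation for its margins (z = -11, significant),
the typical situation for observed PFNs; and under random plant loss the
bird guild decays slowly (R near 0.8), reflecting the many shared partners
of a densely connected network.

`run_all()` chains every stage (simulate → networks → metrics → nulls →
robustness → sampling → stats) with seeded substreams and writes tidy CSV
outputs plus a run manifest; `frugnet_cli()` (or the thin wrapper at
`inst/scripts/frugnet`) exposes the same stages as shell subcommands.

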