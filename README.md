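# nucleoFold

Does higher-order chromatin folding feed back on the nucleosomes beneath
it? Proteins that bridge distant chromatin segments — polymerising
Polycomb subunits such as PH, or loop-anchoring factors such as CTCF —
change both 3D contacts and, experiments suggest, the occupancy of the
underlying nucleosomes. `nucleoFold` packages the two analyses needed to
study that coupling:

* **A coarse-grained chromatin polymer model.** A bead-spring chain whose
  beads carry a binary nucleosome state \(\rho_i\), sampled by Metropolis
  Monte Carlo. The energy couples nucleosome assembly/disassembly
  (chemical potential \(\mu = -\ln(k_{on}/k_{off})\)) to 3D contacts: bound
  bead pairs within \(r_{cut} = 1.5\sigma\) gain \(\varepsilon_s\) when
  both are specifically interacting beads (SIBs, modelling protein-binding
  sites) and the weak inter-nucleosome attraction \(\varepsilon_w\)
  otherwise, on top of harmonic springs
  (\(k_s = 100\,k_BT/\sigma^2\)) and WCA excluded volume:

  \(E = V_{sp} + V_{LJ} + \mu \sum_i \rho_i -
  \sum_{(i,j)}^{3D} [\varepsilon_s \tau_{ij} + \varepsilon_w(1-\tau_{ij})]\,
  \rho_i \rho_j\)

  Drivers sweep \((\mu, \varepsilon_w, \varepsilon_s, f_{SIB})\) for
  phase diagrams of mean nucleosome density \(\bar\rho\) and radius of
  gyration \(R_g\), transition curves of weak-contact counts, per-bead
  occupancy profiles, and a two-region heteropolymer (SIBs confined to
  one half) measuring the left-minus-right density difference.

* **An MNase-titration-seq pipeline.** From mapped paired-end fragments
  at several MNase concentrations: insert-size filtering (50–500 bp),
  hotspot masking (z > 7 on fragment-start counts), 300-bp binning by
  fragment midpoint, reads-per-million normalisation, titration-averaged
  nucleosome occupancy per condition, per-bin condition differences, and
  aggregation around site centres, scaled gene bodies, consolidated
  contact regions and random-site controls. MACC accessibility is the
  per-bin OLS slope of normalised frequency against log10(MNase U),
  GC-corrected by loess detrending; differential accessibility uses an
  empirical replicate-based null with Benjamini–Hochberg control.

* **A synthetic-data generator** emulating the titration design
  (3 conditions × 2 replicates × 5 concentrations) over a toy genome
  with known per-bin protection and accessibility truth, so every
  pipeline stage is testable without sequencing downloads.

## Worked example

Simulate the non-interacting limit, where nucleosome flips decouple from
geometry and per-bead occupancy has the closed form \(1/(1+e^\mu)\):

```r
library(nucleoFold)

state  <- buildSingleRegion(200, fSib = 10, seed = 1)   # 20 SIBs
params <- modelParams(200, mu = 1)                      # eps_s = eps_w = 0
run    <- runSimulation(state, params,
                        mcSchedule(2e4, 2e4, 100, 3, seed = 1))
replicateObservables(run)
#>   replicate  rho_bar       rg n_weak  lr_diff
#> 1         1 0.272300 7.797392 20.495 -0.00550
#> 2         2 0.271575 7.659415 21.130  0.00325
#> 3         3 0.269575 7.738714 21.090 -0.00715
1 / (1 + exp(1))
#> [1] 0.2689414
```

Three independent chains each estimate \(\bar\rho \approx 0.27\),
matching the free-bead expectation at \(\mu = 1\); `n_weak` counts
bound bead pairs within \(r_{cut}\) (a geometric count, nonzero even
though \(\varepsilon_w = 0\) makes them energetically silent here).
Switching on interactions (`epsS = 4, epsW = 0.4`) raises occupancy
preferentially at SIB positions
(`occupancyProfile(run)[state@sibIndices]`) and compacts the chain
(`ensembleRg(run)`).

On the pipeline side, a full recovery run from synthetic fragments:

```r
cfg <- synthConfig()                 # 3 x 2 x 5 titration design, depth 100
g   <- makeToyGenome(cfg)
fr  <- simulateTitration(cfg, "base")
bs  <- rpmNormalize(binFragmentCounts(hotspotFilter(filterFragmentsByInsert(fr)),
                              g$chromSizes, 300))
occ <- rowMeans(signalValues(bs))    # titration-averaged occupancy
cor(occ, truthTable(cfg, "base")$o)
#> [1] 0.9802
macc <- maccTrack(bs, gc = gcFraction(g$bins, g$seq))
cor(macc$macc, truthTable(cfg, "base")$a, method = "spearman")
#> [1] 0.9132
```

Occupancy tracks the generating per-bin protection (r ≈ 0.98) and the
GC-corrected MACC scores track the injected accessibility coefficients
(Spearman ≈ 0.91 at depth 100).

## Package layout

* `R/` — S4 classes (`ModelParams`, `PolymerState`, `McSchedule`,
  `BinnedSignal`, `SiteMatrix`, `SynthConfig`), energy functions, MC
  drivers, observables, pipeline, MACC and generator modules.
* `src/` — the Rcpp Metropolis engine with incremental energy updates.
* `vignettes/methods.Rmd` — the model, its assumptions, parameter
  meanings, numerical conventions and known limitations.
* `tests/testthat/` — unit, property and end-to-end recovery tests.
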