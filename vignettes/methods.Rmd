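---
title: "Methods: coupled nucleosome occupancy and chromatin contacts"
author: "nucleoFold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled nucleosome occupancy and chromatin contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`nucleoFold` couples two analyses of the same biological question — does
higher-order chromatin folding feed back on the nucleosomes underneath it?
— in one package:

1. a coarse-grained Monte Carlo polymer model in which nucleosome
   assembly/disassembly competes with 3D contact energies, used to ask how
   distant specific contacts (of the kind mediated by polymerising
   chromatin proteins such as PH/PRC1 or CTCF-anchored loops) change local
   nucleosome density, and
2. an MNase-titration-seq analysis pipeline (occupancy and MACC
   accessibility) that quantifies the corresponding experimental readout
   around binding sites, contact regions and gene classes, with a fully
   synthetic data generator supplying ground-truth datasets.

# The polymer model

Chromatin is a chain of $N$ beads of diameter $\sigma$ joined by harmonic
springs. Each bead $i$ carries a two-state nucleosome variable
$\rho_i \in \{0, 1\}$, and a subset of beads — the specifically
interacting beads (SIBs) — represent protein-binding sites. The total
energy, in units of $k_BT$, is

$$
E = \sum_{i=1}^{N-1} \tfrac{1}{2} k_s (q_i - q_0)^2
  + \sum_{i<j} V_{\mathrm{WCA}}(r_{ij})
  + \mu \sum_i \rho_i
  - \sum_{(i,j):\, r_{ij} < r_{cut}}
    \left[ \varepsilon_s \tau_{ij} + \varepsilon_w (1 - \tau_{ij}) \right]
    \rho_i \rho_j ,
$$

with $q_i = |r_i - r_{i+1}|$, $V_{\mathrm{WCA}}$ the purely repulsive
(cut-and-shifted at $2^{1/6}\sigma$) Lennard-Jones potential, and
$\tau_{ij} = 1$ iff beads $i$ and $j$ are both SIBs. The chemical
potential $\mu = -\ln(k_{on}/k_{off})$ prices each bound nucleosome:
positive $\mu$ favours disassembly. A bound pair of 3D neighbours
($r_{ij} < r_{cut}$) gains $\varepsilon_s$ if specific (SIB–SIB) and the
weak inter-nucleosome attraction $\varepsilon_w$ otherwise; unbound beads
interact only sterically.

Defaults follow the natural unit system: $\sigma = 1$, $\varepsilon = 1$,
$k_s = 100\,k_BT/\sigma^2$, $q_0 = 1$, $r_{cut} = 1.5\sigma$, maximum
trial displacement $0.5\sigma$, $k_BT = 1$.

## Pair conventions

Two conventions are genuinely open and we fixed them as follows:

* **Chain-adjacent pairs.** Nothing excludes bonded neighbours from the
  3D sums, so by default all unordered pairs participate, including
  $|i-j| \le 1$. `includeChainAdjacent = FALSE` removes bonded pairs from
  the *contact/interaction* sum (and from weak-contact counting) for
  sensitivity checks; the steric term always runs over all pairs, which is
  the standard treatment for harmonically bonded beads.
* **Mixed pairs.** $\tau_{ij} = 1$ only when *both* beads are SIBs;
  SIB–non-SIB and non-SIB pairs use $\varepsilon_w$. Literally, this means
  SIB–SIB pairs lose even the weak attraction when $\varepsilon_s = 0$ —
  a small compositional asymmetry visible in two-region controls.

## Monte Carlo protocol

Sampling uses Metropolis Monte Carlo with the model's two trial moves:
a random bead displaced by a per-coordinate uniform amount in
$[-0.5\sigma, 0.5\sigma]$, and a nucleosome flip $\rho \to 1-\rho$ on an
independently chosen bead. One MC step performs $N$ iterations of one
displacement trial followed by one flip trial. Energy differences are
evaluated incrementally (only terms touching the moved bead), with a pair
pre-filter: a move of bounded length cannot alter any energy term of a
pair whose single-axis separation already exceeds every cutoff plus
$\sqrt{3} \times$ the maximum displacement. The engine recomputes the full
energy at every retained sample and reports the worst bookkeeping
discrepancy; the test suite holds it below $10^{-6}$ (observed
$\sim 10^{-11}$) and independently re-derives sampled energies, radii of
gyration and contact counts in R.

Choices the energy function does not dictate:

* **Initial state**: a self-avoiding random walk with exact bond length
  $q_0$ (non-bonded beads kept $\ge 0.95\sigma$ apart) and all beads
  nucleosome-bound; equilibration then relaxes the high-density phase
  toward the target state.
* **Run lengths** are free parameters of `mcSchedule()`; the package
  default (2×10^5 equilibration + 2×10^5 sampling steps, stride 100,
  5 replicates) comfortably passes the analytic non-interacting check for
  $N = 200$.
* **Replicates** restart the same initial state under seeds
  `seed + 1 ... seed + R`, making every run exactly reproducible;
  standard errors are computed across these independent chains, never
  across autocorrelated within-chain samples. Near the collapse
  transition the global conformation decorrelates slowly, so analyses that
  compare compaction across parameter values either pair runs started
  from the same walk (so the slow mode cancels) or average over
  independently built walks.
* **Coincident-bead guard**: proposals that would bring two beads within
  $10^{-6}\sigma$ are rejected outright; WCA repulsion makes this
  practically unreachable.
* **SIB placement**: "distributed uniformly" is read as evenly spaced
  along the chain (deterministic); uniform random placement is available
  via `sibPlacement = "random"`.

## Observables

* mean nucleosome density $\bar\rho = \langle \frac{1}{N}\sum_i \rho_i
  \rangle$, and the per-bead occupancy profile whose bead-average equals
  $\bar\rho$ exactly;
* radius of gyration: per sample $R_g = \sqrt{\frac{1}{N} \sum_i (r_i -
  r_{com})^2}$; the ensemble value averages the *squared* quantity over
  samples before taking the root, following the placement of the ensemble
  average inside the radical;
* weak contacts: the number of unordered pairs with $r_{ij} < r_{cut}$,
  $\rho_i = \rho_j = 1$ and $\tau_{ij} = 0$. The printed phrase "number
  of beads which interact" is read as a *pair* count (matching the
  parenthetical pair condition); `countBeads = TRUE` gives the bead-count
  variant;
* the two-region model: an even-$N$ chain with SIBs evenly spaced in the
  left half only; the headline quantity is the left-minus-right density
  difference.

Sweep drivers (`sweepSimulations`, `transitionCurves`) emit long-format
tables with replicate means and standard errors; default grid ranges
$\mu \in [0, 2]$, $\varepsilon_w \in [0, 1]$ bracket the printed example
points ($\mu = 0.8, 1.0$; $\varepsilon_w = 0.4, 0.6$;
$\varepsilon_s = 2\!-\!6$; SIB fractions 5–20%). The $\bar\rho = 0.5$
contour of a sweep matrix is the package's only phase-boundary notion; no
free-energy fitting is attempted.

# The MNase-titration pipeline

Inputs are mapped paired-end fragment intervals (insert = fragment
length) tagged by condition, replicate and MNase concentration; the
deposited design is 3 cell lines × 2 replicates × 5 concentrations
(1.5, 6.25, 25, 100, 400 U). Processing:

1. **Insert filter**: keep lengths in [50, 500] bp, bounds inclusive.
2. **Hotspot mask**: z-scores of per-position fragment-start counts
   (default over non-zero-coverage positions, genome-wide; per-chromosome
   and zero-inclusive variants available); positions with $z > 7$ are
   masked and fragments starting there dropped. Whether the original
   filter pooled zero-coverage positions is not recoverable; the
   non-zero default is documented here.
3. **Binning**: 300-bp non-overlapping bins, trailing partial bin kept;
   a fragment is assigned to the bin containing its midpoint (dyad-centric
   and double-counting-free; overlap-proportional weighting available).
4. **Normalisation**: reads per million of the library.
5. **Occupancy**: the unweighted per-bin mean over all (concentration ×
   replicate) tracks of a condition — the "2 × 5 = 10 experiments"
   average; condition differences are per-bin subtractions on the shared
   grid.

Aggregation geometries reproduce the figure-level summaries: site-centred
matrices (sites aligned by centre, `floor((start+end)/2)` in 0-based
coordinates for even widths; windows of 50 bp by default; sites whose
window leaves the chromosome are excluded from column means), scaled-region
matrices (equal sub-intervals per region), midpoint-in-region bin sets for
contact regions, uniform random-site controls, and two-sample t /
Wilcoxon comparisons of per-site value distributions. Contact
consolidation keeps intervals supported by ≥ 2 replicate sets within a
dataset, pools datasets, and merges overlapping/bookended intervals.

Coordinates are held in 1-based closed `GRanges` internally, the native R
representation; BED input/output converts at the boundary, and all
worked examples of the binning and centring arithmetic are specified (and
tested) in 0-based half-open terms.

# MACC accessibility

MACC is the ordinary least-squares slope of RPM-normalised per-bin
frequency against $\log_{10}$(MNase concentration): positive slopes mark
chromatin that releases more fragments as digestion strengthens
(accessible), negative slopes the reverse. The log base only rescales all
slopes by one constant; 10 is used throughout. Replicates enter the
regression as pooled independent points by default
(`averageReplicates = TRUE` averages them per concentration first).

The raw slopes are then GC-corrected: a loess trend (span 0.3, degree 1)
of slope on bin GC fraction is subtracted, leaving residuals with ≈ zero
linear GC correlation while preserving rank order within narrow GC
strata; below 100 bins a linear detrend substitutes. Whether the original
correction acted per concentration before the regression or on the slope
after it is not stated in the source material; the slope-level correction
matches the order of the described steps and the per-concentration
variant can be composed manually from `maccSlope` on corrected tracks.

Differential accessibility between conditions is not specified beyond
volcano-style counts, so the package adopts an explicit artifact
convention: the per-bin difference of replicate-mean MACC scores is
compared against an empirical null built from within-condition
replicate-difference contrasts, scaled so the null variance matches the
between-condition contrast under no effect ($({d_A - d_B})/2$ for two
replicates per condition); two-sided empirical tail probabilities receive
Benjamini–Hochberg control at 0.05. Both the null construction and the
threshold are configurable, and with one replicate per condition the
difference is reported with significance withheld.

# The synthetic-data generator

The generator emulates the *structure* of the deposited titration design
(3 conditions × 2 replicates × 5 concentrations over an annotated
genome), not its sequence biology. Expected fragments in bin $b$ at
concentration $c$:

$$\lambda_{b,c} = \text{depth} \cdot o_b \cdot
  \max\!\left(0,\, 1 + a_b (\log_{10} c - \overline{\log_{10} c})\right)$$

with $o_b$ the condition's per-bin protection — a smooth field (mean 0.7,
range ±0.2) plus a per-condition shift at site bins — and $a_b$ a
three-class accessibility coefficient (25% positive, 25% negative, the
rest zero) with heterogeneous magnitudes within the non-zero classes
(mean 0.5, uniform over 0.25–0.75). The class design matters for what
the recovery tests measure: rank statistics against a truth with a large
tied class are capped by the tie structure alone (a 15/15/70 split with
one shared magnitude caps Spearman below 0.8 even for a perfect
estimator), so fractions and magnitudes are chosen to keep the ceiling
well above the tested range — recovery checks are then noise-limited and
sensitive to estimator quality. Counts are Poisson, midpoints uniform
within the bin, insert lengths normal (150 ± 25 bp) truncated to
[50, 500] with 2% out-of-range contamination to exercise the insert
filter. Chromosome sequences follow a smooth per-bin GC profile
(0.35–0.65) so the GC correction has a real covariate. Everything is
deterministic from one seed (byte-identical regenerated files).

Condition structure mirrors the biology being modelled: `depleted`
(binding-site protection −0.2, mimicking the polymerisation-deficient
state's clear occupancy loss), `enriched` (+0.1, the milder gain of the
stabilised state) and `base`. One hundred non-site bins additionally gain
+0.6 accessibility in `depleted`, the ground truth for differential-MACC
recovery. The separable $o_b \times$ titration-slope form is the minimal
model in which occupancy and MACC are identifiable and independently
perturbable; $|a_b| < 1/\max_c |\log_{10} c - \overline{\log_{10} c}|
\approx 0.82$ keeps expected counts positive at every titration point.

What the generator deliberately does **not** model — MNase sequence cut
bias, nucleosome positioning/phasing, read-level errors, mappability,
hotspot artefacts, real fragment-length mixtures — bounds what passing
recovery tests show: the pipeline's estimators are consistent and
correctly signed on clean, identifiable data at realistic depth, not that
they overcome every artefact of real libraries.

# Problem sizes used by the test suite

Simulation checks run at reduced, fixed scales chosen to keep the full
suite in the tens of minutes while leaving each scientific effect several
standard errors wide: the analytic non-interacting check uses $N = 200$
with 5 chains of 5×10^3 + 2×10^4 steps; the $(\mu, \varepsilon_w)$ phase
diagram uses a 6×6 grid at $N = 100$ with duplicate chains of 2.5×10^3 +
2.5×10^3 steps; transition curves use $N = 200$ with three paired
same-start runs of 1.2×10^4 + 8×10^3 steps per $\varepsilon_s$ (the
compaction contrast, whose global mode relaxes far more slowly than the
density, uses paired endpoint runs of 6×10^4 + 2×10^4 steps pooled over
both weak-interaction strengths); the
two-region contrast uses $N = 400$ with five independently built chains
of 2×10^4 + 10^4 steps. Pipeline recovery runs the generator defaults
(2 × 150 kb chromosomes, 1,000 bins, depth 100 per bin per library).
The acceptance script runs the full-length schedule (5 chains of 2×10^5 +
2×10^5 steps) for the non-interacting density.

# Known limitations

* Single-move Metropolis dynamics equilibrate the collapsed phase slowly;
  no cluster moves, reptation or parallel tempering are provided, so
  deep-globule observables at large $\varepsilon$ need long schedules.
* The model has no bending rigidity, hydrodynamics or explicit protein
  particles, and nucleosome state is binary — by design.
* The differential-MACC null treats bins as exchangeable; bins with
  strong titration slopes have slightly inflated replicate variance, so
  the empirical FDR can exceed the nominal level in their vicinity.
* Real-data coordinate lift-over, alignment, duplicate marking and peak
  calling are out of scope; the pipeline starts from mapped fragment
  intervals.
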