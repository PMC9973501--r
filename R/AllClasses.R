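#' @import methods
#' @importFrom stats rnorm runif rpois sd loess loess.control lm resid
#'   predict p.adjust t.test wilcox.test cor setNames quantile
#' @importFrom utils head tail write.table read.table
NULL

#' Energy and sampling constants of the chromatin polymer model
#'
#' Holds every constant of the coarse-grained bead-spring chromatin model:
#' a chain of `nBeads` beads of diameter `sigma` joined by harmonic springs
#' (stiffness `kSpring`, rest length `q0`), purely repulsive (WCA)
#' Lennard-Jones excluded volume of strength `epsLJ`, a chemical potential
#' `mu` paid per nucleosome-bound bead, and an attractive contact term acting
#' between nucleosome-bound bead pairs closer than `rCut` in 3D: strength
#' `epsS` when both beads are specifically interacting beads (SIBs,
#' representing protein-binding sites) and `epsW` (weak inter-nucleosome
#' attraction) otherwise. All energies are in units of the thermal energy
#' \eqn{k_BT}; all lengths in units of `sigma`.
#'
#' @slot nBeads integer, number of beads (N >= 2).
#' @slot sigma numeric, bead diameter (length unit; default 1).
#' @slot epsLJ numeric, Lennard-Jones energy scale (default 1).
#' @slot kSpring numeric, spring constant in \eqn{k_BT/\sigma^2} (default 100).
#' @slot q0 numeric, equilibrium bond length (default 1).
#' @slot mu numeric, nucleosome chemical potential
#'   \eqn{\mu = -\ln(k_{on}/k_{off})}; higher values favour dissociation.
#' @slot epsS numeric, specific (SIB-SIB) interaction strength, >= 0.
#' @slot epsW numeric, weak inter-nucleosome interaction strength, >= 0.
#' @slot rCut numeric, 3D neighbour cutoff (default 1.5).
#' @slot maxDisp numeric, maximum per-coordinate trial displacement
#'   (default 0.5).
#' @slot includeChainAdjacent logical; if `TRUE` (default) chain-bonded
#'   neighbours (|i-j| <= 1) participate in the 3D contact sum.
#' @export
setClass("ModelParams",
  representation(
    nBeads = "integer", sigma = "numeric", epsLJ = "numeric",
    kSpring = "numeric", q0 = "numeric", mu = "numeric",
    epsS = "numeric", epsW = "numeric", rCut = "numeric",
    maxDisp = "numeric", includeChainAdjacent = "logical"
  )
)

setValidity("ModelParams", function(object) {
  msg <- character()
  if (length(object@nBeads) != 1L || is.na(object@nBeads) || object@nBeads < 2L)
    msg <- c(msg, "nBeads must be a single integer >= 2")
  for (s in c("sigma", "rCut", "kSpring", "maxDisp", "q0"))
    if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be > 0"))
  if (object@epsS < 0) msg <- c(msg, "epsS must be >= 0")
  if (object@epsW < 0) msg <- c(msg, "epsW must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct model parameters
#'
#' @param nBeads number of beads.
#' @param sigma,epsLJ,kSpring,q0,mu,epsS,epsW,rCut,maxDisp model constants;
#'   see [ModelParams-class] for meaning and defaults.
#' @param includeChainAdjacent include chain-bonded pairs in the 3D contact
#'   sum (default `TRUE`).
#' @return A [ModelParams-class] object.
#' @examples
#' modelParams(200, mu = 1, epsS = 4, epsW = 0.4)
#' @export
modelParams <- function(nBeads, sigma = 1, epsLJ = 1, kSpring = 100, q0 = 1,
                        mu = 0, epsS = 0, epsW = 0, rCut = 1.5,
                        maxDisp = 0.5, includeChainAdjacent = TRUE) {
  new("ModelParams",
    nBeads = as.integer(nBeads), sigma = sigma, epsLJ = epsLJ,
    kSpring = kSpring, q0 = q0, mu = mu, epsS = epsS, epsW = epsW,
    rCut = rCut, maxDisp = maxDisp,
    includeChainAdjacent = includeChainAdjacent)
}

#' Instantaneous configuration of the chromatin polymer
#'
#' Bead coordinates (in units of sigma), the binary nucleosome state of every
#' bead (1 = nucleosome bound, 0 = unbound), and the indices of the
#' specifically interacting beads (SIBs). A pair of beads interacts
#' specifically (strength `epsS`) only when both are SIBs.
#'
#' @slot positions numeric N x 3 matrix of bead coordinates.
#' @slot nucState integer vector of length N, entries in {0, 1}.
#' @slot sibIndices sorted integer vector of 1-based SIB bead indices.
#' @export
setClass("PolymerState",
  representation(positions = "matrix", nucState = "integer",
                 sibIndices = "integer")
)

setValidity("PolymerState", function(object) {
  msg <- character()
  if (!is.numeric(object@positions) || ncol(object@positions) != 3L)
    msg <- c(msg, "positions must be a numeric N x 3 matrix")
  n <- nrow(object@positions)
  if (n < 1L) msg <- c(msg, "at least one bead required")
  if (length(object@nucState) != n)
    msg <- c(msg, "nucState length must equal nrow(positions)")
  if (length(object@nucState) && !all(object@nucState %in% c(0L, 1L)))
    msg <- c(msg, "nucState entries must be 0 or 1")
  if (length(object@sibIndices) &&
      (any(object@sibIndices < 1L) || any(object@sibIndices > n)))
    msg <- c(msg, "sibIndices out of range")
  if (anyDuplicated(object@sibIndices))
    msg <- c(msg, "sibIndices must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a polymer state
#'
#' @param positions numeric N x 3 coordinate matrix.
#' @param nucState integer/numeric vector of 0/1 nucleosome states
#'   (default all 1).
#' @param sibIndices integer vector of SIB bead indices (1-based).
#' @return A [PolymerState-class] object.
#' @export
polymerState <- function(positions, nucState = rep(1L, nrow(positions)),
                         sibIndices = integer()) {
  new("PolymerState", positions = positions,
      nucState = as.integer(nucState),
      sibIndices = sort(unique(as.integer(sibIndices))))
}

#' Monte Carlo run schedule
#'
#' Number of equilibration steps discarded, sampling steps, retention stride,
#' replicate count and base seed for a Metropolis run. One Monte Carlo step
#' comprises N displacement trials and N nucleosome flip trials.
#'
#' @slot nEquilSteps integer, equilibration MC steps (discarded).
#' @slot nSampleSteps integer, sampling MC steps.
#' @slot sampleStride integer, steps between retained samples.
#' @slot nReplicates integer, independent chains.
#' @slot seed integer, base RNG seed; replicate r uses `seed + r`.
#' @export
setClass("McSchedule",
  representation(nEquilSteps = "integer", nSampleSteps = "integer",
                 sampleStride = "integer", nReplicates = "integer",
                 seed = "integer")
)

setValidity("McSchedule", function(object) {
  msg <- character()
  for (s in c("nEquilSteps", "nSampleSteps", "sampleStride", "nReplicates"))
    if (slot(object, s) < 1L) msg <- c(msg, paste(s, "must be >= 1"))
  if (object@sampleStride > object@nSampleSteps)
    msg <- c(msg, "sampleStride must not exceed nSampleSteps")
  if (length(msg)) msg else TRUE
})

#' Construct a Monte Carlo schedule
#'
#' Defaults are sized for an N = 200 polymer: 2e5 equilibration and 2e5
#' sampling steps with stride 100 and 5 replicates.
#'
#' @param nEquilSteps,nSampleSteps,sampleStride,nReplicates,seed see
#'   [McSchedule-class].
#' @return A [McSchedule-class] object.
#' @export
mcSchedule <- function(nEquilSteps = 2e5, nSampleSteps = 2e5,
                       sampleStride = 100, nReplicates = 5, seed = 1) {
  new("McSchedule",
    nEquilSteps = as.integer(nEquilSteps),
    nSampleSteps = as.integer(nSampleSteps),
    sampleStride = as.integer(sampleStride),
    nReplicates = as.integer(nReplicates),
    seed = as.integer(seed))
}

#' Parameter grid for phase-diagram sweeps
#'
#' @slot muValues numeric vector of chemical potentials.
#' @slot epsWValues numeric vector of weak interaction strengths.
#' @slot epsS numeric scalar, specific interaction strength.
#' @slot fSib numeric, percent of beads that are SIBs (0-100).
#' @export
setClass("SweepGrid",
  representation(muValues = "numeric", epsWValues = "numeric",
                 epsS = "numeric", fSib = "numeric")
)

setValidity("SweepGrid", function(object) {
  msg <- character()
  if (!length(object@muValues)) msg <- c(msg, "muValues must be non-empty")
  if (!length(object@epsWValues)) msg <- c(msg, "epsWValues must be non-empty")
  if (object@fSib < 0 || object@fSib > 100)
    msg <- c(msg, "fSib must be in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Construct a sweep grid
#'
#' Default ranges bracket the printed example points (mu = 0.8, 1.0;
#' weak strengths 0.4, 0.6).
#'
#' @param muValues,epsWValues,epsS,fSib see [SweepGrid-class].
#' @return A [SweepGrid-class] object.
#' @export
sweepGrid <- function(muValues = seq(0, 2, length.out = 11),
                      epsWValues = seq(0, 1, length.out = 11),
                      epsS = 4, fSib = 10) {
  new("SweepGrid", muValues = as.numeric(muValues),
      epsWValues = as.numeric(epsWValues), epsS = epsS, fSib = fSib)
}

#' Samples from a Metropolis Monte Carlo run
#'
#' One element per replicate chain. Nucleosome state samples are stored in
#' full; geometric observables (radius of gyration, weak-contact count,
#' running total energy) are recorded per retained sample. Coordinate frames
#' are kept only when requested.
#'
#' @slot rho list of integer matrices (samples x N), one per replicate.
#' @slot rg list of numeric vectors, instantaneous radius of gyration.
#' @slot nWeak list of integer vectors, weak-contact counts.
#' @slot energy list of numeric vectors, running (incrementally updated)
#'   total energy at each retained sample.
#' @slot energyCheck list of numeric vectors, total energy recomputed from
#'   scratch at each retained sample (bookkeeping audit).
#' @slot frames list; per replicate either `NULL` or a samples x N x 3 array.
#' @slot params the [ModelParams-class] used.
#' @slot schedule the [McSchedule-class] used.
#' @slot sibIndices SIB indices of the simulated polymer.
#' @slot seeds integer vector of per-replicate seeds.
#' @export
setClass("McSamples",
  representation(rho = "list", rg = "list", nWeak = "list",
                 energy = "list", energyCheck = "list", frames = "list",
                 params = "ModelParams", schedule = "McSchedule",
                 sibIndices = "integer", seeds = "integer")
)

#' Signal matrix around aligned genomic sites
#'
#' Rows are sites/regions (order preserved), columns are positions: either
#' fixed-resolution windows across a symmetric flank around each site centre,
#' or equal fractions of a length-scaled region.
#'
#' @slot mat numeric matrix of signal values.
#' @slot sites the source [GenomicRanges::GRanges] (row order).
#' @slot resolution numeric, column width in bp (`NA` for scaled matrices).
#' @slot flank numeric, flank in bp (`NA` for scaled matrices).
#' @slot kind `"center"` or `"scaled"`.
#' @slot excluded integer vector of row indices whose window left the
#'   chromosome; these rows are `NA` and are dropped from column means.
#' @export
setClass("SiteMatrix",
  representation(mat = "matrix", sites = "GRanges", resolution = "numeric",
                 flank = "numeric", kind = "character", excluded = "integer")
)

#' Configuration of the synthetic MNase-titration dataset generator
#'
#' Defines a toy genome with a smooth GC profile and annotated binding
#' sites, and a generative model for paired-end MNase fragments across a
#' titration: the expected fragment count in bin b of a library at MNase
#' concentration c is `depth * o_b * max(0, 1 + a_b (log10 c - mean log10 c))`
#' where `o_b` is the per-bin nucleosome protection of the condition
#' (smooth base field plus a per-condition shift at site bins) and `a_b` the
#' bin's accessibility coefficient. Realised counts are Poisson; fragment
#' midpoints are uniform within the bin.
#'
#' @slot genomeLength integer, bp per chromosome.
#' @slot nChroms integer, number of chromosomes.
#' @slot binSize integer bp (default 300, the pipeline grid).
#' @slot nSites integer, binding sites per genome.
#' @slot siteWidth integer bp.
#' @slot occupancyBase numeric in (0, 1], mean of the smooth protection field.
#' @slot occupancyShiftAtSites named numeric, per-condition protection offset
#'   applied at site bins.
#' @slot accessibilityFracPos,accessibilityFracNeg numeric, fraction of bins
#'   in the positive / negative accessibility class.
#' @slot accessibilityMagnitude numeric, |a_b| of the non-zero classes.
#' @slot maccShiftBins integer, number of bins given an extra accessibility
#'   offset in the `depleted` condition (differential-MACC truth).
#' @slot maccShiftDelta numeric, size of that offset.
#' @slot depth numeric, expected fragments per bin per library.
#' @slot concentrations numeric, MNase units of the titration points.
#' @slot nReplicates integer, replicates per condition.
#' @slot fragLenMean,fragLenSd numeric bp, insert length distribution.
#' @slot contamFrac numeric, fraction of fragments drawn outside the
#'   50-500 bp window (exercises the insert filter).
#' @slot gcLow,gcHigh numeric, range of the smooth per-bin GC profile.
#' @slot seed integer.
#' @export
setClass("SynthConfig",
  representation(
    genomeLength = "integer", nChroms = "integer", binSize = "integer",
    nSites = "integer", siteWidth = "integer",
    occupancyBase = "numeric", occupancyShiftAtSites = "numeric",
    accessibilityFracPos = "numeric", accessibilityFracNeg = "numeric",
    accessibilityMagnitude = "numeric",
    maccShiftBins = "integer", maccShiftDelta = "numeric",
    depth = "numeric", concentrations = "numeric", nReplicates = "integer",
    fragLenMean = "numeric", fragLenSd = "numeric", contamFrac = "numeric",
    gcLow = "numeric", gcHigh = "numeric", seed = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  for (s in c("genomeLength", "nChroms", "binSize", "siteWidth", "depth",
              "nReplicates"))
    if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be positive"))
  if (object@nSites < 0) msg <- c(msg, "nSites must be >= 0")
  if (object@occupancyBase <= 0 || object@occupancyBase > 1)
    msg <- c(msg, "occupancyBase must be in (0, 1]")
  if (any(object@concentrations <= 0))
    msg <- c(msg, "concentrations must be strictly positive")
  if (length(object@concentrations) < 3)
    msg <- c(msg, "need >= 3 titration points")
  if (object@contamFrac < 0 || object@contamFrac >= 1)
    msg <- c(msg, "contamFrac must be in [0, 1)")
  if (is.null(names(object@occupancyShiftAtSites)))
    msg <- c(msg, "occupancyShiftAtSites must be named by condition")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic-dataset configuration
#'
#' Defaults emulate the structure of the study's titration design: 3
#' conditions x 2 replicates x 5 MNase concentrations (1.5, 6.25, 25, 100,
#' 400 U), 300-bp bins, site-bin protection shifted down by 0.2 in the
#' `depleted` condition and up by 0.1 in the `enriched` condition relative
#' to `base`.
#'
#' @param genomeLength,nChroms,binSize,nSites,siteWidth,occupancyBase,
#'   occupancyShiftAtSites,accessibilityFracPos,accessibilityFracNeg,
#'   accessibilityMagnitude,maccShiftBins,maccShiftDelta,depth,concentrations,
#'   nReplicates,fragLenMean,fragLenSd,contamFrac,gcLow,gcHigh,seed
#'   see [SynthConfig-class].
#' @return A [SynthConfig-class] object.
#' @export
synthConfig <- function(genomeLength = 150000, nChroms = 2, binSize = 300,
                        nSites = 30, siteWidth = 900,
                        occupancyBase = 0.7,
                        occupancyShiftAtSites = c(base = 0, depleted = -0.2,
                                                  enriched = 0.1),
                        accessibilityFracPos = 0.25,
                        accessibilityFracNeg = 0.25,
                        accessibilityMagnitude = 0.5,
                        maccShiftBins = 100, maccShiftDelta = 0.6,
                        depth = 100,
                        concentrations = c(1.5, 6.25, 25, 100, 400),
                        nReplicates = 2,
                        fragLenMean = 150, fragLenSd = 25, contamFrac = 0.02,
                        gcLow = 0.35, gcHigh = 0.65, seed = 1) {
  new("SynthConfig",
    genomeLength = as.integer(genomeLength), nChroms = as.integer(nChroms),
    binSize = as.integer(binSize), nSites = as.integer(nSites),
    siteWidth = as.integer(siteWidth), occupancyBase = occupancyBase,
    occupancyShiftAtSites = occupancyShiftAtSites,
    accessibilityFracPos = accessibilityFracPos,
    accessibilityFracNeg = accessibilityFracNeg,
    accessibilityMagnitude = accessibilityMagnitude,
    maccShiftBins = as.integer(maccShiftBins),
    maccShiftDelta = maccShiftDelta, depth = depth,
    concentrations = concentrations, nReplicates = as.integer(nReplicates),
    fragLenMean = fragLenMean, fragLenSd = fragLenSd,
    contamFrac = contamFrac, gcLow = gcLow, gcHigh = gcHigh,
    seed = as.integer(seed))
}
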