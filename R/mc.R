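#' @useDynLib nucleoFold, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.evenIndices <- function(n, k, offset = 0L) {
  # k indices evenly spaced over 1..n (deterministic)
  if (k == 0L) return(integer())
  as.integer(floor((seq_len(k) - 0.5) * n / k) + 1L) + as.integer(offset)
}

.sawPositions <- function(n, q0 = 1, sigma = 1, minSep = 0.95) {
  # self-avoiding random walk: bond length exactly q0, non-bonded beads
  # kept >= minSep * sigma apart; backtracks when stuck
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- 0
  i <- 2L
  stuck <- 0L
  while (i <= n) {
    placed <- FALSE
    for (try in seq_len(60L)) {
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      cand <- pos[i - 1L, ] + q0 * dir
      if (i > 2L) {
        d2 <- colSums((t(pos[seq_len(i - 2L), , drop = FALSE]) - cand)^2)
        if (min(d2) < (minSep * sigma)^2) next
      }
      pos[i, ] <- cand
      placed <- TRUE
      break
    }
    if (placed) {
      i <- i + 1L
      stuck <- 0L
    } else {
      i <- max(2L, i - 1L)  # backtrack
      stuck <- stuck + 1L
      if (stuck > 200L) {   # restart from scratch (extremely rare)
        pos[] <- NA_real_
        pos[1, ] <- 0
        i <- 2L
        stuck <- 0L
      }
    }
  }
  pos
}

#' Build a single-region polymer
#'
#' Initialises an N-bead chain as a self-avoiding random walk with bond
#' length `q0`, all beads nucleosome-bound, and `round(N * fSib / 100)`
#' beads marked as specifically interacting (SIBs) -- evenly spaced along
#' the chain by default, or placed uniformly at random with
#' `sibPlacement = "random"`.
#'
#' @param nBeads number of beads.
#' @param fSib percent of beads that are SIBs (0-100).
#' @param seed optional integer; if given, seeds the RNG so the built state
#'   (positions and any random SIB placement) is reproducible.
#' @param sibPlacement `"even"` (default, deterministic) or `"random"`.
#' @param q0,sigma bond length and bead diameter for the initial walk.
#' @return A [PolymerState-class] with all `nucState = 1`.
#' @examples
#' s <- buildSingleRegion(200, fSib = 10, seed = 1)
#' length(s@sibIndices)  # 20
#' @export
buildSingleRegion <- function(nBeads, fSib = 10, seed = NULL,
                              sibPlacement = c("even", "random"),
                              q0 = 1, sigma = 1) {
  sibPlacement <- match.arg(sibPlacement)
  if (fSib < 0 || fSib > 100) stop("fSib must be in [0, 100]")
  if (!is.null(seed)) set.seed(seed)
  k <- as.integer(round(nBeads * fSib / 100))
  if (fSib > 0 && k == 0L)
    warning("fSib = ", fSib, " yields 0 SIB beads at N = ", nBeads)
  sib <- if (sibPlacement == "even") .evenIndices(nBeads, k)
         else sort(sample.int(nBeads, k))
  polymerState(.sawPositions(nBeads, q0 = q0, sigma = sigma),
               nucState = rep(1L, nBeads), sibIndices = sib)
}

#' Build a two-region heteropolymer
#'
#' An even-N chain whose left half (beads 1..N/2) carries evenly spaced
#' SIBs at the given percentage while the right half has none; used to
#' contrast nucleosome density with and without distant specific contacts.
#'
#' @param nBeads total beads (must be even).
#' @param fSibLeft percent of left-half beads that are SIBs.
#' @param seed optional integer seed for the initial walk.
#' @param q0,sigma bond length and bead diameter for the initial walk.
#' @return A [PolymerState-class] with all `nucState = 1`.
#' @export
buildTwoRegion <- function(nBeads, fSibLeft = 10, seed = NULL,
                           q0 = 1, sigma = 1) {
  if (nBeads %% 2L != 0L) stop("nBeads must be even for the two-region model")
  if (fSibLeft < 0 || fSibLeft > 100) stop("fSibLeft must be in [0, 100]")
  if (!is.null(seed)) set.seed(seed)
  half <- nBeads %/% 2L
  k <- as.integer(round(half * fSibLeft / 100))
  sib <- .evenIndices(half, k)
  polymerState(.sawPositions(nBeads, q0 = q0, sigma = sigma),
               nucState = rep(1L, nBeads), sibIndices = sib)
}

#' Metropolis acceptance rule
#'
#' Accepts a trial move with probability \eqn{\min(1, e^{-\Delta E})}
#' (energies in \eqn{k_BT}). Vectorised over `deltaE`; draws from the
#' current R RNG stream.
#'
#' @param deltaE numeric vector of energy changes.
#' @return logical vector of acceptance decisions.
#' @export
metropolisAccept <- function(deltaE) {
  deltaE <= 0 | runif(length(deltaE)) < exp(-deltaE)
}

.parList <- function(params) {
  list(sigma = params@sigma, epsLJ = params@epsLJ, kSpring = params@kSpring,
       q0 = params@q0, mu = params@mu, epsS = params@epsS,
       epsW = params@epsW, rCut = params@rCut, maxDisp = params@maxDisp,
       includeChainAdjacent = params@includeChainAdjacent)
}

#' Advance a polymer state by Monte Carlo steps
#'
#' Runs `nSteps` Metropolis MC steps (each N displacement trials followed by
#' N nucleosome flip trials on independently chosen beads) and returns the
#' final state. Uses the current R RNG stream; call `set.seed()` first for
#' a reproducible trajectory.
#'
#' @param state a [PolymerState-class].
#' @param params a [ModelParams-class].
#' @param nSteps number of MC steps (default 1).
#' @return the updated [PolymerState-class].
#' @export
mcStep <- function(state, params, nSteps = 1) {
  res <- .mcRunCpp(state@positions, state@nucState, state@sibIndices,
                   .parList(params), nEquil = as.integer(nSteps) - 1L,
                   nSample = 1L, stride = 1L, keepFrames = FALSE)
  polymerState(res$finalPos, nucState = res$finalRho,
               sibIndices = state@sibIndices)
}

#' Run a replicated Metropolis Monte Carlo simulation
#'
#' Each replicate starts from the same initial state, discards
#' `nEquilSteps`, then retains every `sampleStride`-th configuration over
#' `nSampleSteps` sampling steps. Replicate r is seeded with `seed + r`,
#' independent of any other run, so identical calls reproduce identical
#' trajectories.
#'
#' @param state initial [PolymerState-class].
#' @param params a [ModelParams-class].
#' @param schedule a [McSchedule-class].
#' @param keepFrames store sampled coordinate frames (memory permitting).
#' @return A [McSamples-class].
#' @export
runSimulation <- function(state, params, schedule, keepFrames = FALSE) {
  nKept <- schedule@nSampleSteps %/% schedule@sampleStride
  seeds <- schedule@seed + seq_len(schedule@nReplicates)
  rho <- rg <- nWeak <- energy <- energyCheck <- frames <-
    vector("list", schedule@nReplicates)
  for (r in seq_len(schedule@nReplicates)) {
    set.seed(seeds[r])
    res <- .mcRunCpp(state@positions, state@nucState, state@sibIndices,
                     .parList(params), schedule@nEquilSteps,
                     schedule@nSampleSteps, schedule@sampleStride,
                     keepFrames)
    rho[[r]] <- res$rho
    rg[[r]] <- res$rg
    nWeak[[r]] <- res$nWeak
    energy[[r]] <- res$energy
    energyCheck[[r]] <- res$energyCheck
    frames[[r]] <- if (keepFrames) res$frames else NULL
  }
  new("McSamples", rho = rho, rg = rg, nWeak = nWeak, energy = energy,
      energyCheck = energyCheck, frames = frames, params = params,
      schedule = schedule, sibIndices = state@sibIndices,
      seeds = as.integer(seeds))
}

.replicateObs <- function(samples) {
  # one row per replicate: mean density, ensemble Rg, mean weak contacts
  n <- ncol(samples@rho[[1]])
  data.frame(
    replicate = seq_along(samples@rho),
    rho_bar = vapply(samples@rho, mean, 0),
    rg = vapply(samples@rg, function(v) sqrt(mean(v^2)), 0),
    n_weak = vapply(samples@nWeak, mean, 0),
    lr_diff = vapply(samples@rho, function(m) {
      if (n %% 2L) return(NA_real_)
      mean(m[, seq_len(n %/% 2L)]) - mean(m[, (n %/% 2L + 1L):n])
    }, 0)
  )
}

#' Sweep a (mu, eps_w) grid of simulations
#'
#' Runs one replicated simulation per grid cell at fixed `epsS` and SIB
#' fraction and reports observables in long format: one row per (cell,
#' replicate) with mean nucleosome density, ensemble radius of gyration,
#' mean weak-contact count and (for two-region polymers) the left-minus-
#' right density difference. Each cell is seeded identically from the
#' schedule, so duplicated cells reproduce identical values.
#'
#' @param grid a [SweepGrid-class].
#' @param baseParams a [ModelParams-class] supplying all non-swept constants.
#' @param schedule a [McSchedule-class].
#' @param nBeads polymer length (default `baseParams@nBeads`).
#' @param mode `"single"` region or `"two-region"` (SIBs in the left half).
#' @param buildSeed seed for the initial self-avoiding walk.
#' @return `data.frame` with columns mu, eps_w, eps_s, f_sib, replicate,
#'   rho_bar, rg, n_weak, lr_diff.
#' @export
sweepSimulations <- function(grid, baseParams, schedule,
                             nBeads = baseParams@nBeads,
                             mode = c("single", "two-region"),
                             buildSeed = schedule@seed) {
  mode <- match.arg(mode)
  state <- if (mode == "single")
    buildSingleRegion(nBeads, fSib = grid@fSib, seed = buildSeed)
  else
    buildTwoRegion(nBeads, fSibLeft = grid@fSib, seed = buildSeed)
  cells <- expand.grid(mu = grid@muValues, eps_w = grid@epsWValues,
                       KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    p <- baseParams
    p@nBeads <- as.integer(nBeads)
    p@mu <- cells$mu[k]
    p@epsW <- cells$eps_w[k]
    p@epsS <- grid@epsS
    obs <- .replicateObs(runSimulation(state, p, schedule))
    obs$mu <- cells$mu[k]
    obs$eps_w <- cells$eps_w[k]
    out[[k]] <- obs
  }
  res <- do.call(rbind, out)
  res$eps_s <- grid@epsS
  res$f_sib <- grid@fSib
  res[, c("mu", "eps_w", "eps_s", "f_sib", "replicate",
          "rho_bar", "rg", "n_weak", "lr_diff")]
}

#' Aggregate a sweep table over replicates
#'
#' @param sweepTable output of [sweepSimulations()].
#' @return `data.frame` with per-cell replicate means and standard errors
#'   (SE across independent replicates).
#' @export
aggregateSweep <- function(sweepTable) {
  key <- interaction(sweepTable$mu, sweepTable$eps_w, drop = TRUE)
  aggM <- function(v) as.numeric(tapply(v, key, mean))
  aggS <- function(v)
    as.numeric(tapply(v, key, function(x) sd(x) / sqrt(length(x))))
  out <- data.frame(
    mu = as.numeric(tapply(sweepTable$mu, key, `[`, 1)),
    eps_w = as.numeric(tapply(sweepTable$eps_w, key, `[`, 1)),
    eps_s = sweepTable$eps_s[1], f_sib = sweepTable$f_sib[1],
    rho_bar = aggM(sweepTable$rho_bar),
    rho_bar_se = aggS(sweepTable$rho_bar),
    rg = aggM(sweepTable$rg), rg_se = aggS(sweepTable$rg),
    n_weak = aggM(sweepTable$n_weak), n_weak_se = aggS(sweepTable$n_weak),
    lr_diff = aggM(sweepTable$lr_diff), lr_diff_se = aggS(sweepTable$lr_diff))
  rownames(out) <- NULL
  out
}

#' Wide (heatmap-ready) matrix from an aggregated sweep
#'
#' @param aggTable output of [aggregateSweep()].
#' @param value column to spread (e.g. `"rho_bar"`, `"rg"`, `"lr_diff"`).
#' @return numeric matrix with mu values as rows and eps_w values as columns.
#' @export
sweepMatrix <- function(aggTable, value = "rho_bar") {
  mus <- sort(unique(aggTable$mu))
  ews <- sort(unique(aggTable$eps_w))
  m <- matrix(NA_real_, length(mus), length(ews),
              dimnames = list(mu = mus, eps_w = ews))
  for (i in seq_len(nrow(aggTable)))
    m[match(aggTable$mu[i], mus), match(aggTable$eps_w[i], ews)] <-
      aggTable[[value]][i]
  m
}
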