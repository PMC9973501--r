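## Observables on sampled polymer configurations: mean nucleosome density,
## per-bead occupancy, radius of gyration, weak-contact counts, two-region
## density difference, and the transition-curve driver.

.rhoMatrix <- function(x) {
  # accept a McSamples, a list of rho matrices, or one matrix
  if (is(x, "McSamples")) return(do.call(rbind, x@rho))
  if (is.list(x)) return(do.call(rbind, x))
  if (is.matrix(x)) return(x)
  stop("expected McSamples, list of matrices, or matrix of nucleosome states")
}

#' Mean nucleosome density
#'
#' \eqn{\bar\rho = \langle \frac1N \sum_i \rho_i \rangle}: the nucleosome
#' state averaged over beads, samples and replicates.
#'
#' @param samples a [McSamples-class], a list of sample matrices, or a
#'   samples x N matrix of 0/1 states.
#' @return numeric in \[0, 1\].
#' @export
meanDensity <- function(samples) {
  m <- .rhoMatrix(samples)
  if (!nrow(m)) stop("no samples")
  mean(m)
}

#' Per-bead nucleosome occupancy profile
#'
#' The nucleosome state of each bead averaged over equilibrium samples (and
#' replicates); its mean over beads equals [meanDensity()] exactly.
#'
#' @inheritParams meanDensity
#' @return numeric vector of length N with entries in \[0, 1\].
#' @export
occupancyProfile <- function(samples) {
  m <- .rhoMatrix(samples)
  if (!nrow(m)) stop("no samples")
  colMeans(m)
}

#' Radius of gyration of a configuration
#'
#' \eqn{R_g = \sqrt{\frac1N \sum_i (r_i - r_{com})^2}}, the root-mean-square
#' bead distance from the centre of mass; the standard compaction measure.
#'
#' @param state a [PolymerState-class] or an N x 3 coordinate matrix.
#' @return length in units of sigma.
#' @examples
#' radiusOfGyration(rbind(c(-1, 0, 0), c(1, 0, 0)))  # 1
#' @export
radiusOfGyration <- function(state) {
  pos <- if (is(state, "PolymerState")) state@positions else state
  com <- colMeans(pos)
  sqrt(mean(rowSums((pos - rep(com, each = nrow(pos)))^2)))
}

#' Ensemble radius of gyration
#'
#' Averages the squared per-sample quantity before taking the root,
#' \eqn{\sqrt{\langle \frac1N \sum_i (r_i - r_{com})^2 \rangle}}.
#'
#' @param samples a [McSamples-class] (run with per-sample Rg recorded) or a
#'   numeric vector of per-sample Rg values.
#' @return length in units of sigma.
#' @export
ensembleRg <- function(samples) {
  v <- if (is(samples, "McSamples")) unlist(samples@rg) else samples
  sqrt(mean(v^2))
}

#' Count weak inter-nucleosome contacts
#'
#' Number of unordered bead pairs that are 3D neighbours
#' (\eqn{r_{ij} < r_{cut}}), both nucleosome-bound, and not specifically
#' interacting (\eqn{\tau_{ij} = 0}, i.e. not both SIBs), under the model's
#' pair conventions. With `countBeads = TRUE` returns instead the number of
#' beads engaged in at least one such weak contact.
#'
#' @param state a [PolymerState-class].
#' @param params a [ModelParams-class].
#' @param countBeads count beads rather than pairs (default `FALSE`).
#' @return integer count.
#' @export
countWeakContacts <- function(state, params, countBeads = FALSE) {
  pos <- state@positions
  n <- nrow(pos)
  if (n < 2L) return(0L)
  d <- .pairDistMatrix(pos)
  sel <- !is.na(d) & d < params@rCut
  if (!params@includeChainAdjacent)
    sel <- sel & abs(row(d) - col(d)) > 1L
  bound <- state@nucState == 1L
  sel <- sel & outer(bound, bound, `&`)
  isSib <- logical(n)
  isSib[state@sibIndices] <- TRUE
  sel <- sel & !outer(isSib, isSib, `&`)
  if (!countBeads) return(sum(sel))
  idx <- which(sel, arr.ind = TRUE)
  length(unique(c(idx[, 1], idx[, 2])))
}

#' Left-minus-right nucleosome density difference
#'
#' For an even-N (two-region) polymer: mean nucleosome density over beads
#' 1..N/2 minus that over beads N/2+1..N.
#'
#' @inheritParams meanDensity
#' @return numeric difference (positive when the left, SIB-bearing, region
#'   is denser).
#' @export
twoRegionDensityDifference <- function(samples) {
  m <- .rhoMatrix(samples)
  n <- ncol(m)
  if (n %% 2L != 0L) stop("two-region difference requires even N")
  mean(m[, seq_len(n %/% 2L), drop = FALSE]) -
    mean(m[, (n %/% 2L + 1L):n, drop = FALSE])
}

#' Observables as a function of specific interaction strength
#'
#' Runs one replicated simulation per `epsS` value at otherwise fixed
#' parameters and reports the mean weak-contact count, mean nucleosome
#' density and ensemble radius of gyration with standard errors across
#' replicates -- the transition curves of the folding/occupancy coupling.
#'
#' @param epsSValues numeric vector of specific interaction strengths.
#' @param params a [ModelParams-class] (supplies mu, epsW, etc.).
#' @param schedule a [McSchedule-class].
#' @param nBeads polymer length (default `params@nBeads`).
#' @param fSib SIB percentage (default 10).
#' @param buildSeed seed for the initial walk.
#' @return `data.frame` with one row per `epsS`: n_weak, rho_bar, rg and
#'   their replicate standard errors.
#' @export
transitionCurves <- function(epsSValues, params, schedule,
                             nBeads = params@nBeads, fSib = 10,
                             buildSeed = schedule@seed) {
  state <- buildSingleRegion(nBeads, fSib = fSib, seed = buildSeed)
  rows <- lapply(epsSValues, function(es) {
    p <- params
    p@nBeads <- as.integer(nBeads)
    p@epsS <- es
    obs <- .replicateObs(runSimulation(state, p, schedule))
    se <- function(v) sd(v) / sqrt(length(v))
    data.frame(eps_s = es,
               n_weak = mean(obs$n_weak), n_weak_se = se(obs$n_weak),
               rho_bar = mean(obs$rho_bar), rho_bar_se = se(obs$rho_bar),
               rg = mean(obs$rg), rg_se = se(obs$rg))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-replicate observable table of a run
#'
#' @param samples a [McSamples-class].
#' @return `data.frame` with one row per replicate: mean density, ensemble
#'   Rg, mean weak-contact count and (even N) left-right density difference.
#' @export
replicateObservables <- function(samples) .replicateObs(samples)
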