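## Reference (pure R) implementation of the polymer energy function.
## The Monte Carlo engine re-implements these terms incrementally in C++;
## the functions here are the exact definition and serve as the oracle the
## engine is tested against.

.pairDistMatrix <- function(positions) {
  d <- as.matrix(stats::dist(positions))
  d[lower.tri(d, diag = TRUE)] <- NA_real_
  d
}

#' Harmonic spring (bond) energy
#'
#' \eqn{\sum_{i=1}^{N-1} \tfrac12 k_s (q_i - q_0)^2} with
#' \eqn{q_i = |r_i - r_{i+1}|}: the energetic cost of stretching or
#' compressing each backbone bond away from its rest length.
#'
#' @param state a [PolymerState-class].
#' @param params a [ModelParams-class].
#' @return energy in \eqn{k_BT} (non-negative).
#' @examples
#' p <- modelParams(2)
#' s <- polymerState(rbind(c(0, 0, 0), c(1.1, 0, 0)), nucState = c(0, 0))
#' springEnergy(s, p)  # 0.5 * 100 * 0.1^2 = 0.5
#' @export
springEnergy <- function(state, params) {
  pos <- state@positions
  n <- nrow(pos)
  if (n < 2L) stop("spring energy requires at least 2 beads")
  dq <- sqrt(rowSums((pos[-1L, , drop = FALSE] -
                      pos[-n, , drop = FALSE])^2)) - params@q0
  0.5 * params@kSpring * sum(dq^2)
}

#' Excluded-volume (WCA) energy
#'
#' Sum over all unordered bead pairs of the purely repulsive part of the
#' Lennard-Jones potential:
#' \eqn{V(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + \epsilon} for
#' \eqn{r < 2^{1/6}\sigma}, zero beyond.
#'
#' @inheritParams springEnergy
#' @return energy in \eqn{k_BT} (non-negative).
#' @export
excludedVolumeEnergy <- function(state, params) {
  pos <- state@positions
  if (nrow(pos) < 2L) return(0)
  d <- .pairDistMatrix(pos)
  tiny <- 1e-9 * params@sigma
  if (any(d < tiny, na.rm = TRUE)) {
    idx <- which(d < tiny, arr.ind = TRUE)
    stop("coincident beads: ", paste(idx[1, ], collapse = ","))
  }
  cut <- 2^(1 / 6) * params@sigma
  r <- d[!is.na(d) & d < cut]
  if (!length(r)) return(0)
  s6 <- (params@sigma / r)^6
  sum(4 * params@epsLJ * (s6^2 - s6) + params@epsLJ)
}

.pairEps <- function(state, params) {
  # per-pair interaction strength matrix (upper triangle), NA where no pair
  n <- nrow(state@positions)
  isSib <- logical(n)
  isSib[state@sibIndices] <- TRUE
  eps <- matrix(params@epsW, n, n)
  eps[isSib, isSib] <- params@epsS
  eps
}

#' 3D contact interaction energy
#'
#' \eqn{-\sum_{(i,j)} [\epsilon_s \tau_{ij} \rho_i \rho_j +
#' \epsilon_w (1 - \tau_{ij}) \rho_i \rho_j]} over unordered bead pairs that
#' are 3D neighbours (\eqn{r_{ij} < r_{cut}}). \eqn{\tau_{ij} = 1} iff both
#' beads are SIBs; a pair contributes only when both carry nucleosomes.
#'
#' @inheritParams springEnergy
#' @return energy in \eqn{k_BT} (non-positive).
#' @export
contactInteractionEnergy <- function(state, params) {
  pos <- state@positions
  n <- nrow(pos)
  if (n < 2L) return(0)
  d <- .pairDistMatrix(pos)
  inRange <- !is.na(d) & d < params@rCut
  if (!params@includeChainAdjacent) {
    adj <- abs(row(d) - col(d)) <= 1L
    inRange <- inRange & !adj
  }
  bound <- state@nucState == 1L
  both <- outer(bound, bound, `&`)
  sel <- inRange & both
  if (!any(sel)) return(0)
  eps <- .pairEps(state, params)
  -sum(eps[sel])
}

#' Total energy of the chromatin polymer
#'
#' Spring energy + excluded volume + \eqn{\mu \sum_i \rho_i} + 3D contact
#' interaction energy.
#'
#' @inheritParams springEnergy
#' @return energy in \eqn{k_BT}.
#' @export
totalEnergy <- function(state, params) {
  n <- nrow(state@positions)
  sp <- if (n >= 2L) springEnergy(state, params) else 0
  sp + excludedVolumeEnergy(state, params) +
    params@mu * sum(state@nucState) +
    contactInteractionEnergy(state, params)
}

#' Incremental energy change of a trial move
#'
#' Energy difference `totalEnergy(after) - totalEnergy(before)` for a
#' single-bead displacement or nucleosome flip, recomputing only the terms
#' that involve the moved bead.
#'
#' @inheritParams springEnergy
#' @param move a list: either `list(type = "displace", bead = i,
#'   delta = c(dx, dy, dz))` or `list(type = "flip", bead = i)`.
#' @return energy difference in \eqn{k_BT}.
#' @export
energyDelta <- function(state, params, move) {
  n <- nrow(state@positions)
  i <- move$bead
  if (is.null(i) || i < 1L || i > n) stop("bead index out of range")
  isSib <- logical(n)
  isSib[state@sibIndices] <- TRUE
  epsOf <- function(j) ifelse(isSib[i] & isSib[j], params@epsS, params@epsW)
  contactPartners <- function(pos, posI) {
    j <- setdiff(seq_len(n), i)
    if (!params@includeChainAdjacent) j <- j[abs(j - i) > 1L]
    j <- j[state@nucState[j] == 1L]
    if (!length(j)) return(0)
    r <- sqrt(colSums((t(pos[j, , drop = FALSE]) - posI)^2))
    sum(epsOf(j)[r < params@rCut])
  }
  if (move$type == "flip") {
    gain <- if (state@nucState[i] == 1L) -1 else 1
    dE <- gain * params@mu
    if (params@epsS != 0 || params@epsW != 0)
      dE <- dE - gain * contactPartners(state@positions, state@positions[i, ])
    return(dE)
  }
  if (move$type != "displace") stop("unknown move type")
  old <- state@positions[i, ]
  newp <- old + move$delta
  j <- setdiff(seq_len(n), i)
  rOld <- sqrt(colSums((t(state@positions[j, , drop = FALSE]) - old)^2))
  rNew <- sqrt(colSums((t(state@positions[j, , drop = FALSE]) - newp)^2))
  wca <- function(r) {
    v <- numeric(length(r))
    inR <- r < 2^(1 / 6) * params@sigma
    s6 <- (params@sigma / r[inR])^6
    v[inR] <- 4 * params@epsLJ * (s6^2 - s6) + params@epsLJ
    v
  }
  dE <- sum(wca(rNew)) - sum(wca(rOld))
  bonds <- intersect(c(i - 1L, i + 1L), seq_len(n))
  for (b in bonds) {
    qOld <- sqrt(sum((state@positions[b, ] - old)^2))
    qNew <- sqrt(sum((state@positions[b, ] - newp)^2))
    dE <- dE + 0.5 * params@kSpring *
      ((qNew - params@q0)^2 - (qOld - params@q0)^2)
  }
  if (state@nucState[i] == 1L && (params@epsS != 0 || params@epsW != 0)) {
    dE <- dE - contactPartners(state@positions, newp) +
      contactPartners(state@positions, old)
  }
  dE
}

#' Chemical potential from nucleosome binding/dissociation rates
#'
#' \eqn{\mu = -\ln(k_{on}/k_{off})}: equal rates give \eqn{\mu = 0}; faster
#' dissociation (small \eqn{k_{on}/k_{off}}) gives positive \eqn{\mu} and
#' favours nucleosome loss.
#'
#' @param kOn,kOff strictly positive binding / dissociation rates.
#' @return \eqn{\mu} in \eqn{k_BT}.
#' @examples
#' muFromRates(1, 1)        # 0
#' muFromRates(exp(-1), 1)  # 1
#' @export
muFromRates <- function(kOn, kOff) {
  if (any(kOn <= 0) || any(kOff <= 0))
    stop("rates must be strictly positive")
  -log(kOn / kOff)
}
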