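# shared fixtures and independent oracles used across test files

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# straight chain along x with given bond lengths
chainState <- function(bonds, nucState = NULL, sib = integer()) {
  pos <- cbind(c(0, cumsum(bonds)), 0, 0)
  if (is.null(nucState)) nucState <- rep(1L, nrow(pos))
  polymerState(pos, nucState = nucState, sibIndices = sib)
}

randomRotation <- function() {
  # QR-based random orthogonal matrix with det +1
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

randomState <- function(n, boxHalf = 2, pBound = 0.6, fSib = 0.2) {
  pos <- matrix(runif(n * 3, -boxHalf, boxHalf), n, 3)
  polymerState(pos,
               nucState = as.integer(runif(n) < pBound),
               sibIndices = sample(n, max(1, round(fSib * n))))
}

# O(N^2) double-loop oracle for weak-contact counting, written
# independently of the package implementation
bruteWeakContacts <- function(state, params) {
  pos <- state@positions
  n <- nrow(pos)
  isSib <- seq_len(n) %in% state@sibIndices
  k <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!params@includeChainAdjacent && j - i <= 1) next
    if (state@nucState[i] == 0L || state@nucState[j] == 0L) next
    if (isSib[i] && isSib[j]) next
    if (sqrt(sum((pos[i, ] - pos[j, ])^2)) < params@rCut) k <- k + 1L
  }
  k
}

# brute-force count of in-range bound pairs split by tau
bruteBoundPairs <- function(state, params) {
  pos <- state@positions
  n <- nrow(pos)
  isSib <- seq_len(n) %in% state@sibIndices
  tot <- spec <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!params@includeChainAdjacent && j - i <= 1) next
    if (state@nucState[i] == 0L || state@nucState[j] == 0L) next
    if (sqrt(sum((pos[i, ] - pos[j, ])^2)) < params@rCut) {
      tot <- tot + 1L
      if (isSib[i] && isSib[j]) spec <- spec + 1L
    }
  }
  c(total = tot, specific = spec)
}

# BinnedSignal on a toy genome from an explicit value matrix
toyBS <- function(values, chromLen = NULL, binSizeBp = 300,
                  trackData = NULL) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  if (is.null(chromLen)) chromLen <- nrow(values) * binSizeBp
  bins <- genomeBins(c(chrT = chromLen), binSizeBp)
  stopifnot(length(bins) == nrow(values))
  binnedSignal(values, bins, binSizeBp, trackData = trackData)
}
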