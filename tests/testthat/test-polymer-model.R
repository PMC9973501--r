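# Energy terms of the bead-spring nucleosome polymer, checked against
# hand-evaluated configurations and a full-recompute oracle.

test_that("spring energy matches hand-evaluated chains", {
  p <- modelParams(3)
  expect_equal(springEnergy(chainState(c(1, 1)), p), 0)
  expect_equal(springEnergy(chainState(1.1), modelParams(2)), 0.5)
  expect_equal(springEnergy(chainState(c(0.9, 1.1)), p), 1.0)
  oneBead <- polymerState(matrix(0, 1, 3), nucState = 0L)
  expect_error(springEnergy(oneBead, modelParams(2)), "at least 2")
})

test_that("excluded volume is the repulsive LJ part only", {
  p <- modelParams(2)
  # beyond the WCA cutoff: zero
  far <- chainState(2^(1 / 6) + 1e-9, nucState = c(0, 0))
  expect_equal(excludedVolumeEnergy(far, p), 0)
  # at r = sigma: 4(1 - 1) + 1 = 1
  expect_equal(excludedVolumeEnergy(chainState(1, nucState = c(0, 0)), p), 1)
  # three collinear beads spaced 1: two adjacent pairs, end pair at 2 -> 0
  expect_equal(
    excludedVolumeEnergy(chainState(c(1, 1), nucState = c(0, 0, 0)),
                         modelParams(3)), 2)
  clash <- polymerState(rbind(c(0, 0, 0), c(0, 0, 0)), nucState = c(0, 0))
  expect_error(excludedVolumeEnergy(clash, p), "coincident")
})

test_that("contact interaction follows the eps_s tau + eps_w (1 - tau) rule", {
  # nucleosome-free polymer contributes nothing
  p <- modelParams(3, epsS = 4, epsW = 0.4)
  bare <- chainState(c(1, 1), nucState = c(0, 0, 0))
  expect_equal(contactInteractionEnergy(bare, p), 0)
  # two bound SIBs within r_cut: -eps_s
  sibPair <- chainState(1, sib = c(1, 2))
  expect_equal(contactInteractionEnergy(sibPair, modelParams(2, epsS = 4)),
               -4)
  # three bound beads, no SIBs: two weak pairs in range
  chain3 <- chainState(c(1, 1))
  expect_equal(contactInteractionEnergy(chain3, modelParams(3, epsW = 0.4)),
               -0.8)
  # excluding chain-adjacent pairs removes both
  pNoAdj <- modelParams(3, epsW = 0.4, includeChainAdjacent = FALSE)
  expect_equal(contactInteractionEnergy(chain3, pNoAdj), 0)
})

test_that("total energy is the sum of its four terms", {
  chain3 <- chainState(c(1, 1), nucState = c(0, 0, 0))
  expect_equal(totalEnergy(chain3, modelParams(3, mu = 1, epsW = 0.4)), 2.0)
  bound3 <- chainState(c(1, 1))
  expect_equal(totalEnergy(bound3, modelParams(3, mu = 1, epsW = 0.4)), 4.2)
  oneBead <- polymerState(matrix(0, 1, 3), nucState = 1L)
  expect_equal(totalEnergy(oneBead, modelParams(2, mu = 2)), 2.0)
  # consistency with explicit component sum on a random state
  set.seed(1)
  st <- randomState(12)
  p <- modelParams(12, mu = 0.7, epsS = 3, epsW = 0.5)
  expect_equal(totalEnergy(st, p),
               springEnergy(st, p) + excludedVolumeEnergy(st, p) +
                 p@mu * sum(st@nucState) + contactInteractionEnergy(st, p))
})

test_that("total energy is invariant under rigid motions", {
  set.seed(2)
  st <- buildSingleRegion(20, fSib = 20, seed = 3)
  p <- modelParams(20, mu = 0.5, epsS = 2, epsW = 0.3)
  e0 <- totalEnergy(st, p)
  for (k in 1:5) {
    rot <- randomRotation()
    shift <- rnorm(3, sd = 5)
    st2 <- st
    st2@positions <- st@positions %*% rot +
      matrix(shift, nrow(st@positions), 3, byrow = TRUE)
    expect_equal(totalEnergy(st2, p), e0, tolerance = 1e-9)
  }
})

test_that("contact energy is non-increasing in interaction strengths", {
  set.seed(3)
  st <- randomState(25)
  for (es in c(0, 1, 3)) for (ew in c(0, 0.4)) {
    e1 <- contactInteractionEnergy(st, modelParams(25, epsS = es, epsW = ew))
    e2 <- contactInteractionEnergy(st,
                                   modelParams(25, epsS = es + 1, epsW = ew))
    e3 <- contactInteractionEnergy(st,
                                   modelParams(25, epsS = es, epsW = ew + 0.2))
    expect_lte(e2, e1)
    expect_lte(e3, e1)
  }
})

test_that("a nucleosome-free state is blind to mu and interaction strengths", {
  set.seed(4)
  st <- randomState(15, pBound = 0)
  e0 <- totalEnergy(st, modelParams(15))
  expect_equal(totalEnergy(st, modelParams(15, mu = 5, epsS = 6, epsW = 1)),
               e0)
})

test_that("incremental energy delta agrees with full recomputation", {
  # trivial cases
  st <- polymerState(rbind(c(0, 0, 0), c(10, 0, 0)), nucState = c(0, 0))
  p <- modelParams(2, mu = 1.3)
  expect_equal(energyDelta(st, p, list(type = "flip", bead = 1)), 1.3)
  expect_equal(
    energyDelta(st, p, list(type = "displace", bead = 1,
                            delta = c(0, 0, 0))), 0)
  expect_error(energyDelta(st, p, list(type = "flip", bead = 5)),
               "out of range")
  # oracle equivalence over 1000 Metropolis-filtered random moves
  set.seed(5)
  p10 <- modelParams(10, mu = 0.5, epsS = 3, epsW = 0.5)
  cur <- buildSingleRegion(10, fSib = 20, seed = 6)
  worst <- 0
  for (k in 1:1000) {
    mv <- if (runif(1) < 0.5)
      list(type = "displace", bead = sample(10, 1),
           delta = runif(3, -0.5, 0.5))
    else list(type = "flip", bead = sample(10, 1))
    dE <- energyDelta(cur, p10, mv)
    nxt <- cur
    if (mv$type == "flip")
      nxt@nucState[mv$bead] <- 1L - nxt@nucState[mv$bead]
    else
      nxt@positions[mv$bead, ] <- nxt@positions[mv$bead, ] + mv$delta
    full <- totalEnergy(nxt, p10) - totalEnergy(cur, p10)
    worst <- max(worst, abs(dE - full))
    if (metropolisAccept(dE)) cur <- nxt  # stay on physical configurations
  }
  expect_lt(worst, 1e-9)
})

test_that("chemical potential follows -log(kOn/kOff)", {
  expect_equal(muFromRates(2, 2), 0)
  expect_equal(muFromRates(exp(-1), 1), 1)
  expect_equal(muFromRates(exp(1), 1), -1)
  expect_error(muFromRates(0, 1), "positive")
  expect_error(muFromRates(1, -2), "positive")
})

test_that("parameter and state validity is enforced", {
  expect_error(modelParams(1), "nBeads")
  expect_error(modelParams(5, epsS = -1), "epsS")
  expect_error(polymerState(matrix(0, 2, 3), nucState = c(1, 2)),
               "0 or 1")
  expect_error(polymerState(matrix(0, 2, 3), nucState = c(1, 1),
                            sibIndices = 5), "out of range")
})

test_that("model parameters round-trip through YAML", {
  p <- modelParams(200, mu = 1.2, epsS = 4, epsW = 0.4,
                   includeChainAdjacent = FALSE)
  path <- tempfile(fileext = ".yaml")
  writeModelParams(p, path, seed = 42)
  q <- readModelParams(path)
  for (s in slotNames("ModelParams"))
    expect_equal(slot(q, s), slot(p, s))
  expect_equal(attr(q, "seed"), 42)
  # missing field is refused
  y <- yaml::read_yaml(path)
  y$mu <- NULL
  path2 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(y, path2)
  expect_error(readModelParams(path2), "missing fields")
})
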