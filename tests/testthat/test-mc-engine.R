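# Metropolis sampler: builders, acceptance rule, determinism, analytic
# limits and incremental-energy bookkeeping.

test_that("single-region builder places the right number of SIBs", {
  st <- buildSingleRegion(200, fSib = 10, seed = 1)
  expect_equal(length(st@sibIndices), 20L)
  expect_equal(buildSingleRegion(50, fSib = 0, seed = 1)@sibIndices,
               integer())
  expect_warning(buildSingleRegion(4, fSib = 10, seed = 1), "0 SIB")
  # all beads start nucleosome-bound
  expect_true(all(st@nucState == 1L))
})

test_that("initial walk has exact bonds and self-avoidance", {
  st <- buildSingleRegion(100, fSib = 10, seed = 2)
  pos <- st@positions
  bonds <- sqrt(rowSums((pos[-1, ] - pos[-100, ])^2))
  expect_equal(bonds, rep(1, 99), tolerance = 1e-12)
  d <- as.matrix(dist(pos))
  nonBonded <- abs(row(d) - col(d)) > 1
  expect_gte(min(d[nonBonded & upper.tri(d)]), 0.95)
})

test_that("builders are deterministic from their seed", {
  a <- buildSingleRegion(60, fSib = 15, seed = 7, sibPlacement = "random")
  b <- buildSingleRegion(60, fSib = 15, seed = 7, sibPlacement = "random")
  expect_identical(a@positions, b@positions)
  expect_identical(a@sibIndices, b@sibIndices)
})

test_that("two-region builder confines SIBs to the left half", {
  st <- buildTwoRegion(400, fSibLeft = 10, seed = 3)
  expect_equal(length(st@sibIndices), 20L)
  expect_true(all(st@sibIndices <= 200L))
  expect_equal(length(buildTwoRegion(400, fSibLeft = 20,
                                     seed = 3)@sibIndices), 40L)
  expect_equal(length(buildTwoRegion(400, fSibLeft = 0,
                                     seed = 3)@sibIndices), 0L)
  expect_error(buildTwoRegion(401), "even")
})

test_that("Metropolis rule accepts downhill always, uphill at exp(-dE)", {
  set.seed(11)
  expect_true(all(metropolisAccept(rep(-1, 100))))
  expect_true(all(metropolisAccept(rep(0, 100))))
  n <- 1e5
  acc <- mean(metropolisAccept(rep(log(2), n)))
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(acc - 0.5), 3 * se)
})

test_that("trajectories are reproducible and replicates differ", {
  st <- buildSingleRegion(30, fSib = 10, seed = 4)
  p <- modelParams(30, mu = 0.5, epsS = 2, epsW = 0.3)
  sch <- mcSchedule(200, 400, 20, 3, seed = 9)
  r1 <- runSimulation(st, p, sch)
  r2 <- runSimulation(st, p, sch)
  expect_identical(r1@rho, r2@rho)
  expect_identical(r1@rg, r2@rg)
  # distinct replicate chains explore distinct trajectories
  expect_false(identical(r1@rho[[1]], r1@rho[[2]]))
  expect_false(identical(r1@rho[[2]], r1@rho[[3]]))
})

test_that("strongly positive mu empties the polymer of nucleosomes", {
  st <- buildSingleRegion(30, fSib = 10, seed = 5)
  r <- runSimulation(st, modelParams(30, mu = 50),
                     mcSchedule(300, 100, 10, 1, seed = 2))
  expect_equal(sum(r@rho[[1]]), 0L)
})

test_that("non-interacting occupancy matches the free-bead expectation", {
  # flips decouple from geometry at eps_s = eps_w = 0: P(rho=1) = 1/(1+e^mu)
  st <- buildSingleRegion(50, fSib = 10, seed = 6)
  for (mu in c(-2, 2)) {
    r <- runSimulation(st, modelParams(50, mu = mu),
                       mcSchedule(2000, 8000, 40, 3, seed = 13))
    obs <- replicateObservables(r)
    se <- sd(obs$rho_bar) / sqrt(nrow(obs))
    expect_lt(abs(mean(obs$rho_bar) - 1 / (1 + exp(mu))), 3 * se)
  }
})

test_that("running energy matches full recomputation along a trajectory", {
  st <- buildSingleRegion(40, fSib = 10, seed = 7)
  p <- modelParams(40, mu = 0.8, epsS = 3, epsW = 0.5)
  r <- runSimulation(st, p, mcSchedule(500, 1000, 50, 1, seed = 4),
                     keepFrames = TRUE)
  # engine-internal audit
  expect_lt(max(abs(r@energy[[1]] - r@energyCheck[[1]])), 1e-6)
  # independent R-side recomputation on stored frames
  fr <- r@frames[[1]]
  for (k in seq_len(dim(fr)[1])) {
    stk <- polymerState(fr[k, , ], nucState = r@rho[[1]][k, ],
                        sibIndices = st@sibIndices)
    expect_equal(r@energy[[1]][k], totalEnergy(stk, p), tolerance = 1e-9)
    expect_equal(r@rg[[1]][k], radiusOfGyration(stk), tolerance = 1e-12)
    expect_equal(r@nWeak[[1]][k], countWeakContacts(stk, p))
  }
})

test_that("mcStep advances a state deterministically", {
  st <- buildSingleRegion(20, fSib = 10, seed = 8)
  p <- modelParams(20, mu = 0.5, epsW = 0.3)
  set.seed(3); s1 <- mcStep(st, p, nSteps = 10)
  set.seed(3); s2 <- mcStep(st, p, nSteps = 10)
  expect_identical(s1@positions, s2@positions)
  expect_identical(s1@nucState, s2@nucState)
  expect_false(identical(s1@positions, st@positions))
})

test_that("sweep emits the full parameter grid in long format", {
  g <- sweepGrid(muValues = c(0.5, 1.5), epsWValues = c(0.2, 0.6),
                 epsS = 2, fSib = 10)
  tab <- sweepSimulations(g, modelParams(20), mcSchedule(100, 200, 20, 2,
                                                         seed = 21),
                          nBeads = 20)
  expect_equal(nrow(tab), 8L)  # 2 mu x 2 ew x 2 replicates
  expect_setequal(unique(tab$mu), c(0.5, 1.5))
  expect_setequal(unique(tab$eps_w), c(0.2, 0.6))
  agg <- aggregateSweep(tab)
  expect_equal(nrow(agg), 4L)
  m <- sweepMatrix(agg, "rho_bar")
  expect_equal(dim(m), c(2L, 2L))
  expect_false(anyNA(m))
})

test_that("duplicated sweep cells reproduce identical observables", {
  g <- sweepGrid(muValues = c(1, 1), epsWValues = 0.4, epsS = 0, fSib = 10)
  tab <- sweepSimulations(g, modelParams(20),
                          mcSchedule(100, 200, 20, 1, seed = 22),
                          nBeads = 20)
  expect_equal(tab$rho_bar[1], tab$rho_bar[2])
  expect_equal(tab$rg[1], tab$rg[2])
})

test_that("two-region sweep reports the left-right density difference", {
  g <- sweepGrid(muValues = 1, epsWValues = 0.3, epsS = 0, fSib = 10)
  tab <- sweepSimulations(g, modelParams(40),
                          mcSchedule(100, 200, 20, 2, seed = 23),
                          nBeads = 40, mode = "two-region")
  expect_true(all(is.finite(tab$lr_diff)))
})
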