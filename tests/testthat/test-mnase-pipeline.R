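# MNase-titration pipeline: QC filters, binning, normalisation, occupancy,
# differencing and the aggregation geometries.

test_that("insert-size filter keeps the inclusive 50-500 bp window", {
  fr <- fragmentSet(rep("chr1", 4), c(0, 0, 0, 0), c(49, 50, 500, 501))
  kept <- filterFragmentsByInsert(fr)
  expect_equal(sort(width(kept)), c(50, 500))
  expect_equal(length(filterFragmentsByInsert(fr[0])), 0L)
  all150 <- fragmentSet(rep("chr1", 10), 0:9 * 1000, 0:9 * 1000 + 150)
  expect_equal(length(filterFragmentsByInsert(all150)), 10L)
})

test_that("hotspot filter masks extreme positions only", {
  # uniform coverage: nothing masked (variance is zero, which warns)
  fr <- fragmentSet(rep("chr1", 100), 0:99 * 10, 0:99 * 10 + 100)
  expect_warning(unif <- hotspotFilter(fr), "zero variance")
  expect_equal(length(unif), 100L)
  # one position with a huge pile-up is masked
  pile <- fragmentSet(rep("chr1", 600),
                      c(0:499 * 10, rep(7777, 100)),
                      c(0:499 * 10, rep(7777, 100)) + 100)
  filt <- hotspotFilter(pile)
  expect_equal(length(filt), 500L)
  expect_false(any(start(filt) - 1L == 7777))
  expect_equal(S4Vectors::metadata(filt)$maskedPositions, "chr1:7777")
  # infinite threshold is the identity
  expect_equal(length(hotspotFilter(pile, zThreshold = Inf)), 600L)
  # zero variance: warn, keep everything
  expect_warning(out <- hotspotFilter(fr[1:10]), "zero variance")
  expect_equal(length(out), 10L)
})

test_that("binning uses the midpoint rule on the genome grid", {
  genome <- c(chr1 = 1000)
  bins <- genomeBins(genome, 300)
  expect_equal(length(bins), 4L)
  expect_equal(width(bins), c(300, 300, 300, 100))
  # fragment [10, 160): midpoint 85 -> first bin
  fr <- fragmentSet("chr1", 10, 160)
  bs <- binFragmentCounts(fr, genome, 300)
  expect_equal(as.numeric(signalValues(bs)), c(1, 0, 0, 0))
  # no fragments: all-zero bins
  bs0 <- binFragmentCounts(fr[0], genome, 300)
  expect_equal(as.numeric(signalValues(bs0)), rep(0, 4))
  # out-of-bounds fragment errors with the record
  expect_error(binFragmentCounts(fragmentSet("chr1", 900, 1100), genome, 300),
               "outside genome bounds")
  # a fragment straddling bins counts once, in its midpoint bin
  fr2 <- fragmentSet("chr1", 250, 450)  # midpoint 350 -> bin 2
  expect_equal(as.numeric(signalValues(binFragmentCounts(fr2, genome, 300))),
               c(0, 1, 0, 0))
})

test_that("binning splits tracks by condition, replicate and concentration", {
  genome <- c(chr1 = 3000)
  fr <- fragmentSet(rep("chr1", 6), rep(100, 6), rep(250, 6),
                    condition = rep(c("a", "b"), each = 3),
                    replicate = "rep1",
                    mnaseUnits = rep(c(1.5, 25, 400), 2))
  bs <- binFragmentCounts(fr, genome, 300)
  expect_equal(ncol(bs), 6L)
  expect_setequal(colData(bs)$condition, c("a", "b"))
  expect_true(is.numeric(colData(bs)$mnaseUnits))
  expect_equal(sum(signalValues(bs)), 6)
})

test_that("RPM normalisation scales by library size and is linear", {
  bs <- toyBS(c(5, 0, 15))
  rpm <- rpmNormalize(bs, librarySizes = 1e6)
  expect_equal(as.numeric(signalValues(rpm)), c(5, 0, 15))
  rpm2 <- rpmNormalize(bs, librarySizes = 2e6)
  expect_equal(as.numeric(signalValues(rpm2)), c(2.5, 0, 7.5))
  expect_error(rpmNormalize(bs, librarySizes = 0), "positive")
  # scaling all counts by k leaves default (self-library) RPM unchanged
  k <- 7
  expect_equal(signalValues(rpmNormalize(toyBS(k * c(5, 0, 15)))),
               signalValues(rpmNormalize(bs)))
  # total count is recoverable
  expect_equal(sum(signalValues(rpm)) * 1e6 / 1e6, 20)
})

test_that("occupancy is the unweighted mean across a condition's tracks", {
  vals <- cbind(t1 = c(2, 4), t2 = c(4, 8))
  bs <- toyBS(vals, trackData = data.frame(condition = c("x", "x")))
  occ <- nucleosomeOccupancy(bs)
  expect_equal(as.numeric(signalValues(occ)), c(3, 6))
  # identical tracks: occupancy equals any one of them (idempotence)
  same <- toyBS(cbind(c(1, 2), c(1, 2)),
                trackData = data.frame(condition = c("x", "x")))
  expect_equal(as.numeric(signalValues(nucleosomeOccupancy(same))), c(1, 2))
  # ten tracks: per-bin mean of ten values
  set.seed(6)
  m <- matrix(rpois(40, 20), 4, 10)
  bs10 <- toyBS(m, trackData = data.frame(condition = rep("x", 10)))
  expect_equal(as.numeric(signalValues(nucleosomeOccupancy(bs10))),
               rowMeans(m))
})

test_that("signal difference is exact and antisymmetric", {
  a <- toyBS(c(1, 2))
  b <- toyBS(c(0.5, 3))
  expect_equal(as.numeric(signalValues(signalDifference(a, b))),
               c(0.5, -1))
  expect_equal(signalValues(signalDifference(a, b)),
               -signalValues(signalDifference(b, a)))
  expect_equal(as.numeric(signalValues(signalDifference(a, a))), c(0, 0))
  other <- binnedSignal(1:3, genomeBins(c(chrZ = 900), 300), 300)
  expect_error(signalDifference(a, other), "grids do not match")
})

test_that("centre-aligned windows have the stated geometry", {
  genome <- c(chrT = 20000)
  bins <- genomeBins(genome, 300)
  sig <- binnedSignal(seq_along(bins), bins, 300)
  site <- GRanges("chrT", IRanges(9996, 10005))  # centre at 10000 (0-based)
  sm <- centerAlignedMatrix(site, sig, flank = 5000, resolution = 500)
  expect_equal(ncol(sm@mat), 20L)
  expect_equal(length(sm@excluded), 0L)
  # constant signal gives a constant matrix
  const <- binnedSignal(rep(3.5, length(bins)), bins, 300)
  smc <- centerAlignedMatrix(site, const, flank = 5000, resolution = 500)
  expect_equal(as.numeric(smc@mat), rep(3.5, 20))
  # a site whose window leaves the chromosome is flagged and NA
  edge <- GRanges("chrT", IRanges(1000, 1009))
  sme <- centerAlignedMatrix(c(site, edge), sig, flank = 5000,
                             resolution = 500)
  expect_equal(sme@excluded, 2L)
  expect_true(all(is.na(sme@mat[2, ])))
  expect_false(anyNA(profileMeans(sme)))
})

test_that("a step at the site centre lands at column flank/resolution", {
  genome <- c(chrT = 18000)
  bins <- genomeBins(genome, 300)
  stepVals <- ifelse(end(bins) <= 9000, 0, 1)  # step at position 9000
  sig <- binnedSignal(stepVals, bins, 300)
  site <- GRanges("chrT", IRanges(8996, 9005))  # 0-based centre 9000
  sm <- centerAlignedMatrix(site, sig, flank = 3000, resolution = 500)
  prof <- profileMeans(sm)
  expect_equal(prof[1:6], rep(0, 6), ignore_attr = TRUE)
  expect_equal(prof[7:12], rep(1, 6), ignore_attr = TRUE)
})

test_that("scaled-region matrices resample by equal sub-intervals", {
  genome <- c(chrT = 3000)
  bins <- genomeBins(genome, 300)
  sig <- binnedSignal(c(9, 9, 2, 4, 9, 9, 9, 9, 9, 9), bins, 300)
  # region covering exactly bins 3 and 4 (values 2 and 4), scaled to 4
  region <- GRanges("chrT", IRanges(601, 1200))
  sm <- scaledRegionMatrix(region, sig, 4)
  expect_equal(as.numeric(sm@mat), c(2, 2, 4, 4))
  # region exactly nColumns bins long: identity resampling
  region4 <- GRanges("chrT", IRanges(1, 1200))
  expect_equal(as.numeric(scaledRegionMatrix(region4, sig, 4)@mat),
               c(9, 9, 2, 4))
  # constant signal: constant rows regardless of region length
  const <- binnedSignal(rep(7, 10), bins, 300)
  sm2 <- scaledRegionMatrix(GRanges("chrT", IRanges(c(1, 601), c(2700, 900))),
                            const, 5)
  expect_equal(as.numeric(sm2@mat), rep(7, 10))
  # a region shorter than the column count still yields values
  tiny <- GRanges("chrT", IRanges(601, 603))
  expect_equal(as.numeric(scaledRegionMatrix(tiny, sig, 4)@mat), rep(2, 4))
})

test_that("random sites are reproducible, counted and in bounds", {
  genome <- c(chrA = 5000, chrB = 3000)
  s1 <- randomSites(genome, 200, width = 100, seed = 5)
  s2 <- randomSites(genome, 200, width = 100, seed = 5)
  expect_equal(length(s1), 200L)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_true(all(start(s1) >= 1))
  expect_true(all(end(s1) <= seqlengths(s1)[as.character(seqnames(s1))]))
  expect_error(randomSites(c(chrA = 50), 5, width = 100), "exceeds")
})

test_that("contact consolidation applies the replicate-support rule", {
  dsA <- list(GRanges("chr3R", IRanges(101, 200)),
              GRanges("chr3R", IRanges(151, 250)))
  dsB <- list(GRanges("chr3R", IRanges(401, 500)))
  out <- consolidateContacts(list(dsA, dsB), minReplicates = 2)
  expect_equal(length(out), 1L)
  expect_equal(start(out), 101L)
  expect_equal(end(out), 250L)
  # all replicates identical: merged input survives
  same <- list(GRanges("chr1", IRanges(c(1, 500), c(100, 700))),
               GRanges("chr1", IRanges(c(1, 500), c(100, 700))))
  out2 <- consolidateContacts(list(same))
  expect_equal(length(out2), 2L)
  # disjoint single-replicate intervals everywhere: empty result
  lonely <- list(list(GRanges("chr1", IRanges(1, 10)),
                      GRanges("chr1", IRanges(1000, 1010))))
  expect_equal(length(consolidateContacts(lonely)), 0L)
})

test_that("consolidated output is sorted, disjoint and idempotent", {
  set.seed(7)
  reps <- lapply(1:3, function(k)
    GRanges("chr2", IRanges(sort(sample(1:5000, 30)) * 10, width = 400)))
  out <- consolidateContacts(list(reps), minReplicates = 2)
  expect_true(all(diff(start(out)) > 0))
  expect_true(all(start(out)[-1] > head(end(out), -1) + 1))
  again <- consolidateContacts(list(list(out)), minReplicates = 1)
  expect_identical(as.data.frame(out), as.data.frame(again))
})

test_that("bins-in-regions selects midpoint-contained grid bins once", {
  genome <- c(chr1 = 3000)
  hit <- binsInRegions(GRanges("chr1", IRanges(1, 900)), genome, 300)
  expect_equal(mcols(hit)$bin, 0:2)
  expect_equal(length(binsInRegions(GRanges(), genome, 300)), 0L)
  # overlapping regions do not duplicate bins
  ovl <- GRanges("chr1", IRanges(c(1, 301), c(900, 1200)))
  expect_equal(mcols(binsInRegions(ovl, genome, 300))$bin, 0:3)
})

test_that("site-distribution comparisons run both tests two-sided", {
  same <- c(1, 2, 3, 4, 5)
  res <- compareSiteDistributions(same, same, test = "t")
  expect_equal(res$p.value, 1)
  set.seed(8)
  a <- rnorm(20, 0, 0.01)
  b <- rnorm(20, 10, 0.01)
  expect_lt(compareSiteDistributions(a, b, test = "t")$p.value, 0.01)
  # rank test is invariant under monotone transforms of pooled values
  w1 <- compareSiteDistributions(a, b, test = "wilcoxon")$p.value
  w2 <- compareSiteDistributions(exp(a), exp(b), test = "wilcoxon")$p.value
  expect_equal(w1, w2)
  expect_error(compareSiteDistributions(1, c(1, 2)), "at least 2")
})

test_that("gene-class aggregation splits matrices and per-gene means", {
  genome <- c(chrT = 6000)
  bins <- genomeBins(genome, 300)
  vals <- rep(0, length(bins))
  vals[1:5] <- -2  # depressed signal over the "up" gene
  sig <- binnedSignal(vals, bins, 300)
  genes <- GRanges("chrT", IRanges(c(1, 3001, 4501), c(1500, 4500, 6000)))
  names(genes) <- c("g1", "g2", "g3")
  tb <- data.frame(gene = c("g1", "g2", "g3", "gX"),
                   class = c("up", "none", "none", "up"))
  expect_message(res <- geneClassAggregation(tb, genes, sig, nColumns = 5),
                 "skipped")
  expect_equal(res$nSkipped, 1L)
  expect_equal(nrow(res$matrices[["up"]]@mat), 1L)
  expect_equal(nrow(res$matrices[["none"]]@mat), 2L)
  byClass <- tapply(res$perGene$meanDiff, res$perGene$class, mean)
  expect_lt(byClass["up"], byClass["none"])
  # permuting class labels permutes the outputs accordingly
  tb2 <- tb[c(2, 1, 3, 4), ]
  res2 <- suppressMessages(geneClassAggregation(tb2, genes, sig,
                                                nColumns = 5))
  expect_equal(sort(res2$perGene$meanDiff), sort(res$perGene$meanDiff))
})

test_that("binned tracks export to bedGraph and site matrices to TSV", {
  bs <- toyBS(c(1.5, 0, 2.25))
  bg <- tempfile(fileext = ".bedGraph")
  exportBedGraph(bs, bg)
  back <- rtracklayer::import(bg, format = "bedGraph")
  expect_equal(back$score, c(1.5, 0, 2.25))
  site <- GRanges("chrT", IRanges(401, 500))
  sm <- centerAlignedMatrix(site, bs, flank = 300, resolution = 150)
  p <- tempfile(fileext = ".tsv")
  writeSiteMatrix(sm, p)
  hdr <- readLines(p, n = 1)
  expect_match(hdr, "^# \\{")
  meta <- jsonlite::fromJSON(sub("^# ", "", hdr))
  expect_equal(meta$kind, "center")
  expect_equal(meta$n_sites, 1L)
  body <- read.table(p, skip = 1, sep = "\t")
  expect_equal(dim(as.matrix(body)), dim(sm@mat))
})
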