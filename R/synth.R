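## Synthetic MNase-titration dataset generator with known per-bin ground
## truth: a toy genome with a smooth GC profile and non-overlapping binding
## sites, and Poisson paired-end fragments whose expected counts follow a
## separable protection x titration-slope model, so occupancy and MACC are
## identifiable and independently perturbable.

.synthSeed <- function(config, offset) as.integer(config@seed * 101 + offset)

.smoothField <- function(nBinsPerChrom, low, high, period, phases) {
  mid <- (low + high) / 2
  amp <- (high - low) / 2
  unlist(lapply(seq_along(nBinsPerChrom), function(k) {
    b <- seq_len(nBinsPerChrom[k])
    mid + amp * sin(2 * pi * (b / period + phases[k]))
  }))
}

.synthLayout <- function(config) {
  # everything deterministic from the config seed, shared by all generators
  chroms <- paste0("chrS", seq_len(config@nChroms))
  sizes <- setNames(rep(config@genomeLength, config@nChroms), chroms)
  bins <- genomeBins(sizes, config@binSize)
  nPer <- as.integer(table(factor(as.character(seqnames(bins)),
                                  levels = chroms)))
  nBins <- length(bins)

  set.seed(.synthSeed(config, 1L))
  gcPhase <- runif(config@nChroms)
  oPhase <- runif(config@nChroms)
  gcProfile <- .smoothField(nPer, config@gcLow, config@gcHigh, 40, gcPhase)
  oField <- pmin(1, pmax(0.05, .smoothField(
    nPer, config@occupancyBase - 0.2, config@occupancyBase + 0.2,
    55, oPhase)))

  # non-overlapping sites: one per sampled slot of width 2 * siteWidth
  slotW <- 2L * config@siteWidth
  nSlotPer <- sizes %/% slotW
  slots <- GRanges(
    rep(chroms, nSlotPer),
    IRanges(start = unlist(lapply(nSlotPer, function(ns)
      (seq_len(ns) - 1L) * slotW + 1L), use.names = FALSE),
      width = slotW))
  if (config@nSites > length(slots))
    stop("cannot place ", config@nSites, " non-overlapping sites; ",
         "use fewer or narrower sites")
  sites <- GRanges()
  if (config@nSites > 0L) {
    pick <- sort(sample(seq_along(slots), config@nSites))
    off <- floor(runif(config@nSites) *
                   (slotW - config@siteWidth + 1L))
    sites <- GRanges(seqnames(slots)[pick],
                     IRanges(start(slots)[pick] + off,
                             width = config@siteWidth))
    sites <- sort(sites)
    names(sites) <- paste0("site", seq_along(sites))
  }
  siteBin <- overlapsAny(
    GRanges(seqnames(bins),
            IRanges(start(bins) + width(bins) %/% 2L, width = 1L)),
    sites)

  cls <- sample(c(1, -1, 0), nBins, replace = TRUE,
                prob = c(config@accessibilityFracPos,
                         config@accessibilityFracNeg,
                         1 - config@accessibilityFracPos -
                           config@accessibilityFracNeg))
  # heterogeneous magnitudes within the non-zero classes (mean equals
  # accessibilityMagnitude); a single shared magnitude would tie all
  # non-zero bins and make rank-based recovery insensitive
  aField <- cls * config@accessibilityMagnitude * runif(nBins, 0.5, 1.5)
  maccShift <- logical(nBins)
  freeBins <- which(cls == 0 & !siteBin)
  nShift <- min(config@maccShiftBins, length(freeBins))
  if (nShift) maccShift[sample(freeBins, nShift)] <- TRUE

  list(chroms = chroms, sizes = sizes, bins = bins, gcProfile = gcProfile,
       oField = oField, aField = aField, siteBin = siteBin,
       maccShift = maccShift, sites = sites)
}

.conditionTruth <- function(config, layout, condition) {
  shift <- config@occupancyShiftAtSites[condition]
  if (is.na(shift)) stop("unknown condition: ", condition)
  o <- pmin(1, pmax(0, layout$oField + shift * layout$siteBin))
  a <- layout$aField +
    (condition == "depleted") * config@maccShiftDelta * layout$maccShift
  list(o = o, a = a)
}

#' Conditions defined by a synthetic configuration
#' @param config a [SynthConfig-class].
#' @return character vector of condition labels.
#' @export
synthConditions <- function(config) names(config@occupancyShiftAtSites)

#' Generate the toy genome
#'
#' Random chromosome sequences following the configuration's smooth per-bin
#' GC profile, with non-overlapping binding-site annotations. Deterministic
#' from the config seed.
#'
#' @param config a [SynthConfig-class].
#' @return list with `seq` (named [Biostrings::DNAStringSet]),
#'   `chromSizes` (named integer), `sites` (`GRanges`), `bins` (the genome
#'   bin grid) and `gcProfile` (per-bin target GC).
#' @export
makeToyGenome <- function(config) {
  layout <- .synthLayout(config)
  set.seed(.synthSeed(config, 2L))
  seqs <- lapply(seq_along(layout$chroms), function(k) {
    idx <- which(as.character(seqnames(layout$bins)) == layout$chroms[k])
    pGC <- rep(layout$gcProfile[idx], width(layout$bins)[idx])
    u <- runif(length(pGC))
    base <- ifelse(u < pGC / 2, "G",
            ifelse(u < pGC, "C",
            ifelse(u < pGC + (1 - pGC) / 2, "A", "T")))
    paste(base, collapse = "")
  })
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  names(dss) <- layout$chroms
  list(seq = dss, chromSizes = layout$sizes, sites = layout$sites,
       bins = layout$bins, gcProfile = layout$gcProfile)
}

#' Expected per-bin fragment counts of one library
#'
#' The generative mean: `depth * o_b * max(0, 1 + a_b (log10 c - mean
#' log10 c))` for each bin b and titration point c of the given condition.
#'
#' @param config a [SynthConfig-class].
#' @param condition one of [synthConditions()].
#' @return numeric matrix, bins x concentrations.
#' @export
expectedCounts <- function(config, condition) {
  layout <- .synthLayout(config)
  tr <- .conditionTruth(config, layout, condition)
  x <- log10(config@concentrations)
  xc <- x - mean(x)
  sapply(xc, function(v) config@depth * tr$o * pmax(0, 1 + tr$a * v))
}

#' Simulate a fragment titration series for one condition
#'
#' Draws Poisson fragment counts per bin for every (replicate,
#' concentration) library, places fragment midpoints uniformly within their
#' bin, and draws insert lengths from a truncated normal with a small
#' out-of-range contamination fraction (to exercise the insert filter).
#' Deterministic from the config seed and condition.
#'
#' @param config a [SynthConfig-class].
#' @param condition one of [synthConditions()].
#' @return a fragment `GRanges` (see [fragmentSet()]) tagged with
#'   condition, replicate and mnaseUnits.
#' @export
simulateTitration <- function(config, condition) {
  layout <- .synthLayout(config)
  tr <- .conditionTruth(config, layout, condition)
  condIdx <- match(condition, synthConditions(config))
  set.seed(.synthSeed(config, 100L + condIdx))
  x <- log10(config@concentrations)
  xc <- x - mean(x)
  binChrom <- as.character(seqnames(layout$bins))
  binStart0 <- start(layout$bins) - 1L
  binW <- width(layout$bins)
  sizes <- layout$sizes
  res <- list()
  for (r in seq_len(config@nReplicates)) {
    for (ci in seq_along(config@concentrations)) {
      lambda <- config@depth * tr$o * pmax(0, 1 + tr$a * xc[ci])
      n <- rpois(length(lambda), lambda)
      tot <- sum(n)
      if (!tot) next
      binIdx <- rep(seq_along(n), n)
      mid0 <- binStart0[binIdx] + floor(runif(tot) * binW[binIdx])
      len <- round(rnorm(tot, config@fragLenMean, config@fragLenSd))
      len <- pmin(500L, pmax(50L, as.integer(len)))
      contam <- runif(tot) < config@contamFrac
      nC <- sum(contam)
      if (nC) {
        short <- runif(nC) < 0.5
        len[contam] <- ifelse(short,
                              20L + as.integer(floor(runif(nC) * 30)),
                              501L + as.integer(floor(runif(nC) * 100)))
      }
      s0 <- mid0 - len %/% 2L
      chromLen <- sizes[binChrom[binIdx]]
      s0 <- pmax(0L, pmin(s0, chromLen - len))
      res[[length(res) + 1L]] <- fragmentSet(
        binChrom[binIdx], s0, s0 + len,
        condition = condition, replicate = paste0("rep", r),
        mnaseUnits = config@concentrations[ci], genome = sizes)
    }
  }
  if (!length(res))
    return(fragmentSet(character(), integer(), integer(),
                       genome = sizes)[0])
  out <- do.call(c, res)
  seqinfo(out) <- .asSeqinfo(sizes)
  out
}

#' Ground-truth table for one condition
#'
#' Per-bin generating truth aligned to the pipeline bin grid: protection
#' `o`, accessibility coefficient `a`, site-bin membership, and the
#' differential-accessibility flag.
#'
#' @param config a [SynthConfig-class].
#' @param condition one of [synthConditions()].
#' @return `data.frame` with columns chrom, start (0-based), end, bin, o,
#'   a, site, maccShift.
#' @export
truthTable <- function(config, condition) {
  layout <- .synthLayout(config)
  tr <- .conditionTruth(config, layout, condition)
  data.frame(
    chrom = as.character(seqnames(layout$bins)),
    start = start(layout$bins) - 1L, end = end(layout$bins),
    bin = mcols(layout$bins)$bin, o = tr$o, a = tr$a,
    site = layout$siteBin, maccShift = layout$maccShift)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits FASTA chromosome sequences, a chrom-sizes TSV, the site BED, one
#' fragment TSV per condition (0-based half-open coordinates with
#' condition/replicate/mnaseUnits columns), and per-condition truth TSVs.
#'
#' @param config a [SynthConfig-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
writeSynthDataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- makeToyGenome(config)
  paths <- character()
  p <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(g$seq, p)
  paths <- c(paths, p)
  p <- file.path(dir, "chrom.sizes")
  write.table(data.frame(names(g$chromSizes), g$chromSizes), p,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "sites.bed")
  rtracklayer::export(g$sites, p, format = "BED")
  paths <- c(paths, p)
  for (cond in synthConditions(config)) {
    fr <- simulateTitration(config, cond)
    df <- data.frame(chrom = as.character(seqnames(fr)),
                     start = start(fr) - 1L, end = end(fr),
                     condition = mcols(fr)$condition,
                     replicate = mcols(fr)$replicate,
                     mnaseUnits = mcols(fr)$mnaseUnits)
    p <- file.path(dir, paste0("fragments_", cond, ".tsv"))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(dir, paste0("truth_", cond, ".tsv"))
    write.table(truthTable(config, cond), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a fragment TSV written by [writeSynthDataset()]
#'
#' @param path TSV with columns chrom, start (0-based), end, condition,
#'   replicate, mnaseUnits.
#' @param genome optional named chromosome lengths for bounds checking.
#' @return a fragment `GRanges`.
#' @export
readFragmentsTsv <- function(path, genome = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  fragmentSet(df$chrom, df$start, df$end, condition = df$condition,
              replicate = df$replicate, mnaseUnits = df$mnaseUnits,
              genome = genome)
}
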