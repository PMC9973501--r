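## MNase-titration-seq occupancy pipeline: fragment QC, hotspot masking,
## 300-bp binning, RPM normalisation, titration-averaged occupancy,
## condition differencing, and the aggregation geometries (site-centred
## windows, scaled regions, contact-region bins, random-site controls).

#' Construct a fragment set
#'
#' Builds the paired-end fragment container: a [GenomicRanges::GRanges]
#' whose ranges are the sequenced inserts (1-based, inclusive; insert
#' length equals range width) with `condition`, `replicate` and
#' `mnaseUnits` metadata columns.
#'
#' @param chrom character vector of chromosome names.
#' @param start0,end0 0-based half-open fragment coordinates.
#' @param condition,replicate,mnaseUnits per-fragment labels (recycled).
#' @param genome optional named integer chromosome lengths; if given, the
#'   returned object carries seqlengths and out-of-bound fragments error.
#' @return A `GRanges` of fragments.
#' @export
fragmentSet <- function(chrom, start0, end0, condition = "sample",
                        replicate = "rep1", mnaseUnits = NA_real_,
                        genome = NULL) {
  if (any(end0 <= start0)) stop("fragment end must exceed start")
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
  mcols(gr)$condition <- rep_len(as.character(condition), length(gr))
  mcols(gr)$replicate <- rep_len(as.character(replicate), length(gr))
  mcols(gr)$mnaseUnits <- rep_len(as.numeric(mnaseUnits), length(gr))
  if (!is.null(genome)) {
    si <- .asSeqinfo(genome)
    if (!all(as.character(seqnames(gr)) %in% seqlevels(si)))
      stop("fragment on unknown chromosome")
    seqlevels(gr) <- seqlevels(si)
    seqinfo(gr) <- si
    .checkInBounds(gr)
  }
  gr
}

.checkInBounds <- function(gr) {
  sl <- seqlengths(gr)[as.character(seqnames(gr))]
  bad <- which(start(gr) < 1L | end(gr) > sl)
  if (length(bad))
    stop("fragment outside genome bounds, e.g. record ", bad[1], ": ",
         as.character(seqnames(gr))[bad[1]], ":", start(gr)[bad[1]] - 1L,
         "-", end(gr)[bad[1]])
  invisible(TRUE)
}

#' Filter fragments by insert size
#'
#' Keeps fragments whose insert length lies within `[minLen, maxLen]`
#' (inclusive); the QC step removing sub-nucleosomal and polynucleosomal
#' inserts (default 50-500 bp).
#'
#' @param fragments a fragment `GRanges` (see [fragmentSet()]).
#' @param minLen,maxLen inclusive insert-length bounds in bp.
#' @return the filtered `GRanges`.
#' @export
filterFragmentsByInsert <- function(fragments, minLen = 50, maxLen = 500) {
  fragments[width(fragments) >= minLen & width(fragments) <= maxLen]
}

#' Mask hotspot positions and drop fragments starting there
#'
#' Counts fragment start positions, computes z-scores of the per-position
#' counts (by default over positions with non-zero coverage; per genome, or
#' per chromosome with `perChromosome = TRUE`), masks positions with
#' z-score above `zThreshold`, and removes fragments starting at masked
#' positions. With zero count variance nothing is masked (warning).
#'
#' @param fragments a fragment `GRanges`.
#' @param zThreshold z-score cutoff (default 7).
#' @param perChromosome compute mean/SD per chromosome (default genome-wide).
#' @param includeZero include zero-coverage positions in mean/SD; requires
#'   seqlengths on `fragments`.
#' @return the filtered `GRanges`, with masked positions in
#'   `metadata(...)$maskedPositions` (as "chrom:start0" labels).
#' @export
hotspotFilter <- function(fragments, zThreshold = 7, perChromosome = FALSE,
                          includeZero = FALSE) {
  if (!length(fragments)) return(fragments)
  key <- paste0(as.character(seqnames(fragments)), ":",
                start(fragments) - 1L)
  counts <- table(key)
  grp <- if (perChromosome) sub(":.*", "", names(counts))
         else rep("genome", length(counts))
  masked <- character()
  for (g in unique(grp)) {
    v <- as.numeric(counts[grp == g])
    nZero <- 0
    if (includeZero) {
      sl <- seqlengths(fragments)
      if (any(is.na(sl))) stop("includeZero requires seqlengths")
      tot <- if (perChromosome) sl[g] else sum(sl)
      nZero <- tot - length(v)
    }
    m <- sum(v) / (length(v) + nZero)
    sdv <- sqrt((sum((v - m)^2) + nZero * m^2) /
                  max(1, length(v) + nZero - 1))
    if (!is.finite(sdv) || sdv == 0) {
      warning("zero variance in position counts; nothing masked")
      next
    }
    z <- (v - m) / sdv
    masked <- c(masked, names(counts[grp == g])[z > zThreshold])
  }
  out <- fragments[!(key %in% masked)]
  metadata(out)$maskedPositions <- masked
  out
}

#' Count fragments in fixed-width genome bins
#'
#' Tiles the genome into `binSize`-bp non-overlapping bins (trailing
#' partial bin retained) and assigns each fragment to the bin containing
#' its midpoint. With `by`, one count track is produced per combination of
#' the named fragment metadata columns.
#'
#' @param fragments a fragment `GRanges`.
#' @param genome named integer chromosome lengths or a Seqinfo.
#' @param binSize bin width in bp (default 300).
#' @param by character vector of `mcols(fragments)` columns defining tracks
#'   (default the trio condition/replicate/mnaseUnits when present).
#' @param fullOverlapWeights if `TRUE`, distribute each fragment over the
#'   bins it overlaps proportionally to the overlap length, instead of
#'   midpoint assignment.
#' @return A [BinnedSignal-class] of per-bin counts with track metadata.
#' @export
binFragmentCounts <- function(fragments, genome, binSize = 300, by = NULL,
                      fullOverlapWeights = FALSE) {
  si <- .asSeqinfo(genome)
  bins <- genomeBins(si, binSize)
  if (length(fragments)) {
    if (!all(as.character(seqnames(fragments)) %in% seqlevels(si)))
      stop("fragment on unknown chromosome")
    sl <- seqlengths(si)[as.character(seqnames(fragments))]
    bad <- which(start(fragments) < 1L | end(fragments) > sl)
    if (length(bad))
      stop("fragment outside genome bounds, record ", bad[1])
  }
  if (is.null(by)) {
    cand <- c("condition", "replicate", "mnaseUnits")
    by <- cand[cand %in% names(mcols(fragments))]
  }
  if (!length(fragments)) by <- character()
  grpKey <- if (length(by) && length(fragments))
    do.call(paste, c(lapply(by, function(cl) mcols(fragments)[[cl]]),
                     sep = "|"))
  else rep("counts", length(fragments))
  levs <- if (length(fragments)) unique(grpKey) else "counts"
  vals <- matrix(0, length(bins), length(levs),
                 dimnames = list(NULL, levs))
  if (length(fragments)) {
    if (fullOverlapWeights) {
      frG <- granges(fragments)
      ov <- findOverlaps(frG, bins)
      w <- width(pintersect(frG[queryHits(ov)], bins[subjectHits(ov)])) /
        width(frG[queryHits(ov)])
      for (k in seq_along(levs)) {
        sel <- grpKey[queryHits(ov)] == levs[k]
        if (!any(sel)) next
        rs <- rowsum(w[sel], subjectHits(ov)[sel])
        vals[as.integer(rownames(rs)), k] <- rs[, 1]
      }
    } else {
      mid0 <- (start(fragments) - 1L + end(fragments)) %/% 2L
      midG <- GRanges(seqnames(fragments), IRanges(mid0 + 1L, mid0 + 1L))
      ov <- findOverlaps(midG, bins)
      binIdx <- subjectHits(ov)[order(queryHits(ov))]
      for (k in seq_along(levs)) {
        tb <- tabulate(binIdx[grpKey == levs[k]], nbins = length(bins))
        vals[, k] <- tb
      }
    }
  }
  td <- NULL
  if (length(by)) {
    parts <- strsplit(levs, "|", fixed = TRUE)
    td <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
    names(td) <- by
    if ("mnaseUnits" %in% names(td))
      td$mnaseUnits <- suppressWarnings(as.numeric(td$mnaseUnits))
  }
  binnedSignal(vals, bins, binSize, trackData = td)
}

#' Reads-per-million normalisation
#'
#' Scales each track by `1e6 / librarySize`. By default the library size of
#' a track is its own total count; pass explicit sizes (e.g. total mapped
#' fragments before binning) to normalise against the full library.
#'
#' @param binned a [BinnedSignal-class] of counts.
#' @param librarySizes optional numeric vector, one per track.
#' @return A [BinnedSignal-class] in RPM units; library sizes are stored in
#'   `colData(...)$librarySize`.
#' @export
rpmNormalize <- function(binned, librarySizes = NULL) {
  v <- signalValues(binned)
  if (is.null(librarySizes)) librarySizes <- colSums(v)
  if (any(librarySizes <= 0)) stop("library sizes must be positive")
  out <- binnedSignal(sweep(v, 2, librarySizes, "/") * 1e6,
                      rowRanges(binned), binSize(binned),
                      trackData = as.data.frame(colData(binned)))
  colData(out)$librarySize <- librarySizes
  out
}

#' Titration-averaged nucleosome occupancy
#'
#' The occupancy of a condition is the unweighted per-bin mean of its
#' RPM-normalised tracks across all MNase concentrations and replicates
#' (the study design: 5 concentrations x 2 replicates = 10 tracks per
#' condition).
#'
#' @param normalized a [BinnedSignal-class] of RPM tracks with a
#'   `condition` column in `colData` (or use `groups`).
#' @param groups optional factor/character grouping of tracks overriding
#'   `colData(normalized)$condition`.
#' @return A [BinnedSignal-class] with one occupancy track per condition.
#' @export
nucleosomeOccupancy <- function(normalized, groups = NULL) {
  if (is.null(groups)) groups <- colData(normalized)$condition
  if (is.null(groups)) stop("no condition grouping available")
  groups <- as.character(groups)
  v <- signalValues(normalized)
  levs <- unique(groups)
  out <- vapply(levs, function(g)
    rowMeans(v[, groups == g, drop = FALSE]), numeric(nrow(v)))
  colnames(out) <- levs
  binnedSignal(out, rowRanges(normalized), binSize(normalized),
               trackData = data.frame(condition = levs))
}

#' Per-bin signal difference
#'
#' Subtracts track `b` from track `a` bin by bin (e.g. occupancy of a
#' perturbed condition minus the control). Grids must match exactly.
#'
#' @param a,b [BinnedSignal-class] objects on the same bin grid, or one
#'   object with `trackA`/`trackB` naming two of its columns.
#' @param trackA,trackB column names or indices (default first column of
#'   each object).
#' @return A single-track [BinnedSignal-class] of differences.
#' @export
signalDifference <- function(a, b = a, trackA = 1L, trackB = 1L) {
  .checkSameGrid(a, b)
  va <- signalValues(a)[, trackA]
  vb <- signalValues(b)[, trackB]
  out <- binnedSignal(matrix(va - vb, ncol = 1), rowRanges(a), binSize(a))
  colnames(out) <- "difference"
  out
}

.trackVector <- function(signal, track) {
  v <- signalValues(signal)
  if (is.character(track) && !track %in% colnames(v))
    stop("no track named ", track)
  v[, track]
}

.windowMeans <- function(windows, signal, track) {
  # overlap-weighted mean of per-bp signal (bin values constant within bins)
  bins <- rowRanges(signal)
  v <- .trackVector(signal, track)
  ov <- findOverlaps(windows, bins)
  if (!length(ov)) return(rep(NA_real_, length(windows)))
  w <- width(pintersect(windows[queryHits(ov)], bins[subjectHits(ov)]))
  num <- tapply(w * v[subjectHits(ov)], queryHits(ov), sum)
  den <- tapply(w, queryHits(ov), sum)
  out <- rep(NA_real_, length(windows))
  out[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
  out
}

.siteCenters0 <- function(sites) {
  # 0-based centre: floor((start0 + end0) / 2)
  (start(sites) - 1L + end(sites)) %/% 2L
}

#' Signal matrix around site centres
#'
#' Aligns intervals by their centres and samples the signal in consecutive
#' `resolution`-bp windows across `[centre - flank, centre + flank)`;
#' row order follows the input (heatmap-ready), and column means over
#' retained rows give the average profile. Sites whose window leaves the
#' chromosome are flagged, set to `NA`, and excluded from column means.
#'
#' @param sites a `GRanges` of intervals.
#' @param signal a [BinnedSignal-class].
#' @param flank half-window in bp.
#' @param resolution column width in bp (default 50).
#' @param track signal column (default first).
#' @return A [SiteMatrix-class].
#' @export
centerAlignedMatrix <- function(sites, signal, flank, resolution = 50,
                                track = 1L) {
  nCol <- as.integer(floor(2 * flank / resolution))
  if (nCol < 1L) stop("flank must cover at least one window")
  c0 <- .siteCenters0(sites)
  sl <- seqlengths(rowRanges(signal))[as.character(seqnames(sites))]
  excluded <- which(c0 - flank < 0 | c0 + flank > sl | is.na(sl))
  mat <- matrix(NA_real_, length(sites), nCol)
  keep <- setdiff(seq_along(sites), excluded)
  if (length(keep)) {
    offs <- (seq_len(nCol) - 1L) * resolution
    starts0 <- rep(c0[keep] - flank, each = nCol) + rep(offs, length(keep))
    win <- GRanges(rep(seqnames(sites)[keep], each = nCol),
                   IRanges(starts0 + 1L, starts0 + resolution))
    vals <- .windowMeans(win, signal, track)
    mat[keep, ] <- matrix(vals, ncol = nCol, byrow = TRUE)
  }
  new("SiteMatrix", mat = mat, sites = granges(sites),
      resolution = as.numeric(resolution), flank = as.numeric(flank),
      kind = "center", excluded = as.integer(excluded))
}

#' Signal matrix over length-scaled regions
#'
#' Rescales every region to `nColumns` equal sub-intervals and averages the
#' signal within each (the "scaled gene body" geometry). Regions shorter
#' than `nColumns` bp repeat source values across columns.
#'
#' @param regions a `GRanges` of non-degenerate regions.
#' @param signal a [BinnedSignal-class].
#' @param nColumns number of columns to scale each region to.
#' @param track signal column (default first).
#' @return A [SiteMatrix-class] with `kind = "scaled"`.
#' @export
scaledRegionMatrix <- function(regions, signal, nColumns, track = 1L) {
  if (any(width(regions) < 1L)) stop("degenerate region")
  n <- length(regions)
  mat <- matrix(NA_real_, n, nColumns)
  s0 <- start(regions) - 1L
  w <- width(regions)
  # sub-interval k of region i: [s0 + floor(k w / n), s0 + floor((k+1) w / n))
  for (i in seq_len(n)) {
    b <- s0[i] + floor((0:nColumns) * w[i] / nColumns)
    lo <- b[-length(b)]
    hi <- pmax(b[-1L], lo + 1L)  # width-0 slices sample one bp
    win <- GRanges(rep(seqnames(regions)[i], nColumns),
                   IRanges(lo + 1L, hi))
    mat[i, ] <- .windowMeans(win, signal, track)
  }
  new("SiteMatrix", mat = mat, sites = granges(regions),
      resolution = NA_real_, flank = NA_real_, kind = "scaled",
      excluded = integer())
}

#' Column-mean profile of a site matrix
#'
#' @param x a [SiteMatrix-class].
#' @return numeric vector of column means over non-excluded rows.
#' @export
profileMeans <- function(x) {
  keep <- setdiff(seq_len(nrow(x@mat)), x@excluded)
  colMeans(x@mat[keep, , drop = FALSE], na.rm = TRUE)
}

#' Random genomic intervals
#'
#' Places `n` intervals of fixed width uniformly at random in the genome
#' (chromosome chosen proportionally to placeable length), reproducibly
#' from `seed`; the random-site control for site-centred aggregation.
#'
#' @param genome named integer chromosome lengths or Seqinfo.
#' @param n number of intervals.
#' @param width interval width in bp.
#' @param seed integer seed.
#' @return A `GRanges` of `n` intervals within bounds.
#' @export
randomSites <- function(genome, n, width, seed = 1) {
  si <- .asSeqinfo(genome)
  sl <- seqlengths(si)
  room <- setNames(pmax(0L, sl - as.integer(width) + 1L), names(sl))
  if (all(room == 0L)) stop("width exceeds every chromosome length")
  set.seed(seed)
  chr <- sample(seqlevels(si), n, replace = TRUE, prob = room / sum(room))
  s0 <- floor(runif(n) * room[chr])
  gr <- GRanges(chr, IRanges(s0 + 1L, s0 + as.integer(width)),
                seqinfo = si)
  sort(gr)
}

#' Consolidate replicate contact regions
#'
#' Within each dataset, keeps intervals supported by at least
#' `minReplicates` replicate sets (an interval counts as supported by a set
#' when it overlaps any interval of that set, including its own); the
#' retained intervals are pooled across datasets and merged
#' (overlapping/bookended) into non-overlapping sorted regions.
#'
#' @param contactSets a list of datasets; each dataset a list (or
#'   `GRangesList`) of replicate `GRanges`.
#' @param minReplicates minimum supporting replicate sets (default 2).
#' @return A sorted, non-overlapping `GRanges`.
#' @export
consolidateContacts <- function(contactSets, minReplicates = 2) {
  kept <- list()
  for (ds in contactSets) {
    reps <- as.list(ds)
    all <- do.call(c, lapply(reps, granges))
    if (!length(all)) next
    support <- Reduce(`+`, lapply(reps, function(r)
      as.integer(overlapsAny(all, r))))
    sel <- all[support >= minReplicates]
    if (length(sel)) kept[[length(kept) + 1L]] <- sel
  }
  if (!length(kept)) return(GRanges())
  sort(reduce(do.call(c, kept)))
}

#' Genome-grid bins underlying regions
#'
#' Returns the fixed-width genome bins whose midpoint falls inside any of
#' the given regions (each bin at most once).
#'
#' @param regions a `GRanges`.
#' @param genome named integer chromosome lengths or Seqinfo.
#' @param binSize bin width in bp (default 300).
#' @return A `GRanges` subset of the genome bin grid, with 0-based global
#'   bin indices in `mcols(...)$bin`.
#' @export
binsInRegions <- function(regions, genome, binSize = 300) {
  bins <- genomeBins(genome, binSize)
  mid1 <- start(bins) + width(bins) %/% 2L  # 1-based midpoint position
  midG <- GRanges(seqnames(bins), IRanges(mid1, mid1))
  bins[overlapsAny(midG, regions)]
}

#' Compare two groups of per-site values
#'
#' Two-sided two-sample test of location: Student's t test or the Wilcoxon
#' rank-sum test, as used for box/violin summaries of per-site occupancy
#' differences.
#'
#' @param valuesA,valuesB numeric vectors (>= 2 values each).
#' @param test `"t"` or `"wilcoxon"`.
#' @return list with `statistic`, `p.value` and `method`.
#' @export
compareSiteDistributions <- function(valuesA, valuesB,
                                     test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  if (length(valuesA) < 2 || length(valuesB) < 2)
    stop("need at least 2 values per group")
  res <- if (test == "t") t.test(valuesA, valuesB)
         else wilcox.test(valuesA, valuesB, exact = FALSE)
  list(statistic = unname(res$statistic), p.value = res$p.value,
       method = res$method)
}

#' Aggregate an occupancy-difference signal by gene class
#'
#' For each expression class (e.g. up-regulated / down-regulated /
#' no-change), builds the scaled gene-body signal matrix and the per-gene
#' mean difference distribution. Genes in the class table without
#' coordinates are skipped and counted.
#'
#' @param classTable `data.frame` with columns `gene` and `class`.
#' @param geneCoords a named `GRanges` of gene bodies (names match `gene`).
#' @param signal a [BinnedSignal-class] (typically an occupancy difference).
#' @param nColumns columns of the scaled matrices (default 100).
#' @param track signal column (default first).
#' @return list with `matrices` (one [SiteMatrix-class] per class),
#'   `perGene` (`data.frame` gene/class/meanDiff) and `nSkipped`.
#' @export
geneClassAggregation <- function(classTable, geneCoords, signal,
                                 nColumns = 100, track = 1L) {
  if (is.null(names(geneCoords))) stop("geneCoords must be named")
  have <- classTable$gene %in% names(geneCoords)
  nSkipped <- sum(!have)
  if (nSkipped) message(nSkipped, " gene(s) without coordinates skipped")
  tb <- classTable[have, , drop = FALSE]
  mats <- list()
  perGene <- NULL
  for (cl in unique(tb$class)) {
    g <- geneCoords[tb$gene[tb$class == cl]]
    sm <- scaledRegionMatrix(g, signal, nColumns, track = track)
    mats[[as.character(cl)]] <- sm
    perGene <- rbind(perGene, data.frame(
      gene = tb$gene[tb$class == cl], class = cl,
      meanDiff = rowMeans(sm@mat, na.rm = TRUE)))
  }
  rownames(perGene) <- NULL
  list(matrices = mats, perGene = perGene, nSkipped = nSkipped)
}
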