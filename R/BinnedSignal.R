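#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- queryHits subjectHits
#' @importFrom GenomicRanges GRanges granges tileGenome findOverlaps countOverlaps reduce seqnames start end width strand
#' @importFrom IRanges IRanges overlapsAny pintersect
#' @importFrom GenomeInfoDb seqlengths seqlevels seqlevels<- Seqinfo seqinfo seqinfo<-
#' @importFrom BiocGenerics sort
NULL

#' Fixed-width binned genomic signal
#'
#' A thin extension of [SummarizedExperiment::RangedSummarizedExperiment]
#' holding one value per genome bin (rows) and per track (columns) in a
#' single assay named `"signal"`. Rows follow the genome tiling grid: every
#' chromosome is cut into consecutive `binSize`-bp bins, the last bin
#' truncated at the chromosome end. Track metadata (condition, replicate,
#' MNase concentration) lives in `colData`.
#'
#' @export
setClass("BinnedSignal", contains = "RangedSummarizedExperiment")

setValidity("BinnedSignal", function(object) {
  msg <- character()
  if (!"signal" %in% names(assays(object)))
    msg <- c(msg, "assay 'signal' is required")
  if (is.null(metadata(object)$binSize))
    msg <- c(msg, "metadata binSize is required")
  if (length(msg)) msg else TRUE
})

## re-exports so pipeline users can inspect tracks without attaching
## SummarizedExperiment themselves

#' @export
SummarizedExperiment::colData

#' @export
SummarizedExperiment::rowRanges

#' Genome bin grid
#'
#' Cuts every chromosome into consecutive non-overlapping `binSize`-bp bins,
#' retaining the trailing partial bin. A chromosome of 1,000 bp at bin size
#' 300 yields 4 bins of widths 300, 300, 300 and 100.
#'
#' @param genome named integer vector of chromosome lengths, or a
#'   [GenomeInfoDb::Seqinfo].
#' @param binSize bin width in bp (default 300).
#' @return A [GenomicRanges::GRanges] of bins in genome order, with a
#'   `bin` metadata column giving the 0-based global bin index.
#' @examples
#' genomeBins(c(chr1 = 1000), binSize = 300)
#' @export
genomeBins <- function(genome, binSize = 300) {
  si <- .asSeqinfo(genome)
  bins <- tileGenome(si, tilewidth = binSize, cut.last.tile.in.chrom = TRUE)
  mcols(bins)$bin <- seq_along(bins) - 1L
  bins
}

.asSeqinfo <- function(genome) {
  if (is(genome, "Seqinfo")) return(genome)
  if (is.numeric(genome) && !is.null(names(genome)))
    return(Seqinfo(seqnames = names(genome),
                   seqlengths = as.integer(genome)))
  stop("genome must be a named integer vector of chromosome lengths ",
       "or a Seqinfo object")
}

#' Construct a BinnedSignal
#'
#' @param values numeric matrix (bins x tracks) or vector.
#' @param bins [GenomicRanges::GRanges] bin grid from [genomeBins()].
#' @param binSize bin width in bp.
#' @param trackData optional `data.frame`/`DataFrame` of per-track metadata.
#' @return A [BinnedSignal-class].
#' @export
binnedSignal <- function(values, bins, binSize, trackData = NULL) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("track", seq_len(ncol(values)))
  cd <- if (is.null(trackData)) DataFrame(row.names = colnames(values))
        else DataFrame(trackData, row.names = colnames(values))
  se <- SummarizedExperiment(assays = list(signal = values),
                             rowRanges = bins, colData = cd,
                             metadata = list(binSize = as.integer(binSize)))
  new("BinnedSignal", se)
}

#' Extract the signal matrix of a BinnedSignal
#' @param x a [BinnedSignal-class].
#' @return numeric matrix, bins x tracks.
#' @export
signalValues <- function(x) assay(x, "signal")

#' Bin width of a BinnedSignal
#' @param x a [BinnedSignal-class].
#' @return integer bin size in bp.
#' @export
binSize <- function(x) metadata(x)$binSize

.checkSameGrid <- function(a, b) {
  if (length(rowRanges(a)) != length(rowRanges(b)) ||
      !identical(binSize(a), binSize(b)) ||
      !all(seqnames(rowRanges(a)) == seqnames(rowRanges(b))) ||
      !all(start(rowRanges(a)) == start(rowRanges(b))) ||
      !all(end(rowRanges(a)) == end(rowRanges(b))))
    stop("bin grids do not match")
  invisible(TRUE)
}
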