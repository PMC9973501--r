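## MACC accessibility scores: per-bin ordinary-least-squares slope of the
## RPM-normalised fragment frequency against log10(MNase concentration),
## GC-detrended; plus differential accessibility between conditions.

#' MACC regression slope
#'
#' Ordinary least-squares slope of normalised fragment frequency against
#' log10 of MNase concentration. A positive slope (reads released with
#' increasing digestion) marks accessible chromatin; a negative slope marks
#' inaccessible chromatin. Requires at least 3 distinct concentrations.
#'
#' @param freqs numeric vector of per-concentration normalised frequencies,
#'   or a bins x concentrations matrix (one slope per row).
#' @param concentrations MNase amounts in U, matching `length(freqs)` /
#'   `ncol(freqs)`. Replicate tracks may be pooled by repeating
#'   concentrations.
#' @param logBase base of the concentration log (default 10; the base only
#'   rescales all slopes by a constant).
#' @return numeric slope(s), in frequency units per log-unit concentration.
#' @examples
#' conc <- c(1.5, 6.25, 25, 100, 400)
#' maccSlope(1 + 2 * log10(conc), conc)  # exactly 2
#' @export
maccSlope <- function(freqs, concentrations, logBase = 10) {
  if (is.null(dim(freqs))) freqs <- matrix(freqs, nrow = 1)
  if (ncol(freqs) != length(concentrations))
    stop("frequencies and concentrations do not match")
  if (length(unique(concentrations)) < 3)
    stop("need >= 3 distinct concentrations for a slope")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (any(!is.finite(freqs))) stop("non-finite frequencies")
  x <- log(concentrations, base = logBase)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("zero variance in predictor")
  drop((freqs %*% xc) / sxx)
}

#' GC fraction of genome bins
#'
#' (G+C)/(A+C+G+T) over each bin, ambiguous bases excluded from the
#' denominator; bins with no unambiguous base give `NA`.
#'
#' @param bins a `GRanges` of bins.
#' @param genomeSeq a named [Biostrings::DNAStringSet] of chromosome
#'   sequences.
#' @return numeric vector of GC fractions in \[0, 1\].
#' @export
gcFraction <- function(bins, genomeSeq) {
  if (is.null(names(genomeSeq))) stop("genomeSeq must be named")
  out <- rep(NA_real_, length(bins))
  for (chr in unique(as.character(seqnames(bins)))) {
    idx <- which(as.character(seqnames(bins)) == chr)
    v <- Biostrings::Views(genomeSeq[[chr]], start = start(bins)[idx],
                           end = end(bins)[idx])
    f <- Biostrings::letterFrequency(v, c("G", "C", "A", "T"))
    den <- rowSums(f)
    gc <- (f[, "G"] + f[, "C"]) / den
    gc[den == 0] <- NA_real_
    out[idx] <- gc
  }
  if (anyNA(out)) warning(sum(is.na(out)), " bin(s) entirely ambiguous")
  out
}

#' Remove the GC dependence of raw MACC slopes
#'
#' Fits a smooth local-regression (loess) trend of slope versus GC fraction
#' and returns the residuals as the corrected MACC scores, which then carry
#' about zero linear correlation with GC. With fewer than 100 usable bins a
#' linear detrend is used instead (warning).
#'
#' @param slopes numeric vector of raw per-bin regression slopes.
#' @param gc matched numeric vector of per-bin GC fractions.
#' @param span loess span (default 0.3).
#' @return numeric vector of GC-corrected MACC scores (`NA` where slope or
#'   GC is `NA`).
#' @export
gcCorrect <- function(slopes, gc, span = 0.3) {
  if (length(slopes) != length(gc)) stop("slopes and gc must match")
  ok <- is.finite(slopes) & is.finite(gc)
  out <- rep(NA_real_, length(slopes))
  if (sum(ok) < 100) {
    warning("fewer than 100 bins; falling back to linear detrend")
    if (sum(ok) < 3) stop("too few bins for any GC trend")
    fit <- lm(slopes[ok] ~ gc[ok])
    out[ok] <- resid(fit)
    return(out)
  }
  fit <- loess(s ~ g, data = data.frame(s = slopes[ok], g = gc[ok]),
               span = span, degree = 1,
               control = loess.control(surface = "direct"))
  out[ok] <- slopes[ok] - predict(fit, data.frame(g = gc[ok]))
  out
}

#' Per-bin MACC track for one condition
#'
#' Computes the raw titration slope per bin -- pooling concentrations x
#' replicates as independent regression points by default, or averaging
#' replicates per concentration first -- then GC-corrects it when bin GC
#' fractions are supplied.
#'
#' @param normalized a [BinnedSignal-class] of RPM tracks for one condition
#'   with `mnaseUnits` (and optionally `replicate`) in `colData`.
#' @param gc optional per-bin GC fractions; if given, scores are
#'   GC-corrected.
#' @param span loess span for [gcCorrect()].
#' @param averageReplicates average replicate tracks per concentration
#'   before the regression (default `FALSE`: pooled points).
#' @param logBase concentration log base (default 10).
#' @return `data.frame` with per-bin `rawSlope`, `gc` and `macc` (equal to
#'   `rawSlope` when no GC is supplied).
#' @export
maccTrack <- function(normalized, gc = NULL, span = 0.3,
                      averageReplicates = FALSE, logBase = 10) {
  conc <- colData(normalized)$mnaseUnits
  if (is.null(conc)) stop("colData mnaseUnits required")
  v <- signalValues(normalized)
  if (averageReplicates) {
    levs <- sort(unique(conc))
    v <- vapply(levs, function(cc)
      rowMeans(v[, conc == cc, drop = FALSE]), numeric(nrow(v)))
    conc <- levs
  }
  raw <- maccSlope(v, conc, logBase = logBase)
  macc <- if (is.null(gc)) raw else gcCorrect(raw, gc, span = span)
  data.frame(bin = seq_along(raw) - 1L, rawSlope = raw,
             gc = if (is.null(gc)) NA_real_ else gc, macc = macc)
}

#' Differential MACC between two conditions
#'
#' Per-bin difference of replicate-mean MACC scores (condition A minus
#' condition B) with significance from an empirical null built from
#' within-condition replicate differences: for each bin the contrast
#' `(repDiff_A - repDiff_B) / 2` has, under the null of no condition
#' effect, the same variance as the observed between-condition difference
#' of replicate means. Two-sided empirical p-values are Benjamini-Hochberg
#' adjusted across bins.
#'
#' @param maccA,maccB numeric matrices, bins x replicates, of per-replicate
#'   MACC scores for each condition (vectors are treated as single
#'   replicates).
#' @param alpha BH false-discovery threshold (default 0.05).
#' @return `data.frame` with per-bin `diff`, `p`, `q`, `direction`
#'   (`"A"`/`"B"`: which condition is more accessible) and `significant`;
#'   the attribute `counts` gives the number of significantly more
#'   accessible bins per direction. With a single replicate per condition,
#'   differences are reported and significance is withheld.
#' @export
differentialMacc <- function(maccA, maccB, alpha = 0.05) {
  if (is.null(dim(maccA))) maccA <- matrix(maccA, ncol = 1)
  if (is.null(dim(maccB))) maccB <- matrix(maccB, ncol = 1)
  if (nrow(maccA) != nrow(maccB)) stop("bin grids do not match")
  d <- rowMeans(maccA) - rowMeans(maccB)
  out <- data.frame(bin = seq_along(d) - 1L, diff = d,
                    p = NA_real_, q = NA_real_,
                    direction = ifelse(d > 0, "A", "B"),
                    significant = FALSE)
  if (ncol(maccA) < 2 || ncol(maccB) < 2) {
    message("single replicate: significance withheld")
    attr(out, "counts") <- c(A = NA_integer_, B = NA_integer_)
    return(out)
  }
  contrast <- function(m) {
    # balanced half-vs-half replicate contrast; for 2 reps: rep1 - rep2
    h <- ncol(m) %/% 2
    rowMeans(m[, seq_len(h), drop = FALSE]) -
      rowMeans(m[, (h + 1):(2 * h), drop = FALSE])
  }
  # var(contrast/sqrt(2)) per condition sums to var of the observed
  # between-condition difference of replicate means (balanced designs)
  null <- (contrast(maccA) - contrast(maccB)) / 2
  null <- null[is.finite(null)]
  absd <- abs(d)
  # two-sided empirical tail probability with add-one correction
  out$p <- vapply(absd, function(a)
    (sum(abs(null) >= a) + 1) / (length(null) + 1), 0)
  out$p[!is.finite(d)] <- NA_real_
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$q) & out$q <= alpha & d != 0
  attr(out, "counts") <- c(
    A = sum(out$significant & out$direction == "A"),
    B = sum(out$significant & out$direction == "B"))
  out
}

#' Occupancy around differentially accessible bins
#'
#' Centre-aligned occupancy matrices around the significant bins of a
#' [differentialMacc()] result, one per occupancy track.
#'
#' @param diffResult output of [differentialMacc()].
#' @param occupancy a [BinnedSignal-class] of occupancy tracks.
#' @param flank half-window in bp (default 2000).
#' @param resolution column width in bp (default 50).
#' @param direction optionally restrict to bins more accessible in `"A"`
#'   or `"B"`.
#' @return named list of [SiteMatrix-class], one per occupancy track;
#'   empty list when no bins are significant.
#' @export
occupancyAtMaccSites <- function(diffResult, occupancy, flank = 2000,
                                 resolution = 50, direction = NULL) {
  sel <- diffResult$significant
  if (!is.null(direction)) sel <- sel & diffResult$direction == direction
  idx <- diffResult$bin[sel] + 1L
  if (!length(idx)) return(list())
  sites <- rowRanges(occupancy)[idx]
  out <- lapply(seq_len(ncol(occupancy)), function(k)
    centerAlignedMatrix(sites, occupancy, flank = flank,
                        resolution = resolution, track = k))
  names(out) <- colnames(occupancy)
  out
}
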