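## Serialisation: model parameters to/from flat YAML/JSON-style configs,
## binned tracks to bedGraph/TSV, site matrices to TSV with a one-line
## JSON-ish header.

.paramFields <- c(
  n_beads = "nBeads", sigma = "sigma", eps_lj = "epsLJ",
  k_spring = "kSpring", q0 = "q0", mu = "mu", eps_s = "epsS",
  eps_w = "epsW", r_cut = "rCut", max_disp = "maxDisp",
  include_chain_adjacent_in_contact_sum = "includeChainAdjacent")

#' Write model parameters to a flat YAML config
#'
#' @param params a [ModelParams-class].
#' @param path output file.
#' @param seed optional seed recorded alongside the parameters.
#' @return invisibly, `path`.
#' @export
writeModelParams <- function(params, path, seed = NULL) {
  x <- lapply(.paramFields, function(s) slot(params, s))
  if (!is.null(seed)) x$seed <- as.integer(seed)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read model parameters from a YAML config
#'
#' @param path YAML file written by [writeModelParams()] (flat keys named
#'   n_beads, sigma, eps_lj, k_spring, q0, mu, eps_s, eps_w, r_cut,
#'   max_disp, include_chain_adjacent_in_contact_sum).
#' @return a [ModelParams-class]; any recorded `seed` is attached as the
#'   `"seed"` attribute.
#' @export
readModelParams <- function(path) {
  x <- yaml::read_yaml(path)
  miss <- setdiff(names(.paramFields), names(x))
  if (length(miss)) stop("missing fields: ", paste(miss, collapse = ", "))
  p <- modelParams(
    nBeads = x$n_beads, sigma = x$sigma, epsLJ = x$eps_lj,
    kSpring = x$k_spring, q0 = x$q0, mu = x$mu, epsS = x$eps_s,
    epsW = x$eps_w, rCut = x$r_cut, maxDisp = x$max_disp,
    includeChainAdjacent = x$include_chain_adjacent_in_contact_sum)
  if (!is.null(x$seed)) attr(p, "seed") <- x$seed
  p
}

#' Export a binned track as bedGraph
#'
#' @param binned a [BinnedSignal-class].
#' @param path output file.
#' @param track column name or index (default first).
#' @return invisibly, `path`.
#' @export
exportBedGraph <- function(binned, path, track = 1L) {
  gr <- rowRanges(binned)
  mcols(gr) <- NULL
  mcols(gr)$score <- .trackVector(binned, track)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write a site matrix as TSV with a JSON metadata header
#'
#' First line is `# {json}` describing the geometry (kind, flank,
#' resolution, site count, excluded rows); the body is the numeric matrix.
#'
#' @param x a [SiteMatrix-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeSiteMatrix <- function(x, path) {
  hdr <- jsonlite::toJSON(list(
    kind = x@kind, flank = x@flank, resolution = x@resolution,
    n_sites = nrow(x@mat), excluded_rows = x@excluded),
    auto_unbox = TRUE, null = "null", na = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  write.table(x@mat, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Import a BED file of intervals
#'
#' @param path BED file (0-based half-open on disk; returned as 1-based
#'   `GRanges`).
#' @return a `GRanges`.
#' @export
readBed <- function(path) rtracklayer::import(path, format = "BED")
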