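setMethod("show", "ModelParams", function(object) {
  cat("ModelParams: N =", object@nBeads,
      "| mu =", object@mu,
      "| eps_s =", object@epsS, "| eps_w =", object@epsW,
      "| r_cut =", object@rCut, "sigma\n")
  cat("  k_spring =", object@kSpring, "q0 =", object@q0,
      "| LJ eps =", object@epsLJ, "sigma =", object@sigma,
      "| max disp =", object@maxDisp, "\n")
  cat("  chain-adjacent pairs in contact sum:",
      object@includeChainAdjacent, "\n")
})

setMethod("show", "PolymerState", function(object) {
  n <- nrow(object@positions)
  cat("PolymerState:", n, "beads;",
      sum(object@nucState), "nucleosome-bound;",
      length(object@sibIndices), "SIB\n")
})

setMethod("show", "McSchedule", function(object) {
  cat("McSchedule:", object@nEquilSteps, "equilibration +",
      object@nSampleSteps, "sampling steps, stride",
      object@sampleStride, ",", object@nReplicates,
      "replicate(s), seed", object@seed, "\n")
})

setMethod("show", "McSamples", function(object) {
  cat("McSamples:", length(object@rho), "replicate(s) x",
      nrow(object@rho[[1]]), "samples of N =", ncol(object@rho[[1]]),
      "beads\n")
  cat("  mean density:", round(meanDensity(object), 4),
      "| ensemble Rg:", round(ensembleRg(object), 3), "sigma\n")
})

setMethod("show", "SiteMatrix", function(object) {
  cat("SiteMatrix (", object@kind, "): ", nrow(object@mat), " sites x ",
      ncol(object@mat), " positions", sep = "")
  if (object@kind == "center")
    cat("; flank ", object@flank, " bp @ ", object@resolution, " bp",
        sep = "")
  if (length(object@excluded))
    cat("; ", length(object@excluded), " row(s) excluded", sep = "")
  cat("\n")
})

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig:", object@nChroms, "chrom x", object@genomeLength,
      "bp,", object@nSites, "sites,", length(object@concentrations),
      "MNase concentrations x", object@nReplicates, "replicates\n")
  cat("  conditions:", paste(names(object@occupancyShiftAtSites),
                             collapse = ", "),
      "| depth", object@depth, "frag/bin | seed", object@seed, "\n")
})
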