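#' @rdname accessors
setMethod("transcriptId", "DensityProfile", function(object) object@transcriptId)
#' @rdname accessors
setMethod("transcriptId", "RiboProfile", function(object) object@transcriptId)
#' @rdname accessors
setMethod("transcriptId", "SmoothedProfile", function(object) object@transcriptId)

#' @rdname accessors
setMethod("nCodons", "TasepParams", function(object) object@nCodons)
#' @rdname accessors
setMethod("nCodons", "DensityProfile", function(object) length(object@occupancy))
#' @rdname accessors
setMethod("nCodons", "RiboProfile", function(object) length(object@counts))
#' @rdname accessors
setMethod("nCodons", "SmoothedProfile", function(object) length(object@density))

#' @rdname accessors
setMethod("occupancy", "DensityProfile", function(object) object@occupancy)
#' @rdname accessors
setMethod("current", "DensityProfile", function(object) object@current)

#' @rdname accessors
setMethod("footprintCounts", "RiboProfile", function(object) object@counts)
#' @rdname accessors
setMethod("totalReads", "RiboProfile", function(object) sum(object@counts))

#' @rdname accessors
setMethod("smoothedDensity", "SmoothedProfile", function(object) object@density)
#' @rdname accessors
setMethod("normalizedDensity", "SmoothedProfile", function(object) object@normalized)

#' @rdname accessors
setMethod("regimeLabel", "Regime", function(object) object@label)
#' @rdname accessors
setMethod("elongationRates", "TasepParams", function(object) object@rates)

#' @rdname accessors
setMethod("cohortTruth", "SimulationCohort", function(object) object@truth)
#' @rdname accessors
setMethod("cohortPairs", "SimulationCohort", function(object) object@pairs)

setMethod("show", "TasepParams", function(object) {
  cat("TasepParams:", object@nCodons, "codons, ell =", object@ell, "\n")
  cat("  alpha =", object@alpha, " beta =", object@beta,
      " mean elongation rate =", signif(mean(object@rates), 3), "\n")
  cat("  burn-in", signif(object@burnInTime, 4), "/ sample",
      signif(object@sampleTime, 4), "time units, seed", object@seed, "\n")
})

setMethod("show", "DensityProfile", function(object) {
  cat("DensityProfile", object@transcriptId, ":", nCodons(object), "codons\n")
  cat("  current =", signif(object@current, 4),
      " mean occupancy =", signif(mean(object@occupancy), 4), "\n")
  if (object@lowConfidence)
    cat("  [low confidence: no events in sampling window]\n")
})

setMethod("show", "RiboProfile", function(object) {
  cat("RiboProfile", object@transcriptId, ":", nCodons(object), "codons,",
      totalReads(object), "reads\n")
})

setMethod("show", "SmoothedProfile", function(object) {
  cat("SmoothedProfile", object@transcriptId, ":", nCodons(object), "codons",
      "(normalized sums to 1)\n")
})

setMethod("show", "Regime", function(object) {
  cat("Regime:", object@label,
      if (object@ambiguous) "(ambiguous call, tie-break applied)" else "", "\n")
  print(signif(object@sensitivity, 4))
})

setMethod("show", "SimulationCohort", function(object) {
  tab <- table(object@truth$regime)
  cat("SimulationCohort:", length(object@pairs), "control/mutant pairs\n")
  for (nm in names(tab)) cat(" ", nm, ":", tab[[nm]], "\n")
})
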