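#' @import methods
NULL

#' Parameters of the inhomogeneous l-TASEP translation model
#'
#' Holds the biophysical rates of ribosome traffic on one transcript: the
#' initiation rate \code{alpha} (attempts per unit time to load a ribosome
#' onto codons \code{[0, ell)}), the termination rate \code{beta}, a vector of
#' per-codon elongation rates, and the ribosome exclusion footprint
#' \code{ell} in codons. \code{burnInTime} is simulated time discarded before
#' sampling and \code{sampleTime} the window over which occupancy and current
#' are averaged.
#'
#' @slot nCodons integer, number of codons (lattice sites).
#' @slot alpha,beta non-negative initiation rate and positive termination rate.
#' @slot rates numeric vector of strictly positive per-codon elongation rates.
#' @slot ell integer ribosome footprint in codons.
#' @slot seed integer RNG seed used by \code{\link{simulateTasep}}.
#' @slot burnInTime,sampleTime positive simulated-time windows.
#' @exportClass TasepParams
setClass("TasepParams",
  representation(
    nCodons = "integer",
    alpha = "numeric",
    beta = "numeric",
    rates = "numeric",
    ell = "integer",
    seed = "integer",
    burnInTime = "numeric",
    sampleTime = "numeric"
  )
)

setValidity("TasepParams", function(object) {
  msg <- character()
  n <- object@nCodons
  if (length(n) != 1L || is.na(n) || n < 1L)
    msg <- c(msg, "nCodons must be a positive integer")
  if (length(object@rates) != n)
    msg <- c(msg, "rates must have length nCodons")
  if (any(!is.finite(object@rates)) || any(object@rates <= 0))
    msg <- c(msg, "all elongation rates must be strictly positive")
  if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
  if (object@beta <= 0) msg <- c(msg, "beta must be > 0")
  if (object@ell < 1L || object@ell > n)
    msg <- c(msg, "ell must satisfy 1 <= ell <= nCodons")
  if (object@burnInTime <= 0 || object@sampleTime <= 0)
    msg <- c(msg, "burnInTime and sampleTime must be > 0")
  if (length(msg)) msg else TRUE
})

#' Stationary ribosome density from an l-TASEP simulation
#'
#' @slot transcriptId character identifier.
#' @slot occupancy numeric vector, time-averaged probability that a codon
#'   carries a ribosome A-site (the 5'-most codon of the footprint).
#' @slot current scalar steady-state flux in ribosomes per unit time.
#' @slot sampledEvents number of events observed in the sampling window.
#' @slot lowConfidence flag set when no event fell in the sampling window.
#' @exportClass DensityProfile
setClass("DensityProfile",
  representation(
    transcriptId = "character",
    occupancy = "numeric",
    current = "numeric",
    sampledEvents = "numeric",
    lowConfidence = "logical"
  ),
  prototype(sampledEvents = NA_real_, lowConfidence = FALSE)
)

setValidity("DensityProfile", function(object) {
  msg <- character()
  if (any(object@occupancy < -1e-12) || any(object@occupancy > 1 + 1e-9))
    msg <- c(msg, "occupancy must lie in [0, 1]")
  if (length(object@current) != 1L || object@current < 0)
    msg <- c(msg, "current must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Per-codon footprint counts for one transcript in one condition
#'
#' @slot transcriptId character identifier.
#' @slot counts non-negative integer vector, one entry per CDS codon.
#' @exportClass RiboProfile
setClass("RiboProfile",
  representation(transcriptId = "character", counts = "integer")
)

setValidity("RiboProfile", function(object) {
  if (any(is.na(object@counts)) || any(object@counts < 0L))
    "counts must be non-negative integers" else TRUE
})

#' LOWESS-smoothed, sum-normalized footprint density
#'
#' @slot transcriptId character identifier.
#' @slot density non-negative smoothed per-codon values.
#' @slot normalized \code{density} divided by its sum; sums to 1.
#' @exportClass SmoothedProfile
setClass("SmoothedProfile",
  representation(
    transcriptId = "character",
    density = "numeric",
    normalized = "numeric"
  )
)

setValidity("SmoothedProfile", function(object) {
  msg <- character()
  if (length(object@density) != length(object@normalized))
    msg <- c(msg, "density and normalized must have the same length")
  if (any(object@density < 0)) msg <- c(msg, "density must be non-negative")
  if (abs(sum(object@normalized) - 1) > 1e-9)
    msg <- c(msg, "normalized must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Regime call for a simulated transcript
#'
#' Produced by \code{\link{classifyRegime}}: the label names the process
#' whose small rate increase raises the steady-state ribosome flux the most.
#'
#' @slot label one of \code{initiation_limited}, \code{elongation_limited},
#'   \code{termination_limited}.
#' @slot sensitivity named numeric, relative change in current under each
#'   perturbation.
#' @slot ambiguous flag set when the top two sensitivities are closer than
#'   the tolerance; the label is then the tie-break order
#'   initiation > elongation > termination.
#' @exportClass Regime
setClass("Regime",
  representation(
    label = "character",
    sensitivity = "numeric",
    ambiguous = "logical"
  ),
  prototype(ambiguous = FALSE)
)

setValidity("Regime", function(object) {
  ok <- c("initiation_limited", "elongation_limited", "termination_limited")
  if (length(object@label) != 1L || !(object@label %in% ok))
    "label must be exactly one of the three regime labels" else TRUE
})

#' A paired control/mutant simulation cohort with ground-truth labels
#'
#' @slot pairs list; each element holds \code{transcriptId}, \code{regime},
#'   \code{control}/\code{mutant} \linkS4class{RiboProfile}s and the
#'   underlying \linkS4class{DensityProfile}s.
#' @slot truth data.frame with columns \code{transcript_id}, \code{regime}.
#' @slot config the validated cohort configuration list.
#' @exportClass SimulationCohort
setClass("SimulationCohort",
  representation(pairs = "list", truth = "data.frame", config = "list")
)
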