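.cohortClasses <- c("initiation_limited", "elongation_limited",
                    "termination_limited", "null")

#' Build and validate a simulation-cohort configuration
#'
#' A cohort is a set of simulated transcripts, each with a paired control and
#' mutant footprint profile and a ground-truth regime label for the mutant.
#' Per class the mutant differs from the control as follows:
#' \describe{
#'   \item{elongation_limited}{the mutant carries \code{nPauses} induced deep
#'     pause sites (control rates multiplied by \code{reductionFactor}).}
#'   \item{initiation_limited}{the mutant initiation rate is multiplied by
#'     \code{alphaFoldChange} (default one half), modelling loss of an
#'     initiation activator; elongation rates are untouched so the profile
#'     shape is preserved and only read output changes.}
#'   \item{termination_limited}{the mutant termination rate is multiplied by
#'     \code{reductionFactor}.}
#'   \item{null}{the mutant is a fresh multinomial sampling of the control
#'     density (no kinetic change at all).}
#' }
#'
#' @param classes character vector drawn from the four class labels.
#' @param nPerClass transcripts per class (recycled along \code{classes}).
#' @param lengthRange integer range of transcript lengths in codons.
#' @param alpha,beta,ell kinetic parameters shared by all transcripts.
#' @param gammaShape,gammaScale elongation-rate distribution.
#' @param nPauses,reductionFactor induced-pause parameters.
#' @param alphaFoldChange mutant/control initiation-rate ratio for the
#'   initiation-limited class.
#' @param depthPerCodon mean footprint reads per codon used for
#'   undersampling (total reads = depth x length).
#' @param masterSeed single integer from which every stream of randomness in
#'   the cohort is derived.
#' @return a validated configuration list of class \code{cohort_config}.
#' @export
cohortConfig <- function(classes = c("elongation_limited", "initiation_limited"),
                         nPerClass = 50,
                         lengthRange = c(150, 2000),
                         alpha = 0.5, beta = 1, ell = 10,
                         gammaShape = 2, gammaScale = 0.5,
                         nPauses = 1, reductionFactor = 0.02,
                         alphaFoldChange = 0.5,
                         depthPerCodon = 10,
                         masterSeed = 1L) {
  if (length(classes) == 0) stop("empty class specification")
  bad <- setdiff(classes, .cohortClasses)
  if (length(bad))
    stop("unknown cohort class(es): ", paste(bad, collapse = ", "))
  nPerClass <- rep_len(as.integer(nPerClass), length(classes))
  if (any(is.na(nPerClass)) || any(nPerClass < 0))
    stop("nPerClass must be non-negative")
  if (length(lengthRange) != 2 || lengthRange[1] > lengthRange[2] ||
      lengthRange[1] < 1)
    stop("lengthRange must be an increasing positive pair")
  if (depthPerCodon < 0) stop("depthPerCodon must be >= 0")
  cfg <- list(classes = classes, nPerClass = nPerClass,
              lengthRange = as.integer(lengthRange),
              alpha = alpha, beta = beta, ell = as.integer(ell),
              gammaShape = gammaShape, gammaScale = gammaScale,
              nPauses = as.integer(nPauses),
              reductionFactor = reductionFactor,
              alphaFoldChange = alphaFoldChange,
              depthPerCodon = depthPerCodon,
              masterSeed = as.integer(masterSeed))
  class(cfg) <- "cohort_config"
  cfg
}

#' Simulate a paired control/mutant cohort
#'
#' For every transcript of every configured class, samples a gamma
#' elongation-rate profile, simulates the control and the class-specific
#' mutant to stationarity, and undersamples both densities into footprint
#' counts. All randomness (lengths, rates, pause positions, trajectories,
#' undersampling) derives from \code{masterSeed} through per-transcript
#' substreams, so the cohort is fully reproducible.
#'
#' @param config a \code{\link{cohortConfig}} list.
#' @param keepDensities keep the stationary \linkS4class{DensityProfile}s on
#'   each pair (TRUE by default; set FALSE to save memory).
#' @return a \linkS4class{SimulationCohort}.
#' @export
runSimulationCohort <- function(config, keepDensities = TRUE) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohortConfig, config)
  total <- sum(config$nPerClass)
  if (total == 0)
    return(new("SimulationCohort", pairs = list(),
               truth = data.frame(transcript_id = character(),
                                  regime = character()),
               config = unclass(config)))
  # one block of substream seeds per transcript: length, rates, pauses,
  # control trajectory, mutant trajectory, control reads, mutant reads
  seeds <- withr::with_seed(config$masterSeed,
    matrix(sample.int(.Machine$integer.max - 1L, total * 7L), ncol = 7L))
  lens <- withr::with_seed(config$masterSeed + 1L,
    sample(seq(config$lengthRange[1], config$lengthRange[2]), total,
           replace = TRUE))
  pairs <- vector("list", total)
  idx <- 0L
  for (ci in seq_along(config$classes)) {
    cls <- config$classes[ci]
    for (i in seq_len(config$nPerClass[ci])) {
      idx <- idx + 1L
      s <- seeds[idx, ]
      len <- lens[idx]
      tid <- sprintf("%s_%04d", cls, i)
      rates <- sampleRateProfile(len, config$gammaShape, config$gammaScale,
                                 seed = s[2])
      ctrlPar <- TasepParams(len, alpha = config$alpha, beta = config$beta,
                             rates = rates, ell = config$ell, seed = s[4])
      ctrlDen <- simulateTasep(ctrlPar, transcriptId = tid)
      mutDen <- switch(cls,
        elongation_limited = {
          mrates <- inducePauses(rates, config$nPauses,
                                 config$reductionFactor, config$ell,
                                 seed = s[3])
          simulateTasep(TasepParams(len, alpha = config$alpha,
                                    beta = config$beta, rates = mrates,
                                    ell = config$ell, seed = s[5]),
                        transcriptId = tid)
        },
        initiation_limited = simulateTasep(
          TasepParams(len, alpha = config$alpha * config$alphaFoldChange,
                      beta = config$beta, rates = rates, ell = config$ell,
                      seed = s[5]),
          transcriptId = tid),
        termination_limited = simulateTasep(
          TasepParams(len, alpha = config$alpha,
                      beta = config$beta * config$reductionFactor,
                      rates = rates, ell = config$ell, seed = s[5]),
          transcriptId = tid),
        null = ctrlDen)
      nReads <- round(config$depthPerCodon * len)
      pairs[[idx]] <- list(
        transcriptId = tid, regime = cls, nCodons = len,
        control = undersampleFootprints(ctrlDen, nReads, seed = s[6]),
        mutant = undersampleFootprints(mutDen, nReads, seed = s[7]),
        controlDensity = if (keepDensities) ctrlDen else NULL,
        mutantDensity = if (keepDensities) mutDen else NULL)
    }
  }
  truth <- data.frame(
    transcript_id = vapply(pairs, `[[`, character(1), "transcriptId"),
    regime = vapply(pairs, `[[`, character(1), "regime"),
    stringsAsFactors = FALSE)
  new("SimulationCohort", pairs = pairs, truth = truth,
      config = unclass(config))
}

#' Score a simulated cohort with the stall-detection pipeline
#'
#' Runs the exact analysis applied to real data (joint filtering, LOWESS
#' smoothing, sum normalization, cumulative K-S statistic, grouping) on the
#' paired footprint profiles of a cohort and joins the ground-truth labels.
#'
#' @param cohort a \linkS4class{SimulationCohort}.
#' @param span LOWESS span passed to \code{\link{smoothProfile}}.
#' @param minCodons,minMeanDensity retention filters, see
#'   \code{\link{filterTranscripts}}.
#' @return data.frame: one row per retained pair with K-S columns plus the
#'   true \code{regime}.
#' @export
scoreCohort <- function(cohort, span = 0.1, minCodons = 100,
                        minMeanDensity = 0.5) {
  stopifnot(is(cohort, "SimulationCohort"))
  ctrl <- lapply(cohortPairs(cohort), `[[`, "control")
  mut <- lapply(cohortPairs(cohort), `[[`, "mutant")
  names(ctrl) <- names(mut) <- cohortTruth(cohort)$transcript_id
  tab <- ksTable(ctrl, mut, span = span, minCodons = minCodons,
                 minMeanDensity = minMeanDensity)
  merge(tab, cohortTruth(cohort), by = "transcript_id", sort = FALSE)
}
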