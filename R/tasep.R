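#' Sample a per-codon elongation-rate profile
#'
#' Draws independent gamma-distributed elongation rates for every codon of a
#' simulated transcript. The gamma family mimics the skewed, strictly
#' positive distribution of codon-level elongation rates seen in ribosome
#' profiling; the defaults (shape 2, scale 0.5) give mean 1 with a
#' coefficient of variation of about 0.7.
#'
#' @param nCodons number of codons.
#' @param shape,scale gamma parameters, both strictly positive.
#' @param seed optional integer; when supplied the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return numeric vector of \code{nCodons} strictly positive rates.
#' @export
sampleRateProfile <- function(nCodons, shape = 2, scale = 0.5, seed = NULL) {
  if (length(nCodons) != 1L || is.na(nCodons) || nCodons < 1)
    stop("nCodons must be a positive integer")
  if (!is.numeric(shape) || !is.numeric(scale) || shape <= 0 || scale <= 0)
    stop("shape and scale must be strictly positive")
  draw <- function() stats::rgamma(nCodons, shape = shape, scale = scale)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Induce deep pause sites in an elongation-rate profile
#'
#' Multiplies \code{nPauses} randomly chosen interior rates by
#' \code{reductionFactor}, emulating a mutation that creates strong ribosome
#' pause sites. Pause positions are drawn without replacement and exclude the
#' first and last \code{ell} codons so the induced stall is interior to the
#' transcript.
#'
#' @param rates numeric vector of elongation rates.
#' @param nPauses number of pause sites to create (may be 0).
#' @param reductionFactor multiplicative reduction in (0, 1).
#' @param ell ribosome footprint in codons; terminal exclusion zone.
#' @param seed optional integer seed for the pause positions.
#' @return a copy of \code{rates} with exactly \code{nPauses} entries reduced.
#' @export
inducePauses <- function(rates, nPauses = 1, reductionFactor = 0.02,
                         ell = 10, seed = NULL) {
  if (!is.numeric(rates) || length(rates) == 0)
    stop("rates must be a non-empty numeric vector")
  if (reductionFactor <= 0 || reductionFactor >= 1)
    stop("reductionFactor must lie strictly between 0 and 1")
  n <- length(rates)
  if (nPauses < 0 || nPauses > n) stop("nPauses must lie in [0, length(rates)]")
  if (nPauses == 0) return(rates)
  eligible <- seq_len(n)
  eligible <- eligible[eligible > ell & eligible <= n - ell]
  if (nPauses > length(eligible))
    stop("nPauses exceeds the number of eligible interior positions")
  pick <- function() {
    if (length(eligible) == 1L) eligible else sample(eligible, nPauses)
  }
  sites <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  out <- rates
  out[sites] <- out[sites] * reductionFactor
  out
}

#' Construct simulation parameters for the inhomogeneous l-TASEP
#'
#' When \code{burnInTime}/\code{sampleTime} are not given they default to
#' three times the deterministic traversal time \eqn{\sum_i 1/p_i} (a
#' conservative approach to stationarity) and an equally long sampling
#' window.
#'
#' @param nCodons transcript length in codons.
#' @param alpha,beta initiation and termination rates.
#' @param rates per-codon elongation rates; sampled with
#'   \code{\link{sampleRateProfile}} (gamma shape/scale below) when omitted.
#' @param ell ribosome exclusion footprint in codons (default 10, about a
#'   30-nt footprint).
#' @param seed integer RNG seed for the stochastic simulation.
#' @param burnInTime,sampleTime simulated-time windows; see Details.
#' @param gammaShape,gammaScale used only when \code{rates} is NULL.
#' @return a validated \linkS4class{TasepParams} object.
#' @export
TasepParams <- function(nCodons, alpha, beta = 1, rates = NULL, ell = 10,
                        seed = 1L, burnInTime = NULL, sampleTime = NULL,
                        gammaShape = 2, gammaScale = 0.5) {
  nCodons <- as.integer(nCodons)
  if (is.null(rates))
    rates <- sampleRateProfile(nCodons, gammaShape, gammaScale, seed = seed)
  traversal <- sum(1 / rates)
  if (is.null(burnInTime)) burnInTime <- 3 * traversal
  if (is.null(sampleTime)) sampleTime <- burnInTime
  new("TasepParams",
      nCodons = nCodons, alpha = as.numeric(alpha), beta = as.numeric(beta),
      rates = as.numeric(rates), ell = as.integer(ell),
      seed = as.integer(seed),
      burnInTime = as.numeric(burnInTime), sampleTime = as.numeric(sampleTime))
}

#' Simulate ribosome traffic and return the stationary density profile
#'
#' Runs the continuous-time Gillespie dynamics of the inhomogeneous l-TASEP:
#' a ribosome enters at rate \code{alpha} when the first \code{ell} codons
#' are vacant, hops from codon i to i+1 at rate \code{rates[i]} when codon
#' i+ell is vacant, and exits from the last codon at rate \code{beta}.
#' Occupancy (per-codon A-site dwell fraction) and current (exits per unit
#' time) are averaged over \code{sampleTime} after discarding
#' \code{burnInTime}.
#'
#' @param params a \linkS4class{TasepParams} object.
#' @param transcriptId identifier stored on the result.
#' @param recordHops when TRUE the per-bond hop current is attached as
#'   attribute \code{"hop_current"} (used for flux-conservation checks).
#' @return a \linkS4class{DensityProfile}.
#' @export
simulateTasep <- function(params, transcriptId = "sim", recordHops = FALSE) {
  stopifnot(is(params, "TasepParams"))
  validObject(params)
  res <- withr::with_seed(params@seed,
    tasep_gillespie(params@nCodons, params@alpha, params@beta, params@rates,
                    params@ell, params@burnInTime, params@sampleTime,
                    record_hops = recordHops))
  low <- res$sampled_events == 0
  if (low)
    warning("no events recorded in the sampling window; ",
            "density profile flagged low-confidence")
  out <- new("DensityProfile",
             transcriptId = transcriptId,
             occupancy = pmin(pmax(res$occupancy, 0), 1),
             current = res$current,
             sampledEvents = res$sampled_events,
             lowConfidence = low)
  if (recordHops) attr(out, "hop_current") <- res$hop_current
  out
}

#' Classify the rate-limiting step of a simulated transcript
#'
#' Operationalizes "limited by": the simulation is re-run with the
#' initiation rate, the slowest elongation rate, and the termination rate
#' each increased by \code{factor}, under the same seed family, and the
#' perturbation producing the largest relative increase in steady-state
#' current names the regime. Ties (sensitivities within \code{tol} of each
#' other) are flagged ambiguous and broken in the order
#' initiation > elongation > termination.
#'
#' @param params a \linkS4class{TasepParams}.
#' @param density optional pre-computed baseline \linkS4class{DensityProfile}
#'   for \code{params}; simulated if missing.
#' @param factor multiplicative perturbation (default 1.1).
#' @param tol minimum separation of relative sensitivities below which the
#'   call is flagged ambiguous.
#' @return a \linkS4class{Regime}.
#' @export
classifyRegime <- function(params, density = NULL, factor = 1.1, tol = 0.01) {
  stopifnot(is(params, "TasepParams"))
  if (is.null(density)) density <- simulateTasep(params)
  base <- current(density)
  tweak <- function(p) simulateTasep(p)@current
  pAlpha <- params; pAlpha@alpha <- params@alpha * factor
  pElong <- params
  slow <- which.min(params@rates)
  pElong@rates[slow] <- params@rates[slow] * factor
  pBeta <- params; pBeta@beta <- params@beta * factor
  ref <- max(base, .Machine$double.eps)
  sens <- c(
    initiation_limited = (tweak(pAlpha) - base) / ref,
    elongation_limited = (tweak(pElong) - base) / ref,
    termination_limited = (tweak(pBeta) - base) / ref)
  ord <- sort(sens, decreasing = TRUE)
  ambiguous <- (ord[1] - ord[2]) < tol
  # which.max returns the first maximum, i.e. the tie-break order above
  label <- names(sens)[which.max(sens)]
  new("Regime", label = label, sensitivity = sens, ambiguous = ambiguous)
}

#' Undersample a density profile into footprint counts
#'
#' Emulates the finite sequencing depth of a ribosome profiling experiment:
#' per-codon footprint counts are drawn from a multinomial with probabilities
#' proportional to the stationary occupancy.
#'
#' @param density a \linkS4class{DensityProfile}.
#' @param nReads total number of footprint reads to draw (>= 0).
#' @param seed optional integer seed.
#' @return a \linkS4class{RiboProfile} whose counts sum to \code{nReads}.
#' @export
undersampleFootprints <- function(density, nReads, seed = NULL) {
  stopifnot(is(density, "DensityProfile"))
  if (nReads < 0) stop("nReads must be >= 0")
  occ <- occupancy(density)
  if (nReads == 0)
    return(new("RiboProfile", transcriptId = transcriptId(density),
               counts = integer(length(occ))))
  tot <- sum(occ)
  if (tot <= 0) stop("cannot undersample an all-zero occupancy profile")
  draw <- function() as.integer(stats::rmultinom(1, nReads, occ / tot)[, 1])
  counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  new("RiboProfile", transcriptId = transcriptId(density), counts = counts)
}
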