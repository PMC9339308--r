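.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.profilesToCountsDf <- function(profiles) {
  if (length(profiles) == 0)
    return(data.frame(transcript_id = character(), codon_index = integer(),
                      count = integer()))
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(transcript_id = transcriptId(p),
               codon_index = seq_len(nCodons(p)) - 1L,
               count = footprintCounts(p),
               stringsAsFactors = FALSE)
  }))
}

#' Generate a synthetic cohort on disk
#'
#' Simulates a paired control/mutant cohort (\code{\link{runSimulationCohort}})
#' and writes plain-text outputs: \code{control_counts.tsv} and
#' \code{mutant_counts.tsv} (per-codon counts, all codons written including
#' zeros), \code{truth.tsv} (transcript id and ground-truth regime), and a
#' \code{manifest.json} recording every parameter and the master seed so the
#' run can be reproduced exactly.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param outdir output directory, created if needed.
#' @return (invisibly) the \linkS4class{SimulationCohort}.
#' @export
generateSyntheticCohort <- function(config, outdir) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohortConfig, config)
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", outdir)
  cohort <- runSimulationCohort(config, keepDensities = FALSE)
  ctrl <- lapply(cohortPairs(cohort), `[[`, "control")
  mut <- lapply(cohortPairs(cohort), `[[`, "mutant")
  .writeTsv(.profilesToCountsDf(ctrl), file.path(outdir, "control_counts.tsv"))
  .writeTsv(.profilesToCountsDf(mut), file.path(outdir, "mutant_counts.tsv"))
  .writeTsv(cohortTruth(cohort), file.path(outdir, "truth.tsv"))
  manifest <- list(tool = "ribostall",
                   version = as.character(utils::packageVersion("ribostall")),
                   stage = "synthetic_cohort",
                   config = unclass(config))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(cohort)
}

#' Run the stall-detection pipeline end to end
#'
#' Executes the configured stages in order and writes TSV results plus a
#' reproduction manifest. The configuration is a plain list:
#' \describe{
#'   \item{control / mutant}{per-codon count TSVs (consumed directly), or}
#'   \item{controlReads / mutantReads}{footprint TSVs, requiring
#'     \code{annotation} and either \code{offsets} (TSV with
#'     \code{read_length}, \code{offset_3prime}) or offset estimation from
#'     the control reads.}
#'   \item{annotation}{GTF or flat TSV (see \code{\link{readAnnotation}}).}
#'   \item{targets}{optional file of target ids, one per line, enabling the
#'     enrichment stage.}
#'   \item{span, minCodons, minMeanDensity}{analysis parameters.}
#'   \item{outdir}{where \code{ks.tsv}, \code{enrich.tsv},
#'     \code{manifest.json} are written.}
#' }
#'
#' @param config named list as described above.
#' @return list with \code{ks} (data.frame), \code{enrichment} (data.frame
#'   or NULL) and \code{filterReport}.
#' @export
runPipeline <- function(config) {
  if (is.null(config[["outdir"]])) stop("config$outdir is required")
  ok <- dir.exists(config[["outdir"]]) || dir.create(config[["outdir"]], recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", config[["outdir"]])
  span <- config[["span"]] %||% 0.1
  minCodons <- config[["minCodons"]] %||% 100
  minMeanDensity <- config[["minMeanDensity"]] %||% 0.5

  annotation <- NULL
  if (!is.null(config[["annotation"]])) annotation <- readAnnotation(config[["annotation"]])

  loadSide <- function(countsFile, readsFile, offsets) {
    if (!is.null(countsFile)) return(readCodonCounts(countsFile, annotation))
    if (is.null(readsFile))
      stop("missing stage input: need per-codon counts or footprint reads ",
           "for both conditions")
    if (is.null(annotation))
      stop("missing stage input: annotation is required to place footprints")
    reads <- readFootprints(readsFile)
    assignPsites(reads, offsets, annotation)$profiles
  }

  offsets <- NULL
  if (!is.null(config[["offsets"]])) {
    offsets <- utils::read.delim(config[["offsets"]], stringsAsFactors = FALSE)
  } else if (is.null(config[["control"]]) && !is.null(config[["controlReads"]])) {
    if (is.null(annotation))
      stop("missing stage input: annotation is required to estimate offsets")
    offsets <- estimateOffsets(readFootprints(config[["controlReads"]]), annotation)
  }

  control <- loadSide(config[["control"]], config[["controlReads"]], offsets)
  mutant <- loadSide(config[["mutant"]], config[["mutantReads"]], offsets)

  ks <- ksTable(control, mutant, span = span, minCodons = minCodons,
                minMeanDensity = minMeanDensity)
  .writeTsv(ks, file.path(config[["outdir"]], "ks.tsv"))

  enrichment <- NULL
  if (!is.null(config[["targets"]])) {
    ids <- readLines(config[["targets"]], warn = FALSE)
    ids <- ids[nzchar(trimws(ids))]
    enrichment <- enrichTargets(ks, trimws(ids))
    .writeTsv(enrichment, file.path(config[["outdir"]], "enrich.tsv"))
  }

  manifest <- list(tool = "ribostall",
                   version = as.character(utils::packageVersion("ribostall")),
                   stage = "ks_pipeline",
                   parameters = list(span = span, minCodons = minCodons,
                                     minMeanDensity = minMeanDensity),
                   inputs = config[intersect(names(config),
                     c("control", "mutant", "controlReads", "mutantReads",
                       "annotation", "offsets", "targets"))],
                   n_scored = nrow(ks),
                   n_rejected = nrow(attr(ks, "filter_report")))
  jsonlite::write_json(manifest, file.path(config[["outdir"]], "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(ks = ks, enrichment = enrichment,
       filterReport = attr(ks, "filter_report"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
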