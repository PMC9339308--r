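#' Load the ASD-relevant gene dosage table
#'
#' Reads a TSV of translationally altered autism-relevant genes with their
#' translation-efficiency fold-change (knockout/wild-type), adjusted
#' p-value, protein length, CLIP-target flag and ClinGen
#' haploinsufficiency/triplosensitivity scores (0-3, \code{n/a} for
#' missing). With no \code{path} the table packaged under
#' \code{extdata/table1_dosage.tsv} is used.
#'
#' @param path optional TSV path; columns \code{gene},
#'   \code{te_fold_change}, \code{p_adj}, \code{protein_len_aa},
#'   \code{clip_target}, \code{haplo_score}, \code{triplo_score}.
#' @return data.frame of validated records.
#' @export
loadDosageTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_dosage.tsv", package = "ribostall")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("n/a", "NA", ""))
  if (nrow(df) == 0) stop("dosage table is empty")
  need <- c("gene", "te_fold_change", "p_adj", "protein_len_aa",
            "clip_target", "haplo_score", "triplo_score")
  if (!all(need %in% names(df)))
    stop("dosage table must have columns: ", paste(need, collapse = ", "))
  df$clip_target <- as.logical(df$clip_target)
  problems <- character(0)
  chk <- function(cond, what) {
    bad <- which(cond)
    if (length(bad))
      problems <<- c(problems, paste0(what, " in row(s) ",
                                      paste(bad, collapse = ",")))
  }
  chk(is.na(df$te_fold_change) | df$te_fold_change <= 0,
      "non-positive fold-change")
  chk(!is.na(df$haplo_score) & !(df$haplo_score %in% 0:3),
      "haploinsufficiency score outside 0-3")
  chk(!is.na(df$triplo_score) & !(df$triplo_score %in% 0:3),
      "triplosensitivity score outside 0-3")
  chk(is.na(df$clip_target), "unparseable CLIP flag")
  if (length(problems))
    stop("malformed dosage record(s): ", paste(problems, collapse = "; "))
  df
}

#' Summarize dosage sensitivity of translationally altered genes
#'
#' Tallies the table loaded by \code{\link{loadDosageTable}}:
#' translationally down- vs upregulated genes (fold-change below/above 1;
#' genes at exactly 1 are counted as neither and flagged), CLIP targets
#' among the downregulated, downregulated genes with both ClinGen scores
#' available, and -- over those scored genes -- how many have emerging or
#' sufficient evidence (score >= 2) of haploinsufficiency or
#' triplosensitivity.
#'
#' @param records data.frame from \code{\link{loadDosageTable}}.
#' @return named list of counts: \code{n_total}, \code{n_downregulated},
#'   \code{n_upregulated}, \code{n_unchanged_flagged},
#'   \code{n_clip_among_down}, \code{n_scored}, \code{n_haplo_ge2},
#'   \code{n_triplo_ge2}, \code{min_fc}, \code{max_fc_among_down}.
#' @export
summarizeDosage <- function(records) {
  if (nrow(records) == 0) stop("need at least one dosage record")
  fc <- records$te_fold_change
  down <- fc < 1
  up <- fc > 1
  flat <- fc == 1
  if (any(flat))
    warning(sum(flat), " record(s) with fold-change exactly 1 ",
            "counted as neither down- nor upregulated")
  scored <- down & !is.na(records$haplo_score) & !is.na(records$triplo_score)
  list(
    n_total = nrow(records),
    n_downregulated = sum(down),
    n_upregulated = sum(up),
    n_unchanged_flagged = sum(flat),
    n_clip_among_down = sum(records$clip_target & down),
    n_scored = sum(scored),
    n_haplo_ge2 = sum(scored & records$haplo_score >= 2),
    n_triplo_ge2 = sum(scored & records$triplo_score >= 2),
    min_fc = min(fc),
    max_fc_among_down = if (any(down)) max(fc[down]) else NA_real_)
}
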