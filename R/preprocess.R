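## Table-cleaning stages, in their fixed order:
##   mergePlatformDuplicates -> filterPresence -> imputeMissing -> normalizeMedian
## logParetoScale is applied only for model-based consumers (the two-way
## ANOVA); rank tests and fold changes run on the normalized intensities.

.emptyReport <- function(study) {
  list(stages = character(), n_features_in = nrow(study),
       n_merged_duplicates = 0L, n_removed_by_filter = 0L,
       n_imputed_cells = 0L, parameters = list())
}

.getReport <- function(study) {
  rep <- S4Vectors::metadata(study)$preprocess
  if (is.null(rep)) .emptyReport(study) else rep
}

.setReport <- function(study, rep) {
  S4Vectors::metadata(study)$preprocess <- rep
  study
}

#' Preprocessing report of a study
#'
#' Bookkeeping of the cleaning stages applied so far; feature counts are
#' conserved exactly: \code{n_features_in - n_merged_duplicates -
#' n_removed_by_filter == nrow(study)}.
#'
#' @param study A \linkS4class{MetaboStudy}.
#' @return A named list.
#' @export
preprocessReport <- function(study) .getReport(study)

#' Resolve cross-platform duplicate features
#'
#' Features sharing a canonical metabolite name (case-insensitive, synonym
#' aware) measured on several platforms are collapsed to the single feature
#' with the lowest relative standard deviation in the QC pool samples; ties
#' break by platform order (hilic_pos, hilic_neg, lipid_pos, lipid_neg) then
#' metabolite id.  A duplicate group with no QC RSD at all keeps its first
#' feature by the same tie-break order, with a warning.
#'
#' @param study A \linkS4class{MetaboStudy}.
#' @return The study with duplicate features dropped.
#' @export
mergePlatformDuplicates <- function(study) {
  ann <- annotations(study)
  key <- canonicalName(ann$name)
  keep <- rep(TRUE, nrow(ann))
  platformRank <- match(ann$platform, .PLATFORMS)
  for (grpIdx in split(seq_len(nrow(ann)), key)) {
    if (length(grpIdx) < 2L) next
    rsd <- ann$qc_rsd[grpIdx]
    ord <- order(rsd, platformRank[grpIdx], ann$metabolite_id[grpIdx],
                 na.last = TRUE)
    if (all(is.na(rsd))) {
      warning(sprintf("duplicate group '%s': no QC RSD available, keeping first by tie-break order",
                      key[grpIdx[1]]), call. = FALSE)
      ord <- order(platformRank[grpIdx], ann$metabolite_id[grpIdx])
    }
    keep[grpIdx[-ord[1]]] <- FALSE
  }
  rep <- .getReport(study)
  rep$stages <- c(rep$stages, "merge")
  rep$n_merged_duplicates <- rep$n_merged_duplicates + sum(!keep)
  .setReport(study[keep, ], rep)
}

#' Presence filter
#'
#' A metabolite is kept iff, in at least one tissue, it is observed
#' (non-missing) in at least \code{ceiling(fraction * n_tissue)} of that
#' tissue's biological samples.  QC pool samples are dropped from the study at
#' this stage; they only ever inform the duplicate merge.
#'
#' @param study A \linkS4class{MetaboStudy}.
#' @param fraction Required presence fraction; default 28/32.
#' @return The filtered study (biological samples only).
#' @export
filterPresence <- function(study, fraction = 28 / 32) {
  if (fraction <= 0 || fraction > 1)
    tsValidationError("presence fraction must be in (0, 1], got %g", fraction)
  cd <- sampleMeta(study)
  study <- study[, !cd$is_qc]
  cd <- sampleMeta(study)
  x <- intensityMatrix(study)
  keep <- rep(FALSE, nrow(x))
  for (tt in unique(cd$tissue)) {
    cols <- cd$tissue == tt
    need <- ceiling(fraction * sum(cols))
    keep <- keep | rowSums(!is.na(x[, cols, drop = FALSE])) >= need
  }
  rep <- .getReport(study)
  rep$stages <- c(rep$stages, "filter")
  rep$n_removed_by_filter <- rep$n_removed_by_filter + sum(!keep)
  rep$parameters$presence_fraction <- fraction
  .setReport(study[keep, ], rep)
}

#' Minimum-based missing-value imputation
#'
#' Every missing cell of a metabolite is replaced by the minimum observed
#' intensity of that metabolite across all samples divided by
#' \code{divisor}; a metabolite with no observed value anywhere is set to the
#' \code{fallback} constant.  Idempotent: a second application changes
#' nothing.
#'
#' @param study A \linkS4class{MetaboStudy}.
#' @param divisor Positive divisor of the per-metabolite minimum (default 10).
#' @param fallback Constant for entirely missing metabolites (default 100).
#' @return The imputed study.
#' @export
imputeMissing <- function(study, divisor = 10, fallback = 100) {
  if (divisor <= 0) tsValidationError("impute divisor must be > 0")
  x <- intensityMatrix(study)
  nImp <- sum(is.na(x))
  S4Vectors::metadata(study)$observed <- !is.na(x)
  for (i in seq_len(nrow(x))) {
    miss <- is.na(x[i, ])
    if (!any(miss)) next
    x[i, miss] <- if (all(miss)) fallback else min(x[i, !miss]) / divisor
  }
  SummarizedExperiment::assay(study, "intensity") <- x
  rep <- .getReport(study)
  rep$stages <- c(rep$stages, "impute")
  rep$n_imputed_cells <- rep$n_imputed_cells + nImp
  rep$parameters$impute_divisor <- divisor
  rep$parameters$impute_fallback <- fallback
  .setReport(study, rep)
}

#' Detection indicator per feature within a tissue
#'
#' A feature counts as detected in a tissue when it was observed (non-missing
#' before imputation) in at least one of the tissue's biological samples.
#' Requires the study to have passed \code{\link{imputeMissing}}, which
#' records the observation mask; otherwise every present feature counts as
#' detected.
#'
#' @param study A \linkS4class{MetaboStudy}.
#' @param tissue Tissue label.
#' @return Named logical vector over the features of the study.
#' @export
detectedInTissue <- function(study, tissue) {
  obs <- S4Vectors::metadata(study)$observed
  cd <- sampleMeta(study)
  ids <- rownames(study)
  if (is.null(obs))
    return(stats::setNames(rep(TRUE, length(ids)), ids))
  cols <- intersect(cd$sample_id[cd$tissue == tissue & !cd$is_qc],
                    colnames(obs))
  rows <- intersect(ids, rownames(obs))
  out <- stats::setNames(rep(FALSE, length(ids)), ids)
  out[rows] <- rowSums(obs[rows, cols, drop = FALSE]) > 0
  out
}

#' Median normalization
#'
#' Each sample is rescaled so its median intensity over all metabolites
#' equals the grand median (the median of the per-sample medians); a
#' multiplicative, rank-preserving map per sample.
#'
#' @param study An imputed \linkS4class{MetaboStudy} (no missing cells).
#' @return The normalized study.
#' @export
normalizeMedian <- function(study) {
  x <- intensityMatrix(study)
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  if (any(!is.finite(med) | med == 0)) {
    bad <- colnames(x)[!is.finite(med) | med == 0][1]
    tsDomainError("sample '%s' has zero/undefined median intensity", bad)
  }
  grand <- stats::median(med)
  x <- sweep(x, 2, grand / med, `*`)
  SummarizedExperiment::assay(study, "intensity") <- x
  rep <- .getReport(study)
  rep$stages <- c(rep$stages, "normalize")
  .setReport(study, rep)
}

#' Log transform and Pareto scaling
#'
#' Per metabolite: log2, centre on the mean of the logs, divide by the square
#' root of their sample standard deviation (n - 1 denominator).  Zero-variance
#' metabolites map to all-zero.  The scaled matrix feeds the two-way ANOVA
#' only; it is returned as a matrix, never written back over the intensity
#' assay.
#'
#' @param study A strictly positive (post-imputation) \linkS4class{MetaboStudy},
#'   or a bare numeric matrix.
#' @return Numeric matrix of scaled values (metabolites x samples).
#' @export
logParetoScale <- function(study) {
  x <- if (methods::is(study, "SummarizedExperiment")) intensityMatrix(study) else as.matrix(study)
  if (any(is.na(x)) || any(x <= 0))
    tsDomainError("log/Pareto scaling requires strictly positive, complete intensities (impute first)")
  lx <- log2(x)
  mu <- rowMeans(lx)
  sdv <- apply(lx, 1, stats::sd)
  out <- (lx - mu) / sqrt(ifelse(sdv > 0, sdv, Inf))
  out[sdv == 0, ] <- 0
  out
}

#' Run the full cleaning chain
#'
#' \code{merge -> filter -> impute -> normalize}, with parameters from a run
#' configuration (see \code{\link{defaultRunConfig}}).
#'
#' @param study A raw \linkS4class{MetaboStudy}.
#' @param config A configuration list.
#' @return The cleaned study; inspect \code{\link{preprocessReport}} for the
#'   stage bookkeeping.
#' @export
preprocessStudy <- function(study, config = defaultRunConfig()) {
  study <- mergePlatformDuplicates(study)
  study <- filterPresence(study, fraction = config$presence_fraction)
  study <- imputeMissing(study, divisor = config$impute_divisor,
                         fallback = config$impute_fallback)
  normalizeMedian(study)
}
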