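#' MetaboStudy: container for an organ-resolved metabolomics study
#'
#' A \code{MetaboStudy} extends
#' \linkS4class{SummarizedExperiment} with metabolite features as rows and
#' samples as columns.  The single assay, \code{"intensity"}, holds nonnegative
#' peak-height intensities with \code{NA} for missing (undetected) cells.
#' \code{colData} carries the sample metadata (\code{sample_id},
#' \code{animal_id}, \code{tissue}, \code{age_group}, \code{sex},
#' \code{is_qc}), \code{rowData} the annotation catalog (\code{metabolite_id},
#' \code{name}, \code{superclass}, \code{platform}, \code{qc_rsd}).
#'
#' Validity enforces the study invariants: unique sample and metabolite ids,
#' nonnegative intensities, \code{age_group} in \{young, old\} and \code{sex}
#' in \{female, male\} for all non-QC samples, and tissues drawn from the
#' study vocabulary stored in \code{metadata(x)$tissues}.
#'
#' @aliases MetaboStudy
#' @export
setClass("MetaboStudy", contains = "SummarizedExperiment")

.AGE_LEVELS <- c("young", "old")
.SEX_LEVELS <- c("female", "male")
.PLATFORMS  <- c("hilic_pos", "hilic_neg", "lipid_pos", "lipid_neg")

#' Tissue vocabulary of the aging-atlas study design
#'
#' The closed tissue vocabulary accepted by the readers; QC pool pseudo-samples
#' use the reserved label \code{"qc_pool"}.
#' @return Character vector of tissue labels.
#' @export
defaultTissues <- function() {
  c("BAT", "VAT", "SAT", "quadriceps", "heart", "jejunum", "feces",
    "hippocampus", "lungs", "spleen", "thymus", "pancreas", "gallbladder",
    "stomach", "duodenum", "ileum", "colon", "cecum", "kidney", "bladder",
    "liver", "plasma", "urine", "csf", "testes", "uterus", "qc_pool")
}

setValidity("MetaboStudy", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  cd <- SummarizedExperiment::colData(object)
  rd <- SummarizedExperiment::rowData(object)
  needC <- c("sample_id", "animal_id", "tissue", "age_group", "sex", "is_qc")
  needR <- c("metabolite_id", "name", "superclass", "platform", "qc_rsd")
  if (!all(needC %in% colnames(cd)))
    msg <- c(msg, paste0("colData misses: ",
                         paste(setdiff(needC, colnames(cd)), collapse = ", ")))
  if (!all(needR %in% colnames(rd)))
    msg <- c(msg, paste0("rowData misses: ",
                         paste(setdiff(needR, colnames(rd)), collapse = ", ")))
  if (length(msg)) return(msg)
  if (anyDuplicated(cd$sample_id))
    msg <- c(msg, "duplicate sample_id in colData")
  if (anyDuplicated(rd$metabolite_id))
    msg <- c(msg, "duplicate metabolite_id in rowData")
  bio <- !cd$is_qc
  if (any(!cd$age_group[bio] %in% .AGE_LEVELS))
    msg <- c(msg, "age_group must be 'young' or 'old' for non-QC samples")
  if (any(!cd$sex[bio] %in% .SEX_LEVELS))
    msg <- c(msg, "sex must be 'female' or 'male' for non-QC samples")
  vocab <- S4Vectors::metadata(object)$tissues
  if (is.null(vocab)) vocab <- defaultTissues()
  if (any(!cd$tissue %in% vocab))
    msg <- c(msg, paste0("unknown tissue(s): ",
                         paste(unique(setdiff(cd$tissue, vocab)), collapse = ", ")))
  x <- SummarizedExperiment::assay(object, "intensity")
  if (any(x < 0, na.rm = TRUE))
    msg <- c(msg, "negative intensity cells")
  if (length(msg)) msg else TRUE
})

#' Construct a MetaboStudy
#'
#' @param intensity Numeric matrix, metabolites in rows, samples in columns;
#'   \code{NA} marks missing cells.  Dimnames are taken from the metadata if
#'   absent.
#' @param sampleMeta \code{data.frame} with columns \code{sample_id},
#'   \code{animal_id}, \code{tissue}, \code{age_group}, \code{sex} and
#'   optionally \code{is_qc} (default \code{FALSE}).
#' @param annotations \code{data.frame} with columns \code{metabolite_id},
#'   \code{name}, \code{superclass}, \code{platform}, \code{qc_rsd}.
#' @param tissues Closed tissue vocabulary; defaults to
#'   \code{\link{defaultTissues}}.
#' @return A \linkS4class{MetaboStudy}.
#' @examples
#' m <- matrix(1:6, nrow = 2,
#'             dimnames = list(c("M1", "M2"), c("s1", "s2", "s3")))
#' sm <- data.frame(sample_id = c("s1", "s2", "s3"), animal_id = "a1",
#'                  tissue = "BAT", age_group = c("young", "old", "old"),
#'                  sex = "female")
#' an <- data.frame(metabolite_id = c("M1", "M2"), name = c("glucose", "lactate"),
#'                  superclass = "Carbohydrates", platform = "hilic_pos",
#'                  qc_rsd = 0.05)
#' MetaboStudy(m, sm, an)
#' @export
MetaboStudy <- function(intensity, sampleMeta, annotations,
                        tissues = defaultTissues()) {
  sampleMeta <- as.data.frame(sampleMeta)
  annotations <- as.data.frame(annotations)
  if (is.null(sampleMeta$is_qc)) sampleMeta$is_qc <- FALSE
  sampleMeta$is_qc <- as.logical(sampleMeta$is_qc)
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (is.null(rownames(intensity))) rownames(intensity) <- annotations$metabolite_id
  if (is.null(colnames(intensity))) colnames(intensity) <- sampleMeta$sample_id
  if (!identical(dim(intensity), c(nrow(annotations), nrow(sampleMeta))))
    tsIntegrityError("intensity is %d x %d but study has %d metabolites and %d samples",
                     nrow(intensity), ncol(intensity),
                     nrow(annotations), nrow(sampleMeta))
  if (!setequal(rownames(intensity), annotations$metabolite_id))
    tsIntegrityError("intensity row keys do not match annotation metabolite_ids")
  if (!setequal(colnames(intensity), sampleMeta$sample_id))
    tsIntegrityError("intensity column keys do not match metadata sample_ids")
  intensity <- intensity[match(annotations$metabolite_id, rownames(intensity)),
                         match(sampleMeta$sample_id, colnames(intensity)),
                         drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = S4Vectors::DataFrame(annotations, row.names = annotations$metabolite_id),
    colData = S4Vectors::DataFrame(sampleMeta, row.names = sampleMeta$sample_id),
    metadata = list(tissues = tissues))
  methods::validObject(obj <- methods::new("MetaboStudy", se))
  obj
}

#' @describeIn MetaboStudy Sample metadata as a base \code{data.frame}.
#' @param x A \code{MetaboStudy}.
#' @export
sampleMeta <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

#' @describeIn MetaboStudy Annotation catalog as a base \code{data.frame}.
#' @export
annotations <- function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
}

#' @describeIn MetaboStudy The intensity assay matrix (metabolites x samples).
#' @export
intensityMatrix <- function(x) {
  SummarizedExperiment::assay(x, "intensity")
}

#' @describeIn MetaboStudy Subset to the biological (non-QC) samples of one
#'   tissue.
#' @param tissue Tissue label.
#' @export
tissueSubset <- function(x, tissue) {
  cd <- SummarizedExperiment::colData(x)
  if (!tissue %in% cd$tissue)
    tsDomainError("tissue '%s' has no samples in this study", tissue)
  x[, cd$tissue == tissue & !cd$is_qc]
}

setMethod("show", "MetaboStudy", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("MetaboStudy:", nrow(object), "metabolites x", ncol(object), "samples\n")
  cat("  tissues:", paste(unique(cd$tissue[!cd$is_qc]), collapse = ", "), "\n")
  cat("  QC pool samples:", sum(cd$is_qc), "\n")
  pp <- S4Vectors::metadata(object)$preprocess
  if (!is.null(pp))
    cat("  preprocessed:", paste(pp$stages, collapse = " -> "), "\n")
  invisible(NULL)
})
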