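## Study table readers/writers and run configuration.
##
## On-disk layout: three delimited tables (CSV or TSV, sniffed by extension).
##   metadata:    sample_id, animal_id, tissue, age_group, sex, is_qc
##   annotations: metabolite_id, name, superclass, platform, qc_rsd
##   intensities: sample_id, <one column per metabolite_id>
## Missing intensity cells are empty fields on disk; readers also accept
## "NA"/"NaN" case-insensitively.  Zero is a legal (meaningful) peak height.

.delim <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

.readTable <- function(path, what) {
  if (!file.exists(path)) tsSchemaError("%s file not found: %s", what, path)
  utils::read.table(path, sep = .delim(path), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("", "NA", "na", "NaN", "nan"),
                    comment.char = "", quote = "\"")
}

.requireCols <- function(df, cols, what) {
  miss <- setdiff(cols, colnames(df))
  if (length(miss))
    tsSchemaError("%s table misses column(s): %s", what,
                  paste(miss, collapse = ", "))
}

#' Read a study from its three tables
#'
#' Reads sample metadata, metabolite annotations and the samples x metabolites
#' intensity table, validates referential integrity, and assembles a
#' \linkS4class{MetaboStudy}.
#'
#' @param metadataPath,annotationPath,intensityPath Paths to CSV/TSV files.
#' @param tissues Closed tissue vocabulary (see \code{\link{defaultTissues}}).
#' @return A \linkS4class{MetaboStudy}.
#' @export
readStudy <- function(metadataPath, annotationPath, intensityPath,
                      tissues = defaultTissues()) {
  meta <- .readTable(metadataPath, "metadata")
  .requireCols(meta, c("sample_id", "animal_id", "tissue", "age_group", "sex"),
               "metadata")
  if (is.null(meta$is_qc)) meta$is_qc <- FALSE
  meta$is_qc <- as.logical(meta$is_qc)
  if (anyDuplicated(meta$sample_id))
    tsIntegrityError("duplicate sample_id in metadata: %s",
                     paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
                           collapse = ", "))
  ann <- .readTable(annotationPath, "annotation")
  .requireCols(ann, c("metabolite_id", "name", "superclass", "platform"),
               "annotation")
  if (is.null(ann$qc_rsd)) ann$qc_rsd <- NA_real_
  if (anyDuplicated(ann$metabolite_id))
    tsIntegrityError("duplicate metabolite_id in annotations")
  raw <- .readTable(intensityPath, "intensity")
  .requireCols(raw, "sample_id", "intensity")
  if (any(!raw$sample_id %in% meta$sample_id))
    tsIntegrityError("intensity table references sample(s) absent from metadata: %s",
                     paste(setdiff(raw$sample_id, meta$sample_id), collapse = ", "))
  if (any(!meta$sample_id %in% raw$sample_id))
    tsIntegrityError("metadata sample(s) absent from intensity table: %s",
                     paste(setdiff(meta$sample_id, raw$sample_id), collapse = ", "))
  mets <- setdiff(colnames(raw), "sample_id")
  if (any(!mets %in% ann$metabolite_id))
    tsIntegrityError("intensity columns not in annotations: %s",
                     paste(setdiff(mets, ann$metabolite_id), collapse = ", "))
  ann <- ann[ann$metabolite_id %in% mets, , drop = FALSE]
  vals <- raw[, mets, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        tsParseError("non-numeric intensity at row %d (sample '%s'), column '%s': '%s'",
                     bad[1], raw$sample_id[bad[1]], mets[j], v[bad[1]])
      v <- num
    }
    vals[[j]] <- v
  }
  m <- t(as.matrix(vals))
  dimnames(m) <- list(mets, raw$sample_id)
  MetaboStudy(m, meta, ann, tissues = tissues)
}

#' Write a study to a directory
#'
#' Emits \code{metadata.csv}, \code{annotations.csv} and
#' \code{intensities.csv} with stable ordering (metadata-sorted sample ids,
#' lexicographic metabolite ids) and missing cells as empty fields, so that
#' \code{\link{readStudy}} round-trips the object exactly.
#'
#' @param study A \linkS4class{MetaboStudy}.
#' @param outDir Output directory, created if absent.
#' @return Named character vector of the three file paths, invisibly.
#' @export
writeStudy <- function(study, outDir) {
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(outDir, mode = 2) != 0)
    tsError("thermoshift_io_error", "cannot write to directory: %s", outDir)
  meta <- sampleMeta(study)
  meta <- meta[order(meta$sample_id), , drop = FALSE]
  ann <- annotations(study)
  ann <- ann[order(ann$metabolite_id), , drop = FALSE]
  m <- intensityMatrix(study)
  m <- m[ann$metabolite_id, meta$sample_id, drop = FALSE]
  paths <- c(metadata    = file.path(outDir, "metadata.csv"),
             annotations = file.path(outDir, "annotations.csv"),
             intensities = file.path(outDir, "intensities.csv"))
  utils::write.csv(meta, paths["metadata"], row.names = FALSE, na = "")
  utils::write.csv(ann, paths["annotations"], row.names = FALSE, na = "")
  wide <- data.frame(sample_id = colnames(m), t(m), check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.csv(wide, paths["intensities"], row.names = FALSE, na = "")
  invisible(paths)
}

#' Default run configuration
#'
#' Central tunables of the pipeline, each at its documented default:
#' presence-filter fraction 28/32, imputation divisor 10 with fallback
#' constant 100, raw and FDR significance thresholds 0.05, cardiolipin
#' maturity thresholds (>= 72 acyl carbons and >= 8 double bonds), chain
#' buckets and TG size classes, and the shipped metabolite panels.
#'
#' @return A named list (class \code{thermoshift_config}).
#' @export
defaultRunConfig <- function() {
  structure(list(
    presence_fraction = 28 / 32,
    impute_divisor    = 10,
    impute_fallback   = 100,
    alpha_raw         = 0.05,
    alpha_fdr         = 0.05,
    mature_min_carbons      = 72,
    mature_min_double_bonds = 8,
    ## lower edges of MC / LC / VLC (closed-open intervals)
    chain_bucket_breaks = c(MC = 6, LC = 13, VLC = 22),
    ## lower edges of medium / long TG size classes
    tg_class_breaks     = c(medium = 48, long = 54),
    fc_center           = "mean",
    panels              = defaultPanels(),
    seed                = 1L
  ), class = "thermoshift_config")
}

.validateConfig <- function(cfg) {
  chk <- function(cond, key, why) {
    if (!cond) tsValidationError("config key '%s' invalid: %s", key, why)
  }
  chk(cfg$presence_fraction > 0 && cfg$presence_fraction <= 1,
      "presence_fraction", "must be in (0, 1]")
  chk(cfg$impute_divisor > 0, "impute_divisor", "must be > 0")
  chk(cfg$alpha_raw > 0 && cfg$alpha_raw < 1, "alpha_raw", "must be in (0, 1)")
  chk(cfg$alpha_fdr > 0 && cfg$alpha_fdr < 1, "alpha_fdr", "must be in (0, 1)")
  chk(cfg$mature_min_carbons >= 0, "mature_min_carbons", "must be >= 0")
  chk(cfg$mature_min_double_bonds >= 0, "mature_min_double_bonds", "must be >= 0")
  chk(!is.unsorted(cfg$chain_bucket_breaks), "chain_bucket_breaks",
      "must be nondecreasing")
  chk(!is.unsorted(cfg$tg_class_breaks), "tg_class_breaks",
      "must be nondecreasing")
  cfg
}

#' Load a run configuration from YAML or JSON
#'
#' Absent keys fall back to \code{\link{defaultRunConfig}}; values are
#' validated against the configuration invariants.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} document;
#'   an empty document yields the full default configuration.
#' @return A validated configuration list.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) tsSchemaError("config file not found: %s", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- defaultRunConfig()
  for (key in names(user)) {
    val <- user[[key]]
    if (key %in% c("chain_bucket_breaks", "tg_class_breaks")) val <- unlist(val)
    if (key == "panels") val <- lapply(val, function(p) {
      list(members = unlist(p$members),
           stratify_by_sex = isTRUE(p$stratify_by_sex))
    })
    cfg[[key]] <- val
  }
  .validateConfig(cfg)
}
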