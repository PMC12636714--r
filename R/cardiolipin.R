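## Cardiolipin maturity pools, the nascent-CL/PG cardiolipin-synthase proxy,
## and species-resolved CL/DLCL fold-change tables.

.clAnnotation <- function(study, matureMinCarbons, matureMinDoubleBonds) {
  ann <- annotations(study)
  d <- parseLipidNames(ann$name)
  d$metabolite_id <- ann$metabolite_id
  d$cl_class <- classifyCardiolipin(d$class_code, d$total_carbons,
                                    d$total_double_bonds,
                                    matureMinCarbons, matureMinDoubleBonds)
  d$is_standard[is.na(d$is_standard)] <- FALSE
  d[!d$is_standard, , drop = FALSE]
}

#' Per-sample cardiolipin and phosphatidylglycerol pool sums
#'
#' Sums the preprocessed intensities of each CL-family maturity pool (nascent,
#' mature, remodeling intermediates) and of all PG species, per sample of one
#' tissue.  Internal-standard species are excluded.
#'
#' @param study A preprocessed \linkS4class{MetaboStudy}.
#' @param tissue Tissue label.
#' @param matureMinCarbons,matureMinDoubleBonds Maturity thresholds
#'   (defaults 72 and 8).
#' @return \code{data.frame} with one row per sample: \code{sample_id},
#'   \code{age_group}, \code{sex}, \code{nascent_total}, \code{mature_total},
#'   \code{dlcl_total}, \code{pg_total}, \code{ratio_cl_pg}
#'   (nascent/PG; \code{NA} when \code{pg_total} is 0).
#' @export
clPoolSums <- function(study, tissue, matureMinCarbons = 72,
                       matureMinDoubleBonds = 8) {
  sub <- tissueSubset(study, tissue)
  d <- .clAnnotation(sub, matureMinCarbons, matureMinDoubleBonds)
  x <- intensityMatrix(sub)
  cd <- sampleMeta(sub)
  poolSum <- function(ids) {
    if (!length(ids)) return(rep(0, ncol(x)))
    colSums(x[ids, , drop = FALSE], na.rm = TRUE)
  }
  if (!any(d$cl_class %in% c("nascent", "mature"), na.rm = TRUE))
    warning(sprintf("tissue '%s': no cardiolipin species detected", tissue),
            call. = FALSE)
  out <- data.frame(
    sample_id = cd$sample_id, tissue = tissue,
    age_group = cd$age_group, sex = cd$sex,
    nascent_total = poolSum(d$metabolite_id[d$cl_class %in% "nascent"]),
    mature_total  = poolSum(d$metabolite_id[d$cl_class %in% "mature"]),
    dlcl_total    = poolSum(d$metabolite_id[d$cl_class %in% "remodeling_intermediate"]),
    pg_total      = poolSum(d$metabolite_id[d$class_code %in% "PG"]),
    stringsAsFactors = FALSE)
  out$ratio_cl_pg <- ifelse(out$pg_total > 0,
                            out$nascent_total / out$pg_total, NA_real_)
  out
}

#' Old-vs-young comparison of the nascent-CL/PG synthase proxy
#'
#' The per-sample ratio of the nascent cardiolipin pool to the total PG pool
#' proxies cardiolipin synthase (Crls1) activity.  Each tissue's ratio is
#' compared old vs young by signed fold change and two-sided Mann-Whitney U;
#' q-values are BH-adjusted across the supplied tissues (the ratio family).
#' Samples with a zero PG pool are excluded with a warning.
#'
#' @param study A preprocessed \linkS4class{MetaboStudy}.
#' @param tissues Character vector of tissue labels (default: all biological
#'   tissues present).
#' @param matureMinCarbons,matureMinDoubleBonds Maturity thresholds.
#' @param numerator \code{"nascent"} (default, the product/precursor proxy)
#'   or \code{"total_cl"} for a sensitivity variant.
#' @return \code{data.frame} with one row per tissue: \code{tissue},
#'   \code{fc_signed}, \code{log2fc}, \code{u_stat}, \code{p_raw},
#'   \code{q_fdr}.
#' @export
clPgRatioComparison <- function(study, tissues = NULL,
                                matureMinCarbons = 72,
                                matureMinDoubleBonds = 8,
                                numerator = c("nascent", "total_cl")) {
  numerator <- match.arg(numerator)
  if (is.null(tissues)) {
    cd <- sampleMeta(study)
    tissues <- unique(cd$tissue[!cd$is_qc])
  }
  rows <- lapply(tissues, function(tt) {
    ps <- clPoolSums(study, tt, matureMinCarbons, matureMinDoubleBonds)
    num <- if (numerator == "nascent") ps$nascent_total
           else ps$nascent_total + ps$mature_total
    ratio <- ifelse(ps$pg_total > 0, num / ps$pg_total, NA_real_)
    if (anyNA(ratio)) {
      warning(sprintf("tissue '%s': %d sample(s) with zero PG pool excluded",
                      tt, sum(is.na(ratio))), call. = FALSE)
    }
    keep <- !is.na(ratio)
    oldIdx <- ps$age_group[keep] == "old"
    s <- signedFoldChange(ratio[keep][oldIdx], ratio[keep][!oldIdx])
    mw <- mannWhitneyTwoSided(ratio[keep][oldIdx], ratio[keep][!oldIdx])
    data.frame(tissue = tt, fc_signed = s$fc_signed, log2fc = s$log2fc,
               u_stat = mw$u_stat, p_raw = mw$p_raw, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_fdr <- bhFdr(out$p_raw)
  out
}

#' Species-resolved CL and DLCL fold-change tables
#'
#' Differential records for every detected cardiolipin-family species of one
#' tissue, split into a CL panel and a DLCL/MLCL panel; catalog species not
#' detected in the tissue are listed as absent (the heat-map "x" marker).
#' Significance is masked at raw p below \code{alphaRaw}.
#'
#' @param study A preprocessed \linkS4class{MetaboStudy}.
#' @param tissue Tissue label.
#' @param catalogNames Optional character vector of the full CL-family catalog
#'   (to mark absences); defaults to the species present in the study.
#' @param alphaRaw Significance mask threshold (default 0.05).
#' @param matureMinCarbons,matureMinDoubleBonds Maturity thresholds.
#' @return List with \code{cl} and \code{dlcl} data.frames (columns of
#'   \code{\link{differentialTable}} plus \code{cl_class},
#'   \code{significant}) and \code{absent}, the catalog names not detected.
#' @export
clSpeciesTable <- function(study, tissue, catalogNames = NULL,
                           alphaRaw = 0.05, matureMinCarbons = 72,
                           matureMinDoubleBonds = 8) {
  sub <- tissueSubset(study, tissue)
  d <- .clAnnotation(sub, matureMinCarbons, matureMinDoubleBonds)
  fam <- d[!is.na(d$cl_class), , drop = FALSE]
  recs <- differentialTable(study[fam$metabolite_id, ], tissue)
  det <- detectedInTissue(study, tissue)[recs$metabolite_id]
  recs <- recs[det, , drop = FALSE]
  recs$cl_class <- fam$cl_class[match(recs$metabolite_id, fam$metabolite_id)]
  recs$significant <- recs$p_raw < alphaRaw
  detected <- unique(recs$name)
  absent <- setdiff(fam$name[!det[fam$metabolite_id]], detected)
  if (!is.null(catalogNames)) {
    catParsed <- parseLipidNames(catalogNames)
    catFam <- catalogNames[!is.na(classifyCardiolipin(
      catParsed$class_code, catParsed$total_carbons,
      catParsed$total_double_bonds, matureMinCarbons, matureMinDoubleBonds))]
    absent <- union(absent, setdiff(catFam, detected))
  }
  list(cl = recs[recs$cl_class != "remodeling_intermediate", , drop = FALSE],
       dlcl = recs[recs$cl_class == "remodeling_intermediate", , drop = FALSE],
       absent = absent)
}

#' Full cardiolipin stage report for a set of tissues
#'
#' Bundles \code{\link{clPoolSums}}, pool-level old-vs-young comparisons
#' (nascent and mature totals; BH within tissue across the two pools), the
#' \code{\link{clPgRatioComparison}} across tissues, and per-tissue species
#' tables.
#'
#' @inheritParams clPgRatioComparison
#' @param alphaRaw Significance mask for species tables.
#' @return List with \code{pools} (per-sample sums, all tissues),
#'   \code{pool_comparisons}, \code{ratio} and \code{species}.
#' @export
cardiolipinReport <- function(study, tissues = NULL, matureMinCarbons = 72,
                              matureMinDoubleBonds = 8, alphaRaw = 0.05) {
  if (is.null(tissues)) {
    cd <- sampleMeta(study)
    tissues <- unique(cd$tissue[!cd$is_qc])
  }
  pools <- do.call(rbind, lapply(tissues, clPoolSums, study = study,
                                 matureMinCarbons = matureMinCarbons,
                                 matureMinDoubleBonds = matureMinDoubleBonds))
  cmp <- do.call(rbind, lapply(tissues, function(tt) {
    ps <- pools[pools$tissue == tt, ]
    oldIdx <- ps$age_group == "old"
    do.call(rbind, lapply(c("nascent_total", "mature_total"), function(pool) {
      v <- ps[[pool]]
      if (all(v == 0)) return(NULL)
      s <- signedFoldChange(v[oldIdx], v[!oldIdx])
      mw <- mannWhitneyTwoSided(v[oldIdx], v[!oldIdx])
      data.frame(tissue = tt, pool = pool, fc_signed = s$fc_signed,
                 log2fc = s$log2fc, p_raw = mw$p_raw, stringsAsFactors = FALSE)
    }))
  }))
  if (!is.null(cmp) && nrow(cmp)) {
    cmp$q_fdr <- stats::ave(cmp$p_raw, cmp$tissue, FUN = bhFdr)
  }
  species <- lapply(tissues, function(tt)
    clSpeciesTable(study, tt, alphaRaw = alphaRaw,
                   matureMinCarbons = matureMinCarbons,
                   matureMinDoubleBonds = matureMinDoubleBonds))
  names(species) <- tissues
  list(pools = pools,
       pool_comparisons = cmp,
       ratio = clPgRatioComparison(study, tissues, matureMinCarbons,
                                   matureMinDoubleBonds),
       species = species)
}
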