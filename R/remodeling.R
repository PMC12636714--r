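## Neutral-lipid bulk sums, TG species remodeling tables, and chain-length
## bucketed fold-change matrices for free fatty acids and acylcarnitines.

.parsedNonStandard <- function(study) {
  ann <- annotations(study)
  d <- parseLipidNames(ann$name)
  d$metabolite_id <- ann$metabolite_id
  d[!d$is_standard & !is.na(d$class_code), , drop = FALSE]
}

#' Bulk neutral-lipid sums with old-vs-young comparison
#'
#' Per-sample sums over all parsed species of each class, per tissue, with a
#' signed fold change and Mann-Whitney comparison; BH adjustment across the
#' (class x tissue) family.
#'
#' @param study A preprocessed \linkS4class{MetaboStudy}.
#' @param tissues Tissues to summarise (default: all biological tissues).
#' @param classes Lipid classes to sum (default TG, DG, MG).
#' @return List with \code{sums} (per-sample class totals) and
#'   \code{comparisons} (per class x tissue).
#' @export
bulkSums <- function(study, tissues = NULL, classes = c("TG", "DG", "MG")) {
  if (is.null(tissues)) {
    cd <- sampleMeta(study)
    tissues <- unique(cd$tissue[!cd$is_qc])
  }
  d <- .parsedNonStandard(study)
  sums <- list(); cmps <- list()
  for (tt in tissues) {
    sub <- tissueSubset(study, tt)
    x <- intensityMatrix(sub)
    cd <- sampleMeta(sub)
    for (cls in classes) {
      ids <- d$metabolite_id[d$class_code == cls]
      ids <- intersect(ids, rownames(x))
      if (!length(ids)) {
        warning(sprintf("tissue '%s': no %s species detected, class skipped",
                        tt, cls), call. = FALSE)
        next
      }
      tot <- colSums(x[ids, , drop = FALSE], na.rm = TRUE)
      sums[[length(sums) + 1L]] <- data.frame(
        tissue = tt, class = cls, sample_id = cd$sample_id,
        age_group = cd$age_group, total = tot, stringsAsFactors = FALSE)
      oldIdx <- cd$age_group == "old"
      s <- signedFoldChange(tot[oldIdx], tot[!oldIdx])
      mw <- mannWhitneyTwoSided(tot[oldIdx], tot[!oldIdx])
      cmps[[length(cmps) + 1L]] <- data.frame(
        tissue = tt, class = cls, n_species = length(ids),
        fc_signed = s$fc_signed, log2fc = s$log2fc, p_raw = mw$p_raw,
        stringsAsFactors = FALSE)
    }
  }
  cmp <- do.call(rbind, cmps)
  if (!is.null(cmp)) cmp$q_fdr <- bhFdr(cmp$p_raw)
  list(sums = do.call(rbind, sums), comparisons = cmp)
}

#' TG species remodeling table
#'
#' One row per detected TG species of a tissue with its acyl-composition
#' coordinates (total carbons, total double bonds), differential statistics,
#' and size class -- the data behind carbon-by-unsaturation bubble displays.
#'
#' @param study A preprocessed \linkS4class{MetaboStudy}.
#' @param tissue Tissue label.
#' @param breaks TG size-class lower edges (see \code{\link{tgSizeClass}}).
#' @return \code{data.frame}: \code{metabolite_id}, \code{name},
#'   \code{total_carbons}, \code{total_double_bonds}, \code{log2fc},
#'   \code{fc_signed}, \code{p_raw}, \code{q_fdr}, \code{size_class}.
#' @export
tgRemodelingTable <- function(study, tissue, breaks = c(medium = 48, long = 54)) {
  d <- .parsedNonStandard(study)
  d <- d[d$class_code == "TG", , drop = FALSE]
  recs <- differentialTable(study[d$metabolite_id, ], tissue)
  i <- match(recs$metabolite_id, d$metabolite_id)
  data.frame(metabolite_id = recs$metabolite_id, name = recs$name,
             total_carbons = d$total_carbons[i],
             total_double_bonds = d$total_double_bonds[i],
             log2fc = recs$log2fc, fc_signed = recs$fc_signed,
             p_raw = recs$p_raw, q_fdr = recs$q_fdr,
             size_class = tgSizeClass(rep("TG", nrow(recs)),
                                      d$total_carbons[i], breaks),
             stringsAsFactors = FALSE)
}

#' Chain-bucketed fold-change matrix for FA or CAR species
#'
#' Species x tissue matrix of log2 fold changes for one class (free fatty
#' acids or acylcarnitines), rows ordered by (bucket, carbons, double bonds)
#' and split into saturated (0 double bonds) vs unsaturated sub-groups within
#' each bucket.  Cells of species undetected in a tissue are \code{NA} (the
#' heat-map "x" marker).  Every cell equals the corresponding
#' \code{\link{differentialTable}} record exactly.
#'
#' @param study A preprocessed \linkS4class{MetaboStudy}.
#' @param class \code{"FA"} or \code{"CAR"}.
#' @param tissues Tissues forming the columns (default: all biological).
#' @param breaks Bucket lower edges (see \code{\link{chainBucket}}).
#' @return List with \code{log2fc} (matrix), \code{p_raw} (matrix) and
#'   \code{species} (row metadata: bucket, saturation, coordinates).
#' @export
bucketFcMatrix <- function(study, class = c("FA", "CAR"), tissues = NULL,
                           breaks = c(MC = 6, LC = 13, VLC = 22)) {
  class <- match.arg(class)
  if (is.null(tissues)) {
    cd <- sampleMeta(study)
    tissues <- unique(cd$tissue[!cd$is_qc])
  }
  d <- .parsedNonStandard(study)
  d <- d[d$class_code == class, , drop = FALSE]
  if (!nrow(d)) tsDomainError("no %s species in study", class)
  d$bucket <- chainBucket(d$class_code, d$total_carbons, breaks)
  d$saturation <- ifelse(d$total_double_bonds == 0, "saturated", "unsaturated")
  ord <- order(factor(d$bucket, levels = c("SC", "MC", "LC", "VLC")),
               d$total_carbons, d$total_double_bonds)
  d <- d[ord, , drop = FALSE]
  fcm <- matrix(NA_real_, nrow(d), length(tissues),
                dimnames = list(d$name, tissues))
  pm <- fcm
  for (tt in tissues) {
    recs <- differentialTable(study[d$metabolite_id, ], tt)
    det <- detectedInTissue(study, tt)[recs$metabolite_id]
    recs <- recs[det, , drop = FALSE]
    i <- match(recs$metabolite_id, d$metabolite_id)
    fcm[i, tt] <- recs$log2fc
    pm[i, tt] <- recs$p_raw
  }
  list(log2fc = fcm, p_raw = pm,
       species = d[, c("name", "metabolite_id", "bucket", "saturation",
                       "total_carbons", "total_double_bonds")])
}
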