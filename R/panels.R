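## Named metabolite panels (optionally sex-stratified), product/precursor
## ratio metrics, and the virtual-digestion residue regulation profiles.

#' Default metabolite panels
#'
#' The shipped panel definitions: linoleate/arachidonate-derived oxylipins
#' (sex-stratified), hexosamine biosynthesis, central-carbon energy
#' metabolites plus amino-acid metabolism, omega-oxidation dicarboxylic
#' acids, the lipid-peroxidation marker 18-HODE, and the stress ratio pairs
#' (inosine/IMP, hypoxanthine/xanthine, GSSG/GSH).  Membership is
#' configuration, not code: override via \code{\link{loadConfig}}.
#'
#' @return Named list; each panel has \code{members} and
#'   \code{stratify_by_sex}, and the \code{ratios} element names
#'   numerator/denominator pairs.
#' @export
defaultPanels <- function() {
  aa <- c("alanine", "arginine", "asparagine", "aspartic acid", "cysteine",
          "glutamine", "glutamic acid", "glycine", "histidine", "isoleucine",
          "leucine", "lysine", "methionine", "phenylalanine", "proline",
          "serine", "threonine", "tryptophan", "tyrosine", "valine",
          "ornithine")
  list(
    oxylipin = list(
      members = c("12,13-DiHOME", "13-HpODE", "13-OxoODE", "PGE2",
                  "6-keto-PGF1alpha", "12-HETE"),
      stratify_by_sex = TRUE),
    hexosamine = list(
      members = c("glucosamine-6-phosphate", "N-acetylglucosamine",
                  "UDP-N-acetylglucosamine"),
      stratify_by_sex = FALSE),
    central_carbon = list(
      members = c("glucose", "beta-hydroxybutyrate", "citric acid",
                  "succinic acid", "fumaric acid", "malic acid",
                  "alpha-ketoglutarate", "pyruvate", "lactate", aa),
      stratify_by_sex = FALSE),
    dicarboxylic = list(
      members = c("adipic acid", "suberic acid", "pimelic acid",
                  "hexadecanedioic acid"),
      stratify_by_sex = FALSE),
    hode = list(members = "18-HODE", stratify_by_sex = FALSE),
    ratios = list(
      inosine_imp = c(numerator = "inosine", denominator = "IMP"),
      hypoxanthine_xanthine = c(numerator = "hypoxanthine",
                                denominator = "xanthine"),
      gssg_gsh = c(numerator = "GSSG", denominator = "GSH"))
  )
}

.resolveMembers <- function(study, members) {
  ann <- annotations(study)
  idx <- match(canonicalName(members), canonicalName(ann$name))
  list(ids = ann$metabolite_id[idx[!is.na(idx)]],
       members = members[!is.na(idx)],
       unresolved = members[is.na(idx)])
}

#' Panel report for one tissue
#'
#' Old-vs-young differential records for every resolvable panel member
#' (name resolution is case-insensitive and synonym-aware), BH-adjusted
#' within the panel; with \code{stratifyBySex}, additional per-sex
#' comparisons (old vs young within each sex).  Unresolved members are
#' reported, not fatal.
#'
#' @param study A preprocessed \linkS4class{MetaboStudy}.
#' @param tissue Tissue label.
#' @param members Character vector of member display names, or a panel list
#'   with \code{members} and \code{stratify_by_sex}.
#' @param stratifyBySex Compute per-sex strata as well.
#' @return List with \code{overall} (data.frame), \code{by_sex} (data.frame
#'   or \code{NULL}) and \code{unresolved}.
#' @export
panelReport <- function(study, tissue, members, stratifyBySex = FALSE) {
  if (is.list(members)) {
    stratifyBySex <- isTRUE(members$stratify_by_sex)
    members <- members$members
  }
  res <- .resolveMembers(study, members)
  if (!length(res$ids))
    return(list(overall = NULL, by_sex = NULL, unresolved = res$unresolved))
  recs <- differentialTable(study[res$ids, ], tissue)
  recs$q_fdr <- bhFdr(recs$p_raw)  # family = the panel
  bySex <- NULL
  if (stratifyBySex) {
    sub <- tissueSubset(study[res$ids, ], tissue)
    cd <- sampleMeta(sub)
    x <- intensityMatrix(sub)
    rows <- list()
    for (sx in intersect(.SEX_LEVELS, unique(cd$sex))) {
      sel <- cd$sex == sx
      oldIdx <- cd$age_group[sel] == "old"
      if (sum(oldIdx) < 2 || sum(!oldIdx) < 2) next
      for (i in seq_len(nrow(x))) {
        v <- x[i, sel]
        s <- signedFoldChange(v[oldIdx], v[!oldIdx])
        mw <- mannWhitneyTwoSided(v[oldIdx], v[!oldIdx])
        rows[[length(rows) + 1L]] <- data.frame(
          metabolite_id = rownames(x)[i],
          name = annotations(sub)$name[i], tissue = tissue, sex = sx,
          n_old = sum(oldIdx), n_young = sum(!oldIdx),
          fc_signed = s$fc_signed, log2fc = s$log2fc,
          u_stat = mw$u_stat, p_raw = mw$p_raw, stringsAsFactors = FALSE)
      }
    }
    bySex <- do.call(rbind, rows)
    if (!is.null(bySex))
      bySex$q_fdr <- stats::ave(bySex$p_raw, bySex$sex, FUN = bhFdr)
  }
  list(overall = recs, by_sex = bySex, unresolved = res$unresolved)
}

#' Product/precursor ratio metric
#'
#' Per-sample ratio of the normalized intensities of two metabolites in one
#' tissue, compared old vs young by signed fold change and Mann-Whitney U.
#' The ratio is invariant to per-sample multiplicative normalization since
#' numerator and denominator share the factor.
#'
#' @param study A preprocessed \linkS4class{MetaboStudy}.
#' @param tissue Tissue label.
#' @param numerator,denominator Display names (synonym-aware).
#' @return List with \code{name}, \code{ratios} (per-sample data.frame) and
#'   \code{comparison} (fc_signed, log2fc, u_stat, p_raw).
#' @export
ratioMetric <- function(study, tissue, numerator, denominator) {
  num <- .resolveMembers(study, numerator)
  den <- .resolveMembers(study, denominator)
  if (!length(num$ids))
    tsDomainError("numerator metabolite '%s' not found", numerator)
  if (!length(den$ids))
    tsDomainError("denominator metabolite '%s' not found", denominator)
  sub <- tissueSubset(study, tissue)
  x <- intensityMatrix(sub)
  cd <- sampleMeta(sub)
  r <- x[num$ids[1], ] / x[den$ids[1], ]
  oldIdx <- cd$age_group == "old"
  s <- signedFoldChange(r[oldIdx], r[!oldIdx])
  mw <- mannWhitneyTwoSided(r[oldIdx], r[!oldIdx])
  list(name = sprintf("%s/%s", numerator, denominator),
       ratios = data.frame(sample_id = cd$sample_id, tissue = tissue,
                           age_group = cd$age_group, ratio = unname(r),
                           stringsAsFactors = FALSE),
       comparison = data.frame(tissue = tissue,
                               numerator = numerator, denominator = denominator,
                               fc_signed = s$fc_signed, log2fc = s$log2fc,
                               u_stat = mw$u_stat, p_raw = mw$p_raw,
                               stringsAsFactors = FALSE))
}

#' The configured stress-ratio set with BH across ratios
#'
#' @param study A preprocessed \linkS4class{MetaboStudy}.
#' @param tissue Tissue label.
#' @param ratios Named list of c(numerator, denominator) pairs; defaults to
#'   the shipped stress ratios.
#' @return \code{data.frame} of comparisons with \code{q_fdr} across the set.
#' @export
ratioPanel <- function(study, tissue, ratios = defaultPanels()$ratios) {
  out <- do.call(rbind, lapply(names(ratios), function(nm) {
    rm <- ratioMetric(study, tissue, ratios[[nm]][["numerator"]],
                      ratios[[nm]][["denominator"]])
    cbind(ratio = nm, rm$comparison, stringsAsFactors = FALSE)
  }))
  out$q_fdr <- bhFdr(out$p_raw)
  out
}

#' Residue-level regulation profile of di-/tri-peptides
#'
#' Virtual digestion of the detected small peptides: for each canonical
#' residue, the percentage of detected di-/tri-peptides containing that
#' residue (at least once; multiplicity ignored) that are significantly up-
#' or down-regulated at raw p below \code{alpha}.  Residues contained in no
#' detected peptide are excluded.
#'
#' @param records Differential records (\code{\link{differentialTable}}) for
#'   one tissue; peptide rows are found by name shape.
#' @param alpha Raw-p significance threshold (default 0.05).
#' @return \code{data.frame}: \code{residue},
#'   \code{n_detected_peptides_containing}, \code{pct_up}, \code{pct_down}.
#' @export
residueProfile <- function(records, alpha = 0.05) {
  mem <- peptideResidueMatrix(records$name)
  isPep <- rowSums(mem) > 0
  if (!any(isPep)) {
    warning("no detected di-/tri-peptides; empty residue profile", call. = FALSE)
    return(data.frame(residue = character(),
                      n_detected_peptides_containing = integer(),
                      pct_up = numeric(), pct_down = numeric()))
  }
  mem <- mem[isPep, , drop = FALSE]
  pep <- records[isPep, , drop = FALSE]
  up <- pep$p_raw < alpha & pep$direction == "up"
  down <- pep$p_raw < alpha & pep$direction == "down"
  n <- colSums(mem)
  keep <- n > 0
  data.frame(residue = colnames(mem)[keep],
             n_detected_peptides_containing = unname(n[keep]),
             pct_up = unname(100 * colSums(mem & up)[keep] / n[keep]),
             pct_down = unname(100 * colSums(mem & down)[keep] / n[keep]),
             stringsAsFactors = FALSE)
}

#' Omega-oxidation dicarboxylic acid panel
#'
#' Thin wrapper over \code{\link{panelReport}} with the fixed four-member
#' default panel (adipic, suberic, pimelic, hexadecanedioic acid).
#'
#' @inheritParams panelReport
#' @export
dicarboxylicPanel <- function(study, tissue) {
  panelReport(study, tissue, defaultPanels()$dicarboxylic)
}
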