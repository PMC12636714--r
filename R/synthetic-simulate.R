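## Synthetic study generator, part 2: effect assembly, intensity simulation
## with MNAR + MCAR missingness, platform duplicates with QC pools, and the
## ground-truth table.

## Resolve the pinned-effect selectors against the catalog features.
.resolvePinned <- function(feat, pinned) {
  hits <- lapply(seq_len(nrow(pinned)), function(k) {
    p <- pinned[k, ]
    idx <- switch(p$type,
      name = which(canonicalName(feat$name) == canonicalName(p$key)),
      cl_class = which(feat$cl_class %in% p$key),
      class = which(feat$class_code %in% p$key),
      tg_class = which(feat$class_code %in% "TG" & feat$tg_class %in% p$key),
      bucket = {
        parts <- strsplit(p$key, ":", fixed = TRUE)[[1]]
        which(feat$class_code %in% parts[1] & feat$bucket %in% parts[2])
      },
      tsValidationError("unknown pinned-effect selector type '%s'", p$type))
    if (!length(idx)) return(NULL)
    data.frame(row = idx, tissue = p$tissue, fc = p$fc, sexes = p$sexes,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, hits)
}

## Build the per-(feature, tissue) effect tables: age fc (with sex
## restriction), sex fc, interaction fc, affected flag.  Pinned and peptide
## effects are laid down first; the random remainder is drawn so the total
## affected count and the directional split match the configured values.
## Random effects are restricted to features whose expected level in the
## tissue cannot cross the tissue median under the effect, so per-sample
## medians stay effect-free (the regime median normalization assumes).
.assembleEffects <- function(cat, config, levels) {
  feat <- cat$features
  n <- nrow(feat)
  tissues <- config$tissues
  ageFc <- matrix(1, n, length(tissues), dimnames = list(feat$metabolite_id, tissues))
  sexFc <- ageFc; intFc <- ageFc
  sexes <- matrix("both", n, length(tissues),
                  dimnames = list(feat$metabolite_id, tissues))
  pinnedHits <- .resolvePinned(feat, defaultPinnedEffects())
  pinnedHits <- pinnedHits[pinnedHits$tissue %in% tissues, , drop = FALSE]
  pepMem <- peptideResidueMatrix(feat$name)
  maxE <- config$effect_range[2]
  m <- config$median_margin
  for (k in seq_len(NROW(pinnedHits))) {
    h <- pinnedHits[k, ]
    ageFc[h$row, h$tissue] <- h$fc
    sexes[h$row, h$tissue] <- h$sexes
  }
  for (tt in intersect(names(config$peptides), tissues)) {
    pc <- config$peptides[[tt]]
    pool <- which(feat$family == "peptide")
    if (!is.null(pc$require_residues))
      pool <- pool[rowSums(pepMem[pool, pc$require_residues, drop = FALSE]) > 0]
    if (!is.null(pc$exclude_residues))
      pool <- pool[rowSums(pepMem[pool, pc$exclude_residues, drop = FALSE]) == 0]
    sel <- sample(pool, round(pc$fraction * length(pool)))
    ageFc[sel, tt] <- pc$fc
  }
  for (ti in seq_along(tissues)) {
    tt <- tissues[ti]
    aff <- config$affected[config$affected$tissue == tt, ]
    if (!nrow(aff)) next
    pinnedRows <- which(ageFc[, tt] != 1)
    nPinDown <- sum(ageFc[pinnedRows, tt] < 1)
    ## random pool: not pinned here, never CL-family/PG (keeps the synthase
    ## proxy clean), never peptides (residue profiles have their own model)
    base <- which(!feat$family %in% c("CL", "DLCL", "PG", "peptide"))
    base <- setdiff(base, pinnedRows)
    lev <- levels[, ti]
    med <- stats::median(lev)
    ## crossing-free eligibility: a down shift may not drag a feature from
    ## above to below the median, an up shift not push one across from below
    eligDown <- base[lev[base] > med + maxE + m | lev[base] < med - m]
    eligUp   <- base[lev[base] > med + m | lev[base] < med - maxE - m]
    nRandom <- max(0L, aff$n_affected - length(pinnedRows))
    nDownTotal <- round(aff$prop_down * aff$n_affected)
    nDown <- min(nRandom, max(0L, nDownTotal - nPinDown))
    nUp <- nRandom - nDown
    selDown <- sample(eligDown, min(nDown, length(eligDown)))
    selUp <- sample(setdiff(eligUp, selDown), min(nUp, length(eligUp)))
    sel <- c(selDown, selUp)
    mag <- 2^stats::runif(length(sel), config$effect_range[1], config$effect_range[2])
    dir <- rep(c(-1, 1), c(length(selDown), length(selUp)))
    ageFc[sel, tt] <- mag^dir
    ## sex main effects and age x sex interactions on non-pinned features
    sexPool <- setdiff(seq_len(n), pinnedRows)
    sSel <- sample(sexPool, round(config$sex_effect_fraction * n))
    sexFc[sSel, tt] <- 2^(sample(c(-1, 1), length(sSel), replace = TRUE) *
                            stats::runif(length(sSel), config$sex_effect_range[1],
                                         config$sex_effect_range[2]))
    iSel <- sample(setdiff(sel, sSel), round(config$interaction_fraction * length(sel)))
    intFc[iSel, tt] <- 2^(sample(c(-1, 1), length(iSel), replace = TRUE) *
                            stats::runif(length(iSel), config$interaction_range[1],
                                         config$interaction_range[2]))
  }
  list(age_fc = ageFc, sex_fc = sexFc, interaction_fc = intFc, sexes = sexes)
}

#' Simulate a synthetic multi-organ study
#'
#' Draws log2-normal intensities under the additive-in-log2 model
#' \deqn{log_2 x = b_j + o_{jt} + log_2(sexFC) 1[male] + log_2(ageFC) 1[old]
#'       + log_2(intFC) 1[old, male] + N(0, sd)}
#' per feature j and tissue t, applies MNAR masking (cells below the
#' feature's low quantile across all biological samples) and MCAR masking,
#' emits a fraction of features on a second platform as duplicates, appends
#' QC pool replicates, and computes each feature's QC relative standard
#' deviation into the annotations.
#'
#' @param cat Catalog from \code{\link{buildCatalog}}.
#' @param config Generator configuration.
#' @param seed Integer seed.
#' @return List with \code{study} (a raw \linkS4class{MetaboStudy}) and
#'   \code{truth} (per feature x tissue: true effects, affected flag, family
#'   and CL class).
#' @export
simulateStudy <- function(cat = buildCatalog(), config = generatorConfig(),
                          seed = 1L) {
  feat <- cat$features
  n <- nrow(feat)
  tissues <- config$tissues
  nCell <- config$n_per_cell
  ## sample sheet: nCell animals per (age, sex) cell per tissue
  grid <- expand.grid(rep = seq_len(nCell), sex = .SEX_LEVELS,
                      age_group = .AGE_LEVELS, tissue = tissues,
                      stringsAsFactors = FALSE)
  meta <- data.frame(
    sample_id = sprintf("%s_%s_%s_%d", grid$tissue, grid$age_group,
                        substr(grid$sex, 1, 1), grid$rep),
    animal_id = sprintf("an_%s_%s_%d", grid$age_group,
                        substr(grid$sex, 1, 1), grid$rep),
    tissue = grid$tissue, age_group = grid$age_group, sex = grid$sex,
    is_qc = FALSE, stringsAsFactors = FALSE)
  qcMeta <- data.frame(
    sample_id = sprintf("qc_pool_%d", seq_len(config$qc_replicates)),
    animal_id = NA_character_, tissue = "qc_pool",
    age_group = NA_character_, sex = NA_character_, is_qc = TRUE,
    stringsAsFactors = FALSE)
  withSeed(seed + 7919L, {
    baseline <- stats::runif(n, config$baseline_range[1], config$baseline_range[2])
    offset <- matrix(stats::rnorm(n * length(tissues), 0, config$tissue_offset_sd),
                     n, length(tissues), dimnames = list(NULL, tissues))
    ## structured lipid families: class-level location and tissue offset
    ## shared by the family, tighter species-level dispersion on top
    for (fam in config$structured_families) {
      rows <- which(feat$family == fam)
      if (!length(rows)) next
      classLevel <- stats::runif(1, config$baseline_range[1] + 1.5,
                                 config$baseline_range[2] - 1.5)
      baseline[rows] <- classLevel + stats::runif(length(rows),
                                                  config$family_baseline_range[1],
                                                  config$family_baseline_range[2])
      classOffset <- stats::rnorm(length(tissues), 0, config$tissue_offset_sd)
      offset[rows, ] <- rep(classOffset, each = length(rows)) +
        matrix(stats::rnorm(length(rows) * length(tissues), 0,
                            config$family_species_offset_sd),
               length(rows), length(tissues))
    }
    eff <- .assembleEffects(cat, config, levels = baseline + offset)
    ## pinned species are quantified species in their reporting tissue: keep
    ## them above the feature's detection floor there (the low tail that MNAR
    ## masking eats lives in some other tissue), even after a down effect.
    ## The floor approximates the feature's pooled low quantile (mixture of
    ## the other tissues' cell distributions) plus a 3-sigma cell margin.
    cellSd <- max(sqrt(config$noise_sd^2 + config$sample_drift_sd^2), 0.05)
    mnarFloor <- function(otherLevels) {
      if (config$mnar_quantile <= 0) return(min(otherLevels))
      f <- function(q) mean(stats::pnorm(q, otherLevels, cellSd)) -
        max(config$mnar_quantile, 1e-6)
      stats::uniroot(f, c(min(otherLevels) - 8 * cellSd,
                          max(otherLevels) + 8 * cellSd))$root + 3 * cellSd
    }
    pinnedHits <- .resolvePinned(feat, defaultPinnedEffects())
    pinnedHits <- pinnedHits[pinnedHits$tissue %in% tissues, , drop = FALSE]
    for (k in seq_len(NROW(pinnedHits))) {
      j <- pinnedHits$row[k]
      ti3 <- match(pinnedHits$tissue[k], tissues)
      e <- log2(eff$age_fc[j, ti3])
      floorLev <- mnarFloor(baseline[j] + offset[j, -ti3]) - min(0, e)
      if (baseline[j] + offset[j, ti3] < floorLev)
        offset[j, ti3] <- floorLev - baseline[j]
    }
    ## pinned and peptide effects are tied to named species, so their tissue
    ## levels may fall in the median-crossing zone; nudge those levels out of
    ## the zone on their own side, which leaves the tissue median untouched
    ## while keeping per-sample medians effect-free
    m <- config$median_margin
    for (ti2 in seq_along(tissues)) {
      lev <- baseline + offset[, ti2]
      med <- stats::median(lev)
      e <- log2(eff$age_fc[, ti2])
      for (j in which(e != 0)) {
        lo <- med - ifelse(e[j] > 0, e[j], 0) - m
        hi <- med + ifelse(e[j] < 0, -e[j], 0) + m
        if (lev[j] > lo && lev[j] < hi) {
          lev[j] <- if (lev[j] > med) hi + stats::runif(1, 0, 0.3)
                    else lo - stats::runif(1, 0, 0.3)
        }
      }
      offset[, ti2] <- lev - baseline
    }
    ## a zone nudge may have pushed a pinned species back under its floor;
    ## resolve upward (out of the zone and above the floor)
    for (k in seq_len(NROW(pinnedHits))) {
      j <- pinnedHits$row[k]
      ti3 <- match(pinnedHits$tissue[k], tissues)
      e <- log2(eff$age_fc[j, ti3])
      floorLev <- mnarFloor(baseline[j] + offset[j, -ti3]) - min(0, e)
      if (baseline[j] + offset[j, ti3] < floorLev) {
        med <- stats::median(baseline + offset[, ti3])
        hi <- med + max(0, -e) + m
        offset[j, ti3] <- max(floorLev, hi + 0.1) - baseline[j]
      }
    }
    drift <- stats::rnorm(nrow(meta), 0, config$sample_drift_sd)
    ## expected log2 value per (feature, biological sample)
    ti <- match(meta$tissue, tissues)
    isOld <- meta$age_group == "old"
    isMale <- meta$sex == "male"
    mu <- matrix(0, n, nrow(meta))
    for (s in seq_len(nrow(meta))) {
      t <- ti[s]
      a <- baseline + offset[, t] + drift[s]
      if (isMale[s]) a <- a + log2(eff$sex_fc[, t])
      if (isOld[s]) {
        lim <- eff$sexes[, t]
        applies <- lim == "both" | (lim == "male") == isMale[s]
        a <- a + ifelse(applies, log2(eff$age_fc[, t]), 0)
        if (isMale[s]) a <- a + log2(eff$interaction_fc[, t])
      }
      mu[, s] <- a
    }
    x <- 2^(mu + matrix(stats::rnorm(n * nrow(meta), 0, config$noise_sd),
                        n, nrow(meta)))
    ## MNAR: per-feature low-intensity threshold across all biological samples
    thr <- apply(x, 1, stats::quantile, probs = config$mnar_quantile)
    x[x < thr] <- NA
    ## MCAR on top
    x[matrix(stats::runif(length(x)) < config$mcar_rate, n, nrow(meta))] <- NA
    ## QC pools: per-feature grand mean across tissues, tight replicate noise
    qcMu <- baseline + rowMeans(offset)
    qc <- 2^(qcMu + matrix(stats::rnorm(n * config$qc_replicates, 0,
                                        config$qc_noise_sd[["primary"]]),
                           n, config$qc_replicates))
    ## platform duplicates: re-draw noise around the same expectations with a
    ## platform offset and a noisier QC profile
    nDup <- floor(config$duplicate_fraction * n)
    dupIdx <- sort(sample.int(n, nDup))
    dupX <- 2^(mu[dupIdx, , drop = FALSE] + 1 +
                 matrix(stats::rnorm(nDup * nrow(meta), 0, config$noise_sd),
                        nDup, nrow(meta)))
    dupQc <- 2^(qcMu[dupIdx] + 1 +
                  matrix(stats::rnorm(nDup * config$qc_replicates, 0,
                                      config$qc_noise_sd[["duplicate"]]),
                         nDup, config$qc_replicates))
    ann <- cat$annotations
    otherPlatform <- c(hilic_pos = "hilic_neg", hilic_neg = "hilic_pos",
                       lipid_pos = "lipid_neg", lipid_neg = "lipid_pos")
    dupAnn <- ann[dupIdx, , drop = FALSE]
    dupAnn$metabolite_id <- paste0(dupAnn$metabolite_id, "d")
    dupAnn$platform <- otherPlatform[dupAnn$platform]
    rsd <- function(m) apply(m, 1, function(v) stats::sd(v) / mean(v))
    ann$qc_rsd <- rsd(qc)
    dupAnn$qc_rsd <- rsd(dupQc)
    allAnn <- rbind(ann, dupAnn)
    allX <- cbind(rbind(x, dupX), rbind(qc, dupQc))
    rownames(allX) <- allAnn$metabolite_id
    allMeta <- rbind(meta, qcMeta)
    colnames(allX) <- allMeta$sample_id
    truth <- data.frame(
      metabolite_id = rep(feat$metabolite_id, length(tissues)),
      tissue = rep(tissues, each = n),
      true_fc = as.vector(eff$age_fc),
      sex_limited = as.vector(eff$sexes),
      sex_fc = as.vector(eff$sex_fc),
      interaction_fc = as.vector(eff$interaction_fc),
      affected = as.vector(eff$age_fc != 1),
      family = rep(feat$family, length(tissues)),
      cl_class = rep(feat$cl_class, length(tissues)),
      stringsAsFactors = FALSE)
    list(study = MetaboStudy(allX, allMeta, allAnn), truth = truth)
  })
}

#' Generate and write a complete synthetic study
#'
#' Builds the catalog, simulates intensities, and writes the three study
#' tables plus the ground-truth CSV to \code{outDir}; the tables round-trip
#' through \code{\link{readStudy}}.
#'
#' @param config Generator configuration.
#' @param seed Integer seed (catalog and intensities derive sub-seeds from it).
#' @param outDir Output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
generateStudy <- function(config = generatorConfig(), seed = 1L, outDir) {
  cat <- buildCatalog(config, seed)
  sim <- simulateStudy(cat, config, seed)
  paths <- writeStudy(sim$study, outDir)
  truthPath <- file.path(outDir, "truth.csv")
  utils::write.csv(sim$truth, truthPath, row.names = FALSE, na = "")
  invisible(c(paths, truth = truthPath))
}
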