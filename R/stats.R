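## Core statistics: signed fold change, two-sided Mann-Whitney U, BH-FDR,
## two-way age x sex ANOVA, the per-tissue dysregulation census, and kernel
## density summaries of fold changes.

#' Signed fold change (old over young)
#'
#' With \eqn{r = mean(old)/mean(young)}: the signed fold change is \eqn{r}
#' when \eqn{r \ge 1} and \eqn{-1/r} otherwise, so its magnitude is always at
#' least 1 and its sign carries the direction (the field's usual
#' "FC = -2.8"-style convention); \code{log2fc} is \eqn{log_2 r}.
#'
#' @param old,young Strictly positive numeric vectors.
#' @param center \code{"mean"} (default) or \code{"median"}.
#' @return List with \code{fc_signed} and \code{log2fc}.
#' @export
signedFoldChange <- function(old, young, center = c("mean", "median")) {
  center <- match.arg(center)
  f <- if (center == "mean") mean else stats::median
  if (!length(old) || !length(young))
    tsDomainError("both groups must be non-empty")
  mo <- f(old); my <- f(young)
  if (!is.finite(mo) || !is.finite(my) || mo <= 0 || my <= 0)
    tsDomainError("group centers must be strictly positive (got %g and %g)", mo, my)
  r <- mo / my
  list(fc_signed = if (r >= 1) r else -1 / r, log2fc = log2(r))
}

#' Two-sided Mann-Whitney U test
#'
#' Exact null enumeration when the pooled sample size is at most 20 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction.  U is reported for the first group.  Two identical constant
#' groups return p = 1 by convention.
#'
#' @param x,y Numeric vectors with at least 2 observations each.
#' @return List with \code{u_stat} and \code{p_raw}.
#' @export
mannWhitneyTwoSided <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    tsDomainError("each group needs >= 2 observations")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    return(list(u_stat = length(x) * length(y) / 2, p_raw = 1))
  ties <- anyDuplicated(pooled) > 0L
  exact <- !ties && length(pooled) <= 20L
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(u_stat = unname(wt$statistic), p_raw = min(1, wt$p.value))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment: \eqn{q_{(i)} = \min_{j \ge i} m p_{(j)} / j},
#' capped at 1, order-preserving on ties; idempotent.
#'
#' @param p Numeric vector of p-values in [0, 1]; \code{NA}s propagate.
#' @return Numeric vector of q-values, same length and order.
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    tsDomainError("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-tissue differential abundance table
#'
#' For every metabolite of one tissue: signed fold change on the normalized
#' (not log/Pareto-scaled) intensities, two-sided Mann-Whitney U old vs
#' young, BH q-values within the tissue, and a direction call from the sign
#' of \code{log2fc} (\code{flat} for an exact zero, excluded from directional
#' percentages downstream).
#'
#' @param study A preprocessed \linkS4class{MetaboStudy}.
#' @param tissue Tissue label.
#' @param center Fold-change center passed to \code{\link{signedFoldChange}}.
#' @return \code{data.frame}: \code{metabolite_id}, \code{name},
#'   \code{tissue}, \code{fc_signed}, \code{log2fc}, \code{u_stat},
#'   \code{p_raw}, \code{q_fdr}, \code{direction}.
#' @export
differentialTable <- function(study, tissue, center = "mean") {
  sub <- tissueSubset(study, tissue)
  cd <- sampleMeta(sub)
  x <- intensityMatrix(sub)
  oldIdx <- cd$age_group == "old"
  if (!any(oldIdx) || !all(table(cd$age_group) >= 2))
    tsDomainError("tissue '%s' needs >= 2 samples per age group", tissue)
  n <- nrow(x)
  fc <- numeric(n); l2 <- numeric(n); u <- numeric(n); p <- numeric(n)
  for (i in seq_len(n)) {
    s <- signedFoldChange(x[i, oldIdx], x[i, !oldIdx], center = center)
    mw <- mannWhitneyTwoSided(x[i, oldIdx], x[i, !oldIdx])
    fc[i] <- s$fc_signed; l2[i] <- s$log2fc
    u[i] <- mw$u_stat; p[i] <- mw$p_raw
  }
  ann <- annotations(sub)
  data.frame(metabolite_id = ann$metabolite_id, name = ann$name,
             tissue = tissue, fc_signed = fc, log2fc = l2, u_stat = u,
             p_raw = p, q_fdr = bhFdr(p),
             direction = ifelse(l2 > 0, "up", ifelse(l2 < 0, "down", "flat")),
             stringsAsFactors = FALSE)
}

#' Two-way age x sex ANOVA per metabolite
#'
#' Fixed-effects ANOVA on the log-transformed, Pareto-scaled intensities with
#' factors age, sex and their interaction.  Balanced designs reduce to the
#' classical decomposition; unbalanced designs use Type II sums of squares
#' (\code{car::Anova}).  Metabolites whose design has an empty (age, sex)
#' cell are skipped with a warning.  BH adjustment is applied per term across
#' metabolites within the tissue.
#'
#' @param study A preprocessed \linkS4class{MetaboStudy}.
#' @param tissue Tissue label.
#' @return \code{data.frame}: \code{metabolite_id}, \code{tissue},
#'   \code{p_age}, \code{p_sex}, \code{p_interaction}, \code{q_age},
#'   \code{q_sex}, \code{q_interaction}.
#' @export
anovaAgeSex <- function(study, tissue) {
  sub <- tissueSubset(study, tissue)
  cd <- sampleMeta(sub)
  cells <- table(cd$age_group, cd$sex)
  if (any(dim(cells) < 2) || any(cells < 2)) {
    warning(sprintf("tissue '%s': incomplete age x sex design, ANOVA skipped", tissue),
            call. = FALSE)
    return(data.frame(metabolite_id = character(), tissue = character(),
                      p_age = numeric(), p_sex = numeric(),
                      p_interaction = numeric(), q_age = numeric(),
                      q_sex = numeric(), q_interaction = numeric()))
  }
  scaled <- logParetoScale(sub)
  age <- factor(cd$age_group, levels = .AGE_LEVELS)
  sex <- factor(cd$sex, levels = .SEX_LEVELS)
  n <- nrow(scaled)
  pAge <- pSex <- pInt <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    y <- scaled[i, ]
    if (stats::sd(y) == 0) { pAge[i] <- pSex[i] <- pInt[i] <- 1; next }
    fit <- stats::lm(y ~ age * sex)
    a <- car::Anova(fit, type = 2)
    pv <- a[["Pr(>F)"]]
    rn <- rownames(a)
    pAge[i] <- pv[rn == "age"]
    pSex[i] <- pv[rn == "sex"]
    pInt[i] <- pv[rn == "age:sex"]
  }
  ann <- annotations(sub)
  data.frame(metabolite_id = ann$metabolite_id, tissue = tissue,
             p_age = pAge, p_sex = pSex, p_interaction = pInt,
             q_age = bhFdr(pAge), q_sex = bhFdr(pSex),
             q_interaction = bhFdr(pInt), stringsAsFactors = FALSE)
}

#' Tissue-level dysregulation census
#'
#' Descriptive summary in the atlas style: metabolites with raw
#' \eqn{p < \alpha} are counted as dysregulated, split into increased and
#' decreased by direction (flat excluded), and, when ANOVA records are
#' supplied, the fraction of dysregulated metabolites with an age x sex
#' interaction at FDR \eqn{< \alpha} is reported as sex dependence.
#'
#' @param records Output of \code{\link{differentialTable}} for one tissue.
#' @param anovaRecords Optional output of \code{\link{anovaAgeSex}}.
#' @param alphaRaw Raw-p threshold (default 0.05).
#' @param alphaFdr Interaction FDR threshold (default 0.05).
#' @return One-row \code{data.frame}: \code{tissue}, \code{n_detected},
#'   \code{n_dysregulated}, \code{pct_dysregulated}, \code{pct_up},
#'   \code{pct_down}, \code{n_sex_dependent},
#'   \code{pct_sex_dependent_of_dysregulated}.
#' @export
tissueCensus <- function(records, anovaRecords = NULL,
                         alphaRaw = 0.05, alphaFdr = 0.05) {
  sig <- records$p_raw < alphaRaw & records$direction != "flat"
  nDys <- sum(sig)
  nUp <- sum(sig & records$direction == "up")
  nDown <- nDys - nUp
  nSex <- NA_integer_; pctSex <- NA_real_
  if (!is.null(anovaRecords) && nrow(anovaRecords)) {
    qi <- anovaRecords$q_interaction[match(records$metabolite_id,
                                           anovaRecords$metabolite_id)]
    nSex <- sum(sig & !is.na(qi) & qi < alphaFdr)
    pctSex <- if (nDys > 0) 100 * nSex / nDys else 0
  }
  data.frame(tissue = records$tissue[1],
             n_detected = nrow(records),
             n_dysregulated = nDys,
             pct_dysregulated = 100 * nDys / max(1, nrow(records)),
             pct_up = if (nDys > 0) 100 * nUp / nDys else 0,
             pct_down = if (nDys > 0) 100 * nDown / nDys else 0,
             n_sex_dependent = nSex,
             pct_sex_dependent_of_dysregulated = pctSex,
             stringsAsFactors = FALSE)
}

#' Kernel density summary of signed fold changes
#'
#' Gaussian kernel over the \code{fc_signed} values of significantly
#' dysregulated metabolites, bandwidth by Silverman's rule (reported as
#' \code{w}), evaluated on a grid spanning the data plus three bandwidths on
#' each side.  The trapezoidal integral of the curve is within 1\% of 1.
#'
#' @param fc Numeric vector of signed fold changes (>= 2 values).
#' @return List with \code{grid}, \code{density} and bandwidth \code{w}.
#' @export
fcDensity <- function(fc) {
  fc <- fc[is.finite(fc)]
  if (length(fc) < 2L) tsDomainError("fcDensity needs >= 2 fold changes")
  w <- stats::bw.nrd0(fc)
  d <- stats::density(fc, bw = w, kernel = "gaussian",
                      from = min(fc) - 3 * w, to = max(fc) + 3 * w, n = 512)
  list(grid = d$x, density = d$y, w = w)
}
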