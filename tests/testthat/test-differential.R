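test_that("signed fold change follows the magnitude-with-sign convention", {
  expect_equal(signedFoldChange(c(2, 2), c(2, 2)),
               list(fc_signed = 1, log2fc = 0))
  expect_equal(signedFoldChange(c(4, 4), c(2, 2))$fc_signed, 2)
  s <- signedFoldChange(c(1, 1), c(2, 2))
  expect_equal(s$fc_signed, -2)
  expect_equal(s$log2fc, -1)
  ## antisymmetry under group exchange
  set.seed(9)
  for (i in 1:20) {
    a <- 2^rnorm(6, 8); b <- 2^rnorm(6, 8)
    expect_equal(signedFoldChange(a, b)$fc_signed,
                 -signedFoldChange(b, a)$fc_signed, tolerance = 1e-12)
  }
  expect_true(abs(signedFoldChange(2^rnorm(5, 8), 2^rnorm(5, 8))$fc_signed) >= 1)
  expect_error(signedFoldChange(numeric(0), 1:3),
               class = "thermoshift_domain_error")
})

test_that("Mann-Whitney agrees with exact enumeration and handles degeneracy", {
  r <- mannWhitneyTwoSided(c(10, 11, 12), c(1, 2, 3))
  expect_equal(r$u_stat, 9)
  expect_equal(r$p_raw, 0.1)  # 2 extreme arrangements of C(6,3)=20
  expect_equal(r$p_raw, enumMannWhitneyP(c(10, 11, 12), c(1, 2, 3)))
  ## exact path equals the enumeration oracle on random small samples
  set.seed(21)
  for (i in 1:15) {
    x <- rnorm(4); y <- rnorm(5)
    expect_equal(mannWhitneyTwoSided(x, y)$p_raw, enumMannWhitneyP(x, y),
                 tolerance = 1e-12)
  }
  ## identical multisets and constant data give p = 1
  expect_equal(mannWhitneyTwoSided(c(1, 2, 3), c(3, 2, 1))$p_raw, 1)
  expect_equal(mannWhitneyTwoSided(c(5, 5), c(5, 5))$p_raw, 1)
  ## normal approximation tracks the exact law within 0.02 at n = 8 vs 8
  set.seed(33)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8, 0.5)
    exact <- enumMannWhitneyP(x, y)
    approx <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("Mann-Whitney p is invariant under strictly monotone transforms", {
  set.seed(14)
  x <- 2^rnorm(9, 8); y <- 2^rnorm(7, 9)
  p0 <- mannWhitneyTwoSided(x, y)$p_raw
  expect_equal(mannWhitneyTwoSided(log(x), log(y))$p_raw, p0)
  expect_equal(mannWhitneyTwoSided(x^3, y^3)$p_raw, p0)
  expect_equal(mannWhitneyTwoSided(-1 / x, -1 / y)$p_raw, p0)
})

test_that("BH adjustment equals the step-up oracle and is rank-monotone", {
  expect_equal(bhFdr(0.03), 0.03)
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  set.seed(8)
  for (i in 1:10) {
    p <- runif(50)^2
    q <- bhFdr(p)
    expect_equal(q, stepUpBH(p), tolerance = 1e-12)
    expect_false(is.unsorted(q[order(p)]))
    ## deterministic function of the p-values
    expect_equal(bhFdr(p), q)
  }
  expect_error(bhFdr(c(0.5, 1.2)), class = "thermoshift_domain_error")
})

test_that("two-way ANOVA is calibrated under the null and detects interaction", {
  ## null: no effects anywhere, n = 8 per cell
  set.seed(101)
  nMet <- 400
  cells <- expand.grid(rep = 1:8, sex = c("female", "male"),
                       age_group = c("young", "old"))
  meta <- data.frame(sample_id = sprintf("s%02d", seq_len(nrow(cells))),
                     animal_id = sprintf("a%02d", seq_len(nrow(cells))),
                     tissue = "BAT", age_group = cells$age_group,
                     sex = cells$sex, is_qc = FALSE)
  vals <- matrix(2^(10 + rnorm(nMet * nrow(cells), 0, 0.5)), nrow = nMet)
  ann <- data.frame(metabolite_id = sprintf("M%03d", 1:nMet),
                    name = sprintf("m%03d", 1:nMet),
                    superclass = "Organic acids", platform = "hilic_pos",
                    qc_rsd = 0.1)
  dimnames(vals) <- list(ann$metabolite_id, meta$sample_id)
  study <- MetaboStudy(vals, meta, ann)
  a <- anovaAgeSex(study, "BAT")
  for (term in c("p_age", "p_sex", "p_interaction")) {
    frac <- mean(a[[term]] < 0.05)
    expect_gte(frac, 0.01)
    expect_lte(frac, 0.09)
  }
  ## constructed pure interaction: cell means +d,-d,-d,+d with d >> noise
  d <- 3
  mu <- with(cells, ifelse((age_group == "old") == (sex == "male"), d, -d))
  one <- matrix(2^(10 + mu + rnorm(nrow(cells), 0, 0.2)), nrow = 1)
  dimnames(one) <- list("M001", meta$sample_id)
  s1 <- MetaboStudy(one, meta, ann[1, ])
  a1 <- anovaAgeSex(s1, "BAT")
  expect_lt(a1$p_interaction, 0.001)
  expect_gt(a1$p_age, 0.05)
  expect_gt(a1$p_sex, 0.05)
  ## balanced design: Type II equals the classical sequential decomposition
  y <- logParetoScale(s1)[1, ]
  age <- factor(meta$age_group); sex <- factor(meta$sex)
  classical <- anova(lm(y ~ age * sex))[["Pr(>F)"]][1:3]
  expect_equal(unlist(a1[c("p_age", "p_sex", "p_interaction")]),
               classical, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("tissue census counts and percentages are conserved", {
  recs <- data.frame(metabolite_id = sprintf("m%d", 1:10), name = "x",
                     tissue = "BAT",
                     fc_signed = c(rep(-2, 7), rep(2, 3)),
                     log2fc = c(rep(-1, 7), rep(1, 3)),
                     u_stat = 1, p_raw = c(rep(0.01, 10)),
                     q_fdr = 0.02,
                     direction = c(rep("down", 7), rep("up", 3)))
  cen <- tissueCensus(recs)
  expect_equal(cen$n_dysregulated, 10)
  expect_equal(cen$pct_down, 70)
  expect_equal(cen$pct_up + cen$pct_down, 100)
  ## nothing significant
  recs$p_raw <- 0.5
  cen0 <- tissueCensus(recs)
  expect_equal(cen0$n_dysregulated, 0)
  expect_equal(cen0$pct_up, 0)
  ## sex dependence from ANOVA interaction q-values
  recs$p_raw <- 0.01
  an <- data.frame(metabolite_id = recs$metabolite_id, tissue = "BAT",
                   p_age = 0.5, p_sex = 0.5,
                   p_interaction = c(rep(0.001, 4), rep(0.9, 6)),
                   q_age = 0.5, q_sex = 0.5,
                   q_interaction = c(rep(0.004, 4), rep(0.9, 6)))
  cen2 <- tissueCensus(recs, an)
  expect_equal(cen2$n_sex_dependent, 4)
  expect_equal(cen2$pct_sex_dependent_of_dysregulated, 40)
})

test_that("fold-change density is normalized, symmetric and mode-consistent", {
  d <- fcDensity(c(-2, 2, -2, 2, -2.5, 2.5))
  trap <- sum(diff(d$grid) * (head(d$density, -1) + tail(d$density, -1)) / 2)
  expect_lt(abs(trap - 1), 0.01)
  ## symmetric input -> density symmetric about 0
  mid <- d$density[order(abs(d$grid))[1:10]]
  expect_equal(d$density, rev(d$density), tolerance = 1e-6)
  expect_equal(d$w, stats::bw.nrd0(c(-2, 2, -2, 2, -2.5, 2.5)))
  ## unimodal input: mode within one grid step of the sample median
  set.seed(2)
  x <- rnorm(400, 3, 0.5)
  dd <- fcDensity(x)
  mode <- dd$grid[which.max(dd$density)]
  expect_lt(abs(mode - median(x)), dd$w)
  expect_error(fcDensity(1), class = "thermoshift_domain_error")
})
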