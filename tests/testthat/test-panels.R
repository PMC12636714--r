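test_that("panel reports resolve members case-insensitively with synonyms", {
  vals <- matrix(rep(c(8, 8, 8, 8), each = 3), nrow = 3, byrow = FALSE)
  study <- makeValueStudy(matrix(8, 3, 4),
                          names = c("Beta-Hydroxybutyrate", "glucose",
                                    "citric acid"))
  pr <- panelReport(study, "BAT",
                    c("beta-hydroxybutyrate", "GLUCOSE", "unobtainium"))
  expect_equal(nrow(pr$overall), 2)
  expect_equal(pr$unresolved, "unobtainium")
  ## identical groups: fc 1, p 1
  expect_equal(pr$overall$fc_signed, c(1, 1))
  expect_equal(pr$overall$p_raw, c(1, 1))
})

test_that("dicarboxylic panel carries exactly the four omega-oxidation acids", {
  members <- defaultPanels()$dicarboxylic$members
  expect_setequal(members, c("adipic acid", "suberic acid", "pimelic acid",
                             "hexadecanedioic acid"))
  study <- makeValueStudy(matrix(5, 4, 4), names = members)
  pr <- dicarboxylicPanel(study, "BAT")
  expect_equal(nrow(pr$overall), 4)
  expect_equal(pr$overall$direction, rep("flat", 4))
})

test_that("hexosamine panel members match the biosynthetic pathway trio", {
  expect_setequal(defaultPanels()$hexosamine$members,
                  c("glucosamine-6-phosphate", "N-acetylglucosamine",
                    "UDP-N-acetylglucosamine"))
})

test_that("ratio metrics equal element-wise division and its comparison", {
  vals <- rbind(c(2, 4, 6, 8), c(1, 2, 2, 2))
  study <- makeValueStudy(vals, names = c("inosine", "IMP"))
  rm <- ratioMetric(study, "BAT", "inosine", "IMP")
  expect_equal(rm$ratios$ratio, c(2, 2, 3, 4))
  ## old ratios (3,4) vs young (2,2): fc = mean(3,4)/mean(2,2)
  expect_equal(rm$comparison$fc_signed, 3.5 / 2)
  ## numerator == denominator: all ratios 1, p 1
  same <- ratioMetric(study, "BAT", "inosine", "inosine")
  expect_equal(same$ratios$ratio, rep(1, 4))
  expect_equal(same$comparison$p_raw, 1)
  expect_error(ratioMetric(study, "BAT", "inosine", "xanthine"),
               class = "thermoshift_domain_error")
  ## scale invariance under per-sample factors
  x2 <- sweep(vals, 2, c(3, 5, 0.5, 10), `*`)
  s2 <- makeValueStudy(x2, names = c("inosine", "IMP"))
  expect_equal(ratioMetric(s2, "BAT", "inosine", "IMP")$ratios$ratio,
               rm$ratios$ratio)
})

test_that("residue profiles equal brute-force enumeration on a toy catalog", {
  peps <- c("Val-Tyr-Val", "Gly-Leu", "Leu-Ala", "Ala-Gly-Leu", "Trp-Phe",
            "Phe-Ser", "Ser-Thr", "Tyr-Pro", "Met-Gln", "Pro-Met-Gln")
  recs <- data.frame(
    metabolite_id = sprintf("p%02d", 1:11),
    name = c(peps, "glucose"), tissue = "BAT",
    fc_signed = 2, log2fc = c(1, 1, -1, 1, 1, -1, 1, -1, 1, 1, 1),
    u_stat = 1,
    p_raw = c(0.01, 0.2, 0.01, 0.01, 0.6, 0.03, 0.9, 0.01, 0.04, 0.2, 0.001),
    q_fdr = 0.1,
    direction = c("up", "up", "down", "up", "up", "down", "up", "down",
                  "up", "up", "up"))
  prof <- residueProfile(recs, alpha = 0.05)
  ## independent enumeration
  mem <- sapply(c("Leu", "Tyr", "Met"), function(r)
    vapply(peps, function(p) r %in% strsplit(p, "-")[[1]], logical(1)))
  up <- recs$p_raw[1:10] < 0.05 & recs$direction[1:10] == "up"
  down <- recs$p_raw[1:10] < 0.05 & recs$direction[1:10] == "down"
  for (r in c("Leu", "Tyr", "Met")) {
    row <- prof[prof$residue == r, ]
    expect_equal(row$n_detected_peptides_containing, sum(mem[, r]))
    expect_equal(row$pct_up, 100 * sum(mem[, r] & up) / sum(mem[, r]))
    expect_equal(row$pct_down, 100 * sum(mem[, r] & down) / sum(mem[, r]))
  }
  ## glucose (non-peptide) never counts; absent residues are excluded
  expect_false(any(!prof$residue %in% unlist(strsplit(peps, "-"))))
  expect_true(all(prof$pct_up + prof$pct_down <= 100))
  ## Leu example: 3 detected Leu peptides... handled above; two-peptide case:
  two <- recs[c(2, 3), ]
  two$p_raw <- c(0.01, 0.2); two$direction <- c("up", "up")
  p2 <- residueProfile(two)
  expect_equal(p2$pct_up[p2$residue == "Leu"], 50)
  ## no peptides at all warns and returns empty
  expect_warning(p0 <- residueProfile(recs[11, ]), "no detected")
  expect_equal(nrow(p0), 0)
})

test_that("sex-stratified panels detect a male-only effect", {
  ## construct: PGE2 halved in old males only; 4 per (age, sex) cell
  cells <- expand.grid(rep = 1:8, sex = c("female", "male"),
                       age_group = c("young", "old"))
  meta <- data.frame(sample_id = sprintf("s%02d", seq_len(nrow(cells))),
                     animal_id = sprintf("a%02d", seq_len(nrow(cells))),
                     tissue = "BAT", age_group = cells$age_group,
                     sex = cells$sex, is_qc = FALSE)
  set.seed(31)
  base <- 2^(10 + rnorm(nrow(cells), 0, 0.1))
  eff <- ifelse(cells$age_group == "old" & cells$sex == "male", 0.25, 1)
  vals <- matrix(base * eff, nrow = 1)
  ann <- data.frame(metabolite_id = "M1", name = "PGE2",
                    superclass = "Fatty acyls", platform = "lipid_neg",
                    qc_rsd = 0.05)
  dimnames(vals) <- list("M1", meta$sample_id)
  study <- MetaboStudy(vals, meta, ann)
  pr <- panelReport(study, "BAT", list(members = "PGE2",
                                       stratify_by_sex = TRUE))
  male <- pr$by_sex[pr$by_sex$sex == "male", ]
  female <- pr$by_sex[pr$by_sex$sex == "female", ]
  expect_lt(male$p_raw, 0.05)
  expect_lt(male$fc_signed, -2)
  expect_gt(female$p_raw, 0.05)
  expect_equal(male$n_old, 8)
})
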