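test_that("platform duplicates collapse to the lowest-RSD feature", {
  study <- makeToyStudy()  # two 'glucose' rows, RSD 0.08 (T09) vs 0.15 (T10)
  merged <- mergePlatformDuplicates(study)
  expect_true("T09" %in% rownames(merged))
  expect_false("T10" %in% rownames(merged))
  expect_equal(preprocessReport(merged)$n_merged_duplicates, 1L)
  ## no duplicates: identity
  single <- study[1:5, ]
  expect_equal(rownames(mergePlatformDuplicates(single)), rownames(single))
  ## three-way tie on RSD resolves by platform order
  ann <- annotations(study)
  ann$name[c(9, 10, 11)] <- "serine"
  ann$qc_rsd[c(9, 10, 11)] <- c(0.2, 0.1, 0.1)
  ann$platform[c(9, 10, 11)] <- c("hilic_pos", "lipid_neg", "hilic_neg")
  s2 <- MetaboStudy(intensityMatrix(study), sampleMeta(study), ann)
  kept <- rownames(mergePlatformDuplicates(s2))
  expect_true("T11" %in% kept)   # RSD 0.1, hilic_neg precedes lipid_neg
  expect_false(any(c("T09", "T10") %in% kept))
  ## all-NA RSD group keeps first by tie-break, with a warning
  ann$qc_rsd[c(9, 10, 11)] <- NA
  s3 <- MetaboStudy(intensityMatrix(study), sampleMeta(study), ann)
  expect_warning(m3 <- mergePlatformDuplicates(s3), "no QC RSD")
  expect_true("T09" %in% rownames(m3))
})

test_that("presence filter keeps features observed in >= ceiling(f*n) in one tissue", {
  ## toy: 2 tissues x 4 samples, fraction 0.75 => need ceiling(3) = 3
  vals <- matrix(100, nrow = 3, ncol = 8)
  vals[1, 1] <- NA                 # present 3/4 in tissue A -> kept
  vals[2, c(1, 2, 5, 6)] <- NA     # 2/4 in both tissues -> removed
  vals[3, 5:8] <- NA               # 4/4 in A, 0/4 in B -> kept
  meta <- data.frame(sample_id = sprintf("s%d", 1:8),
                     animal_id = sprintf("a%d", 1:8),
                     tissue = rep(c("BAT", "heart"), each = 4),
                     age_group = rep(c("young", "old"), 4),
                     sex = "female", is_qc = FALSE)
  ann <- data.frame(metabolite_id = c("m1", "m2", "m3"), name = c("x", "y", "z"),
                    superclass = "Organic acids", platform = "hilic_pos",
                    qc_rsd = 0.1)
  dimnames(vals) <- list(ann$metabolite_id, meta$sample_id)
  study <- MetaboStudy(vals, meta, ann)
  kept <- filterPresence(study, fraction = 0.75)
  expect_setequal(rownames(kept), c("m1", "m3"))
  expect_equal(preprocessReport(kept)$n_removed_by_filter, 1L)
  ## default rule at 28/32: exactly 27 observed fails, 28 passes
  v2 <- matrix(1, nrow = 2, ncol = 32)
  v2[1, 1:4] <- NA  # 28/32
  v2[2, 1:5] <- NA  # 27/32
  meta2 <- data.frame(sample_id = sprintf("q%02d", 1:32),
                      animal_id = sprintf("b%02d", 1:32), tissue = "BAT",
                      age_group = rep(c("young", "old"), each = 16),
                      sex = "female", is_qc = FALSE)
  ann2 <- data.frame(metabolite_id = c("k1", "k2"), name = c("u", "v"),
                     superclass = "Organic acids", platform = "hilic_pos",
                     qc_rsd = 0.1)
  dimnames(v2) <- list(ann2$metabolite_id, meta2$sample_id)
  kept2 <- filterPresence(MetaboStudy(v2, meta2, ann2))
  expect_equal(rownames(kept2), "k1")
})

test_that("imputation fills min/divisor with fallback and is idempotent", {
  vals <- matrix(c(50, NA, 200, 80,
                   NA, NA, NA, NA), nrow = 2, byrow = TRUE)
  study <- makeValueStudy(vals)
  imp <- imputeMissing(study)
  x <- intensityMatrix(imp)
  expect_equal(unname(x[1, 2]), 5)       # min 50 / 10
  expect_equal(unname(x[2, ]), rep(100, 4))  # all-missing -> fallback
  expect_equal(preprocessReport(imp)$n_imputed_cells, 5L)
  twice <- imputeMissing(imp)
  expect_equal(intensityMatrix(twice), x)
})

test_that("median normalization equalizes sample medians multiplicatively", {
  ## two samples with medians 10 and 20 -> grand median 15, factors 1.5 and 0.75
  vals <- matrix(c(5, 10, 15, 10, 20, 30), nrow = 3)
  study <- makeValueStudy(cbind(vals, vals))  # 4 samples for a valid design
  norm <- normalizeMedian(study)
  x <- intensityMatrix(norm)
  expect_equal(unname(apply(x, 2, median)), rep(15, 4))
  expect_equal(unname(x[, 1]), c(5, 10, 15) * 1.5)
  expect_equal(unname(x[, 2]), c(10, 20, 30) * 0.75)
  ## rank order within each sample preserved
  expect_equal(apply(x, 2, order), apply(intensityMatrix(study), 2, order))
  ## identity when medians already equal
  same <- makeValueStudy(matrix(c(1, 2, 3), 3, 4))
  expect_equal(intensityMatrix(normalizeMedian(same)),
               intensityMatrix(same))
  ## zero median errors naming the sample
  z <- makeValueStudy(matrix(0, 2, 4))
  expect_error(normalizeMedian(z), "s01")
})

test_that("log/Pareto scaling matches its closed form", {
  ## logged values {-a, +a}: mean 0, sample sd = a*sqrt(2), scaled +-a/sqrt(sd)
  a <- 2
  vals <- matrix(2^c(-a, a, -a, a), nrow = 1)
  study <- makeValueStudy(vals)
  sc <- logParetoScale(study)
  sdv <- sd(c(-a, a, -a, a))
  expect_equal(unname(sc[1, ]), c(-a, a, -a, a) / sqrt(sdv))
  ## constant feature maps to zero; column means of a random table are ~0
  const <- makeValueStudy(matrix(7, 1, 4))
  expect_equal(unname(logParetoScale(const)[1, ]), rep(0, 4))
  set.seed(3)
  big <- makeValueStudy(matrix(2^rnorm(200), 20, 10))
  expect_equal(unname(rowMeans(logParetoScale(big))), rep(0, 20),
               tolerance = 1e-12)
  expect_error(logParetoScale(makeValueStudy(matrix(c(0, 1, 1, 1), 1))),
               class = "thermoshift_domain_error")
})

test_that("rank statistics are invariant to equal per-sample scale factors", {
  set.seed(5)
  vals <- matrix(2^(8 + rnorm(80)), nrow = 10)
  study <- makeValueStudy(vals)
  scaled <- MetaboStudy(intensityMatrix(study) * 3.7, sampleMeta(study),
                        annotations(study))
  p1 <- differentialTable(study, "BAT")$p_raw
  p2 <- differentialTable(scaled, "BAT")$p_raw
  expect_equal(p1, p2)
})

test_that("feature bookkeeping is conserved through the cleaning chain", {
  study <- makeToyStudy(missing = TRUE)
  clean <- preprocessStudy(study)
  rep <- preprocessReport(clean)
  expect_equal(rep$n_features_in - rep$n_merged_duplicates -
                 rep$n_removed_by_filter, nrow(clean))
  expect_equal(rep$stages, c("merge", "filter", "impute", "normalize"))
})
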