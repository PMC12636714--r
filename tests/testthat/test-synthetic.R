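# The generator is exercised at its default scale in test-acceptance.R; here
# the structural and determinism contracts are covered, mostly on a reduced
# configuration to keep runtimes low.

smallConfig <- function() {
  cfg <- generatorConfig()
  cfg$tissues <- c("BAT", "heart")
  cfg$n_per_cell <- 3L
  cfg$affected <- cfg$affected[cfg$affected$tissue %in% cfg$tissues, ]
  cfg$affected$n_affected <- c(80L, 60L)
  cfg
}

test_that("default catalog reproduces the cardiolipin family structure", {
  cat <- buildCatalog(seed = 1)
  f <- cat$features
  expect_equal(sum(f$family %in% c("CL", "DLCL")), 66)
  expect_equal(sum(f$family == "DLCL"), 6)
  expect_equal(sum(f$cl_class %in% "nascent"), 36)
  expect_equal(sum(f$cl_class %in% "mature"), 24)
  expect_equal(sum(f$cl_class %in% "remodeling_intermediate"), 6)
  expect_equal(nrow(cat$annotations), generatorConfig()$catalog_size)
  ## superclass vocabulary has 18 entries and covers the catalog
  expect_lte(length(unique(cat$annotations$superclass)), 18)
  ## every default panel member is present by canonical name
  members <- unlist(lapply(defaultPanels()[c("oxylipin", "hexosamine",
                                             "central_carbon", "dicarboxylic",
                                             "hode")],
                           `[[`, "members"))
  hit <- canonicalName(members) %in% canonicalName(cat$annotations$name)
  expect_true(all(hit))
})

test_that("catalog lipid and peptide names round-trip through the parsers", {
  cat <- buildCatalog(seed = 3)
  f <- cat$features
  lip <- f[f$family %in% c("CL", "DLCL", "PG", "TG", "DG", "MG", "FA", "CAR"), ]
  parsed <- parseLipidNames(lip$name)
  expect_false(anyNA(parsed$class_code))
  expect_equal(parsed$class_code, lip$family)
  peps <- f$name[f$family == "peptide"]
  mem <- peptideResidueMatrix(peps)
  expect_true(all(rowSums(mem) > 0))
  ## all 20 residues represented
  expect_true(all(colSums(mem) > 0))
})

test_that("generation is deterministic and the written study round-trips", {
  cfg <- smallConfig()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generateStudy(cfg, seed = 9, outDir = d1)
  generateStudy(cfg, seed = 9, outDir = d2)
  for (f in c("metadata.csv", "annotations.csv", "intensities.csv", "truth.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  study <- readStudy(file.path(d1, "metadata.csv"),
                     file.path(d1, "annotations.csv"),
                     file.path(d1, "intensities.csv"))
  expect_s4_class(study, "MetaboStudy")
  truth <- read.csv(file.path(d1, "truth.csv"))
  expect_equal(nrow(truth), cfg$catalog_size * length(cfg$tissues))
  ## different seed changes the intensities
  d3 <- withr::local_tempdir()
  generateStudy(cfg, seed = 10, outDir = d3)
  expect_false(identical(readLines(file.path(d1, "intensities.csv")),
                         readLines(file.path(d3, "intensities.csv"))))
})

test_that("the noise-free limit reproduces configured effects exactly", {
  cfg <- smallConfig()
  cfg$noise_sd <- 0
  cfg$sample_drift_sd <- 0
  cfg$mnar_quantile <- 0
  cfg$mcar_rate <- 0
  cfg$sex_effect_fraction <- 0
  cfg$interaction_fraction <- 0
  cat <- buildCatalog(cfg, seed = 2)
  sim <- simulateStudy(cat, cfg, seed = 2)
  x <- intensityMatrix(sim$study)
  cd <- sampleMeta(sim$study)
  tr <- sim$truth
  bat <- tr[tr$tissue == "BAT" & tr$sex_limited == "both", ]
  sel <- cd$tissue == "BAT" & !cd$is_qc
  oldIdx <- sel & cd$age_group == "old"
  ratio <- rowMeans(x[bat$metabolite_id, cd$sample_id[oldIdx], drop = FALSE]) /
    rowMeans(x[bat$metabolite_id, cd$sample_id[sel & cd$age_group == "young"],
               drop = FALSE])
  expect_equal(unname(ratio), bat$true_fc, tolerance = 1e-9)
  ## zero effects, zero noise: old equals young
  null <- bat$metabolite_id[!bat$affected]
  expect_equal(x[null, cd$sample_id[oldIdx]][, 1],
               x[null, cd$sample_id[sel & cd$age_group == "young"]][, 1])
})

test_that("the simulated missingness mechanism is low-intensity biased", {
  cfg <- smallConfig()
  cat <- buildCatalog(cfg, seed = 5)
  sim <- simulateStudy(cat, cfg, seed = 5)
  x <- intensityMatrix(sim$study)
  cd <- sampleMeta(sim$study)
  bio <- x[, !cd$is_qc]
  frac <- mean(is.na(bio))
  ## ~2% MNAR + ~1% MCAR
  expect_gt(frac, 0.015)
  expect_lt(frac, 0.06)
  ## QC pools are complete and tighter than biology
  qc <- x[, cd$is_qc, drop = FALSE]
  expect_false(anyNA(qc))
  ann <- annotations(sim$study)
  expect_true(all(ann$qc_rsd > 0))
  ## duplicate features carry the noisier QC profile
  dups <- grepl("d$", ann$metabolite_id)
  expect_equal(sum(dups), floor(cfg$duplicate_fraction * cfg$catalog_size))
  expect_gt(median(ann$qc_rsd[dups]), median(ann$qc_rsd[!dups]))
})

test_that("pinned effects are recovered by the pipeline on the default atlas", {
  ## one seed at default scale; the seed-averaged criteria live in the
  ## acceptance suite
  cat <- buildCatalog(seed = 17)
  sim <- simulateStudy(cat, generatorConfig(), seed = 17)
  clean <- preprocessStudy(sim$study)
  cc <- panelReport(clean, "quadriceps", defaultPanels()$central_carbon)$overall
  bhb <- cc[canonicalName(cc$name) == "beta-hydroxybutyrate", ]
  expect_gt(bhb$fc_signed, 1.5)
  expect_lt(bhb$p_raw, 0.01)
  dic <- dicarboxylicPanel(clean, "quadriceps")$overall
  expect_equal(nrow(dic), 4)
  expect_true(all(dic$direction == "up"))
  expect_true(all(dic$q_fdr < 0.05))
  ## residue profile: quadriceps peptides broadly up except Phe/Trp carriers
  prof <- residueProfile(differentialTable(clean, "quadriceps"))
  expect_gt(mean(prof$pct_up[!prof$residue %in% c("Phe", "Trp")]), 15)
  expect_lt(max(prof$pct_up[prof$residue %in% c("Phe", "Trp")]), 15)
})
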