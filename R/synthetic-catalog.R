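## Synthetic study generator, part 1: configuration and the annotation
## catalog.  The defaults encode the study conditions the pipeline is
## validated against: 7 tissues x 32 sex-balanced samples, a 1,000-feature
## catalog whose cardiolipin family has exactly 60 CL (36 nascent / 24 mature
## under the default maturity thresholds) plus 6 dilyso intermediates, and
## per-tissue effect tables pinning the headline fold changes.

#' Default synthetic-study generator configuration
#'
#' @return Named list of generator parameters; see the fields themselves and
#'   the methods vignette for rationale.
#' @export
generatorConfig <- function() {
  list(
    tissues = c("BAT", "VAT", "SAT", "quadriceps", "heart", "jejunum", "feces"),
    n_per_cell = 8L,            # animals per (age, sex) cell => 16 per age group
    catalog_size = 1000L,       # biological features before platform duplicates
    noise_sd = 0.35,            # log2 residual sd
    baseline_range = c(16, 24), # log2 peak-height baselines
    tissue_offset_sd = 2,       # log2 sd of per-(feature, tissue) baseline shifts
    ## species of one lipid class sit in a narrower abundance band around a
    ## class-level location and move with a shared class-level tissue offset;
    ## species-level tissue dispersion is tighter than for unrelated features
    family_baseline_range = c(-1.5, 1.5),   # species spread around class level
    family_species_offset_sd = 0.8,
    structured_families = c("CL", "DLCL", "PG", "TG", "DG", "MG", "FA", "CAR"),
    sample_drift_sd = 0.25,     # log2 sd of per-sample multiplicative drift
    mnar_quantile = 0.02,       # per-feature low-intensity masking quantile
    mcar_rate = 0.01,           # uniform random masking rate
    duplicate_fraction = 0.05,  # features emitted on a second platform
    qc_replicates = 5L,
    qc_noise_sd = c(primary = 0.05, duplicate = 0.15),  # log2 sd in QC pools
    ## random (non-pinned) effect magnitudes, |log2 FC|
    effect_range = c(0.6, 1.5),
    ## random effects only on features that cannot cross the tissue median
    ## under the effect (keeps per-sample medians effect-free)
    median_margin = 0.7,
    sex_effect_fraction = 0.10,
    sex_effect_range = c(0.26, 0.68),
    interaction_fraction = 0.05,
    interaction_range = c(0.38, 0.77),
    ## per-tissue affected feature counts and directional splits
    affected = data.frame(
      tissue    = c("BAT", "VAT", "SAT", "quadriceps", "heart", "jejunum", "feces"),
      n_affected = c(375L,  380L,  350L,  320L,         300L,    350L,      520L),
      prop_down  = c(0.70,  0.25,  0.50,  0.40,         0.40,    0.65,      0.24),
      stringsAsFactors = FALSE),
    ## small-peptide family effects (residue-selective regulation)
    peptides = list(
      quadriceps = list(mode = "up", fraction = 0.35, fc = 1.7,
                        exclude_residues = c("Phe", "Trp")),
      BAT = list(mode = "down", fraction = 0.5, fc = 0.55,
                 require_residues = c("Tyr", "Pro", "Met", "Gln"))
    )
  )
}

#' Pinned per-tissue effects of the default generator
#'
#' The named fold changes the synthetic atlas holds as ground truth: the
#' nascent-CL depletion driving the CL/PG synthase proxy (BAT 1/2.8,
#' jejunum 1/1.7, heart 1.1), the cardiac loss of tetralinoleoyl cardiolipin
#' (CL 72:8, 1/1.6), the quadriceps ketone (beta-hydroxybutyrate 2.1) and
#' aromatic amino-acid (1.3) increases, the omega-oxidation dicarboxylic
#' acids (1.8), the tissue-divergent 12,13-DiHOME pattern, the BAT oxylipin
#' and hexosamine declines with the male-only PGE2 effect, BAT TG size-class
#' remodeling, and the chain-length shifts of free fatty acids and
#' acylcarnitines.
#'
#' @return \code{data.frame} with columns \code{tissue}, \code{type} (one of
#'   \code{name}, \code{cl_class}, \code{class}, \code{tg_class},
#'   \code{bucket}), \code{key}, \code{fc} (multiplicative old/young) and
#'   \code{sexes} (\code{"both"}, \code{"male"} or \code{"female"}).
#' @export
defaultPinnedEffects <- function() {
  pe <- function(tissue, type, key, fc, sexes = "both")
    data.frame(tissue = tissue, type = type, key = key, fc = fc,
               sexes = sexes, stringsAsFactors = FALSE)
  rbind(
    pe("BAT", "cl_class", "nascent", 1 / 2.8),
    pe("jejunum", "cl_class", "nascent", 1 / 1.7),
    pe("heart", "cl_class", "nascent", 1.1),
    pe("heart", "name", "CL 72:8", 1 / 1.6),
    pe("BAT", "name", "12,13-DiHOME", 0.5),
    pe("VAT", "name", "12,13-DiHOME", 1.5),
    pe("quadriceps", "name", "12,13-DiHOME", 1.5),
    pe("BAT", "name", "13-HpODE", 0.6),
    pe("BAT", "name", "13-OxoODE", 0.6),
    pe("BAT", "name", "6-keto-PGF1alpha", 0.6),
    pe("BAT", "name", "12-HETE", 1.5),
    pe("BAT", "name", "PGE2", 0.4, sexes = "male"),
    pe("BAT", "name", "glucosamine-6-phosphate", 0.6),
    pe("BAT", "name", "N-acetylglucosamine", 0.6),
    pe("BAT", "name", "UDP-N-acetylglucosamine", 0.6),
    pe("BAT", "name", "citric acid", 5.0),
    pe("BAT", "tg_class", "short", 0.7),
    pe("BAT", "tg_class", "medium", 0.75),
    pe("BAT", "tg_class", "long", 1.4),
    pe("BAT", "bucket", "FA:LC", 0.7),
    pe("quadriceps", "name", "beta-hydroxybutyrate", 2.1),
    pe("quadriceps", "name", "phenylalanine", 1.3),
    pe("quadriceps", "name", "tryptophan", 1.3),
    pe("quadriceps", "name", "adipic acid", 1.8),
    pe("quadriceps", "name", "suberic acid", 1.8),
    pe("quadriceps", "name", "pimelic acid", 1.8),
    pe("quadriceps", "name", "hexadecanedioic acid", 1.8),
    pe("quadriceps", "bucket", "FA:LC", 1.5),
    pe("quadriceps", "bucket", "FA:VLC", 1.5),
    pe("quadriceps", "bucket", "CAR:LC", 1.5),
    pe("quadriceps", "bucket", "CAR:VLC", 1.5),
    pe("quadriceps", "class", "DG", 1.4),
    pe("quadriceps", "class", "MG", 1.4),
    pe("quadriceps", "name", "inosine", 1.6),
    pe("quadriceps", "name", "GSSG", 1.5),
    pe("quadriceps", "name", "GSH", 0.8),
    pe("quadriceps", "name", "18-HODE", 1.6),
    pe("quadriceps", "name", "hypoxanthine", 1.2)
  )
}

.SUPERCLASSES <- c(
  "Fatty acyls", "Glycerolipids", "Glycerophospholipids", "Sphingolipids",
  "Sterol lipids", "Prenol lipids", "Organic acids", "Amino acids and peptides",
  "Carbohydrates", "Nucleic acids", "Organoheterocyclic compounds",
  "Benzenoids", "Organic nitrogen compounds", "Organic oxygen compounds",
  "Alkaloids", "Polyketides", "Vitamins and cofactors", "Phenylpropanoids")

## Fixed cardiolipin-family species grid: 36 nascent, 24 mature, 6 DLCL under
## the default thresholds (>= 72 carbons and >= 8 double bonds for mature).
.clFamilySpecies <- function() {
  nas <- rbind(expand.grid(c = seq(62, 70, 2), db = 2:7),
               data.frame(c = c(72, 72, 74, 74, 76, 76),
                          db = c(5, 6, 6, 7, 6, 7)))
  mat <- rbind(expand.grid(c = c(72, 74, 76, 78), db = 8:12),
               data.frame(c = 80, db = c(8, 9, 10, 12)))
  dlcl <- data.frame(c = c(34, 34, 36, 36, 36, 38), db = c(1, 2, 2, 3, 4, 4))
  c(sprintf("CL %d:%d", nas$c, nas$db),
    sprintf("CL %d:%d", mat$c, mat$db),
    sprintf("DLCL %d:%d", dlcl$c, dlcl$db))
}

.namedPolar <- function() {
  c("12,13-DiHOME", "13-HpODE", "13-OxoODE", "PGE2", "6-keto-PGF1alpha",
    "12-HETE", "18-HODE",
    "glucosamine-6-phosphate", "N-acetylglucosamine", "UDP-N-acetylglucosamine",
    "inosine", "IMP", "hypoxanthine", "xanthine", "GSSG", "GSH",
    "glucose", "beta-hydroxybutyrate", "citric acid", "succinic acid",
    "fumaric acid", "malic acid", "alpha-ketoglutarate", "pyruvate", "lactate",
    "alanine", "arginine", "asparagine", "aspartic acid", "cysteine",
    "glutamine", "glutamic acid", "glycine", "histidine", "isoleucine",
    "leucine", "lysine", "methionine", "phenylalanine", "proline", "serine",
    "threonine", "tryptophan", "tyrosine", "valine", "ornithine",
    "adipic acid", "suberic acid", "pimelic acid", "hexadecanedioic acid")
}

#' Build the synthetic annotation catalog
#'
#' Assembles the full feature catalog: the fixed 66-species cardiolipin
#' family, phosphatidylglycerols, a TG/DG/MG acyl-composition grid, free
#' fatty acids and acylcarnitines across all chain buckets, the named polar
#' metabolites behind every shipped panel, seeded random di-/tri-peptides
#' covering all 20 residues, and unnamed filler compounds up to
#' \code{catalog_size}.  Every lipid and peptide name round-trips through the
#' parsers; the result is deterministic given the seed.
#'
#' @param config Generator configuration (\code{\link{generatorConfig}}).
#' @param seed Integer seed.
#' @return List with \code{annotations} (metabolite_id, name, superclass,
#'   platform, qc_rsd placeholder) and \code{features} (per-feature family,
#'   parsed coordinates, CL class, TG size class, chain bucket).
#' @export
buildCatalog <- function(config = generatorConfig(), seed = 1L) {
  withSeed(seed, {
    clFam <- .clFamilySpecies()
    pg <- sprintf("PG %d:%d", expand.grid(c = c(32, 34, 36, 38, 40), db = 0:3)$c,
                  expand.grid(c = c(32, 34, 36, 38, 40), db = 0:3)$db)
    tgGrid <- expand.grid(c = seq(40, 60, 2), db = 0:5)
    tg <- sprintf("TG %d:%d", tgGrid$c, tgGrid$db)
    dgGrid <- expand.grid(c = c(30, 32, 34, 36, 38), db = 0:2)
    dg <- sprintf("DG %d:%d", dgGrid$c, dgGrid$db)
    mg <- sprintf("MG %d:%d", c(16, 18, 20, 22, 24), c(0, 1, 0, 1, 0))
    fa <- c(sprintf("FA %d:0", c(4, 6, 8, 10, 12, 14, 16, 18, 20, 22, 24, 26)),
            "FA 16:1", "FA 18:1", "FA 18:2", "FA 20:4", "FA 22:6", "FA 24:1",
            "FA 26:2")
    car <- c(sprintf("CAR %d:0", c(2, 3, 4, 5, 6, 8, 10, 12, 14, 16, 18, 20, 22, 24, 26)),
             "CAR 18:1", "CAR 18:2", "CAR 20:4", "CAR 22:5", "CAR 24:1")
    polar <- .namedPolar()
    ## seeded di-/tri-peptides over the canonical residues, all 20 covered
    nPep <- 80L
    peps <- character(0)
    while (length(unique(peps)) < nPep) {
      len <- sample(2:3, nPep, replace = TRUE)
      peps <- unique(c(peps, vapply(len, function(l)
        paste(sample(.AA3, l, replace = TRUE), collapse = "-"), character(1))))
    }
    peps <- peps[seq_len(nPep)]
    miss <- setdiff(.AA3, unique(unlist(strsplit(peps, "-"))))
    for (r in miss) peps <- c(peps[-1], paste(r, sample(.AA3, 1), sep = "-"))
    named <- c(clFam, pg, tg, dg, mg, fa, car, polar, peps)
    nFill <- config$catalog_size - length(named)
    if (nFill < 0)
      tsValidationError("catalog_size %d smaller than the named catalog (%d)",
                        config$catalog_size, length(named))
    filler <- sprintf("compound_%04d", seq_len(nFill))
    name <- c(named, filler)
    family <- c(rep("CL", sum(startsWith(clFam, "CL "))),
                rep("DLCL", sum(startsWith(clFam, "DLCL"))),
                rep("PG", length(pg)), rep("TG", length(tg)),
                rep("DG", length(dg)), rep("MG", length(mg)),
                rep("FA", length(fa)), rep("CAR", length(car)),
                rep("polar", length(polar)), rep("peptide", length(peps)),
                rep("other", nFill))
    parsed <- parseLipidNames(name)
    if (any(!is.na(parsed$class_code) &
            parsed$class_code != "other" &
            parsed$class_code != family))
      tsValidationError("catalog species failed parser round-trip")
    superclass <- c(
      CL = "Glycerophospholipids", DLCL = "Glycerophospholipids",
      PG = "Glycerophospholipids", TG = "Glycerolipids", DG = "Glycerolipids",
      MG = "Glycerolipids", FA = "Fatty acyls", CAR = "Fatty acyls",
      polar = "Organic acids", peptide = "Amino acids and peptides")[family]
    superclass[is.na(superclass)] <- sample(.SUPERCLASSES, sum(is.na(superclass)),
                                            replace = TRUE)
    platform <- rep("hilic_pos", length(name))
    platform[family %in% c("CL", "DLCL", "PG", "FA")] <- "lipid_neg"
    platform[family %in% c("TG", "DG", "MG")] <- "lipid_pos"
    platform[family %in% c("polar", "other")] <-
      rep_len(c("hilic_pos", "hilic_neg"), sum(family %in% c("polar", "other")))
    feat <- data.frame(
      metabolite_id = sprintf("M%04d", seq_along(name)),
      name = name, family = family,
      class_code = parsed$class_code,
      total_carbons = parsed$total_carbons,
      total_double_bonds = parsed$total_double_bonds,
      stringsAsFactors = FALSE)
    feat$cl_class <- classifyCardiolipin(feat$class_code, feat$total_carbons,
                                         feat$total_double_bonds)
    feat$tg_class <- NA_character_
    isTG <- feat$class_code %in% c("TG", "DG", "MG")
    feat$tg_class[isTG] <- tgSizeClass(feat$class_code[isTG],
                                       feat$total_carbons[isTG])
    feat$bucket <- NA_character_
    isFC <- feat$class_code %in% c("FA", "CAR")
    feat$bucket[isFC] <- chainBucket(feat$class_code[isFC],
                                     feat$total_carbons[isFC])
    ann <- data.frame(metabolite_id = feat$metabolite_id, name = feat$name,
                      superclass = superclass, platform = platform,
                      qc_rsd = NA_real_, stringsAsFactors = FALSE)
    list(annotations = ann, features = feat)
  })
}
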