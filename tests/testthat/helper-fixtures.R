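# Small deterministic fixtures built in code.

# A toy two-tissue study: 2 animals per (age, sex) cell, 12 features covering
# the lipid families, a duplicate-platform pair, a peptide and polar names.
makeToyStudy <- function(seed = 42, missing = FALSE) {
  ann <- data.frame(
    metabolite_id = sprintf("T%02d", 1:12),
    name = c("CL 72:8", "CL 64:2", "DLCL 36:4", "PG 34:1", "TG 44:1",
             "TG 54:6", "FA 18:1", "CAR 4:0", "glucose", "glucose",
             "Val-Tyr-Val", "beta-hydroxybutyrate"),
    superclass = "Organic acids",
    platform = c(rep("lipid_neg", 4), "lipid_pos", "lipid_pos", "lipid_neg",
                 "hilic_pos", "hilic_pos", "hilic_neg", "hilic_pos", "hilic_pos"),
    qc_rsd = c(rep(0.05, 8), 0.08, 0.15, 0.05, 0.05),
    stringsAsFactors = FALSE)
  cells <- expand.grid(rep = 1:2, sex = c("female", "male"),
                       age_group = c("young", "old"),
                       tissue = c("BAT", "heart"), stringsAsFactors = FALSE)
  meta <- data.frame(
    sample_id = sprintf("s%02d", seq_len(nrow(cells))),
    animal_id = sprintf("a%d", seq_len(nrow(cells))),
    tissue = cells$tissue, age_group = cells$age_group, sex = cells$sex,
    is_qc = FALSE, stringsAsFactors = FALSE)
  set.seed(seed)
  m <- matrix(2^(10 + stats::runif(12 * nrow(meta), 0, 2)),
              nrow = 12, dimnames = list(ann$metabolite_id, meta$sample_id))
  if (missing) m[1, 2] <- NA
  MetaboStudy(m, meta, ann)
}

# A minimal preprocessed-like study for one tissue with explicit values.
makeValueStudy <- function(values, tissue = "BAT",
                           names = sprintf("met%02d", seq_len(nrow(values)))) {
  nSamp <- ncol(values)
  stopifnot(nSamp %% 2 == 0)
  meta <- data.frame(
    sample_id = sprintf("s%02d", seq_len(nSamp)),
    animal_id = sprintf("a%02d", seq_len(nSamp)),
    tissue = tissue,
    age_group = rep(c("young", "old"), each = nSamp / 2),
    sex = rep(c("female", "male"), length.out = nSamp),
    is_qc = FALSE, stringsAsFactors = FALSE)
  ann <- data.frame(metabolite_id = sprintf("M%02d", seq_len(nrow(values))),
                    name = names, superclass = "Organic acids",
                    platform = "hilic_pos", qc_rsd = 0.05,
                    stringsAsFactors = FALSE)
  dimnames(values) <- list(ann$metabolite_id, meta$sample_id)
  MetaboStudy(values, meta, ann)
}

# Independent brute-force two-sided Mann-Whitney p by full enumeration of
# rank assignments (no ties assumed).
enumMannWhitneyP <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  uObs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(pooled), n)
  us <- apply(combos, 2, function(idx)
    sum(rank(pooled)[idx]) - n * (n + 1) / 2)
  mid <- length(x) * length(y) / 2
  mean(abs(us - mid) >= abs(uObs - mid))
}

# Independent BH step-up oracle.
stepUpBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(1, q)
  out
}
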