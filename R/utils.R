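## Internal helpers: classed conditions, seeded evaluation, name canonicalisation.

tsError <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "thermoshift_error")))
}

tsSchemaError    <- function(fmt, ...) tsError("thermoshift_schema_error", fmt, ...)
tsIntegrityError <- function(fmt, ...) tsError("thermoshift_integrity_error", fmt, ...)
tsParseError     <- function(fmt, ...) tsError("thermoshift_parse_error", fmt, ...)
tsDomainError    <- function(fmt, ...) tsError("thermoshift_domain_error", fmt, ...)
tsValidationError<- function(fmt, ...) tsError("thermoshift_validation_error", fmt, ...)

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
## All stochastic code paths in the package funnel through this; there is no
## hidden dependence on the global seed.
withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Synonym map used for case-insensitive panel-member resolution.
.nameSynonyms <- c(
  "beta-hydroxybutyrate"            = "beta-hydroxybutyrate",
  "\u03b2-hydroxybutyrate"          = "beta-hydroxybutyrate",
  "bhb"                             = "beta-hydroxybutyrate",
  "beta-hb"                         = "beta-hydroxybutyrate",
  "oxidized glutathione"            = "gssg",
  "glutathione disulfide"           = "gssg",
  "glutathione"                     = "gsh",
  "reduced glutathione"             = "gsh",
  "inosine monophosphate"           = "imp",
  "inosine 5'-monophosphate"        = "imp",
  "udp-n-acetylglucosamine"         = "udp-n-acetylglucosamine",
  "uridine 5'-diphosphate-n-acetylglucosamine" = "udp-n-acetylglucosamine",
  "6-keto-pgf1alpha"                = "6-keto-pgf1alpha",
  "6-keto-pgf1\u03b1"               = "6-keto-pgf1alpha",
  "alpha-ketoglutarate"             = "alpha-ketoglutarate",
  "\u03b1-ketoglutarate"            = "alpha-ketoglutarate",
  "18-hydroxylinoleic acid"         = "18-hode",
  "12,13-dihome"                    = "12,13-dihome"
)

## Canonical key for metabolite display names: lower case, trimmed, synonyms
## collapsed.  Used for duplicate-platform grouping and panel resolution.
canonicalName <- function(x) {
  key <- tolower(trimws(as.character(x)))
  hit <- match(key, names(.nameSynonyms))
  ifelse(is.na(hit), key, unname(.nameSynonyms[hit]))
}

logMsg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}
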