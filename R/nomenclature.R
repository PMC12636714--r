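## Lipid shorthand and small-peptide name parsing, plus the classifiers built
## on the parsed descriptors: cardiolipin maturity, fatty-acid/acylcarnitine
## chain buckets, and TG size classes.
##
## Grammar (deliberately narrow; anything else parses to nothing):
##   summed notation:         "CL 72:8", "TG(52:3)"
##   chain-resolved notation: "CL(18:2/18:2/18:2/18:2)", "TG 14:0/16:1/14:0"
## Internal-standard suffixes ("-d5", "-13C6", "-15N2") are stripped and the
## species flagged; ether/oxidised decorations (O-, P-) map to class "other".

.CLASS_ARITY <- c(CL = 4L, DLCL = 2L, MLCL = 3L, PG = 2L, TG = 3L, DG = 2L,
                  MG = 1L, FA = 1L, CAR = 1L)

.STD_SUFFIX <- "[-_ ]?(d[0-9]+|13C[0-9]+|15N[0-9]+)$"

#' Parse a lipid display name into a structured descriptor
#'
#' @param name A single display string.
#' @return A list with elements \code{class_code}, \code{total_carbons},
#'   \code{total_double_bonds}, \code{chains} (a two-column matrix or
#'   \code{NULL}) and \code{is_standard}, or \code{NULL} when the name is not
#'   a recognised lipid.  A chain list inconsistent with the class arity
#'   raises a parse error.
#' @examples
#' parseLipidName("CL(18:2/18:2/18:2/18:2)")  # class CL, totals 72:8
#' parseLipidName("TG 52:3")
#' parseLipidName("glucosamine-6-phosphate")  # NULL
#' @export
parseLipidName <- function(name) {
  if (length(name) != 1L) tsDomainError("parseLipidName takes a single name")
  raw <- trimws(as.character(name))
  if (is.na(raw) || !nzchar(raw)) return(NULL)
  isStd <- grepl(.STD_SUFFIX, raw)
  s <- sub(.STD_SUFFIX, "", raw)
  s <- trimws(s)
  ## ether / oxidised decorations: recognised shape, analytically out of scope
  if (grepl("^[A-Za-z]+[ (]+[OP]-", s)) {
    return(list(class_code = "other", total_carbons = NA_integer_,
                total_double_bonds = NA_integer_, chains = NULL,
                is_standard = isStd))
  }
  m <- regmatches(s, regexec(
    "^([A-Za-z]+)[ (]+([0-9]+:[0-9]+(?:/[0-9]+:[0-9]+)*)\\)?$", s))[[1]]
  if (length(m) == 0L) return(NULL)
  cls <- toupper(m[2])
  if (!cls %in% names(.CLASS_ARITY)) return(NULL)
  parts <- strsplit(m[3], "/", fixed = TRUE)[[1]]
  nums <- vapply(strsplit(parts, ":", fixed = TRUE), as.integer,
                 integer(2))
  if (length(parts) == 1L) {
    chains <- NULL
    carbons <- nums[1, 1]
    db <- nums[2, 1]
  } else {
    arity <- .CLASS_ARITY[[cls]]
    if (length(parts) != arity)
      tsParseError("'%s': class %s requires %d chains, got %d",
                   raw, cls, arity, length(parts))
    chains <- t(nums)
    colnames(chains) <- c("carbons", "double_bonds")
    carbons <- sum(chains[, "carbons"])
    db <- sum(chains[, "double_bonds"])
  }
  list(class_code = cls, total_carbons = carbons, total_double_bonds = db,
       chains = chains, is_standard = isStd)
}

#' Parse a vector of display names into a descriptor table
#'
#' Vectorised front end to \code{\link{parseLipidName}}; names that are not
#' lipids yield \code{NA} rows, so the result always has one row per input.
#'
#' @param names Character vector of display names.
#' @return \code{data.frame} with columns \code{name}, \code{class_code},
#'   \code{total_carbons}, \code{total_double_bonds}, \code{is_standard}.
#' @export
parseLipidNames <- function(names) {
  ds <- lapply(names, function(nm) {
    d <- tryCatch(parseLipidName(nm), thermoshift_parse_error = function(e) NULL)
    if (is.null(d))
      list(class_code = NA_character_, total_carbons = NA_integer_,
           total_double_bonds = NA_integer_, is_standard = FALSE)
    else d
  })
  data.frame(
    name = as.character(names),
    class_code = vapply(ds, function(d) as.character(d$class_code), character(1)),
    total_carbons = vapply(ds, function(d) as.integer(d$total_carbons), integer(1)),
    total_double_bonds = vapply(ds, function(d) as.integer(d$total_double_bonds),
                                integer(1)),
    is_standard = vapply(ds, function(d) isTRUE(d$is_standard), logical(1)),
    stringsAsFactors = FALSE)
}

#' Classify cardiolipin-family species by remodeling maturity
#'
#' Dilyso and monolyso species (DLCL/MLCL) are remodeling intermediates.
#' A CL is \emph{mature} iff its total acyl carbons and total double bonds both
#' reach the thresholds (defaults 72 and 8, so that tetralinoleoyl cardiolipin
#' CL 72:8 is the archetypal mature species); otherwise it is \emph{nascent}.
#' The classification is exhaustive and mutually exclusive over the CL family.
#'
#' @param classCode Character vector of class codes (or a descriptor list from
#'   \code{\link{parseLipidName}}, in which case the remaining arguments are
#'   taken from it).
#' @param totalCarbons,totalDoubleBonds Integer vectors.
#' @param matureMinCarbons,matureMinDoubleBonds Maturity thresholds.
#' @return Character vector in \{\code{"nascent"}, \code{"mature"},
#'   \code{"remodeling_intermediate"}\}, \code{NA} for non-CL-family species.
#' @export
classifyCardiolipin <- function(classCode, totalCarbons = NULL,
                                totalDoubleBonds = NULL,
                                matureMinCarbons = 72,
                                matureMinDoubleBonds = 8) {
  if (is.list(classCode) && !is.null(classCode$class_code)) {
    totalCarbons <- classCode$total_carbons
    totalDoubleBonds <- classCode$total_double_bonds
    classCode <- classCode$class_code
  }
  out <- rep(NA_character_, length(classCode))
  out[classCode %in% c("DLCL", "MLCL")] <- "remodeling_intermediate"
  isCL <- !is.na(classCode) & classCode == "CL"
  out[isCL] <- ifelse(totalCarbons[isCL] >= matureMinCarbons &
                        totalDoubleBonds[isCL] >= matureMinDoubleBonds,
                      "mature", "nascent")
  out
}

#' Chain-length bucket for free fatty acids and acylcarnitines
#'
#' Buckets are closed-open on the lower edge: with the default breaks,
#' SC covers <= 5 carbons, MC 6-12, LC 13-21, VLC >= 22.
#'
#' @param classCode Character vector of class codes; only \code{FA} and
#'   \code{CAR} are in the bucketing domain.
#' @param totalCarbons Integer vector of total carbons.
#' @param breaks Named lower edges of MC, LC and VLC.
#' @return Character vector in \{SC, MC, LC, VLC\}.
#' @export
chainBucket <- function(classCode, totalCarbons,
                        breaks = c(MC = 6, LC = 13, VLC = 22)) {
  bad <- !classCode %in% c("FA", "CAR")
  if (any(bad))
    tsDomainError("chain buckets are defined for FA/CAR only, got: %s",
                  paste(unique(classCode[bad]), collapse = ", "))
  as.character(cut(totalCarbons,
                   breaks = c(-Inf, breaks, Inf), right = FALSE,
                   labels = c("SC", "MC", "LC", "VLC")))
}

#' Triacylglycerol size class by total acyl carbons
#'
#' DG and MG species use the same total-carbon scale.  Defaults (closed-open):
#' short < 48, medium 48-53, long >= 54.
#'
#' @param classCode Character vector; only \code{TG}, \code{DG}, \code{MG}.
#' @param totalCarbons Integer vector.
#' @param breaks Named lower edges of medium and long.
#' @return Character vector in \{short, medium, long\}.
#' @export
tgSizeClass <- function(classCode, totalCarbons,
                        breaks = c(medium = 48, long = 54)) {
  bad <- !classCode %in% c("TG", "DG", "MG")
  if (any(bad))
    tsDomainError("TG size classes are defined for TG/DG/MG only, got: %s",
                  paste(unique(classCode[bad]), collapse = ", "))
  as.character(cut(totalCarbons,
                   breaks = c(-Inf, breaks, Inf), right = FALSE,
                   labels = c("short", "medium", "long")))
}

.AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
          "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
          "Tyr", "Val")

#' Parse a di-/tri-peptide display name
#'
#' Accepts hyphen-separated three-letter residue codes, two or three residues,
#' case-insensitively (\code{"Val-Tyr-Val"}, \code{"gly-leu"}).  Names that do
#' not have peptide shape return \code{NULL}; a peptide-shaped name with an
#' unknown residue code raises a parse error.
#'
#' @param name A single display string.
#' @return Character vector of canonical residue codes, or \code{NULL}.
#' @export
parsePeptideName <- function(name) {
  s <- trimws(as.character(name))
  if (is.na(s) || !grepl("^[A-Za-z]{3}(-[A-Za-z]{3}){1,2}$", s)) return(NULL)
  toks <- strsplit(s, "-", fixed = TRUE)[[1]]
  idx <- match(tolower(toks), tolower(.AA3))
  if (anyNA(idx)) {
    ## distinguish "unknown residue in a peptide-shaped name" from arbitrary
    ## hyphenated words: require at least one recognised residue
    if (all(is.na(idx))) return(NULL)
    tsParseError("'%s': unknown residue code '%s'", s, toks[which(is.na(idx))[1]])
  }
  .AA3[idx]
}

#' Residue membership matrix for a set of peptide names
#'
#' @param names Character vector of display names.
#' @return Logical matrix, one row per input name, one column per canonical
#'   residue; rows of non-peptide names are all-\code{FALSE}.  Residue
#'   multiplicity is ignored (membership is "contains at least one").
#' @export
peptideResidueMatrix <- function(names) {
  m <- matrix(FALSE, nrow = length(names), ncol = length(.AA3),
              dimnames = list(names, .AA3))
  for (i in seq_along(names)) {
    r <- tryCatch(parsePeptideName(names[i]),
                  thermoshift_parse_error = function(e) NULL)
    if (!is.null(r)) m[i, unique(r)] <- TRUE
  }
  m
}
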