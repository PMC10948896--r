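#' Recognized lipid class tokens
#'
#' Class vocabulary used by [parse_lipid_name()]: free fatty acids (FA),
#' mono-/di-/triglycerides (MG, DG, TG), glycerophospholipids (PC, PE, PI,
#' PS, PA, PG), lyso-lipids (LPA, LPC, LPE, LPI), ceramide (Cer),
#' sphingomyelin (SM), sphingosine (So), cholesterol (Cho) and cholesterol
#' ester (ChE).
#'
#' @return Character vector of class tokens.
#' @export
lipid_classes <- function() {
  c("FA", "MG", "DG", "TG", "PC", "PE", "PI", "PS", "PA", "PG",
    "LPA", "LPC", "LPE", "LPI", "Cer", "SM", "So", "Cho", "ChE")
}

# classes that may appear without a chain descriptor; carbons/double bonds 0
.chainless_classes <- c("Cho", "ChE", "So")

#' Saturation category from double-bond count
#'
#' @param double_bonds Integer vector of total double bonds.
#' @return Character vector: `"SFA"` (0 double bonds), `"MUFA"` (1),
#'   `"PUFA"` (2 or more).
#' @export
saturation_category <- function(double_bonds) {
  stopifnot(is.numeric(double_bonds), all(double_bonds >= 0))
  ifelse(double_bonds == 0, "SFA", ifelse(double_bonds == 1, "MUFA", "PUFA"))
}

#' Parse lipid species names
#'
#' Parses species-level lipid nomenclature into class, total acyl carbons,
#' total double bonds, ether linkage and saturation category. Two dialects
#' are accepted: `"CLASS(C:D)"` (optionally with a `p` suffix marking a
#' plasmalogen, e.g. `"PE(38:5p)"`) and `"CLASS C:D"` (e.g. `"FA 16:1"`).
#' Chain-less classes (`Cho`, `ChE`, `So`) may appear as a bare class token;
#' their carbons and double bonds default to 0.
#'
#' Identification is at the species level: the total carbon and double-bond
#' counts over all acyl chains, with no per-chain decomposition.
#'
#' @param name Character vector of species names.
#' @return A `data.frame` of class `"lipid_species"` with columns `name`,
#'   `lipid_class`, `carbons`, `double_bonds`, `ether` (`"none"` or
#'   `"plasmalogen"`) and `saturation` (`"SFA"`, `"MUFA"`, `"PUFA"`).
#' @examples
#' parse_lipid_name(c("PE(38:5p)", "FA 16:1", "TG(52:0)", "Cho"))
#' @export
parse_lipid_name <- function(name) {
  if (length(name) == 0 || any(is.na(name)) || any(!nzchar(name)))
    stop("lipid names must be non-empty strings")
  one <- function(nm) {
    s <- trimws(nm)
    # paren dialect: CLASS(C:D[suffix])
    m <- regmatches(s, regexec("^([A-Za-z]+)\\(([^)]*)\\)$", s))[[1]]
    if (length(m) == 3) {
      return(.parse_class_chain(nm, m[2], m[3]))
    }
    # spaced dialect: CLASS C:D[suffix]
    m <- regmatches(s, regexec("^([A-Za-z]+)[ ]+(\\S+)$", s))[[1]]
    if (length(m) == 3) {
      return(.parse_class_chain(nm, m[2], m[3]))
    }
    # bare class token (chain-less classes only)
    if (s %in% .chainless_classes) {
      return(list(lipid_class = s, carbons = 0L, double_bonds = 0L,
                  ether = "none"))
    }
    if (s %in% lipid_classes())
      stop(sprintf("lipid name '%s': class '%s' requires a chain descriptor",
                   nm, s))
    stop(sprintf("lipid name '%s': unrecognized class token '%s'", nm, s))
  }
  parts <- lapply(name, one)
  out <- data.frame(
    name = name,
    lipid_class = vapply(parts, `[[`, character(1), "lipid_class"),
    carbons = vapply(parts, `[[`, integer(1), "carbons"),
    double_bonds = vapply(parts, `[[`, integer(1), "double_bonds"),
    ether = vapply(parts, `[[`, character(1), "ether"),
    stringsAsFactors = FALSE
  )
  out$saturation <- saturation_category(out$double_bonds)
  class(out) <- c("lipid_species", "data.frame")
  out
}

.parse_class_chain <- function(nm, cls, chain) {
  if (!cls %in% lipid_classes())
    stop(sprintf("lipid name '%s': unrecognized class token '%s'", nm, cls))
  m <- regmatches(chain, regexec("^([0-9]+):([0-9]+)([A-Za-z]?)$", chain))[[1]]
  if (length(m) != 4)
    stop(sprintf("lipid name '%s': malformed chain descriptor '%s'", nm, chain))
  ether <- "none"
  if (nzchar(m[4])) {
    if (m[4] == "p") ether <- "plasmalogen"
    else stop(sprintf("lipid name '%s': unknown chain suffix '%s'", nm, m[4]))
  }
  list(lipid_class = cls, carbons = as.integer(m[2]),
       double_bonds = as.integer(m[3]), ether = ether)
}

#' Serialize lipid species to canonical names
#'
#' The canonical form is `"CLASS(C:D)"` with a `p` suffix for plasmalogens;
#' chain-less species (carbons 0 on a chain-less class) serialize to the bare
#' class token. Parsing a canonical name and re-serializing it is the
#' identity.
#'
#' @param species A `"lipid_species"` data frame from [parse_lipid_name()].
#' @return Character vector of canonical names.
#' @export
format_lipid_name <- function(species) {
  stopifnot(inherits(species, "lipid_species") || is.data.frame(species))
  suffix <- ifelse(species$ether == "plasmalogen", "p", "")
  bare <- species$lipid_class %in% .chainless_classes &
    species$carbons == 0 & species$double_bonds == 0
  ifelse(bare, species$lipid_class,
         sprintf("%s(%d:%d%s)", species$lipid_class, species$carbons,
                 species$double_bonds, suffix))
}
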