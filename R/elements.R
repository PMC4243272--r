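## Element reference data used across bond perception, formula arithmetic
## and metal-coordination detection.

# Single-bond covalent radii (Angstrom), Cordero-style consensus values.
.COVALENT_RADII <- c(
  H = 0.31, D = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  NA_ = 1.66, MG = 1.41, AL = 1.21, SI = 1.11, P = 1.07, S = 1.05, CL = 1.02,
  K = 2.03, CA = 1.76, MN = 1.39, FE = 1.32, CO = 1.26, NI = 1.24,
  CU = 1.32, ZN = 1.22, SE = 1.20, BR = 1.20, MO = 1.54, I = 1.39,
  W = 1.62, HG = 1.32, CD = 1.44, AS = 1.19, LI = 1.28
)

# Standard atomic masses (g/mol) for formula-weight computation.
.ATOMIC_MASSES <- c(
  H = 1.008, D = 2.014, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, NA_ = 22.990, MG = 24.305, AL = 26.982, SI = 28.086,
  P = 30.974, S = 32.06, CL = 35.45, K = 39.098, CA = 40.078, MN = 54.938,
  FE = 55.845, CO = 58.933, NI = 58.693, CU = 63.546, ZN = 65.38,
  SE = 78.971, BR = 79.904, MO = 95.95, I = 126.904, W = 183.84,
  HG = 200.592, CD = 112.414, AS = 74.922, LI = 6.94
)

# Metals supported as coordination centres.
.COORDINATION_METALS <- c("ZN", "MG", "CA", "FE", "MN", "NA", "K",
                          "CU", "NI", "CO", "CD", "HG", "LI")

# Donor atoms considered as metal ligators: N/O/S plus halides.
.METAL_DONORS <- c("N", "O", "S", "SE", "F", "CL", "BR", "I")

# Metal-donor distance cutoffs (Angstrom) by element pair; fall-through
# default 3.0. Alkali metals coordinate at longer range.
.METAL_CUTOFFS <- list(
  "ZN|N" = 2.6, "ZN|O" = 2.6, "ZN|S" = 2.8,
  "MG|O" = 2.6, "MG|N" = 2.6,
  "CA|O" = 2.9,
  "NA|O" = 3.2, "K|O" = 3.2, "LI|O" = 2.6,
  "FE|N" = 2.6, "FE|O" = 2.6, "FE|S" = 2.8,
  "MN|O" = 2.6, "MN|N" = 2.6,
  "CU|N" = 2.6, "CU|O" = 2.6, "CU|S" = 2.8,
  "NI|N" = 2.6, "NI|O" = 2.6,
  "CO|N" = 2.6, "CO|O" = 2.6
)
.METAL_CUTOFF_DEFAULT <- 3.0

# Water component ids; waters are never ligands of interest.
.WATER_IDS <- c("HOH", "DOD", "WAT", "H2O")

# Standard polymeric residues: the 20 amino acids plus RNA/DNA nucleotides.
.STANDARD_AMINO_ACIDS <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)
.STANDARD_NUCLEOTIDES <- c("A", "C", "G", "U", "DA", "DC", "DG", "DT", "DU")
.STANDARD_RESIDUES <- c(.STANDARD_AMINO_ACIDS, .STANDARD_NUCLEOTIDES)

.normElement <- function(element) {
  el <- toupper(trimws(element))
  el[el == "NA"] <- "NA_"   # avoid clash with R's NA when indexing by name
  el
}

#' Covalent radius lookup
#'
#' Returns the single-bond covalent radius for each element symbol.
#' Unknown elements are an error: silent fallbacks would corrupt bond
#' perception.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of radii in Angstrom.
#' @export
covalentRadius <- function(element) {
  el <- .normElement(element)
  r <- .COVALENT_RADII[el]
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  }
  unname(r)
}

.atomicMass <- function(element) {
  el <- .normElement(element)
  m <- .ATOMIC_MASSES[el]
  if (anyNA(m)) {
    stop("no atomic mass for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

.isKnownElement <- function(element) {
  .normElement(element) %in% names(.COVALENT_RADII)
}

.isWater <- function(compId) toupper(compId) %in% .WATER_IDS

.isStandardResidue <- function(compId) toupper(compId) %in% .STANDARD_RESIDUES

.metalCutoff <- function(metal, donor, cutoffs = NULL) {
  key <- paste(toupper(metal), toupper(donor), sep = "|")
  if (!is.null(cutoffs) && key %in% names(cutoffs)) return(cutoffs[[key]])
  if (key %in% names(.METAL_CUTOFFS)) return(.METAL_CUTOFFS[[key]])
  if (!is.null(cutoffs) && "default" %in% names(cutoffs)) return(cutoffs[["default"]])
  .METAL_CUTOFF_DEFAULT
}

#' Hill-order chemical formula from element counts
#'
#' Carbon first, then hydrogen, then all other elements alphabetically;
#' when no carbon is present all elements are alphabetical.
#'
#' @param elements character vector, one entry per atom.
#' @return single formula string such as \code{"C6 H12 O6"}.
#' @export
hillFormula <- function(elements) {
  if (length(elements) == 0L) return("")
  el <- toupper(trimws(elements))
  counts <- table(el)
  nm <- names(counts)
  if ("C" %in% nm) {
    ord <- c("C", if ("H" %in% nm) "H", sort(setdiff(nm, c("C", "H"))))
  } else {
    ord <- sort(nm)
  }
  paste(vapply(ord, function(e) {
    n <- counts[[e]]
    sym <- paste0(substr(e, 1, 1), tolower(substr(e, 2, nchar(e))))
    if (n == 1L) sym else paste0(sym, n)
  }, character(1)), collapse = " ")
}

.parseFormula <- function(formula) {
  ## "C6 H12 O6" (or "C6H12O6") -> named integer counts, names uppercase
  if (is.na(formula) || !nzchar(trimws(formula))) return(integer(0))
  m <- gregexpr("([A-Za-z]{1,2})([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  counts <- integer(0)
  for (tok in toks) {
    sym <- toupper(gsub("[0-9]", "", tok))
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  counts
}
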