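## Central S4 classes. Validity here checks structural integrity (slot
## shapes, required columns); the scientific invariants of a dictionary
## definition are checked by validateDef(), which reports issues rather
## than refusing to construct an object -- curators need to hold invalid
## definitions in hand to inspect them.

.ATOM_COLS <- c("atomId", "element", "charge", "aromatic", "stereoConfig",
                "leaving", "idealX", "idealY", "idealZ",
                "modelX", "modelY", "modelZ")
.BOND_COLS <- c("atomId1", "atomId2", "order", "aromatic", "stereo")
.DESC_COLS <- c("descType", "program", "value")

.SITE_COLS <- c("serial", "atomName", "altLoc", "compId", "authChain",
                "authSeq", "insCode", "labelChain", "x", "y", "z",
                "occupancy", "bFactor", "element", "modelNum", "isHet",
                "groupId")

.CONTACT_COLS <- c("compId", "authChain", "authSeq", "insCode",
                   "symLabel", "minDistance")

.emptyAtoms <- function() {
  data.frame(atomId = character(0), element = character(0),
             charge = integer(0), aromatic = logical(0),
             stereoConfig = character(0), leaving = logical(0),
             idealX = numeric(0), idealY = numeric(0), idealZ = numeric(0),
             modelX = numeric(0), modelY = numeric(0), modelZ = numeric(0),
             stringsAsFactors = FALSE)
}

.emptyBonds <- function() {
  data.frame(atomId1 = character(0), atomId2 = character(0),
             order = character(0), aromatic = logical(0),
             stereo = character(0), stringsAsFactors = FALSE)
}

.emptyDescriptors <- function() {
  data.frame(descType = character(0), program = character(0),
             value = character(0), stringsAsFactors = FALSE)
}

.emptyAtomSites <- function() {
  data.frame(serial = integer(0), atomName = character(0),
             altLoc = character(0), compId = character(0),
             authChain = character(0), authSeq = integer(0),
             insCode = character(0), labelChain = character(0),
             x = numeric(0), y = numeric(0), z = numeric(0),
             occupancy = numeric(0), bFactor = numeric(0),
             element = character(0), modelNum = integer(0),
             isHet = logical(0), groupId = character(0),
             stringsAsFactors = FALSE)
}

.emptyContacts <- function() {
  data.frame(compId = character(0), authChain = character(0),
             authSeq = integer(0), insCode = character(0),
             symLabel = character(0), minDistance = numeric(0),
             stringsAsFactors = FALSE)
}

#' ChemCompDef: one chemical component dictionary definition
#'
#' Holds the identity, atom table (with leaving-atom flags and both ideal
#' and example model coordinates), bond table with orders, and opaque
#' chemical descriptors for one dictionary component. Atom and bond rows
#' keep their input order so that writing is byte-stable.
#'
#' @slot compId component identifier (1-3 alphanumeric characters, upper case).
#' @slot name systematic or common name.
#' @slot synonyms character vector of alternative names.
#' @slot formula Hill-order formula string.
#' @slot formulaWeight molecular weight, g/mol.
#' @slot formalCharge net formal charge.
#' @slot compType controlled type string, e.g. "L-peptide linking".
#' @slot pdbxType controlled class string, e.g. "ATOMP".
#' @slot parentCompIds parent component ids (possibly empty).
#' @slot atoms data.frame of atom definitions; absent coordinates are NA,
#'   never zero.
#' @slot bonds data.frame of bonds (order in SING/DOUB/TRIP/AROM).
#' @slot descriptors data.frame of opaque descriptor strings.
#' @slot extraCategories unrecognised CIF categories, preserved for round-trip.
#' @export
setClass("ChemCompDef",
  representation(compId = "character", name = "character",
                 synonyms = "character", formula = "character",
                 formulaWeight = "numeric", formalCharge = "integer",
                 compType = "character", pdbxType = "character",
                 parentCompIds = "character", atoms = "data.frame",
                 bonds = "data.frame", descriptors = "data.frame",
                 extraCategories = "list"),
  prototype(compId = NA_character_, name = NA_character_,
            synonyms = character(0), formula = NA_character_,
            formulaWeight = NA_real_, formalCharge = 0L,
            compType = NA_character_, pdbxType = NA_character_,
            parentCompIds = character(0), atoms = .emptyAtoms(),
            bonds = .emptyBonds(), descriptors = .emptyDescriptors(),
            extraCategories = list()))

setValidity("ChemCompDef", function(object) {
  msg <- character(0)
  if (length(object@compId) != 1L) msg <- c(msg, "compId must be length 1")
  if (!all(.ATOM_COLS %in% names(object@atoms)))
    msg <- c(msg, "atoms table lacks required columns")
  if (!all(.BOND_COLS %in% names(object@bonds)))
    msg <- c(msg, "bonds table lacks required columns")
  if (!all(.DESC_COLS %in% names(object@descriptors)))
    msg <- c(msg, "descriptors table lacks required columns")
  if (length(msg)) msg else TRUE
})

#' CrystalCell: unit cell plus space-group operators
#'
#' @slot a,b,c cell edges, Angstrom.
#' @slot alpha,beta,gamma cell angles, degrees.
#' @slot spaceGroup Hermann-Mauguin symbol.
#' @slot operators list of symmetry operators, each
#'   \code{list(rot = 3x3 matrix, trans = length-3 fractional vector,
#'   opIndex = integer)}; the identity is always present.
#' @export
setClass("CrystalCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric",
                 spaceGroup = "character", operators = "list"))

setValidity("CrystalCell", function(object) {
  msg <- character(0)
  len <- c(object@a, object@b, object@c)
  ang <- c(object@alpha, object@beta, object@gamma)
  if (any(!is.finite(len)) || any(len <= 0)) msg <- c(msg, "cell edges must be > 0")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    msg <- c(msg, "cell angles must lie in (0, 180)")
  if (!length(object@operators)) msg <- c(msg, "operator list must be nonempty")
  hasId <- FALSE
  for (op in object@operators) {
    d <- round(det(op$rot))
    if (abs(d) != 1) msg <- c(msg, "operator rotation determinant must be +/-1")
    if (all(op$rot == diag(3)) && all(op$trans %% 1 == 0)) hasId <- TRUE
  }
  if (!hasId) msg <- c(msg, "operator list must contain the identity")
  if (length(msg)) unique(msg) else TRUE
})

setClassUnion("CrystalCellOrNULL", c("CrystalCell", "NULL"))

#' StructureModel: atom sites, components and crystal symmetry
#'
#' The substrate for all annotation operations: a flat atom-site table in
#' orthogonal Angstrom coordinates (author addressing is the public scheme),
#' with the crystallographic cell and space-group operators when the input
#' declared them. Observed components (residues, ligands, waters) are
#' derived from the table via [modelComponents()].
#'
#' @slot atomSites data.frame, one row per atom site of the loaded model.
#' @slot cell a [CrystalCell-class] or NULL when the input had no cell.
#' @slot title optional title string.
#' @export
setClass("StructureModel",
  representation(atomSites = "data.frame", cell = "CrystalCellOrNULL",
                 title = "character"),
  prototype(atomSites = .emptyAtomSites(), cell = NULL, title = NA_character_))

setValidity("StructureModel", function(object) {
  if (!all(.SITE_COLS %in% names(object@atomSites)))
    return("atomSites lacks required columns")
  occ <- object@atomSites$occupancy
  if (length(occ) && any(!is.na(occ) & (occ < 0 | occ > 1)))
    return("occupancy must lie in [0, 1]")
  TRUE
})

#' ComponentMatch: observed component identified against a dictionary entry
#'
#' @slot compId matched dictionary component id.
#' @slot atomMap named character vector: observed atom name -> dictionary
#'   atom id; injective, element-consistent.
#' @slot missingAtoms data.frame(atomId, kind) of dictionary atoms with no
#'   observed partner; kind is one of leaving/hydrogen/other.
#' @slot extraAtoms observed atom names left unmapped.
#' @slot rmsdAfterFit RMSD (Angstrom) over mapped atoms after least-squares
#'   superposition onto the dictionary coordinates.
#' @slot exact TRUE when there are no missing "other" atoms and no extras.
#' @export
setClass("ComponentMatch",
  representation(compId = "character", atomMap = "character",
                 missingAtoms = "data.frame", extraAtoms = "character",
                 rmsdAfterFit = "numeric", exact = "logical"))

setValidity("ComponentMatch", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@atomMap)) msg <- c(msg, "atomMap must be injective")
  if (anyDuplicated(names(object@atomMap)))
    msg <- c(msg, "atomMap keys must be unique")
  if (length(msg)) msg else TRUE
})

#' BindingSite: one ligand's symmetry-qualified contact environment
#'
#' @slot siteId alphanumeric identifier (AC1 ... ZZ9 scheme).
#' @slot ligand data.frame of the ligand's component keys
#'   (compId, authChain, authSeq, insCode); several rows for grouped
#'   multi-component molecules such as oligosaccharides.
#' @slot evidence provenance string, "Software" for computed sites.
#' @slot contacts data.frame of residue-level contacts with symmetry label
#'   and minimum atom-atom distance.
#' @slot details author-provided catalytic-site text or NA.
#' @export
setClass("BindingSite",
  representation(siteId = "character", ligand = "data.frame",
                 evidence = "character", contacts = "data.frame",
                 details = "character"),
  prototype(evidence = "Software", details = NA_character_,
            contacts = .emptyContacts()))

setValidity("BindingSite", function(object) {
  if (!all(.CONTACT_COLS %in% names(object@contacts)))
    return("contacts lacks required columns")
  TRUE
})

#' CoordinationCenter: a metal with its ligators and all pairwise angles
#'
#' @slot metal one-row data.frame locating the metal atom.
#' @slot ligators data.frame of donor atoms (N/O/S/halide) within the
#'   element-pair cutoff, one row per altloc-resolved donor, with symmetry
#'   label and distance.
#' @slot angles data.frame with one row per unordered ligator pair and the
#'   angle (degrees) subtended at the metal: k ligators give k(k-1)/2 rows.
#' @export
setClass("CoordinationCenter",
  representation(metal = "data.frame", ligators = "data.frame",
                 angles = "data.frame"))

setValidity("CoordinationCenter", function(object) {
  k <- nrow(object@ligators)
  if (nrow(object@angles) != k * (k - 1L) / 2L)
    return("angles must have exactly k(k-1)/2 rows")
  if (nrow(object@angles) &&
      any(object@angles$degrees <= 0 | object@angles$degrees > 180 + 1e-9))
    return("angles must lie in (0, 180]")
  TRUE
})

#' PeptideClassification: BIRD representation category for a molecule
#'
#' @slot category POLYMER, NONPOLYMER_SUBCOMPONENTS or GROUP.
#' @slot maxConsecutivePeptideBonds longest run of consecutive peptide bonds.
#' @slot subcomponentSequence comp ids ordered amino- to carboxy-terminal
#'   (the peptide core for GROUP molecules).
#' @slot nonpeptideAttachments comp ids of saccharide/lipid subcomponents
#'   attached to the peptide core.
#' @export
setClass("PeptideClassification",
  representation(category = "character",
                 maxConsecutivePeptideBonds = "integer",
                 subcomponentSequence = "character",
                 nonpeptideAttachments = "character"))

setValidity("PeptideClassification", function(object) {
  ok <- c("POLYMER", "NONPOLYMER_SUBCOMPONENTS", "GROUP")
  if (!(object@category %in% ok))
    return(paste("category must be one of", paste(ok, collapse = "/")))
  if (object@category == "GROUP" && !length(object@nonpeptideAttachments))
    return("GROUP requires nonpeptide attachments")
  if (object@category != "GROUP" && length(object@nonpeptideAttachments))
    return("nonpeptide attachments imply GROUP")
  TRUE
})

#' PrdEntry: chemical reference description of one peptide-like molecule
#'
#' @slot prdId identifier matching \code{PRD_} followed by six digits.
#' @slot name molecule name.
#' @slot compositionChains list of character vectors: subcomponent comp ids
#'   per chain, N- to C-terminal.
#' @slot linkages data.frame of inter-subcomponent bonds.
#' @slot structuralClass e.g. glycopeptide, anthracycline, lipopeptide.
#' @slot functionText e.g. immunosuppressant, thrombin inhibitor.
#' @slot sourceRefs opaque cross-reference accessions.
#' @slot extraCategories unrecognised CIF categories, preserved.
#' @export
setClass("PrdEntry",
  representation(prdId = "character", name = "character",
                 compositionChains = "list", linkages = "data.frame",
                 structuralClass = "character", functionText = "character",
                 sourceRefs = "character", extraCategories = "list"),
  prototype(name = NA_character_, structuralClass = NA_character_,
            functionText = NA_character_, sourceRefs = character(0),
            extraCategories = list()))

setValidity("PrdEntry", function(object) {
  if (!grepl("^PRD_[0-9]{6}$", object@prdId))
    return("prdId must match PRD_ followed by 6 digits")
  TRUE
})

#' PrdFamily: a family of chemically similar peptide-like molecules
#'
#' @slot famId identifier matching \code{FAM_} followed by six digits.
#' @slot memberPrdIds PRD ids of the members (nonempty).
#' @slot functionText,mechanism,pharmacology biological annotation strings.
#' @export
setClass("PrdFamily",
  representation(famId = "character", memberPrdIds = "character",
                 functionText = "character", mechanism = "character",
                 pharmacology = "character"),
  prototype(functionText = NA_character_, mechanism = NA_character_,
            pharmacology = NA_character_))

setValidity("PrdFamily", function(object) {
  msg <- character(0)
  if (!grepl("^FAM_[0-9]{6}$", object@famId))
    msg <- c(msg, "famId must match FAM_ followed by 6 digits")
  if (!length(object@memberPrdIds)) msg <- c(msg, "members must be nonempty")
  if (length(msg)) msg else TRUE
})

#' LldfResult: local ligand density fit for one ligand
#'
#' @slot ligand data.frame of the ligand's component keys.
#' @slot ligandRsr the ligand's real-space R-value.
#' @slot neighbors data.frame of the polymeric standard residues within the
#'   cutoff that carried RSR values.
#' @slot nNeighbors,meanRsr,sdRsr neighbour statistics (sample sd, n-1).
#' @slot lldf the Z-score (ligandRsr - meanRsr) / sdRsr.
#' @slot flagged TRUE iff lldf > 2.
#' @export
setClass("LldfResult",
  representation(ligand = "data.frame", ligandRsr = "numeric",
                 neighbors = "data.frame", nNeighbors = "integer",
                 meanRsr = "numeric", sdRsr = "numeric",
                 lldf = "numeric", flagged = "logical"))

setValidity("LldfResult", function(object) {
  if (is.finite(object@lldf) && !identical(object@flagged, object@lldf > 2))
    return("flagged must equal (lldf > 2)")
  TRUE
})

#' GeometryReport: deviations of an observed ligand from dictionary geometry
#'
#' @slot bonds data.frame(atomId1, atomId2, ideal, observed, deviation) in
#'   Angstrom for every dictionary bond with both atoms observed.
#' @slot angles data.frame of bond-angle deviations in degrees.
#' @slot chiralityFlips atom ids of chiral centres with inverted handedness.
#' @slot rmsZBonds,rmsZAngles root-mean-square Z with fixed sigma
#'   (0.02 Angstrom for bonds, 2 degrees for angles).
#' @slot notice limitations of the report (e.g. missing ideal coordinates).
#' @export
setClass("GeometryReport",
  representation(bonds = "data.frame", angles = "data.frame",
                 chiralityFlips = "character", rmsZBonds = "numeric",
                 rmsZAngles = "numeric", notice = "character"),
  prototype(notice = NA_character_))
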