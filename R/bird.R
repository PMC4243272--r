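## BIRD representation rules for peptide-like inhibitors and antibiotics:
## peptide-bond detection between subcomponents, consecutive-bond
## counting, polymer / non-polymer-with-subcomponents / group
## classification, and PRD/FAM reference-dictionary file handling.

#' Assemble a peptide-like molecule description
#'
#' A molecule is a set of CCD-identified subcomponents plus the
#' inter-subcomponent linkages joining them; classification is a pure
#' function of this topology (coordinates, atom order and chain naming do
#' not enter).
#'
#' @param subcomponents data.frame with columns \code{key} (unique
#'   subcomponent key) and \code{compId} (dictionary id).
#' @param linkages data.frame with columns \code{key1, atom1, key2, atom2}:
#'   one row per inter-subcomponent bond.
#' @return list of class \code{"birdMolecule"}.
#' @export
birdMolecule <- function(subcomponents, linkages) {
  stopifnot(all(c("key", "compId") %in% names(subcomponents)),
            all(c("key1", "atom1", "key2", "atom2") %in% names(linkages)))
  if (anyDuplicated(subcomponents$key))
    stop("subcomponent keys must be unique")
  bad <- setdiff(c(linkages$key1, linkages$key2), subcomponents$key)
  if (length(bad))
    stop("linkage references unknown subcomponent(s): ",
         paste(unique(bad), collapse = ", "))
  structure(list(subcomponents = subcomponents, linkages = linkages),
            class = "birdMolecule")
}

## does atom `atomId` of definition `def` carry a carbonyl oxygen?
.hasCarbonylO <- function(def, atomId) {
  b <- def@bonds; a <- def@atoms
  part <- b[(b$atomId1 == atomId | b$atomId2 == atomId) &
              b$order %in% c("DOUB", "AROM"), , drop = FALSE]
  if (!nrow(part)) return(FALSE)
  other <- ifelse(part$atomId1 == atomId, part$atomId2, part$atomId1)
  any(a$element[match(other, a$atomId)] == "O")
}

## is atom `atomId` bonded to at least one carbon within its definition?
.bondedToCarbon <- function(def, atomId) {
  b <- def@bonds; a <- def@atoms
  part <- b[b$atomId1 == atomId | b$atomId2 == atomId, , drop = FALSE]
  if (!nrow(part)) return(FALSE)
  other <- ifelse(part$atomId1 == atomId, part$atomId2, part$atomId1)
  any(a$element[match(other, a$atomId)] == "C")
}

#' Detect peptide bonds between subcomponents
#'
#' A peptide bond is an inter-subcomponent C-N bond whose carbon carries a
#' double-bonded oxygen (a carbonyl) within its own subcomponent and whose
#' nitrogen is bonded to at least one carbon of the downstream
#' subcomponent. Bonds are directed C to N, which is the amino- to
#' carboxy-terminal chain direction read residue-by-residue. Ester-linked
#' depsipeptide junctions (C-O-C) fail the nitrogen criterion and are not
#' peptide bonds.
#'
#' @param molecule a [birdMolecule()].
#' @param dictionary named list of [ChemCompDef-class] covering every
#'   subcomponent comp id.
#' @return data.frame(fromKey, toKey, atomC, atomN), one row per peptide
#'   bond, directed from the carbonyl-bearing subcomponent to the
#'   nitrogen-bearing one.
#' @export
detectPeptideBonds <- function(molecule, dictionary) {
  sub <- molecule$subcomponents
  lk <- molecule$linkages
  defFor <- function(key) {
    cid <- sub$compId[sub$key == key]
    def <- dictionary[[cid]]
    if (is.null(def)) stop("no dictionary definition for ", cid)
    def
  }
  out <- data.frame(fromKey = character(0), toKey = character(0),
                    atomC = character(0), atomN = character(0),
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(lk))) {
    for (dir in 1:2) {
      kC <- if (dir == 1) lk$key1[r] else lk$key2[r]
      kN <- if (dir == 1) lk$key2[r] else lk$key1[r]
      aC <- if (dir == 1) lk$atom1[r] else lk$atom2[r]
      aN <- if (dir == 1) lk$atom2[r] else lk$atom1[r]
      defC <- defFor(kC); defN <- defFor(kN)
      elC <- defC@atoms$element[match(aC, defC@atoms$atomId)]
      elN <- defN@atoms$element[match(aN, defN@atoms$atomId)]
      if (is.na(elC) || is.na(elN) || elC != "C" || elN != "N") next
      if (!.hasCarbonylO(defC, aC)) next
      if (!.bondedToCarbon(defN, aN)) next
      out <- rbind(out, data.frame(fromKey = kC, toKey = kN,
                                   atomC = aC, atomN = aN,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Longest run of consecutive peptide bonds
#'
#' Length (in bonds) of the longest path of directed peptide bonds through
#' consecutive subcomponents; branch points contribute their longest
#' branch, and cycles are traversed as simple paths.
#'
#' @param peptideBonds data.frame from [detectPeptideBonds()].
#' @return integer >= 0.
#' @export
maxConsecutivePeptideBonds <- function(peptideBonds) {
  if (!nrow(peptideBonds)) return(0L)
  edges <- unique(peptideBonds[, c("fromKey", "toKey")])
  verts <- unique(c(edges$fromKey, edges$toKey))
  adj <- split(edges$toKey, factor(edges$fromKey, levels = verts))
  best <- 0L
  walk <- function(v, visited, len) {
    best <<- max(best, len)
    for (w in adj[[v]]) {
      if (!(w %in% visited)) walk(w, c(visited, w), len + 1L)
    }
  }
  for (v in verts) walk(v, v, 0L)
  best
}

.peptideSequence <- function(molecule, peptideBonds) {
  ## N->C order along the longest peptide path; ties and cyclic molecules
  ## resolved by the canonical start (lowest comp id, then key order)
  sub <- molecule$subcomponents
  if (!nrow(peptideBonds)) return(character(0))
  edges <- unique(peptideBonds[, c("fromKey", "toKey")])
  verts <- unique(c(edges$fromKey, edges$toKey))
  adj <- split(edges$toKey, factor(edges$fromKey, levels = verts))
  bestPath <- character(0)
  walk <- function(v, visited) {
    if (length(visited) > length(bestPath)) bestPath <<- visited
    for (w in adj[[v]]) if (!(w %in% visited)) walk(w, c(visited, w))
  }
  hasIncoming <- verts %in% edges$toKey
  starts <- verts[!hasIncoming]
  if (!length(starts)) {
    # cyclic: deterministic canonical rotation
    cid <- sub$compId[match(verts, sub$key)]
    starts <- verts[order(cid, verts)][1]
  }
  for (v in starts) walk(v, v)
  bestPath
}

#' Classify a peptide-like molecule for BIRD representation
#'
#' Applies the representation rules in order: if saccharide or lipid
#' subcomponents are covalently attached to the peptide core, the molecule
#' is represented as a GROUP of its polymeric and non-polymeric
#' constituents; otherwise two or more consecutive peptide bonds make it a
#' standard POLYMER; otherwise it is a non-polymer with an identifiable
#' subcomponent sequence running from the amino (N) to the carboxy (C)
#' terminus. (Group precedence is deliberate: a glycopeptide core alone
#' would qualify as a polymer, yet the attachments force group
#' representation.)
#'
#' @param molecule a [birdMolecule()].
#' @param dictionary named list of [ChemCompDef-class].
#' @return a [PeptideClassification-class].
#' @export
classifyPeptideLike <- function(molecule, dictionary) {
  sub <- molecule$subcomponents
  bonds <- detectPeptideBonds(molecule, dictionary)
  mx <- maxConsecutivePeptideBonds(bonds)
  typeOf <- function(cid) {
    def <- dictionary[[cid]]
    if (is.null(def)) stop("no dictionary definition for ", cid)
    tolower(paste(def@compType, def@pdbxType))
  }
  types <- vapply(sub$compId, typeOf, character(1))
  isAttachment <- grepl("saccharide|lipid", types)
  # an attachment must actually be bonded to the rest of the molecule
  linked <- unique(c(molecule$linkages$key1, molecule$linkages$key2))
  attachments <- sub$compId[isAttachment & sub$key %in% linked]
  seqKeys <- .peptideSequence(molecule, bonds)
  coreSeq <- sub$compId[match(seqKeys, sub$key)]
  if (length(attachments)) {
    new("PeptideClassification", category = "GROUP",
        maxConsecutivePeptideBonds = mx,
        subcomponentSequence = coreSeq,
        nonpeptideAttachments = unique(attachments))
  } else if (mx >= 2L) {
    new("PeptideClassification", category = "POLYMER",
        maxConsecutivePeptideBonds = mx,
        subcomponentSequence = character(0),
        nonpeptideAttachments = character(0))
  } else {
    # sequence: peptide path first, then any remaining subcomponents in
    # key order (e.g. a non-peptide warhead)
    rest <- setdiff(sub$key, seqKeys)
    seqAll <- sub$compId[match(c(seqKeys, sort(rest)), sub$key)]
    new("PeptideClassification", category = "NONPOLYMER_SUBCOMPONENTS",
        maxConsecutivePeptideBonds = mx,
        subcomponentSequence = seqAll,
        nonpeptideAttachments = character(0))
  }
}

.PRD_CATS <- c("pdbx_reference_molecule", "pdbx_reference_entity_poly_seq",
               "pdbx_reference_entity_link")

#' Read and write PRD reference entries
#'
#' The PRD dialect is implemented minimally -- identity, composition
#' chains, inter-subcomponent linkages, structural class and function --
#' with unknown categories passed through verbatim so documents
#' round-trip.
#'
#' @param text PRD CIF text.
#' @return [PrdEntry-class] for \code{parsePrd}; CIF text for
#'   \code{writePrd}.
#' @export
parsePrd <- function(text) {
  block <- parseCif(text)[[1]]
  rm_ <- .getCat(block, "pdbx_reference_molecule")
  prdId <- .catChr(rm_, "prd_id")[1]
  if (is.na(prdId) || !grepl("^PRD_[0-9]{6}$", prdId))
    stop("malformed or missing PRD identifier: ", prdId)
  seqCat <- .getCat(block, "pdbx_reference_entity_poly_seq")
  chains <- list()
  if (!is.null(seqCat) && nrow(seqCat)) {
    ord <- order(seqCat$ref_entity_id, as.integer(seqCat$num))
    seqCat <- seqCat[ord, , drop = FALSE]
    chains <- split(seqCat$mon_id, seqCat$ref_entity_id)
    chains <- lapply(chains, as.character)
  }
  lkCat <- .getCat(block, "pdbx_reference_entity_link")
  linkDf <- if (!is.null(lkCat) && nrow(lkCat)) data.frame(
    entity1 = lkCat$ref_entity_id_1, seq1 = as.integer(lkCat$entity_seq_num_1),
    compId1 = lkCat$comp_id_1, atom1 = lkCat$atom_id_1,
    entity2 = lkCat$ref_entity_id_2, seq2 = as.integer(lkCat$entity_seq_num_2),
    compId2 = lkCat$comp_id_2, atom2 = lkCat$atom_id_2,
    stringsAsFactors = FALSE)
  else data.frame(entity1 = character(0), seq1 = integer(0),
                  compId1 = character(0), atom1 = character(0),
                  entity2 = character(0), seq2 = integer(0),
                  compId2 = character(0), atom2 = character(0),
                  stringsAsFactors = FALSE)
  src <- .catChr(rm_, "source")[1]
  new("PrdEntry", prdId = prdId, name = .catChr(rm_, "name")[1],
      compositionChains = chains, linkages = linkDf,
      structuralClass = .catChr(rm_, "class")[1],
      functionText = .catChr(rm_, "function")[1],
      sourceRefs = if (is.na(src)) character(0) else
        trimws(strsplit(src, ";", fixed = TRUE)[[1]]),
      extraCategories = block$categories[setdiff(names(block$categories),
                                                 .PRD_CATS)])
}

#' @rdname parsePrd
#' @param entry a [PrdEntry-class].
#' @export
writePrd <- function(entry) {
  validObject(entry)
  cats <- list()
  cats[["pdbx_reference_molecule"]] <- structure(data.frame(
    prd_id = entry@prdId, name = entry@name,
    class = entry@structuralClass, "function" = entry@functionText,
    source = if (length(entry@sourceRefs))
      paste(entry@sourceRefs, collapse = "; ") else NA_character_,
    check.names = FALSE, stringsAsFactors = FALSE), loop = FALSE)
  if (length(entry@compositionChains)) {
    rows <- do.call(rbind, lapply(names(entry@compositionChains), function(ch) {
      mon <- entry@compositionChains[[ch]]
      data.frame(prd_id = entry@prdId, ref_entity_id = ch,
                 num = as.character(seq_along(mon)), mon_id = mon,
                 stringsAsFactors = FALSE)
    }))
    cats[["pdbx_reference_entity_poly_seq"]] <- structure(rows, loop = TRUE)
  }
  if (nrow(entry@linkages)) {
    lk <- entry@linkages
    cats[["pdbx_reference_entity_link"]] <- structure(data.frame(
      link_id = as.character(seq_len(nrow(lk))),
      ref_entity_id_1 = lk$entity1, entity_seq_num_1 = as.character(lk$seq1),
      comp_id_1 = lk$compId1, atom_id_1 = lk$atom1,
      ref_entity_id_2 = lk$entity2, entity_seq_num_2 = as.character(lk$seq2),
      comp_id_2 = lk$compId2, atom_id_2 = lk$atom2,
      stringsAsFactors = FALSE), loop = TRUE)
  }
  cats <- c(cats, entry@extraCategories)
  writeCif(list(list(name = entry@prdId, categories = cats)))
}

#' Read and write FAM family files
#'
#' A family groups chemically similar peptide-like molecules (e.g. the
#' glycopeptide antibiotics) and carries the shared biological
#' annotation: function, mechanism of action, pharmacological action, and
#' the member PRD ids.
#'
#' @param text FAM CIF text.
#' @return [PrdFamily-class] for \code{parseFam}; CIF text for
#'   \code{writeFam}.
#' @export
parseFam <- function(text) {
  block <- parseCif(text)[[1]]
  fm <- .getCat(block, "pdbx_reference_molecule_family")
  famId <- .catChr(fm, "family_prd_id")[1]
  if (is.na(famId) || !grepl("^FAM_[0-9]{6}$", famId))
    stop("malformed or missing FAM identifier: ", famId)
  ml <- .getCat(block, "pdbx_reference_molecule_list")
  members <- if (!is.null(ml)) as.character(ml$prd_id) else character(0)
  new("PrdFamily", famId = famId, memberPrdIds = members,
      functionText = .catChr(fm, "function")[1],
      mechanism = .catChr(fm, "mechanism_of_action")[1],
      pharmacology = .catChr(fm, "pharmacology")[1])
}

#' @rdname parseFam
#' @param family a [PrdFamily-class].
#' @export
writeFam <- function(family) {
  validObject(family)
  cats <- list(
    pdbx_reference_molecule_family = structure(data.frame(
      family_prd_id = family@famId,
      "function" = family@functionText,
      mechanism_of_action = family@mechanism,
      pharmacology = family@pharmacology,
      check.names = FALSE, stringsAsFactors = FALSE), loop = FALSE),
    pdbx_reference_molecule_list = structure(data.frame(
      family_prd_id = family@famId, prd_id = family@memberPrdIds,
      stringsAsFactors = FALSE), loop = TRUE))
  writeCif(list(list(name = family@famId, categories = cats)))
}

#' Validate family membership against loaded PRD entries
#'
#' @param family a [PrdFamily-class].
#' @param prdIds character vector of known PRD identifiers.
#' @return data.frame of issues (code, message); empty when every member
#'   resolves.
#' @export
validateFamily <- function(family, prdIds) {
  unknown <- setdiff(family@memberPrdIds, prdIds)
  if (!length(unknown))
    return(data.frame(code = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  data.frame(code = "member-unknown",
             message = sprintf("family %s lists unknown member %s",
                               family@famId, unknown),
             stringsAsFactors = FALSE)
}
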