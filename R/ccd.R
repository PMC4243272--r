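## Chemical component dictionary (CCD) reader, writer, validator and
## molecular-graph view. The dialect is PDBx/mmCIF with one data block per
## component and the categories _chem_comp, _chem_comp_atom, _chem_comp_bond
## and _pdbx_chem_comp_descriptor; anything else is preserved verbatim for
## round-trips.

.CCD_CATS <- c("chem_comp", "chem_comp_atom", "chem_comp_bond",
               "pdbx_chem_comp_descriptor")

.yn <- function(x) !is.na(x) & toupper(x) == "Y"
.asYN <- function(x) ifelse(x, "Y", "N")

.num3 <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.3f", x))

.blockToDef <- function(block) {
  cc <- .getCat(block, "chem_comp")
  id <- toupper(.catChr(cc, "id")[1])
  if (is.na(id)) id <- toupper(block$name)
  syn <- .catChr(cc, "pdbx_synonyms")[1]
  syn <- if (is.na(syn)) character(0) else trimws(strsplit(syn, ";", fixed = TRUE)[[1]])
  parents <- .catChr(cc, "mon_nstd_parent_comp_id")[1]
  parents <- if (is.na(parents)) character(0) else
    toupper(trimws(strsplit(parents, ",", fixed = TRUE)[[1]]))

  ca <- .getCat(block, "chem_comp_atom")
  atoms <- if (is.null(ca) || !nrow(ca)) .emptyAtoms() else data.frame(
    atomId = .catChr(ca, "atom_id"),
    element = toupper(.catChr(ca, "type_symbol")),
    charge = {
      ch <- suppressWarnings(as.integer(.catChr(ca, "charge")))
      ifelse(is.na(ch), 0L, ch)   # absent charge means neutral
    },
    aromatic = .yn(.catChr(ca, "pdbx_aromatic_flag")),
    stereoConfig = {
      s <- .catChr(ca, "pdbx_stereo_config")
      ifelse(is.na(s), "N", toupper(s))
    },
    leaving = .yn(.catChr(ca, "pdbx_leaving_atom_flag")),
    idealX = .catNum(ca, "pdbx_model_Cartn_x_ideal"),
    idealY = .catNum(ca, "pdbx_model_Cartn_y_ideal"),
    idealZ = .catNum(ca, "pdbx_model_Cartn_z_ideal"),
    modelX = .catNum(ca, "model_Cartn_x"),
    modelY = .catNum(ca, "model_Cartn_y"),
    modelZ = .catNum(ca, "model_Cartn_z"),
    stringsAsFactors = FALSE)

  cb <- .getCat(block, "chem_comp_bond")
  bondDf <- if (is.null(cb) || !nrow(cb)) .emptyBonds() else data.frame(
    atomId1 = .catChr(cb, "atom_id_1"),
    atomId2 = .catChr(cb, "atom_id_2"),
    order = {
      o <- toupper(.catChr(cb, "value_order"))
      ifelse(is.na(o), "SING", o)
    },
    aromatic = .yn(.catChr(cb, "pdbx_aromatic_flag")),
    stereo = {
      s <- .catChr(cb, "pdbx_stereo_config")
      ifelse(is.na(s), "N", toupper(s))
    },
    stringsAsFactors = FALSE)

  cd <- .getCat(block, "pdbx_chem_comp_descriptor")
  descDf <- if (is.null(cd) || !nrow(cd)) .emptyDescriptors() else data.frame(
    descType = .catChr(cd, "type"),
    program = .catChr(cd, "program"),
    value = .catChr(cd, "descriptor"),
    stringsAsFactors = FALSE)

  extras <- block$categories[setdiff(names(block$categories), .CCD_CATS)]

  new("ChemCompDef",
      compId = id,
      name = .catChr(cc, "name")[1],
      synonyms = syn,
      formula = .catChr(cc, "formula")[1],
      formulaWeight = .catNum(cc, "formula_weight")[1],
      formalCharge = {
        q <- suppressWarnings(as.integer(.catChr(cc, "pdbx_formal_charge")[1]))
        if (is.na(q)) 0L else q
      },
      compType = .catChr(cc, "type")[1],
      pdbxType = .catChr(cc, "pdbx_type")[1],
      parentCompIds = parents,
      atoms = atoms, bonds = bondDf, descriptors = descDf,
      extraCategories = extras)
}

#' Parse a chemical component dictionary
#'
#' Reads CCD CIF text into [ChemCompDef-class] objects, one per
#' \code{data_} block. Unknown categories are kept verbatim so that
#' [writeCCD()] round-trips the document. Scientific invariants are
#' checked via [validateDef()]: violations are reported (bond rows naming
#' unknown atoms are an error; everything else a warning), never silently
#' repaired.
#'
#' @param text CCD CIF document (string or character vector of lines).
#' @param strict error on bonds that reference unknown atoms (default TRUE).
#' @return list of [ChemCompDef-class], named by component id.
#' @examples
#' glc <- makeCcdFixture("GLC-like")
#' defs <- parseCCD(writeCCD(list(glc)))
#' atoms(defs[[1]])$atomId
#' @export
parseCCD <- function(text, strict = TRUE) {
  blocks <- parseCif(text)
  defs <- lapply(blocks, .blockToDef)
  names(defs) <- vapply(defs, compId, character(1))
  for (def in defs) {
    issues <- validateDef(def)
    dangling <- issues[issues$code == "bond-dangling", , drop = FALSE]
    if (strict && nrow(dangling))
      stop("invalid CCD definition ", compId(def), ": ",
           paste(dangling$message, collapse = "; "))
    if (nrow(issues))
      warning("CCD definition ", compId(def), " has ", nrow(issues),
              " issue(s): ", paste(issues$message, collapse = "; "),
              call. = FALSE)
  }
  defs
}

.defToBlock <- function(def) {
  a <- def@atoms
  cats <- list()
  cats[["chem_comp"]] <- structure(data.frame(
    id = def@compId,
    name = def@name,
    type = def@compType,
    pdbx_type = def@pdbxType,
    formula = def@formula,
    mon_nstd_parent_comp_id = if (length(def@parentCompIds))
      paste(def@parentCompIds, collapse = ",") else NA_character_,
    pdbx_synonyms = if (length(def@synonyms))
      paste(def@synonyms, collapse = "; ") else NA_character_,
    pdbx_formal_charge = as.character(def@formalCharge),
    formula_weight = ifelse(is.na(def@formulaWeight), NA_character_,
                            sprintf("%.3f", def@formulaWeight)),
    stringsAsFactors = FALSE), loop = FALSE)
  if (nrow(a)) {
    cats[["chem_comp_atom"]] <- structure(data.frame(
      comp_id = def@compId,
      atom_id = a$atomId,
      type_symbol = a$element,
      charge = as.character(a$charge),
      pdbx_aromatic_flag = .asYN(a$aromatic),
      pdbx_leaving_atom_flag = .asYN(a$leaving),
      pdbx_stereo_config = a$stereoConfig,
      model_Cartn_x = .num3(a$modelX),
      model_Cartn_y = .num3(a$modelY),
      model_Cartn_z = .num3(a$modelZ),
      pdbx_model_Cartn_x_ideal = .num3(a$idealX),
      pdbx_model_Cartn_y_ideal = .num3(a$idealY),
      pdbx_model_Cartn_z_ideal = .num3(a$idealZ),
      pdbx_ordinal = as.character(seq_len(nrow(a))),
      stringsAsFactors = FALSE), loop = TRUE)
  }
  b <- def@bonds
  if (nrow(b)) {
    cats[["chem_comp_bond"]] <- structure(data.frame(
      comp_id = def@compId,
      atom_id_1 = b$atomId1,
      atom_id_2 = b$atomId2,
      value_order = b$order,
      pdbx_aromatic_flag = .asYN(b$aromatic),
      pdbx_stereo_config = b$stereo,
      pdbx_ordinal = as.character(seq_len(nrow(b))),
      stringsAsFactors = FALSE), loop = TRUE)
  }
  d <- def@descriptors
  if (nrow(d)) {
    cats[["pdbx_chem_comp_descriptor"]] <- structure(data.frame(
      comp_id = def@compId,
      type = d$descType,
      program = d$program,
      descriptor = d$value,
      stringsAsFactors = FALSE), loop = TRUE)
  }
  cats <- c(cats, def@extraCategories)
  list(name = def@compId, categories = cats)
}

#' Write a chemical component dictionary
#'
#' Serialises definitions to CCD CIF text, one \code{data_} block per
#' component, categories in the canonical order (identity, atoms, bonds,
#' descriptors, then preserved extras), atom and bond rows in input order.
#' Definitions that fail [validateDef()] are refused: a dictionary writer
#' must not emit files it would itself reject.
#'
#' @param defs list of [ChemCompDef-class].
#' @param validate refuse to write invalid definitions (default TRUE).
#' @return CCD CIF text as one string.
#' @export
writeCCD <- function(defs, validate = TRUE) {
  if (is(defs, "ChemCompDef")) defs <- list(defs)
  if (validate) {
    for (def in defs) {
      issues <- validateDef(def)
      if (nrow(issues))
        stop("refusing to write invalid definition ", compId(def), ": ",
             paste(issues$message, collapse = "; "))
    }
  }
  writeCif(lapply(defs, .defToBlock))
}

.issue <- function(code, message) {
  data.frame(code = code, message = message, stringsAsFactors = FALSE)
}

#' Validate a dictionary definition
#'
#' Checks the scientific invariants of a component definition and returns
#' the violations as a table of machine-readable issue codes with
#' human-readable messages; an empty table means the definition is valid.
#'
#' Checked: component-id pattern (1-3 alphanumeric, upper case); atom-id
#' presence and uniqueness; known element symbols; bonds referencing two
#' distinct existing atoms, each unordered pair at most once, with a legal
#' order code; the stated formula reconciling with per-element atom counts
#' (hydrogens included); and the formal charge equalling the sum of
#' per-atom charges.
#'
#' @param def a [ChemCompDef-class].
#' @return data.frame with columns \code{code} and \code{message}.
#' @export
validateDef <- function(def) {
  issues <- .issue(character(0), character(0))
  a <- def@atoms; b <- def@bonds
  if (is.na(def@compId) || !grepl("^[A-Z0-9]{1,3}$", def@compId))
    issues <- rbind(issues, .issue("comp-id",
      sprintf("comp_id '%s' is not 1-3 uppercase alphanumeric characters",
              def@compId)))
  if (nrow(a)) {
    if (any(!nzchar(a$atomId) | is.na(a$atomId)))
      issues <- rbind(issues, .issue("atom-id-empty", "empty atom_id"))
    dup <- unique(a$atomId[duplicated(a$atomId)])
    for (d in dup)
      issues <- rbind(issues, .issue("atom-id-duplicate",
        sprintf("duplicate atom_id '%s'", d)))
    unk <- unique(a$element[!.isKnownElement(a$element)])
    for (e in unk)
      issues <- rbind(issues, .issue("element-unknown",
        sprintf("unknown element '%s'", e)))
    bad <- unique(a$stereoConfig[!a$stereoConfig %in% c("N", "R", "S")])
    for (s in bad)
      issues <- rbind(issues, .issue("stereo-config",
        sprintf("stereo_config '%s' not one of N/R/S", s)))
  }
  if (nrow(b)) {
    for (i in seq_len(nrow(b))) {
      if (identical(b$atomId1[i], b$atomId2[i]))
        issues <- rbind(issues, .issue("bond-self",
          sprintf("bond %s-%s joins an atom to itself",
                  b$atomId1[i], b$atomId2[i])))
      for (at in c(b$atomId1[i], b$atomId2[i])) {
        if (!(at %in% a$atomId))
          issues <- rbind(issues, .issue("bond-dangling",
            sprintf("comp_id %s: bond references unknown atom_id '%s'",
                    def@compId, at)))
      }
    }
    key <- apply(cbind(pmin(b$atomId1, b$atomId2),
                       pmax(b$atomId1, b$atomId2)), 1, paste, collapse = "|")
    for (d in unique(key[duplicated(key)]))
      issues <- rbind(issues, .issue("bond-duplicate",
        sprintf("duplicate bond %s", gsub("|", "-", d, fixed = TRUE))))
    badOrder <- unique(b$order[!b$order %in% c("SING", "DOUB", "TRIP", "AROM")])
    for (o in badOrder)
      issues <- rbind(issues, .issue("bond-order",
        sprintf("bond order '%s' not one of SING/DOUB/TRIP/AROM", o)))
  }
  # formula reconciliation, hydrogens included
  if (!is.na(def@formula) && nrow(a) &&
      !nrow(issues[issues$code == "element-unknown", , drop = FALSE])) {
    stated <- .parseFormula(def@formula)
    derived <- table(toupper(a$element))
    allEl <- union(names(stated), names(derived))
    for (e in allEl) {
      ns <- if (e %in% names(stated)) stated[[e]] else 0L
      nd <- if (e %in% names(derived)) derived[[e]] else 0L
      if (ns != nd) {
        issues <- rbind(issues, .issue("formula-mismatch",
          sprintf("formula says %d %s, atom list has %d", ns, e, nd)))
      }
    }
  }
  if (nrow(a) && sum(a$charge) != def@formalCharge)
    issues <- rbind(issues, .issue("charge-mismatch",
      sprintf("formal charge %d but atom charges sum to %d",
              def@formalCharge, sum(a$charge))))
  issues
}

#' Molecular graph of a dictionary definition
#'
#' Builds the element-labelled molecular graph of a component, optionally
#' excluding hydrogens and/or leaving atoms (with their incident bonds).
#' Excluding leaving atoms yields the covalently-bound form of the
#' component; this is the view the matcher compares observations against.
#'
#' @param def a [ChemCompDef-class].
#' @param includeHydrogens keep H/D atoms (default TRUE).
#' @param includeLeaving keep leaving atoms (default TRUE).
#' @return an \pkg{igraph} graph; vertices carry \code{name} (atom id) and
#'   \code{element}, edges carry \code{order}.
#' @export
componentGraph <- function(def, includeHydrogens = TRUE,
                           includeLeaving = TRUE) {
  a <- def@atoms
  keep <- rep(TRUE, nrow(a))
  if (!includeHydrogens) keep <- keep & !(a$element %in% c("H", "D"))
  if (!includeLeaving) keep <- keep & !a$leaving
  a <- a[keep, , drop = FALSE]
  b <- def@bonds
  b <- b[b$atomId1 %in% a$atomId & b$atomId2 %in% a$atomId, , drop = FALSE]
  g <- igraph::make_empty_graph(n = nrow(a), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = a$atomId)
  g <- igraph::set_vertex_attr(g, "element", value = a$element)
  if (nrow(b)) {
    g <- igraph::add_edges(g, rbind(match(b$atomId1, a$atomId),
                                    match(b$atomId2, a$atomId)))
    g <- igraph::set_edge_attr(g, "order", value = b$order)
  }
  g
}
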