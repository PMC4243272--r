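## Coordinate-file reading (PDB and PDBx/mmCIF), component grouping and
## crystallographic symmetry expansion.

.compKey <- function(compId, authChain, authSeq, insCode) {
  ins <- ifelse(is.na(insCode) | !nzchar(insCode), " ", insCode)
  paste(authChain, authSeq, ins, compId, sep = "|")
}

.siteKeys <- function(sites) {
  .compKey(sites$compId, sites$authChain, sites$authSeq, sites$insCode)
}

.substrTrim <- function(x, start, stop) trimws(substr(x, start, stop))

.elementFromName <- function(name) {
  # PDB atom names encode the element in columns 13-14; after trimming,
  # strip digits/primes and take the leading alphabetic run
  n <- gsub("[0-9']", "", trimws(name))
  el <- toupper(substr(n, 1, 2))
  one <- toupper(substr(n, 1, 1))
  ifelse(el %in% names(.COVALENT_RADII) & nchar(n) > 1 &
           !(one %in% c("C", "N", "O", "H", "P", "S")),
         el, one)
}

.parsePdbText <- function(lines, modelNum = 1L) {
  cell <- NULL
  cr <- lines[startsWith(lines, "CRYST1")]
  if (length(cr)) {
    cr <- cr[1]
    sg <- .substrTrim(cr, 56, 66)
    cell <- crystalCell(
      a = as.numeric(substr(cr, 7, 15)),
      b = as.numeric(substr(cr, 16, 24)),
      c = as.numeric(substr(cr, 25, 33)),
      alpha = as.numeric(substr(cr, 34, 40)),
      beta = as.numeric(substr(cr, 41, 47)),
      gamma = as.numeric(substr(cr, 48, 54)),
      spaceGroup = if (nzchar(sg)) sg else "P 1")
  }
  curModel <- 1L
  rows <- vector("list", length(lines))
  nr <- 0L
  for (ln in lines) {
    rec <- substr(ln, 1, 6)
    if (rec == "MODEL ") {
      curModel <- as.integer(.substrTrim(ln, 11, 14))
    } else if (rec %in% c("ATOM  ", "HETATM")) {
      if (curModel != modelNum) next
      nr <- nr + 1L
      el <- .substrTrim(ln, 77, 78)
      name <- .substrTrim(ln, 13, 16)
      rows[[nr]] <- data.frame(
        serial = as.integer(.substrTrim(ln, 7, 11)),
        atomName = name,
        altLoc = substr(ln, 17, 17),
        compId = .substrTrim(ln, 18, 20),
        authChain = substr(ln, 22, 22),
        authSeq = as.integer(.substrTrim(ln, 23, 26)),
        insCode = substr(ln, 27, 27),
        labelChain = NA_character_,
        x = as.numeric(substr(ln, 31, 38)),
        y = as.numeric(substr(ln, 39, 46)),
        z = as.numeric(substr(ln, 47, 54)),
        occupancy = {
          o <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
          if (is.na(o)) 1 else o
        },
        bFactor = {
          b <- suppressWarnings(as.numeric(substr(ln, 61, 66)))
          if (is.na(b)) 0 else b
        },
        element = if (nzchar(el)) toupper(el) else .elementFromName(name),
        modelNum = curModel,
        isHet = rec == "HETATM",
        groupId = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  sites <- if (nr) do.call(rbind, rows[seq_len(nr)]) else .emptyAtomSites()
  sites$altLoc[sites$altLoc == " "] <- ""
  sites$insCode[sites$insCode == " "] <- ""
  new("StructureModel", atomSites = sites, cell = cell)
}

.parseMmcifBlocks <- function(blocks, modelNum = 1L) {
  if (!length(blocks)) return(new("StructureModel"))
  block <- blocks[[1]]
  cellCat <- .getCat(block, "cell")
  symCat <- .getCat(block, "symmetry")
  cell <- NULL
  if (!is.null(cellCat)) {
    sg <- .catChr(symCat, "space_group_name_H-M")[1]
    if (is.na(sg)) sg <- .catChr(symCat, "space_group_name_H_M")[1]
    cell <- crystalCell(
      a = .catNum(cellCat, "length_a")[1],
      b = .catNum(cellCat, "length_b")[1],
      c = .catNum(cellCat, "length_c")[1],
      alpha = .catNum(cellCat, "angle_alpha")[1],
      beta = .catNum(cellCat, "angle_beta")[1],
      gamma = .catNum(cellCat, "angle_gamma")[1],
      spaceGroup = if (is.na(sg)) "P 1" else sg)
  }
  as <- .getCat(block, "atom_site")
  if (is.null(as) || !nrow(as)) {
    return(new("StructureModel", atomSites = .emptyAtomSites(), cell = cell))
  }
  n <- nrow(as)
  authChain <- .catChr(as, "auth_asym_id")
  if (all(is.na(authChain))) authChain <- .catChr(as, "label_asym_id")
  authSeq <- .catChr(as, "auth_seq_id")
  if (all(is.na(authSeq))) authSeq <- .catChr(as, "label_seq_id")
  compId <- .catChr(as, "auth_comp_id")
  if (all(is.na(compId))) compId <- .catChr(as, "label_comp_id")
  atomName <- .catChr(as, "auth_atom_id")
  if (all(is.na(atomName))) atomName <- .catChr(as, "label_atom_id")
  mn <- suppressWarnings(as.integer(.catChr(as, "pdbx_PDB_model_num")))
  mn[is.na(mn)] <- 1L
  alt <- .catChr(as, "label_alt_id"); alt[is.na(alt)] <- ""
  ins <- .catChr(as, "pdbx_PDB_ins_code"); ins[is.na(ins)] <- ""
  occ <- .catNum(as, "occupancy"); occ[is.na(occ)] <- 1
  bf <- .catNum(as, "B_iso_or_equiv"); bf[is.na(bf)] <- 0
  grp <- .catChr(as, "group_PDB"); grp[is.na(grp)] <- "ATOM"
  sites <- data.frame(
    serial = {
      s <- suppressWarnings(as.integer(.catChr(as, "id")))
      ifelse(is.na(s), seq_len(n), s)
    },
    atomName = atomName,
    altLoc = alt,
    compId = toupper(compId),
    authChain = authChain,
    authSeq = as.integer(authSeq),
    insCode = ins,
    labelChain = .catChr(as, "label_asym_id"),
    x = .catNum(as, "Cartn_x"),
    y = .catNum(as, "Cartn_y"),
    z = .catNum(as, "Cartn_z"),
    occupancy = occ,
    bFactor = bf,
    element = toupper(.catChr(as, "type_symbol")),
    modelNum = mn,
    isHet = toupper(grp) == "HETATM",
    groupId = NA_character_,
    stringsAsFactors = FALSE)
  sites <- sites[sites$modelNum == modelNum, , drop = FALSE]
  rownames(sites) <- NULL
  new("StructureModel", atomSites = sites, cell = cell)
}

#' Parse a macromolecular structure
#'
#' Reads PDB or PDBx/mmCIF coordinate text (auto-detected) into a
#' [StructureModel-class]: all ATOM/HETATM sites of the requested model
#' (model 1 by default), the crystallographic cell and space-group
#' operators when declared, and author-scheme addressing throughout.
#' Without a cell the model is usable but symmetry operations refuse to
#' run. Unknown space-group symbols are an error naming the symbol.
#'
#' @param text character: coordinate text, or the path of an existing file.
#' @param format "auto" (default), "pdb" or "mmcif".
#' @param modelNum which model of a multi-model file to load (default 1).
#' @return a [StructureModel-class].
#' @export
parseStructure <- function(text, format = c("auto", "pdb", "mmcif"),
                           modelNum = 1L) {
  format <- match.arg(format)
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  if (format == "auto") {
    format <- if (any(grepl("^data_", lines)) ||
                  any(grepl("^\\s*_atom_site\\.", lines))) "mmcif" else "pdb"
  }
  if (format == "pdb") .parsePdbText(lines, modelNum = modelNum)
  else .parseMmcifBlocks(parseCif(lines), modelNum = modelNum)
}

#' Observed components of a structure
#'
#' Groups the atom-site table into observed components (one per residue /
#' ligand / water, keyed by comp id + author chain + seq + insertion code).
#' Polymer residues are those from ATOM records that are not waters; waters
#' are never polymeric and never ligands of interest.
#'
#' @param model a [StructureModel-class].
#' @return data.frame with one row per component: key, compId, authChain,
#'   authSeq, insCode, groupId, isPolymerResidue, isWater, nAtoms.
#' @export
modelComponents <- function(model) {
  s <- model@atomSites
  if (!nrow(s)) {
    return(data.frame(key = character(0), compId = character(0),
                      authChain = character(0), authSeq = integer(0),
                      insCode = character(0), groupId = character(0),
                      isPolymerResidue = logical(0), isWater = logical(0),
                      nAtoms = integer(0), stringsAsFactors = FALSE))
  }
  key <- .siteKeys(s)
  first <- !duplicated(key)
  comp <- data.frame(
    key = key[first],
    compId = s$compId[first],
    authChain = s$authChain[first],
    authSeq = s$authSeq[first],
    insCode = s$insCode[first],
    groupId = s$groupId[first],
    isPolymerResidue = !s$isHet[first] & !.isWater(s$compId[first]),
    isWater = .isWater(s$compId[first]),
    nAtoms = as.integer(table(key)[key[first]]),
    stringsAsFactors = FALSE)
  rownames(comp) <- NULL
  comp
}

#' Atom sites of one component
#'
#' @param model a [StructureModel-class].
#' @param key component key as produced by [modelComponents()].
#' @return data.frame subset of the atom-site table.
#' @export
componentAtoms <- function(model, key) {
  s <- model@atomSites
  s[.siteKeys(s) %in% key, , drop = FALSE]
}

#' Declare multi-component groups
#'
#' Ties several observed components (e.g. the sugars of an
#' oligosaccharide, or the subcomponents of a peptide-like molecule) into
#' one named group: binding-site delineation then treats the group as a
#' single ligand.
#'
#' @param model a [StructureModel-class].
#' @param groups named list; each element a character vector of component
#'   keys (see [modelComponents()]).
#' @return the model with group ids assigned.
#' @export
setComponentGroups <- function(model, groups) {
  s <- model@atomSites
  key <- .siteKeys(s)
  for (g in names(groups)) {
    hit <- key %in% groups[[g]]
    s$groupId[hit] <- g
  }
  model@atomSites <- s
  model
}

.applySymOpFrac <- function(frac, op, shift = c(0, 0, 0)) {
  sweep(frac %*% t(op$rot), 2, op$trans + shift, "+")
}

#' Apply a symmetry operator to orthogonal coordinates
#'
#' @param xyz n x 3 matrix of orthogonal coordinates (Angstrom).
#' @param op an operator from [spaceGroupOperators()].
#' @param cell the [CrystalCell-class].
#' @param shift integer lattice translation (default none).
#' @return transformed n x 3 matrix.
#' @export
applySymOp <- function(xyz, op, cell, shift = c(0L, 0L, 0L)) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  orthogonalize(.applySymOpFrac(fractionalize(xyz, cell), op, shift), cell)
}

#' Symmetry expansion around center atoms
#'
#' Generates every crystallographic image (space-group operator x lattice
#' translation within +/-1 cell) of every model atom that lies within
#' \code{radius} of any center atom, excluding the identity-with-zero-shift
#' copies of the center atoms themselves. Each image is labelled with its
#' operator index and 555-style translation code.
#'
#' @param model a [StructureModel-class] with a cell (error otherwise).
#' @param centerAtoms data.frame of atom sites (rows of
#'   \code{atomSites(model)}) or their integer row indices.
#' @param radius search radius in Angstrom.
#' @return data.frame: one row per in-range image with the source-atom
#'   fields, image coordinates \code{x,y,z}, \code{opIndex},
#'   \code{shift1..3}, \code{symLabel} and \code{distance} (minimum
#'   distance to the center atoms).
#' @export
expandSymmetry <- function(model, centerAtoms, radius) {
  if (is.null(model@cell))
    stop("symmetry expansion requires a crystal cell; none present")
  s <- model@atomSites
  if (is.numeric(centerAtoms)) centerAtoms <- s[centerAtoms, , drop = FALSE]
  empty <- cbind(s[0, , drop = FALSE],
                 data.frame(opIndex = integer(0), shift1 = integer(0),
                            shift2 = integer(0), shift3 = integer(0),
                            symLabel = character(0), distance = numeric(0)))
  if (!nrow(centerAtoms) || !nrow(s) || radius <= 0) return(empty)
  cell <- model@cell
  C <- as.matrix(centerAtoms[, c("x", "y", "z")])
  X <- as.matrix(s[, c("x", "y", "z")])
  F <- fractionalize(X, cell)
  centerIdx <- which(s$serial %in% centerAtoms$serial &
                       .siteKeys(s) %in% .siteKeys(centerAtoms))
  c2 <- rowSums(C^2)
  out <- list(); nout <- 0L
  shifts <- as.matrix(expand.grid(s1 = -1:1, s2 = -1:1, s3 = -1:1))
  for (op in cell@operators) {
    Fop <- F %*% t(op$rot)
    isIdentity <- all(op$rot == diag(3)) && all(op$trans == 0)
    for (r in seq_len(nrow(shifts))) {
      sh <- shifts[r, ]
      Y <- orthogonalize(sweep(Fop, 2, op$trans + sh, "+"), cell)
      d2 <- outer(rowSums(Y^2), c2, "+") - 2 * (Y %*% t(C))
      dmin <- sqrt(pmax(0, apply(d2, 1, min)))
      sel <- which(dmin <= radius)
      if (isIdentity && all(sh == 0)) sel <- setdiff(sel, centerIdx)
      if (!length(sel)) next
      img <- s[sel, , drop = FALSE]
      img$x <- Y[sel, 1]; img$y <- Y[sel, 2]; img$z <- Y[sel, 3]
      img$opIndex <- op$opIndex
      img$shift1 <- sh[1]; img$shift2 <- sh[2]; img$shift3 <- sh[3]
      img$symLabel <- symLabel(op$opIndex, sh)
      img$distance <- dmin[sel]
      nout <- nout + 1L
      out[[nout]] <- img
    }
  }
  if (!nout) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a structure as PDBx/mmCIF
#'
#' Emits the atom-site table (plus cell and symmetry when present) as a
#' minimal mmCIF block; extra annotation categories (binding sites,
#' linkages, angles) can be appended by the corresponding writers.
#'
#' @param model a [StructureModel-class].
#' @param blockName data block name.
#' @param extraCategories named list of additional categories to append.
#' @return mmCIF text.
#' @export
writeStructureMmcif <- function(model, blockName = "annotated",
                                extraCategories = list()) {
  s <- model@atomSites
  cats <- list()
  if (!is.null(model@cell)) {
    cc <- model@cell
    cats[["cell"]] <- structure(data.frame(
      length_a = sprintf("%.3f", cc@a), length_b = sprintf("%.3f", cc@b),
      length_c = sprintf("%.3f", cc@c),
      angle_alpha = sprintf("%.2f", cc@alpha),
      angle_beta = sprintf("%.2f", cc@beta),
      angle_gamma = sprintf("%.2f", cc@gamma),
      stringsAsFactors = FALSE), loop = FALSE)
    cats[["symmetry"]] <- structure(data.frame(
      `space_group_name_H-M` = cc@spaceGroup,
      check.names = FALSE, stringsAsFactors = FALSE), loop = FALSE)
  }
  if (nrow(s)) {
    cats[["atom_site"]] <- structure(data.frame(
      group_PDB = ifelse(s$isHet, "HETATM", "ATOM"),
      id = as.character(s$serial),
      type_symbol = s$element,
      label_atom_id = s$atomName,
      label_alt_id = ifelse(nzchar(s$altLoc), s$altLoc, NA_character_),
      label_comp_id = s$compId,
      label_asym_id = ifelse(is.na(s$labelChain), s$authChain, s$labelChain),
      Cartn_x = sprintf("%.3f", s$x),
      Cartn_y = sprintf("%.3f", s$y),
      Cartn_z = sprintf("%.3f", s$z),
      occupancy = sprintf("%.2f", s$occupancy),
      B_iso_or_equiv = sprintf("%.2f", s$bFactor),
      auth_comp_id = s$compId,
      auth_asym_id = s$authChain,
      auth_seq_id = as.character(s$authSeq),
      pdbx_PDB_ins_code = ifelse(nzchar(s$insCode), s$insCode, NA_character_),
      auth_atom_id = s$atomName,
      pdbx_PDB_model_num = as.character(s$modelNum),
      stringsAsFactors = FALSE), loop = TRUE)
  }
  cats <- c(cats, extraCategories)
  writeCif(list(list(name = blockName, categories = cats)))
}

#' Write a structure in PDB format
#'
#' @param model a [StructureModel-class].
#' @param remarks character vector of preformatted REMARK (or other header)
#'   lines placed before the coordinates.
#' @return PDB-format text.
#' @export
writeStructurePdb <- function(model, remarks = character(0)) {
  out <- character(0)
  if (!is.null(model@cell)) {
    cc <- model@cell
    out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                          cc@a, cc@b, cc@c, cc@alpha, cc@beta, cc@gamma,
                          cc@spaceGroup))
  }
  out <- c(out, remarks)
  s <- model@atomSites
  if (nrow(s)) {
    name4 <- ifelse(nchar(s$atomName) >= 4 | nchar(s$element) == 2,
                    formatC(s$atomName, width = -4),
                    paste0(" ", formatC(s$atomName, width = -3)))
    out <- c(out, sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                          ifelse(s$isHet, "HETATM", "ATOM"),
                          s$serial, name4,
                          ifelse(nzchar(s$altLoc), s$altLoc, " "),
                          s$compId, s$authChain, s$authSeq,
                          ifelse(nzchar(s$insCode), s$insCode, " "),
                          s$x, s$y, s$z, s$occupancy, s$bFactor, s$element))
  }
  paste0(paste(c(out, "END"), collapse = "\n"), "\n")
}
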