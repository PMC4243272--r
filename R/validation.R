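## Ligand validation: geometry deviations against dictionary ideal
## geometry, and the local ligand density fit (LLDF) Z-score on per-residue
## real-space R-values (RSR).

.LLDF_CUTOFF <- 5.0     # neighbour cutoff, Angstrom
.LLDF_FLAG <- 2         # Z-scores above this are highlighted
.SIGMA_BOND <- 0.02     # Angstrom, fixed sigma for bond-length Z
.SIGMA_ANGLE <- 2       # degrees, fixed sigma for bond-angle Z

## dictionary bond angles: one row per pair of bonds sharing an atom
.dictAngles <- function(def) {
  b <- def@bonds
  out <- list()
  for (at in def@atoms$atomId) {
    part <- b[b$atomId1 == at | b$atomId2 == at, , drop = FALSE]
    if (nrow(part) < 2L) next
    nb <- ifelse(part$atomId1 == at, part$atomId2, part$atomId1)
    pairs <- t(combn(sort(nb), 2))
    out[[length(out) + 1L]] <- data.frame(
      atomId1 = pairs[, 1], center = at, atomId2 = pairs[, 2],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(atomId1 = character(0), center = character(0),
                      atomId2 = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

.xyzOf <- function(coords, ids) {
  as.matrix(coords[match(ids, rownames(coords)), , drop = FALSE])
}

## heavy neighbours of a dictionary atom, in atom-table order
.dictNeighbors <- function(def, atomId) {
  b <- def@bonds
  nb <- c(b$atomId2[b$atomId1 == atomId], b$atomId1[b$atomId2 == atomId])
  el <- def@atoms$element[match(nb, def@atoms$atomId)]
  nb <- nb[!(el %in% c("H", "D"))]
  nb[order(match(nb, def@atoms$atomId))]
}

#' Geometry check against dictionary ideal geometry
#'
#' For every dictionary bond and bond angle with all atoms observed,
#' reports the deviation of the observed value from the value computed on
#' the dictionary's idealized coordinates, plus chirality comparison by
#' signed volume at each annotated stereocentre. Without ideal coordinates
#' the report is limited to chirality (model coordinates are an
#' observation, not a reference) and carries a notice.
#'
#' @param component data.frame of observed atom sites.
#' @param match the [ComponentMatch-class] for this component.
#' @param def the matched [ChemCompDef-class].
#' @return a [GeometryReport-class].
#' @export
geometryCheck <- function(component, match, def) {
  amap <- match@atomMap     # observed name -> dict id
  obs <- .uniqueAtomRows(component)
  obsXyz <- as.matrix(obs[, c("x", "y", "z")])
  rownames(obsXyz) <- unname(amap[match(obs$atomName, names(amap))])
  obsXyz <- obsXyz[!is.na(rownames(obsXyz)), , drop = FALSE]

  a <- def@atoms
  haveIdeal <- !anyNA(a[, c("idealX", "idealY", "idealZ")])
  idealXyz <- as.matrix(a[, c("idealX", "idealY", "idealZ")])
  rownames(idealXyz) <- a$atomId

  emptyBondDev <- data.frame(atomId1 = character(0), atomId2 = character(0),
                             ideal = numeric(0), observed = numeric(0),
                             deviation = numeric(0), stringsAsFactors = FALSE)
  emptyAngDev <- data.frame(atomId1 = character(0), center = character(0),
                            atomId2 = character(0), ideal = numeric(0),
                            observed = numeric(0), deviation = numeric(0),
                            stringsAsFactors = FALSE)
  bondDev <- emptyBondDev
  angDev <- emptyAngDev
  notice <- NA_character_

  if (haveIdeal) {
    b <- def@bonds
    ok <- b$atomId1 %in% rownames(obsXyz) & b$atomId2 %in% rownames(obsXyz)
    b <- b[ok, , drop = FALSE]
    if (nrow(b)) {
      idl <- sqrt(rowSums((.xyzOf(idealXyz, b$atomId1) -
                             .xyzOf(idealXyz, b$atomId2))^2))
      obsLen <- sqrt(rowSums((.xyzOf(obsXyz, b$atomId1) -
                                .xyzOf(obsXyz, b$atomId2))^2))
      bondDev <- data.frame(atomId1 = b$atomId1, atomId2 = b$atomId2,
                            ideal = idl, observed = obsLen,
                            deviation = obsLen - idl,
                            stringsAsFactors = FALSE)
    }
    angles <- .dictAngles(def)
    ok <- angles$atomId1 %in% rownames(obsXyz) &
      angles$center %in% rownames(obsXyz) &
      angles$atomId2 %in% rownames(obsXyz)
    angles <- angles[ok, , drop = FALSE]
    if (nrow(angles)) {
      idl <- vapply(seq_len(nrow(angles)), function(r)
        .angleDeg(idealXyz[angles$atomId1[r], ], idealXyz[angles$center[r], ],
                  idealXyz[angles$atomId2[r], ]), numeric(1))
      obsA <- vapply(seq_len(nrow(angles)), function(r)
        .angleDeg(obsXyz[angles$atomId1[r], ], obsXyz[angles$center[r], ],
                  obsXyz[angles$atomId2[r], ]), numeric(1))
      angDev <- cbind(angles, data.frame(ideal = idl, observed = obsA,
                                         deviation = obsA - idl))
    }
  } else {
    notice <- "definition lacks ideal coordinates; report limited to chirality"
  }

  # chirality by signed volume, same substituent order on both sides
  flips <- character(0)
  centers <- a$atomId[a$stereoConfig %in% c("R", "S")]
  refXyz <- if (haveIdeal) idealXyz else {
    mx <- as.matrix(a[, c("modelX", "modelY", "modelZ")])
    rownames(mx) <- a$atomId
    mx
  }
  for (ct in centers) {
    nb <- .dictNeighbors(def, ct)
    if (length(nb) < 3L) next
    nb <- nb[1:3]
    if (!all(c(ct, nb) %in% rownames(obsXyz)) ||
        anyNA(refXyz[c(ct, nb), ])) next
    vRef <- .signedVolume(refXyz[ct, ], refXyz[nb[1], ], refXyz[nb[2], ],
                          refXyz[nb[3], ])
    vObs <- .signedVolume(obsXyz[ct, ], obsXyz[nb[1], ], obsXyz[nb[2], ],
                          obsXyz[nb[3], ])
    if (sign(vRef) != 0 && sign(vObs) != 0 && sign(vRef) != sign(vObs))
      flips <- c(flips, ct)
  }

  rmsz <- function(dev, sigma) {
    if (!length(dev)) NA_real_ else sqrt(mean((dev / sigma)^2))
  }
  new("GeometryReport", bonds = bondDev, angles = angDev,
      chiralityFlips = flips,
      rmsZBonds = rmsz(bondDev$deviation, .SIGMA_BOND),
      rmsZAngles = rmsz(angDev$deviation, .SIGMA_ANGLE),
      notice = notice)
}

#' Read / write a per-residue RSR table
#'
#' Plain tab-separated text with header columns \code{chain}, \code{seq},
#' \code{ins}, \code{comp_id}, \code{rsr}.
#'
#' @param text file path or TSV text.
#' @return data.frame with those columns.
#' @export
readRsrTable <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    df <- read.delim(text, stringsAsFactors = FALSE,
                     colClasses = c("character", "integer", "character",
                                    "character", "numeric"))
  } else {
    df <- read.delim(textConnection(paste(text, collapse = "\n")),
                     stringsAsFactors = FALSE,
                     colClasses = c("character", "integer", "character",
                                    "character", "numeric"))
  }
  need <- c("chain", "seq", "ins", "comp_id", "rsr")
  if (!all(need %in% names(df)))
    stop("RSR table must have columns: ", paste(need, collapse = ", "))
  if (any(df$rsr < 0, na.rm = TRUE)) stop("RSR values must be >= 0")
  df$ins[is.na(df$ins)] <- ""
  df
}

#' @rdname readRsrTable
#' @param rsr RSR data.frame.
#' @param path output file path.
#' @export
writeRsrTable <- function(rsr, path) {
  write.table(rsr, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.rsrLookup <- function(rsr, compId, chain, seq, ins) {
  hit <- which(rsr$chain == chain & rsr$seq == seq &
                 rsr$ins == ins & toupper(rsr$comp_id) == toupper(compId))
  if (length(hit)) rsr$rsr[hit[1]] else NA_real_
}

#' Local ligand density fit (LLDF)
#'
#' The Z-score of a ligand's real-space R-value relative to the mean and
#' sample standard deviation (n-1) of the RSR values of the neighbouring
#' polymeric standard residues -- the 20 amino acids and standard
#' nucleotides -- having any atom (or crystallographic symmetry image)
#' within the cutoff (5 Angstrom) of any ligand atom. Values above 2 are
#' flagged. Fewer than two RSR-carrying neighbours, or a zero neighbour
#' spread, leave the score undefined and are an error rather than a
#' silent zero.
#'
#' @param model a [StructureModel-class].
#' @param rsr RSR table from [readRsrTable()].
#' @param ligandKeys component key(s) of the ligand (a group passes all its
#'   members; the group carries one RSR row, looked up by its first
#'   component).
#' @param cutoff neighbour cutoff in Angstrom (default 5.0).
#' @return an [LldfResult-class].
#' @export
lldf <- function(model, rsr, ligandKeys, cutoff = .LLDF_CUTOFF) {
  comp <- modelComponents(model)
  ligRows <- comp[comp$key %in% ligandKeys, , drop = FALSE]
  if (!nrow(ligRows)) stop("no such ligand component(s): ",
                           paste(ligandKeys, collapse = ", "))
  ligandRsr <- NA_real_
  for (i in seq_len(nrow(ligRows))) {
    ligandRsr <- .rsrLookup(rsr, ligRows$compId[i], ligRows$authChain[i],
                            ligRows$authSeq[i], ligRows$insCode[i])
    if (!is.na(ligandRsr)) break
  }
  if (is.na(ligandRsr))
    stop("ligand ", paste(ligandKeys, collapse = "+"),
         " is missing from the RSR table")
  contacts <- .contactScan(model, ligRows$key, cutoff,
                           useSymmetry = !is.null(model@cell),
                           includeWaters = FALSE)
  std <- contacts[.isStandardResidue(contacts$compId), , drop = FALSE]
  # restrict to residues that are polymeric in this model
  stdKeys <- .compKey(std$compId, std$authChain, std$authSeq, std$insCode)
  polyKeys <- comp$key[comp$isPolymerResidue]
  std <- std[stdKeys %in% polyKeys, , drop = FALSE]
  if (nrow(std)) {
    std$rsr <- vapply(seq_len(nrow(std)), function(i)
      .rsrLookup(rsr, std$compId[i], std$authChain[i], std$authSeq[i],
                 std$insCode[i]), numeric(1))
    std <- std[!is.na(std$rsr), , drop = FALSE]
  }
  if (nrow(std) < 2L)
    stop("LLDF undefined: fewer than 2 neighbouring standard residues ",
         "with RSR values (found ", nrow(std), ")")
  m <- mean(std$rsr)
  sdev <- sd(std$rsr)
  if (sdev == 0)
    stop("LLDF undefined: neighbour RSR standard deviation is zero")
  z <- (ligandRsr - m) / sdev
  new("LldfResult",
      ligand = ligRows[, c("compId", "authChain", "authSeq", "insCode", "key")],
      ligandRsr = ligandRsr, neighbors = std, nNeighbors = nrow(std),
      meanRsr = m, sdRsr = sdev, lldf = z, flagged = z > .LLDF_FLAG)
}

#' Format a ligand validation report
#'
#' Structured, JSON-like text plus a human-readable summary naming the
#' ligands whose LLDF exceeds the flagging threshold.
#'
#' @param lldfResults list of [LldfResult-class].
#' @param geometryReports optional named list of [GeometryReport-class].
#' @return single character string.
#' @export
formatValidationReport <- function(lldfResults, geometryReports = list()) {
  ligName <- function(res)
    paste(res@ligand$compId[1], res@ligand$authChain[1], res@ligand$authSeq[1])
  lines <- c("{", '  "ligands": [')
  for (i in seq_along(lldfResults)) {
    res <- lldfResults[[i]]
    lines <- c(lines, sprintf(
      '    {"ligand": "%s", "rsr": %.4f, "n_neighbors": %d, "mean_rsr": %.4f, "sd_rsr": %.4f, "lldf": %.3f, "flagged": %s}%s',
      ligName(res), res@ligandRsr, res@nNeighbors, res@meanRsr, res@sdRsr,
      res@lldf, if (res@flagged) "true" else "false",
      if (i < length(lldfResults)) "," else ""))
  }
  lines <- c(lines, "  ]", "}")
  flagged <- Filter(isFlagged, lldfResults)
  lines <- c(lines, "", sprintf("Ligand validation summary: %d ligand(s), %d flagged (LLDF > %g).",
                                length(lldfResults), length(flagged), .LLDF_FLAG))
  for (res in flagged)
    lines <- c(lines, sprintf("  FLAGGED %s: LLDF = %.2f", ligName(res),
                              res@lldf))
  for (nm in names(geometryReports)) {
    gr <- geometryReports[[nm]]
    lines <- c(lines, sprintf(
      "  geometry %s: rmsZ(bonds) = %s, rmsZ(angles) = %s, chirality flips: %s",
      nm,
      ifelse(is.na(gr@rmsZBonds), "n/a", sprintf("%.2f", gr@rmsZBonds)),
      ifelse(is.na(gr@rmsZAngles), "n/a", sprintf("%.2f", gr@rmsZAngles)),
      if (length(gr@chiralityFlips)) paste(gr@chiralityFlips, collapse = ",")
      else "none"))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
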