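## Covalent-linkage and metal-coordination annotation: inter-component
## bonds (_struct_conn), coordination centres with all pairwise angles
## (REMARK 620 / _pdbx_struct_conn_angle).

.LINK_SCAN_RADIUS <- 3.5   # covers covalent range and all metal cutoffs

.linkageRow <- function(kind, a, b, symB, d) {
  data.frame(kind = kind,
             compId1 = a$compId, chain1 = a$authChain, seq1 = a$authSeq,
             ins1 = a$insCode, atom1 = a$atomName, alt1 = a$altLoc,
             sym1 = symLabel(1L),
             compId2 = b$compId, chain2 = b$authChain, seq2 = b$authSeq,
             ins2 = b$insCode, atom2 = b$atomName, alt2 = b$altLoc,
             sym2 = symB, distance = d, stringsAsFactors = FALSE)
}

.emptyLinkages <- function() {
  data.frame(kind = character(0), compId1 = character(0),
             chain1 = character(0), seq1 = integer(0), ins1 = character(0),
             atom1 = character(0), alt1 = character(0), sym1 = character(0),
             compId2 = character(0), chain2 = character(0), seq2 = integer(0),
             ins2 = character(0), atom2 = character(0), alt2 = character(0),
             sym2 = character(0), distance = numeric(0),
             stringsAsFactors = FALSE)
}

## TRUE for the standard polymer backbone bond between sequence-adjacent
## residues of the same chain: peptide C-N and nucleic O3'-P. Genuine
## nonstandard cross-links (different chains, non-adjacent residues or
## other atom pairs) are retained.
.isBackboneBond <- function(a, b) {
  if (a$authChain != b$authChain) return(FALSE)
  if (abs(a$authSeq - b$authSeq) != 1L) return(FALSE)
  pep <- (a$atomName == "C" & b$atomName == "N" & a$authSeq + 1L == b$authSeq) |
         (b$atomName == "C" & a$atomName == "N" & b$authSeq + 1L == a$authSeq)
  nuc <- (a$atomName == "O3'" & b$atomName == "P" & a$authSeq + 1L == b$authSeq) |
         (b$atomName == "O3'" & a$atomName == "P" & b$authSeq + 1L == a$authSeq)
  pep || nuc
}

.classifyPair <- function(a, b, d, tol, metalCutoffs) {
  elA <- toupper(a$element); elB <- toupper(b$element)
  metalA <- elA %in% .COORDINATION_METALS
  metalB <- elB %in% .COORDINATION_METALS
  if (xor(metalA, metalB)) {
    metal <- if (metalA) elA else elB
    donor <- if (metalA) elB else elA
    if (donor %in% .METAL_DONORS && d <= .metalCutoff(metal, donor, metalCutoffs))
      return("metalc")
  }
  if (d > covalentRadius(elA) + covalentRadius(elB) + tol) return(NA_character_)
  if (metalA || metalB) return("metalc")
  if (elA == "S" && elB == "S" &&
      toupper(a$compId) == "CYS" && toupper(b$compId) == "CYS")
    return("disulf")
  if (.isWater(a$compId) || .isWater(b$compId)) return(NA_character_)
  "covale"
}

#' Detect covalent linkages between components
#'
#' Scans all inter-component atom pairs (crystallographic symmetry
#' included when a cell is present) with the bond-perception distance
#' criterion plus the metal-coordination cutoff table, and classifies each
#' link: S-S between two cysteines is \code{disulf}, metal-donor pairs are
#' \code{metalc}, everything else in covalent range is \code{covale}.
#' Standard polymer backbone bonds (peptide C-N and nucleic O3'-P between
#' sequence-adjacent residues of a chain) are excluded; hydrogens are
#' ignored.
#'
#' @param model a [StructureModel-class].
#' @param dictionary optional dictionary (accepted for interface
#'   compatibility; the criterion is geometric).
#' @param matches optional component matches (idem).
#' @param tol covalent perception tolerance (default 0.45 Angstrom).
#' @param metalCutoffs optional named list overriding metal-donor cutoffs,
#'   keys like \code{"ZN|O"} plus optional \code{"default"}.
#' @return data.frame of linkages: kind (covale/metalc/disulf), the two
#'   partners (comp id, chain, seq, insertion code, atom, altloc, symmetry
#'   label) and the distance.
#' @export
detectLinkages <- function(model, dictionary = NULL, matches = NULL,
                           tol = .BOND_TOL, metalCutoffs = NULL) {
  s <- model@atomSites
  s <- s[!(s$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(s) < 2L) return(.emptyLinkages())
  key <- .siteKeys(s)
  out <- list(); nout <- 0L
  addPair <- function(a, b, symB, d) {
    kind <- .classifyPair(a, b, d, tol, metalCutoffs)
    if (is.na(kind)) return(invisible())
    if (kind == "covale" && .isBackboneBond(a, b)) return(invisible())
    altOk <- a$altLoc == b$altLoc || a$altLoc == "" || b$altLoc == ""
    if (!altOk) return(invisible())
    nout <<- nout + 1L
    out[[nout]] <<- .linkageRow(kind, a, b, symB, d)
  }
  # identity copies: all-pairs scan
  X <- as.matrix(s[, c("x", "y", "z")])
  D <- as.matrix(dist(X))
  cand <- which(D <= .LINK_SCAN_RADIUS & upper.tri(D), arr.ind = TRUE)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (key[i] == key[j]) next
    addPair(s[i, , drop = FALSE], s[j, , drop = FALSE],
            symLabel(1L), D[i, j])
  }
  # symmetry images against the identity copy
  if (!is.null(model@cell) && length(model@cell@operators) >= 1L) {
    fullModel <- model
    fullModel@atomSites <- s
    img <- expandSymmetry(fullModel, seq_len(nrow(s)), .LINK_SCAN_RADIUS)
    img <- img[img$symLabel != symLabel(1L), , drop = FALSE]
    if (nrow(img)) {
      Y <- as.matrix(img[, c("x", "y", "z")])
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * (X %*% t(Y))
      hits <- which(d2 <= .LINK_SCAN_RADIUS^2, arr.ind = TRUE)
      for (r in seq_len(nrow(hits))) {
        i <- hits[r, 1]; m <- hits[r, 2]
        d <- sqrt(max(0, d2[i, m]))
        addPair(s[i, , drop = FALSE], img[m, , drop = FALSE],
                img$symLabel[m], d)
      }
    }
  }
  if (!nout) return(.emptyLinkages())
  res <- do.call(rbind, out)
  # canonical dedup: unordered partner pair + symmetry relation
  p1 <- paste(res$compId1, res$chain1, res$seq1, res$ins1, res$atom1,
              res$alt1, res$sym1)
  p2 <- paste(res$compId2, res$chain2, res$seq2, res$ins2, res$atom2,
              res$alt2, res$sym2)
  dedupKey <- paste(pmin(p1, p2), pmax(p1, p2), round(res$distance, 3))
  res <- res[!duplicated(dedupKey), , drop = FALSE]
  res <- res[order(res$kind, res$chain1, res$seq1, res$atom1,
                   res$chain2, res$seq2, res$atom2, res$sym2), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.angleDeg <- function(a, m, b) {
  u <- a - m; v <- b - m
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Metal coordination centre with all pairwise angles
#'
#' Collects the donor atoms (N, O, S, Se and halides) within the
#' element-pair cutoff of a metal atom -- crystallographic symmetry
#' included, and with alternate conformers kept as separate ligators, the
#' way curation lists both conformers of a disordered carboxylate -- and
#' computes every pairwise angle subtended at the metal: k ligators give
#' k(k-1)/2 angles.
#'
#' @param model a [StructureModel-class].
#' @param metalAtom one row of \code{atomSites(model)} (or its row index)
#'   whose element is a supported coordination metal.
#' @param metalCutoffs optional cutoff overrides (see [detectLinkages()]).
#' @return a [CoordinationCenter-class].
#' @export
coordinationCenter <- function(model, metalAtom, metalCutoffs = NULL) {
  s <- model@atomSites
  if (is.numeric(metalAtom)) metalAtom <- s[metalAtom, , drop = FALSE]
  metal <- toupper(metalAtom$element[1])
  if (!(metal %in% .COORDINATION_METALS))
    stop("unsupported coordination metal: ", metal, " (supported: ",
         paste(.COORDINATION_METALS, collapse = ", "), ")")
  mpos <- as.numeric(metalAtom[1, c("x", "y", "z")])
  maxCut <- max(unlist(.METAL_CUTOFFS), .METAL_CUTOFF_DEFAULT,
                unlist(metalCutoffs))
  if (!is.null(model@cell)) {
    img <- expandSymmetry(model, metalAtom, maxCut)
  } else {
    d <- sqrt(rowSums(sweep(as.matrix(s[, c("x", "y", "z")]), 2, mpos)^2))
    keep <- which(d <= maxCut & d > 0)
    img <- s[keep, , drop = FALSE]
    if (nrow(img)) {
      img$symLabel <- symLabel(1L)
      img$distance <- d[keep]
    } else img$symLabel <- character(0)
  }
  if (nrow(img)) {
    donors <- toupper(img$element) %in% .METAL_DONORS
    within <- vapply(seq_len(nrow(img)), function(i)
      img$distance[i] <= .metalCutoff(metal, img$element[i], metalCutoffs),
      logical(1))
    img <- img[donors & within, , drop = FALSE]
  }
  lig <- if (nrow(img)) data.frame(
    compId = img$compId, authChain = img$authChain, authSeq = img$authSeq,
    insCode = img$insCode, atomName = img$atomName, altLoc = img$altLoc,
    symLabel = img$symLabel, distance = img$distance,
    x = img$x, y = img$y, z = img$z, stringsAsFactors = FALSE)
  else data.frame(compId = character(0), authChain = character(0),
                  authSeq = integer(0), insCode = character(0),
                  atomName = character(0), altLoc = character(0),
                  symLabel = character(0), distance = numeric(0),
                  x = numeric(0), y = numeric(0), z = numeric(0),
                  stringsAsFactors = FALSE)
  lig <- lig[order(lig$authChain, lig$authSeq, lig$atomName, lig$altLoc,
                   lig$symLabel), , drop = FALSE]
  rownames(lig) <- NULL
  k <- nrow(lig)
  ang <- if (k >= 2L) {
    pairs <- t(combn(k, 2))
    data.frame(i = pairs[, 1], j = pairs[, 2],
               degrees = vapply(seq_len(nrow(pairs)), function(r)
                 .angleDeg(as.numeric(lig[pairs[r, 1], c("x", "y", "z")]),
                           mpos,
                           as.numeric(lig[pairs[r, 2], c("x", "y", "z")])),
                 numeric(1)),
               stringsAsFactors = FALSE)
  } else data.frame(i = integer(0), j = integer(0), degrees = numeric(0))
  new("CoordinationCenter",
      metal = metalAtom[1, , drop = FALSE], ligators = lig, angles = ang)
}

#' Write coordination centres as REMARK 620
#'
#' Fixed-column PDB REMARK 620 block per centre: the ligator list with one
#' angle column per previously listed ligator (the lower triangle of the
#' angle matrix, 0.1 degree precision).
#'
#' @param centers list of [CoordinationCenter-class].
#' @return character string of REMARK 620 text.
#' @export
writeRemark620 <- function(centers) {
  out <- c("REMARK 620",
           "REMARK 620 METAL COORDINATION",
           "REMARK 620 (M=MODEL NUMBER; RES=RESIDUE NAME; C=CHAIN IDENTIFIER; SSEQ=SEQUENCE NUMBER; I=INSERTION CODE):")
  for (cc in centers) {
    m <- cc@metal
    out <- c(out, "REMARK 620",
             "REMARK 620 COORDINATION ANGLES FOR:  M RES CSSEQI METAL",
             sprintf("REMARK 620                      1 %3s %1s%4d%1s  %2s",
                     m$compId[1], m$authChain[1], m$authSeq[1],
                     ifelse(nzchar(m$insCode[1]), m$insCode[1], " "),
                     toupper(m$element[1])),
             "REMARK 620 N RES CSSEQI ATOM")
    lig <- cc@ligators
    ang <- cc@angles
    for (i in seq_len(nrow(lig))) {
      nm <- lig$atomName[i]
      if (nzchar(lig$altLoc[i])) nm <- paste0(nm, "(", lig$altLoc[i], ")")
      row <- sprintf("REMARK 620 %1d %3s %1s%4d%1s  %-8s",
                     i, lig$compId[i], lig$authChain[i], lig$authSeq[i],
                     ifelse(nzchar(lig$insCode[i]), lig$insCode[i], " "), nm)
      if (i > 1L) {
        vals <- vapply(seq_len(i - 1L), function(j) {
          deg <- ang$degrees[(ang$i == j & ang$j == i) |
                               (ang$i == i & ang$j == j)]
          sprintf("%6.1f", deg[1])
        }, character(1))
        row <- paste0(row, paste(vals, collapse = ""))
      }
      out <- c(out, row)
    }
    if (nrow(lig) > 1L)
      out <- c(out, paste0("REMARK 620 N", strrep(" ", 21),
                           paste(sprintf("%6d", seq_len(nrow(lig) - 1L)),
                                 collapse = "")))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Read REMARK 620 angles back
#'
#' Re-extracts the ligator lists and angle values from REMARK 620 text;
#' used for round-trip verification at 0.1 degree precision.
#'
#' @param text REMARK 620 text.
#' @return list with one element per centre:
#'   \code{list(metal, ligators, angles)}; angles is a data.frame(i, j,
#'   degrees).
#' @export
parseRemark620 <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n")[[1]]
  centers <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) centers[[length(centers) + 1L]] <<- cur
  }
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^REMARK 620 COORDINATION ANGLES FOR:", ln)) {
      flush()
      metalLine <- lines[i + 1L]
      cur <- list(metal = trimws(substr(metalLine, 35, 47)),
                  ligators = character(0),
                  angles = data.frame(i = integer(0), j = integer(0),
                                      degrees = numeric(0)))
      i <- i + 3L
    } else if (!is.null(cur) && grepl("^REMARK 620 [1-9] ", ln)) {
      idx <- as.integer(substr(ln, 12, 12))
      cur$ligators <- c(cur$ligators, trimws(substr(ln, 14, 33)))
      if (idx > 1L) {
        tail <- substring(ln, 34)
        vals <- suppressWarnings(as.numeric(
          regmatches(tail, gregexpr("-?[0-9]+\\.[0-9]", tail))[[1]]))
        for (j in seq_along(vals)) {
          cur$angles <- rbind(cur$angles,
                              data.frame(i = j, j = idx, degrees = vals[j]))
        }
      }
      i <- i + 1L
    } else i <- i + 1L
  }
  flush()
  centers
}

.connPtnr <- function(prefix, compId, chain, seq, ins, atom, alt, sym) {
  df <- data.frame(
    auth_comp_id = compId, auth_asym_id = chain,
    auth_seq_id = as.character(seq),
    ins_code = ifelse(nzchar(ins), ins, NA_character_),
    label_atom_id = atom,
    label_alt_id = ifelse(nzchar(alt), alt, NA_character_),
    symmetry = sym, stringsAsFactors = FALSE)
  names(df) <- paste0(prefix, "_", names(df))
  df
}

#' Write linkages as a _struct_conn category
#'
#' @param linkages data.frame from [detectLinkages()].
#' @param asText return mmCIF text (default) or the category list.
#' @return mmCIF text or category list.
#' @export
writeStructConn <- function(linkages, asText = TRUE) {
  if (!nrow(linkages)) {
    return(if (asText) writeCif(list(list(name = "links",
                                          categories = list()))) else list())
  }
  rows <- cbind(
    data.frame(id = paste0(linkages$kind,
                           stats::ave(seq_len(nrow(linkages)), linkages$kind,
                                      FUN = seq_along)),
               conn_type_id = linkages$kind, stringsAsFactors = FALSE),
    .connPtnr("ptnr1", linkages$compId1, linkages$chain1, linkages$seq1,
              linkages$ins1, linkages$atom1, linkages$alt1, linkages$sym1),
    .connPtnr("ptnr2", linkages$compId2, linkages$chain2, linkages$seq2,
              linkages$ins2, linkages$atom2, linkages$alt2, linkages$sym2),
    data.frame(pdbx_dist_value = sprintf("%.3f", linkages$distance),
               stringsAsFactors = FALSE))
  cats <- list(struct_conn = structure(rows, loop = TRUE))
  if (asText) writeCif(list(list(name = "links", categories = cats))) else cats
}

#' Read a _struct_conn category back into a linkage table
#'
#' @param text mmCIF text containing \code{_struct_conn}.
#' @return linkage data.frame in the layout of [detectLinkages()].
#' @export
parseStructConn <- function(text) {
  blocks <- parseCif(text)
  sc <- NULL
  for (b in blocks) {
    sc <- .getCat(b, "struct_conn")
    if (!is.null(sc)) break
  }
  if (is.null(sc)) return(.emptyLinkages())
  chr0 <- function(x) { x[is.na(x)] <- ""; x }
  data.frame(kind = sc$conn_type_id,
             compId1 = sc$ptnr1_auth_comp_id, chain1 = sc$ptnr1_auth_asym_id,
             seq1 = as.integer(sc$ptnr1_auth_seq_id),
             ins1 = chr0(.catChr(sc, "ptnr1_ins_code")),
             atom1 = sc$ptnr1_label_atom_id,
             alt1 = chr0(.catChr(sc, "ptnr1_label_alt_id")),
             sym1 = sc$ptnr1_symmetry,
             compId2 = sc$ptnr2_auth_comp_id, chain2 = sc$ptnr2_auth_asym_id,
             seq2 = as.integer(sc$ptnr2_auth_seq_id),
             ins2 = chr0(.catChr(sc, "ptnr2_ins_code")),
             atom2 = sc$ptnr2_label_atom_id,
             alt2 = chr0(.catChr(sc, "ptnr2_label_alt_id")),
             sym2 = sc$ptnr2_symmetry,
             distance = as.numeric(sc$pdbx_dist_value),
             stringsAsFactors = FALSE)
}

#' Write coordination angles as _pdbx_struct_conn_angle
#'
#' One row per pairwise angle: partners 1 and 3 are the ligators, partner
#' 2 the metal, \code{value} the angle in degrees (0.1 precision).
#'
#' @param centers list of [CoordinationCenter-class].
#' @param asText return mmCIF text (default) or the category list.
#' @return mmCIF text or category list.
#' @export
writeConnAngle <- function(centers, asText = TRUE) {
  rows <- list()
  for (cc in centers) {
    lig <- cc@ligators; ang <- cc@angles; m <- cc@metal
    if (!nrow(ang)) next
    for (r in seq_len(nrow(ang))) {
      li <- lig[ang$i[r], ]; lj <- lig[ang$j[r], ]
      rows[[length(rows) + 1L]] <- cbind(
        .connPtnr("ptnr1", li$compId, li$authChain, li$authSeq, li$insCode,
                  li$atomName, li$altLoc, li$symLabel),
        .connPtnr("ptnr2", m$compId[1], m$authChain[1], m$authSeq[1],
                  m$insCode[1], m$atomName[1], m$altLoc[1], symLabel(1L)),
        .connPtnr("ptnr3", lj$compId, lj$authChain, lj$authSeq, lj$insCode,
                  lj$atomName, lj$altLoc, lj$symLabel),
        data.frame(value = sprintf("%.1f", ang$degrees[r]),
                   stringsAsFactors = FALSE))
    }
  }
  cats <- if (length(rows)) {
    df <- do.call(rbind, rows)
    df <- cbind(data.frame(id = as.character(seq_len(nrow(df))),
                           stringsAsFactors = FALSE), df)
    list(pdbx_struct_conn_angle = structure(df, loop = TRUE))
  } else list()
  if (asText) writeCif(list(list(name = "angles", categories = cats))) else cats
}

#' Read _pdbx_struct_conn_angle values back
#'
#' @param text mmCIF text containing \code{_pdbx_struct_conn_angle}.
#' @return data.frame with ligator/metal identifiers and \code{value}
#'   (degrees), one row per angle.
#' @export
parseConnAngle <- function(text) {
  blocks <- parseCif(text)
  ca <- NULL
  for (b in blocks) {
    ca <- .getCat(b, "pdbx_struct_conn_angle")
    if (!is.null(ca)) break
  }
  if (is.null(ca))
    return(data.frame(value = numeric(0)))
  ca$value <- as.numeric(ca$value)
  ca
}
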