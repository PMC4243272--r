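## Component identification against the dictionary: distance-based bond
## perception, element-labelled graph matching tolerant of absent
## hydrogens and leaving atoms, atom renaming, and drafting of new
## definitions for molecules new to the archive.

.BOND_TOL <- 0.45      # perception tolerance, Angstrom
.MIN_BOND <- 0.4       # below this atoms are considered coincident, not bonded

.TYPICAL_VALENCE <- c(H = 1, D = 1, C = 4, N = 3, O = 2, S = 2, P = 5,
                      F = 1, CL = 1, BR = 1, I = 1, B = 3, SE = 2, SI = 4)

#' Perceive covalent bonds from coordinates
#'
#' Two atoms are bonded iff their distance is at most the sum of their
#' single-bond covalent radii plus a tolerance (default 0.45 Angstrom,
#' chosen to accept standard covalent bonds while rejecting hydrogen-bond
#' distances, which are at least ~2.4 Angstrom heavy-to-heavy), and their
#' altlocs are compatible (equal, or either blank). Coincident atoms
#' (< 0.4 Angstrom) are never bonded.
#'
#' @param component data.frame of atom sites (needs atomName, element,
#'   altLoc, x, y, z).
#' @param tol perception tolerance in Angstrom.
#' @return data.frame with one row per bonded pair: i, j (row indices,
#'   i < j), atomName1, atomName2, distance.
#' @export
perceiveBonds <- function(component, tol = .BOND_TOL) {
  a <- component
  if (nrow(a) < 1L) stop("component has no atoms")
  r <- covalentRadius(a$element)   # errors on unknown elements
  if (nrow(a) == 1L) {
    return(data.frame(i = integer(0), j = integer(0),
                      atomName1 = character(0), atomName2 = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  }
  X <- as.matrix(a[, c("x", "y", "z")])
  D <- as.matrix(dist(X))
  thresh <- outer(r, r, "+") + tol
  alt <- if ("altLoc" %in% names(a)) a$altLoc else rep("", nrow(a))
  alt[is.na(alt)] <- ""
  altOk <- outer(alt, alt, function(u, v) u == v | u == "" | v == "")
  hit <- which(D <= thresh & D > .MIN_BOND & altOk & upper.tri(D), arr.ind = TRUE)
  data.frame(i = hit[, 1], j = hit[, 2],
             atomName1 = a$atomName[hit[, 1]],
             atomName2 = a$atomName[hit[, 2]],
             distance = D[hit], stringsAsFactors = FALSE)
}

## Collapse altloc copies: one representative row per atom name.
.uniqueAtomRows <- function(component) {
  component[!duplicated(component$atomName), , drop = FALSE]
}

## Element-labelled graph of an observed component (heavy atoms only).
.observedGraph <- function(component) {
  heavy <- component[!(component$element %in% c("H", "D")), , drop = FALSE]
  ua <- .uniqueAtomRows(heavy)
  if (!nrow(ua)) return(NULL)
  bonds <- if (nrow(heavy) > 1L) perceiveBonds(heavy) else NULL
  g <- igraph::make_empty_graph(n = nrow(ua), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ua$atomName)
  g <- igraph::set_vertex_attr(g, "element", value = ua$element)
  if (!is.null(bonds) && nrow(bonds)) {
    e <- unique(data.frame(a = pmin(bonds$atomName1, bonds$atomName2),
                           b = pmax(bonds$atomName1, bonds$atomName2),
                           stringsAsFactors = FALSE))
    g <- igraph::add_edges(g, rbind(match(e$a, ua$atomName),
                                    match(e$b, ua$atomName)))
  }
  list(graph = g, atoms = ua)
}

.kabschRmsd <- function(P, Q) {
  ## optimal rigid superposition of P onto Q, both n x 3
  keep <- stats::complete.cases(P) & stats::complete.cases(Q)
  P <- P[keep, , drop = FALSE]; Q <- Q[keep, , drop = FALSE]
  if (nrow(P) == 0L) return(NA_real_)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
}

.dictCoords <- function(def, atomIds) {
  a <- def@atoms[match(atomIds, def@atoms$atomId), , drop = FALSE]
  if (all(!is.na(a$idealX))) {
    as.matrix(a[, c("idealX", "idealY", "idealZ")])
  } else {
    as.matrix(a[, c("modelX", "modelY", "modelZ")])
  }
}

.matchKey <- function(match) {
  nOther <- sum(match@missingAtoms$kind == "other")
  mapStr <- paste(match@atomMap[order(names(match@atomMap))], collapse = "|")
  list(nOther = nOther,
       rmsd = if (is.na(match@rmsdAfterFit)) Inf else match@rmsdAfterFit,
       mapStr = mapStr)
}

.betterMatch <- function(a, b) {
  ## TRUE when a ranks before b: fewest missing non-leaving atoms, then
  ## lowest rmsd after fit, then lexicographic atom map
  ka <- .matchKey(a); kb <- .matchKey(b)
  if (ka$nOther != kb$nOther) return(ka$nOther < kb$nOther)
  if (ka$rmsd != kb$rmsd) return(ka$rmsd < kb$rmsd)
  ka$mapStr < kb$mapStr
}

#' Match an observed component against one dictionary definition
#'
#' Seeks a subgraph embedding of the observed heavy-atom graph (bonds
#' perceived from coordinates) into the dictionary heavy-atom graph with
#' element labels required to agree. Dictionary hydrogens and leaving
#' atoms may be absent from the observation without penalty; a bounded
#' number of other dictionary atoms may also be missing (disordered
#' ligands), up to \code{maxMissingFrac} of the dictionary heavy-atom
#' count. Bond orders are not compared: they are unobservable in X-ray
#' coordinates. Among all embeddings the best is chosen by (fewest missing
#' non-leaving atoms, lowest RMSD after least-squares fit onto dictionary
#' coordinates, lexicographic atom map).
#'
#' @param component data.frame of observed atom sites.
#' @param def a [ChemCompDef-class].
#' @param maxMissingFrac missing-atom budget for non-leaving, non-hydrogen
#'   dictionary atoms, as a fraction of dictionary heavy atoms (default 0.2).
#' @return a [ComponentMatch-class], or NULL when no acceptable embedding
#'   exists (including the zero-heavy-atom case).
#' @export
matchComponent <- function(component, def, maxMissingFrac = 0.2) {
  og <- .observedGraph(component)
  if (is.null(og)) return(NULL)
  dg <- componentGraph(def, includeHydrogens = FALSE, includeLeaving = TRUE)
  nObs <- igraph::vcount(og$graph)
  nDict <- igraph::vcount(dg)
  if (nObs > nDict || nDict == 0L) return(NULL)
  obsEl <- igraph::vertex_attr(og$graph, "element")
  dictEl <- igraph::vertex_attr(dg, "element")
  domains <- lapply(obsEl, function(e) which(dictEl == e))
  if (any(lengths(domains) == 0L)) return(NULL)
  maps <- igraph::subgraph_isomorphisms(pattern = og$graph, target = dg,
                                        method = "lad", domains = domains,
                                        induced = FALSE)
  if (!length(maps)) return(NULL)
  dictAtoms <- def@atoms
  heavyIds <- dictAtoms$atomId[!(dictAtoms$element %in% c("H", "D"))]
  budget <- floor(maxMissingFrac * length(heavyIds) + 1e-9)
  obsNames <- igraph::vertex_attr(og$graph, "name")
  obsXyz <- as.matrix(og$atoms[, c("x", "y", "z")])

  best <- NULL
  for (m in maps) {
    dictIds <- igraph::vertex_attr(dg, "name")[as.integer(m)]
    missing <- setdiff(dictAtoms$atomId, dictIds)
    mrows <- dictAtoms[match(missing, dictAtoms$atomId), , drop = FALSE]
    kind <- ifelse(mrows$element %in% c("H", "D"), "hydrogen",
                   ifelse(mrows$leaving, "leaving", "other"))
    if (sum(kind == "other") > budget) next
    amap <- stats::setNames(dictIds, obsNames)
    rmsd <- .kabschRmsd(obsXyz, .dictCoords(def, dictIds))
    hObs <- component$atomName[component$element %in% c("H", "D")]
    cand <- new("ComponentMatch", compId = def@compId, atomMap = amap,
                missingAtoms = data.frame(atomId = missing, kind = kind,
                                          stringsAsFactors = FALSE),
                extraAtoms = unique(hObs),
                rmsdAfterFit = rmsd,
                # exact means the free form was observed in full: any
                # missing heavy atom, leaving included, drops the flag
                # (a bound sugar without O1 is identified but not exact)
                exact = sum(kind != "hydrogen") == 0L)
    if (is.null(best) || .betterMatch(cand, best)) best <- cand
  }
  best
}

#' Identify a component against a dictionary
#'
#' Pre-filters dictionary candidates by heavy-atom element multiset
#' (observed counts must not exceed dictionary counts, and the total
#' deficit must be coverable by leaving atoms plus the missing-atom
#' budget), then matches each candidate and ranks the results best-first
#' by the match tie-break key. An empty result means the molecule is new
#' to the archive and a draft definition should be built.
#'
#' @param component data.frame of observed atom sites.
#' @param dictionary list of [ChemCompDef-class] (nonempty).
#' @param maxMissingFrac see [matchComponent()].
#' @return list of [ComponentMatch-class], best first (possibly empty).
#' @export
identifyComponent <- function(component, dictionary, maxMissingFrac = 0.2) {
  if (!length(dictionary)) stop("dictionary is empty")
  heavy <- component[!(component$element %in% c("H", "D")), , drop = FALSE]
  obsCounts <- table(toupper(.uniqueAtomRows(heavy)$element))
  candidates <- Filter(function(def) {
    da <- def@atoms[!(def@atoms$element %in% c("H", "D")), , drop = FALSE]
    dictCounts <- table(toupper(da$element))
    for (e in names(obsCounts)) {
      nd <- if (e %in% names(dictCounts)) dictCounts[[e]] else 0L
      if (obsCounts[[e]] > nd) return(FALSE)
    }
    deficit <- sum(dictCounts) - sum(obsCounts)
    budget <- floor(maxMissingFrac * nrow(da) + 1e-9)
    deficit <= sum(da$leaving) + budget
  }, dictionary)
  matches <- Filter(Negate(is.null),
                    lapply(candidates, matchComponent, component = component,
                           maxMissingFrac = maxMissingFrac))
  if (length(matches) > 1L) {
    ord <- order(vapply(matches, function(m) .matchKey(m)$nOther, numeric(1)),
                 vapply(matches, function(m) .matchKey(m)$rmsd, numeric(1)),
                 vapply(matches, function(m) .matchKey(m)$mapStr, character(1)))
    matches <- matches[ord]
  }
  unname(matches)
}

#' Rename observed atoms to dictionary nomenclature
#'
#' Replaces observed atom names by their mapped dictionary atom ids;
#' coordinates are untouched. Observed atoms outside the map keep their
#' original names and are reported in the \code{"unmappedAtoms"}
#' attribute of the result.
#'
#' @param component data.frame of observed atom sites.
#' @param match the [ComponentMatch-class] obtained from this component.
#' @return the component with updated atom names.
#' @export
renameAtoms <- function(component, match) {
  amap <- match@atomMap
  absent <- setdiff(names(amap), component$atomName)
  if (length(absent))
    stop("atom map references atom(s) absent from the component: ",
         paste(absent, collapse = ", "))
  idx <- match(component$atomName, names(amap))
  renamed <- component
  renamed$atomName <- ifelse(is.na(idx), component$atomName, amap[idx])
  attr(renamed, "unmappedAtoms") <- unique(component$atomName[is.na(idx)])
  renamed
}

.signedVolume <- function(center, n1, n2, n3) {
  det(rbind(n1 - center, n2 - center, n3 - center)) / 6
}

## Draft stereo assignment: substituents ranked by atomic number (ties by
## name); positive signed volume of the top three about the centre -> "R",
## negative -> "S", |V| <= 0.1 A^3 -> "N". A convention, not full CIP.
.stereoFromGeometry <- function(center, subs) {
  if (nrow(subs) < 3L) return("N")
  z <- .atomicMass(subs$element)   # mass ranks identically to Z here
  ord <- order(-z, subs$atomName)
  subs <- subs[ord[1:3], , drop = FALSE]
  v <- .signedVolume(center, as.numeric(subs[1, c("x", "y", "z")]),
                     as.numeric(subs[2, c("x", "y", "z")]),
                     as.numeric(subs[3, c("x", "y", "z")]))
  if (abs(v) <= 0.1) "N" else if (v > 0) "R" else "S"
}

.ringIsPlanar <- function(X, tolA = 0.1) {
  Xc <- sweep(X, 2, colMeans(X))
  s <- svd(Xc)
  sqrt(mean((Xc %*% s$v[, 3])^2)) < tolA
}

#' Draft a new dictionary definition from an observed component
#'
#' For molecules absent from the dictionary: copies the observed atoms and
#' perceived bonds into a definition with the observed coordinates stored
#' as the model conformer (no idealized coordinates are generated). Bond
#' orders come from a greedy valence-satisfaction heuristic plus aromatic
#' perception for planar six-membered C/N rings, and tetrahedral
#' stereocentres are assigned from the signed volume of their
#' substituents; the result is draft quality and marked for curator
#' review via an audit category.
#'
#' @param component data.frame of observed atom sites.
#' @param proposedId new component id (must not collide with the dictionary).
#' @param dictionary optional list of existing definitions to check the id
#'   against.
#' @return a draft [ChemCompDef-class] that passes [validateDef()].
#' @export
buildNewDefinition <- function(component, proposedId, dictionary = list()) {
  proposedId <- toupper(proposedId)
  existing <- vapply(dictionary, compId, character(1))
  if (proposedId %in% existing)
    stop("proposed id '", proposedId, "' already exists in the dictionary")
  ua <- .uniqueAtomRows(component)
  pb <- perceiveBonds(ua)
  n <- nrow(ua)
  deg <- tabulate(c(pb$i, pb$j), nbins = n)
  el <- toupper(ua$element)
  valence <- .TYPICAL_VALENCE[el]
  valence[is.na(valence)] <- 8   # effectively unconstrained

  bondOrder <- rep("SING", nrow(pb))
  aromaticAtom <- rep(FALSE, n)
  # aromatic perception: planar 6-rings of C/N
  if (nrow(pb)) {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::add_edges(g, rbind(pb$i, pb$j))
    rings <- tryCatch(.findSixRings(g), error = function(e) list())
    for (ring in rings) {
      if (all(el[ring] %in% c("C", "N")) &&
          .ringIsPlanar(as.matrix(ua[ring, c("x", "y", "z")]))) {
        aromaticAtom[ring] <- TRUE
        inRing <- (pb$i %in% ring) & (pb$j %in% ring)
        bondOrder[inRing] <- "AROM"
      }
    }
  }
  # greedy upgrade SING -> DOUB between mutually under-valent atoms whose
  # distance is short enough for a multiple bond (hydrogens are routinely
  # unobserved, so under-valence alone is not evidence: an isolated C-C
  # pair at 1.54 A stays single), shortest bonds first
  bondVal <- c(SING = 1, DOUB = 2, TRIP = 3, AROM = 1.5)
  doubleMax <- covalentRadius(el[pb$i]) + covalentRadius(el[pb$j]) - 0.11
  repeat {
    used <- numeric(n)
    for (k in seq_len(nrow(pb)))
      used[c(pb$i[k], pb$j[k])] <- used[c(pb$i[k], pb$j[k])] + bondVal[bondOrder[k]]
    free <- valence - used
    cand <- which(bondOrder == "SING" & free[pb$i] >= 1 & free[pb$j] >= 1 &
                    pb$distance <= doubleMax &
                    !aromaticAtom[pb$i] & !aromaticAtom[pb$j])
    if (!length(cand)) break
    k <- cand[which.min(pb$distance[cand])]
    bondOrder[k] <- "DOUB"
  }

  stereo <- vapply(seq_len(n), function(i) {
    nb <- c(pb$j[pb$i == i], pb$i[pb$j == i])
    if (el[i] != "C" || length(nb) < 3L || length(nb) > 4L) return("N")
    .stereoFromGeometry(as.numeric(ua[i, c("x", "y", "z")]),
                        ua[nb, , drop = FALSE])
  }, character(1))

  atoms <- data.frame(
    atomId = ua$atomName, element = el, charge = 0L,
    aromatic = aromaticAtom, stereoConfig = stereo, leaving = FALSE,
    idealX = NA_real_, idealY = NA_real_, idealZ = NA_real_,
    modelX = ua$x, modelY = ua$y, modelZ = ua$z,
    stringsAsFactors = FALSE)
  bondDf <- if (nrow(pb)) data.frame(
    atomId1 = ua$atomName[pb$i], atomId2 = ua$atomName[pb$j],
    order = bondOrder, aromatic = bondOrder == "AROM", stereo = "N",
    stringsAsFactors = FALSE) else .emptyBonds()

  new("ChemCompDef",
      compId = proposedId,
      name = paste0("draft definition ", proposedId),
      formula = hillFormula(el),
      formulaWeight = sum(.atomicMass(el)),
      formalCharge = 0L,
      compType = "non-polymer",
      pdbxType = "HETAIN",
      atoms = atoms, bonds = bondDf,
      extraCategories = list(
        pdbx_chem_comp_audit = structure(data.frame(
          comp_id = proposedId, action_type = "Create component",
          details = "draft: connectivity, orders and stereo deduced from coordinates; curator review required",
          stringsAsFactors = FALSE), loop = TRUE)))
}

## All simple 6-cycles of a small graph (used for aromatic perception).
.findSixRings <- function(g) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g)
  rings <- list()
  seen <- character(0)
  path <- integer(6)
  dfs <- function(start, v, depth) {
    path[depth] <<- v
    if (depth == 6L) {
      if (start %in% as.integer(adj[[v]])) {
        key <- paste(sort(path), collapse = "-")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1L]] <<- path
        }
      }
      return(invisible())
    }
    for (w in as.integer(adj[[v]])) {
      if (w > start && !(w %in% path[seq_len(depth)])) dfs(start, w, depth + 1L)
    }
  }
  for (v in seq_len(n)) dfs(v, v, 1L)
  rings
}
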