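## Deterministic synthetic-data generator: chemically consistent CCD
## definitions, crystal structures with known ground truth, and RSR
## tables. Every input format the toolkit consumes can be produced here,
## so the full pipeline runs without any external archive.
##
## Ground truth is computed by self-contained brute-force code at the
## bottom of this file (explicit operator x lattice-shift loops with its
## own orthogonalization matrix), deliberately independent of the contact
## engine and linkage detector it is used to check.

## Counter-based derivation: every stochastic draw uses (seed, stream) so
## adding a fixture never shifts the draws of existing ones.
.fixtureSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 100003 + as.numeric(stream) * 7919) %%
               2147483647)
}

.withFixtureSeed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.fixtureSeed(seed, stream))
  force(expr)
}

.atomRow <- function(atomId, element, x, y, z, leaving = FALSE, charge = 0L) {
  data.frame(atomId = atomId, element = element, charge = charge,
             aromatic = FALSE, stereoConfig = "N", leaving = leaving,
             idealX = x, idealY = y, idealZ = z,
             modelX = x, modelY = y, modelZ = z, stringsAsFactors = FALSE)
}

.bondRow <- function(a1, a2, order = "SING") {
  data.frame(atomId1 = a1, atomId2 = a2, order = order,
             aromatic = order == "AROM", stereo = "N",
             stringsAsFactors = FALSE)
}

## assign R/S at carbons with >= 3 heavy neighbours from ideal geometry
.assignStereoFromIdeal <- function(def) {
  a <- def@atoms
  xyz <- as.matrix(a[, c("idealX", "idealY", "idealZ")])
  rownames(xyz) <- a$atomId
  for (i in seq_len(nrow(a))) {
    if (a$element[i] != "C") next
    nb <- .dictNeighbors(def, a$atomId[i])
    if (length(nb) < 3L) next
    v <- .signedVolume(xyz[a$atomId[i], ], xyz[nb[1], ], xyz[nb[2], ],
                       xyz[nb[3], ])
    if (abs(v) > 0.1) a$stereoConfig[i] <- if (v > 0) "R" else "S"
  }
  def@atoms <- a
  def
}

.glcLikeDef <- function(seed) {
  ringNames <- c("C1", "C2", "C3", "C4", "C5", "O5")
  ringEl <- c("C", "C", "C", "C", "C", "O")
  th <- (0:5) * pi / 3
  ring <- data.frame(x = 1.5 * cos(th), y = 1.5 * sin(th), z = 0)
  atoms <- do.call(rbind, lapply(1:6, function(i)
    .atomRow(ringNames[i], ringEl[i], ring$x[i], ring$y[i], ring$z[i])))
  bondsList <- lapply(1:6, function(i)
    .bondRow(ringNames[i], ringNames[i %% 6 + 1]))
  # hydroxyl / exocyclic substituents on C1..C5; z alternates (puckered)
  subOn <- c(C1 = "O1", C2 = "O2", C3 = "O3", C4 = "O4", C5 = "C6")
  subEl <- c(O1 = "O", O2 = "O", O3 = "O", O4 = "O", C6 = "C")
  for (i in 1:5) {
    zsgn <- if (i %% 2 == 1) 1 else -1
    dir <- c(cos(th[i]), sin(th[i]), 0)
    pos <- as.numeric(ring[i, ]) + 1.43 * (dir * cos(pi / 6)) +
      c(0, 0, zsgn * 1.43 * sin(pi / 6))
    nm <- subOn[[ringNames[i]]]
    atoms <- rbind(atoms, .atomRow(nm, subEl[[nm]], pos[1], pos[2], pos[3],
                                   leaving = nm == "O1"))
    bondsList <- c(bondsList, list(.bondRow(ringNames[i], nm)))
    # ring-carbon hydrogen on the opposite face
    h <- as.numeric(ring[i, ]) + c(0, 0, -zsgn * 1.0)
    hn <- paste0("H", i)
    atoms <- rbind(atoms, .atomRow(hn, "H", h[1], h[2], h[3]))
    bondsList <- c(bondsList, list(.bondRow(ringNames[i], hn)))
    if (nm != "C6") {
      # hydroxyl hydrogen, radially outward
      ho <- pos + 0.96 * dir
      hon <- paste0("H", substring(nm, 2), "O")
      atoms <- rbind(atoms, .atomRow(hon, "H", ho[1], ho[2], ho[3]))
      bondsList <- c(bondsList, list(.bondRow(nm, hon)))
    }
  }
  # O6 and the two C6 hydrogens
  c6 <- as.numeric(atoms[atoms$atomId == "C6", c("idealX", "idealY", "idealZ")])
  dir5 <- c(cos(th[5]), sin(th[5]), 0)
  o6 <- c6 + 1.43 * dir5
  atoms <- rbind(atoms, .atomRow("O6", "O", o6[1], o6[2], o6[3]))
  bondsList <- c(bondsList, list(.bondRow("C6", "O6")))
  tang <- c(-sin(th[5]), cos(th[5]), 0)
  for (s in c(1, -1)) {
    h <- c6 + s * 1.09 * tang
    hn <- if (s > 0) "H61" else "H62"
    atoms <- rbind(atoms, .atomRow(hn, "H", h[1], h[2], h[3]))
    bondsList <- c(bondsList, list(.bondRow("C6", hn)))
  }
  ho6 <- o6 + 0.96 * dir5
  atoms <- rbind(atoms, .atomRow("H6O", "H", ho6[1], ho6[2], ho6[3]))
  bondsList <- c(bondsList, list(.bondRow("O6", "H6O")))

  def <- new("ChemCompDef", compId = "GLC",
             name = "alpha-D-glucopyranose (synthetic fixture geometry)",
             formula = hillFormula(atoms$element),
             formulaWeight = sum(.atomicMass(atoms$element)),
             formalCharge = 0L, compType = "D-saccharide",
             pdbxType = "ATOMS",
             atoms = atoms, bonds = do.call(rbind, bondsList),
             descriptors = data.frame(
               descType = "SMILES", program = "fixture",
               value = "OCC1OC(O)C(O)C(O)C1O", stringsAsFactors = FALSE))
  def <- .assignStereoFromIdeal(def)
  .jitterModelCoords(def, seed)
}

.alaLikeDef <- function(seed) {
  atoms <- rbind(
    .atomRow("N", "N", 0.000, 0.000, 0.000),
    .atomRow("CA", "C", 1.458, 0.000, 0.000),
    .atomRow("C", "C", 2.009, 1.420, 0.000),
    .atomRow("O", "O", 1.251, 2.390, 0.000),
    .atomRow("CB", "C", 1.988, -0.773, -1.199),
    .atomRow("OXT", "O", 3.332, 1.536, 0.000, leaving = TRUE),
    .atomRow("H", "H", -0.500, -0.870, 0.000),
    .atomRow("H2", "H", -0.500, 0.870, 0.000),
    .atomRow("HA", "H", 1.790, -0.450, 0.950),
    .atomRow("HB1", "H", 1.620, -1.780, -1.150),
    .atomRow("HB2", "H", 3.060, -0.800, -1.200),
    .atomRow("HB3", "H", 1.650, -0.300, -2.110),
    .atomRow("HXT", "H", 3.650, 2.430, 0.000))
  bonds <- rbind(
    .bondRow("N", "CA"), .bondRow("CA", "C"), .bondRow("C", "O", "DOUB"),
    .bondRow("CA", "CB"), .bondRow("C", "OXT"),
    .bondRow("N", "H"), .bondRow("N", "H2"), .bondRow("CA", "HA"),
    .bondRow("CB", "HB1"), .bondRow("CB", "HB2"), .bondRow("CB", "HB3"),
    .bondRow("OXT", "HXT"))
  def <- new("ChemCompDef", compId = "ALA",
             name = "L-alanine (synthetic fixture geometry)",
             formula = hillFormula(atoms$element),
             formulaWeight = sum(.atomicMass(atoms$element)),
             formalCharge = 0L, compType = "L-peptide linking",
             pdbxType = "ATOMP",
             atoms = atoms, bonds = bonds,
             descriptors = data.frame(
               descType = "SMILES", program = "fixture",
               value = "C[C@@H](N)C(O)=O", stringsAsFactors = FALSE))
  def <- .assignStereoFromIdeal(def)
  .jitterModelCoords(def, seed)
}

.benzeneLikeDef <- function(seed) {
  th <- (0:5) * pi / 3
  atoms <- do.call(rbind, c(
    lapply(1:6, function(i)
      .atomRow(paste0("C", i), "C", 1.39 * cos(th[i]), 1.39 * sin(th[i]), 0)),
    lapply(1:6, function(i)
      .atomRow(paste0("H", i), "H", 2.48 * cos(th[i]), 2.48 * sin(th[i]), 0))))
  atoms$aromatic[atoms$element == "C"] <- TRUE
  bonds <- do.call(rbind, c(
    lapply(1:6, function(i)
      .bondRow(paste0("C", i), paste0("C", i %% 6 + 1), "AROM")),
    lapply(1:6, function(i) .bondRow(paste0("C", i), paste0("H", i)))))
  def <- new("ChemCompDef", compId = "BNZ",
             name = "benzene (synthetic fixture geometry)",
             formula = hillFormula(atoms$element),
             formulaWeight = sum(.atomicMass(atoms$element)),
             formalCharge = 0L, compType = "non-polymer",
             pdbxType = "HETAIN", atoms = atoms, bonds = bonds,
             descriptors = data.frame(
               descType = "SMILES", program = "fixture",
               value = "c1ccccc1", stringsAsFactors = FALSE))
  .jitterModelCoords(def, seed)
}

.hohDef <- function(seed) {
  atoms <- rbind(.atomRow("O", "O", 0, 0, 0),
                 .atomRow("H1", "H", 0.96, 0, 0),
                 .atomRow("H2", "H", -0.24, 0.93, 0))
  bonds <- rbind(.bondRow("O", "H1"), .bondRow("O", "H2"))
  def <- new("ChemCompDef", compId = "HOH", name = "water",
             formula = hillFormula(atoms$element),
             formulaWeight = sum(.atomicMass(atoms$element)),
             formalCharge = 0L, compType = "non-polymer",
             pdbxType = "HETAIN", atoms = atoms, bonds = bonds)
  .jitterModelCoords(def, seed)
}

.lipidLikeDef <- function(seed) {
  # short acyl chain with a carboxylate-like head: C1(=O1)(O2)-C2-...-C6
  n <- 6
  atoms <- do.call(rbind, lapply(1:n, function(i)
    .atomRow(paste0("C", i), "C", 1.3 * (i - 1), 0.5 * (i %% 2), 0)))
  atoms <- rbind(atoms,
                 .atomRow("O1", "O", -0.7, 1.05, 0),
                 .atomRow("O2", "O", -0.75, -1.0, 0))
  bondsList <- lapply(seq_len(n - 1), function(i)
    .bondRow(paste0("C", i), paste0("C", i + 1)))
  bondsList <- c(bondsList, list(.bondRow("C1", "O1", "DOUB"),
                                 .bondRow("C1", "O2")))
  def <- new("ChemCompDef", compId = "LIP",
             name = "hexanoyl chain (synthetic fixture geometry)",
             formula = hillFormula(atoms$element),
             formulaWeight = sum(.atomicMass(atoms$element)),
             formalCharge = 0L, compType = "lipid",
             pdbxType = "HETAIN", atoms = atoms,
             bonds = do.call(rbind, bondsList))
  .jitterModelCoords(def, seed)
}

.jitterModelCoords <- function(def, seed) {
  ## topology and ideal coordinates are canonical; the example model
  ## conformer is perturbed per seed (sd 0.01 A, far below perception tol)
  .withFixtureSeed(seed, 17L, {
    n <- nrow(def@atoms)
    def@atoms$modelX <- def@atoms$idealX + rnorm(n, sd = 0.01)
    def@atoms$modelY <- def@atoms$idealY + rnorm(n, sd = 0.01)
    def@atoms$modelZ <- def@atoms$idealZ + rnorm(n, sd = 0.01)
    def
  })
}

#' Synthetic chemical component definitions
#'
#' Deterministic, chemically consistent dictionary fixtures: a glucose
#' analogue with its anomeric hydroxyl flagged as the leaving atom, an
#' L-alanine analogue with a leaving OXT, a benzene ring, water, and a
#' short fatty-acyl chain. Topology and ideal coordinates are canonical;
#' the example model conformer is seed-perturbed.
#'
#' @param kind one of "GLC-like", "amino-acid", "benzene-like", "HOH",
#'   "lipid-like".
#' @param seed integer fixture seed.
#' @return a [ChemCompDef-class].
#' @export
makeCcdFixture <- function(kind = c("GLC-like", "amino-acid", "benzene-like",
                                    "HOH", "lipid-like"), seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
         "GLC-like" = .glcLikeDef(seed),
         "amino-acid" = .alaLikeDef(seed),
         "benzene-like" = .benzeneLikeDef(seed),
         "HOH" = .hohDef(seed),
         "lipid-like" = .lipidLikeDef(seed))
}

#' Synthetic dictionary covering all fixture components
#'
#' @param seed integer fixture seed.
#' @return named list of [ChemCompDef-class].
#' @export
makeCcdDictionary <- function(seed = 1L) {
  kinds <- c("GLC-like", "amino-acid", "benzene-like", "HOH", "lipid-like")
  defs <- lapply(kinds, makeCcdFixture, seed = seed)
  names(defs) <- vapply(defs, compId, character(1))
  defs
}

## rotation taking unit x to unit vector u
.rotAlignX <- function(u) {
  u <- u / sqrt(sum(u^2))
  v <- c(1, 0, 0)
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])   # v x u reversed sign handled below
  cth <- sum(u * v)
  if (abs(cth - 1) < 1e-12) return(diag(3))
  if (abs(cth + 1) < 1e-12) return(diag(c(-1, -1, 1)))
  w <- c(v[2] * u[3] - v[3] * u[2], v[3] * u[1] - v[1] * u[3],
         v[1] * u[2] - v[2] * u[1])
  K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K / (1 + cth)
}

.rotZ <- function(phi) {
  matrix(c(cos(phi), -sin(phi), 0, sin(phi), cos(phi), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

.rotX <- function(phi) {
  matrix(c(1, 0, 0, 0, cos(phi), -sin(phi), 0, sin(phi), cos(phi)),
         3, 3, byrow = TRUE)
}

## heavy atoms of a def as an atom-site block
.defSites <- function(def, compId, chain, seq, serialStart, isHet = TRUE,
                      rot = diag(3), origin = c(0, 0, 0),
                      dropAtoms = character(0), dropH = TRUE) {
  a <- def@atoms
  if (dropH) a <- a[!(a$element %in% c("H", "D")), , drop = FALSE]
  a <- a[!(a$atomId %in% dropAtoms), , drop = FALSE]
  xyz <- as.matrix(a[, c("idealX", "idealY", "idealZ")]) %*% t(rot)
  xyz <- sweep(xyz, 2, origin, "+")
  data.frame(serial = seq_len(nrow(a)) + serialStart - 1L,
             atomName = a$atomId, altLoc = "", compId = compId,
             authChain = chain, authSeq = seq, insCode = "",
             labelChain = NA_character_,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = 1, bFactor = 20, element = a$element,
             modelNum = 1L, isHet = isHet, groupId = NA_character_,
             stringsAsFactors = FALSE)
}

#' Synthetic crystal structures with ground truth
#'
#' Builds a small crystal: a scatter of alanine-like residues (polymer,
#' chain A), plus optional probe ligands at stated distances, a ligand
#' placed near a symmetry mate, a cyclodextrin-like ring of seven sugars,
#' a peptide chain, and/or a tetrahedrally coordinated zinc. All
#' randomness derives from the seed (counter-based streams); the returned
#' ground truth (exact contact lists, linkage list, metal-centre angles)
#' is computed by an independent brute-force path, not by the annotation
#' engines.
#'
#' @param spec list of options: \code{spaceGroup} (default "P 1"),
#'   \code{cell} (lengths, default c(40, 45, 50)), \code{nResidues}
#'   (default 5), \code{ligandDistances} (numeric: one probe-residue pair
#'   per entry at exactly that separation), \code{symContactDistance}
#'   (place a probe ligand at this distance from a symmetry image of a
#'   protein atom), \code{cyclodextrin} (logical), \code{peptideLength}
#'   (build an ALA chain of this length as chain P), \code{metal}
#'   ("ZN-tetrahedral"), \code{contactCutoff} for the ground-truth contact
#'   list (default 3.7).
#' @param seed integer fixture seed.
#' @return list with \code{model} (a [StructureModel-class]),
#'   \code{ligandKeys} (keys of the probe/sugar ligand entity),
#'   \code{groups} (group declarations, when any), and \code{truth}
#'   (brute-force ground truth).
#' @export
makeStructureFixture <- function(spec = list(), seed = 1L) {
  sg <- spec$spaceGroup %||% "P 1"
  cl <- spec$cell %||% c(40, 45, 50)
  cutoff <- spec$contactCutoff %||% 3.7
  cell <- crystalCell(cl[1], cl[2], cl[3], spaceGroup = sg)
  ala <- makeCcdFixture("amino-acid", seed = 1L)
  glc <- makeCcdFixture("GLC-like", seed = 1L)
  blocks <- list()
  serial <- 1L
  addBlock <- function(b) {
    blocks[[length(blocks) + 1L]] <<- b
    serial <<- serial + nrow(b)
  }

  nRes <- spec$nResidues %||% 5L
  center <- c(cl[1], cl[2], cl[3]) * 0.25
  resOrigins <- .withFixtureSeed(seed, 101L, {
    if (nRes == 0L) matrix(numeric(0), ncol = 3)
    else matrix(runif(nRes * 3, -6, 6), ncol = 3) +
      matrix(rep(center, each = nRes), ncol = 3)
  })
  # keep residues apart so they never fuse into one blob of contacts
  for (i in seq_len(nRes)) {
    tries <- 0L
    repeat {
      ok <- TRUE
      if (i > 1L) {
        d <- sqrt(rowSums(sweep(resOrigins[seq_len(i - 1L), , drop = FALSE],
                                2, resOrigins[i, ])^2))
        ok <- all(d > 7.5)
      }
      if (ok || tries > 200L) break
      tries <- tries + 1L
      resOrigins[i, ] <- .withFixtureSeed(seed, 1000L + 211L * i + tries, {
        runif(3, -6, 6) + center
      })
    }
  }
  for (i in seq_len(nRes)) {
    addBlock(.defSites(ala, "ALA", "A", i, serial, isHet = FALSE,
                       dropAtoms = c("OXT"), origin = resOrigins[i, ]))
  }

  ligandKeys <- character(0)
  groups <- list()

  # probe ligand + one residue placed at each requested separation
  if (!is.null(spec$ligandDistances)) {
    dists <- spec$ligandDistances
    lpos <- center + c(18, 0, 0)   # away from the residue scatter
    probe <- data.frame(serial = serial, atomName = "C1", altLoc = "",
                        compId = "PRB", authChain = "B", authSeq = 1L,
                        insCode = "", labelChain = NA_character_,
                        x = lpos[1], y = lpos[2], z = lpos[3],
                        occupancy = 1, bFactor = 20, element = "C",
                        modelNum = 1L, isHet = TRUE,
                        groupId = NA_character_, stringsAsFactors = FALSE)
    addBlock(probe)
    ligandKeys <- .compKey("PRB", "B", 1L, "")
    dirs <- .withFixtureSeed(seed, 202L, {
      m <- matrix(rnorm(length(dists) * 3), ncol = 3)
      m / sqrt(rowSums(m^2))
    })
    # well-separated directions: regenerate clashes deterministically
    for (i in seq_along(dists)) {
      tries <- 0L
      while (i > 1L &&
             any((dirs[seq_len(i - 1L), , drop = FALSE] %*% dirs[i, ]) > 0.5) &&
             tries < 50L) {
        tries <- tries + 1L
        dirs[i, ] <- .withFixtureSeed(seed, 202L + 31L * i + tries, {
          v <- rnorm(3); v / sqrt(sum(v^2))
        })
      }
    }
    for (i in seq_along(dists)) {
      rot <- .rotAlignX(dirs[i, ])
      origin <- lpos + dists[i] * dirs[i, ]   # residue N sits exactly here
      addBlock(.defSites(ala, "ALA", "C", i, serial, isHet = FALSE,
                         dropAtoms = "OXT", rot = rot, origin = origin))
    }
  }

  # ligand probe near a symmetry image of residue 1's N atom
  if (!is.null(spec$symContactDistance)) {
    d <- spec$symContactDistance
    ops <- cell@operators
    op <- if (length(ops) > 1L) ops[[2L]] else ops[[1L]]
    shift <- if (length(ops) > 1L) c(0L, 0L, 0L) else c(1L, 0L, 0L)
    p <- resOrigins[1L, ]                       # residue 1 N position
    M <- .bruteOrthoMatrix(cell)
    pf <- solve(M) %*% p
    imgF <- op$rot %*% pf + op$trans + shift
    img <- as.numeric(M %*% imgF)
    u <- .withFixtureSeed(seed, 303L, { v <- rnorm(3); v / sqrt(sum(v^2)) })
    lpos <- img + d * u
    probe <- data.frame(serial = serial, atomName = "C1", altLoc = "",
                        compId = "PRB", authChain = "S", authSeq = 1L,
                        insCode = "", labelChain = NA_character_,
                        x = lpos[1], y = lpos[2], z = lpos[3],
                        occupancy = 1, bFactor = 20, element = "C",
                        modelNum = 1L, isHet = TRUE,
                        groupId = NA_character_, stringsAsFactors = FALSE)
    addBlock(probe)
    ligandKeys <- c(ligandKeys, .compKey("PRB", "S", 1L, ""))
  }

  # cyclodextrin-like ring: seven sugars, O1 eliminated, O4_k+1 -- C1_k
  if (isTRUE(spec$cyclodextrin)) {
    ringCenter <- center + c(0, 18, 0)
    n <- 7L
    tilt <- pi / 3   # about the tangent axis: clears the inner rim
    sugarRot <- function(k) .rotZ(2 * pi * (k - 1) / n + pi / 2) %*% .rotX(tilt)
    sugarOrigin <- function(k, R) {
      phi <- 2 * pi * (k - 1) / n
      ringCenter + R * c(cos(phi), sin(phi), 0)
    }
    glcIdeal <- function(atomId) {
      a <- glc@atoms
      as.numeric(a[a$atomId == atomId, c("idealX", "idealY", "idealZ")])
    }
    gap <- function(R) {
      c1 <- sugarRot(1) %*% glcIdeal("C1") + sugarOrigin(1, R)
      o4 <- sugarRot(2) %*% glcIdeal("O4") + sugarOrigin(2, R)
      sqrt(sum((c1 - o4)^2)) - 1.43
    }
    # outer of the two geometric solutions: larger radius, no overlap
    R <- stats::uniroot(gap, c(5.3, 20))$root
    keys <- character(n)
    for (k in seq_len(n)) {
      addBlock(.defSites(glc, "GLC", "G", k, serial, isHet = TRUE,
                         dropAtoms = "O1", rot = sugarRot(k),
                         origin = sugarOrigin(k, R)))
      keys[k] <- .compKey("GLC", "G", k, "")
    }
    groups[["CD7"]] <- keys
    ligandKeys <- c(ligandKeys, keys)
  }

  # linear ALA chain (polymer, chain P) for peptide-count ground truth
  if (!is.null(spec$peptideLength)) {
    k <- spec$peptideLength
    base <- center + c(0, -15, 0)
    for (i in seq_len(k)) {
      addBlock(.defSites(ala, "ALA", "P", i, serial, isHet = FALSE,
                         dropAtoms = "OXT", origin = base + c(6 * (i - 1), 0, 0)))
    }
  }

  # tetrahedral zinc with four water-oxygen ligators at 2.0 A
  metalTruth <- NULL
  if (identical(spec$metal, "ZN-tetrahedral")) {
    mpos <- center + c(-15, 5, 0)
    zn <- data.frame(serial = serial, atomName = "ZN", altLoc = "",
                     compId = "ZN", authChain = "M", authSeq = 1L,
                     insCode = "", labelChain = NA_character_,
                     x = mpos[1], y = mpos[2], z = mpos[3],
                     occupancy = 1, bFactor = 15, element = "ZN",
                     modelNum = 1L, isHet = TRUE, groupId = NA_character_,
                     stringsAsFactors = FALSE)
    addBlock(zn)
    verts <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
      sqrt(3)
    for (v in seq_len(4)) {
      o <- mpos + 2.0 * verts[v, ]
      w <- data.frame(serial = serial, atomName = "O", altLoc = "",
                      compId = "HOH", authChain = "W", authSeq = v,
                      insCode = "", labelChain = NA_character_,
                      x = o[1], y = o[2], z = o[3],
                      occupancy = 1, bFactor = 25, element = "O",
                      modelNum = 1L, isHet = TRUE, groupId = NA_character_,
                      stringsAsFactors = FALSE)
      addBlock(w)
    }
    metalTruth <- list(metalKey = .compKey("ZN", "M", 1L, ""),
                       nLigators = 4L,
                       angleDeg = acos(-1 / 3) * 180 / pi)
  }

  sites <- do.call(rbind, blocks)
  rownames(sites) <- NULL
  model <- new("StructureModel", atomSites = sites, cell = cell)
  if (length(groups)) model <- setComponentGroups(model, groups)

  truth <- list(
    contactCutoff = cutoff,
    peptideBondCount = if (!is.null(spec$peptideLength))
      spec$peptideLength - 1L else NULL,
    metal = metalTruth)
  if (length(ligandKeys)) {
    truth$contacts <- .bruteContacts(model, ligandKeys, cutoff,
                                     includeWaters = TRUE)
    truth$linkages <- .bruteInterComponentLinks(model)
  }
  list(model = model, ligandKeys = ligandKeys, groups = groups, truth = truth)
}

#' Synthetic per-residue RSR table
#'
#' Emulates the statistical structure the LLDF assumes: polymeric
#' neighbour residues draw RSR from Normal(base, noiseSd) while every
#' non-water ligand gets exactly base + ligandOffset, so the expected
#' LLDF is approximately ligandOffset / noiseSd.
#'
#' @param model a [StructureModel-class].
#' @param base mean neighbour RSR (dimensionless fraction).
#' @param ligandOffset additive offset for ligand rows.
#' @param noiseSd neighbour RSR standard deviation (0 produces a constant
#'   table, which downstream LLDF rejects as undefined).
#' @param seed integer fixture seed.
#' @return RSR data.frame in the [readRsrTable()] layout.
#' @export
makeRsrFixture <- function(model, base = 0.12, ligandOffset = 0,
                           noiseSd = 0.02, seed = 1L) {
  comp <- modelComponents(model)
  vals <- .withFixtureSeed(seed, 404L, rnorm(nrow(comp), base, noiseSd))
  isLig <- !comp$isPolymerResidue & !comp$isWater
  vals[isLig] <- base + ligandOffset
  data.frame(chain = comp$authChain, seq = comp$authSeq, ins = comp$insCode,
             comp_id = comp$compId, rsr = round(pmax(vals, 0), 6),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- independent brute-force ground-truth code -------------------------

.bruteOrthoMatrix <- function(cell) {
  d <- pi / 180
  ca <- cos(cell@alpha * d); cb <- cos(cell@beta * d); cg <- cos(cell@gamma * d)
  sg <- sin(cell@gamma * d)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(cell@a, cell@b * cg, cell@c * cb,
           0, cell@b * sg, cell@c * (ca - cb * cg) / sg,
           0, 0, cell@c * v / sg), nrow = 3, byrow = TRUE)
}

## Residue-level contact ground truth: explicit loops over every operator,
## every lattice shift in -1..1, every atom pair. Same aggregation rule as
## the spec: one row per residue, minimum distance, its symmetry label.
.bruteContacts <- function(model, ligandKeys, cutoff, includeWaters = TRUE) {
  s <- model@atomSites
  keys <- .siteKeys(s)
  ligIdx <- which(keys %in% ligandKeys)
  L <- as.matrix(s[ligIdx, c("x", "y", "z"), drop = FALSE])
  cell <- model@cell
  M <- .bruteOrthoMatrix(cell)
  Minv <- solve(M)
  best <- list()
  for (i in seq_len(nrow(s))) {
    if (!includeWaters && .isWater(s$compId[i])) next
    fi <- Minv %*% as.numeric(s[i, c("x", "y", "z")])
    for (op in cell@operators) {
      isId <- all(op$rot == diag(3)) && all(op$trans == 0)
      for (u in -1:1) for (v in -1:1) for (w in -1:1) {
        if (isId && u == 0 && v == 0 && w == 0 &&
            keys[i] %in% ligandKeys) next
        y <- M %*% (op$rot %*% fi + op$trans + c(u, v, w))
        d <- sqrt(min(colSums((t(L) - as.numeric(y))^2)))
        if (d > cutoff) next
        lab <- sprintf("%d_%d%d%d", op$opIndex, 5 + u, 5 + v, 5 + w)
        if (keys[i] %in% ligandKeys && lab == "1_555") next
        k <- keys[i]
        if (is.null(best[[k]]) || d < best[[k]]$d ||
            (d == best[[k]]$d && lab < best[[k]]$lab)) {
          best[[k]] <- list(compId = s$compId[i], chain = s$authChain[i],
                            seq = s$authSeq[i], ins = s$insCode[i],
                            d = d, lab = lab)
        }
      }
    }
  }
  if (!length(best)) return(.emptyContacts())
  res <- do.call(rbind, lapply(best, function(b)
    data.frame(compId = b$compId, authChain = b$chain, authSeq = b$seq,
               insCode = b$ins, symLabel = b$lab, minDistance = b$d,
               stringsAsFactors = FALSE)))
  res <- res[order(res$authChain, res$authSeq, res$insCode, res$compId), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

## Inter-component covalent-range pairs by direct double loop (identity
## copies only; fixtures place their covalent partners in the asymmetric
## unit). Uses its own radius table lookup through covalentRadius().
.bruteInterComponentLinks <- function(model, tol = 0.45) {
  s <- model@atomSites
  s <- s[!(s$element %in% c("H", "D")), , drop = FALSE]
  keys <- .siteKeys(s)
  out <- list()
  for (i in seq_len(nrow(s) - 1L)) {
    for (j in (i + 1L):nrow(s)) {
      if (keys[i] == keys[j]) next
      d <- sqrt(sum((as.numeric(s[i, c("x", "y", "z")]) -
                       as.numeric(s[j, c("x", "y", "z")]))^2))
      lim <- covalentRadius(s$element[i]) + covalentRadius(s$element[j]) + tol
      if (d <= lim && d > 0.4) {
        out[[length(out) + 1L]] <- data.frame(
          key1 = keys[i], atom1 = s$atomName[i],
          key2 = keys[j], atom2 = s$atomName[j], distance = d,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(key1 = character(0), atom1 = character(0),
                      key2 = character(0), atom2 = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
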