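# Component matcher: bond perception, graph matching, renaming, drafts.

dict <- makeCcdDictionary()
glc <- dict$GLC
ala <- dict$ALA

test_that("bond perception follows the covalent-radius criterion", {
  two <- function(d) data.frame(atomName = c("Ca", "Cb"), element = "C",
                                altLoc = "", x = c(0, d), y = 0, z = 0)
  expect_equal(nrow(perceiveBonds(two(1.54))), 1L)  # r_C 0.76*2 + 0.45 = 1.97
  expect_equal(nrow(perceiveBonds(two(2.5))), 0L)
  one <- data.frame(atomName = "C1", element = "C", altLoc = "",
                    x = 0, y = 0, z = 0)
  expect_equal(nrow(perceiveBonds(one)), 0L)
  bad <- data.frame(atomName = "X1", element = "Xx", altLoc = "",
                    x = 0, y = 0, z = 0)
  expect_error(perceiveBonds(bad), "Xx")
})

test_that("ideal-geometry glucose reproduces the dictionary bond set", {
  comp <- obsFromDef(glc, dropH = FALSE)
  pb <- perceiveBonds(comp)
  got <- sort(paste(pmin(pb$atomName1, pb$atomName2),
                    pmax(pb$atomName1, pb$atomName2)))
  b <- bonds(glc)
  want <- sort(paste(pmin(b$atomId1, b$atomId2),
                     pmax(b$atomId1, b$atomId2)))
  expect_equal(got, want)
})

test_that("altloc-incompatible atom pairs are never bonded", {
  comp <- data.frame(atomName = c("C1", "C2", "C3"), element = "C",
                     altLoc = c("A", "B", ""), x = c(0, 1.5, 3.0),
                     y = 0, z = 0)
  pb <- perceiveBonds(comp)
  # A-B pair excluded; blank pairs with both
  expect_false(any(pb$atomName1 == "C1" & pb$atomName2 == "C2"))
  expect_true(any(pb$atomName1 == "C2" & pb$atomName2 == "C3"))
})

test_that("glucose observed without its leaving O1 is still identified", {
  comp <- obsFromDef(glc, drop = "O1")
  m <- matchComponent(comp, glc)
  expect_false(is.null(m))
  miss <- missingAtoms(m)
  expect_equal(miss$kind[miss$atomId == "O1"], "leaving")
  expect_equal(sum(miss$kind == "other"), 0L)
  expect_false(isExact(m))  # not exact, but accepted as identified
  expect_equal(length(atomMap(m)), 11L)
})

test_that("matching is invariant under permutation and rigid motion", {
  set.seed(11)
  for (rep in 1:5) {
    comp <- obsFromDef(glc, rot = randomRotation(), shift = rnorm(3, 0, 10),
                       permute = TRUE, scramble = TRUE)
    m <- matchComponent(comp, glc)
    expect_false(is.null(m))
    expect_equal(m@rmsdAfterFit, 0, tolerance = 1e-8)
    expect_true(isExact(m))
    # element labels agree across the map
    a <- atoms(glc)
    obsEl <- comp$element[match(names(atomMap(m)), comp$atomName)]
    dictEl <- a$element[match(atomMap(m), a$atomId)]
    expect_equal(obsEl, dictEl)
  }
})

test_that("any subset of leaving atoms and hydrogens may be absent", {
  for (drop in list(character(0), "O1")) {
    comp <- obsFromDef(glc, drop = drop, dropH = TRUE)
    expect_false(is.null(matchComponent(comp, glc)))
    comp2 <- obsFromDef(glc, drop = drop, dropH = FALSE)
    expect_false(is.null(matchComponent(comp2, glc)))
  }
  # alanine: OXT leaving may be gone too
  m <- matchComponent(obsFromDef(ala, drop = "OXT"), ala)
  expect_false(is.null(m))
  expect_equal(missingAtoms(m)$kind[missingAtoms(m)$atomId == "OXT"],
               "leaving")
})

test_that("atom maps agree with the exhaustive-permutation oracle", {
  set.seed(23)
  cases <- list(
    list(def = glc, drop = character(0)),
    list(def = glc, drop = "O1"),
    list(def = ala, drop = character(0)),
    list(def = ala, drop = "OXT"),
    list(def = dict$BNZ, drop = character(0)),
    list(def = dict$LIP, drop = character(0)),
    list(def = dict$HOH, drop = character(0)))
  for (cs in cases) {
    comp <- obsFromDef(cs$def, drop = cs$drop, rot = randomRotation(),
                       shift = rnorm(3, 0, 5), permute = TRUE,
                       scramble = TRUE)
    m <- matchComponent(comp, cs$def)
    o <- oracleMatch(comp, cs$def)
    expect_false(is.null(m), info = compId(cs$def))
    expect_false(is.null(o), info = compId(cs$def))
    expect_equal(atomMap(m)[order(names(atomMap(m)))],
                 o$map[order(names(o$map))], info = compId(cs$def))
  }
})

test_that("identification ranks the right component first", {
  comp <- obsFromDef(glc, drop = "O1", scramble = TRUE)
  hits <- identifyComponent(comp, dict)
  expect_gt(length(hits), 0L)
  expect_equal(compId(hits[[1]]), "GLC")

  water <- data.frame(atomName = "O", element = "O", altLoc = "",
                      x = 0, y = 0, z = 0)
  expect_equal(compId(identifyComponent(water, dict)[[1]]), "HOH")

  # a molecule formula-incompatible with everything -> empty result
  novel <- data.frame(atomName = c("P1", "P2", "P3"), element = "P",
                      altLoc = "", x = c(0, 2.2, 4.4), y = 0, z = 0)
  expect_length(identifyComponent(novel, dict), 0L)
})

test_that("renaming restores dictionary nomenclature and is idempotent", {
  comp <- obsFromDef(glc, permute = TRUE, scramble = TRUE)
  m <- matchComponent(comp, glc)
  renamed <- renameAtoms(comp, m)
  expect_setequal(renamed$atomName,
                  atoms(glc)$atomId[!(atoms(glc)$element %in% c("H", "D"))])
  expect_equal(renamed$x, comp$x)  # coordinates untouched
  # re-matching the renamed component gives the identity map
  m2 <- matchComponent(renamed, glc)
  expect_true(all(atomMap(m2) == names(atomMap(m2))))
  # identity map leaves the component unchanged
  renamed2 <- renameAtoms(renamed, m2)
  expect_equal(renamed2$atomName, renamed$atomName)
  # map referencing absent atoms errors
  bad <- comp[-1, , drop = FALSE]
  expect_error(renameAtoms(bad, m), "absent")
})

test_that("draft definitions are built for novel molecules", {
  ethane <- data.frame(atomName = c("C1", "C2"), element = "C", altLoc = "",
                       x = c(0, 1.54), y = 0, z = 0)
  draft <- buildNewDefinition(ethane, "ETX")
  expect_equal(draft@formula, "C2")
  expect_equal(bonds(draft)$order, "SING")
  expect_equal(nrow(validateDef(draft)), 0L)
  expect_error(buildNewDefinition(ethane, "GLC", dict), "GLC")

  # alanine heavy atoms: CA called with the handedness of the signed-volume
  # oracle applied to the same coordinates
  comp <- obsFromDef(ala, drop = "OXT")
  draft2 <- buildNewDefinition(comp, "NEW")
  ca <- atoms(draft2)[atoms(draft2)$atomId == "CA", ]
  # oracle: priority N > C(ties by name: C before CB), signed volume
  xyz <- function(n) as.numeric(comp[comp$atomName == n, c("x", "y", "z")])
  v <- det(rbind(xyz("N") - xyz("CA"), xyz("C") - xyz("CA"),
                 xyz("CB") - xyz("CA"))) / 6
  expect_equal(ca$stereoConfig, if (v > 0.1) "R" else if (v < -0.1) "S"
               else "N")
  expect_true(ca$stereoConfig %in% c("R", "S"))

  # planar aromatic ring is perceived in drafts
  benz <- obsFromDef(dict$BNZ)
  draft3 <- buildNewDefinition(benz, "NBZ")
  expect_equal(sum(bonds(draft3)$order == "AROM"), 6L)
  expect_equal(nrow(validateDef(draft3)), 0L)
})

test_that("the missing-atom budget bounds disorder tolerance", {
  # drop 2 non-leaving heavy atoms of 12: over the default 20% budget
  comp <- obsFromDef(glc, drop = c("O6", "O3", "C6"))
  expect_null(matchComponent(comp, glc))
  # a single missing terminal O6 fits the budget (floor(0.2*12) = 2)
  comp2 <- obsFromDef(glc, drop = "O6")
  m <- matchComponent(comp2, glc)
  expect_false(is.null(m))
  expect_equal(sum(missingAtoms(m)$kind == "other"), 1L)
  expect_false(isExact(m))
})
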