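# Covalent linkages and metal coordination.

mkSite <- function(serial, name, el, comp, chain, seq, x, y, z,
                   het = TRUE, alt = "") {
  data.frame(serial = serial, atomName = name, altLoc = alt, compId = comp,
             authChain = chain, authSeq = seq, insCode = "",
             labelChain = NA_character_, x = x, y = y, z = z,
             occupancy = 1, bFactor = 10, element = el, modelNum = 1L,
             isHet = het, groupId = NA_character_, stringsAsFactors = FALSE)
}

mkModel <- function(...) {
  new("StructureModel", atomSites = do.call(rbind, list(...)), cell = NULL)
}

test_that("a glycosidic O-C pair across components is a covale linkage", {
  m <- mkModel(mkSite(1, "O4", "O", "GLC", "A", 1, 0, 0, 0),
               mkSite(2, "C1", "C", "GLC", "A", 2, 1.42, 0, 0))
  lk <- detectLinkages(m)
  expect_equal(nrow(lk), 1L)
  expect_equal(lk$kind, "covale")
  expect_equal(lk$distance, 1.42, tolerance = 1e-9)
})

test_that("a lone component yields no linkages", {
  m <- mkModel(mkSite(1, "C1", "C", "LIG", "A", 1, 0, 0, 0),
               mkSite(2, "C2", "C", "LIG", "A", 1, 1.5, 0, 0))
  expect_equal(nrow(detectLinkages(m)), 0L)
})

test_that("the cyclodextrin-like ring has exactly seven covalent links", {
  fx <- makeStructureFixture(list(cyclodextrin = TRUE, cell = c(60, 60, 60)),
                             seed = 3)
  lk <- detectLinkages(fx$model)
  expect_equal(nrow(lk), 7L)
  expect_true(all(lk$kind == "covale"))
  # circular: every sugar appears in exactly two links
  seqs <- c(lk$seq1, lk$seq2)
  expect_true(all(table(seqs) == 2L))
  # each link is anomeric carbon to the 4-hydroxyl oxygen
  expect_setequal(unique(paste(sort(c(lk$atom1, lk$atom2)))),
                  c("C1", "O4"))
  # and the brute-force inter-component scan agrees
  expect_equal(nrow(fx$truth$linkages), 7L)
})

test_that("standard backbone bonds are excluded, cross-links kept", {
  # two sequence-adjacent residues with a genuine peptide C-N geometry
  m <- mkModel(
    mkSite(1, "CA", "C", "ALA", "A", 1, -1.52, 0, 0, het = FALSE),
    mkSite(2, "C", "C", "ALA", "A", 1, 0, 0, 0, het = FALSE),
    mkSite(3, "N", "N", "ALA", "A", 2, 1.20, 0.55, 0, het = FALSE),
    mkSite(4, "CA", "C", "ALA", "A", 2, 2.66, 0.55, 0, het = FALSE))
  expect_equal(nrow(detectLinkages(m)), 0L)
  # same geometry, non-adjacent residues: retained as a cross-link
  m2 <- mkModel(
    mkSite(1, "C", "C", "ALA", "A", 1, 0, 0, 0, het = FALSE),
    mkSite(2, "N", "N", "ALA", "A", 5, 1.20, 0.55, 0, het = FALSE))
  expect_equal(nrow(detectLinkages(m2)), 1L)
})

test_that("disulfides and metal contacts are classified by kind", {
  m <- mkModel(
    mkSite(1, "SG", "S", "CYS", "A", 1, 0, 0, 0, het = FALSE),
    mkSite(2, "SG", "S", "CYS", "A", 8, 2.05, 0, 0, het = FALSE),
    mkSite(3, "ZN", "ZN", "ZN", "B", 1, 10, 0, 0),
    mkSite(4, "OD1", "O", "ASP", "A", 3, 12.1, 0, 0, het = FALSE))
  lk <- detectLinkages(m)
  expect_setequal(lk$kind, c("disulf", "metalc"))
  zn <- lk[lk$kind == "metalc", ]
  expect_equal(zn$distance, 2.1, tolerance = 1e-9)
})

test_that("every metalc linkage corresponds to one coordination ligator", {
  fx <- makeStructureFixture(list(metal = "ZN-tetrahedral",
                                  cell = c(50, 50, 50)), seed = 2)
  m <- fx$model
  lk <- detectLinkages(m)
  zn <- lk[lk$kind == "metalc", ]
  cc <- coordinationCenter(m, which(atomSites(m)$element == "ZN"))
  expect_equal(nrow(zn), nrow(ligators(cc)))
  expect_setequal(paste(zn$chain2, zn$seq2, zn$atom2),
                  paste(ligators(cc)$authChain, ligators(cc)$authSeq,
                        ligators(cc)$atomName))
})

test_that("coordination angles match closed forms", {
  # collinear A-M-B
  m <- mkModel(mkSite(1, "ZN", "ZN", "ZN", "A", 1, 0, 0, 0),
               mkSite(2, "O", "O", "HOH", "W", 1, 2, 0, 0),
               mkSite(3, "O", "O", "HOH", "W", 2, -2, 0, 0))
  cc <- coordinationCenter(m, 1L)
  expect_equal(nrow(ligators(cc)), 2L)
  expect_equal(coordinationAngles(cc)$degrees, 180, tolerance = 1e-9)

  # perfect tetrahedron: all six angles arccos(-1/3)
  fx <- makeStructureFixture(list(metal = "ZN-tetrahedral",
                                  cell = c(50, 50, 50)), seed = 2)
  cc2 <- coordinationCenter(fx$model,
                            which(atomSites(fx$model)$element == "ZN"))
  ang <- coordinationAngles(cc2)
  expect_equal(nrow(ang), 6L)   # k(k-1)/2 for k = 4
  expect_equal(ang$degrees, rep(acos(-1 / 3) * 180 / pi, 6),
               tolerance = 1e-6)
  expect_equal(ang$degrees, rep(fx$truth$metal$angleDeg, 6),
               tolerance = 1e-6)
})

test_that("angles are symmetric and invariant under rigid motion", {
  set.seed(31)
  base <- list(m = c(0, 0, 0), a = c(2.1, 0.2, -0.3), b = c(-0.5, 1.9, 0.8))
  a0 <- oracleAngle(base$a, base$m, base$b)
  for (i in 1:5) {
    R <- randomRotation(); t <- rnorm(3, 0, 20)
    m <- mkModel(
      mkSite(1, "ZN", "ZN", "ZN", "A", 1,
             (R %*% base$m)[1] + t[1], (R %*% base$m)[2] + t[2],
             (R %*% base$m)[3] + t[3]),
      mkSite(2, "O", "O", "HOH", "W", 1,
             (R %*% base$a)[1] + t[1], (R %*% base$a)[2] + t[2],
             (R %*% base$a)[3] + t[3]),
      mkSite(3, "N", "N", "HIS", "B", 5,
             (R %*% base$b)[1] + t[1], (R %*% base$b)[2] + t[2],
             (R %*% base$b)[3] + t[3], het = FALSE))
    cc <- coordinationCenter(m, 1L)
    expect_equal(coordinationAngles(cc)$degrees, a0, tolerance = 1e-8)
  }
})

test_that("alternate conformers are listed as separate ligators", {
  m <- mkModel(
    mkSite(1, "ZN", "ZN", "ZN", "A", 1, 0, 0, 0),
    mkSite(2, "OE1", "O", "GLU", "B", 195, 2.0, 0, 0, het = FALSE,
           alt = "A"),
    mkSite(3, "OE1", "O", "GLU", "B", 195, 1.4, 1.4, 0, het = FALSE,
           alt = "B"),
    mkSite(4, "NE2", "N", "HIS", "B", 165, 0, -2.1, 0, het = FALSE))
  cc <- coordinationCenter(m, 1L)
  expect_equal(nrow(ligators(cc)), 3L)     # both Glu conformers + His
  expect_equal(nrow(coordinationAngles(cc)), 3L)
  # cross-conformer angle is present
  lig <- ligators(cc)
  iA <- which(lig$altLoc == "A"); iB <- which(lig$altLoc == "B")
  ang <- coordinationAngles(cc)
  expect_true(any((ang$i == iA & ang$j == iB) | (ang$i == iB & ang$j == iA)))
})

test_that("unsupported metals are an error", {
  m <- mkModel(mkSite(1, "C1", "C", "LIG", "A", 1, 0, 0, 0))
  expect_error(coordinationCenter(m, 1L), "unsupported")
})

test_that("REMARK 620 and _pdbx_struct_conn_angle round-trip at 0.1 degree", {
  fx <- makeStructureFixture(list(metal = "ZN-tetrahedral",
                                  cell = c(50, 50, 50)), seed = 5)
  cc <- coordinationCenter(fx$model,
                           which(atomSites(fx$model)$element == "ZN"))
  txt <- writeRemark620(list(cc))
  back <- parseRemark620(txt)
  expect_length(back, 1L)
  expect_length(back[[1]]$ligators, 4L)
  got <- back[[1]]$angles
  want <- coordinationAngles(cc)
  key <- function(df) df[order(df$i, df$j), "degrees"]
  expect_equal(key(got), round(key(want), 1), tolerance = 0.051)

  angTxt <- writeConnAngle(list(cc))
  pa <- parseConnAngle(angTxt)
  expect_equal(nrow(pa), 6L)
  expect_equal(sort(pa$value), sort(round(want$degrees, 1)),
               tolerance = 0.051)

  # zero-ligator centre: header only, no angle rows
  lone <- mkModel(mkSite(1, "ZN", "ZN", "ZN", "A", 1, 0, 0, 0))
  cc0 <- coordinationCenter(lone, 1L)
  expect_equal(nrow(ligators(cc0)), 0L)
  txt0 <- writeRemark620(list(cc0))
  expect_false(grepl("REMARK 620 1 ", txt0, fixed = TRUE))
  expect_length(parseConnAngle(writeConnAngle(list(cc0)))$value, 0L)
})

test_that("_struct_conn rows round-trip", {
  fx <- makeStructureFixture(list(cyclodextrin = TRUE, cell = c(60, 60, 60)),
                             seed = 3)
  lk <- detectLinkages(fx$model)
  back <- parseStructConn(writeStructConn(lk))
  expect_equal(nrow(back), nrow(lk))
  expect_equal(back$kind, lk$kind)
  expect_equal(back$atom1, lk$atom1)
  expect_equal(back$distance, lk$distance, tolerance = 1e-3)
})
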