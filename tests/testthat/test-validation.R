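# Geometry checks and the LLDF Z-score.

dict <- makeCcdDictionary()
glc <- dict$GLC

test_that("observed == ideal coordinates gives zero deviations", {
  comp <- obsFromDef(glc)
  m <- matchComponent(comp, glc)
  gr <- geometryCheck(comp, m, glc)
  expect_gt(nrow(gr@bonds), 0L)
  expect_gt(nrow(gr@angles), 0L)
  expect_lt(max(abs(gr@bonds$deviation)), 1e-9)
  expect_lt(max(abs(gr@angles$deviation)), 1e-9)
  expect_length(gr@chiralityFlips, 0L)
  # deviations stay zero under a rigid transform of the observation
  set.seed(3)
  comp2 <- obsFromDef(glc, rot = randomRotation(), shift = rnorm(3, 0, 8))
  gr2 <- geometryCheck(comp2, matchComponent(comp2, glc), glc)
  expect_lt(max(abs(gr2@bonds$deviation)), 1e-6)
  expect_lt(max(abs(gr2@angles$deviation)), 1e-6)
})

test_that("a single stretched bond is flagged with its exact deviation", {
  comp <- obsFromDef(glc)
  # stretch the exocyclic C6-O6 bond by +0.3 A along its axis
  i6 <- which(comp$atomName == "O6"); c6 <- which(comp$atomName == "C6")
  u <- as.numeric(comp[i6, c("x", "y", "z")] - comp[c6, c("x", "y", "z")])
  u <- u / sqrt(sum(u^2))
  comp[i6, c("x", "y", "z")] <- comp[i6, c("x", "y", "z")] + 0.3 * u
  m <- matchComponent(comp, glc)
  gr <- geometryCheck(comp, m, glc)
  hit <- gr@bonds[gr@bonds$atomId1 %in% c("C6", "O6") &
                    gr@bonds$atomId2 %in% c("C6", "O6"), ]
  expect_equal(hit$deviation, 0.300, tolerance = 1e-6)
  others <- gr@bonds[!(gr@bonds$atomId1 %in% "O6" |
                         gr@bonds$atomId2 %in% "O6"), ]
  expect_lt(max(abs(others$deviation)), 1e-9)
  expect_gt(gr@rmsZBonds, 1)
})

test_that("a mirror-image ligand flips every chiral centre", {
  comp <- obsFromDef(glc)
  comp$z <- -comp$z
  m <- matchComponent(comp, glc)
  gr <- geometryCheck(comp, m, glc)
  centers <- atoms(glc)$atomId[atoms(glc)$stereoConfig %in% c("R", "S")]
  expect_setequal(gr@chiralityFlips, centers)
  expect_gt(length(centers), 0L)
})

test_that("a definition without ideal coordinates limits the report", {
  def <- glc
  def@atoms$idealX <- NA_real_
  comp <- obsFromDef(glc)
  m <- matchComponent(comp, def)
  gr <- geometryCheck(comp, m, def)
  expect_equal(nrow(gr@bonds), 0L)
  expect_match(gr@notice, "ideal")
})

test_that("the LLDF formula and flagging follow the Z-score definition", {
  fx <- makeStructureFixture(list(nResidues = 0L,
                                  ligandDistances = c(3.0, 3.5, 4.0),
                                  cell = c(90, 90, 90),
                                  contactCutoff = 5.0), seed = 9)
  m <- fx$model
  rsr <- makeRsrFixture(m, base = 0.12, noiseSd = 0.02, seed = 1)
  rsr$rsr[rsr$chain == "C"] <- c(0.10, 0.12, 0.14)  # hand-picked neighbours
  rsr$rsr[rsr$comp_id == "PRB"] <- 0.32
  res <- lldf(m, rsr, fx$ligandKeys[1])
  # hand computation: mean 0.12, sample sd 0.02, (0.32-0.12)/0.02 = 10
  expect_equal(res@meanRsr, 0.12, tolerance = 1e-12)
  expect_equal(res@sdRsr, 0.02, tolerance = 1e-12)
  expect_equal(lldfScore(res), 10.0, tolerance = 1e-9)
  expect_true(isFlagged(res))
  expect_equal(res@nNeighbors, 3L)

  # ligand at the neighbour mean: z = 0, not flagged
  rsr$rsr[rsr$comp_id == "PRB"] <- 0.12
  expect_false(isFlagged(lldf(m, rsr, fx$ligandKeys[1])))
  # just over the threshold flags
  rsr$rsr[rsr$comp_id == "PRB"] <- 0.12 + 2.5 * 0.02
  res3 <- lldf(m, rsr, fx$ligandKeys[1])
  expect_equal(lldfScore(res3), 2.5, tolerance = 1e-9)
  expect_true(isFlagged(res3))
  rsr$rsr[rsr$comp_id == "PRB"] <- 0.12 + 1.99 * 0.02
  expect_false(isFlagged(lldf(m, rsr, fx$ligandKeys[1])))
})

test_that("LLDF is invariant under shared shift and positive scale", {
  fx <- makeStructureFixture(list(nResidues = 0L,
                                  ligandDistances = c(3.0, 3.5, 4.2, 4.8),
                                  cell = c(90, 90, 90)), seed = 14)
  rsr <- makeRsrFixture(fx$model, base = 0.15, ligandOffset = 0.06,
                        noiseSd = 0.02, seed = 2)
  z0 <- lldfScore(lldf(fx$model, rsr, fx$ligandKeys[1]))
  for (tr in list(c(1, 0.05), c(2.5, 0), c(0.3, 0.41))) {
    rsr2 <- rsr
    rsr2$rsr <- rsr$rsr * tr[1] + tr[2]
    expect_equal(lldfScore(lldf(fx$model, rsr2, fx$ligandKeys[1])), z0,
                 tolerance = 1e-9)
  }
})

test_that("a neighbour beyond the cutoff never enters the score", {
  fx <- makeStructureFixture(list(nResidues = 0L,
                                  ligandDistances = c(3.0, 3.5, 4.2, 9.0),
                                  cell = c(90, 90, 90)), seed = 15)
  rsr <- makeRsrFixture(fx$model, base = 0.15, ligandOffset = 0.05,
                        noiseSd = 0.02, seed = 3)
  res <- lldf(fx$model, rsr, fx$ligandKeys[1])
  expect_equal(res@nNeighbors, 3L)
  # changing the far residue's RSR cannot move the score
  far <- which(rsr$chain == "C" & rsr$seq == 4)
  rsr2 <- rsr; rsr2$rsr[far] <- 0.9
  expect_equal(lldfScore(lldf(fx$model, rsr2, fx$ligandKeys[1])),
               lldfScore(res), tolerance = 1e-12)
})

test_that("degenerate neighbour sets are an error, not a silent zero", {
  fx <- makeStructureFixture(list(nResidues = 0L,
                                  ligandDistances = c(3.0, 8.0, 8.5),
                                  cell = c(90, 90, 90)), seed = 16)
  rsr <- makeRsrFixture(fx$model, base = 0.15, noiseSd = 0.02, seed = 4)
  expect_error(lldf(fx$model, rsr, fx$ligandKeys[1]), "fewer than 2")
  # ligand missing from the table
  fx2 <- makeStructureFixture(list(nResidues = 0L,
                                   ligandDistances = c(3.0, 3.5, 4.0),
                                   cell = c(90, 90, 90)), seed = 17)
  rsr2 <- makeRsrFixture(fx2$model, seed = 5)
  rsr2 <- rsr2[rsr2$comp_id != "PRB", ]
  expect_error(lldf(fx2$model, rsr2, fx2$ligandKeys[1]), "missing")
  # zero neighbour spread (sigma = 0 table) is undefined
  rsr3 <- makeRsrFixture(fx2$model, base = 0.2, ligandOffset = 0.1,
                         noiseSd = 0, seed = 6)
  expect_error(lldf(fx2$model, rsr3, fx2$ligandKeys[1]), "zero")
})

test_that("neighbour selection matches the 5-Angstrom contact engine", {
  fx <- makeStructureFixture(list(nResidues = 6L,
                                  ligandDistances = c(3.0, 4.4),
                                  spaceGroup = "P 1 21 1",
                                  cell = c(32, 34, 36)), seed = 18)
  m <- fx$model
  rsr <- makeRsrFixture(m, base = 0.15, ligandOffset = 0.04,
                        noiseSd = 0.015, seed = 7)
  res <- lldf(m, rsr, fx$ligandKeys[1])
  sites <- delineateSites(m, siteParams(cutoff = 5.0,
                                        includeWatersAsNeighbors = FALSE))
  idx <- which(vapply(sites, function(s) s@ligand$compId[1] == "PRB",
                      logical(1)))
  ct <- siteContacts(sites[[idx]])
  ct <- ct[ct$compId == "ALA", , drop = FALSE]
  expect_setequal(paste(res@neighbors$authChain, res@neighbors$authSeq),
                  paste(ct$authChain, ct$authSeq))
})

test_that("RSR tables round-trip through the TSV reader and writer", {
  fx <- makeStructureFixture(list(nResidues = 3L, ligandDistances = 3.2,
                                  cell = c(80, 80, 80)), seed = 19)
  rsr <- makeRsrFixture(fx$model, seed = 8)
  path <- tempfile(fileext = ".tsv")
  writeRsrTable(rsr, path)
  back <- readRsrTable(path)
  expect_equal(back$rsr, rsr$rsr, tolerance = 1e-9)
  expect_equal(back$comp_id, rsr$comp_id)
  bad <- rsr; bad$rsr[1] <- -0.1
  writeRsrTable(bad, path)
  expect_error(readRsrTable(path), ">= 0")
})

test_that("the validation report names flagged ligands", {
  fx <- makeStructureFixture(list(nResidues = 0L,
                                  ligandDistances = c(3.0, 3.5, 4.0),
                                  cell = c(90, 90, 90)), seed = 9)
  rsr <- makeRsrFixture(fx$model, base = 0.12, ligandOffset = 0.2,
                        noiseSd = 0.02, seed = 1)
  res <- lldf(fx$model, rsr, fx$ligandKeys[1])
  txt <- formatValidationReport(list(res))
  expect_match(txt, "FLAGGED")
  expect_match(txt, "\"flagged\": true")
  expect_match(txt, "PRB")
})
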