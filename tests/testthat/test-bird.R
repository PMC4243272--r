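# BIRD representation rules and PRD/FAM handling.

dict <- makeCcdDictionary()

test_that("peptide bonds are detected by the carbonyl-C-to-N criterion", {
  mol <- linearPeptide(2)
  pb <- detectPeptideBonds(mol, dict)
  expect_equal(nrow(pb), 1L)
  expect_equal(pb$fromKey, "R1")
  expect_equal(pb$toKey, "R2")

  # ester-linked junction (C-O) is not a peptide bond
  ester <- birdMolecule(
    data.frame(key = c("R1", "R2"), compId = "ALA"),
    data.frame(key1 = "R1", atom1 = "C", key2 = "R2", atom2 = "O",
               stringsAsFactors = FALSE))
  expect_equal(nrow(detectPeptideBonds(ester, dict)), 0L)

  # a C-N bond whose carbon has no carbonyl is not a peptide bond either
  keto <- birdMolecule(
    data.frame(key = c("R1", "R2"), compId = "ALA"),
    data.frame(key1 = "R1", atom1 = "CB", key2 = "R2", atom2 = "N",
               stringsAsFactors = FALSE))
  expect_equal(nrow(detectPeptideBonds(keto, dict)), 0L)
})

test_that("a seven-residue core carries six peptide bonds", {
  mol <- linearPeptide(7)
  pb <- detectPeptideBonds(mol, dict)
  expect_equal(nrow(pb), 6L)
  expect_equal(maxConsecutivePeptideBonds(pb), 6L)
})

test_that("branched chains contribute their longest branch", {
  # two chains of lengths 2 and 3 feeding one acceptor residue
  sub <- data.frame(key = c("A1", "A2", "B1", "B2", "B3", "X"),
                    compId = "ALA", stringsAsFactors = FALSE)
  lk <- data.frame(
    key1 = c("A1", "B1", "B2", "A2", "B3"),
    atom1 = "C",
    key2 = c("A2", "B2", "B3", "X", "X"),
    atom2 = "N", stringsAsFactors = FALSE)
  pb <- detectPeptideBonds(birdMolecule(sub, lk), dict)
  # exhaustive path-search oracle on the directed edge list
  edges <- pb[, c("fromKey", "toKey")]
  longest <- 0L
  walk <- function(v, seen, len) {
    longest <<- max(longest, len)
    nxt <- edges$toKey[edges$fromKey == v]
    for (w in nxt) if (!(w %in% seen)) walk(w, c(seen, w), len + 1L)
  }
  for (v in unique(c(edges$fromKey, edges$toKey))) walk(v, v, 0L)
  expect_equal(longest, 3L)
  expect_equal(maxConsecutivePeptideBonds(pb), 3L)
})

test_that("linear peptides classify by the consecutive-bond rule", {
  for (k in 1:6) {
    cl <- classifyPeptideLike(linearPeptide(k), dict)
    expect_equal(cl@maxConsecutivePeptideBonds, max(0L, k - 1L))
    if (k >= 3) {
      expect_equal(cl@category, "POLYMER")
    } else {
      expect_equal(cl@category, "NONPOLYMER_SUBCOMPONENTS")
      expect_equal(cl@subcomponentSequence, rep("ALA", k))
    }
  }
})

test_that("an N-to-C subcomponent sequence is recovered for dipeptides", {
  # distinguishable ends: reverse the key order in the tables to prove the
  # sequence follows bond direction, not input order
  sub <- data.frame(key = c("R2", "R1"), compId = c("GLC", "ALA")[c(1, 2)],
                    stringsAsFactors = FALSE)
  sub$compId <- c("ALA", "ALA")
  lk <- data.frame(key1 = "R1", atom1 = "C", key2 = "R2", atom2 = "N",
                   stringsAsFactors = FALSE)
  cl <- classifyPeptideLike(birdMolecule(sub, lk), dict)
  expect_equal(cl@category, "NONPOLYMER_SUBCOMPONENTS")
  pb <- detectPeptideBonds(birdMolecule(sub, lk), dict)
  expect_equal(pb$fromKey, "R1")   # R1 is N-terminal
})

test_that("PPACK-like warheads stay below two consecutive peptide bonds", {
  # dipeptide + a non-peptide (ketone-linked) warhead
  sub <- data.frame(key = c("R1", "R2", "W"), compId = c("ALA", "ALA", "BNZ"),
                    stringsAsFactors = FALSE)
  lk <- data.frame(key1 = c("R1", "R2"), atom1 = c("C", "CB"),
                   key2 = c("R2", "W"), atom2 = c("N", "C1"),
                   stringsAsFactors = FALSE)
  cl <- classifyPeptideLike(birdMolecule(sub, lk), dict)
  expect_lte(cl@maxConsecutivePeptideBonds, 1L)
  expect_equal(cl@category, "NONPOLYMER_SUBCOMPONENTS")
})

test_that("sugar or acyl attachments force group representation", {
  # teicoplanin-like: peptide core (>= 2 consecutive bonds) + sugars + acyl
  sub <- data.frame(key = c(paste0("R", 1:7), "S1", "S2", "S3", "L1"),
                    compId = c(rep("ALA", 7), rep("GLC", 3), "LIP"),
                    stringsAsFactors = FALSE)
  lk <- rbind(
    data.frame(key1 = paste0("R", 1:6), atom1 = "C",
               key2 = paste0("R", 2:7), atom2 = "N"),
    data.frame(key1 = c("R2", "R4", "R6", "S1"),
               atom1 = c("CB", "CB", "CB", "O6"),
               key2 = c("S1", "S2", "S3", "L1"),
               atom2 = c("C1", "C1", "C1", "C1")))
  cl <- classifyPeptideLike(birdMolecule(sub, lk), dict)
  expect_equal(cl@category, "GROUP")
  expect_setequal(cl@nonpeptideAttachments, c("GLC", "LIP"))
  # the peptide core keeps >= 2 consecutive bonds: group takes precedence
  expect_gte(cl@maxConsecutivePeptideBonds, 2L)
  expect_equal(cl@subcomponentSequence, rep("ALA", 7))
})

test_that("classification ignores chain naming and linkage order", {
  sub <- data.frame(key = c("Z9", "M5", "A1"), compId = "ALA",
                    stringsAsFactors = FALSE)
  lk <- data.frame(key1 = c("M5", "Z9"), atom1 = "C",
                   key2 = c("A1", "M5"), atom2 = "N",
                   stringsAsFactors = FALSE)
  cl1 <- classifyPeptideLike(birdMolecule(sub, lk), dict)
  cl2 <- classifyPeptideLike(birdMolecule(sub[3:1, ], lk[2:1, ]), dict)
  expect_equal(cl1@category, "POLYMER")
  expect_equal(cl2@category, cl1@category)
  expect_equal(cl2@maxConsecutivePeptideBonds,
               cl1@maxConsecutivePeptideBonds)
})

test_that("cyclic peptides start at the canonical rotation", {
  sub <- data.frame(key = paste0("R", 1:4), compId = "ALA",
                    stringsAsFactors = FALSE)
  lk <- data.frame(key1 = paste0("R", 1:4), atom1 = "C",
                   key2 = paste0("R", c(2:4, 1)), atom2 = "N",
                   stringsAsFactors = FALSE)
  cl <- classifyPeptideLike(birdMolecule(sub, lk), dict)
  expect_equal(cl@category, "POLYMER")   # 3 consecutive bonds along the cycle
  expect_equal(cl@maxConsecutivePeptideBonds, 3L)
})

test_that("PRD entries round-trip and ids are validated", {
  prd <- new("PrdEntry", prdId = "PRD_000123",
             name = "vancomycin-like fixture",
             compositionChains = list(
               "1" = c("ALA", "ALA", "ALA", "ALA", "ALA"),
               "2" = c("GLC", "GLC", "GLC", "LIP")),
             linkages = data.frame(
               entity1 = "1", seq1 = 2L, compId1 = "ALA", atom1 = "CB",
               entity2 = "2", seq2 = 1L, compId2 = "GLC", atom2 = "C1",
               stringsAsFactors = FALSE),
             structuralClass = "glycopeptide",
             functionText = "antibiotic",
             sourceRefs = "NOR00001")
  txt <- writePrd(prd)
  back <- parsePrd(txt)
  expect_equal(back@prdId, prd@prdId)
  expect_equal(back@compositionChains, prd@compositionChains)
  expect_equal(back@linkages, prd@linkages)
  expect_equal(back@structuralClass, "glycopeptide")
  expect_equal(back@sourceRefs, "NOR00001")
  expect_equal(sum(lengths(back@compositionChains)), 9L)

  expect_error(new("PrdEntry", prdId = "PRD_12", compositionChains = list(),
                   linkages = data.frame()), "PRD_")
  expect_error(parsePrd(gsub("PRD_000123", "PRDX123", txt)), "PRD")
})

test_that("FAM files round-trip and unknown members are reported", {
  fam <- new("PrdFamily", famId = "FAM_000010",
             memberPrdIds = c("PRD_000123", "PRD_000124", "PRD_000125"),
             functionText = "glycopeptide antibiotic",
             mechanism = "cell-wall synthesis inhibition")
  back <- parseFam(writeFam(fam))
  expect_equal(back@memberPrdIds, fam@memberPrdIds)
  expect_equal(back@mechanism, fam@mechanism)
  expect_length(back@memberPrdIds, 3L)

  iss <- validateFamily(back, c("PRD_000123", "PRD_000124"))
  expect_equal(nrow(iss), 1L)
  expect_match(iss$message, "PRD_000125")
  expect_equal(nrow(validateFamily(back, fam@memberPrdIds)), 0L)

  expect_error(new("PrdFamily", famId = "FAM_000011",
                   memberPrdIds = character(0)), "nonempty")
})
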