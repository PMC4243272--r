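# Binding-site delineation, identifiers, _struct_site output.

test_that("only residues inside the cutoff enter the site", {
  fx <- makeStructureFixture(list(nResidues = 0L,
                                  ligandDistances = c(3.0, 3.2, 3.4, 3.6,
                                                      4.0, 4.1),
                                  cell = c(90, 90, 90)), seed = 4)
  sites <- delineateSites(fx$model, siteParams(cutoff = 3.7))
  expect_length(sites, 1L)
  ct <- siteContacts(sites[[1]])
  expect_equal(nrow(ct), 4L)
  expect_true(all(ct$minDistance <= 3.7))
  expect_equal(sort(ct$minDistance), c(3.0, 3.2, 3.4, 3.6),
               tolerance = 1e-6)
  # and the contact list equals the brute-force ground truth
  tr <- fx$truth$contacts
  expect_equal(paste(ct$authChain, ct$authSeq, ct$symLabel),
               paste(tr$authChain, tr$authSeq, tr$symLabel))
  expect_equal(ct$minDistance, tr$minDistance, tolerance = 1e-9)
})

test_that("a grouped oligosaccharide gets one site for the whole molecule", {
  fx <- makeStructureFixture(list(cyclodextrin = TRUE, nResidues = 3L,
                                  cell = c(60, 60, 60)), seed = 6)
  sites <- delineateSites(fx$model, siteParams())
  expect_length(sites, 1L)           # one site, not seven
  expect_equal(nrow(sites[[1]]@ligand), 7L)
  # intra-group sugars never appear among their own contacts
  ct <- siteContacts(sites[[1]])
  expect_false(any(ct$compId == "GLC" & ct$symLabel == "1_555"))
})

test_that("an isolated ligand yields a site with empty contacts", {
  fx <- makeStructureFixture(list(nResidues = 0L, ligandDistances = 25,
                                  cell = c(120, 120, 120)), seed = 2)
  # the placed residue sits 25 A away: nothing within 3.7
  sites <- delineateSites(fx$model, siteParams())
  expect_length(sites, 1L)
  expect_equal(nrow(siteContacts(sites[[1]])), 0L)
})

test_that("site identifiers follow the declared AC1...ZZ9 enumeration", {
  expect_equal(assignSiteIds(3), c("AC1", "AC2", "AC3"))
  expect_equal(assignSiteIds(0), character(0))
  ids <- assignSiteIds(10)
  expect_equal(ids[10], "AD1")          # digit fastest, then second letter
  expect_equal(ids[9], "AC9")
  all_ <- assignSiteIds(24 * 9 + 1)      # first letter rolls A -> B
  expect_equal(all_[24 * 9 + 1], "BA1")
  expect_false(anyDuplicated(assignSiteIds(500)) > 0)
  expect_error(assignSiteIds(10^6), "capacity")
})

test_that("_struct_site output has the right shape and joins", {
  fx <- makeStructureFixture(list(nResidues = 0L,
                                  ligandDistances = c(3.0, 3.2, 3.4, 3.6),
                                  cell = c(90, 90, 90)), seed = 4)
  sites <- delineateSites(fx$model, siteParams(),
                          details = stats::setNames("author note",
                                                    fx$ligandKeys[1]))
  txt <- writeStructSite(sites)
  blocks <- parseCif(txt)
  ss <- blocks[[1]]$categories$struct_site
  gen <- blocks[[1]]$categories$struct_site_gen
  expect_equal(nrow(ss), 1L)
  expect_equal(nrow(gen), 4L)
  expect_true(all(gen$site_id %in% ss$id))   # foreign-key join
  expect_equal(ss$details, "author note")
  # round trip reproduces the sites
  back <- parseStructSite(txt)
  expect_length(back, 1L)
  expect_equal(siteId(back[[1]]), siteId(sites[[1]]))
  expect_equal(siteContacts(back[[1]])$symLabel,
               siteContacts(sites[[1]])$symLabel)
  expect_equal(siteContacts(back[[1]])$minDistance,
               siteContacts(sites[[1]])$minDistance, tolerance = 1e-3)
  expect_equal(back[[1]]@ligand$key, sites[[1]]@ligand$key)
  # empty site list -> no categories
  expect_length(writeStructSite(list(), asText = FALSE), 0L)
  # duplicate ids refused
  s2 <- sites[[1]]
  expect_error(writeStructSite(list(sites[[1]], s2)), "duplicate")
})

test_that("with a huge P1 cell the engine equals the naive computation", {
  fx <- makeStructureFixture(list(nResidues = 4L, ligandDistances = 3.1,
                                  spaceGroup = "P 1",
                                  cell = c(200, 200, 200)), seed = 9)
  withSym <- delineateSites(fx$model, siteParams(useSymmetry = TRUE))
  noSym <- delineateSites(fx$model, siteParams(useSymmetry = FALSE))
  expect_equal(siteContacts(withSym[[1]]), siteContacts(noSym[[1]]),
               tolerance = 1e-9)
})

test_that("results are invariant under internal atom-order relabeling", {
  fx <- makeStructureFixture(list(nResidues = 2L, ligandDistances = 3.1,
                                  cell = c(80, 80, 80)), seed = 10)
  m <- fx$model
  ct1 <- siteContacts(delineateSites(m, siteParams())[[1]])
  perm <- m
  set.seed(1)
  perm@atomSites <- m@atomSites[sample(nrow(m@atomSites)), , drop = FALSE]
  ct2 <- siteContacts(delineateSites(perm, siteParams())[[1]])
  expect_equal(ct1, ct2, ignore_attr = TRUE)
})

test_that("enlarging the cutoff never removes a contact", {
  fx <- makeStructureFixture(list(nResidues = 5L,
                                  ligandDistances = c(3.0, 3.5, 4.5),
                                  cell = c(90, 90, 90)), seed = 12)
  key <- function(ct) paste(ct$authChain, ct$authSeq, ct$symLabel)
  prev <- character(0)
  for (cut in c(3.0, 3.7, 4.6, 6.0)) {
    ct <- siteContacts(delineateSites(fx$model,
                                      siteParams(cutoff = cut))[[1]])
    expect_true(all(prev %in% key(ct)), info = paste("cutoff", cut))
    prev <- key(ct)
  }
})

test_that("a group's contacts equal the union of member contacts minus itself", {
  fx <- makeStructureFixture(list(cyclodextrin = TRUE, nResidues = 3L,
                                  cell = c(60, 60, 60)), seed = 7)
  m <- fx$model
  grouped <- delineateSites(m, siteParams())
  expect_length(grouped, 1L)
  gKey <- paste(siteContacts(grouped[[1]])$authChain,
                siteContacts(grouped[[1]])$authSeq,
                siteContacts(grouped[[1]])$symLabel)
  # ungrouped: one site per sugar
  m2 <- m
  m2@atomSites$groupId <- NA_character_
  single <- delineateSites(m2, siteParams())
  expect_length(single, 7L)
  unionKeys <- character(0)
  for (st in single) {
    ct <- siteContacts(st)
    # drop intra-group residues (the sugars live on chain G)
    keep <- !(ct$compId == "GLC" & ct$authChain == "G" &
                ct$symLabel == "1_555")
    unionKeys <- union(unionKeys,
                       paste(ct$authChain, ct$authSeq, ct$symLabel)[keep])
  }
  expect_setequal(gKey, unionKeys)
})

test_that("waters can be excluded from the neighbour list", {
  fx <- makeStructureFixture(list(metal = "ZN-tetrahedral", nResidues = 0L,
                                  cell = c(50, 50, 50)), seed = 3)
  withW <- delineateSites(fx$model,
                          siteParams(cutoff = 3.0,
                                     includeWatersAsNeighbors = TRUE))
  noW <- delineateSites(fx$model,
                        siteParams(cutoff = 3.0,
                                   includeWatersAsNeighbors = FALSE))
  znW <- withW[[which(vapply(withW, function(s) s@ligand$compId[1] == "ZN",
                             logical(1)))]]
  znN <- noW[[which(vapply(noW, function(s) s@ligand$compId[1] == "ZN",
                           logical(1)))]]
  expect_true(any(znW@contacts$compId == "HOH"))
  expect_false(any(znN@contacts$compId == "HOH"))
})

test_that("explicitly requesting symmetry without a cell is an error", {
  fx <- makeStructureFixture(list(nResidues = 1L, ligandDistances = 3.0,
                                  cell = c(80, 80, 80)), seed = 1)
  m <- fx$model
  m@cell <- NULL
  expect_error(delineateSites(m, siteParams(useSymmetry = TRUE)), "cell")
  # the auto default quietly falls back to the naive computation
  expect_silent(delineateSites(m, siteParams()))
})
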