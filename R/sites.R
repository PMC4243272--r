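## Binding-site delineation: symmetry-aware contact search at a fixed
## cutoff (3.7 A by default), grouping of multi-component molecules into
## single sites, AC1...ZZ9 site identifiers, and the
## _struct_site/_struct_site_gen writer and reader.

#' Site-delineation parameters
#'
#' @param cutoff contact cutoff in Angstrom (default 3.7).
#' @param includeWatersAsNeighbors waters count as neighbours (default TRUE);
#'   waters are never ligands of interest themselves.
#' @param useSymmetry include crystallographic symmetry mates. The default
#'   NA means "when the model has a cell"; an explicit TRUE on a cell-less
#'   model is an error rather than a silent non-symmetric fallback.
#' @return list of parameters for [delineateSites()].
#' @export
siteParams <- function(cutoff = 3.7, includeWatersAsNeighbors = TRUE,
                       useSymmetry = NA) {
  stopifnot(cutoff > 0)
  list(cutoff = cutoff,
       includeWatersAsNeighbors = includeWatersAsNeighbors,
       useSymmetry = useSymmetry)
}

## Residue-level contact scan around a set of ligand atoms.
## Returns one row per contacting residue with the minimum atom-atom
## distance over all atoms/altlocs/images and the symmetry label at which
## that minimum occurs. Residues in excludeKeys are suppressed only for
## their identity (1_555) copies: a symmetry mate of the ligand itself is
## a genuine crystal-packing neighbour.
.contactScan <- function(model, ligandKeys, cutoff, useSymmetry = TRUE,
                         includeWaters = TRUE, excludeKeys = ligandKeys) {
  s <- model@atomSites
  ligAtoms <- componentAtoms(model, ligandKeys)
  if (!nrow(ligAtoms)) return(.emptyContacts())
  if (useSymmetry) {
    if (is.null(model@cell))
      stop("symmetry-aware contact search requested but the model has no cell")
    img <- expandSymmetry(model, ligAtoms, cutoff)
  } else {
    C <- as.matrix(ligAtoms[, c("x", "y", "z")])
    X <- as.matrix(s[, c("x", "y", "z")])
    d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * (X %*% t(C))
    dmin <- sqrt(pmax(0, apply(d2, 1, min)))
    keep <- which(dmin <= cutoff)
    keep <- setdiff(keep, which(s$serial %in% ligAtoms$serial &
                                  .siteKeys(s) %in% ligandKeys))
    img <- s[keep, , drop = FALSE]
    if (nrow(img)) {
      img$opIndex <- 1L; img$shift1 <- 0L; img$shift2 <- 0L; img$shift3 <- 0L
      img$symLabel <- symLabel(1L)
      img$distance <- dmin[keep]
    } else {
      img <- cbind(s[0, , drop = FALSE],
                   data.frame(opIndex = integer(0), shift1 = integer(0),
                              shift2 = integer(0), shift3 = integer(0),
                              symLabel = character(0), distance = numeric(0)))
    }
  }
  if (!nrow(img)) return(.emptyContacts())
  key <- .siteKeys(img)
  drop <- (key %in% excludeKeys & img$symLabel == symLabel(1L)) |
    (!includeWaters & .isWater(img$compId))
  img <- img[!drop, , drop = FALSE]
  if (!nrow(img)) return(.emptyContacts())
  key <- .siteKeys(img)
  ord <- order(key, img$distance, img$symLabel)
  img <- img[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  res <- data.frame(compId = img$compId[first],
                    authChain = img$authChain[first],
                    authSeq = img$authSeq[first],
                    insCode = img$insCode[first],
                    symLabel = img$symLabel[first],
                    minDistance = img$distance[first],
                    stringsAsFactors = FALSE)
  res <- res[order(res$authChain, res$authSeq, res$insCode, res$compId), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Delineate ligand-binding sites
#'
#' Builds one binding site per non-polymeric, non-water ligand (or per
#' declared multi-component group: oligosaccharides and peptide-like
#' molecules get a single site for the whole molecule rather than one per
#' moiety). A residue is a contact iff any of its atoms -- or their
#' crystallographic symmetry images, when enabled -- lies within the
#' cutoff of any ligand atom; contacts are deduplicated at residue level,
#' keeping the minimum distance and its symmetry label. Sites are ordered
#' by ligand author addressing and assigned AC1, AC2, ... identifiers.
#'
#' @param model a [StructureModel-class].
#' @param params a [siteParams()] list.
#' @param groups optional named list of component-key vectors declaring
#'   multi-component ligands (see [setComponentGroups()]).
#' @param details optional named character vector of author-provided
#'   catalytic-site details, keyed by ligand component key or group name.
#' @return list of [BindingSite-class].
#' @export
delineateSites <- function(model, params = siteParams(), groups = NULL,
                           details = NULL) {
  if (!is.null(groups)) model <- setComponentGroups(model, groups)
  if (isTRUE(params$useSymmetry) && is.null(model@cell))
    stop("symmetry-aware site delineation requested but the model has no cell")
  useSym <- if (is.na(params$useSymmetry)) !is.null(model@cell)
            else isTRUE(params$useSymmetry)
  comp <- modelComponents(model)
  lig <- comp[!comp$isPolymerResidue & !comp$isWater, , drop = FALSE]
  if (!nrow(lig)) return(list())
  # one entity per group, one per ungrouped ligand component
  entities <- list()
  grouped <- lig[!is.na(lig$groupId), , drop = FALSE]
  for (g in unique(grouped$groupId)) {
    rows <- grouped[grouped$groupId == g, , drop = FALSE]
    entities[[length(entities) + 1L]] <-
      list(name = g, keys = rows$key, members = rows)
  }
  single <- lig[is.na(lig$groupId), , drop = FALSE]
  for (i in seq_len(nrow(single))) {
    entities[[length(entities) + 1L]] <-
      list(name = single$key[i], keys = single$key[i],
           members = single[i, , drop = FALSE])
  }
  # deterministic order: ligand author addressing of the first member
  ordKey <- vapply(entities, function(e)
    sprintf("%s|%09d|%s|%s", e$members$authChain[1], e$members$authSeq[1],
            e$members$insCode[1], e$members$compId[1]), character(1))
  entities <- entities[order(ordKey)]
  ids <- assignSiteIds(length(entities))
  sites <- vector("list", length(entities))
  for (i in seq_along(entities)) {
    e <- entities[[i]]
    contacts <- .contactScan(model, e$keys, params$cutoff,
                             useSymmetry = useSym,
                             includeWaters = params$includeWatersAsNeighbors)
    det <- NA_character_
    if (!is.null(details)) {
      hit <- intersect(c(e$name, e$keys), names(details))
      if (length(hit)) det <- unname(details[[hit[1]]])
    }
    sites[[i]] <- new("BindingSite", siteId = ids[i],
                      ligand = e$members[, c("compId", "authChain", "authSeq",
                                             "insCode", "key")],
                      evidence = "Software", contacts = contacts,
                      details = det)
  }
  sites
}

#' Binding-site identifier sequence
#'
#' Deterministic AC1 ... ZZ9 enumeration: two uppercase letters and one
#' digit 1-9; the digit advances fastest, then the second letter, then the
#' first, starting at AC1 (AC1...AC9, AD1, ...). Identifiers are never
#' reused; asking for more than the scheme holds is an error.
#'
#' @param n number of identifiers (>= 0).
#' @return character vector of n identifiers.
#' @export
assignSiteIds <- function(n) {
  stopifnot(n >= 0)
  if (n == 0L) return(character(0))
  grid <- expand.grid(digit = 1:9, second = LETTERS, first = LETTERS,
                      stringsAsFactors = FALSE)
  ids <- sprintf("%s%s%d", grid$first, grid$second, grid$digit)
  ids <- ids[!(grid$first == "A" & grid$second %in% c("A", "B"))]
  if (n > length(ids))
    stop("site-id scheme capacity (", length(ids), ") exceeded: ", n)
  ids[seq_len(n)]
}

#' Write binding sites as mmCIF categories
#'
#' Emits \code{_struct_site} (one row per site) and
#' \code{_struct_site_gen} (one row per contact residue, joined by
#' \code{site_id}); the full composition of grouped ligands is kept in an
#' auxiliary category so [parseStructSite()] reproduces the sites. An
#' empty site list yields no categories.
#'
#' @param sites list of [BindingSite-class].
#' @param asText return CIF text (default); otherwise the category list.
#' @return mmCIF text, or a named category list when \code{asText = FALSE}.
#' @export
writeStructSite <- function(sites, asText = TRUE) {
  if (!length(sites)) {
    return(if (asText) writeCif(list(list(name = "sites",
                                          categories = list()))) else list())
  }
  ids <- vapply(sites, siteId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate site id(s): ", paste(unique(ids[duplicated(ids)]),
                                         collapse = ", "))
  siteRows <- do.call(rbind, lapply(sites, function(st) {
    lig <- st@ligand
    data.frame(id = st@siteId,
               pdbx_evidence_code = st@evidence,
               pdbx_auth_comp_id = lig$compId[1],
               pdbx_auth_asym_id = lig$authChain[1],
               pdbx_auth_seq_id = as.character(lig$authSeq[1]),
               pdbx_auth_ins_code = if (nzchar(lig$insCode[1]))
                 lig$insCode[1] else NA_character_,
               pdbx_num_residues = as.character(nrow(st@contacts)),
               details = st@details,
               stringsAsFactors = FALSE)
  }))
  genRows <- do.call(rbind, lapply(sites, function(st) {
    ct <- st@contacts
    if (!nrow(ct)) return(NULL)
    data.frame(site_id = st@siteId,
               auth_comp_id = ct$compId,
               auth_asym_id = ct$authChain,
               auth_seq_id = as.character(ct$authSeq),
               pdbx_auth_ins_code = ifelse(nzchar(ct$insCode), ct$insCode,
                                           NA_character_),
               symmetry = ct$symLabel,
               pdbx_min_distance = sprintf("%.3f", ct$minDistance),
               stringsAsFactors = FALSE)
  }))
  ligRows <- do.call(rbind, lapply(sites, function(st) {
    lig <- st@ligand
    data.frame(site_id = st@siteId,
               comp_id = lig$compId,
               auth_asym_id = lig$authChain,
               auth_seq_id = as.character(lig$authSeq),
               pdbx_auth_ins_code = ifelse(nzchar(lig$insCode), lig$insCode,
                                           NA_character_),
               stringsAsFactors = FALSE)
  }))
  cats <- list(struct_site = structure(siteRows, loop = TRUE))
  if (!is.null(genRows)) {
    genRows <- cbind(data.frame(id = as.character(seq_len(nrow(genRows))),
                                stringsAsFactors = FALSE), genRows)
    cats$struct_site_gen <- structure(genRows, loop = TRUE)
  }
  cats$ligand_curation_site_ligand <- structure(ligRows, loop = TRUE)
  if (asText) writeCif(list(list(name = "sites", categories = cats))) else cats
}

#' Read binding sites back from mmCIF
#'
#' Inverse of [writeStructSite()]; used for round-trip verification.
#'
#' @param text mmCIF text containing the site categories.
#' @return list of [BindingSite-class].
#' @export
parseStructSite <- function(text) {
  blocks <- parseCif(text)
  block <- NULL
  for (b in blocks) if (!is.null(.getCat(b, "struct_site"))) { block <- b; break }
  if (is.null(block)) return(list())
  ss <- .getCat(block, "struct_site")
  gen <- .getCat(block, "struct_site_gen")
  ligcat <- .getCat(block, "ligand_curation_site_ligand")
  lapply(seq_len(nrow(ss)), function(i) {
    id <- ss$id[i]
    lig <- if (!is.null(ligcat)) {
      rows <- ligcat[ligcat$site_id == id, , drop = FALSE]
      ins <- .catChr(rows, "pdbx_auth_ins_code"); ins[is.na(ins)] <- ""
      data.frame(compId = rows$comp_id, authChain = rows$auth_asym_id,
                 authSeq = as.integer(rows$auth_seq_id), insCode = ins,
                 key = .compKey(rows$comp_id, rows$auth_asym_id,
                                as.integer(rows$auth_seq_id), ins),
                 stringsAsFactors = FALSE)
    } else {
      ins <- .catChr(ss[i, , drop = FALSE], "pdbx_auth_ins_code")
      ins[is.na(ins)] <- ""
      data.frame(compId = ss$pdbx_auth_comp_id[i],
                 authChain = ss$pdbx_auth_asym_id[i],
                 authSeq = as.integer(ss$pdbx_auth_seq_id[i]), insCode = ins,
                 key = NA_character_, stringsAsFactors = FALSE)
    }
    contacts <- .emptyContacts()
    if (!is.null(gen)) {
      rows <- gen[gen$site_id == id, , drop = FALSE]
      if (nrow(rows)) {
        ins <- .catChr(rows, "pdbx_auth_ins_code"); ins[is.na(ins)] <- ""
        contacts <- data.frame(
          compId = rows$auth_comp_id, authChain = rows$auth_asym_id,
          authSeq = as.integer(rows$auth_seq_id), insCode = ins,
          symLabel = rows$symmetry,
          minDistance = as.numeric(rows$pdbx_min_distance),
          stringsAsFactors = FALSE)
      }
    }
    new("BindingSite", siteId = id, ligand = lig,
        evidence = .catChr(ss[i, , drop = FALSE], "pdbx_evidence_code"),
        contacts = contacts,
        details = .catChr(ss[i, , drop = FALSE], "details"))
  })
}
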