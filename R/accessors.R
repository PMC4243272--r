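## Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for LigandCuration classes
#' @description Slot accessors: use these rather than \code{@}.
#' @param object an object of the documented class.
#' @return the slot contents.
NULL

#' @rdname accessors
#' @export
setGeneric("compId", function(object) standardGeneric("compId"))
#' @rdname accessors
#' @export
setMethod("compId", "ChemCompDef", function(object) object@compId)
#' @rdname accessors
#' @export
setMethod("compId", "ComponentMatch", function(object) object@compId)

#' @rdname accessors
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setMethod("atoms", "ChemCompDef", function(object) object@atoms)

#' @rdname accessors
#' @export
setGeneric("bonds", function(object) standardGeneric("bonds"))
#' @rdname accessors
#' @export
setMethod("bonds", "ChemCompDef", function(object) object@bonds)

#' @rdname accessors
#' @export
setGeneric("descriptors", function(object) standardGeneric("descriptors"))
#' @rdname accessors
#' @export
setMethod("descriptors", "ChemCompDef", function(object) object@descriptors)

#' @rdname accessors
#' @export
setGeneric("atomSites", function(object) standardGeneric("atomSites"))
#' @rdname accessors
#' @export
setMethod("atomSites", "StructureModel", function(object) object@atomSites)

#' @rdname accessors
#' @export
setGeneric("modelCell", function(object) standardGeneric("modelCell"))
#' @rdname accessors
#' @export
setMethod("modelCell", "StructureModel", function(object) object@cell)

#' @rdname accessors
#' @export
setGeneric("atomMap", function(object) standardGeneric("atomMap"))
#' @rdname accessors
#' @export
setMethod("atomMap", "ComponentMatch", function(object) object@atomMap)

#' @rdname accessors
#' @export
setGeneric("missingAtoms", function(object) standardGeneric("missingAtoms"))
#' @rdname accessors
#' @export
setMethod("missingAtoms", "ComponentMatch", function(object) object@missingAtoms)

#' @rdname accessors
#' @export
setGeneric("isExact", function(object) standardGeneric("isExact"))
#' @rdname accessors
#' @export
setMethod("isExact", "ComponentMatch", function(object) object@exact)

#' @rdname accessors
#' @export
setGeneric("siteId", function(object) standardGeneric("siteId"))
#' @rdname accessors
#' @export
setMethod("siteId", "BindingSite", function(object) object@siteId)

#' @rdname accessors
#' @export
setGeneric("siteContacts", function(object) standardGeneric("siteContacts"))
#' @rdname accessors
#' @export
setMethod("siteContacts", "BindingSite", function(object) object@contacts)

#' @rdname accessors
#' @export
setGeneric("ligators", function(object) standardGeneric("ligators"))
#' @rdname accessors
#' @export
setMethod("ligators", "CoordinationCenter", function(object) object@ligators)

#' @rdname accessors
#' @export
setGeneric("coordinationAngles",
           function(object) standardGeneric("coordinationAngles"))
#' @rdname accessors
#' @export
setMethod("coordinationAngles", "CoordinationCenter",
          function(object) object@angles)

#' @rdname accessors
#' @export
setGeneric("lldfScore", function(object) standardGeneric("lldfScore"))
#' @rdname accessors
#' @export
setMethod("lldfScore", "LldfResult", function(object) object@lldf)

#' @rdname accessors
#' @export
setGeneric("isFlagged", function(object) standardGeneric("isFlagged"))
#' @rdname accessors
#' @export
setMethod("isFlagged", "LldfResult", function(object) object@flagged)

setMethod("show", "ChemCompDef", function(object) {
  cat("ChemCompDef", object@compId,
      if (!is.na(object@name)) paste0("(", object@name, ")"), "\n")
  cat("  formula:", object@formula,
      " charge:", object@formalCharge,
      " type:", object@compType, "\n")
  cat("  atoms:", nrow(object@atoms),
      " bonds:", nrow(object@bonds),
      " leaving:", sum(object@atoms$leaving), "\n")
})

setMethod("show", "StructureModel", function(object) {
  comp <- modelComponents(object)
  cat("StructureModel:", nrow(object@atomSites), "atom sites,",
      nrow(comp), "components",
      sprintf("(%d polymeric, %d water)",
              sum(comp$isPolymerResidue), sum(.isWater(comp$compId))), "\n")
  if (!is.null(object@cell)) {
    cc <- object@cell
    cat(sprintf("  cell %.2f %.2f %.2f / %.1f %.1f %.1f  '%s' (%d ops)\n",
                cc@a, cc@b, cc@c, cc@alpha, cc@beta, cc@gamma,
                cc@spaceGroup, length(cc@operators)))
  } else cat("  no crystal cell\n")
})

setMethod("show", "ComponentMatch", function(object) {
  cat("ComponentMatch ->", object@compId,
      if (object@exact) "[exact]" else "[partial]", "\n")
  cat("  mapped:", length(object@atomMap),
      " missing:", nrow(object@missingAtoms),
      " extra:", length(object@extraAtoms),
      sprintf(" rmsd: %.3f A\n", object@rmsdAfterFit))
})

setMethod("show", "BindingSite", function(object) {
  lig <- paste(object@ligand$compId, object@ligand$authChain,
               object@ligand$authSeq, collapse = " + ")
  cat("BindingSite", object@siteId, "for", lig, "-",
      nrow(object@contacts), "contact residue(s)\n")
})

setMethod("show", "CoordinationCenter", function(object) {
  m <- object@metal
  cat("CoordinationCenter:", m$element[1], m$compId[1], m$authChain[1],
      m$authSeq[1], "-", nrow(object@ligators), "ligator(s),",
      nrow(object@angles), "angle(s)\n")
})

setMethod("show", "PeptideClassification", function(object) {
  cat("PeptideClassification:", object@category,
      sprintf("(max consecutive peptide bonds: %d)\n",
              object@maxConsecutivePeptideBonds))
  if (length(object@subcomponentSequence))
    cat("  sequence (N->C):",
        paste(object@subcomponentSequence, collapse = "-"), "\n")
  if (length(object@nonpeptideAttachments))
    cat("  attachments:",
        paste(object@nonpeptideAttachments, collapse = ", "), "\n")
})

setMethod("show", "LldfResult", function(object) {
  cat(sprintf("LLDF %.2f (ligand RSR %.3f vs %d neighbours %.3f +/- %.3f)%s\n",
              object@lldf, object@ligandRsr, object@nNeighbors,
              object@meanRsr, object@sdRsr,
              if (isTRUE(object@flagged)) "  ** flagged (>2)" else ""))
})

setMethod("show", "PrdEntry", function(object) {
  cat("PrdEntry", object@prdId,
      if (!is.na(object@name)) paste0("(", object@name, ")"), "\n")
  cat("  chains:", length(object@compositionChains),
      " subcomponents:", sum(lengths(object@compositionChains)),
      " class:", object@structuralClass, "\n")
})

setMethod("show", "PrdFamily", function(object) {
  cat("PrdFamily", object@famId, "-", length(object@memberPrdIds),
      "member(s)\n")
})
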