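# Independent oracles used across the suite. These deliberately do not
# share code paths with the implementation they check: the matcher oracle
# enumerates label-compatible bijections by backtracking, and superposition
# is re-derived here from the SVD rather than calling package internals.

# --- rigid-superposition RMSD (oracle copy) ------------------------------
oracleRmsd <- function(P, Q) {
  if (nrow(P) == 0L) return(NA_real_)
  Pc <- scale(P, scale = FALSE); Qc <- scale(Q, scale = FALSE)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  dsign <- sign(det(sv$v) * det(sv$u))
  R <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
  sqrt(sum((Pc %*% t(R) - Qc)^2) / nrow(P))
}

# --- exhaustive-permutation component matcher ----------------------------
# obs: data.frame(atomName, element, x, y, z) heavy atoms only
# Returns the best atom map by the declared tie-break (fewest missing
# non-leaving dict atoms, lowest rmsd, lexicographic map) or NULL.
oracleMatch <- function(obs, def, maxMissingFrac = 0.2) {
  da <- atoms(def)
  heavy <- da[!(da$element %in% c("H", "D")), , drop = FALSE]
  if (!nrow(obs) || nrow(obs) > nrow(heavy)) return(NULL)
  db <- bonds(def)
  dictEdge <- paste(pmin(db$atomId1, db$atomId2),
                    pmax(db$atomId1, db$atomId2))
  pb <- perceiveBonds(obs)
  obsEdges <- cbind(pb$i, pb$j)
  budget <- floor(maxMissingFrac * nrow(heavy) + 1e-9)
  dictXyz <- if (all(!is.na(heavy$idealX)))
    as.matrix(heavy[, c("idealX", "idealY", "idealZ")])
  else as.matrix(heavy[, c("modelX", "modelY", "modelZ")])
  rownames(dictXyz) <- heavy$atomId

  n <- nrow(obs)
  best <- NULL
  assign_ <- integer(n)    # obs index -> heavy row index
  used <- logical(nrow(heavy))
  consider <- function() {
    ids <- heavy$atomId[assign_]
    missing <- setdiff(da$atomId, ids)
    mrows <- da[match(missing, da$atomId), , drop = FALSE]
    kind <- ifelse(mrows$element %in% c("H", "D"), "hydrogen",
                   ifelse(mrows$leaving, "leaving", "other"))
    nOther <- sum(kind == "other")
    if (nOther > budget) return(invisible())
    rmsd <- oracleRmsd(as.matrix(obs[, c("x", "y", "z")]),
                       dictXyz[ids, , drop = FALSE])
    amap <- stats::setNames(ids, obs$atomName)
    mapStr <- paste(amap[order(names(amap))], collapse = "|")
    key <- list(nOther = nOther, rmsd = if (is.na(rmsd)) Inf else rmsd,
                mapStr = mapStr)
    better <- is.null(best) ||
      key$nOther < best$key$nOther ||
      (key$nOther == best$key$nOther && key$rmsd < best$key$rmsd) ||
      (key$nOther == best$key$nOther && key$rmsd == best$key$rmsd &&
         key$mapStr < best$key$mapStr)
    if (better) best <<- list(map = amap, key = key,
                              missing = data.frame(atomId = missing,
                                                   kind = kind))
  }
  bt <- function(i) {
    if (i > n) { consider(); return(invisible()) }
    for (j in seq_len(nrow(heavy))) {
      if (used[j] || heavy$element[j] != obs$element[i]) next
      # every already-perceived obs edge incident to i must map to a dict bond
      ok <- TRUE
      for (r in seq_len(nrow(obsEdges))) {
        a <- obsEdges[r, 1]; b <- obsEdges[r, 2]
        if (a == i && assign_[b] > 0L) {
          e <- paste(pmin(heavy$atomId[j], heavy$atomId[assign_[b]]),
                     pmax(heavy$atomId[j], heavy$atomId[assign_[b]]))
          if (!(e %in% dictEdge)) { ok <- FALSE; break }
        } else if (b == i && assign_[a] > 0L) {
          e <- paste(pmin(heavy$atomId[j], heavy$atomId[assign_[a]]),
                     pmax(heavy$atomId[j], heavy$atomId[assign_[a]]))
          if (!(e %in% dictEdge)) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      assign_[i] <<- j; used[j] <<- TRUE
      bt(i + 1L)
      assign_[i] <<- 0L; used[j] <<- FALSE
    }
  }
  bt(1L)
  best
}

# --- angle oracle --------------------------------------------------------
oracleAngle <- function(a, m, b) {
  u <- a - m; v <- b - m
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}
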