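# Construction helpers: observed components derived from dictionary
# definitions, with optional rigid transforms, renames and deletions.

randomRotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

obsFromDef <- function(def, coords = c("ideal", "model"),
                       drop = character(0), dropH = TRUE,
                       rot = NULL, shift = c(0, 0, 0),
                       permute = FALSE, scramble = FALSE) {
  coords <- match.arg(coords)
  a <- atoms(def)
  if (dropH) a <- a[!(a$element %in% c("H", "D")), , drop = FALSE]
  a <- a[!(a$atomId %in% drop), , drop = FALSE]
  xyz <- if (coords == "ideal")
    as.matrix(a[, c("idealX", "idealY", "idealZ")])
  else as.matrix(a[, c("modelX", "modelY", "modelZ")])
  if (!is.null(rot)) xyz <- xyz %*% t(rot)
  xyz <- sweep(xyz, 2, shift, "+")
  comp <- data.frame(atomName = a$atomId, element = a$element, altLoc = "",
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                     stringsAsFactors = FALSE)
  if (permute) comp <- comp[sample(nrow(comp)), , drop = FALSE]
  if (scramble) comp$atomName <- paste0("Q", seq_len(nrow(comp)))
  rownames(comp) <- NULL
  comp
}

linearPeptide <- function(k, compIds = rep("ALA", k)) {
  sub <- data.frame(key = paste0("R", seq_len(k)), compId = compIds,
                    stringsAsFactors = FALSE)
  lk <- if (k > 1L)
    data.frame(key1 = paste0("R", seq_len(k - 1L)), atom1 = "C",
               key2 = paste0("R", 2:k), atom2 = "N",
               stringsAsFactors = FALSE)
  else data.frame(key1 = character(0), atom1 = character(0),
                  key2 = character(0), atom2 = character(0),
                  stringsAsFactors = FALSE)
  birdMolecule(sub, lk)
}
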