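## Embedded space-group operator table. Operators are given as standard
## "x,y,z"-style triplets (International Tables settings) and parsed into
## rotation matrices + fractional translations. The table covers the
## common macromolecular groups used by the fixture generator; unknown
## symbols are an error -- a silent non-symmetric fallback would corrupt
## every downstream contact search.

.SG_OPS <- list(
  "P 1" = c("x,y,z"),
  "P 1 2 1" = c("x,y,z", "-x,y,-z"),
  "P 1 21 1" = c("x,y,z", "-x,y+1/2,-z"),
  "C 1 2 1" = c("x,y,z", "-x,y,-z",
                "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z"),
  "P 2 2 2" = c("x,y,z", "-x,-y,z", "-x,y,-z", "x,-y,-z"),
  "P 21 21 2" = c("x,y,z", "-x,-y,z",
                  "-x+1/2,y+1/2,-z", "x+1/2,-y+1/2,-z"),
  "P 21 21 21" = c("x,y,z", "-x+1/2,-y,z+1/2",
                   "x+1/2,-y+1/2,-z", "-x,y+1/2,-z+1/2")
)

.SG_ALIASES <- c(
  "P1" = "P 1",
  "P2" = "P 1 2 1", "P 2" = "P 1 2 1",
  "P21" = "P 1 21 1", "P 21" = "P 1 21 1", "P 1 21 1" = "P 1 21 1",
  "C2" = "C 1 2 1", "C 2" = "C 1 2 1",
  "P212121" = "P 21 21 21", "P 21 21 21" = "P 21 21 21",
  "P21212" = "P 21 21 2", "P 21 21 2" = "P 21 21 2",
  "P222" = "P 2 2 2", "P 2 2 2" = "P 2 2 2"
)

.parseXyzOp <- function(triplet, opIndex) {
  parts <- strsplit(gsub(" ", "", tolower(triplet)), ",", fixed = TRUE)[[1]]
  if (length(parts) != 3L) stop("malformed operator triplet: ", triplet)
  rot <- matrix(0, 3, 3)
  trans <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # split into signed terms
    expr <- gsub("-", "+-", expr, fixed = TRUE)
    terms <- strsplit(expr, "+", fixed = TRUE)[[1]]
    terms <- terms[nzchar(terms)]
    for (term in terms) {
      sign <- 1
      if (startsWith(term, "-")) { sign <- -1; term <- substring(term, 2L) }
      if (term %in% c("x", "y", "z")) {
        rot[i, match(term, c("x", "y", "z"))] <- sign
      } else if (grepl("^[0-9]+/[0-9]+$", term)) {
        frac <- as.numeric(strsplit(term, "/", fixed = TRUE)[[1]])
        trans[i] <- trans[i] + sign * frac[1] / frac[2]
      } else if (grepl("^[0-9.]+$", term)) {
        trans[i] <- trans[i] + sign * as.numeric(term)
      } else stop("malformed operator term '", term, "' in ", triplet)
    }
  }
  list(rot = rot, trans = trans %% 1, opIndex = opIndex)
}

.normalizeSgSymbol <- function(symbol) {
  s <- toupper(trimws(gsub("\\s+", " ", symbol)))
  if (s %in% names(.SG_OPS)) return(s)
  key <- names(.SG_ALIASES)[match(s, toupper(names(.SG_ALIASES)))]
  if (!is.na(key)) return(.SG_ALIASES[[key]])
  compact <- gsub(" ", "", s)
  hit <- which(toupper(gsub(" ", "", names(.SG_ALIASES))) == compact)
  if (length(hit)) return(.SG_ALIASES[[hit[1]]])
  hit <- which(toupper(gsub(" ", "", names(.SG_OPS))) == compact)
  if (length(hit)) return(names(.SG_OPS)[hit[1]])
  NA_character_
}

#' Symmetry operators for a space group
#'
#' Looks up the operators of a Hermann-Mauguin space-group symbol in the
#' embedded table (P 1, P 1 2 1, P 1 21 1, C 1 2 1, P 2 2 2, P 21 21 2,
#' P 21 21 21, plus compact aliases like "P212121"). Unknown symbols are an
#' error listing the symbol.
#'
#' @param symbol Hermann-Mauguin symbol, spacing-insensitive.
#' @return list of operators \code{list(rot, trans, opIndex)}.
#' @export
spaceGroupOperators <- function(symbol) {
  canon <- .normalizeSgSymbol(symbol)
  if (is.na(canon))
    stop("unknown space-group symbol '", symbol, "'; known symbols: ",
         paste(names(.SG_OPS), collapse = ", "))
  ops <- .SG_OPS[[canon]]
  lapply(seq_along(ops), function(i) .parseXyzOp(ops[i], i))
}

#' Construct a crystal cell
#'
#' @param a,b,c cell edges in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees (default 90).
#' @param spaceGroup Hermann-Mauguin symbol (default "P 1").
#' @return a [CrystalCell-class].
#' @export
crystalCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                        spaceGroup = "P 1") {
  canon <- .normalizeSgSymbol(spaceGroup)
  if (is.na(canon))
    stop("unknown space-group symbol '", spaceGroup, "'")
  new("CrystalCell", a = a, b = b, c = c,
      alpha = alpha, beta = beta, gamma = gamma,
      spaceGroup = canon, operators = spaceGroupOperators(canon))
}

## Orthogonalization matrix, PDB convention: a along x, b in the xy plane.
.orthoMatrix <- function(cell) {
  d <- pi / 180
  ca <- cos(cell@alpha * d); cb <- cos(cell@beta * d); cg <- cos(cell@gamma * d)
  sg <- sin(cell@gamma * d)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(cell@a, cell@b * cg, cell@c * cb,
           0,      cell@b * sg, cell@c * (ca - cb * cg) / sg,
           0,      0,           cell@c * v / sg),
         nrow = 3, byrow = TRUE)
}

#' Fractional/orthogonal coordinate conversion
#'
#' Mutually inverse conversions between fractional cell coordinates and
#' orthogonal Angstrom coordinates (PDB convention: a along x, b in the
#' x-y plane).
#'
#' @param frac,xyz numeric length-3 vector or n x 3 matrix.
#' @param cell a [CrystalCell-class].
#' @return matrix (or vector) of converted coordinates.
#' @export
orthogonalize <- function(frac, cell) {
  M <- .orthoMatrix(cell)
  if (is.null(dim(frac))) as.numeric(M %*% frac) else t(M %*% t(frac))
}

#' @rdname orthogonalize
#' @export
fractionalize <- function(xyz, cell) {
  Minv <- solve(.orthoMatrix(cell))
  if (is.null(dim(xyz))) as.numeric(Minv %*% xyz) else t(Minv %*% t(xyz))
}

#' Symmetry-label string for an operator + lattice shift
#'
#' Formats the customary \code{op_555}-style label: operator index followed
#' by the three lattice-translation digits offset by 5, so the identity
#' copy is \code{1_555}.
#'
#' @param opIndex 1-based operator index.
#' @param shift integer length-3 lattice shift.
#' @return character label.
#' @export
symLabel <- function(opIndex, shift = c(0L, 0L, 0L)) {
  sprintf("%d_%d%d%d", opIndex, 5L + shift[1], 5L + shift[2], 5L + shift[3])
}
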