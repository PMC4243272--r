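## Minimal CIF engine shared by the CCD, PRD/FAM and mmCIF readers/writers.
## A CIF document is represented as a list of blocks; each block is
##   list(name = <chr>, categories = <named list of character data.frames>)
## with attr(df, "loop") marking loop_ categories. All values are character;
## the CIF placeholders "." and "?" both parse to NA.

.CIF_NA <- c(".", "?")

.cifTokenizeLine <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line, perl = TRUE)[[1]]
  if (m[1] == -1L) return(list(tok = character(0), quoted = logical(0)))
  toks <- regmatches(line, list(m))[[1]]
  quoted <- grepl("^'.*'$|^\".*\"$", toks) & nchar(toks) >= 2L
  # comment: first unquoted token starting with '#' ends the line
  hash <- which(!quoted & startsWith(toks, "#"))
  if (length(hash)) {
    keep <- seq_len(hash[1] - 1L)
    toks <- toks[keep]; quoted <- quoted[keep]
  }
  toks[quoted] <- substr(toks[quoted], 2L, nchar(toks[quoted]) - 1L)
  list(tok = toks, quoted = quoted)
}

.cifTokenize <- function(text) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  toks <- character(0); quoted <- logical(0); lineno <- integer(0)
  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (startsWith(lines[i], ";")) {
      start <- i
      buf <- substring(lines[i], 2L)
      i <- i + 1L
      while (i <= n && !startsWith(lines[i], ";")) {
        buf <- c(buf, lines[i]); i <- i + 1L
      }
      if (i > n) stop("CIF parse error at line ", start,
                      ": unterminated text field")
      val <- paste(buf, collapse = "\n")
      if (startsWith(val, "\n")) val <- substring(val, 2L)
      toks <- c(toks, val); quoted <- c(quoted, TRUE)
      lineno <- c(lineno, start)
      i <- i + 1L
    } else {
      tl <- .cifTokenizeLine(lines[i])
      if (length(tl$tok)) {
        toks <- c(toks, tl$tok); quoted <- c(quoted, tl$quoted)
        lineno <- c(lineno, rep(i, length(tl$tok)))
      }
      i <- i + 1L
    }
  }
  list(tok = toks, quoted = quoted, line = lineno)
}

.splitTag <- function(tag) {
  body <- substring(tag, 2L)
  dot <- regexpr(".", body, fixed = TRUE)
  if (dot == -1L) c(body, "value") else
    c(substr(body, 1L, dot - 1L), substring(body, dot + 1L))
}

.cifValue <- function(x) {
  x[x %in% .CIF_NA] <- NA_character_
  x
}

#' Parse CIF text
#'
#' General-purpose CIF reader covering the subset of the syntax used by
#' component dictionaries and coordinate files: data blocks, key-value
#' items, \code{loop_} tables, quoted and semicolon-delimited text fields,
#' and comments. Category order within a block is preserved so writers can
#' round-trip documents.
#'
#' @param text character; CIF document (single string or vector of lines).
#' @return list of blocks, each \code{list(name, categories)}; categories are
#'   character data.frames, loop categories carry \code{attr(, "loop") = TRUE}.
#' @export
parseCif <- function(text) {
  tk <- .cifTokenize(text)
  toks <- tk$tok; quoted <- tk$quoted; lineno <- tk$line
  n <- length(toks)
  blocks <- list()
  cur <- NULL

  isTag <- function(k) !quoted[k] && startsWith(toks[k], "_")
  isKw <- function(k, kw) !quoted[k] && identical(tolower(toks[k]), kw)
  isData <- function(k) !quoted[k] && grepl("^data_", toks[k], ignore.case = TRUE)

  flush <- function() {
    if (!is.null(cur)) blocks[[length(blocks) + 1L]] <<- cur
  }
  newBlock <- function(name) {
    flush()
    cur <<- list(name = name, categories = list())
  }
  addCat <- function(cat, df, loop) {
    if (is.null(cur)) newBlock("")
    attr(df, "loop") <- loop
    if (cat %in% names(cur$categories) && !loop &&
        !isTRUE(attr(cur$categories[[cat]], "loop"))) {
      old <- cur$categories[[cat]]
      for (nm in names(df)) old[[nm]] <- df[[nm]]
      attr(old, "loop") <- FALSE
      cur$categories[[cat]] <<- old
    } else {
      cur$categories[[cat]] <<- df
    }
  }

  k <- 1L
  while (k <= n) {
    if (isData(k)) {
      newBlock(substring(toks[k], 6L))
      k <- k + 1L
    } else if (isKw(k, "loop_")) {
      k <- k + 1L
      tags <- character(0)
      while (k <= n && isTag(k)) { tags <- c(tags, toks[k]); k <- k + 1L }
      if (!length(tags)) stop("CIF parse error at line ", lineno[k - 1L],
                              ": loop_ without tags")
      vals <- character(0)
      while (k <= n && !isTag(k) && !isKw(k, "loop_") && !isData(k)) {
        vals <- c(vals, toks[k]); k <- k + 1L
      }
      if (length(vals) %% length(tags) != 0L)
        stop("CIF parse error at line ", lineno[k - 1L],
             ": loop value count ", length(vals),
             " not a multiple of tag count ", length(tags))
      mat <- matrix(.cifValue(vals), ncol = length(tags), byrow = TRUE)
      parts <- vapply(tags, .splitTag, character(2))
      cat <- parts[1L, 1L]
      if (!all(parts[1L, ] == cat))
        stop("CIF parse error at line ", lineno[k - 1L],
             ": loop mixes categories ", paste(unique(parts[1L, ]), collapse = ", "))
      df <- as.data.frame(mat, stringsAsFactors = FALSE)
      names(df) <- parts[2L, ]
      addCat(cat, df, loop = TRUE)
    } else if (isTag(k)) {
      if (k + 1L > n) stop("CIF parse error at line ", lineno[k],
                           ": tag ", toks[k], " without a value")
      parts <- .splitTag(toks[k])
      df <- data.frame(x = .cifValue(toks[k + 1L]), stringsAsFactors = FALSE)
      names(df) <- parts[2L]
      addCat(parts[1L], df, loop = FALSE)
      k <- k + 2L
    } else {
      stop("CIF parse error at line ", lineno[k],
           ": unexpected value '", toks[k], "'")
    }
  }
  flush()
  blocks
}

.cifQuote <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("?")
    if (grepl("\n", v, fixed = TRUE) ||
        (grepl("'", v, fixed = TRUE) && grepl("\"", v, fixed = TRUE)))
      return(paste0("\n;", v, "\n;"))
    needs <- !nzchar(v) || grepl("[ \t]", v) || v %in% .CIF_NA ||
      grepl("^[_#$\\[\\]]", v) || grepl("^data_|^loop_", v, ignore.case = TRUE) ||
      grepl("['\"]", v)
    if (!needs) return(v)
    if (grepl("'", v, fixed = TRUE)) paste0("\"", v, "\"") else paste0("'", v, "'")
  }, character(1), USE.NAMES = FALSE)
}

.writeCifCategory <- function(cat, df) {
  tags <- paste0("_", cat, ".", names(df))
  loop <- isTRUE(attr(df, "loop")) || nrow(df) > 1L
  out <- character(0)
  if (loop) {
    out <- c(out, "loop_", tags)
    if (nrow(df)) {
      cols <- lapply(df, function(col) .cifQuote(as.character(col)))
      rows <- do.call(paste, cols)
      # semicolon fields must start at column 1: fall back to per-value lines
      if (any(grepl("\n;", rows, fixed = TRUE))) {
        rows <- vapply(seq_len(nrow(df)), function(i)
          paste(vapply(cols, `[`, character(1), i), collapse = " "),
          character(1))
      }
      out <- c(out, rows)
    }
  } else {
    vals <- .cifQuote(as.character(df[1L, ]))
    width <- max(nchar(tags))
    out <- c(out, paste0(formatC(tags, width = -width), " ", vals))
  }
  c(out, "#")
}

#' Write CIF text
#'
#' Inverse of [parseCif()]: serialises blocks back to CIF, preserving
#' block and category order. Values containing whitespace are quoted;
#' values containing newlines become semicolon-delimited text fields;
#' `NA` is written as `?`.
#'
#' @param blocks list of blocks as returned by [parseCif()].
#' @return single character string of CIF text.
#' @export
writeCif <- function(blocks) {
  out <- character(0)
  for (b in blocks) {
    out <- c(out, paste0("data_", b$name), "#")
    for (cat in names(b$categories)) {
      out <- c(out, .writeCifCategory(cat, b$categories[[cat]]))
    }
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

.getCat <- function(block, cat) {
  if (cat %in% names(block$categories)) block$categories[[cat]] else NULL
}

.catNum <- function(df, col, default = NA_real_) {
  if (is.null(df) || !(col %in% names(df))) return(rep(default, max(1L, NROW(df))))
  suppressWarnings(as.numeric(df[[col]]))
}

.catChr <- function(df, col, default = NA_character_) {
  if (is.null(df) || !(col %in% names(df))) return(rep(default, max(1L, NROW(df))))
  as.character(df[[col]])
}
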