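#' Build a phylogenetic character matrix
#'
#' Container for mixed discrete and continuous parsimony characters.
#' Discrete cells hold a state set (a single state, a polymorphic set such as
#' \{0,1\}, or empty = missing); continuous cells hold a real value or
#' \code{NA}. Inapplicable codings (\code{"-"}) are distinguished from plain
#' missing (\code{"?"}) at parse time and preserved for reporting, but both
#' are reductively coded, i.e. score as missing.
#'
#' @param cells list of length \code{p}: for a discrete character a list of
#'   \code{n} integer vectors (\code{integer(0)} = missing); for a continuous
#'   character a numeric vector of length \code{n} (\code{NA} = missing).
#' @param taxa character vector of unique taxon names (length \code{n}).
#' @param kind per-character type: \code{"unordered"}, \code{"ordered"} or
#'   \code{"continuous"}.
#' @param weight per-character positive weight (default 1, equal weighting).
#' @param inapplicable optional \code{n x p} logical matrix flagging cells
#'   coded inapplicable.
#' @return an object of class \code{"characterMatrix"}.
#' @export
characterMatrix <- function(cells, taxa, kind,
                            weight = rep(1, length(cells)),
                            inapplicable = NULL) {
  n <- length(taxa); p <- length(cells)
  if (anyDuplicated(taxa)) stop("duplicate taxa")
  if (length(kind) != p || length(weight) != p)
    stop("kind/weight must have one entry per character")
  bad <- setdiff(unique(kind), c("unordered", "ordered", "continuous"))
  if (length(bad)) stop("unknown character kind: ", paste(bad, collapse = ", "))
  if (any(weight <= 0)) stop("weights must be positive")
  for (j in seq_len(p)) {
    if (kind[j] == "continuous") {
      if (!is.numeric(cells[[j]]) || length(cells[[j]]) != n)
        stop("continuous character ", j, " must be a numeric vector of length n")
      if (any(!is.finite(cells[[j]]) & !is.na(cells[[j]])))
        stop("non-finite value in continuous character ", j)
    } else {
      if (!is.list(cells[[j]]) || length(cells[[j]]) != n)
        stop("discrete character ", j, " must be a list of state sets of length n")
    }
  }
  if (is.null(inapplicable)) inapplicable <- matrix(FALSE, n, p)
  structure(list(cells = cells, taxa = taxa, kind = kind, weight = weight,
                 inapplicable = inapplicable),
            class = "characterMatrix")
}

#' @export
print.characterMatrix <- function(x, ...) {
  cat("characterMatrix:", length(x$taxa), "taxa x", length(x$kind), "characters\n")
  tab <- table(factor(x$kind, c("unordered", "ordered", "continuous")))
  cat("  kinds:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  missing cells:", sum(vapply(seq_along(x$cells), function(j)
    if (x$kind[j] == "continuous") sum(is.na(x$cells[[j]]))
    else sum(lengths(x$cells[[j]]) == 0L), 0L)),
    "(of which inapplicable:", sum(x$inapplicable), ")\n")
  invisible(x)
}

#' @rdname characterMatrix
#' @param x a \code{"characterMatrix"}.
#' @export
nTaxa <- function(x) length(x$taxa)

#' @rdname characterMatrix
#' @export
nChars <- function(x) length(x$kind)

#' Read a TNT/NEXUS-style character matrix
#'
#' Parses the dialect written by [writeCharacterMatrix()], a documented
#' superset of a TNT \code{xread} block with discrete and continuous
#' partitions:
#' \preformatted{
#' xread
#' 5 3
#' &[num]
#' TaxonA 01?[01]
#' TaxonB 0110
#' TaxonC 1-11
#' &[cont]
#' TaxonA 0.37
#' TaxonB ?
#' TaxonC 1.20
#' ;
#' ord: 2;
#' }
#' The dimensions line is \code{nchar ntax} (TNT order). Discrete symbols are
#' \code{0}-\code{9}, \code{?} (missing), \code{-} (inapplicable, preserved
#' but scored as missing), and \code{[..]} for polymorphic state sets.
#' Continuous values are whitespace-separated reals with \code{?} for
#' missing. Characters are numbered globally in order of appearance; an
#' optional trailing \code{ord:} statement lists (1-based) indices of ordered
#' discrete characters. A matrix with no \code{&[..]} partition marker is
#' read as all-discrete.
#'
#' @param text the matrix as a single string or character vector of lines.
#' @param file alternatively, a path to read.
#' @return a \code{"characterMatrix"}.
#' @export
readCharacterMatrix <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) text <- readLines(file, warn = FALSE)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(text)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  i <- 1L
  if (i <= length(lines) && grepl("^xread", lines[i], ignore.case = TRUE)) i <- i + 1L
  if (i <= length(lines) && grepl("^'", lines[i])) i <- i + 1L  # optional title
  dims <- suppressWarnings(as.integer(strsplit(lines[i], "\\s+")[[1]]))
  if (length(dims) != 2L || anyNA(dims) || any(dims < 1L))
    stop("expected a dimensions line 'nchar ntax', got: ", lines[i])
  p_decl <- dims[1]; n_decl <- dims[2]
  i <- i + 1L

  blocks <- list(); cur_type <- "num"; cur_rows <- list()
  flush <- function() {
    if (length(cur_rows))
      blocks[[length(blocks) + 1L]] <<- list(type = cur_type, rows = cur_rows)
    cur_rows <<- list()
  }
  ord_idx <- integer(0)
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^&\\[", ln)) {
      flush()
      cur_type <- if (grepl("cont", ln, ignore.case = TRUE)) "cont" else "num"
    } else if (ln == ";") {
      flush()
    } else if (grepl("^ord\\s*:", ln, ignore.case = TRUE)) {
      body <- sub("^ord\\s*:", "", ln, ignore.case = TRUE)
      ord_idx <- as.integer(strsplit(trimws(sub(";\\s*$", "", body)), "\\s+")[[1]])
    } else {
      tok <- regmatches(ln, regexpr("^\\S+", ln))
      cur_rows[[length(cur_rows) + 1L]] <- list(taxon = tok,
                                                body = trimws(sub("^\\S+", "", ln)))
    }
    i <- i + 1L
  }
  flush()
  if (!length(blocks)) stop("no data rows found")

  taxa <- vapply(blocks[[1]]$rows, `[[`, "", "taxon")
  if (length(taxa) != n_decl)
    stop("dimension mismatch: declared ", n_decl, " taxa, found ", length(taxa))
  cells <- list(); kind <- character(0)
  inap_cols <- list()
  for (b in blocks) {
    btaxa <- vapply(b$rows, `[[`, "", "taxon")
    if (!identical(sort(btaxa), sort(taxa)))
      stop("taxa differ between partitions")
    ord <- match(taxa, btaxa)
    bodies <- vapply(b$rows, `[[`, "", "body")[ord]
    if (b$type == "cont") {
      toks <- strsplit(bodies, "\\s+")
      nc <- unique(lengths(toks))
      if (length(nc) != 1L) stop("dimension mismatch: ragged continuous rows")
      for (j in seq_len(nc)) {
        v <- vapply(toks, `[[`, "", j)
        miss <- v %in% c("?", "-")
        inap <- v == "-"
        num <- suppressWarnings(as.numeric(ifelse(miss, NA, v)))
        if (any(is.na(num) & !miss))
          stop("unknown symbol in continuous partition: ",
               paste(unique(v[is.na(num) & !miss]), collapse = ", "))
        cells[[length(cells) + 1L]] <- num
        kind <- c(kind, "continuous")
        inap_cols[[length(inap_cols) + 1L]] <- inap
      }
    } else {
      parsed <- lapply(bodies, .parseDiscreteRow)
      nc <- unique(lengths(parsed))
      if (length(nc) != 1L) stop("dimension mismatch: ragged discrete rows")
      for (j in seq_len(nc)) {
        col <- lapply(parsed, function(row) row[[j]]$states)
        inap <- vapply(parsed, function(row) row[[j]]$inapplicable, TRUE)
        cells[[length(cells) + 1L]] <- col
        kind <- c(kind, "unordered")
        inap_cols[[length(inap_cols) + 1L]] <- inap
      }
    }
  }
  if (length(cells) != p_decl)
    stop("dimension mismatch: declared ", p_decl, " characters, found ", length(cells))
  if (length(ord_idx)) {
    if (any(ord_idx < 1L | ord_idx > length(cells)))
      stop("ord: index out of range")
    if (any(kind[ord_idx] == "continuous"))
      stop("ord: cannot apply to a continuous character")
    kind[ord_idx] <- "ordered"
  }
  characterMatrix(cells, taxa, kind,
                  inapplicable = do.call(cbind, inap_cols))
}

.parseDiscreteRow <- function(body) {
  s <- gsub("\\s+", "", body)
  chars <- strsplit(s, "")[[1]]
  out <- list(); k <- 1L
  while (k <= length(chars)) {
    ch <- chars[k]
    if (ch == "?") {
      out[[length(out) + 1L]] <- list(states = integer(0), inapplicable = FALSE)
    } else if (ch == "-") {
      out[[length(out) + 1L]] <- list(states = integer(0), inapplicable = TRUE)
    } else if (grepl("[0-9]", ch)) {
      out[[length(out) + 1L]] <- list(states = as.integer(ch), inapplicable = FALSE)
    } else if (ch == "[") {
      close <- k
      while (close <= length(chars) && chars[close] != "]") close <- close + 1L
      if (close > length(chars)) stop("unterminated '[' in discrete row")
      states <- chars[(k + 1L):(close - 1L)]
      if (!all(grepl("[0-9]", states)) || close == k + 1L)
        stop("malformed polymorphic set in discrete row")
      out[[length(out) + 1L]] <- list(states = sort(as.integer(states)),
                                      inapplicable = FALSE)
      k <- close
    } else {
      stop("unknown symbol '", ch, "' in discrete row")
    }
    k <- k + 1L
  }
  out
}

#' Write a character matrix in the TNT-style dialect read by
#' [readCharacterMatrix()]
#'
#' @param cm a \code{"characterMatrix"}.
#' @param file optional path; when omitted the text is returned.
#' @param digits significant digits for continuous values.
#' @return the serialised lines, invisibly when written to a file.
#' @export
writeCharacterMatrix <- function(cm, file = NULL, digits = 10) {
  stopifnot(inherits(cm, "characterMatrix"))
  n <- nTaxa(cm); p <- nChars(cm)
  disc <- which(cm$kind != "continuous")
  cont <- which(cm$kind == "continuous")
  out <- c("xread", paste(p, n))
  if (length(disc)) {
    out <- c(out, "&[num]")
    for (t in seq_len(n)) {
      row <- vapply(disc, function(j) {
        st <- cm$cells[[j]][[t]]
        if (length(st) == 0L) {
          if (cm$inapplicable[t, j]) "-" else "?"
        } else if (length(st) == 1L) as.character(st)
        else paste0("[", paste(st, collapse = ""), "]")
      }, "")
      out <- c(out, paste(cm$taxa[t], paste(row, collapse = "")))
    }
  }
  if (length(cont)) {
    out <- c(out, "&[cont]")
    for (t in seq_len(n)) {
      row <- vapply(cont, function(j) {
        v <- cm$cells[[j]][t]
        if (is.na(v)) {
          if (cm$inapplicable[t, j]) "-" else "?"
        } else format(v, digits = digits)
      }, "")
      out <- c(out, paste(cm$taxa[t], paste(row, collapse = " ")))
    }
  }
  out <- c(out, ";")
  ord_global <- which(cm$kind == "ordered")
  if (length(ord_global)) {
    # global indices follow write order: discrete partition first
    remap <- match(ord_global, c(disc, cont))
    out <- c(out, paste0("ord: ", paste(remap, collapse = " "), ";"))
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
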