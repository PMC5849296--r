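#' Build an occurrence table of stratigraphic ranges
#'
#' One row per taxon with first (\code{fad}) and last (\code{lad}) appearance
#' ages in Ma before present (larger = older). An optional \code{override_fad}
#' column encodes curation rules where a taxon's own first occurrence is too
#' poorly constrained to use and the first occurrence of a close relative is
#' substituted; the override replaces \code{fad} before any computation and
#' the reported value is kept in \code{fad_reported}.
#'
#' @param taxon character vector of unique taxon names.
#' @param fad,lad numeric ages in Ma, \code{fad >= lad >= 0}.
#' @param override_fad optional numeric, \code{NA} where absent.
#' @param bin optional per-taxon time-bin label.
#' @return a \code{data.frame} of class \code{"occurrenceTable"}.
#' @export
occurrenceTable <- function(taxon, fad, lad, override_fad = NULL, bin = NULL) {
  taxon <- as.character(taxon)
  if (length(taxon) == 0L) stop("empty occurrence table")
  if (anyDuplicated(taxon))
    stop("duplicate taxon: ", paste(unique(taxon[duplicated(taxon)]), collapse = ", "))
  fad <- as.numeric(fad); lad <- as.numeric(lad)
  if (anyNA(fad) || anyNA(lad)) stop("fad/lad must be numeric and non-missing")
  out <- data.frame(taxon = taxon, fad = fad, lad = lad,
                    stringsAsFactors = FALSE)
  out$fad_reported <- fad
  if (!is.null(override_fad)) {
    override_fad <- as.numeric(override_fad)
    repl <- !is.na(override_fad)
    out$fad[repl] <- override_fad[repl]
  }
  bad <- which(out$fad < out$lad)
  if (length(bad))
    stop("reversed range (fad < lad) for: ",
         paste(out$taxon[bad], collapse = ", "), " (row ",
         paste(bad, collapse = ", "), ")")
  if (any(out$lad < 0)) stop("negative ages not allowed")
  if (!is.null(bin)) out$bin <- as.character(bin)
  class(out) <- c("occurrenceTable", "data.frame")
  out
}

#' Read an occurrence table from CSV
#'
#' Expects columns \code{taxon,fad,lad} with optional \code{override_fad} and
#' \code{bin}. Comma-separated, UTF-8, header mandatory; missing = empty cell
#' or \code{NA}.
#'
#' @param file path to a CSV file.
#' @return an \code{"occurrenceTable"}.
#' @export
readOccurrences <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("taxon", "fad", "lad")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  occurrenceTable(df$taxon, df$fad, df$lad,
                  override_fad = if ("override_fad" %in% names(df)) df$override_fad,
                  bin = if ("bin" %in% names(df)) df$bin)
}

#' Write an occurrence table to CSV
#' @param occ an \code{"occurrenceTable"}.
#' @param file output path.
#' @export
writeOccurrences <- function(occ, file) {
  stopifnot(inherits(occ, "occurrenceTable"))
  write.csv(as.data.frame(occ), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Build a functional character matrix
#'
#' Taxa by typed characters (categorical, ordered or continuous) with missing
#' values allowed, plus an optional per-taxon time-bin label. This is the
#' container for trait tables such as habitat, wingspan, jaw curvature,
#' cervical and hindlimb elongation and the ulna:humerus and
#' metacarpal IV:humerus ratios.
#'
#' @param data data.frame of trait values, rownames = taxa; missing as
#'   \code{NA} or \code{""}.
#' @param kinds named character vector mapping each column of \code{data} to
#'   \code{"categorical"}, \code{"ordered"} or \code{"continuous"}.
#' @param levels named list giving, for each ordered character, its states
#'   from lowest to highest (mandatory for ordered; optional state universe
#'   for categorical).
#' @param bin optional named character vector of bin labels per taxon.
#' @return an object of class \code{"functionalMatrix"}.
#' @export
functionalMatrix <- function(data, kinds, levels = list(), bin = NULL) {
  data <- as.data.frame(data)
  if (is.null(rownames(data)) || anyDuplicated(rownames(data)))
    stop("data must have unique taxon rownames")
  if (!setequal(names(kinds), colnames(data)))
    stop("kinds must name every character column")
  kinds <- kinds[colnames(data)]
  bad <- setdiff(unique(kinds), c("categorical", "ordered", "continuous"))
  if (length(bad)) stop("unknown character type: ", paste(bad, collapse = ", "))
  for (j in colnames(data)) {
    v <- data[[j]]
    v[!is.na(v) & v == ""] <- NA
    if (kinds[[j]] == "continuous") {
      v <- suppressWarnings(as.numeric(v))
      if (!all(is.finite(v) | is.na(v))) stop("non-finite value in continuous character ", j)
    } else {
      v <- as.character(v)
      if (kinds[[j]] == "ordered") {
        if (is.null(levels[[j]]))
          stop("ordered character ", j, " needs a state order in `levels`")
        unk <- setdiff(v[!is.na(v)], levels[[j]])
        if (length(unk)) stop("state not in declared order for ", j, ": ",
                              paste(unk, collapse = ", "))
      }
    }
    data[[j]] <- v
  }
  obs <- !is.na(as.matrix(data))
  if (any(rowSums(obs) == 0L))
    stop("taxon with no observed characters: ",
         paste(rownames(data)[rowSums(obs) == 0L], collapse = ", "))
  if (any(colSums(obs) == 0L))
    stop("character with no observed values: ",
         paste(colnames(data)[colSums(obs) == 0L], collapse = ", "))
  if (!is.null(bin)) bin <- setNames(as.character(bin[rownames(data)]), rownames(data))
  structure(list(data = data, kinds = kinds, levels = levels, bin = bin),
            class = "functionalMatrix")
}

#' @export
print.functionalMatrix <- function(x, ...) {
  cat("functionalMatrix:", nrow(x$data), "taxa x", ncol(x$data), "characters\n")
  tab <- table(factor(x$kinds, c("categorical", "ordered", "continuous")))
  cat("  kinds:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  missing: %.1f%%\n", 100 * mean(is.na(as.matrix(x$data)))))
  if (!is.null(x$bin))
    cat("  bins:", paste(names(table(x$bin)), table(x$bin), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a functional matrix from CSV plus a schema sidecar
#'
#' The CSV has a \code{taxon} column and one column per character; the schema
#' (YAML) declares each character's kind and, for ordered characters, the
#' state order:
#' \preformatted{
#' characters:
#'   habitat:        {kind: categorical, states: [continental, brackish, marine]}
#'   wingspan:       {kind: continuous, unit: m}
#'   jaw_curvature:  {kind: ordered, states: [straight, curved, strongly_curved]}
#' bin_column: bin
#' }
#'
#' @param file CSV path.
#' @param schema YAML path or pre-parsed list.
#' @return a \code{"functionalMatrix"}.
#' @export
readFunctionalMatrix <- function(file, schema) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  if (!"taxon" %in% names(df)) stop("missing required column: taxon")
  if (anyDuplicated(df$taxon)) stop("duplicate taxon in functional matrix")
  rownames(df) <- df$taxon
  df$taxon <- NULL
  if (is.character(schema)) schema <- yaml::read_yaml(schema)
  chars <- schema$characters
  if (is.null(chars)) stop("schema lacks a `characters` mapping")
  bin <- NULL
  if (!is.null(schema$bin_column)) {
    if (!schema$bin_column %in% names(df))
      stop("declared bin column absent: ", schema$bin_column)
    bin <- setNames(as.character(df[[schema$bin_column]]), rownames(df))
    df[[schema$bin_column]] <- NULL
  }
  miss <- setdiff(names(df), names(chars))
  if (length(miss)) stop("characters not in schema: ", paste(miss, collapse = ", "))
  df <- df[, names(chars)[names(chars) %in% names(df)], drop = FALSE]
  kinds <- vapply(chars[colnames(df)], function(ch) ch$kind %||% "categorical", "")
  lv <- lapply(chars[colnames(df)], function(ch) unlist(ch$states))
  lv <- lv[!vapply(lv, is.null, TRUE)]
  functionalMatrix(df, kinds, levels = lv, bin = bin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
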