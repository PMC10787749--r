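#' Read a gene-by-sample count matrix
#'
#' TSV (first column = gene id, remaining columns = samples) or
#' MatrixMarket coordinate format. MatrixMarket carries no identifiers, so
#' `<path>` is accompanied by `<path>.genes` and `<path>.samples`
#' sidecar files (one id per line), as written by [write_counts()].
#'
#' @param path File path; format inferred from the `.mtx` extension unless
#'   `format` is given.
#' @param format `"tsv"` or `"mtx"`.
#' @return Integer matrix with dimnames.
#' @export
read_counts <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(paste0(path, ".genes"))
    cn <- readLines(paste0(path, ".samples"))
    dimnames(m) <- list(rn, cn)
  } else {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (anyDuplicated(df[[1]]))
      stop("duplicate gene id(s) in ", path, ": ",
           paste(head(unique(df[[1]][duplicated(df[[1]])]), 3), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  if (any(m < 0)) stop("negative counts in ", path)
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix (TSV or MatrixMarket)
#'
#' @param counts Integer matrix with dimnames.
#' @param path Output path (use a `.mtx` extension for MatrixMarket; gene
#'   and sample sidecar files are written next to it).
#' @param format `"tsv"` or `"mtx"` (inferred from the extension).
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = NULL) {
  format <- format %||% if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".genes"))
    writeLines(colnames(counts), paste0(path, ".samples"))
  } else {
    df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' Plain TSV with a `sample_id` column; an `alcohol` column, when present,
#' is restored as an ordered factor with the four consumption categories.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(sample_id = "character"))
  if (!"sample_id" %in% colnames(df))
    stop("metadata must contain a `sample_id` column")
  if ("alcohol" %in% colnames(df))
    df$alcohol <- factor(df$alcohol, levels = c("0", "1-2", "3-5", ">5"),
                         ordered = TRUE)
  df
}

# Serialize doubles at full precision so written tables round-trip to the
# exact binary values (write.table's default 15 digits loses the last bit).
full_precision <- function(df) {
  for (j in seq_along(df)) {
    x <- df[[j]]
    if (is.double(x)) df[[j]] <- sprintf("%.17g", x)
  }
  df
}

#' Write a sample metadata table
#' @param samples data.frame with `sample_id`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(samples, path) {
  write.table(full_precision(samples), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene...`.
#'
#' @param path GMT path.
#' @return Named list of gene sets.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write gene sets to a GMT file
#'
#' @param sets Named list of gene sets.
#' @param path GMT path.
#' @param descriptions Optional per-set descriptions (defaults to the set
#'   names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% names(sets)
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a scored edge list (regulatory or protein-interaction)
#'
#' Three-column TSV. For `type = "ppi"` the score dialect is auto-detected:
#' files carrying the 0-1000 integer convention are rescaled to \[0,1\]
#' (e.g. 700 becomes 0.7). Self-loops and duplicate (unordered, for PPI)
#' pairs are rejected.
#'
#' @param path TSV path with header.
#' @param type `"grn"` (columns tf, target, confidence) or `"ppi"`
#'   (protein_a, protein_b, score).
#' @return data.frame with canonical column names.
#' @export
read_edge_list <- function(path, type = c("grn", "ppi")) {
  type <- match.arg(type)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("edge list needs 3 columns: ", path)
  df <- df[, 1:3]
  colnames(df) <- if (type == "grn") c("tf", "target", "confidence") else
    c("protein_a", "protein_b", "score")
  sc <- df[[3]]
  if (anyNA(sc) || !is.numeric(sc)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(sc))))[1]
    stop("malformed score at line ", bad + 1L, " of ", path)
  }
  if (type == "ppi" && all(sc == round(sc)) && max(sc) > 1) sc <- sc / 1000
  if (any(sc < 0 | sc > 1)) stop("scores outside [0, 1] in ", path)
  df[[3]] <- sc
  if (any(df[[1]] == df[[2]])) stop("self-loop edge(s) in ", path)
  key <- if (type == "ppi")
    paste(pmin(df[[1]], df[[2]]), pmax(df[[1]], df[[2]])) else
      paste(df[[1]], df[[2]])
  if (anyDuplicated(key)) stop("duplicate edge(s) in ", path)
  df
}

#' Write a scored edge list
#' @param edges data.frame as returned by [read_edge_list()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  write.table(full_precision(edges), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a pathway parent-child hierarchy
#' @param path TSV with columns parent, child.
#' @return data.frame `parent`, `child`.
#' @export
read_hierarchy <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("hierarchy needs 2 columns: ", path)
  df <- df[, 1:2]
  colnames(df) <- c("parent", "child")
  assert_acyclic(df)
  df
}

#' Write a pathway parent-child hierarchy
#' @param parent_edges data.frame `parent`, `child`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(parent_edges, path) {
  write.table(parent_edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write ground truth as JSON
#' @param truth A [ground_truth()] object.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}
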