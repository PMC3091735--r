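#' Read a FASTA file
#'
#' Parses protein or nucleotide FASTA. Record IDs are taken as the first
#' whitespace-delimited token of each header line; sequences are uppercased
#' and line wrapping is collapsed. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences (names are record IDs).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("failed to parse FASTA '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Read a protein feature table (ptt-style) into a COG category map
#'
#' Expects a tab-delimited table with a column literally named `COG` (the
#' NCBI ptt layout, possibly preceded by free-text preamble lines). Protein
#' IDs come from a `Synonym`, `PID` or `protein_id` column, falling back to
#' the first column. A COG cell such as `"COG0583K"` or `"KL"` yields the
#' set of category letters; `"-"` or an empty cell yields the empty set.
#' An optional leading `COG\\d+` accession token is stripped before the
#' remaining letters are read as categories (ptt dialects vary).
#'
#' @param path Path to the table.
#' @return Named list mapping protein ID to a character vector of
#'   single-letter COG categories (possibly empty).
#' @export
read_protein_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines)) stop("empty protein table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  is_header <- vapply(fields, function(f) any(toupper(trimws(f)) == "COG"),
                      logical(1))
  header_i <- which(is_header)[1]
  if (is.na(header_i)) stop("no COG column found in ", path)
  header <- trimws(fields[[header_i]])
  cog_col <- which(toupper(header) == "COG")[1]
  id_candidates <- c("Synonym", "protein_id", "PID")
  id_col <- match(id_candidates, header)
  id_col <- id_col[!is.na(id_col)][1]
  if (is.na(id_col) || !length(id_col)) id_col <- 1L
  if (header_i >= length(fields)) stop("protein table has no data rows: ", path)
  body <- fields[seq.int(header_i + 1L, length(fields))]
  ok <- lengths(body) == length(header)
  if (any(!ok)) {
    warning(sum(!ok), " malformed row(s) skipped out of ", length(body),
            " in ", path)
    body <- body[ok]
  }
  ids <- vapply(body, function(f) trimws(f[[id_col]]), character(1))
  cogs <- lapply(body, function(f) parse_cog_cell(f[[cog_col]]))
  names(cogs) <- ids
  cogs
}

#' @noRd
parse_cog_cell <- function(x) {
  x <- toupper(trimws(x))
  x <- gsub("COG[0-9]+", "", x)
  x <- gsub("[^A-Z]", "", x)
  if (!nzchar(x)) return(character(0))
  sort(unique(strsplit(x, "")[[1]]))
}

#' Write / read a weighted edge list as 3-column TSV
#'
#' The format (`source`, `target`, `weight`) is importable by standard graph
#' viewers (e.g. Cytoscape). Rows are written in lexicographic order of
#' (source, target) so runs are diffable.
#'
#' @param edges Data frame with columns `source`, `target`, `weight`, or a
#'   `species_graph` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(edges, path) {
  if (inherits(edges, "species_graph")) edges <- edges$edges
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(source = character(0), target = character(0),
                        weight = numeric(0))
  }
  stopifnot(all(c("source", "target", "weight") %in% names(edges)))
  edges <- edges[order(edges$source, edges$target),
                 c("source", "target", "weight"), drop = FALSE]
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "weight") %in% names(df)))
  df
}

#' Write / read a matrix as TSV with row and column headers
#'
#' Rows are ordered lexicographically by row name for deterministic output.
#'
#' @param m A matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a generic result table as TSV
#'
#' @param table A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(table, path) {
  stopifnot(is.data.frame(table))
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a square distance matrix in PHYLIP format
#'
#' @param dm Symmetric numeric matrix with identical row/column names.
#' @param path Output path.
#' @param digits Number of decimal digits.
#' @return Invisibly, `path`.
#' @export
write_phylip <- function(dm, path, digits = 6L) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm), !is.null(rownames(dm)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  fmt <- paste0("%.", digits, "f")
  for (i in seq_len(nrow(dm))) {
    writeLines(paste(c(sprintf("%-12s", rownames(dm)[i]),
                       sprintf(fmt, dm[i, ])), collapse = " "), con)
  }
  invisible(path)
}
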