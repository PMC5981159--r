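# Tab-separated matrix I/O. Tables are UTF-8, LF, dot-decimal, one header
# row, first column = ID. A leading "#OTU ID" header cell (the BIOM-classic
# dialect) is accepted as equivalent to a plain ID header.

#' Read a tab-separated numeric table into a matrix
#'
#' Reads a TSV file whose first column holds row IDs and whose remaining
#' columns are numeric. The BIOM-classic header `#OTU ID` is recognized.
#' Parse failures are fatal and name the file, line and column of the
#' offending cell.
#'
#' @param path Path to a tab-separated file.
#' @param allow_negative Permit negative values (default `FALSE`; count
#'   tables in this package are non-negative by contract).
#' @return A numeric matrix with row names taken from the first column and
#'   column names from the header.
#' @export
read_tsv_matrix <- function(path, allow_negative = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, comment.char = "",
                          quote = "", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L)
    stop(path, ": expected an ID column plus at least one data column")
  ids <- trimws(as.character(df[[1L]]))
  if (anyDuplicated(ids))
    stop(path, ": duplicate row IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  raw <- as.matrix(df[, -1L, drop = FALSE])
  m <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                               dimnames = list(ids, colnames(raw))))
  bad <- which(is.na(m) & !(raw %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("%s: non-numeric cell '%s' at line %d, column %d (row '%s', column '%s')",
                 path, raw[bad[1L, 1L], bad[1L, 2L]],
                 bad[1L, 1L] + 1L, bad[1L, 2L] + 1L,
                 ids[bad[1L, 1L]], colnames(raw)[bad[1L, 2L]]))
  }
  if (!allow_negative && any(m < 0, na.rm = TRUE)) {
    neg <- which(m < 0, arr.ind = TRUE)
    stop(sprintf("%s: negative value %s at line %d, column %d (row '%s', column '%s')",
                 path, format(m[neg[1L, 1L], neg[1L, 2L]]),
                 neg[1L, 1L] + 1L, neg[1L, 2L] + 1L,
                 ids[neg[1L, 1L]], colnames(m)[neg[1L, 2L]]))
  }
  m
}

#' Write a numeric matrix as a tab-separated table
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_header Header for the ID column; `"#OTU ID"` emits the
#'   BIOM-classic dialect.
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(m, path, id_header = "ID") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  header <- paste(c(id_header, colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], as.character(m[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path, sep = "\n")
  invisible(path)
}

#' Read a KO-to-BRITE membership table
#'
#' Expects four tab-separated columns: KO identifier and the three BRITE
#' hierarchy levels. One row per membership; a KO appearing on several rows
#' belongs to several pathways, in row order.
#'
#' @param path Path to the 4-column TSV.
#' @return A `data.frame` with columns `ko`, `level1`, `level2`, `level3`.
#' @export
read_brite_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, comment.char = "",
                          quote = "", stringsAsFactors = FALSE)
  if (ncol(df) != 4L)
    stop(path, ": BRITE map must have 4 columns (ko, level1, level2, level3)")
  names(df) <- c("ko", "level1", "level2", "level3")
  as_brite_map(df)
}

#' Write a BRITE membership table
#' @param brite A BRITE map `data.frame` (see [read_brite_map()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_brite_map <- function(brite, path) {
  brite <- as_brite_map(brite)
  utils::write.table(brite, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Validate and normalize a BRITE map
#'
#' @param df `data.frame` with columns `ko`, `level1`, `level2`, `level3`.
#' @return The validated `data.frame`.
#' @export
as_brite_map <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("ko", "level1", "level2", "level3") %in% names(df)))
  df <- df[, c("ko", "level1", "level2", "level3")]
  key <- paste(df$ko, df$level1, df$level2, df$level3, sep = "\r")
  if (anyDuplicated(key))
    stop("BRITE map: duplicated membership for KO ",
         df$ko[duplicated(key)][1L])
  df
}

# FASTA read/write thin wrappers; sequences are kept as DNAStringSet.
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}
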