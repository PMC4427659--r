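#' The BLOSUM62 substitution matrix
#'
#' Returns the BLOSUM62 matrix shipped with Biostrings, the default
#' comparison matrix for profile construction and ortholog scoring.
#'
#' @return a symmetric integer matrix with residue row/column names.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Read a substitution matrix in NCBI/EMBOSS text format
#'
#' Parses the usual whitespace-separated matrix layout: `#` comment lines,
#' a header line of column residues, then one row per residue. The matrix
#' must be symmetric.
#'
#' @param path path to the matrix file.
#' @return a symmetric numeric matrix with residue dimnames.
#' @export
readSubstitutionMatrix <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) stop("not a substitution matrix file: ", path)
  cols <- strsplit(lines[1L], "\\s+")[[1L]]
  body <- strsplit(lines[-1L], "\\s+")
  rn <- vapply(body, `[`, "", 1L)
  vals <- lapply(body, function(x) as.numeric(x[-1L]))
  if (any(lengths(vals) != length(cols)))
    stop("matrix row lengths do not match the header")
  m <- do.call(rbind, vals)
  dimnames(m) <- list(rn, cols)
  if (!identical(rownames(m), colnames(m)) || !isTRUE(all.equal(m, t(m))))
    stop("substitution matrix must be symmetric")
  m
}

checkMatrixAlphabet <- function(matrix, residues, what = "sequence") {
  bad <- setdiff(residues, rownames(matrix))
  if (length(bad))
    stop(what, " contains residue(s) absent from the substitution matrix: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}
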