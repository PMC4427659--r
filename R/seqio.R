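IUPAC_NT <- c("A", "C", "G", "T", "U", "N",
              "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_EXT <- c(AA20, "X", "*", "B", "Z")

firstToken <- function(x) sub("[ \t].*$", "", x)

checkUniqueIds <- function(ids, what = "record") {
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate ", what, " id(s): ", paste(unique(dup), collapse = ", "))
  invisible(ids)
}

#' Read a FASTA file into a Biostrings sequence set
#'
#' Reads plain (wrapped or unwrapped) FASTA. Sequences are uppercased and
#' the alphabet is auto-detected: a file in which at least 90% of residues
#' are in `{A,C,G,T,U,N}` is read as nucleotide (a [Biostrings::DNAStringSet]
#' with `U` converted to `T`), otherwise as protein (an
#' [Biostrings::AAStringSet]). Record ids (the first whitespace-delimited
#' header token) must be unique.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"auto"` (default), `"nucleotide"` or `"protein"` to
#'   override detection.
#' @return a named `DNAStringSet` or `AAStringSet`; an empty set for an
#'   empty file.
#' @export
readFasta <- function(path, alphabet = c("auto", "nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  raw <- Biostrings::readBStringSet(path)
  ids <- firstToken(names(raw))
  checkUniqueIds(ids)
  seqs <- toupper(as.character(raw))
  if (alphabet == "auto") {
    chars <- unlist(strsplit(seqs, "", fixed = TRUE))
    frac <- if (length(chars)) mean(chars %in% c("A", "C", "G", "T", "U", "N")) else 1
    alphabet <- if (frac >= 0.9) "nucleotide" else "protein"
  }
  if (alphabet == "nucleotide") {
    bad <- setdiff(unique(unlist(strsplit(seqs, "", fixed = TRUE))), IUPAC_NT)
    if (length(bad))
      stop("non-IUPAC nucleotide character(s): ", paste(bad, collapse = ", "))
    out <- Biostrings::DNAStringSet(chartr("U", "T", seqs))
  } else {
    bad <- setdiff(unique(unlist(strsplit(seqs, "", fixed = TRUE))), AA_EXT)
    if (length(bad))
      stop("non-protein character(s): ", paste(bad, collapse = ", "))
    out <- Biostrings::AAStringSet(seqs)
  }
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param x a named `XStringSet` (or a named character vector).
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, width = 60L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file with Phred+33 qualities
#'
#' Reads 4-line FASTQ records (Sanger Phred+33 encoding) into a
#' [Biostrings::QualityScaledDNAStringSet]. A quality string whose length
#' differs from its sequence, or quality characters outside the Phred+33
#' range `[0, 93]`, raise an error.
#'
#' @param path path to an (uncompressed or gzipped) FASTQ file.
#' @return a `QualityScaledDNAStringSet`.
#' @export
readFastq <- function(path) {
  # validate the 4-line structure first: the Biostrings reader does not
  # reliably reject quality lines whose length differs from the sequence
  con <- gzfile(path)
  on.exit(close(con))
  lines <- readLines(con)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (!length(lines))
    return(Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(), Biostrings::PhredQuality(character())))
  if (length(lines) %% 4L != 0L)
    stop("not a 4-line-record FASTQ file: ", path)
  ids <- firstToken(sub("^@", "", lines[seq(1L, length(lines), by = 4L)]))
  sq <- lines[seq(2L, length(lines), by = 4L)]
  qu <- lines[seq(4L, length(lines), by = 4L)]
  bad <- nchar(qu) != nchar(sq)
  if (any(bad))
    stop("quality string length differs from sequence length for read(s): ",
         paste(ids[bad], collapse = ", "))
  qascii <- as.integer(charToRaw(paste(qu, collapse = "")))
  if (length(qascii) && (min(qascii) < 33L || max(qascii) > 126L))
    stop("quality characters outside the Phred+33 range [0, 93]")
  reads <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path,
                                              quality.scoring = "phred"),
    warning = function(w) {
      # Biostrings emits a cosmetic note about dropped metadata columns
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  names(reads) <- firstToken(names(reads))
  reads
}

# per-read integer Phred values of a QualityScaledDNAStringSet
phredValues <- function(reads) {
  methods::as(Biostrings::quality(reads), "IntegerList")
}

#' Translate a nucleotide sequence in one reading frame
#'
#' Standard genetic code (translation table 1). Frames `-1/-2/-3` are read
#' on the reverse complement. A trailing partial codon is dropped; stop
#' codons are rendered `*`; any codon containing an ambiguity code is
#' rendered `X`.
#'
#' @param nt nucleotide sequence (character or `DNAString`).
#' @param frame one of `1, 2, 3, -1, -2, -3`.
#' @return the protein sequence as a character string (possibly empty).
#' @export
translateFrame <- function(nt, frame = 1L) {
  if (!frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
    stop("frame must be one of +1, +2, +3, -1, -2, -3")
  s <- chartr("U", "T", toupper(as.character(nt)))
  if (frame < 0)
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  off <- abs(frame) - 1L
  ncod <- (nchar(s) - off) %/% 3L
  if (is.na(ncod) || ncod < 1L) return("")
  s <- substr(s, off + 1L, off + 3L * ncod)
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

# split a translation at stop codons; returns 0-based fragment starts
splitAtStops <- function(aa) {
  n <- nchar(aa)
  if (n == 0L)
    return(data.frame(aa_start = integer(), residues = character(),
                      stringsAsFactors = FALSE))
  stops <- which(strsplit(aa, "", fixed = TRUE)[[1L]] == "*")
  bounds <- c(0L, stops, n + 1L)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L] - 1L
  keep <- ends >= starts + 1L
  data.frame(aa_start = starts[keep],
             residues = substring(aa, starts[keep] + 1L, ends[keep]),
             stringsAsFactors = FALSE)
}

#' Six-frame translation fragments of a nucleotide sequence
#'
#' Translates the sequence in all six frames, splits each translation at
#' stop codons, and returns the stop-free fragments of at least
#' `minAaLen` residues. Fragments are ordered frames `+1, +2, +3, -1, -2,
#' -3`, then left to right within a frame; `aa_start` is 0-based in the
#' frame's amino-acid coordinates.
#'
#' @param nt nucleotide sequence (character or `DNAString`).
#' @param minAaLen minimum fragment length in residues.
#' @param id source sequence id recorded in the output.
#' @return data.frame with columns `source_id`, `frame`, `aa_start`,
#'   `residues`.
#' @export
sixFrameFragments <- function(nt, minAaLen = 1L, id = "seq") {
  s <- toupper(as.character(nt))
  if (any(!strsplit(s, "", fixed = TRUE)[[1L]] %in% IUPAC_NT) && nzchar(s))
    stop("sixFrameFragments requires a nucleotide sequence")
  out <- lapply(c(1L, 2L, 3L, -1L, -2L, -3L), function(f) {
    fr <- splitAtStops(translateFrame(s, f))
    fr <- fr[nchar(fr$residues) >= minAaLen, , drop = FALSE]
    if (nrow(fr))
      cbind(data.frame(source_id = id, frame = f, stringsAsFactors = FALSE), fr)
    else
      NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(source_id = character(), frame = integer(),
                      aa_start = integer(), residues = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
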