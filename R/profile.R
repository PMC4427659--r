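#' Construct a MarkerAlignment
#'
#' @param ids unique sequence identifiers.
#' @param rows equal-length aligned rows (gap character `-`).
#' @param genus optional genus labels parallel to `ids`.
#' @return a [MarkerAlignment-class] object.
#' @export
markerAlignment <- function(ids, rows, genus = character()) {
  methods::new("MarkerAlignment", ids = as.character(ids),
               rows = toupper(as.character(rows)),
               genus = as.character(genus))
}

#' Read an aligned FASTA file into a MarkerAlignment
#'
#' @param path path to an aligned FASTA file (gap character `-`).
#' @param genus optional genus labels, one per record in file order.
#' @return a [MarkerAlignment-class].
#' @export
readAlignedFasta <- function(path, genus = character()) {
  raw <- Biostrings::readBStringSet(path)
  ids <- firstToken(names(raw))
  checkUniqueIds(ids)
  markerAlignment(ids, as.character(raw), genus)
}

#' @describeIn alignmentAccessors number of rows
#' @export
alignmentIds <- function(msa) msa@ids

#' Accessors for MarkerAlignment
#'
#' @param msa a [MarkerAlignment-class].
#' @name alignmentAccessors
#' @return `alignmentIds`: the ids; `alignmentRows`: the aligned rows.
NULL

#' @describeIn alignmentAccessors aligned rows
#' @export
alignmentRows <- function(msa) msa@rows

# genus labels, parsing them from id prefixes when absent
alignmentGenus <- function(msa) {
  if (length(msa@genus)) return(msa@genus)
  g <- sub("[_|. -].*$", "", msa@ids)
  unparseable <- g == msa@ids | !nzchar(g)
  if (any(unparseable))
    stop("cannot parse genus from id(s): ",
         paste(msa@ids[unparseable], collapse = ", "),
         " -- supply genus labels explicitly")
  g
}

pruneAllGapColumns <- function(rows) {
  if (!length(rows)) return(rows)
  cols <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  keep <- !apply(cols == "-", 2L, all)
  apply(cols[, keep, drop = FALSE], 1L, paste, collapse = "")
}

#' Keep one randomly chosen sequence per genus
#'
#' Reduces taxonomic sampling bias before profile construction: for each
#' genus exactly one row is retained, chosen uniformly at random under the
#' given seed. Columns left all-gap by the removal are deleted.
#'
#' @param msa a [MarkerAlignment-class]; genus labels are taken from the
#'   object or parsed from the id prefix (text before the first `_`, `|`,
#'   `.`, space or `-`).
#' @param seed integer seed; the selection is deterministic for a fixed
#'   seed.
#' @return a [MarkerAlignment-class] with one row per genus.
#' @export
onePerGenus <- function(msa, seed) {
  genus <- alignmentGenus(msa)
  genera <- unique(genus)
  pick <- vapply(seq_along(genera), function(k) {
    cand <- which(genus == genera[k])
    if (length(cand) == 1L) cand
    else withSeed(mixSeed(seed, k), sample(cand, 1L))
  }, integer(1))
  pick <- sort(pick)
  markerAlignment(msa@ids[pick], pruneAllGapColumns(msa@rows[pick]),
                  genus[pick])
}

#' Build a Gribskov-style profile from a multiple alignment
#'
#' For alignment column `p` and alphabet residue `a`, the profile score is
#' the mean over all `N` rows of the substitution-matrix entry between the
#' row's residue at `p` and `a`, with gap cells contributing 0 to the sum.
#' Per-position gap penalties are the global penalties scaled by the
#' column's non-gap fraction, so gappy alignment columns are cheap to skip.
#'
#' @param msa a [MarkerAlignment-class].
#' @param matrix symmetric substitution matrix (default [blosum62()]).
#' @param gapOpen,gapExtend global gap penalties in matrix units,
#'   `gapOpen >= gapExtend >= 0`.
#' @param name profile name.
#' @return a [GribskovProfile-class].
#' @export
buildProfile <- function(msa, matrix = blosum62(), gapOpen = 10,
                         gapExtend = 0.5, name = "profile") {
  if (!length(msa@rows)) stop("cannot build a profile from an empty alignment")
  if (gapExtend < 0 || gapOpen < gapExtend)
    stop("need gapOpen >= gapExtend >= 0")
  alphabet <- setdiff(rownames(matrix), c("*", "-"))
  cols <- do.call(rbind, strsplit(msa@rows, "", fixed = TRUE))
  checkMatrixAlphabet(matrix, setdiff(unique(as.vector(cols)), "-"),
                      "alignment")
  n <- nrow(cols)
  L <- ncol(cols)
  M <- matrix(0, nrow = L, ncol = length(alphabet),
              dimnames = list(NULL, alphabet))
  go <- ge <- numeric(L)
  for (p in seq_len(L)) {
    res <- cols[, p]
    nongap <- res != "-"
    if (any(nongap))
      M[p, ] <- colSums(matrix[res[nongap], alphabet, drop = FALSE]) / n
    frac <- mean(nongap)
    go[p] <- gapOpen * frac
    ge[p] <- gapExtend * frac
  }
  methods::new("GribskovProfile", name = name, alphabet = alphabet, M = M,
               gapOpen = go, gapExtend = ge, nSequences = as.integer(n),
               sourceIds = msa@ids)
}

#' @describeIn profileAccessors number of profile positions
#' @export
profileLength <- function(profile) nrow(profile@M)

#' Accessors for GribskovProfile
#'
#' @param profile a [GribskovProfile-class].
#' @name profileAccessors
#' @return `profileLength`: integer; `profileMatrix`: the position-score
#'   matrix; `profileName`: the name; `gapPenalties`: a two-column matrix
#'   of per-position open/extend penalties.
NULL

#' @describeIn profileAccessors position-score matrix
#' @export
profileMatrix <- function(profile) profile@M

#' @describeIn profileAccessors profile name
#' @export
profileName <- function(profile) profile@name

#' @describeIn profileAccessors per-position gap penalties
#' @export
gapPenalties <- function(profile)
  cbind(open = profile@gapOpen, extend = profile@gapExtend)

#' Consensus sequence of a profile
#'
#' The per-position argmax of the position-score matrix; ties are broken
#' by alphabet order.
#'
#' @param profile a [GribskovProfile-class].
#' @return a protein string of length `profileLength(profile)`.
#' @export
profileConsensus <- function(profile) {
  paste(profile@alphabet[apply(profile@M, 1L, which.max)], collapse = "")
}

# one-row ProfileHit data.frame
hitRow <- function(target_id = NA_character_, frame = 0L,
                   aa_start = NA_integer_, aa_end = NA_integer_,
                   nt_start = NA_integer_, nt_end = NA_integer_,
                   score = 0, passed = NA) {
  data.frame(target_id = target_id, frame = as.integer(frame),
             aa_start = as.integer(aa_start), aa_end = as.integer(aa_end),
             nt_start = as.integer(nt_start), nt_end = as.integer(nt_end),
             score = as.numeric(score), passed = passed,
             stringsAsFactors = FALSE)
}

emptyHits <- function() hitRow()[0L, , drop = FALSE]

#' Score a protein sequence against a profile
#'
#' Optimal local (Smith-Waterman-style) alignment of the sequence against
#' the profile by dynamic programming with affine, position-specific gap
#' penalties: skipping profile column `p` costs `gapOpen[p]` (then
#' `gapExtend[p]` per further column), while an unmatched sequence residue
#' between two profile columns costs the mean of the flanking columns'
#' penalties. The score is floored at 0 (the empty alignment); among
#' equal-scoring hits the leftmost, then longest, is returned.
#'
#' @param profile a [GribskovProfile-class].
#' @param seq non-empty protein string (residues absent from the profile
#'   alphabet score 0 against every column).
#' @param cutoff optional score cutoff used to set the hit's `passed`
#'   flag.
#' @param id target id recorded in the hit.
#' @return a one-row ProfileHit data.frame with columns `target_id`,
#'   `frame` (0 for direct protein input), `aa_start`, `aa_end` (0-based
#'   half-open), `nt_start`, `nt_end` (`NA` here), `score`, `passed`. A
#'   degenerate score-0 result has `NA` coordinates and `passed = FALSE`.
#' @export
scoreSequence <- function(profile, seq, cutoff = NULL, id = "seq") {
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop("cannot score an empty sequence")
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1L]], profile@alphabet)
  idx[is.na(idx)] <- 0L
  res <- profile_align_c(profile@M, profile@gapOpen, profile@gapExtend,
                         as.integer(idx - 1L))
  degenerate <- res$start < 0L
  passed <- if (is.null(cutoff)) NA else (!degenerate && res$score >= cutoff)
  if (degenerate) passed <- if (is.null(cutoff)) FALSE else passed
  hitRow(target_id = id, frame = 0L,
         aa_start = if (degenerate) NA_integer_ else res$start,
         aa_end = if (degenerate) NA_integer_ else res$end,
         score = res$score,
         passed = if (degenerate) FALSE else passed)
}

# map 0-based half-open aa coords within a frame translation to 1-based
# inclusive nt coords on the forward strand of a record of length ntLen
aaToNt <- function(frame, aaStart, aaEnd, ntLen) {
  fr <- abs(frame)
  s0 <- (fr - 1L) + 3L * aaStart
  e0 <- (fr - 1L) + 3L * (aaEnd - 1L) + 2L
  if (frame < 0L) {
    tmp <- s0
    s0 <- ntLen - 1L - e0
    e0 <- ntLen - 1L - tmp
  }
  c(s0 + 1L, e0 + 1L)
}

#' Scan a sequence record for profile hits
#'
#' Protein records are scored directly. Nucleotide records are expanded
#' into six-frame stop-free fragments of at least `minAaLen` residues
#' ([sixFrameFragments()]) and each fragment is scored; hits at or above
#' the cutoff are reduced greedily (by descending score) to a set that is
#' non-overlapping in nucleotide coordinates.
#'
#' @param profile a [GribskovProfile-class].
#' @param record sequence (character, `DNAString` or `AAString`).
#' @param cutoff non-negative score cutoff; only hits with
#'   `score >= cutoff` are returned.
#' @param minAaLen minimum translated fragment length scored.
#' @param id record id used in the hits.
#' @param alphabet `"auto"`, `"nucleotide"` or `"protein"`.
#' @return a ProfileHit data.frame (possibly empty), sorted by `nt_start`
#'   then `frame` for nucleotide input. `aa_start`/`aa_end` are in the
#'   scored fragment's coordinates; `nt_start`/`nt_end` are 1-based
#'   inclusive forward-strand coordinates.
#' @export
scanRecord <- function(profile, record, cutoff, minAaLen = 50L, id = "seq",
                       alphabet = c("auto", "nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (cutoff < 0) stop("cutoff must be non-negative")
  s <- toupper(as.character(record))
  if (alphabet == "auto") {
    if (methods::is(record, "DNAString") || methods::is(record, "DNAStringSet")) {
      alphabet <- "nucleotide"
    } else if (methods::is(record, "AAString") || methods::is(record, "AAStringSet")) {
      alphabet <- "protein"
    } else {
      chars <- strsplit(s, "", fixed = TRUE)[[1L]]
      alphabet <- if (!length(chars) ||
                      mean(chars %in% c("A", "C", "G", "T", "U", "N")) >= 0.9)
        "nucleotide" else "protein"
    }
  }
  if (alphabet == "protein") {
    if (!nzchar(s)) return(emptyHits())
    hit <- scoreSequence(profile, s, cutoff = cutoff, id = id)
    return(if (isTRUE(hit$passed)) hit else emptyHits())
  }
  frags <- sixFrameFragments(s, minAaLen = minAaLen, id = id)
  if (!nrow(frags)) return(emptyHits())
  hits <- do.call(rbind, lapply(seq_len(nrow(frags)), function(k) {
    h <- scoreSequence(profile, frags$residues[k], cutoff = cutoff, id = id)
    if (!isTRUE(h$passed)) return(NULL)
    h$frame <- frags$frame[k]
    nt <- aaToNt(frags$frame[k], frags$aa_start[k] + h$aa_start,
                 frags$aa_start[k] + h$aa_end, nchar(s))
    h$nt_start <- nt[1L]
    h$nt_end <- nt[2L]
    h
  }))
  if (is.null(hits) || !nrow(hits)) return(emptyHits())
  # greedy non-overlap reduction in nt coordinates, by descending score
  ord <- order(-hits$score, hits$nt_start, hits$frame)
  kept <- integer()
  for (k in ord) {
    if (!any(hits$nt_start[k] <= hits$nt_end[kept] &
             hits$nt_end[k] >= hits$nt_start[kept]))
      kept <- c(kept, k)
  }
  hits <- hits[kept[order(hits$nt_start[kept], hits$frame[kept])], ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Serialize a profile to a versioned TSV file
#'
#' Writes a header block (format version, name, alphabet, number of source
#' sequences, source ids) followed by one row per profile position with
#' the gap penalties and the position scores. Numbers are written with 17
#' significant digits so that [readProfile()] round-trips bit-exactly.
#'
#' @param profile a [GribskovProfile-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProfile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# sporescan profile v1",
               paste0("# name=", profile@name),
               paste0("# alphabet=", paste(profile@alphabet, collapse = ",")),
               paste0("# n_sequences=", profile@nSequences),
               paste0("# source_ids=", paste(profile@sourceIds, collapse = ","))),
             con)
  writeLines(paste(c("pos", "gap_open", "gap_extend", profile@alphabet),
                   collapse = "\t"), con)
  num <- function(x) sprintf("%.17g", x)
  for (p in seq_len(nrow(profile@M)))
    writeLines(paste(c(p, num(profile@gapOpen[p]), num(profile@gapExtend[p]),
                       num(profile@M[p, ])), collapse = "\t"), con)
  invisible(path)
}

#' Read a profile written by [writeProfile()]
#'
#' @param path path to a profile TSV file.
#' @return a [GribskovProfile-class].
#' @export
readProfile <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1L] != "# sporescan profile v1")
    stop("not a sporescan profile file: ", path)
  header <- lines[startsWith(lines, "# ") | startsWith(lines, "#")]
  getField <- function(key) {
    ln <- grep(paste0("^# ", key, "="), lines, value = TRUE)
    if (!length(ln)) stop("profile file missing header field: ", key)
    sub(paste0("^# ", key, "="), "", ln[1L])
  }
  name <- getField("name")
  alphabet <- strsplit(getField("alphabet"), ",", fixed = TRUE)[[1L]]
  nSeq <- as.integer(getField("n_sequences"))
  srcRaw <- getField("source_ids")
  sourceIds <- if (nzchar(srcRaw)) strsplit(srcRaw, ",", fixed = TRUE)[[1L]]
               else character()
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(colnames(tab)[1:3], c("pos", "gap_open", "gap_extend")))
    stop("malformed profile table in: ", path)
  M <- as.matrix(tab[, -(1:3), drop = FALSE])
  dimnames(M) <- list(NULL, alphabet)
  methods::new("GribskovProfile", name = name, alphabet = alphabet, M = M,
               gapOpen = as.numeric(tab$gap_open),
               gapExtend = as.numeric(tab$gap_extend),
               nSequences = nSeq, sourceIds = sourceIds)
}
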