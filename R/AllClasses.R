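#' @import methods
NULL

#' MarkerAlignment: a gapped protein multiple alignment with genus labels
#'
#' Holds a pre-computed multiple alignment of marker protein sequences
#' (gap character `-`), the input from which a [GribskovProfile-class] is
#' built. Genus labels support taxonomic de-biasing via [onePerGenus()].
#'
#' @slot ids character vector of unique sequence identifiers.
#' @slot rows character vector of equal-length aligned rows, parallel to
#'   `ids`.
#' @slot genus character vector of genus labels parallel to `ids`, or a
#'   zero-length vector when no labels are attached.
#'
#' @seealso [readAlignedFasta()], [buildProfile()], [onePerGenus()]
#' @export
setClass("MarkerAlignment",
  representation(ids = "character", rows = "character", genus = "character"),
  prototype(ids = character(), rows = character(), genus = character())
)

setValidity("MarkerAlignment", function(object) {
  msgs <- character()
  if (length(object@ids) != length(object@rows))
    msgs <- c(msgs, "ids and rows must have the same length")
  if (anyDuplicated(object@ids))
    msgs <- c(msgs, "alignment ids must be unique")
  if (length(object@rows) > 0L) {
    w <- nchar(object@rows)
    if (length(unique(w)) != 1L)
      msgs <- c(msgs, "all alignment rows must have the same length")
    else if (w[1L] < 1L)
      msgs <- c(msgs, "alignment rows must be non-empty")
    else {
      cols <- do.call(rbind, strsplit(object@rows, "", fixed = TRUE))
      if (any(apply(cols == "-", 2L, all)))
        msgs <- c(msgs, "alignment contains an all-gap column")
    }
  }
  if (length(object@genus) > 0L && length(object@genus) != length(object@ids))
    msgs <- c(msgs, "genus labels must be parallel to ids")
  if (length(msgs)) msgs else TRUE
})

#' GribskovProfile: a position-specific scoring matrix with gap penalties
#'
#' A Gribskov-style profile: for each alignment column, the mean of the
#' substitution-matrix rows of the residues observed in that column, plus
#' position-specific affine gap penalties scaled by the column's non-gap
#' fraction. Sequences are scored against the profile by local
#' dynamic-programming alignment ([scoreSequence()]).
#'
#' @slot name profile name (e.g. `"spo0A"`).
#' @slot alphabet ordered residue alphabet (columns of `M`).
#' @slot M numeric matrix, `length x |alphabet|`, of position scores.
#' @slot gapOpen,gapExtend numeric vectors of per-position gap penalties
#'   (matrix units, non-negative, `gapOpen >= gapExtend` positionwise).
#' @slot nSequences number of alignment rows the profile was built from.
#' @slot sourceIds ids of those rows.
#'
#' @seealso [buildProfile()], [scoreSequence()], [writeProfile()]
#' @export
setClass("GribskovProfile",
  representation(name = "character", alphabet = "character", M = "matrix",
                 gapOpen = "numeric", gapExtend = "numeric",
                 nSequences = "integer", sourceIds = "character")
)

setValidity("GribskovProfile", function(object) {
  msgs <- character()
  L <- nrow(object@M)
  if (L < 1L) msgs <- c(msgs, "profile must have at least one position")
  if (ncol(object@M) != length(object@alphabet))
    msgs <- c(msgs, "M must have one column per alphabet residue")
  if (length(object@gapOpen) != L || length(object@gapExtend) != L)
    msgs <- c(msgs, "gap penalty vectors must have one entry per position")
  else if (any(object@gapExtend < 0) || any(object@gapOpen < object@gapExtend))
    msgs <- c(msgs, "need gapOpen[p] >= gapExtend[p] >= 0 at every position")
  if (anyDuplicated(object@alphabet))
    msgs <- c(msgs, "alphabet residues must be unique")
  if (length(msgs)) msgs else TRUE
})

#' CutoffCalibration: score cutoff from positives vs shuffled negatives
#'
#' Records the score distribution of the profile's own (positive) sequence
#' set, the null distribution obtained by scoring composition-preserving
#' residue shuffles of the same set, and the cutoff placed at the midpoint
#' of the gap between the two distributions.
#'
#' @slot profileName name of the calibrated profile.
#' @slot positiveScores scores of the positive sequences.
#' @slot nullScores scores of all shuffles (length
#'   `nShufflesPerPositive * length(positiveScores)`).
#' @slot nShufflesPerPositive shuffles generated per positive sequence.
#' @slot seed user seed the shuffle seeds were derived from.
#' @slot cutoff midpoint of `[max(nullScores), min(positiveScores)]`.
#' @slot margin `min(positiveScores) - max(nullScores)`; positive for any
#'   successful calibration.
#'
#' @seealso [calibrateCutoff()], [validateProfile()]
#' @export
setClass("CutoffCalibration",
  representation(profileName = "character", positiveScores = "numeric",
                 nullScores = "numeric", nShufflesPerPositive = "integer",
                 seed = "integer", cutoff = "numeric", margin = "numeric")
)

setValidity("CutoffCalibration", function(object) {
  msgs <- character()
  if (length(object@nullScores) !=
      object@nShufflesPerPositive * length(object@positiveScores))
    msgs <- c(msgs, "nullScores length must be nShufflesPerPositive * n positives")
  if (object@margin > 0) {
    if (object@cutoff <= max(object@nullScores) ||
        object@cutoff > min(object@positiveScores))
      msgs <- c(msgs, "cutoff must lie inside the positive/null gap")
  }
  if (length(msgs)) msgs else TRUE
})

#' DatasetScreenResult: per-dataset contig screening tallies
#'
#' @slot datasetId dataset identifier.
#' @slot nInput number of input records.
#' @slot nPassedLength records surviving the length filter.
#' @slot hits data.frame of profile hits (see [scanRecord()]).
#' @slot nPassingHits number of hits with `passed == TRUE`.
#'
#' @seealso [screenDataset()]
#' @export
setClass("DatasetScreenResult",
  representation(datasetId = "character", nInput = "integer",
                 nPassedLength = "integer", hits = "data.frame",
                 nPassingHits = "integer")
)

setValidity("DatasetScreenResult", function(object) {
  msgs <- character()
  if (object@nPassedLength > object@nInput)
    msgs <- c(msgs, "nPassedLength cannot exceed nInput")
  if (object@nPassingHits != sum(object@hits$passed))
    msgs <- c(msgs, "nPassingHits must equal the number of passing hits")
  if (length(msgs)) msgs else TRUE
})

#' AmpliconQCResult: amplicon pipeline stage counts
#'
#' Counts of reads surviving each stage of the amplicon confirmation
#' pipeline: Phred quality filter, length filter, full-length (stop-free)
#' ORF requirement, and profile score confirmation.
#'
#' @slot nInput,nAfterQuality,nAfterLength,nFullLengthOrf,nProfileConfirmed
#'   monotone non-increasing stage counts.
#' @slot confirmedIds ids of the profile-confirmed reads.
#'
#' @seealso [ampliconPipeline()]
#' @export
setClass("AmpliconQCResult",
  representation(nInput = "integer", nAfterQuality = "integer",
                 nAfterLength = "integer", nFullLengthOrf = "integer",
                 nProfileConfirmed = "integer", confirmedIds = "character")
)

setValidity("AmpliconQCResult", function(object) {
  counts <- c(object@nInput, object@nAfterQuality, object@nAfterLength,
              object@nFullLengthOrf, object@nProfileConfirmed)
  if (any(diff(counts) > 0L) || any(counts < 0L))
    return("stage counts must be non-negative and non-increasing")
  TRUE
})

setMethod("show", "MarkerAlignment", function(object) {
  cat("MarkerAlignment:", length(object@ids), "sequences x",
      if (length(object@rows)) nchar(object@rows[1L]) else 0L, "columns\n")
  if (length(object@genus))
    cat("  genera:", paste(unique(object@genus), collapse = ", "), "\n")
})

setMethod("show", "GribskovProfile", function(object) {
  cat("GribskovProfile '", object@name, "': ", nrow(object@M),
      " positions, alphabet size ", length(object@alphabet),
      ", built from ", object@nSequences, " sequences\n", sep = "")
})

setMethod("show", "CutoffCalibration", function(object) {
  cat("CutoffCalibration for '", object@profileName, "'\n", sep = "")
  cat(sprintf("  %d positives (min score %.2f), %d null scores (max %.2f)\n",
              length(object@positiveScores), min(object@positiveScores),
              length(object@nullScores), max(object@nullScores)))
  cat(sprintf("  cutoff %.2f, margin %.2f\n", object@cutoff, object@margin))
})

setMethod("show", "DatasetScreenResult", function(object) {
  cat("DatasetScreenResult '", object@datasetId, "': ", object@nInput,
      " records, ", object@nPassedLength, " passed length filter, ",
      object@nPassingHits, " passing hits\n", sep = "")
})

setMethod("show", "AmpliconQCResult", function(object) {
  cat("AmpliconQCResult:", object@nInput, "reads ->", object@nAfterQuality,
      "after quality ->", object@nAfterLength, "after length ->",
      object@nFullLengthOrf, "full-length ORFs ->",
      object@nProfileConfirmed, "profile-confirmed\n")
})
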