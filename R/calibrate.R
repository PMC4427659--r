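#' Shuffle the residues of a sequence
#'
#' Uniform random permutation (Fisher-Yates via `sample()`) of the
#' residues: the length and residue multiset are preserved exactly, the
#' order is randomized. Deterministic for a fixed seed.
#'
#' @param seq a sequence string.
#' @param seed integer seed.
#' @return the shuffled string.
#' @export
shuffleResidues <- function(seq, seed) {
  seq <- as.character(seq)
  if (nchar(seq) < 2L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  withSeed(seed, paste(sample(chars), collapse = ""))
}

#' Null score distribution from shuffled positives
#'
#' Scores composition-preserving shuffles of the positive sequences
#' against the profile: the negative control of cutoff calibration. Each
#' shuffle's seed is derived deterministically from the user seed and the
#' (positive, shuffle) indices, so the full distribution is reproducible.
#'
#' @param profile a [GribskovProfile-class].
#' @param positives non-empty character vector (or `AAStringSet`) of
#'   positive protein sequences.
#' @param nShuffles shuffles per positive sequence (>= 1).
#' @param seed integer seed.
#' @return numeric vector of length `nShuffles * length(positives)`, in
#'   (positive index, shuffle index) order.
#' @export
nullScores <- function(profile, positives, nShuffles = 100L, seed = 1L) {
  positives <- as.character(positives)
  if (!length(positives)) stop("no positive sequences supplied")
  if (nShuffles < 1L) stop("nShuffles must be >= 1")
  unlist(lapply(seq_along(positives), function(i) {
    vapply(seq_len(nShuffles), function(j) {
      scoreSequence(profile,
                    shuffleResidues(positives[i], mixSeed(seed, i, j)))$score
    }, numeric(1))
  }))
}

#' Calibrate a profile score cutoff from positives and shuffled nulls
#'
#' Scores the positive set and `nShuffles` residue shuffles of each
#' positive, then places the cutoff at the midpoint of the gap
#' `[max(null), min(positive)]`. If the distributions overlap (margin
#' `<= 0`) calibration fails with an error of class
#' `"sporescanCalibrationError"` carrying both score distributions.
#'
#' @inheritParams nullScores
#' @return a [CutoffCalibration-class].
#' @export
calibrateCutoff <- function(profile, positives, nShuffles = 100L, seed = 1L) {
  positives <- as.character(positives)
  if (!length(positives)) stop("no positive sequences supplied")
  pos <- vapply(positives, function(s) scoreSequence(profile, s)$score,
                numeric(1), USE.NAMES = FALSE)
  nul <- nullScores(profile, positives, nShuffles, seed)
  margin <- min(pos) - max(nul)
  if (margin <= 0) {
    cnd <- structure(
      class = c("sporescanCalibrationError", "error", "condition"),
      list(message = sprintf(
             paste0("calibration failed: positive and null score ",
                    "distributions overlap (min positive %.3f <= max null ",
                    "%.3f)"), min(pos), max(nul)),
           call = sys.call(-1L),
           positiveScores = pos, nullScores = nul))
    stop(cnd)
  }
  methods::new("CutoffCalibration", profileName = profile@name,
               positiveScores = pos, nullScores = nul,
               nShufflesPerPositive = as.integer(nShuffles),
               seed = as.integer(seed),
               cutoff = (max(nul) + min(pos)) / 2, margin = margin)
}

#' @describeIn calibrationAccessors the calibrated cutoff
#' @export
cutoffValue <- function(calibration) calibration@cutoff

#' Accessors for CutoffCalibration
#'
#' @param calibration a [CutoffCalibration-class].
#' @name calibrationAccessors
#' @return `cutoffValue`/`calibrationMargin`: numbers;
#'   `positiveScores`/`nullScoreValues`: the score distributions.
NULL

#' @describeIn calibrationAccessors min positive minus max null score
#' @export
calibrationMargin <- function(calibration) calibration@margin

#' @describeIn calibrationAccessors positive score distribution
#' @export
positiveScores <- function(calibration) calibration@positiveScores

#' @describeIn calibrationAccessors null score distribution
#' @export
nullScoreValues <- function(calibration) calibration@nullScores

#' Write a calibration report to JSON
#'
#' @param calibration a [CutoffCalibration-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCalibration <- function(calibration, path) {
  jsonlite::write_json(
    list(profile_name = calibration@profileName,
         seed = calibration@seed,
         n_shuffles_per_positive = calibration@nShufflesPerPositive,
         positive_scores = calibration@positiveScores,
         null_scores = calibration@nullScores,
         cutoff = calibration@cutoff,
         margin = calibration@margin),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration report written by [writeCalibration()]
#'
#' @param path path to a calibration JSON file.
#' @return a [CutoffCalibration-class].
#' @export
readCalibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("CutoffCalibration", profileName = x$profile_name,
               positiveScores = as.numeric(x$positive_scores),
               nullScores = as.numeric(x$null_scores),
               nShufflesPerPositive = as.integer(x$n_shuffles_per_positive),
               seed = as.integer(x$seed), cutoff = as.numeric(x$cutoff),
               margin = as.numeric(x$margin))
}

#' Validate a calibrated profile against labelled genomes
#'
#' Scans each genome with [scanRecord()] and reports the number of
#' passing, non-overlapping hits and the best score. On a well-separated
#' marker, positive genomes (one embedded marker gene) yield exactly one
#' hit and negative controls none; counts are reported faithfully either
#' way.
#'
#' @param profile a [GribskovProfile-class].
#' @param cutoff calibrated score cutoff.
#' @param genomes named `DNAStringSet` (or named character vector) of
#'   genome/contig sequences.
#' @param labels character vector (`"positive"`/`"negative"`) parallel to
#'   `genomes`.
#' @param minAaLen minimum translated fragment length scored.
#' @return data.frame with columns `genome_id`, `label`, `n_hits`,
#'   `best_score`.
#' @export
validateProfile <- function(profile, cutoff, genomes, labels,
                            minAaLen = 50L) {
  if (length(genomes) != length(labels))
    stop("labels must be parallel to genomes")
  if (!all(labels %in% c("positive", "negative")))
    stop("labels must be 'positive' or 'negative'")
  ids <- names(genomes)
  if (is.null(ids)) ids <- sprintf("genome%03d", seq_along(genomes))
  out <- lapply(seq_along(genomes), function(k) {
    hits <- scanRecord(profile, genomes[[k]], cutoff, minAaLen = minAaLen,
                       id = ids[k], alphabet = "nucleotide")
    data.frame(genome_id = ids[k], label = labels[k],
               n_hits = nrow(hits),
               best_score = if (nrow(hits)) max(hits$score) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
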