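#' Filter sequence records by length
#'
#' The metagenome screen keeps contigs strictly longer than 800 bp
#' (`strict = TRUE`); the amplicon pipeline removes reads shorter than
#' 600 bp, i.e. keeps length `>=` the threshold (`strict = FALSE`).
#'
#' @param records an `XStringSet` (qualities, if any, are carried along).
#' @param minLen length threshold in residues/bases.
#' @param strict `TRUE` keeps `length > minLen`; `FALSE` keeps
#'   `length >= minLen`.
#' @return the surviving records.
#' @export
filterByLength <- function(records, minLen, strict = TRUE) {
  if (minLen < 0) stop("minLen must be >= 0")
  w <- Biostrings::width(records)
  records[if (strict) w > minLen else w >= minLen]
}

#' Screen one dataset of contigs for profile hits
#'
#' The metagenome screening pipeline: contigs are length-filtered
#' (strictly longer than `minLen`), six-frame translated, and each
#' stop-free fragment of at least `minAaLen` residues is scored against
#' the profile; passing hits are reduced to a non-overlapping set per
#' contig ([scanRecord()]).
#'
#' @param profile a [GribskovProfile-class].
#' @param cutoff calibrated score cutoff.
#' @param records named `DNAStringSet` of contigs.
#' @param datasetId dataset identifier for the report.
#' @param minLen contig length threshold (strict; default the screen's
#'   800 bp).
#' @param minAaLen minimum translated fragment length scored.
#' @return a [DatasetScreenResult-class].
#' @export
screenDataset <- function(profile, cutoff, records, datasetId = "dataset",
                          minLen = 800L, minAaLen = 50L) {
  ids <- names(records)
  if (is.null(ids)) ids <- sprintf("contig%05d", seq_along(records))
  names(records) <- ids
  kept <- filterByLength(records, minLen, strict = TRUE)
  hits <- emptyHits()
  for (id in names(kept)) {
    h <- scanRecord(profile, kept[[id]], cutoff, minAaLen = minAaLen,
                    id = id, alphabet = "nucleotide")
    if (nrow(h)) hits <- rbind(hits, h)
  }
  if (nrow(hits)) {
    hits <- hits[order(hits$target_id, hits$aa_start, hits$frame), ,
                 drop = FALSE]
    rownames(hits) <- NULL
  }
  methods::new("DatasetScreenResult", datasetId = datasetId,
               nInput = length(records), nPassedLength = length(kept),
               hits = hits, nPassingHits = sum(hits$passed))
}

#' @describeIn screenAccessors hit table of a screen result
#' @export
screenHits <- function(result) result@hits

#' Accessors for DatasetScreenResult
#'
#' @param result a [DatasetScreenResult-class].
#' @name screenAccessors
#' @return `screenHits`: ProfileHit data.frame; `screenCounts`: named
#'   integer vector of the stage tallies.
NULL

#' @describeIn screenAccessors stage tallies
#' @export
screenCounts <- function(result) {
  c(n_input = result@nInput, n_passed_length = result@nPassedLength,
    n_passing_hits = result@nPassingHits)
}

#' Filter reads by Phred quality
#'
#' @param reads a `QualityScaledDNAStringSet` (reads without qualities
#'   raise an error).
#' @param minQ Phred threshold (the amplicon pipeline's default is 30).
#' @param mode `"mean"` keeps reads whose mean base quality is
#'   `>= minQ` (the default interpretation of a "minimum of 30"
#'   read-quality filter); `"min"` requires every base to reach `minQ`.
#' @return the surviving reads.
#' @export
qualityFilter <- function(reads, minQ = 30, mode = c("mean", "min")) {
  mode <- match.arg(mode)
  if (!methods::is(reads, "QualityScaledXStringSet"))
    stop("reads must carry qualities (a QualityScaledDNAStringSet)")
  qv <- phredValues(reads)
  stat <- vapply(qv, function(q) {
    if (!length(q)) return(-Inf)
    if (mode == "mean") mean(q) else min(q)
  }, numeric(1))
  reads[stat >= minQ]
}

#' First stop-free full-length reading frame of a read
#'
#' Tries frames `+1, +2, +3, -1, -2, -3` in order and returns the first
#' whose translation of the entire read (trailing partial codon dropped)
#' contains no stop codon.
#'
#' @param read nucleotide sequence (character or `DNAString`).
#' @return `list(frame =, protein =)` or `NULL` when every frame contains
#'   a stop (or the read is too short to translate).
#' @export
fullLengthOrf <- function(read) {
  for (f in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    aa <- translateFrame(read, f)
    if (nzchar(aa) && !grepl("*", aa, fixed = TRUE))
      return(list(frame = f, protein = aa))
  }
  NULL
}

#' Amplicon quality-control and profile-confirmation pipeline
#'
#' The marker amplicon confirmation chain: Phred quality filter, length
#' filter (reads shorter than `minLen` removed), full-length ORF
#' requirement ([fullLengthOrf()]), and profile score confirmation
#' (`score >= cutoff` via [scoreSequence()]). Stage counts are recorded
#' and are non-increasing by construction.
#'
#' @param profile a [GribskovProfile-class].
#' @param cutoff calibrated score cutoff.
#' @param reads a named `QualityScaledDNAStringSet`.
#' @param minQ Phred threshold.
#' @param minLen read length threshold (non-strict: `minLen` itself is
#'   kept).
#' @param qualityMode passed to [qualityFilter()].
#' @return an [AmpliconQCResult-class].
#' @export
ampliconPipeline <- function(profile, cutoff, reads, minQ = 30,
                             minLen = 600L, qualityMode = c("mean", "min")) {
  qualityMode <- match.arg(qualityMode)
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%05d", seq_along(reads))
  q <- qualityFilter(reads, minQ, qualityMode)
  l <- filterByLength(q, minLen, strict = FALSE)
  orfs <- lapply(as.character(l), fullLengthOrf)
  hasOrf <- !vapply(orfs, is.null, logical(1))
  orfReads <- names(l)[hasOrf]
  confirmed <- orfReads[vapply(orfs[hasOrf], function(o) {
    scoreSequence(profile, o$protein)$score >= cutoff
  }, logical(1))]
  methods::new("AmpliconQCResult", nInput = length(reads),
               nAfterQuality = length(q), nAfterLength = length(l),
               nFullLengthOrf = sum(hasOrf),
               nProfileConfirmed = length(confirmed),
               confirmedIds = as.character(confirmed))
}

#' @describeIn ampliconAccessors stage counts
#' @export
ampliconCounts <- function(result) {
  c(n_input = result@nInput, n_after_quality = result@nAfterQuality,
    n_after_length = result@nAfterLength,
    n_full_length_orf = result@nFullLengthOrf,
    n_profile_confirmed = result@nProfileConfirmed)
}

#' Accessors for AmpliconQCResult
#'
#' @param result an [AmpliconQCResult-class].
#' @name ampliconAccessors
#' @return `ampliconCounts`: named integer vector; `confirmedIds`: ids of
#'   the profile-confirmed reads.
NULL

#' @describeIn ampliconAccessors ids of confirmed reads
#' @export
confirmedIds <- function(result) result@confirmedIds
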