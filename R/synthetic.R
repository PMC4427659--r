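# background amino-acid frequencies (Robinson & Robinson style), used for
# random consensus and decoy protein composition
AA_BACKGROUND <- c(A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
                   Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.051,
                   L = 0.091, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
                   S = 0.071, T = 0.058, W = 0.013, Y = 0.032, V = 0.064)

#' Simulate a divergent protein marker family
#'
#' Draws a random consensus of `consensusLength` residues (background
#' amino-acid frequencies), then `nSequences` descendants by i.i.d.
#' per-site substitution (uniform over the 19 alternative residues) and
#' single-residue indels. The returned alignment tracks positions exactly:
#' a deletion leaves a gap in its row, an insertion adds a column gapped
#' in all other rows; columns left all-gap are pruned. The defaults mirror
#' the regime of a curated marker set: 14 sequences, a 150-residue
#' conserved core, moderate divergence.
#'
#' @param consensusLength consensus length in residues.
#' @param nSequences number of descendant sequences (>= 1).
#' @param substitutionRate per-site substitution probability in `[0, 1)`.
#' @param indelRate per-site indel probability in `[0, 0.1)` (split evenly
#'   between deletion and insertion-after).
#' @param seed integer seed; the family is a pure function of the
#'   parameters and the seed.
#' @return `list(alignment = MarkerAlignment, consensus = character)`.
#' @export
makeFamily <- function(consensusLength = 150L, nSequences = 14L,
                       substitutionRate = 0.15, indelRate = 0.01,
                       seed = 1L) {
  if (nSequences < 1L) stop("nSequences must be >= 1")
  if (substitutionRate < 0 || substitutionRate >= 1)
    stop("substitutionRate must be in [0, 1)")
  if (indelRate < 0 || indelRate >= 0.1)
    stop("indelRate must be in [0, 0.1)")
  L <- as.integer(consensusLength)
  aa <- names(AA_BACKGROUND)
  consensus <- withSeed(mixSeed(seed, 101L),
                        sample(aa, L, replace = TRUE, prob = AA_BACKGROUND))
  res <- matrix("", nrow = nSequences, ncol = L)   # residue or "-"
  ins <- matrix("", nrow = nSequences, ncol = L)   # insertion after position
  for (r in seq_len(nSequences)) {
    withSeed(mixSeed(seed, 200L, r), {
      row <- consensus
      sub <- stats::runif(L) < substitutionRate
      if (any(sub))
        row[sub] <- vapply(row[sub],
                           function(x) sample(setdiff(aa, x), 1L), "")
      u <- stats::runif(L)
      row[u < indelRate / 2] <- "-"
      insHere <- u >= indelRate / 2 & u < indelRate
      if (any(insHere))
        ins[r, insHere] <- sample(aa, sum(insHere), replace = TRUE,
                                  prob = AA_BACKGROUND)
      res[r, ] <- row
    })
  }
  rows <- vapply(seq_len(nSequences), function(r) {
    paste(unlist(lapply(seq_len(L), function(p) {
      extra <- if (any(nzchar(ins[, p]))) {
        ifelse(nzchar(ins[r, p]), ins[r, p], "-")
      } else character()
      c(res[r, p], extra)
    })), collapse = "")
  }, "")
  rows <- pruneAllGapColumns(rows)
  list(alignment = markerAlignment(sprintf("seq%02d", seq_len(nSequences)),
                                   rows),
       consensus = paste(consensus, collapse = ""))
}

#' Reverse-translate a protein into a random synonymous coding sequence
#'
#' Each residue is encoded by a synonymous codon of the standard genetic
#' code chosen uniformly at random; `translateFrame(result, 1)` always
#' round-trips to the input.
#'
#' @param aa protein string over the 20 standard amino acids (no `*`).
#' @param seed integer seed.
#' @return a nucleotide string of length `3 * nchar(aa)`.
#' @export
reverseTranslate <- function(aa, seed = 1L) {
  aa <- toupper(as.character(aa))
  chars <- strsplit(aa, "", fixed = TRUE)[[1L]]
  if (any(chars == "*")) stop("cannot reverse-translate a stop codon")
  if (any(!chars %in% names(AA_BACKGROUND)))
    stop("reverseTranslate requires the 20 standard amino acids")
  syn <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)
  nt <- withSeed(seed,
                 vapply(chars, function(x) sample(syn[[x]], 1L), "",
                        USE.NAMES = FALSE))
  out <- paste(nt, collapse = "")
  stopifnot(identical(translateFrame(out, 1L), aa))
  out
}

randomNt <- function(n, composition = c(A = 0.25, C = 0.25, G = 0.25,
                                        T = 0.25)) {
  paste(sample(names(composition), n, replace = TRUE, prob = composition),
        collapse = "")
}

#' Generate a synthetic contig set with embedded marker genes
#'
#' Decoy contigs are drawn i.i.d. from the given nucleotide composition.
#' Marker contigs embed a start/stop-framed coding cassette
#' (`ATG` + reverse-translated marker + `TAA`) at a random offset on a
#' random strand, padded with decoy sequence. A ground-truth table maps
#' each record to its marker status, strand and 1-based forward-strand
#' cassette coordinates.
#'
#' @param markerAa marker protein sequence to embed.
#' @param nDecoys number of decoy contigs.
#' @param decoyLengthRange `c(min, max)` decoy length in nt.
#' @param nMarkerContigs number of marker-bearing contigs.
#' @param markerContigLength marker contig length in nt (must hold the
#'   cassette: at least `3 * nchar(markerAa) + 6`).
#' @param composition named nucleotide frequency vector.
#' @param seed integer seed.
#' @return `list(records = DNAStringSet, truth = data.frame)` with truth
#'   columns `id`, `marker`, `strand`, `nt_start`, `nt_end`.
#' @export
makeContigSet <- function(markerAa, nDecoys = 100L,
                          decoyLengthRange = c(900L, 1200L),
                          nMarkerContigs = 3L, markerContigLength = 1000L,
                          composition = c(A = 0.25, C = 0.25, G = 0.25,
                                          T = 0.25),
                          seed = 1L) {
  casLen <- 3L * nchar(markerAa) + 6L
  if (nMarkerContigs > 0L && casLen > markerContigLength)
    stop("marker cassette (", casLen, " nt) longer than markerContigLength")
  recs <- character()
  truth <- list()
  for (k in seq_len(nMarkerContigs)) {
    id <- sprintf("marker%02d", k)
    cassette <- paste0("ATG", reverseTranslate(markerAa,
                                               mixSeed(seed, 300L, k)),
                       "TAA")
    withSeed(mixSeed(seed, 310L, k), {
      maxOff <- markerContigLength - casLen
      off <- if (maxOff == 0L) 0L else sample(0:maxOff, 1L)
      strand <- sample(c("+", "-"), 1L)
      body <- if (strand == "-")
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(cassette)))
      else cassette
      contig <- paste0(randomNt(off, composition), body,
                       randomNt(maxOff - off, composition))
    })
    recs[id] <- contig
    truth[[length(truth) + 1L]] <-
      data.frame(id = id, marker = TRUE, strand = strand,
                 nt_start = off + 1L, nt_end = off + casLen,
                 stringsAsFactors = FALSE)
  }
  for (k in seq_len(nDecoys)) {
    id <- sprintf("decoy%03d", k)
    recs[id] <- withSeed(mixSeed(seed, 320L, k), {
      len <- if (decoyLengthRange[1L] == decoyLengthRange[2L])
        decoyLengthRange[1L]
      else sample(decoyLengthRange[1L]:decoyLengthRange[2L], 1L)
      randomNt(len, composition)
    })
    truth[[length(truth) + 1L]] <-
      data.frame(id = id, marker = FALSE, strand = NA_character_,
                 nt_start = NA_integer_, nt_end = NA_integer_,
                 stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(id = character(), marker = logical(),
                           strand = character(), nt_start = integer(),
                           nt_end = integer(), stringsAsFactors = FALSE)
  list(records = Biostrings::DNAStringSet(recs), truth = truth)
}

#' Generate synthetic marker amplicon reads with Phred qualities
#'
#' Each read is an in-frame (codon-aligned) window of an independently
#' reverse-translated copy of the marker, so frame `+1` of every read is
#' stop-free. Per-base qualities are drawn from a normal distribution
#' clipped to the Phred range `[0, 93]` and rounded to integers.
#'
#' @param markerAa marker protein sequence.
#' @param n number of reads.
#' @param lengthNt read length in nt (at most `3 * nchar(markerAa)`).
#' @param meanQ,sdQ mean and sd of the per-base Phred quality.
#' @param seed integer seed.
#' @return a named `QualityScaledDNAStringSet`.
#' @export
makeAmplicons <- function(markerAa, n = 10L, lengthNt = 602L, meanQ = 40,
                          sdQ = 0, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  if (lengthNt > 3L * nchar(markerAa))
    stop("lengthNt exceeds the marker coding length")
  seqs <- character(n)
  quals <- character(n)
  for (i in seq_len(n)) {
    nt <- reverseTranslate(markerAa, mixSeed(seed, 400L, i))
    maxStartCodon <- (nchar(nt) - lengthNt) %/% 3L
    st <- if (maxStartCodon == 0L) 0L
          else withSeed(mixSeed(seed, 410L, i),
                        sample(0:maxStartCodon, 1L))
    seqs[i] <- substr(nt, 3L * st + 1L, 3L * st + lengthNt)
    q <- withSeed(mixSeed(seed, 420L, i),
                  round(stats::rnorm(lengthNt, meanQ, sdQ)))
    q <- pmin(pmax(q, 0L), 93L)
    quals[i] <- rawToChar(as.raw(q + 33L))
  }
  names(seqs) <- sprintf("amp%03d", seq_len(n))
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(Biostrings::BStringSet(quals)))
}
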