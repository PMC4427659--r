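makeToyProfile <- function(seed = 51L, len = 70L) {
  fam <- makeFamily(consensusLength = len, nSequences = 6L,
                    substitutionRate = 0.1, indelRate = 0, seed = seed)
  prof <- buildProfile(fam$alignment)
  cal <- calibrateCutoff(prof, familyPositives(fam), nShuffles = 10L,
                         seed = seed)
  list(profile = prof, cutoff = cutoffValue(cal),
       consensus = profileConsensus(prof))
}

test_that("filterByLength applies strict and non-strict boundaries", {
  recs <- Biostrings::DNAStringSet(c(a = strrep("A", 800L),
                                     b = strrep("A", 801L)))
  expect_identical(names(filterByLength(recs, 800L, strict = TRUE)), "b")
  expect_identical(names(filterByLength(recs, 800L, strict = FALSE)),
                   c("a", "b"))

  lens <- c(100L, 900L, 2000L)
  recs2 <- Biostrings::DNAStringSet(stats::setNames(strrep("A", lens),
                                                    c("x", "y", "z")))
  expect_length(filterByLength(recs2, 800L, strict = TRUE), 2L)
  expect_length(filterByLength(Biostrings::DNAStringSet(), 800L), 0L)
})

test_that("screenDataset recovers embedded markers and respects the filter", {
  toy <- makeToyProfile()
  cs <- makeContigSet(toy$consensus, nDecoys = 30L,
                      decoyLengthRange = c(850L, 1100L),
                      nMarkerContigs = 3L, markerContigLength = 900L,
                      seed = 23L)
  res <- screenDataset(toy$profile, toy$cutoff, cs$records, "toy",
                       minLen = 800L, minAaLen = 30L)
  expect_identical(unname(screenCounts(res)), c(33L, 33L, 3L))
  expect_setequal(screenHits(res)$target_id, cs$truth$id[cs$truth$marker])

  # decoys only -> zero passing hits
  dec <- makeContigSet(toy$consensus, nDecoys = 20L, nMarkerContigs = 0L,
                       seed = 24L)
  res0 <- screenDataset(toy$profile, toy$cutoff, dec$records, "decoys")
  expect_identical(res0@nPassingHits, 0L)

  # markers only in contigs <= 800 bp are excluded before scanning
  short <- makeContigSet(toy$consensus, nDecoys = 0L, nMarkerContigs = 2L,
                         markerContigLength = 800L, seed = 25L)
  resS <- screenDataset(toy$profile, toy$cutoff, short$records, "short")
  expect_identical(unname(screenCounts(resS)), c(2L, 0L, 0L))
})

test_that("screen hits are invariant under input record order", {
  toy <- makeToyProfile(seed = 52L)
  cs <- makeContigSet(toy$consensus, nDecoys = 15L, nMarkerContigs = 2L,
                      markerContigLength = 900L, seed = 26L)
  ref <- screenDataset(toy$profile, toy$cutoff, cs$records, "d")
  for (seed in 1:3) {
    set.seed(seed)
    perm <- cs$records[sample(length(cs$records))]
    got <- screenDataset(toy$profile, toy$cutoff, perm, "d")
    expect_identical(screenHits(got), screenHits(ref))
    expect_identical(screenCounts(got), screenCounts(ref))
  }
})

test_that("qualityFilter supports mean and per-base minimum modes", {
  mk <- function(id, quals) {
    q <- rawToChar(as.raw(quals + 33L))
    Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(stats::setNames(strrep("A", length(quals)), id)),
      Biostrings::PhredQuality(Biostrings::BStringSet(stats::setNames(q, id))))
  }
  q40 <- mk("hi", rep(40L, 10L))
  expect_length(qualityFilter(q40, 30, "mean"), 1L)
  expect_length(qualityFilter(q40, 30, "min"), 1L)

  q29 <- mk("lo", rep(29L, 10L))
  expect_length(qualityFilter(q29, 30, "mean"), 0L)

  # mean 35 but one base Q2: kept under mean, dropped under min
  mixed <- mk("mix", c(rep(39L, 9L), 2L))
  expect_length(qualityFilter(mixed, 30, "mean"), 1L)
  expect_length(qualityFilter(mixed, 30, "min"), 0L)

  expect_error(qualityFilter(Biostrings::DNAStringSet("ACGT"), 30))
})

test_that("fullLengthOrf returns the first stop-free frame or NULL", {
  # a clean in-frame coding read
  nt <- reverseTranslate("MKVLAWQE", seed = 2L)
  orf <- fullLengthOrf(nt)
  expect_identical(orf$frame, 1L)
  expect_identical(orf$protein, "MKVLAWQE")

  # deterministic search for a read with stops in all six frames
  found <- NULL
  for (seed in 1:200) {
    set.seed(seed)
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE,
                      prob = c(.4, .1, .1, .4)), collapse = "")
    stopped <- vapply(c(1L, 2L, 3L, -1L, -2L, -3L), function(f)
      grepl("*", translateFrame(s, f), fixed = TRUE), logical(1))
    if (all(stopped)) { found <- s; break }
  }
  expect_false(is.null(found))
  expect_null(fullLengthOrf(found))

  expect_null(fullLengthOrf(""))
})

test_that("ampliconPipeline confirms clean marker reads and rejects decoys", {
  fam <- makeFamily(consensusLength = 210L, nSequences = 8L,
                    substitutionRate = 0.1, indelRate = 0, seed = 61L)
  prof <- buildProfile(fam$alignment)
  cal <- calibrateCutoff(prof, familyPositives(fam), nShuffles = 10L,
                         seed = 6L)
  cons <- profileConsensus(prof)

  amps <- makeAmplicons(cons, n = 10L, lengthNt = 602L, meanQ = 40,
                        sdQ = 0, seed = 7L)
  res <- ampliconPipeline(prof, cutoffValue(cal), amps)
  expect_identical(unname(ampliconCounts(res)), rep(10L, 5L))
  expect_length(confirmedIds(res), 10L)

  # the same reads truncated to 599 nt all fail the length stage
  trunc <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::subseq(as(amps, "DNAStringSet"), 1L, 599L),
    Biostrings::PhredQuality(Biostrings::subseq(
      methods::as(Biostrings::quality(amps), "BStringSet"), 1L, 599L)))
  names(trunc) <- names(amps)
  resT <- ampliconPipeline(prof, cutoffValue(cal), trunc)
  expect_identical(unname(ampliconCounts(resT))[3:5], rep(0L, 3L))

  # shuffled-nucleotide decoy reads are never profile-confirmed
  dec <- as.character(amps)
  dec <- vapply(seq_along(dec), function(i) shuffleResidues(dec[i], i), "")
  names(dec) <- paste0("dec", seq_along(dec))
  decoys <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(dec),
    Biostrings::quality(amps))
  resD <- ampliconPipeline(prof, cutoffValue(cal), decoys)
  expect_identical(resD@nProfileConfirmed, 0L)

  # low-quality reads are removed at the first stage
  low <- makeAmplicons(cons, n = 5L, lengthNt = 602L, meanQ = 20, sdQ = 0,
                       seed = 8L)
  resL <- ampliconPipeline(prof, cutoffValue(cal), low)
  expect_identical(resL@nAfterQuality, 0L)
})

test_that("amplicon stage counts are monotone on random read sets", {
  fam <- makeFamily(consensusLength = 60L, nSequences = 5L,
                    substitutionRate = 0.1, indelRate = 0, seed = 71L)
  prof <- buildProfile(fam$alignment)
  cons <- profileConsensus(prof)
  for (seed in 1:40) {
    amps <- makeAmplicons(cons, n = 4L,
                          lengthNt = 3L * sample(20:60, 1),
                          meanQ = sample(15:45, 1), sdQ = sample(0:8, 1),
                          seed = seed)
    res <- ampliconPipeline(prof, cutoff = 10, amps,
                            minLen = sample(c(60L, 120L, 180L), 1L))
    counts <- ampliconCounts(res)
    expect_true(all(diff(counts) <= 0L))
  }
})
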