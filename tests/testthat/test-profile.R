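test_that("onePerGenus keeps exactly one row per genus, deterministically", {
  msa <- markerAlignment(c("Bacillus_a", "Bacillus_b", "Clostridium_c"),
                         c("MK-", "MKV", "MLV"))
  r1 <- onePerGenus(msa, seed = 4L)
  expect_identical(length(alignmentIds(r1)), 2L)
  expect_identical(sub("_.*", "", alignmentIds(r1)),
                   c("Bacillus", "Clostridium"))
  expect_identical(onePerGenus(msa, seed = 4L), r1)

  # already one per genus -> identity
  msa2 <- markerAlignment(c("Bacillus_a", "Clostridium_c"), c("MKV", "MLV"))
  expect_identical(alignmentIds(onePerGenus(msa2, 1L)),
                   alignmentIds(msa2))

  # unparseable ids without explicit genus labels -> error
  msa3 <- markerAlignment(c("x", "y"), c("MK", "ML"))
  expect_error(onePerGenus(msa3, 1L), "genus")
})

test_that("buildProfile implements the mean-of-matrix-rows formula", {
  idm <- toyMatrix(c("M", "K", "A"), match = 1, mismatch = 0)
  p1 <- buildProfile(markerAlignment("s", "MK"), idm, gapOpen = 10,
                     gapExtend = 0.5)
  expect_equal(profileMatrix(p1)[1L, ], c(M = 1, K = 0, A = 0))
  expect_equal(unname(gapPenalties(p1)[, "open"]), c(10, 10))

  # gap cells contribute 0 and scale the gap penalties
  p2 <- buildProfile(markerAlignment(c("x", "y"), c("A-", "AA")), idm,
                     gapOpen = 10, gapExtend = 0.5)
  expect_equal(unname(profileMatrix(p2)[2L, "A"]), 0.5)
  expect_equal(unname(gapPenalties(p2)[2L, ]), c(10 * 0.5, 0.5 * 0.5))

  expect_error(buildProfile(markerAlignment(character(), character()), idm))
})

test_that("buildProfile is invariant under row duplication", {
  mat <- blosum62()
  for (seed in 1:10) {
    fam <- makeFamily(consensusLength = 25L, nSequences = 4L,
                      substitutionRate = 0.2, indelRate = 0.02, seed = seed)
    msa <- fam$alignment
    dup <- markerAlignment(c(alignmentIds(msa), paste0(alignmentIds(msa), "b")),
                           rep(alignmentRows(msa), 2L))
    a <- buildProfile(msa, mat)
    b <- buildProfile(dup, mat)
    expect_equal(profileMatrix(a), profileMatrix(b))
    expect_equal(gapPenalties(a), gapPenalties(b))
  }
})

test_that("profileConsensus takes the per-position argmax with alphabet-order ties", {
  m <- toyMatrix(c("M", "K", "V"), match = 2, mismatch = -1)
  prof <- buildProfile(markerAlignment("s", "MKV"), m)
  expect_identical(profileConsensus(prof), "MKV")

  # exact tie between two residues -> first in the profile alphabet
  tied <- methods::new("GribskovProfile", name = "t",
                       alphabet = c("A", "C"),
                       M = matrix(c(1, 1), 1L, 2L), gapOpen = 1,
                       gapExtend = 0, nSequences = 1L, sourceIds = "s")
  expect_identical(profileConsensus(tied), "A")

  # identical rows: consensus equals the row (diagonal-dominant matrix)
  prof3 <- buildProfile(markerAlignment(c("a", "b", "c"),
                                        rep("MKV", 3L)), m)
  expect_identical(profileConsensus(prof3), "MKV")
})

test_that("the consensus scores the sum of per-position maxima", {
  fam <- makeFamily(consensusLength = 30L, nSequences = 5L,
                    substitutionRate = 0.1, indelRate = 0, seed = 2L)
  prof <- buildProfile(fam$alignment)
  hit <- scoreSequence(prof, profileConsensus(prof))
  expect_equal(hit$score, sum(apply(profileMatrix(prof), 1L, max)))
  expect_identical(c(hit$aa_start, hit$aa_end), c(0L, profileLength(prof)))
})

test_that("scoreSequence equals exhaustive enumeration on tiny profiles", {
  set.seed(7)
  alpha <- c("A", "C", "G", "T")
  for (rep in 1:150) {
    L <- sample(1:4, 1)
    M <- matrix(sample(-4:6, L * 4L, TRUE), L, 4L,
                dimnames = list(NULL, alpha))
    open <- round(runif(L, 0.5, 6), 2)
    ext <- round(runif(L, 0, 1) * open, 2)
    prof <- methods::new("GribskovProfile", name = "t", alphabet = alpha,
                         M = M, gapOpen = open, gapExtend = ext,
                         nSequences = 1L, sourceIds = "s")
    seq <- paste(sample(alpha, sample(1:5, 1), TRUE), collapse = "")
    idx <- match(strsplit(seq, "")[[1L]], alpha)
    expect_equal(scoreSequence(prof, seq)$score,
                 bruteProfileAlign(M, open, ext, idx),
                 info = paste(rep, seq))
  }
})

test_that("hits are shift-invariant and mutation never raises the score", {
  fam <- makeFamily(consensusLength = 40L, nSequences = 6L,
                    substitutionRate = 0.1, indelRate = 0, seed = 9L)
  prof <- buildProfile(fam$alignment)
  cons <- profileConsensus(prof)
  base <- scoreSequence(prof, cons)
  # prepending unrelated residues shifts coordinates, not the score
  pre <- strrep("W", 7L)
  shifted <- scoreSequence(prof, paste0(pre, cons))
  expect_equal(shifted$score, base$score)
  expect_identical(shifted$aa_start, base$aa_start + 7L)

  # point mutations of the consensus never increase the score
  set.seed(11)
  aas <- rownames(blosum62())[1:20]
  for (k in sample(nchar(cons), 10L)) {
    mut <- cons
    substr(mut, k, k) <- sample(setdiff(aas, substr(cons, k, k)), 1L)
    expect_lte(scoreSequence(prof, mut)$score, base$score)
  }
})

test_that("scanRecord finds embedded markers on either strand, non-overlapping", {
  fam <- makeFamily(consensusLength = 60L, nSequences = 6L,
                    substitutionRate = 0.1, indelRate = 0, seed = 21L)
  prof <- buildProfile(fam$alignment)
  cons <- profileConsensus(prof)
  cutoff <- 0.5 * scoreSequence(prof, cons)$score

  # reverse-complemented marker -> one negative-frame hit
  cas <- paste0("ATG", reverseTranslate(cons, 3L), "TAA")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cas)))
  set.seed(5)
  contig <- paste0(paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = ""),
                   rc,
                   paste(sample(c("A", "C", "G", "T"), 90, TRUE), collapse = ""))
  hits <- scanRecord(prof, contig, cutoff, minAaLen = 20L, id = "rc")
  expect_identical(nrow(hits), 1L)
  expect_lt(hits$frame, 0L)
  # the hit's nt span lies inside the cassette's ground-truth span
  expect_gte(hits$nt_start, 121L)
  expect_lte(hits$nt_end, 120L + nchar(cas))

  # two tandem markers separated by stops -> two non-overlapping hits
  tandem <- paste0(cas, "TAATAA", paste0("ATG", reverseTranslate(cons, 4L), "TAA"))
  hits2 <- scanRecord(prof, tandem, cutoff, minAaLen = 20L)
  expect_identical(nrow(hits2), 2L)
  expect_true(hits2$nt_end[1L] < hits2$nt_start[2L])

  # unrelated sequence -> no hits
  set.seed(6)
  noise <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  expect_identical(nrow(scanRecord(prof, noise, cutoff, minAaLen = 20L)), 0L)
})

test_that("profile TSV serialization round-trips bit-exactly", {
  fam <- makeFamily(consensusLength = 35L, nSequences = 7L,
                    substitutionRate = 0.25, indelRate = 0.03, seed = 13L)
  prof <- buildProfile(fam$alignment, gapOpen = 10, gapExtend = 0.5,
                       name = "spo0A")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeProfile(prof, f)
  back <- readProfile(f)
  expect_identical(profileMatrix(back), profileMatrix(prof))
  expect_identical(back@gapOpen, prof@gapOpen)
  expect_identical(back@gapExtend, prof@gapExtend)
  expect_identical(back@name, prof@name)
  expect_identical(back@sourceIds, prof@sourceIds)
  expect_identical(back@nSequences, prof@nSequences)
})
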