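#' Build a protein entry table
#'
#' @param species,seq_id,residues parallel character vectors; the
#'   `(species, seq_id)` pairs must be unique.
#' @return a data.frame of protein entries.
#' @export
proteinEntries <- function(species, seq_id, residues) {
  df <- data.frame(species = as.character(species),
                   seq_id = as.character(seq_id),
                   residues = toupper(as.character(residues)),
                   stringsAsFactors = FALSE)
  checkUniqueIds(paste(df$species, df$seq_id, sep = "|"), "(species, seq_id)")
  if (any(!nzchar(df$residues))) stop("empty protein sequence")
  df
}

#' Read a combined proteome FASTA with species-tagged headers
#'
#' Headers are `species<delim>seq_id`; the default delimiter is `|`.
#'
#' @param path path to a protein FASTA file.
#' @param delim delimiter between species and sequence id.
#' @return a protein entry data.frame (see [proteinEntries()]).
#' @export
readProteinSet <- function(path, delim = "|") {
  seqs <- readFasta(path, alphabet = "protein")
  parts <- strsplit(names(seqs), delim, fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("header(s) without a '", delim, "' species delimiter")
  proteinEntries(vapply(parts, `[`, "", 1L),
                 vapply(parts, function(x) paste(x[-1L], collapse = delim), ""),
                 as.character(seqs))
}

#' Optimal local alignment score of two protein sequences
#'
#' Smith-Waterman-style local alignment with affine gap penalties (a gap
#' of length `k` costs `gapOpen + (k - 1) * gapExtend`). Used in place of
#' heuristic BLASTp for best-reciprocal-hit orthology: at the scale of
#' curated marker sets the optimal score subsumes the heuristic one. The
#' defaults mirror BLASTp (BLOSUM62, 11/1).
#'
#' @param a,b non-empty protein strings over the matrix alphabet.
#' @param matrix symmetric substitution matrix.
#' @param gapOpen,gapExtend gap penalties, `gapOpen >= gapExtend >= 0`.
#' @return the (non-negative) optimal local alignment score; symmetric in
#'   `a` and `b`.
#' @export
pairwiseScore <- function(a, b, matrix = blosum62(), gapOpen = 11,
                          gapExtend = 1) {
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  if (gapExtend < 0 || gapOpen < gapExtend)
    stop("need gapOpen >= gapExtend >= 0")
  achars <- strsplit(a, "", fixed = TRUE)[[1L]]
  checkMatrixAlphabet(matrix, unique(achars))
  alphabet <- colnames(matrix)
  M <- matrix[achars, , drop = FALSE]
  dimnames(M) <- NULL
  idx <- match(strsplit(b, "", fixed = TRUE)[[1L]], alphabet)
  idx[is.na(idx)] <- 0L
  L <- length(achars)
  profile_align_c(M, rep(gapOpen, L), rep(gapExtend, L),
                  as.integer(idx - 1L))$score
}

entryKey <- function(species, seq_id) paste(species, seq_id, sep = "|")

# all cross-species pairwise scores, each unordered pair computed once
crossScores <- function(entries, matrix, gapOpen, gapExtend) {
  n <- nrow(entries)
  sc <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (entries$species[i] == entries$species[j]) next
    sc[i, j] <- sc[j, i] <- pairwiseScore(entries$residues[i],
                                          entries$residues[j],
                                          matrix, gapOpen, gapExtend)
  }
  sc
}

#' Best cross-species hit of every query protein
#'
#' For each query and each species other than the query's own, the single
#' highest-scoring target is retained (ties broken by lexicographic
#' `seq_id`); hits with score `<= 0` are dropped, as are same-species
#' comparisons (avoiding paralogs).
#'
#' @param entries a protein entry data.frame ([proteinEntries()]).
#' @param matrix,gapOpen,gapExtend see [pairwiseScore()].
#' @return data.frame with columns `query_species`, `query_id`,
#'   `target_species`, `target_id`, `score`; empty when fewer than two
#'   species are present.
#' @export
bestHits <- function(entries, matrix = blosum62(), gapOpen = 11,
                     gapExtend = 1) {
  empty <- data.frame(query_species = character(), query_id = character(),
                      target_species = character(), target_id = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (length(unique(entries$species)) < 2L) return(empty)
  sc <- crossScores(entries, matrix, gapOpen, gapExtend)
  rows <- list()
  for (i in seq_len(nrow(entries))) {
    for (sp in setdiff(unique(entries$species), entries$species[i])) {
      cand <- which(entries$species == sp)
      cand <- cand[order(-sc[i, cand], entries$seq_id[cand])]
      best <- cand[1L]
      if (is.na(sc[i, best]) || sc[i, best] <= 0) next
      rows[[length(rows) + 1L]] <-
        data.frame(query_species = entries$species[i],
                   query_id = entries$seq_id[i],
                   target_species = sp,
                   target_id = entries$seq_id[best],
                   score = sc[i, best], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$query_species, out$query_id, out$target_species), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Best reciprocal hit (BRH) pairs
#'
#' A pair `(x, y)` is emitted iff `y` is `x`'s best hit in `y`'s species
#' and `x` is `y`'s best hit in `x`'s species. Pairs are stored in
#' canonical order (`species_a|id_a` lexicographically smaller) and never
#' join two members of the same species.
#'
#' @inheritParams bestHits
#' @return data.frame with columns `species_a`, `id_a`, `species_b`,
#'   `id_b`, `score`.
#' @export
brhPairs <- function(entries, matrix = blosum62(), gapOpen = 11,
                     gapExtend = 1) {
  bh <- bestHits(entries, matrix, gapOpen, gapExtend)
  empty <- data.frame(species_a = character(), id_a = character(),
                      species_b = character(), id_b = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (!nrow(bh)) return(empty)
  qk <- entryKey(bh$query_species, bh$query_id)
  tk <- entryKey(bh$target_species, bh$target_id)
  # reciprocal: the reversed (target -> query) edge must also be a best hit
  reciprocal <- paste(tk, qk) %in% paste(qk, tk)
  bh <- bh[reciprocal & qk < tk, , drop = FALSE]
  if (!nrow(bh)) return(empty)
  out <- data.frame(species_a = bh$query_species, id_a = bh$query_id,
                    species_b = bh$target_species, id_b = bh$target_id,
                    score = bh$score, stringsAsFactors = FALSE)
  out <- out[order(out$species_a, out$id_a, out$species_b, out$id_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster BRH pairs into ortholog groups
#'
#' Ortholog groups are the connected components of the undirected graph
#' whose edges are the BRH pairs. Singletons are never emitted (a group
#' needs at least one BRH edge). Groups are sorted by decreasing size,
#' then by their lexicographically smallest member; members are sorted
#' within each group.
#'
#' @param pairs a BRH pair data.frame from [brhPairs()].
#' @return a list of character vectors of `species|seq_id` member keys.
#' @export
clusterBRH <- function(pairs) {
  if (!nrow(pairs)) return(list())
  edges <- cbind(entryKey(pairs$species_a, pairs$id_a),
                 entryKey(pairs$species_b, pairs$id_b))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(unname(groups), sort)
  groups <- groups[lengths(groups) >= 2L]
  ord <- order(-lengths(groups), vapply(groups, `[`, "", 1L))
  groups[ord]
}
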