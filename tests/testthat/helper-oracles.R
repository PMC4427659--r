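# Independent brute-force oracles used against the package's DP and
# graph code. They share only the operation definitions (scoring
# conventions), never the implementation.

# exhaustive enumeration of local profile alignments: every alignment
# starts and ends with a residue matched to a column; between consecutive
# matches the gap is purely in the profile (skipped columns, first costs
# open[col], then extend[col] per column) or purely in the sequence
# (residues consumed after column p, first costs the mean of columns
# p/p+1's open, then that of their extend); score floored at 0.
bruteProfileAlign <- function(M, open, ext, idx) {
  L <- nrow(M)
  n <- length(idx)
  sc <- function(i, p) if (idx[i] > 0L) unname(M[p, idx[i]]) else 0
  insOpen <- function(p) if (p < L) (open[p] + open[p + 1L]) / 2 else open[L]
  insExt <- function(p) if (p < L) (ext[p] + ext[p + 1L]) / 2 else ext[L]
  memo <- matrix(NA_real_, n, L)
  after <- function(i, p) {
    if (!is.na(memo[i, p])) return(memo[i, p])
    best <- 0
    if (i < n && p < L) {
      for (p2 in (p + 1L):L) for (i2 in (i + 1L):n) {
        dp <- p2 - p
        di <- i2 - i
        if (dp > 1L && di > 1L) next
        cost <- 0
        if (dp > 1L) {
          cost <- open[p + 1L]
          if (dp > 2L) cost <- cost + sum(ext[(p + 2L):(p2 - 1L)])
        } else if (di > 1L) {
          cost <- insOpen(p)
          if (di > 2L) cost <- cost + (di - 2L) * insExt(p)
        }
        cand <- -cost + sc(i2, p2) + after(i2, p2)
        if (cand > best) best <- cand
      }
    }
    memo[i, p] <<- best
    best
  }
  best <- 0
  for (i in seq_len(n)) for (p in seq_len(L)) {
    v <- sc(i, p) + after(i, p)
    if (v > best) best <- v
  }
  best
}

# brute-force pairwise local alignment score via the profile form of the
# same conventions (constant per-position gap penalties)
brutePairScore <- function(a, b, mat, open, ext) {
  ac <- strsplit(a, "", fixed = TRUE)[[1L]]
  bc <- strsplit(b, "", fixed = TRUE)[[1L]]
  M <- mat[ac, , drop = FALSE]
  dimnames(M) <- NULL
  idx <- match(bc, colnames(mat))
  idx[is.na(idx)] <- 0L
  bruteProfileAlign(M, rep(open, length(ac)), rep(ext, length(ac)), idx)
}

# a diagonal-dominant toy substitution matrix over a reduced alphabet
toyMatrix <- function(alphabet = c("A", "C", "G", "T"), match = 5,
                      mismatch = -4) {
  m <- matrix(mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}

# brute-force best hits: direct scan of a full cross-species score table
bruteBestHits <- function(entries, scores) {
  out <- list()
  for (i in seq_len(nrow(entries))) {
    for (sp in setdiff(unique(entries$species), entries$species[i])) {
      cand <- which(entries$species == sp)
      best <- NULL
      for (j in cand) {
        if (is.null(best) || scores[i, j] > scores[i, best] ||
            (scores[i, j] == scores[i, best] &&
             entries$seq_id[j] < entries$seq_id[best]))
          best <- j
      }
      if (scores[i, best] > 0)
        out[[length(out) + 1L]] <- c(i = i, j = best)
    }
  }
  out
}

# brute-force connected components by repeated neighbourhood expansion
bruteComponents <- function(nodes, edges) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1L]
      b <- edges[k, 2L]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(names(comp), comp), sort))
}

# ungapped rows of a family alignment (the positive sequence set)
familyPositives <- function(fam) gsub("-", "", alignmentRows(fam$alignment))
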