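# Independent oracles used by the test suite. These deliberately avoid the
# code paths they check: the alignment oracle scans every diagonal of every
# frame exhaustively, and the rank-test oracle counts pairs directly per
# labeling instead of using rank sums.

# best ungapped local alignment score over all six frames, all reference
# proteins and all diagonals (exhaustive)
bruteForceBestScore <- function(dna, refProteins,
                                mat = hydroprofiler:::.score_matrix()) {
  kadane <- function(v) {
    cs <- cumsum(v)
    max(0, max(cs - cummin(c(0, cs[-length(cs)]))))
  }
  best <- 0
  for (P in sixFrameTranslate(dna)) {
    lp <- nchar(P)
    if (lp == 0) next
    pv <- strsplit(P, "")[[1]]
    for (Rp in as.character(refProteins)) {
      rv <- strsplit(Rp, "")[[1]]
      lr <- length(rv)
      sm <- mat[pv, rv, drop = FALSE]
      for (d in (-(lp - 1)):(lr - 1)) {
        qs <- max(1, 1 - d):min(lp, lr - d)
        v <- sm[cbind(qs, qs + d)]
        best <- max(best, kadane(v))
      }
    }
  }
  best
}

# minimal raw score that can pass the e-value cutoff for a given mate
minReportableRaw <- function(dna, db, params = searchParams()) {
  queryRes <- sum(nchar(sixFrameTranslate(dna)))
  space <- sum(Biostrings::width(dbProteins(db))) * queryRes
  bitMin <- log2(space / params@evalueCutoff)
  ceiling((bitMin * log(2) + log(params@karlinK)) / params@karlinLambda)
}

# exact two-sided Mann-Whitney p by enumeration, counting (x > y) pairs
# directly (ties as half) for every labeling
mwEnumerationOracle <- function(x, y) {
  pool <- c(x, y)
  n <- length(x); N <- length(pool)
  ustat <- function(xs, ys)
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  U <- ustat(x, y)
  mid <- n * (N - n) / 2
  labelings <- utils::combn(N, n)
  Us <- apply(labelings, 2, function(ix) ustat(pool[ix], pool[-ix]))
  list(U = U, p = mean(abs(Us - mid) >= abs(U - mid) - 1e-9))
}

# build a small reference database directly
makeTinyDb <- function(seqs, cats = NULL, metals = "NiFe") {
  if (is.null(cats)) cats <- rep_len(HYD_CATEGORIES, length(seqs))
  HydrogenaseDb(seqs, data.frame(entry_id = names(seqs),
                                 metal_class = rep_len(metals, length(seqs)),
                                 activity_category = cats))
}

# random protein helper for fixtures built in tests
randomProtein <- function(n) {
  paste0(sample(setdiff(hydroprofiler:::.AA_ALPHABET, "X"), n,
                replace = TRUE), collapse = "")
}
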