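#' Construct translated-search parameters
#'
#' Defaults: exact 4-aa seeds, e-value cutoff 0.001, BLOSUM62 with the
#' published ungapped Karlin-Altschul constants (lambda = 0.318,
#' K = 0.13). The search space is recomputed per run as total active
#' reference residues times translated query residues.
#'
#' @param seedLength exact-match seed length in amino acids (>= 3).
#' @param evalueCutoff reporting e-value threshold (> 0).
#' @param minBitScore additional bit-score floor (0 disables).
#' @param matrixName substitution matrix; only `"BLOSUM62"` is shipped.
#' @param karlinLambda,karlinK ungapped Karlin-Altschul constants.
#' @return A [SearchParams-class].
#' @export
searchParams <- function(seedLength = 4L, evalueCutoff = 0.001,
                         minBitScore = 0, matrixName = "BLOSUM62",
                         karlinLambda = 0.318, karlinK = 0.13) {
  if (!identical(matrixName, "BLOSUM62"))
    stop("only BLOSUM62 is available")
  methods::new("SearchParams", seedLength = as.integer(seedLength),
               minBitScore = minBitScore, evalueCutoff = evalueCutoff,
               matrixName = matrixName, karlinLambda = karlinLambda,
               karlinK = karlinK)
}

setMethod("show", "SearchParams", function(object) {
  cat("SearchParams: seed", object@seedLength, "aa,",
      object@matrixName, ", e-value cutoff", object@evalueCutoff,
      sprintf("(lambda %.3f, K %.3f)\n",
              object@karlinLambda, object@karlinK))
})

.mean_phred <- function(qual) {
  uq <- unique(qual)
  mu <- vapply(uq, function(s) {
    if (!nzchar(s)) return(0)
    mean(utf8ToInt(s)) - 33
  }, numeric(1), USE.NAMES = FALSE)
  mu[match(qual, uq)]
}

#' Quality-filter read pairs
#'
#' Retains pairs where both mates have mean Phred quality at least
#' `minMeanQuality` and length at least `minLength`; a pair is dropped
#' whole if either mate fails. Order is preserved.
#'
#' @param reads a [PairedReadSet-class].
#' @param minMeanQuality minimum mean Phred score per mate.
#' @param minLength minimum mate length (nt).
#' @return the filtered [PairedReadSet-class].
#' @export
qualityFilter <- function(reads, minMeanQuality = 20, minLength = 50L) {
  if (!length(reads)) return(reads)
  keep <- .mean_phred(qualities1(reads)) >= minMeanQuality &
          .mean_phred(qualities2(reads)) >= minMeanQuality &
          Biostrings::width(mate1(reads)) >= minLength &
          Biostrings::width(mate2(reads)) >= minLength
  reads[keep]
}

#' Remove host-derived read pairs by exact k-mer matching
#'
#' A pair is dropped when either mate shares at least `minSharedKmers`
#' exact k-mers (either strand, canonicalized) with the host genome.
#' Deterministic; no alignment involved.
#'
#' @param reads a [PairedReadSet-class].
#' @param hostGenome host [SyntheticGenome-class] (or anything with a
#'   `genomeSeq` method).
#' @param kmerLength k-mer length (<= read length, <= 31).
#' @param minSharedKmers k-mers shared with the host needed to drop a
#'   pair.
#' @return the decontaminated [PairedReadSet-class].
#' @export
filterHostReads <- function(reads, hostGenome, kmerLength = 25L,
                            minSharedKmers = 1L) {
  if (!length(reads)) return(reads)
  if (kmerLength > min(Biostrings::width(mate1(reads))))
    stop("kmerLength exceeds the read length")
  if (kmerLength > 31L) stop("kmerLength must be <= 31")
  drop <- cpp_host_filter(as.character(mate1(reads)),
                          as.character(mate2(reads)),
                          as.character(genomeSeq(hostGenome)),
                          as.integer(kmerLength),
                          as.integer(minSharedKmers))
  reads[!drop]
}

#' Translate a nucleotide sequence in all six frames
#'
#' Frames +1, +2, +3 read the forward strand at offsets 0, 1, 2; frames
#' -1, -2, -3 read the reverse complement the same way. Trailing partial
#' codons are dropped, stops render `*`, and codons containing an
#' ambiguous base render `X`.
#'
#' @param dna a nucleotide string (A/C/G/T/N) of length >= 3.
#' @return named character vector of the six peptides
#'   (`+1`,`+2`,`+3`,`-1`,`-2`,`-3`).
#' @examples
#' sixFrameTranslate("ATGAAA")
#' @export
sixFrameTranslate <- function(dna) {
  dna <- as.character(dna)
  if (nchar(dna) < 3L) stop("dna must be at least 3 nt")
  d <- Biostrings::DNAString(dna)
  rc <- Biostrings::reverseComplement(d)
  one <- function(x, off) {
    w <- (length(x) - off) %/% 3L * 3L
    if (w == 0L) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(x, off + 1L, off + w),
      no.init.codon = TRUE, if.fuzzy.codon = "X"))
  }
  c("+1" = one(d, 0L), "+2" = one(d, 1L), "+3" = one(d, 2L),
    "-1" = one(rc, 0L), "-2" = one(rc, 1L), "-3" = one(rc, 2L))
}

#' Search read pairs against the hydrogenase reference
#'
#' Each mate is searched independently in all six translated frames
#' against the active (non-excluded) reference entries: exact seeds of
#' `seedLength` amino acids anchor candidate diagonals, every seeded
#' diagonal is scanned for its maximum-scoring ungapped segment under
#' BLOSUM62, and the best segment per mate is reported as a hit when its
#' e-value is at or below the cutoff. Ties in raw score break to the
#' lexicographically smallest entry id, so repeated runs are identical.
#'
#' Bit score is `(lambda * raw - ln K) / ln 2`; e-value is
#' `search_space * 2^-bit` with search space = total active reference
#' residues x translated query residues of that mate.
#'
#' @param reads a [PairedReadSet-class].
#' @param db a [HydrogenaseDb-class] with at least one active entry.
#' @param params a [searchParams()] object.
#' @return data.frame of hits with columns `read_id` (`<pair>/1` or
#'   `<pair>/2`), `entry_id`, `frame`, `alignment_start` (0-based offset
#'   in the entry protein), `raw_score`, `bit_score`, `evalue`, sorted by
#'   (`read_id`, `entry_id`); at most one row per mate.
#' @export
searchReads <- function(reads, db, params = searchParams()) {
  act <- activeIds(db)
  if (!length(act)) stop("reference database has no active entries")
  refs <- dbProteins(db, active = TRUE)
  mat <- .score_matrix()
  alpha <- rownames(mat)
  ids <- names(mate1(reads))
  hits <- cpp_search(
    c(as.character(mate1(reads)), as.character(mate2(reads))),
    c(paste0(ids, "/1"), paste0(ids, "/2")),
    as.character(refs), names(refs),
    params@seedLength, mat, alpha,
    params@karlinLambda, params@karlinK, params@evalueCutoff,
    params@minBitScore)
  hits[order(hits$read_id, hits$entry_id), , drop = FALSE]
}

#' Write / read a hit table TSV
#'
#' Seven columns (`read_id`, `entry_id`, `frame`, `alignment_start`,
#' `raw_score`, `bit_score`, `evalue`) in the stable (`read_id`,
#' `entry_id`) sort order.
#'
#' @param hits data.frame from [searchReads()].
#' @param file path.
#' @export
writeHits <- function(hits, file) {
  utils::write.table(hits[order(hits$read_id, hits$entry_id), ,
                          drop = FALSE],
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeHits
#' @export
readHits <- function(file) {
  utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE)
}
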