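#' Activity-annotated hydrogenase reference database
#'
#' Container for a hydrogenase protein reference in the style of a HydDB
#' export: one amino-acid sequence per entry plus per-entry metadata (active
#' site metal class, predicted activity category, free-text source label),
#' and a set of entry ids excluded by curation. Iteration over "active"
#' entries never yields an excluded id.
#'
#' @slot proteins [Biostrings::AAStringSet] named by entry id.
#' @slot entryMeta [S4Vectors::DataFrame] with columns `metal_class`,
#'   `activity_category`, `source_label`, rows parallel to `proteins`.
#' @slot excluded character vector of excluded entry ids.
#' @slot versionTag free-text provenance string.
#' @export
setClass("HydrogenaseDb",
  slots = c(proteins  = "AAStringSet",
            entryMeta = "DataFrame",
            excluded  = "character",
            versionTag = "character"))

setValidity("HydrogenaseDb", function(object) {
  msg <- character()
  if (length(object@proteins) != nrow(object@entryMeta))
    msg <- c(msg, "proteins and entryMeta have different lengths")
  if (!all(c("metal_class", "activity_category", "source_label") %in%
           colnames(object@entryMeta)))
    msg <- c(msg, "entryMeta must have metal_class, activity_category, source_label")
  if (length(msg)) msg else TRUE
})

#' Synthetic genome with annotated gene features
#'
#' A nucleotide genome carrying reverse-translated protein coding sequences
#' at annotated positions. Features are stored as a
#' [GenomicRanges::GRanges] (1-based, closed intervals, the Bioconductor
#' convention) with metadata columns `entry_id` (the protein the CDS
#' encodes) and `type` (`"hydrogenase"` or `"background"`). Knockout
#' variants carry `isKnockout = TRUE` and no hydrogenase features.
#'
#' @slot genomeId character scalar.
#' @slot seq [Biostrings::DNAString] genome sequence.
#' @slot features [GenomicRanges::GRanges] non-overlapping CDS features.
#' @slot isKnockout logical scalar.
#' @export
setClass("SyntheticGenome",
  slots = c(genomeId = "character",
            seq = "DNAString",
            features = "GRanges",
            isKnockout = "logical"))

setValidity("SyntheticGenome", function(object) {
  msg <- character()
  f <- object@features
  if (length(f)) {
    if (!all(c("entry_id", "type") %in% colnames(S4Vectors::mcols(f))))
      msg <- c(msg, "features need mcols entry_id and type")
    if (min(GenomicRanges::start(f)) < 1 ||
        max(GenomicRanges::end(f)) > length(object@seq))
      msg <- c(msg, "feature out of genome bounds")
    if (any(GenomicRanges::width(f) %% 3L != 0L))
      msg <- c(msg, "feature width not divisible by 3")
    if (length(f) > 1) {
      o <- GenomicRanges::findOverlaps(f, drop.self = TRUE)
      if (length(o)) msg <- c(msg, "overlapping features")
    }
    if (isTRUE(object@isKnockout) &&
        any(S4Vectors::mcols(f)$type == "hydrogenase"))
      msg <- c(msg, "knockout genome retains hydrogenase features")
  }
  if (length(msg)) msg else TRUE
})

#' Paired-end read set with optional ground truth
#'
#' Mate sequences and flat quality strings for a set of read pairs, plus an
#' optional per-pair truth table recording the source genome, the 1-based
#' fragment start, and for each mate the overlapped CDS entry (if any) with
#' the overlap width in nucleotides.
#'
#' @slot mate1,mate2 [Biostrings::DNAStringSet] named by pair id.
#' @slot qual1,qual2 character vectors of Phred+33 quality strings.
#' @slot truth [S4Vectors::DataFrame] with zero rows when no truth is
#'   available, otherwise columns `genome_id`, `frag_start`, `entry1`,
#'   `overlap1`, `entry2`, `overlap2`.
#' @export
setClass("PairedReadSet",
  slots = c(mate1 = "DNAStringSet", mate2 = "DNAStringSet",
            qual1 = "character",   qual2 = "character",
            truth = "DataFrame"))

setValidity("PairedReadSet", function(object) {
  n <- length(object@mate1)
  msg <- character()
  if (length(object@mate2) != n) msg <- c(msg, "mate1/mate2 length mismatch")
  if (length(object@qual1) != n || length(object@qual2) != n)
    msg <- c(msg, "quality vectors must parallel the mates")
  if (n && (any(nchar(object@qual1) != Biostrings::width(object@mate1)) ||
            any(nchar(object@qual2) != Biostrings::width(object@mate2))))
    msg <- c(msg, "quality string length != sequence length")
  if (nrow(object@truth) && nrow(object@truth) != n)
    msg <- c(msg, "truth rows must match the number of pairs")
  if (length(msg)) msg else TRUE
})

#' Translated-search parameters
#'
#' Tuning of the six-frame seed-and-extend search and of its
#' Karlin-Altschul significance statistics. The e-value cutoff (default
#' 0.001) is the reporting contract; bit score = (lambda * raw - ln K) /
#' ln 2 and e-value = search_space * 2^-bit with search_space = total
#' active reference residues x translated query residues, recomputed per
#' run.
#'
#' @slot seedLength integer, exact-match seed length in amino acids.
#' @slot minBitScore numeric, additional bit-score floor (0 disables).
#' @slot evalueCutoff numeric reporting threshold.
#' @slot matrixName substitution matrix name (only "BLOSUM62" shipped).
#' @slot karlinLambda,karlinK ungapped Karlin-Altschul constants.
#' @export
setClass("SearchParams",
  slots = c(seedLength = "integer", minBitScore = "numeric",
            evalueCutoff = "numeric", matrixName = "character",
            karlinLambda = "numeric", karlinK = "numeric"))

setValidity("SearchParams", function(object) {
  msg <- character()
  if (object@seedLength < 3L) msg <- c(msg, "seedLength must be >= 3")
  if (object@evalueCutoff <= 0) msg <- c(msg, "evalueCutoff must be > 0")
  if (length(msg)) msg else TRUE
})
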