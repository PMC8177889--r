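#' Construct a synthetic genome
#'
#' @param genomeId scalar id.
#' @param seq genome sequence ([Biostrings::DNAString] or character).
#' @param features [GenomicRanges::GRanges] with mcols `entry_id`, `type`
#'   (may be empty).
#' @param isKnockout logical flag.
#' @return A [SyntheticGenome-class].
#' @export
SyntheticGenome <- function(genomeId, seq, features = NULL,
                            isKnockout = FALSE) {
  if (!methods::is(seq, "DNAString")) seq <- Biostrings::DNAString(seq)
  if (is.null(features))
    features <- GenomicRanges::GRanges(seqnames = character(),
                                       ranges = IRanges::IRanges(),
                                       entry_id = character(),
                                       type = character())
  methods::new("SyntheticGenome", genomeId = as.character(genomeId),
               seq = seq, features = features,
               isKnockout = isTRUE(isKnockout))
}

#' @describeIn SyntheticGenome genome id
#' @param x a `SyntheticGenome`.
#' @export
setMethod("genomeId", "SyntheticGenome", function(x) x@genomeId)

#' @describeIn SyntheticGenome genome sequence (`DNAString`)
#' @export
setMethod("genomeSeq", "SyntheticGenome", function(x) x@seq)

#' @describeIn SyntheticGenome CDS features (`GRanges`)
#' @export
setMethod("genomeFeatures", "SyntheticGenome", function(x) x@features)

#' @describeIn SyntheticGenome has this genome had its hydrogenases
#'   excised?
#' @export
setMethod("isKnockout", "SyntheticGenome", function(x) x@isKnockout)

#' @describeIn SyntheticGenome genome length in nucleotides
#' @export
setMethod("length", "SyntheticGenome", function(x) length(x@seq))

setMethod("show", "SyntheticGenome", function(object) {
  f <- object@features
  cat("SyntheticGenome", object@genomeId, "-", length(object@seq), "nt,",
      length(f), "features",
      if (object@isKnockout) "(knockout)\n" else "\n")
  if (length(f)) {
    tab <- table(S4Vectors::mcols(f)$type)
    cat("  ", paste(names(tab), as.integer(tab), sep = ":",
                    collapse = "  "), "\n")
  }
})

#' Translate an annotated CDS feature back to its protein
#'
#' Extracts the feature interval from the genome (reverse-complementing
#' minus-strand features) and translates it with the standard code. Used
#' to verify the reverse-translation round trip.
#'
#' @param genome a [SyntheticGenome-class].
#' @param i feature index (or indices).
#' @return character vector of amino-acid sequences.
#' @export
translateFeature <- function(genome, i = seq_along(genomeFeatures(genome))) {
  f <- genomeFeatures(genome)[i]
  vapply(seq_along(f), function(k) {
    cds <- Biostrings::subseq(genomeSeq(genome),
                              GenomicRanges::start(f)[k],
                              GenomicRanges::end(f)[k])
    if (as.character(GenomicRanges::strand(f)[k]) == "-")
      cds <- Biostrings::reverseComplement(cds)
    as.character(Biostrings::translate(cds, no.init.codon = TRUE))
  }, character(1))
}

#' Write / read genome FASTA and feature BED
#'
#' Genome sequences go to FASTA via Biostrings; features go to 6-column
#' BED (0-based half-open, strand in column 6) via rtracklayer. Because
#' BED has no free metadata column, the name field carries
#' `entry_id|type`.
#'
#' @param genome a [SyntheticGenome-class].
#' @param fastaFile,bedFile output paths.
#' @export
writeGenome <- function(genome, fastaFile, bedFile = NULL) {
  s <- Biostrings::DNAStringSet(genomeSeq(genome))
  names(s) <- genomeId(genome)
  Biostrings::writeXStringSet(s, fastaFile)
  if (!is.null(bedFile)) {
    f <- genomeFeatures(genome)
    names(f) <- paste(S4Vectors::mcols(f)$entry_id,
                      S4Vectors::mcols(f)$type, sep = "|")
    S4Vectors::mcols(f) <- NULL
    rtracklayer::export(f, bedFile, format = "bed")
  }
  invisible(fastaFile)
}

#' @rdname writeGenome
#' @param isKnockout flag to set on the reconstructed genome.
#' @export
readGenome <- function(fastaFile, bedFile = NULL, isKnockout = FALSE) {
  s <- Biostrings::readDNAStringSet(fastaFile)
  gid <- sub("\\s.*$", "", names(s)[1])
  feats <- NULL
  if (!is.null(bedFile)) {
    gr <- rtracklayer::import(bedFile, format = "bed")
    parts <- strsplit(gr$name, "|", fixed = TRUE)
    feats <- GenomicRanges::GRanges(
      seqnames = gid,
      ranges = IRanges::IRanges(GenomicRanges::start(gr),
                                GenomicRanges::end(gr)),
      strand = GenomicRanges::strand(gr),
      entry_id = vapply(parts, `[`, "", 1L),
      type = vapply(parts, `[`, "", 2L))
  }
  SyntheticGenome(gid, s[[1]], feats, isKnockout = isKnockout)
}

#' Excise all hydrogenase coding sequences from a genome
#'
#' Removes the exact annotated interval of every feature with
#' `type == "hydrogenase"` and concatenates the flanks. Background
#' (non-hydrogenase) features are retained with shifted coordinates. The
#' result is flagged `isKnockout`; no substring of the output equals any
#' excised CDS (the excision removes the full interval, so only chimeric
#' junction sequence remains).
#'
#' @param genome a non-knockout [SyntheticGenome-class].
#' @return the knockout [SyntheticGenome-class].
#' @export
knockoutGenome <- function(genome) {
  if (isKnockout(genome))
    stop("genome is already a knockout")
  f <- genomeFeatures(genome)
  hyd <- f[S4Vectors::mcols(f)$type == "hydrogenase"]
  keep <- f[S4Vectors::mcols(f)$type != "hydrogenase"]
  if (!length(hyd))
    return(SyntheticGenome(genomeId(genome), genomeSeq(genome), keep,
                           isKnockout = TRUE))
  cut <- IRanges::IRanges(GenomicRanges::start(hyd), GenomicRanges::end(hyd))
  cut <- cut[order(IRanges::start(cut))]
  newseq <- Biostrings::replaceAt(genomeSeq(genome), cut, value = "")
  if (length(keep)) {
    shift <- vapply(GenomicRanges::start(keep), function(s)
      sum(IRanges::width(cut)[IRanges::end(cut) < s]), numeric(1))
    keep <- GenomicRanges::GRanges(
      seqnames = genomeId(genome),
      ranges = IRanges::IRanges(GenomicRanges::start(keep) - shift,
                                GenomicRanges::end(keep) - shift),
      strand = GenomicRanges::strand(keep),
      entry_id = S4Vectors::mcols(keep)$entry_id,
      type = S4Vectors::mcols(keep)$type)
  }
  SyntheticGenome(genomeId(genome), newseq, keep, isKnockout = TRUE)
}
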