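#' Construct a paired-end read set
#'
#' @param mate1,mate2 [Biostrings::DNAStringSet] or character vectors;
#'   `mate1` must be named by pair id.
#' @param qual1,qual2 Phred+33 quality strings (default: flat Q40).
#' @param truth optional per-pair truth table (see
#'   [PairedReadSet-class]).
#' @return A [PairedReadSet-class].
#' @export
PairedReadSet <- function(mate1, mate2, qual1 = NULL, qual2 = NULL,
                          truth = NULL) {
  if (!methods::is(mate1, "DNAStringSet")) mate1 <- Biostrings::DNAStringSet(mate1)
  if (!methods::is(mate2, "DNAStringSet")) mate2 <- Biostrings::DNAStringSet(mate2)
  if (is.null(names(mate1)))
    names(mate1) <- sprintf("pair%06d", seq_along(mate1))
  names(mate2) <- names(mate1)
  flat <- function(ss) strrep("I", Biostrings::width(ss))
  if (is.null(qual1)) qual1 <- flat(mate1)
  if (is.null(qual2)) qual2 <- flat(mate2)
  if (is.null(truth)) truth <- S4Vectors::DataFrame()
  if (!methods::is(truth, "DataFrame")) truth <- S4Vectors::DataFrame(truth)
  methods::new("PairedReadSet", mate1 = mate1, mate2 = mate2,
               qual1 = as.character(qual1), qual2 = as.character(qual2),
               truth = truth)
}

#' @describeIn PairedReadSet number of read pairs
#' @param x a `PairedReadSet`.
#' @export
setMethod("length", "PairedReadSet", function(x) length(x@mate1))

#' @describeIn PairedReadSet first-mate sequences
#' @export
setMethod("mate1", "PairedReadSet", function(x) x@mate1)

#' @describeIn PairedReadSet second-mate sequences
#' @export
setMethod("mate2", "PairedReadSet", function(x) x@mate2)

#' @describeIn PairedReadSet first-mate quality strings
#' @export
setMethod("qualities1", "PairedReadSet", function(x) x@qual1)

#' @describeIn PairedReadSet second-mate quality strings
#' @export
setMethod("qualities2", "PairedReadSet", function(x) x@qual2)

#' @describeIn PairedReadSet per-pair ground-truth table (zero rows when
#'   absent)
#' @export
setMethod("readTruth", "PairedReadSet", function(x) x@truth)

#' @describeIn PairedReadSet subset pairs by index, logical mask or pair id
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PairedReadSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@mate1))
  tr <- if (nrow(x@truth)) x@truth[i, , drop = FALSE] else x@truth
  methods::new("PairedReadSet", mate1 = x@mate1[i], mate2 = x@mate2[i],
               qual1 = x@qual1[i], qual2 = x@qual2[i], truth = tr)
})

setMethod("show", "PairedReadSet", function(object) {
  n <- length(object)
  cat("PairedReadSet with", n, "pairs")
  if (n) cat(", mate widths",
             paste(range(Biostrings::width(object@mate1)), collapse = "-"))
  cat(if (nrow(object@truth)) ", with truth\n" else "\n")
})

#' Write / read paired FASTQ
#'
#' Files are `<prefix>_1.fastq` and `<prefix>_2.fastq`, uncompressed,
#' Phred+33. The truth table is not serialized here (see the TSV writers
#' used by the pipeline).
#'
#' @param reads a [PairedReadSet-class].
#' @param prefix path prefix without the `_1.fastq` suffix.
#' @return `writePairedFastq`: the two file paths, invisibly.
#' @export
writePairedFastq <- function(reads, prefix) {
  f1 <- paste0(prefix, "_1.fastq"); f2 <- paste0(prefix, "_2.fastq")
  ids <- names(reads@mate1)
  m1 <- reads@mate1; names(m1) <- paste0(ids, "/1")
  m2 <- reads@mate2; names(m2) <- paste0(ids, "/2")
  Biostrings::writeXStringSet(m1, f1, format = "fastq",
                              qualities = Biostrings::BStringSet(reads@qual1))
  Biostrings::writeXStringSet(m2, f2, format = "fastq",
                              qualities = Biostrings::BStringSet(reads@qual2))
  invisible(c(f1, f2))
}

#' @rdname writePairedFastq
#' @export
readPairedFastq <- function(prefix) {
  f1 <- paste0(prefix, "_1.fastq"); f2 <- paste0(prefix, "_2.fastq")
  m1 <- Biostrings::readDNAStringSet(f1, format = "fastq",
                                     with.qualities = TRUE)
  m2 <- Biostrings::readDNAStringSet(f2, format = "fastq",
                                     with.qualities = TRUE)
  ids <- sub("/1$", "", sub("\\s.*$", "", names(m1)))
  q1 <- as.character(S4Vectors::mcols(m1)$qualities)
  q2 <- as.character(S4Vectors::mcols(m2)$qualities)
  names(m1) <- ids
  PairedReadSet(m1, m2, q1, q2)
}
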