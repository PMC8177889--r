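#' Construct a hydrogenase reference database
#'
#' @param proteins [Biostrings::AAStringSet] (or named character vector)
#'   of entry protein sequences; names are the entry ids.
#' @param meta data.frame-like with columns `entry_id`, `metal_class`,
#'   `activity_category` and optionally `source_label`. Category and metal
#'   tokens are matched case-insensitively after stripping brackets, so
#'   `"[NiFe]"` and `"nife"` both canonicalize to `"NiFe"`.
#' @param versionTag free-text provenance string.
#' @return A [HydrogenaseDb-class] with no exclusions.
#' @examples
#' db <- HydrogenaseDb(c(h1 = "MKLVAW", h2 = "MTTREQW"),
#'                     data.frame(entry_id = c("h1", "h2"),
#'                                metal_class = c("NiFe", "FeFe"),
#'                                activity_category = c("uptake", "evolving")))
#' entryIds(db)
#' @export
HydrogenaseDb <- function(proteins, meta, versionTag = "") {
  if (!methods::is(proteins, "AAStringSet"))
    proteins <- Biostrings::AAStringSet(proteins)
  if (is.null(names(proteins)) || anyNA(names(proteins)))
    stop("proteins must be named by entry id")
  meta <- as.data.frame(meta)
  if (!all(c("entry_id", "metal_class", "activity_category") %in% names(meta)))
    stop("meta needs entry_id, metal_class and activity_category columns")
  if (is.null(meta$source_label)) meta$source_label <- ""

  fids <- names(proteins)
  mids <- as.character(meta$entry_id)
  miss_meta  <- setdiff(fids, mids)
  miss_fasta <- setdiff(mids, fids)
  if (length(miss_meta))
    stop("entries missing from metadata: ", paste(miss_meta, collapse = ", "))
  if (length(miss_fasta))
    stop("metadata rows without a sequence: ",
         paste(miss_fasta, collapse = ", "))
  if (anyDuplicated(fids))
    stop("duplicate entry id(s): ",
         paste(unique(fids[duplicated(fids)]), collapse = ", "))

  meta <- meta[match(fids, mids), , drop = FALSE]
  em <- S4Vectors::DataFrame(
    metal_class = .canon_metal(meta$metal_class),
    activity_category = .canon_category(meta$activity_category),
    source_label = as.character(meta$source_label),
    row.names = fids)

  db <- methods::new("HydrogenaseDb", proteins = proteins, entryMeta = em,
                     excluded = character(), versionTag = versionTag)
  bad <- .protein_alphabet_issues(db)
  if (length(bad)) stop(paste(bad, collapse = "; "))
  db
}

# issues (not errors) for sequences straying off the 20-aa + X alphabet
.protein_alphabet_issues <- function(db) {
  seqs <- db@proteins
  if (!length(seqs)) return(character())
  freq <- Biostrings::alphabetFrequency(seqs)
  ok <- colnames(freq) %in% .AA_ALPHABET
  off <- rowSums(freq[, !ok, drop = FALSE])
  empty <- Biostrings::width(seqs) == 0L
  c(if (any(off > 0))
      paste0("entry ", names(seqs)[off > 0],
             ": letters outside the amino-acid alphabet (plus X)"),
    if (any(empty)) paste0("entry ", names(seqs)[empty], ": empty sequence"))
}

#' Read a reference database from FASTA + metadata TSV
#'
#' The metadata file is a tab-separated table with header columns
#' `entry_id`, `metal_class`, `activity_category`, `source_label`. Every
#' FASTA record id must appear exactly once in the metadata and vice
#' versa; mismatches fail naming the offending ids.
#'
#' @param fastaFile path to the protein FASTA.
#' @param metadataFile path to the metadata TSV.
#' @param versionTag free-text provenance string.
#' @return A [HydrogenaseDb-class].
#' @export
readHydrogenaseDb <- function(fastaFile, metadataFile, versionTag = "") {
  prot <- Biostrings::readAAStringSet(fastaFile)
  names(prot) <- sub("\\s.*$", "", names(prot))
  meta <- utils::read.delim(metadataFile, sep = "\t",
                            stringsAsFactors = FALSE)
  HydrogenaseDb(prot, meta, versionTag = versionTag)
}

#' Write a reference database as FASTA + metadata TSV
#'
#' Round-trips through [readHydrogenaseDb()] preserving every field.
#' Exclusions are not embedded in these files; persist them with
#' [writeExclusionList()].
#'
#' @param db a [HydrogenaseDb-class].
#' @param fastaFile,metadataFile output paths.
#' @export
writeHydrogenaseDb <- function(db, fastaFile, metadataFile) {
  Biostrings::writeXStringSet(db@proteins, fastaFile)
  meta <- data.frame(entry_id = names(db@proteins),
                     metal_class = db@entryMeta$metal_class,
                     activity_category = db@entryMeta$activity_category,
                     source_label = db@entryMeta$source_label)
  utils::write.table(meta, metadataFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fastaFile, metadataFile))
}

#' Validate a reference database
#'
#' Reports (never raises) one human-readable issue per violated invariant:
#' empty or off-alphabet protein sequences, duplicate ids, enum
#' violations, exclusions pointing at unknown ids. An empty character
#' vector means the database is well formed.
#'
#' @param db a [HydrogenaseDb-class].
#' @return character vector of issue descriptions (possibly empty).
#' @export
validateDb <- function(db) {
  issues <- character()
  ids <- names(db@proteins)
  if (anyDuplicated(ids))
    issues <- c(issues, paste0("duplicate entry id: ",
                               unique(ids[duplicated(ids)])))
  issues <- c(issues, .protein_alphabet_issues(db))
  badcat <- !(db@entryMeta$activity_category %in% HYD_CATEGORIES)
  if (any(badcat))
    issues <- c(issues, paste0("entry ", ids[badcat],
                               ": activity_category not in enum"))
  badmet <- !(db@entryMeta$metal_class %in% HYD_METAL_CLASSES)
  if (any(badmet))
    issues <- c(issues, paste0("entry ", ids[badmet],
                               ": metal_class not in enum"))
  orphan <- setdiff(db@excluded, ids)
  if (length(orphan))
    issues <- c(issues, paste0("excluded id not in database: ", orphan))
  issues
}

#' @describeIn HydrogenaseDb all entry ids (including excluded ones)
#' @param x a `HydrogenaseDb`.
#' @export
setMethod("entryIds", "HydrogenaseDb", function(x) names(x@proteins))

#' @describeIn HydrogenaseDb ids not excluded by curation
#' @export
setMethod("activeIds", "HydrogenaseDb",
          function(x) setdiff(names(x@proteins), x@excluded))

#' @describeIn HydrogenaseDb ids excluded by curation
#' @export
setMethod("excludedIds", "HydrogenaseDb", function(x) x@excluded)

#' @describeIn HydrogenaseDb per-entry metadata (`DataFrame`)
#' @export
setMethod("dbMeta", "HydrogenaseDb", function(x) x@entryMeta)

#' @describeIn HydrogenaseDb protein sequences, active entries only by
#'   default
#' @param active return only non-excluded entries?
#' @export
setMethod("dbProteins", "HydrogenaseDb", function(x, active = TRUE) {
  if (active) x@proteins[activeIds(x)] else x@proteins
})

#' @describeIn HydrogenaseDb named vector of activity categories
#' @export
setMethod("activityCategories", "HydrogenaseDb", function(x, active = TRUE) {
  cats <- stats::setNames(x@entryMeta$activity_category, names(x@proteins))
  if (active) cats[activeIds(x)] else cats
})

#' @describeIn HydrogenaseDb exclude entries (idempotent, set semantics);
#'   unknown ids are an error
#' @param ids character vector of entry ids to exclude.
#' @export
setMethod("applyExclusions", "HydrogenaseDb", function(x, ids) {
  ids <- unique(as.character(ids))
  unknown <- setdiff(ids, names(x@proteins))
  if (length(unknown))
    stop("cannot exclude unknown entry id(s): ",
         paste(unknown, collapse = ", "))
  x@excluded <- sort(union(x@excluded, ids))
  methods::validObject(x)
  x
})

setMethod("show", "HydrogenaseDb", function(object) {
  cat("HydrogenaseDb with", length(object@proteins), "entries (",
      length(activeIds(object)), "active,",
      length(object@excluded), "excluded )\n")
  tab <- table(factor(object@entryMeta$activity_category,
                      levels = HYD_CATEGORIES))
  cat("  categories:",
      paste(names(tab), as.integer(tab), sep = ":", collapse = "  "), "\n")
  if (nzchar(object@versionTag))
    cat("  version:", object@versionTag, "\n")
})

#' Read / write an exclusion list
#'
#' Plain text, one entry id per line; the format written by the curation
#' pipeline and accepted back by [applyExclusions()].
#'
#' @param file path.
#' @return `readExclusionList`: character vector of ids.
#' @export
readExclusionList <- function(file) {
  ids <- readLines(file)
  ids[nzchar(trimws(ids))]
}

#' @rdname readExclusionList
#' @param ids character vector of entry ids.
#' @export
writeExclusionList <- function(ids, file) {
  writeLines(as.character(ids), file)
  invisible(file)
}
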