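#' Count best-hit reads per reference entry
#'
#' Summarizes a hit list to per-entry read counts. The best-hit contract
#' upstream guarantees at most one hit per read; a duplicated `read_id`
#' is a contract violation and an error. Entries with no hits are absent
#' from the result (treated as zero downstream).
#'
#' @param hits data.frame from [searchReads()] (or [readHits()]).
#' @return named integer vector entry_id -> read count.
#' @export
countHits <- function(hits) {
  if (!nrow(hits)) return(stats::setNames(integer(), character()))
  if (anyDuplicated(hits$read_id))
    stop("duplicate read_id in hits (best-hit contract violated): ",
         paste(unique(hits$read_id[duplicated(hits$read_id)])[1:3],
               collapse = ", "))
  tab <- table(hits$entry_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Curate the reference with the in-silico knockout twofold rule
#'
#' Compares per-entry read recruitment between a hydrogenase-containing
#' (wild-type) dataset and a hydrogenase-free (knockout) dataset.
#' Relative abundances are computed per dataset over the total
#' hydrogenase-mapped reads of that dataset, and an entry is excluded
#' when its knockout relative abundance is at least `foldThreshold`
#' times its wild-type relative abundance. Zero conventions: an entry
#' with reads only in the knockout dataset is excluded (this is exactly
#' the failure mode the rule targets); an entry with no reads in either
#' dataset is retained (merely untested).
#'
#' @param wtCounts,koCounts named counts from [countHits()] for the
#'   wild-type and knockout datasets (both totals must be positive).
#' @param db the [HydrogenaseDb-class] being curated; counts must
#'   reference its active entries.
#' @param foldThreshold exclusion threshold (default 2, inclusive).
#' @return `list(report, db)`: `report` is a data.frame with one row per
#'   active entry (`entry_id`, `wt_count`, `ko_count`, `wt_relative`,
#'   `ko_relative`, `enrichment_ratio`, `excluded`); `db` is the curated
#'   database with the exclusions applied.
#' @export
curateDb <- function(wtCounts, koCounts, db, foldThreshold = 2) {
  act <- activeIds(db)
  unknown <- setdiff(c(names(wtCounts), names(koCounts)), act)
  if (length(unknown))
    stop("counts reference unknown or inactive entry id(s): ",
         paste(unknown, collapse = ", "))
  wt <- stats::setNames(rep(0, length(act)), act)
  ko <- wt
  wt[names(wtCounts)] <- wtCounts
  ko[names(koCounts)] <- koCounts
  if (sum(wt) <= 0 || sum(ko) <= 0)
    stop("both datasets must have at least one hydrogenase-mapped read")
  wtRel <- wt / sum(wt)
  koRel <- ko / sum(ko)
  ratio <- ifelse(wtRel > 0, koRel / wtRel,
                  ifelse(koRel > 0, Inf, NA_real_))
  excluded <- !is.na(ratio) & ratio >= foldThreshold
  report <- data.frame(entry_id = act, wt_count = unname(wt),
                       ko_count = unname(ko), wt_relative = unname(wtRel),
                       ko_relative = unname(koRel),
                       enrichment_ratio = unname(ratio),
                       excluded = unname(excluded))
  curated <- if (any(excluded)) applyExclusions(db, act[excluded]) else db
  list(report = report, db = curated)
}

#' Write a curation report TSV
#'
#' @param report the report data.frame from [curateDb()].
#' @param file path.
#' @export
writeCurationReport <- function(report, file) {
  utils::write.table(report, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
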