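# Sample x entry profiling and the between-group rank statistic.
# Hit tables live in SummarizedExperiment objects with entries as rows
# and samples as columns (colData carries the group labels); the TSV
# writers transpose to the samples-x-entries layout used on disk.

#' Build a sample-by-entry hit table
#'
#' @param perSampleCounts named list (sample id -> named counts from
#'   [countHits()]).
#' @param groups named character vector sample id -> group label; every
#'   sample must have a label.
#' @param entryIds optional full set of entry ids (e.g.
#'   `activeIds(db)`) so that entries never hit anywhere appear as
#'   structural zero rows.
#' @return [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` (entries x samples, sorted ids both ways) and a `group`
#'   column in `colData`.
#' @export
buildHitTable <- function(perSampleCounts, groups, entryIds = NULL) {
  samples <- sort(names(perSampleCounts))
  nogroup <- setdiff(samples, names(groups))
  if (length(nogroup))
    stop("sample(s) without a group label: ",
         paste(nogroup, collapse = ", "))
  entries <- sort(unique(c(entryIds,
                           unlist(lapply(perSampleCounts, names)))))
  counts <- matrix(0L, length(entries), length(samples),
                   dimnames = list(entries, samples))
  for (s in samples) {
    cs <- perSampleCounts[[s]]
    if (length(cs)) counts[names(cs), s] <- as.integer(cs)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(group = unname(groups[samples]),
                                   row.names = samples))
}

#' Normalize a hit table to per-sample hydrogenase-mapped totals
#'
#' Divides each sample's counts by that sample's total reads aligned to
#' any queried hydrogenase. Samples with zero total stay all-zero and
#' are flagged in `colData()$zero_total`.
#'
#' @param se the hit-table `SummarizedExperiment` from
#'   [buildHitTable()].
#' @return the same object with an added `relabund` assay and the
#'   `zero_total` flag.
#' @export
normalizeHitTable <- function(se) {
  counts <- SummarizedExperiment::assay(se, "counts")
  tot <- colSums(counts)
  rel <- sweep(counts, 2, ifelse(tot > 0, tot, 1), "/")
  SummarizedExperiment::assays(se)$relabund <- rel
  SummarizedExperiment::colData(se)$total_mapped <- tot
  SummarizedExperiment::colData(se)$zero_total <- tot == 0
  se
}

#' Aggregate normalized abundances by activity category
#'
#' Sums each sample's normalized entry abundances within the five
#' activity categories. Category sums equal the row sums of the
#' normalized table (a partition identity), so they are 1 for samples
#' with any mapped reads.
#'
#' @param se normalized hit table from [normalizeHitTable()].
#' @param db the [HydrogenaseDb-class]; every table entry must map to
#'   one activity category.
#' @return `SummarizedExperiment` (5 categories x samples) with assay
#'   `abundance` and the per-sample totals carried through `colData`.
#' @export
aggregateCategories <- function(se, db) {
  rel <- SummarizedExperiment::assay(se, "relabund")
  cats <- activityCategories(db, active = FALSE)
  missing <- setdiff(rownames(rel), names(cats))
  if (length(missing))
    stop("entries without an activity category: ",
         paste(missing, collapse = ", "))
  f <- factor(cats[rownames(rel)], levels = HYD_CATEGORIES)
  agg <- rowsum(rel, f)
  full <- matrix(0, length(HYD_CATEGORIES), ncol(rel),
                 dimnames = list(HYD_CATEGORIES, colnames(rel)))
  full[rownames(agg), ] <- agg
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = full),
    colData = SummarizedExperiment::colData(se))
}

#' Per-entry group averages with zero substitution
#'
#' Arithmetic mean of each entry's normalized abundance within each
#' group; any mean exactly equal to zero is replaced by `pseudoValue`
#' (the substitution happens after averaging across samples). The
#' murine preset is 0.05 and the human preset 0.0005.
#'
#' @param se normalized hit table from [normalizeHitTable()] with two
#'   groups, each with at least one sample.
#' @param pseudoValue substitution constant for zero averages.
#' @return matrix entries x 2 groups of substituted means.
#' @export
perEntryGroupAverages <- function(se, pseudoValue = 0.05) {
  rel <- SummarizedExperiment::assay(se, "relabund")
  grp <- SummarizedExperiment::colData(se)$group
  glev <- sort(unique(grp))
  if (length(glev) != 2L) stop("exactly two groups required")
  means <- vapply(glev, function(g)
    rowMeans(rel[, grp == g, drop = FALSE]),
    numeric(nrow(rel)))
  means[means == 0] <- pseudoValue
  means
}

.mw_cache <- new.env(parent = emptyenv())

#' Mann-Whitney U test (exact by enumeration for small samples)
#'
#' U is computed from the rank sums with average ranks for ties. The
#' two-sided p-value is exact by enumeration of all `choose(n + m, n)`
#' group labelings when `n + m <= 16` (correct under ties, where the
#' classical exact null does not apply), and otherwise uses the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors (each non-empty).
#' @return `list(U, p.value, method)`, U oriented on `x` (number of
#'   `(x, y)` pairs with `x > y`, counting ties as half).
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (N <= 16L) {
    key <- paste(N, n, sep = "_")
    idx <- .mw_cache[[key]]
    if (is.null(idx)) {
      idx <- utils::combn(N, n)
      .mw_cache[[key]] <- idx
    }
    Us <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    p <- mean(abs(Us - n * m / 2) >= abs(U - n * m / 2) - 1e-9)
    list(U = U, p.value = p, method = "exact enumeration")
  } else {
    t <- table(r)
    sigma2 <- n * m / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(U = U, p.value = 1,
                                 method = "normal approximation"))
    dev <- U - n * m / 2
    z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
    list(U = U, p.value = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal approximation")
  }
}

#' Bonferroni adjustment
#'
#' `p -> min(1, m * p)` with `m = length(p)`; raw p-values must lie in
#' (0, 1].
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values.
#' @export
bonferroniAdjust <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "bonferroni")
}

#' Compare activity categories between two groups
#'
#' For each activity category the two groups' vectors of per-entry
#' average normalized abundances (zero averages replaced by
#' `pseudoValue`) are compared with [mannWhitneyU()], and p-values are
#' Bonferroni-adjusted across the testable categories (categories with
#' no active entries are reported untestable and do not count toward
#' the correction).
#'
#' @param se normalized hit table from [normalizeHitTable()] (two
#'   groups).
#' @param db the [HydrogenaseDb-class] mapping entries to categories.
#' @param pseudoValue zero-average substitution constant (0.05 murine
#'   preset, 0.0005 human preset).
#' @return data.frame with one row per category: `category`,
#'   `n_entries`, `U`, `p_raw`, `p_bonferroni`, `pseudo_value`,
#'   `testable`. U is oriented on the alphabetically first group label.
#' @export
compareGroups <- function(se, db, pseudoValue = 0.05) {
  means <- perEntryGroupAverages(se, pseudoValue)
  cats <- activityCategories(db, active = FALSE)
  out <- data.frame(category = HYD_CATEGORIES,
                    n_entries = 0L, U = NA_real_, p_raw = NA_real_,
                    p_bonferroni = NA_real_, pseudo_value = pseudoValue,
                    testable = FALSE)
  for (i in seq_along(HYD_CATEGORIES)) {
    ids <- intersect(rownames(means),
                     names(cats)[cats == HYD_CATEGORIES[i]])
    out$n_entries[i] <- length(ids)
    if (!length(ids)) next
    mw <- mannWhitneyU(means[ids, 1], means[ids, 2])
    out$U[i] <- mw$U
    out$p_raw[i] <- mw$p.value
    out$testable[i] <- TRUE
  }
  if (any(out$testable))
    out$p_bonferroni[out$testable] <- bonferroniAdjust(
      out$p_raw[out$testable])
  out
}

#' Write profile outputs as TSV / JSON
#'
#' `writeHitTable` transposes to the on-disk samples-x-entries layout;
#' `writeCategoryProfile` writes the category x sample abundances;
#' `writeComparison` writes the group-comparison table as TSV or, with
#' a `.json` path, as JSON.
#'
#' @param se a hit-table or category `SummarizedExperiment`.
#' @param file output path.
#' @param assay assay name to write.
#' @export
writeHitTable <- function(se, file, assay = "counts") {
  m <- t(SummarizedExperiment::assay(se, assay))
  df <- data.frame(sample_id = rownames(m),
                   group = SummarizedExperiment::colData(se)$group,
                   m, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname writeHitTable
#' @export
writeCategoryProfile <- function(se, file) {
  writeHitTable(se, file, assay = "abundance")
}

#' @rdname writeHitTable
#' @param comparison data.frame from [compareGroups()].
#' @export
writeComparison <- function(comparison, file) {
  if (grepl("\\.json$", file)) {
    jsonlite::write_json(comparison, file, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.table(comparison, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(file)
}
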