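test_that("hit tables assemble with zero fill and sorted ids", {
  counts <- list(s2 = c(e1 = 3L), s1 = c(e2 = 1L))
  groups <- c(s1 = "A", s2 = "B")
  se <- buildHitTable(counts, groups)
  m <- SummarizedExperiment::assay(se, "counts")
  expect_equal(dimnames(m), list(c("e1", "e2"), c("s1", "s2")))
  expect_equal(unname(m), matrix(c(0L, 1L, 3L, 0L), 2))
  # empty counts become an all-zero column
  se2 <- buildHitTable(list(s1 = c(e1 = 2L), s2 = integer()), groups)
  expect_equal(sum(SummarizedExperiment::assay(se2)[, "s2"]), 0L)
  expect_error(buildHitTable(counts, c(s1 = "A")), "s2")
  # structural zeros for never-hit entries
  se3 <- buildHitTable(counts, groups, entryIds = c("e1", "e2", "e9"))
  expect_true("e9" %in% rownames(se3))
})

test_that("normalization divides by hydrogenase-mapped totals", {
  se <- buildHitTable(list(s1 = c(e1 = 8L, e2 = 2L), s2 = integer()),
                      c(s1 = "A", s2 = "B"))
  se <- normalizeHitTable(se)
  rel <- SummarizedExperiment::assay(se, "relabund")
  expect_equal(unname(rel[, "s1"]), c(0.8, 0.2))
  expect_equal(unname(rel[, "s2"]), c(0, 0))
  expect_identical(unname(SummarizedExperiment::colData(se)$zero_total),
                   c(FALSE, TRUE))
  expect_equal(unname(colSums(rel)[1]), 1)
})

test_that("category aggregation is a partition of the normalized table", {
  db <- makeTinyDb(c(e1 = randomProtein(60), e2 = randomProtein(60),
                     e3 = randomProtein(60)),
                   cats = c("uptake", "evolving", "uptake"))
  se <- buildHitTable(list(s1 = c(e1 = 6L, e2 = 2L, e3 = 2L),
                           s2 = c(e1 = 1L, e2 = 3L)),
                      c(s1 = "A", s2 = "B"))
  se <- normalizeHitTable(se)
  cp <- aggregateCategories(se, db)
  ab <- SummarizedExperiment::assay(cp, "abundance")
  expect_equal(ab["uptake", "s1"], 0.8)
  expect_equal(ab["evolving", "s1"], 0.2)
  expect_equal(unname(colSums(ab)),
               unname(colSums(SummarizedExperiment::assay(se, "relabund"))))
  # unmapped entries fail loudly
  seBad <- buildHitTable(list(s1 = c(zz = 1L)), c(s1 = "A"))
  expect_error(aggregateCategories(normalizeHitTable(seBad), db), "zz")
})

test_that("zero group averages take the pseudo-value after averaging", {
  se <- buildHitTable(list(s1 = c(e1 = 0L, e2 = 5L), s2 = c(e2 = 5L),
                           s3 = c(e1 = 3L, e2 = 7L), s4 = c(e1 = 2L, e2 = 8L)),
                      c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
  se <- normalizeHitTable(se)
  mm <- perEntryGroupAverages(se, pseudoValue = 0.05)
  expect_equal(mm["e1", "A"], 0.05)          # zero mean -> pseudo
  expect_equal(mm["e1", "B"], (0.3 + 0.2) / 2)
  expect_equal(mm["e2", "A"], 1)             # untouched
  # all-zero entry in both groups -> both means at the pseudo-value
  se2 <- buildHitTable(list(s1 = c(e1 = 1L), s2 = c(e1 = 1L)),
                       c(s1 = "A", s2 = "B"), entryIds = c("e1", "e9"))
  mm2 <- perEntryGroupAverages(normalizeHitTable(se2), 0.0005)
  expect_equal(unname(mm2["e9", ]), c(0.0005, 0.0005))
})

test_that("Mann-Whitney U matches enumeration, ties included", {
  res <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p.value, 0.1)
  tie <- mannWhitneyU(5, 5)
  expect_equal(tie$U, 0.5)
  expect_equal(tie$p.value, 1)
  # swapping the samples reflects U and keeps p
  a <- c(2, 9, 4); b <- c(3, 3, 8, 1)
  r1 <- mannWhitneyU(a, b); r2 <- mannWhitneyU(b, a)
  expect_equal(r1$U + r2$U, length(a) * length(b))
  expect_equal(r1$p.value, r2$p.value)
  # oracle property over random small inputs with ties
  set.seed(7)
  for (i in 1:60) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    x <- sample(1:5, n, replace = TRUE)
    y <- sample(1:5, m, replace = TRUE)
    got <- mannWhitneyU(x, y)
    want <- mwEnumerationOracle(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p.value, want$p)
  }
  expect_error(mannWhitneyU(numeric(), 1), "non-empty")
})

test_that("the large-sample approximation matches the classical form", {
  set.seed(8)
  x <- rnorm(20); y <- rnorm(20, 0.5)
  got <- mannWhitneyU(x, y)
  expect_equal(got$method, "normal approximation")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-9)
})

test_that("Bonferroni adjustment is min(1, m p) with validation", {
  expect_equal(bonferroniAdjust(0.01), 0.01)
  expect_equal(bonferroniAdjust(c(0.01, 0.2, 0.3, 0.4, 0.5))[1], 0.05)
  expect_equal(bonferroniAdjust(c(0.4, 0.4, 0.4, 0.4, 0.4)), rep(1, 5))
  expect_error(bonferroniAdjust(c(0.1, 0)), "0, 1")
  expect_error(bonferroniAdjust(1.2), "0, 1")
})

test_that("group comparison flags a planted category and honors m", {
  set.seed(9)
  ids <- paste0(rep(HYD_CATEGORIES[1:4], each = 6), "_", 1:6)
  db <- makeTinyDb(stats::setNames(replicate(24, randomProtein(60)), ids),
                   cats = rep(HYD_CATEGORIES[1:4], each = 6))
  spread <- c(1, 1.2, 1.45, 1.75, 2.1, 2.5)
  mkSample <- function(shift) {
    mu <- 60 * rep(spread, 4)
    mu[1:6] <- mu[1:6] * shift
    stats::setNames(rpois(24, mu), ids)
  }
  counts <- c(lapply(1:6, function(i) mkSample(1)),
              lapply(1:6, function(i) mkSample(10)))
  names(counts) <- paste0("s", 1:12)
  groups <- stats::setNames(rep(c("A", "B"), each = 6), names(counts))
  se <- normalizeHitTable(buildHitTable(counts, groups,
                                        entryIds = entryIds(db)))
  cmp <- compareGroups(se, db, pseudoValue = 0.05)
  # sensory has no entries: untestable, excluded from the correction
  expect_false(cmp$testable[cmp$category == "sensory"])
  m <- sum(cmp$testable)
  expect_equal(m, 4L)
  expect_equal(cmp$p_bonferroni[cmp$testable],
               pmin(1, m * cmp$p_raw[cmp$testable]))
  expect_lt(cmp$p_bonferroni[cmp$category == "uptake"], 0.05)
})

test_that("profiles and p-values ignore per-sample sequencing depth", {
  set.seed(10)
  ids <- paste0(rep(HYD_CATEGORIES, each = 2), "_", 1:2)
  db <- makeTinyDb(stats::setNames(replicate(10, randomProtein(60)), ids),
                   cats = rep(HYD_CATEGORIES, each = 2))
  counts <- lapply(1:6, function(i)
    stats::setNames(rpois(10, 30) + 1L, ids))
  names(counts) <- paste0("s", 1:6)
  groups <- stats::setNames(rep(c("A", "B"), each = 3), names(counts))
  base <- counts
  scaled <- counts
  scaled$s2 <- scaled$s2 * 7L
  seB <- normalizeHitTable(buildHitTable(base, groups))
  seS <- normalizeHitTable(buildHitTable(scaled, groups))
  expect_equal(SummarizedExperiment::assay(seB, "relabund"),
               SummarizedExperiment::assay(seS, "relabund"))
  expect_equal(compareGroups(seB, db)[, c("U", "p_raw", "p_bonferroni")],
               compareGroups(seS, db)[, c("U", "p_raw", "p_bonferroni")])
})

test_that("profile writers produce the samples-by-entries layout", {
  db <- makeTinyDb(c(e1 = randomProtein(60), e2 = randomProtein(60)),
                   cats = c("uptake", "evolving"))
  se <- normalizeHitTable(buildHitTable(
    list(s1 = c(e1 = 3L, e2 = 1L), s2 = c(e1 = 1L)),
    c(s1 = "A", s2 = "B")))
  f <- tempfile(fileext = ".tsv")
  writeHitTable(se, f)
  back <- utils::read.delim(f)
  expect_equal(back$sample_id, c("s1", "s2"))
  expect_equal(back$e1, c(3L, 1L))
  fj <- tempfile(fileext = ".json")
  writeComparison(compareGroups(se, db), fj)
  expect_equal(jsonlite::read_json(fj)[[1]]$category, "uptake")
})
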