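test_that("reference generator fills every category and is seed-stable", {
  ref <- simulateReferenceAndDecoys(2, 80, nDecoys = 3, seed = 11)
  expect_equal(length(entryIds(ref$db)), 10L)
  expect_equal(as.vector(table(activityCategories(ref$db))),
               rep(2L, 5))
  ref2 <- simulateReferenceAndDecoys(2, 80, nDecoys = 3, seed = 11)
  expect_identical(as.character(dbProteins(ref$db)),
                   as.character(dbProteins(ref2$db)))
  expect_identical(ref$decoys, ref2$decoys)
  ref3 <- simulateReferenceAndDecoys(2, 80, nDecoys = 3, seed = 12)
  expect_false(identical(as.character(dbProteins(ref$db)),
                         as.character(dbProteins(ref3$db))))
})

test_that("decoys share no 8-residue substring with any entry", {
  ref <- simulateReferenceAndDecoys(2, 100, nDecoys = 3, seed = 21)
  entries <- as.character(dbProteins(ref$db))
  for (d in ref$decoys) {
    kmers <- substring(d, 1:(nchar(d) - 7), 8:nchar(d))
    hitAny <- vapply(entries, function(e)
      any(vapply(kmers, grepl, logical(1), x = e, fixed = TRUE)),
      logical(1))
    expect_false(any(hitAny))
  }
})

test_that("genomes embed reverse-translated CDS that translate back", {
  prots <- data.frame(
    entry_id = c("p1", "p2", "p3", "p4"),
    sequence = replicate(4, randomProtein(70)),
    type = c("hydrogenase", "hydrogenase", "background", "hydrogenase"))
  g <- simulateGenome("g1", 5000, prots, seed = 31)
  expect_equal(length(g), 5000L)
  f <- genomeFeatures(g)
  expect_equal(length(f), 4L)
  expect_true(all(GenomicRanges::width(f) == 210L))
  got <- translateFeature(g)
  expect_identical(unname(got),
                   prots$sequence[match(f$entry_id, prots$entry_id)])
  # determinism
  g2 <- simulateGenome("g1", 5000, prots, seed = 31)
  expect_identical(as.character(genomeSeq(g)), as.character(genomeSeq(g2)))
  # infeasible embedding fails loudly
  expect_error(simulateGenome("g3", 100, prots, seed = 1), "3x")
})

test_that("knockout excises every hydrogenase CDS and shifts the rest", {
  prots <- data.frame(
    entry_id = c("h1", "h2", "d1"),
    sequence = c(randomProtein(100), randomProtein(150), randomProtein(80)),
    type = c("hydrogenase", "hydrogenase", "background"))
  g <- simulateGenome("g1", 5000, prots, seed = 41)
  cds <- lapply(seq_along(genomeFeatures(g)), function(i) {
    f <- genomeFeatures(g)[i]
    as.character(Biostrings::subseq(genomeSeq(g), GenomicRanges::start(f),
                                    GenomicRanges::end(f)))
  })
  names(cds) <- genomeFeatures(g)$entry_id
  ko <- knockoutGenome(g)
  expect_true(isKnockout(ko))
  expect_equal(length(ko), 5000L - 300L - 450L)
  expect_equal(genomeFeatures(ko)$entry_id, "d1")
  # exhaustive scan: excised CDS (as inserted) occur zero times
  for (id in c("h1", "h2")) {
    expect_equal(Biostrings::countPattern(cds[[id]], genomeSeq(ko)), 0L)
  }
  # background feature still translates to its protein after the shift
  expect_identical(unname(translateFeature(ko, 1)), prots$sequence[3])
  # decoy-only genome: sequence unchanged, only the flag flips
  gBg <- simulateGenome("g2", 2000,
                        data.frame(entry_id = "d9",
                                   sequence = randomProtein(60),
                                   type = "background"), seed = 42)
  koBg <- knockoutGenome(gBg)
  expect_identical(as.character(genomeSeq(koBg)),
                   as.character(genomeSeq(gBg)))
  expect_true(isKnockout(koBg))
  expect_error(knockoutGenome(koBg), "already")
})

test_that("read counts follow the coverage formula and errors are seeded", {
  g <- simulateGenome("g1", 10000,
                      data.frame(entry_id = "h1",
                                 sequence = randomProtein(100),
                                 type = "hydrogenase"), seed = 51)
  for (fc in c(5, 20, 33.3)) {
    rd <- simulateReads(g, fc, 100, 0, seed = 52)
    expect_equal(length(rd), round(fc * 10000 / 200))
  }
  rd <- simulateReads(g, 20, 100, 0, seed = 52)
  # error-free mates are exact substrings of the genome or its
  # reverse complement
  G <- as.character(genomeSeq(g))
  Grc <- as.character(Biostrings::reverseComplement(genomeSeq(g)))
  idx <- sample.int(length(rd), 25)
  for (i in idx) {
    expect_true(grepl(as.character(mate1(rd))[i], G, fixed = TRUE))
    expect_true(grepl(as.character(mate2(rd))[i], Grc, fixed = TRUE))
  }
  # determinism / divergence across seeds
  rdB <- simulateReads(g, 20, 100, 0.01, seed = 52)
  rdC <- simulateReads(g, 20, 100, 0.01, seed = 52)
  expect_identical(as.character(mate1(rdB)), as.character(mate1(rdC)))
  rdD <- simulateReads(g, 20, 100, 0.01, seed = 53)
  expect_false(identical(as.character(mate1(rdB)),
                         as.character(mate1(rdD))))
  # truth records per-mate CDS overlap of at least 1 nt
  f <- genomeFeatures(g)
  tr <- readTruth(rd)
  ov <- pmin(tr$frag_start + 99L, GenomicRanges::end(f)) -
        pmax(tr$frag_start, GenomicRanges::start(f)) + 1L
  expect_identical(!is.na(tr$entry1), ov >= 1L)
})

test_that("condition samples follow the design and report truth", {
  ref <- simulateReferenceAndDecoys(1, c(60, 60), nDecoys = 0, seed = 61)
  cats <- activityCategories(ref$db)
  genomes <- lapply(HYD_CATEGORIES, function(cat) {
    ids <- names(cats)[cats == cat]
    simulateGenome(paste0("carrier_", cat), 3000,
                   data.frame(entry_id = ids,
                              sequence = as.character(dbProteins(ref$db)[ids]),
                              type = "hydrogenase"),
                   seed = 62 + match(cat, HYD_CATEGORIES))
  })
  host <- simulateGenome("host", 3000,
                         data.frame(entry_id = character(),
                                    sequence = character(),
                                    type = character()), seed = 70)
  ab <- cbind(c(0.1, rep(0.225, 4)), c(0.4, rep(0.15, 4)))
  dimnames(ab) <- list(paste0("carrier_", HYD_CATEGORIES),
                       c("control", "inflamed"))
  des <- communityDesign(ab, samplesPerGroup = 3, readPairsPerSample = 800,
                         errorRate = 0, hostFraction = 0.5, seed = 71)
  sim <- simulateConditionSamples(des, genomes, host, db = ref$db)
  expect_equal(length(sim$samples), 6L)
  expect_equal(as.vector(table(sim$groups)), c(3L, 3L))
  # host fraction 0.5: binomial expectation under the fixed seed
  hostPairs <- vapply(sim$samples, function(s)
    sum(readTruth(s)$genome_id == "host"), integer(1))
  expect_true(all(abs(hostPairs - 400) < 4 * sqrt(800 * 0.25)))
  # equal-density carriers: expected uptake fraction ratio is exactly 4
  ex <- sim$expected
  up <- ex$expected_fraction[ex$category == "uptake"]
  expect_equal(up[ex$group[ex$category == "uptake"] == "inflamed"] /
               up[ex$group[ex$category == "uptake"] == "control"], 4,
               tolerance = 1e-9)
  expect_error(
    simulateConditionSamples(des, genomes[-1], host),
    "carrier_uptake")
})

test_that("design validation rejects malformed communities", {
  ab <- cbind(c(0.5, 0.6), c(0.5, 0.5))
  dimnames(ab) <- list(c("a", "b"), c("g1", "g2"))
  expect_error(communityDesign(ab, 2, 100), "sum to 1")
  ab[2, 1] <- 0.5
  expect_error(communityDesign(ab, 2, 100, errorRate = 0.2), "errorRate")
  expect_error(communityDesign(ab, 2, 100, hostFraction = 1), "hostFraction")
  expect_s3_class(communityDesign(ab, 2, 100), "CommunityDesign")
})

test_that("paired FASTQ round-trips reads and qualities", {
  g <- simulateGenome("g1", 2000,
                      data.frame(entry_id = "h1",
                                 sequence = randomProtein(60),
                                 type = "hydrogenase"), seed = 81)
  rd <- simulateReads(g, 10, 100, 0.01, seed = 82)
  pre <- file.path(tempdir(), "rt")
  writePairedFastq(rd, pre)
  back <- readPairedFastq(pre)
  expect_identical(as.character(mate1(back)), as.character(mate1(rd)))
  expect_identical(as.character(mate2(back)), as.character(mate2(rd)))
  expect_identical(qualities1(back), qualities1(rd))
  expect_identical(names(mate1(back)), names(mate1(rd)))
})
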