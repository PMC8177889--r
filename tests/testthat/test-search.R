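test_that("six-frame translation matches hand-derived frames", {
  expect_identical(unname(sixFrameTranslate("ATGAAA")),
                   c("MK", "*", "E", "FH", "F", "S"))
  expect_identical(unname(sixFrameTranslate("ATG")),
                   c("M", "", "", "H", "", ""))
  expect_error(sixFrameTranslate("AT"), "3 nt")
  # codons containing N render X
  expect_identical(unname(sixFrameTranslate("ATGNAA"))[1], "MX")
  # frame length arithmetic on random sequences
  set.seed(1)
  for (len in c(3, 7, 10, 31)) {
    dna <- paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
    fr <- sixFrameTranslate(dna)
    expect_equal(nchar(fr), stats::setNames(
      rep((len - 0:2) %/% 3, 2), names(fr)))
  }
})

test_that("the C++ translator agrees with the Biostrings-based one", {
  set.seed(2)
  for (i in 1:25) {
    dna <- paste0(sample(c("A", "C", "G", "T", "N"), sample(3:120, 1),
                         replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
                  collapse = "")
    expect_identical(unname(hydroprofiler:::cpp_six_frames(dna)[1, ]),
                     unname(sixFrameTranslate(dna)))
  }
})

test_that("quality filtering drops whole pairs on either failing mate", {
  m1 <- c(a = strrep("A", 100), b = strrep("C", 100), c = strrep("G", 100))
  rs <- PairedReadSet(m1, m1,
                      qual1 = c(strrep("I", 100), strrep("I", 100),
                                strrep("#", 100)),
                      qual2 = c(strrep("I", 100), strrep("#", 100),
                                strrep("I", 100)))
  keep <- qualityFilter(rs, minMeanQuality = 20, minLength = 50)
  expect_equal(names(mate1(keep)), "a")
  # all at maximum quality: identical output
  rs2 <- PairedReadSet(m1, m1)
  expect_equal(length(qualityFilter(rs2, 20, 50)), 3L)
  # short mates fail the length floor
  rs3 <- PairedReadSet(c(a = "ACGTACGT"), c(a = "ACGTACGT"))
  expect_equal(length(qualityFilter(rs3, 0, 50)), 0L)
  empty <- PairedReadSet(Biostrings::DNAStringSet(),
                         Biostrings::DNAStringSet())
  expect_equal(length(qualityFilter(empty, 20, 50)), 0L)
})

test_that("host k-mer filtering removes host-derived pairs", {
  host <- simulateGenome("host", 5000,
                         data.frame(entry_id = character(),
                                    sequence = character(),
                                    type = character()), seed = 91)
  other <- simulateGenome("bug", 5000,
                          data.frame(entry_id = character(),
                                     sequence = character(),
                                     type = character()), seed = 92)
  hostReads <- simulateReads(host, 8, 100, 0, seed = 93)
  bugReads <- simulateReads(other, 8, 100, 0, seed = 94)
  expect_equal(length(filterHostReads(hostReads, host)), 0L)
  expect_equal(length(filterHostReads(bugReads, host)),
               length(bugReads))
  # with sequencing errors, nearly all host pairs are still caught
  hostErr <- simulateReads(host, 20, 100, 0.005, seed = 95)
  kept <- filterHostReads(hostErr, host)
  expect_lt(length(kept) / length(hostErr), 0.01)
  expect_error(filterHostReads(bugReads, host, kmerLength = 200L),
               "read length")
})

test_that("perfect in-frame copies hit their entry; junk does not", {
  set.seed(3)
  prots <- stats::setNames(replicate(5, randomProtein(80)),
                           paste0("e", 1:5))
  db <- makeTinyDb(prots)
  # an exact 100 nt window inside e2's CDS, forward frame
  cds <- hydroprofiler:::with_seed(7, reverseTranslate(prots[["e2"]]))
  win <- substr(cds, 31, 130)
  rs <- PairedReadSet(c(q = win), c(q = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(win)))))
  hits <- searchReads(rs, db)
  expect_equal(nrow(hits), 2L)          # both mates, independently
  expect_true(all(hits$entry_id == "e2"))
  expect_true(all(hits$evalue <= 0.001))
  # a mate sharing no seed with any entry yields no hit
  junk <- PairedReadSet(c(j = strrep("ACGT", 25)),
                        c(j = strrep("TTTT", 25)))
  expect_equal(nrow(searchReads(junk, db)), 0L)
  # excluded entries can never be hit
  db2 <- applyExclusions(db, "e2")
  hits2 <- searchReads(rs, db2)
  expect_false(any(hits2$entry_id == "e2"))
})

test_that("lowering the e-value cutoff only removes hits", {
  g <- simulateGenome("g1", 8000, data.frame(
    entry_id = paste0("e", 1:4),
    sequence = replicate(4, randomProtein(90)),
    type = "hydrogenase"), seed = 101)
  db <- makeTinyDb(stats::setNames(translateFeature(g),
                                   genomeFeatures(g)$entry_id))
  rd <- simulateReads(g, 15, 100, 0.01, seed = 102)
  loose <- searchReads(rd, db, searchParams(evalueCutoff = 0.01))
  tight <- searchReads(rd, db, searchParams(evalueCutoff = 1e-6))
  keyL <- paste(loose$read_id, loose$entry_id)
  keyT <- paste(tight$read_id, tight$entry_id)
  expect_true(all(keyT %in% keyL))
  expect_lte(length(keyT), length(keyL))
  # determinism of repeated runs
  again <- searchReads(rd, db, searchParams(evalueCutoff = 0.01))
  expect_identical(loose, again)
})

test_that("reported raw scores equal the exhaustive alignment oracle", {
  set.seed(4)
  params <- searchParams()
  nAgree <- 0L; nInstances <- 40L
  for (i in seq_len(nInstances)) {
    prots <- stats::setNames(replicate(4, randomProtein(70)),
                             paste0("e", 1:4))
    db <- makeTinyDb(prots)
    # plant a read from a random window with up to 2 residue changes
    src <- sample(names(prots), 1)
    aa <- strsplit(prots[[src]], "")[[1]]
    start <- sample(length(aa) - 19, 1)
    win <- aa[start:(start + 19)]
    nmut <- sample(0:2, 1)
    if (nmut > 0) {
      at <- sample(20, nmut)
      win[at] <- sample(setdiff(hydroprofiler:::.AA_ALPHABET, "X"), nmut,
                        replace = TRUE)
    }
    dna <- hydroprofiler:::with_seed(1000 + i,
             reverseTranslate(paste0(win, collapse = "")))
    rs <- PairedReadSet(stats::setNames(Biostrings::DNAStringSet(dna), "q"),
                        Biostrings::DNAStringSet(dna))
    hit <- searchReads(rs, db, params)
    hit <- hit[hit$read_id == "q/1", ]
    oracle <- bruteForceBestScore(dna, dbProteins(db))
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$raw_score, oracle)
    nAgree <- nAgree + (nrow(hit) == 1L && hit$raw_score == oracle)
  }
  expect_equal(nAgree, nInstances)
  # purely random reads: nothing reportable exists for the oracle either
  for (i in 1:15) {
    dna <- paste0(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                  collapse = "")
    prots <- stats::setNames(replicate(4, randomProtein(70)),
                             paste0("e", 1:4))
    db <- makeTinyDb(prots)
    rs <- PairedReadSet(stats::setNames(Biostrings::DNAStringSet(dna), "q"),
                        Biostrings::DNAStringSet(dna))
    hit <- searchReads(rs, db, params)
    if (nrow(hit) == 0L)
      expect_lt(bruteForceBestScore(dna, dbProteins(db)),
                minReportableRaw(dna, db, params))
  }
})
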