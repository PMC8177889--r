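# Study-condition fixtures: complete seeded experiments built from the
# primitive generators. Defaults encode the conditions the pipeline is
# validated under; see the methods vignette for the power analysis behind
# them.

#' Simulate a two-condition hydrogenase profiling study
#'
#' Builds a full synthetic study: a reference of `nPerCategory` entries
#' per activity category, one carrier genome per category embedding that
#' category's entries, a featureless host genome, and condition-stratified
#' samples in which the uptake carrier is `uptakeFoldChange` times more
#' abundant in the second group while the other carriers share the
#' remainder equally. Because every carrier has the same length and CDS
#' profile, the expected uptake fraction of hydrogenase-mapped reads
#' differs between groups by exactly `uptakeFoldChange`.
#'
#' Default protein lengths span 80-400 aa, giving each category a ~3.5x
#' within-category abundance spread; see the vignette for why this
#' matters for the rank test.
#'
#' @param seed integer seed (sub-seeds are derived by small offsets).
#' @param nPerCategory entries per category.
#' @param proteinLengths protein lengths recycled within each category.
#' @param genomeLength carrier and host genome length (nt).
#' @param samplesPerGroup samples per condition group.
#' @param readPairsPerSample read pairs per sample.
#' @param readLength read length (nt).
#' @param errorRate per-base substitution probability.
#' @param hostFraction fraction of pairs drawn from the host genome.
#' @param uptakeFoldChange fold enrichment of the uptake carrier in the
#'   second group.
#' @param uptakeAbundance uptake-carrier relative abundance in the first
#'   group.
#' @param groups the two condition labels.
#' @return list with `db`, `genomes` (5 carriers), `host`, `samples`,
#'   `groups`, `expected` and the `design`.
#' @export
simulateStudy <- function(seed,
                          nPerCategory = 6L,
                          proteinLengths = c(80L, 110L, 152L, 210L, 290L, 400L),
                          genomeLength = 20000L,
                          samplesPerGroup = 6L,
                          readPairsPerSample = 20000L,
                          readLength = 100L,
                          errorRate = 0.005,
                          hostFraction = 0.05,
                          uptakeFoldChange = 4,
                          uptakeAbundance = 0.1,
                          groups = c("control", "inflamed")) {
  ref <- simulateReferenceAndDecoys(nPerCategory, proteinLengths,
                                    nDecoys = 0L, seed = seed)
  db <- ref$db
  cats <- activityCategories(db)
  genomes <- list()
  for (i in seq_along(HYD_CATEGORIES)) {
    cat <- HYD_CATEGORIES[i]
    ids <- names(cats)[cats == cat]
    prot <- data.frame(entry_id = ids,
                       sequence = as.character(dbProteins(db)[ids]),
                       type = "hydrogenase")
    genomes[[cat]] <- simulateGenome(paste0("carrier_", cat), genomeLength,
                                     prot, seed = seed + i)
  }
  host <- simulateGenome("host", genomeLength,
                         data.frame(entry_id = character(),
                                    sequence = character(),
                                    type = character()),
                         seed = seed + 10L)
  upB <- uptakeAbundance * uptakeFoldChange
  if (upB >= 1) stop("uptakeAbundance * uptakeFoldChange must stay below 1")
  ab <- cbind(c(uptakeAbundance, rep((1 - uptakeAbundance) / 4, 4)),
              c(upB, rep((1 - upB) / 4, 4)))
  dimnames(ab) <- list(paste0("carrier_", HYD_CATEGORIES), groups)
  design <- communityDesign(ab, samplesPerGroup, readPairsPerSample,
                            readLength, errorRate, hostFraction,
                            seed = seed + 20L)
  sim <- simulateConditionSamples(design, genomes, host, db = db)
  list(db = db, genomes = genomes, host = host, samples = sim$samples,
       groups = sim$groups, expected = sim$expected, design = design)
}

#' Simulate an in-silico knockout decoy experiment
#'
#' Builds the validation design for reference curation: a reference of
#' true hydrogenase entries plus decoy entries whose proteins duplicate
#' background (non-hydrogenase) genes of the simulated genome, a wild-type
#' genome carrying both, its hydrogenase-free knockout, and reads
#' simulated from each at `foldCoverage`.
#'
#' Reads from the knockout recruit only to the decoy entries, which the
#' twofold curation rule then excludes while retaining every true entry.
#'
#' @param seed integer seed.
#' @param nPerCategory true entries per activity category (ignored when
#'   `db` is supplied).
#' @param proteinLength reference/decoy protein length(s) in residues.
#' @param nDecoys decoy entries planted in the reference.
#' @param genomeLength wild-type genome length (nt).
#' @param foldCoverage read fold coverage per dataset.
#' @param readLength read length (nt).
#' @param errorRate per-base substitution probability.
#' @param db optional existing [HydrogenaseDb-class] to curate instead of
#'   generating a fresh reference; decoys are then drawn against it.
#' @return list with `db` (true + decoy entries), `trueIds`, `decoyIds`,
#'   `genome`, `koGenome`, `wtReads`, `koReads`.
#' @export
simulateKnockoutExperiment <- function(seed,
                                       nPerCategory = 2L,
                                       proteinLength = 120L,
                                       nDecoys = 3L,
                                       genomeLength = 50000L,
                                       foldCoverage = 50,
                                       readLength = 100L,
                                       errorRate = 0.005,
                                       db = NULL) {
  if (is.null(db)) {
    ref <- simulateReferenceAndDecoys(nPerCategory, proteinLength,
                                      nDecoys = nDecoys, seed = seed)
    baseDb <- ref$db
    decoys <- ref$decoys
  } else {
    baseDb <- db
    decoys <- with_seed(seed, {
      out <- character()
      combined <- paste(as.character(dbProteins(baseDb, active = FALSE)),
                        collapse = "|")
      for (d in seq_len(nDecoys)) {
        ok <- FALSE
        for (try in 1:100) {
          cand <- .random_protein(proteinLength[1])
          if (!.shares_kmer(cand, combined, 8L)) { ok <- TRUE; break }
        }
        if (!ok) stop("could not draw a decoy free of 8-mer overlap")
        out[sprintf("decoy_%02d", d)] <- cand
        combined <- paste(combined, cand, sep = "|")
      }
      out
    })
  }
  trueIds <- entryIds(baseDb)
  decoyIds <- names(decoys)
  prot <- c(as.character(dbProteins(baseDb, active = FALSE)), decoys)
  meta <- data.frame(
    entry_id = names(prot),
    metal_class = c(as.character(dbMeta(baseDb)$metal_class),
                    rep_len(HYD_METAL_CLASSES, length(decoyIds))),
    activity_category = c(as.character(activityCategories(baseDb,
                                                          active = FALSE)),
                          rep_len(HYD_CATEGORIES, length(decoyIds))),
    source_label = c(rep("synthetic", length(trueIds)),
                     rep("synthetic decoy", length(decoyIds))))
  fullDb <- HydrogenaseDb(prot, meta,
                          versionTag = sprintf("synthetic-ko-seed-%d", seed))
  emb <- data.frame(entry_id = names(prot),
                    sequence = unname(prot),
                    type = c(rep("hydrogenase", length(trueIds)),
                             rep("background", length(decoyIds))))
  genome <- simulateGenome("wt_genome", genomeLength, emb, seed = seed + 1L)
  ko <- knockoutGenome(genome)
  wtReads <- simulateReads(genome, foldCoverage, readLength, errorRate,
                           seed = seed + 2L, idPrefix = "wt")
  koReads <- simulateReads(ko, foldCoverage, readLength, errorRate,
                           seed = seed + 3L, idPrefix = "ko")
  list(db = fullDb, trueIds = trueIds, decoyIds = decoyIds, genome = genome,
       koGenome = ko, wtReads = wtReads, koReads = koReads)
}

#' Simulate a competition-experiment CFU table
#'
#' Emulates serial-dilution plating of a two-strain (wild type vs mutant)
#' competition: per animal, the wild-type output abundance is log-normal
#' around `baseLog10Cfu` and the mutant is lower by the true competitive
#' index `ciTrue` with log10-normal animal-to-animal noise `sdLog10`. A
#' plating dilution is chosen per measurement so colony counts stay
#' countable, and the long-format table carries everything
#' [cfuPerGram()] needs.
#'
#' @param seed integer seed.
#' @param nAnimals number of animals.
#' @param ciTrue true competitive index (WT advantage, > 0).
#' @param sdLog10 per-animal sd of the log10 competitive index.
#' @param baseLog10Cfu mean log10 wild-type CFU/g.
#' @param inoculumCfu CFU of each strain in the (1:1) inoculum.
#' @param compartment compartment label for all rows.
#' @return `list(cfu = data.frame, inoculum = data.frame, ci_true)`.
#' @export
simulateCfuTable <- function(seed, nAnimals = 8L, ciTrue = 12,
                             sdLog10 = 0.4, baseLog10Cfu = 7,
                             inoculumCfu = 5e7, compartment = "colon") {
  with_seed(seed, {
    wt <- 10^stats::rnorm(nAnimals, baseLog10Cfu, 0.3)
    mut <- wt / ciTrue * 10^stats::rnorm(nAnimals, 0, sdLog10)
    long <- do.call(rbind, lapply(seq_len(nAnimals), function(a) {
      rows <- lapply(c(wt = wt[a], mut = mut[a]), function(cfu) {
        raw <- cfu * 0.1 * 0.1 / 1     # count at dilution 10^0
        expn <- max(0L, floor(log10(max(raw, 1))) - 2L)
        data.frame(colony_count = as.integer(round(raw / 10^expn)),
                   dilution_exponent = expn, plated_volume_ml = 0.1,
                   homogenate_volume_ml = 1, sample_mass_g = 0.1)
      })
      cbind(data.frame(animal_id = sprintf("m%02d", a),
                       compartment = compartment,
                       strain_label = c("wt", "mut")),
            do.call(rbind, rows))
    }))
    rownames(long) <- NULL
    list(cfu = long,
         inoculum = data.frame(strain_label = c("wt", "mut"),
                               cfu = c(inoculumCfu, inoculumCfu)),
         ci_true = ciTrue)
  })
}

#' Simulate a comparative-Ct qPCR table
#'
#' Control samples have target delta-Ct (target minus reference) around
#' `baseDeltaCt`; treated samples are shifted by `-log2(foldChange)` so
#' their expected fold change under the comparative-Ct method equals
#' `foldChange`.
#'
#' @param seed integer seed.
#' @param nPerGroup samples per group.
#' @param foldChange true expression fold change in the treated group.
#' @param baseDeltaCt mean control delta-Ct.
#' @param sdCt technical sd on each Ct value.
#' @return data.frame with `sample_id`, `group`, `target_ct`,
#'   `reference_ct`.
#' @export
simulateQpcrTable <- function(seed, nPerGroup = 6L, foldChange = 8,
                              baseDeltaCt = 8, sdCt = 0.15) {
  with_seed(seed, {
    n <- 2L * nPerGroup
    grp <- rep(c("control", "treated"), each = nPerGroup)
    dct <- baseDeltaCt - ifelse(grp == "treated", log2(foldChange), 0) +
      stats::rnorm(n, 0, sdCt)
    ref <- stats::rnorm(n, 18, 0.3)
    data.frame(sample_id = sprintf("q%02d", seq_len(n)), group = grp,
               target_ct = ref + dct, reference_ct = ref)
  })
}
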