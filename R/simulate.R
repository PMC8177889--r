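# Synthetic-data generators. Every generator takes an explicit seed and is
# bit-reproducible under it; the caller's RNG state is left untouched.

.codon_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc), unname(gc))
    }
    cache
  }
})

.random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.random_protein <- function(n) {
  paste0(sample(setdiff(.AA_ALPHABET, "X"), n, replace = TRUE),
         collapse = "")
}

#' Reverse-translate a protein with random synonymous codons
#'
#' Each residue is encoded by a codon drawn uniformly from its synonymous
#' set under the standard genetic code, using the current RNG stream (wrap
#' in a seeded context for determinism). No stop codon is appended, so
#' translating the result reproduces the protein exactly.
#'
#' @param protein amino-acid string (20-letter alphabet).
#' @return nucleotide string of length `3 * nchar(protein)`.
#' @export
reverseTranslate <- function(protein) {
  tab <- .codon_table()
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(aas, function(a) {
    cs <- tab[[a]]
    if (is.null(cs)) stop("no codon for residue: ", a)
    cs[sample.int(length(cs), 1L)]
  }, character(1), USE.NAMES = FALSE)
  paste0(codons, collapse = "")
}

# does `a` share any exact k-residue substring with string `b`?
.shares_kmer <- function(a, b, k = 8L) {
  n <- nchar(a)
  if (n < k || nchar(b) < k) return(FALSE)
  kmers <- unique(substring(a, 1:(n - k + 1), k:n))
  any(vapply(kmers, function(x) grepl(x, b, fixed = TRUE), logical(1)))
}

#' Generate an activity-annotated reference plus decoy proteins
#'
#' Draws `5 * nPerCategory` random reference proteins (`nPerCategory` per
#' activity category) and `nDecoys` decoy proteins guaranteed to share no
#' exact substring of 8 or more residues with any reference entry
#' (bounded retries, then failure). Deterministic under `seed`.
#'
#' @param nPerCategory entries per activity category (>= 1).
#' @param proteinLength protein length(s) in residues (>= 50); a vector is
#'   recycled across the entries of each category, giving every category
#'   the same length profile.
#' @param nDecoys number of decoy proteins.
#' @param seed integer seed.
#' @param decoyLength decoy protein length (default: first
#'   `proteinLength`).
#' @return `list(db = HydrogenaseDb, decoys = named character vector)`.
#' @export
simulateReferenceAndDecoys <- function(nPerCategory, proteinLength,
                                       nDecoys = 0L, seed,
                                       decoyLength = proteinLength[1]) {
  stopifnot(nPerCategory >= 1L, all(proteinLength >= 50L))
  with_seed(seed, {
    lens <- rep_len(proteinLength, nPerCategory)
    ids <- character(); seqs <- character(); cats <- character()
    for (cat in HYD_CATEGORIES) {
      for (i in seq_len(nPerCategory)) {
        ids <- c(ids, sprintf("%s_%02d", cat, i))
        seqs <- c(seqs, .random_protein(lens[i]))
        cats <- c(cats, cat)
      }
    }
    names(seqs) <- ids
    db <- HydrogenaseDb(
      seqs,
      data.frame(entry_id = ids,
                 metal_class = rep_len(HYD_METAL_CLASSES, length(ids)),
                 activity_category = cats,
                 source_label = "synthetic"),
      versionTag = sprintf("synthetic-seed-%d", seed))
    decoys <- character()
    combined <- paste(seqs, collapse = "|")
    for (d in seq_len(nDecoys)) {
      ok <- FALSE
      for (try in 1:100) {
        cand <- .random_protein(decoyLength)
        if (!.shares_kmer(cand, combined, 8L)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not draw a decoy free of 8-mer overlap ",
                    "after bounded retries")
      decoys[sprintf("decoy_%02d", d)] <- cand
      combined <- paste(combined, cand, sep = "|")
    }
    list(db = db, decoys = decoys)
  })
}

#' Embed proteins in a random genome as reverse-translated CDS
#'
#' Each protein is placed once at a random non-overlapping position on a
#' random strand; the remaining background is random nucleotide sequence.
#' Placement retries are bounded, then failure.
#'
#' @param genomeId id for the genome.
#' @param backgroundLength genome length in nt (must be at least 3x the
#'   total embedded protein length).
#' @param proteins data.frame with columns `entry_id`, `sequence`
#'   (amino acids) and `type` (`"hydrogenase"` or `"background"`); may
#'   have zero rows.
#' @param seed integer seed.
#' @return A [SyntheticGenome-class].
#' @export
simulateGenome <- function(genomeId, backgroundLength, proteins, seed) {
  proteins <- as.data.frame(proteins)
  totalAA <- if (nrow(proteins)) sum(nchar(proteins$sequence)) else 0L
  if (backgroundLength < 3L * totalAA)
    stop("backgroundLength must be >= 3x total embedded protein length")
  with_seed(seed, {
    bg <- Biostrings::DNAString(.random_dna(backgroundLength))
    if (!nrow(proteins))
      return(SyntheticGenome(genomeId, bg))
    cds <- vapply(proteins$sequence, reverseTranslate, character(1),
                  USE.NAMES = FALSE)
    strands <- sample(c("+", "-"), nrow(proteins), replace = TRUE)
    ins <- ifelse(strands == "-",
                  as.character(Biostrings::reverseComplement(
                    Biostrings::DNAStringSet(cds))),
                  cds)
    lens <- nchar(ins)
    placed <- IRanges::IRanges()
    starts <- integer(nrow(proteins))
    for (i in seq_len(nrow(proteins))) {
      ok <- FALSE
      for (try in 1:500) {
        s <- sample.int(backgroundLength - lens[i] + 1L, 1L)
        cand <- IRanges::IRanges(s, s + lens[i] - 1L)
        if (!length(IRanges::findOverlaps(cand, placed))) {
          placed <- c(placed, cand); starts[i] <- s; ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place protein ", proteins$entry_id[i],
                    " without overlap after bounded retries")
    }
    seq <- Biostrings::replaceAt(
      bg, IRanges::IRanges(starts, width = lens),
      value = Biostrings::DNAStringSet(ins))
    feats <- GenomicRanges::GRanges(
      seqnames = genomeId,
      ranges = IRanges::IRanges(starts, width = lens),
      strand = strands,
      entry_id = as.character(proteins$entry_id),
      type = as.character(proteins$type))
    SyntheticGenome(genomeId, seq, sort(feats))
  })
}

# substitution-only error model: flip `rbinom(N, rate)` uniformly chosen
# bases to one of the three other bases. seqs must share one length.
.inject_errors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  w <- nchar(seqs[1])
  full <- paste0(seqs, collapse = "")
  N <- nchar(full)
  nerr <- stats::rbinom(1L, N, rate)
  if (nerr == 0L) return(seqs)
  raw <- charToRaw(full)
  idx <- sample.int(N, nerr)
  bases <- c("A", "C", "G", "T")
  cur <- match(rawToChar(raw[idx], multiple = TRUE), bases)
  shift <- sample.int(3L, nerr, replace = TRUE)
  raw[idx] <- charToRaw(paste0(bases[(cur - 1L + shift) %% 4L + 1L],
                               collapse = ""))
  full <- rawToChar(raw)
  substring(full, seq(1L, N, by = w), seq(w, N, by = w))
}

# overlap of mate intervals with genome features: best feature per mate
.mate_overlaps <- function(starts, readLength, genome) {
  f <- genomeFeatures(genome)
  out <- list(entry = rep(NA_character_, length(starts)),
              width = integer(length(starts)))
  if (!length(f)) return(out)
  q <- IRanges::IRanges(starts, width = readLength)
  hits <- IRanges::findOverlaps(q, IRanges::ranges(f))
  if (!length(hits)) return(out)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ow <- pmin(IRanges::end(q)[qh], GenomicRanges::end(f)[sh]) -
        pmax(IRanges::start(q)[qh], GenomicRanges::start(f)[sh]) + 1L
  o <- order(qh, -ow)
  first <- !duplicated(qh[o])
  qh <- qh[o][first]; sh <- sh[o][first]; ow <- ow[o][first]
  out$entry[qh] <- S4Vectors::mcols(f)$entry_id[sh]
  out$width[qh] <- ow
  out
}

# core pair sampler (uses current RNG stream)
.sample_pairs <- function(genome, nPairs, readLength, errorRate,
                          idPrefix = "p") {
  G <- as.character(genomeSeq(genome))
  L <- nchar(G)
  if (2L * readLength > L)
    stop("fragment (2x read length) longer than genome")
  if (nPairs == 0L)
    return(PairedReadSet(Biostrings::DNAStringSet(),
                         Biostrings::DNAStringSet()))
  pos <- sample.int(L - 2L * readLength + 1L, nPairs, replace = TRUE)
  m1 <- substring(G, pos, pos + readLength - 1L)
  f2 <- substring(G, pos + readLength, pos + 2L * readLength - 1L)
  both <- .inject_errors(c(m1, f2), errorRate)
  m1 <- Biostrings::DNAStringSet(both[seq_len(nPairs)])
  m2 <- Biostrings::reverseComplement(
    Biostrings::DNAStringSet(both[nPairs + seq_len(nPairs)]))
  names(m1) <- sprintf("%s%06d", idPrefix, seq_len(nPairs))
  ov1 <- .mate_overlaps(pos, readLength, genome)
  ov2 <- .mate_overlaps(pos + readLength, readLength, genome)
  truth <- S4Vectors::DataFrame(
    genome_id = genomeId(genome), frag_start = pos,
    entry1 = ov1$entry, overlap1 = ov1$width,
    entry2 = ov2$entry, overlap2 = ov2$width)
  PairedReadSet(m1, m2, truth = truth)
}

#' Simulate error-bearing paired-end reads from a genome
#'
#' Fragments of length `2 * readLength` are drawn uniformly over genome
#' positions (forward strand); mate 1 is the fragment's near end, mate 2
#' the reverse complement of its far end (abutting mates, no insert gap).
#' The number of pairs is `round(foldCoverage * genomeLength /
#' (2 * readLength))`. Substitution errors are applied per base at
#' `errorRate`; qualities are flat Q40. The truth table records, per
#' mate, the CDS feature overlapped by at least 1 nt (if any) and the
#' overlap width.
#'
#' @param genome a [SyntheticGenome-class].
#' @param foldCoverage target fold coverage (> 0).
#' @param readLength read length in nt (default 100).
#' @param errorRate per-base substitution probability.
#' @param seed integer seed.
#' @param idPrefix prefix for pair ids.
#' @return A [PairedReadSet-class] with truth.
#' @export
simulateReads <- function(genome, foldCoverage, readLength = 100L,
                          errorRate = 0, seed, idPrefix = "p") {
  stopifnot(foldCoverage > 0)
  nPairs <- as.integer(round(foldCoverage * length(genome) /
                             (2 * readLength)))
  with_seed(seed,
    .sample_pairs(genome, nPairs, as.integer(readLength), errorRate,
                  idPrefix))
}

#' Describe a two-group community design
#'
#' @param abundances numeric matrix (genomes x 2 groups) of per-group
#'   relative abundances; rownames are genome ids, colnames the two group
#'   labels. Each column must sum to 1 (tolerance 1e-9).
#' @param samplesPerGroup samples per condition group.
#' @param readPairsPerSample read pairs per sample.
#' @param readLength read length in nt.
#' @param errorRate per-base substitution probability (in [0, 0.1)).
#' @param hostFraction fraction of read pairs drawn from the host genome
#'   (in [0, 1)).
#' @param seed integer seed.
#' @return a validated `CommunityDesign` list.
#' @export
communityDesign <- function(abundances, samplesPerGroup,
                            readPairsPerSample, readLength = 100L,
                            errorRate = 0.005, hostFraction = 0.05,
                            seed = 1L) {
  abundances <- as.matrix(abundances)
  if (ncol(abundances) != 2L) stop("exactly two condition groups required")
  if (is.null(rownames(abundances)) || is.null(colnames(abundances)))
    stop("abundances needs genome ids as rownames and group labels as colnames")
  if (any(abs(colSums(abundances) - 1) > 1e-9))
    stop("per-group abundances must each sum to 1")
  if (errorRate < 0 || errorRate >= 0.1) stop("errorRate must be in [0, 0.1)")
  if (hostFraction < 0 || hostFraction >= 1)
    stop("hostFraction must be in [0, 1)")
  structure(list(abundances = abundances,
                 groups = colnames(abundances),
                 samplesPerGroup = as.integer(samplesPerGroup),
                 readPairsPerSample = as.integer(readPairsPerSample),
                 readLength = as.integer(readLength),
                 errorRate = errorRate, hostFraction = hostFraction,
                 seed = as.integer(seed)),
            class = "CommunityDesign")
}

#' Simulate condition-stratified community samples
#'
#' For every sample, the number of host pairs is binomial
#' (`hostFraction`), and the remaining pairs are split across member
#' genomes by a multinomial draw with that group's abundances. Sample ids
#' carry their group label (`<group>_s<i>`). When `db` is given, the
#' truth summary also reports the expected per-category fraction of
#' hydrogenase-overlapping mates per group (computed from abundances and
#' per-feature overlap windows, ignoring genome-edge effects).
#'
#' @param design a [communityDesign()] object.
#' @param genomes list of [SyntheticGenome-class] for the community
#'   members (matched to `rownames(design$abundances)` by genome id).
#' @param hostGenome the host [SyntheticGenome-class].
#' @param db optional [HydrogenaseDb-class] used to map entries to
#'   activity categories in the truth summary.
#' @return `list(samples = named list of PairedReadSet, groups = named
#'   character vector sample -> group, expected = data.frame(group,
#'   category, expected_fraction) or NULL)`.
#' @export
simulateConditionSamples <- function(design, genomes, hostGenome,
                                     db = NULL) {
  stopifnot(inherits(design, "CommunityDesign"))
  gids <- vapply(genomes, genomeId, character(1))
  names(genomes) <- gids
  want <- rownames(design$abundances)
  missing <- setdiff(want, gids)
  if (length(missing))
    stop("unresolved genome id(s): ", paste(missing, collapse = ", "))
  samples <- list(); groups <- character()
  with_seed(design$seed, {
    for (g in design$groups) {
      ab <- design$abundances[, g]
      for (s in seq_len(design$samplesPerGroup)) {
        sid <- sprintf("%s_s%d", g, s)
        nHost <- stats::rbinom(1L, design$readPairsPerSample,
                               design$hostFraction)
        nMem <- stats::rmultinom(1L, design$readPairsPerSample - nHost,
                                 ab)[, 1]
        parts <- list()
        for (m in seq_along(want)) {
          if (nMem[m] == 0L) next
          parts[[length(parts) + 1L]] <-
            .sample_pairs(genomes[[want[m]]], nMem[m], design$readLength,
                          design$errorRate,
                          idPrefix = sprintf("%s_g%d_", sid, m))
        }
        if (nHost > 0L)
          parts[[length(parts) + 1L]] <-
            .sample_pairs(hostGenome, nHost, design$readLength,
                          design$errorRate,
                          idPrefix = sprintf("%s_host_", sid))
        samples[[sid]] <- .concat_readsets(parts)
        groups[sid] <- g
      }
    }
  })
  expected <- if (!is.null(db))
    .expected_category_fractions(design, genomes[want], db)
  list(samples = samples, groups = groups, expected = expected)
}

.concat_readsets <- function(parts) {
  if (length(parts) == 1L) return(parts[[1]])
  PairedReadSet(
    do.call(c, lapply(parts, mate1)),
    do.call(c, lapply(parts, mate2)),
    unlist(lapply(parts, qualities1), use.names = FALSE),
    unlist(lapply(parts, qualities2), use.names = FALSE),
    do.call(rbind, lapply(parts, readTruth)))
}

.expected_category_fractions <- function(design, genomes, db) {
  cats <- activityCategories(db, active = FALSE)
  R <- design$readLength
  rows <- list()
  for (g in design$groups) {
    wt <- stats::setNames(numeric(length(HYD_CATEGORIES)), HYD_CATEGORIES)
    for (m in names(genomes)) {
      f <- genomeFeatures(genomes[[m]])
      f <- f[S4Vectors::mcols(f)$type == "hydrogenase"]
      if (!length(f)) next
      nPos <- length(genomes[[m]]) - 2L * R + 1L
      win <- 2 * (GenomicRanges::width(f) + R - 1) / nPos
      cc <- cats[S4Vectors::mcols(f)$entry_id]
      for (k in seq_along(f))
        wt[cc[k]] <- wt[cc[k]] + design$abundances[m, g] * win[k]
    }
    frac <- if (sum(wt) > 0) wt / sum(wt) else wt
    rows[[g]] <- data.frame(group = g, category = names(frac),
                            expected_fraction = unname(frac))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
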