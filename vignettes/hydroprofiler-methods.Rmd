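---
title: "Methods: hydrogenase activity profiling and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrogenase activity profiling and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Molecular hydrogen is a central currency of anaerobic gut metabolism.
Hydrogenases — the enzymes that oxidize or produce H2 — fall into five
activity classes predictable from primary sequence: **uptake** (H2
oxidation feeding respiration), **evolving**, **bidirectional**,
**bifurcating**, and **sensory**. Shifts between these classes in a gut
metagenome are informative about the redox state of the community: an
enrichment of uptake hydrogenases points at respiratory H2 consumption,
a hallmark of the inflamed gut where Enterobacteriaceae expand.

`hydroprofiler` quantifies these classes in shotgun metagenomes and
compares them between two host conditions, and provides the fitness
statistics (competitive index, limit-of-detection handling,
comparative-Ct expression) used in the accompanying style of
gnotobiotic competition experiments.

## The analysis chain

1. **Quality filter** (`qualityFilter`): a read pair is kept when both
   mates have mean Phred quality ≥ 20 and length ≥ 50 nt. The pair is
   the unit of filtering; a single failing mate drops both.
2. **Host decontamination** (`filterHostReads`): exact, canonicalized
   k-mer matching (default k = 25, one shared k-mer suffices) against
   the host genome. At 0.5% sequencing error virtually every host mate
   retains at least one clean 25-mer, so >99% of host pairs are removed
   while random 25-mer collisions with non-host reads are essentially
   impossible.
3. **Translated search** (`searchReads`): each mate is translated in
   all six frames; exact 4-aa seeds against the active reference
   entries anchor candidate diagonals; each seeded diagonal is scanned
   exhaustively for its maximum-scoring ungapped segment under BLOSUM62
   (stops score the matrix minimum, so reported alignments never cross
   a stop). Significance uses ungapped Karlin–Altschul statistics
   (lambda = 0.318, K = 0.13; bit = (lambda·raw − ln K)/ln 2; e-value =
   search-space · 2^−bit with search space = total active reference
   residues × translated query residues). A mate reports at most one
   hit — the best raw score, ties broken to the lexicographically
   smallest entry id — and only when e-value ≤ 0.001. Mates are
   searched as independent single-end queries, matching read-level
   counting downstream.
4. **Reference curation** (`curateDb`): see below.
5. **Profiling** (`buildHitTable`, `normalizeHitTable`,
   `aggregateCategories`): per-sample entry counts are divided by the
   sample's total hydrogenase-mapped reads and summed within activity
   categories.
6. **Group comparison** (`compareGroups`): for each category, the two
   groups' vectors of per-entry average normalized abundances (the
   plotted unit: one point per reference sequence) are compared with a
   Mann–Whitney U test; per-entry averages exactly equal to zero are
   replaced by a pseudo-value before testing (presets 0.05 for
   murine-scale data and 0.0005 for deeper human-scale data); p-values
   are Bonferroni-corrected across the testable categories.

### Design choices in the search

*Full-diagonal scan instead of X-drop.* Translated 100-bp mates are at
most 33 aa, so scanning the entire seeded diagonal costs the same as an
X-drop pass while guaranteeing the reported score is the true optimum
on that diagonal. This makes the aligner exactly checkable against a
brute-force oracle whenever the optimal diagonal contains a seed, which
is always the case for reads genuinely derived from a reference protein
(≤ 2 aa of divergence over a 20-aa window forces an exact run of ≥ 6
aa). For biologically unrelated sequence the optimal segment may lack a
4-aa seed, but such segments score far below the reporting threshold
(raw ≈ 55–60 at desk-scale search spaces), so seeding never changes
what is reported.

*Gapless, single-hit seeding.* 33-residue queries essentially never
benefit from gapped extension, and gapless scoring keeps the
statistics in the well-characterized ungapped Karlin–Altschul regime.

## Decoy curation: the in-silico knockout rule

Reference databases can contain entries that recruit reads from
non-hydrogenase sequence (mis-annotations, or genes with high local
homology to common genomic background). The curation procedure
simulates reads from genomes that carry hydrogenases (wild type) and
from the same genomes with every hydrogenase CDS excised (knockout),
maps both against the reference, and computes per-entry relative
abundances **over each dataset's hydrogenase-mapped total**. An entry
is excluded when its knockout relative abundance is **≥ 2×** its
wild-type relative abundance.

Two readings were possible for both the normalization (hydrogenase
totals vs. all sequenced reads) and the boundary (strict vs.
inclusive); the hydrogenase-total normalization makes the rule
sequencing-depth-invariant (a tested property) and the inclusive
boundary follows the operative removal wording. Both are parameters
(`foldThreshold`; counts are supplied by the caller).

Zero conventions: reads only in the knockout dataset → excluded (that
is precisely the failure mode targeted); reads in neither → retained
(the entry is merely untested).

## The rank statistic

`mannWhitneyU` computes U from rank sums with average ranks for ties.
For n + m ≤ 16 the two-sided p is exact by enumeration of all
`choose(n+m, n)` labelings — the correct conditional null under ties,
where classical exact tables do not apply — and is verified in the test
suite against an independent pair-counting enumeration oracle. Larger
samples use the normal approximation with tie and continuity
correction. The worked example x = (1,2,3), y = (4,5,6) gives U = 0 and
exact p = 2/20 = 0.1.

Bonferroni correction uses m = number of testable categories (≤ 5);
categories with no active entries are reported untestable and do not
count toward m.

## What the synthetic generator emulates

The generator produces every input the pipeline consumes, seeded and
bit-reproducible:

* random reference proteins per category, plus decoys guaranteed to
  share no ≥ 8-residue substring with any entry;
* genomes embedding reverse-translated CDS (uniform synonymous codons,
  avoiding artificial codon signatures) at random non-overlapping
  positions and strands, with knockout variants excising exactly the
  annotated intervals;
* paired-end reads: fragments uniform over positions, abutting
  100-nt mates (mate 2 reverse-complemented), substitution-only errors
  at a uniform rate, flat Q40 qualities, and a per-mate ground-truth
  map of overlapped CDS features;
* two-condition communities with per-group member abundances, binomial
  host contamination, and multinomial allocation of pairs to members;
* serial-dilution CFU tables with log-normal strain abundances and a
  countable plating dilution per measurement, and comparative-Ct qPCR
  tables with a planted fold change.

It deliberately does **not** model indels, quality decay, GC bias, PCR
duplicates, insert-size variation, real codon usage, or real protein
families. Passing tests therefore demonstrate that the chain is
correct and well-calibrated under a clean substitution-error model —
not that it matches any particular real instrument or that remote
homologs are handled; with a real reference database, paralogy between
entries (absent here by construction) would make read assignment
ambiguous in ways these fixtures do not probe.

## Study-scale fixtures and their power analysis

Two fixture designs are frozen as defaults and used by the acceptance
checks (`scripts/acceptance.R`) and the end-to-end tests:

**Knockout validation** (`simulateKnockoutExperiment`): 10 true
entries (2 per category, 120 aa) plus 3 decoy entries duplicating
background genes of a 50-kb genome; 50× coverage, 0.5% error. Expected
behavior: decoys recruit comparably in both datasets but dominate the
knockout's hydrogenase-mapped total (the true entries recruit nothing
there), so their enrichment ratio is ≈ 4–5 and they are excluded, while
true entries sit at ratio ≈ 0 and are retained.

**Planted enrichment** (`simulateStudy`): 6 entries per category with
protein lengths 80–400 aa, one 20-kb carrier genome per category, 6 + 6
samples of 20,000 pairs, 5% host contamination, 0.5% error; the uptake
carrier has relative abundance 0.10 in the control group and 0.40 in
the inflamed group (the other four carriers share the remainder
equally). Because all carriers have identical length and CDS profiles,
the expected uptake fraction of hydrogenase-mapped reads differs by
exactly 4×.

The length spread is the deliberate part. Abundance fractions are
compositional: raising uptake 4× depresses every other category's
normalized fraction by ≈ 1.5× (0.667×). The rank test compares the two
groups' per-entry averages, so a category is flagged only when the
between-group shift exceeds the within-category spread of entry
abundances. With a ~3.5× length spread, the 4× uptake shift separates
the twelve per-entry averages completely (U = 36/36, exact
p·5 ≈ 0.011 < 0.05) while the 1.5× compositional leakage stays
rank-interleaved (U ≈ 26/36, p ≈ 0.19 before correction). Counts per
entry per sample are in the hundreds, so Poisson noise (~3%) cannot
bridge the ≥ 4% gaps between adjacent rank values. These sizes were
fixed by this analysis before the fixtures were run; they keep one
study replicate under ~20 s on one CPU, and the acceptance checks use
20 replicates.

## Fitness analytics

* `cfuPerGram`: colony count × 10^dilution / plated volume ×
  homogenate volume / sample mass.
* `applyLod`: values below 10 CFU/g (including zero) become 10 CFU/g,
  **before** any ratio is taken, which is what makes the competitive
  index well defined for non-colonized animals.
* `competitiveIndex`: (WT/mutant) output ÷ (WT/mutant) inoculum;
  values > 1 read as a wild-type advantage (a CI of 12 means the wild
  type outcompeted the mutant 12-fold).
* `geometricMeanCI`: t-based 95% interval of the log-mean,
  back-transformed. On log-normal cohorts this has exactly nominal
  coverage; the acceptance check verifies ≈ 95% over 200 simulated
  cohorts (8 animals, true CI 12, σ_log10 = 0.4).
* `pairedLogTTest`: `t.test` on paired log differences. A zero-variance
  difference vector is reported with an explicit `degenerate` flag
  (p = 1 for identical vectors, p = 0 for a constant non-zero ratio)
  instead of an arbitrary finite p.
* `relativeExpressionDdct`: fold = 2^−ΔΔCt with ΔCt = target −
  reference and the baseline at the control-group mean ΔCt.

## Numerical and interface conventions

* Genome features use Bioconductor `GRanges` (1-based, closed)
  internally; BED output through `rtracklayer` is 0-based half-open as
  the format requires.
* All generators take an explicit seed and restore the caller's RNG
  state; composite experiments derive stage seeds by fixed small
  offsets, so stages are independently reproducible.
* Zero-total samples stay all-zero after normalization and are
  flagged, never silently dropped.
* The exclusion boundary (≥ 2), pseudo-values, LOD value, e-value
  cutoff and k-mer parameters are all exposed as arguments with the
  defaults stated above.

## Known limitations

* Classification quality is taken from the reference metadata; there
  is no sequence-based re-classification of hydrogenase subgroups.
* The aligner is deliberately not a DIAMOND reimplementation: no
  gapped or frameshift-aware alignment, no double indexing, and its
  scores/e-values are calibrated but not numerically identical to any
  external tool. The e-value cutoff is the contract.
* Paired mates are counted separately (two potential hits per
  fragment); fragment-level counting would halve counts uniformly and
  leave all normalized quantities unchanged.
* The count-model (DESeq2-style) category test and taxonomic binning
  are out of scope; the implemented statistic is the per-entry
  rank-test chain described above.
* Real-accession reproduction (public murine/human datasets against a
  real HydDB export) requires large downloads and a database version
  that is not pinned; the profile stage accepts such inputs through
  the same FASTA/TSV/FASTQ interfaces but no result from them is
  claimed here.
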