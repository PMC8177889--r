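# Small end-to-end demo: a simulated two-condition study with decoy
# curation and simulated fitness tables. Keys inside `simulate` follow
# the arguments of simulateStudy().
seed: 1
output_dir: hydroprofiler_demo_out
simulate:
  nPerCategory: 2
  proteinLengths: [60, 90]
  genomeLength: 4000
  samplesPerGroup: 2
  readPairsPerSample: 1500
  errorRate: 0.005
  hostFraction: 0.1
  uptakeFoldChange: 4
  uptakeAbundance: 0.1
search:
  seed_length: 4
  evalue_cutoff: 0.001
filter:
  min_mean_quality: 20
  min_length: 50
  kmer_length: 25
  min_shared_kmers: 1
curate:
  enabled: true
  n_decoys: 2
  decoy_length: 80
  genome_length: 12000
  fold_coverage: 30
  fold_threshold: 2
profile:
  pseudo_value: 0.05
fitness:
  simulate: true
  n_animals: 8
  ci_true: 12
  fold_change: 8
  lod_value: 10
  control_group: control
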