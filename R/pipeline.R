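# End-to-end orchestration: simulate (optional) -> quality/host filter ->
# translated search -> decoy curation (optional) -> category profiling ->
# fitness analytics (optional), with a checksummed output manifest.

#' Read a pipeline configuration file
#'
#' YAML with an explicit `seed` field; see
#' `system.file("extdata", "demo_config.yaml", package = "hydroprofiler")`
#' for a complete simulated-study example.
#'
#' @param file path to the YAML config.
#' @return the configuration list.
#' @export
readPipelineConfig <- function(file) {
  if (!file.exists(file)) stop("config file does not exist: ", file)
  yaml::read_yaml(file)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.cfg <- function(x, name, default = NULL) {
  if (is.null(x[[name]])) default else x[[name]]
}

#' Run the profiling pipeline end to end
#'
#' Stages: simulate (when the config has a `simulate` block; otherwise
#' reference FASTA/TSV and paired FASTQ samples are read from the
#' configured paths), quality and host filtering, translated search,
#' decoy curation (optional), category profiling with the group
#' comparison, and fitness analytics (optional). All outputs are written
#' under the output directory and listed, with MD5 checksums, in
#' `manifest.json`; identical config and seed reproduce identical
#' checksums. A stage failure aborts with the stage name and leaves a
#' `FAILED` marker next to any partial outputs.
#'
#' @param config path to a YAML config or an equivalent list.
#' @param seed optional seed overriding the config's.
#' @param outDir optional output directory overriding the config's.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config, seed = NULL, outDir = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  seed <- as.integer(if (!is.null(seed)) seed else .cfg(config, "seed", 1L))
  outDir <- if (!is.null(outDir)) outDir
            else .cfg(config, "output_dir", "hydroprofiler_out")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  failed <- file.path(outDir, "FAILED")
  if (file.exists(failed)) unlink(failed)
  on.exit(if (is.null(manifest)) writeLines("pipeline failed", failed))
  manifest <- NULL
  outputs <- character()
  emit <- function(path) outputs <<- c(outputs, path)

  sr <- .cfg(config, "search", list())
  params <- searchParams(
    seedLength = .cfg(sr, "seed_length", 4L),
    evalueCutoff = .cfg(sr, "evalue_cutoff", 0.001))
  filt <- .cfg(config, "filter", list())

  # ---- inputs: simulate or load -------------------------------------
  if (!is.null(config$simulate)) {
    sim <- .stage("simulate", {
      sc <- config$simulate
      do.call(simulateStudy, c(list(seed = seed),
        sc[intersect(names(sc),
                     setdiff(names(formals(simulateStudy)), "seed"))]))
    })
    db <- sim$db
    samples <- sim$samples
    groups <- sim$groups
    host <- sim$host
    .stage("simulate", {
      writeHydrogenaseDb(db, file.path(outDir, "reference.fasta"),
                         file.path(outDir, "reference.tsv"))
      emit(file.path(outDir, "reference.fasta"))
      emit(file.path(outDir, "reference.tsv"))
    })
  } else {
    db <- .stage("load_reference", {
      ref <- config$reference
      if (is.null(ref$fasta) || !file.exists(ref$fasta))
        stop("reference fasta path missing or does not exist: ",
             if (is.null(ref$fasta)) "<unset>" else ref$fasta)
      if (is.null(ref$metadata) || !file.exists(ref$metadata))
        stop("reference metadata path missing or does not exist: ",
             if (is.null(ref$metadata)) "<unset>" else ref$metadata)
      d <- readHydrogenaseDb(ref$fasta, ref$metadata)
      if (!is.null(ref$exclusions))
        d <- applyExclusions(d, readExclusionList(ref$exclusions))
      d
    })
    samples <- .stage("load_reads", {
      lapply(config$samples, readPairedFastq)
    })
    groups <- .stage("load_reads", {
      g <- utils::read.delim(config$groups_file, stringsAsFactors = FALSE)
      stats::setNames(g[[2]], g[[1]])
    })
    host <- if (!is.null(config$host_fasta))
      .stage("load_reads", readGenome(config$host_fasta)) else NULL
    sim <- NULL
  }

  # ---- decoy curation -----------------------------------------------
  cur <- .cfg(config, "curate", list())
  if (isTRUE(cur$enabled)) {
    curated <- .stage("curate", {
      ko <- simulateKnockoutExperiment(
        seed + 500L, db = db,
        nDecoys = .cfg(cur, "n_decoys", 3L),
        proteinLength = .cfg(cur, "decoy_length", 120L),
        genomeLength = .cfg(cur, "genome_length", 50000L),
        foldCoverage = .cfg(cur, "fold_coverage", 50),
        errorRate = .cfg(cur, "error_rate", 0.005))
      wtHits <- searchReads(ko$wtReads, ko$db, params)
      koHits <- searchReads(ko$koReads, ko$db, params)
      curateDb(countHits(wtHits), countHits(koHits), ko$db,
               foldThreshold = .cfg(cur, "fold_threshold", 2))
    })
    .stage("curate", {
      writeCurationReport(curated$report,
                          file.path(outDir, "curation_report.tsv"))
      writeExclusionList(excludedIds(curated$db),
                         file.path(outDir, "exclusions.txt"))
      emit(file.path(outDir, "curation_report.tsv"))
      emit(file.path(outDir, "exclusions.txt"))
    })
    db <- applyExclusions(db, intersect(excludedIds(curated$db),
                                        entryIds(db)))
  }

  # ---- filter + search ----------------------------------------------
  counts <- .stage("search", {
    out <- list()
    for (sid in names(samples)) {
      rs <- qualityFilter(samples[[sid]],
                          .cfg(filt, "min_mean_quality", 20),
                          .cfg(filt, "min_length", 50L))
      if (!is.null(host))
        rs <- filterHostReads(rs, host,
                              .cfg(filt, "kmer_length", 25L),
                              .cfg(filt, "min_shared_kmers", 1L))
      hits <- searchReads(rs, db, params)
      writeHits(hits, file.path(outDir, paste0("hits_", sid, ".tsv")))
      emit(file.path(outDir, paste0("hits_", sid, ".tsv")))
      out[[sid]] <- countHits(hits)
    }
    out
  })

  # ---- profile -------------------------------------------------------
  comparison <- .stage("profile", {
    se <- buildHitTable(counts, groups, entryIds = activeIds(db))
    se <- normalizeHitTable(se)
    catse <- aggregateCategories(se, db)
    cmp <- compareGroups(se, db,
                         pseudoValue = .cfg(.cfg(config, "profile", list()),
                                            "pseudo_value", 0.05))
    writeHitTable(se, file.path(outDir, "hit_table.tsv"))
    writeCategoryProfile(catse, file.path(outDir, "category_profile.tsv"))
    writeComparison(cmp, file.path(outDir, "group_comparison.tsv"))
    writeComparison(cmp, file.path(outDir, "group_comparison.json"))
    emit(file.path(outDir, "hit_table.tsv"))
    emit(file.path(outDir, "category_profile.tsv"))
    emit(file.path(outDir, "group_comparison.tsv"))
    emit(file.path(outDir, "group_comparison.json"))
    cmp
  })

  # ---- fitness (optional) --------------------------------------------
  fit <- .cfg(config, "fitness", list())
  if (length(fit)) {
    .stage("fitness", {
      if (isTRUE(fit$simulate)) {
        sim_cfu <- simulateCfuTable(seed + 900L,
                                    nAnimals = .cfg(fit, "n_animals", 8L),
                                    ciTrue = .cfg(fit, "ci_true", 12))
        cfu <- sim_cfu$cfu; inoc <- sim_cfu$inoculum
        qpcr <- simulateQpcrTable(seed + 901L,
                                  foldChange = .cfg(fit, "fold_change", 8))
      } else {
        cfu <- utils::read.delim(fit$cfu_table, stringsAsFactors = FALSE)
        inoc <- utils::read.delim(fit$inoculum_table,
                                  stringsAsFactors = FALSE)
        qpcr <- if (!is.null(fit$qpcr_table))
          utils::read.delim(fit$qpcr_table, stringsAsFactors = FALSE)
          else NULL
      }
      cs <- competitionSummary(cfu, inoc,
                               lodValue = .cfg(fit, "lod_value", 10))
      utils::write.table(cs$perAnimal,
                         file.path(outDir, "competitive_index.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cs$summary,
                         file.path(outDir, "competition_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit(file.path(outDir, "competitive_index.tsv"))
      emit(file.path(outDir, "competition_summary.tsv"))
      if (!is.null(qpcr)) {
        dd <- relativeExpressionDdct(qpcr,
                                     .cfg(fit, "control_group", "control"))
        utils::write.table(dd, file.path(outDir, "qpcr_fold_change.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        emit(file.path(outDir, "qpcr_fold_change.tsv"))
      }
    })
  }

  manifest <- list(
    seed = seed,
    outputs = data.frame(
      path = basename(outputs),
      md5 = unname(tools::md5sum(outputs))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(manifest)
}
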