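# Pipeline orchestration: a strict YAML RunConfig, stage execution in
# dependency order, and a manifest with per-output md5 checksums so
# identical configs + inputs yield identical, verifiable runs.

.defaultConfig <- function() {
  list(
    seed = 1L,
    out_dir = "beeprofiler_run",
    stages = list(simulate = TRUE, profile = TRUE, ani = TRUE,
                  community = TRUE, supermatrix = TRUE),
    thresholds = list(ani_threshold = 95, gap_fraction = 0.5,
                      min_reads = 5000, other_threshold = 0.01),
    inputs = list(rules = NULL, annotations = NULL, genomes = NULL,
                  asv_counts = NULL, asv_taxonomy = NULL,
                  sample_metadata = NULL, orthogroups = NULL,
                  alignment_dir = NULL),
    simulate = list(n_genomes = 4L, genome_length = 20000L,
                    divergence = 0.05, n_pathways = 8L, n_species = 3L,
                    samples_per_species = 4L, group_effect = 1,
                    n_orthogroups = 10L, gap_rate = 0.2))
}

.mergeStrict <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!(key %in% names(base)))
      configError("unknown config key '%s'", full)
    if (is.list(base[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]]))
        configError("config key '%s' must be a mapping", full)
      base[[key]] <- .mergeStrict(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Read and validate a pipeline run configuration
#'
#' The configuration is YAML with top-level keys `seed`, `out_dir`,
#' `stages` (logical toggles: simulate, profile, ani, community,
#' supermatrix), `thresholds` (`ani_threshold`, `gap_fraction`,
#' `min_reads`, `other_threshold`), `inputs` (paths, required per enabled
#' stage unless the simulate stage generates them) and `simulate`
#' (generator sizes). Unknown keys are rejected; thresholds are range
#' checked.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return validated config list (class `beeRunConfig`).
#' @export
readRunConfig <- function(path) {
  user <- if (is.list(path)) path
          else if (file.exists(path)) yaml::read_yaml(path)
          else configError("config file '%s' not found", path)
  cfg <- .mergeStrict(.defaultConfig(), user)
  th <- cfg$thresholds
  if (th$ani_threshold < 0 || th$ani_threshold > 100)
    configError("ani_threshold must lie in [0, 100]")
  if (th$gap_fraction < 0 || th$gap_fraction > 1)
    configError("gap_fraction must lie in [0, 1]")
  if (th$min_reads < 0) configError("min_reads must be nonnegative")
  if (th$other_threshold < 0 || th$other_threshold > 1)
    configError("other_threshold must lie in [0, 1]")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    configError("seed must be a single integer")
  structure(cfg, class = c("beeRunConfig", "list"))
}

.requireInput <- function(cfg, key, stage) {
  p <- cfg$inputs[[key]]
  if (is.null(p))
    configError("stage '%s' is enabled but input '%s' is not set",
                stage, key)
  if (!file.exists(p))
    configError("stage '%s': input '%s' (%s) does not exist",
                stage, key, p)
  p
}

#' Run the full profiling pipeline from a configuration
#'
#' Executes the enabled stages in dependency order — simulate, profile,
#' ani, community, supermatrix — writing every stage output under
#' `out_dir` and returning a manifest. When the simulate stage is enabled
#' it generates all inputs the later stages need (seeded, so two runs with
#' the same config give byte-identical outputs); otherwise the
#' corresponding `inputs` paths must be set. Configuration problems abort
#' before any stage executes; a failure inside a stage aborts with the
#' failing stage named.
#'
#' @param config a YAML path or config list (see [readRunConfig()]).
#' @return the run manifest (class `beeRunManifest`): the config, a config
#'   checksum, per-stage status and per-output md5 checksums.
#' @export
runPipeline <- function(config) {
  cfg <- readRunConfig(config)
  outDir <- cfg$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  st <- cfg$stages

  # ---- pre-flight: validate inputs for all enabled stages ----
  if (!st$simulate) {
    if (st$profile) {
      .requireInput(cfg, "rules", "profile")
      .requireInput(cfg, "annotations", "profile")
    }
    if (st$ani) .requireInput(cfg, "genomes", "ani")
    if (st$community) {
      .requireInput(cfg, "asv_counts", "community")
      .requireInput(cfg, "asv_taxonomy", "community")
      .requireInput(cfg, "sample_metadata", "community")
    }
    if (st$supermatrix) {
      .requireInput(cfg, "orthogroups", "supermatrix")
      .requireInput(cfg, "alignment_dir", "supermatrix")
    }
  } else if (st$profile && !is.null(cfg$inputs$rules) &&
             !file.exists(cfg$inputs$rules)) {
    configError("stage 'profile': rule file '%s' does not exist",
                cfg$inputs$rules)
  }

  manifest <- list(config = unclass(cfg),
                   configChecksum = .configChecksum(cfg),
                   stages = list(), outputs = character(0L))
  addOutputs <- function(paths) {
    manifest$outputs <<- c(manifest$outputs,
                           tools::md5sum(normalizePath(paths)))
  }
  runStage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    paths <- tryCatch(fun(), error = function(e) stageError(name, e))
    addOutputs(paths)
    manifest$stages[[name]] <<- list(
      status = "ok", outputs = basename(paths),
      wallTimeSec = round(proc.time()[["elapsed"]] - t0, 3))
  }
  seed <- as.integer(cfg$seed)
  sim <- cfg$simulate
  paths <- list(
    rules = cfg$inputs$rules, annotations = cfg$inputs$annotations,
    genomes = cfg$inputs$genomes, asvDir = NULL,
    orthogroups = cfg$inputs$orthogroups,
    alnDir = cfg$inputs$alignment_dir)

  if (st$simulate) runStage("simulate", function() {
    simDir <- file.path(outDir, "simulated")
    dir.create(simDir, showWarnings = FALSE)
    out <- character(0L)
    if (is.null(paths$rules)) {
      # disjoint-KO-pool rules so any planted step count is constructible
      paths$rules <<- file.path(simDir, "pathway_rules.yaml")
      writeRules(simulateRules(sim$n_pathways, seed = seed), paths$rules)
      out <- c(out, paths$rules)
    }
    rules <- parseRules(paths$rules)
    nSteps <- vapply(rules, function(r) length(r@steps), integer(1L))
    planted <- withSeed(forkSeed(seed, "plant"), {
      m <- matrix(0, sim$n_genomes, length(rules))
      for (p in seq_along(rules))
        m[, p] <- sample.int(nSteps[p] + 1L, sim$n_genomes,
                             replace = TRUE) - 1L
      sweep(m, 2L, nSteps, "/")
    })
    ann <- simulateAnnotations(rules, planted, seed = seed)
    paths$annotations <<- file.path(simDir, "ko_annotations.tsv")
    writeKoAnnotations(ann, paths$annotations)
    out <- c(out, paths$annotations)

    anc <- simulateGenome(sim$genome_length, seed)
    gdir <- file.path(simDir, "genomes")
    dir.create(gdir, showWarnings = FALSE)
    gfiles <- character(sim$n_genomes)
    for (i in seq_len(sim$n_genomes)) {
      g <- if (i == 1L) anc
           else mutateSequence(anc, sim$divergence, seed + i)
      gfiles[i] <- file.path(gdir, sprintf("genome_%02d.fasta", i))
      writeXStringSet(DNAStringSet(stats::setNames(as.character(g),
                                                   sprintf("genome_%02d", i))),
                      gfiles[i])
    }
    paths$genomes <<- gdir
    out <- c(out, gfiles)

    asv <- simulateAsvTable(sim$n_species, sim$samples_per_species,
                            groupEffect = sim$group_effect, seed = seed)
    paths$asvDir <<- file.path(simDir, "asv")
    writeAsvTable(asv, paths$asvDir)
    out <- c(out, list.files(paths$asvDir, full.names = TRUE))

    og <- simulateOrthogroups(sim$n_genomes, sim$n_orthogroups,
                              gapRate = sim$gap_rate, seed = seed,
                              nMultiCopy = 1L)
    paths$orthogroups <<- file.path(simDir, "orthogroups.tsv")
    writeOrthogroups(og$table, paths$orthogroups)
    paths$alnDir <<- file.path(simDir, "alignments")
    dir.create(paths$alnDir, showWarnings = FALSE)
    afiles <- vapply(names(og$alignments), function(id) {
      f <- file.path(paths$alnDir, paste0(id, ".faa"))
      writeXStringSet(og$alignments[[id]], f)
      f
    }, character(1L))
    c(out, paths$orthogroups, afiles)
  })

  if (st$profile) runStage("profile", function() {
    rules <- parseRules(paths$rules)
    ann <- readKoAnnotations(paths$annotations)
    cm <- completenessMatrix(rules, ann)
    f <- file.path(outDir, "pathway_completeness.tsv")
    writeMatrixTsv(completeness(cm), f, idColumn = "genome_id")
    f
  })

  if (st$ani) runStage("ani", function() {
    files <- list.files(paths$genomes, pattern = "\\.(fa|fasta|fna)$",
                        full.names = TRUE)
    if (!length(files)) stop("no FASTA files found in genomes directory")
    names(files) <- sub("\\.(fa|fasta|fna)$", "", basename(files))
    am <- aniMatrix(files)
    cl <- clusterSpecies(am, threshold = cfg$thresholds$ani_threshold)
    f1 <- file.path(outDir, "ani_matrix.tsv")
    writeMatrixTsv(as.matrix(am), f1, idColumn = "genome_id")
    f2 <- file.path(outDir, "species_clusters.tsv")
    utils::write.table(
      data.frame(genome_id = names(clusterMembership(cl)),
                 cluster_id = unname(clusterMembership(cl))),
      f2, sep = "\t", quote = FALSE, row.names = FALSE)
    c(f1, f2)
  })

  if (st$community) runStage("community", function() {
    x <- if (!is.null(paths$asvDir))
      readAsvTable(file.path(paths$asvDir, "asv_counts.tsv"),
                   file.path(paths$asvDir, "asv_taxonomy.tsv"),
                   file.path(paths$asvDir, "sample_metadata.tsv"))
    else readAsvTable(cfg$inputs$asv_counts, cfg$inputs$asv_taxonomy,
                      cfg$inputs$sample_metadata)
    x <- filterAsvs(x)
    x <- filterSamples(x, minReads = if (st$simulate) 0L
                       else cfg$thresholds$min_reads)
    ra <- relativeAbundance(x)
    d <- brayCurtis(ra)
    f1 <- file.path(outDir, "bray_curtis.tsv")
    writeMatrixTsv(d, f1, idColumn = "sample_id")
    pr <- permanova(d, colData(x)$host_species, nPermutations = 999L,
                    seed = seed)
    f2 <- file.path(outDir, "permanova.tsv")
    utils::write.table(
      data.frame(factor = "host_species", pseudo_F = pr$pseudoF,
                 p_value = pr$pValue, n_permutations = pr$nPermutations,
                 df_between = pr$dfBetween, df_within = pr$dfWithin),
      f2, sep = "\t", quote = FALSE, row.names = FALSE)
    sh <- sharedAsvSummary(x)
    f3 <- file.path(outDir, "shared_asvs.tsv")
    utils::write.table(sh$perAsv, f3, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    fam <- aggregateFamilies(x, otherThreshold =
                               cfg$thresholds$other_threshold)
    f4 <- file.path(outDir, "family_abundance.tsv")
    writeMatrixTsv(fam, f4, idColumn = "sample_id")
    c(f1, f2, f3, f4)
  })

  if (st$supermatrix) runStage("supermatrix", function() {
    table <- readOrthogroups(paths$orthogroups)
    res <- buildSupermatrix(table, paths$alnDir,
                            maxGapFraction = cfg$thresholds$gap_fraction)
    f1 <- file.path(outDir, "supermatrix.faa")
    f2 <- file.path(outDir, "supermatrix_partitions.txt")
    writeSupermatrix(res$supermatrix, f1, f2)
    c(f1, f2)
  })

  for (f in manifest$outputs) stopifnot(!is.na(f))
  manifest$versions <- list(
    beeprofiler = as.character(utils::packageVersion("beeprofiler")),
    R = paste(R.version$major, R.version$minor, sep = "."))
  class(manifest) <- c("beeRunManifest", "list")
  jsonlite::write_json(unclass(manifest),
                       file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest
}

.configChecksum <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL    # where results land is not part of the analysis
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.beeRunManifest <- function(x, ...) {
  cat("beeprofiler run manifest\n")
  cat(sprintf("  config checksum: %s\n", x$configChecksum))
  for (s in names(x$stages))
    cat(sprintf("  stage %-11s %s (%d output file(s), %.2fs)\n", s,
                x$stages[[s]]$status, length(x$stages[[s]]$outputs),
                x$stages[[s]]$wallTimeSec))
  invisible(x)
}
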