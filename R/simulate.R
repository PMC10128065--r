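# Synthetic-data generators: every analysis stage of the package can be
# exercised on inputs with known ground truth. A single global seed is
# forked per generator stream, so the modules are reproducible
# independently of call order.

BASES <- c("A", "C", "G", "T")

#' Simulate a random nucleotide sequence
#'
#' @param length sequence length in nt.
#' @param seed integer seed.
#' @return a DNAString of i.i.d. uniform A/C/G/T.
#' @export
simulateGenome <- function(length, seed) {
  withSeed(forkSeed(seed, "genome"), {
    DNAString(paste(sample(BASES, length, replace = TRUE), collapse = ""))
  })
}

#' Substitute positions of a nucleotide sequence at a fixed divergence
#'
#' Each position is independently substituted (always to a different base)
#' with probability `divergence`; the length is preserved — a
#' substitution-only model, which keeps recovered ANI analytically
#' predictable (expected identity 1 - divergence).
#'
#' @param seq a DNAString or A/C/G/T string.
#' @param divergence per-site substitution probability in [0, 1].
#' @param seed integer seed.
#' @return a DNAString of the same length.
#' @export
mutateSequence <- function(seq, divergence, seed) {
  if (divergence < 0 || divergence > 1)
    stop("divergence must lie in [0, 1]", call. = FALSE)
  chars <- strsplit(as.character(seq), "", fixed = TRUE)[[1L]]
  if (any(!(chars %in% BASES)))
    stop("sequence must contain only A, C, G, T", call. = FALSE)
  withSeed(forkSeed(seed, "mutate"), {
    hit <- which(stats::runif(length(chars)) < divergence)
    if (length(hit)) {
      idx <- match(chars[hit], BASES)
      step <- sample.int(3L, length(hit), replace = TRUE)
      chars[hit] <- BASES[(idx - 1L + step) %% 4L + 1L]
    }
    DNAString(paste(chars, collapse = ""))
  })
}

#' Simulate pathway rules with disjoint KO pools
#'
#' Generates syntactically valid rules whose steps draw from
#' non-overlapping KO pools, so planted completeness is exactly
#' recoverable: satisfying one step can never accidentally satisfy
#' another. Step expressions mix plain leaves, ANY alternatives and ALL
#' complexes.
#'
#' @param nPathways number of pathways.
#' @param stepsPerPathway steps per pathway (recycled).
#' @param seed integer seed.
#' @return named list of [PathwayRule-class].
#' @export
simulateRules <- function(nPathways, stepsPerPathway = 4L, seed = 1L) {
  stepsPerPathway <- rep_len(stepsPerPathway, nPathways)
  withSeed(forkSeed(seed, "rules"), {
    nextKo <- 0L
    takeKo <- function(n) {
      ids <- sprintf("K%05d", nextKo + seq_len(n))
      nextKo <<- nextKo + n
      ids
    }
    rules <- vector("list", nPathways)
    for (p in seq_len(nPathways)) {
      nSteps <- stepsPerPathway[p]
      text <- character(nSteps)
      for (s in seq_len(nSteps)) {
        kind <- sample(c("leaf", "any", "all", "mixed"), 1L)
        text[s] <- switch(kind,
          leaf = takeKo(1L),
          any  = paste(takeKo(sample(2:3, 1L)), collapse = " OR "),
          all  = paste(takeKo(sample(2:3, 1L)), collapse = " AND "),
          mixed = {
            complex <- paste(takeKo(2L), collapse = " AND ")
            sprintf("(%s) OR %s", complex, takeKo(1L))
          })
      }
      id <- sprintf("pathway_%02d", p)
      rules[[p]] <- new("PathwayRule", pathwayId = id,
                        category = "energy/carbon",
                        steps = lapply(text, parseStepExpression),
                        stepText = text)
    }
    stats::setNames(rules, vapply(rules, function(r) r@pathwayId,
                                  character(1L)))
  })
}

# choose a minimal KO set satisfying one expression (random branch of ANY)
.satisfyExpr <- function(expr) {
  switch(expr$op,
    KO  = expr$ko,
    ANY = .satisfyExpr(expr$children[[sample.int(length(expr$children), 1L)]]),
    ALL = unlist(lapply(expr$children, .satisfyExpr), use.names = FALSE))
}

.exprKos <- function(expr) {
  if (expr$op == "KO") return(expr$ko)
  unlist(lapply(expr$children, .exprKos), use.names = FALSE)
}

#' Simulate genome annotations with planted pathway completeness
#'
#' For each genome and pathway, a KO set is constructed so that exactly the
#' planted number of steps is satisfiable; distractor KOs unused by any
#' rule are added on top. Each planted fraction must be representable as
#' k / n_steps for its rule. The construction is verified by re-scoring:
#' if shared KOs between steps make a planted count unreachable under the
#' given rules, generation retries with fresh draws and eventually errors.
#'
#' @param rules named list of [PathwayRule-class].
#' @param planted either a named numeric vector (pathway -> fraction,
#'   applied to every genome) or a genomes x pathways matrix of fractions.
#' @param nGenomes number of genomes (ignored when `planted` is a matrix).
#' @param seed integer seed.
#' @param nDistractors distractor KOs per genome (default 5).
#' @return named list of [GenomeAnnotation-class].
#' @export
simulateAnnotations <- function(rules, planted, nGenomes = 1L, seed = 1L,
                                nDistractors = 5L) {
  pids <- vapply(rules, function(r) r@pathwayId, character(1L))
  if (is.matrix(planted)) {
    if (ncol(planted) != length(rules))
      stop("planted matrix must have one column per rule", call. = FALSE)
    colnames(planted) <- pids
  } else {
    if (is.null(names(planted)) || !all(pids %in% names(planted)))
      stop("planted must name every pathway", call. = FALSE)
    planted <- matrix(planted[pids], nGenomes, length(pids), byrow = TRUE,
                      dimnames = list(NULL, pids))
  }
  nSteps <- vapply(rules, function(r) length(r@steps), integer(1L))
  kTarget <- sweep(planted, 2L, nSteps, "*")
  if (any(abs(kTarget - round(kTarget)) > 1e-9))
    stop("planted fraction not representable as k / n_steps", call. = FALSE)
  kTarget <- round(kTarget)
  storage.mode(kTarget) <- "integer"
  ruleKos <- sort(unique(unlist(lapply(rules, function(r)
    lapply(r@steps, .exprKos)), use.names = FALSE)))

  withSeed(forkSeed(seed, "annotations"), {
    genomes <- vector("list", nrow(kTarget))
    for (g in seq_len(nrow(kTarget))) {
      kos <- NULL
      for (attempt in seq_len(20L)) {
        kos <- character(0L)
        for (p in seq_along(rules)) {
          k <- kTarget[g, p]
          if (k == 0L) next
          sat <- sample.int(nSteps[p], k)
          for (s in sat)
            kos <- c(kos, .satisfyExpr(rules[[p]]@steps[[s]]))
        }
        kos <- unique(kos)
        got <- vapply(seq_along(rules), function(p)
          sum(vapply(rules[[p]]@steps, evaluateStep, logical(1L),
                     kos = kos)), integer(1L))
        if (identical(got, unname(kTarget[g, ]))) break
        kos <- NULL
      }
      if (is.null(kos))
        stop(sprintf(
          "genome %d: planted completeness unreachable under these rules", g),
          call. = FALSE)
      if (nDistractors > 0L) {
        pool <- setdiff(sprintf("K%05d", 90000L + seq_len(9999L)), ruleKos)
        kos <- c(kos, sample(pool, nDistractors))
      }
      geneIds <- sprintf("gene_%04d", seq_along(kos))
      genomes[[g]] <- GenomeAnnotation(sprintf("genome_%03d", g),
                                       ko = stats::setNames(as.list(kos),
                                                            geneIds))
    }
    stats::setNames(genomes, vapply(genomes, genomeId, character(1L)))
  })
}

#' Simulate an ASV count table with planted host-species sharing
#'
#' Counts follow a negative-binomial model (per-ASV log-normal base mean,
#' fixed dispersion), the overdispersion typical of amplicon data. An ASV
#' is only ever observed in the host species its `sharingDesign` entry
#' lists — zero counts everywhere else — and the generator guarantees at
#' least one read in every designed (ASV, species) pair so the planted
#' sharing structure is exactly recoverable. `groupEffect` multiplies the
#' mean of each ASV in its first-listed ("home") species by
#' (1 + groupEffect); with `groupEffect = 0` and an all-species design the
#' table is exchangeable across species (a clean null for type-I-error
#' experiments).
#'
#' @param nSpecies number of host species.
#' @param samplesPerSpecies samples per species.
#' @param sharingDesign named list: ASV id -> character vector of host
#'   species (subset of `species_1..species_n`). Default: a seeded random
#'   design over `nAsvs` ASVs in which roughly half the ASVs are
#'   species-specific.
#' @param groupEffect nonnegative mean multiplier (see above).
#' @param seed integer seed.
#' @param nAsvs number of ASVs when `sharingDesign` is NULL.
#' @param dispersion negative-binomial size parameter (default 2).
#' @param baseMeanLog mean of the per-ASV log-normal base mean on the log
#'   scale (default log(50) reads).
#' @return an [AsvExperiment-class] with host_species / host_genus /
#'   location / colony metadata and synthetic taxonomy (family, genus,
#'   sequence of 250-256 nt).
#' @export
simulateAsvTable <- function(nSpecies, samplesPerSpecies,
                             sharingDesign = NULL, groupEffect = 0,
                             seed = 1L, nAsvs = 30L, dispersion = 2,
                             baseMeanLog = log(50)) {
  if (groupEffect < 0) stop("groupEffect must be nonnegative", call. = FALSE)
  species <- sprintf("species_%d", seq_len(nSpecies))
  withSeed(forkSeed(seed, "asv"), {
    if (is.null(sharingDesign)) {
      sharingDesign <- lapply(seq_len(nAsvs), function(i) {
        k <- if (stats::runif(1L) < 0.5) 1L
             else sample.int(nSpecies, 1L)
        sample(species, k)
      })
      names(sharingDesign) <- sprintf("ASV_%03d", seq_len(nAsvs))
    }
    if (any(lengths(sharingDesign) < 1L))
      stop("every ASV needs at least one host species", call. = FALSE)
    if (!all(unlist(sharingDesign) %in% species))
      stop("sharingDesign refers to unknown species", call. = FALSE)
    asvs <- names(sharingDesign)
    nA <- length(asvs)
    sampleSpecies <- rep(species, each = samplesPerSpecies)
    sampleIds <- sprintf("sample_%03d", seq_along(sampleSpecies))
    baseMean <- stats::rlnorm(nA, meanlog = baseMeanLog, sdlog = 1)
    counts <- matrix(0L, nA, length(sampleIds),
                     dimnames = list(asvs, sampleIds))
    for (i in seq_len(nA)) {
      home <- sharingDesign[[i]][1L]
      for (sp in sharingDesign[[i]]) {
        cols <- which(sampleSpecies == sp)
        mu <- baseMean[i] * if (sp == home) 1 + groupEffect else 1
        counts[i, cols] <- stats::rnbinom(length(cols), mu = mu,
                                          size = dispersion)
        if (all(counts[i, cols] == 0L))   # guarantee planted presence
          counts[i, cols[1L]] <- 1L
      }
    }
    famPool <- c("Neisseriaceae", "Orbaceae", "Lactobacillaceae",
                 "Bifidobacteriaceae", "Acetobacteraceae",
                 "Streptococcaceae", "Leuconostocaceae",
                 "Enterobacteriaceae", "Moraxellaceae")
    fam <- famPool[(seq_len(nA) - 1L) %% length(famPool) + 1L]
    seqLen <- sample(250:256, nA, replace = TRUE)
    seqs <- vapply(seqLen, function(L)
      paste(sample(BASES, L, replace = TRUE), collapse = ""), character(1L))
    taxonomy <- data.frame(domain = "Bacteria", family = fam,
                           genus = sub("aceae$", "", fam),
                           row.names = asvs, stringsAsFactors = FALSE)
    metadata <- data.frame(
      host_species = sampleSpecies,
      host_genus = sprintf("genus_%d",
                           (match(sampleSpecies, species) - 1L) %/% 2L + 1L),
      location = sprintf("location_%d",
                         (match(sampleSpecies, species) - 1L) %% 3L + 1L),
      colony = sprintf("colony_%02d", seq_along(sampleIds)),
      row.names = sampleIds, stringsAsFactors = FALSE)
    x <- AsvExperiment(counts, taxonomy = taxonomy, metadata = metadata,
                       sequences = stats::setNames(seqs, asvs))
    metadata(x)$sharingDesign <- sharingDesign
    x
  })
}

#' Simulate orthogroups with alignments carrying planted gap patterns
#'
#' A configurable subset of groups is single-copy-universal; the remainder
#' get either a duplicated gene in the first genome or a missing gene in
#' the first genome, so single-copy selection has known ground truth.
#' Alignment cells are gapped independently with probability `gapRate`,
#' making the expected fraction of trimmed columns the binomial tail
#' P(Binom(n_rows, gapRate) > n_rows/2).
#'
#' @param nGenomes number of genomes.
#' @param nGroups number of orthogroups.
#' @param gapRate per-cell gap probability in [0, 1].
#' @param seed integer seed.
#' @param nMultiCopy number of groups with a duplicated gene in genome 1.
#' @param nMissing number of groups absent from genome 1.
#' @param lengthRange alignment length range (columns), sampled per group.
#' @return list with `table` (orthogroup table as from
#'   [readOrthogroups()]), `alignments` (named list of AAStringSets keyed
#'   by orthogroup, records named by gene id) and `singleCopy` (character
#'   vector of the planted single-copy-universal group ids).
#' @export
simulateOrthogroups <- function(nGenomes, nGroups, gapRate = 0, seed = 1L,
                                nMultiCopy = 0L, nMissing = 0L,
                                lengthRange = c(60L, 120L)) {
  if (gapRate < 0 || gapRate > 1)
    stop("gapRate must lie in [0, 1]", call. = FALSE)
  if (nMultiCopy + nMissing > nGroups)
    stop("more degenerate groups than groups", call. = FALSE)
  genomes <- sprintf("genome_%02d", seq_len(nGenomes))
  ogs <- sprintf("OG%04d", seq_len(nGroups))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  withSeed(forkSeed(seed, "orthogroups"), {
    multi <- if (nMultiCopy) ogs[seq_len(nMultiCopy)] else character(0L)
    miss <- if (nMissing) ogs[nMultiCopy + seq_len(nMissing)] else character(0L)
    table <- list(); alignments <- list()
    for (og in ogs) {
      members <- lapply(genomes, function(g) paste0(g, "_", og, "_1"))
      names(members) <- genomes
      if (og %in% multi)
        members[[1L]] <- c(members[[1L]], paste0(genomes[1L], "_", og, "_2"))
      if (og %in% miss)
        members[[1L]] <- character(0L)
      table[[og]] <- members
      L <- sample(seq.int(lengthRange[1L], lengthRange[2L]), 1L)
      geneIds <- unlist(members, use.names = FALSE)
      rows <- vapply(geneIds, function(gid) {
        res <- sample(aa, L, replace = TRUE)
        res[stats::runif(L) < gapRate] <- "-"
        paste(res, collapse = "")
      }, character(1L))
      alignments[[og]] <- AAStringSet(stats::setNames(rows, geneIds))
    }
    list(table = table, alignments = alignments,
         singleCopy = setdiff(ogs, c(multi, miss)))
  })
}

#' Write pathway rules to the YAML format read by [parseRules()]
#'
#' @param rules named list of [PathwayRule-class].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
writeRules <- function(rules, path) {
  records <- lapply(rules, function(r)
    list(pathway = r@pathwayId, category = r@category,
         steps = as.list(r@stepText)))
  yaml::write_yaml(unname(records), path)
  invisible(path)
}

#' Write an orthogroup table in the Orthogroups.tsv dialect
#'
#' @param table orthogroup table (orthogroup -> genome -> gene ids).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeOrthogroups <- function(table, path) {
  genomes <- names(table[[1L]])
  rows <- vapply(names(table), function(og)
    paste(c(og, vapply(genomes, function(g)
      paste(table[[og]][[g]], collapse = ", "), character(1L))),
      collapse = "\t"), character(1L))
  writeLines(c(paste(c("Orthogroup", genomes), collapse = "\t"), rows), path)
  invisible(path)
}

#' Write an ASV experiment as the counts/taxonomy/metadata TSV triple
#'
#' @param x an [AsvExperiment-class].
#' @param dir output directory; files `asv_counts.tsv`, `asv_taxonomy.tsv`,
#'   `sample_metadata.tsv` are created.
#' @return the directory, invisibly.
#' @export
writeAsvTable <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMatrixTsv(assay(x, "counts"), file.path(dir, "asv_counts.tsv"),
                 idColumn = "asv_id")
  rd <- as.data.frame(rowData(x))
  utils::write.table(cbind(asv_id = rownames(x), rd),
                     file.path(dir, "asv_taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(colData(x))
  utils::write.table(cbind(sample_id = colnames(x), cd),
                     file.path(dir, "sample_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
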