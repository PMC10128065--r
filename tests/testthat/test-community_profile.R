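suppressMessages({
  library(SummarizedExperiment)
})

# small hand-built table: 4 ASVs x 4 samples across 2 host species
makeToyAsv <- function() {
  counts <- matrix(c(10L, 0L, 5L, 1L,
                     20L, 2L, 0L, 0L,
                     0L, 30L, 1L, 0L,
                     0L, 0L, 8L, 9L), 4L, 4L, byrow = TRUE,
                   dimnames = list(paste0("ASV_", 1:4), paste0("s", 1:4)))
  tax <- data.frame(domain = "Bacteria",
                    family = c("Orbaceae", "Orbaceae", "Neisseriaceae",
                               "Mitochondria"),
                    genus = c("Gilliamella", "Gilliamella", "Snodgrassella",
                              "unknown"),
                    row.names = rownames(counts))
  meta <- data.frame(host_species = c("sp1", "sp1", "sp2", "sp2"),
                     location = c("L1", "L1", "L2", "L2"),
                     row.names = colnames(counts))
  seqs <- stats::setNames(
    vapply(c(253L, 249L, 250L, 256L), function(L)
      paste(rep("A", L), collapse = ""), character(1L)),
    rownames(counts))
  AsvExperiment(counts, taxonomy = tax, metadata = meta, sequences = seqs)
}

test_that("ASV filtering applies the inclusive length range and taxon exclusion", {
  x <- makeToyAsv()
  f <- filterAsvs(x)
  # 249 nt dropped, 250 kept (inclusive boundary); Mitochondria dropped
  expect_setequal(rownames(f), c("ASV_1", "ASV_3"))
  # 256 is inside the range, only taxonomy removed ASV_4
  f2 <- filterAsvs(x, excludedTaxa = character(0L))
  expect_setequal(rownames(f2), c("ASV_1", "ASV_3", "ASV_4"))
  # no exclusions and full-range lengths -> identity
  f3 <- filterAsvs(x, lengthRange = c(1L, 1000L),
                   excludedTaxa = character(0L))
  expect_identical(rownames(f3), rownames(x))
  expect_identical(assay(f3, "counts"), assay(x, "counts"))
})

test_that("sample filtering drops strictly-below-threshold samples", {
  counts <- matrix(c(4999L, 5000L, 12000L), 1L, 3L,
                   dimnames = list("ASV_1", c("low", "edge", "high")))
  x <- AsvExperiment(counts)
  f <- filterSamples(x, minReads = 5000L)
  expect_setequal(colnames(f), c("edge", "high"))   # 4,999 out, 5,000 in
  expect_identical(colnames(filterSamples(x, minReads = 0L)), colnames(x))
  expect_error(filterSamples(x, minReads = 1e6), "all samples")
})

test_that("relative abundance rows sum to one and zero-total samples error", {
  counts <- matrix(c(2L, 2L, 0L, 7L), 2L, 2L,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  ra <- relativeAbundance(counts)
  expect_equal(ra["s1", ], c(a = 0.5, b = 0.5))
  expect_equal(ra["s2", ], c(a = 0, b = 1))

  set.seed(7)
  for (i in seq_len(10L)) {
    m <- matrix(rpois(60, 20) + 1L, 6L, 10L,
                dimnames = list(paste0("a", 1:6), paste0("s", 1:10)))
    expect_equal(unname(rowSums(relativeAbundance(m))), rep(1, 10),
                 tolerance = 1e-12)
  }
  zero <- matrix(c(1L, 0L), 1L, 2L,
                 dimnames = list("a", c("ok", "empty")))
  expect_error(relativeAbundance(zero), "zero-total")
})

test_that("family aggregation pools strictly-below-threshold ASVs as Other", {
  # one family at 100%
  one <- matrix(1, 1L, 1L, dimnames = list("s1", "a1"))
  agg <- aggregateFamilies(one, families = c(a1 = "Orbaceae"))
  expect_equal(agg["s1", "Orbaceae"], 1)
  expect_equal(agg["s1", "Other"], 0)

  # an ASV at exactly 1% stays in its family (strict <)
  ra <- matrix(c(0.01, 0.99), 1L, 2L,
               dimnames = list("s1", c("a1", "a2")))
  agg2 <- aggregateFamilies(ra, families = c(a1 = "F1", a2 = "F2"),
                            otherThreshold = 0.01)
  expect_equal(agg2["s1", "F1"], 0.01)
  expect_equal(agg2["s1", "Other"], 0)

  # mass conservation + naive two-pass oracle on random tables
  set.seed(9)
  for (i in seq_len(10L)) {
    cnt <- matrix(rpois(80, 10) + 1L, 8L, 10L,
                  dimnames = list(paste0("a", 1:8), paste0("s", 1:10)))
    raM <- relativeAbundance(cnt)
    fam <- stats::setNames(sample(c("F1", "F2", "F3"), 8L, replace = TRUE),
                           paste0("a", 1:8))
    agg <- aggregateFamilies(raM, families = fam, otherThreshold = 0.05)
    expect_equal(unname(rowSums(agg)), rep(1, 10), tolerance = 1e-12)
    expect_equal(agg, oracleAggregateFamilies(raM, fam[colnames(raM)], 0.05))
  }
})

test_that("shared-ASV summary uses the one-read presence rule", {
  counts <- matrix(c(5L, 8L, 0L, 0L,    # sp1 only -> specific
                     1L, 0L, 1L, 0L,    # one read in each species -> shared
                     0L, 0L, 3L, 4L),   # sp2 only -> specific
                   3L, 4L, byrow = TRUE,
                   dimnames = list(paste0("ASV_", 1:3), paste0("s", 1:4)))
  meta <- data.frame(host_species = c("sp1", "sp1", "sp2", "sp2"),
                     row.names = colnames(counts))
  x <- AsvExperiment(counts, metadata = meta)
  sh <- sharedAsvSummary(x)
  expect_identical(sh$nShared, 1L)
  expect_identical(sh$nSpecific, 2L)
  expect_identical(sh$nShared + sh$nSpecific, sh$nTotal)
  expect_identical(sh$perAsv$n_groups, c(1L, 2L, 1L))
  expect_equal(unname(sh$sharedReadFraction),
               c(1 / 6, 0, 1 / 4, 0))

  # removing a species' samples never increases any ASV's species count
  sub <- sharedAsvSummary(x[, 1:2])
  expect_true(all(sub$perAsv$n_groups <= sh$perAsv$n_groups))
})

test_that("planted sharing designs are recovered exactly", {
  species <- paste0("species_", 1:4)
  design <- list(ASV_A = species[1L],
                 ASV_B = species[1:2],
                 ASV_C = species,
                 ASV_D = species[c(2L, 4L)],
                 ASV_E = species[3L])
  x <- simulateAsvTable(4L, 3L, sharingDesign = design, seed = 21)
  sh <- sharedAsvSummary(x)
  expect_identical(stats::setNames(sh$perAsv$n_groups, sh$perAsv$asv_id),
                   vapply(design, length, integer(1L)))
  expect_identical(sh$nShared, 3L)
  expect_identical(sh$nSpecific, 2L)
  # zero counts outside the design
  cnt <- assay(x, "counts")
  sp <- colData(x)$host_species
  for (a in names(design)) {
    outside <- !(sp %in% design[[a]])
    expect_true(all(cnt[a, outside] == 0L))
  }
})

test_that("Bray-Curtis matches the formula and the vegan implementation", {
  x <- matrix(c(0.25, 0.75,
                0.75, 0.25), 2L, 2L, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  d <- brayCurtis(x)
  expect_equal(d["s1", "s2"], 0.5)     # |0.25-0.75| + |0.75-0.25| over 2

  same <- rbind(s1 = c(0.4, 0.6), s2 = c(0.4, 0.6))
  expect_equal(brayCurtis(same)["s1", "s2"], 0)
  disjoint <- rbind(s1 = c(1, 0), s2 = c(0, 1))
  expect_equal(brayCurtis(disjoint)["s1", "s2"], 1)

  skip_if_not_installed("vegan")
  set.seed(13)
  for (i in seq_len(5L)) {
    m <- matrix(runif(40), 5L, 8L,
                dimnames = list(paste0("s", 1:5), paste0("a", 1:8)))
    got <- brayCurtis(m)
    ref <- as.matrix(vegan::vegdist(m, method = "bray"))
    expect_equal(got, ref, tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= 1))
    expect_equal(got, t(got))
    expect_equal(unname(diag(got)), rep(0, 5))
  }
})

test_that("PERMANOVA pseudo-F matches vegan and the Gower-trace oracle", {
  skip_if_not_installed("vegan")
  set.seed(17)
  for (i in seq_len(5L)) {
    m <- matrix(runif(120), 12L, 10L,
                dimnames = list(paste0("s", 1:12), paste0("a", 1:10)))
    grp <- sample(rep(c("A", "B", "C"), each = 4L))
    d <- brayCurtis(m)
    got <- permanova(d, grp, nPermutations = 99L, seed = 1L)
    ref <- vegan::adonis2(stats::as.dist(d) ~ g,
                          data = data.frame(g = grp), permutations = 99)
    expect_equal(got$pseudoF, ref$F[1L], tolerance = 1e-10)
    expect_equal(got$pseudoF, oraclePermanovaF(d, grp), tolerance = 1e-10)
    expect_identical(got$dfBetween, 2L)
    expect_identical(got$dfWithin, 9L)
  }
})

test_that("PERMANOVA p-value is reproducible, relabel-invariant and exact when exhaustive", {
  set.seed(19)
  m <- matrix(runif(60), 6L, 10L,
              dimnames = list(paste0("s", 1:6), paste0("a", 1:10)))
  grp <- c("A", "A", "A", "B", "B", "B")
  d <- brayCurtis(m)

  r1 <- permanova(d, grp, nPermutations = 199L, seed = 7L)
  r2 <- permanova(d, grp, nPermutations = 199L, seed = 7L)
  expect_identical(r1$pValue, r2$pValue)

  # pseudo-F invariant under sample relabeling (consistent reordering)
  ord <- sample(6L)
  r3 <- permanova(d[ord, ord], grp[ord], nPermutations = 9L, seed = 1L)
  expect_equal(r3$pseudoF, r1$pseudoF, tolerance = 1e-12)

  # exhaustive enumeration over all 720 orderings vs independent oracle
  ex <- permanova(d, grp, exhaustive = TRUE)
  perms <- oraclePerms(6L)
  fAll <- apply(perms, 1L, function(p) oraclePermanovaF(d, grp[p]))
  pOracle <- mean(fAll >= oraclePermanovaF(d, grp) - 1e-12)
  expect_identical(ex$nPermutations, 720L)
  expect_equal(ex$pValue, pOracle, tolerance = 1e-9)
})

test_that("PERMANOVA degenerate cases behave as specified", {
  # two groups of duplicated identical samples: within-distances all 0,
  # SS_between maximal, pseudo-F infinite; large enough groups that a
  # random permutation essentially never reproduces the grouping, so the
  # permutation p hits its attainable minimum 1/(n_perm + 1)
  m <- rbind(matrix(rep(c(1, 0), each = 6L), 6L, 2L),
             matrix(rep(c(0, 1), each = 6L), 6L, 2L))
  rownames(m) <- paste0("s", 1:12)
  d <- brayCurtis(m)
  grp <- rep(c("A", "B"), each = 6L)
  r <- permanova(d, grp, nPermutations = 99L, seed = 3L)
  expect_identical(r$pValue, 1 / 100)
  expect_true(is.infinite(r$pseudoF) || r$pseudoF > 1e10)

  expect_error(permanova(d, rep("A", 12L)), "two groups")
  expect_error(permanova(d, c("A", "B")), "length")
})

test_that("ASV table TSV round trip preserves counts, taxonomy and metadata", {
  x <- simulateAsvTable(3L, 2L, seed = 23, nAsvs = 12L)
  dir <- tempfile()
  writeAsvTable(x, dir)
  y <- readAsvTable(file.path(dir, "asv_counts.tsv"),
                    file.path(dir, "asv_taxonomy.tsv"),
                    file.path(dir, "sample_metadata.tsv"))
  expect_identical(assay(y, "counts"), assay(x, "counts"))
  expect_identical(rowData(y)$family, rowData(x)$family)
  expect_identical(colData(y)$host_species, colData(x)$host_species)
  expect_identical(rowData(y)$sequence, rowData(x)$sequence)
})
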