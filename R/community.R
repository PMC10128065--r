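# ASV-table filtering, family-level aggregation, shared-ASV statistics,
# Bray-Curtis dissimilarity and one-factor PERMANOVA.

TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Construct an AsvExperiment
#'
#' @param counts integer matrix of read counts with ASVs as rows and samples
#'   as columns (row/column names required).
#' @param taxonomy data.frame of per-ASV taxonomy (columns among domain,
#'   phylum, class, order, family, genus), rownames matching ASV ids.
#' @param metadata data.frame of per-sample host metadata (e.g.
#'   host_species, host_genus, location, colony), rownames matching sample
#'   ids.
#' @param sequences optional named character vector of denoised ASV
#'   sequences; stored as rowData column `sequence`.
#' @return an [AsvExperiment-class].
#' @export
AsvExperiment <- function(counts, taxonomy = NULL, metadata = NULL,
                          sequences = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  rd <- if (is.null(taxonomy)) DataFrame(row.names = rownames(counts))
        else DataFrame(taxonomy[rownames(counts), , drop = FALSE],
                       row.names = rownames(counts))
  if (!is.null(sequences)) rd$sequence <- unname(sequences[rownames(counts)])
  cd <- if (is.null(metadata)) DataFrame(row.names = colnames(counts))
        else DataFrame(metadata[colnames(counts), , drop = FALSE],
                       row.names = colnames(counts))
  se <- SummarizedExperiment(assays = list(counts = counts),
                             rowData = rd, colData = cd)
  new("AsvExperiment", se)
}

#' Read an ASV table (counts + taxonomy + metadata TSVs)
#'
#' Accepts the common supplementary-table layout exported to TSV: a counts
#' table with an `asv_id` column followed by one column per sample; a
#' taxonomy table with `asv_id`, rank columns and optionally `sequence`; a
#' metadata table with `sample_id` followed by per-sample columns.
#'
#' @param countsPath,taxPath,metaPath TSV paths; taxonomy and metadata are
#'   optional.
#' @return an [AsvExperiment-class].
#' @export
readAsvTable <- function(countsPath, taxPath = NULL, metaPath = NULL) {
  cdf <- readTsv(countsPath)
  if (colnames(cdf)[1L] != "asv_id")
    stop("counts table must start with an 'asv_id' column", call. = FALSE)
  counts <- as.matrix(cdf[, -1L, drop = FALSE])
  rownames(counts) <- cdf$asv_id
  taxonomy <- sequences <- NULL
  if (!is.null(taxPath)) {
    tdf <- readTsv(taxPath)
    rownames(tdf) <- tdf$asv_id
    if ("sequence" %in% colnames(tdf))
      sequences <- stats::setNames(tdf$sequence, tdf$asv_id)
    taxonomy <- tdf[, setdiff(colnames(tdf), c("asv_id", "sequence")),
                    drop = FALSE]
  }
  metadata <- NULL
  if (!is.null(metaPath)) {
    mdf <- readTsv(metaPath)
    rownames(mdf) <- mdf$sample_id
    metadata <- mdf[, setdiff(colnames(mdf), "sample_id"), drop = FALSE]
  }
  AsvExperiment(counts, taxonomy = taxonomy, metadata = metadata,
                sequences = sequences)
}

#' Filter ASVs by sequence length and excluded taxa
#'
#' Drops ASVs whose sequence length falls outside the inclusive
#' `lengthRange` (250-256 nt by default, the expected V4 amplicon range) or
#' whose taxonomy matches any excluded label at any rank; by default
#' Eukaryota, Chloroplast and Mitochondria assignments are removed.
#'
#' @param x an [AsvExperiment-class].
#' @param lengthRange inclusive (min, max) sequence length in nt, or NULL
#'   to skip the length filter.
#' @param excludedTaxa character vector of taxonomy labels to exclude
#'   (exact match at any rank).
#' @return the filtered [AsvExperiment-class].
#' @export
filterAsvs <- function(x, lengthRange = c(250L, 256L),
                       excludedTaxa = c("Eukaryota", "Chloroplast",
                                        "Mitochondria")) {
  keep <- rep(TRUE, nrow(x))
  if (!is.null(lengthRange)) {
    if (!("sequence" %in% colnames(rowData(x))))
      stop("length filter requested but ASV sequences are absent",
           call. = FALSE)
    len <- nchar(rowData(x)$sequence)
    keep <- keep & len >= lengthRange[1L] & len <= lengthRange[2L]
  }
  if (length(excludedTaxa)) {
    ranks <- intersect(TAXONOMY_RANKS, colnames(rowData(x)))
    for (rk in ranks)
      keep <- keep & !(rowData(x)[[rk]] %in% excludedTaxa)
  }
  x[keep, ]
}

#' Drop low-depth samples
#'
#' Samples with fewer than `minReads` total reads are removed (strictly
#' fewer: a sample at exactly the threshold is kept).
#'
#' @param x an [AsvExperiment-class].
#' @param minReads minimum total read count (default 5000).
#' @return the filtered [AsvExperiment-class].
#' @export
filterSamples <- function(x, minReads = 5000L) {
  keep <- colSums(assay(x, "counts")) >= minReads
  if (!any(keep))
    stop("all samples fall below the read-count threshold", call. = FALSE)
  x[, keep]
}

#' Per-sample relative abundance
#'
#' @param x an [AsvExperiment-class] or a counts matrix (ASVs x samples).
#' @return numeric samples x ASVs matrix; each row sums to 1.
#' @export
relativeAbundance <- function(x) {
  cnt <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else as.matrix(x)
  tot <- colSums(cnt)
  if (any(tot == 0))
    stop(sprintf("zero-total sample(s): %s",
                 paste(colnames(cnt)[tot == 0], collapse = ", ")),
         call. = FALSE)
  t(sweep(cnt, 2L, tot, "/"))
}

#' Aggregate relative abundances to the family level with an "Other" pool
#'
#' Per sample, ASVs with relative abundance strictly below `otherThreshold`
#' are pooled into an `Other` column; the remaining ASVs are summed by
#' family. An ASV at exactly the threshold is kept in its family. Output
#' rows still sum to 1.
#'
#' @param x an [AsvExperiment-class], or a samples x ASVs relative-abundance
#'   matrix (then `families` is required).
#' @param families named character vector mapping ASV id to family; taken
#'   from `rowData(x)$family` when `x` is an AsvExperiment.
#' @param otherThreshold pooling threshold on per-sample relative abundance
#'   (default 0.01).
#' @return numeric samples x family matrix (families sorted, `Other` last).
#' @export
aggregateFamilies <- function(x, families = NULL, otherThreshold = 0.01) {
  if (is(x, "SummarizedExperiment")) {
    if (is.null(families)) {
      if (!("family" %in% colnames(rowData(x))))
        stop("taxonomy with a 'family' column is required", call. = FALSE)
      families <- stats::setNames(rowData(x)$family, rownames(x))
    }
    ra <- relativeAbundance(x)
  } else ra <- as.matrix(x)
  if (is.null(families) || !all(colnames(ra) %in% names(families)))
    stop("every ASV needs a family assignment", call. = FALSE)
  fam <- families[colnames(ra)]
  pooled <- ra < otherThreshold          # per-sample, strict
  famLevels <- sort(unique(fam))
  out <- matrix(0, nrow(ra), length(famLevels) + 1L,
                dimnames = list(rownames(ra), c(famLevels, "Other")))
  kept <- ra * !pooled
  for (f in famLevels)
    out[, f] <- rowSums(kept[, fam == f, drop = FALSE])
  out[, "Other"] <- rowSums(ra * pooled)
  out
}

#' Shared-ASV summary across host groups
#'
#' An ASV is "present" in a host group when it has at least one read in at
#' least one of the group's samples; it is "shared" when present in two or
#' more groups and "group-specific" otherwise. Also reports, per sample,
#' the fraction of reads attributable to shared ASVs.
#'
#' @param x an [AsvExperiment-class].
#' @param grouping name of the colData column defining host groups
#'   (default `"host_species"`).
#' @return a list of class `sharedAsvSummary`: `perAsv` (data.frame with
#'   `asv_id`, `n_groups`, `shared`), `nShared`, `nSpecific`, `nTotal`, and
#'   `sharedReadFraction` (named per-sample numeric).
#' @export
sharedAsvSummary <- function(x, grouping = "host_species") {
  if (!(grouping %in% colnames(colData(x))))
    stop(sprintf("metadata column '%s' not found", grouping), call. = FALSE)
  cnt <- assay(x, "counts")
  grp <- as.character(colData(x)[[grouping]])
  groups <- unique(grp)
  pres <- vapply(groups, function(g)
    rowSums(cnt[, grp == g, drop = FALSE]) >= 1L,
    logical(nrow(cnt)))
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = nrow(cnt))
  nGroups <- as.integer(rowSums(pres))
  shared <- nGroups >= 2L
  sharedReads <- colSums(cnt[shared, , drop = FALSE])
  out <- list(
    perAsv = data.frame(asv_id = rownames(cnt), n_groups = nGroups,
                        shared = shared, stringsAsFactors = FALSE),
    nShared = sum(shared), nSpecific = sum(!shared), nTotal = nrow(cnt),
    sharedReadFraction = sharedReads / colSums(cnt),
    grouping = grouping)
  class(out) <- "sharedAsvSummary"
  out
}

#' @export
print.sharedAsvSummary <- function(x, ...) {
  cat(sprintf("Shared-ASV summary by %s:\n", x$grouping))
  cat(sprintf("  %d of %d ASVs shared across groups (%.1f%%), %d specific\n",
              x$nShared, x$nTotal, 100 * x$nShared / max(1L, x$nTotal),
              x$nSpecific))
  cat(sprintf("  shared-ASV read fraction per sample: %.3f-%.3f\n",
              min(x$sharedReadFraction), max(x$sharedReadFraction)))
  invisible(x)
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(j, k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik) over ASVs i, for
#' sample rows j, k. Two all-zero samples have distance 0.
#'
#' @param x numeric samples x ASVs matrix (typically relative abundances
#'   from [relativeAbundance()]), or an [AsvExperiment-class].
#' @return symmetric samples x samples matrix with zero diagonal, values in
#'   [0, 1].
#' @export
brayCurtis <- function(x) {
  if (is(x, "SummarizedExperiment")) x <- relativeAbundance(x)
  x <- as.matrix(x)
  if (any(x < 0)) stop("abundances must be nonnegative", call. = FALSE)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (j in seq_len(max(0L, n - 1L))) for (k in seq.int(j + 1L, n)) {
    den <- sum(x[j, ] + x[k, ])
    num <- sum(abs(x[j, ] - x[k, ]))
    d[j, k] <- d[k, j] <- if (den == 0) 0 else num / den
  }
  d
}

# squared-distance variance partition for one grouping
.permanovaSS <- function(d2, grp) {
  N <- nrow(d2)
  ssTotal <- sum(d2[upper.tri(d2)]) / N
  ssWithin <- 0
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx, drop = FALSE]
      ssWithin <- ssWithin + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ssTotal, within = ssWithin, between = ssTotal - ssWithin)
}

.allPerms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .allPerms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) for (p in sub) {
    k <- k + 1L
    out[[k]] <- c(i, ifelse(p >= i, p + 1L, p))
  }
  out
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Partitions the squared-distance variance of a symmetric dissimilarity
#' matrix among the levels of a single grouping factor (Anderson's
#' one-factor formulation): SS_total is the sum of all pairwise squared
#' distances divided by N; SS_within sums, per group, the within-group
#' pairwise squared distances divided by the group size; SS_between is the
#' difference; pseudo-F = (SS_between / (a-1)) / (SS_within / (N-a)) for a
#' groups and N samples. Significance comes from permuting group labels:
#' p = (#\{F_perm >= F_obs\} + 1) / (nPermutations + 1), or the exact
#' fraction over all N! label orderings when `exhaustive = TRUE`.
#'
#' @param d symmetric distance matrix (e.g. from [brayCurtis()]).
#' @param groups grouping vector/factor, one entry per sample.
#' @param nPermutations number of random label permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param exhaustive enumerate all label orderings instead (N <= 8 only).
#' @return a list of class `beePermanova` with `pseudoF`, `pValue`,
#'   `nPermutations`, `dfBetween`, `dfWithin`, `ssBetween`, `ssWithin`,
#'   `ssTotal`.
#' @export
permanova <- function(d, groups, nPermutations = 999L, seed = 1L,
                      exhaustive = FALSE) {
  d <- as.matrix(d)
  grp <- as.character(groups)
  N <- nrow(d)
  if (length(grp) != N)
    stop("groups length must match the distance matrix", call. = FALSE)
  a <- length(unique(grp))
  if (a < 2L) stop("at least two groups are required", call. = FALSE)
  if (nPermutations < 1L && !exhaustive)
    stop("nPermutations must be >= 1", call. = FALSE)
  d2 <- d * d
  ss <- .permanovaSS(d2, grp)
  dfB <- a - 1L; dfW <- N - a
  fObs <- (ss["between"] / dfB) / (ss["within"] / dfW)
  fStat <- function(g) {
    s <- .permanovaSS(d2, g)
    (s["between"] / dfB) / (s["within"] / dfW)
  }
  if (exhaustive) {
    if (N > 8L) stop("exhaustive enumeration is limited to N <= 8",
                     call. = FALSE)
    perms <- .allPerms(N)
    fPerm <- vapply(perms, function(p) fStat(grp[p]), numeric(1L))
    p <- mean(fPerm >= fObs)   # identity ordering is among the N!
    nPermutations <- length(perms)
  } else {
    fPerm <- withSeed(seed, vapply(seq_len(nPermutations), function(i)
      fStat(grp[sample.int(N)]), numeric(1L)))
    p <- (sum(fPerm >= fObs) + 1) / (nPermutations + 1)
  }
  out <- list(pseudoF = unname(fObs), pValue = unname(p),
              nPermutations = as.integer(nPermutations),
              dfBetween = dfB, dfWithin = dfW,
              ssBetween = unname(ss["between"]),
              ssWithin = unname(ss["within"]), ssTotal = unname(ss["total"]))
  class(out) <- "beePermanova"
  out
}

#' @export
print.beePermanova <- function(x, ...) {
  cat("One-factor PERMANOVA\n")
  cat(sprintf("  pseudo-F = %.4g on (%d, %d) df;  p = %.4g (%d permutations)\n",
              x$pseudoF, x$dfBetween, x$dfWithin, x$pValue, x$nPermutations))
  invisible(x)
}
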