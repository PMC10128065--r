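#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom Biostrings AAStringSet DNAStringSet DNAString readDNAStringSet
#'   readAAStringSet writeXStringSet pairwiseAlignment nmatch nmismatch
#'   subseq PDict matchPDict alignedPattern alignedSubject
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

VALID_CATEGORIES <- c("energy/carbon", "amino-acid", "cofactor/nucleoside",
                      "secretion", "adhesion/motility")

KO_PATTERN      <- "^K[0-9]{5}$"
CAZYME_PATTERN  <- "^(GH|PL|GT|CE|CBM)[0-9]+(_[0-9]+)?$"

#' PathwayRule: one pathway as an ordered list of boolean steps
#'
#' A pathway rule is an ordered list of steps, each a boolean expression over
#' KEGG Orthology (KO) identifiers. A step expression tree has operator nodes
#' \code{ANY} (alternative enzymes, logical OR) and \code{ALL} (multi-subunit
#' complexes, logical AND) over KO leaves. Pathway completeness of a genome is
#' the fraction of steps whose expression is satisfied by the genome's KO set.
#'
#' @slot pathwayId single short identifier, unique within a rule set.
#' @slot category one of \code{"energy/carbon"}, \code{"amino-acid"},
#'   \code{"cofactor/nucleoside"}, \code{"secretion"}, \code{"adhesion/motility"}.
#' @slot steps list of parsed expression trees (internal nested-list form).
#' @slot stepText the original expression strings, one per step.
#'
#' @seealso [parseRules()], [pathwayCompleteness()]
#' @export
setClass("PathwayRule",
  representation(pathwayId = "character", category = "character",
                 steps = "list", stepText = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@pathwayId) != 1L || !nzchar(object@pathwayId))
      msg <- c(msg, "pathwayId must be a single non-empty string")
    if (length(object@category) != 1L ||
        !(object@category %in% VALID_CATEGORIES))
      msg <- c(msg, sprintf("category must be one of: %s",
                            paste(VALID_CATEGORIES, collapse = ", ")))
    if (length(object@steps) < 1L)
      msg <- c(msg, "a pathway rule needs at least one step")
    if (length(object@steps) != length(object@stepText))
      msg <- c(msg, "steps and stepText lengths differ")
    for (i in seq_along(object@steps)) {
      bad <- .validateExprTree(object@steps[[i]])
      if (!is.null(bad))
        msg <- c(msg, sprintf("step %d: %s", i, bad))
    }
    if (length(msg)) msg else TRUE
  })

# recursive structural check of a step expression tree
.validateExprTree <- function(node) {
  if (!is.list(node) || is.null(node$op)) return("malformed expression node")
  if (node$op == "KO") {
    if (is.null(node$ko) || !grepl(KO_PATTERN, node$ko))
      return(sprintf("invalid KO identifier '%s'", node$ko))
    return(NULL)
  }
  if (!(node$op %in% c("ANY", "ALL")))
    return(sprintf("unknown operator '%s'", node$op))
  if (length(node$children) < 2L)
    return("operator node with fewer than 2 children")
  for (ch in node$children) {
    bad <- .validateExprTree(ch)
    if (!is.null(bad)) return(bad)
  }
  NULL
}

#' GenomeAnnotation: a genome's KO and CAZyme assignments keyed by gene
#'
#' @slot genomeId genome identifier.
#' @slot ko named list, gene id -> character vector of KO identifiers.
#' @slot cazymes named list, gene id -> character vector of CAZyme family
#'   labels (e.g. \code{GH13}, \code{PL1}).
#'
#' @seealso [readKoAnnotations()], [koSet()], [countCazymes()]
#' @export
setClass("GenomeAnnotation",
  representation(genomeId = "character", ko = "list", cazymes = "list"),
  prototype(ko = structure(list(), names = character()),
            cazymes = structure(list(), names = character())),
  validity = function(object) {
    msg <- character()
    if (length(object@genomeId) != 1L || !nzchar(object@genomeId))
      msg <- c(msg, "genomeId must be a single non-empty string")
    for (slotname in c("ko", "cazymes")) {
      x <- slot(object, slotname)
      if (length(x) && (is.null(names(x)) || anyDuplicated(names(x))))
        msg <- c(msg, sprintf("gene ids in '%s' must be unique", slotname))
    }
    fams <- unlist(object@cazymes, use.names = FALSE)
    bad <- fams[!grepl(CAZYME_PATTERN, fams)]
    if (length(bad))
      msg <- c(msg, sprintf("malformed CAZyme family label(s): %s",
                            paste(unique(bad), collapse = ", ")))
    kos <- unlist(object@ko, use.names = FALSE)
    badko <- kos[!grepl(KO_PATTERN, kos)]
    if (length(badko))
      msg <- c(msg, sprintf("malformed KO identifier(s): %s",
                            paste(unique(badko), collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' CompletenessMatrix: genomes x pathways pathway-completeness fractions
#'
#' Each cell is the exact rational n_present / n_total for one genome and one
#' pathway: the number of satisfied steps over the total number of steps.
#'
#' @slot completeness numeric genomes x pathways matrix of fractions in [0,1].
#' @slot stepsPresent integer matrix of satisfied-step counts, same dim.
#' @slot stepsTotal named integer vector of per-pathway step totals.
#'
#' @seealso [completenessMatrix()]
#' @export
setClass("CompletenessMatrix",
  representation(completeness = "matrix", stepsPresent = "matrix",
                 stepsTotal = "integer"),
  validity = function(object) {
    msg <- character()
    cm <- object@completeness; sp <- object@stepsPresent
    if (!identical(dim(cm), dim(sp)))
      msg <- c(msg, "completeness and stepsPresent dimensions differ")
    if (ncol(cm) != length(object@stepsTotal))
      msg <- c(msg, "stepsTotal length must equal number of pathways")
    else {
      expected <- sweep(sp, 2L, object@stepsTotal, "/")
      if (!isTRUE(all.equal(unname(cm), unname(expected), tolerance = 0)))
        msg <- c(msg, "completeness must equal stepsPresent / stepsTotal exactly")
    }
    if (length(cm) && (min(cm) < 0 || max(cm) > 1))
      msg <- c(msg, "completeness values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' CazymeCountMatrix: genomes x CAZyme-family gene counts
#'
#' @slot counts integer genomes x family matrix of gene counts.
#' @slot ghTotal named integer vector: per-genome total over GH families.
#' @slot plTotal named integer vector: per-genome total over PL families.
#'
#' @seealso [countCazymes()]
#' @export
setClass("CazymeCountMatrix",
  representation(counts = "matrix", ghTotal = "integer", plTotal = "integer"),
  validity = function(object) {
    msg <- character()
    cnt <- object@counts
    if (length(cnt) && min(cnt) < 0)
      msg <- c(msg, "counts must be nonnegative")
    gh <- grepl("^GH", colnames(cnt)); pl <- grepl("^PL", colnames(cnt))
    ghExp <- as.integer(rowSums(cnt[, gh, drop = FALSE]))
    plExp <- as.integer(rowSums(cnt[, pl, drop = FALSE]))
    if (!identical(unname(object@ghTotal), ghExp))
      msg <- c(msg, "ghTotal must equal row sums over GH families")
    if (!identical(unname(object@plTotal), plExp))
      msg <- c(msg, "plTotal must equal row sums over PL families")
    if (length(msg)) msg else TRUE
  })

#' AniMatrix: pairwise symmetric average nucleotide identity (percent)
#'
#' Off-diagonal cells may be NA where neither direction found homologous
#' fragments ("no-homology" pairs); the diagonal is exactly 100.
#'
#' @slot ani numeric symmetric genomes x genomes percent matrix.
#'
#' @seealso [aniMatrix()], [clusterSpecies()]
#' @export
setClass("AniMatrix",
  representation(ani = "matrix"),
  validity = function(object) {
    m <- object@ani
    msg <- character()
    if (nrow(m) != ncol(m) || is.null(rownames(m)) ||
        !identical(rownames(m), colnames(m)))
      msg <- c(msg, "matrix must be square with matching dimnames")
    else {
      if (!isTRUE(all.equal(m, t(m))))
        msg <- c(msg, "matrix must be symmetric")
      if (!isTRUE(all(diag(m) == 100)))
        msg <- c(msg, "diagonal must be exactly 100")
      off <- m[row(m) != col(m)]
      if (any(!is.na(off) & (off < 0 | off > 100)))
        msg <- c(msg, "ANI values must lie in [0, 100]")
    }
    if (length(msg)) msg else TRUE
  })

#' SpeciesClustering: partition of genomes at an ANI threshold
#'
#' @slot membership named integer vector mapping genome id -> cluster id;
#'   cluster ids are 1..k in order of first appearance.
#' @slot threshold the ANI percent threshold used (default 95).
#'
#' @seealso [clusterSpecies()]
#' @export
setClass("SpeciesClustering",
  representation(membership = "integer", threshold = "numeric"),
  validity = function(object) {
    msg <- character()
    if (is.null(names(object@membership)) ||
        anyDuplicated(names(object@membership)))
      msg <- c(msg, "membership must be named by unique genome ids")
    k <- length(unique(object@membership))
    if (k && !identical(sort(unique(object@membership)), seq_len(k)))
      msg <- c(msg, "cluster ids must be 1..k")
    if (length(msg)) msg else TRUE
  })

#' AsvExperiment: an ASV count table with taxonomy and sample metadata
#'
#' Extends SummarizedExperiment: rows are amplicon sequence variants (ASVs),
#' columns are samples. \code{assay(x, "counts")} holds nonnegative integer
#' read counts; \code{rowData} carries the per-ASV taxonomy (and optionally
#' the denoised sequence); \code{colData} carries per-sample host metadata
#' (host species, host genus, location, colony).
#'
#' @seealso [AsvExperiment()], [readAsvTable()], [filterAsvs()]
#' @export
setClass("AsvExperiment", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
      return("an 'counts' assay is required")
    cnt <- assay(object, "counts")
    if (any(cnt < 0) || any(cnt != round(cnt)))
      msg <- c(msg, "counts must be nonnegative integers")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
      msg <- c(msg, "ASV ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
      msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (length(msg)) msg else TRUE
  })

#' Supermatrix: concatenated trimmed single-copy alignments
#'
#' @slot sequences AAStringSet, one equal-length concatenated amino-acid
#'   sequence per genome.
#' @slot partitions named IRanges, one contiguous 1-based inclusive range per
#'   source orthogroup, jointly covering the full alignment length.
#'
#' @seealso [concatenateAlignments()], [writeSupermatrix()]
#' @export
setClass("Supermatrix",
  representation(sequences = "AAStringSet", partitions = "IRanges"),
  validity = function(object) {
    msg <- character()
    w <- Biostrings::width(object@sequences)
    if (length(w) && length(unique(w)) != 1L)
      msg <- c(msg, "all genome sequences must have equal length")
    p <- object@partitions
    if (length(p)) {
      starts <- IRanges::start(p); ends <- IRanges::end(p)
      if (starts[1L] != 1L)
        msg <- c(msg, "first partition must start at 1")
      if (length(p) > 1L &&
          !all(starts[-1L] == ends[-length(p)] + 1L))
        msg <- c(msg, "partitions must be contiguous and non-overlapping")
      if (length(w) && ends[length(p)] != w[1L])
        msg <- c(msg, "partitions must cover the full alignment length")
      if (is.null(names(p)))
        msg <- c(msg, "partitions must be named by orthogroup id")
    }
    if (length(msg)) msg else TRUE
  })
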