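# Single-copy ortholog selection, gap-column trimming and supermatrix
# construction for core-genome phylogenomics.

GAP_CHARS <- c("-", ".")   # both '-' and '.' count as gaps; 'X' does not

#' Read an orthogroup membership table (OrthoFinder Orthogroups.tsv dialect)
#'
#' First column `Orthogroup`, one column per genome; cells hold comma (+
#' optional space) separated gene ids, empty when the genome lacks the
#' group.
#'
#' @param path TSV path.
#' @return named list: orthogroup id -> named list (genome id -> character
#'   vector of gene ids).
#' @export
readOrthogroups <- function(path) {
  df <- readTsv(path)
  if (colnames(df)[1L] != "Orthogroup")
    stop("expected an 'Orthogroup' first column", call. = FALSE)
  genomes <- colnames(df)[-1L]
  out <- lapply(seq_len(nrow(df)), function(r) {
    row <- lapply(genomes, function(g) {
      cell <- df[r, g]
      if (is.na(cell) || !nzchar(cell)) character(0L)
      else trimws(strsplit(cell, ",")[[1L]])
    })
    stats::setNames(row, genomes)
  })
  stats::setNames(out, df$Orthogroup)
}

#' Select single-copy-universal orthogroups
#'
#' An orthogroup qualifies when it has exactly one gene in every listed
#' genome — the standard basis for core-genome phylogenies.
#'
#' @param table orthogroup table from [readOrthogroups()] (orthogroup ->
#'   genome -> gene ids).
#' @param genomes character vector of genome ids that must each contribute
#'   exactly one gene.
#' @return character vector of qualifying orthogroup ids, in input order.
#' @export
selectSingleCopy <- function(table, genomes) {
  if (!length(genomes)) stop("genomes must be nonempty", call. = FALSE)
  ok <- vapply(table, function(og)
    all(vapply(genomes, function(g)
      length(og[[g]]) == 1L, logical(1L))), logical(1L))
  names(table)[ok]
}

.alignmentMatrix <- function(aln) {
  chars <- as.character(aln)
  if (length(unique(nchar(chars))) != 1L)
    stop("alignment rows must have equal length", call. = FALSE)
  do.call(rbind, strsplit(chars, "", fixed = TRUE))
}

#' Trim alignment columns exceeding a gap fraction
#'
#' A column is removed iff its gap count / number of rows is strictly
#' greater than `maxGapFraction` (default 0.5: positions with more than 50%
#' gaps go; a column at exactly 50% stays). `-` and `.` count as gaps;
#' ambiguous residues such as `X` do not.
#'
#' @param aln an AAStringSet (or named character vector) of aligned,
#'   equal-length sequences.
#' @param maxGapFraction strict gap-fraction threshold in [0, 1].
#' @return a list with `alignment` (trimmed AAStringSet) and `kept`
#'   (integer indices of retained columns in the input alignment — the
#'   column provenance record).
#' @export
trimAlignment <- function(aln, maxGapFraction = 0.5) {
  if (!is(aln, "AAStringSet")) aln <- AAStringSet(aln)
  if (!length(aln) || Biostrings::width(aln)[1L] == 0L)
    stop("alignment is empty", call. = FALSE)
  m <- .alignmentMatrix(aln)
  gapFrac <- colMeans(matrix(m %in% GAP_CHARS, nrow = nrow(m)))
  kept <- which(gapFrac <= maxGapFraction)
  trimmed <- apply(m[, kept, drop = FALSE], 1L, paste, collapse = "")
  out <- AAStringSet(stats::setNames(trimmed, names(aln)))
  list(alignment = out, kept = kept)
}

#' Concatenate trimmed alignments into a partitioned supermatrix
#'
#' @param alignments named list of AAStringSets sharing one genome set
#'   (names are orthogroup ids; sequence names are genome ids).
#' @return a [Supermatrix-class]: per-genome concatenated sequences plus
#'   1-based inclusive partition coordinates per orthogroup.
#' @export
concatenateAlignments <- function(alignments) {
  if (!length(alignments)) stop("no alignments given", call. = FALSE)
  if (is.null(names(alignments)))
    stop("alignments must be named by orthogroup id", call. = FALSE)
  genomes <- names(alignments[[1L]])
  for (og in names(alignments)) {
    nm <- names(alignments[[og]])
    if (is.null(nm) || !setequal(nm, genomes))
      stop(sprintf("alignment '%s' does not cover the shared genome set", og),
           call. = FALSE)
  }
  widths <- vapply(alignments, function(a) Biostrings::width(a)[1L],
                   integer(1L))
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  concat <- vapply(genomes, function(g)
    paste(vapply(alignments, function(a) as.character(a[[g]]), character(1L)),
          collapse = ""), character(1L))
  new("Supermatrix",
      sequences = AAStringSet(concat),
      partitions = IRanges(start = starts, end = ends,
                           names = names(alignments)))
}

#' Build a supermatrix from an orthogroup table and an alignment directory
#'
#' Convenience wrapper: selects single-copy-universal orthogroups, reads
#' their FASTA alignments (`<orthogroup>.faa`/`.fa`/`.fasta` in `alnDir`),
#' renames records to genome ids via the orthogroup table, trims gap-heavy
#' columns and concatenates.
#'
#' @param table orthogroup table from [readOrthogroups()].
#' @param alnDir directory of per-orthogroup FASTA alignments; record names
#'   are gene ids (prefix before the first whitespace).
#' @param genomes genome ids to require (default: all genomes in the table).
#' @param maxGapFraction passed to [trimAlignment()].
#' @return list with `supermatrix` ([Supermatrix-class]), `keptColumns`
#'   (named list of per-orthogroup kept-column indices) and `orthogroups`
#'   (the selected ids).
#' @export
buildSupermatrix <- function(table, alnDir, genomes = NULL,
                             maxGapFraction = 0.5) {
  if (is.null(genomes)) genomes <- names(table[[1L]])
  ogs <- selectSingleCopy(table, genomes)
  if (!length(ogs)) stop("no single-copy-universal orthogroups", call. = FALSE)
  trimmed <- list(); keptCols <- list()
  for (og in ogs) {
    f <- NULL
    for (ext in c(".faa", ".fa", ".fasta")) {
      cand <- file.path(alnDir, paste0(og, ext))
      if (file.exists(cand)) { f <- cand; break }
    }
    if (is.null(f))
      stop(sprintf("alignment file for '%s' not found in %s", og, alnDir),
           call. = FALSE)
    aln <- readAAStringSet(f)
    names(aln) <- sub("\\s.*$", "", names(aln))   # gene id = prefix
    gene2genome <- stats::setNames(
      rep(genomes, vapply(table[[og]][genomes], length, integer(1L))),
      unlist(table[[og]][genomes], use.names = FALSE))
    hit <- names(aln) %in% names(gene2genome)
    aln <- aln[hit]
    names(aln) <- unname(gene2genome[names(aln)])
    if (!setequal(names(aln), genomes))
      stop(sprintf("alignment '%s' is missing genome(s): %s", og,
                   paste(setdiff(genomes, names(aln)), collapse = ", ")),
           call. = FALSE)
    tr <- trimAlignment(aln[genomes], maxGapFraction)
    trimmed[[og]] <- tr$alignment
    keptCols[[og]] <- tr$kept
  }
  list(supermatrix = concatenateAlignments(trimmed),
       keptColumns = keptCols, orthogroups = ogs)
}

#' Write a supermatrix as FASTA plus a RAxML/IQ-TREE partition file
#'
#' @param sm a [Supermatrix-class].
#' @param fastaPath output FASTA path.
#' @param partitionPath output partition file path (`AA, <og> = start-end`
#'   lines); omitted when NULL.
#' @return invisibly, the FASTA path.
#' @export
writeSupermatrix <- function(sm, fastaPath, partitionPath = NULL) {
  writeXStringSet(sm@sequences, fastaPath)
  if (!is.null(partitionPath)) {
    p <- sm@partitions
    writeLines(sprintf("AA, %s = %d-%d", names(p), IRanges::start(p),
                       IRanges::end(p)), partitionPath)
  }
  invisible(fastaPath)
}
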