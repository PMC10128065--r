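# Fragment-based average nucleotide identity (ANI), 16S identity and
# species-level clustering.
#
# ANI follows the classic fragment definition: the query is cut into
# consecutive 1,020-nt fragments, each fragment is aligned to its best hit
# in the reference, fragments are kept if the alignment reaches >= 30%
# identity over >= 70% of the fragment length, and ANI is the mean identity
# of the kept fragments. The aligner is seed-and-extend: exact 16-mer seeds
# vote on a diagonal, and the fragment is then aligned end-to-end against
# the seeded reference window (reference ends free).

ANI_FRAGMENT_LENGTH <- 1020L
ANI_MIN_IDENTITY    <- 0.30
ANI_MIN_COVERAGE    <- 0.70

.asGenome <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is(x, "DNAString")) return(DNAStringSet(x))
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(readDNAStringSet(x))
  if (is.character(x)) return(DNAStringSet(x))
  stop("expected a DNAStringSet, DNAString, sequence string or FASTA path",
       call. = FALSE)
}

# cut every contig into consecutive full-length fragments; a trailing
# remainder shorter than fragLen is dropped
.fragmentGenome <- function(genome, fragLen = ANI_FRAGMENT_LENGTH) {
  frags <- character(0L)
  chars <- as.character(genome)
  for (ci in seq_along(chars)) {
    L <- nchar(chars[ci])
    n <- L %/% fragLen
    if (n >= 1L) {
      starts <- (seq_len(n) - 1L) * fragLen + 1L
      frags <- c(frags, substring(chars[ci], starts, starts + fragLen - 1L))
    }
  }
  frags
}

# seed votes: for each fragment, the modal diagonal per reference contig.
# Returns a data.frame (fragment, contig, diag, votes) with one row per
# fragment that seeded anywhere; ties break toward the smallest diagonal.
.seedFragments <- function(frags, reference, seedLen = 16L, seedStep = 20L) {
  fragLen <- nchar(frags[1L])
  offsets <- seq.int(1L, fragLen - seedLen + 1L, by = seedStep)
  seedStr <- unlist(lapply(frags, substring, offsets, offsets + seedLen - 1L))
  seedFrag <- rep(seq_along(frags), each = length(offsets))
  seedOff <- rep(offsets, times = length(frags))
  clean <- !grepl("[^ACGT]", seedStr)
  if (!any(clean)) return(NULL)
  pd <- PDict(DNAStringSet(seedStr[clean]))
  seedFrag <- seedFrag[clean]; seedOff <- seedOff[clean]

  best <- NULL
  for (ci in seq_along(reference)) {
    mi <- matchPDict(pd, reference[[ci]])
    starts <- IRanges::start(mi)          # IntegerList, one element per seed
    hitsPerSeed <- lengths(starts)
    if (!sum(hitsPerSeed)) next
    hs <- unlist(starts, use.names = FALSE)
    hf <- rep(seedFrag, hitsPerSeed)
    ho <- rep(seedOff, hitsPerSeed)
    dg <- hs - ho                          # subject pos of fragment pos 1, minus 1
    for (f in unique(hf)) {
      d <- dg[hf == f]
      cnt <- table(d)
      vmax <- max(cnt)
      dbest <- min(as.integer(names(cnt)[cnt == vmax]))
      row <- data.frame(fragment = f, contig = ci, diag = dbest,
                        votes = as.integer(vmax))
      if (is.null(best)) best <- row else best <- rbind(best, row)
    }
  }
  if (is.null(best)) return(NULL)
  # keep the best-voted contig per fragment (smallest diag on ties)
  best <- best[order(best$fragment, -best$votes, best$diag), , drop = FALSE]
  best[!duplicated(best$fragment), , drop = FALSE]
}

#' Directional ANI of a query genome against a reference genome
#'
#' @param query,reference genome sequences: DNAStringSet (multi-contig
#'   allowed), a single sequence string, or a FASTA path.
#' @param fragLen fragment length in nt (default 1020).
#' @param minIdentity,minCoverage keep-filter: a fragment is retained when
#'   its alignment identity is at least `minIdentity` over at least
#'   `minCoverage` of the fragment length.
#' @return a list with `ani` (percent; NA when no fragment passes the
#'   filter, an explicit no-homology result), `nFragmentsTotal`,
#'   `nFragmentsKept`.
#' @seealso [symmetricAni()], [aniMatrix()]
#' @export
aniDirectional <- function(query, reference, fragLen = ANI_FRAGMENT_LENGTH,
                           minIdentity = ANI_MIN_IDENTITY,
                           minCoverage = ANI_MIN_COVERAGE) {
  query <- .asGenome(query); reference <- .asGenome(reference)
  if (!length(query) || !sum(Biostrings::width(query)) ||
      !length(reference) || !sum(Biostrings::width(reference)))
    stop("query and reference must be nonempty", call. = FALSE)
  frags <- .fragmentGenome(query, fragLen)
  nTotal <- length(frags)
  if (!nTotal)
    return(list(ani = NA_real_, nFragmentsTotal = 0L, nFragmentsKept = 0L))
  seeds <- .seedFragments(frags, reference)
  idents <- numeric(0L)
  if (!is.null(seeds)) {
    pad <- 30L
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                       mismatch = -1)
    for (r in seq_len(nrow(seeds))) {
      f <- seeds$fragment[r]
      ctg <- reference[[seeds$contig[r]]]
      ws <- max(1L, seeds$diag[r] + 1L - pad)
      we <- min(length(ctg), seeds$diag[r] + nchar(frags[f]) + pad)
      aln <- pairwiseAlignment(DNAString(frags[f]), subseq(ctg, ws, we),
                               type = "global-local",
                               substitutionMatrix = submat,
                               gapOpening = 4, gapExtension = 2)
      cols <- nchar(as.character(alignedPattern(aln)))
      alignedFrac <- (cols - Biostrings::nindel(aln)@deletion[1L, "WidthSum"]) /
        nchar(frags[f])
      # with glocal extension the whole fragment is aligned; alignedFrac
      # guards degenerate windows clipped at contig ends
      identity <- nmatch(aln) / cols
      if (identity >= minIdentity && alignedFrac >= minCoverage)
        idents <- c(idents, identity)
    }
  }
  if (!length(idents))
    return(list(ani = NA_real_, nFragmentsTotal = nTotal, nFragmentsKept = 0L))
  list(ani = 100 * mean(idents), nFragmentsTotal = nTotal,
       nFragmentsKept = length(idents))
}

#' Symmetric ANI of a genome pair
#'
#' The arithmetic mean of the two directional ANIs; when only one direction
#' finds homologous fragments, that direction is used; when neither does,
#' the result is NA.
#'
#' @inheritParams aniDirectional
#' @param ... passed on to [aniDirectional()].
#' @return ANI percent (numeric scalar, NA for a no-homology pair).
#' @export
symmetricAni <- function(query, reference, ...) {
  a <- aniDirectional(query, reference, ...)$ani
  b <- aniDirectional(reference, query, ...)$ani
  if (is.na(a) && is.na(b)) return(NA_real_)
  mean(c(a, b), na.rm = TRUE)
}

#' Pairwise symmetric ANI matrix over a set of genomes
#'
#' @param genomes named list of genomes (DNAStringSet / sequence strings /
#'   FASTA paths), or a character vector of FASTA paths named by genome id.
#' @param ... passed on to [aniDirectional()].
#' @return an [AniMatrix-class] with diagonal exactly 100.
#' @export
aniMatrix <- function(genomes, ...) {
  if (is.character(genomes)) genomes <- as.list(genomes)
  if (is.null(names(genomes)) || anyDuplicated(names(genomes)))
    stop("genomes must be uniquely named", call. = FALSE)
  seqs <- lapply(genomes, .asGenome)
  n <- length(seqs)
  m <- matrix(NA_real_, n, n, dimnames = list(names(seqs), names(seqs)))
  diag(m) <- 100
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      v <- symmetricAni(seqs[[i]], seqs[[j]], ...)
      m[i, j] <- m[j, i] <- v
    }
  }
  new("AniMatrix", ani = m)
}

#' Species-level clustering of genomes at an ANI threshold
#'
#' Single-linkage: genomes are nodes, an edge joins every pair with
#' ANI >= `threshold` (ties at the threshold join, since distinct species
#' are defined by ANI strictly below it), and clusters are the connected
#' components. NA (no-homology) pairs contribute no edge.
#'
#' @param ani an [AniMatrix-class] or a symmetric numeric percent matrix.
#' @param threshold ANI percent threshold (default 95, the conventional
#'   bacterial species boundary).
#' @return a [SpeciesClustering-class]; cluster ids follow first appearance
#'   in the input genome order.
#' @export
clusterSpecies <- function(ani, threshold = 95) {
  m <- if (is(ani, "AniMatrix")) as.matrix(ani) else ani
  if (!isTRUE(all.equal(m, t(m))))
    stop("ANI matrix must be symmetric", call. = FALSE)
  adj <- !is.na(m) & m >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  relabel <- match(comp, unique(comp))   # ids in first-appearance order
  new("SpeciesClustering",
      membership = stats::setNames(as.integer(relabel), rownames(m)),
      threshold = threshold)
}

#' Pairwise 16S rRNA gene identity
#'
#' Semi-global (ends-free) alignment with match +1, mismatch -1, gap
#' opening 2 and gap extension 0.5; identity is matches over aligned
#' columns, excluding terminal overhangs.
#'
#' @param a,b nucleotide sequences (DNAString, string, or single-record
#'   FASTA path); at least 500 nt each.
#' @return identity percent.
#' @export
identity16S <- function(a, b) {
  toDna <- function(x) {
    g <- .asGenome(x)
    if (length(g) != 1L) stop("expected a single 16S record", call. = FALSE)
    g[[1L]]
  }
  a <- toDna(a); b <- toDna(b)
  if (length(a) < 500L || length(b) < 500L)
    stop("16S sequences must be at least 500 nt", call. = FALSE)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- pairwiseAlignment(a, b, type = "overlap",
                           substitutionMatrix = submat,
                           gapOpening = 2, gapExtension = 0.5)
  cols <- nchar(as.character(alignedPattern(aln)))   # overhangs excluded
  100 * nmatch(aln) / cols
}

#' ANI versus 16S identity for all same-family genome pairs
#'
#' @param genomes named list of genome sequences (see [aniMatrix()]).
#' @param seqs16s named list (or DNAStringSet) of 16S sequences keyed by
#'   genome id; genomes without a 16S entry get NA identity.
#' @param families named character vector mapping genome id to bacterial
#'   family; only same-family pairs are compared.
#' @param ... passed on to [aniDirectional()].
#' @return data.frame with columns genome_a, genome_b, family, ani,
#'   identity_16s — one row per unordered same-family pair.
#' @export
aniVs16sTable <- function(genomes, seqs16s, families, ...) {
  ids <- names(genomes)
  if (is.null(ids)) stop("genomes must be named", call. = FALSE)
  if (!all(ids %in% names(families)))
    stop("every genome needs a family assignment", call. = FALSE)
  rows <- list()
  for (fam in unique(families[ids])) {
    members <- ids[families[ids] == fam]
    if (length(members) < 2L) next
    for (i in seq_len(length(members) - 1L))
      for (j in seq.int(i + 1L, length(members))) {
        ga <- members[i]; gb <- members[j]
        id16 <- if (!is.null(seqs16s) && ga %in% names(seqs16s) &&
                    gb %in% names(seqs16s))
          identity16S(seqs16s[[ga]], seqs16s[[gb]]) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          genome_a = ga, genome_b = gb, family = fam,
          ani = symmetricAni(genomes[[ga]], genomes[[gb]], ...),
          identity_16s = id16, stringsAsFactors = FALSE)
      }
  }
  if (!length(rows))
    return(data.frame(genome_a = character(), genome_b = character(),
                      family = character(), ani = numeric(),
                      identity_16s = numeric()))
  do.call(rbind, rows)
}
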