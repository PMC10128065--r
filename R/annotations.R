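# Reading and writing per-genome annotation tables (KO and CAZyme).

#' Construct a GenomeAnnotation
#'
#' @param genomeId genome identifier.
#' @param ko named list mapping gene id to a character vector of KO
#'   identifiers, or NULL.
#' @param cazymes named list mapping gene id to a character vector of CAZyme
#'   family labels (GH/PL/GT/CE/CBM + number), or NULL.
#' @return a [GenomeAnnotation-class].
#' @examples
#' GenomeAnnotation("g1", ko = list(gene1 = "K00844", gene2 = c("K01810")))
#' @export
GenomeAnnotation <- function(genomeId, ko = NULL, cazymes = NULL) {
  emptyMap <- structure(list(), names = character())
  new("GenomeAnnotation", genomeId = genomeId,
      ko = if (is.null(ko)) emptyMap else ko,
      cazymes = if (is.null(cazymes)) emptyMap else cazymes)
}

#' Read KO annotations from a long-format TSV
#'
#' Expects columns `genome_id`, `gene_id`, `KO` with one KO per line (a gene
#' with several KOs appears on several lines).
#'
#' @param path TSV path.
#' @return named list of [GenomeAnnotation-class], one per genome, in first
#'   appearance order.
#' @export
readKoAnnotations <- function(path) {
  df <- readTsv(path)
  need <- c("genome_id", "gene_id", "KO")
  if (!all(need %in% colnames(df)))
    stop(sprintf("expected columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  gids <- unique(df$genome_id)
  out <- lapply(gids, function(g) {
    sub <- df[df$genome_id == g, , drop = FALSE]
    ko <- split(sub$KO, factor(sub$gene_id, levels = unique(sub$gene_id)))
    GenomeAnnotation(g, ko = lapply(ko, unique))
  })
  stats::setNames(out, gids)
}

#' Write KO annotations to the long-format TSV read by [readKoAnnotations()]
#'
#' @param genomes list of [GenomeAnnotation-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeKoAnnotations <- function(genomes, path) {
  rows <- lapply(genomes, function(g) {
    if (!length(g@ko)) return(NULL)
    data.frame(genome_id = g@genomeId,
               gene_id = rep(names(g@ko), lengths(g@ko)),
               KO = unlist(g@ko, use.names = FALSE))
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(genome_id = character(), gene_id = character(),
                     KO = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read CAZyme family assignments from a dbCAN-style TSV
#'
#' Expects columns `genome_id`, `gene_id`, `family`; `family` may hold a
#' single label (e.g. `GH13`) or several joined by `+` as in dbCAN HMMER
#' output (`GH13+CBM48`).
#'
#' @param path TSV path.
#' @param genomes optional named list of existing [GenomeAnnotation-class]
#'   objects to attach the CAZyme assignments to (matched by genome id).
#' @return named list of [GenomeAnnotation-class].
#' @export
readCazymeAnnotations <- function(path, genomes = NULL) {
  df <- readTsv(path)
  need <- c("genome_id", "gene_id", "family")
  if (!all(need %in% colnames(df)))
    stop(sprintf("expected columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  # strip dbCAN coordinate suffixes like GH13(23-310), split fused labels
  fams <- gsub("\\([^)]*\\)", "", df$family)
  famList <- strsplit(fams, "+", fixed = TRUE)
  gids <- unique(df$genome_id)
  out <- lapply(gids, function(g) {
    idx <- which(df$genome_id == g)
    caz <- split(unlist(famList[idx], use.names = FALSE),
                 rep(factor(df$gene_id[idx], levels = unique(df$gene_id[idx])),
                     lengths(famList[idx])))
    caz <- lapply(caz, unique)
    if (!is.null(genomes) && g %in% names(genomes)) {
      ga <- genomes[[g]]
      ga@cazymes <- caz
      validObject(ga)
      ga
    } else GenomeAnnotation(g, cazymes = caz)
  })
  out <- stats::setNames(out, gids)
  if (!is.null(genomes)) {
    untouched <- setdiff(names(genomes), gids)
    out <- c(out, genomes[untouched])[union(names(genomes), gids)]
  }
  out
}

#' Count CAZyme genes per family and total GH / PL genes per genome
#'
#' A gene assigned to k families contributes one count to each of the k
#' families. Per-genome totals are reported over the glycoside hydrolase
#' (GH) and polysaccharide lyase (PL) families, the two classes most
#' relevant to carbohydrate degradation in bee-gut symbionts.
#'
#' @param genomes list of [GenomeAnnotation-class].
#' @return a [CazymeCountMatrix-class]; rows follow input genome order,
#'   family columns are sorted lexicographically.
#' @export
countCazymes <- function(genomes) {
  gids <- vapply(genomes, genomeId, character(1L))
  allFam <- sort(unique(unlist(lapply(genomes, function(g)
    unlist(g@cazymes, use.names = FALSE)), use.names = FALSE)))
  cnt <- matrix(0L, length(genomes), length(allFam),
                dimnames = list(gids, allFam))
  for (g in seq_along(genomes)) {
    fams <- unlist(genomes[[g]]@cazymes, use.names = FALSE)
    if (length(fams)) {
      tab <- table(factor(fams, levels = allFam))
      cnt[g, ] <- as.integer(tab)
    }
  }
  gh <- grepl("^GH", allFam); pl <- grepl("^PL", allFam)
  new("CazymeCountMatrix", counts = cnt,
      ghTotal = stats::setNames(as.integer(rowSums(cnt[, gh, drop = FALSE])), gids),
      plTotal = stats::setNames(as.integer(rowSums(cnt[, pl, drop = FALSE])), gids))
}
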