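#' @rdname CompletenessMatrix-class
#' @param object,x an object.
#' @export
setGeneric("completeness", function(x) standardGeneric("completeness"))

#' @rdname CompletenessMatrix-class
#' @export
setGeneric("stepsPresent", function(x) standardGeneric("stepsPresent"))

#' @rdname CompletenessMatrix-class
#' @export
setGeneric("stepsTotal", function(x) standardGeneric("stepsTotal"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' Union KO set of a genome annotation
#'
#' Pathway completeness is evaluated on the union of all KO assignments of a
#' genome; gene-level structure is ignored.
#'
#' @param x a [GenomeAnnotation-class] object.
#' @return character vector of unique KO identifiers, sorted.
#' @export
setGeneric("koSet", function(x) standardGeneric("koSet"))

#' @rdname CazymeCountMatrix-class
#' @export
setGeneric("cazymeCounts", function(x) standardGeneric("cazymeCounts"))

#' @rdname CazymeCountMatrix-class
#' @export
setGeneric("ghTotal", function(x) standardGeneric("ghTotal"))

#' @rdname CazymeCountMatrix-class
#' @export
setGeneric("plTotal", function(x) standardGeneric("plTotal"))

#' @rdname SpeciesClustering-class
#' @export
setGeneric("clusterMembership", function(x) standardGeneric("clusterMembership"))

#' @rdname SpeciesClustering-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname Supermatrix-class
#' @export
setGeneric("partitions", function(x) standardGeneric("partitions"))

setGeneric("aniThreshold", function(x) standardGeneric("aniThreshold"))

# ---- accessor methods ----

#' @rdname CompletenessMatrix-class
#' @export
setMethod("completeness", "CompletenessMatrix", function(x) x@completeness)

#' @rdname CompletenessMatrix-class
#' @export
setMethod("stepsPresent", "CompletenessMatrix", function(x) x@stepsPresent)

#' @rdname CompletenessMatrix-class
#' @export
setMethod("stepsTotal", "CompletenessMatrix", function(x) x@stepsTotal)

#' @rdname GenomeAnnotation-class
#' @export
setMethod("genomeId", "GenomeAnnotation", function(x) x@genomeId)

#' @rdname koSet
#' @export
setMethod("koSet", "GenomeAnnotation",
          function(x) sort(unique(unlist(x@ko, use.names = FALSE))))

#' @rdname CazymeCountMatrix-class
#' @export
setMethod("cazymeCounts", "CazymeCountMatrix", function(x) x@counts)

#' @rdname CazymeCountMatrix-class
#' @export
setMethod("ghTotal", "CazymeCountMatrix", function(x) x@ghTotal)

#' @rdname CazymeCountMatrix-class
#' @export
setMethod("plTotal", "CazymeCountMatrix", function(x) x@plTotal)

#' @rdname SpeciesClustering-class
#' @export
setMethod("clusterMembership", "SpeciesClustering", function(x) x@membership)

#' @rdname SpeciesClustering-class
#' @export
setMethod("nClusters", "SpeciesClustering",
          function(x) length(unique(x@membership)))

#' @rdname SpeciesClustering-class
#' @export
setMethod("aniThreshold", "SpeciesClustering", function(x) x@threshold)

#' @rdname AniMatrix-class
#' @param x an AniMatrix.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "AniMatrix", function(x, ...) x@ani)

#' @rdname Supermatrix-class
#' @export
setMethod("partitions", "Supermatrix", function(x) x@partitions)

#' @rdname Supermatrix-class
#' @param x a Supermatrix.
#' @export
setMethod("as.character", "Supermatrix",
          function(x) as.character(x@sequences))

# ---- show methods ----

setMethod("show", "PathwayRule", function(object) {
  cat(sprintf("PathwayRule '%s' [%s], %d step(s)\n",
              object@pathwayId, object@category, length(object@steps)))
  for (i in seq_along(object@stepText))
    cat(sprintf("  step %d: %s\n", i, object@stepText[i]))
})

setMethod("show", "GenomeAnnotation", function(object) {
  cat(sprintf(
    "GenomeAnnotation '%s': %d gene(s) with KOs (%d distinct KOs), %d CAZyme gene(s)\n",
    object@genomeId, length(object@ko), length(koSet(object)),
    length(object@cazymes)))
})

setMethod("show", "CompletenessMatrix", function(object) {
  cat(sprintf("CompletenessMatrix: %d genome(s) x %d pathway(s)\n",
              nrow(object@completeness), ncol(object@completeness)))
})

setMethod("show", "CazymeCountMatrix", function(object) {
  cat(sprintf("CazymeCountMatrix: %d genome(s) x %d family(ies)\n",
              nrow(object@counts), ncol(object@counts)))
})

setMethod("show", "AniMatrix", function(object) {
  cat(sprintf("AniMatrix: %d genome(s)\n", nrow(object@ani)))
})

setMethod("show", "SpeciesClustering", function(object) {
  cat(sprintf("SpeciesClustering: %d genome(s) in %d cluster(s) at ANI >= %g%%\n",
              length(object@membership), nClusters(object), object@threshold))
})

setMethod("show", "Supermatrix", function(object) {
  w <- if (length(object@sequences)) Biostrings::width(object@sequences)[1L] else 0L
  cat(sprintf("Supermatrix: %d genome(s), %d column(s), %d partition(s)\n",
              length(object@sequences), w, length(object@partitions)))
})
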