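#' @import methods
#' @importFrom stats lm deviance df.residual pf aggregate sd quantile
#'   p.adjust t.test rnorm rbinom runif setNames
#' @importFrom utils read.delim write.table packageVersion head
NULL

#' Gene identifiers held by an object
#'
#' @param x a \linkS4class{GeneUniverse}, \linkS4class{SignedGeneSet} or
#'   \linkS4class{AnnotationTrack}.
#' @return Character vector of normalized gene IDs.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Size of the gene universe an object refers to
#'
#' @param x a \linkS4class{GeneUniverse}, \linkS4class{AnnotationTrack} or
#'   \linkS4class{NullDistribution}.
#' @return Integer scalar N.
#' @export
setGeneric("universeSize", function(x) standardGeneric("universeSize"))

#' Label of a gene set or annotation track
#'
#' @param x a \linkS4class{SignedGeneSet} or \linkS4class{AnnotationTrack}.
#' @return Character scalar.
#' @export
setGeneric("geneSetLabel", function(x) standardGeneric("geneSetLabel"))

#' Per-gene directions of a signed gene set
#'
#' @param x a \linkS4class{SignedGeneSet}.
#' @return Named integer vector with values in \{-1, 0, +1\}; 0 marks a
#'   gene whose direction has not been assigned yet (raw table rows with
#'   log2 fold change exactly zero).
#' @export
setGeneric("geneDirections", function(x) standardGeneric("geneDirections"))

#' Restrict a gene set or annotation track to a universe
#'
#' Drops members absent from the universe so that hypergeometric marginals
#' are well defined. The number of dropped IDs is reported via
#' \code{message()}; an input that becomes empty while the original was not
#' raises a warning, never an error.
#'
#' @param x a \linkS4class{SignedGeneSet} or \linkS4class{AnnotationTrack}.
#' @param universe a \linkS4class{GeneUniverse}.
#' @return An object of the same class as \code{x}.
#' @export
setGeneric("restrictToUniverse",
           function(x, universe) standardGeneric("restrictToUniverse"))

#' @rdname OverlapResult-class
#' @param x an \linkS4class{OverlapResult}.
#' @export
setGeneric("overlapCount", function(x) standardGeneric("overlapCount"))

#' @rdname OverlapResult-class
#' @export
setGeneric("overlapPvalue", function(x) standardGeneric("overlapPvalue"))

#' @rdname OverlapResult-class
#' @export
setGeneric("directionPartition",
           function(x) standardGeneric("directionPartition"))

#' @rdname OverlapResult-class
#' @export
setGeneric("partitionPvalues",
           function(x) standardGeneric("partitionPvalues"))

#' @rdname OverlapResult-class
#' @param style \code{"exact"} (raw value), \code{"decimal"} (one decimal
#'   place) or \code{"integer"} (nearest integer, the style used when a
#'   percentage is quoted as e.g. 26\%).
#' @export
setGeneric("percentOfA",
           function(x, style = c("exact", "decimal", "integer"))
             standardGeneric("percentOfA"))

#' @rdname OverlapResult-class
#' @export
setGeneric("percentOfB",
           function(x, style = c("exact", "decimal", "integer"))
             standardGeneric("percentOfB"))

#' @rdname NullDistribution-class
#' @param x a \linkS4class{NullDistribution}.
#' @export
setGeneric("nullPvalues", function(x) standardGeneric("nullPvalues"))
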