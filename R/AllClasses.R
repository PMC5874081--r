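#' GeneUniverse: the finite reference set of genes
#'
#' The universe defines the population size N used by every hypergeometric
#' overlap probability in the package. IDs are normalized (uppercase,
#' transcript suffix after \code{"."} stripped) and must be unique.
#' An empty universe is representable (restriction to it yields empty sets
#' with a warning) but cannot be used for overlap testing.
#'
#' @slot ids character vector of unique normalized gene IDs.
#'
#' @examples
#' u <- geneUniverse(c("at1g01010", "AT1G01020.1", "AT2G00100"))
#' universeSize(u)
#' @name GeneUniverse-class
#' @aliases GeneUniverse
#' @exportClass GeneUniverse
setClass("GeneUniverse", slots = c(ids = "character"))

setValidity("GeneUniverse", function(object) {
  if (anyNA(object@ids)) return("ids must not contain NA")
  if (any(!nzchar(object@ids))) return("ids must not contain empty strings")
  if (anyDuplicated(object@ids)) return("duplicate gene IDs in universe")
  TRUE
})

#' @param ids character vector of gene IDs; normalized on construction.
#' @return \code{geneUniverse()} returns a \code{GeneUniverse}.
#' @rdname GeneUniverse-class
#' @export
geneUniverse <- function(ids) {
  new("GeneUniverse", ids = unique(normalizeGeneIds(as.character(ids))))
}

#' SignedGeneSet: a gene list with per-gene direction
#'
#' Represents a differentially-expressed-gene (DEG) list in which every
#' member carries a direction of change: +1 (up-regulated) or -1
#' (down-regulated). Raw DE tables read from file may temporarily hold
#' direction 0 for rows with a log2 fold change of exactly zero; such
#' members are rejected by \code{\link{filterDEGs}} if they survive the
#' significance filter and by all directional analyses. Optional per-gene
#' \code{log2fc} and \code{padj} (BH-adjusted p-value) columns are kept
#' when available so the significance filter can be applied after reading.
#'
#' @slot ids character, unique normalized gene IDs.
#' @slot direction integer in \{-1, 0, +1\}, parallel to \code{ids}.
#' @slot log2fc numeric, parallel to \code{ids}, or length 0 if absent.
#' @slot padj numeric in [0, 1], parallel to \code{ids}, or length 0.
#' @slot label character scalar naming the set.
#'
#' @examples
#' s <- signedGeneSet(c("AT1G01010", "AT1G01020"), direction = c(1L, -1L),
#'                    label = "demo")
#' geneDirections(s)
#' @name SignedGeneSet-class
#' @aliases SignedGeneSet
#' @exportClass SignedGeneSet
setClass("SignedGeneSet",
         slots = c(ids = "character", direction = "integer",
                   log2fc = "numeric", padj = "numeric",
                   label = "character"))

setValidity("SignedGeneSet", function(object) {
  n <- length(object@ids)
  if (anyNA(object@ids)) return("ids must not contain NA")
  if (anyDuplicated(object@ids)) return("duplicate gene IDs in set")
  if (length(object@direction) != n)
    return("direction must be parallel to ids")
  if (!all(object@direction %in% c(-1L, 0L, 1L)))
    return("direction values must be -1, 0 or +1")
  if (length(object@log2fc) != 0L && length(object@log2fc) != n)
    return("log2fc must be empty or parallel to ids")
  if (length(object@padj) != 0L) {
    if (length(object@padj) != n) return("padj must be empty or parallel to ids")
    ok <- is.na(object@padj) | (object@padj >= 0 & object@padj <= 1)
    if (!all(ok)) return("padj values must lie in [0, 1]")
  }
  if (length(object@label) != 1L) return("label must be a single string")
  TRUE
})

#' @param ids character vector of gene IDs (normalized on construction).
#' @param direction integer vector in \{-1, 0, +1\}, recycled if scalar.
#' @param log2fc optional numeric vector parallel to \code{ids}.
#' @param padj optional numeric vector in [0, 1] parallel to \code{ids}.
#' @param label character scalar naming the set.
#' @return \code{signedGeneSet()} returns a \code{SignedGeneSet}.
#' @rdname SignedGeneSet-class
#' @export
signedGeneSet <- function(ids, direction = 1L, log2fc = numeric(0),
                          padj = numeric(0), label = "gene_set") {
  ids <- normalizeGeneIds(as.character(ids))
  n <- length(ids)
  direction <- as.integer(direction)
  if (length(direction) == 1L) direction <- rep(direction, n)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    keep <- !duplicated(ids)
    for (d in dup) {
      dirs <- unique(direction[ids == d])
      if (length(dirs) > 1L)
        stop("conflicting directions for gene ", d)
    }
    ids <- ids[keep]; direction <- direction[keep]
    if (length(log2fc)) log2fc <- log2fc[keep]
    if (length(padj)) padj <- padj[keep]
  }
  new("SignedGeneSet", ids = ids, direction = direction,
      log2fc = as.numeric(log2fc), padj = as.numeric(padj),
      label = as.character(label))
}

#' AnnotationTrack: a binary gene label over a universe
#'
#' A set of genes sharing a chromatin/annotation label, e.g. genes with
#' high H2A.Z enrichment in their gene bodies, or H3K9-acetylated genes.
#' Members are constrained to lie inside the associated universe.
#'
#' @slot label character scalar, e.g. \code{"high_H2A.Z"}.
#' @slot ids character, unique normalized gene IDs, subset of the universe.
#' @slot universe the governing \linkS4class{GeneUniverse}.
#'
#' @name AnnotationTrack-class
#' @aliases AnnotationTrack
#' @exportClass AnnotationTrack
setClass("AnnotationTrack",
         slots = c(label = "character", ids = "character",
                   universe = "GeneUniverse"))

setValidity("AnnotationTrack", function(object) {
  if (length(object@label) != 1L) return("label must be a single string")
  if (anyDuplicated(object@ids)) return("duplicate gene IDs in track")
  if (!all(object@ids %in% object@universe@ids))
    return("track members must be a subset of the universe")
  TRUE
})

#' @param label character scalar.
#' @param ids character vector of member gene IDs.
#' @param universe a \linkS4class{GeneUniverse}.
#' @return \code{annotationTrack()} returns an \code{AnnotationTrack}.
#' @rdname AnnotationTrack-class
#' @export
annotationTrack <- function(label, ids, universe) {
  new("AnnotationTrack", label = as.character(label),
      ids = unique(normalizeGeneIds(as.character(ids))),
      universe = universe)
}

.PARTITION_CLASSES <- c("concordant_up", "concordant_down",
                        "discordant_a_up", "discordant_a_down")

#' OverlapResult: one pairwise overlap comparison
#'
#' Holds the counts and probabilities of a single overlap test between a
#' gene set A and a second set or annotation track B over a universe of
#' size N: the overlap count k, the hypergeometric upper-tail p-value,
#' the percentage of each list covered by the overlap, and (when both
#' inputs are signed) the directional partition of the overlap into the
#' four classes \code{concordant_up} (up in both), \code{concordant_down}
#' (down in both), \code{discordant_a_up} (up in A, down in B) and
#' \code{discordant_a_down} (down in A, up in B), each with its own
#' upper-tail p-value computed against the per-direction margins.
#'
#' @slot labelA,labelB character scalars naming the compared lists.
#' @slot N,nA,nB,k integer scalars: universe size, list sizes, overlap.
#' @slot pUpper numeric scalar, hypergeometric upper-tail probability.
#' @slot partition named integer of length 4 (or 0 if either input
#'   is unsigned); always sums to \code{k} when present.
#' @slot classP named numeric of length 4 (or 0), per-class p-values.
#' @slot percentA,percentB numeric scalars, 100*k/nA and 100*k/nB.
#'
#' @name OverlapResult-class
#' @aliases OverlapResult
#' @exportClass OverlapResult
setClass("OverlapResult",
         slots = c(labelA = "character", labelB = "character",
                   N = "integer", nA = "integer", nB = "integer",
                   k = "integer", pUpper = "numeric",
                   partition = "integer", classP = "numeric",
                   percentA = "numeric", percentB = "numeric"))

setValidity("OverlapResult", function(object) {
  with(list(o = object), {
    if (o@k < max(0L, o@nA + o@nB - o@N) || o@k > min(o@nA, o@nB))
      return("overlap count k outside the feasible hypergeometric support")
    if (!(o@pUpper > 0 && o@pUpper <= 1))
      return("pUpper must lie in (0, 1]")
    if (length(o@partition)) {
      if (!identical(names(o@partition), .PARTITION_CLASSES))
        return("partition must be named by the four direction classes")
      if (sum(o@partition) != o@k)
        return("directional partition counts must sum to k")
    }
    if (length(o@classP) &&
        !identical(names(o@classP), .PARTITION_CLASSES))
      return("classP must be named by the four direction classes")
    TRUE
  })
})

#' NullDistribution: empirical null of overlap p-values
#'
#' The sorted hypergeometric upper-tail p-values of K random gene-list
#' pairs resampled from a universe, used to locate observed overlap
#' p-values empirically (Monte Carlo calibration).
#'
#' @slot pvals sorted ascending numeric vector of length K, values in (0, 1].
#' @slot K integer, number of resampled pairs.
#' @slot universeSize integer N used for sampling and testing.
#' @slot sizeRange integer length 2, inclusive range of list sizes.
#' @slot seed integer seed the simulation was run with.
#'
#' @name NullDistribution-class
#' @aliases NullDistribution
#' @exportClass NullDistribution
setClass("NullDistribution",
         slots = c(pvals = "numeric", K = "integer",
                   universeSize = "integer", sizeRange = "integer",
                   seed = "integer"))

setValidity("NullDistribution", function(object) {
  if (length(object@pvals) != object@K)
    return("pvals length must equal K")
  if (any(object@pvals <= 0 | object@pvals > 1))
    return("null p-values must lie in (0, 1]")
  if (is.unsorted(object@pvals))
    return("pvals must be sorted ascending")
  if (length(object@sizeRange) != 2L ||
      object@sizeRange[1L] > object@sizeRange[2L])
    return("sizeRange must be (min, max) with min <= max")
  TRUE
})

#' AnovaResult: two-factor interaction ANOVA summary
#'
#' Sums of squares and degrees of freedom for the two main effects, the
#' interaction and the residual, together with the interaction F statistic
#' and its p-value. For unbalanced data the decomposition is the
#' model-comparison (Type II) one; on balanced designs it coincides with
#' the classical partition.
#'
#' @slot ss named numeric (factorA, factorB, interaction, residual).
#' @slot df named integer with the same names.
#' @slot fInteraction,pInteraction numeric scalars.
#'
#' @name AnovaResult-class
#' @aliases AnovaResult
#' @exportClass AnovaResult
setClass("AnovaResult",
         slots = c(ss = "numeric", df = "integer",
                   fInteraction = "numeric", pInteraction = "numeric"))

setValidity("AnovaResult", function(object) {
  nm <- c("factorA", "factorB", "interaction", "residual")
  if (!identical(names(object@ss), nm) || !identical(names(object@df), nm))
    return("ss and df must be named factorA, factorB, interaction, residual")
  if (any(object@ss < -1e-8)) return("sums of squares must be non-negative")
  TRUE
})

## ---- accessors ----

#' @rdname GeneUniverse-class
#' @param x,object a \code{GeneUniverse}.
#' @export
setMethod("geneIds", "GeneUniverse", function(x) x@ids)

#' @rdname GeneUniverse-class
#' @export
setMethod("universeSize", "GeneUniverse", function(x) length(x@ids))

#' @rdname GeneUniverse-class
#' @export
setMethod("length", "GeneUniverse", function(x) length(x@ids))

#' @rdname SignedGeneSet-class
#' @param x,object a \code{SignedGeneSet}.
#' @export
setMethod("geneIds", "SignedGeneSet", function(x) x@ids)

#' @rdname SignedGeneSet-class
#' @export
setMethod("geneDirections", "SignedGeneSet",
          function(x) setNames(x@direction, x@ids))

#' @rdname SignedGeneSet-class
#' @export
setMethod("geneSetLabel", "SignedGeneSet", function(x) x@label)

#' @rdname SignedGeneSet-class
#' @export
setMethod("length", "SignedGeneSet", function(x) length(x@ids))

#' @rdname AnnotationTrack-class
#' @param x,object an \code{AnnotationTrack}.
#' @export
setMethod("geneIds", "AnnotationTrack", function(x) x@ids)

#' @rdname AnnotationTrack-class
#' @export
setMethod("geneSetLabel", "AnnotationTrack", function(x) x@label)

#' @rdname AnnotationTrack-class
#' @export
setMethod("universeSize", "AnnotationTrack",
          function(x) length(x@universe@ids))

#' @rdname AnnotationTrack-class
#' @export
setMethod("length", "AnnotationTrack", function(x) length(x@ids))

#' @rdname OverlapResult-class
#' @export
setMethod("overlapCount", "OverlapResult", function(x) x@k)

#' @rdname OverlapResult-class
#' @export
setMethod("overlapPvalue", "OverlapResult", function(x) x@pUpper)

#' @rdname OverlapResult-class
#' @export
setMethod("directionPartition", "OverlapResult", function(x) x@partition)

#' @rdname OverlapResult-class
#' @export
setMethod("partitionPvalues", "OverlapResult", function(x) x@classP)

.stylePercent <- function(p, style) {
  switch(style, exact = p, decimal = round(p, 1), integer = round(p))
}

#' @rdname OverlapResult-class
#' @export
setMethod("percentOfA", "OverlapResult", function(x, style = c("exact", "decimal", "integer")) {
  .stylePercent(x@percentA, match.arg(style))
})

#' @rdname OverlapResult-class
#' @export
setMethod("percentOfB", "OverlapResult", function(x, style = c("exact", "decimal", "integer")) {
  .stylePercent(x@percentB, match.arg(style))
})

#' @rdname NullDistribution-class
#' @export
setMethod("nullPvalues", "NullDistribution", function(x) x@pvals)

#' @rdname NullDistribution-class
#' @export
setMethod("universeSize", "NullDistribution", function(x) x@universeSize)

#' @rdname NullDistribution-class
#' @export
setMethod("length", "NullDistribution", function(x) x@K)

## ---- show methods ----

setMethod("show", "GeneUniverse", function(object) {
  cat("GeneUniverse with", length(object@ids), "genes\n")
  if (length(object@ids))
    cat("  head:", paste(head(object@ids, 4L), collapse = ", "), "...\n")
})

setMethod("show", "SignedGeneSet", function(object) {
  up <- sum(object@direction == 1L)
  dn <- sum(object@direction == -1L)
  z <- sum(object@direction == 0L)
  cat("SignedGeneSet \"", object@label, "\": ", length(object@ids),
      " genes (", up, " up, ", dn, " down",
      if (z) paste0(", ", z, " unassigned") else "", ")\n", sep = "")
  cat("  log2fc: ", if (length(object@log2fc)) "present" else "absent",
      "; padj: ", if (length(object@padj)) "present" else "absent",
      "\n", sep = "")
})

setMethod("show", "AnnotationTrack", function(object) {
  cat("AnnotationTrack \"", object@label, "\": ", length(object@ids),
      " of ", length(object@universe@ids), " universe genes\n", sep = "")
})

setMethod("show", "OverlapResult", function(object) {
  cat("OverlapResult: ", object@labelA, " vs ", object@labelB, "\n", sep = "")
  cat(sprintf("  N = %d, n_a = %d, n_b = %d, k = %d\n",
              object@N, object@nA, object@nB, object@k))
  cat(sprintf("  p_upper = %.4g; %% of A = %.1f (%d); %% of B = %.1f (%d)\n",
              object@pUpper, round(object@percentA, 1),
              round(object@percentA), round(object@percentB, 1),
              round(object@percentB)))
  if (length(object@partition)) {
    cat("  direction partition:\n")
    for (cl in .PARTITION_CLASSES)
      cat(sprintf("    %-18s %6d  (p = %.4g)\n", cl,
                  object@partition[[cl]], object@classP[[cl]]))
  }
})

setMethod("show", "NullDistribution", function(object) {
  cat("NullDistribution: K =", object@K, "random list pairs, N =",
      object@universeSize, "\n")
  cat(sprintf("  list sizes in [%d, %d], seed %d\n",
              object@sizeRange[1L], object@sizeRange[2L], object@seed))
  cat(sprintf("  min p = %.3g, fraction <= 0.05: %.4f\n",
              min(object@pvals), mean(object@pvals <= 0.05)))
})

setMethod("show", "AnovaResult", function(object) {
  cat("Two-factor ANOVA with interaction\n")
  tab <- data.frame(SS = object@ss, df = object@df)
  print(tab)
  cat(sprintf("  interaction: F(%d, %d) = %.4g, p = %.4g\n",
              object@df[["interaction"]], object@df[["residual"]],
              object@fInteraction, object@pInteraction))
})
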