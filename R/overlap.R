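#' Hypergeometric tail probability of a set overlap
#'
#' For two sets of sizes \code{nA} and \code{nB} drawn from a universe of
#' size \code{N}, the overlap size X is hypergeometric. The enrichment
#' test used throughout the package is the upper tail P[X >= k]; a lower
#' tail P[X <= k] (depletion) is available behind the \code{tail} flag but
#' is never the default.
#'
#' The sum is accumulated in log space from log-gamma binomial
#' coefficients (log-sum-exp), so probabilities are accurate down to the
#' smallest positive normal double (~1e-308); a result is never reported
#' as exactly zero.
#'
#' @param k observed overlap count (vectorized).
#' @param nA,nB set sizes.
#' @param N universe size.
#' @param tail \code{"upper"} for enrichment (default), \code{"lower"}
#'   for depletion.
#' @return Numeric vector of probabilities in (0, 1].
#' @examples
#' hypergeomUpperTail(3, 5, 5, 20)
#' hypergeomUpperTail(0, 5, 5, 20)  # certain event: 1
#' @export
hypergeomUpperTail <- function(k, nA, nB, N, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  stopifnot(length(nA) == 1L, length(nB) == 1L, length(N) == 1L)
  nA <- as.integer(nA); nB <- as.integer(nB); N <- as.integer(N)
  k <- as.integer(k)
  if (N < 0L || nA < 0L || nB < 0L || nA > N || nB > N)
    stop("margins must satisfy 0 <= nA, nB <= N")
  lo <- max(0L, nA + nB - N)
  hi <- min(nA, nB)
  if (any(k < lo | k > hi))
    stop("k outside the feasible support [", lo, ", ", hi, "]")
  vapply(k, function(ki) {
    j <- if (tail == "upper") ki:hi else lo:ki
    lt <- lchoose(nA, j) + lchoose(N - nA, nB - j) - lchoose(N, nB)
    m <- max(lt)
    p <- exp(m + log(sum(exp(lt - m))))
    if ((tail == "upper" && ki <= lo) || (tail == "lower" && ki >= hi))
      p <- 1
    min(max(p, .Machine$double.xmin), 1)
  }, numeric(1))
}

.percent <- function(k, n) if (n > 0L) 100 * k / n else NA_real_

.signedDirections <- function(x) {
  if (!is(x, "SignedGeneSet")) return(NULL)
  d <- geneDirections(x)
  if (any(d == 0L))
    stop("set \"", geneSetLabel(x), "\" contains members without a ",
         "+/-1 direction; run filterDEGs first")
  d
}

#' Test the overlap of a gene set against a second set or track
#'
#' Restricts both inputs to the universe, counts the overlap k and
#' computes the hypergeometric upper-tail probability of observing an
#' overlap at least that large, together with the percentage of each list
#' covered. When both inputs are signed DEG lists the overlap is further
#' partitioned into the four direction classes (up in both, down in both,
#' up in A/down in B, down in A/up in B) and each class count receives its
#' own upper-tail p-value, computed against the per-direction margins
#' (e.g. up-genes of A vs up-genes of B) over the same N.
#'
#' @param a a \linkS4class{SignedGeneSet}.
#' @param b a \linkS4class{SignedGeneSet} or \linkS4class{AnnotationTrack}.
#' @param universe the governing \linkS4class{GeneUniverse}.
#' @param tail passed to \code{\link{hypergeomUpperTail}}; the default
#'   tests enrichment.
#' @return An \linkS4class{OverlapResult}.
#' @examples
#' u <- geneUniverse(sprintf("G%02d", 1:10))
#' a <- signedGeneSet(c("G01", "G02", "G03"), c(1L, 1L, -1L), label = "a")
#' b <- signedGeneSet(c("G02", "G03", "G04"), c(1L, 1L, -1L), label = "b")
#' overlapTest(a, b, u)
#' @export
overlapTest <- function(a, b, universe, tail = "upper") {
  stopifnot(is(a, "SignedGeneSet"),
            is(b, "SignedGeneSet") || is(b, "AnnotationTrack"),
            is(universe, "GeneUniverse"))
  N <- length(universe)
  if (N == 0L) stop("overlap testing requires a non-empty universe")
  a <- suppressMessages(restrictToUniverse(a, universe))
  b <- suppressMessages(restrictToUniverse(b, universe))
  idsA <- geneIds(a); idsB <- geneIds(b)
  nA <- length(idsA); nB <- length(idsB)
  shared <- intersect(idsA, idsB)
  k <- length(shared)
  pUpper <- hypergeomUpperTail(k, nA, nB, N, tail = tail)

  partition <- integer(0)
  classP <- numeric(0)
  if (is(b, "SignedGeneSet")) {
    dA <- .signedDirections(a)
    dB <- .signedDirections(b)
    da <- dA[shared]; db <- dB[shared]
    counts <- c(concordant_up     = sum(da == 1L & db == 1L),
                concordant_down   = sum(da == -1L & db == -1L),
                discordant_a_up   = sum(da == 1L & db == -1L),
                discordant_a_down = sum(da == -1L & db == 1L))
    margins <- list(
      concordant_up     = c(sum(dA == 1L),  sum(dB == 1L)),
      concordant_down   = c(sum(dA == -1L), sum(dB == -1L)),
      discordant_a_up   = c(sum(dA == 1L),  sum(dB == -1L)),
      discordant_a_down = c(sum(dA == -1L), sum(dB == 1L)))
    classP <- vapply(.PARTITION_CLASSES, function(cl) {
      m <- margins[[cl]]
      hypergeomUpperTail(counts[[cl]], m[1L], m[2L], N, tail = tail)
    }, numeric(1))
    partition <- as.integer(counts)
    names(partition) <- .PARTITION_CLASSES
  }

  new("OverlapResult",
      labelA = geneSetLabel(a), labelB = geneSetLabel(b),
      N = N, nA = nA, nB = nB, k = as.integer(k), pUpper = pUpper,
      partition = partition, classP = classP,
      percentA = .percent(k, nA), percentB = .percent(k, nB))
}

#' Overlap of a gene set against each of several annotation strata
#'
#' Runs \code{\link{overlapTest}} of \code{a} against every stratum (for
#' example H3K9ac genes split by high vs low gene-body H2A.Z), all tested
#' against the same universe size N. Strata may overlap; disjointness is
#' not assumed.
#'
#' @param a a \linkS4class{SignedGeneSet}.
#' @param strata non-empty list of \linkS4class{AnnotationTrack}s.
#' @param universe the governing \linkS4class{GeneUniverse}.
#' @return A list of \linkS4class{OverlapResult}, named by stratum label.
#' @seealso \code{\link{intersectTracks}} to build strata such as
#'   "H3K9ac AND high_H2A.Z".
#' @export
stratifiedOverlap <- function(a, strata, universe) {
  stopifnot(length(strata) >= 1L,
            all(vapply(strata, is, logical(1), "AnnotationTrack")))
  res <- lapply(strata, overlapTest, a = a, universe = universe)
  names(res) <- vapply(strata, geneSetLabel, character(1))
  res
}

#' Intersect two annotation tracks
#'
#' @param x,y \linkS4class{AnnotationTrack}s over the same universe.
#' @param label label for the result; defaults to
#'   \code{"<x> AND <y>"}.
#' @return An \linkS4class{AnnotationTrack}.
#' @export
intersectTracks <- function(x, y, label = NULL) {
  stopifnot(is(x, "AnnotationTrack"), is(y, "AnnotationTrack"))
  if (is.null(label))
    label <- paste(geneSetLabel(x), "AND", geneSetLabel(y))
  annotationTrack(label, intersect(geneIds(x), geneIds(y)), x@universe)
}

#' One-sided Fisher exact test for enrichment
#'
#' For the 2x2 table with cells a (in set and annotated), b (in set, not
#' annotated), c (annotated, not in set) and d (neither), the one-sided
#' (enrichment) Fisher exact p-value equals the hypergeometric upper tail
#' \code{hypergeomUpperTail(a, a + b, a + c, a + b + c + d)}, and is
#' computed exactly that way.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return The one-sided enrichment p-value.
#' @examples
#' fisherExactUpper(5, 0, 0, 5)  # 1 / choose(10, 5)
#' @export
fisherExactUpper <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(length(cells) == 4L, all(cells >= 0),
            all(cells == as.integer(cells)))
  N <- a + b + c + d
  hypergeomUpperTail(a, a + b, a + c, N)
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up false-discovery-rate adjustment valid under arbitrary
#' dependence, inflating by the harmonic-sum factor
#' c(m) = sum_{i=1..m} 1/i. Delegates to \code{stats::p.adjust(method =
#' "BY")}; adjusted values are clipped to 1 and are monotone
#' non-decreasing in rank order.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return Numeric vector of adjusted p-values, same length and order.
#' @examples
#' benjaminiYekutieli(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjaminiYekutieli <- function(pvals) {
  stopifnot(is.numeric(pvals), all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  if (!length(pvals)) return(numeric(0))
  p.adjust(pvals, method = "BY")
}

#' Flatten overlap results to a data frame
#'
#' One row per comparison with the columns written to the pipeline's
#' overlap TSV: labels, margins, overlap count, upper-tail p-value,
#' direction-class counts and p-values, and percents at one-decimal and
#' nearest-integer precision.
#'
#' @param x an \linkS4class{OverlapResult} or a list of them.
#' @param row.names,optional,... ignored; present for the S3 generic.
#' @return A \code{data.frame}.
#' @export
overlapResultTable <- function(x) {
  if (is(x, "OverlapResult")) x <- list(x)
  stopifnot(all(vapply(x, is, logical(1), "OverlapResult")))
  rows <- lapply(x, function(r) {
    base <- data.frame(
      label_a = r@labelA, label_b = r@labelB,
      N = r@N, n_a = r@nA, n_b = r@nB, k = r@k, p_upper = r@pUpper,
      percent_of_a = round(r@percentA, 1),
      percent_of_a_int = round(r@percentA),
      percent_of_b = round(r@percentB, 1),
      percent_of_b_int = round(r@percentB),
      stringsAsFactors = FALSE)
    if (length(r@partition)) {
      for (cl in .PARTITION_CLASSES) {
        base[[paste0("n_", cl)]] <- r@partition[[cl]]
        base[[paste0("p_", cl)]] <- r@classP[[cl]]
      }
    } else {
      for (cl in .PARTITION_CLASSES) {
        base[[paste0("n_", cl)]] <- NA_integer_
        base[[paste0("p_", cl)]] <- NA_real_
      }
    }
    base
  })
  do.call(rbind, rows)
}

#' @describeIn overlapResultTable S3 coercion calling
#'   \code{overlapResultTable}.
#' @export
as.data.frame.OverlapResult <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  overlapResultTable(x)
}
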