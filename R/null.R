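#' Simulate the empirical null of overlap p-values
#'
#' Builds the Monte Carlo null against which observed overlap p-values
#' are calibrated: K random pairs of gene lists are drawn from the
#' universe and the hypergeometric upper-tail probability of each pair's
#' chance overlap is recorded. Per replicate, the seeded generator is
#' consumed in the fixed order size_a, list_a, size_b, list_b; the two
#' list sizes are drawn independently and uniformly over the integer
#' \code{sizeRange}, and each list is sampled without replacement,
#' independently of the other, so overlap arises by chance alone.
#'
#' Because a valid p-value is super-uniform under its null, the fraction
#' of simulated values at or below alpha is close to (never far above)
#' alpha; the distribution is the reference for
#' \code{\link{empiricalPercentile}} and \code{\link{nullReport}}.
#'
#' @param universe a \linkS4class{GeneUniverse} (only its size matters).
#' @param K number of resampled pairs; the full-scale default is 100000,
#'   scaled-down runs commonly use 10000.
#' @param sizeRange integer (min, max) of list sizes, inclusive;
#'   default c(500, 2000).
#' @param seed integer seed; runs are reproducible given the same seed
#'   and R's default Mersenne-Twister generator (recorded on
#'   serialization).
#' @return A \linkS4class{NullDistribution}.
#' @export
simulateNull <- function(universe, K = 100000L, sizeRange = c(500L, 2000L),
                         seed = 1L) {
  stopifnot(is(universe, "GeneUniverse"), K >= 1L)
  N <- length(universe)
  sizeRange <- as.integer(sizeRange)
  if (length(sizeRange) != 2L || sizeRange[1L] > sizeRange[2L])
    stop("sizeRange must be (min, max) with min <= max")
  if (sizeRange[2L] > N)
    stop("maximum list size exceeds the universe size")
  K <- as.integer(K)
  sizes <- sizeRange[1L]:sizeRange[2L]
  pvals <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(K), function(i) {
      sizeA <- if (length(sizes) == 1L) sizes else sample(sizes, 1L)
      listA <- sample.int(N, sizeA)
      sizeB <- if (length(sizes) == 1L) sizes else sample(sizes, 1L)
      listB <- sample.int(N, sizeB)
      k <- sum(listB %in% listA)
      hypergeomUpperTail(k, sizeA, sizeB, N)
    }, numeric(1))
  })
  new("NullDistribution", pvals = sort(pvals), K = K,
      universeSize = N, sizeRange = sizeRange, seed = as.integer(seed))
}

#' Locate an observed p-value in the empirical null
#'
#' @param nd a \linkS4class{NullDistribution}.
#' @param pObs observed probability (vectorized).
#' @return A data frame with, per observation, \code{fraction} = (number
#'   of null p-values <= pObs) / K and \code{empirical_p} = the add-one
#'   estimate (count + 1) / (K + 1), the recommended empirical p-value
#'   (it can never be exactly zero).
#' @examples
#' nd <- simulateNull(geneUniverse(sprintf("G%03d", 1:500)), K = 50,
#'                    sizeRange = c(10, 50), seed = 7)
#' empiricalPercentile(nd, 0.05)
#' @export
empiricalPercentile <- function(nd, pObs) {
  stopifnot(is(nd, "NullDistribution"), length(nd@pvals) >= 1L)
  count <- findInterval(pObs, nd@pvals)  # pvals sorted: count of <= pObs
  data.frame(p_obs = pObs,
             fraction = count / nd@K,
             empirical_p = (count + 1) / (nd@K + 1))
}

#' Summarize a null distribution and place observed overlaps in it
#'
#' Produces the summary used to judge observed overlap p-values against
#' the simulated chance distribution: quantiles of the null, the fraction
#' of simulated tests below 0.05 (the sub-distribution usually displayed),
#' and for each observation its empirical percentile, with a flag when the
#' observed value falls entirely below the simulated minimum (outside the
#' null distribution).
#'
#' @param nd a \linkS4class{NullDistribution}.
#' @param observed optional data frame with columns \code{label} and
#'   \code{p} (or a named numeric vector) of observed p-values.
#' @return A list with elements \code{summary} (one-row data frame) and
#'   \code{observations} (data frame, NULL rows when nothing observed).
#' @export
nullReport <- function(nd, observed = NULL) {
  stopifnot(is(nd, "NullDistribution"))
  p <- nd@pvals
  summary <- data.frame(
    K = nd@K, N = nd@universeSize,
    size_min = nd@sizeRange[1L], size_max = nd@sizeRange[2L],
    min_p = min(p), q25 = quantile(p, 0.25, names = FALSE),
    median = quantile(p, 0.5, names = FALSE),
    q75 = quantile(p, 0.75, names = FALSE),
    fraction_below_0.05 = mean(p < 0.05))
  if (is.null(observed)) {
    obs <- data.frame(label = character(0), p_obs = numeric(0),
                      fraction = numeric(0), empirical_p = numeric(0),
                      outside_null = logical(0))
  } else {
    if (is.numeric(observed))
      observed <- data.frame(label = names(observed), p = unname(observed))
    stopifnot(all(c("label", "p") %in% names(observed)))
    loc <- empiricalPercentile(nd, observed$p)
    obs <- data.frame(label = observed$label, loc,
                      outside_null = observed$p < min(p))
  }
  list(summary = summary, observations = obs)
}

#' Serialize / deserialize a null distribution as TSV
#'
#' The file has metadata header lines (\code{#K}, \code{#N},
#' \code{#size_range}, \code{#seed}, \code{#rng}) followed by two
#' columns, replicate and p. \code{readNullDistribution} inverts it.
#'
#' @param nd a \linkS4class{NullDistribution}.
#' @param path output/input file.
#' @return \code{writeNullDistribution}: \code{path} invisibly;
#'   \code{readNullDistribution}: a \linkS4class{NullDistribution}.
#' @export
writeNullDistribution <- function(nd, path) {
  stopifnot(is(nd, "NullDistribution"))
  header <- c(paste0("#K=", nd@K),
              paste0("#N=", nd@universeSize),
              paste0("#size_range=", nd@sizeRange[1L], "-", nd@sizeRange[2L]),
              paste0("#seed=", nd@seed),
              paste0("#rng=", RNGkind()[1L]),
              "replicate\tp")
  body <- paste(seq_len(nd@K), format(nd@pvals, digits = 17), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname writeNullDistribution
#' @export
readNullDistribution <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  val <- function(key) sub(paste0("^#", key, "="), "",
                           meta[startsWith(meta, paste0("#", key, "="))][1L])
  rng <- strsplit(val("size_range"), "-", fixed = TRUE)[[1L]]
  tab <- read.delim(text = lines[!startsWith(lines, "#")], sep = "\t")
  new("NullDistribution", pvals = sort(as.numeric(tab$p)),
      K = as.integer(val("K")), universeSize = as.integer(val("N")),
      sizeRange = as.integer(rng), seed = as.integer(val("seed")))
}

#' Histogram of log-transformed null p-values
#'
#' Plots the frequency distribution of -log10 of the simulated null
#' p-values (log-transformed so the magnitudes of extreme observed
#' overlaps can be compared against it), with observed values marked as
#' vertical lines.
#'
#' @param nd a \linkS4class{NullDistribution}.
#' @param observed optional named numeric vector of observed p-values.
#' @param ... passed to \code{graphics::hist}.
#' @return The histogram object, invisibly.
#' @importFrom graphics hist abline mtext
#' @export
plotNullHistogram <- function(nd, observed = NULL, ...) {
  stopifnot(is(nd, "NullDistribution"))
  lp <- -log10(nd@pvals)
  xmax <- max(lp, if (!is.null(observed)) -log10(observed))
  h <- hist(lp, main = "Null distribution of overlap p-values",
            xlab = "-log10(p)", xlim = c(0, xmax * 1.05), ...)
  if (!is.null(observed)) {
    abline(v = -log10(observed), col = "red3", lwd = 2)
    mtext(names(observed), at = -log10(observed), side = 3, cex = 0.7)
  }
  invisible(h)
}
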