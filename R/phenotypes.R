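#' Validate a two-factor phenotype table
#'
#' A phenotype table is a data frame with columns \code{factor_a} (e.g.
#' genotype), \code{factor_b} (e.g. growth temperature),
#' \code{replicate} and \code{value} (the measurement, e.g. hypocotyl
#' length in mm). For interaction testing every factor needs at least two
#' levels, every cell at least one observation, and at least one cell
#' more than one observation (so the residual has degrees of freedom).
#'
#' @param df data frame to validate.
#' @param requireComplete if TRUE (default) an empty cell is an error
#'   naming the cell.
#' @return The validated data frame (factors coerced), invisibly usable
#'   downstream.
#' @export
phenotypeTable <- function(df, requireComplete = TRUE) {
  need <- c("factor_a", "factor_b", "value")
  if (!all(need %in% names(df)))
    stop("phenotype table needs columns ", paste(need, collapse = ", "))
  df$factor_a <- factor(df$factor_a)
  df$factor_b <- factor(df$factor_b)
  df$value <- as.numeric(df$value)
  if (anyNA(df$value)) stop("phenotype values must be numeric, no NA")
  if (nlevels(df$factor_a) < 2L || nlevels(df$factor_b) < 2L)
    stop("each factor needs at least two levels")
  if (requireComplete) {
    counts <- table(df$factor_a, df$factor_b)
    if (any(counts == 0L)) {
      idx <- which(counts == 0L, arr.ind = TRUE)[1L, ]
      stop("empty cell: factor_a=", rownames(counts)[idx[1L]],
           ", factor_b=", colnames(counts)[idx[2L]])
    }
  }
  df
}

#' Two-factor ANOVA with interaction
#'
#' Fits the two-factor fixed-effects model with interaction and tests the
#' interaction term — the statistic behind genotype-by-environment (GxE),
#' drug-by-genotype and drug-by-temperature claims. The interaction sum
#' of squares is obtained by model comparison (Type II): the residual SS
#' of the additive model minus that of the full model, which on balanced
#' designs coincides with the classical partition. F is the interaction
#' mean square over the residual mean square of the full model; the
#' p-value comes from the F distribution.
#'
#' @param df a phenotype table (see \code{\link{phenotypeTable}}).
#' @return An \linkS4class{AnovaResult}.
#' @examples
#' df <- generatePhenotypes(generatorConfig(
#'   phenotype = list(betaInt = 2, sigma = 0.5, n = 5), seed = 1))
#' twoWayAnovaInteraction(df)
#' @export
twoWayAnovaInteraction <- function(df) {
  df <- phenotypeTable(df)
  nCells <- nlevels(df$factor_a) * nlevels(df$factor_b)
  dfRes <- nrow(df) - nCells
  if (dfRes < 1L)
    stop("no residual degrees of freedom: need replication within cells")
  full <- lm(value ~ factor_a * factor_b, data = df)
  additive <- lm(value ~ factor_a + factor_b, data = df)
  onlyB <- lm(value ~ factor_b, data = df)
  onlyA <- lm(value ~ factor_a, data = df)
  ssRes <- deviance(full)
  ssInt <- max(deviance(additive) - ssRes, 0)
  ssA <- max(deviance(onlyB) - deviance(additive), 0)
  ssB <- max(deviance(onlyA) - deviance(additive), 0)
  dfInt <- (nlevels(df$factor_a) - 1L) * (nlevels(df$factor_b) - 1L)
  msInt <- ssInt / dfInt
  msRes <- ssRes / dfRes
  f <- if (msRes > 0) msInt / msRes else if (msInt > 0) Inf else 0
  p <- pf(f, dfInt, dfRes, lower.tail = FALSE)
  new("AnovaResult",
      ss = c(factorA = ssA, factorB = ssB,
             interaction = ssInt, residual = ssRes),
      df = c(factorA = nlevels(df$factor_a) - 1L,
             factorB = nlevels(df$factor_b) - 1L,
             interaction = dfInt, residual = as.integer(dfRes)),
      fInteraction = f, pInteraction = p)
}

#' Student's t-test between two groups
#'
#' Two-sided test of equal means. The default is the classical pooled-
#' variance Student's t (degrees of freedom n1 + n2 - 2); Welch's unequal-
#' variance form is available behind the \code{welch} flag. When both
#' groups have zero variance and equal means the test is degenerate and
#' returns t = 0, p = 1 by convention; zero variance with unequal means
#' returns p = 0 with an infinite t.
#'
#' @param group1,group2 numeric vectors, each with >= 2 observations.
#' @param welch use Welch's correction instead of pooled variance.
#' @return A list with elements \code{t}, \code{df} and \code{p}.
#' @examples
#' studentsT(c(2.1, 2.5, 2.3), c(3.1, 3.3, 2.9))
#' @export
studentsT <- function(group1, group2, welch = FALSE) {
  stopifnot(length(group1) >= 2L, length(group2) >= 2L)
  if (sd(group1) == 0 && sd(group2) == 0) {
    df <- if (welch) NA_real_ else length(group1) + length(group2) - 2
    if (mean(group1) == mean(group2))
      return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mean(group1) - mean(group2)) * Inf, df = df, p = 0))
  }
  fit <- t.test(group1, group2, var.equal = !welch)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Cell means and standard errors for reaction-norm plots
#'
#' Summarizes a phenotype table into per-cell mean, standard error and n,
#' the quantities plotted as reaction norms (the profile of a phenotype's
#' mean across environments for each genotype). Cells with a single
#' observation get a missing standard error.
#'
#' @param df a phenotype table; empty cells are allowed here.
#' @return Data frame with columns factor_a, factor_b, n, mean, se.
#' @export
reactionNormSummary <- function(df) {
  df <- phenotypeTable(df, requireComplete = FALSE)
  agg <- aggregate(value ~ factor_a + factor_b, data = df,
                   FUN = function(v) c(n = length(v), mean = mean(v),
                                       se = if (length(v) > 1L)
                                         sd(v) / sqrt(length(v))
                                       else NA_real_))
  out <- data.frame(factor_a = agg$factor_a, factor_b = agg$factor_b,
                    n = as.integer(agg$value[, "n"]),
                    mean = agg$value[, "mean"], se = agg$value[, "se"])
  out[order(out$factor_a, out$factor_b), , drop = FALSE]
}

#' Read / write phenotype tables as TSV
#'
#' @param path file with header columns factor_a, factor_b, replicate,
#'   value.
#' @return \code{readPhenotypeTable}: a validated data frame.
#' @export
readPhenotypeTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  phenotypeTable(read.delim(path, sep = "\t", comment.char = "#"),
                 requireComplete = FALSE)
}

#' @rdname readPhenotypeTable
#' @param df a phenotype table.
#' @export
writePhenotypeTable <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
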