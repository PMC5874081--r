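# Independent oracles used to freeze expected values. Each takes a
# different computational path from the implementation it checks.

# P[X >= k] by brute-force enumeration of every nB-subset of 1..N against
# the fixed set 1..nA. Only feasible for small N.
enumHyperOracle <- function(k, nA, nB, N) {
  if (nB == 0L) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, nB)
  mean(colSums(subsets <= nA) >= k)
}

# P[X >= k] by direct term-wise summation of the hypergeometric pmf in
# linear space with base choose().
sumHyperOracle <- function(k, nA, nB, N) {
  j <- k:min(nA, nB)
  sum(choose(nA, j) * choose(N - nA, nB - j)) / choose(N, nB)
}

# Benjamini-Yekutieli by the rank formula p * m * c(m) / i with step-up
# cummin from the largest rank.
byOracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  raw <- pmin(1, p[ord] * cm * m / seq_len(m))
  adj <- rev(cummin(rev(raw)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Residual sum of squares of a linear model fitted by explicit normal
# equations on hand-built dummy columns (no model.matrix / lm).
rssNormalEquations <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  sum((y - X %*% beta)^2)
}

dummyCols <- function(f) {
  lev <- levels(f)
  cols <- lapply(lev[-1L], function(l) as.numeric(f == l))
  do.call(cbind, cols)
}

# Type II interaction SS via normal equations: RSS(additive) - RSS(full).
anovaOracle <- function(df) {
  a <- factor(df$factor_a); b <- factor(df$factor_b)
  y <- df$value
  Da <- dummyCols(a); Db <- dummyCols(b)
  Dab <- matrix(0, nrow(df), 0)
  for (i in seq_len(ncol(Da)))
    for (j in seq_len(ncol(Db)))
      Dab <- cbind(Dab, Da[, i] * Db[, j])
  one <- rep(1, nrow(df))
  rssAdd <- rssNormalEquations(cbind(one, Da, Db), y)
  rssFull <- rssNormalEquations(cbind(one, Da, Db, Dab), y)
  list(ssInt = rssAdd - rssFull, ssRes = rssFull,
       ssA = rssNormalEquations(cbind(one, Db), y) - rssAdd,
       ssB = rssNormalEquations(cbind(one, Da), y) - rssAdd)
}

# Classical balanced-design interaction SS from cell means.
balancedInteractionSS <- function(df) {
  cm <- tapply(df$value, list(df$factor_a, df$factor_b), mean)
  n <- nrow(df) / length(cm)
  am <- rowMeans(cm); bm <- colMeans(cm); gm <- mean(cm)
  n * sum((sweep(sweep(cm, 1, am), 2, bm) + gm)^2)
}

# Pooled-variance Student's t from the textbook formula.
pooledTOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2,
       p = 2 * pt(abs(t), nx + ny - 2, lower.tail = FALSE))
}
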