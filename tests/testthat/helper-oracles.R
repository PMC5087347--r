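# Independent oracles: straight-line implementations kept deliberately
# separate from the package's code paths.

# Literal O(n^2) multi-class ReliefF: explicit loops, manual distances,
# manual neighbor sort with lowest-index tie-break. No dist(), no package
# internals.
brute_relieff <- function(x, y, k) {
  n <- nrow(x)
  p <- ncol(x)
  y <- as.character(y)
  classes <- unique(y)
  prior <- sapply(classes, function(cl) sum(y == cl) / n)
  fmax <- apply(x, 2, max)
  fmin <- apply(x, 2, min)
  m <- n
  w <- rep(0, p)
  for (i in 1:n) {
    d <- rep(0, n)
    for (j in 1:n) d[j] <- sqrt(sum((x[i, ] - x[j, ])^2))
    for (cl in classes) {
      cand <- which(y == cl)
      if (cl == y[i]) cand <- setdiff(cand, i)
      cand <- cand[order(d[cand], cand)]
      nb <- cand[1:k]
      for (l in 1:p) {
        s <- 0
        for (j in nb) {
          denom <- fmax[l] - fmin[l]
          s <- s + if (denom > 0) abs(x[i, l] - x[j, l]) / denom else 0
        }
        if (cl == y[i]) {
          w[l] <- w[l] - s / (m * k)
        } else {
          w[l] <- w[l] + (prior[[cl]] / (1 - prior[[y[i]]])) * s / (m * k)
        }
      }
    }
  }
  w
}

# Explicit O(N^2) DFT; returns (1/N) * sum_k |X(k)|^2, the literal
# band-power sum, applied to the raw (unfiltered) input.
dft_power <- function(x) {
  N <- length(x)
  total <- 0
  idx <- 0:(N - 1)
  for (k in idx) {
    re <- sum(x * cos(-2 * pi * k * idx / N))
    im <- sum(x * sin(-2 * pi * k * idx / N))
    total <- total + re^2 + im^2
  }
  total / N
}

# Literal F-score: between-class over pooled within-class scatter.
brute_fscore <- function(x, y) {
  y <- as.character(y)
  grand <- mean(x)
  num <- 0
  den <- 0
  for (cl in unique(y)) {
    xi <- x[y == cl]
    num <- num + length(xi) * (mean(xi) - grand)^2
    den <- den + sum((xi - mean(xi))^2)
  }
  num / den
}
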