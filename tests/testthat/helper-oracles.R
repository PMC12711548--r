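# Independent brute-force oracles used to cross-check the implementation.

# Onnela weighted clustering coefficient by exhaustive triplet enumeration.
oracleClustering <- function(w) {
  n <- nrow(w)
  wn <- if (max(w) > 0) w / max(w) else w
  node <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      acc <- acc + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
    }
    node[i] <- acc / (k * (k - 1))
  }
  list(node = node, global = mean(node))
}

# All-pairs shortest paths by Floyd-Warshall on the length matrix.
oracleFloydWarshall <- function(len) {
  n <- nrow(len)
  d <- len
  d[d == 0] <- Inf
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

lengthsFromWeights <- function(w, map = "inverse") {
  l <- w
  pos <- w > 0
  l[pos] <- if (map == "inverse") 1 / w[pos] else 1 - w[pos]
  l[!pos] <- 0
  l
}

oracleGlobalEfficiency <- function(w, map = "inverse", variant = "mean_inverse") {
  d <- oracleFloydWarshall(lengthsFromWeights(w, map))
  off <- d[row(d) != col(d)]
  if (variant == "mean_inverse") {
    mean(ifelse(is.finite(off), 1 / off, 0))
  } else {
    fin <- off[is.finite(off)]
    if (!length(fin)) 0 else 1 / mean(fin)
  }
}

oracleLocalEfficiency <- function(w, map = "inverse") {
  n <- nrow(w)
  node <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) next
    node[i] <- oracleGlobalEfficiency(w[nb, nb, drop = FALSE], map)
  }
  list(node = node, global = mean(node))
}

# Raw periodogram by direct DFT sums (no FFT), one-sided density scaling.
oraclePeriodogram <- function(x, fs) {
  n <- length(x)
  nf <- n %/% 2 + 1
  P <- numeric(nf)
  for (k in seq_len(nf)) {
    f <- exp(-2i * pi * (k - 1) * (seq_len(n) - 1) / n)
    P[k] <- Mod(sum(x * f))^2 / (fs * n)
  }
  dbl <- rep(2, nf); dbl[1] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1) * fs / n, power = P * dbl)
}

# Benjamini-Hochberg step-up, literal definition.
oracleBhMask <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * alpha / m)
  mask <- logical(m)
  if (length(k)) mask[o[seq_len(max(k))]] <- TRUE
  mask
}

# random symmetric weighted graph with zero diagonal
randomWeightedGraph <- function(n, density = 0.7) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- sample(ut, max(1, round(density * length(ut))))
  w[on] <- runif(length(on), 0.05, 1)
  w + t(w)
}
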