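# Weighted graph metrics on unthresholded connectivity matrices.
#
# Conventions: weights are a symmetric non-negative matrix with zero
# diagonal. The clustering coefficient uses the geometric-mean (Onnela)
# weighted form with weights normalised by the global maximum; efficiencies
# map weights to lengths via l = 1/w by default (a '1 - w' map is available)
# and use the Latora-Marchiori mean-of-inverse-distances form, with the
# literal inverse-of-mean-path variant behind a flag.

checkWeights <- function(w) {
  if (!is.matrix(w) || nrow(w) != ncol(w)) stop("weights must be a square matrix")
  if (max(abs(w - t(w))) > 1e-10) stop("weights must be symmetric")
  if (any(w < 0)) stop("weights must be non-negative")
  if (any(diag(w) != 0)) stop("weight diagonal must be zero")
  w
}

#' Weighted adjacency matrix from a connectivity matrix
#'
#' Drops the unit diagonal of a PLV matrix, yielding the weighted graph the
#' metrics operate on.
#'
#' @param x A `ConnectivityMatrix` or plain symmetric matrix.
#' @return Symmetric non-negative matrix with zero diagonal.
#' @export
asWeightedGraph <- function(x) {
  w <- if (is(x, "ConnectivityMatrix")) x@values else x
  diag(w) <- 0
  checkWeights(w)
}

#' Weighted clustering coefficient (geometric-mean form)
#'
#' Onnela's formulation: with weights normalised by the global maximum,
#' `C_i = sum_{j,h} (w_ij w_ih w_jh)^{1/3} / (k_i (k_i - 1))` where `k_i`
#' counts nonzero-weight neighbours; nodes with fewer than two neighbours
#' contribute 0. The global value is the mean over nodes. Lies in \[0, 1\]
#' for weights in \[0, 1\].
#'
#' @param w Weighted adjacency matrix (see [asWeightedGraph()]), n >= 3.
#' @return List with `node` (per-node vector) and `global` (mean).
#' @export
clusteringCoefficient <- function(w) {
  w <- checkWeights(w)
  n <- nrow(w)
  if (n < 3) stop("need at least 3 nodes")
  mx <- max(w)
  node <- rep(0, n)
  if (mx > 0) {
    w13 <- (w / mx)^(1 / 3)
    num <- diag(w13 %*% w13 %*% w13)
    k <- rowSums(w > 0)
    ok <- k >= 2
    node[ok] <- num[ok] / (k[ok] * (k[ok] - 1))
  }
  names(node) <- rownames(w)
  list(node = node, global = mean(node))
}

# shortest-path distance matrix under the chosen weight -> length map
spDistances <- function(w, lengthMap = c("inverse", "one_minus")) {
  lengthMap <- match.arg(lengthMap)
  l <- w
  pos <- w > 0
  l[!pos] <- 0
  l[pos] <- if (lengthMap == "inverse") 1 / w[pos] else 1 - w[pos]
  g <- igraph::graph_from_adjacency_matrix(l, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  # igraph orders vertices as in the matrix; restore any dropped names
  unname(d)
}

#' Weighted global efficiency
#'
#' Edge lengths are `1/w` (infinite for absent edges); `d_ij` is the
#' shortest weighted path. The default (`variant = "mean_inverse"`) is the
#' Latora-Marchiori efficiency, the mean over ordered node pairs of
#' `1/d_ij` (0 for disconnected pairs), which is robust to disconnection.
#' `variant = "inverse_mean"` returns the literal inverse of the average
#' shortest path length over connected pairs.
#'
#' @param w Weighted adjacency matrix, n >= 2.
#' @param lengthMap `"inverse"` (default, `l = 1/w`) or `"one_minus"`
#'   (`l = 1 - w`).
#' @param variant `"mean_inverse"` (default) or `"inverse_mean"`.
#' @return Scalar efficiency.
#' @export
globalEfficiency <- function(w, lengthMap = c("inverse", "one_minus"),
                             variant = c("mean_inverse", "inverse_mean")) {
  w <- checkWeights(w)
  variant <- match.arg(variant)
  n <- nrow(w)
  if (n < 2) stop("need at least 2 nodes")
  d <- spDistances(w, match.arg(lengthMap))
  off <- d[row(d) != col(d)]
  if (variant == "mean_inverse") {
    mean(ifelse(is.finite(off), 1 / off, 0))
  } else {
    fin <- off[is.finite(off)]
    if (!length(fin)) 0 else 1 / mean(fin)
  }
}

#' Weighted local efficiency
#'
#' Per node, the global efficiency of the subgraph induced by its
#' nonzero-weight neighbours (0 when fewer than two); the global value is
#' the mean over nodes.
#'
#' @inheritParams globalEfficiency
#' @return List with `node` and `global`.
#' @export
localEfficiency <- function(w, lengthMap = c("inverse", "one_minus"),
                            variant = c("mean_inverse", "inverse_mean")) {
  w <- checkWeights(w)
  lengthMap <- match.arg(lengthMap)
  variant <- match.arg(variant)
  n <- nrow(w)
  if (n < 2) stop("need at least 2 nodes")
  node <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    globalEfficiency(w[nb, nb, drop = FALSE], lengthMap, variant)
  }, numeric(1))
  names(node) <- rownames(w)
  list(node = node, global = mean(node))
}

#' Weighted degree centrality (node strength)
#'
#' Node strength `s_i = sum_j w_ij`; the network value is the mean strength
#' across nodes.
#'
#' @param w Weighted adjacency matrix.
#' @return List with `node` (strengths) and `global` (mean strength).
#' @export
degreeCentrality <- function(w) {
  w <- checkWeights(w)
  node <- rowSums(w)
  list(node = node, global = mean(node))
}

#' All four weighted network metrics
#'
#' @param x A `ConnectivityMatrix` or weighted adjacency matrix.
#' @param ... Passed to the efficiency functions (`lengthMap`, `variant`).
#' @return List with scalars `cc`, `le`, `ge`, `dc` and a `node`
#'   data.frame of the per-node vectors.
#' @export
networkMetrics <- function(x, ...) {
  w <- asWeightedGraph(x)
  cc <- clusteringCoefficient(w)
  le <- localEfficiency(w, ...)
  ge <- globalEfficiency(w, ...)
  dc <- degreeCentrality(w)
  list(cc = cc$global, le = le$global, ge = ge, dc = dc$global,
       node = data.frame(node = rownames(w) %||% as.character(seq_len(nrow(w))),
                         cc = unname(cc$node), le = unname(le$node),
                         dc = unname(dc$node), stringsAsFactors = FALSE))
}

# retain the strongest edges at a target density (share of possible edges)
thresholdDensity <- function(w, density) {
  n <- nrow(w)
  ut <- which(upper.tri(w))
  m <- round(density * length(ut))
  if (m < n - 1)
    warning(sprintf("density %.2f retains %d < n-1 edges; graph may disconnect",
                    density, m))
  keep <- ut[order(w[ut], decreasing = TRUE)][seq_len(m)]
  out <- matrix(0, n, n, dimnames = dimnames(w))
  out[keep] <- w[keep]
  out + t(out)
}

#' Density-threshold robustness sweep
#'
#' For each target density the strongest edges are retained, the four
#' metrics are recomputed, and surrogate null graphs are built by permuting
#' the retained weights across the retained edge positions (preserving
#' topology and the weight multiset). Observed values are reported as
#' z-scores against the surrogate distribution.
#'
#' @param w Weighted adjacency matrix.
#' @param densities Proportions in (0, 1\] (default 0.1, 0.2, 0.3, 0.4).
#' @param nSurrogates Number of weight-shuffle surrogates (default 100).
#' @param seed Integer seed for the surrogate shuffles.
#' @param ... Passed to [networkMetrics()].
#' @return Long `data.frame` with columns `density`, `metric`, `observed`,
#'   `null_mean`, `null_sd`, `z`.
#' @export
densitySweep <- function(w, densities = c(0.1, 0.2, 0.3, 0.4),
                         nSurrogates = 100, seed = 1, ...) {
  w <- checkWeights(w)
  if (any(densities <= 0 | densities > 1)) stop("densities must lie in (0, 1]")
  set.seed(seed)
  out <- list()
  for (dens in densities) {
    wt <- if (dens >= 1) w else suppressWarnings(thresholdDensity(w, dens))
    if (dens < 1) {
      m <- round(dens * sum(upper.tri(w)))
      if (m < nrow(w) - 1)
        warning(sprintf("density %.2f retains %d < n-1 edges", dens, m))
    }
    obs <- networkMetrics(wt, ...)
    obs <- c(cc = obs$cc, le = obs$le, ge = obs$ge, dc = obs$dc)
    nulls <- vapply(seq_len(nSurrogates), function(k) {
      pos <- which(upper.tri(wt) & wt > 0)
      ws <- matrix(0, nrow(wt), ncol(wt))
      ws[pos] <- sample(wt[pos])
      ws <- ws + t(ws)
      mm <- networkMetrics(ws, ...)
      c(cc = mm$cc, le = mm$le, ge = mm$ge, dc = mm$dc)
    }, numeric(4))
    mu <- rowMeans(nulls); sdev <- apply(nulls, 1, sd)
    out[[length(out) + 1L]] <- data.frame(
      density = dens, metric = names(obs), observed = unname(obs),
      null_mean = unname(mu), null_sd = unname(sdev),
      z = unname(ifelse(sdev > 0, (obs - mu) / sdev, 0)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
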