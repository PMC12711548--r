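# Condition contrasts with family-wise error control, and FVC-edge Pearson
# correlation with Benjamini-Hochberg false-discovery control.

# vectorized two-sample pooled-variance (or paired) t statistics per column
tStatistics <- function(a, b, paired = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("feature count mismatch")
  if (paired) {
    if (nrow(a) != nrow(b)) stop("paired groups must have equal size")
    d <- a - b
    n <- nrow(d)
    mu <- colMeans(d)
    s <- sqrt(colSums((d - rep(mu, each = n))^2) / (n - 1))
    t <- mu / (s / sqrt(n))
    df <- n - 1
  } else {
    na <- nrow(a); nb <- nrow(b)
    ma <- colMeans(a); mb <- colMeans(b)
    va <- colSums((a - rep(ma, each = na))^2) / (na - 1)
    vb <- colSums((b - rep(mb, each = nb))^2) / (nb - 1)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  zero <- !is.finite(t)
  if (any(zero)) {
    md <- if (paired) colMeans(a - b) else colMeans(a) - colMeans(b)
    degen <- zero & md != 0
    if (any(degen))
      warning(sprintf("%d feature(s) with zero variance and nonzero mean difference", sum(degen)))
    t[zero & md == 0] <- 0
    t[degen] <- sign(md[degen]) * Inf
  }
  list(t = t, df = df)
}

#' Per-feature condition contrast t-tests
#'
#' Two-sample pooled-variance t-tests (the default, matching the group
#' analysis design) or paired t-tests across a feature map (channels, edges
#' or network metrics).
#'
#' @param valuesA,valuesB Subjects x features matrices for the two
#'   conditions (>= 3 subjects each).
#' @param paired Use paired tests (rows matched by subject).
#' @param label Contrast label stored in the result (e.g. `"SB-BH"`).
#' @return List of class `ContrastResult`: `t`, `p`, `df`, `label`,
#'   `paired`, `features`.
#' @export
contrastTtest <- function(valuesA, valuesB, paired = FALSE, label = "A-B") {
  valuesA <- as.matrix(valuesA); valuesB <- as.matrix(valuesB)
  if (nrow(valuesA) < 3 || nrow(valuesB) < 3)
    stop("need at least 3 subjects per group")
  ts <- tStatistics(valuesA, valuesB, paired)
  p <- 2 * pt(-abs(ts$t), ts$df)
  p[is.infinite(ts$t)] <- 0
  structure(list(t = ts$t, p = p, df = ts$df, label = label, paired = paired,
                 features = colnames(valuesA) %||% as.character(seq_along(ts$t))),
            class = "ContrastResult")
}

#' Family-wise error control for a contrast
#'
#' `method = "maxT"` (default): group labels are permuted (or signs flipped,
#' for paired contrasts), the null distribution of the maximum absolute t
#' across features is built, and each feature receives the FWE-adjusted
#' p-value `(1 + #{max|t*| >= |t|}) / (nPerm + 1)`; features with adjusted
#' p <= alpha are flagged. Permutation is preferred for correlated EEG
#' feature maps. `method = "bonferroni"` flags `p < alpha / m`.
#'
#' @inheritParams contrastTtest
#' @param alpha Family-wise error level (default 0.01).
#' @param method `"maxT"` or `"bonferroni"`.
#' @param nPerm Number of permutations (default 5000).
#' @param seed Integer seed for the permutations.
#' @return List of class `FweResult`: `t`, `p` (raw), `pFwe` (maxT only),
#'   `mask`, `alpha`, `method`, and for maxT the null max-|t| sample.
#' @export
fweCorrect <- function(valuesA, valuesB, alpha = 0.01,
                       method = c("maxT", "bonferroni"), nPerm = 5000,
                       seed = 1, paired = FALSE, label = "A-B") {
  method <- match.arg(method)
  res <- contrastTtest(valuesA, valuesB, paired = paired, label = label)
  m <- length(res$t)
  if (method == "bonferroni") {
    mask <- res$p < alpha / m
    return(structure(list(t = res$t, p = res$p, pFwe = pmin(res$p * m, 1),
                          mask = mask, alpha = alpha, method = method,
                          label = label, features = res$features),
                     class = "FweResult"))
  }
  if (nPerm < 1 / alpha - 1)
    warning(sprintf("nPerm = %d is small for alpha = %g (minimum attainable p = %g)",
                    nPerm, alpha, 1 / (nPerm + 1)))
  set.seed(seed)
  a <- as.matrix(valuesA); b <- as.matrix(valuesB)
  maxNull <- numeric(nPerm)
  if (paired) {
    d <- a - b
    n <- nrow(d)
    for (k in seq_len(nPerm)) {
      fl <- sample(c(-1, 1), n, replace = TRUE)
      maxNull[k] <- max(abs(tStatistics(d * fl, d * 0, paired = TRUE)$t))
    }
  } else {
    pool <- rbind(a, b)
    na <- nrow(a)
    for (k in seq_len(nPerm)) {
      idx <- sample.int(nrow(pool))
      maxNull[k] <- max(abs(tStatistics(pool[idx[seq_len(na)], , drop = FALSE],
                                        pool[idx[-seq_len(na)], , drop = FALSE])$t))
    }
  }
  pFwe <- vapply(abs(res$t), function(tt) (1 + sum(maxNull >= tt)) / (nPerm + 1),
                 numeric(1))
  structure(list(t = res$t, p = res$p, pFwe = pFwe, mask = pFwe <= alpha,
                 alpha = alpha, method = method, nPerm = nPerm,
                 nullMax = maxNull, label = label, features = res$features),
            class = "FweResult")
}

#' Benjamini-Hochberg step-up procedure
#'
#' Flags the features at ranks up to the largest k with
#' `p_(k) <= k * alpha / m`. Missing p-values are ignored (excluded from m).
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @param alpha FDR level (default 0.01).
#' @return List with `mask` (logical, NA entries FALSE) and `padj`
#'   (BH-adjusted p-values).
#' @export
bhFdr <- function(pvals, alpha = 0.01) {
  if (!length(pvals)) stop("empty p-value vector")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  ok <- !is.na(pvals)
  padj <- rep(NA_real_, length(pvals))
  padj[ok] <- p.adjust(pvals[ok], method = "BH")
  mask <- !is.na(padj) & padj <= alpha
  list(mask = mask, padj = padj)
}

#' Edge-wise Pearson correlation with FVC
#'
#' For each condition (and one band at a time) the PLV edge values are
#' correlated with the per-subject FVC; the Benjamini-Hochberg procedure is
#' applied across the whole family (all conditions jointly). With
#' `mode = "full"` the family follows the full-matrix convention (all n^2
#' matrix entries per condition, 256 x 3 = 768 rows for 16 channels;
#' constant diagonal entries yield NA correlations and are excluded from
#' the BH ranking); `mode = "unique"` uses the 120 unique pairs per
#' condition.
#'
#' @param edgeMatrices Named list (condition -> subjects x edges matrix), as
#'   produced by [stackEdgeVectors()] with the matching `mode`.
#' @param fvc Per-subject FVC vector (>= 4 non-missing values).
#' @param alpha FDR level (default 0.01).
#' @param mode `"full"` or `"unique"`; only used to label the output.
#' @param band Band label carried into the table.
#' @return `data.frame` of class `CorrelationTable` with columns `band`,
#'   `condition`, `edge`, `r`, `p`, `padj`, `significant`.
#' @export
fvcCorrelation <- function(edgeMatrices, fvc, alpha = 0.01,
                           mode = c("full", "unique"), band = "") {
  mode <- match.arg(mode)
  if (sum(!is.na(fvc)) < 4) stop("need at least 4 subjects with FVC")
  if (sd(fvc, na.rm = TRUE) == 0) stop("FVC vector is constant")
  rows <- list()
  for (cond in names(edgeMatrices)) {
    x <- edgeMatrices[[cond]]
    if (nrow(x) != length(fvc)) stop("subject count mismatch for ", cond)
    n <- sum(!is.na(fvc))
    r <- suppressWarnings(as.numeric(cor(fvc, x, use = "complete.obs")))
    r[!is.finite(r)] <- NA_real_
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), n - 2)
    p[is.na(r)] <- NA_real_
    rows[[cond]] <- data.frame(band = band, condition = cond,
                               edge = colnames(x), r = r, p = p,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  fdr <- bhFdr(out$p, alpha)
  out$padj <- fdr$padj
  out$significant <- fdr$mask
  class(out) <- c("CorrelationTable", class(out))
  out
}
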