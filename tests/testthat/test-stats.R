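# Condition contrasts, FWE control, BH-FDR and FVC correlation.

test_that("contrast t-tests match closed forms and t.test", {
  # identical groups: t = 0, p = 1 everywhere
  a <- matrix(rnorm(30), 5, 6)
  res <- contrastTtest(a, a)
  expect_equal(res$t, setNames(rep(0, 6), res$features), ignore_attr = TRUE)
  expect_equal(res$p, rep(1, 6), ignore_attr = TRUE)

  # 3-vs-3 toy against the pooled-variance closed form
  A <- matrix(c(1, 2, 3), 3, 1); B <- matrix(c(4, 5, 6), 3, 1)
  res2 <- contrastTtest(A, B)
  sp <- sqrt((2 * var(A[, 1]) + 2 * var(B[, 1])) / 4)
  expect_equal(unname(res2$t), (mean(A) - mean(B)) / (sp * sqrt(2 / 3)))
  ref <- t.test(A[, 1], B[, 1], var.equal = TRUE)
  expect_equal(unname(res2$t), unname(ref$statistic))
  expect_equal(res2$p, ref$p.value, ignore_attr = TRUE)

  # antisymmetry
  set.seed(3)
  x <- matrix(rnorm(40), 8, 5); y <- matrix(rnorm(40, 1), 8, 5)
  expect_equal(contrastTtest(x, y)$t, -contrastTtest(y, x)$t)

  # paired mode agrees with t.test(paired)
  resP <- contrastTtest(x, y, paired = TRUE)
  refP <- t.test(x[, 2], y[, 2], paired = TRUE)
  expect_equal(unname(resP$t[2]), unname(refP$statistic))

  expect_error(contrastTtest(x[1:2, ], y), "3 subjects")
})

test_that("a planted 2-SD mean shift attains the cohort's max |t|", {
  set.seed(21)
  n <- 47; m <- 50
  a <- matrix(rnorm(n * m), n, m)
  b <- matrix(rnorm(n * m), n, m)
  b[, 17] <- b[, 17] + 2
  res <- contrastTtest(a, b)
  expect_equal(which.max(abs(res$t)), 17)
})

test_that("max-T permutation FWE is seeded, reproducible and sane", {
  set.seed(4)
  a <- matrix(rnorm(60), 10, 6); b <- matrix(rnorm(60), 10, 6)
  b[, 3] <- b[, 3] + 4                       # one strong effect
  r1 <- fweCorrect(a, b, alpha = 0.05, nPerm = 499, seed = 11)
  r2 <- fweCorrect(a, b, alpha = 0.05, nPerm = 499, seed = 11)
  expect_identical(r1$pFwe, r2$pFwe)
  expect_true(r1$mask[3])
  rb <- fweCorrect(a, b, alpha = 0.05, method = "bonferroni")
  expect_true(rb$mask[3])
  # Bonferroni with m = 1 reduces to the uncorrected threshold
  one <- fweCorrect(a[, 3, drop = FALSE], b[, 3, drop = FALSE],
                    alpha = 0.05, method = "bonferroni")
  expect_equal(one$mask, contrastTtest(a[, 3, drop = FALSE],
                                       b[, 3, drop = FALSE])$p < 0.05,
               ignore_attr = TRUE)
  expect_warning(fweCorrect(a, b, alpha = 0.001, nPerm = 99, seed = 1),
                 "small")
})

test_that("max-T flags weak correlated effects more often than Bonferroni", {
  # weak shift spread over many correlated features
  set.seed(31)
  hits <- c(maxT = 0, bonf = 0)
  for (i in 1:20) {
    base <- rnorm(12)
    a <- matrix(rnorm(12 * 40, sd = 0.6), 12, 40) + base
    b <- matrix(rnorm(12 * 40, sd = 0.6), 12, 40) + rnorm(12)
    b[, 1:5] <- b[, 1:5] + 0.9
    hits["maxT"] <- hits["maxT"] +
      sum(fweCorrect(a, b, alpha = 0.05, nPerm = 199, seed = i)$mask[1:5])
    hits["bonf"] <- hits["bonf"] +
      sum(fweCorrect(a, b, alpha = 0.05, method = "bonferroni")$mask[1:5])
  }
  expect_gte(hits[["maxT"]], hits[["bonf"]])
})

test_that("BH step-up matches the literal definition", {
  res <- bhFdr(c(0.001, 0.002, 0.9), alpha = 0.01)
  expect_equal(res$mask, c(TRUE, TRUE, FALSE))
  expect_equal(bhFdr(rep(1, 5), alpha = 0.01)$mask, rep(FALSE, 5))
  expect_equal(bhFdr(0.009, alpha = 0.01)$mask, TRUE)
  expect_error(bhFdr(numeric(0)), "empty")
  expect_error(bhFdr(c(0.5, 1.2)), "outside")
  # randomized agreement with the step-up oracle + alpha-monotonicity
  set.seed(12)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    for (alpha in c(0.01, 0.05, 0.2)) {
      expect_equal(bhFdr(p, alpha)$mask, oracleBhMask(p, alpha))
    }
    expect_true(all(bhFdr(p, 0.01)$mask <= bhFdr(p, 0.05)$mask))
  }
})

test_that("FVC correlation flags a perfectly correlated edge and validates input", {
  set.seed(9)
  n <- 20
  x <- matrix(runif(n * 10, 0.2, 0.8), n, 10,
              dimnames = list(NULL, paste0("e", 1:10)))
  fvc <- x[, 4]                          # FVC literally equals one edge
  tab <- fvcCorrelation(list(SB = x), fvc, alpha = 0.01, mode = "unique")
  expect_equal(tab$r[tab$edge == "e4"], 1)
  expect_true(tab$significant[tab$edge == "e4"])
  expect_error(fvcCorrelation(list(SB = x), rep(2, n)), "constant")
  expect_error(fvcCorrelation(list(SB = x), fvc[1:10]), "mismatch")
  expect_error(fvcCorrelation(list(SB = x[1:3, ]), fvc[1:3]), "4 subjects")
})

test_that("full-matrix mode reproduces the 256 x conditions family layout", {
  set.seed(10)
  chans <- defaultMontage()
  cms <- lapply(1:6, function(s) {
    m <- matrix(runif(256, 0.2, 0.9), 16, 16, dimnames = list(chans, chans))
    m <- (m + t(m)) / 2; diag(m) <- 1
    new("ConnectivityMatrix", values = m, band = "theta", condition = "PB",
        subjectId = paste0("S", s), nSamples = 100)
  })
  full <- stackEdgeVectors(cms, mode = "full")
  expect_equal(dim(full), c(6, 256))
  em <- list(SB = full, BH = full, PB = full)
  tab <- fvcCorrelation(em, rnorm(6, 4), mode = "full")
  expect_equal(nrow(tab), 768)
  # constant diagonal entries carry NA correlations, never flagged
  diagRows <- grepl("^(\\w+)-\\1$", tab$edge)
  expect_equal(sum(diagRows), 48)
  expect_true(all(is.na(tab$r[diagRows])))
  expect_true(!any(tab$significant[diagRows]))
})
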