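mkTable <- function(log2fc, cluster, padj = 0, gene = NULL) {
  data.frame(gene_id = if (is.null(gene)) sprintf("g%03d", seq_along(log2fc)) else gene,
             log2fc = log2fc, padj = padj, cluster = cluster,
             stringsAsFactors = FALSE)
}

test_that("cumulative log2fc includes |fc| above threshold and is order-invariant", {
  tab <- mkTable(c(0.5, 0.3, -0.1, 0.4), "pre_implantation")
  res <- cumulativeLog2fc(tab, "pre_implantation")
  expect_equal(res$includedGenes, 3L)
  expect_equal(res$endpoint, 1.2)
  expect_equal(unname(res$series), c(0.5, 0.4, 0.9, 1.2)[c(1, 3, 4)])

  zero <- cumulativeLog2fc(mkTable(rep(0, 5), "pre_implantation"),
                           "pre_implantation")
  expect_equal(zero$endpoint, 0)
  expect_equal(zero$includedGenes, 0L)

  # permuting rows leaves the endpoint unchanged
  set.seed(1)
  big <- mkTable(rnorm(200, 0, 0.5), "post_implantation")
  e1 <- cumulativeLog2fc(big, "post_implantation")$endpoint
  e2 <- cumulativeLog2fc(big[sample(200), ], "post_implantation")$endpoint
  expect_equal(e1, e2)

  expect_error(cumulativeLog2fc(tab, "mystery_cluster"), "unknown cluster")
})

test_that("planted opposite shifts produce diverging cumulative series", {
  sc <- signatureScenario(nGenes = 1000,
                          clusterSizes = c(pre_implantation = 200L,
                                           post_implantation = 200L),
                          clusterShifts = c(pre_implantation = 0.5,
                                            post_implantation = -0.5),
                          noiseSd = 0.3, seed = 8)
  tab <- simulateExpressionTable(sc)
  pre <- cumulativeLog2fc(tab, "pre_implantation")
  post <- cumulativeLog2fc(tab, "post_implantation")
  expect_gt(pre$endpoint, 0)
  expect_lt(post$endpoint, 0)
})

test_that("direction fractions split significant genes by sign and sum to 100", {
  tab <- mkTable(c(1, 1, 1, -1), "naive")
  res <- directionFractions(tab, "naive")
  expect_equal(res$pctUp, 75)
  expect_equal(res$pctDown, 25)
  expect_equal(res$pctUp + res$pctDown, 100)

  # planted up-fraction 0.8 recovered within binomial tolerance
  n <- 500
  shift <- 0.3 * qnorm(0.8)
  set.seed(12)
  tabP <- mkTable(shift + rnorm(n, 0, 0.3), "pre_implantation")
  resP <- directionFractions(tabP, "pre_implantation")
  expect_lt(abs(resP$pctUp - 80), 2 * sqrt(0.8 * 0.2 / n) * 100)

  none <- directionFractions(mkTable(c(1, -1), "naive", padj = 0.9), "naive")
  expect_false(none$defined)
  expect_true(is.na(none$pctUp))
})

test_that("ERK concordance summarises both target clusters and fold magnitudes", {
  tab <- rbind(mkTable(c(-0.5, -0.7, -0.9), "erk_activated"),
               mkTable(c(0.6, 0.8), "erk_suppressed",
                       gene = c("h1", "h2")),
               mkTable(c(0.05, -0.02), "none", gene = c("n1", "n2")))
  res <- erkConcordance(tab)
  expect_equal(res$activated$pctDown, 100)
  expect_equal(res$suppressed$pctUp, 100)
  expect_gt(res$meanAbsLog2fcErk, res$meanAbsLog2fcNonTarget)
  expect_true(res$magnitudeComparisonAvailable)

  noNone <- tab[tab$cluster != "none", ]
  res2 <- erkConcordance(noNone)
  expect_false(res2$magnitudeComparisonAvailable)
  expect_true(is.na(res2$meanAbsLog2fcNonTarget))

  expect_error(erkConcordance(mkTable(1, "erk_activated")), "erk_suppressed")
})

test_that("planted ERK concordance levels are recovered within binomial error", {
  tab <- simulateExpressionTable(signatureScenario(seed = 5))
  res <- erkConcordance(tab)
  expect_lt(abs(res$activated$pctDown - 90), 3 * sqrt(0.9 * 0.1 / 150) * 100)
  expect_lt(abs(res$suppressed$pctUp - 85), 3 * sqrt(0.85 * 0.15 / 150) * 100)
})

test_that("reversing planted effect signs swaps pct_up and pct_down exactly", {
  sizes <- c(pre_implantation = 150L, post_implantation = 150L)
  shifts <- c(pre_implantation = 0.4, post_implantation = -0.3)
  t1 <- simulateExpressionTable(signatureScenario(
    nGenes = 600, clusterSizes = sizes, clusterShifts = shifts, seed = 31))
  t2 <- t1
  t2$log2fc <- -t2$log2fc
  for (cl in names(sizes)) {
    a <- directionFractions(t1, cl)
    b <- directionFractions(t2, cl)
    expect_identical(a$pctUp, b$pctDown)
    expect_identical(a$pctDown, b$pctUp)
  }
})

test_that("permutation test is degenerate-safe, reproducible, and powerful", {
  set.seed(3)
  tab <- mkTable(rnorm(500, 0, 0.3), "none")
  # gene set = whole table: every null draw equals the observed mean
  resAll <- permutationSystematic(tab, tab$gene_id, nPermutations = 199,
                                  seed = 1)
  expect_equal(resAll$pValue, 1)

  # reproducibility: identical seed, identical null distribution
  gs <- tab$gene_id[1:40]
  r1 <- permutationSystematic(tab, gs, nPermutations = 199, seed = 7)
  r2 <- permutationSystematic(tab, gs, nPermutations = 199, seed = 7)
  expect_identical(r1$nullDistribution, r2$nullDistribution)
  expect_identical(r1$pValue, r2$pValue)
  expect_gt(r1$pValue, 0)

  # planted shift on the set: p at the add-one floor
  tabS <- tab
  tabS$log2fc[1:50] <- tabS$log2fc[1:50] + 1.0
  rs <- permutationSystematic(tabS, tab$gene_id[1:50],
                              nPermutations = 999, seed = 11)
  expect_lte(rs$pValue, 0.001)

  expect_error(permutationSystematic(tab, c(tab$gene_id[1], "absent")),
               "absent")
  expect_error(permutationSystematic(tab, gs, nPermutations = 10), ">= 100")
})

test_that("null permutation p-values are approximately uniform", {
  set.seed(17)
  tab <- mkTable(rnorm(800, 0, 0.3), "none")
  pv <- vapply(1:200, function(i)
    permutationSystematic(tab, sample(tab$gene_id, 30),
                          nPermutations = 199, seed = 1000 + i)$pValue,
    numeric(1))
  expect_gt(min(pv), 0)          # add-one correction guarantees p > 0
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_lt(unname(ks$statistic), 0.12)
})

test_that("expression tables are validated strictly", {
  tab <- mkTable(c(0.1, 0.2), "naive")
  bad <- tab; bad$padj <- c(0.5, 1.7)
  expect_error(validateExpressionTable(bad), "padj")
  bad2 <- tab; bad2$cluster <- "unheard_of"
  expect_error(validateExpressionTable(bad2), "unknown cluster")
  bad3 <- tab; bad3$gene_id <- c("a", "a")
  expect_error(validateExpressionTable(bad3), "unique")
})
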