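## build a GLSTable directly from lnL values (bypassing the engine)
glsFromLnL <- function(L, ids = c("T1", "T2", "T3")) {
  tab <- data.frame(locus_id = sprintf("g%03d", seq_len(nrow(L))))
  for (k in seq_along(ids)) tab[[paste0("lnL_", ids[k])]] <- L[, k]
  new("GLSTable", table = tab, topologyIds = ids, focal = NA_character_,
      threshold = 2, pca = list())
}

test_that("deltaGLS computes ordered-pair differences and the dependency", {
  g <- deltaGLS(glsFromLnL(rbind(c(-1000, -1002, -1005))))
  d <- glsTable(g)
  expect_equal(d$delta_T1_T2, 2)
  expect_equal(d$delta_T1_T3, 5)
  expect_equal(d$delta_T2_T3, 3)
  expect_equal(d$delta_T1_T2, d$delta_T1_T3 - d$delta_T2_T3)

  gz <- deltaGLS(glsFromLnL(rbind(c(-5, -5, -5))))
  expect_equal(unlist(glsTable(gz)[, c("delta_T1_T2", "delta_T1_T3",
                                       "delta_T2_T3")]),
               c(delta_T1_T2 = 0, delta_T1_T3 = 0, delta_T2_T3 = 0))
})

test_that("the delta dependency holds on every locus of a random table", {
  set.seed(5)
  L <- matrix(-1000 + rnorm(300) * 10, ncol = 3)
  d <- glsTable(deltaGLS(glsFromLnL(L)))
  expect_lt(max(abs(d$delta_T1_T2 - (d$delta_T1_T3 - d$delta_T2_T3))), 1e-6)
})

test_that("indistinguishable pairs are forced to zero delta", {
  g <- glsFromLnL(rbind(c(-100, -100.4, -103)))
  g@table$identical_T1_T2 <- TRUE
  d <- glsTable(deltaGLS(g))
  expect_equal(d$delta_T1_T2, 0)
  ## dependency still holds after collapsing
  expect_equal(d$delta_T1_T2, d$delta_T1_T3 - d$delta_T2_T3)
})

test_that("non-finite lnL drops the locus with a warning", {
  g <- glsFromLnL(rbind(c(-1, -2, -3), c(NA, -2, -3)))
  expect_warning(d <- deltaGLS(g), "non-finite")
  expect_equal(nrow(glsTable(d)), 1)
})

test_that("PCA explained variances sum to 100 (rank-2 delta space)", {
  set.seed(9)
  L <- matrix(-500 + rnorm(150) * 5, ncol = 3)
  g <- pcaRotate(deltaGLS(glsFromLnL(L)), focal = "T1")
  pct <- g@pca$explainedVarPct
  expect_equal(unname(sum(pct)), 100, tolerance = 1e-6)
  expect_gte(pct[["PC1"]], pct[["PC2"]])
})

test_that("collinear deltas put all variance on PC1", {
  c_ <- seq(-3, 3, length.out = 20)
  ## lnL rows chosen so deltas are c * (1, 2, 1)
  L <- cbind(0, -c_, -2 * c_)
  g <- pcaRotate(deltaGLS(glsFromLnL(L)), focal = "T1")
  expect_equal(unname(g@pca$explainedVarPct[["PC1"]]), 100,
               tolerance = 1e-9)
  expect_equal(unname(g@pca$explainedVarPct[["PC2"]]), 0, tolerance = 1e-9)
})

test_that("PC1 tracks support for the focal topology in a mixture", {
  ## simulated deltas: 50 loci favour T1, 25 favour T2, 25 favour T3
  set.seed(21)
  mk <- function(n, mu) cbind(rnorm(n, mu[1], 2), rnorm(n, mu[2], 2))
  d13 <- rbind(mk(50, c(8, 8)), mk(25, c(-8, 0)), mk(25, c(0, -8)))
  L <- cbind(0, -d13[, 1], -d13[, 2])   # lnL rows realizing the deltas
  g <- pcaRotate(deltaGLS(glsFromLnL(L)), focal = "T1")
  tab <- glsTable(g)
  fd <- (tab$delta_T1_T2 + tab$delta_T1_T3) / 2
  rho1 <- cor(tab$PC1, tab$delta_T1_T2, method = "spearman")
  rho2 <- cor(tab$PC1, tab$delta_T1_T3, method = "spearman")
  expect_gt(abs(rho1), 0.7)
  expect_gt(abs(rho2), 0.7)
  expect_gt(cor(tab$PC1, fd), 0)      # sign convention
})

test_that("PCA scores are invariant to per-locus lnL shifts", {
  set.seed(33)
  L <- matrix(-800 + rnorm(90) * 4, ncol = 3)
  g1 <- pcaRotate(deltaGLS(glsFromLnL(L)), focal = "T1")
  L2 <- L + stats::runif(30, -50, 50)   # per-row constant shift
  g2 <- pcaRotate(deltaGLS(glsFromLnL(L2)), focal = "T1")
  expect_equal(glsTable(g1)$PC1, glsTable(g2)$PC1, tolerance = 1e-8)
  expect_equal(glsTable(g1)$PC2, glsTable(g2)$PC2, tolerance = 1e-8)
})

test_that("categorization follows the focal-involving threshold rules", {
  mkDeltas <- function(d12, d13) {
    ## lnL realizing delta_T1_T2 = d12, delta_T1_T3 = d13
    glsFromLnL(rbind(c(0, -d12, -d13)))
  }
  cat1 <- function(d12, d13) {
    g <- categorizeLoci(deltaGLS(mkDeltas(d12, d13)), focal = "T1")
    as.character(glsTable(g)$category)
  }
  expect_equal(cat1(5, 3), "B")        # favours focal against both
  expect_equal(cat1(-5, 1), "C")       # rejected against one alternative
  expect_equal(cat1(1, -1.5), "A")     # all within threshold
  expect_equal(cat1(2, -2), "A")       # inclusive boundary
  expect_equal(cat1(2.0001, 0), "B")   # strictly beyond
  ## focal comparisons inside threshold but non-focal pair outside:
  ## delta_T2_T3 = d13 - d12 = -3.4
  g <- categorizeLoci(deltaGLS(mkDeltas(1.5, -1.9)), focal = "T1")
  expect_equal(as.character(glsTable(g)$category), "A")
  expect_true(glsTable(g)$flag_alternative_only)
  ## conflicting evidence: larger |delta| wins, tie goes to C
  g2 <- categorizeLoci(deltaGLS(mkDeltas(5, -3)), focal = "T1")
  expect_equal(as.character(glsTable(g2)$category), "B")
  expect_true(glsTable(g2)$flag_conflict)
  g3 <- categorizeLoci(deltaGLS(mkDeltas(3, -5)), focal = "T1")
  expect_equal(as.character(glsTable(g3)$category), "C")
  g4 <- categorizeLoci(deltaGLS(mkDeltas(4, -4)), focal = "T1")
  expect_equal(as.character(glsTable(g4)$category), "C")  # tie -> C
})

test_that("categorization is invariant to relabeling the non-focal pair", {
  set.seed(41)
  L <- matrix(-300 + rnorm(120) * 3, ncol = 3)
  g12 <- categorizeLoci(deltaGLS(glsFromLnL(L)), focal = "T1")
  Lsw <- L[, c(1, 3, 2)]
  gsw <- categorizeLoci(deltaGLS(glsFromLnL(Lsw)), focal = "T1")
  expect_equal(as.character(glsTable(g12)$category),
               as.character(glsTable(gsw)$category))
})

test_that("raising the threshold never shrinks the uninformative set", {
  set.seed(49)
  L <- matrix(-300 + rnorm(240) * 3, ncol = 3)
  g <- deltaGLS(glsFromLnL(L))
  prevA <- character(0)
  for (thr in c(0.5, 1, 2, 4, 8)) {
    gc <- categorizeLoci(g, focal = "T1", threshold = thr)
    nowA <- glsTable(gc)$locus_id[glsTable(gc)$category == "A"]
    expect_true(all(prevA %in% nowA))
    prevA <- nowA
  }
})

test_that("category summaries count and percentage correctly", {
  set.seed(57)
  ## construct 60/20/20 A/B/C exactly
  mk <- function(d12, d13, n) cbind(0, rep(-d12, n), rep(-d13, n))
  L <- rbind(mk(0, 0, 6), mk(5, 5, 2), mk(-5, -5, 2))
  g <- categorizeLoci(deltaGLS(glsFromLnL(L)), focal = "T1")
  s <- categorySummary(g)
  expect_equal(s$pct_A, 60)
  expect_equal(s$pct_B, 20)
  expect_equal(s$pct_C, 20)
  sub <- categorySummary(g, subsets = list(first3 = sprintf("g%03d", 1:3)))
  expect_equal(sub$n[2], 3)
  expect_equal(sub$pct_A[2], 100)
  expect_error(categorySummary(g, subsets = list(bad = "nope")), "unknown")
})

test_that("random subsets keep category proportions within binomial CI", {
  set.seed(65)
  n <- 400
  mu <- rbind(c(0, 0), c(6, 6), c(-6, -6))[sample(1:3, n, TRUE,
                                                  c(0.5, 0.25, 0.25)), ]
  d <- mu + matrix(rnorm(2 * n, 0, 0.5), ncol = 2)
  L <- cbind(0, -d[, 1], -d[, 2])
  g <- categorizeLoci(deltaGLS(glsFromLnL(L)), focal = "T1")
  full <- categorySummary(g)
  half <- sample(glsTable(g)$locus_id, n / 2)
  s <- categorySummary(g, subsets = list(half = half))
  pFull <- full$pct_B / 100
  ci <- 1.96 * sqrt(pFull * (1 - pFull) / (n / 2))
  expect_lt(abs(s$pct_B[2] / 100 - pFull), ci + 0.01)
})

test_that("support breakdown separates one- and two-alternative support", {
  mk <- function(d12, d13) c(0, -d12, -d13)
  L <- rbind(mk(5, 5), mk(5, 1), mk(-5, -5), mk(-5, 0), mk(0, 0))
  g <- categorizeLoci(deltaGLS(glsFromLnL(L)), focal = "T1")
  b <- categoryBreakdown(g)
  expect_equal(b$supporting_both, 1)
  expect_equal(b$supporting_one, 1)
  expect_equal(b$rejecting_both, 1)
  expect_equal(b$rejecting_one, 1)
  expect_equal(b$uninformative, 1)
})
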