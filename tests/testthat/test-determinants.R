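test_that("vector fitting nails perfect and degenerate fits", {
  set.seed(121)
  S <- cbind(PC1 = rnorm(100, sd = 4), PC2 = rnorm(100, sd = 2))
  ## property identical to PC1: R2 = 1, direction (+-1, 0), minimal p
  v1 <- vectorFit(S, S[, 1], nPerm = 499, seed = 2)
  expect_equal(v1$rSquared, 1, tolerance = 1e-12)
  expect_equal(abs(v1$direction), c(1, 0), tolerance = 1e-8)
  expect_equal(v1$pValue, 1 / 500)
  ## property = PC2
  v2 <- vectorFit(S, S[, 2], nPerm = 499, seed = 2)
  expect_equal(abs(v2$direction), c(0, 1), tolerance = 1e-8)
  ## constant property
  v3 <- vectorFit(S, rep(3, 100), nPerm = 99, seed = 2)
  expect_equal(v3$rSquared, 0)
  expect_equal(v3$pValue, 1)
})

test_that("vector fitting agrees with vegan's envfit", {
  skip_if_not_installed("vegan")
  set.seed(129)
  S <- cbind(rnorm(80), rnorm(80))
  y <- 0.6 * S[, 1] - 0.3 * S[, 2] + rnorm(80, sd = 0.8)
  mine <- vectorFit(S, y, nPerm = 999, seed = 3)
  ef <- vegan::envfit(S, data.frame(y = y), permutations = 999)
  expect_equal(mine$rSquared, unname(ef$vectors$r[1]), tolerance = 1e-8)
  dirV <- as.numeric(ef$vectors$arrows[1, ])
  ## directions agree up to overall sign
  agree <- min(sum(abs(mine$direction - dirV)),
               sum(abs(mine$direction + dirV)))
  expect_lt(agree, 1e-6)
  ## permutation p-values land in the same region
  expect_lt(abs(mine$pValue - unname(ef$vectors$pvals[1])), 0.05)
})

test_that("vector-fit p-values are calibrated under independence", {
  set.seed(137)
  n <- 200
  S <- cbind(rnorm(n), rnorm(n))
  nrep <- 200
  rej <- 0L
  for (r in seq_len(nrep)) {
    y <- rnorm(n)
    v <- vectorFit(S, y, nPerm = 199, seed = 1000 + r)
    if (v$pValue <= 0.05) rej <- rej + 1L
  }
  expect_gte(rej / nrep, 0.02)
  expect_lte(rej / nrep, 0.09)
})

test_that("the preference factor passes categories through with fixed levels", {
  L <- rbind(c(0, -5, -5), c(0, 5, 5), c(0, 0, 0))
  tab <- data.frame(locus_id = c("a", "b", "c"),
                    lnL_T1 = L[, 1], lnL_T2 = L[, 2], lnL_T3 = L[, 3])
  g <- new("GLSTable", table = tab, topologyIds = c("T1", "T2", "T3"),
           focal = NA_character_, threshold = 2, pca = list())
  g <- categorizeLoci(deltaGLS(g), focal = "T1")
  f <- categorizeFactor(g)
  expect_identical(levels(f), c("A", "B", "C"))
  expect_equal(as.character(f), c("B", "C", "A"))
  ## degenerate single-level input warns
  tabA <- data.frame(locus_id = c("a", "b"), lnL_T1 = c(0, 0),
                     lnL_T2 = c(0, 0), lnL_T3 = c(0, 0))
  gA <- new("GLSTable", table = tabA, topologyIds = c("T1", "T2", "T3"),
            focal = NA_character_, threshold = 2, pca = list())
  gA <- categorizeLoci(deltaGLS(gA), focal = "T1")
  expect_warning(categorizeFactor(gA), "single-level")
})

## panel of independent noise predictors
noisePanel <- function(n, seed) {
  withr::with_seed(seed, {
    out <- data.frame(locus_id = sprintf("n%04d", 1:n))
    nm <- c("alignment_length", "pct_missing", "prop_variable_sites",
            "prop_parsimony_informative", "n_taxa", "mean_site_entropy",
            "rcfv", "avg_bootstrap", "rf_similarity",
            "root_to_tip_variance", "saturation", "total_tree_length",
            "avg_patristic_distance", "treeness", "treeness_over_rcfv")
    for (v in nm) out[[v]] <- rnorm(n)
    out
  })
}

test_that("a deterministic length threshold is recovered as a single split", {
  set.seed(145)
  n <- 300
  pan <- noisePanel(n, 7)
  pan$alignment_length <- round(runif(n, 50, 400))
  f <- factor(ifelse(pan$alignment_length < 150, "A",
                     sample(c("B", "C"), n, TRUE)),
              levels = c("A", "B", "C"))
  tree <- fitSignalTree(pan, f)
  expect_equal(tree$root$type, "split")
  expect_equal(tree$root$predictor, "alignment_length")
  gap <- sort(unique(pan$alignment_length))
  expect_lt(abs(tree$root$cut - 150), 10)  # within the inter-point gap
  tab <- signalTreeTable(tree)
  expect_true(all(tab$p_adjusted[tab$type == "split"] <= 0.05))
})

test_that("null simulations keep the tree root-only at the nominal rate", {
  set.seed(153)
  nrep <- 60
  rootOnly <- 0L
  for (r in seq_len(nrep)) {
    pan <- noisePanel(120, 2000 + r)
    f <- factor(sample(c("A", "B", "C"), 120, TRUE, c(0.5, 0.25, 0.25)),
                levels = c("A", "B", "C"))
    tr <- fitSignalTree(pan, f)
    if (signalTreeSplits(tr) == 0L) rootOnly <- rootOnly + 1L
  }
  expect_gte(rootOnly / nrep, 0.9)
})

test_that("alpha limits and the Bonferroni rule behave monotonically", {
  set.seed(161)
  pan <- noisePanel(200, 11)
  pan$alignment_length <- runif(200, 0, 1)
  f <- factor(ifelse(pan$alignment_length < 0.5, "A",
                     sample(c("B", "C"), 200, TRUE)),
              levels = c("A", "B", "C"))
  ## monotone in alpha; a noise factor gives a root-only tree at tiny alpha
  expect_lte(signalTreeSplits(fitSignalTree(pan, f, alpha = 1e-12)),
             signalTreeSplits(fitSignalTree(pan, f, alpha = 0.05)))
  fNoise <- factor(sample(c("A", "B", "C"), 200, TRUE),
                   levels = c("A", "B", "C"))
  expect_equal(signalTreeSplits(fitSignalTree(pan, fNoise, alpha = 1e-12)),
               0L)
  tBig <- fitSignalTree(pan, f, alpha = 0.05)
  expect_gte(signalTreeSplits(tBig), 1L)
  ## a marginal p of 0.01 with 15 predictors is not split-eligible at 0.05
  expect_gt(0.01 * 15, 0.05)
  ## duplicating all rows preserves the first split
  pan2 <- rbind(pan, pan)
  f2 <- factor(c(as.character(f), as.character(f)), levels = levels(f))
  t1 <- fitSignalTree(pan, f)
  t2 <- fitSignalTree(pan2, f2)
  expect_equal(t2$root$predictor, t1$root$predictor)
  expect_equal(t2$root$cut, t1$root$cut, tolerance = 0.05)
})

test_that("permutation p-values drive the same split decisions", {
  set.seed(169)
  pan <- noisePanel(150, 13)
  pan$saturation <- runif(150)
  f <- factor(ifelse(pan$saturation > 0.6, "C",
                     sample(c("A", "B"), 150, TRUE)),
              levels = c("A", "B", "C"))
  tr <- fitSignalTree(pan, f, method = "permutation", nPerm = 499, seed = 5)
  expect_equal(tr$root$predictor, "saturation")
  ## deterministic given seed
  tr2 <- fitSignalTree(pan, f, method = "permutation", nPerm = 499, seed = 5)
  expect_identical(signalTreeTable(tr), signalTreeTable(tr2))
})
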