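## Determinants of topological preference: permutation-tested vector
## fitting of each gene property onto the deltaGLS ordination plane, and a
## conditional-inference-style classification tree on the three-level
## preference factor with Bonferroni correction across predictors.

#' Fit a gene property onto the ordination plane
#'
#' Least-squares regression of the (centred) property on the two PCA score
#' columns gives the direction of maximum correlation (unit vector) and the
#' squared multiple correlation R2; significance is assessed by permuting
#' the property vector: `p = (1 + #{permuted R2 >= observed}) / (1 + nPerm)`.
#'
#' @param scores n x 2 matrix of ordination scores.
#' @param property numeric vector of length n (loci with missing values are
#'   dropped pairwise).
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed.
#' @param name property name carried into the result.
#' @return List with `property`, `direction` (unit 2-vector), `rSquared`,
#'   `pValue`, `nPermutations`, `n`.
#' @export
vectorFit <- function(scores, property, nPerm = 10000L, seed = 1L,
                      name = "property") {
  S <- as.matrix(scores)
  if (ncol(S) != 2L) stop("scores must have two columns")
  ok <- stats::complete.cases(S) & is.finite(property)
  S <- S[ok, , drop = FALSE]
  y <- property[ok]
  n <- length(y)
  if (n < 10L) stop("need >= 10 loci with finite values")
  if (stats::sd(y) == 0) {
    return(list(property = name, direction = c(NA_real_, NA_real_),
                rSquared = 0, pValue = 1, nPermutations = as.integer(nPerm),
                n = n))
  }
  Sc <- scale(S, center = TRUE, scale = FALSE)
  qr_ <- qr(Sc)
  Q <- qr.Q(qr_)
  yc <- y - mean(y)
  ss <- sum(yc^2)
  proj <- crossprod(Q, yc)
  r2 <- sum(proj^2) / ss
  beta <- qr.coef(qr_, yc)
  dir <- beta / sqrt(sum(beta^2))
  permR2 <- withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      yp <- yc[sample.int(n)]
      sum(crossprod(Q, yp)^2) / ss
    }, 0)
  })
  p <- (1 + sum(permR2 >= r2 - 1e-12)) / (1 + nPerm)
  list(property = name, direction = as.numeric(dir), rSquared = r2,
       pValue = p, nPermutations = as.integer(nPerm), n = n)
}

#' Vector-fit every property of a panel onto the ordination
#'
#' @param gls a [GLSTable-class] with `PC1`/`PC2` scores (see
#'   [pcaRotate()]).
#' @param panel property panel from [genePropertyPanel()] (matched by
#'   `locus_id`).
#' @param nPerm,seed passed to [vectorFit()] (seed fanned out per property).
#' @return data.frame: property, direction components, `r_squared`, `p`,
#'   Bonferroni-adjusted `p_adjusted`.
#' @export
vectorFitPanel <- function(gls, panel, nPerm = 10000L, seed = 1L) {
  tab <- glsTable(gls)
  if (!all(c("PC1", "PC2") %in% names(tab)))
    stop("run pcaRotate() first")
  idx <- match(tab$locus_id, panel$locus_id)
  cols <- propertyColumns(panel)
  rows <- lapply(cols, function(cn) {
    v <- vectorFit(cbind(tab$PC1, tab$PC2), panel[[cn]][idx],
                   nPerm = nPerm,
                   seed = substreamSeed(seed, paste0("envfit_", cn)),
                   name = cn)
    data.frame(property = cn, dir1 = v$direction[1L], dir2 = v$direction[2L],
               r_squared = v$rSquared, p = v$pValue, n = v$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "bonferroni")
  rownames(out) <- NULL
  out
}

#' Topological-preference factor
#'
#' The three-level category (A = uninformative, B = supporting the focal
#' topology, C = rejecting it) as an ordered-level factor, level order fixed
#' at A, B, C. Degenerate single-level inputs are returned with a warning
#' (they cannot support tree fitting).
#'
#' @param gls a categorized [GLSTable-class].
#' @return Factor of length n_loci, names = locus ids.
#' @export
categorizeFactor <- function(gls) {
  tab <- glsTable(gls)
  if (!"category" %in% names(tab)) stop("run categorizeLoci() first")
  f <- factor(as.character(tab$category), levels = c("A", "B", "C"))
  names(f) <- tab$locus_id
  if (length(unique(f[!is.na(f)])) < 2L)
    warning("single-level preference factor; degenerate for tree fitting")
  f
}

## Kruskal-Wallis chi-square statistic of predictor x by factor g
kwStatistic <- function(x, g) {
  r <- rank(x)
  n <- length(x)
  tieAdj <- 1 - sum(tapply(r, r, length)^3 - tapply(r, r, length)) /
    (n^3 - n)
  grp <- split(r, g, drop = TRUE)
  H <- 12 / (n * (n + 1)) *
    sum(vapply(grp, function(ri) length(ri) * mean(ri)^2, 0)) -
    3 * (n + 1)
  if (tieAdj > 0) H / tieAdj else 0
}

## p-value for predictor/factor association: asymptotic chi-square on rank
## scores or permutation of the factor
kwTest <- function(x, g, method = c("asymptotic", "permutation"),
                   nPerm = 9999L, seed = 1L) {
  method <- match.arg(method)
  g <- droplevels(g)
  df <- nlevels(g) - 1L
  if (df < 1L || stats::sd(x) == 0) return(list(stat = 0, p = 1))
  H <- kwStatistic(x, g)
  p <- if (method == "asymptotic") {
    stats::pchisq(H, df, lower.tail = FALSE)
  } else {
    perm <- withSeed(seed, vapply(seq_len(nPerm), function(i)
      kwStatistic(x, sample(g)), 0))
    (1 + sum(perm >= H - 1e-12)) / (1 + nPerm)
  }
  list(stat = H, p = p)
}

## best binary cutpoint: maximizes the chi-square statistic of the 2 x K
## table (left/right of cut x factor levels)
bestCutpoint <- function(x, g, minBucket = 7L) {
  ux <- sort(unique(x))
  if (length(ux) < 2L) return(NULL)
  cuts <- (ux[-1L] + ux[-length(ux)]) / 2
  if (length(cuts) > 200L)
    cuts <- unique(stats::quantile(x, probs = seq(0.01, 0.99, length.out = 200),
                                   names = FALSE, type = 1))
  lv <- levels(droplevels(g))
  best <- NULL
  for (cv in cuts) {
    left <- x <= cv
    nl <- sum(left); nr <- sum(!left)
    if (nl < minBucket || nr < minBucket) next
    tabL <- tabulate(match(g[left], lv), length(lv))
    tabR <- tabulate(match(g[!left], lv), length(lv))
    tot <- tabL + tabR
    expL <- tot * nl / (nl + nr)
    expR <- tot * nr / (nl + nr)
    ok <- tot > 0
    stat <- sum((tabL[ok] - expL[ok])^2 / expL[ok] +
                (tabR[ok] - expR[ok])^2 / expR[ok])
    if (is.null(best) || stat > best$stat) best <- list(cut = cv, stat = stat)
  }
  best
}

#' Conditional-inference-style classification tree
#'
#' Recursive partitioning of loci on gene properties against the three-level
#' preference factor. At each node every predictor's association with the
#' factor is measured by a Kruskal-Wallis rank statistic; p-values
#' (asymptotic chi-square by default, or permutation) are
#' Bonferroni-corrected across predictors, and the node splits on the most
#' significant predictor only when its adjusted p is at most `alpha` — so
#' every split is justified by a multiplicity-corrected permutation-style
#' test, and overfitting is controlled without pruning. The split point
#' maximizes the two-sample chi-square association between the binary split
#' and the factor. Recursion stops when no predictor is significant, the
#' node holds fewer than `minSplit` loci, or depth reaches `maxDepth`.
#'
#' @param panel property panel data.frame (predictors are its numeric
#'   metric columns).
#' @param factor_ three-level factor from [categorizeFactor()], parallel to
#'   `panel` rows.
#' @param alpha significance level for adjusted p-values (default 0.05).
#' @param method `"asymptotic"` or `"permutation"` p-values.
#' @param nPerm permutations when `method = "permutation"`.
#' @param minSplit minimum node size eligible for splitting (default 20).
#' @param maxDepth depth limit (default 5).
#' @param seed integer seed (used by permutation p-values).
#' @return An object of class `signalTree`: nested list of nodes
#'   (`split`/`leaf`), printable with `print()`.
#' @export
fitSignalTree <- function(panel, factor_, alpha = 0.05,
                          method = c("asymptotic", "permutation"),
                          nPerm = 9999L, minSplit = 20L, maxDepth = 5L,
                          seed = 1L) {
  method <- match.arg(method)
  cols <- propertyColumns(panel)
  X <- panel[, cols, drop = FALSE]
  g <- factor_
  if (nrow(X) != length(g)) stop("panel and factor lengths differ")
  keep <- !is.na(g)
  X <- X[keep, , drop = FALSE]
  g <- g[keep]
  grow <- function(idx, depth) {
    counts <- table(g[idx])
    leaf <- list(type = "leaf", n = length(idx), counts = counts)
    if (length(idx) < minSplit || depth >= maxDepth ||
        length(unique(g[idx])) < 2L)
      return(leaf)
    tests <- lapply(seq_along(cols), function(j) {
      x <- X[idx, j]
      ok <- is.finite(x)
      if (sum(ok) < minSplit || length(unique(g[idx][ok])) < 2L)
        return(list(stat = 0, p = 1))
      kwTest(x[ok], g[idx][ok], method = method, nPerm = nPerm,
             seed = substreamSeed(seed, paste0("kw_", depth, "_", cols[j])))
    })
    pAdj <- pmin(vapply(tests, `[[`, 0, "p") * length(cols), 1)
    jBest <- which.min(pAdj)
    if (pAdj[jBest] > alpha) return(leaf)
    x <- X[idx, jBest]
    ok <- is.finite(x)
    cut <- bestCutpoint(x[ok], g[idx][ok])
    if (is.null(cut)) return(leaf)
    left <- idx[ok][x[ok] <= cut$cut]
    right <- idx[ok][x[ok] > cut$cut]
    if (!length(left) || !length(right)) return(leaf)
    list(type = "split", predictor = cols[jBest], cut = cut$cut,
         pAdjusted = pAdj[jBest], n = length(idx),
         left = grow(left, depth + 1L), right = grow(right, depth + 1L))
  }
  out <- list(root = grow(seq_along(g), 0L), alpha = alpha,
              predictors = cols, n = length(g))
  class(out) <- "signalTree"
  out
}

#' @export
print.signalTree <- function(x, ...) {
  cat("signalTree on", x$n, "loci (alpha =", x$alpha, ")\n")
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(pad, "leaf n=", node$n, " [",
          paste(names(node$counts), node$counts, sep = "=", collapse = " "),
          "]\n", sep = "")
    } else {
      cat(pad, node$predictor, " <= ", signif(node$cut, 5),
          "  (adj p = ", signif(node$pAdjusted, 3), ", n = ", node$n, ")\n",
          sep = "")
      rec(node$left, indent + 1L)
      rec(node$right, indent + 1L)
    }
  }
  rec(x$root, 1L)
  invisible(x)
}

#' Flatten a signalTree into a nested table
#'
#' @param tree a `signalTree`.
#' @return data.frame with node id, parent id, type, predictor, cut,
#'   adjusted p and category counts.
#' @export
signalTreeTable <- function(tree) {
  rows <- list()
  walk <- function(node, parent) {
    id <- length(rows) + 1L
    rows[[id]] <<- data.frame(
      node = id, parent = parent, type = node$type,
      predictor = if (node$type == "split") node$predictor else NA,
      cut = if (node$type == "split") node$cut else NA,
      p_adjusted = if (node$type == "split") node$pAdjusted else NA,
      n = node$n,
      n_A = if (node$type == "leaf" && "A" %in% names(node$counts))
        as.integer(node$counts[["A"]]) else NA_integer_,
      n_B = if (node$type == "leaf" && "B" %in% names(node$counts))
        as.integer(node$counts[["B"]]) else NA_integer_,
      n_C = if (node$type == "leaf" && "C" %in% names(node$counts))
        as.integer(node$counts[["C"]]) else NA_integer_,
      stringsAsFactors = FALSE)
    if (node$type == "split") {
      walk(node$left, id)
      walk(node$right, id)
    }
  }
  walk(tree$root, NA_integer_)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count internal splits of a signalTree
#'
#' @param tree a `signalTree`.
#' @return Integer number of split nodes (0 = root-only tree).
#' @export
signalTreeSplits <- function(tree) {
  cnt <- function(node)
    if (node$type == "leaf") 0L else 1L + cnt(node$left) + cnt(node$right)
  cnt(tree$root)
}
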