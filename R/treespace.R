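## Gene-tree treespace: quartet dissimilarities, PCoA ordination, centroid
## disparity with subsampling null distributions, and clade-recovery
## scoring.

## Topology code of every quartet of `universe` taxa in `tree`:
## 0 = unresolved or taxon missing; 1 = ab|cd, 2 = ac|bd, 3 = ad|bc,
## indices referring to the quartet's own sorted taxon order. Uses the
## four-point condition on path lengths with unit branch lengths.
quartetCodes <- function(tree, universe, comb = NULL) {
  if (is.null(comb)) comb <- utils::combn(length(universe), 4L)
  idx <- match(universe, tree$tip.label)
  t1 <- tree
  t1$edge.length <- rep(1, nrow(t1$edge))
  D <- ape::cophenetic.phylo(t1)[tree$tip.label, tree$tip.label]
  a <- idx[comb[1L, ]]; b <- idx[comb[2L, ]]
  c_ <- idx[comb[3L, ]]; d <- idx[comb[4L, ]]
  ok <- !(is.na(a) | is.na(b) | is.na(c_) | is.na(d))
  out <- integer(ncol(comb))
  if (!any(ok)) return(replace(out, !ok, NA_integer_))
  s1 <- D[cbind(a[ok], b[ok])] + D[cbind(c_[ok], d[ok])]
  s2 <- D[cbind(a[ok], c_[ok])] + D[cbind(b[ok], d[ok])]
  s3 <- D[cbind(a[ok], d[ok])] + D[cbind(b[ok], c_[ok])]
  mn <- pmin(s1, s2, s3)
  nmin <- (s1 == mn) + (s2 == mn) + (s3 == mn)
  code <- integer(sum(ok))
  code[nmin == 1L & s1 == mn] <- 1L
  code[nmin == 1L & s2 == mn] <- 2L
  code[nmin == 1L & s3 == mn] <- 3L
  out[ok] <- code
  out[!ok] <- NA_integer_
  out
}

#' Quartet dissimilarity between two trees
#'
#' Both trees are pruned to their shared tips; over all four-taxon subsets
#' of the shared tips, the dissimilarity is the fraction resolved
#' differently among those resolved in both trees (quartets unresolved in
#' either tree are excluded from numerator and denominator). When no
#' quartet is resolved in both, the value is 0 with attribute
#' `noResolved = TRUE`; with fewer than 4 shared tips the value is `NA`.
#'
#' @param t1,t2 `phylo` trees.
#' @return Numeric in \[0, 1\] (or `NA`).
#' @export
quartetDissimilarity <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4L) return(NA_real_)
  shared <- sort(shared)
  p1 <- ape::keep.tip(t1, shared)
  p2 <- ape::keep.tip(t2, shared)
  comb <- utils::combn(length(shared), 4L)
  q1 <- quartetCodes(p1, shared, comb)
  q2 <- quartetCodes(p2, shared, comb)
  both <- q1 > 0L & q2 > 0L
  denom <- sum(both)
  if (denom == 0L) {
    out <- 0
    attr(out, "noResolved") <- TRUE
    return(out)
  }
  sum(q1[both] != q2[both]) / denom
}

#' Pairwise quartet dissimilarity matrix for a set of gene trees
#'
#' Each tree's quartet topologies over the union taxon set are computed
#' once, then compared pairwise on the quartets whose four taxa both trees
#' sample and both resolve. Pairs with fewer than four shared tips are
#' recorded as missing and median-imputed (with a warning), marked in the
#' `"imputed"` attribute.
#'
#' @param trees list of `phylo` (named; names become matrix dimnames).
#' @return Symmetric matrix of dissimilarities in \[0, 1\].
#' @export
treespaceDissimilarity <- function(trees) {
  n <- length(trees)
  if (is.null(names(trees))) names(trees) <- paste0("t", seq_len(n))
  universe <- sort(Reduce(union, lapply(trees, `[[`, "tip.label")))
  comb <- utils::combn(length(universe), 4L)
  codes <- lapply(trees, quartetCodes, universe = universe, comb = comb)
  D <- matrix(0, n, n, dimnames = list(names(trees), names(trees)))
  miss <- matrix(FALSE, n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1L)) {
    qi <- codes[[i]]
    for (j in (i + 1L):n) {
      qj <- codes[[j]]
      both <- !is.na(qi) & !is.na(qj) & qi > 0L & qj > 0L
      nb <- sum(both)
      nShared <- length(intersect(trees[[i]]$tip.label,
                                  trees[[j]]$tip.label))
      if (nShared < 4L) {
        miss[i, j] <- miss[j, i] <- TRUE
        D[i, j] <- D[j, i] <- NA_real_
      } else if (nb == 0L) {
        D[i, j] <- D[j, i] <- 0
      } else {
        d <- sum(qi[both] != qj[both]) / nb
        D[i, j] <- D[j, i] <- d
      }
    }
  }
  if (any(miss)) {
    warning(sum(miss) / 2, " tree pair(s) share < 4 tips; ",
            "median-imputed for ordination")
    D[miss] <- stats::median(D[upper.tri(D)], na.rm = TRUE)
  }
  attr(D, "imputed") <- miss
  D
}

#' Principal coordinate analysis of a dissimilarity matrix
#'
#' Classical scaling (double-centred \eqn{-D^2/2}) via [ape::pcoa()]. When
#' the most negative eigenvalue exceeds 1e-8 in magnitude the Cailliez
#' correction is applied. Axes with positive eigenvalues are retained, in
#' decreasing eigenvalue order.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @return List with `coordinates` (rows match `D`), `eigenvalues`, and
#'   `corrected` (logical).
#' @export
treespacePcoa <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("dissimilarity matrix must be symmetric")
  p0 <- ape::pcoa(D)
  eig <- p0$values$Eigenvalues
  corrected <- FALSE
  if (min(eig) < -1e-8) {
    p0 <- ape::pcoa(D, correction = "cailliez")
    corrected <- TRUE
    vec <- if (!is.null(p0$vectors.cor)) p0$vectors.cor else p0$vectors
    eig <- if ("Corr_eig" %in% names(p0$values)) p0$values$Corr_eig else
      p0$values$Eigenvalues
  } else vec <- p0$vectors
  keep <- which(eig > 1e-8 * max(eig))
  keep <- keep[keep <= ncol(vec)]
  coords <- vec[, keep, drop = FALSE]
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("Axis", seq_along(keep))
  list(coordinates = coords, eigenvalues = eig[keep], corrected = corrected)
}

#' Topological disparity: mean distance to the subset centroid
#'
#' @param coordinates numeric matrix of ordination coordinates (all retained
#'   axes).
#' @param subset row names or indices to use (default: all rows).
#' @return Mean Euclidean distance of the subset's points to their own
#'   centroid (0 for a single point).
#' @export
disparity <- function(coordinates, subset = NULL) {
  X <- as.matrix(coordinates)
  if (!is.null(subset)) {
    X <- X[subset, , drop = FALSE]
  }
  if (nrow(X) == 0L) stop("empty subset")
  ctr <- colMeans(X)
  mean(sqrt(rowSums(sweep(X, 2L, ctr)^2)))
}

#' Subsampling null distribution for disparity
#'
#' Draws `nReps` uniform random subsets of size `k` (without replacement
#' within a replicate), computes each subset's disparity, and locates an
#' observed disparity in that null: `percentile` is the proportion of null
#' values less than or equal to the observed. A significant reduction in
#' conflict is reported one-tailed at `percentile <= 0.05`.
#'
#' @inheritParams disparity
#' @param k subset size (`k <= nrow(coordinates)`).
#' @param observed observed disparity to locate (e.g. of a filtered subset).
#' @param nReps number of replicates (default 1000).
#' @param seed integer seed for reproducibility.
#' @return List with `null` (length `nReps`), `observed`, `percentile`,
#'   `significantReduction`.
#' @export
subsampleNull <- function(coordinates, k, observed, nReps = 1000L,
                          seed = 1L) {
  X <- as.matrix(coordinates)
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of points")
  null <- withSeed(seed, {
    vapply(seq_len(nReps),
           function(i) disparity(X, sample.int(n, k)), 0)
  })
  pct <- mean(null <= observed)
  list(null = null, observed = observed, percentile = pct,
       significantReduction = pct <= 0.05)
}

#' Build a treespace with disparity statistics and nulls
#'
#' Convenience orchestrator: pairwise quartet dissimilarities, PCoA, full
#' disparity, and for each named subset its disparity plus a subsampling
#' null of matching size.
#'
#' @param trees named list of `phylo` gene trees.
#' @param subsets optional named list of tree-name vectors.
#' @param nReps null replicates per subset.
#' @param seed master seed (fanned out per subset).
#' @return A [TreespaceResult-class].
#' @export
buildTreespace <- function(trees, subsets = NULL, nReps = 1000L, seed = 1L) {
  D <- treespaceDissimilarity(trees)
  imputed <- attr(D, "imputed")
  attr(D, "imputed") <- NULL
  ord <- treespacePcoa(D)
  dispFull <- disparity(ord$coordinates)
  subDisp <- numeric(0)
  nulls <- list()
  pct <- numeric(0)
  if (!is.null(subsets)) {
    for (nm in names(subsets)) {
      ids <- subsets[[nm]]
      obs <- disparity(ord$coordinates, ids)
      nl <- subsampleNull(ord$coordinates, length(ids), obs, nReps,
                          seed = substreamSeed(seed, paste0("null_", nm)))
      subDisp[nm] <- obs
      nulls[[nm]] <- nl$null
      pct[nm] <- nl$percentile
    }
  }
  new("TreespaceResult", dissimilarity = D, coordinates = ord$coordinates,
      eigenvalues = ord$eigenvalues, disparityFull = dispFull,
      subsetDisparities = subDisp, nullDistributions = nulls,
      percentileP = pct,
      imputed = if (any(imputed)) imputed else matrix(FALSE, 0, 0))
}

#' Clade recovery by a gene tree
#'
#' A clade is testable when at least two of its members are among the gene
#' tree's tips and at least one non-member tip is present; it is recovered
#' when its sampled members form one side of a bipartition of the unrooted
#' gene tree. The summary proportion uses testable clades only.
#'
#' @param geneTree a `phylo`.
#' @param clades named list of taxon-label vectors (see
#'   [readCladeDefinitions()]).
#' @return List with `status` (named character:
#'   `"recovered"`/`"not_recovered"`/`"untestable"`) and
#'   `proportionRecovered` (`NA` when nothing is testable).
#' @export
cladeRecovery <- function(geneTree, clades) {
  tips <- geneTree$tip.label
  status <- vapply(clades, function(members) {
    sampled <- intersect(members, tips)
    outgroup <- setdiff(tips, members)
    if (length(sampled) < 2L || length(outgroup) < 1L) return("untestable")
    rooted <- ape::root(geneTree, outgroup = outgroup[1L],
                        resolve.root = TRUE)
    if (ape::is.monophyletic(rooted, sampled)) "recovered" else
      "not_recovered"
  }, character(1))
  testable <- status != "untestable"
  list(status = status,
       proportionRecovered = if (any(testable))
         mean(status[testable] == "recovered") else NA_real_)
}

#' Clade-recovery table over many gene trees
#'
#' @param trees named list of `phylo`.
#' @inheritParams cladeRecovery
#' @return data.frame: one row per tree with per-clade status columns and
#'   `proportion_recovered`.
#' @export
cladeRecoveryTable <- function(trees, clades) {
  if (is.null(names(trees))) names(trees) <- paste0("t", seq_along(trees))
  rows <- lapply(names(trees), function(nm) {
    r <- cladeRecovery(trees[[nm]], clades)
    df <- data.frame(locus_id = nm, stringsAsFactors = FALSE)
    for (cl in names(r$status)) df[[cl]] <- r$status[[cl]]
    df$proportion_recovered <- r$proportionRecovered
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
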