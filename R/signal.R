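## Dissection of gene-wise log-likelihood scores: pairwise deltaGLS, PCA
## rotation of the (rank-2) delta space, threshold categorization of
## per-locus topological preference, and subset summaries.

#' Pairwise gene-wise log-likelihood differences (deltaGLS)
#'
#' Adds the ordered-pair difference columns `delta_<x>_<y> = lnL_x - lnL_y`
#' to a [GLSTable-class]. With three candidates the differences obey the
#' linear dependency `delta_12 = delta_13 - delta_23` exactly. For a pair
#' flagged indistinguishable after per-locus pruning, the later topology's
#' score is replaced by the earlier one's before differencing, forcing that
#' delta to zero while preserving the dependency. Loci with non-finite
#' scores are dropped with a warning.
#'
#' @param gls a [GLSTable-class] from [computeGLS()].
#' @return The table with delta columns added.
#' @export
deltaGLS <- function(gls) {
  tab <- gls@table
  ids <- gls@topologyIds
  lnLCols <- paste0("lnL_", ids)
  L <- as.matrix(tab[, lnLCols])
  bad <- !apply(is.finite(L), 1L, all)
  if (any(bad)) {
    warning(sum(bad), " locus/loci with non-finite lnL dropped")
    tab <- tab[!bad, , drop = FALSE]
    L <- L[!bad, , drop = FALSE]
  }
  pairIdx <- utils::combn(seq_along(ids), 2L)
  ## indistinguishable pairs: collapse the later lnL onto the earlier
  for (pi_ in seq_len(ncol(pairIdx))) {
    col <- paste0("identical_", ids[pairIdx[1L, pi_]], "_",
                  ids[pairIdx[2L, pi_]])
    if (col %in% names(tab)) {
      f <- tab[[col]]
      L[f, pairIdx[2L, pi_]] <- L[f, pairIdx[1L, pi_]]
    }
  }
  for (pi_ in seq_len(ncol(pairIdx))) {
    nm <- paste0("delta_", ids[pairIdx[1L, pi_]], "_", ids[pairIdx[2L, pi_]])
    tab[[nm]] <- L[, pairIdx[1L, pi_]] - L[, pairIdx[2L, pi_]]
  }
  methods::initialize(gls, table = tab)
}

## oriented focal-involving deltas: matrix n x (K-1) of delta(focal - other)
focalDeltas <- function(gls, focal) {
  ids <- gls@topologyIds
  others <- setdiff(ids, focal)
  out <- sapply(others, function(o) {
    c1 <- paste0("delta_", focal, "_", o)
    c2 <- paste0("delta_", o, "_", focal)
    if (c1 %in% names(gls@table)) gls@table[[c1]] else -gls@table[[c2]]
  })
  out <- matrix(out, ncol = length(others),
                dimnames = list(NULL, others))
  out
}

#' PCA rotation of the deltaGLS space
#'
#' Principal components of the centered (unscaled — all deltas share
#' log-likelihood units) locus x delta matrix. With three candidate
#' topologies the matrix has rank at most 2, so the first two components
#' account for 100\% of the variance. The sign convention orients PC1 so
#' positive scores associate with support for the focal topology (positive
#' mean focal-involving delta), and PC2 so its loading on the non-focal pair
#' delta is non-negative.
#'
#' @param gls a [GLSTable-class] with delta columns (see [deltaGLS()]).
#' @param focal focal topology id (defaults to the first).
#' @return The table with `PC1`, `PC2` score columns and the `pca` slot
#'   filled (`loadings` 2 x n_delta, `explainedVarPct`).
#' @export
pcaRotate <- function(gls, focal = gls@topologyIds[1L]) {
  ids <- gls@topologyIds
  dn <- deltaPairNames(ids)
  if (!all(dn %in% names(gls@table)))
    stop("delta columns missing; run deltaGLS() first")
  D <- as.matrix(gls@table[, dn])
  if (nrow(D) < 3L) stop("need >= 3 loci for PCA")
  Dc <- scale(D, center = TRUE, scale = FALSE)
  if (all(abs(Dc) < 1e-12)) {
    warning("zero variance in deltaGLS; degenerate PCA")
    tab <- gls@table; tab$PC1 <- 0; tab$PC2 <- 0
    return(methods::initialize(gls, table = tab,
      pca = list(loadings = matrix(0, 2, length(dn),
                                   dimnames = list(c("PC1", "PC2"), dn)),
                 explainedVarPct = c(PC1 = 0, PC2 = 0))))
  }
  sv <- svd(Dc)
  ev <- sv$d^2
  pct <- 100 * ev / sum(ev)
  rot <- sv$v[, 1:2, drop = FALSE]
  scores <- Dc %*% rot
  ## sign conventions
  fd <- rowMeans(focalDeltas(gls, focal))
  s1 <- stats::cov(scores[, 1L], fd)
  if (is.finite(s1) && s1 < 0) { rot[, 1L] <- -rot[, 1L]; scores[, 1L] <- -scores[, 1L] }
  npCol <- which(!grepl(focal, dn, fixed = TRUE))[1L]
  if (!is.na(npCol) && rot[npCol, 2L] < 0) {
    rot[, 2L] <- -rot[, 2L]; scores[, 2L] <- -scores[, 2L]
  }
  tab <- gls@table
  tab$PC1 <- scores[, 1L]
  tab$PC2 <- scores[, 2L]
  loadings <- t(rot)
  dimnames(loadings) <- list(c("PC1", "PC2"), dn)
  methods::initialize(gls, table = tab, focal = focal,
    pca = list(loadings = loadings,
               explainedVarPct = c(PC1 = pct[1L], PC2 = pct[2L])))
}

#' Categorize loci by topological preference
#'
#' Assigns each locus to one of three categories against a focal topology:
#' `A` (uninformative: all deltas within the threshold, inclusive), `B`
#' (supporting: at least one focal-involving comparison favours the focal
#' topology by more than the threshold and none disfavours it beyond it),
#' or `C` (rejecting: the reverse). Loci carrying evidence in both
#' directions are assigned by the larger absolute focal-involving delta
#' (ties to `C`) and flagged `conflict`. Loci whose only above-threshold
#' delta is the non-focal pair are assigned `A` and flagged
#' `alternative_only`.
#'
#' @param gls a [GLSTable-class] with delta columns.
#' @param focal focal topology id.
#' @param threshold positive deltaGLS cutoff (default 2 log-likelihood
#'   units; "within" is inclusive, "beyond" strict).
#' @return The table with `category`, `flag_conflict`,
#'   `flag_alternative_only` and per-alternative support columns
#'   `favours_<id>` / `rejects_<id>` added; `focal` and `threshold` slots
#'   set.
#' @export
categorizeLoci <- function(gls, focal = gls@topologyIds[1L], threshold = 2) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (!focal %in% gls@topologyIds) stop("unknown focal topology: ", focal)
  dn <- deltaPairNames(gls@topologyIds)
  if (!all(dn %in% names(gls@table)))
    stop("delta columns missing; run deltaGLS() first")
  tab <- gls@table
  allD <- as.matrix(tab[, dn])
  fd <- focalDeltas(gls, focal)
  n <- nrow(tab)
  category <- character(n)
  conflict <- logical(n)
  altOnly <- logical(n)
  for (i in seq_len(n)) {
    if (all(abs(allD[i, ]) <= threshold)) {
      category[i] <- "A"
      next
    }
    fav <- fd[i, ] > threshold
    dis <- fd[i, ] < -threshold
    if (!any(fav) && !any(dis)) {
      category[i] <- "A"
      altOnly[i] <- TRUE
    } else if (any(fav) && !any(dis)) {
      category[i] <- "B"
    } else if (any(dis) && !any(fav)) {
      category[i] <- "C"
    } else {
      conflict[i] <- TRUE
      mFav <- max(abs(fd[i, fav])); mDis <- max(abs(fd[i, dis]))
      category[i] <- if (mFav > mDis) "B" else "C"
    }
  }
  tab$category <- factor(category, levels = c("A", "B", "C"))
  tab$flag_conflict <- conflict
  tab$flag_alternative_only <- altOnly
  for (o in colnames(fd)) {
    tab[[paste0("favours_", o)]] <- fd[, o] > threshold
    tab[[paste0("rejects_", o)]] <- fd[, o] < -threshold
  }
  methods::initialize(gls, table = tab, focal = focal, threshold = threshold)
}

#' Category counts and percentages, overall and per subset
#'
#' @param gls a categorized [GLSTable-class].
#' @param subsets optional named list of locus-id vectors (e.g. the
#'   usefulness-ranked halves); unknown ids raise an error.
#' @return data.frame with one row per subset (plus `"all"`): `n`, counts
#'   and percentages of categories A/B/C.
#' @export
categorySummary <- function(gls, subsets = NULL) {
  tab <- gls@table
  if (!"category" %in% names(tab)) stop("run categorizeLoci() first")
  one <- function(name, ids) {
    unknown <- setdiff(ids, tab$locus_id)
    if (length(unknown))
      stop("unknown locus id(s) in subset '", name, "': ",
           paste(utils::head(unknown, 3), collapse = ", "))
    sub <- tab[tab$locus_id %in% ids, ]
    cnt <- table(sub$category)
    data.frame(subset = name, n = nrow(sub),
               n_A = as.integer(cnt[["A"]]), n_B = as.integer(cnt[["B"]]),
               n_C = as.integer(cnt[["C"]]),
               pct_A = 100 * cnt[["A"]] / max(nrow(sub), 1L),
               pct_B = 100 * cnt[["B"]] / max(nrow(sub), 1L),
               pct_C = 100 * cnt[["C"]] / max(nrow(sub), 1L),
               stringsAsFactors = FALSE)
  }
  out <- one("all", tab$locus_id)
  if (!is.null(subsets))
    for (nm in names(subsets)) out <- rbind(out, one(nm, subsets[[nm]]))
  rownames(out) <- NULL
  out
}

#' Support breakdown against one vs both alternatives
#'
#' For informative loci, counts those favouring (or rejecting) the focal
#' topology against both alternatives versus only one — the
#' "coloured vs white" wheel-section breakdown of the categorization plot.
#'
#' @param gls a categorized [GLSTable-class].
#' @return data.frame with counts: `uninformative`, `supporting_both`,
#'   `supporting_one`, `rejecting_both`, `rejecting_one`.
#' @export
categoryBreakdown <- function(gls) {
  tab <- gls@table
  if (!"category" %in% names(tab)) stop("run categorizeLoci() first")
  fd <- focalDeltas(gls, gls@focal)
  thr <- gls@threshold
  nFav <- rowSums(fd > thr)
  nDis <- rowSums(fd < -thr)
  data.frame(
    uninformative = sum(tab$category == "A"),
    supporting_both = sum(tab$category == "B" & nFav == ncol(fd)),
    supporting_one = sum(tab$category == "B" & nFav < ncol(fd)),
    rejecting_both = sum(tab$category == "C" & nDis == ncol(fd)),
    rejecting_one = sum(tab$category == "C" & nDis < ncol(fd)))
}
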