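## Per-locus gene properties: fifteen metrics spanning phylogenetic signal
## (bootstrap support, congruence with a reference topology), systematic
## bias (saturation, compositional heterogeneity, clocklikeness) and
## information content / rate (length, occupancy, variability, tree length,
## entropy), plus the usefulness ranking built from them.

isMissingResidue <- function(m) m == "X" | m == "-"

#' Relative composition frequency variability (RCFV)
#'
#' Mean absolute deviation of per-taxon residue frequencies from the
#' across-taxon mean frequency, summed over the 20 states and averaged over
#' taxa: `sum_t sum_s |f_st - fbar_s| / n_taxa`. Frequencies are computed
#' over non-missing cells per taxon. A compositional-bias proxy: 0 when all
#' taxa share the same composition.
#'
#' @param aln a [LocusAlignment-class] with >= 2 taxa.
#' @return Non-negative numeric.
#' @export
rcfv <- function(aln) {
  if (nTaxa(aln) < 2L) stop("RCFV needs >= 2 taxa")
  m <- aln@seqs
  F <- t(apply(m, 1L, function(r) {
    r <- r[!isMissingResidue(r)]
    if (!length(r)) return(rep(0, 20))
    tabulate(match(r, aminoAcids()), 20L) / length(r)
  }))
  fbar <- colMeans(F)
  sum(abs(sweep(F, 2L, fbar))) / nrow(F)
}

#' Substitution saturation of a locus
#'
#' Regresses observed (uncorrected p) pairwise distances on patristic
#' distances from the gene tree through the origin and returns `1 - slope`.
#' Near 0 when observed divergence tracks inferred distance linearly; grows
#' toward 1 as multiple substitutions erode the relationship.
#'
#' @param aln a [LocusAlignment-class].
#' @param geneTree `phylo` with branch lengths over (a subset of) the
#'   alignment's taxa.
#' @return `1 - slope` of the origin-constrained least-squares fit.
#' @export
saturationIndex <- function(aln, geneTree) {
  taxa <- intersect(geneTree$tip.label, taxonLabels(aln))
  if (length(taxa) < 4L) stop("saturation needs >= 4 taxa")
  pat <- ape::cophenetic.phylo(geneTree)[taxa, taxa]
  pd <- pDistances(aln, taxa)
  ut <- upper.tri(pat)
  x <- pat[ut]; y <- pd[ut]
  ok <- is.finite(x) & is.finite(y)
  if (sum(x[ok]^2) == 0) return(0)
  slope <- sum(x[ok] * y[ok]) / sum(x[ok]^2)
  1 - slope
}

## uncorrected p-distance matrix, pairwise-deletion of missing cells
pDistances <- function(aln, taxa = taxonLabels(aln)) {
  m <- aln@seqs[taxa, , drop = FALSE]
  miss <- isMissingResidue(m)
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !miss[i, ] & !miss[j, ]
    out[i, j] <- out[j, i] <-
      if (any(ok)) mean(m[i, ok] != m[j, ok]) else NA_real_
  }
  out
}

## per-column Shannon entropy in bits over non-missing residues
siteEntropies <- function(aln) {
  apply(aln@seqs, 2L, function(col) {
    col <- col[!isMissingResidue(col)]
    if (length(col) < 2L) return(0)
    p <- table(col) / length(col)
    -sum(p * log2(p))
  })
}

#' Compute the fifteen-metric gene-property record for one locus
#'
#' Alignment metrics: `alignment_length`, `pct_missing`,
#' `prop_variable_sites`, `prop_parsimony_informative`, `n_taxa`,
#' `mean_site_entropy`, `rcfv`. Tree metrics (midpoint-rooted where rooting
#' matters): `avg_bootstrap`, `rf_similarity` (1 - normalized
#' Robinson-Foulds distance to the reference, shared taxa), `root_to_tip_variance`,
#' `saturation`, `total_tree_length`, `avg_patristic_distance`, `treeness`
#' (internal branch length over total), `treeness_over_rcfv`. With fewer
#' than four taxa only the alignment-level fields are populated.
#'
#' @param aln a [LocusAlignment-class].
#' @param geneTree `phylo` with branch lengths, tips within the alignment's
#'   taxa; node labels taken as support values when present.
#' @param referenceTree `phylo` spanning a superset of the gene tree's tips.
#' @return One-row data.frame with `locus_id` and the 15 metrics.
#' @export
computeGeneProperties <- function(aln, geneTree, referenceTree) {
  m <- aln@seqs
  miss <- isMissingResidue(m)
  nonMissPerCol <- colSums(!miss)
  varSite <- apply(m, 2L, function(col) {
    r <- col[!isMissingResidue(col)]
    length(unique(r)) > 1L
  })
  parsInf <- apply(m, 2L, function(col) {
    r <- col[!isMissingResidue(col)]
    tab <- table(r)
    sum(tab >= 2L) >= 2L
  })
  rec <- data.frame(
    locus_id = locusId(aln),
    alignment_length = nSites(aln),
    pct_missing = 100 * mean(miss),
    prop_variable_sites = mean(varSite[nonMissPerCol >= 2L]),
    prop_parsimony_informative = mean(parsInf),
    n_taxa = nTaxa(aln),
    mean_site_entropy = mean(siteEntropies(aln)),
    rcfv = rcfv(aln),
    stringsAsFactors = FALSE)
  treeFields <- c("avg_bootstrap", "rf_similarity", "root_to_tip_variance",
                  "saturation", "total_tree_length",
                  "avg_patristic_distance", "treeness",
                  "treeness_over_rcfv")
  if (is.null(geneTree) || length(geneTree$tip.label) < 4L ||
      is.null(geneTree$edge.length)) {
    rec[treeFields] <- NA_real_
    return(rec)
  }
  gt <- geneTree
  ## support values from internal node labels, scale-agnostic
  supp <- suppressWarnings(as.numeric(gt$node.label))
  rec$avg_bootstrap <- if (length(supp) && any(is.finite(supp)))
    mean(supp[is.finite(supp)]) else NA_real_
  shared <- intersect(gt$tip.label, referenceTree$tip.label)
  rec$rf_similarity <- if (length(shared) >= 4L) {
    g <- ape::unroot(ape::keep.tip(gt, shared))
    r <- ape::unroot(ape::keep.tip(referenceTree, shared))
    maxRF <- 2 * (length(shared) - 3L)
    1 - phangorn::RF.dist(g, r) / maxRF
  } else NA_real_
  mid <- tryCatch(phangorn::midpoint(gt), error = function(e) NULL)
  rec$root_to_tip_variance <- if (!is.null(mid)) {
    depths <- ape::node.depth.edgelength(mid)[seq_along(mid$tip.label)]
    stats::var(depths)
  } else NA_real_
  rec$saturation <- saturationIndex(aln, gt)
  rec$total_tree_length <- sum(gt$edge.length)
  pat <- ape::cophenetic.phylo(gt)
  rec$avg_patristic_distance <- mean(pat[upper.tri(pat)])
  internal <- gt$edge[, 2L] > length(gt$tip.label)
  rec$treeness <- if (sum(gt$edge.length) > 0)
    sum(gt$edge.length[internal]) / sum(gt$edge.length) else 0
  rec$treeness_over_rcfv <- if (rec$rcfv > 0) rec$treeness / rec$rcfv else
    NA_real_
  rec
}

#' Gene-property panel for many loci
#'
#' @param loci list of [LocusAlignment-class].
#' @param geneTrees list of `phylo` parallel to `loci` (entries may be
#'   `NULL`).
#' @param referenceTree reference `phylo` for congruence metrics.
#' @return data.frame with one row per locus.
#' @export
genePropertyPanel <- function(loci, geneTrees, referenceTree) {
  rows <- lapply(seq_along(loci), function(i)
    computeGeneProperties(loci[[i]],
                          if (i <= length(geneTrees)) geneTrees[[i]] else NULL,
                          referenceTree))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## the metric columns of a property panel
propertyColumns <- function(panel) {
  setdiff(names(panel), c("locus_id", "usefulness", "rank"))
}

#' Rank loci by phylogenetic usefulness
#'
#' Principal components of the z-scored property panel (missing values
#' median-imputed). The usefulness axis is chosen among the first two
#' components: each is oriented so the signal metrics (`avg_bootstrap`,
#' `rf_similarity`) load positively, then scored by the contrast between
#' the mean signal loading and the mean bias loading
#' (`root_to_tip_variance`, `saturation`, `rcfv`); the axis with the larger
#' positive contrast wins (an error is raised when neither axis separates
#' signal from bias). Scores are signed so signal-rich loci rank first;
#' ties are broken by locus id. Deterministic: no randomness is involved.
#'
#' @param panel data.frame from [genePropertyPanel()] (>= 10 loci).
#' @return List with `ranked` (locus ids, most useful first), `scores`
#'   (named usefulness scores in that order), `axis` (which PC was used) and
#'   `loadings`.
#' @export
usefulnessSort <- function(panel) {
  if (nrow(panel) < 10L) stop("usefulness ranking needs >= 10 loci")
  cols <- propertyColumns(panel)
  X <- as.matrix(panel[, cols])
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    if (anyNA(x)) x[is.na(x)] <- stats::median(x, na.rm = TRUE)
    X[, j] <- x
  }
  sds <- apply(X, 2L, stats::sd)
  keep <- sds > 0
  Z <- scale(X[, keep, drop = FALSE])
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  good <- intersect(c("avg_bootstrap", "rf_similarity"), colnames(Z))
  badM <- intersect(c("root_to_tip_variance", "saturation", "rcfv"),
                    colnames(Z))
  if (length(good) < 2L || length(badM) < 1L)
    stop("panel lacks the signal/bias metrics needed for the usefulness axis")
  contrast <- numeric(2)
  for (k in 1:2) {
    ld <- pc$rotation[, k]
    if (sum(ld[good]) < 0) ld <- -ld            # orient: signal positive
    contrast[k] <- mean(ld[good]) - mean(ld[badM])
  }
  if (max(contrast) <= 0)
    stop("neither of the first two PCs separates signal from bias ",
         "metrics; inspect the loadings and choose an axis manually")
  axis <- which.max(contrast)
  ld <- pc$rotation[, axis]
  score <- pc$x[, axis]
  if (sum(ld[good]) < 0) { score <- -score; ld <- -ld }
  ord <- order(-score, panel$locus_id)
  list(ranked = panel$locus_id[ord],
       scores = stats::setNames(score[ord], panel$locus_id[ord]),
       axis = axis, loadings = ld)
}

#' Top fraction of a usefulness ranking
#'
#' Returns the top `ceiling(fraction * n)` locus ids of a ranked list; an
#' explicit `n` overrides the fraction (e.g. to reproduce a published count
#' that was taken after additional filtering).
#'
#' @param ranked character vector of locus ids, most useful first.
#' @param fraction fraction in (0, 1\].
#' @param n optional explicit count overriding `fraction`.
#' @return Character vector of locus ids.
#' @export
subsetByUsefulness <- function(ranked, fraction = 0.5, n = NULL) {
  if (is.null(n)) {
    if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
    n <- ceiling(fraction * length(ranked))
  }
  ranked[seq_len(min(n, length(ranked)))]
}
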