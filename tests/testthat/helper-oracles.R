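## Independent oracles used to validate the package's own implementations.
## These deliberately take different computational routes than the code
## under test.

## Brute-force site log-likelihoods by explicit summation over all internal
## node state assignments (only feasible for tiny trees).
bruteForceSiteLnL <- function(aln, tree, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  internal <- sort(unique(tree$edge[, 1L]))
  nInt <- length(internal)
  rates <- topodissect::discreteGammaRates(
    if (length(model@gammaShape)) model@gammaShape else 1,
    if (length(model@gammaShape)) model@nRateCategories else 1L)
  if (!length(model@gammaShape)) rates <- 1
  pi_ <- model@frequencies
  root <- tree$edge[nrow(tree$edge), 1L]
  codes <- match(aln@seqs[tree$tip.label, , drop = FALSE],
                 topodissect::aminoAcids())
  dim(codes) <- dim(aln@seqs[tree$tip.label, , drop = FALSE])
  grid <- as.matrix(expand.grid(rep(list(1:20), nInt)))
  colnames(grid) <- internal
  out <- numeric(ncol(codes))
  for (col in seq_len(ncol(codes))) {
    likTot <- 0
    for (r in rates) {
      Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
        topodissect::transitionProbs(model, tree$edge.length[e], r))
      lik <- pi_[grid[, as.character(root)]]
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
        ap <- grid[, as.character(p)]
        if (ch <= ntip) {
          s <- codes[ch, col]
          if (!is.na(s)) lik <- lik * Ps[[e]][cbind(ap, s)]
          ## missing tip contributes a factor of 1
        } else {
          lik <- lik * Ps[[e]][cbind(ap, grid[, as.character(ch)])]
        }
      }
      likTot <- likTot + sum(lik) / length(rates)
    }
    out[col] <- log(likTot)
  }
  out
}

## Quartet dissimilarity by explicit pruning of every four-taxon subset and
## Robinson-Foulds comparison of the pruned trees.
quartetOracle <- function(t1, t2) {
  shared <- sort(intersect(t1$tip.label, t2$tip.label))
  if (length(shared) < 4L) return(NA_real_)
  quads <- utils::combn(shared, 4L)
  nBoth <- 0L; nDiff <- 0L
  for (qi in seq_len(ncol(quads))) {
    q <- quads[, qi]
    p1 <- ape::unroot(ape::keep.tip(t1, q))
    p2 <- ape::unroot(ape::keep.tip(t2, q))
    r1 <- p1$Nnode == 2L
    r2 <- p2$Nnode == 2L
    if (!(r1 && r2)) next
    nBoth <- nBoth + 1L
    if (ape::dist.topo(p1, p2)[1L] > 0) nDiff <- nDiff + 1L
  }
  if (nBoth == 0L) return(0)
  nDiff / nBoth
}

## random binary tree with branch lengths in a range
randomTree <- function(n, minLen = 0.05, maxLen = 0.4,
                       labels = paste0("t", seq_len(n))) {
  tr <- ape::rtree(n, tip.label = labels)
  tr$edge.length <- stats::runif(nrow(tr$edge), minLen, maxLen)
  tr
}

## small alignment from named sequence strings
aln_ <- function(...) topodissect::locusAlignment(c(...))
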