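## Amino-acid phylogenetic likelihood: Felsenstein pruning with per-node
## scaling, discrete-gamma mixtures, and per-edge branch-length optimization
## performed in the eigenbasis of the symmetrized generator (so each 1-D
## line search costs a 20-vector contraction per site, not a tree traversal).

## ---- alignment encoding -------------------------------------------------

## integer codes 1..20 (aminoAcids order), NA = missing/gap; pattern-compress
encodeAlignment <- function(aln, taxa = taxonLabels(aln)) {
  m <- aln@seqs[taxa, , drop = FALSE]
  codes <- matrix(match(m, aminoAcids()), nrow = nrow(m),
                  dimnames = list(taxa, NULL))
  key <- apply(codes, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  patIdx <- match(key, key[first])
  list(codes = codes[, first, drop = FALSE],
       w = as.numeric(tabulate(patIdx, sum(first))),
       siteToPattern = patIdx, nSites = ncol(m), taxa = taxa)
}

## ---- tree bookkeeping ---------------------------------------------------

treeInfo <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  root <- tree$edge[nrow(tree$edge), 1L]
  list(tree = tree, edge = tree$edge, ntip = ntip, root = root,
       nodes = ntip + tree$Nnode,
       childEdges = split(seq_len(nrow(tree$edge)), tree$edge[, 1L]))
}

## cheap per-column scaling factor (any positive magnitude proxy works)
.colScale <- function(M) .colMeans(M, nrow(M), ncol(M))

## ---- pruning ------------------------------------------------------------

## One post-order pass for one rate category. Returns per-pattern
## log-likelihood plus down partials and per-edge propagated contributions
## (needed by the branch-length optimizer).
downPass <- function(enc, ti, el, eig, rate, keepParts = FALSE,
                     Pcache = NULL) {
  ntip <- ti$ntip; npat <- length(enc$w)
  tipCode <- enc$codes[match(ti$tree$tip.label, enc$taxa), , drop = FALSE]
  Dpart <- vector("list", ti$nodes)
  Dscale <- vector("list", ti$nodes)
  Cmat <- if (keepParts) vector("list", nrow(ti$edge)) else NULL
  Cscale <- if (keepParts) vector("list", nrow(ti$edge)) else NULL
  zero <- rep(0, npat)
  for (e in seq_len(nrow(ti$edge))) {
    p <- ti$edge[e, 1L]; ch <- ti$edge[e, 2L]
    P <- if (is.null(Pcache)) transitionProbs(eig, el[e], rate) else
      Pcache[[e]]
    if (ch <= ntip) {
      idx <- tipCode[ch, ]
      idx[is.na(idx)] <- 21L
      C <- cbind(P, rep(1, 20L))[, idx, drop = FALSE]
      cs <- zero
    } else {
      C <- P %*% Dpart[[ch]]
      cs <- Dscale[[ch]]
    }
    if (keepParts) { Cmat[[e]] <- C; Cscale[[e]] <- cs }
    if (is.null(Dpart[[p]])) {
      Dpart[[p]] <- C
      Dscale[[p]] <- cs
    } else {
      M <- Dpart[[p]] * C
      s <- .colScale(M)
      if (any(s <= 0) || anyNA(s)) {
        bad <- which(s <= 0 | is.na(s))[1L]
        stop("non-finite partial likelihood at alignment column ",
             which(enc$siteToPattern == bad)[1L])
      }
      Dpart[[p]] <- M * rep(1 / s, each = 20L)
      Dscale[[p]] <- Dscale[[p]] + cs + log(s)
    }
  }
  lik <- colSums(eig$pi * Dpart[[ti$root]])
  list(patLnL = as.vector(log(lik) + Dscale[[ti$root]]),
       Dpart = Dpart, Dscale = Dscale, Cmat = Cmat, Cscale = Cscale,
       tipCode = tipCode)
}

## Pre-order pass: for every edge, the "rest of tree" partial F seen from the
## parent side, plus up partials for recursion.
upPass <- function(ti, el, eig, rate, dp, Pcache = NULL) {
  npat <- length(dp$Dscale[[ti$root]])
  ones <- matrix(1, 20L, npat)
  Upart <- vector("list", ti$nodes); Uscale <- vector("list", ti$nodes)
  Upart[[ti$root]] <- ones; Uscale[[ti$root]] <- rep(0, npat)
  Fmat <- vector("list", nrow(ti$edge)); Fscale <- vector("list", nrow(ti$edge))
  for (e in rev(seq_len(nrow(ti$edge)))) {   # pre-order
    p <- ti$edge[e, 1L]; ch <- ti$edge[e, 2L]
    FF <- Upart[[p]]
    fs <- Uscale[[p]]
    for (e2 in ti$childEdges[[as.character(p)]]) {
      if (e2 == e) next
      FF <- FF * dp$Cmat[[e2]]
      fs <- fs + dp$Cscale[[e2]]
    }
    s <- .colScale(FF)
    FF <- FF * rep(1 / s, each = 20L); fs <- fs + log(s)
    Fmat[[e]] <- FF; Fscale[[e]] <- fs
    if (ch > ti$ntip) {
      P <- if (is.null(Pcache)) transitionProbs(eig, el[e], rate) else
        Pcache[[e]]
      U <- crossprod(P, FF)
      s <- .colScale(U)
      Upart[[ch]] <- U * rep(1 / s, each = 20L)
      Uscale[[ch]] <- fs + log(s)
    }
  }
  list(Fmat = Fmat, Fscale = Fscale)
}

## per-pattern log-likelihood across gamma categories (equal weights)
mixPatterns <- function(catLnL) {
  if (length(catLnL) == 1L) return(catLnL[[1L]])
  M <- do.call(rbind, catLnL)
  mx <- apply(M, 2L, max)
  log(colMeans(exp(sweep(M, 2L, mx, "-")))) + mx
}

## ---- public: site log-likelihoods --------------------------------------

#' Per-site log-likelihoods under a fixed tree and model
#'
#' Felsenstein pruning in post-order with per-node rescaling against
#' underflow. Missing residues and gaps contribute all-ones partial vectors
#' (an entirely missing column has log-likelihood 0). Discrete-gamma
#' mixtures are averaged over equally weighted categories.
#'
#' @param aln a [LocusAlignment-class]; the tree's tips must be a subset of
#'   its taxa (the alignment is restricted to the tips).
#' @param tree a `phylo` with branch lengths.
#' @param model a [SubstitutionModel-class].
#' @param topologyId identifier recorded in the result.
#' @param minTaxa minimum tip count admitted (default 4; lower values are
#'   useful for closed-form checks on toy trees).
#' @return A [SiteLikelihoodResult-class].
#' @export
siteLogLikelihoods <- function(aln, tree, model, topologyId = "T",
                               minTaxa = 4L) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  missingTips <- setdiff(tree$tip.label, taxonLabels(aln))
  if (length(missingTips))
    stop("tree tips absent from alignment: ",
         paste(missingTips, collapse = ", "))
  if (length(tree$tip.label) < minTaxa)
    stop("need >= ", minTaxa, " taxa for likelihood computation")
  enc <- encodeAlignment(aln, tree$tip.label)
  ti <- treeInfo(tree)
  el <- ti$tree$edge.length
  eig <- modelEigen(model)
  rates <- modelRates(model)
  catLnL <- lapply(rates, function(r) downPass(enc, ti, el, eig, r)$patLnL)
  patLnL <- mixPatterns(catLnL)
  siteLnL <- patLnL[enc$siteToPattern]
  if (any(!is.finite(siteLnL)))
    stop("non-finite site log-likelihood at column ",
         which(!is.finite(siteLnL))[1L])
  new("SiteLikelihoodResult", locusId = locusId(aln),
      topologyId = topologyId, siteLnL = siteLnL, geneLnL = sum(siteLnL),
      tree = ti$tree, converged = TRUE)
}

## ---- branch-length optimization -----------------------------------------

## f(t) for one edge from cached flank partials, all categories
edgeLnLFun <- function(parts, w, lambda, rates) {
  k <- length(rates)
  function(t) {
    cat <- vector("list", k)
    for (ci in seq_len(k)) {
      ev <- exp(lambda * rates[ci] * t)
      L <- pmax(colSums(parts$C[[ci]] * ev), 1e-300)
      cat[[ci]] <- log(L) + parts$scale[[ci]]
    }
    sum(w * mixPatterns(cat))
  }
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate-wise bounded scalar optimization (branch lengths constrained to
#' \[1e-8, 10\]) cycling over all branches until the gene log-likelihood
#' improves by less than `tol` between sweeps or `maxSweeps` elapse. Each
#' sweep evaluates candidate lengths against cached flank partial
#' likelihoods; the best-scoring length vector seen is returned, so the
#' result is never worse than the initial tree.
#'
#' @inheritParams siteLogLikelihoods
#' @param topology a `phylo`; existing branch lengths are used as the
#'   starting point, otherwise all branches start at `init`.
#' @param init fallback initial branch length.
#' @param tol convergence tolerance in log-likelihood units between sweeps.
#' @param maxSweeps sweep limit; hitting it sets `converged = FALSE` with a
#'   warning.
#' @param bounds length-2 numeric search interval for every branch.
#' @return A [SiteLikelihoodResult-class] with the optimized tree.
#' @export
optimizeBranchLengths <- function(aln, topology, model, topologyId = "T",
                                  init = 0.1, tol = 1e-3, maxSweeps = 50L,
                                  bounds = c(1e-8, 10)) {
  tree <- ape::unroot(topology)
  missingTips <- setdiff(tree$tip.label, taxonLabels(aln))
  if (length(missingTips))
    stop("tree tips absent from alignment: ",
         paste(missingTips, collapse = ", "))
  if (length(tree$tip.label) < 4L)
    stop("need >= 4 taxa for likelihood computation")
  ti <- treeInfo(tree)
  nE <- nrow(ti$edge)
  el <- if (!is.null(ti$tree$edge.length))
    pmin(pmax(ti$tree$edge.length, bounds[1L]), bounds[2L]) else
    rep(init, nE)
  enc <- encodeAlignment(aln, tree$tip.label)
  eig <- modelEigen(model)
  rates <- modelRates(model)
  k <- length(rates)
  sqrtPi <- eig$sqrtPi

  npat <- length(enc$w)
  ## tip partial-likelihood indicators, shared across categories/sweeps
  tipCode <- enc$codes[match(tree$tip.label, enc$taxa), , drop = FALSE]
  tipG <- vector("list", ti$ntip)
  for (tp in seq_len(ti$ntip)) {
    idx <- tipCode[tp, ]
    G <- matrix(0, 20L, npat)
    G[cbind(idx[!is.na(idx)], which(!is.na(idx)))] <- 1
    G[, is.na(idx)] <- 1
    tipG[[tp]] <- G
  }
  zero <- rep(0, npat)

  makePcache <- function(el) lapply(rates, function(r)
    lapply(seq_len(nE), function(e) transitionProbs(eig, el[e], r)))
  evalAt <- function(el, Pcache) {
    dps <- lapply(seq_len(k), function(ci)
      downPass(enc, ti, el, eig, rates[ci], keepParts = TRUE,
               Pcache = Pcache[[ci]]))
    lnL <- sum(enc$w * mixPatterns(lapply(dps, `[[`, "patLnL")))
    list(dps = dps, lnL = lnL)
  }

  Pc <- makePcache(el)
  ev <- evalAt(el, Pc)
  cur <- list(el = el, lnL = ev$lnL)
  best <- cur
  converged <- FALSE
  for (sweep_i in seq_len(maxSweeps)) {
    ups <- lapply(seq_len(k), function(ci)
      upPass(ti, cur$el, eig, rates[ci], ev$dps[[ci]], Pcache = Pc[[ci]]))
    elNew <- cur$el
    for (e in seq_len(nE)) {
      ch <- ti$edge[e, 2L]
      C <- vector("list", k); sc <- vector("list", k)
      for (ci in seq_len(k)) {
        FF <- ups[[ci]]$Fmat[[e]]
        if (ch <= ti$ntip) {
          G <- tipG[[ch]]
          gs <- zero
        } else {
          G <- ev$dps[[ci]]$Dpart[[ch]]
          gs <- ev$dps[[ci]]$Dscale[[ch]]
        }
        a <- crossprod(eig$U, FF * sqrtPi)
        b <- crossprod(eig$U, G * sqrtPi)
        C[[ci]] <- a * b
        sc[[ci]] <- ups[[ci]]$Fscale[[e]] + gs
      }
      f <- edgeLnLFun(list(C = C, scale = sc), enc$w, eig$lambda, rates)
      opt <- stats::optimize(f, interval = bounds, maximum = TRUE,
                             tol = 1e-5)
      cand_t <- opt$maximum
      cand_o <- opt$objective
      fl <- f(bounds[1L])          # golden search cannot land on a bound
      if (fl >= cand_o) { cand_t <- bounds[1L]; cand_o <- fl }
      if (cand_o >= f(elNew[e])) elNew[e] <- cand_t
    }
    PcNew <- makePcache(elNew)
    evNew <- evalAt(elNew, PcNew)
    if (evNew$lnL < cur$lnL - 1e-9) {
      ## damped fallback: geometric-mean step towards the proposal
      elMid <- sqrt(elNew * cur$el)
      PcMid <- makePcache(elMid)
      evMid <- evalAt(elMid, PcMid)
      if (evMid$lnL > cur$lnL) {
        cur <- list(el = elMid, lnL = evMid$lnL)
        Pc <- PcMid; ev <- evMid
      } else {
        converged <- TRUE
        break
      }
    } else {
      improved <- evNew$lnL - cur$lnL
      cur <- list(el = elNew, lnL = evNew$lnL)
      Pc <- PcNew; ev <- evNew
      if (improved < tol) { converged <- TRUE; break }
    }
    if (cur$lnL > best$lnL) best <- cur
  }
  if (cur$lnL > best$lnL) best <- cur
  if (!converged)
    warning("branch-length optimization did not converge for locus '",
            locusId(aln), "' (", maxSweeps, " sweeps); best-so-far returned")
  outTree <- ti$tree
  outTree$edge.length <- best$el
  res <- siteLogLikelihoods(aln, outTree, model, topologyId = topologyId)
  res@converged <- converged
  res
}

## ---- model selection -----------------------------------------------------

#' Default model candidate set
#'
#' @param names empirical matrix names (plus `"Poisson"`).
#' @param gamma also include +G4 variants?
#' @return List of candidate descriptors for [selectModel()].
#' @export
defaultCandidates <- function(names = c("Poisson", "LG", "WAG", "JTT"),
                              gamma = TRUE) {
  out <- list()
  for (nm in names) out[[length(out) + 1L]] <- list(name = nm, gamma = FALSE)
  if (gamma)
    for (nm in names) out[[length(out) + 1L]] <- list(name = nm, gamma = TRUE)
  out
}

makeCandidateModel <- function(cand, shape = NULL) {
  if (cand$name == "Poisson")
    poissonModel(gammaShape = shape)
  else empiricalModel(cand$name, gammaShape = shape)
}

#' Select a substitution model by BIC
#'
#' Evaluates each candidate on the fixed guide tree (branch lengths are not
#' refit per candidate; for +G candidates the gamma shape is optimized by a
#' bounded 1-D search). BIC = -2 lnL + k log(n_sites) with k counting only
#' the gamma shape (exchangeabilities and frequencies are fixed empirical).
#' Ties go to the candidate with fewer parameters, then to candidate order.
#'
#' @inheritParams siteLogLikelihoods
#' @param guideTree `phylo` with branch lengths on the locus' taxa.
#' @param candidates list as produced by [defaultCandidates()].
#' @return The winning [SubstitutionModel-class] (gamma shape fitted), with
#'   attributes `"BIC"` and `"lnL"`.
#' @export
selectModel <- function(aln, guideTree, candidates = defaultCandidates()) {
  if (!length(candidates)) stop("empty candidate list")
  n <- nSites(aln)
  fits <- lapply(candidates, function(cand) {
    if (isTRUE(cand$gamma)) {
      f <- function(a) {
        m <- makeCandidateModel(cand, shape = a)
        siteLogLikelihoods(aln, guideTree, m)@geneLnL
      }
      opt <- stats::optimize(f, interval = c(0.05, 50), maximum = TRUE,
                             tol = 0.01)
      list(model = makeCandidateModel(cand, shape = opt$maximum),
           lnL = opt$objective, k = 1L)
    } else {
      m <- makeCandidateModel(cand)
      list(model = m, lnL = siteLogLikelihoods(aln, guideTree, m)@geneLnL,
           k = 0L)
    }
  })
  bic <- vapply(fits, function(f) -2 * f$lnL + f$k * log(n), 0)
  kpar <- vapply(fits, function(f) f$k, 0L)
  ## tie-break: fewest parameters, then candidate order
  ord <- order(round(bic, 9), kpar, seq_along(fits))
  win <- fits[[ord[1L]]]
  out <- win$model
  attr(out, "BIC") <- bic[ord[1L]]
  attr(out, "lnL") <- win$lnL
  out
}

## ---- gene-wise log-likelihood scores ------------------------------------

#' Gene-wise log-likelihood scores under competing topologies
#'
#' For each locus, every candidate topology is pruned to the locus' taxa and
#' branch lengths are refit under a per-locus model; the gene-wise score is
#' the sum of site log-likelihoods. The model is selected once per locus
#' (by BIC on the first topology after an initial branch-length fit under
#' the first candidate matrix) and reused across topologies. Pairs of
#' candidate topologies that become identical after pruning are flagged
#' indistinguishable; their score difference is forced to zero downstream.
#'
#' @param loci list of [LocusAlignment-class].
#' @param topologies named list of `phylo` candidate topologies spanning the
#'   union taxon set (2 or more; the usual case is 3).
#' @param modelChoices matrix names passed to [defaultCandidates()].
#' @param gammaCandidates include +G4 candidates in model selection?
#' @param tol,maxSweeps passed to [optimizeBranchLengths()].
#' @param verbose print per-locus progress?
#' @return A [GLSTable-class] with `lnL_<id>` columns, taxon counts,
#'   selected model names and indistinguishability flags.
#' @export
computeGLS <- function(loci, topologies,
                       modelChoices = c("Poisson", "LG", "WAG", "JTT"),
                       gammaCandidates = TRUE, tol = 1e-3, maxSweeps = 50L,
                       verbose = FALSE) {
  if (length(topologies) < 2L) stop("need >= 2 candidate topologies")
  if (is.null(names(topologies)))
    names(topologies) <- paste0("T", seq_along(topologies))
  ids <- names(topologies)
  cand <- defaultCandidates(modelChoices, gamma = gammaCandidates)
  pairIdx <- utils::combn(seq_along(ids), 2L)
  pairCols <- paste0("identical_", ids[pairIdx[1L, ]], "_", ids[pairIdx[2L, ]])
  rows <- vector("list", length(loci))
  for (li in seq_along(loci)) {
    aln <- loci[[li]]
    taxa <- taxonLabels(aln)
    pruned <- lapply(topologies, function(tp) {
      keep <- intersect(tp$tip.label, taxa)
      if (length(keep) < 4L) return(NULL)
      ape::keep.tip(tp, keep)
    })
    if (any(vapply(pruned, is.null, TRUE))) {
      warning("locus '", locusId(aln), "' has < 4 usable taxa; skipped")
      next
    }
    same <- logical(ncol(pairIdx))
    for (pi_ in seq_len(ncol(pairIdx))) {
      t1 <- pruned[[pairIdx[1L, pi_]]]; t2 <- pruned[[pairIdx[2L, pi_]]]
      same[pi_] <- identical(sort(t1$tip.label), sort(t2$tip.label)) &&
        phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
    }
    base <- optimizeBranchLengths(aln, pruned[[1L]],
                                  makeCandidateModel(cand[[1L]]),
                                  topologyId = ids[1L],
                                  tol = tol, maxSweeps = maxSweeps)
    model <- selectModel(aln, base@tree, cand)
    lnL <- numeric(length(ids))
    conv <- TRUE
    for (k in seq_along(ids)) {
      ## identical-after-pruning topologies share their likelihood
      prev <- which(pairIdx[2L, ] == k & same)
      reuse <- if (length(prev)) pairIdx[1L, prev[1L]] else 0L
      if (reuse > 0L && lnL[reuse] != 0) {
        lnL[k] <- lnL[reuse]
        next
      }
      if (k == 1L && model@name == makeCandidateModel(cand[[1L]])@name) {
        ## selected model is the baseline: topology 1 already fitted
        lnL[k] <- base@geneLnL
        conv <- conv && base@converged
        next
      }
      fit <- optimizeBranchLengths(aln, pruned[[k]], model,
                                   topologyId = ids[k],
                                   tol = tol, maxSweeps = maxSweeps)
      lnL[k] <- fit@geneLnL
      conv <- conv && fit@converged
    }
    row <- data.frame(locus_id = locusId(aln), n_taxa = length(taxa),
                      model = model@name, converged = conv,
                      stringsAsFactors = FALSE)
    for (k in seq_along(ids)) row[[paste0("lnL_", ids[k])]] <- lnL[k]
    for (pi_ in seq_len(ncol(pairIdx))) row[[pairCols[pi_]]] <- same[pi_]
    rows[[li]] <- row
    if (verbose) message("GLS ", locusId(aln), " [", li, "/", length(loci),
                         "] model=", model@name)
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(tab) <- NULL
  new("GLSTable", table = tab, topologyIds = ids, focal = NA_character_,
      threshold = 2, pca = list())
}
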