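## Synthetic-data generator: candidate topologies differing only in the
## attachment of one clade, sequence simulation along trees, and full
## scenario generation (mixture of topologies, heterogeneous rates,
## per-locus missing taxa, gene-tree error) with an auditable truth table.

#' ScenarioConfig: parameters of a synthetic phylogenomic scenario
#'
#' Defaults emulate a phylogenomic study of ~39 taxa (35 ingroup plus 4
#' outgroup-like terminals) with ~10^3 short amino-acid loci: lognormal
#' locus lengths with mean about 240 columns clamped to \[100, 650\],
#' lognormal per-locus rate multipliers centred on 1, 30\% missing taxa per
#' locus (a 70\% occupancy matrix), a three-topology mixture differing only
#' in one clade's attachment, and gene-tree error as single NNI moves.
#'
#' @slot nTaxa total taxa.
#' @slot nLoci number of loci.
#' @slot mixtureWeights length-3 non-negative weights summing to 1 over the
#'   candidate topologies (focal first).
#' @slot lengthMeanLog,lengthSdLog lognormal parameters of locus length.
#' @slot lengthRange clamp range for locus lengths (columns, >= 50).
#' @slot rateMeanLog,rateSdLog lognormal parameters of the per-locus rate
#'   multiplier.
#' @slot missingTaxonFraction per-locus probability a taxon is unsampled.
#' @slot modelName generating substitution matrix (`"LG"`, `"WAG"`,
#'   `"JTT"`, `"Poisson"`).
#' @slot gammaShape optional within-locus discrete-gamma shape (numeric(0)
#'   = homogeneous sites).
#' @slot nniProb scales gene-tree error: each gene tree receives a Poisson
#'   number of NNI moves with mean `2 * nniProb * rate_multiplier`, so
#'   faster-evolving loci get noisier trees (as in real data).
#' @slot biasTaxa taxa receiving compositional bias (may be empty).
#' @slot biasStrength per-site probability of residue replacement for
#'   biased taxa.
#' @slot rngSeed master seed.
#' @export
setClass("ScenarioConfig",
  representation(nTaxa = "integer", nLoci = "integer",
                 mixtureWeights = "numeric",
                 lengthMeanLog = "numeric", lengthSdLog = "numeric",
                 lengthRange = "numeric",
                 rateMeanLog = "numeric", rateSdLog = "numeric",
                 missingTaxonFraction = "numeric", modelName = "character",
                 gammaShape = "numeric", nniProb = "numeric",
                 biasTaxa = "character", biasStrength = "numeric",
                 rngSeed = "integer"))

setValidity("ScenarioConfig", function(object) {
  msg <- character()
  if (object@nTaxa < 12L) msg <- c(msg, "nTaxa must be >= 12")
  if (object@nLoci < 1L) msg <- c(msg, "nLoci must be >= 1")
  w <- object@mixtureWeights
  if (length(w) != 3L || any(w < 0) || abs(sum(w) - 1) > 1e-9)
    msg <- c(msg, "mixtureWeights must be 3 non-negative values summing to 1")
  if (object@lengthRange[1L] < 50) msg <- c(msg, "locus lengths must be >= 50")
  if (object@missingTaxonFraction < 0 || object@missingTaxonFraction >= 1)
    msg <- c(msg, "missingTaxonFraction must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname ScenarioConfig-class
#' @param nTaxa,nLoci,mixtureWeights,lengthMeanLog,lengthSdLog,lengthRange
#'   see slots.
#' @param rateMeanLog,rateSdLog,missingTaxonFraction,modelName,gammaShape
#'   see slots.
#' @param nniProb,biasTaxa,biasStrength,rngSeed see slots.
#' @return A `ScenarioConfig`.
#' @export
scenarioConfig <- function(nTaxa = 39L, nLoci = 100L,
                           mixtureWeights = c(1, 1, 1) / 3,
                           lengthMeanLog = log(225), lengthSdLog = 0.35,
                           lengthRange = c(100, 650),
                           rateMeanLog = -0.08, rateSdLog = 0.4,
                           missingTaxonFraction = 0.3, modelName = "LG",
                           gammaShape = NULL, nniProb = 0.25,
                           biasTaxa = character(0), biasStrength = 0.1,
                           rngSeed = 1L) {
  new("ScenarioConfig", nTaxa = as.integer(nTaxa), nLoci = as.integer(nLoci),
      mixtureWeights = mixtureWeights, lengthMeanLog = lengthMeanLog,
      lengthSdLog = lengthSdLog, lengthRange = lengthRange,
      rateMeanLog = rateMeanLog, rateSdLog = rateSdLog,
      missingTaxonFraction = missingTaxonFraction, modelName = modelName,
      gammaShape = if (is.null(gammaShape)) numeric(0) else gammaShape,
      nniProb = nniProb, biasTaxa = biasTaxa, biasStrength = biasStrength,
      rngSeed = as.integer(rngSeed))
}

setMethod("show", "ScenarioConfig", function(object) {
  cat("ScenarioConfig: ", object@nLoci, " loci, ", object@nTaxa,
      " taxa, weights (", paste(signif(object@mixtureWeights, 3),
                                collapse = ", "),
      "), model ", object@modelName, "\n", sep = "")
})

## clade sizes proportional to the 39-taxon default shape
.cladeSizes <- function(nTaxa) {
  base <- c(outgroup = 4, cladeA = 5, cladeB = 6, cladeC = 6,
            dendro = 7, synall = 5, persic = 3, molpad = 3)
  sizes <- stats::setNames(pmax(2L, floor(base / sum(base) * nTaxa)),
                           names(base))
  sizes["outgroup"] <- max(1L, sizes[["outgroup"]])
  diff <- nTaxa - sum(sizes)
  ord <- order(-base)
  i <- 1L
  while (diff != 0L) {
    nm <- names(base)[ord[(i - 1L) %% length(base) + 1L]]
    step <- sign(diff)
    if (sizes[[nm]] + step >= 2L) {
      sizes[nm] <- sizes[[nm]] + step
      diff <- diff - step
    }
    i <- i + 1L
  }
  sizes
}

## random clade subtree as a newick fragment (no trailing ";")
.cladeNewick <- function(prefix, n, depthScale = 0.3) {
  tips <- paste0(prefix, seq_len(n))
  tr <- ape::rtree(n, tip.label = tips)
  tr$edge.length <- tr$edge.length * depthScale
  sub(";$", "", ape::write.tree(tr))
}

#' Three candidate topologies differing in one clade's attachment
#'
#' Builds a random base tree containing five labelled "order-level" clades
#' plus a movable clade and outgroups, then produces three candidates that
#' differ only in where the movable clade attaches: sister to `synall`
#' (the focal, coalescent-style resolution), sister to `persic`
#' (partitioned-style), or sister to `dendro + synall` (site-heterogeneous
#' style). All three share the identical taxon set and all non-movable
#' subtrees; pruning away the movable clade makes them identical.
#'
#' @param nTaxa total number of taxa (>= 12).
#' @param seed integer seed.
#' @param internalLength internal branch length of the contested edges.
#' @return List with `topologies` (named `phylo` list: `focal`,
#'   `partitioned`, `catpmsf`), `clades` (five order-level clade
#'   definitions), and `movedClade` (taxon labels of the movable clade).
#' @export
makeCandidateTopologies <- function(nTaxa = 39L, seed = 1L,
                                    internalLength = 0.08) {
  sizes <- .cladeSizes(nTaxa)
  withSeed(seed, {
    frag <- list(
      out = .cladeNewick("out", sizes[["outgroup"]]),
      A = .cladeNewick("apo", sizes[["cladeA"]]),
      B = .cladeNewick("ela", sizes[["cladeB"]]),
      C = .cladeNewick("hol", sizes[["cladeC"]]),
      den = .cladeNewick("den", sizes[["dendro"]]),
      syn = .cladeNewick("syn", sizes[["synall"]]),
      per = .cladeNewick("per", sizes[["persic"]]),
      mol = .cladeNewick("mol", sizes[["molpad"]]))
    il <- internalLength
    neo <- list(
      focal = sprintf("(%s:%.3f,(%s:%.3f,(%s:%.3f,%s:%.3f):%.3f):%.3f)",
                      frag$per, il, frag$den, il, frag$syn, il, frag$mol, il,
                      il, il),
      partitioned = sprintf("((%s:%.3f,%s:%.3f):%.3f,(%s:%.3f,%s:%.3f):%.3f)",
                            frag$per, il, frag$mol, il, il, frag$den, il,
                            frag$syn, il, il),
      catpmsf = sprintf("(%s:%.3f,(%s:%.3f,(%s:%.3f,%s:%.3f):%.3f):%.3f)",
                        frag$per, il, frag$mol, il, frag$den, il, frag$syn,
                        il, il, il))
    topo <- lapply(neo, function(nk) {
      txt <- sprintf("(%s:%.3f,(%s:%.3f,(%s:%.3f,(%s:%.3f,%s:%.3f):%.3f):%.3f):%.3f);",
                     frag$out, il, frag$A, il, frag$B, il, frag$C, il, nk,
                     il, il, il, il)
      ape::read.tree(text = txt)
    })
    sizesN <- sizes
    clades <- list(
      cladeA = paste0("apo", seq_len(sizesN[["cladeA"]])),
      cladeB = paste0("ela", seq_len(sizesN[["cladeB"]])),
      cladeC = paste0("hol", seq_len(sizesN[["cladeC"]])),
      synall = paste0("syn", seq_len(sizesN[["synall"]])),
      dendro = paste0("den", seq_len(sizesN[["dendro"]])))
    list(topologies = topo, clades = clades,
         movedClade = paste0("mol", seq_len(sizesN[["molpad"]])))
  })
}

#' Simulate an amino-acid alignment along a tree
#'
#' Root states are drawn from the model's stationary frequencies and
#' evolved along each branch with the model's transition probabilities;
#' when the model carries a discrete gamma, each site is assigned one of
#' the equiprobable category rates.
#'
#' @param tree `phylo` with branch lengths.
#' @param model a [SubstitutionModel-class].
#' @param nSites number of columns.
#' @param seed integer seed.
#' @param locusId identifier for the returned alignment.
#' @return List with `aln` (a [LocusAlignment-class]), `tree`, and
#'   `siteRates`.
#' @export
simulateLocus <- function(tree, model, nSites, seed = 1L,
                          locusId = "locus") {
  eig <- modelEigen(model)
  rates <- modelRates(model)
  withSeed(seed, {
    siteCat <- if (length(rates) > 1L)
      sample.int(length(rates), nSites, replace = TRUE) else
      rep(1L, nSites)
    ti <- treeInfo(tree)
    states <- matrix(NA_integer_, ti$nodes, nSites)
    states[ti$root, ] <- sample.int(20L, nSites, replace = TRUE,
                                    prob = eig$pi)
    for (e in rev(seq_len(nrow(ti$edge)))) {     # pre-order
      p <- ti$edge[e, 1L]; ch <- ti$edge[e, 2L]
      t_ <- ti$tree$edge.length[e]
      for (ci in unique(siteCat)) {
        P <- transitionProbs(eig, t_, rates[ci])
        cols <- which(siteCat == ci)
        ps <- states[p, cols]
        for (s in unique(ps)) {
          sel <- cols[ps == s]
          states[ch, sel] <- sample.int(20L, length(sel), replace = TRUE,
                                        prob = P[s, ])
        }
      }
    }
    m <- matrix(aminoAcids()[states[seq_len(ti$ntip), , drop = FALSE]],
                nrow = ti$ntip,
                dimnames = list(ti$tree$tip.label, NULL))
    list(aln = new("LocusAlignment", locusId = as.character(locusId),
                   seqs = m),
         tree = ti$tree, siteRates = rates[siteCat])
  })
}

## Beta-distributed pseudo-bootstrap supports: edges whose bipartition
## survives in the true tree get [50, 100], perturbed edges [20, 90].
.pseudoSupports <- function(geneTree, trueTree) {
  nInt <- geneTree$Nnode
  agree <- tryCatch({
    pc <- ape::prop.clades(geneTree, trueTree)
    !is.na(pc) & pc > 0
  }, error = function(e) rep(TRUE, nInt))
  if (length(agree) < nInt) agree <- c(agree, rep(TRUE, nInt - length(agree)))
  lo <- ifelse(agree, 50, 20)
  hi <- ifelse(agree, 100, 90)
  round(lo + (hi - lo) * stats::rbeta(nInt, 3, 1.2))
}

#' Generate a full synthetic scenario
#'
#' Per locus: a generating topology drawn from the mixture, branch lengths
#' scaled by a lognormal rate multiplier, taxa dropped at the missing
#' fraction (at least four kept), an alignment simulated under the
#' configured model, optional compositional bias injected into selected
#' taxa, and a gene tree equal to the true tree optionally perturbed by one
#' NNI move with Beta pseudo-bootstrap supports. Every draw is recorded in
#' the truth table; downstream analyses must not consume truth fields.
#'
#' @param config a [ScenarioConfig-class].
#' @return List with `loci`, `geneTrees` (both named by locus), `topologies`,
#'   `clades`, `movedClade`, and `truth` (data.frame).
#' @export
generateScenario <- function(config) {
  methods::validObject(config)
  seed <- config@rngSeed
  cand <- makeCandidateTopologies(config@nTaxa,
                                  seed = substreamSeed(seed, "topologies"))
  topo <- cand$topologies
  ids <- names(topo)
  model <- if (config@modelName == "Poisson")
    poissonModel(gammaShape = if (length(config@gammaShape))
      config@gammaShape else NULL)
  else empiricalModel(config@modelName,
                      gammaShape = if (length(config@gammaShape))
                        config@gammaShape else NULL)
  allTaxa <- topo[[1L]]$tip.label
  draws <- withSeed(substreamSeed(seed, "draws"), {
    rate <- stats::rlnorm(config@nLoci, config@rateMeanLog, config@rateSdLog)
    list(topo = sample(ids, config@nLoci, replace = TRUE,
                       prob = config@mixtureWeights),
         rate = rate,
         len = as.integer(pmin(pmax(
           stats::rlnorm(config@nLoci, config@lengthMeanLog,
                         config@lengthSdLog),
           config@lengthRange[1L]), config@lengthRange[2L])),
         keepTaxa = lapply(seq_len(config@nLoci), function(i) {
           keep <- allTaxa[stats::runif(length(allTaxa)) >=
                             config@missingTaxonFraction]
           if (length(keep) < 4L)
             keep <- sample(allTaxa, 4L)
           keep
         }),
         ## gene-tree error grows with the locus' evolutionary rate
         nniMoves = stats::rpois(config@nLoci, 2 * config@nniProb * rate))
  })
  loci <- vector("list", config@nLoci)
  geneTrees <- vector("list", config@nLoci)
  lids <- sprintf("locus%04d", seq_len(config@nLoci))
  for (i in seq_len(config@nLoci)) {
    trueTree <- ape::keep.tip(topo[[draws$topo[i]]], draws$keepTaxa[[i]])
    trueTree$edge.length <- trueTree$edge.length * draws$rate[i]
    sim <- simulateLocus(trueTree, model, draws$len[i],
                         seed = substreamSeed(seed, paste0("locus", i)),
                         locusId = lids[i])
    aln <- sim$aln
    if (length(config@biasTaxa)) {
      aln <- withSeed(substreamSeed(seed, paste0("bias", i)),
                      .injectBias(aln, config@biasTaxa,
                                  config@biasStrength))
    }
    gt <- trueTree
    withSeed(substreamSeed(seed, paste0("genetree", i)), {
      if (draws$nniMoves[i] > 0L)
        gt <- phangorn::rNNI(ape::unroot(gt), draws$nniMoves[i])
      gt$node.label <- as.character(.pseudoSupports(gt, trueTree))
    })
    loci[[i]] <- aln
    geneTrees[[i]] <- gt
  }
  names(loci) <- lids
  names(geneTrees) <- lids
  truth <- data.frame(locus_id = lids, true_topology = draws$topo,
                      rate_multiplier = draws$rate, n_sites = draws$len,
                      n_taxa = lengths(draws$keepTaxa),
                      has_moved_clade = vapply(draws$keepTaxa, function(k)
                        sum(k %in% cand$movedClade) > 0L, TRUE),
                      nni_moves = draws$nniMoves,
                      stringsAsFactors = FALSE)
  list(loci = loci, geneTrees = geneTrees, topologies = topo,
       clades = cand$clades, movedClade = cand$movedClade, truth = truth)
}

## compositional bias: replace residues of biased taxa with draws from a
## frequency vector tilted toward the first five residues
.injectBias <- function(aln, biasTaxa, strength) {
  m <- aln@seqs
  tilt <- c(rep(3, 5), rep(1, 15))
  tilt <- tilt / sum(tilt)
  for (tx in intersect(biasTaxa, rownames(m))) {
    hit <- stats::runif(ncol(m)) < strength & !isMissingResidue(m[tx, ])
    if (any(hit))
      m[tx, hit] <- sample(aminoAcids(), sum(hit), replace = TRUE,
                           prob = tilt)
  }
  new("LocusAlignment", locusId = aln@locusId, seqs = m)
}

#' Write a scenario to disk in exchange formats
#'
#' Per-locus FASTA alignments, Newick gene trees, the candidate topologies,
#' a clade-definition file and the truth table, laid out for re-import with
#' the package's readers.
#'
#' @param scenario list from [generateScenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeScenario <- function(scenario, dir) {
  dir.create(file.path(dir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "gene_trees"), showWarnings = FALSE)
  for (nm in names(scenario$loci)) {
    a <- scenario$loci[[nm]]
    seqs <- apply(a@seqs, 1L, paste, collapse = "")
    writeLines(paste0(">", names(seqs), "\n", seqs),
               file.path(dir, "alignments", paste0(nm, ".fasta")))
    writeTree(scenario$geneTrees[[nm]],
              file.path(dir, "gene_trees", paste0(nm, ".nwk")))
  }
  for (nm in names(scenario$topologies))
    writeTree(scenario$topologies[[nm]],
              file.path(dir, paste0("topology_", nm, ".nwk")))
  cl <- scenario$clades
  df <- data.frame(clade = rep(names(cl), lengths(cl)),
                   taxon = unlist(cl, use.names = FALSE))
  utils::write.table(df, file.path(dir, "clades.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(scenario$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
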