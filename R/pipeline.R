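#' Pipeline configuration
#'
#' Bundles the inputs and tuning constants of a full signal-dissection run:
#' where the per-locus alignments, gene trees, candidate topologies and
#' clade definitions live, which candidate is the focal (reference)
#' resolution, the deltaGLS threshold, replicate counts and the master
#' seed. Defaults follow the package's standing conventions (threshold 2
#' log-likelihood units, 1000 subsampling replicates, 10000 permutations).
#'
#' @param alignmentDir directory of per-locus FASTA files.
#' @param geneTreeDir directory of Newick gene trees (same basenames).
#' @param topologyFiles named character vector of candidate topology files.
#' @param cladeFile clade-definition TSV (may be `NA`).
#' @param focal id (name in `topologyFiles`) of the focal topology.
#' @param threshold positive deltaGLS cutoff.
#' @param nNullReps subsampling replicates for disparity nulls.
#' @param nPermutations permutations for vector fitting.
#' @param modelChoices candidate matrices for per-locus model selection.
#' @param gammaCandidates include +G4 candidates?
#' @param rngSeed master seed fanned out to named substreams per stage.
#' @return A validated list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(alignmentDir, geneTreeDir, topologyFiles,
                           cladeFile = NA_character_,
                           focal = names(topologyFiles)[1L], threshold = 2,
                           nNullReps = 1000L, nPermutations = 10000L,
                           modelChoices = c("Poisson", "LG", "WAG", "JTT"),
                           gammaCandidates = TRUE, rngSeed = 1L) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (nNullReps < 1L || nPermutations < 1L)
    stop("replicate/permutation counts must be >= 1")
  if (is.null(names(topologyFiles)) || !focal %in% names(topologyFiles))
    stop("focal must name one of the supplied topologies")
  structure(list(alignmentDir = alignmentDir, geneTreeDir = geneTreeDir,
                 topologyFiles = topologyFiles, cladeFile = cladeFile,
                 focal = focal, threshold = threshold,
                 nNullReps = as.integer(nNullReps),
                 nPermutations = as.integer(nPermutations),
                 modelChoices = modelChoices,
                 gammaCandidates = gammaCandidates,
                 rngSeed = as.integer(rngSeed)),
            class = "pipelineConfig")
}

#' Run the full signal-dissection pipeline from files
#'
#' Reads alignments, gene trees, candidate topologies and clade definitions,
#' then runs: gene-wise log-likelihood scores under every candidate,
#' deltaGLS + PCA + categorization against the focal topology; the quartet
#' treespace with disparity; the gene-property panel with usefulness
#' ranking; and the determinant scan (vector fitting + classification
#' tree).
#'
#' @param config a [pipelineConfig()].
#' @param verbose print progress?
#' @return List with `gls` ([GLSTable-class]), `summary`, `treespace`
#'   ([TreespaceResult-class]), `properties`, `usefulness`, `vectorFits`,
#'   `tree` (`signalTree`), `cladeRecovery`.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipelineConfig"))
  alnFiles <- sort(list.files(config$alignmentDir, "\\.(fa|fasta)$",
                              full.names = TRUE))
  loci <- lapply(alnFiles, readAlignment, format = "fasta")
  names(loci) <- vapply(loci, locusId, "")
  treeFiles <- file.path(config$geneTreeDir,
                         paste0(names(loci), c(".nwk")))
  geneTrees <- lapply(treeFiles, function(f)
    if (file.exists(f)) readTree(f) else NULL)
  names(geneTrees) <- names(loci)
  topologies <- lapply(config$topologyFiles, readTree)
  clades <- if (!is.na(config$cladeFile))
    readCladeDefinitions(config$cladeFile) else NULL
  analyzeScenario(loci, geneTrees, topologies, clades,
                  focal = config$focal, threshold = config$threshold,
                  nNullReps = config$nNullReps,
                  nPermutations = config$nPermutations,
                  modelChoices = config$modelChoices,
                  gammaCandidates = config$gammaCandidates,
                  seed = config$rngSeed, verbose = verbose)
}

#' Run the signal-dissection stages on in-memory objects
#'
#' The in-memory counterpart of [runPipeline()], convenient for synthetic
#' scenarios from [generateScenario()].
#'
#' @param loci named list of [LocusAlignment-class].
#' @param geneTrees named list of `phylo` (entries may be `NULL`).
#' @param topologies named list of candidate `phylo`.
#' @param clades optional clade definitions for recovery scoring.
#' @param focal,threshold categorization parameters.
#' @param nNullReps,nPermutations replicate counts.
#' @param modelChoices,gammaCandidates model-selection controls.
#' @param seed master seed.
#' @param verbose print progress?
#' @return See [runPipeline()].
#' @export
analyzeScenario <- function(loci, geneTrees, topologies, clades = NULL,
                            focal = names(topologies)[1L], threshold = 2,
                            nNullReps = 1000L, nPermutations = 10000L,
                            modelChoices = c("Poisson", "LG", "WAG", "JTT"),
                            gammaCandidates = TRUE, seed = 1L,
                            verbose = FALSE) {
  gls <- computeGLS(loci, topologies, modelChoices = modelChoices,
                    gammaCandidates = gammaCandidates, verbose = verbose)
  gls <- deltaGLS(gls)
  gls <- pcaRotate(gls, focal = focal)
  gls <- categorizeLoci(gls, focal = focal, threshold = threshold)
  summary_ <- categorySummary(gls)
  haveTrees <- !vapply(geneTrees, is.null, TRUE)
  ts <- if (sum(haveTrees) >= 5L)
    buildTreespace(geneTrees[haveTrees],
                   seed = substreamSeed(seed, "treespace"),
                   nReps = nNullReps) else NULL
  ref <- topologies[[focal]]
  panel <- genePropertyPanel(loci, geneTrees, ref)
  use <- tryCatch(usefulnessSort(panel), error = function(e) NULL)
  vf <- vectorFitPanel(gls, panel, nPerm = nPermutations,
                       seed = substreamSeed(seed, "envfit"))
  fac <- categorizeFactor(gls)
  idx <- match(glsTable(gls)$locus_id, panel$locus_id)
  tree <- fitSignalTree(panel[idx, , drop = FALSE], fac,
                        seed = substreamSeed(seed, "ctree"))
  cr <- if (!is.null(clades))
    cladeRecoveryTable(geneTrees[haveTrees], clades) else NULL
  list(gls = gls, summary = summary_, treespace = ts, properties = panel,
       usefulness = use, vectorFits = vf, tree = tree, cladeRecovery = cr)
}
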