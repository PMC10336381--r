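#' @import methods
NULL

#' Amino-acid alphabet used throughout the package
#'
#' The twenty standard residues in the conventional order of empirical
#' exchangeability matrices (A, R, N, D, C, Q, E, G, H, I, L, K, M, F, P, S,
#' T, W, Y, V). All rate matrices, frequency vectors and partial-likelihood
#' arrays are indexed in this order.
#'
#' @return Character vector of length 20.
#' @export
aminoAcids <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

## Residues treated as fully missing (marginalized in the likelihood).
## Ambiguity codes B/Z/J, stop '*', unknowns X/?/. and the gap '-' are all
## coded as missing: none is modelled as a 21st state.
.MISSING_CODES <- c("X", "?", "-", ".", "B", "Z", "J", "*")

#' LocusAlignment: one locus' amino-acid alignment
#'
#' Stores an alignment as a character matrix (rows = taxa, columns = sites)
#' over the 20 one-letter residue codes plus `"X"` for missing and `"-"` for
#' gaps. Built by [readAlignment()] or [locusAlignment()].
#'
#' @slot locusId single character identifier.
#' @slot seqs character matrix of single residues, rownames = taxon labels.
#'
#' @seealso [readAlignment()], [nSites()], [nTaxa()], [taxonLabels()]
#' @export
setClass("LocusAlignment",
  representation(locusId = "character", seqs = "matrix"))

setValidity("LocusAlignment", function(object) {
  msg <- character()
  if (length(object@locusId) != 1L) msg <- c(msg, "locusId must be length 1")
  if (!is.character(object@seqs)) msg <- c(msg, "seqs must be a character matrix")
  if (ncol(object@seqs) < 1L) msg <- c(msg, "alignment must have >= 1 column")
  labs <- rownames(object@seqs)
  if (is.null(labs) || anyDuplicated(labs))
    msg <- c(msg, "taxon labels must be present and unique")
  ok <- object@seqs %in% c(aminoAcids(), "X", "-")
  if (!all(ok)) msg <- c(msg, "residues must be canonical one-letter codes, 'X' or '-'")
  if (length(msg)) msg else TRUE
})

#' Construct a LocusAlignment from sequences
#'
#' Residues are upper-cased; gap characters are kept as `"-"`; ambiguity and
#' unknown codes (`B`, `Z`, `J`, `*`, `?`, `.`, and anything unrecognized)
#' are mapped to missing `"X"`, with a warning for characters outside the
#' documented set.
#'
#' @param seqs named character vector of equal-length sequence strings, or a
#'   character matrix of single residues with rownames.
#' @param locusId identifier for the locus.
#' @return A [LocusAlignment-class] object.
#' @export
locusAlignment <- function(seqs, locusId = "locus") {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs))) stop("sequences must be named by taxon")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      bad <- names(seqs)[which(lens != lens[1L])[1L]]
      stop("ragged alignment: sequence length differs for taxon '", bad, "'")
    }
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- names(seqs)
  }
  if (anyDuplicated(rownames(m)))
    stop("duplicate taxon label: '",
         rownames(m)[duplicated(rownames(m))][1L], "'")
  m[] <- toupper(m)
  known <- c(aminoAcids(), .MISSING_CODES)
  unknown <- setdiff(unique(as.vector(m)), known)
  if (length(unknown)) {
    warning("unknown residue code(s) ", paste(sQuote(unknown), collapse = ", "),
            " mapped to missing")
    m[m %in% unknown] <- "X"
  }
  amb <- setdiff(.MISSING_CODES, c("X", "-"))
  if (any(m %in% amb)) {
    warning("ambiguous/unknown residues (", paste(amb, collapse = ""),
            ") coded as missing")
    m[m %in% amb] <- "X"
  }
  new("LocusAlignment", locusId = as.character(locusId), seqs = m)
}

#' @describeIn LocusAlignment-class number of alignment columns
#' @param x a `LocusAlignment`
#' @export
nSites <- function(x) ncol(x@seqs)

#' @describeIn LocusAlignment-class number of taxa
#' @export
nTaxa <- function(x) nrow(x@seqs)

#' @describeIn LocusAlignment-class taxon labels
#' @export
taxonLabels <- function(x) rownames(x@seqs)

#' @describeIn LocusAlignment-class locus identifier
#' @export
locusId <- function(x) x@locusId

#' Restrict an alignment to a subset of taxa
#'
#' @param x a [LocusAlignment-class]
#' @param taxa taxon labels to keep (order preserved as given).
#' @return A `LocusAlignment` over the requested taxa.
#' @export
restrictTaxa <- function(x, taxa) {
  miss <- setdiff(taxa, taxonLabels(x))
  if (length(miss))
    stop("taxa not in alignment: ", paste(miss, collapse = ", "))
  new("LocusAlignment", locusId = x@locusId, seqs = x@seqs[taxa, , drop = FALSE])
}

setMethod("show", "LocusAlignment", function(object) {
  cat("LocusAlignment '", object@locusId, "': ", nTaxa(object), " taxa x ",
      nSites(object), " sites\n", sep = "")
})

#' SubstitutionModel: time-reversible amino-acid substitution model
#'
#' An empirical (or flat) exchangeability matrix with stationary frequencies
#' and optional discrete-gamma rate heterogeneity. Build with
#' [substitutionModel()], [empiricalModel()] or [poissonModel()].
#'
#' @slot name model name, e.g. `"LG+G4"`.
#' @slot exchangeabilities symmetric 20x20 matrix, zero diagonal.
#' @slot frequencies stationary frequencies, length 20, positive, sum 1.
#' @slot gammaShape numeric(1) shape of the discrete gamma, or numeric(0) for
#'   rate homogeneity.
#' @slot nRateCategories integer count of discrete gamma categories.
#' @export
setClass("SubstitutionModel",
  representation(name = "character", exchangeabilities = "matrix",
                 frequencies = "numeric", gammaShape = "numeric",
                 nRateCategories = "integer"))

setValidity("SubstitutionModel", function(object) {
  msg <- character()
  S <- object@exchangeabilities
  if (!all(dim(S) == c(20L, 20L))) msg <- c(msg, "exchangeabilities must be 20x20")
  else {
    if (max(abs(S - t(S))) > 1e-10) msg <- c(msg, "exchangeabilities must be symmetric")
    if (any(S < 0)) msg <- c(msg, "exchangeabilities must be non-negative")
  }
  p <- object@frequencies
  if (length(p) != 20L) msg <- c(msg, "frequencies must have length 20")
  else {
    if (any(p <= 0)) msg <- c(msg, "frequencies must be strictly positive")
    if (abs(sum(p) - 1) > 1e-8) msg <- c(msg, "frequencies must sum to 1")
  }
  if (length(object@gammaShape) > 1L) msg <- c(msg, "gammaShape must be length 0 or 1")
  if (length(object@gammaShape) == 1L && object@gammaShape <= 0)
    msg <- c(msg, "gammaShape must be positive")
  if (object@nRateCategories < 1L) msg <- c(msg, "nRateCategories must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SubstitutionModel", function(object) {
  cat("SubstitutionModel ", object@name, sep = "")
  if (length(object@gammaShape))
    cat(" (gamma shape ", signif(object@gammaShape, 4), ", ",
        object@nRateCategories, " categories)", sep = "")
  cat("\n")
})

#' SiteLikelihoodResult: per-site log-likelihoods for one locus x topology
#'
#' @slot locusId,topologyId identifiers.
#' @slot siteLnL numeric vector of per-column log-likelihoods (all <= 0).
#' @slot geneLnL their sum (the gene-wise log-likelihood score, GLS).
#' @slot tree the `phylo` used (branch lengths as evaluated/optimized).
#' @slot converged logical; `FALSE` when branch-length optimization hit the
#'   sweep limit.
#' @export
setClass("SiteLikelihoodResult",
  representation(locusId = "character", topologyId = "character",
                 siteLnL = "numeric", geneLnL = "numeric",
                 tree = "ANY", converged = "logical"))

setValidity("SiteLikelihoodResult", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(sum(object@siteLnL), object@geneLnL,
                        tolerance = 1e-9)))
    msg <- c(msg, "geneLnL must equal sum(siteLnL)")
  if (any(object@siteLnL > 1e-9)) msg <- c(msg, "site log-likelihoods must be <= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SiteLikelihoodResult", function(object) {
  cat("SiteLikelihoodResult ", object@locusId, " / ", object@topologyId,
      ": lnL = ", format(object@geneLnL), " over ", length(object@siteLnL),
      " sites\n", sep = "")
})

#' GLSTable: gene-wise log-likelihood scores and their dissection
#'
#' One row per locus. Created by [computeGLS()]; [deltaGLS()],
#' [pcaRotate()] and [categorizeLoci()] add columns. Access the underlying
#' data frame with [glsTable()].
#'
#' @slot table data.frame with columns `locus_id`, `lnL_<id>` per topology,
#'   then (as stages run) `delta_<x>_<y>`, `PC1`, `PC2`, `category`, flags.
#' @slot topologyIds candidate topology identifiers (order fixes the delta
#'   pairs).
#' @slot focal identifier of the focal (reference) topology, or `NA`.
#' @slot threshold deltaGLS informativeness cutoff (log-likelihood units).
#' @slot pca list with `loadings`, `explainedVarPct` as filled by
#'   [pcaRotate()], else empty.
#' @export
setClass("GLSTable",
  representation(table = "data.frame", topologyIds = "character",
                 focal = "character", threshold = "numeric", pca = "list"))

setValidity("GLSTable", function(object) {
  msg <- character()
  if (!"locus_id" %in% names(object@table)) msg <- c(msg, "table needs locus_id")
  want <- paste0("lnL_", object@topologyIds)
  if (!all(want %in% names(object@table)))
    msg <- c(msg, "table needs one lnL_<topology> column per topology")
  if (anyDuplicated(object@table$locus_id)) msg <- c(msg, "locus ids must be unique")
  if (length(object@threshold) && object@threshold <= 0)
    msg <- c(msg, "threshold must be > 0")
  dn <- deltaPairNames(object@topologyIds)
  if (length(object@topologyIds) == 3L && all(dn %in% names(object@table))) {
    d <- object@table[, dn]
    if (nrow(d) && max(abs(d[[1L]] - (d[[2L]] - d[[3L]])), na.rm = TRUE) > 1e-6)
      msg <- c(msg, "delta linear dependency violated (d12 != d13 - d23)")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GLSTable-class the per-locus data frame
#' @param x a `GLSTable`
#' @export
glsTable <- function(x) x@table

#' @describeIn GLSTable-class candidate topology identifiers
#' @export
topologyIds <- function(x) x@topologyIds

setMethod("show", "GLSTable", function(object) {
  cat("GLSTable: ", nrow(object@table), " loci x ",
      length(object@topologyIds), " topologies (",
      paste(object@topologyIds, collapse = ", "), ")\n", sep = "")
  if (!is.na(object@focal))
    cat("  focal topology: ", object@focal, " (threshold ",
        object@threshold, ")\n", sep = "")
  if ("category" %in% names(object@table)) {
    tab <- table(object@table$category)
    cat("  categories:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  if (length(object@pca))
    cat("  PCA: ", paste(sprintf("%s %.1f%%", c("PC1", "PC2"),
        object@pca$explainedVarPct), collapse = ", "), "\n", sep = "")
})

## internal: delta column names for ordered pairs (1,2), (1,3), (2,3)
deltaPairNames <- function(ids) {
  if (length(ids) < 2L) return(character())
  pr <- utils::combn(seq_along(ids), 2L)
  paste0("delta_", ids[pr[1L, ]], "_", ids[pr[2L, ]])
}

#' TreespaceResult: quartet treespace, ordination and disparity
#'
#' @slot dissimilarity symmetric matrix of pairwise quartet dissimilarities
#'   in \[0, 1\] (diagonal 0), possibly median-imputed (see `imputed`).
#' @slot coordinates PCoA coordinates (rows = trees, columns = axes with
#'   positive eigenvalues).
#' @slot eigenvalues eigenvalues of the retained axes.
#' @slot disparityFull mean distance to centroid over all trees.
#' @slot subsetDisparities named disparities of evaluated subsets.
#' @slot nullDistributions named list of subsampling null vectors.
#' @slot percentileP named proportion of null values <= observed.
#' @slot imputed logical matrix marking imputed entries (or 0x0 when none).
#' @export
setClass("TreespaceResult",
  representation(dissimilarity = "matrix", coordinates = "matrix",
                 eigenvalues = "numeric", disparityFull = "numeric",
                 subsetDisparities = "numeric", nullDistributions = "list",
                 percentileP = "numeric", imputed = "matrix"))

setValidity("TreespaceResult", function(object) {
  D <- object@dissimilarity
  msg <- character()
  if (nrow(D) != ncol(D)) msg <- c(msg, "dissimilarity must be square")
  else {
    if (max(abs(D - t(D))) > 1e-12) msg <- c(msg, "dissimilarity must be symmetric")
    if (any(diag(D) != 0)) msg <- c(msg, "dissimilarity diagonal must be 0")
    if (any(D < -1e-12) || any(D > 1 + 1e-12))
      msg <- c(msg, "dissimilarities must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TreespaceResult", function(object) {
  cat("TreespaceResult: ", nrow(object@dissimilarity), " trees, ",
      ncol(object@coordinates), " PCoA axes, full disparity ",
      signif(object@disparityFull, 4), "\n", sep = "")
  if (length(object@subsetDisparities)) {
    for (nm in names(object@subsetDisparities)) {
      cat("  subset '", nm, "': disparity ",
          signif(object@subsetDisparities[[nm]], 4), sep = "")
      if (nm %in% names(object@percentileP))
        cat(", null percentile ", signif(object@percentileP[[nm]], 3), sep = "")
      cat("\n")
    }
  }
})
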