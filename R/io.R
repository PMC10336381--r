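#' Read a per-locus amino-acid alignment
#'
#' Reads FASTA or relaxed (whitespace-delimited) PHYLIP into a
#' [LocusAlignment-class]. Residues are case-normalized; ambiguity codes and
#' unknown characters are mapped to missing (`"X"`) with a warning; gaps are
#' kept as `"-"` (both are marginalized in likelihood computations). The same
#' data read from either dialect yield identical objects.
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"` (relaxed: taxon label and sequence
#'   separated by whitespace, sequences possibly interleaved).
#' @param locusId identifier; defaults to the file name without extension.
#' @return A [LocusAlignment-class].
#' @export
readAlignment <- function(path, format = c("fasta", "phylip"),
                          locusId = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(locusId)) locusId <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  seqs <- switch(format,
    fasta = parseFasta(lines, path),
    phylip = parsePhylip(lines, path))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- names(seqs)[which(lens != max(lens))[1L]]
    stop("ragged alignment in ", path, ": taxon '", bad,
         "' has length ", nchar(seqs[[bad]]), " (expected ", max(lens), ")")
  }
  locusAlignment(seqs, locusId = locusId)
}

parseFasta <- function(lines, path) {
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  nm <- sub("^>\\s*", "", lines[hdr])
  nm <- sub("\\s.*$", "", nm)
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (starts[i] > ends[i]) return("")
    gsub("\\s", "", paste(lines[starts[i]:ends[i]], collapse = ""))
  }, character(1))
  if (anyDuplicated(nm))
    stop("duplicate taxon label in ", path, ": '", nm[duplicated(nm)][1L], "'")
  stats::setNames(seqs, nm)
}

parsePhylip <- function(lines, path) {
  lines <- lines[nzchar(trimws(lines))]
  hd <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(hd) < 2L || anyNA(suppressWarnings(as.integer(hd[1:2]))))
    stop("missing PHYLIP header in ", path)
  ntax <- as.integer(hd[1L]); nchar_ <- as.integer(hd[2L])
  body <- lines[-1L]
  if (length(body) < ntax) stop("truncated PHYLIP file: ", path)
  first <- body[seq_len(ntax)]
  parts <- strsplit(trimws(first), "\\s+")
  nm <- vapply(parts, `[[`, character(1), 1L)
  seqs <- vapply(parts, function(p) paste(p[-1L], collapse = ""), character(1))
  ## interleaved continuation blocks, if any
  extra <- body[-seq_len(ntax)]
  i <- 0L
  while (length(extra)) {
    take <- extra[seq_len(min(ntax, length(extra)))]
    extra <- extra[-seq_len(length(take))]
    for (j in seq_along(take)) {
      seqs[j] <- paste0(seqs[j], gsub("\\s", "", take[j]))
    }
    i <- i + 1L
  }
  if (anyDuplicated(nm))
    stop("duplicate taxon label in ", path, ": '", nm[duplicated(nm)][1L], "'")
  if (any(nchar(seqs) != nchar_))
    warning("PHYLIP header declares ", nchar_, " columns; found ",
            paste(unique(nchar(seqs)), collapse = "/"))
  stats::setNames(seqs, nm)
}

#' Read and write Newick trees
#'
#' Thin wrappers over \pkg{ape} that enforce the package's contracts:
#' unique tip labels, non-negative branch lengths, support values taken from
#' internal node labels, square-bracket comments stripped. Round-tripping
#' preserves topology, branch lengths (to float formatting) and supports.
#'
#' @param path file path (`readTree`) containing one Newick tree.
#' @param tree a `phylo` (`writeTree`).
#' @param file optional output path for `writeTree`; when `NULL` the Newick
#'   string is returned.
#' @return `readTree`: a `phylo` with, when present, `node.label` support
#'   values. `writeTree`: the Newick string (invisibly when written to file).
#' @export
readTree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  txt <- gsub("\\[[^]]*\\]", "", txt)
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("failed to parse Newick in ", path,
                                          ": ", conditionMessage(e)))
  if (is.null(tr)) stop("failed to parse Newick in ", path)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip label: '",
         tr$tip.label[duplicated(tr$tip.label)][1L], "'")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch length in ", path)
  tr
}

#' @rdname readTree
#' @export
writeTree <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Read a clade-definition file
#'
#' Two tab-separated columns, `clade_name` and `taxon`, one member per row.
#'
#' @param path file path.
#' @return Named list of character vectors (members per clade).
#' @export
readCladeDefinitions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("clade", "taxon"),
                          stringsAsFactors = FALSE)
  cl <- split(df$taxon, df$clade)
  if (any(lengths(cl) < 1L)) stop("empty clade definition")
  cl
}

#' Read a partition table and slice a supermatrix
#'
#' The partition table maps loci to supermatrix columns as
#' `locus_id TAB start TAB end` (1-based, inclusive).
#'
#' @param path partition table path.
#' @return `readPartitionTable`: data.frame with `locus_id`, `start`, `end`.
#' @export
readPartitionTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("locus_id", "start", "end"),
                          stringsAsFactors = FALSE)
  if (any(df$start < 1L) || any(df$end < df$start))
    stop("invalid partition bounds")
  df
}

#' @rdname readPartitionTable
#' @param supermatrix a [LocusAlignment-class] holding the concatenated
#'   matrix.
#' @param partitions data.frame from `readPartitionTable`.
#' @return `sliceSupermatrix`: list of [LocusAlignment-class], one per
#'   partition row.
#' @export
sliceSupermatrix <- function(supermatrix, partitions) {
  if (max(partitions$end) > nSites(supermatrix))
    stop("partition exceeds supermatrix width")
  out <- lapply(seq_len(nrow(partitions)), function(i) {
    m <- supermatrix@seqs[, partitions$start[i]:partitions$end[i], drop = FALSE]
    ## drop taxa entirely missing in this slice
    present <- apply(m, 1L, function(r) any(!(r %in% c("X", "-"))))
    new("LocusAlignment", locusId = partitions$locus_id[i],
        seqs = m[present, , drop = FALSE])
  })
  stats::setNames(out, partitions$locus_id)
}

#' Export pipeline tables as TSV
#'
#' Writes tab-separated tables with headers, one row per locus, deterministic
#' column order: re-exporting the same object is byte-identical.
#'
#' @param x a [GLSTable-class], [TreespaceResult-class], or data.frame (e.g.
#'   a gene-property panel).
#' @param file output path.
#' @param what for `TreespaceResult`: which table to write
#'   (`"coordinates"`, `"dissimilarity"` or `"disparity"`).
#' @return The path, invisibly.
#' @export
exportTable <- function(x, file,
                        what = c("coordinates", "dissimilarity", "disparity")) {
  df <- if (is(x, "GLSTable")) {
    glsTable(x)
  } else if (is(x, "TreespaceResult")) {
    what <- match.arg(what)
    switch(what,
      coordinates = data.frame(tree_id = rownames(x@coordinates),
                               x@coordinates, check.names = FALSE),
      dissimilarity = data.frame(tree_id = rownames(x@dissimilarity),
                                 x@dissimilarity, check.names = FALSE),
      disparity = {
        nm <- names(x@subsetDisparities)
        data.frame(subset = c("full", nm),
          disparity = c(x@disparityFull, unname(x@subsetDisparities)),
          null_mean = c(NA, vapply(nm, function(n)
            if (n %in% names(x@nullDistributions))
              mean(x@nullDistributions[[n]]) else NA_real_, 0)),
          null_q05 = c(NA, vapply(nm, function(n)
            if (n %in% names(x@nullDistributions))
              unname(stats::quantile(x@nullDistributions[[n]], 0.05)) else
              NA_real_, 0)),
          percentile_p = c(NA, vapply(nm, function(n)
            if (n %in% names(x@percentileP)) x@percentileP[[n]] else NA_real_,
            0)))
      })
  } else as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], formatNum)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Export per-site log-likelihoods for audit
#'
#' One line per result: `locus_id TAB topology_id TAB` comma-separated site
#' log-likelihoods, appendable across loci and topologies.
#'
#' @param results a [SiteLikelihoodResult-class] or a list of them.
#' @param file output path.
#' @return The path, invisibly.
#' @export
writeSiteLnL <- function(results, file) {
  if (is(results, "SiteLikelihoodResult")) results <- list(results)
  lines <- vapply(results, function(r)
    paste(r@locusId, r@topologyId,
          paste(formatNum(r@siteLnL), collapse = ","), sep = "\t"),
    character(1))
  writeLines(lines, file)
  invisible(file)
}
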