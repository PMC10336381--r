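## Internal helpers shared across modules.

#' Derive a reproducible substream seed for a named pipeline stage
#'
#' All randomness in the package flows from a single master seed; each stage
#' (simulation, subsampling nulls, permutation tests, ...) draws its own
#' substream seed from the master so the full pipeline is replayable and
#' stages can be re-run in isolation.
#'
#' @param masterSeed integer master seed.
#' @param stage character stage name.
#' @return An integer seed in \[0, 2^31).
#' @export
substreamSeed <- function(masterSeed, stage) {
  h <- sum(utf8ToInt(stage) * (31L^(seq_len(nchar(stage)) %% 7L)))
  as.integer((as.numeric(masterSeed) * 48271 + h) %% 2147483647)
}

## run code with a local RNG state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## unrooted binary check helpers
isBinaryUnrooted <- function(tree) {
  ape::is.binary(ape::unroot(tree))
}

## stable numeric formatting for TSV export
formatNum <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))
}
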