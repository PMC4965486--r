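#' @keywords internal
"_PACKAGE"

## Named substreams derived from a master seed, so that independent stages
## (genotypes, effects, locations, residuals, CV replicates, ...) can be
## re-run in isolation without disturbing each other's draws.
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L)
  codes <- utf8ToInt(as.character(name))
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147480009
  as.integer((abs(master) %% 2147480009 * 7919 + h) %% 2147480009 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
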