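#' Default species panel
#'
#' The 21 vertebrate species abbreviations used for the per-species
#' evolutionary features (e.g. `"mmus"` = *Mus musculus*, `"ptro"` =
#' *Pan troglodytes*).
#'
#' @return Character vector of 21 species codes.
#' @export
#' @examples
#' species_panel()
species_panel <- function() {
  c("amel", "btau", "cfam", "cjac", "cpor", "ecab", "itri",
    "lafr", "mdom", "mfur", "mluc", "mmul", "mmus", "nleu",
    "ocun", "ogar", "pabe", "ptro", "rnor", "shar", "sscr")
}

# Derive one of several independent sub-stream seeds from a master seed,
# kept below 2^31 so it is a valid R integer seed. Each sub-generator of
# the synthetic study uses its own stream so that, e.g., adding species
# does not perturb the network draw.
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  (abs(as.integer(seed)) %% 1000003L) * 2011L + as.integer(stream)
}

# Evaluate expr under a temporary RNG state seeded from (seed, stream),
# restoring the caller's RNG state afterwards.
with_stream <- function(seed, stream, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
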