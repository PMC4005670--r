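`%||%` <- function(a, b) if (is.null(a)) b else a

# run code with a temporary RNG state; the caller's stream is untouched
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  force(code)
}

# one documented derivation of per-stage seeds from the top-level seed
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 1000003 * as.numeric(stage)) %% 2147483587 + 1)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_clean_dna <- function(x) !grepl("[^ACGT]", x)
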