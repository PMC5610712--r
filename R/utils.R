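# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a stream of child seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# Reverse complement for plain character vectors.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Translate coding-strand nucleotide sequences to protein, dropping the
# trailing stop.
translate_cds <- function(nt) {
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAStringSet(nt), if.fuzzy.codon = "X")
  ))
  sub("\\*$", "", aa)
}

# Locate an external executable, with an informative error.
find_tool <- function(name) {
  path <- Sys.which(name)
  if (!nzchar(path)) {
    abort(sprintf("external tool '%s' not found on PATH", name))
  }
  unname(path)
}
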