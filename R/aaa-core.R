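# Internal nucleotide encoding used by the hot paths: A=1, C=2, G=3, T=4.
.BASES <- c("A", "C", "G", "T")

.seq2int <- function(x) {
  v <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], .BASES)
  if (anyNA(v)) {
    bad <- which(is.na(v))[1]
    abort(sprintf("non-ACGT symbol at position %d", bad), class = "splicevolver_bad_base")
  }
  v
}

.int2seq <- function(v) paste(.BASES[v], collapse = "")

# Run code under a temporary, seeded RNG state; restores the caller's stream.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
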