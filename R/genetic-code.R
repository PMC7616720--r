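# Genetic-code arithmetic. The standard (human nuclear) code only: the
# constructs this package designs are human minigenes.

# 64-entry lookup, names = DNA codons, values = one-letter amino acids ("*" stop).
.GENETIC_CODE <- as.character(Biostrings::GENETIC_CODE)
names(.GENETIC_CODE) <- names(Biostrings::GENETIC_CODE)

# aa indexed by 16*(b1-1) + 4*(b2-1) + b3 for the engine's integer sequences
.CODON_AA <- local({
  idx <- expand.grid(b3 = 1:4, b2 = 1:4, b1 = 1:4)
  codons <- paste0(.BASES[idx$b1], .BASES[idx$b2], .BASES[idx$b3])
  aa <- unname(.GENETIC_CODE[codons])
  ord <- 16L * (idx$b1 - 1L) + 4L * (idx$b2 - 1L) + idx$b3
  out <- character(64)
  out[ord] <- aa
  out
})

.codon_index <- function(b1, b2, b3) 16L * (b1 - 1L) + 4L * (b2 - 1L) + b3

# synonymous codon integers (triplet matrix) per codon index, precomputed
.SYN_SETS <- local({
  all <- expand.grid(b3 = 1:4, b2 = 1:4, b1 = 1:4)
  all <- all[, c("b1", "b2", "b3")]
  ci <- .codon_index(all$b1, all$b2, all$b3)
  aa <- .CODON_AA[ci]
  sets <- vector("list", 64)
  for (i in seq_len(64)) {
    same <- which(aa == aa[ci[i]])
    sets[[ci[i]]] <- as.matrix(all[same, , drop = FALSE])
  }
  sets
})

#' The standard genetic code as a tidy table
#'
#' @return A tibble with columns `codon` (DNA 3-mer), `aa` (one-letter amino
#'   acid, `"*"` for stop) and `degeneracy` (size of the synonymous family).
#' @export
#' @examples
#' genetic_code()
genetic_code <- function() {
  tb <- tibble(codon = names(.GENETIC_CODE), aa = unname(.GENETIC_CODE))
  counts <- table(tb$aa)
  tb$degeneracy <- as.integer(counts[tb$aa])
  tb
}

#' Translate a coding sequence
#'
#' Translates `cds` in the given frame up to and including the first stop
#' codon (reported as absent from the protein string) or the end of the
#' sequence. Trailing bases that do not fill a codon are ignored.
#'
#' @param cds A DNA string (ACGT only).
#' @param frame Integer offset (0, 1 or 2) at which translation starts.
#' @return The amino-acid string. `translation_report()` returns the same
#'   information as a one-row tibble including whether a stop codon occurred
#'   before the final codon (`internal_stop`).
#' @export
#' @examples
#' translate_cds("ATGGCG")
#' translation_report("ATGTAAATG")
translate_cds <- function(cds, frame = 0) {
  translation_report(cds, frame)$protein
}

#' @rdname translate_cds
#' @export
translation_report <- function(cds, frame = 0) {
  stopifnot(length(cds) == 1, frame %in% 0:2)
  v <- .seq2int(cds)
  if (length(v) - frame < 3) {
    abort("sequence too short to translate: need at least one full codon past `frame`")
  }
  v <- v[(frame + 1):length(v)]
  n_codon <- length(v) %/% 3
  aa <- .translate_int(v[seq_len(3 * n_codon)])
  stop_at <- match("*", aa)
  internal_stop <- !is.na(stop_at) && stop_at < n_codon
  if (!is.na(stop_at)) aa <- aa[seq_len(stop_at - 1)]
  tibble(
    protein = paste(aa, collapse = ""),
    internal_stop = internal_stop,
    stopped = !is.na(stop_at),
    n_codons = n_codon
  )
}

.translate_int <- function(v) {
  b <- matrix(v, nrow = 3)
  .CODON_AA[.codon_index(b[1, ], b[2, ], b[3, ])]
}

#' Synonymous codons of a sense codon
#'
#' The returned set always contains the input codon. Stop codons are
#' rejected: the design engine never mutates them.
#'
#' @param codon A DNA 3-mer encoding an amino acid.
#' @return Character vector of codons encoding the same amino acid.
#' @export
#' @examples
#' synonymous_codons("ATG") # Met: just itself
#' synonymous_codons("CTG") # Leu: six codons
synonymous_codons <- function(codon) {
  stopifnot(length(codon) == 1)
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) {
    abort(sprintf("'%s' is not a concrete DNA codon", codon), class = "splicevolver_bad_codon")
  }
  aa <- unname(.GENETIC_CODE[codon])
  if (aa == "*") {
    abort("stop codons have no synonymous set here: they are never mutated",
      class = "splicevolver_stop_codon"
    )
  }
  sort(names(.GENETIC_CODE)[.GENETIC_CODE == aa])
}

# Reverse lookup: codons (character) for an amino acid
.codons_for_aa <- function(aa) names(.GENETIC_CODE)[.GENETIC_CODE == aa]
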