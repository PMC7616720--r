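# IUPAC-degenerate sequence handling. Design templates mix cases
# (lowercase = fixed annotation such as splice-site consensus, e.g. "GTaag")
# and ambiguity codes (N, R, Y, ... = positions the evolution engine may vary).

.IUPAC <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  lapply(m, function(x) strsplit(x, "", fixed = TRUE)[[1]])
})

#' Expand an IUPAC nucleotide code
#'
#' @param code Single IUPAC letter (case-insensitive).
#' @return Character vector of concrete bases the code stands for.
#' @export
#' @examples
#' iupac_expand("R")
iupac_expand <- function(code) {
  x <- .IUPAC[[toupper(code)]]
  if (is.null(x)) {
    abort(sprintf("'%s' is not an IUPAC nucleotide code", code),
      class = "splicevolver_bad_iupac"
    )
  }
  x
}

#' Concretize a degenerate design template
#'
#' Replaces every degenerate position by a uniformly sampled member of its
#' expansion set and records, per position, the set of bases the position is
#' allowed to take. Literal positions (including lowercase annotation) keep a
#' singleton allowed set; a position is *free* when its allowed set has more
#' than one member. Reproducible for a fixed `seed`.
#'
#' @param template Sequence over the IUPAC alphabet, possibly mixed-case.
#' @param seed Optional integer seed for the sampling.
#' @return A list of class `resolved_sequence`: `sequence` (concrete ACGT,
#'   uppercase), `template`, `free` (integer positions with >1 allowed base),
#'   `allowed` (list of character vectors, one per position), `lowercase`
#'   (logical per position).
#' @export
#' @examples
#' resolve_degenerate("GTaagNNNNcAG", seed = 1)$sequence
resolve_degenerate <- function(template, seed = NULL) {
  stopifnot(length(template) == 1, is.character(template))
  chars <- strsplit(template, "", fixed = TRUE)[[1]]
  lower <- chars %in% letters
  up <- toupper(chars)
  bad <- which(!up %in% names(.IUPAC))
  if (length(bad)) {
    abort(sprintf("invalid IUPAC symbol '%s' at position %d", chars[bad[1]], bad[1]),
      class = "splicevolver_bad_iupac"
    )
  }
  allowed <- .IUPAC[up]
  # lowercase marks fixed annotation: computation case-folds, mutability does not
  allowed[lower] <- lapply(which(lower), function(i) {
    if (length(allowed[[i]]) > 1) {
      abort(sprintf(
        "position %d is both lowercase (fixed) and degenerate ('%s')",
        i, chars[i]
      ))
    }
    allowed[[i]]
  })
  allowed <- unname(allowed)
  n_opt <- lengths(allowed)
  concrete <- up
  degen <- which(n_opt > 1)
  if (length(degen)) {
    concrete[degen] <- .with_seed(seed, vapply(
      allowed[degen],
      function(s) s[sample.int(length(s), 1)], character(1)
    ))
  }
  structure(
    list(
      sequence = paste(concrete, collapse = ""),
      template = template,
      free = degen,
      allowed = allowed,
      lowercase = lower
    ),
    class = "resolved_sequence"
  )
}

#' @export
print.resolved_sequence <- function(x, ...) {
  cat(
    "<resolved_sequence> ", nchar(x$sequence), " nt, ",
    length(x$free), " free position(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Windowed UG/TG-dinucleotide density
#'
#' TDP-43 binds UG-rich RNA; this scan is the design constraint used to keep
#' cryptic splice sites under TDP-43 control. The density at position *i* is
#' the number of TG dimer starts (any phase) within the centered window of
#' `window` nucleotides, divided by `window - 1` (the number of dimer starts
#' the window holds). Input may use U or T. Positions whose centered window
#' would overhang the sequence use the clipped window (same normalization by
#' actual dimer-start count), so values always lie in [0, 1].
#'
#' @param seq DNA or RNA string.
#' @param window Window width in nucleotides (>= 2).
#' @return Tibble with `position` and `density`.
#' @export
#' @examples
#' ug_density("TGTGTGTG", window = 8)
ug_density <- function(seq, window = 20) {
  stopifnot(length(seq) == 1, window >= 2)
  s <- chartr("Uu", "Tt", toupper(seq))
  n <- nchar(s)
  if (window > n) {
    abort(sprintf("window (%d) exceeds sequence length (%d)", window, n))
  }
  tibble(position = seq_len(n), density = .ug_density_vec(s, window))
}

.ug_density_vec <- function(s, window) {
  chars <- strsplit(toupper(chartr("U", "T", s)), "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_tg <- c(chars[-n] == "T" & chars[-1] == "G", FALSE) # dimer starting at i
  cum <- c(0, cumsum(is_tg))
  half <- window %/% 2
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, lo + window - 1L)
  lo <- pmax(1L, hi - window + 1L)
  starts_in <- (hi - lo) # dimer starts fully inside [lo, hi]
  count <- cum[pmax(lo + starts_in, lo)] - cum[lo]
  ifelse(starts_in > 0, count / starts_in, 0)
}
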