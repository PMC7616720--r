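# Splice predictor contract and the deterministic surrogate scorer.
#
# Contract: a predictor maps an ACGT sequence to per-nucleotide donor and
# acceptor probabilities in [0,1]. Coordinate convention (applied identically
# to ideal targets and predictions throughout the package):
#   * the donor score sits on the LAST EXONIC base, i.e. position p scores the
#     junction exon]p | p+1[intron with the invariant GT at p+1,p+2;
#   * the acceptor score sits on the FIRST EXONIC base, i.e. position p scores
#     the junction with the invariant AG at p-2,p-1.

#' Surrogate splice-site predictor
#'
#' A deterministic position-weight scorer used in place of a deep-learning
#' splice model. Donor sites are scored from a 9-mer spanning \[-3,+6\] around
#' the exon/intron boundary (hard GT gate), acceptors from a 23-mer covering
#' an 18-nt polypyrimidine tract (PPT), the invariant AG and one exonic base
#' (hard AG gate). Scores are log2-odds against a uniform background,
#' squashed to \[0,1\] by a logistic with fixed parameters; the acceptor score
#' is strictly increasing in the pyrimidine fraction of the PPT. Parameters
#' are pinned in a versioned JSON shipped with the package.
#'
#' @param params Parameter list, default [surrogate_params()].
#' @return An object of class `c("surrogate_predictor", "splice_predictor")`
#'   with fields `name`, `version`, `context_padding` (flanking nucleotides a
#'   window consumes) and `deterministic`.
#' @export
#' @examples
#' pred <- surrogate_predictor()
#' pred$deterministic
surrogate_predictor <- function(params = surrogate_params()) {
  structure(
    list(
      name = "surrogate",
      version = params$version,
      params = params,
      context_padding = 22L,
      deterministic = TRUE
    ),
    class = c("surrogate_predictor", "splice_predictor")
  )
}

#' @rdname surrogate_predictor
#' @export
surrogate_params <- function() {
  path <- system.file("extdata", "surrogate_params_v1.json", package = "splicevolver")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @export
print.splice_predictor <- function(x, ...) {
  cat(sprintf(
    "<splice_predictor> %s (version %s), deterministic: %s\n",
    x$name, x$version %||% "?", x$deterministic
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- compiled numeric form used by the hot loop -----------------------------

# Turns the JSON parameters into plain vectors/matrices for vectorized scoring.
.compile_surrogate <- function(params) {
  d <- params$donor
  offs <- as.integer(d$offsets)
  lo <- t(vapply(
    as.character(offs),
    function(k) log2(as.numeric(d$freq[[k]]) / params$background),
    numeric(4)
  ))
  # window offset -> sequence offset from the scored (last exonic) base:
  # -3,-2,-1 -> -2,-1,0 ; +1..+6 -> +1..+6
  seq_off <- ifelse(offs < 0, offs + 1L, offs)
  a <- params$acceptor
  a_lo20 <- log2(as.numeric(a$freq[["20"]]) / params$background)
  a_lo23 <- log2(as.numeric(a$freq[["23"]]) / params$background)
  list(
    d_lo = lo, d_off = seq_off,
    d_k = d$logistic$k, d_s0 = d$logistic$s0,
    a_ppt_w = a$ppt_weight, a_lo20 = a_lo20, a_lo23 = a_lo23,
    a_k = a$logistic$k, a_s0 = a$logistic$s0
  )
}

# Vectorized surrogate scoring over an integer-encoded sequence.
# Returns list(donor=..., acceptor=...), numeric vectors of length(v).
.surrogate_profile <- function(v, cp) {
  n <- length(v)
  donor <- numeric(n)
  acceptor <- numeric(n)
  if (n < 9L) {
    return(list(donor = donor, acceptor = acceptor))
  }
  # donor: scored base p needs p-2 >= 1 and p+6 <= n
  p <- seq.int(3L, n - 6L)
  gate <- v[p + 1L] == 3L & v[p + 2L] == 4L # G, T
  pg <- p[gate]
  if (length(pg)) {
    s <- numeric(length(pg))
    for (j in seq_along(cp$d_off)) {
      s <- s + cp$d_lo[j, v[pg + cp$d_off[j]]]
    }
    donor[pg] <- stats::plogis(cp$d_k * (s - cp$d_s0))
  }
  # acceptor: scored base p needs window p-22 .. p
  if (n >= 23L) {
    p <- seq.int(23L, n)
    gate <- v[p - 2L] == 1L & v[p - 1L] == 3L # A, G
    pg <- p[gate]
    if (length(pg)) {
      pyr <- as.numeric(v == 2L | v == 4L)
      cum <- c(0, cumsum(pyr))
      # PPT occupies window positions 1..18 = sequence p-22 .. p-5
      frac <- (cum[pg - 4L] - cum[pg - 22L]) / 18
      s <- cp$a_ppt_w * frac + cp$a_lo20[v[pg - 3L]] + cp$a_lo23[v[pg]]
      acceptor[pg] <- stats::plogis(cp$a_k * (s - cp$a_s0))
    }
  }
  list(donor = donor, acceptor = acceptor)
}

#' Predict a per-nucleotide splicing profile
#'
#' @param sequence ACGT string (resolve degenerate bases first); must be at
#'   least 23 nt so one full acceptor window fits.
#' @param predictor A predictor object; default the surrogate.
#' @return Tibble with `position`, `donor`, `acceptor` (probabilities). See
#'   [surrogate_predictor()] for the coordinate convention.
#' @export
#' @examples
#' prof <- predict_splice_profile(paste0(
#'   strrep("A", 30), "CAGGTAAGT", strrep("A", 30)
#' ))
#' prof[which.max(prof$donor), ]
predict_splice_profile <- function(sequence, predictor = surrogate_predictor()) {
  stopifnot(inherits(predictor, "splice_predictor"))
  if (nchar(sequence) < 23) {
    abort(
      "sequence shorter than the minimum predictor context: need >= 23 nt (22 nt of acceptor-window padding plus the scored base)",
      class = "splicevolver_short_sequence"
    )
  }
  v <- .seq2int(sequence)
  prof <- .predict_int(v, predictor)
  tibble(position = seq_along(v), donor = prof$donor, acceptor = prof$acceptor)
}

.predict_int <- function(v, predictor) {
  if (inherits(predictor, "surrogate_predictor")) {
    cp <- predictor$compiled %||% .compile_surrogate(predictor$params)
    .surrogate_profile(v, cp)
  } else if (inherits(predictor, "external_predictor")) {
    predictor$predict_fun(.int2seq(v))
  } else {
    abort("unknown predictor class")
  }
}

#' Score a single donor or acceptor window
#'
#' Direct access to the surrogate's window scorers, mainly for inspection and
#' testing. The donor window is the 9-mer \[-3,+6\] around the exon/intron
#' boundary; the acceptor window is the 23-mer PPT + AG + first exonic base.
#'
#' @param window DNA string of exactly 9 (donor) or 23 (acceptor) nt.
#' @param params Surrogate parameters.
#' @return A probability in \[0,1\]; exactly 0 when the invariant GT / AG
#'   dinucleotide is absent.
#' @export
#' @examples
#' score_donor_window("CAGGTAAGT")
#' score_donor_window("CAGGGAAGT") # GT destroyed -> 0
score_donor_window <- function(window, params = surrogate_params()) {
  if (nchar(window) != 9) abort("donor window must be exactly 9 nt")
  v <- .seq2int(window)
  .surrogate_profile(c(v, rep(1L, 14L)), .compile_surrogate(params))$donor[3L]
}

#' @rdname score_donor_window
#' @export
score_acceptor_window <- function(window, params = surrogate_params()) {
  if (nchar(window) != 23) abort("acceptor window must be exactly 23 nt")
  v <- .seq2int(window)
  .surrogate_profile(v, .compile_surrogate(params))$acceptor[23L]
}

#' Adapter for an external deep-learning splice predictor
#'
#' Wraps a user-supplied scoring function (for example, a wrapper around a
#' deep splice model served out-of-process) in the predictor contract used by
#' the evolution engine, which is indifferent to the backend. The function
#' must accept an ACGT string and return a list with numeric `donor` and
#' `acceptor` vectors matching the input length. External backends are always
#' asked to rescore the full sequence; no incremental shortcut is assumed.
#'
#' @param predict_fun Scoring function, or `NULL` if no backend is available.
#' @param name Backend name.
#' @param context_padding Flanking context the model consumes, in nt.
#' @param deterministic Whether repeated calls are guaranteed identical.
#' @return A predictor object of class
#'   `c("external_predictor", "splice_predictor")`.
#' @export
external_predictor <- function(predict_fun, name = "external",
                               context_padding = 5000L, deterministic = TRUE) {
  if (is.null(predict_fun) || !is.function(predict_fun)) {
    abort(
      paste0(
        "no external splice-model backend is available; pass a scoring ",
        "function, or use surrogate_predictor() for offline work"
      ),
      class = "splicevolver_backend_unavailable"
    )
  }
  raw <- predict_fun
  wrapped <- function(sequence) {
    out <- raw(sequence)
    n <- nchar(sequence)
    if (!is.list(out) || length(out$donor) != n || length(out$acceptor) != n) {
      abort("external predictor violated the contract: donor/acceptor must match input length")
    }
    if (any(out$donor < 0 | out$donor > 1) || any(out$acceptor < 0 | out$acceptor > 1)) {
      abort("external predictor violated the contract: scores must lie in [0,1]")
    }
    out
  }
  structure(
    list(
      name = name, version = NA_character_, predict_fun = wrapped,
      context_padding = as.integer(context_padding), deterministic = deterministic
    ),
    class = c("external_predictor", "splice_predictor")
  )
}
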