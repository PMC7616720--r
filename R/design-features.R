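# Rational-design generators composed with the evolution engine: synonymous
# polypyrimidine-tract recoding, competitor splice-site placement, and
# UG-rich region construction.

#' Synonymous pyrimidine maximization of a coding segment
#'
#' Recodes each codon to the synonymous codon with the most pyrimidines
#' (C/T), the move used to build an alternative polypyrimidine tract inside
#' a coding exon. Ties are broken toward more T (U-rich tracts are the
#' canonical PPT), then alphabetically. The protein is unchanged; the
#' resulting pyrimidine fraction is the synonymous maximum, so the operation
#' is idempotent and never lowers the pyrimidine fraction.
#'
#' @param cds In-frame coding segment (length a multiple of 3, no stops).
#' @return The recoded segment.
#' @export
#' @examples
#' pyrimidine_maximize("CTGAAA") # Leu Lys -> CTT AAA
pyrimidine_maximize <- function(cds) {
  stopifnot(length(cds) == 1)
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) abort("segment length must be a multiple of 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(vapply(codons, .pyr_max_codon, character(1)), collapse = "")
}

.pyr_count <- function(codon) {
  sum(strsplit(codon, "", fixed = TRUE)[[1]] %in% c("C", "T"))
}

.t_count <- function(codon) {
  sum(strsplit(codon, "", fixed = TRUE)[[1]] == "T")
}

.pyr_max_codon <- function(codon) {
  syn <- synonymous_codons(codon)
  pyr <- vapply(syn, .pyr_count, integer(1))
  best <- syn[pyr == max(pyr)]
  tc <- vapply(best, .t_count, integer(1))
  best <- best[tc == max(tc)]
  sort(best)[1]
}

#' Recode a polypyrimidine tract inside a layout
#'
#' Applies [pyrimidine_maximize()] to the codons lying wholly inside the
#' given construct window (alt-3' designs: the window upstream of the
#' competitor acceptor). Codons outside coding regions, inside mutation
#' trims, or carrying anchor-invariant dinucleotides are not available, and
#' a window that overlaps a fixed (non-recodable) stretch is an error.
#'
#' @param layout A `construct_layout`.
#' @param window Length-2 integer vector `c(start, end)` in construct
#'   coordinates.
#' @return The layout with its sequence recoded (revalidated).
#' @export
design_ppt <- function(layout, window) {
  stopifnot(inherits(layout, "construct_layout"), length(window) == 2)
  window <- as.integer(window)
  if (window[1] < 1 || window[2] > layout$length || window[1] > window[2]) {
    abort("window out of range")
  }
  idx <- layout$index
  pos <- seq.int(window[1], window[2])
  role <- layout$regions$role[idx$region_of[pos]]
  if (any(!role %in% c("cds_exon", "cryptic_exon"))) {
    abort("PPT window overlaps a fixed (non-coding) region",
      class = "splicevolver_fixed_overlap"
    )
  }
  v <- .seq2int(layout$sequence)
  inside <- apply(idx$codon_pos >= window[1] & idx$codon_pos <= window[2], 2, all)
  targets <- intersect(which(inside), idx$mutable_codon)
  for (ci in targets) {
    p <- idx$codon_pos[, ci]
    new <- .pyr_max_codon(.int2seq(v[p]))
    v[p] <- .seq2int(new)
  }
  layout$sequence <- .int2seq(v)
  validate_layout(layout)
  layout
}

#' Place a competitor splice site in a coding exon
#'
#' For alternative-splice designs the construct needs a second, competing
#' site that wins splicing when TDP-43 represses the cryptic site. The scan
#' considers every codon-frame-respecting position in the permitted zone
#' (`alt_position = "in_exon"`: inside a coding exon, outside mutation trims
#' and the 3' `alt_end_trim`) at least `min_alt_dist` nt from the cryptic
#' anchor, asks whether the invariant dinucleotide (AG for an acceptor
#' upstream-adjacent to the site, GT for a donor downstream-adjacent) is
#' reachable by synonymous recoding, recodes the supporting context
#' (synonymous PPT maximization for acceptors), and scores the site with the
#' predictor. The best-scoring feasible position wins; ties go to the
#' 5'-most position, so the result is deterministic and independent of scan
#' order.
#'
#' @param layout An alt-3' or alt-5' `construct_layout`.
#' @param predictor Splice predictor used for scoring.
#' @param ppt_window Length (nt) of coding sequence upstream of a candidate
#'   acceptor recoded toward pyrimidines before scoring.
#' @return A list of class `competitor_plan`: `kind`, `position`, `score`,
#'   `distance`, `candidates` (tibble of scanned positions) and `layout`,
#'   the updated layout with the recoded sequence and the competitor anchor
#'   appended (its ideal score is the design's `target_const_acc` /
#'   `target_const_donor`).
#' @export
place_competitor <- function(layout, predictor = surrogate_predictor(),
                             ppt_window = 18) {
  spec <- layout$spec
  if (!spec$design_type %in% c("alt3prime_single_intron", "alt5prime_single_intron")) {
    abort("competitor sites are placed only for alternative-splice designs",
      class = "splicevolver_bad_config"
    )
  }
  alt3 <- spec$design_type == "alt3prime_single_intron"
  if (inherits(predictor, "surrogate_predictor") && is.null(predictor$compiled)) {
    predictor$compiled <- .compile_surrogate(predictor$params)
  }
  cryptic <- layout$anchors$position[grepl("^cryptic", layout$anchors$kind)][1]
  idx <- layout$index
  r <- layout$regions
  intron_i <- which(r$role == "intron")[1]
  exon_region <- if (alt3) {
    r$region_id[r$role == "cds_exon" & r$region_id > intron_i][1]
  } else {
    rev(r$region_id[r$role == "cds_exon" & r$region_id < intron_i])[1]
  }
  if (is.na(exon_region)) abort("no coding exon available in the competitor zone")
  zone <- seq.int(r$start[exon_region], r$end[exon_region])
  limit <- layout$length - spec$alt_end_trim
  v0 <- .seq2int(layout$sequence)

  cand <- tibble(
    position = zone,
    feasible = FALSE, reason = NA_character_, score = NA_real_
  )
  best <- NULL
  for (ri in seq_len(nrow(cand))) {
    p <- cand$position[ri]
    if (abs(p - cryptic) < spec$min_alt_dist) {
      cand$reason[ri] <- "min_alt_dist"
      next
    }
    if (p > limit) {
      cand$reason[ri] <- "alt_end_trim"
      next
    }
    din <- if (alt3) c(p - 2L, p - 1L) else c(p + 1L, p + 2L)
    if (any(din < r$start[exon_region]) || any(din > r$end[exon_region])) {
      cand$reason[ri] <- "dinucleotide outside exon"
      next
    }
    if (alt3 && p - 22L < 1L) {
      cand$reason[ri] <- "insufficient 5' context"
      next
    }
    if (!alt3 && p + 6L > layout$length) {
      cand$reason[ri] <- "insufficient 3' context"
      next
    }
    trial <- .reach_dinucleotide(layout, v0, din, if (alt3) c(1L, 3L) else c(3L, 4L))
    if (is.null(trial)) {
      cand$reason[ri] <- "dinucleotide not synonymously reachable"
      next
    }
    sc <- 0
    best_tv <- NULL
    for (tv in trial) {
      if (alt3 && ppt_window > 0) {
        tv <- .ppt_recode_int(layout, tv, c(max(1L, p - 22L), p - 5L))
      }
      prof <- .predict_int(tv, predictor)
      s <- if (alt3) prof$acceptor[p] else prof$donor[p]
      if (is.null(best_tv) || s > sc) {
        sc <- s
        best_tv <- tv
      }
    }
    cand$feasible[ri] <- TRUE
    cand$score[ri] <- sc
    if (is.null(best) || sc > best$score) {
      best <- list(position = p, score = sc, v = best_tv)
    }
  }
  if (is.null(best)) {
    tally <- table(cand$reason[!is.na(cand$reason)])
    abort(
      paste0(
        "no feasible competitor position; constraints violated: ",
        paste(sprintf("%s (%d)", names(tally), as.integer(tally)), collapse = ", ")
      ),
      class = "splicevolver_no_competitor"
    )
  }
  layout$sequence <- .int2seq(best$v)
  layout$anchors <- dplyr::bind_rows(layout$anchors, tibble(
    kind = if (alt3) "competitor_acceptor" else "competitor_donor",
    site = if (alt3) "acceptor" else "donor",
    position = best$position,
    target_score = if (alt3) spec$target_const_acc else spec$target_const_donor,
    weight = 1, fixed = TRUE
  ))
  layout <- .index_layout(layout)
  validate_layout(layout)
  structure(
    list(
      kind = if (alt3) "acceptor" else "donor",
      position = best$position, score = best$score,
      distance = abs(best$position - cryptic),
      candidates = cand, layout = layout
    ),
    class = "competitor_plan"
  )
}

#' @export
print.competitor_plan <- function(x, ...) {
  cat(sprintf(
    "<competitor_plan> %s at position %d (score %.3f, distance %d nt, %d/%d positions feasible)\n",
    x$kind, x$position, x$score, x$distance,
    sum(x$candidates$feasible), nrow(x$candidates)
  ))
  invisible(x)
}

# Enumerate synonymous codon assignments putting `bases` (int) at positions
# `din`; returns list of candidate integer sequences, or NULL if unreachable.
.reach_dinucleotide <- function(layout, v, din, bases) {
  idx <- layout$index
  ci1 <- which(apply(idx$codon_pos == din[1], 2, any))
  ci2 <- which(apply(idx$codon_pos == din[2], 2, any))
  if (!length(ci1) || !length(ci2)) {
    return(NULL)
  }
  needed <- unique(c(ci1, ci2))
  if (!all(needed %in% idx$mutable_codon)) {
    # codon under a trim or anchor: only usable if the bases are already there
    if (v[din[1]] == bases[1] && v[din[2]] == bases[2]) {
      return(list(v))
    }
    return(NULL)
  }
  combos <- list(v)
  for (ci in needed) {
    pos <- idx$codon_pos[, ci]
    cur <- .codon_index(v[pos[1]], v[pos[2]], v[pos[3]])
    syn <- .SYN_SETS[[cur]]
    new_combos <- list()
    for (w in combos) {
      for (rw in seq_len(nrow(syn))) {
        w2 <- w
        w2[pos] <- syn[rw, ]
        new_combos[[length(new_combos) + 1]] <- w2
      }
    }
    combos <- new_combos
  }
  ok <- purrr::keep(combos, ~ .x[din[1]] == bases[1] && .x[din[2]] == bases[2])
  if (!length(ok)) {
    return(NULL)
  }
  ok
}

# Pyrimidine-maximize the codons wholly inside [window] that are mutable;
# integer-vector version used during competitor scanning.
.ppt_recode_int <- function(layout, v, window) {
  idx <- layout$index
  inside <- apply(idx$codon_pos >= window[1] & idx$codon_pos <= window[2], 2, all)
  for (ci in intersect(which(inside), idx$mutable_codon)) {
    p <- idx$codon_pos[, ci]
    v[p] <- .seq2int(.pyr_max_codon(.int2seq(v[p])))
  }
  v
}

#' Build a UG-rich TDP-43 binding region
#'
#' Generates the RNA element that puts a designed splice site under TDP-43
#' control. Three styles mirror the arrangements seen at natural
#' TDP-43-repressed exons: `pure_repeat` is an uninterrupted (TG)n run;
#' `interrupted_repeat` breaks the run with an AA dinucleotide after every
#' `max_run` TG dimers (the same interruption used to make long repeats
#' synthesizable); `ug_rich_no_repeat` scatters TG dimers without extended
#' runs. Passing `max_run` to `pure_repeat` likewise caps run length via AA
#' interruptions (the "short UG-repeats" used to limit binding affinity).
#' Outputs are ACGT-only and deterministic given `seed`; their TG-dimer
#' density (see [ug_density()]) meets documented floors of 0.45
#' (uninterrupted pure), 0.30 (interrupted or capped) and 0.20 (rich).
#'
#' @param length Region length in nt (>= 2).
#' @param style One of `"pure_repeat"`, `"interrupted_repeat"`,
#'   `"ug_rich_no_repeat"`.
#' @param max_run Maximum consecutive TG dimers (optional for
#'   `pure_repeat`; default 4 for `interrupted_repeat`).
#' @param seed Seed for the stochastic `ug_rich_no_repeat` style.
#' @return A DNA string of the requested length.
#' @export
#' @examples
#' build_ug_region(8, "pure_repeat")
build_ug_region <- function(length, style = c("pure_repeat", "interrupted_repeat", "ug_rich_no_repeat"),
                            max_run = NULL, seed = NULL) {
  style <- match.arg(style)
  length <- as.integer(length)
  if (length < 2) abort("length must be >= 2")
  out <- switch(style,
    pure_repeat = .ug_pure(length, max_run),
    interrupted_repeat = .ug_pure(length, max_run %||% 4L),
    ug_rich_no_repeat = .ug_rich(length, seed)
  )
  floor_needed <- if (style == "pure_repeat" && is.null(max_run)) {
    0.45
  } else if (style == "ug_rich_no_repeat") {
    0.20
  } else {
    0.30
  }
  dens <- max(.ug_density_vec(out, min(length, 20L)))
  if (dens < floor_needed) {
    abort(sprintf(
      "infeasible length/style combination: achieved density %.2f < floor %.2f",
      dens, floor_needed
    ), class = "splicevolver_infeasible")
  }
  out
}

.ug_pure <- function(length, max_run) {
  if (is.null(max_run)) {
    return(substr(strrep("TG", ceiling(length / 2)), 1, length))
  }
  unit <- paste0(strrep("TG", max_run), "AA")
  substr(strrep(unit, ceiling(length / nchar(unit)) + 1L), 1, length)
}

.ug_rich <- function(length, seed) {
  # TG dimers separated by single non-G spacers: never two TG dimers in a row
  .with_seed(seed, {
    parts <- character(0)
    total <- 0L
    while (total < length) {
      parts <- c(parts, "TG", sample(c("A", "C", "T"), 1))
      total <- total + 3L
    }
    substr(paste(parts, collapse = ""), 1, length)
  })
}
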