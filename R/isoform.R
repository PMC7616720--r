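# Splicing quantification: PSI from junction counts, isoform classification
# from per-read junction chains, productive-transcript calling with
# reading-frame and NMD logic.

#' Percent spliced in (PSI)
#'
#' `PSI = inclusion / (inclusion + exclusion) * 100`. Vectorized; when both
#' counts are zero the PSI is undefined and `NA` is returned (never 0).
#'
#' @param inclusion,exclusion Non-negative read counts.
#' @return PSI in \[0,100\], or `NA` where both counts are zero.
#' @export
#' @examples
#' psi(3, 1) # 75
psi <- function(inclusion, exclusion) {
  if (any(inclusion < 0) || any(exclusion < 0)) {
    abort("read counts must be non-negative")
  }
  total <- inclusion + exclusion
  ifelse(total > 0, 100 * inclusion / total, NA_real_)
}

#' Reference junctions of the AARS1 cryptic exon
#'
#' The three splice junctions used to quantify the human *AARS1* cryptic
#' exon from STAR splice-junction tables (hg38, minus strand): the two novel
#' junctions flanking the cryptic exon count as inclusion, the annotated
#' exon-exon junction as exclusion.
#'
#' @return Tibble with `chrom`, `start`, `end`, `name`, `strand`, `role`.
#' @export
#' @examples
#' aars1_junctions()
aars1_junctions <- function() {
  tibble(
    chrom = "chr16",
    start = c(70272882L, 70271972L, 70271972L),
    end = c(70276486L, 70272796L, 70276486L),
    name = c("AARS1_novel_acceptor", "AARS1_novel_donor", "AARS1_annotated"),
    strand = "-",
    role = c("inclusion", "inclusion", "exclusion")
  )
}

#' PSI from a junction-count table
#'
#' Matches junction counts against a set of inclusion/exclusion junction
#' definitions (default: the AARS1 cryptic-exon trio) and computes PSI.
#' When several junctions flank the same segment their counts are summed by
#' default; `mode = "mean"` averages them instead (both interpretations are
#' defensible for a cassette segment flanked by two novel junctions).
#' Junctions absent from the table count 0.
#'
#' @param counts Tibble with `chrom`, `start`, `end` and `count` (e.g. from
#'   [read_star_junctions()]).
#' @param definitions Junction definition tibble with `chrom`, `start`,
#'   `end`, `role` (`"inclusion"`/`"exclusion"`).
#' @param mode `"sum"` (default) or `"mean"` aggregation within a role.
#' @return PSI in \[0,100\] (or `NA` when no reads match).
#' @export
psi_from_junctions <- function(counts, definitions = aars1_junctions(),
                               mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  agg <- if (mode == "sum") sum else mean
  hit <- dplyr::left_join(
    definitions, dplyr::select(counts, "chrom", "start", "end", "count"),
    by = c("chrom", "start", "end")
  )
  hit$count[is.na(hit$count)] <- 0
  inc <- agg(hit$count[hit$role == "inclusion"])
  exc <- agg(hit$count[hit$role == "exclusion"])
  psi(inc, exc)
}

#' Read a STAR SJ.out.tab splice-junction table
#'
#' Column mapping (STAR dialect): chromosome; first and last base of the
#' intron (1-based); strand code (0 undefined, 1 `+`, 2 `-`); splice motif
#' code; annotation flag; uniquely-mapping read count; multi-mapping read
#' count; maximum overhang. The uniquely-mapping count is exposed as
#' `count`.
#'
#' @param path TSV file in SJ.out.tab layout (no header).
#' @return Tibble with decoded columns plus `count`.
#' @export
read_star_junctions <- function(path) {
  cols <- c(
    "chrom", "start", "end", "strand_code", "motif",
    "annotated", "unique_reads", "multimap_reads", "max_overhang"
  )
  x <- readr::read_tsv(
    path,
    col_names = cols,
    col_types = readr::cols(
      chrom = readr::col_character(), .default = readr::col_integer()
    ),
    progress = FALSE
  )
  x$strand <- c("*", "+", "-")[x$strand_code + 1L]
  x$count <- x$unique_reads
  x
}

# ---- transcript models and per-read classification -------------------------

#' Transcript model of a designed construct
#'
#' The exon/intron architecture the quantifier classifies reads against:
#' exon intervals on the construct (1-based closed, ascending, gaps are
#' introns), which exons are cryptic, where the start codon sits, and the
#' full-length protein the productive isoform must yield (default: the
#' translation of the fully spliced, all-exon mRNA).
#'
#' @param sequence Construct DNA (ACGT).
#' @param exons Tibble with `start`, `end` and `role`
#'   (`"constitutive"`/`"cryptic"`).
#' @param cds_start Construct coordinate of the `A` of the start codon
#'   (must lie in an exon).
#' @param protein Expected full-length protein; derived from the all-exon
#'   mRNA when `NULL`.
#' @return A `transcript_model` object.
#' @export
transcript_model <- function(sequence, exons, cds_start, protein = NULL) {
  sequence <- toupper(sequence)
  exons <- arrange(as_tibble(exons), .data$start)
  stopifnot(all(c("start", "end", "role") %in% names(exons)))
  if (any(exons$end < exons$start) ||
    any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    abort("exons must be non-overlapping and ascending")
  }
  if (any(!exons$role %in% c("constitutive", "cryptic"))) {
    abort("exon role must be 'constitutive' or 'cryptic'")
  }
  exons$exon_id <- seq_len(nrow(exons))
  model <- structure(
    list(sequence = sequence, exons = exons, cds_start = as.integer(cds_start)),
    class = "transcript_model"
  )
  if (is.null(protein)) {
    mrna <- .splice_out(model, .model_introns(model))
    protein <- .mrna_protein(mrna, model)
  }
  model$protein <- protein
  model
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "<transcript_model> %d nt, %d exons (%d cryptic), protein %d aa\n",
    nchar(x$sequence), nrow(x$exons), sum(x$exons$role == "cryptic"),
    nchar(x$protein)
  ))
  invisible(x)
}

#' Convert a construct layout into a transcript model
#'
#' Maximal runs of non-intron regions become exons; a run containing a
#' cryptic segment is a cryptic exon. The start codon is taken as the first
#' base of the first coding region.
#'
#' @param layout A `construct_layout`.
#' @return A `transcript_model`.
#' @export
as_transcript_model <- function(layout) {
  r <- layout$regions
  is_intron <- r$role == "intron"
  grp <- cumsum(c(TRUE, diff(is_intron) != 0))
  exons <- dplyr::bind_rows(lapply(split(seq_len(nrow(r)), grp), function(ix) {
    if (is_intron[ix[1]]) {
      return(NULL)
    }
    tibble(
      start = r$start[ix[1]], end = r$end[ix[length(ix)]],
      role = if (any(r$role[ix] == "cryptic_exon")) "cryptic" else "constitutive"
    )
  }))
  cds_start <- min(r$start[r$role %in% c("cds_exon", "cryptic_exon")])
  transcript_model(layout$sequence, exons, cds_start, protein = layout$protein)
}

# introns implied by the exon chain: tibble(start, end) of removed intervals
.model_introns <- function(model) {
  e <- model$exons
  if (nrow(e) < 2) {
    return(tibble(start = integer(0), end = integer(0)))
  }
  tibble(start = e$end[-nrow(e)] + 1L, end = e$start[-1] - 1L)
}

# Remove closed intervals from the construct; returns list(mrna, junctions)
# where junctions are mRNA coordinates of the base 5' of each junction.
.splice_out <- function(model, introns) {
  v <- strsplit(model$sequence, "", fixed = TRUE)[[1]]
  n <- length(v)
  keep <- rep(TRUE, n)
  for (i in seq_len(nrow(introns))) {
    keep[introns$start[i]:introns$end[i]] <- FALSE
  }
  map <- cumsum(keep) # construct -> mRNA coordinate (for kept bases)
  junctions <- sort(map[pmax(introns$start - 1L, 1L)])
  list(
    mrna = paste(v[keep], collapse = ""),
    junctions = junctions,
    map = ifelse(keep, map, NA_integer_)
  )
}

# Translate an mRNA from the mapped start codon; returns list(protein,
# stopped, stop_end_mrna)
.mrna_translate <- function(spliced, model) {
  start <- spliced$map[model$cds_start]
  if (is.na(start)) {
    return(list(protein = "", stopped = FALSE, stop_end = NA_integer_))
  }
  mrna <- spliced$mrna
  if (nchar(mrna) - start + 1 < 3) {
    return(list(protein = "", stopped = FALSE, stop_end = NA_integer_))
  }
  rep <- translation_report(substr(mrna, start, nchar(mrna)))
  stop_end <- if (rep$stopped) start - 1L + 3L * (nchar(rep$protein) + 1L) else NA_integer_
  list(protein = rep$protein, stopped = rep$stopped, stop_end = stop_end)
}

.mrna_protein <- function(spliced, model) .mrna_translate(spliced, model)$protein

#' Classify isoforms from per-read junction chains
#'
#' Maps each read's splice junctions onto the transcript model (donor = last
#' base of an upstream exon, acceptor = first base of a downstream exon,
#' nearest-anchor matching within `tolerance` nt; ambiguous or unmatched
#' junctions send the read to category `"other"`, never dropped), derives
#' which cryptic exons the transcript includes as a bit-vector, splices the
#' construct in silico accordingly, and calls the transcript *productive*
#' when translation from the start codon yields the full design protein and
#' no premature termination codon triggers the NMD rule (a stop more than
#' `nmd_boundary` nt upstream of the final exon-exon junction).
#'
#' Every read lands in exactly one category: a cryptic-exon pattern such as
#' `"101"`, or `"other"`.
#'
#' @param reads Tibble with `read_id`, `donor`, `acceptor` (construct
#'   coordinates of each junction; zero-junction reads are unspliced) and
#'   optionally `count` (per-read weight, default 1).
#' @param model A [transcript_model()].
#' @param tolerance Junction-matching tolerance in nt.
#' @param nmd_boundary PTC-to-last-junction distance (nt) beyond which NMD
#'   is assumed.
#' @return One row per read: `read_id`, `count`, `category` (CE pattern or
#'   `"other"`), `n_ce`, `productive` (NA for `"other"`), `ptc`.
#' @export
classify_isoforms <- function(reads, model, tolerance = 3, nmd_boundary = 50) {
  stopifnot(inherits(model, "transcript_model"))
  reads <- as_tibble(reads)
  if (!"count" %in% names(reads)) reads$count <- 1L
  e <- model$exons
  n_ex <- nrow(e)
  donors <- e$end[-n_ex] # valid donor anchors (exon index 1..n-1)
  acceptors <- e$start[-1] # valid acceptor anchors (exon index 2..n)
  cryptic_ids <- e$exon_id[e$role == "cryptic"]

  ids <- unique(reads$read_id)
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    rr <- reads[reads$read_id == ids[k], , drop = FALSE]
    count <- rr$count[1]
    jn <- rr[!is.na(rr$donor) & !is.na(rr$acceptor), , drop = FALSE]
    res <- .classify_one(jn, model, donors, acceptors, cryptic_ids, tolerance, nmd_boundary)
    out[[k]] <- tibble(
      read_id = ids[k], count = count,
      category = res$category, n_ce = res$n_ce,
      productive = res$productive, ptc = res$ptc
    )
  }
  dplyr::bind_rows(out)
}

.match_anchor <- function(x, anchors, tolerance) {
  d <- abs(anchors - x)
  hits <- which(d <= tolerance)
  if (length(hits) == 0) {
    return(NA_integer_)
  }
  best <- hits[d[hits] == min(d[hits])]
  if (length(best) > 1) {
    return(NA_integer_)
  } # ambiguous
  best
}

.classify_one <- function(jn, model, donors, acceptors, cryptic_ids,
                          tolerance, nmd_boundary) {
  other <- list(category = "other", n_ce = NA_integer_, productive = NA, ptc = NA)
  n_ex <- nrow(model$exons)
  spans <- NULL
  if (nrow(jn) > 0) {
    di <- vapply(jn$donor, .match_anchor, integer(1), anchors = donors, tolerance = tolerance)
    ai <- vapply(jn$acceptor, .match_anchor, integer(1), anchors = acceptors, tolerance = tolerance)
    if (anyNA(di) || anyNA(ai)) {
      return(other)
    }
    # donor after exon di, acceptor at exon ai+1: must move forward
    if (any(ai + 1L <= di)) {
      return(other)
    }
    spans <- tibble(start = donors[di] + 1L, end = acceptors[ai] - 1L, from = di, to = ai + 1L)
    spans <- arrange(spans, .data$start)
    if (nrow(spans) > 1 && any(spans$start[-1] <= spans$end[-nrow(spans)])) {
      return(other) # overlapping junctions
    }
  } else {
    spans <- tibble(
      start = integer(0), end = integer(0),
      from = integer(0), to = integer(0)
    )
  }
  skipped <- integer(0)
  for (i in seq_len(nrow(spans))) {
    if (spans$to[i] > spans$from[i] + 1L) {
      skipped <- c(skipped, seq.int(spans$from[i] + 1L, spans$to[i] - 1L))
    }
  }
  included <- setdiff(seq_len(n_ex), skipped)
  bits <- as.integer(cryptic_ids %in% included)
  spliced <- .splice_out(model, spans[, c("start", "end")])
  tr <- .mrna_translate(spliced, model)
  full <- identical(tr$protein, model$protein) && tr$stopped
  ptc <- FALSE
  if (tr$stopped && length(spliced$junctions) > 0) {
    last_jn <- max(spliced$junctions)
    ptc <- !is.na(tr$stop_end) && (last_jn - tr$stop_end) > nmd_boundary
  }
  list(
    category = paste(bits, collapse = ""),
    n_ce = sum(bits),
    productive = full && !ptc,
    ptc = ptc
  )
}

#' Summarize isoform classes and the productive fraction
#'
#' `summarize_isoforms()` tallies read-count-weighted fractions per
#' category; fractions sum to 100% over all classified reads (including
#' `"other"`). `productive_fraction()` returns the percentage of reads whose
#' transcript is productive.
#'
#' @inheritParams classify_isoforms
#' @return `summarize_isoforms()`: tibble with `category`, `n_ce`,
#'   `productive`, `reads`, `fraction_pct`. `productive_fraction()`: a
#'   single percentage (`NA` on an empty table).
#' @export
summarize_isoforms <- function(reads, model, tolerance = 3, nmd_boundary = 50) {
  calls <- classify_isoforms(reads, model, tolerance, nmd_boundary)
  calls |>
    group_by(.data$category, .data$n_ce, .data$productive) |>
    summarise(reads = sum(.data$count), .groups = "drop") |>
    mutate(fraction_pct = 100 * .data$reads / sum(.data$reads)) |>
    arrange(dplyr::desc(.data$reads))
}

#' @rdname summarize_isoforms
#' @export
productive_fraction <- function(reads, model, tolerance = 3, nmd_boundary = 50) {
  reads <- as_tibble(reads)
  if (nrow(reads) == 0) {
    return(NA_real_)
  }
  calls <- classify_isoforms(reads, model, tolerance, nmd_boundary)
  100 * sum(calls$count[calls$productive %in% TRUE]) / sum(calls$count)
}

#' Reading-frame shift of a cassette insertion
#'
#' Inserting a cassette segment of length `L` into a CDS shifts the
#' downstream reading frame by `L mod 3`; a shift of 0 preserves frame. This
#' is the arithmetic behind frame-switch designs, where the start codon is
#' in frame with the transgene only when the cryptic exon (whose length is
#' deliberately not a multiple of 3) is included.
#'
#' @param length Insertion length(s) in nt.
#' @return Integer frame shift(s) in `0:2`.
#' @export
#' @examples
#' cassette_frame_shift(23)
cassette_frame_shift <- function(length) {
  as.integer(length) %% 3L
}
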