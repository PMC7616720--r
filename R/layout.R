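# Construct model: annotated regions, splice-site anchors, mutability, and
# the ideal per-position splicing profile the evolution engine optimizes
# toward. Coordinates are 1-based closed intervals on the construct.

.DESIGN_TYPES <- c(
  "internal_cassette_exon", "alt3prime_single_intron",
  "alt5prime_single_intron", "intron_retention"
)

#' Specify a cryptic splicing design
#'
#' Collects the user-settable parameters of a design: which kind of cryptic
#' event to build, where it sits in the CDS (nucleotide offsets from the CDS
#' start; `ce_start == ce_end` places a single intron rather than a cassette
#' exon), the ideal scores for each splice site, per-region mutation
#' behaviour, and the evolution budget.
#'
#' Ideal scores follow the design logic of TDP-43-responsive vectors:
#' constitutive sites want scores near 1, cryptic sites anywhere from weak
#' (0.01-0.1) to strong depending on the desired leakiness, competitor sites
#' may be deliberately imperfect to balance the competition, and every other
#' position wants 0 to suppress off-target splicing.
#'
#' @param design_type One of `"internal_cassette_exon"`,
#'   `"alt3prime_single_intron"`, `"alt5prime_single_intron"`,
#'   `"intron_retention"`.
#' @param ce_start,ce_end Cryptic-segment boundaries as nucleotide offsets
#'   from the CDS start: the first intron is inserted after CDS nucleotide
#'   `ce_start`; for cassette designs the cryptic exon is CDS nucleotides
#'   `ce_start+1 .. ce_end` and the second intron follows `ce_end`.
#' @param target_const_donor,target_const_acc,target_cryptic_donor,target_cryptic_acc
#'   Ideal probabilities in \[0,1\] for the anchors the design uses.
#' @param ce_score_weight Fitness weight multiplying both channels at cryptic
#'   anchors (all other positions weigh 1).
#' @param ignore_end Number of 3'-terminal nucleotides excluded from the
#'   off-target penalty (weight 0).
#' @param upstream_mut_chance,downstream_mut_chance,intron1_mut_chance,intron2_mut_chance
#'   Per-proposal probability that the region receives mutations. "Upstream"
#'   and "downstream" refer to the regions 5' and 3' of the (first) intron.
#' @param upstream_mut_n,downstream_mut_n,intron_mut_n Number of mutated
#'   units when a region fires (codons in coding regions, single nucleotides
#'   elsewhere).
#' @param cds_mut_start_trim,cds_mut_end_trim Nucleotides at the CDS start /
#'   end excluded from mutation.
#' @param min_alt_dist Minimum distance (nt) between a cryptic anchor and its
#'   competitor site (alternative-splice designs only).
#' @param alt_position Permitted competitor zone; `"in_exon"` constrains the
#'   competitor anchor to a coding exon.
#' @param alt_end_trim Nucleotides at the construct 3' end excluded from the
#'   competitor scan.
#' @param n_iterations,early_stop,lambda Evolution budget: maximum
#'   iterations, patience (iterations without strict improvement before
#'   stopping), and proposals per iteration.
#' @param frame_shift Declare that the cryptic segment intentionally shifts
#'   the downstream reading frame (its length need not be a multiple of 3).
#' @return A `design_spec` list.
#' @export
design_spec <- function(design_type,
                        ce_start, ce_end = ce_start,
                        target_const_donor = 1, target_const_acc = 1,
                        target_cryptic_donor = 0.5, target_cryptic_acc = 0.5,
                        ce_score_weight = 1,
                        ignore_end = 0,
                        upstream_mut_chance = 0.3, downstream_mut_chance = 0.3,
                        intron1_mut_chance = 0.5, intron2_mut_chance = 0.5,
                        upstream_mut_n = 1, downstream_mut_n = 1, intron_mut_n = 1,
                        cds_mut_start_trim = 0, cds_mut_end_trim = 0,
                        min_alt_dist = 40, alt_position = "in_exon",
                        alt_end_trim = 0,
                        n_iterations = 3000, early_stop = 500, lambda = 10,
                        frame_shift = FALSE) {
  design_type <- match.arg(design_type, .DESIGN_TYPES)
  fields <- mget(names(formals(design_spec)))
  fields$design_type <- design_type
  probs <- c(
    target_const_donor, target_const_acc, target_cryptic_donor,
    target_cryptic_acc, upstream_mut_chance, downstream_mut_chance,
    intron1_mut_chance, intron2_mut_chance
  )
  if (any(probs < 0 | probs > 1)) {
    abort("all target scores and mutation chances must lie in [0,1]",
      class = "splicevolver_bad_config"
    )
  }
  if (n_iterations < 1) abort("n_iterations must be >= 1", class = "splicevolver_bad_config")
  if (early_stop > n_iterations) {
    abort("early_stop cannot exceed n_iterations", class = "splicevolver_bad_config")
  }
  if (ce_end < ce_start) abort("ce_end must be >= ce_start", class = "splicevolver_bad_config")
  if (design_type == "internal_cassette_exon" && ce_end == ce_start) {
    abort("a cassette design needs ce_end > ce_start", class = "splicevolver_bad_config")
  }
  structure(fields, class = "design_spec")
}

#' Assemble a construct layout from a design and its sequences
#'
#' Builds the annotated construct the evolution engine operates on: ordered
#' regions (UTRs, coding exons, introns, cryptic segment) tiling the
#' construct, splice-site anchors with their ideal scores, the protein
#' constraint (translation of `cds`), and the concrete start sequence with
#' its mutability map (degenerate template positions are the freely mutable
#' ones; coding regions mutate synonymously per codon).
#'
#' @param spec A [design_spec()].
#' @param cds Initial coding sequence (ACGT; translates without internal
#'   stop). The protein it encodes becomes the hard constraint.
#' @param intron1,intron2 Intron templates (IUPAC; lowercase = fixed
#'   annotation). `intron2` only for cassette designs.
#' @param five_utr,three_utr Flanking templates (may be empty).
#' @param seed Seed used to concretize degenerate template positions.
#' @return A `construct_layout` object.
#' @export
build_layout <- function(spec, cds, intron1, intron2 = NULL,
                         five_utr = "", three_utr = "", seed = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  cds <- toupper(cds)
  rep_cds <- translation_report(cds)
  if (rep_cds$internal_stop) {
    abort("initial CDS contains an internal stop codon", class = "splicevolver_bad_cds")
  }
  n_cds <- nchar(cds)
  if (spec$ce_start < 1 || spec$ce_end > n_cds) {
    abort("ce coordinates fall outside the CDS", class = "splicevolver_bad_config")
  }
  if (is.null(intron1) || !nzchar(intron1)) {
    abort("an intron sequence is required", class = "splicevolver_bad_config")
  }
  cassette <- spec$design_type == "internal_cassette_exon"
  if (cassette && (is.null(intron2) || !nzchar(intron2))) {
    abort("a cassette design needs a second intron", class = "splicevolver_bad_config")
  }
  if (spec$design_type == "intron_retention" && !is.null(intron2)) {
    abort("an intron-retention design has exactly one intron",
      class = "splicevolver_bad_config"
    )
  }
  if (n_cds %% 3 != 0 && !spec$frame_shift) {
    abort("CDS length is not a multiple of 3 (declare frame_shift if intended)",
      class = "splicevolver_frame"
    )
  }

  up_cds <- substr(cds, 1, spec$ce_start)
  ce_seg <- if (cassette) substr(cds, spec$ce_start + 1, spec$ce_end) else ""
  down_cds <- substr(cds, (if (cassette) spec$ce_end else spec$ce_start) + 1, n_cds)
  if (cassette && nchar(ce_seg) %% 3 != 0 && !spec$frame_shift) {
    abort(
      "cryptic exon length is not a multiple of 3; declare frame_shift = TRUE if the frame shift is intended",
      class = "splicevolver_frame"
    )
  }

  pieces <- list(
    list(role = "five_utr", template = five_utr, mutability = "free_within_degeneracy",
         chance = spec$upstream_mut_chance, mut_n = spec$upstream_mut_n),
    list(role = "cds_exon", template = up_cds, mutability = "synonymous_only",
         chance = spec$upstream_mut_chance, mut_n = spec$upstream_mut_n),
    list(role = "intron", template = intron1, mutability = "free_within_degeneracy",
         chance = spec$intron1_mut_chance, mut_n = spec$intron_mut_n)
  )
  if (cassette) {
    pieces <- c(pieces, list(
      list(role = "cryptic_exon", template = ce_seg, mutability = "synonymous_only",
           chance = spec$downstream_mut_chance, mut_n = spec$downstream_mut_n),
      list(role = "intron", template = intron2, mutability = "free_within_degeneracy",
           chance = spec$intron2_mut_chance, mut_n = spec$intron_mut_n)
    ))
  }
  pieces <- c(pieces, list(
    list(role = "cds_exon", template = down_cds, mutability = "synonymous_only",
         chance = spec$downstream_mut_chance, mut_n = spec$downstream_mut_n),
    list(role = "three_utr", template = three_utr, mutability = "free_within_degeneracy",
         chance = spec$downstream_mut_chance, mut_n = spec$downstream_mut_n)
  ))
  pieces <- purrr::keep(pieces, ~ nzchar(.x$template))

  lens <- purrr::map_int(pieces, ~ nchar(.x$template))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  regions <- tibble(
    region_id = seq_along(pieces),
    role = purrr::map_chr(pieces, "role"),
    start = starts, end = ends,
    mutability = purrr::map_chr(pieces, "mutability"),
    mutation_chance = purrr::map_dbl(pieces, "chance"),
    mut_n = purrr::map_int(pieces, ~ as.integer(.x$mut_n)),
    template = purrr::map_chr(pieces, "template")
  )

  template <- paste(regions$template, collapse = "")
  resolved <- resolve_degenerate(template, seed = seed)

  anchors <- .design_anchors(spec, regions)
  layout <- structure(
    list(
      spec = spec,
      sequence = resolved$sequence,
      template = template,
      regions = regions,
      anchors = anchors,
      protein = rep_cds$protein,
      resolved = resolved,
      length = nchar(template)
    ),
    class = "construct_layout"
  )
  layout <- .index_layout(layout)
  validate_layout(layout)
  layout
}

# Anchor placement per design type. Donor = last exonic base; acceptor =
# first exonic base.
.design_anchors <- function(spec, regions) {
  r <- regions
  intr <- which(r$role == "intron")
  i1 <- intr[1]
  donor1 <- r$end[i1 - 1] # last base of exon upstream of intron 1
  acc1 <- r$start[i1 + 1] # first base of exon downstream of intron 1
  w_ce <- spec$ce_score_weight
  a <- switch(spec$design_type,
    internal_cassette_exon = {
      i2 <- intr[2]
      tibble(
        kind = c("constitutive_donor", "cryptic_acceptor", "cryptic_donor", "constitutive_acceptor"),
        site = c("donor", "acceptor", "donor", "acceptor"),
        position = c(donor1, acc1, r$end[i2 - 1], r$start[i2 + 1]),
        target_score = c(
          spec$target_const_donor, spec$target_cryptic_acc,
          spec$target_cryptic_donor, spec$target_const_acc
        ),
        weight = c(1, w_ce, w_ce, 1)
      )
    },
    alt3prime_single_intron = tibble(
      kind = c("constitutive_donor", "cryptic_acceptor"),
      site = c("donor", "acceptor"),
      position = c(donor1, acc1),
      target_score = c(spec$target_const_donor, spec$target_cryptic_acc),
      weight = c(1, w_ce)
    ),
    alt5prime_single_intron = tibble(
      kind = c("cryptic_donor", "constitutive_acceptor"),
      site = c("donor", "acceptor"),
      position = c(donor1, acc1),
      target_score = c(spec$target_cryptic_donor, spec$target_const_acc),
      weight = c(w_ce, 1)
    ),
    intron_retention = tibble(
      kind = c("cryptic_donor", "cryptic_acceptor"),
      site = c("donor", "acceptor"),
      position = c(donor1, acc1),
      target_score = c(spec$target_cryptic_donor, spec$target_cryptic_acc),
      weight = c(w_ce, w_ce)
    )
  )
  a$fixed <- TRUE
  a
}

# Precompute the mutation machinery: codon map for coding regions (respecting
# trims and anchor-critical dinucleotides) and free positions for
# degeneracy-mutable regions.
.index_layout <- function(layout) {
  r <- layout$regions
  coding <- r$role %in% c("cds_exon", "cryptic_exon")
  cds_pos <- unlist(purrr::map2(r$start[coding], r$end[coding], seq.int))
  n_codon <- length(cds_pos) %/% 3
  codon_pos <- matrix(cds_pos[seq_len(3 * n_codon)], nrow = 3)
  # critical positions: invariant GT/AG of every anchor must never change
  crit <- unlist(purrr::pmap(layout$anchors, function(site, position, ...) {
    if (site == "donor") c(position + 1L, position + 2L) else c(position - 2L, position - 1L)
  }))
  spec <- layout$spec
  trim_lo <- spec$cds_mut_start_trim # first trim_lo CDS nt immutable
  trim_hi <- spec$cds_mut_end_trim # last trim_hi CDS nt immutable
  n_cds_nt <- length(cds_pos)
  cds_rank <- seq_len(3 * n_codon) # rank within CDS of each mapped position
  in_trim <- cds_rank <= trim_lo | cds_rank > (n_cds_nt - trim_hi)
  trim_mat <- matrix(in_trim, nrow = 3)
  region_of <- integer(layout$length)
  for (i in seq_len(nrow(r))) region_of[r$start[i]:r$end[i]] <- r$region_id[i]
  codon_region <- region_of[codon_pos[1, ]]
  aa <- strsplit(layout$protein, "")[[1]]
  mutable_codon <- !apply(trim_mat, 2, any) &
    !apply(matrix(codon_pos %in% crit, nrow = 3), 2, any) &
    seq_len(n_codon) <= length(aa) # never touch the stop codon
  # degeneracy-mutable free positions, excluding anchor-critical ones
  free <- setdiff(layout$resolved$free, crit)
  free_region <- region_of[free]
  free_ok <- r$mutability[free_region] == "free_within_degeneracy"
  allowed_int <- lapply(layout$resolved$allowed[free], function(b) match(b, .BASES))
  layout$index <- list(
    codon_pos = codon_pos,
    codon_region = codon_region,
    mutable_codon = which(mutable_codon),
    free_pos = free[free_ok],
    free_region = free_region[free_ok],
    free_allowed = allowed_int[free_ok],
    region_of = region_of,
    crit = crit
  )
  layout
}

#' Validate a construct layout
#'
#' Checks the structural invariants: regions tile the construct in order
#' without overlap, coding-segment lengths respect the frame rule, anchors
#' sit on GT/AG dinucleotides of the current sequence, target scores lie in
#' \[0,1\], and the CDS still translates to the protein constraint.
#'
#' @param layout A `construct_layout`.
#' @return The layout, invisibly; errors describe the violated invariant.
#' @export
validate_layout <- function(layout) {
  r <- layout$regions
  if (any(r$start != c(1L, head(r$end, -1) + 1L))) {
    abort("regions do not tile the construct in order", class = "splicevolver_bad_layout")
  }
  a <- layout$anchors
  if (any(a$target_score < 0 | a$target_score > 1)) {
    abort("anchor target scores must lie in [0,1]", class = "splicevolver_bad_layout")
  }
  v <- .seq2int(layout$sequence)
  for (i in seq_len(nrow(a))) {
    p <- a$position[i]
    ok <- if (a$site[i] == "donor") {
      p + 2 <= layout$length && v[p + 1] == 3L && v[p + 2] == 4L
    } else {
      p - 2 >= 1 && v[p - 2] == 1L && v[p - 1] == 3L
    }
    if (!ok && isTRUE(a$fixed[i])) {
      abort(sprintf(
        "anchor '%s' at position %d lacks its invariant %s dinucleotide",
        a$kind[i], p, if (a$site[i] == "donor") "GT" else "AG"
      ), class = "splicevolver_bad_layout")
    }
  }
  if (.layout_protein(layout, v) != layout$protein) {
    abort("construct no longer translates to the protein constraint",
      class = "splicevolver_bad_layout"
    )
  }
  invisible(layout)
}

# Translation of the coding positions of an integer sequence under a layout.
.layout_protein <- function(layout, v) {
  cp <- layout$index$codon_pos
  aa <- .CODON_AA[.codon_index(v[cp[1, ]], v[cp[2, ]], v[cp[3, ]])]
  stop_at <- match("*", aa)
  if (!is.na(stop_at)) aa <- aa[seq_len(stop_at - 1)]
  paste(aa, collapse = "")
}

#' Ideal splicing profile of a layout
#'
#' Zero desired score everywhere except the anchors (off-target
#' suppression), per-position weights of 1 except `ce_score_weight` at
#' cryptic anchors, and weight 0 across the final `ignore_end` nucleotides.
#'
#' @param layout A `construct_layout`.
#' @return Tibble with `position`, `donor_target`, `acceptor_target`,
#'   `donor_weight`, `acceptor_weight`.
#' @export
ideal_profile <- function(layout) {
  tp <- .target_vectors(layout)
  tibble(
    position = seq_len(layout$length),
    donor_target = tp$donor_target, acceptor_target = tp$acceptor_target,
    donor_weight = tp$donor_weight, acceptor_weight = tp$acceptor_weight
  )
}

.target_vectors <- function(layout) {
  n <- layout$length
  dt <- numeric(n); at <- numeric(n)
  dw <- rep(1, n); aw <- rep(1, n)
  a <- layout$anchors
  for (i in seq_len(nrow(a))) {
    if (a$site[i] == "donor") {
      dt[a$position[i]] <- a$target_score[i]
      dw[a$position[i]] <- a$weight[i]
    } else {
      at[a$position[i]] <- a$target_score[i]
      aw[a$position[i]] <- a$weight[i]
    }
  }
  ie <- layout$spec$ignore_end
  if (ie > 0) {
    zone <- seq.int(max(1L, n - ie + 1L), n)
    dw[zone] <- 0; aw[zone] <- 0
  }
  list(donor_target = dt, acceptor_target = at, donor_weight = dw, acceptor_weight = aw)
}

#' @export
print.construct_layout <- function(x, ...) {
  cat(sprintf(
    "<construct_layout> %s, %d nt, %d regions, %d anchors, protein %d aa\n",
    x$spec$design_type, x$length, nrow(x$regions), nrow(x$anchors),
    nchar(x$protein)
  ))
  print(dplyr::select(x$regions, -"template"))
  print(x$anchors)
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

#' Serialize a layout to JSON (and back)
#'
#' The JSON form captures the template, current sequence, regions, anchors
#' and design spec; `layout_from_json()` rebuilds the full object (indices
#' are recomputed), giving a round trip that preserves all fields.
#'
#' @param layout A `construct_layout`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @export
layout_to_json <- function(layout, path = NULL) {
  obj <- list(
    spec = unclass(layout$spec),
    template = layout$template,
    sequence = layout$sequence,
    regions = dplyr::select(layout$regions, -"template"),
    anchors = layout$anchors,
    protein = layout$protein
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) {
    return(js)
  }
  writeLines(js, path)
  invisible(path)
}

#' @rdname layout_to_json
#' @param json JSON string or file path produced by `layout_to_json()`.
#' @export
layout_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  spec <- do.call(design_spec, obj$spec)
  regions <- as_tibble(obj$regions)
  # carve region templates back out of the full template
  regions$template <- substring(obj$template, regions$start, regions$end)
  resolved <- resolve_degenerate(obj$template)
  resolved$sequence <- obj$sequence # keep the serialized concrete state
  layout <- structure(
    list(
      spec = spec, sequence = obj$sequence, template = obj$template,
      regions = regions, anchors = as_tibble(obj$anchors),
      protein = obj$protein, resolved = resolved, length = nchar(obj$template)
    ),
    class = "construct_layout"
  )
  layout <- .index_layout(layout)
  validate_layout(layout)
  layout
}

#' Export layout features as BED
#'
#' Writes regions and anchors as BED6 lines on the construct (named
#' reference `construct`), for genome-browser-style inspection of a design.
#'
#' @param layout A `construct_layout`.
#' @param path Output file.
#' @export
layout_to_bed <- function(layout, path) {
  feats <- dplyr::bind_rows(
    tibble(
      start0 = layout$regions$start - 1L, end0 = layout$regions$end,
      name = layout$regions$role
    ),
    tibble(
      start0 = layout$anchors$position - 1L, end0 = layout$anchors$position,
      name = layout$anchors$kind
    )
  )
  lines <- sprintf("construct\t%d\t%d\t%s\t0\t+", feats$start0, feats$end0, feats$name)
  writeLines(lines, path)
  invisible(path)
}
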