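# Deterministic toy design bundles: small constructs with planted,
# surrogate-scorable splice sites and junction tables with known ground
# truth, so the whole pipeline is testable offline.

# toy protein helpers ---------------------------------------------------------

# A short random CDS with Gln codons planted where exons will end (CAG is
# synonymously reachable there, so the -3..-1 exonic context of a planted
# donor can be recoded to the surrogate donor consensus).
.toy_cds <- function(n_codons = 24, seed = 1, gln_at = integer(0)) {
  .with_seed(seed, {
    sense <- names(.GENETIC_CODE)[.GENETIC_CODE != "*" & .GENETIC_CODE != "M"]
    codons <- c("ATG", sample(sense, n_codons - 2, replace = TRUE), "TAA")
    codons[setdiff(gln_at, c(1L, n_codons))] <- "CAA"
    paste(codons, collapse = "")
  })
}

#' Generate a deterministic toy design bundle
#'
#' Small, fully offline fixtures exercising every pipeline stage: evolvable
#' toy constructs for each design type (CDS <= 300 nt with planted
#' surrogate-scorable sites and degenerate intron positions for the engine
#' to work with), a seven-exon multi-cryptic-exon transcript model with a
#' planted read population, and an AARS1-style junction-count table with
#' known PSI. Ground truth is emitted alongside the inputs; the same seed
#' always returns the identical bundle.
#'
#' @param kind One of `"cassette"`, `"alt3"`, `"alt5"`, `"retention"`,
#'   `"multi_ce"`, `"junction_table"`.
#' @param seed Integer seed.
#' @return A list whose elements depend on `kind`; always contains `truth`,
#'   a list of planted ground-truth values.
#' @export
#' @examples
#' fx <- generate_fixture("junction_table")
#' fx$truth$psi
generate_fixture <- function(kind = c(
                               "cassette", "alt3", "alt5", "retention",
                               "multi_ce", "junction_table"
                             ),
                             seed = 1) {
  kind <- match.arg(kind)
  switch(kind,
    cassette = .fx_cassette(seed),
    alt3 = .fx_alt3(seed),
    alt5 = .fx_alt5(seed),
    retention = .fx_retention(seed),
    multi_ce = .fx_multi_ce(seed),
    junction_table = .fx_junction_table(seed)
  )
}

# evolvable intron template: fixed GTaag donor consensus, free Ns, a UG-rich
# TDP-43 binding stretch, then a fully-free branch/polypyrimidine stretch in
# front of the fixed cAG acceptor (so consensus-grade acceptors are reachable)
.toy_intron <- function(n_free = 8) {
  paste0(
    "GTaag", strrep("N", n_free),
    build_ug_region(12, "pure_repeat"),
    strrep("N", 19), "cAG"
  )
}

.fx_cassette <- function(seed) {
  cds <- .toy_cds(26, seed = seed, gln_at = c(12L, 19L))
  spec <- design_spec(
    "internal_cassette_exon",
    ce_start = 36, ce_end = 57,
    target_const_donor = 1, target_const_acc = 1,
    target_cryptic_donor = 0.5, target_cryptic_acc = 0.5,
    ce_score_weight = 3,
    upstream_mut_chance = 0.3, downstream_mut_chance = 0.3,
    intron1_mut_chance = 0.5, intron2_mut_chance = 0.5,
    n_iterations = 300, early_stop = 300, lambda = 10,
    frame_shift = nchar(cds) %% 3 != 0 || (57 - 36) %% 3 != 0
  )
  layout <- build_layout(
    spec, cds,
    intron1 = .toy_intron(), intron2 = .toy_intron(),
    five_utr = "CTTCAAC", three_utr = "CATCATCATTAAT",
    seed = seed
  )
  list(kind = "cassette", layout = layout, truth = list(protein = layout$protein))
}

.fx_alt3 <- function(seed, target_cryptic_acc = 0.75) {
  cds <- .toy_cds(30, seed = seed, gln_at = 12L)
  spec <- design_spec(
    "alt3prime_single_intron",
    ce_start = 36, ce_end = 36,
    target_const_donor = 1, target_const_acc = 0.5,
    target_cryptic_acc = target_cryptic_acc,
    ce_score_weight = 3, min_alt_dist = 12,
    n_iterations = 300, early_stop = 300, lambda = 10
  )
  layout <- build_layout(
    spec, cds,
    intron1 = .toy_intron(),
    five_utr = "CTTCAAC", three_utr = "CATCATCATTAAT",
    seed = seed
  )
  list(kind = "alt3", layout = layout, truth = list(protein = layout$protein))
}

.fx_alt5 <- function(seed) {
  cds <- .toy_cds(30, seed = seed, gln_at = 15L)
  spec <- design_spec(
    "alt5prime_single_intron",
    ce_start = 45, ce_end = 45,
    target_const_acc = 1, target_cryptic_donor = 0.5,
    ce_score_weight = 3, min_alt_dist = 12,
    n_iterations = 300, early_stop = 300, lambda = 10
  )
  layout <- build_layout(
    spec, cds,
    intron1 = .toy_intron(),
    five_utr = "CTTCAAC", three_utr = "CATCATCATTAAT",
    seed = seed
  )
  list(kind = "alt5", layout = layout, truth = list(protein = layout$protein))
}

.fx_retention <- function(seed) {
  cds <- .toy_cds(24, seed = seed, gln_at = 12L)
  spec <- design_spec(
    "intron_retention",
    ce_start = 36, ce_end = 36,
    target_cryptic_donor = 0.1, target_cryptic_acc = 0.1,
    ce_score_weight = 3,
    n_iterations = 300, early_stop = 300, lambda = 10
  )
  layout <- build_layout(
    spec, cds,
    intron1 = .toy_intron(),
    five_utr = "CTTCAAC", three_utr = "CATCATCATTAAT",
    seed = seed
  )
  list(kind = "retention", layout = layout, truth = list(protein = layout$protein))
}

# Seven-exon split-enzyme construct: exons 2, 4 and 6 are cryptic, each
# 22 nt (frame shift 1), so skipping any one of them breaks the frame while
# the full seven-exon transcript encodes the complete protein.
.fx_multi_ce <- function(seed) {
  .with_seed(seed, {
    # exon coding lengths (nt): constitutive 45,33,33,45 and cryptic 22,22,22
    ex_len <- c(45L, 22L, 33L, 22L, 33L, 22L, 45L)
    roles <- c(
      "constitutive", "cryptic", "constitutive", "cryptic",
      "constitutive", "cryptic", "constitutive"
    )
    total <- sum(ex_len) # 222, divisible by 3
    n_codons <- total / 3L
    sense <- names(.GENETIC_CODE)[!.GENETIC_CODE %in% c("*", "M")]
    # avoid stop codons in any local frame by excluding A-rich stop makers
    safe <- sense[!grepl("TA|AG$", sense)]
    cds <- paste(c("ATG", sample(safe, n_codons - 2, replace = TRUE), "TAA"),
      collapse = ""
    )
    intron <- function(i) {
      paste0("GTAAGT", strrep("C", 6), build_ug_region(10, "pure_repeat"), "TTTTTCCTTCAG")
    }
    pieces <- character(0)
    pos <- 0L
    exons <- tibble(start = integer(0), end = integer(0), role = character(0))
    cds_off <- 0L
    for (i in seq_along(ex_len)) {
      seg <- substr(cds, cds_off + 1L, cds_off + ex_len[i])
      cds_off <- cds_off + ex_len[i]
      pieces <- c(pieces, seg)
      exons <- dplyr::bind_rows(exons, tibble(
        start = pos + 1L, end = pos + ex_len[i], role = roles[i]
      ))
      pos <- pos + ex_len[i]
      if (i < length(ex_len)) {
        intr <- intron(i)
        pieces <- c(pieces, intr)
        pos <- pos + nchar(intr)
      }
    }
    sequence <- paste(pieces, collapse = "")
    model <- transcript_model(sequence, exons, cds_start = 1L)

    # planted read population: CE-inclusion patterns with known fractions
    plan <- tibble(
      pattern = c("111", "000", "100", "110", "011"),
      n = c(10L, 60L, 15L, 10L, 5L)
    )
    reads <- dplyr::bind_rows(purrr::pmap(plan, function(pattern, n) {
      jn <- .reads_for_pattern(model, pattern)
      dplyr::bind_rows(lapply(seq_len(n), function(k) {
        dplyr::mutate(jn, read_id = paste0(pattern, "_", k))
      }))
    }))
    truth <- list(
      fractions = setNames(100 * plan$n / sum(plan$n), plan$pattern),
      three_ce_pct = 100 * plan$n[plan$pattern == "111"] / sum(plan$n),
      productive_pct = 100 * plan$n[plan$pattern == "111"] / sum(plan$n),
      n_reads = sum(plan$n)
    )
    list(kind = "multi_ce", model = model, reads = reads, truth = truth)
  })
}

# junction chain of the transcript including exactly the cryptic exons
# flagged '1' in pattern (constitutive exons always included)
.reads_for_pattern <- function(model, pattern) {
  e <- model$exons
  bits <- as.integer(strsplit(pattern, "", fixed = TRUE)[[1]])
  cry <- e$exon_id[e$role == "cryptic"]
  included <- sort(c(e$exon_id[e$role == "constitutive"], cry[bits == 1]))
  tibble(
    donor = e$end[included[-length(included)]],
    acceptor = e$start[included[-1]]
  )
}

.fx_junction_table <- function(seed) {
  defs <- aars1_junctions()
  counts <- tibble(
    chrom = defs$chrom, start = defs$start, end = defs$end,
    count = c(75L, 75L, 50L)
  )
  truth <- list(
    psi = psi(75 + 75, 50), # sum mode over the two novel junctions
    psi_mean = psi(75, 50)
  )
  list(kind = "junction_table", counts = counts, definitions = defs, truth = truth)
}

#' Synthetic frame-switch minigene
#'
#' A transcript model emulating the frame-switch reporter logic: an
#' upstream start codon, a cryptic exon whose length (23 nt, i.e. 22 plus
#' one frame-shifting adenosine) is not a multiple of 3, and a downstream
#' transgene followed by a constitutively spliced 3' intron whose exon
#' junction triggers NMD when a premature stop is met. Only when the
#' cryptic exon is included is the start codon in frame with the transgene;
#' exclusion shifts the frame, hits an early stop and the transcript is
#' degraded.
#'
#' @param seed Integer seed (fixture is fully deterministic; kept for
#'   interface symmetry).
#' @return List with `model` (a [transcript_model()]), `reads_included`,
#'   `reads_excluded` (single-read junction tables) and `truth`.
#' @export
v1_minigene <- function(seed = 1) {
  # exon1: 9 nt 5'UTR + ATG + 6 nt of upstream peptide (CDS offset so far: 9)
  exon1 <- "CTTCAACCAATGGCTGCA"
  # cryptic exon: 23 nt (22 + extra A), no stop in the in-frame reading
  ce <- "AGCTGCTGCTGCAGCAGCAGCAA"
  stopifnot(nchar(ce) == 23)
  # transgene exon: with CE included, frame entering exon3 is (9 + 23) %% 3 = 2
  # -> one base completes the codon, then the transgene ORF with its stop
  # 6 nt before the exon end (escapes NMD). With the CE excluded the exon is
  # read in the shifted frame, whose second codon (TGA) is a PTC far enough
  # upstream of the final exon junction to trigger NMD.
  exon3 <- paste0(
    "A", "GCTGAG",
    "GCTGGAGCTGGTGCTGGAGCTGGTGCTGGAGCTGGTGCTGGAGCT",
    "TAA", "GATTAC"
  )
  # short 3' exon after a constitutive intron: its junction sits downstream
  # of any PTC produced by the frame-shifted (CE-excluded) transcript
  exon4 <- "CTCCTCCTTGCA"
  intr1 <- paste0("GTAAGT", build_ug_region(12, "pure_repeat"), "TTCTTTCCTCAG")
  intr2 <- paste0("GTAAGT", build_ug_region(12, "pure_repeat"), "CTTTTTCCACAG")
  # constitutive 3' intron: long enough that a PTC upstream of it is > 50 nt
  # from the final junction
  intr3 <- paste0("GTAAGT", strrep("CT", 8), "TTCTTTCCTCAG")
  sequence <- paste0(exon1, intr1, ce, intr2, exon3, intr3, exon4)
  l1 <- nchar(exon1); i1 <- nchar(intr1); lce <- nchar(ce)
  i2 <- nchar(intr2); l3 <- nchar(exon3); i3 <- nchar(intr3)
  exons <- tibble(
    start = c(
      1L, l1 + i1 + 1L, l1 + i1 + lce + i2 + 1L,
      l1 + i1 + lce + i2 + l3 + i3 + 1L
    ),
    end = c(
      l1, l1 + i1 + lce, l1 + i1 + lce + i2 + l3,
      l1 + i1 + lce + i2 + l3 + i3 + nchar(exon4)
    ),
    role = c("constitutive", "cryptic", "constitutive", "constitutive")
  )
  model <- transcript_model(sequence, exons, cds_start = 10L)
  reads_included <- tibble(
    read_id = "inc",
    donor = c(exons$end[1], exons$end[2], exons$end[3]),
    acceptor = c(exons$start[2], exons$start[3], exons$start[4])
  )
  reads_excluded <- tibble(
    read_id = "exc",
    donor = c(exons$end[1], exons$end[3]),
    acceptor = c(exons$start[3], exons$start[4])
  )
  list(
    model = model,
    reads_included = reads_included,
    reads_excluded = reads_excluded,
    truth = list(
      ce_length = nchar(ce),
      frame_shift = cassette_frame_shift(nchar(ce)),
      included_productive = TRUE,
      excluded_productive = FALSE
    )
  )
}
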