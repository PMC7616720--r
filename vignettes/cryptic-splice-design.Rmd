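---
title: "Designing TDP-43-regulated cryptic splicing events by in silico directed evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing TDP-43-regulated cryptic splicing events by in silico directed evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicevolver)
```

## The problem

Loss of nuclear TDP-43 function (TDP-LOF) derepresses *cryptic exons* —
exonic segments that are normally silenced by TDP-43 bound to UG-rich RNA
near their splice sites. Because cryptic splicing is a specific molecular
signature of the disease state, a transgene whose expression *requires* a
cryptic splicing event is switched on exactly when and where TDP-LOF occurs.
splicevolver designs such constructs: it embeds a de novo cryptic event
(cassette exon, alternative 5'/3' splice site, or a retained intron) inside
a protein-coding sequence using only synonymous codon changes, and provides
the quantification used to validate the designs from sequencing data.

## The optimization model

A design is a `construct_layout`: ordered regions (5'UTR, coding exons,
introns, an optional cryptic segment, 3'UTR) tiling the construct, plus
*splice-site anchors* — positions carrying an ideal donor or acceptor score.
The ideal profile assigns:

* scores near 1 to constitutive sites (they must always splice),
* a user-chosen score to cryptic sites — low (0.01–0.1) for tight
  off-state repression through very strong (near 1) for maximal on-state
  splicing,
* a deliberately imperfect score to a competitor site in alternative-splice
  designs, so the competition between the two sites is balanced,
* 0 everywhere else, suppressing off-target splicing,

with per-position weights of 1 except at cryptic anchors, which carry
`ce_score_weight`, and 0 across the final `ignore_end` nucleotides (vector
backbone sequence whose predicted splicing is not under design control).

Given a predictor that returns per-nucleotide donor and acceptor
probabilities, the fitness of a candidate sequence is the negative sum of
weighted absolute differences between predicted and ideal scores at every
position and channel. Fitness is 0 exactly when the prediction matches the
ideal profile at every weighted position, and negative otherwise.

The search is a (1+λ) elitist directed evolution. Each iteration draws λ
(default 10) mutated proposals from the incumbent: every mutable region
fires independently with its `mutation_chance`, and a firing region mutates
`mut_n` units — a whole codon replaced by a *different synonymous* codon in
coding regions, or a single nucleotide resampled within its IUPAC degeneracy
set elsewhere. The best of parent and proposals is retained; on exact
fitness ties the parent wins (minimizing neutral drift), then the
lexicographically smallest sequence, so runs are deterministic given a seed.
The run stops after `n_iterations` or once `early_stop` consecutive
iterations bring no strict improvement (beyond 1e-9, to keep the patience
counter immune to floating-point noise).

### What "mutable" means

Design templates are mixed-case IUPAC strings, and the package reads them
the way design sequences are conventionally written:

* lowercase letters are fixed annotation (splice-site consensus such as
  `GTaag` and `cAG`) and are never mutated, only case-folded for scoring;
* degenerate codes (`N`, `R`, ...) mark the evolvable positions, each
  restricted to its own expansion set;
* literal uppercase letters outside coding regions are fixed — a
  `free_within_degeneracy` region varies exactly within the degeneracy the
  designer wrote into it (a literal base has a singleton set);
* coding regions mutate synonymously per codon, excluding the
  `cds_mut_start_trim`/`cds_mut_end_trim` ranges, stop codons, and any codon
  carrying an anchor's invariant GT/AG dinucleotide.

Consequently the protein constraint and every anchor dinucleotide hold in
every candidate by construction, not merely by penalty — both are also
revalidated in the test suite on every retained generation.

The "upstream"/"downstream" mutation flags are interpreted as the regions 5'
and 3' of the (first) intron respectively, and `*_mut_n` counts mutated
units per firing region: single nucleotides in degeneracy regions, codons in
coding regions (a synonymous codon swap may change up to three adjacent
nucleotides — codons are the natural mutation quantum under a protein
constraint).

## The splice predictor

The engine is predictor-agnostic: anything returning per-nucleotide donor
and acceptor probabilities can drive it (`external_predictor()` wraps an
out-of-process deep-learning model in that contract and always rescores the
full sequence). The bundled surrogate is a deterministic position-weight
scorer designed to respond to the same sequence features a deep splice model
rewards, while being fast and exactly reproducible offline:

* **Donor** (9-mer, `[-3,+6]` around the exon|intron boundary): hard GT
  gate at `+1,+2`, log2-odds of the remaining seven positions against a
  uniform background, logistic squash (`k = 1`, midpoint 4.2 bits). The
  score sits on the **last exonic base**.
* **Acceptor** (23-mer: 18-nt polypyrimidine tract, one spacer, a
  pyrimidine-preferring position, the invariant AG, one exonic base): hard
  AG gate, a PPT term strictly increasing in pyrimidine fraction (9 bits at
  saturation), two positional log-odds terms, logistic squash (`k = 1.4`,
  midpoint 8.5 bits). The score sits on the **first exonic base**.

These conventions are applied identically to ideal profiles and
predictions, which is all that matters for the fitness; parameters are
pinned in a versioned JSON (`surrogate_params()`), so tests and replays
reference an explicit surrogate version. Two calibration choices deserve
mention. First, consensus sites score above 0.95, so "close to 100%" ideal
targets are attainable. Second, A and G are co-maximal at the last exonic
donor position; natural donors prefer G there, but the tie makes the strong
`CAAGTAAG` donor motif used in published designs a surrogate consensus,
which keeps rational seeding and surrogate scoring consistent with each
other.

Because the surrogate's reachable scores at a given anchor form a discrete
set (the exonic context moves in synonymous-codon steps), a site evolved
toward an intermediate target such as 0.75 settles on the nearest reachable
level, which may sit a few hundredths away — the package's own acceptance
checks therefore treat intermediate targets directionally (closer after
evolution than before) and only near-1 targets absolutely.

## Rational-design helpers

Evolution is composed with three deterministic generators:

* `place_competitor()` scans every position in the permitted zone (default:
  inside the coding exon, at least `min_alt_dist` nt from the cryptic
  anchor, outside trims), enumerates the synonymous codon assignments that
  create the invariant AG (or GT), recodes the upstream window toward
  pyrimidines for acceptors, and keeps the best-scoring feasible position
  (ties to the 5'-most, making the scan order irrelevant).
* `design_ppt()` / `pyrimidine_maximize()` recode a coding window to the
  per-codon pyrimidine maximum — an exhaustively verifiable property — with
  ties broken toward T (U-rich tracts are the canonical PPT), then
  alphabetically. The operation is idempotent.
* `build_ug_region()` produces the UG-rich TDP-43 binding elements:
  uninterrupted (UG)n, repeats interrupted by AA after every `max_run`
  dimers (the same interruption that makes long repeats synthesizable, and
  the way short repeats limit binding affinity), or UG-rich sequence
  without extended repeats.

UG content is measured by `ug_density()`: TG dimer starts at any phase in a
centered window, divided by the `window - 1` dimer starts the window holds.
Under this normalization a perfect (TG)n run scores about 0.5 (alternate
dimer starts are GT), so the style floors are set at 0.45 / 0.30 / 0.20 for
pure, interrupted and rich styles respectively. The window size is a free
parameter (default 20 nt), as no canonical choice exists.

## Quantification

`psi()` implements percent-spliced-in, `inclusion / (inclusion +
exclusion) × 100`, returning `NA` (never 0) when both counts are zero.
`aars1_junctions()` ships the reference junction trio used to quantify the
human *AARS1* cryptic exon from STAR `SJ.out.tab` tables (both novel
junctions count as inclusion — summed by default, with a documented `mean`
alternative since either aggregation of two junctions flanking one cassette
is defensible).

`classify_isoforms()` consumes per-read junction chains (long-read style),
matches each junction to the transcript model's exon boundaries within a
±3 nt tolerance (long-read alignments wobble; ambiguous or unmatched
junctions classify the read as `"other"`, never silently dropped), derives
the cryptic-exon inclusion bit-vector, splices the construct in silico and
calls the transcript productive when translation from the start codon
yields the full design protein and no premature termination codon lies more
than 50 nt upstream of the final exon-exon junction (the standard NMD
boundary rule; the threshold is exposed).

The frame-switch construct logic follows from plain arithmetic: a cassette
of length L shifts the downstream frame by L mod 3, so a cryptic exon whose
length is deliberately not a multiple of 3 puts an upstream start codon in
frame with the transgene only upon inclusion; exclusion frame-shifts into a
premature stop upstream of a constitutive 3' intron's junction and the
transcript is degraded. `v1_minigene()` builds a synthetic minigene
exercising exactly this logic end to end.

## What the toy fixtures emulate — and what they do not

`generate_fixture()` builds small designs (coding sequences under 300 nt)
whose intron templates plant fixed `GTaag`/`cAG` consensus, a UG-rich
element, and enough degenerate positions that consensus-grade sites are
reachable; Gln codons are planted at exon ends so donor contexts can be
recoded to consensus synonymously. The multi-cryptic-exon fixture is a
seven-exon split-enzyme construct with cryptic exons 2, 4 and 6 (each
22 nt, so skipping any one breaks the frame) and a planted read population
with known isoform fractions.

Passing tests on these fixtures demonstrate the algorithmic guarantees —
elitism, protein conservation, seeded reproducibility, exact quantifier
recoveries — under a predictor whose fitness landscape is far smoother and
lower-dimensional than a deep model's. They do not demonstrate that evolved
sequences splice as predicted in cells, nor that the surrogate ranks real
sequences as a deep model would; for real design work the external-predictor
adapter exists precisely so the same engine can run against a deep model.

## Numerical and interface choices

* Coordinates are 1-based closed intervals, the R/Bioconductor convention;
  command-line integers from published design commands are nucleotide
  offsets from the CDS start and are consumed unchanged (an intron inserted
  "after CDS nucleotide 216" means the same thing in both conventions).
* Problem sizes in the package's own checks: the full-budget evolution
  check runs 3000 iterations with λ = 10 on a ~190-nt cassette toy;
  target-attainment runs 1500 iterations on the alternative-3' toy; the
  polypyrimidine check recodes 1000 random windows against per-codon
  enumeration.
* Sequence-valued command flags absorb consecutive non-flag tokens, so
  commands whose long sequences were line-wrapped in print parse
  unchanged; repeated flags keep the last value.
* `--aa generate_it` derives the protein constraint by translating the
  supplied initial CDS. `-a` (predictor scan window) is accepted and stored
  in the run manifest; the surrogate derives its window sizes from its own
  parameters.
* Degenerate template positions are concretized uniformly at random from
  their expansion sets under the run seed; all randomness flows from one
  seeded stream, and the JSON run manifest (seed, config, surrogate
  version) replays a surrogate run bit-identically.

## Known limitations

The surrogate scores donors and acceptors independently and knows nothing
about branch points beyond the PPT term, nothing about RNA structure, and
nothing about exon-definition interactions between sites. Codon-usage
optimization for expression is out of scope (the engine optimizes splicing,
not codon adaptation). The quantifier consumes junction tables, not
alignments: basecalling, alignment and junction extraction happen upstream.
AAV packaging limits are reported only as construct length.
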