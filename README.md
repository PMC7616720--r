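# splicevolver

In silico directed evolution of TDP-43-regulated cryptic splicing events
inside protein-coding sequences — plus the splicing quantification needed to
validate the designs.

## The problem

Loss of nuclear TDP-43 function (TDP-LOF) is a molecular hallmark of ALS
and related neurodegeneration: TDP-43 normally binds UG-rich RNA next to
*cryptic exons* and keeps them out of mRNA. A transgene engineered so that
its expression **requires** a cryptic splicing event therefore switches on
specifically where the disease process is active. splicevolver is for
researchers building such reporters and therapeutic vectors: it designs de
novo cryptic events (cassette exons, alternative 5'/3' splice sites,
intron retention) under a hard protein constraint, and quantifies splicing
outcomes from junction counts.

## The algorithm

A design couples three ingredients:

1. **An ideal splicing profile.** Per position and channel
   (donor/acceptor): constitutive splice sites want scores near 1, cryptic
   sites a user-chosen score `s ∈ [0,1]` (weak for tight repression, strong
   for maximal on-state splicing), competitor sites a deliberately
   "balanced" score, and every other position 0 (off-target suppression),
   with weight `w_CE` at cryptic anchors and weight 0 over an ignored 3'
   tail.

2. **A fitness.** For predicted profile `p` and ideal profile `t` with
   weights `w`,

   `F(seq) = − Σ_i Σ_c∈{donor,acceptor} w_c(i) · | t_c(i) − p_c(i) |`,

   so `F ≤ 0` with equality exactly at a perfect match. Predictions come
   from a pluggable per-nucleotide splice predictor — a deterministic
   position-weight surrogate ships with the package; an adapter contract
   (`external_predictor()`) plugs in a deep-learning model at runtime.

3. **A (1+λ) elitist search** over constrained mutations: coding regions
   mutate only by whole-codon synonymous replacement (the protein is
   invariant by construction), non-coding regions only within the IUPAC
   degeneracy written into the design template (`N`, `R`, ...; lowercase =
   fixed annotation such as `GTaag`). The best of parent ∪ λ proposals is
   retained; ties prefer the parent, then the lexicographically smallest
   sequence, so a run is fully reproducible from its seed.

Rational-design helpers compose with the search: competitor splice-site
placement (`place_competitor()`), synonymous polypyrimidine-tract recoding
(`design_ppt()`), and UG-rich TDP-43 binding-region construction
(`build_ug_region()`).

The quantifier implements `PSI = inclusion/(inclusion+exclusion) × 100`
from junction-count tables (STAR `SJ.out.tab` dialect), per-read
multi-cryptic-exon isoform classification from long-read junction chains,
and productive-transcript calling with reading-frame arithmetic and the
50-nt NMD boundary rule.

## Worked example

Evolve a toy alternative-3' design (planted constitutive donor with ideal
score 1.0, cryptic acceptor with ideal score 0.75) with the surrogate
predictor:

```r
library(splicevolver)

fx <- generate_fixture("alt3", seed = 1)
fx$layout
#> <construct_layout> alt3prime_single_intron, 157 nt, 5 regions, 2 anchors, protein 29 aa

ev <- evolve_construct(fx$layout, n_iterations = 1500, early_stop = 1500,
                       lambda = 10, seed = 1)
glance(ev)
#> # A tibble: 1 × 7
#>   n_generations initial_fitness best_fitness converged lambda  seed predictor
#>           <int>           <dbl>        <dbl> <lgl>      <dbl> <dbl> <chr>
#> 1          1500           -3.10       -0.193 FALSE         10     1 surrogate
```

The fitness rose from −3.10 (the random start's predicted profile is far
from ideal) to −0.19. The planted anchors reached their targets:

```r
#   kind               position target_score evolved_score
#> 1 constitutive_donor       43         1            0.970
#> 2 cryptic_acceptor         91         0.75         0.799
```

0.970 is the surrogate's consensus-donor maximum — the search recoded the
exon end and the free intron positions to the full consensus. The acceptor
settled on 0.799, the reachable score level nearest 0.75 given the
synonymous-codon granularity of its exonic context. `tidy(ev)` returns the
per-generation trajectory, `autoplot(ev)` the fitness curve, and
`plot_score_heatmap(ev)` (for runs with `track_scores = TRUE`) the
per-position score tracks in which designed sites strengthen and
off-target sites are depleted.

Published design command lines parse directly:

```r
cfg    <- parse_design_command(example_design_command())  # full mScarlet alt-3' design
layout <- layout_from_config(cfg, seed = 1)
ev     <- evolve_construct(layout, seed = 1)              # n = 3000, early_stop = 500
```

Quantification:

```r
psi(3, 1)
#> [1] 75
psi_from_junctions(generate_fixture("junction_table")$counts)  # AARS1 junction trio
#> [1] 75

mc <- generate_fixture("multi_ce", seed = 1)   # 7-exon construct, cryptic exons 2/4/6
productive_fraction(mc$reads, mc$model)
#> [1] 10
```

A thin command-line wrapper (`inst/scripts/splicevolver`) exposes `evolve`,
`quantify` and `fixtures` subcommands.

## Package layout

| Where | What |
| --- | --- |
| `R/genetic-code.R`, `R/degenerate.R` | genetic-code arithmetic, synonymous sets, IUPAC templates, UG-density scans |
| `R/surrogate.R` | predictor contract, surrogate scorer, external-model adapter |
| `R/layout.R` | design specs, construct layouts, ideal profiles, JSON/BED export |
| `R/evolve.R` | fitness, mutation proposals, the evolution loop, tidy/glance/autoplot |
| `R/design-features.R` | competitor placement, PPT recoding, UG regions |
| `R/isoform.R` | PSI, junction tables, isoform classification, frame/NMD logic |
| `R/config.R`, `R/fixtures.R` | command parsing, run configs, toy fixtures |
| `vignettes/cryptic-splice-design.Rmd` | the methods vignette |
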