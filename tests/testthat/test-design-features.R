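test_that("pyrimidine maximization is per-codon optimal, synonymous, idempotent", {
  # Leu: CTT and CTC carry 3 pyrimidines; the T-preferring tie-break picks CTT
  expect_equal(pyrimidine_maximize("CTG"), "CTT")
  # an all-Phe window is already pyrimidine-maximal
  expect_equal(pyrimidine_maximize("TTTTTTTTT"), "TTTTTTTTT")
  # among equally pyrimidine-rich codons the T-richer one wins (TTC -> TTT)
  expect_equal(pyrimidine_maximize("TTC"), "TTT")

  pyr_frac <- function(s) {
    mean(strsplit(s, "")[[1]] %in% c("C", "T"))
  }
  set.seed(21)
  sense <- genetic_code()$codon[genetic_code()$aa != "*"]
  for (i in 1:200) {
    w <- paste(sample(sense, sample(3:8, 1), replace = TRUE), collapse = "")
    out <- pyrimidine_maximize(w)
    # synonymous
    expect_identical(translate_cds(out), translate_cds(w))
    # never lowers the pyrimidine fraction
    expect_gte(pyr_frac(out), pyr_frac(w))
    # idempotent
    expect_identical(pyrimidine_maximize(out), out)
    # per-codon exhaustive optimality
    for (k in seq(1, nchar(out), 3)) {
      codon <- substr(out, k, k + 2)
      syn <- synonymous_codons(codon)
      best <- max(vapply(
        strsplit(syn, ""),
        function(ch) sum(ch %in% c("C", "T")), integer(1)
      ))
      expect_equal(sum(strsplit(codon, "")[[1]] %in% c("C", "T")), best)
    }
  }
})

test_that("design_ppt recodes only coding windows and keeps the protein", {
  fx <- generate_fixture("alt3", seed = 1)
  layout <- fx$layout
  exon2 <- layout$regions[layout$regions$role == "cds_exon" &
    layout$regions$start > layout$regions$start[2], ]
  win <- c(exon2$start + 6, exon2$start + 23)
  out <- design_ppt(layout, win)
  expect_identical(out$protein, layout$protein)
  expect_identical(layout_protein_oracle(out), layout$protein)
  # idempotent at the layout level too
  out2 <- design_ppt(out, win)
  expect_identical(out2$sequence, out$sequence)
  # window touching the intron is rejected
  intr <- layout$regions[layout$regions$role == "intron", ]
  expect_error(
    design_ppt(layout, c(intr$start - 2, intr$start + 2)),
    class = "splicevolver_fixed_overlap"
  )
})

# a controlled alt-3' layout whose downstream exon offers exactly one
# synonymously reachable AG (inside its single Glu codon)
unique_ag_layout <- function(min_alt_dist = 12) {
  # downstream exon: pyrimidine-rich codons whose synonymous families can
  # never produce AG (no Ser, nothing G-starting, the codon before the Glu
  # cannot end in A), plus one Glu whose GAA -> GAG recode is the single
  # reachable AG
  down <- c(
    "TTT", "CTT", "CCT", "TTC", "CTC", "CCC", "CTT", "TTC",
    "GAA", "TTC", "CAT", "TAA"
  )
  cds <- paste(c("ATG", "GCT", "CAA", down), collapse = "")
  spec <- design_spec("alt3prime_single_intron",
    ce_start = 9, ce_end = 9,
    target_const_acc = 0.5, min_alt_dist = min_alt_dist
  )
  build_layout(spec, cds,
    intron1 = "GTaagNNNNNNNNNNNNNNNNNNNNNNNNNNNNNcAG",
    five_utr = "CCTCTTC", seed = 1
  )
}

test_that("place_competitor picks the unique feasible acceptor deterministically", {
  layout <- unique_ag_layout()
  plan <- place_competitor(layout)
  expect_s3_class(plan, "competitor_plan")
  # the AG can only come from the Glu codon (GAA->GAG): acceptor sits on the
  # base after that AG
  feas <- plan$candidates[plan$candidates$feasible, ]
  r <- layout$regions
  exon2_start <- r$start[r$role == "cds_exon" & r$start > r$start[r$role == "intron"][1]][1]
  glu_pos <- exon2_start + 8 * 3 # Glu codon start within downstream exon
  expect_equal(plan$position, glu_pos + 3)
  expect_gte(plan$distance, layout$spec$min_alt_dist)
  # recode actually wrote the AG and kept the protein
  expect_identical(
    substr(plan$layout$sequence, plan$position - 2, plan$position - 1), "AG"
  )
  expect_identical(layout_protein_oracle(plan$layout), layout$protein)
  # competitor anchor appended with the design's constitutive-acceptor target
  expect_true("competitor_acceptor" %in% plan$layout$anchors$kind)
  expect_equal(
    plan$layout$anchors$target_score[plan$layout$anchors$kind == "competitor_acceptor"],
    0.5
  )
  # deterministic
  plan2 <- place_competitor(unique_ag_layout())
  expect_equal(plan2$position, plan$position)
  expect_equal(plan2$score, plan$score)
})

test_that("place_competitor errors when no position satisfies the constraints", {
  layout <- unique_ag_layout(min_alt_dist = 500)
  err <- expect_error(place_competitor(layout), class = "splicevolver_no_competitor")
  expect_match(conditionMessage(err), "min_alt_dist")
  # wrong design type
  fx <- generate_fixture("retention", seed = 1)
  expect_error(place_competitor(fx$layout), class = "splicevolver_bad_config")
})

test_that("UG region styles meet their density floors and constraints", {
  expect_equal(build_ug_region(8, "pure_repeat"), "TGTGTGTG")
  expect_equal(build_ug_region(2, "pure_repeat"), "TG")

  capped <- build_ug_region(10, "pure_repeat", max_run = 4)
  expect_equal(nchar(capped), 10)
  expect_false(grepl("(TG){5}", capped))

  inter <- build_ug_region(30, "interrupted_repeat")
  expect_false(grepl("(TG){5}", inter))
  expect_gte(max(ug_density(inter, 20)$density), 0.30)

  rich <- build_ug_region(40, "ug_rich_no_repeat", seed = 5)
  expect_equal(nchar(rich), 40)
  expect_false(grepl("TGTG", rich)) # no extended repeats
  expect_gte(max(ug_density(rich, 20)$density), 0.20)
  expect_identical(rich, build_ug_region(40, "ug_rich_no_repeat", seed = 5))

  for (s in c(
    build_ug_region(17, "pure_repeat"),
    build_ug_region(23, "interrupted_repeat", max_run = 3),
    build_ug_region(21, "ug_rich_no_repeat", seed = 2)
  )) {
    expect_match(s, "^[ACGT]+$")
  }
  expect_error(build_ug_region(1, "pure_repeat"))
})
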