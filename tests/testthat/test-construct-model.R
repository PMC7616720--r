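test_that("build_layout validates inputs and frame rules", {
  spec <- design_spec("alt3prime_single_intron", ce_start = 6, ce_end = 6)
  # internal stop in CDS
  expect_error(
    build_layout(spec, "ATGTAACGGGAA", intron1 = "GTaagNNNNNcAG"),
    class = "splicevolver_bad_cds"
  )
  # ce outside CDS
  bad <- design_spec("alt3prime_single_intron", ce_start = 99, ce_end = 99)
  expect_error(
    build_layout(bad, "ATGGCTGGATAA", intron1 = "GTaagNNNNNcAG"),
    class = "splicevolver_bad_config"
  )
  # missing intron
  expect_error(
    build_layout(spec, "ATGGCTGGATAA", intron1 = ""),
    class = "splicevolver_bad_config"
  )
  # cassette without second intron
  cas <- design_spec("internal_cassette_exon", ce_start = 6, ce_end = 12)
  expect_error(
    build_layout(cas, "ATGGCTGGAGCTGGTTAA", intron1 = "GTaagNNNNNcAG"),
    class = "splicevolver_bad_config"
  )
  # cassette whose CE length is not 0 mod 3 fails unless frame shift declared
  cas13 <- design_spec("internal_cassette_exon", ce_start = 6, ce_end = 13)
  expect_error(
    build_layout(cas13, "ATGGCTGGAGCTGGTTAA",
      intron1 = "GTaagNNNNNcAG", intron2 = "GTaagNNNNNcAG"
    ),
    class = "splicevolver_frame"
  )
  cas13f <- design_spec("internal_cassette_exon",
    ce_start = 6, ce_end = 13, frame_shift = TRUE
  )
  expect_s3_class(
    build_layout(cas13f, "ATGGCTGGAGCTGGTTAA",
      intron1 = "GTaagNNNNNcAG", intron2 = "GTaagNNNNNcAG", seed = 1
    ),
    "construct_layout"
  )
})

test_that("anchors demand their invariant dinucleotides at build time", {
  spec <- design_spec("alt3prime_single_intron", ce_start = 6, ce_end = 6)
  # intron not starting GT: constitutive donor anchor is violated
  expect_error(
    build_layout(spec, "ATGGCTGGATAA", intron1 = "CCaagNNNNNcAG", seed = 1),
    class = "splicevolver_bad_layout"
  )
})

test_that("the ideal profile is zero off-anchor, weighted at cryptic sites", {
  fx <- generate_fixture("cassette", seed = 1)
  tp <- ideal_profile(fx$layout)
  a <- fx$layout$anchors
  donor_anchors <- a$position[a$site == "donor"]
  acc_anchors <- a$position[a$site == "acceptor"]
  expect_equal(sum(tp$donor_target[-donor_anchors]), 0)
  expect_equal(sum(tp$acceptor_target[-acc_anchors]), 0)
  expect_equal(
    tp$donor_target[donor_anchors],
    a$target_score[a$site == "donor"]
  )
  # cryptic anchors carry the configured weight, everything else 1
  cryptic <- a[grepl("^cryptic", a$kind), ]
  for (i in seq_len(nrow(cryptic))) {
    col <- if (cryptic$site[i] == "donor") "donor_weight" else "acceptor_weight"
    expect_equal(tp[[col]][cryptic$position[i]], 3)
  }
  expect_true(all(tp$donor_weight[-a$position] == 1))
})

test_that("ignore_end zeroes the weights across the 3' terminal zone", {
  spec <- design_spec("alt3prime_single_intron",
    ce_start = 6, ce_end = 6, ignore_end = 15
  )
  layout <- build_layout(spec, "ATGGCTGGATAA",
    intron1 = "GTaagNNNNNNNNNNNNNNNNNNNNNNNcAG",
    three_utr = "CATCATCATCATCAT", seed = 1
  )
  tp <- ideal_profile(layout)
  zone <- (layout$length - 14):layout$length
  expect_true(all(tp$donor_weight[zone] == 0))
  expect_true(all(tp$acceptor_weight[zone] == 0))
  expect_true(all(tp$donor_weight[seq_len(layout$length - 15)] > 0))
})

test_that("layouts survive a JSON round trip", {
  for (kind in c("cassette", "alt3", "retention")) {
    fx <- generate_fixture(kind, seed = 2)
    js <- layout_to_json(fx$layout)
    back <- layout_from_json(js)
    expect_identical(back$sequence, fx$layout$sequence)
    expect_identical(back$template, fx$layout$template)
    expect_identical(back$protein, fx$layout$protein)
    expect_equal(back$regions, fx$layout$regions)
    expect_equal(back$anchors, fx$layout$anchors)
    expect_equal(unclass(back$spec), unclass(fx$layout$spec))
  }
})

test_that("proposals never touch fixed positions, trims or anchor dinucleotides", {
  spec <- design_spec("alt3prime_single_intron",
    ce_start = 9, ce_end = 9,
    upstream_mut_chance = 1, downstream_mut_chance = 1,
    intron1_mut_chance = 1,
    cds_mut_start_trim = 3, cds_mut_end_trim = 3
  )
  cds <- "ATGGCTCAAGGTGCTGGATTGTCCTAA"
  layout <- build_layout(spec, cds,
    intron1 = "GTaagNNNNNNNNNNNNNNNNNNNNNNNNNcAG",
    five_utr = "CCTTAAG", seed = 1
  )
  v0 <- strsplit(layout$sequence, "")[[1]]
  lower <- strsplit(layout$template, "")[[1]] %in% letters
  r <- layout$regions
  utr <- seq(r$start[r$role == "five_utr"], r$end[r$role == "five_utr"])
  cds_pos <- unlist(Map(seq, r$start[r$role == "cds_exon"], r$end[r$role == "cds_exon"]))
  start_trim <- cds_pos[1:3]
  end_trim <- tail(cds_pos, 3)
  a <- layout$anchors
  crit <- unlist(Map(
    function(site, p) if (site == "donor") c(p + 1, p + 2) else c(p - 2, p - 1),
    a$site, a$position
  ))

  set.seed(99)
  for (i in 1:400) {
    prop <- strsplit(propose_mutations(layout), "")[[1]]
    expect_identical(prop[utr], v0[utr]) # literal UTR: no degenerate positions
    expect_identical(prop[lower], v0[lower])
    expect_identical(prop[start_trim], v0[start_trim])
    expect_identical(prop[end_trim], v0[end_trim])
    expect_identical(prop[crit], v0[crit])
    expect_identical(
      layout_protein_oracle(layout, paste(prop, collapse = "")),
      layout$protein
    )
  }
})

test_that("mutation-count semantics: a firing degeneracy region changes one position", {
  spec <- design_spec("alt3prime_single_intron",
    ce_start = 6, ce_end = 6,
    upstream_mut_chance = 0, downstream_mut_chance = 1, downstream_mut_n = 1,
    intron1_mut_chance = 0, cds_mut_end_trim = 6
  )
  layout <- build_layout(spec, "ATGGCTGGATAA",
    intron1 = "GTaagNNNNNNNNNNNNNNNNNNNNNNNcAG",
    three_utr = strrep("N", 12), seed = 1
  )
  v0 <- strsplit(layout$sequence, "")[[1]]
  set.seed(7)
  diffs <- replicate(200, {
    prop <- strsplit(propose_mutations(layout), "")[[1]]
    sum(prop != v0)
  })
  expect_true(all(diffs == 1)) # chance 1, n 1: exactly one downstream position
})

test_that("zero mutation chance freezes a region entirely", {
  spec <- design_spec("alt3prime_single_intron",
    ce_start = 6, ce_end = 6,
    upstream_mut_chance = 0, downstream_mut_chance = 0, intron1_mut_chance = 0
  )
  layout <- build_layout(spec, "ATGGCTGGATAA",
    intron1 = "GTaagNNNNNNNNNNNNNNNNNNNNNNNcAG", seed = 1
  )
  set.seed(3)
  for (i in 1:50) expect_identical(propose_mutations(layout), layout$sequence)
})

test_that("layout BED export lists regions and anchors", {
  fx <- generate_fixture("alt3", seed = 1)
  path <- withr::local_tempfile(fileext = ".bed")
  layout_to_bed(fx$layout, path)
  lines <- readLines(path)
  expect_length(lines, nrow(fx$layout$regions) + nrow(fx$layout$anchors))
  expect_true(all(grepl("^construct\t", lines)))
})
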