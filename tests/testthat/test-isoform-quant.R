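test_that("psi computes the inclusion percentage with explicit missingness", {
  expect_equal(psi(50, 50), 50)
  expect_equal(psi(0, 100), 0)
  expect_equal(psi(3, 1), 75)
  expect_true(is.na(psi(0, 0))) # undefined, never 0
  expect_error(psi(-1, 5))

  # complementarity: psi(a,b) + psi(b,a) == 100 whenever a+b > 0
  set.seed(8)
  a <- sample(0:500, 50)
  b <- sample(0:500, 50)
  keep <- a + b > 0
  expect_equal(psi(a, b)[keep] + psi(b, a)[keep], rep(100, sum(keep)))
})

test_that("the AARS1 junction trio is defined verbatim with its roles", {
  j <- aars1_junctions()
  expect_equal(nrow(j), 3)
  expect_true(all(j$chrom == "chr16") && all(j$strand == "-"))
  expect_equal(
    j[j$name == "AARS1_novel_acceptor", c("start", "end")],
    tibble::tibble(start = 70272882L, end = 70276486L)
  )
  expect_equal(
    j[j$name == "AARS1_novel_donor", c("start", "end")],
    tibble::tibble(start = 70271972L, end = 70272796L)
  )
  expect_equal(
    j[j$name == "AARS1_annotated", c("start", "end")],
    tibble::tibble(start = 70271972L, end = 70276486L)
  )
  expect_setequal(j$role[grepl("novel", j$name)], "inclusion")
  expect_equal(j$role[j$name == "AARS1_annotated"], "exclusion")
})

test_that("junction-table PSI recovers planted truth in both modes", {
  fx <- generate_fixture("junction_table", seed = 1)
  expect_equal(psi_from_junctions(fx$counts), fx$truth$psi)
  expect_equal(psi_from_junctions(fx$counts), 75)
  expect_equal(psi_from_junctions(fx$counts, mode = "mean"), fx$truth$psi_mean)
  # junctions missing from the table count zero
  expect_equal(psi_from_junctions(fx$counts[3, ]), 0)
  expect_true(is.na(psi_from_junctions(fx$counts[0, ])))
})

test_that("STAR SJ.out.tab files read with the documented column mapping", {
  path <- withr::local_tempfile(fileext = ".tab")
  writeLines(
    c(
      "chr16\t70272882\t70276486\t2\t2\t0\t75\t3\t38",
      "chr16\t70271972\t70272796\t2\t2\t0\t75\t1\t40",
      "chr16\t70271972\t70276486\t2\t2\t1\t50\t2\t41"
    ),
    path
  )
  x <- read_star_junctions(path)
  expect_equal(x$count, c(75L, 75L, 50L))
  expect_true(all(x$strand == "-"))
  expect_equal(psi_from_junctions(x), 75)
})

test_that("multi-CE classification recovers every planted pattern exactly", {
  fx <- generate_fixture("multi_ce", seed = 1)
  expect_equal(nrow(fx$model$exons), 7)
  expect_equal(which(fx$model$exons$role == "cryptic"), c(2L, 4L, 6L))

  calls <- classify_isoforms(fx$reads, fx$model)
  # per-read ground truth is encoded in the read id prefix
  expect_identical(calls$category, sub("_.*$", "", calls$read_id))

  s <- summarize_isoforms(fx$reads, fx$model)
  expect_equal(sum(s$fraction_pct), 100)
  for (pat in names(fx$truth$fractions)) {
    expect_equal(s$fraction_pct[s$category == pat], unname(fx$truth$fractions[pat]))
  }
  expect_equal(
    s$fraction_pct[s$category == "111"],
    fx$truth$three_ce_pct
  )
  expect_equal(productive_fraction(fx$reads, fx$model), fx$truth$productive_pct)

  # only the full seven-exon transcript is productive
  expect_true(all(s$productive[s$category == "111"]))
  expect_false(any(s$productive[s$category != "111"]))
})

test_that("classification is total: junctions off anchors become 'other'", {
  fx <- generate_fixture("multi_ce", seed = 1)
  stray <- tibble::tibble(read_id = "stray", donor = 7L, acceptor = 200L)
  call <- classify_isoforms(stray, fx$model)
  expect_equal(call$category, "other")
  expect_true(is.na(call$productive))

  # mixed population: every read in exactly one category
  reads <- dplyr::bind_rows(fx$reads, stray)
  s <- summarize_isoforms(reads, fx$model)
  expect_equal(sum(s$reads), length(unique(reads$read_id)))
  expect_equal(sum(s$fraction_pct), 100)

  # tolerance: +/- 3 nt wobble still matches, beyond does not
  wob <- fx$reads[fx$reads$read_id == "111_1", ]
  wob$donor <- wob$donor + c(3L, -3L, 2L)
  expect_equal(classify_isoforms(wob, fx$model)$category, "111")
  far <- wob
  far$donor <- far$donor + 10L
  expect_equal(classify_isoforms(far, fx$model)$category, "other")
})

test_that("productive fraction weights read counts and handles empties", {
  fx <- generate_fixture("multi_ce", seed = 1)
  inc <- .reads_one <- fx$reads[fx$reads$read_id == "111_1", ]
  skip_all <- fx$reads[fx$reads$read_id == "000_1", ]
  reads <- dplyr::bind_rows(
    dplyr::mutate(inc, count = 90L),
    dplyr::mutate(skip_all, count = 10L)
  )
  expect_equal(productive_fraction(reads, fx$model), 90)
  expect_true(is.na(productive_fraction(fx$reads[0, ], fx$model)))
})

test_that("cassette insertions shift the downstream frame by length mod 3", {
  # independent construction oracle: insert an L-mer of AAA... into a codon
  # boundary and see whether the downstream peptide is preserved
  upstream <- "ATGGCT"
  downstream <- "GGTGCTGATTAA" # GAD* when in frame
  for (L in 1:30) {
    shifted <- cassette_frame_shift(L)
    expect_equal(shifted, L %% 3L)
    mrna <- paste0(upstream, strrep("A", L), downstream)
    prot <- translate_cds(mrna)
    in_frame <- endsWith(prot, "GAD")
    expect_equal(in_frame, shifted == 0L)
  }
})

test_that("the frame-switch minigene expresses only with its cryptic exon", {
  v1 <- v1_minigene()
  expect_equal(cassette_frame_shift(v1$truth$ce_length), 2L)

  inc <- classify_isoforms(v1$reads_included, v1$model)
  exc <- classify_isoforms(v1$reads_excluded, v1$model)
  expect_equal(inc$category, "1")
  expect_true(inc$productive)
  expect_false(inc$ptc)
  expect_equal(exc$category, "0")
  expect_false(exc$productive)
  # exclusion shifts the frame into a premature stop far enough upstream of
  # the final junction to trigger NMD
  expect_true(exc$ptc)
})
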