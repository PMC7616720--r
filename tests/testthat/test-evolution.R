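test_that("fitness equals the brute-force double loop and its edge cases", {
  # identity: perfect match scores exactly 0
  tp <- tibble::tibble(
    position = 1:10,
    donor_target = c(rep(0, 9), 1), acceptor_target = rep(0, 10),
    donor_weight = rep(1, 10), acceptor_weight = rep(1, 10)
  )
  prof <- tibble::tibble(
    position = 1:10,
    donor = tp$donor_target, acceptor = tp$acceptor_target
  )
  expect_identical(fitness_score(prof, tp), 0)

  # one discordant position, weight 1: -|1 - 0.75|
  prof$donor[10] <- 0.75
  expect_equal(fitness_score(prof, tp), -0.25)

  # random instances against the independent oracle
  set.seed(123)
  for (i in 1:30) {
    x <- random_profile_pair(50)
    expect_equal(
      fitness_score(x$profile, x$target),
      brute_force_fitness(x$profile, x$target),
      tolerance = 1e-12
    )
  }
  expect_error(
    fitness_score(prof, tp[1:5, ]),
    class = "splicevolver_length_mismatch"
  )
})

test_that("evolution is elitist, protein-conserving and seed-reproducible", {
  fx <- generate_fixture("cassette", seed = 1)
  ev <- evolve_construct(fx$layout, n_iterations = 200, lambda = 8, seed = 42)

  expect_gte(ev$best$fitness, ev$initial_fitness)
  expect_true(all(diff(ev$trajectory$fitness) >= 0))

  # every retained candidate encodes the constraint protein and keeps the
  # anchor dinucleotides
  a <- fx$layout$anchors
  for (s in unique(ev$trajectory$sequence)) {
    expect_identical(layout_protein_oracle(fx$layout, s), fx$layout$protein)
    for (i in seq_len(nrow(a))) {
      din <- if (a$site[i] == "donor") {
        substr(s, a$position[i] + 1, a$position[i] + 2)
      } else {
        substr(s, a$position[i] - 2, a$position[i] - 1)
      }
      expect_identical(din, if (a$site[i] == "donor") "GT" else "AG")
    }
  }

  ev2 <- evolve_construct(fx$layout, n_iterations = 200, lambda = 8, seed = 42)
  expect_identical(ev$trajectory, ev2$trajectory)
  expect_identical(ev$best, ev2$best)

  # a different seed explores differently (same start, other path)
  ev3 <- evolve_construct(fx$layout, n_iterations = 200, lambda = 8, seed = 43)
  expect_false(identical(ev$trajectory$sequence, ev3$trajectory$sequence))
})

test_that("early stopping halts after the configured patience", {
  fx <- generate_fixture("retention", seed = 1)
  ev <- evolve_construct(fx$layout,
    n_iterations = 300, early_stop = 25, lambda = 4, seed = 1
  )
  expect_true(ev$converged || nrow(ev$trajectory) == 300)
  if (ev$converged) {
    tail_fit <- tail(ev$trajectory$fitness, 25)
    expect_true(all(tail_fit - tail_fit[1] <= 1e-9))
  }
})

test_that("score tracking yields one matrix row per generation", {
  fx <- generate_fixture("alt3", seed = 1)
  ev <- evolve_construct(fx$layout,
    n_iterations = 10, early_stop = 10, lambda = 3,
    seed = 1, track_scores = TRUE
  )
  m <- trajectory_matrix(ev, "donor")
  expect_equal(dim(m), c(10, fx$layout$length))
  expect_true(all(m >= 0 & m <= 1))

  long <- export_trajectory(ev)
  expect_equal(nrow(long), 2 * 10 * fx$layout$length)
  expect_setequal(unique(long$channel), c("donor", "acceptor"))

  path <- withr::local_tempfile(fileext = ".tsv")
  export_trajectory(ev, path)
  expect_equal(nrow(readr::read_tsv(path, show_col_types = FALSE)), nrow(long))

  # without tracking the export is an explicit error
  ev0 <- evolve_construct(fx$layout, n_iterations = 5, early_stop = 5, lambda = 2, seed = 1)
  expect_error(export_trajectory(ev0), class = "splicevolver_no_tracks")
  expect_error(trajectory_matrix(ev0), class = "splicevolver_no_tracks")
})

test_that("off-target donor activity is depleted over a converging run", {
  fx <- generate_fixture("alt3", seed = 1)
  ev <- evolve_construct(fx$layout,
    n_iterations = 400, early_stop = 400, lambda = 10,
    seed = 2, track_scores = TRUE
  )
  m <- trajectory_matrix(ev, "donor")
  anchor_cols <- fx$layout$anchors$position
  off <- m[, -anchor_cols, drop = FALSE]
  half <- nrow(off) %/% 2
  # soft check: the worst off-target score does not grow over the second half
  expect_lte(max(off[nrow(off), ]), max(off[half, ]) + 1e-9)
})

test_that("tidy, glance and the plots expose the run", {
  fx <- generate_fixture("alt3", seed = 1)
  ev <- evolve_construct(fx$layout,
    n_iterations = 15, early_stop = 15, lambda = 3,
    seed = 1, track_scores = TRUE
  )
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("generation", "fitness", "improved", "sequence"))
  gl <- glance(ev)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_generations, 15)
  expect_s3_class(ggplot2::autoplot(ev), "ggplot")
  expect_s3_class(plot_score_heatmap(ev), "ggplot")

  fa <- withr::local_tempfile(fileext = ".fa")
  write_best_fasta(ev, fa)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(seqs[[1]]), ev$best$sequence)

  mj <- withr::local_tempfile(fileext = ".json")
  write_run_manifest(ev, mj)
  man <- jsonlite::read_json(mj)
  expect_equal(man$config$seed, 1)
  expect_equal(man$best_fitness, ev$best$fitness)
})

test_that("predictor failures surface with the generation index", {
  fx <- generate_fixture("retention", seed = 1)
  flaky <- external_predictor(function(s) stop("backend down"), name = "flaky")
  expect_error(
    evolve_construct(fx$layout, predictor = flaky, n_iterations = 3, early_stop = 3, lambda = 2, seed = 1),
    class = "splicevolver_predictor_error"
  )
})
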