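# Directed-evolution loop: (1+lambda) elitist search over synonymous and
# degeneracy-constrained mutations, scored against the ideal profile.

#' Fitness of a predicted splicing profile against an ideal profile
#'
#' The fitness is the negative weighted sum of absolute differences between
#' desired and predicted splicing scores at every position, over both the
#' donor and the acceptor channel. It is 0 exactly when prediction matches
#' target at every position carrying nonzero weight, and negative otherwise.
#'
#' @param profile Tibble from [predict_splice_profile()] (columns `donor`,
#'   `acceptor`).
#' @param target Tibble from [ideal_profile()] (columns `donor_target`,
#'   `acceptor_target`, `donor_weight`, `acceptor_weight`).
#' @return A single number `<= 0`.
#' @export
#' @examples
#' prof <- tibble::tibble(position = 1, donor = 0.75, acceptor = 0)
#' targ <- tibble::tibble(
#'   position = 1, donor_target = 1, acceptor_target = 0,
#'   donor_weight = 1, acceptor_weight = 1
#' )
#' fitness_score(prof, targ) # -0.25
fitness_score <- function(profile, target) {
  if (nrow(profile) != nrow(target)) {
    abort("profile and target lengths differ", class = "splicevolver_length_mismatch")
  }
  .fitness(
    profile$donor, profile$acceptor,
    list(
      donor_target = target$donor_target, acceptor_target = target$acceptor_target,
      donor_weight = target$donor_weight, acceptor_weight = target$acceptor_weight
    )
  )
}

.fitness <- function(donor, acceptor, tp) {
  -(sum(tp$donor_weight * abs(tp$donor_target - donor)) +
    sum(tp$acceptor_weight * abs(tp$acceptor_target - acceptor)))
}

#' Propose a mutated construct sequence
#'
#' Each mutable region independently receives mutations with its
#' `mutation_chance`; when a region fires, `mut_n` units are mutated — a
#' whole codon replaced by a different synonymous codon in coding regions, a
#' single position resampled within its degeneracy set elsewhere. Fixed
#' regions, trimmed codon ranges and the invariant GT/AG dinucleotides of
#' anchors are never touched, so every proposal encodes the same protein.
#' Draws come from R's RNG stream (seed it for reproducibility). A proposal
#' may equal its parent when no region fires.
#'
#' @param layout A `construct_layout`.
#' @param sequence Parent sequence (defaults to the layout's current one).
#' @return The proposed sequence as a string.
#' @export
propose_mutations <- function(layout, sequence = layout$sequence) {
  v <- .propose_int(layout, .seq2int(sequence))
  .int2seq(v)
}

.propose_int <- function(layout, v) {
  idx <- layout$index
  r <- layout$regions
  for (i in seq_len(nrow(r))) {
    chance <- r$mutation_chance[i]
    if (chance <= 0) next
    if (stats::runif(1) >= chance) next
    if (r$mutability[i] == "synonymous_only") {
      pool <- idx$mutable_codon[idx$codon_region[idx$mutable_codon] == r$region_id[i]]
      if (!length(pool)) next
      for (k in seq_len(r$mut_n[i])) {
        ci <- pool[sample.int(length(pool), 1)]
        pos <- idx$codon_pos[, ci]
        cur <- .codon_index(v[pos[1]], v[pos[2]], v[pos[3]])
        syn <- .SYN_SETS[[cur]]
        if (nrow(syn) < 2) next
        cur_row <- which(syn[, 1] == v[pos[1]] & syn[, 2] == v[pos[2]] & syn[, 3] == v[pos[3]])
        choices <- setdiff(seq_len(nrow(syn)), cur_row)
        pick <- syn[choices[sample.int(length(choices), 1)], ]
        v[pos] <- pick
      }
    } else if (r$mutability[i] == "free_within_degeneracy") {
      pool <- which(idx$free_region == r$region_id[i])
      if (!length(pool)) next
      for (k in seq_len(r$mut_n[i])) {
        j <- pool[sample.int(length(pool), 1)]
        p <- idx$free_pos[j]
        opts <- idx$free_allowed[[j]]
        opts <- opts[opts != v[p]]
        if (!length(opts)) next
        v[p] <- opts[sample.int(length(opts), 1)]
      }
    }
  }
  v
}

#' Evolve a construct toward its ideal splicing profile
#'
#' Runs a (1+lambda) elitist directed-evolution search: each iteration draws
#' `lambda` mutated proposals from the current best sequence, scores them
#' with the predictor, and retains the fittest of parent and proposals. On
#' fitness ties the parent wins (minimizing drift), then the
#' lexicographically smallest sequence (determinism). The run stops after
#' `n_iterations`, or earlier once `early_stop` consecutive iterations pass
#' without strict improvement (more than 1e-9 above the incumbent). Given a
#' seed and a deterministic predictor the whole run is reproducible.
#'
#' @param layout A `construct_layout`.
#' @param predictor A splice predictor; default the surrogate.
#' @param n_iterations,early_stop,lambda Search budget; defaults come from
#'   the layout's design spec.
#' @param seed Integer seed for the mutation stream.
#' @param track_scores Record the best candidate's full donor/acceptor score
#'   vectors every iteration (needed for [trajectory_matrix()] and the
#'   heatmap plot).
#' @return A `splice_evolution` object: `best` (sequence, fitness, profile),
#'   `trajectory` tibble (one row per iteration), optional score `tracks`,
#'   and the run `config`. Methods: [tidy()][generics::tidy()],
#'   [glance()][generics::glance()], `autoplot()`.
#' @export
evolve_construct <- function(layout, predictor = surrogate_predictor(),
                             n_iterations = NULL, early_stop = NULL,
                             lambda = NULL, seed = 1, track_scores = FALSE) {
  stopifnot(inherits(layout, "construct_layout"))
  n_iterations <- n_iterations %||% layout$spec$n_iterations
  early_stop <- early_stop %||% layout$spec$early_stop
  lambda <- lambda %||% layout$spec$lambda
  if (n_iterations < 1) abort("n_iterations must be >= 1")
  if (inherits(predictor, "surrogate_predictor") && is.null(predictor$compiled)) {
    predictor$compiled <- .compile_surrogate(predictor$params)
  }
  tp <- .target_vectors(layout)
  v <- .seq2int(layout$sequence)
  prof <- tryCatch(
    .score_candidate(v, predictor, layout),
    error = function(e) {
      abort(sprintf("predictor failed at generation 0: %s", conditionMessage(e)),
        class = "splicevolver_predictor_error"
      )
    }
  )
  best_fit <- .fitness(prof$donor, prof$acceptor, tp)
  best_v <- v
  best_prof <- prof

  fitness_tr <- numeric(n_iterations)
  improved_tr <- logical(n_iterations)
  seq_tr <- character(n_iterations)
  tr_d <- if (track_scores) matrix(NA_real_, n_iterations, layout$length) else NULL
  tr_a <- if (track_scores) matrix(NA_real_, n_iterations, layout$length) else NULL

  .with_seed(seed, {
    stale <- 0L
    gen <- 0L
    while (gen < n_iterations) {
      gen <- gen + 1L
      cand_v <- best_v
      cand_fit <- best_fit
      cand_prof <- best_prof
      parent_wins <- TRUE
      for (j in seq_len(lambda)) {
        pv <- .propose_int(layout, best_v)
        pp <- tryCatch(
          .score_candidate(pv, predictor, layout),
          error = function(e) {
            abort(sprintf("predictor failed at generation %d: %s", gen, conditionMessage(e)),
              class = "splicevolver_predictor_error"
            )
          }
        )
        pf <- .fitness(pp$donor, pp$acceptor, tp)
        take <- if (pf > cand_fit) {
          TRUE
        } else if (pf == cand_fit && !parent_wins) {
          # tie among proposals: lexicographically smallest sequence
          .lex_less(pv, cand_v)
        } else {
          FALSE
        }
        if (take) {
          cand_v <- pv
          cand_fit <- pf
          cand_prof <- pp
          parent_wins <- FALSE
        }
      }
      if (cand_fit > best_fit + 1e-9) {
        stale <- 0L
        improved_tr[gen] <- TRUE
      } else {
        stale <- stale + 1L
      }
      if (cand_fit > best_fit) {
        best_v <- cand_v
        best_fit <- cand_fit
        best_prof <- cand_prof
      }
      fitness_tr[gen] <- best_fit
      seq_tr[gen] <- .int2seq(best_v)
      if (track_scores) {
        tr_d[gen, ] <- best_prof$donor
        tr_a[gen, ] <- best_prof$acceptor
      }
      if (stale >= early_stop) break
    }
    n_run <- gen
    structure(
      list(
        best = list(
          sequence = .int2seq(best_v),
          fitness = best_fit,
          profile = tibble(
            position = seq_len(layout$length),
            donor = best_prof$donor, acceptor = best_prof$acceptor
          )
        ),
        trajectory = tibble(
          generation = seq_len(n_run),
          fitness = fitness_tr[seq_len(n_run)],
          improved = improved_tr[seq_len(n_run)],
          sequence = seq_tr[seq_len(n_run)]
        ),
        tracks = if (track_scores) {
          list(
            donor = tr_d[seq_len(n_run), , drop = FALSE],
            acceptor = tr_a[seq_len(n_run), , drop = FALSE]
          )
        } else {
          NULL
        },
        initial_fitness = {
          p0 <- .score_candidate(.seq2int(layout$sequence), predictor, layout)
          .fitness(p0$donor, p0$acceptor, tp)
        },
        layout = layout,
        config = list(
          n_iterations = n_iterations, early_stop = early_stop, lambda = lambda,
          seed = seed, predictor = predictor$name,
          predictor_version = predictor$version, track_scores = track_scores
        ),
        converged = n_run < n_iterations
      ),
      class = "splice_evolution"
    )
  })
}

.score_candidate <- function(v, predictor, layout) {
  .predict_int(v, predictor)
}

# TRUE if integer sequence a sorts strictly before b
.lex_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

#' @export
print.splice_evolution <- function(x, ...) {
  cat(sprintf(
    "<splice_evolution> %d generation(s), fitness %.4f -> %.4f%s\n",
    nrow(x$trajectory), x$initial_fitness, x$best$fitness,
    if (x$converged) " (early-stopped)" else ""
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-generation trajectory of an evolution run
#'
#' @param x A `splice_evolution` object.
#' @param ... Unused.
#' @return One row per generation: `generation`, `fitness` (best so far),
#'   `improved`, and the retained best `sequence`.
#' @exportS3Method generics::tidy
#' @export
tidy.splice_evolution <- function(x, ...) x$trajectory

#' @rdname tidy.splice_evolution
#' @return `glance()`: a one-row run summary.
#' @exportS3Method generics::glance
#' @export
glance.splice_evolution <- function(x, ...) {
  tibble(
    n_generations = nrow(x$trajectory),
    initial_fitness = x$initial_fitness,
    best_fitness = x$best$fitness,
    converged = x$converged,
    lambda = x$config$lambda,
    seed = x$config$seed,
    predictor = x$config$predictor
  )
}

#' Trajectory exports: tidy score tracks and heatmap matrix
#'
#' `export_trajectory()` returns (and optionally writes as TSV) the long-form
#' per-generation, per-position score tracks of a run made with
#' `track_scores = TRUE`; `trajectory_matrix()` returns the heatmap-ready
#' matrix (rows = generations, columns = positions) for one channel.
#'
#' @param x A `splice_evolution` run with score tracking enabled.
#' @param path Optional TSV output path.
#' @param channel `"donor"` or `"acceptor"`.
#' @export
export_trajectory <- function(x, path = NULL) {
  tr <- .require_tracks(x)
  long <- dplyr::bind_rows(
    .track_long(tr$donor, "donor"),
    .track_long(tr$acceptor, "acceptor")
  )
  if (!is.null(path)) {
    readr::write_tsv(long, path)
    return(invisible(path))
  }
  long
}

#' @rdname export_trajectory
#' @export
trajectory_matrix <- function(x, channel = c("donor", "acceptor")) {
  channel <- match.arg(channel)
  .require_tracks(x)[[channel]]
}

.require_tracks <- function(x) {
  stopifnot(inherits(x, "splice_evolution"))
  if (is.null(x$tracks) || nrow(x$trajectory) == 0) {
    abort("run has no score tracks: evolve with track_scores = TRUE",
      class = "splicevolver_no_tracks"
    )
  }
  x$tracks
}

.track_long <- function(m, channel) {
  tibble(
    generation = rep(seq_len(nrow(m)), times = ncol(m)),
    position = rep(seq_len(ncol(m)), each = nrow(m)),
    channel = channel,
    score = as.vector(m)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an evolution run
#'
#' `autoplot()` draws the fitness trajectory; [plot_score_heatmap()] draws
#' the per-position score tracks as a heatmap (generations on the y axis),
#' the standard way to inspect where splice sites are being evolved in and
#' off-target sites depleted.
#'
#' @param object,x A `splice_evolution`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.splice_evolution <- function(object, ...) {
  ggplot2::ggplot(object$trajectory, ggplot2::aes(x = .data$generation, y = .data$fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "iteration", y = "fitness (negative weighted L1 error)",
      title = "Directed-evolution trajectory"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.splice_evolution
#' @export
plot_score_heatmap <- function(x, ...) {
  long <- export_trajectory(x)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$generation, fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel, ncol = 1) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "construct position", y = "iteration") +
    ggplot2::theme_minimal()
}

#' Write the best evolved sequence as FASTA
#'
#' @param x A `splice_evolution`.
#' @param path Output FASTA path.
#' @param name Record name.
#' @export
write_best_fasta <- function(x, path, name = "evolved_construct") {
  seqs <- Biostrings::DNAStringSet(setNames(x$best$sequence, name))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a replayable run manifest
#'
#' Captures seed, configuration, predictor version and final fitness as
#' JSON; with the surrogate predictor this suffices to replay the run
#' bit-identically.
#'
#' @param x A `splice_evolution`.
#' @param path Output JSON path.
#' @export
write_run_manifest <- function(x, path) {
  jsonlite::write_json(
    list(
      config = x$config,
      initial_fitness = x$initial_fitness,
      best_fitness = x$best$fitness,
      n_generations = nrow(x$trajectory),
      design_type = x$layout$spec$design_type,
      construct_length = x$layout$length
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
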