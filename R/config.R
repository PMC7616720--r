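# Command-line surface: a parser for the flag vocabulary of the original
# Python design tool, so published design commands reproduce directly, plus
# config (de)serialization and the config -> layout bridge.

# flag registry: type is one of "flag", "int", "num", "str", "seq".
# Sequence-valued flags concatenate consecutive non-flag tokens, which makes
# line-wrapped commands (sequence broken across lines) parse unchanged.
.FLAG_SPEC <- function() {
  tribble_ <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    tibble(flag = m[, 1], dest = m[, 2], type = m[, 3])
  }
  tribble_(
    "--initial_cds", "initial_cds", "seq",
    "--initial_intron1", "initial_intron1", "seq",
    "--initial_intron2", "initial_intron2", "seq",
    "--five_utr", "five_utr", "seq",
    "--three_utr", "three_utr", "seq",
    "--aa", "aa", "str",
    "--ce_start", "ce_start", "int",
    "--ce_end", "ce_end", "int",
    "--ignore_end", "ignore_end", "int",
    "--upstream_mut_chance", "upstream_mut_chance", "num",
    "--downstream_mut_chance", "downstream_mut_chance", "num",
    "--intron1_mut_chance", "intron1_mut_chance", "num",
    "--intron2_mut_chance", "intron2_mut_chance", "num",
    "--upstream_mut_n", "upstream_mut_n", "int",
    "--downstream_mut_n", "downstream_mut_n", "int",
    "-a", "acceptor_window", "int",
    "-n", "n_iterations", "int",
    "--cds_mut_start_trim", "cds_mut_start_trim", "int",
    "--cds_mut_end_trim", "cds_mut_end_trim", "int",
    "--overwrite", "overwrite", "flag",
    "--ce_score_weight", "ce_score_weight", "num",
    "--early_stop", "early_stop", "int",
    "--target_const_donor", "target_const_donor", "num",
    "--target_const_acc", "target_const_acc", "num",
    "--target_cryptic_donor", "target_cryptic_donor", "num",
    "--target_cryptic_acc", "target_cryptic_acc", "num",
    "--alt_3p", "alt_3p", "flag",
    "--alt_5p", "alt_5p", "flag",
    "--intron_retention", "intron_retention", "flag",
    "--alt_position", "alt_position", "str",
    "--alt_3p_end_trim", "alt_3p_end_trim", "int",
    "--alt_5p_start_trim", "alt_5p_start_trim", "int",
    "--downstream_mut_chance", "downstream_mut_chance", "num",
    "--min_alt_dist", "min_alt_dist", "int",
    "--track_splice_scores", "track_splice_scores", "flag",
    "--seed", "seed", "int",
    "--predictor", "predictor", "str",
    "--lambda", "lambda", "int",
    "--out", "out", "str"
  )
}

.CONFIG_DEFAULTS <- list(
  initial_cds = NULL, initial_intron1 = NULL, initial_intron2 = NULL,
  five_utr = "", three_utr = "", aa = NULL,
  ce_start = NULL, ce_end = NULL, ignore_end = 0L,
  upstream_mut_chance = 0.3, downstream_mut_chance = 0.3,
  intron1_mut_chance = 0.5, intron2_mut_chance = 0.5,
  upstream_mut_n = 1L, downstream_mut_n = 1L,
  acceptor_window = 30L, n_iterations = 3000L,
  cds_mut_start_trim = 0L, cds_mut_end_trim = 0L,
  overwrite = FALSE, ce_score_weight = 1,
  early_stop = 500L,
  target_const_donor = 1, target_const_acc = 1,
  target_cryptic_donor = 0.5, target_cryptic_acc = 0.5,
  alt_3p = FALSE, alt_5p = FALSE, intron_retention = FALSE,
  alt_position = "in_exon", alt_3p_end_trim = 0L, alt_5p_start_trim = 0L,
  min_alt_dist = 40L, track_splice_scores = FALSE,
  seed = 1L, predictor = "surrogate", lambda = 10L, out = NULL
)

.usage <- function() {
  paste0(
    "usage: splicevolver evolve --initial_cds SEQ --initial_intron1 SEQ ",
    "--ce_start N --ce_end N [--aa generate_it|PROTEIN] [design and ",
    "mutation flags...]\nsee ?parse_design_command for the full flag list"
  )
}

#' Parse a design command line into a run configuration
#'
#' Accepts the flag vocabulary of the published cryptic-splicing design
#' commands (one string or a token vector). Leading non-flag tokens (an
#' interpreter or program name) are skipped; sequence-valued flags absorb
#' consecutive non-flag tokens, so commands whose long sequences were
#' line-wrapped in print still parse; a repeated flag keeps its last value.
#' `--aa generate_it` means "derive the protein constraint by translating
#' `--initial_cds`". Unknown flags, out-of-range probabilities, missing
#' sequence inputs and contradictory design flags (e.g. `--alt_3p` with
#' `--intron_retention`) are usage errors.
#'
#' @param command Character: a full command line or a vector of tokens.
#' @return A `run_config` list of all parsed fields.
#' @export
#' @examples
#' cfg <- parse_design_command(
#'   "--initial_cds ATGGCTGGATAA --initial_intron1 GTaagNNNNcAG --ce_start 6 --ce_end 6 --alt_3p"
#' )
#' cfg$design_type
parse_design_command <- function(command) {
  if (length(command) == 1 && grepl("\\s", command)) {
    command <- strsplit(trimws(command), "\\s+")[[1]]
  }
  toks <- command[nzchar(command)]
  spec <- .FLAG_SPEC()
  if (length(toks) == 0) {
    abort(.usage(), class = "splicevolver_usage")
  }
  # skip interpreter/program tokens before the first flag
  first_flag <- which(startsWith(toks, "-"))[1]
  if (is.na(first_flag)) abort(.usage(), class = "splicevolver_usage")
  toks <- toks[first_flag:length(toks)]

  cfg <- .CONFIG_DEFAULTS
  i <- 1L
  while (i <= length(toks)) {
    t <- toks[i]
    row <- which(spec$flag == t)
    if (!length(row)) {
      abort(paste0("unknown flag '", t, "'\n", .usage()), class = "splicevolver_usage")
    }
    row <- row[1]
    type <- spec$type[row]
    dest <- spec$dest[row]
    if (type == "flag") {
      cfg[[dest]] <- TRUE
      i <- i + 1L
      next
    }
    if (i == length(toks)) {
      abort(paste0("flag '", t, "' needs a value"), class = "splicevolver_usage")
    }
    if (type == "seq") {
      j <- i + 1L
      parts <- character(0)
      while (j <= length(toks) && !startsWith(toks[j], "-")) {
        parts <- c(parts, toks[j])
        j <- j + 1L
      }
      if (!length(parts)) {
        abort(paste0("flag '", t, "' needs a sequence value"), class = "splicevolver_usage")
      }
      cfg[[dest]] <- paste(parts, collapse = "")
      i <- j
      next
    }
    val <- toks[i + 1L]
    cfg[[dest]] <- switch(type,
      int = {
        x <- suppressWarnings(as.integer(val))
        if (is.na(x)) abort(paste0("flag '", t, "' expects an integer, got '", val, "'"), class = "splicevolver_usage")
        x
      },
      num = {
        x <- suppressWarnings(as.numeric(val))
        if (is.na(x)) abort(paste0("flag '", t, "' expects a number, got '", val, "'"), class = "splicevolver_usage")
        x
      },
      str = val
    )
    i <- i + 2L
  }
  validate_config(structure(cfg, class = "run_config"))
}

#' Validate a run configuration
#'
#' @param cfg A `run_config`.
#' @return The config with `design_type` filled in, or a usage error.
#' @export
validate_config <- function(cfg) {
  probs <- c(
    upstream_mut_chance = cfg$upstream_mut_chance,
    downstream_mut_chance = cfg$downstream_mut_chance,
    intron1_mut_chance = cfg$intron1_mut_chance,
    intron2_mut_chance = cfg$intron2_mut_chance,
    target_const_donor = cfg$target_const_donor,
    target_const_acc = cfg$target_const_acc,
    target_cryptic_donor = cfg$target_cryptic_donor,
    target_cryptic_acc = cfg$target_cryptic_acc
  )
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad)) {
    abort(paste0("values out of [0,1]: ", paste(bad, collapse = ", ")),
      class = "splicevolver_usage"
    )
  }
  if (cfg$n_iterations < 1) abort("-n must be >= 1", class = "splicevolver_usage")
  if (cfg$early_stop > cfg$n_iterations) {
    abort("--early_stop cannot exceed -n", class = "splicevolver_usage")
  }
  n_modes <- sum(cfg$alt_3p, cfg$alt_5p, cfg$intron_retention)
  if (n_modes > 1) {
    abort("contradictory design flags: choose one of --alt_3p / --alt_5p / --intron_retention",
      class = "splicevolver_usage"
    )
  }
  if (is.null(cfg$initial_cds) && (is.null(cfg$aa) || identical(cfg$aa, "generate_it"))) {
    abort("missing sequence input: provide --initial_cds (or --aa with an explicit protein)",
      class = "splicevolver_usage"
    )
  }
  if (is.null(cfg$ce_start)) {
    abort("missing --ce_start", class = "splicevolver_usage")
  }
  if (is.null(cfg$ce_end)) cfg$ce_end <- cfg$ce_start
  cfg$design_type <- if (cfg$alt_3p) {
    "alt3prime_single_intron"
  } else if (cfg$alt_5p) {
    "alt5prime_single_intron"
  } else if (cfg$intron_retention) {
    "intron_retention"
  } else {
    "internal_cassette_exon"
  }
  if (cfg$design_type == "internal_cassette_exon" && cfg$ce_end == cfg$ce_start) {
    abort("cassette designs need --ce_end > --ce_start (equal values denote a single-intron design: pass --alt_3p, --alt_5p or --intron_retention)",
      class = "splicevolver_usage"
    )
  }
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> %s, n=%d, early_stop=%d, seed=%d\n",
    x$design_type %||% "?", x$n_iterations, x$early_stop, x$seed
  ))
  invisible(x)
}

#' Serialize a run configuration to JSON (and back)
#'
#' The round trip `config -> JSON -> config` is the identity, which is what
#' makes a logged run manifest replayable.
#'
#' @param cfg A `run_config`.
#' @param path Optional output path; string returned when `NULL`.
#' @export
config_to_json <- function(cfg, path = NULL) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) {
    return(js)
  }
  writeLines(js, path)
  invisible(path)
}

#' @rdname config_to_json
#' @param json JSON string or path from `config_to_json()`.
#' @export
config_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, obj[names(obj) != "design_type"],
    keep.null = TRUE
  )
  # JSON does not distinguish integer from double: restore the field types
  for (nm in names(cfg)) {
    proto <- .CONFIG_DEFAULTS[[nm]]
    if (is.null(proto) || is.null(cfg[[nm]])) next
    cfg[[nm]] <- if (is.integer(proto)) {
      as.integer(cfg[[nm]])
    } else if (is.double(proto)) {
      as.double(cfg[[nm]])
    } else if (is.logical(proto)) {
      as.logical(cfg[[nm]])
    } else {
      as.character(cfg[[nm]])
    }
  }
  validate_config(structure(cfg, class = "run_config"))
}

#' Build a construct layout from a parsed run configuration
#'
#' Bridges [parse_design_command()] to [build_layout()]: derives the design
#' spec from the flags (`--aa generate_it` takes the protein constraint from
#' translating the initial CDS) and concretizes degenerate template
#' positions with the configured seed.
#'
#' @param cfg A `run_config`.
#' @param seed Overrides `cfg$seed` when given.
#' @return A `construct_layout`.
#' @export
layout_from_config <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  spec <- design_spec(
    design_type = cfg$design_type,
    ce_start = cfg$ce_start, ce_end = cfg$ce_end,
    target_const_donor = cfg$target_const_donor,
    target_const_acc = cfg$target_const_acc,
    target_cryptic_donor = cfg$target_cryptic_donor,
    target_cryptic_acc = cfg$target_cryptic_acc,
    ce_score_weight = cfg$ce_score_weight,
    ignore_end = cfg$ignore_end,
    upstream_mut_chance = cfg$upstream_mut_chance,
    downstream_mut_chance = cfg$downstream_mut_chance,
    intron1_mut_chance = cfg$intron1_mut_chance,
    intron2_mut_chance = cfg$intron2_mut_chance,
    upstream_mut_n = cfg$upstream_mut_n,
    downstream_mut_n = cfg$downstream_mut_n,
    cds_mut_start_trim = cfg$cds_mut_start_trim,
    cds_mut_end_trim = cfg$cds_mut_end_trim,
    min_alt_dist = cfg$min_alt_dist,
    alt_position = cfg$alt_position,
    alt_end_trim = if (cfg$alt_3p) cfg$alt_3p_end_trim else cfg$alt_5p_start_trim,
    n_iterations = cfg$n_iterations, early_stop = cfg$early_stop,
    lambda = cfg$lambda
  )
  build_layout(
    spec,
    cds = cfg$initial_cds,
    intron1 = cfg$initial_intron1,
    intron2 = cfg$initial_intron2,
    five_utr = cfg$five_utr %||% "",
    three_utr = cfg$three_utr %||% "",
    seed = seed %||% cfg$seed
  )
}

#' The bundled published design command
#'
#' Returns the full single-intron alternative-3' mScarlet design command
#' shipped with the package (a published command whose line-wrapped
#' sequences have been rejoined), useful as a worked end-to-end example.
#'
#' @return The command as one string.
#' @export
example_design_command <- function() {
  path <- system.file("extdata", "mscarlet_alt3_command.txt", package = "splicevolver")
  readLines(path, warn = FALSE)[1]
}
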