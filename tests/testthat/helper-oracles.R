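# Independent oracles and small generators shared across tests.

# brute-force fitness: explicit double loop over positions and channels
brute_force_fitness <- function(profile, target) {
  total <- 0
  for (i in seq_len(nrow(profile))) {
    for (channel in c("donor", "acceptor")) {
      t <- target[[paste0(channel, "_target")]][i]
      w <- target[[paste0(channel, "_weight")]][i]
      p <- profile[[channel]][i]
      total <- total + w * abs(t - p)
    }
  }
  -total
}

random_profile_pair <- function(n) {
  list(
    profile = tibble::tibble(
      position = seq_len(n),
      donor = stats::runif(n), acceptor = stats::runif(n)
    ),
    target = tibble::tibble(
      position = seq_len(n),
      donor_target = stats::runif(n), acceptor_target = stats::runif(n),
      donor_weight = stats::runif(n, 0, 3), acceptor_weight = stats::runif(n, 0, 3)
    )
  )
}

# brute-force TG-dimer density at one position (mirrors the documented
# definition, written independently of the package internals)
brute_force_ug_density <- function(seq, window, pos) {
  chars <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  n <- length(chars)
  half <- window %/% 2
  lo <- max(1, pos - half)
  hi <- min(n, lo + window - 1)
  lo <- max(1, hi - window + 1)
  count <- 0
  for (i in lo:(hi - 1)) {
    if (chars[i] == "T" && chars[i + 1] == "G") count <- count + 1
  }
  count / (hi - lo)
}

# random ACGT string
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# all single-base variants of a window at the given positions
single_mismatch_variants <- function(window, positions) {
  out <- character(0)
  chars <- strsplit(window, "")[[1]]
  for (i in positions) {
    for (b in setdiff(c("A", "C", "G", "T"), chars[i])) {
      w <- chars
      w[i] <- b
      out <- c(out, paste(w, collapse = ""))
    }
  }
  out
}

# protein of the coding (cds_exon/cryptic_exon) positions of a layout
# sequence, computed independently with Biostrings
layout_protein_oracle <- function(layout, sequence = layout$sequence) {
  r <- layout$regions
  coding <- r[r$role %in% c("cds_exon", "cryptic_exon"), ]
  cds <- paste(substring(sequence, coding$start, coding$end), collapse = "")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1, 3 * (nchar(cds) %/% 3)))
  ))
  sub("\\*.*$", "", aa)
}
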