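# Shared fixtures: all synthetic, built in code at test time.

no_ibd <- function() {
  empty <- tibble::tibble(chrom = character(), start = numeric(),
    end = numeric())
  list(P1 = empty, P2 = empty)
}

# Small configurable F1 cross; defaults give a quick clean BC-style setting
# (parent 1 fully heterozygous, parent 2 fully homozygous).
quick_config <- function(n_progeny = 50, chrom_lengths = c(Pp01 = 1e7),
                         marker_density = 20, map_length_morgans = 0.5,
                         het_prob = c(1, 0), error_rate = 0,
                         missing_rate = 0, seed = 1,
                         ibd_intervals = no_ibd()) {
  sim_config(
    n_progeny = n_progeny, chrom_lengths = chrom_lengths,
    marker_density = marker_density,
    map_length_morgans = map_length_morgans,
    ibd_intervals = ibd_intervals, het_prob = het_prob,
    error_rate = error_rate, missing_rate = missing_rate, seed = seed
  )
}

# Hand-built genotype matrix from a character call matrix.
toy_geno <- function(calls, chrom = "Pp01", pos = NULL) {
  m <- nrow(calls)
  if (is.null(pos)) pos <- seq_len(m) * 1e5
  pos <- as.integer(pos)
  markers <- tibble::tibble(
    marker = paste0(chrom, "_", pos), chrom = chrom, pos = pos
  )
  geno_matrix(markers, calls, parents = c("P1", "P2"))
}

# Hand-built marker states (binning-layer container).
toy_states <- function(states, pos, chrom = "Pp01") {
  pos <- as.integer(pos)
  markers <- tibble::tibble(
    marker = paste0(chrom, "_", pos), chrom = chrom, pos = pos
  )
  marker_states(markers, states)
}
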