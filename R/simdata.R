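# Synthetic F1 populations with the statistical structure the downstream
# analysis assumes: two outbred parents, eight chromosomes, Poisson
# crossovers without interference, parent-specific IBD segments carrying no
# heterozygosity, uniform genotyping-error flips, missing-data injection,
# QTLs with additive + dominance effects, and CIELAB color values generated
# from latent grades.

# Approximate peach chromosome lengths (bp), dihaploid reference v2.
peach_chrom_lengths <- c(
  Pp01 = 47.8e6, Pp02 = 30.4e6, Pp03 = 27.4e6, Pp04 = 25.8e6,
  Pp05 = 18.5e6, Pp06 = 30.8e6, Pp07 = 22.6e6, Pp08 = 22.6e6
)

#' Simulation configuration for a synthetic F1 cross
#'
#' Bundles and validates the parameters of the synthetic-data generator. The
#' defaults emulate the study design the package targets: an F1 progeny of
#' 235 individuals from two heterozygous parents over eight chromosomes,
#' with parent-specific identical-by-descent (IBD) segments in which that
#' parent carries no heterozygosity.
#'
#' @param n_progeny Number of F1 individuals (default 235).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param marker_density Expected polymorphic markers per Mb (default 25, a
#'   desk-scale density that preserves the many-markers-per-crossover regime).
#' @param map_length_morgans Expected crossovers per chromosome per meiosis
#'   (default 0.6, i.e. ~60 cM chromosomes).
#' @param ibd_intervals Named list with elements `P1` and `P2`, each a tibble
#'   (`chrom`, `start`, `end`) of intervals within which that parent is
#'   homozygous at every marker. Defaults place one large IBD block per
#'   parent (chromosome 5 for P1, chromosome 2 for P2), echoing the
#'   near-whole-chromosome IBD blocks seen in real cultivars.
#' @param het_prob Probability that a parent is heterozygous at a marker
#'   outside its IBD intervals (default 0.6). A length-2 vector gives each
#'   parent its own probability.
#' @param error_rate Per-genotype probability of a flip to one of the other
#'   two states (default 0.01).
#' @param missing_rate Per-genotype missing probability (default 0.05).
#' @param seed Integer seed; all randomness in the generator flows from it
#'   through deterministic per-stage derived seeds.
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(n_progeny = 50, chrom_lengths = c(Pp01 = 1e7), seed = 1)
#' @export
sim_config <- function(n_progeny = 235,
                       chrom_lengths = peach_chrom_lengths,
                       marker_density = 25,
                       map_length_morgans = 0.6,
                       ibd_intervals = NULL,
                       het_prob = 0.6,
                       error_rate = 0.01,
                       missing_rate = 0.05,
                       seed = 1L) {
  stopifnot(
    n_progeny >= 2, length(chrom_lengths) >= 1, all(chrom_lengths > 0),
    marker_density > 0, map_length_morgans >= 0,
    all(het_prob >= 0), all(het_prob <= 1), length(het_prob) %in% 1:2,
    error_rate >= 0, error_rate <= 1,
    missing_rate >= 0, missing_rate <= 1
  )
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- sprintf("Pp%02d", seq_along(chrom_lengths))
  }
  if (is.null(ibd_intervals)) {
    ibd_intervals <- list(
      P1 = if ("Pp05" %in% names(chrom_lengths)) {
        tibble::tibble(chrom = "Pp05", start = 1,
          end = floor(0.6 * chrom_lengths[["Pp05"]]))
      } else {
        tibble::tibble(chrom = character(), start = numeric(),
          end = numeric())
      },
      P2 = if ("Pp02" %in% names(chrom_lengths)) {
        tibble::tibble(chrom = "Pp02", start = 1,
          end = floor(0.5 * chrom_lengths[["Pp02"]]))
      } else {
        tibble::tibble(chrom = character(), start = numeric(),
          end = numeric())
      }
    )
  }
  stopifnot(is.list(ibd_intervals), all(c("P1", "P2") %in% names(ibd_intervals)))
  for (p in c("P1", "P2")) {
    iv <- tibble::as_tibble(ibd_intervals[[p]])
    if (nrow(iv)) {
      stopifnot(
        all(iv$chrom %in% names(chrom_lengths)),
        all(iv$start >= 1),
        all(iv$end <= chrom_lengths[iv$chrom]),
        all(iv$start <= iv$end)
      )
    }
    ibd_intervals[[p]] <- iv
  }
  structure(
    list(
      n_progeny = as.integer(n_progeny), chrom_lengths = chrom_lengths,
      marker_density = marker_density,
      map_length_morgans = map_length_morgans,
      ibd_intervals = ibd_intervals, het_prob = rep(het_prob, length.out = 2),
      error_rate = error_rate, missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

in_intervals <- function(chrom, pos, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(intervals))) {
    out <- out | (chrom == intervals$chrom[i] &
      pos >= intervals$start[i] & pos <= intervals$end[i])
  }
  out
}

#' Simulate parental haplotypes and marker positions
#'
#' Places markers along each chromosome at the configured density and draws
#' four parental haplotypes (two per parent). Inside a parent's IBD interval
#' its two haplotypes are forced identical; elsewhere each parent is
#' heterozygous with probability `het_prob`. Alleles are coded 0/1.
#'
#' @param config A [sim_config()].
#' @return A `sim_parents` list with `markers` (tibble `marker`, `chrom`,
#'   `pos`) and `haps`, an integer matrix markers x 4 with columns
#'   `P1.1, P1.2, P2.1, P2.2`.
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 101L), {
    marker_list <- lapply(names(config$chrom_lengths), function(ch) {
      len <- config$chrom_lengths[[ch]]
      n <- rpois(1, config$marker_density * len / 1e6)
      n <- max(n, 2L)
      pos <- sort(sample.int(len, n, replace = FALSE))
      tibble::tibble(chrom = ch, pos = pos)
    })
    markers <- dplyr::bind_rows(marker_list) |>
      dplyr::mutate(marker = paste0(.data$chrom, "_", .data$pos)) |>
      dplyr::relocate("marker")
    if (anyDuplicated(markers$marker)) {
      stop("duplicate marker positions generated; reduce density or retry")
    }
    m <- nrow(markers)
    haps <- matrix(0L, m, 4,
      dimnames = list(markers$marker, c("P1.1", "P1.2", "P2.1", "P2.2")))
    for (pi in 1:2) {
      ibd <- in_intervals(markers$chrom, markers$pos,
        config$ibd_intervals[[paste0("P", pi)]])
      het <- rbinom(m, 1, config$het_prob[pi]) == 1 & !ibd
      # heterozygous markers carry alleles in consistent orientation
      # (haplotype 1 = allele 0), emulating curated AHB labels that are
      # locally consistent with the diplotypes; homozygous: random allele
      h1 <- ifelse(het, 0L, rbinom(m, 1, 0.5))
      h2 <- ifelse(het, 1L, h1)
      haps[, 2 * pi - 1] <- as.integer(h1)
      haps[, 2 * pi] <- as.integer(h2)
    }
    structure(list(markers = markers, haps = haps, config = config),
      class = "sim_parents")
  })
}

#' Simulate F1 progeny by meiosis with Poisson crossovers
#'
#' Each meiosis draws a Poisson number of crossovers per chromosome (mean
#' `map_length_morgans`), placed uniformly on the physical length with no
#' interference, and transmits the resulting recombinant haplotype. True
#' progeny genotypes are the union of one transmitted haplotype per parent.
#'
#' @param parents A `sim_parents` object from [simulate_parents()].
#' @param n_progeny Number of F1 individuals.
#' @param map_length_morgans Expected crossovers per chromosome per meiosis.
#' @param seed Integer seed.
#' @return A `true_population` list with elements `markers`, `parents`,
#'   `transmitted` (list of two 0/1 matrices, the allele transmitted by each
#'   parent), `true_geno` (markers x progeny allele-count matrix 0/1/2),
#'   `true_calls` (same in AHB coding), and `crossovers` (tibble
#'   `individual`, `parent`, `chrom`, `pos`).
#' @export
simulate_progeny <- function(parents, n_progeny = parents$config$n_progeny,
                             map_length_morgans =
                               parents$config$map_length_morgans,
                             seed = derive_seed(parents$config$seed, 202L)) {
  stopifnot(inherits(parents, "sim_parents"), n_progeny >= 1)
  markers <- parents$markers
  chroms <- unique(markers$chrom)
  lens <- parents$config$chrom_lengths
  ids <- sprintf("F1_%03d", seq_len(n_progeny))
  m <- nrow(markers)
  with_seed(seed, {
    transmitted <- list(
      P1 = matrix(0L, m, n_progeny, dimnames = list(markers$marker, ids)),
      P2 = matrix(0L, m, n_progeny, dimnames = list(markers$marker, ids))
    )
    xo_list <- list()
    for (ch in chroms) {
      idx <- which(markers$chrom == ch)
      pos <- markers$pos[idx]
      len <- lens[[ch]]
      for (pi in 1:2) {
        hap_a <- parents$haps[idx, 2 * pi - 1]
        hap_b <- parents$haps[idx, 2 * pi]
        for (j in seq_len(n_progeny)) {
          k <- rpois(1, map_length_morgans)
          breaks <- if (k > 0) sort(runif(k, 0, len)) else numeric(0)
          start <- rbinom(1, 1, 0.5)
          # haplotype index at each marker: parity of crossovers passed
          hap_idx <- (start + findInterval(pos, breaks)) %% 2
          transmitted[[pi]][idx, j] <- ifelse(hap_idx == 0, hap_a, hap_b)
          if (k > 0) {
            xo_list[[length(xo_list) + 1]] <- tibble::tibble(
              individual = ids[j], parent = paste0("P", pi),
              chrom = ch, pos = breaks
            )
          }
        }
      }
    }
    true_geno <- transmitted$P1 + transmitted$P2
    true_calls <- matrix(c("A", "H", "B")[true_geno + 1L], m, n_progeny,
      dimnames = dimnames(true_geno))
    crossovers <- if (length(xo_list)) dplyr::bind_rows(xo_list) else
      tibble::tibble(individual = character(), parent = character(),
        chrom = character(), pos = numeric())
    structure(
      list(
        markers = markers, parents = parents, transmitted = transmitted,
        true_geno = true_geno, true_calls = true_calls,
        crossovers = crossovers, ids = ids
      ),
      class = "true_population"
    )
  })
}

#' Inject genotyping errors and missing data
#'
#' Each progeny call is independently flipped to one of the two other AHB
#' states with probability `error_rate`, then set missing with probability
#' `missing_rate`. Parental calls are carried through unchanged (the filter
#' cascade presumes curated parental genotypes).
#'
#' @param truth A `true_population` from [simulate_progeny()].
#' @param error_rate,missing_rate Per-genotype rates in `[0, 1]`.
#' @param seed Integer seed.
#' @return A [geno_matrix()] including parent columns `P1`, `P2`, with
#'   attributes `realized_error_rate` and `realized_missing_rate`.
#' @export
degrade_genotypes <- function(truth,
                              error_rate = truth$parents$config$error_rate,
                              missing_rate =
                                truth$parents$config$missing_rate,
                              seed = derive_seed(truth$parents$config$seed,
                                303L)) {
  stopifnot(inherits(truth, "true_population"),
    error_rate >= 0, error_rate <= 1, missing_rate >= 0, missing_rate <= 1)
  calls <- truth$true_calls
  n_cells <- length(calls)
  with_seed(seed, {
    flip <- runif(n_cells) < error_rate
    if (any(flip)) {
      states <- c("A", "H", "B")
      cur <- calls[flip]
      # flip to a uniformly random *different* state
      pick <- vapply(cur, function(s) sample(setdiff(states, s), 1), "")
      calls[flip] <- pick
    }
    miss <- runif(n_cells) < missing_rate
    calls[miss] <- NA_character_
  })
  p_haps <- truth$parents$haps
  p1 <- c("A", "H", "B")[p_haps[, "P1.1"] + p_haps[, "P1.2"] + 1L]
  p2 <- c("A", "H", "B")[p_haps[, "P2.1"] + p_haps[, "P2.2"] + 1L]
  full <- cbind(P1 = p1, P2 = p2, calls)
  out <- geno_matrix(truth$markers, full, parents = c("P1", "P2"))
  attr(out, "realized_error_rate") <- mean(flip)
  attr(out, "realized_missing_rate") <- mean(miss)
  out
}

#' Simulate phenotypes from QTL effects on true genotypes
#'
#' Each QTL acts through the true genotype of the nearest simulated marker:
#' the A homozygote contributes `+a`, the heterozygote `d`, and the B
#' homozygote `-a` (so a = (A - B) / 2 and d = H - (A + B) / 2 by
#' construction). Gaussian residual noise with the per-QTL `sd` is added.
#'
#' @param truth A `true_population`.
#' @param qtl_specs Tibble with columns `chrom`, `pos`, `a`, `d`, `sd`.
#' @param trait,year Labels attached to the output.
#' @param seed Integer seed.
#' @return Tibble `individual`, `trait`, `year`, `value`.
#' @export
simulate_phenotypes <- function(truth, qtl_specs, trait = "trait",
                                year = 2021L,
                                seed = derive_seed(
                                  truth$parents$config$seed, 404L)) {
  stopifnot(inherits(truth, "true_population"))
  qtl_specs <- tibble::as_tibble(qtl_specs)
  stopifnot(all(c("chrom", "pos", "a", "d", "sd") %in% names(qtl_specs)),
    all(qtl_specs$sd >= 0))
  lens <- truth$parents$config$chrom_lengths
  if (!all(qtl_specs$chrom %in% names(lens)) ||
    any(qtl_specs$pos < 1 | qtl_specs$pos > lens[qtl_specs$chrom])) {
    stop("QTL position outside simulated chromosomes")
  }
  n <- length(truth$ids)
  value <- numeric(n)
  with_seed(seed, {
    for (i in seq_len(nrow(qtl_specs))) {
      idx <- which(truth$markers$chrom == qtl_specs$chrom[i])
      near <- idx[which.min(abs(truth$markers$pos[idx] - qtl_specs$pos[i]))]
      g <- truth$true_geno[near, ] # 0 = A, 1 = H, 2 = B
      eff <- c(qtl_specs$a[i], qtl_specs$d[i], -qtl_specs$a[i])[g + 1L]
      noise <- if (qtl_specs$sd[i] > 0) rnorm(n, 0, qtl_specs$sd[i]) else 0
      value <- value + eff + noise
    }
  })
  tibble::tibble(individual = truth$ids, trait = trait,
    year = as.integer(year), value = value)
}

#' Simulate CIELAB color measurements from latent grades
#'
#' Draws a latent color grade per sample, then generates (L, a*, b*) so that
#' the specified linear combination `b0 + b1*L + b2*a + b3*b` reproduces the
#' grade up to Gaussian noise (noise is added on the grade scale before
#' solving for b*). `L` and `a*` co-vary with the grade so that no single
#' channel is a perfect predictor.
#'
#' @param n_samples Number of samples.
#' @param coefficients Numeric `c(b0, b1, b2, b3)`; `b3` must be nonzero.
#' @param grade_range Integer vector of grades to draw from (default `1:10`,
#'   the 10-level color card).
#' @param noise_sd Grade-scale noise standard deviation (default 0.25).
#' @param seed Integer seed.
#' @return Tibble `L`, `a`, `b`, `grade`.
#' @export
simulate_color <- function(n_samples, coefficients = c(-4, -0.05, 0.08, 0.12),
                           grade_range = 1:10, noise_sd = 0.25, seed = 1L) {
  stopifnot(n_samples >= 1, length(coefficients) == 4,
    coefficients[4] != 0, noise_sd >= 0)
  if (length(unique(grade_range)) == 1) {
    warning("grade_range has a single level: zero-variance response")
  }
  with_seed(seed, {
    g <- if (length(grade_range) == 1) rep(grade_range, n_samples) else
      sample(grade_range, n_samples, replace = TRUE)
    L <- 75 - 1.5 * g + rnorm(n_samples, 0, 2)
    a <- 2 + 1.2 * g + rnorm(n_samples, 0, 1.5)
    b <- (g - coefficients[1] - coefficients[2] * L -
      coefficients[3] * a) / coefficients[4]
    # grading noise enters the recorded grade, not the color channels, so
    # the linear combination of (L, a, b) reproduces the grade up to noise
    e <- if (noise_sd > 0) rnorm(n_samples, 0, noise_sd) else 0
    tibble::tibble(L = L, a = a, b = b, grade = as.numeric(g) + e)
  })
}

#' Simulate a complete degraded F1 genotype data set
#'
#' Convenience wrapper chaining [simulate_parents()], [simulate_progeny()]
#' and [degrade_genotypes()] under one configuration.
#'
#' @param config A [sim_config()].
#' @return List with `truth` (the `true_population`) and `geno` (the
#'   degraded [geno_matrix()]).
#' @export
simulate_f1_population <- function(config) {
  parents <- simulate_parents(config)
  truth <- simulate_progeny(parents)
  geno <- degrade_genotypes(truth)
  list(truth = truth, geno = geno)
}
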