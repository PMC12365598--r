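test_that("phasing leaves in-phase data alone and repairs inversions", {
  # 6 markers x 10 individuals, constant haplotype profile
  base <- matrix(rep(c(rep("H", 5), rep("A", 5)), 6), nrow = 6,
    byrow = TRUE)
  colnames(base) <- sprintf("F1_%02d", 1:10)
  ms <- toy_states(base, pos = 1:6 * 1e5)
  ph <- phase_markers(ms)
  expect_false(any(ph$markers$flipped))
  expect_true(all(apply(ph$states, 2, function(col) length(unique(col))) == 1))

  # invert every second marker: alternating flips must restore constancy
  inv <- base
  swap <- seq(2, 6, by = 2)
  inv[swap, ] <- ifelse(base[swap, ] == "H", "A", "H")
  ph2 <- phase_markers(toy_states(inv, pos = 1:6 * 1e5))
  expect_equal(which(ph2$markers$flipped), swap)
  mism <- mean(ph2$states[-1, ] != ph2$states[-6, ])
  expect_equal(mism, 0)
})

test_that("phased states recover transmitted haplotypes up to inversion", {
  cfg <- quick_config(n_progeny = 40, chrom_lengths = c(Pp01 = 8e6,
    Pp02 = 8e6), marker_density = 15, seed = 7)
  tru <- simulate_progeny(simulate_parents(cfg))
  flt <- filter_genotypes(degrade_genotypes(tru))
  ph <- phase_markers(flt$sets$sf_set)
  # truth: the haplotype index transmitted by parent 1
  par <- tru$parents
  idx <- match(ph$markers$marker, tru$markers$marker)
  hap2_allele <- par$haps[idx, "P1.2"]
  hap_index <- 1L * (tru$transmitted$P1[idx, ] == hap2_allele)
  for (ch in unique(ph$markers$chrom)) {
    rows <- ph$markers$chrom == ch
    agree <- mean(ph$states[rows, ] == hap_index[rows, ], na.rm = TRUE)
    expect_true(agree > 0.999 || agree < 0.001)
  }
})

test_that("a single chromosome marker is returned unchanged with warning", {
  ms <- toy_states(matrix(c("H", "A"), 1, dimnames = list(NULL,
    c("F1_01", "F1_02"))), pos = 1e5)
  expect_warning(ph <- phase_markers(ms), "< 2 markers")
  expect_equal(unname(ph$states[1, ]), c(1L, 0L))
})

test_that("the DR rule accepts and rejects the canonical run shapes", {
  rule <- dr_rule()
  # isolated single-marker flip: error, regardless of span
  det1 <- detect_breakpoints(c(0, 0, 1, 0, 0),
    pos = c(1, 2, 3, 4, 5) * 2e5, rule)
  expect_equal(nrow(det1$breakpoints), 0)
  expect_equal(det1$errors, 3L)

  # two-marker run spanning 150 kb: two accepted breakpoints
  det2 <- detect_breakpoints(c(0, 0, 1, 1, 0, 0),
    pos = c(100, 200, 300, 450, 550, 650) * 1e3, rule)
  expect_equal(det2$breakpoints$left_idx, c(2L, 4L))
  expect_equal(det2$breakpoints$right_idx, c(3L, 5L))
  expect_equal(length(det2$errors), 0)

  # two-marker run spanning 50 kb: rejected, calls flagged
  det3 <- detect_breakpoints(c(0, 0, 1, 1, 0, 0),
    pos = c(100, 200, 300, 350, 550, 650) * 1e3, rule)
  expect_equal(nrow(det3$breakpoints), 0)
  expect_equal(det3$errors, c(3L, 4L))
})

test_that("terminal runs are single recombinations, always accepted", {
  det <- detect_breakpoints(c(0, 0, 0, 1), pos = 1:4 * 1e4, dr_rule())
  expect_equal(det$breakpoints$left_idx, 3L)
  expect_equal(det$breakpoints$right_idx, 4L)
  expect_equal(length(det$errors), 0)
})

test_that("missing calls are skipped, not treated as state changes", {
  det <- detect_breakpoints(c(0, NA, 1, 1, NA, 0, 0),
    pos = c(1, 2, 3, 4.2, 5, 6, 7) * 1e5, dr_rule())
  # 1-run spans 1.2e5 >= 1e5 with 2 markers: accepted
  expect_equal(nrow(det$breakpoints), 2)
  expect_equal(length(det$errors), 0)
})

test_that("three-state transitions through H are not DR candidates", {
  det <- detect_breakpoints(c("A", "A", "H", "B", "B"),
    pos = 1:5 * 1e4, dr_rule())
  expect_equal(nrow(det$breakpoints), 2)
  expect_equal(length(det$errors), 0)
})

test_that("bins form at true crossovers and conserve markers", {
  cfg <- quick_config(n_progeny = 50, chrom_lengths = c(Pp01 = 1e7),
    marker_density = 2, map_length_morgans = 0.4, seed = 15)
  tru <- simulate_progeny(simulate_parents(cfg))
  flt <- filter_genotypes(degrade_genotypes(tru))
  ph <- phase_markers(flt$sets$sf_set)
  bs <- build_bins(ph)
  # conservation: every marker in exactly one bin
  expect_equal(sum(bs$bins$n_markers), nrow(ph$markers))
  expect_false(any(duplicated(unlist(bs$bins$members))))
  # oracle: boundaries from the true transmitted haplotypes (clean data).
  # Het markers carry alleles in haplotype order, so the transmitted
  # allele sequence is the haplotype-index sequence; single-marker
  # reversions (true double crossovers around one marker) are removed
  # first, since the acceptance rule deliberately treats them as errors.
  idx <- match(ph$markers$marker, tru$markers$marker)
  tm <- tru$transmitted$P1[idx, ]
  true_cuts <- integer(0)
  for (j in seq_len(ncol(tm))) {
    s <- tm[, j]
    repeat {
      r <- rle(s)
      if (length(r$lengths) <= 2) break
      ends <- cumsum(r$lengths)
      bad <- which(r$lengths == 1 &
        seq_along(r$lengths) > 1 &
        seq_along(r$lengths) < length(r$lengths))
      if (!length(bad)) break
      for (b in bad) s[ends[b]] <- r$values[b - 1]
    }
    true_cuts <- c(true_cuts, cumsum(rle(s)$lengths))
  }
  true_cuts <- sort(unique(true_cuts[true_cuts < nrow(tm)]))
  got_cuts <- sort(match(
    bs$bins$representative[-1], ph$markers$marker) - 1)
  expect_equal(got_cuts, true_cuts)
})

test_that("no accepted breakpoints means one bin per chromosome", {
  cfg <- quick_config(n_progeny = 20, chrom_lengths = c(Pp01 = 2e6,
    Pp02 = 2e6), marker_density = 5, map_length_morgans = 0, seed = 4)
  tru <- simulate_progeny(simulate_parents(cfg))
  flt <- filter_genotypes(degrade_genotypes(tru))
  bs <- build_bins(phase_markers(flt$sets$sf_set))
  expect_equal(nrow(bs$bins), length(unique(bs$bins$chrom)))
})

test_that("isolated genotyping errors are absorbed without splitting bins", {
  cfg <- quick_config(n_progeny = 50, chrom_lengths = c(Pp01 = 1e7),
    marker_density = 20, map_length_morgans = 0.4, seed = 25)
  tru <- simulate_progeny(simulate_parents(cfg))
  bins_clean <- build_bins(phase_markers(
    filter_genotypes(degrade_genotypes(tru,
      error_rate = 0, missing_rate = 0))$sets$sf_set))
  bins_err <- build_bins(phase_markers(
    filter_genotypes(degrade_genotypes(tru,
      error_rate = 0.01, missing_rate = 0))$sets$sf_set))
  expect_equal(nrow(bins_err$bins), nrow(bins_clean$bins))
  expect_gt(nrow(bins_err$errors), 0)
})

test_that("one-bin construction imputes missing and error-flagged calls", {
  inds <- c("F1_01", "F1_02", "F1_03")
  # one bin of four markers: ind 1's representative call is missing,
  # ind 2 has an isolated internal flip (rejected DR, error-flagged)
  states <- matrix(c(
    NA, 0L, 0L,
    0L, 1L, 0L,
    0L, 0L, 0L,
    0L, 0L, 0L
  ), nrow = 4, byrow = TRUE, dimnames = list(NULL, inds))
  bs <- build_bins(toy_states(states, pos = 1:4 * 2e5), dr_rule())
  expect_equal(nrow(bs$bins), 1)
  expect_equal(bs$errors$individual, "F1_02")
  ob <- make_onebin(bs)
  expect_equal(unname(ob$states[1, ]), c(0L, 0L, 0L))
  expect_equal(ob$markers$n_markers, 4L)
  expect_equal(ob$markers$marker, "Pp01_200000")
})

test_that("a contradictory representative call is replaced by the rest", {
  inds <- c("F1_01", "F1_02", "F1_03")
  # ind 1 recombines between markers 1 and 2 (accepted terminal run),
  # creating bins {m1} and {m2..m5}; ind 2's isolated flip at m2 (the
  # second bin's representative) is a rejected DR
  states <- matrix(c(
    0L, 0L, 0L,
    1L, 1L, 0L,
    1L, 0L, 0L,
    1L, 0L, 0L,
    1L, 0L, 0L
  ), nrow = 5, byrow = TRUE, dimnames = list(NULL, inds))
  bs <- build_bins(toy_states(states, pos = 1:5 * 2e5), dr_rule())
  expect_equal(bs$bins$n_markers, c(1L, 4L))
  ob <- make_onebin(bs)
  # representative m2 call of ind 2 contradicts the rest of its bin
  expect_equal(unname(ob$states[2, ]), c(1L, 0L, 0L))
})

test_that("single-marker-bin rejected-DR calls become missing", {
  inds <- c("F1_01", "F1_02", "F1_03")
  # boundaries from inds 1 and 2 isolate marker 3 as a single-marker bin;
  # ind 3's isolated flip there is a rejected DR
  states <- matrix(c(
    0L, 0L, 0L,
    0L, 0L, 0L,
    1L, 0L, 1L,
    1L, 1L, 0L,
    1L, 1L, 0L
  ), nrow = 5, byrow = TRUE, dimnames = list(NULL, inds))
  bs <- build_bins(toy_states(states, pos = 1:5 * 2e5), dr_rule())
  expect_equal(bs$bins$n_markers, c(2L, 1L, 2L))
  expect_true(any(bs$errors$individual == "F1_03"))
  ob <- make_onebin(bs)
  expect_true(is.na(ob$states[2, "F1_03"]))
  expect_equal(unname(ob$states[2, 1:2]), c(1L, 0L))
})

test_that("divergent markers are dropped by local-consensus curation", {
  base <- matrix(0L, 10, 20,
    dimnames = list(NULL, sprintf("F1_%02d", 1:20)))
  base[5, 1:10] <- 1L # half the individuals disagree at marker 5
  ph <- marker_states(
    tibble::tibble(marker = paste0("Pp01_", 1:10 * 1e5), chrom = "Pp01",
      pos = 1:10 * 1e5),
    base
  )
  out <- drop_divergent_markers(ph, max_disagree = 0.2)
  expect_equal(nrow(out$markers), 9)
  expect_false(paste0("Pp01_", 5e5) %in% out$markers$marker)
})

test_that("binning keeps apparent recombination near truth under error", {
  cfg <- quick_config(n_progeny = 40, chrom_lengths = c(Pp01 = 1e7),
    marker_density = 25, map_length_morgans = 0.5, seed = 33)
  tru <- simulate_progeny(simulate_parents(cfg))
  deg <- degrade_genotypes(tru, error_rate = 0.01, missing_rate = 0)
  flt <- filter_genotypes(deg)
  ph <- phase_markers(flt$sets$sf_set)
  ob <- make_onebin(build_bins(ph))
  count_apparent <- function(ms) {
    tot <- 0
    for (v in seq_len(ncol(ms$states))) {
      s <- ms$states[, v]
      s <- s[!is.na(s)]
      tot <- tot + sum(diff(s) != 0)
    }
    tot
  }
  pos <- ph$markers$pos
  xo <- tru$crossovers[tru$crossovers$parent == "P1" &
    tru$crossovers$pos > min(pos) & tru$crossovers$pos < max(pos), ]
  truth <- nrow(xo)
  apparent_binned <- count_apparent(ob)
  apparent_raw <- count_apparent(ph)
  expect_lt(abs(apparent_binned - truth) / truth, 0.15)
  expect_gt(apparent_raw / truth, 5)
})
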