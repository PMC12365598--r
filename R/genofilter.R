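# Marker filtering cascade for an F1 pseudo-testcross population:
# biallelic -> informative parents -> Mendelian masking -> offspring
# missingness -> segregation, then AHB orientation and the split into the
# two 1:1 parental datasets and the 1:2:1 combined dataset.

#' Filtering thresholds for the marker cascade
#'
#' @param max_offspring_missing Markers are dropped when the fraction of
#'   missing offspring genotypes *exceeds* this value (default 0.20).
#' @param fa_max,fa_min Markers are dropped when the A-genotype frequency
#'   among non-missing offspring is `> fa_max` (default 0.9) or `< fa_min`
#'   (default 0.1).
#' @param fh_min Markers are dropped when the H frequency is `< fh_min`
#'   (default 0.15).
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_offspring_missing = 0.20, fa_max = 0.9,
                          fa_min = 0.1, fh_min = 0.15) {
  stopifnot(0 <= fa_min, fa_min < fa_max, fa_max <= 1,
    fh_min >= 0, fh_min <= 1,
    max_offspring_missing >= 0, max_offspring_missing <= 1)
  structure(list(
    max_offspring_missing = max_offspring_missing,
    fa_max = fa_max, fa_min = fa_min, fh_min = fh_min
  ), class = "filter_config")
}

subset_markers <- function(geno, keep) {
  geno_matrix(geno$markers[keep, , drop = FALSE],
    geno$calls[keep, , drop = FALSE], geno$parents)
}

#' Drop uninformative markers
#'
#' Removes markers where either parental genotype is missing or both parents
#' are homozygous (which includes A x B markers, monomorphic or uniformly
#' heterozygous in the progeny). Retained markers have both parental calls
#' present and at least one heterozygous parent.
#'
#' @param geno A [geno_matrix()].
#' @return A filtered [geno_matrix()].
#' @export
drop_uninformative <- function(geno) {
  p1 <- geno$calls[, geno$parents[1]]
  p2 <- geno$calls[, geno$parents[2]]
  keep <- !is.na(p1) & !is.na(p2) & (p1 == "H" | p2 == "H")
  subset_markers(geno, keep)
}

# Offspring states possible for each ordered parental genotype pair,
# by enumeration of transmitted alleles.
allowed_offspring <- function(p1, p2) {
  gametes <- list(A = 0L, H = 0:1, B = 1L)
  g <- outer(gametes[[p1]], gametes[[p2]], `+`)
  c("A", "H", "B")[sort(unique(as.vector(g))) + 1L]
}

#' Mask Mendelian-inconsistent offspring calls
#'
#' Offspring genotypes impossible given the parental genotypes (e.g. a B
#' offspring from an A x H cross) are set to missing.
#'
#' @param geno A [geno_matrix()].
#' @return The [geno_matrix()] with impossible calls set `NA` and an
#'   attribute `n_masked` giving the number of masked calls.
#' @export
mendelian_mask <- function(geno) {
  p1 <- geno$calls[, geno$parents[1]]
  p2 <- geno$calls[, geno$parents[2]]
  prog <- progeny_ids(geno)
  calls <- geno$calls
  n_masked <- 0L
  combos <- unique(stats::na.omit(cbind(p1, p2)))
  for (i in seq_len(nrow(combos))) {
    ok <- allowed_offspring(combos[i, 1], combos[i, 2])
    if (length(ok) == 3) next
    rows <- which(p1 == combos[i, 1] & p2 == combos[i, 2])
    block <- calls[rows, prog, drop = FALSE]
    bad <- !is.na(block) & !(block %in% ok)
    if (any(bad)) {
      block[bad] <- NA_character_
      calls[rows, prog] <- block
      n_masked <- n_masked + sum(bad)
    }
  }
  out <- geno_matrix(geno$markers, calls, geno$parents)
  attr(out, "n_masked") <- n_masked
  out
}

#' Filter markers on offspring missingness
#'
#' Drops markers whose fraction of missing offspring genotypes exceeds
#' `config$max_offspring_missing` (strictly greater than; a marker at
#' exactly the threshold is kept).
#'
#' @param geno A [geno_matrix()].
#' @param config A [filter_config()].
#' @return A filtered [geno_matrix()].
#' @export
missingness_filter <- function(geno, config = filter_config()) {
  prog <- progeny_calls(geno)
  frac <- rowMeans(is.na(prog))
  subset_markers(geno, frac <= config$max_offspring_missing)
}

#' Orient AHB labels at 1:1 markers
#'
#' At markers where exactly one parent is heterozygous, relabels the two
#' homozygous classes (swapping A and B throughout the marker's calls) so
#' that the homozygous parent's genotype is coded A. This is a pure
#' relabeling of the arbitrary allele orientation inherited from the
#' reference; without it, frequency rules expressed in terms of f(A) would
#' discard valid H x B markers whose progeny segregate {H, B}.
#'
#' @param geno A [geno_matrix()].
#' @return A relabeled [geno_matrix()].
#' @export
recode_ahb <- function(geno) {
  p1 <- geno$calls[, geno$parents[1]]
  p2 <- geno$calls[, geno$parents[2]]
  flip <- (p1 == "B" & p2 == "H") | (p1 == "H" & p2 == "B")
  flip[is.na(flip)] <- FALSE
  calls <- geno$calls
  if (any(flip)) {
    block <- calls[flip, , drop = FALSE]
    swapped <- block
    swapped[block == "A"] <- "B"
    swapped[block == "B"] <- "A"
    calls[flip, ] <- swapped
  }
  geno_matrix(geno$markers, calls, geno$parents)
}

#' Filter markers on segregation pattern
#'
#' Applies, among non-missing offspring: (i) drop markers exhibiting a
#' single genotype; (ii) drop markers with f(A) > `fa_max` or
#' f(A) < `fa_min`; (iii) drop markers with f(H) < `fh_min`. Markers with
#' zero non-missing offspring are dropped with a warning. Call
#' [recode_ahb()] first so the f(A) rule sees oriented labels.
#'
#' @param geno A [geno_matrix()].
#' @param config A [filter_config()].
#' @return A filtered [geno_matrix()].
#' @export
segregation_filter <- function(geno, config = filter_config()) {
  prog <- progeny_calls(geno)
  n_ok <- rowSums(!is.na(prog))
  if (any(n_ok == 0)) {
    warning(sum(n_ok == 0), " marker(s) with no non-missing offspring dropped")
  }
  fa <- rowSums(prog == "A", na.rm = TRUE) / pmax(n_ok, 1)
  fh <- rowSums(prog == "H", na.rm = TRUE) / pmax(n_ok, 1)
  fb <- rowSums(prog == "B", na.rm = TRUE) / pmax(n_ok, 1)
  n_classes <- (fa > 0) + (fh > 0) + (fb > 0)
  keep <- n_ok > 0 & n_classes > 1 &
    fa <= config$fa_max & fa >= config$fa_min & fh >= config$fh_min
  subset_markers(geno, keep)
}

#' Split filtered markers into pseudo-testcross datasets
#'
#' Partitions markers into the two 1:1 parental datasets (heterozygous in
#' one parent, homozygous in the other) and the 1:2:1 dataset (heterozygous
#' in both parents). In the 1:1 sets, offspring carry states {A, H} relative
#' to the segregating parent; any residual B call (which should have been
#' Mendelian-masked) is set missing.
#'
#' @param geno A filtered, [recode_ahb()]-oriented [geno_matrix()].
#' @return A `testcross_sets` list with elements `sf_set` (parent 1
#'   segregating), `zp_set` (parent 2 segregating), `f2_set` (both), each a
#'   [geno_matrix()], plus `assignment`, a tibble mapping markers to sets.
#' @export
split_testcross <- function(geno) {
  p1 <- geno$calls[, geno$parents[1]]
  p2 <- geno$calls[, geno$parents[2]]
  set <- dplyr::case_when(
    p1 == "H" & p2 == "H" ~ "f2",
    p1 == "H" & p2 != "H" ~ "sf",
    p2 == "H" & p1 != "H" ~ "zp",
    TRUE ~ NA_character_
  )
  clean_1to1 <- function(g) {
    prog <- progeny_ids(g)
    bad <- !is.na(g$calls[, prog]) & g$calls[, prog] == "B"
    if (any(bad)) {
      block <- g$calls[, prog]
      block[bad] <- NA_character_
      g$calls[, prog] <- block
    }
    g
  }
  out <- list(
    sf_set = clean_1to1(subset_markers(geno, !is.na(set) & set == "sf")),
    zp_set = clean_1to1(subset_markers(geno, !is.na(set) & set == "zp")),
    f2_set = subset_markers(geno, !is.na(set) & set == "f2"),
    assignment = tibble::tibble(marker = geno$markers$marker, set = set)
  )
  structure(out, class = "testcross_sets")
}

#' Run the full marker filter cascade
#'
#' Applies, in order: [drop_uninformative()], [mendelian_mask()],
#' [missingness_filter()], [recode_ahb()], [segregation_filter()], then
#' [split_testcross()]. The cascade is idempotent: re-running it on its own
#' output removes nothing further.
#'
#' @param geno A raw [geno_matrix()] (biallelic markers).
#' @param config A [filter_config()].
#' @return A list with `sets` (a `testcross_sets`), `geno` (the filtered
#'   matrix) and `report`, a tibble of marker counts surviving each step.
#' @export
filter_genotypes <- function(geno, config = filter_config()) {
  steps <- list(input = geno)
  steps$informative <- drop_uninformative(steps$input)
  steps$mendelian_masked <- mendelian_mask(steps$informative)
  steps$missingness <- missingness_filter(steps$mendelian_masked, config)
  steps$recoded <- recode_ahb(steps$missingness)
  steps$segregation <- segregation_filter(steps$recoded, config)
  sets <- split_testcross(steps$segregation)
  report <- tibble::tibble(
    step = names(steps),
    n_markers = vapply(steps, function(g) nrow(g$markers), 1L),
    n_masked_calls = c(NA, NA, attr(steps$mendelian_masked, "n_masked"),
      NA, NA, NA)
  )
  list(sets = sets, geno = steps$segregation, report = report)
}
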