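# Genetic map construction from one-bin matrices: two-point recombination
# fraction and LOD (backcross-type for 1:1 data, EM over the intercross
# likelihood for 1:2:1 data), single-linkage grouping, Kosambi distances
# along physical order, IBD-gap detection and map summary statistics.

# Two-point probabilities for the phase-known F2 intercross (coupling):
# rows/cols A, H, B.
f2_class_probs <- function(r) {
  matrix(c(
    (1 - r)^2 / 4, r * (1 - r) / 2, r^2 / 4,
    r * (1 - r) / 2, ((1 - r)^2 + r^2) / 2, r * (1 - r) / 2,
    r^2 / 4, r * (1 - r) / 2, (1 - r)^2 / 4
  ), 3, 3, byrow = TRUE, dimnames = list(c("A", "H", "B"), c("A", "H", "B")))
}

f2_loglik <- function(r, counts) {
  p <- f2_class_probs(r)
  sum(counts[p > 0] * log(p[p > 0]))
}

# Expected recombinant gametes (out of 2) per class, given r.
f2_rec_expect <- function(r) {
  e <- matrix(c(
    0, 1, 2,
    1, 2 * r^2 / ((1 - r)^2 + r^2), 1,
    2, 1, 0
  ), 3, 3, byrow = TRUE)
  e
}

f2_em_rf <- function(counts, tol = 1e-10, max_iter = 1000) {
  n <- sum(counts)
  r <- 0.25
  for (i in seq_len(max_iter)) {
    r_new <- sum(counts * f2_rec_expect(r)) / (2 * n)
    r_new <- min(max(r_new, 1e-12), 0.5 - 1e-12)
    if (abs(r_new - r) < tol) {
      r <- r_new
      break
    }
    r <- r_new
  }
  r
}

#' Two-point recombination fraction and linkage LOD
#'
#' For 1:1 (`design = "BC"`) data the recombination fraction is the
#' recombinant fraction among co-called pairs and
#' `LOD = nR * log10(2 r) + nNR * log10(2 (1 - r))` (with `0 * log10(0) = 0`).
#' For 1:2:1 (`design = "F2"`) data, r is estimated by EM over the standard
#' phase-unknown intercross likelihood; linkage phase (coupling vs
#' repulsion) is resolved by likelihood, and the LOD is the log10 likelihood
#' ratio against r = 0.5.
#'
#' @param x,y Two state vectors over the same individuals (0/1 for BC,
#'   "A"/"H"/"B" for F2).
#' @param design `"BC"` or `"F2"`.
#' @return Tibble with `r_hat`, `lod`, `n` (co-called individuals), and a
#'   logical `defined` (FALSE when fewer than 2 co-called individuals).
#' @export
pairwise_rf_lod <- function(x, y, design = c("BC", "F2")) {
  design <- match.arg(design)
  co <- !is.na(x) & !is.na(y)
  n <- sum(co)
  if (n < 2) {
    return(tibble::tibble(r_hat = NA_real_, lod = NA_real_, n = n,
      defined = FALSE))
  }
  if (design == "BC") {
    nr <- sum(x[co] != y[co])
    nnr <- n - nr
    r <- nr / n
    lod <- (if (nr > 0) nr * log10(2 * r) else 0) +
      (if (nnr > 0) nnr * log10(2 * (1 - r)) else 0)
    return(tibble::tibble(r_hat = r, lod = lod, n = n, defined = TRUE))
  }
  lv <- c("A", "H", "B")
  counts <- table(factor(x[co], lv), factor(y[co], lv))
  counts <- matrix(as.numeric(counts), 3, 3, dimnames = list(lv, lv))
  # repulsion = coupling with one marker's homozygote labels swapped
  counts_rep <- counts[, c(3, 2, 1)]
  r_c <- f2_em_rf(counts)
  r_r <- f2_em_rf(counts_rep)
  ll_c <- f2_loglik(r_c, counts)
  ll_r <- f2_loglik(r_r, counts_rep)
  if (ll_r > ll_c) {
    r <- r_r
    ll <- ll_r
    ll0 <- f2_loglik(0.5, counts_rep)
  } else {
    r <- r_c
    ll <- ll_c
    ll0 <- f2_loglik(0.5, counts)
  }
  tibble::tibble(r_hat = r, lod = (ll - ll0) / log(10), n = n,
    defined = TRUE)
}

# All-pairs BC recombination counts via indicator cross-products.
bc_pair_matrices <- function(states) {
  m0 <- (states == 0L)
  m1 <- (states == 1L)
  m0[is.na(m0)] <- FALSE
  m1[is.na(m1)] <- FALSE
  storage.mode(m0) <- "double"
  storage.mode(m1) <- "double"
  nnr <- tcrossprod(m0) + tcrossprod(m1)
  nr <- tcrossprod(m0, m1) + tcrossprod(m1, m0)
  list(nr = nr, n = nr + nnr)
}

bc_lod_from_counts <- function(nr, n) {
  r <- ifelse(n > 0, nr / n, NA_real_)
  nnr <- n - nr
  term1 <- ifelse(nr > 0, nr * log10(2 * pmax(r, 1e-300)), 0)
  term2 <- ifelse(nnr > 0, nnr * log10(2 * pmax(1 - r, 1e-300)), 0)
  term1 + term2
}

#' Cluster bins into linkage groups by two-point LOD
#'
#' Single-linkage clustering: two bins belong to one group iff they are
#' connected by a chain of pairs with linkage LOD at or above the
#' threshold. Groups are labeled by the majority chromosome of their
#' members.
#'
#' @param onebin A [marker_states()] (one row per bin).
#' @param design `"BC"` or `"F2"`.
#' @param lod_threshold Grouping threshold (default 19).
#' @return Tibble `marker`, `chrom`, `pos`, `group`.
#' @export
group_markers <- function(onebin, design = c("BC", "F2"),
                          lod_threshold = 19) {
  design <- match.arg(design)
  m <- nrow(onebin$markers)
  if (design == "BC") {
    pm <- bc_pair_matrices(onebin$states)
    lod <- bc_lod_from_counts(pm$nr, pm$n)
    lod[pm$n < 2] <- NA_real_
  } else {
    lod <- matrix(NA_real_, m, m)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        lod[i, j] <- lod[j, i] <-
          pairwise_rf_lod(onebin$states[i, ], onebin$states[j, ], "F2")$lod
      }
    }
  }
  # union-find over edges with lod >= threshold
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (is.finite(lod_threshold)) {
    edges <- which(lod >= lod_threshold & upper.tri(lod), arr.ind = TRUE)
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1])
      b <- find(edges[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  comp <- vapply(seq_len(m), find, 1L)
  comp <- match(comp, unique(comp))
  out <- onebin$markers |>
    dplyr::mutate(component = comp) |>
    dplyr::group_by(.data$component) |>
    dplyr::mutate(group_chrom = names(sort(table(.data$chrom),
      decreasing = TRUE))[1]) |>
    dplyr::ungroup()
  # stable group labels: by majority chromosome, then component id
  lab <- out |>
    dplyr::distinct(.data$component, .data$group_chrom) |>
    dplyr::arrange(.data$group_chrom, .data$component) |>
    dplyr::group_by(.data$group_chrom) |>
    dplyr::mutate(suffix = if (dplyr::n() > 1)
      paste0(".", dplyr::row_number()) else "") |>
    dplyr::ungroup() |>
    dplyr::mutate(group = paste0("LG_", .data$group_chrom, .data$suffix))
  out |>
    dplyr::left_join(dplyr::select(lab, "component", "group"),
      by = "component") |>
    dplyr::select(dplyr::any_of(c("marker", "chrom", "pos", "n_markers")),
      "group")
}

#' Build a genetic map from a one-bin matrix
#'
#' Bins are ordered by physical position within each linkage group;
#' cumulative Kosambi cM positions accumulate the consecutive-pair
#' recombination fractions. Undefined consecutive-pair estimates contribute
#' zero distance with a warning; estimates at or above 0.5 are clamped via
#' [kosambi_cm()].
#'
#' @param onebin A [marker_states()] of bin representatives.
#' @param groups Optional grouping tibble from [group_markers()]; by default
#'   each chromosome is one linkage group.
#' @param design `"BC"` or `"F2"`.
#' @param max_gap_cm Clamp for unlinked consecutive pairs (default 49.9).
#' @return A `genetic_map` object: `table` (tibble `group`, `marker`,
#'   `chrom`, `pos`, `n_markers`, `r_adj`, `lod_adj`, `cm`), `states`
#'   (reordered bin states), `design`.
#' @export
build_map <- function(onebin, groups = NULL, design = c("BC", "F2"),
                      max_gap_cm = 49.9) {
  design <- match.arg(design)
  mk <- onebin$markers
  if (!"n_markers" %in% names(mk)) mk$n_markers <- 1L
  if (is.null(groups)) {
    groups <- dplyr::mutate(mk, group = paste0("LG_", .data$chrom))
  }
  tab <- mk |>
    dplyr::left_join(dplyr::select(groups, "marker", "group"),
      by = "marker") |>
    dplyr::arrange(.data$group, .data$chrom, .data$pos)
  states <- onebin$states[match(tab$marker, mk$marker), , drop = FALSE]
  tab$r_adj <- NA_real_
  tab$lod_adj <- NA_real_
  tab$cm <- 0
  n_undef <- 0L
  for (g in unique(tab$group)) {
    idx <- which(tab$group == g)
    if (length(idx) < 2) next
    d <- numeric(length(idx))
    for (k in 2:length(idx)) {
      est <- pairwise_rf_lod(states[idx[k - 1], ], states[idx[k], ], design)
      tab$r_adj[idx[k]] <- est$r_hat
      tab$lod_adj[idx[k]] <- est$lod
      if (!est$defined || is.na(est$r_hat)) {
        n_undef <- n_undef + 1L
        d[k] <- 0
      } else {
        d[k] <- min(
          suppressWarnings(kosambi_cm(est$r_hat, max_cm = max_gap_cm)),
          max_gap_cm
        )
      }
    }
    tab$cm[idx] <- cumsum(d)
  }
  if (n_undef > 0) {
    warning(n_undef, " consecutive-pair estimate(s) undefined; distance 0 imputed")
  }
  structure(list(table = tab, states = states, design = design),
    class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  tot <- x$table |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(cm = max(.data$cm), n = dplyr::n(), .groups = "drop")
  cat("<genetic_map> ", nrow(x$table), " bins in ", nrow(tot),
    " linkage group(s); total ", round(sum(tot$cm), 1), " cM (",
    x$design, " design)\n", sep = "")
  invisible(x)
}

#' Tidy a genetic map
#' @param x A `genetic_map`.
#' @param ... Unused.
#' @return The map table (`group`, `marker`, `chrom`, `pos`, `cm`, ...).
#' @export
tidy.genetic_map <- function(x, ...) x$table

#' One-row map overview
#' @param x A `genetic_map`.
#' @param ... Unused.
#' @return Tibble with `n_groups`, `n_bins`, `n_snps`, `total_cm`,
#'   `mean_cm_per_bin`.
#' @export
glance.genetic_map <- function(x, ...) {
  tot <- x$table |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(cm = max(.data$cm), .groups = "drop")
  tibble::tibble(
    n_groups = nrow(tot), n_bins = nrow(x$table),
    n_snps = sum(x$table$n_markers), total_cm = sum(tot$cm),
    mean_cm_per_bin = cm_per_bin(sum(tot$cm), nrow(x$table))
  )
}

#' Detect candidate IBD intervals from marker gaps
#'
#' Maximal regions without polymorphic markers spanning at least `min_gap`
#' bp are reported as possibly identical by descent. Telomeric gaps (from
#' position 1 to the first marker, and from the last marker to the
#' chromosome end) are included; an empty chromosome is one whole-length
#' gap.
#'
#' @param markers Tibble with `chrom` and `pos` (or a [marker_states()]).
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param min_gap Minimum gap length in bp (default 2.5e6).
#' @return List with `intervals` (tibble `chrom`, `start`, `end`, `length`)
#'   and `summary` (per-chromosome and genome-wide IBD percentages; the
#'   genome row has `chrom == "genome"`).
#' @export
detect_ibd <- function(markers, chrom_lengths, min_gap = 2.5e6) {
  if (inherits(markers, "marker_states")) markers <- markers$markers
  iv <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    pos <- sort(markers$pos[markers$chrom == ch])
    bounds <- if (length(pos) == 0) {
      tibble::tibble(start = 1, end = len)
    } else {
      tibble::tibble(
        start = c(1, pos),
        end = c(pos, len)
      )
    }
    bounds$length <- bounds$end - bounds$start
    iv[[ch]] <- bounds |>
      dplyr::filter(.data$length >= min_gap) |>
      dplyr::mutate(chrom = ch) |>
      dplyr::select("chrom", "start", "end", "length")
  }
  intervals <- dplyr::bind_rows(iv)
  per_chrom <- tibble::tibble(
    chrom = names(chrom_lengths),
    chrom_length = as.numeric(chrom_lengths)
  ) |>
    dplyr::left_join(
      intervals |>
        dplyr::group_by(.data$chrom) |>
        dplyr::summarise(ibd_bp = sum(.data$length), .groups = "drop"),
      by = "chrom"
    ) |>
    dplyr::mutate(
      ibd_bp = dplyr::coalesce(.data$ibd_bp, 0),
      ibd_pct = 100 * .data$ibd_bp / .data$chrom_length
    )
  genome <- tibble::tibble(
    chrom = "genome",
    chrom_length = sum(per_chrom$chrom_length),
    ibd_bp = sum(per_chrom$ibd_bp),
    ibd_pct = 100 * sum(per_chrom$ibd_bp) / sum(per_chrom$chrom_length)
  )
  list(intervals = intervals,
    summary = dplyr::bind_rows(per_chrom, genome))
}

#' Write IBD intervals as BED
#'
#' Converts internal 1-based closed intervals to 0-based half-open BED.
#'
#' @param ibd Result of [detect_ibd()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ibd_bed <- function(ibd, path) {
  bed <- ibd$intervals |>
    dplyr::transmute(.data$chrom, start = .data$start - 1, end = .data$end)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Summarize a genetic map
#'
#' Per linkage group: number of SNPs, number of bins, average SNPs per bin,
#' genetic length (cM), and physical coverage (distance between the first
#' and last mapped marker as a percentage of the chromosome length), plus a
#' totals row (`group == "TOTAL"`) whose `mean_cm_per_bin` is the total map
#' length over the total bin count, rounded to one decimal.
#'
#' @param map A `genetic_map`.
#' @param chrom_lengths Named chromosome lengths (bp).
#' @return A tibble, one row per group plus the totals row.
#' @export
map_summary <- function(map, chrom_lengths) {
  per <- map$table |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      chrom = names(sort(table(.data$chrom), decreasing = TRUE))[1],
      n_snps = sum(.data$n_markers),
      n_bins = dplyr::n(),
      avg_snps_per_bin = round(sum(.data$n_markers) / dplyr::n(), 1),
      cm = max(.data$cm),
      span_bp = max(.data$pos) - min(.data$pos),
      .groups = "drop"
    ) |>
    dplyr::mutate(coverage_pct =
      100 * .data$span_bp / as.numeric(chrom_lengths[.data$chrom]))
  if (any(per$n_bins == 1)) {
    warning("group(s) with a single bin: coverage span is zero")
  }
  total <- tibble::tibble(
    group = "TOTAL", chrom = NA_character_,
    n_snps = sum(per$n_snps), n_bins = sum(per$n_bins),
    avg_snps_per_bin = round(sum(per$n_snps) / sum(per$n_bins), 1),
    cm = sum(per$cm), span_bp = sum(per$span_bp),
    coverage_pct = 100 * sum(per$span_bp) /
      sum(as.numeric(chrom_lengths[per$chrom]))
  )
  dplyr::bind_rows(per, total) |>
    dplyr::mutate(mean_cm_per_bin = cm_per_bin(.data$cm, .data$n_bins)) |>
    dplyr::select(-"span_bp")
}
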