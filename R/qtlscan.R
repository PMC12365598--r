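# Interval-mapping QTL detection by Haley-Knott regression on the bin maps,
# genome-wide permutation thresholds, LOD-drop support intervals truncated
# at IBD boundaries, additive/dominance estimation with gene-action
# classification, segregation chi-square tests, and qualitative placement
# of major genes.

#' Scan configuration
#'
#' @param step Scan step in cM (default 1.0).
#' @param n_permutations Number of genome-wide permutations for the
#'   significance threshold (default 10000; simulations in the package's
#'   tests use 1000).
#' @param alpha Genome-wide type-I error rate (default 0.05).
#' @param seed Integer seed for the permutation stream.
#' @return A `scan_config` list.
#' @export
scan_config <- function(step = 1.0, n_permutations = 10000, alpha = 0.05,
                        seed = 1L) {
  stopifnot(step > 0, alpha > 0, alpha < 1, n_permutations >= 1)
  if (n_permutations < 100) {
    warning("fewer than 100 permutations: threshold will be unstable")
  }
  structure(list(step = step, n_permutations = as.integer(n_permutations),
    alpha = alpha, seed = as.integer(seed)), class = "scan_config")
}

bc_transition <- function(r) {
  matrix(c(1 - r, r, r, 1 - r), 2, 2)
}

#' QTL genotype probabilities at an arbitrary map position
#'
#' Conditional QTL-genotype class probabilities for each individual given
#' the nearest non-missing flanking bin genotypes, with recombination
#' fractions obtained from the cM distances through the inverse Kosambi
#' function and a no-interference Markov model along the chromosome. For
#' the BC design the two classes are the phased parental states 0/1; for
#' the F2 design the three classes A/H/B arise from two independent
#' meioses (each parent transmitting allele 0 or 1), and the heterozygote
#' class sums both ordered configurations. Individuals with both flanks
#' missing get their prior probabilities (1/2, 1/2 or 1/4, 1/2, 1/4).
#'
#' @param map A `genetic_map` from [build_map()].
#' @param group Linkage group label.
#' @param pos_cm Position in cM within the group.
#' @return Matrix individuals x classes, rows summing to 1.
#' @export
qtl_genotype_probs <- function(map, group, pos_cm) {
  idx <- which(map$table$group == group)
  stopifnot(length(idx) > 0)
  cm <- map$table$cm[idx]
  stopifnot(pos_cm >= min(cm) - 1e-9, pos_cm <= max(cm) + 1e-9)
  states <- map$states[idx, , drop = FALSE]
  n <- ncol(states)
  if (map$design == "BC") {
    probs <- matrix(0.5, n, 2, dimnames = list(colnames(states), c("0", "1")))
    classes <- c("0", "1")
  } else {
    probs <- matrix(rep(c(0.25, 0.5, 0.25), each = n), n, 3,
      dimnames = list(colnames(states), c("A", "H", "B")))
    classes <- c("A", "H", "B")
  }
  for (v in seq_len(n)) {
    ok <- which(!is.na(states[, v]))
    if (length(ok) == 0) next
    lefts <- ok[cm[ok] <= pos_cm + 1e-9]
    rights <- ok[cm[ok] >= pos_cm - 1e-9]
    li <- if (length(lefts)) lefts[length(lefts)] else NA
    ri <- if (length(rights)) rights[1] else NA
    if (!is.na(li) && !is.na(ri) && li == ri) {
      # position coincides with a non-missing marker: indicator
      p <- as.numeric(classes == as.character(states[li, v]))
      probs[v, ] <- p
      next
    }
    r1 <- if (!is.na(li)) kosambi_inv(pos_cm - cm[li]) else NA
    r2 <- if (!is.na(ri)) kosambi_inv(cm[ri] - pos_cm) else NA
    if (map$design == "BC") {
      gl <- if (!is.na(li)) states[li, v] + 1L else NA
      gr <- if (!is.na(ri)) states[ri, v] + 1L else NA
      if (!is.na(li) && !is.na(ri)) {
        t1 <- bc_transition(r1)[gl, ]
        t2 <- bc_transition(r2)[, gr]
        p <- t1 * t2
      } else if (!is.na(li)) {
        p <- bc_transition(r1)[gl, ]
      } else if (!is.na(ri)) {
        p <- bc_transition(r2)[, gr]
      } else {
        p <- c(0.5, 0.5)
      }
      probs[v, ] <- p / sum(p)
    } else {
      # enumerate ordered two-allele states (one allele per parent) at the
      # flank(s) and the position; each allele follows its own BC chain
      ord <- cbind(u = c(0L, 0L, 1L, 1L), w = c(0L, 1L, 0L, 1L))
      cls_l <- if (!is.na(li)) s_num_class(states[li, v]) else NA
      cls_r <- if (!is.na(ri)) s_num_class(states[ri, v]) else NA
      p3 <- c(0, 0, 0)
      for (ip in 1:4) {
        u <- ord[ip, 1]
        w <- ord[ip, 2]
        lf <- if (is.na(li)) 0.25 else {
          acc <- 0
          for (il in 1:4) {
            if (ord[il, 1] + ord[il, 2] != cls_l) next
            acc <- acc + 0.25 *
              bc_transition(r1)[ord[il, 1] + 1, u + 1] *
              bc_transition(r1)[ord[il, 2] + 1, w + 1]
          }
          acc
        }
        rf <- if (is.na(ri)) 1 else {
          acc <- 0
          for (ir in 1:4) {
            if (ord[ir, 1] + ord[ir, 2] != cls_r) next
            acc <- acc +
              bc_transition(r2)[u + 1, ord[ir, 1] + 1] *
              bc_transition(r2)[w + 1, ord[ir, 2] + 1]
          }
          acc
        }
        p3[u + w + 1] <- p3[u + w + 1] + lf * rf
      }
      probs[v, ] <- p3 / sum(p3)
    }
  }
  probs
}

s_num_class <- function(s) match(s, c("A", "H", "B")) - 1L

#' Haley-Knott interval-mapping scan
#'
#' At each step position, regresses the phenotype on the expected additive
#' score (and, for the F2 design, the expected dominance score) computed
#' from [qtl_genotype_probs()]. `LOD = (n/2) * log10(RSS0 / RSS1)` and
#' `%EV = 100 * (1 - RSS1 / RSS0)`. Effects follow the 1:2:1 / 1:1
#' conventions: for F2, `a = (A - B) / 2` and `d = H - (A + B) / 2` from
#' the fitted class means; for BC, `a` is the difference between the two
#' fitted class means (its sign depends on the phase orientation of the
#' chromosome) and `d` is undefined.
#'
#' @param map A `genetic_map`.
#' @param phenotypes Tibble with columns `individual` and `value` (missing
#'   values are dropped).
#' @param config A [scan_config()].
#' @return A `qtl_scan` object whose `profile` tibble has columns `group`,
#'   `pos_cm`, `lod`, `pct_ev`, `a`, `d`.
#' @export
scan_interval_mapping <- function(map, phenotypes, config = scan_config()) {
  eng <- scan_engine(map, config$step)
  ph <- tibble::as_tibble(phenotypes)
  stopifnot(all(c("individual", "value") %in% names(ph)))
  y_all <- ph$value[match(colnames(map$states), ph$individual)]
  keep <- !is.na(y_all)
  y <- y_all[keep]
  n <- length(y)
  if (n < 2 || var(y) == 0) {
    warning("phenotype has (near) zero variance or too few values; ",
      "all-zero profile returned")
    prof <- dplyr::mutate(eng$grid, lod = 0, pct_ev = 0, a = NA_real_,
      d = NA_real_)
    return(structure(list(profile = prof, map = map, n = n),
      class = "qtl_scan"))
  }
  yc <- y - mean(y)
  tss <- sum(yc^2)
  prof <- eng$grid
  prof$lod <- NA_real_
  prof$pct_ev <- NA_real_
  prof$a <- NA_real_
  prof$d <- NA_real_
  for (i in seq_len(nrow(prof))) {
    X <- eng$design[[i]][keep, , drop = FALSE]
    fit <- stats::lm.fit(cbind(1, X), y)
    rss <- sum(fit$residuals^2)
    prof$lod[i] <- (n / 2) * log10(tss / rss)
    prof$pct_ev[i] <- 100 * (1 - rss / tss)
    cf <- fit$coefficients
    if (map$design == "BC") {
      # class means: state0 = intercept, state1 = intercept + slope
      prof$a[i] <- -cf[2]
    } else {
      prof$a[i] <- -cf[2] # a = (muA - muB)/2 with x = P(B) - P(A)
      prof$d[i] <- cf[3] # d = muH - (muA + muB)/2 with z = P(H)
    }
  }
  structure(list(profile = prof, map = map, n = n), class = "qtl_scan")
}

# Precompute the scan grid and per-position HK design matrices.
scan_engine <- function(map, step) {
  grid_list <- list()
  design <- list()
  for (g in unique(map$table$group)) {
    cms <- map$table$cm[map$table$group == g]
    pts <- unique(c(seq(min(cms), max(cms), by = step), max(cms)))
    for (p in pts) {
      probs <- qtl_genotype_probs(map, g, p)
      X <- if (map$design == "BC") {
        cbind(x = probs[, "1"])
      } else {
        cbind(x = probs[, "B"] - probs[, "A"], z = probs[, "H"])
      }
      design[[length(design) + 1]] <- X
      grid_list[[length(grid_list) + 1]] <-
        tibble::tibble(group = g, pos_cm = p)
    }
  }
  list(grid = dplyr::bind_rows(grid_list), design = design)
}

#' @export
print.qtl_scan <- function(x, ...) {
  pk <- x$profile[which.max(x$profile$lod), ]
  cat("<qtl_scan> ", nrow(x$profile), " positions, n = ", x$n,
    "; max LOD ", round(pk$lod, 2), " at ", pk$group, " ",
    round(pk$pos_cm, 1), " cM\n", sep = "")
  invisible(x)
}

#' @export
tidy.qtl_scan <- function(x, ...) x$profile

#' @export
glance.qtl_scan <- function(x, ...) {
  pk <- x$profile[which.max(x$profile$lod), ]
  tibble::tibble(n = x$n, max_lod = pk$lod, peak_group = pk$group,
    peak_cm = pk$pos_cm, pct_ev = pk$pct_ev)
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the phenotype vector against the genotypes (jointly across the
#' genome, preserving the marker structure), records the genome-wide
#' maximum LOD of each permutation, and returns the empirical
#' `1 - alpha` quantile.
#'
#' @inheritParams scan_interval_mapping
#' @return List with `threshold`, `max_lods` (one per permutation), and
#'   `config`.
#' @export
permutation_threshold <- function(map, phenotypes, config = scan_config()) {
  ph <- tibble::as_tibble(phenotypes)
  y_all <- ph$value[match(colnames(map$states), ph$individual)]
  keep <- !is.na(y_all)
  y <- y_all[keep]
  n <- length(y)
  eng <- scan_engine(map, config$step)
  Q <- hk_orthonormal(eng, keep)
  with_seed(derive_seed(config$seed, 707L), {
    Y <- replicate(config$n_permutations, sample(y))
  })
  max_lods <- max_lod_matrix(Q, Y, n)
  thr <- as.numeric(quantile(max_lods, 1 - config$alpha, type = 1))
  list(threshold = thr, max_lods = max_lods, config = config)
}

# Orthonormalize each position's centered HK design; returns a list of
# n x k matrices plus bookkeeping for the vectorized max-LOD computation.
hk_orthonormal <- function(eng, keep) {
  lapply(eng$design, function(X) {
    Xk <- X[keep, , drop = FALSE]
    Xc <- sweep(Xk, 2, colMeans(Xk))
    qr_x <- qr(Xc)
    rank <- qr_x$rank
    if (rank == 0) return(matrix(0, nrow(Xc), 1))
    qr.Q(qr_x)[, seq_len(rank), drop = FALSE]
  })
}

# Genome-wide maximum LOD for each column of a centered phenotype matrix.
max_lod_matrix <- function(Q_list, Y, n) {
  Yc <- sweep(Y, 2, colMeans(Y))
  tss <- colSums(Yc^2)
  big <- do.call(cbind, Q_list)
  proj <- crossprod(big, Yc)^2 # (sum k_p) x m
  ks <- vapply(Q_list, ncol, 1L)
  pos_id <- rep(seq_along(Q_list), ks)
  r2_max <- apply(rowsum(proj, pos_id), 2, max) / tss
  -(n / 2) * log10(pmax(1 - r2_max, 1e-300))
}

#' LOD-drop support interval, truncated at IBD
#'
#' Finds the nearest scan positions left and right of the peak where the
#' LOD falls to `peak - drop` or below, maps them to the physical positions
#' of the flanking bins, and truncates a bound at the beginning of an IBD
#' region when the interval extends into one. If the profile never drops by
#' `drop` on a side, the interval extends to the end of the group and is
#' flagged.
#'
#' @param scan A `qtl_scan`.
#' @param group Linkage group to examine (default: the group with the
#'   genome-wide peak).
#' @param drop LOD units to descend from the peak (default 1.0).
#' @param ibd Optional `intervals` tibble from [detect_ibd()].
#' @return Tibble with `group`, `peak_cm`, `peak_lod`, `cm_lo`, `cm_hi`,
#'   `bp_lo`, `bp_hi`, `truncated_at_ibd`, `open_ended`.
#' @export
lod_support_interval <- function(scan, group = NULL, drop = 1.0,
                                 ibd = NULL) {
  prof <- scan$profile
  if (is.null(group)) group <- prof$group[which.max(prof$lod)]
  pr <- prof[prof$group == group, ]
  pk <- which.max(pr$lod)
  peak_lod <- pr$lod[pk]
  target <- peak_lod - drop
  left <- which(pr$lod[seq_len(pk)] <= target)
  right <- which(pr$lod[pk:nrow(pr)] <= target) + pk - 1
  open <- length(left) == 0 || length(right) == 0
  cm_lo <- if (length(left)) pr$pos_cm[max(left)] else min(pr$pos_cm)
  cm_hi <- if (length(right)) pr$pos_cm[min(right)] else max(pr$pos_cm)
  mt <- scan$map$table[scan$map$table$group == group, ]
  # flanking bins of the LOD-drop positions
  bp_lo <- max(c(min(mt$pos), mt$pos[mt$cm <= cm_lo + 1e-9]))
  bp_hi <- min(c(max(mt$pos), mt$pos[mt$cm >= cm_hi - 1e-9]))
  peak_bp <- mt$pos[which.min(abs(mt$cm - pr$pos_cm[pk]))]
  truncated <- FALSE
  if (!is.null(ibd) && nrow(ibd)) {
    chrom <- mt$chrom[1]
    ivs <- ibd[ibd$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(ivs))) {
      if (ivs$start[i] > peak_bp && ivs$start[i] < bp_hi) {
        bp_hi <- ivs$start[i]
        truncated <- TRUE
      }
      if (ivs$end[i] < peak_bp && ivs$end[i] > bp_lo) {
        bp_lo <- ivs$end[i]
        truncated <- TRUE
      }
    }
  }
  tibble::tibble(group = group, peak_cm = pr$pos_cm[pk],
    peak_lod = peak_lod, cm_lo = cm_lo, cm_hi = cm_hi,
    bp_lo = bp_lo, bp_hi = bp_hi, truncated_at_ibd = truncated,
    open_ended = open)
}

#' Classify gene action from additive and dominance effects
#'
#' Bands on the |d/a| ratio: `<= 0.25` additive (A), `(0.25, 0.75]` partly
#' dominant (PD), `(0.75, 1.25]` dominant (D), `> 1.25` overdominant (OD).
#' Ties at band edges fall to the lower-dominance class. `a = 0` (or any
#' missing input) gives `"n/a"`.
#'
#' @param a,d Additive and dominance effects (vectorized).
#' @return Character vector of classes.
#' @examples
#' classify_gene_action(-4.5, -1.2) # "PD"
#' @export
classify_gene_action <- function(a, d) {
  ratio <- abs(d / a)
  out <- dplyr::case_when(
    is.na(a) | is.na(d) | a == 0 ~ "n/a",
    ratio <= 0.25 ~ "A",
    ratio <= 0.75 ~ "PD",
    ratio <= 1.25 ~ "D",
    TRUE ~ "OD"
  )
  out
}

#' Segregation chi-square test
#'
#' Pearson goodness-of-fit chi-square against an expected ratio, without
#' continuity correction; degrees of freedom = classes - 1.
#'
#' @param observed Non-negative counts.
#' @param expected_ratio Positive expected ratio, e.g. `c(1, 1)` or
#'   `c(1, 2, 1)`.
#' @return Tibble with `chi2`, `df`, `p`.
#' @examples
#' segregation_chi2(c(85, 91), c(1, 1)) # chi2 ~ 0.20
#' @export
segregation_chi2 <- function(observed, expected_ratio) {
  stopifnot(length(observed) == length(expected_ratio),
    all(observed >= 0), all(expected_ratio > 0))
  if (sum(observed) == 0) stop("all observed counts are zero")
  ct <- suppressWarnings(
    chisq.test(observed, p = expected_ratio / sum(expected_ratio),
      correct = FALSE)
  )
  tibble::tibble(chi2 = as.numeric(ct$statistic),
    df = as.integer(ct$parameter), p = ct$p.value)
}

#' Map a binary trait as a pseudo-marker
#'
#' Codes a binary trait as a marker and finds the bin minimizing the
#' mismatch fraction against it, allowing a global label swap. A best
#' mismatch rate above 0.20 flags the trait as unlinked.
#'
#' @param trait Named binary vector (two levels, names = individuals).
#' @param onebin A [marker_states()].
#' @return Tibble with `bin`, `chrom`, `pos`, `mismatch_rate`,
#'   `n_compared`, `linked`.
#' @export
map_major_gene <- function(trait, onebin) {
  lev <- sort(unique(stats::na.omit(as.vector(trait))))
  if (length(lev) != 2) stop("trait is not binary (", length(lev),
    " level(s) observed)")
  t01 <- as.integer(trait == lev[2])
  names(t01) <- names(trait)
  t_ord <- t01[colnames(onebin$states)]
  s <- onebin$states
  lev_s <- sort(unique(stats::na.omit(as.vector(s))))
  rates <- vapply(seq_len(nrow(s)), function(i) {
    sv <- s[i, ]
    s01 <- as.integer(sv == lev_s[length(lev_s)])
    co <- !is.na(s01) & !is.na(t_ord)
    if (sum(co) < 2) return(NA_real_)
    mm <- mean(s01[co] != t_ord[co])
    min(mm, 1 - mm)
  }, 1.0)
  i_best <- which.min(rates)
  tibble::tibble(
    bin = onebin$markers$marker[i_best],
    chrom = onebin$markers$chrom[i_best],
    pos = onebin$markers$pos[i_best],
    mismatch_rate = rates[i_best],
    n_compared = sum(!is.na(s[i_best, ]) & !is.na(t_ord)),
    linked = rates[i_best] <= 0.20
  )
}

#' Apply the cross-map QTL reporting rules
#'
#' Given candidate QTL entries from the three maps, reports, for each
#' (trait, year, region): the entry with the highest LOD among the maps
#' where it is significant; entries significant *only* in the combined
#' (both-parent) map are excluded. Regions significant in more than one
#' year are flagged consistent.
#'
#' @param results Tibble with columns `trait`, `year`, `map` (values e.g.
#'   `"SF"`, `"ZP"`, `"SFxZP"`), `region`, `lod`, `threshold`, and any
#'   extra columns to carry through.
#' @param combined_map Label of the combined map (default `"SFxZP"`).
#' @return The reported subset with an added logical `consistent`.
#' @export
report_qtls <- function(results, combined_map = "SFxZP") {
  res <- tibble::as_tibble(results) |>
    dplyr::mutate(significant = .data$lod >= .data$threshold)
  sig <- dplyr::filter(res, .data$significant)
  picked <- sig |>
    dplyr::group_by(.data$trait, .data$year, .data$region) |>
    dplyr::filter(!all(.data$map == combined_map)) |>
    dplyr::slice_max(.data$lod, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  years_per <- picked |>
    dplyr::distinct(.data$trait, .data$region, .data$year) |>
    dplyr::count(.data$trait, .data$region, name = "n_years")
  picked |>
    dplyr::left_join(years_per, by = c("trait", "region")) |>
    dplyr::mutate(consistent = .data$n_years > 1) |>
    dplyr::select(-"n_years")
}
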