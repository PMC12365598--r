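# Bin-based genotyping-error correction: phase the 1:1 datasets along
# physical order, detect genuine recombination breakpoints per individual
# under the double-recombination (DR) acceptance rule, group markers into
# bins sharing one segregation pattern, and emit a one-marker-per-bin
# matrix with error-aware imputation.

#' Double-recombination acceptance rule
#'
#' A candidate DR (a genotype run that reverts to the flanking state on both
#' sides within one individual) is accepted as two real recombinations only
#' if it is supported by at least `min_markers` contiguous markers *and* the
#' physical span between the first and last marker involved is at least
#' `min_span_bp`. Shorter or narrower runs are treated as genotyping errors.
#'
#' @param min_markers Minimum run length in markers (default 2).
#' @param min_span_bp Minimum physical span in bp (default 1e5, i.e. 100 kb).
#' @return A `dr_rule` list.
#' @export
dr_rule <- function(min_markers = 2L, min_span_bp = 1e5) {
  stopifnot(min_markers >= 1, min_span_bp >= 0)
  structure(list(min_markers = as.integer(min_markers),
    min_span_bp = min_span_bp), class = "dr_rule")
}

#' Phase a 1:1 marker dataset along physical order
#'
#' Automated analogue of visual phasing: walking along each chromosome in
#' physical order, a marker's 0/1 coding (H = 1, homozygote = 0) is flipped
#' iff more than half of the co-called individuals disagree with the
#' previous phased marker; ties keep the current phase. Chromosomes with
#' fewer than two markers are returned unchanged with a warning.
#'
#' @param set_1to1 A [geno_matrix()] holding one 1:1 dataset (offspring
#'   states in {A, H}), or a [marker_states()] with such calls.
#' @return A [marker_states()] with integer 0/1 states (phase-0 /
#'   phase-1 transmitted haplotype) and a logical `flipped` column in
#'   `$markers`.
#' @export
phase_markers <- function(set_1to1) {
  ms <- if (inherits(set_1to1, "geno_matrix")) as_marker_states(set_1to1)
  else set_1to1
  raw <- matrix(NA_integer_, nrow(ms$states), ncol(ms$states),
    dimnames = dimnames(ms$states))
  raw[ms$states == "H"] <- 1L
  raw[ms$states == "A"] <- 0L
  raw[ms$states == "B"] <- NA_integer_ # residual third state: missing
  flipped <- logical(nrow(raw))
  for (ch in unique(ms$markers$chrom)) {
    idx <- which(ms$markers$chrom == ch)
    if (length(idx) < 2) {
      warning("chromosome ", ch, " has < 2 markers; phasing skipped")
      next
    }
    prev <- raw[idx[1], ]
    for (k in idx[-1]) {
      cur <- raw[k, ]
      co <- !is.na(cur) & !is.na(prev)
      if (any(co)) {
        mism <- mean(cur[co] != prev[co])
        if (mism > 0.5) {
          cur <- 1L - cur
          flipped[k] <- TRUE
          raw[k, ] <- cur
        }
      }
      if (any(!is.na(cur))) prev <- cur
    }
  }
  markers <- dplyr::mutate(ms$markers, flipped = flipped)
  marker_states(markers, raw)
}

#' Drop markers diverging from the local phased consensus
#'
#' Automated stand-in for manual curation of obviously divergent markers: a
#' marker is discarded when its phased calls disagree with the element-wise
#' majority of its phased neighbours (up to two markers each side) in more
#' than `max_disagree` of co-called individuals.
#'
#' @param phased A phased [marker_states()].
#' @param max_disagree Disagreement fraction above which a marker is
#'   dropped (default 0.2).
#' @return A filtered [marker_states()].
#' @export
drop_divergent_markers <- function(phased, max_disagree = 0.2) {
  s <- phased$states
  keep <- rep(TRUE, nrow(s))
  for (ch in unique(phased$markers$chrom)) {
    idx <- which(phased$markers$chrom == ch)
    if (length(idx) < 3) next
    for (j in seq_along(idx)) {
      nb <- idx[setdiff(max(1, j - 2):min(length(idx), j + 2), j)]
      cons <- matrix(s[nb, , drop = FALSE], nrow = length(nb))
      votes1 <- colSums(cons == 1L, na.rm = TRUE)
      votes0 <- colSums(cons == 0L, na.rm = TRUE)
      maj <- ifelse(votes1 > votes0, 1L, ifelse(votes0 > votes1, 0L,
        NA_integer_))
      cur <- s[idx[j], ]
      co <- !is.na(cur) & !is.na(maj)
      if (sum(co) >= 5 && mean(cur[co] != maj[co]) > max_disagree) {
        keep[idx[j]] <- FALSE
      }
    }
  }
  marker_states(phased$markers[keep, , drop = FALSE],
    s[keep, , drop = FALSE])
}

#' Harmonize A/B label orientation in a 1:2:1 dataset
#'
#' The A/B homozygote labels of 1:2:1 markers inherit the arbitrary
#' reference/alternate orientation of each SNP, so two adjacent markers in
#' perfect coupling can read as mirror images. Walking along physical
#' order, a marker's A and B labels are swapped iff more than half of the
#' individuals called homozygous at both it and the previous harmonized
#' marker disagree. Heterozygous calls are unaffected; no haplotype phase
#' is assigned (the two parental contributions remain indistinguishable).
#'
#' @param f2_set A [geno_matrix()] or [marker_states()] with A/H/B calls.
#' @return A [marker_states()] with harmonized labels and a logical
#'   `swapped` column in `$markers`.
#' @export
align_f2_labels <- function(f2_set) {
  ms <- if (inherits(f2_set, "geno_matrix")) as_marker_states(f2_set)
  else f2_set
  s <- ms$states
  swapped <- logical(nrow(s))
  for (ch in unique(ms$markers$chrom)) {
    idx <- which(ms$markers$chrom == ch)
    if (length(idx) < 2) next
    prev <- s[idx[1], ]
    for (k in idx[-1]) {
      cur <- s[k, ]
      hom <- !is.na(cur) & !is.na(prev) & cur != "H" & prev != "H"
      if (any(hom)) {
        mism <- mean(cur[hom] != prev[hom])
        if (mism > 0.5) {
          cur <- chartr("AB", "BA", cur)
          swapped[k] <- TRUE
          s[k, ] <- cur
        }
      }
      if (any(!is.na(cur) & cur != "H")) prev <- cur
    }
  }
  markers <- dplyr::mutate(ms$markers, swapped = swapped)
  marker_states(markers, s)
}

#' Detect recombination breakpoints in one individual's state series
#'
#' Segments one individual's ordered non-missing states on one chromosome
#' into runs. Internal runs whose two flanking runs share the same state are
#' candidate double recombinations, accepted only under the [dr_rule()];
#' rejected runs are flagged as genotyping errors and absorbed into the
#' surrounding run. Terminal runs, and internal runs whose flanks differ
#' (possible only with three-state data), are single recombinations and are
#' always accepted.
#'
#' @param states Vector of states (0/1 or "A"/"H"/"B"), `NA` = missing.
#' @param pos Physical positions (bp), same length, increasing.
#' @param rule A [dr_rule()].
#' @return List with `breakpoints`, a tibble (`left_idx`, `right_idx`,
#'   `left_pos`, `right_pos`) of accepted recombination intervals (indices
#'   into `states`), and `errors`, integer indices of calls flagged as
#'   errors.
#' @export
detect_breakpoints <- function(states, pos, rule = dr_rule()) {
  stopifnot(length(states) == length(pos))
  keep <- which(!is.na(states))
  errors <- integer(0)
  if (length(keep) == 0) {
    return(list(breakpoints = tibble::tibble(left_idx = integer(),
      right_idx = integer(), left_pos = numeric(), right_pos = numeric()),
      errors = errors))
  }
  repeat {
    s <- states[keep]
    r <- rle(as.vector(s))
    n_runs <- length(r$lengths)
    if (n_runs <= 2) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    rejected <- integer(0)
    for (j in 2:(n_runs - 1)) {
      if (!identical(r$values[j - 1], r$values[j + 1])) next # true transition
      run_idx <- keep[starts[j]:ends[j]]
      span <- pos[run_idx[length(run_idx)]] - pos[run_idx[1]]
      if (r$lengths[j] < rule$min_markers || span < rule$min_span_bp) {
        rejected <- c(rejected, run_idx)
      }
    }
    if (length(rejected) == 0) break
    errors <- c(errors, rejected)
    keep <- setdiff(keep, rejected)
    if (length(keep) == 0) break
  }
  if (length(keep) == 0) {
    bps <- tibble::tibble(left_idx = integer(), right_idx = integer(),
      left_pos = numeric(), right_pos = numeric())
  } else {
    s <- states[keep]
    r <- rle(as.vector(s))
    ends <- cumsum(r$lengths)
    if (length(r$lengths) > 1) {
      left <- keep[ends[-length(ends)]]
      right <- keep[ends[-length(ends)] + 1]
      bps <- tibble::tibble(left_idx = left, right_idx = right,
        left_pos = pos[left], right_pos = pos[right])
    } else {
      bps <- tibble::tibble(left_idx = integer(), right_idx = integer(),
        left_pos = numeric(), right_pos = numeric())
    }
  }
  list(breakpoints = bps, errors = sort(unique(errors)))
}

#' Group markers into bins from per-individual breakpoints
#'
#' Runs [detect_breakpoints()] for every individual on every chromosome and
#' places bin boundaries at the union, over individuals, of accepted
#' breakpoints. Markers between two consecutive boundaries form exactly one
#' bin. Each bin's consensus genotype per individual is the majority of its
#' non-error, non-missing member calls (ties give `NA`).
#'
#' @param ms A phased [marker_states()] (1:1 data) or an unphased A/H/B
#'   [marker_states()] (1:2:1 data).
#' @param rule A [dr_rule()].
#' @return A `bin_set` list: `bins` (tibble `bin`, `chrom`, `start`, `end`,
#'   `n_markers`, `representative`, `members` list-column), `consensus`
#'   (bins x individuals matrix), `member_states` (the input states),
#'   `errors` (tibble `marker`, `individual`), `markers`.
#' @export
build_bins <- function(ms, rule = dr_rule()) {
  stopifnot(inherits(ms, "marker_states"))
  inds <- colnames(ms$states)
  err_list <- list()
  bins_out <- list()
  cons_list <- list()
  bin_id <- 0L
  error_mask <- matrix(FALSE, nrow(ms$states), ncol(ms$states),
    dimnames = dimnames(ms$states))
  for (ch in unique(ms$markers$chrom)) {
    idx <- which(ms$markers$chrom == ch)
    if (length(idx) == 0) stop("chromosome ", ch, " has zero markers")
    pos <- ms$markers$pos[idx]
    cut_after <- logical(length(idx)) # boundary between i and i+1
    for (v in seq_along(inds)) {
      det <- detect_breakpoints(ms$states[idx, v], pos, rule)
      if (nrow(det$breakpoints)) {
        # boundary before the first marker of each new run
        cut_after[det$breakpoints$right_idx - 1L] <- TRUE
      }
      if (length(det$errors)) {
        error_mask[idx[det$errors], v] <- TRUE
      }
    }
    bounds <- which(cut_after[-length(idx)])
    starts <- c(1, bounds + 1)
    ends <- c(bounds, length(idx))
    for (b in seq_along(starts)) {
      bin_id <- bin_id + 1L
      mem <- idx[starts[b]:ends[b]]
      block <- ms$states[mem, , drop = FALSE]
      block[error_mask[mem, , drop = FALSE]] <- NA
      cons <- apply(block, 2, majority_call)
      if (is.integer(ms$states)) cons <- as.integer(cons)
      cons_list[[bin_id]] <- cons
      bins_out[[bin_id]] <- tibble::tibble(
        bin = bin_id, chrom = ch,
        start = ms$markers$pos[mem[1]],
        end = ms$markers$pos[mem[length(mem)]],
        n_markers = length(mem),
        representative = ms$markers$marker[mem[1]],
        members = list(ms$markers$marker[mem])
      )
    }
  }
  bins <- dplyr::bind_rows(bins_out)
  consensus <- do.call(rbind, cons_list)
  dimnames(consensus) <- list(bins$representative, inds)
  err_idx <- which(error_mask, arr.ind = TRUE)
  errors <- tibble::tibble(
    marker = ms$markers$marker[err_idx[, 1]],
    individual = inds[err_idx[, 2]]
  )
  structure(list(bins = bins, consensus = consensus,
    member_states = ms, errors = errors, markers = ms$markers),
    class = "bin_set")
}

#' @export
print.bin_set <- function(x, ...) {
  cat("<bin_set> ", nrow(x$bins), " bins over ",
    length(unique(x$bins$chrom)), " chromosome(s); ",
    sum(x$bins$n_markers), " markers; ", nrow(x$errors),
    " calls flagged as errors\n", sep = "")
  invisible(x)
}

#' Tidy a bin set
#' @param x A `bin_set`.
#' @param ... Unused.
#' @return The `bins` tibble without the list-column.
#' @export
tidy.bin_set <- function(x, ...) {
  dplyr::select(x$bins, -"members")
}

#' Build the one-marker-per-bin matrix
#'
#' One row per bin, named by the representative marker (the first SNP of the
#' bin, closest to the top of the chromosome). The representative's missing
#' or contradictory calls (those disagreeing with the majority of the other
#' members) are imputed with the most frequent genotype of the rest of the
#' bin; an undefined (tied) majority leaves the call as is, or missing if
#' the representative was missing. For single-marker bins, calls that were
#' flagged as rejected double recombinations are set missing.
#'
#' @param binset A `bin_set` from [build_bins()].
#' @return A [marker_states()] whose `$markers` carries `n_markers`, the
#'   number of SNPs each bin contains.
#' @export
make_onebin <- function(binset) {
  stopifnot(inherits(binset, "bin_set"))
  ms <- binset$member_states
  err <- matrix(FALSE, nrow(ms$states), ncol(ms$states),
    dimnames = dimnames(ms$states))
  if (nrow(binset$errors)) {
    err[cbind(match(binset$errors$marker, ms$markers$marker),
      match(binset$errors$individual, colnames(ms$states)))] <- TRUE
  }
  n_bins <- nrow(binset$bins)
  out <- matrix(NA, n_bins, ncol(ms$states),
    dimnames = list(binset$bins$representative, colnames(ms$states)))
  if (is.integer(ms$states)) storage.mode(out) <- "integer"
  else storage.mode(out) <- "character"
  for (b in seq_len(n_bins)) {
    mem <- match(binset$bins$members[[b]], ms$markers$marker)
    rep_row <- ms$states[mem[1], ]
    if (length(mem) == 1) {
      rep_row[err[mem[1], ]] <- NA # rejected-DR calls -> missing
      out[b, ] <- rep_row
      next
    }
    rest <- ms$states[mem[-1], , drop = FALSE]
    rest[err[mem[-1], , drop = FALSE]] <- NA
    maj <- apply(rest, 2, majority_call)
    if (is.integer(ms$states)) maj <- as.integer(maj)
    rep_err <- err[mem[1], ]
    fill <- is.na(rep_row) | rep_err |
      (!is.na(maj) & !is.na(rep_row) & rep_row != maj)
    rep_row[fill] <- maj[fill]
    out[b, ] <- rep_row
  }
  markers <- tibble::tibble(
    marker = binset$bins$representative,
    chrom = binset$bins$chrom,
    pos = ms$markers$pos[match(binset$bins$representative,
      ms$markers$marker)],
    n_markers = binset$bins$n_markers
  )
  marker_states(markers, out)
}
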