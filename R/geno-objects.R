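# Core genotype containers.
#
# geno_matrix: markers x individuals AHB call matrix with marker metadata and
#   the two parents flagged. Calls are "A", "H", "B" or NA.
# marker_states: a leaner markers x progeny state matrix used by the binning
#   and mapping stages (states are "A"/"H"/"B" for 1:2:1 data or 0/1 integers
#   for phased 1:1 data).

#' Construct a genotype matrix object
#'
#' @param markers Tibble with columns `marker`, `chrom`, `pos` (1-based bp),
#'   one row per marker, positions strictly increasing within a chromosome.
#' @param calls Character matrix (values `"A"`, `"H"`, `"B"`, `NA`) with one
#'   row per marker and one named column per individual, parents included.
#' @param parents Character vector of length 2 naming the parent columns
#'   (first parent = female, second = male by convention).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(markers, calls, parents) {
  markers <- tibble::as_tibble(markers)
  stopifnot(
    all(c("marker", "chrom", "pos") %in% names(markers)),
    nrow(markers) == nrow(calls),
    length(parents) == 2, all(parents %in% colnames(calls)),
    !anyDuplicated(markers$marker)
  )
  ord_ok <- markers |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(diff(.data$pos) > 0), .groups = "drop")
  if (!all(ord_ok$ok)) {
    first_bad <- ord_ok$chrom[!ord_ok$ok][1]
    pos <- markers$pos[markers$chrom == first_bad]
    idx <- which(diff(pos) <= 0)[1] + 1
    stop("positions not strictly increasing on ", first_bad,
      "; first offending marker: ",
      markers$marker[markers$chrom == first_bad][idx])
  }
  rownames(calls) <- markers$marker
  structure(
    list(markers = markers, calls = calls, parents = parents),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$markers), " markers x ",
    ncol(x$calls), " individuals (", length(progeny_ids(x)),
    " progeny; parents: ", paste(x$parents, collapse = ", "), ")\n",
    sep = ""
  )
  cat("  chromosomes:", paste(unique(x$markers$chrom), collapse = " "), "\n")
  invisible(x)
}

#' Progeny identifiers of a genotype matrix
#' @param geno A [geno_matrix()].
#' @return Character vector of progeny column names.
#' @export
progeny_ids <- function(geno) {
  setdiff(colnames(geno$calls), geno$parents)
}

progeny_calls <- function(geno) {
  geno$calls[, progeny_ids(geno), drop = FALSE]
}

#' Tidy a genotype matrix into a long tibble
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `marker`, `chrom`, `pos`, `individual`,
#'   `call`, and a logical `is_parent`.
#' @export
tidy.geno_matrix <- function(x, ...) {
  long <- tibble::as_tibble(x$calls) |>
    dplyr::mutate(marker = x$markers$marker) |>
    tidyr::pivot_longer(-"marker", names_to = "individual", values_to = "call")
  x$markers |>
    dplyr::left_join(long, by = "marker") |>
    dplyr::mutate(is_parent = .data$individual %in% x$parents)
}

#' Construct a marker-state object
#'
#' A minimal markers-by-progeny state container used by the binning and map
#' construction stages. States are `"A"/"H"/"B"` for unphased 1:2:1 data or
#' integer `0/1` for phased 1:1 data.
#'
#' @param markers Marker metadata tibble (`marker`, `chrom`, `pos`, and
#'   optionally `n_markers` for bin representatives).
#' @param states Matrix of states, rows matching `markers`.
#' @return An object of class `marker_states`.
#' @export
marker_states <- function(markers, states) {
  markers <- tibble::as_tibble(markers)
  stopifnot(nrow(markers) == nrow(states))
  rownames(states) <- markers$marker
  structure(list(markers = markers, states = states), class = "marker_states")
}

#' @export
print.marker_states <- function(x, ...) {
  cat("<marker_states> ", nrow(x$markers), " markers x ", ncol(x$states),
    " individuals\n",
    sep = ""
  )
  invisible(x)
}

#' Convert a genotype matrix to progeny marker states
#' @param geno A [geno_matrix()].
#' @return A [marker_states()] with the progeny AHB calls.
#' @export
as_marker_states <- function(geno) {
  marker_states(geno$markers, progeny_calls(geno))
}

#' @export
tidy.marker_states <- function(x, ...) {
  tibble::as_tibble(x$states) |>
    dplyr::mutate(marker = x$markers$marker) |>
    tidyr::pivot_longer(-"marker", names_to = "individual",
      values_to = "state") |>
    dplyr::left_join(x$markers, by = "marker") |>
    dplyr::relocate("marker", "chrom", "pos")
}
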