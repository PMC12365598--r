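# Internal helpers shared across modules.

# Deterministically derive a child seed from a parent seed and an integer key.
# Keeps all derived seeds in [0, 2^31 - 2] so they are valid R integer seeds.
# Doubles are exact well below 2^53, so the arithmetic is reproducible.
derive_seed <- function(seed, key) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(key) * 16807 + 1
  as.integer(s %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Kosambi map function
#'
#' Convert a recombination fraction to a map distance in centimorgans using
#' the Kosambi map function, d = 25 * ln((1 + 2r) / (1 - 2r)).
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param max_cm Distance (cM) to which values with `r >= 0.5` are clamped,
#'   with a warning. Default 49.9.
#' @return Map distance(s) in cM.
#' @examples
#' kosambi_cm(0.25) # 25 * log(3) ~ 27.47
#' kosambi_inv(kosambi_cm(0.1))
#' @seealso [kosambi_inv()]
#' @export
kosambi_cm <- function(r, max_cm = 49.9) {
  stopifnot(is.numeric(r), all(r >= 0 | is.na(r)))
  out <- ifelse(r < 0.5, 25 * log((1 + 2 * r) / (1 - 2 * r)), NA_real_)
  if (any(!is.na(r) & r >= 0.5)) {
    warning("recombination fraction(s) >= 0.5 clamped to ", max_cm, " cM")
    out[!is.na(r) & r >= 0.5] <- max_cm
  }
  out
}

#' Inverse Kosambi map function
#'
#' @param d Map distance(s) in centimorgans.
#' @return Recombination fraction(s); `kosambi_cm(kosambi_inv(d)) == d` to
#'   numerical precision.
#' @export
kosambi_inv <- function(d) {
  stopifnot(is.numeric(d), all(d >= 0 | is.na(d)))
  tanh(d / 50) / 2
}

#' Mean genetic interval per bin
#'
#' Average map interval, total map length divided by the number of bins,
#' rounded to one decimal as reported in map summary tables.
#'
#' @param total_cm Total genetic distance in cM.
#' @param n_bins Number of bins.
#' @return Mean cM per bin, rounded to 1 decimal.
#' @examples
#' cm_per_bin(431.9, 508)
#' @export
cm_per_bin <- function(total_cm, n_bins) {
  stopifnot(n_bins > 0)
  round(total_cm / n_bins, 1)
}

# Majority vote over a character/integer vector ignoring NA; ties -> NA.
majority_call <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA)
  tab <- sort(table(x), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) return(NA)
  names(tab)[1]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
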