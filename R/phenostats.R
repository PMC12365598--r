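# Trait descriptive statistics and normality tests, between-trait and
# between-year correlations, broad-sense heritability from a one-way
# random-effects decomposition, the early/late maturity comparison, and
# the expression-based candidate-gene screen.

#' Per-trait summary statistics with normality test
#'
#' Mean, standard deviation, range, and the Shapiro-Wilk normality test per
#' (trait, year). Constant traits get `NA` normality results and a flag.
#'
#' @param pheno Tibble with columns `individual`, `trait`, `year`, `value`.
#' @return Tibble with one row per (trait, year): `n`, `mean`, `sd`, `min`,
#'   `max`, `shapiro_w`, `shapiro_p`, `constant`.
#' @export
trait_summary <- function(pheno) {
  pheno <- tibble::as_tibble(pheno)
  stopifnot(all(c("individual", "trait", "year", "value") %in% names(pheno)))
  pheno |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$trait, .data$year) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 3) {
        stop("trait ", key$trait, " year ", key$year,
          ": need at least 3 non-missing values")
      }
      constant <- sd(df$value) == 0
      sw <- if (!constant) shapiro.test(df$value) else
        list(statistic = NA_real_, p.value = NA_real_)
      tibble::tibble(
        n = nrow(df), mean = mean(df$value), sd = sd(df$value),
        min = min(df$value), max = max(df$value),
        shapiro_w = as.numeric(sw$statistic), shapiro_p = sw$p.value,
        constant = constant
      )
    }) |>
    dplyr::ungroup()
}

#' Pairwise trait correlations
#'
#' Correlation and two-sided p-value for every pair of trait-year columns,
#' using pairwise-complete observations. Pairs with fewer than 3 complete
#' observations or zero variance give `NA`.
#'
#' @param pheno Tibble with `individual`, `trait`, `year`, `value`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Tibble `var1`, `var2`, `r`, `p`, `n` over unordered pairs.
#' @export
trait_correlations <- function(pheno, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  wide <- tibble::as_tibble(pheno) |>
    dplyr::mutate(var = paste0(.data$trait, "_", .data$year)) |>
    dplyr::select("individual", "var", "value") |>
    tidyr::pivot_wider(names_from = "var", values_from = "value")
  vars <- setdiff(names(wide), "individual")
  pairs <- expand.grid(i = seq_along(vars), j = seq_along(vars)) |>
    dplyr::filter(.data$i <= .data$j)
  purrr::pmap_dfr(pairs, function(i, j) {
    x <- wide[[vars[i]]]
    y <- wide[[vars[j]]]
    co <- !is.na(x) & !is.na(y)
    n <- sum(co)
    if (n < 3 || sd(x[co]) == 0 || sd(y[co]) == 0) {
      return(tibble::tibble(var1 = vars[i], var2 = vars[j],
        r = NA_real_, p = NA_real_, n = n))
    }
    if (i == j) {
      return(tibble::tibble(var1 = vars[i], var2 = vars[j], r = 1,
        p = 0, n = n))
    }
    ct <- cor.test(x[co], y[co], method = method, exact = FALSE)
    tibble::tibble(var1 = vars[i], var2 = vars[j],
      r = as.numeric(ct$estimate), p = ct$p.value, n = n)
  })
}

#' Broad-sense heritability from year replicates
#'
#' One-way random-effects decomposition with genotype (individual) as the
#' random factor and years as replicates: from the one-way ANOVA,
#' `sigma2_E = MS_within` and `sigma2_G = (MS_between - MS_within) / n0`
#' (`n0` = the standard unbalanced-design replicate number), giving
#' `H2 = sigma2_G / (sigma2_G + sigma2_E)`, clamped to `[0, 1]`.
#'
#' @param pheno Tibble with `individual`, `trait`, `year`, `value`.
#' @param trait Trait name to analyze.
#' @return Tibble with `trait`, `h2`, `sigma2_g`, `sigma2_e`, `n_ind`,
#'   `n_obs`.
#' @export
broad_sense_h2 <- function(pheno, trait) {
  df <- tibble::as_tibble(pheno) |>
    dplyr::filter(.data$trait == !!trait, !is.na(.data$value))
  if (length(unique(df$year)) < 2) {
    stop("broad-sense heritability needs at least 2 years of data")
  }
  df <- df |>
    dplyr::group_by(.data$individual) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::ungroup()
  fit <- stats::aov(value ~ individual, data = df)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  ms_b <- ms[1]
  ms_w <- ms[2]
  n_i <- table(df$individual)
  n_tot <- sum(n_i)
  a <- length(n_i)
  n0 <- (n_tot - sum(n_i^2) / n_tot) / (a - 1)
  s2g <- max((ms_b - ms_w) / n0, 0)
  s2e <- ms_w
  h2 <- if (s2g + s2e == 0) NA_real_ else s2g / (s2g + s2e)
  tibble::tibble(trait = trait, h2 = min(max(h2, 0), 1),
    sigma2_g = s2g, sigma2_e = s2e, n_ind = a, n_obs = n_tot)
}

#' Compare color score between early- and late-maturing groups
#'
#' Dichotomizes individuals at a maturity-date cutoff (late = at or after
#' the cutoff) and tests whether the early group has a higher color score
#' with a one-tailed Welch t-test.
#'
#' @param data Tibble with columns `individual`, `md` (maturity, Julian
#'   days) and `fcs` (color score).
#' @param cutoff Maturity-date value at or above which an individual is
#'   late.
#' @return Tibble with group sizes and means, `t`, `df`, `p` (one-tailed,
#'   early > late).
#' @export
early_late_compare <- function(data, cutoff) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("md", "fcs") %in% names(data)))
  early <- data$fcs[data$md < cutoff & !is.na(data$md)]
  late <- data$fcs[data$md >= cutoff & !is.na(data$md)]
  if (length(early) == 0) stop("empty early group at cutoff ", cutoff)
  if (length(late) == 0) stop("empty late group at cutoff ", cutoff)
  tt <- t.test(early, late, alternative = "greater", var.equal = FALSE)
  tibble::tibble(
    n_early = length(early), n_late = length(late),
    mean_early = mean(early, na.rm = TRUE),
    mean_late = mean(late, na.rm = TRUE),
    t = as.numeric(tt$statistic), df = as.numeric(tt$parameter),
    p = tt$p.value
  )
}

#' Screen candidate genes by expression level and parental contrast
#'
#' Drops genes whose combined FPKM (the sum of the per-stage, per-parent
#' mean FPKM over all stages in both parents) is at or below `fpkm_floor`.
#' For the survivors, runs an independent Welch t-test between the two
#' parents' replicates at each developmental stage; a gene is flagged as a
#' candidate when any stage has p below `alpha`. Stages with fewer than 2
#' replicates in either parent are skipped with a warning.
#'
#' @param expr Tibble with columns `gene`, `stage`, `parent`, `replicate`,
#'   `fpkm`.
#' @param fpkm_floor Combined-FPKM floor (default 10; genes at or below it
#'   are filtered out).
#' @param alpha Per-stage significance threshold (default 0.05).
#' @return List with `genes` (tibble `gene`, `combined_fpkm`, `retained`,
#'   `flagged`, `sig_stages`, `min_p`) and `stage_tests` (per gene-stage
#'   t-test results).
#' @export
expression_screen <- function(expr, fpkm_floor = 10, alpha = 0.05) {
  expr <- tibble::as_tibble(expr)
  stopifnot(all(c("gene", "stage", "parent", "replicate", "fpkm")
    %in% names(expr)), all(expr$fpkm >= 0))
  combined <- expr |>
    dplyr::group_by(.data$gene, .data$stage, .data$parent) |>
    dplyr::summarise(cell = mean(.data$fpkm), .groups = "drop") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(combined_fpkm = sum(.data$cell), .groups = "drop") |>
    dplyr::mutate(retained = .data$combined_fpkm > fpkm_floor)
  survivors <- combined$gene[combined$retained]
  skipped <- 0L
  stage_tests <- expr |>
    dplyr::filter(.data$gene %in% survivors) |>
    dplyr::group_by(.data$gene, .data$stage) |>
    dplyr::group_modify(function(df, key) {
      groups <- split(df$fpkm, df$parent)
      if (length(groups) < 2 || any(vapply(groups, length, 1L) < 2)) {
        skipped <<- skipped + 1L
        return(tibble::tibble(p = NA_real_, diff = NA_real_))
      }
      tt <- t.test(groups[[1]], groups[[2]], var.equal = FALSE)
      tibble::tibble(p = tt$p.value,
        diff = mean(groups[[1]]) - mean(groups[[2]]))
    }) |>
    dplyr::ungroup()
  if (skipped > 0) {
    warning(skipped, " gene-stage test(s) skipped (fewer than 2 replicates)")
  }
  flags <- stage_tests |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      flagged = any(.data$p < alpha, na.rm = TRUE),
      sig_stages = list(.data$stage[!is.na(.data$p) & .data$p < alpha]),
      min_p = if (all(is.na(.data$p))) NA_real_ else
        min(.data$p, na.rm = TRUE),
      .groups = "drop"
    )
  genes <- combined |>
    dplyr::left_join(flags, by = "gene") |>
    dplyr::mutate(flagged = dplyr::coalesce(.data$flagged, FALSE))
  list(genes = genes, stage_tests = stage_tests)
}
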