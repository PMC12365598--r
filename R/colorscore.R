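# The fruit color comprehensive score (FCS): an ordinary least-squares
# model mapping CIELAB (L, a*, b*) readings to a continuous yellow-to-
# orange grade, with a 70/30 train/test split and k-fold cross-validation
# on the training subset.

eval_metrics <- function(obs, pred) {
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  tibble::tibble(
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    mae = mean(abs(obs - pred)),
    rmse = sqrt(mean((obs - pred)^2))
  )
}

#' Fit the fruit color score model
#'
#' Splits the data into a training fraction and a held-out test fraction,
#' fits `grade ~ L + a + b` by OLS on the training rows, and evaluates
#' R-squared, MAE and RMSE on the held-out rows. The fitted score is
#' `FCS = b0 + b1*L + b2*a + b3*b`.
#'
#' @param data Tibble with numeric columns `L`, `a`, `b`, `grade`
#'   (at least 10 rows).
#' @param split Training fraction (default 0.70).
#' @param seed Integer seed for the random split.
#' @param stratify If `TRUE`, the split is stratified by grade band
#'   (default `FALSE`, a uniform random split).
#' @return An `fcs_model` object with elements `coefficients`
#'   (`b0`, `b1`, `b2`, `b3`), `fit` (the underlying `lm`), `metrics_test`,
#'   `train_rows`, `n`, `split`, `seed`, `grade_range`.
#' @export
fit_fcs <- function(data, split = 0.70, seed = 1L, stratify = FALSE) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("L", "a", "b", "grade") %in% names(data)),
    is.numeric(data$grade), split > 0, split < 1)
  n <- nrow(data)
  if (n < 10) stop("need at least 10 rows to fit the color model")
  with_seed(derive_seed(seed, 11L), {
    if (stratify) {
      idx_by_grade <- split(seq_len(n), cut(data$grade,
        breaks = unique(quantile(data$grade, 0:5 / 5)),
        include.lowest = TRUE))
      train <- sort(unlist(lapply(idx_by_grade, function(ix) {
        sample(ix, max(1, round(split * length(ix))))
      }), use.names = FALSE))
    } else {
      train <- sort(sample.int(n, round(split * n)))
    }
  })
  test <- setdiff(seq_len(n), train)
  X <- as.matrix(data[train, c("L", "a", "b")])
  if (qr(cbind(1, X))$rank < 4) {
    stop("rank-deficient design: a color channel is constant or collinear")
  }
  fit <- lm(grade ~ L + a + b, data = data[train, ])
  pred_test <- predict(fit, data[test, ])
  model <- structure(
    list(
      coefficients = setNames(coef(fit), c("b0", "b1", "b2", "b3")),
      fit = fit,
      metrics_test = eval_metrics(data$grade[test], pred_test),
      train_rows = train, n = n, split = split, seed = seed,
      grade_range = range(data$grade[train])
    ),
    class = "fcs_model"
  )
  model
}

#' @export
print.fcs_model <- function(x, ...) {
  cf <- round(x$coefficients, 4)
  cat("<fcs_model> FCS = ", cf[1], " + ", cf[2], "*L + ", cf[3], "*a + ",
    cf[4], "*b\n", sep = "")
  cat("  trained on ", length(x$train_rows), "/", x$n, " samples; test R2 = ",
    round(x$metrics_test$r2, 3), "\n", sep = "")
  invisible(x)
}

#' Tidy the FCS model coefficients
#' @param x An `fcs_model`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
tidy.fcs_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("b0", "b1", "b2", "b3"),
    estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4]
  )
}

#' One-row FCS model summary
#' @param x An `fcs_model`.
#' @param ... Unused.
#' @return Tibble with training size and held-out test metrics.
#' @export
glance.fcs_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n = x$n, n_train = length(x$train_rows),
      split = x$split),
    dplyr::rename_with(x$metrics_test, ~ paste0("test_", .x))
  )
}

#' Cross-validate the FCS model
#'
#' Random k-fold partition of the rows; each fold serves once as the
#' validation set for a model fitted on the remaining folds. Reports
#' R-squared, MAE and RMSE per fold and their mean and standard deviation.
#' A fold with zero response variance yields `NA` R-squared and is flagged
#' with a warning.
#'
#' @param data Tibble with `L`, `a`, `b`, `grade` (typically the training
#'   subset).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return List with `folds` (per-fold metrics tibble) and `summary`
#'   (tibble of `metric`, `mean`, `sd`).
#' @export
cross_validate_fcs <- function(data, k = 5, seed = 1L) {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  stopifnot(k >= 2, n >= k)
  with_seed(derive_seed(seed, 22L), {
    fold <- sample(rep(seq_len(k), length.out = n))
  })
  res <- purrr::map_dfr(seq_len(k), function(f) {
    tr <- data[fold != f, ]
    va <- data[fold == f, ]
    fit <- lm(grade ~ L + a + b, data = tr)
    m <- eval_metrics(va$grade, predict(fit, va))
    dplyr::mutate(m, fold = f, n_validate = nrow(va), .before = 1)
  })
  if (anyNA(res$r2)) {
    warning("fold(s) with zero response variance: R2 undefined there")
  }
  summary <- res |>
    tidyr::pivot_longer(c("r2", "mae", "rmse"), names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
      .groups = "drop")
  list(folds = res, summary = summary)
}

#' Predict fruit color scores
#'
#' Applies the linear formula to new (L, a*, b*) triplets. Predictions
#' beyond the training grade range are permitted but flagged via the
#' `extrapolated` attribute.
#'
#' @param model An `fcs_model`.
#' @param L,a,b Numeric vectors (recycled to a common length), or `L` may
#'   be a data frame with columns `L`, `a`, `b`.
#' @return Numeric vector of scores with attribute `extrapolated`.
#' @export
predict_fcs <- function(model, L, a = NULL, b = NULL) {
  stopifnot(inherits(model, "fcs_model"))
  if (is.data.frame(L)) {
    df <- L
    stopifnot(all(c("L", "a", "b") %in% names(df)))
    L <- df$L
    a <- df$a
    b <- df$b
  }
  if (!all(is.finite(L), is.finite(a), is.finite(b))) {
    stop("non-finite color input")
  }
  cf <- model$coefficients
  score <- cf[["b0"]] + cf[["b1"]] * L + cf[["b2"]] * a + cf[["b3"]] * b
  extra <- score < model$grade_range[1] | score > model$grade_range[2]
  attr(score, "extrapolated") <- extra
  score
}
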