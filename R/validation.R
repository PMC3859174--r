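#' Individual percentage deviations (IPD)
#'
#' Per-point percentage deviation of prediction from observation:
#' 100 |pred - obs| / obs. Points with a zero observation are undefined:
#' they are returned as NA with a warning and excluded from summaries.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return Percent series (NA where observed is zero).
#' @export
ipd <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  out <- 100 * abs(predicted - observed) / abs(observed)
  zero <- observed == 0
  if (any(zero)) {
    warning(sum(zero), " point(s) with zero observed value excluded")
    out[zero] <- NA_real_
  }
  out
}

#' Mean percentage deviation (MPD)
#'
#' Mean and standard deviation of the IPD series.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return List of class `error_stats`: `mpd`, `sd`, `ipd` (the series),
#'   `n` (points used).
#' @export
mpd <- function(observed, predicted) {
  series <- ipd(observed, predicted)
  series_ok <- series[!is.na(series)]
  if (length(series_ok) == 0) stop("empty IPD series")
  structure(list(mpd = mean(series_ok), sd = stats::sd(series_ok),
                 ipd = series, n = length(series_ok)),
            class = "error_stats")
}

#' @export
print.error_stats <- function(x, ...) {
  cat(sprintf("MPD = %.1f (+/- %.1f) %%, n = %d\n", x$mpd, x$sd, x$n))
  invisible(x)
}

#' Inter-laboratory relative standard deviation (ILRSD)
#'
#' For a set of replicate measurements of the same quantity by different
#' laboratories: (100/N) * sum |Y - mean(Y)| / mean(Y). Scale-invariant.
#'
#' @param per_lab_values Numeric vector of replicate values (>= 2).
#' @return Percent scalar.
#' @export
ilrsd <- function(per_lab_values) {
  if (length(per_lab_values) < 2) stop("need at least 2 replicate values")
  m <- mean(per_lab_values)
  if (m == 0) stop("replicate mean is zero")
  100 * mean(abs(per_lab_values - m)) / abs(m)
}

#' IPD frequency bins
#'
#' Fractions of points with IPD below 15 percent, between 15 and 30
#' percent (inclusive), and above 30 percent. NA entries are dropped.
#'
#' @param ipd_series Percent series from [ipd()].
#' @return Named length-3 vector summing to 1 (`lt15`, `b15_30`, `gt30`).
#' @export
ipd_bins <- function(ipd_series) {
  x <- ipd_series[!is.na(ipd_series)]
  n <- length(x)
  if (n == 0) return(c(lt15 = NA_real_, b15_30 = NA_real_, gt30 = NA_real_))
  c(lt15 = sum(x < 15) / n,
    b15_30 = sum(x >= 15 & x <= 30) / n,
    gt30 = sum(x > 30) / n)
}

#' Goodness-of-fit statistics for observed vs predicted values
#'
#' R2 is the squared Pearson correlation of observed and predicted; RMSE
#' the root mean squared deviation; adjusted R2 and the F statistic use
#' the standard OLS forms with `p` predictors; SEP is the standard
#' deviation of the residuals (n - 1 denominator).
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @param p Number of predictors behind the predictions (for adjusted
#'   R2 / F; default 6).
#' @return List: `r2`, `adj_r2`, `rmse`, `f`, `sep`, `n`.
#' @export
fit_quality <- function(observed, predicted, p = 6) {
  stopifnot(length(observed) == length(predicted))
  n <- length(observed)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("degenerate input: zero variance")
  }
  r2 <- stats::cor(observed, predicted)^2
  rmse <- sqrt(mean((observed - predicted)^2))
  res <- observed - predicted
  sep <- stats::sd(res)
  adj_r2 <- f <- NA_real_
  if (n > p + 1) {
    adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
    f <- (r2 / p) / ((1 - r2) / (n - p - 1))
  }
  list(r2 = r2, adj_r2 = adj_r2, rmse = rmse, f = f, sep = sep, n = n)
}

#' Cross-validated q2
#'
#' Leave-one-out or leave-many-out cross-validation of a model factory:
#' q2 = 1 - PRESS / SS_total with held-out predictions, SS_total against
#' the overall response mean. LMO uses 10 folds by default.
#'
#' @param matrix Numeric descriptor matrix.
#' @param response Numeric response.
#' @param scheme `"loo"` or `"lmo"`.
#' @param n_folds Folds for LMO (default 10).
#' @param model_factory `function(matrix, response)` returning an object
#'   with a `predict(object, newdata)` method (default [fit_mlr()]).
#' @param seed Integer seed for the fold draw.
#' @return List of class `crossval_result`: `q2`, `rmse`, `folds`
#'   (assignment per row), `predictions` (held-out), `scheme`.
#' @export
q2_crossval <- function(matrix, response, scheme = c("lmo", "loo"),
                        n_folds = 10, model_factory = fit_mlr, seed = 1L) {
  scheme <- match.arg(scheme)
  matrix <- as.matrix(matrix)
  n <- nrow(matrix)
  k <- if (scheme == "loo") n else n_folds
  if (n < k || k < 2) stop("need n >= folds >= 2")
  assign <- if (scheme == "loo") seq_len(n) else
    with_seed(seed, sample(rep_len(seq_len(k), n)))
  preds <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    hold <- assign == f
    if (stats::sd(response[!hold]) == 0) {
      stop("a training fold has zero response variance")
    }
    m <- model_factory(matrix[!hold, , drop = FALSE], response[!hold])
    preds[hold] <- predict(m, matrix[hold, , drop = FALSE])
  }
  press <- sum((response - preds)^2)
  sstot <- sum((response - mean(response))^2)
  structure(list(q2 = 1 - press / sstot, rmse = sqrt(press / n),
                 folds = assign, predictions = preds, scheme = scheme),
            class = "crossval_result")
}

#' Y-randomization (response scrambling)
#'
#' Shuffles the response, refits the model and records the training R2
#' of each shuffle. Real structure in the descriptors produces shuffle
#' R2 values near zero; values approaching the true-fit R2 indicate
#' chance correlation.
#'
#' @param matrix Numeric descriptor matrix.
#' @param response Numeric response.
#' @param n_shuffles Number of shuffles (default 10).
#' @param model_factory As in [q2_crossval()].
#' @param seed Integer seed.
#' @return List: `r2` (per shuffle), `true_r2` (unshuffled fit).
#' @export
y_randomization <- function(matrix, response, n_shuffles = 10,
                            model_factory = fit_mlr, seed = 1L) {
  matrix <- as.matrix(matrix)
  true_fit <- model_factory(matrix, response)
  true_r2 <- fit_quality(response, predict(true_fit, matrix),
                         p = ncol(matrix))$r2
  r2 <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    ys <- sample(response)
    m <- model_factory(matrix, ys)
    fit_quality(ys, predict(m, matrix), p = ncol(matrix))$r2
  }, numeric(1)))
  list(r2 = r2, true_r2 = true_r2)
}

#' External-validation criteria (Golbraikh-Tropsha and Roy)
#'
#' Computes, for an external set: R2 (squared Pearson correlation);
#' the through-origin coefficients of determination R0^2 (observed fit by
#' k * predicted) and R0'^2 (predicted fit by k' * observed); the two
#' through-origin slopes K and K'; Roy's Rm2 = R2 (1 - sqrt(R2 - R0^2));
#' and the pass flags for the four published inequalities:
#' R2 > 0.6; (R2 - R0^2)/R2 < 0.1 with 0.85 <= K <= 1.15 *or* the primed
#' pair of the same; |R0^2 - R0'^2| < 0.3; Rm2 > 0.5.
#'
#' @param observed,predicted Numeric vectors (n >= 3).
#' @return List of class `external_validation`: `r2`, `r0_sq`,
#'   `r0_prime_sq`, `k`, `k_prime`, `rm_sq`, and logical `pass` flags.
#' @export
external_criteria <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("degenerate input: zero variance")
  }
  r2 <- stats::cor(observed, predicted)^2
  k <- sum(observed * predicted) / sum(predicted^2)
  k_prime <- sum(observed * predicted) / sum(observed^2)
  r0_sq <- 1 - sum((observed - k * predicted)^2) /
    sum((observed - mean(observed))^2)
  r0_prime_sq <- 1 - sum((predicted - k_prime * observed)^2) /
    sum((predicted - mean(predicted))^2)
  rm_sq <- r2 * (1 - sqrt(max(r2 - r0_sq, 0)))
  pass <- list(
    r2_gt_0.6 = r2 > 0.6,
    slope_ratio = ((r2 - r0_sq) / r2 < 0.1 && k >= 0.85 && k <= 1.15) ||
      ((r2 - r0_prime_sq) / r2 < 0.1 && k_prime >= 0.85 && k_prime <= 1.15),
    r0_gap_lt_0.3 = abs(r0_sq - r0_prime_sq) < 0.3,
    rm_sq_gt_0.5 = rm_sq > 0.5)
  structure(list(r2 = r2, r0_sq = r0_sq, r0_prime_sq = r0_prime_sq,
                 k = k, k_prime = k_prime, rm_sq = rm_sq, pass = pass),
            class = "external_validation")
}

#' @export
print.external_validation <- function(x, ...) {
  cat(sprintf(
    "R2 = %.3f  R0^2 = %.3f  R0'^2 = %.3f  K = %.3f  K' = %.3f  Rm2 = %.3f\n",
    x$r2, x$r0_sq, x$r0_prime_sq, x$k, x$k_prime, x$rm_sq))
  cat("pass:", paste(names(x$pass)[unlist(x$pass)], collapse = ", "), "\n")
  invisible(x)
}

#' Full validation report for one (model, partition) pair
#'
#' Bundles the error statistics (MPD, IPD bins), the goodness-of-fit
#' block and, when requested, the external-validation criteria, into one
#' serializable record.
#'
#' @param observed,predicted Numeric vectors.
#' @param model Model label.
#' @param partition Partition label.
#' @param p Predictor count for adjusted R2 / F.
#' @param external Include the external-criteria block (default TRUE when
#'   n >= 3).
#' @return List of class `validation_report`.
#' @export
validation_report <- function(observed, predicted, model = "model",
                              partition = "set", p = 6,
                              external = length(observed) >= 3) {
  err <- mpd(observed, predicted)
  structure(list(
    model = model, partition = partition, n = length(observed),
    mpd = err$mpd, mpd_sd = err$sd, ipd_bins = ipd_bins(err$ipd),
    fit = fit_quality(observed, predicted, p = p),
    external = if (external) external_criteria(observed, predicted)),
    class = "validation_report")
}

#' Serialize validation reports to JSON
#'
#' @param reports A `validation_report` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_reports <- function(reports, path) {
  if (inherits(reports, "validation_report")) reports <- list(reports)
  strip <- function(r) {
    r <- unclass(r)
    if (!is.null(r$external)) r$external <- unclass(r$external)
    r
  }
  jsonlite::write_json(lapply(reports, strip), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
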