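#' Predict bitterness with the published six-descriptor equation
#'
#' Applies the fixed reference MLR equation (see
#' [published_coefficients()]) to one or more descriptor rows. The map is
#' affine: intercept plus dot product with the published slopes.
#'
#' @param vector Named numeric vector, or a matrix/data.frame with columns
#'   SPAN, Mor11v, MSD, HATS8u, G3p, E3s.
#' @return Predicted log(1/T), one value per row.
#' @export
predict_published <- function(vector) {
  cf <- published_coefficients()
  if (is.null(dim(vector))) vector <- t(as.matrix(vector))
  vector <- as.matrix(vector)
  missing <- setdiff(names(cf$slopes), colnames(vector))
  if (length(missing) > 0) {
    stop("descriptor field(s) missing: ", paste(missing, collapse = ", "))
  }
  x <- vector[, names(cf$slopes), drop = FALSE]
  if (any(!is.finite(x))) stop("descriptor values must be finite")
  drop(cf$intercept + x %*% cf$slopes)
}

new_qsbr_model <- function(family, columns, predict_fn, details = list()) {
  structure(list(family = family, columns = columns,
                 predict_fn = predict_fn, details = details),
            class = "qsbr_model")
}

#' @export
predict.qsbr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$columns, colnames(newdata))
  if (length(missing) > 0) {
    stop("prediction needs column(s): ", paste(missing, collapse = ", "))
  }
  object$predict_fn(newdata[, object$columns, drop = FALSE])
}

#' @export
print.qsbr_model <- function(x, ...) {
  cat("qsbr_model:", x$family, "on", length(x$columns), "descriptors\n")
  invisible(x)
}

#' Ordinary least squares bitterness model
#'
#' Fits an MLR model on the raw descriptor scale (so coefficients are
#' directly comparable with the published equation) and reports the
#' coefficient table with standard errors plus R2, adjusted R2, F and the
#' standard error of prediction.
#'
#' @param matrix Numeric descriptor matrix with column names.
#' @param response Numeric response.
#' @return A `qsbr_model` with `details`: `coefficients` (estimate, se, t,
#'   p), `r2`, `adj_r2`, `f`, `sep`, `n`.
#' @export
fit_mlr <- function(matrix, response) {
  matrix <- as.matrix(matrix)
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- paste0("V", seq_len(ncol(matrix)))
  }
  n <- nrow(matrix); p <- ncol(matrix)
  if (n <= p + 1) stop("need n > p + 1 observations")
  d <- data.frame(.y = response, matrix, check.names = FALSE)
  fm <- stats::as.formula(paste(".y ~",
    paste(sprintf("`%s`", colnames(matrix)), collapse = " + ")))
  fit <- stats::lm(fm, data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- gsub("`", "", names(stats::coef(fit))[is.na(stats::coef(fit))])
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  coefs <- sm$coefficients
  rownames(coefs) <- gsub("`", "", rownames(coefs))
  cols <- colnames(matrix)
  beta <- stats::coef(fit)
  names(beta) <- gsub("`", "", names(beta))
  predict_fn <- function(x) drop(beta[1] + x %*% beta[cols])
  new_qsbr_model("mlr", cols, predict_fn, details = list(
    coefficients = coefs, r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
    f = unname(sm$fstatistic[1]), sep = sm$sigma, n = n))
}

#' Support vector regression configuration
#'
#' Defaults are the reported optimum of the reference study: capacity
#' C = 91, tube width epsilon = 0.07, RBF width gamma = 0.06, tuned by
#' 10-fold cross-validation.
#'
#' @param C Capacity (> 0).
#' @param epsilon Insensitivity tube width (> 0).
#' @param gamma RBF kernel width (> 0).
#' @param folds Cross-validation folds for tuning (default 10).
#' @return List of class `svr_config`.
#' @export
svr_config <- function(C = 91, epsilon = 0.07, gamma = 0.06, folds = 10) {
  stopifnot(C > 0, epsilon > 0, gamma > 0, folds >= 2)
  structure(list(C = C, epsilon = epsilon, gamma = gamma, folds = folds),
            class = "svr_config")
}

#' Epsilon-SVR bitterness model with RBF kernel
#'
#' Features are standardized on training statistics (z-scores) before the
#' kernel; predictions are returned on the response scale. Deterministic
#' given inputs.
#'
#' @param matrix Numeric descriptor matrix.
#' @param response Numeric response.
#' @param config An [svr_config()].
#' @return A `qsbr_model` (`details` holds the svm fit and the
#'   standardization constants).
#' @export
fit_svr <- function(matrix, response, config = svr_config()) {
  matrix <- as.matrix(matrix)
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- paste0("V", seq_len(ncol(matrix)))
  }
  ctr <- colMeans(matrix)
  scl <- apply(matrix, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(matrix, center = ctr, scale = scl)
  fit <- e1071::svm(xs, response, type = "eps-regression",
                    kernel = "radial", cost = config$C,
                    epsilon = config$epsilon, gamma = config$gamma,
                    scale = FALSE)
  cols <- colnames(matrix)
  predict_fn <- function(x) {
    as.numeric(stats::predict(fit, scale(x, center = ctr, scale = scl)))
  }
  new_qsbr_model("svr", cols, predict_fn,
                 details = list(fit = fit, config = config,
                                center = ctr, scale = scl, n = nrow(matrix)))
}

#' Tune SVR hyperparameters by grid-search cross-validation
#'
#' Exhaustive search over the supplied grid minimizing cross-validated
#' RMSE; fold assignment is drawn once from `seed` and reused for every
#' cell so the comparison is paired. Ties prefer smaller C, then larger
#' epsilon (the flatter, more regularized model).
#'
#' @param matrix Numeric descriptor matrix.
#' @param response Numeric response.
#' @param grid Data frame with columns C, epsilon, gamma.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold draw.
#' @return The winning [svr_config()] with attribute `cv_rmse` (per-cell
#'   results).
#' @export
tune_svr <- function(matrix, response, grid, folds = 10, seed = 1L) {
  stopifnot(nrow(grid) > 0, all(c("C", "epsilon", "gamma") %in% names(grid)))
  matrix <- as.matrix(matrix)
  n <- nrow(matrix)
  assign <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  rmse <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- svr_config(grid$C[i], grid$epsilon[i], grid$gamma[i], folds)
    press <- 0
    for (k in seq_len(folds)) {
      hold <- assign == k
      if (sum(hold) == 0) next
      m <- fit_svr(matrix[!hold, , drop = FALSE], response[!hold], cfg)
      pred <- predict(m, matrix[hold, , drop = FALSE])
      press <- press + sum((response[hold] - pred)^2)
    }
    sqrt(press / n)
  }, numeric(1))
  ord <- order(rmse, grid$C, -grid$epsilon)
  best <- ord[1]
  out <- svr_config(grid$C[best], grid$epsilon[best], grid$gamma[best],
                    folds)
  attr(out, "cv_rmse") <- cbind(grid, rmse = rmse)
  out
}

#' Neural network configuration
#'
#' A single hidden layer of bounded-sigmoid (tanh) units with a linear
#' output, trained by Levenberg-Marquardt damped least squares with early
#' stopping on an internal random validation split (70/15/15 by default).
#'
#' @param hidden_units Hidden neurons (default 3).
#' @param split Internal train/validation/test fractions.
#' @param max_epochs Total Levenberg-Marquardt iterations (default 1000).
#' @param patience Early-stopping patience in validation checks
#'   (default 6).
#' @param check_every Iterations between validation checks (default 10).
#' @param seed Integer seed for the split and weight initialization.
#' @return List of class `ann_config`.
#' @export
ann_config <- function(hidden_units = 3,
                       split = c(train = 0.70, validation = 0.15,
                                 test = 0.15),
                       max_epochs = 1000, patience = 6, check_every = 10,
                       seed = 1L) {
  stopifnot(hidden_units >= 1, length(split) == 3, all(split > 0))
  structure(list(hidden_units = hidden_units, split = split / sum(split),
                 max_epochs = max_epochs, patience = patience,
                 check_every = check_every, seed = as.integer(seed)),
            class = "ann_config")
}

ann_forward <- function(theta, x, h) {
  p <- ncol(x)
  w1 <- matrix(theta[seq_len(h * (p + 1))], nrow = h)
  rest <- theta[-seq_len(h * (p + 1))]
  b2 <- rest[1]; w2 <- rest[-1]
  a <- tanh(w1[, 1] + w1[, -1, drop = FALSE] %*% t(x))
  drop(b2 + crossprod(a, w2))
}

#' Feed-forward neural network bitterness model
#'
#' Inputs and response are z-scored on training statistics; weights are
#' fit by Levenberg-Marquardt (damped Gauss-Newton) on the sum-of-squares
#' loss of the internal training part, run in short bursts between
#' validation checks; the weights with the best validation RMSE are kept
#' (early stopping). Reproducible from `config$seed`. A warning is issued
#' when n is below ten observations per weight.
#'
#' @param matrix Numeric descriptor matrix.
#' @param response Numeric response.
#' @param config An [ann_config()].
#' @return A `qsbr_model` (`details` holds the flat weight vector `theta`,
#'   laid out as hidden biases+weights row-major then output bias+weights,
#'   the split indices, and the standardization constants).
#' @export
fit_ann <- function(matrix, response, config = ann_config()) {
  matrix <- as.matrix(matrix)
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- paste0("V", seq_len(ncol(matrix)))
  }
  # canonical column order: the seeded weight initialization then attaches
  # to the same inputs whatever order the caller supplies
  matrix <- matrix[, order(colnames(matrix)), drop = FALSE]
  n <- nrow(matrix); p <- ncol(matrix); h <- config$hidden_units
  n_par <- h * (p + 1) + h + 1
  if (n < 10 * n_par) {
    warning("fewer than 10 observations per network weight (n = ", n,
            ", weights = ", n_par, ")")
  }
  ctr <- colMeans(matrix); scl <- apply(matrix, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(matrix, center = ctr, scale = scl)
  ym <- mean(response); ys <- stats::sd(response)
  if (ys == 0) ys <- 1
  yz <- (response - ym) / ys

  state <- with_seed(config$seed, {
    idx <- sample.int(n)
    n_tr <- max(2, round(config$split[1] * n))
    n_va <- max(1, round(config$split[2] * n))
    list(tr = idx[seq_len(n_tr)],
         va = idx[(n_tr + 1):min(n, n_tr + n_va)],
         theta = stats::runif(n_par, -0.5, 0.5))
  })
  tr <- state$tr; va <- state$va
  theta <- state$theta
  resid_fn <- function(th) yz[tr] - ann_forward(th, xs[tr, , drop = FALSE], h)
  va_rmse <- function(th) {
    sqrt(mean((yz[va] - ann_forward(th, xs[va, , drop = FALSE], h))^2))
  }
  best <- theta; best_va <- va_rmse(theta); bad <- 0
  epochs <- 0
  while (epochs < config$max_epochs) {
    # maxiter is the burst length, not a convergence failure: silence the
    # iteration-cap warning nls.lm raises on every burst
    out <- suppressWarnings(minpack.lm::nls.lm(
      par = theta, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = config$check_every,
                                           nprint = 0)))
    theta <- out$par
    epochs <- epochs + config$check_every
    v <- va_rmse(theta)
    if (v < best_va - 1e-6) { best <- theta; best_va <- v; bad <- 0 }
    else bad <- bad + 1
    if (bad >= config$patience) break
    if (out$info %in% c(1, 2, 3) && sqrt(sum(out$fvec^2)) < 1e-8) break
  }
  if (any(!is.finite(best))) stop("network training diverged")
  cols <- colnames(matrix)
  predict_fn <- function(x) {
    xz <- scale(x, center = ctr, scale = scl)
    ym + ys * ann_forward(best, xz, h)
  }
  new_qsbr_model("ann", cols, predict_fn, details = list(
    theta = best, hidden_units = h, split = list(train = tr, validation = va),
    center = ctr, scale = scl, y_center = ym, y_scale = ys,
    validation_rmse = best_va, epochs = epochs, config = config))
}

#' Serialize a fitted model to JSON
#'
#' Stores the family, training columns and the family-specific parameters
#' (MLR coefficients, SVR hyperparameters and support-vector summary, ANN
#' flat weight vector with its layout).
#'
#' @param model A `qsbr_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  det <- switch(model$family,
    mlr = list(coefficients = model$details$coefficients[, 1],
               r2 = model$details$r2),
    svr = list(config = unclass(model$details$config),
               n_support = model$details$fit$tot.nSV,
               center = model$details$center, scale = model$details$scale),
    ann = list(theta = model$details$theta,
               hidden_units = model$details$hidden_units,
               layout = "hidden biases+weights row-major, output bias+weights",
               center = model$details$center, scale = model$details$scale,
               y_center = model$details$y_center,
               y_scale = model$details$y_scale),
    list())
  jsonlite::write_json(list(family = model$family, columns = model$columns,
                            parameters = det),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
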