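#' Published six-descriptor bitterness equation coefficients
#'
#' Intercept and slopes (with printed standard errors) of the reference MLR
#' bitterness equation on the log(1/T) scale:
#' log(1/T) = 5.45 + 0.10 SPAN + 0.32 Mor11v - 7.88 MSD - 1.55 HATS8u
#'            - 5.39 G3p + 0.92 E3s.
#'
#' @return A list with `intercept`, named `slopes`, and `se` (standard errors,
#'   intercept first).
#' @export
published_coefficients <- function() {
  list(
    intercept = 5.45,
    slopes = c(SPAN = 0.10, Mor11v = 0.32, MSD = -7.88,
               HATS8u = -1.55, G3p = -5.39, E3s = 0.92),
    se = c(intercept = 0.63, SPAN = 0.02, Mor11v = 0.09, MSD = 1.25,
           HATS8u = 0.30, G3p = 2.1, E3s = 0.35)
  )
}

#' Reported descriptor-activity correlation matrix
#'
#' The 7x7 correlation matrix over (response, SPAN, Mor11v, MSD, HATS8u,
#' G3p, E3s) used as the default joint structure of the synthetic generator.
#'
#' @return Symmetric 7x7 matrix with unit diagonal.
#' @export
qsbr_correlation <- function() {
  v <- c("response", "SPAN", "Mor11v", "MSD", "HATS8u", "G3p", "E3s")
  r <- diag(7)
  dimnames(r) <- list(v, v)
  lower <- list(
    SPAN   = c(response = 0.79),
    Mor11v = c(response = 0.34, SPAN = 0.09),
    MSD    = c(response = -0.81, SPAN = -0.78, Mor11v = -0.20),
    HATS8u = c(response = -0.56, SPAN = -0.52, Mor11v = -0.25, MSD = 0.38),
    G3p    = c(response = -0.63, SPAN = -0.64, Mor11v = -0.13, MSD = 0.64,
               HATS8u = 0.30),
    E3s    = c(response = 0.41, SPAN = 0.22, Mor11v = 0.31, MSD = -0.38,
               HATS8u = -0.16, G3p = -0.25)
  )
  for (row in names(lower)) {
    r[row, names(lower[[row]])] <- lower[[row]]
    r[names(lower[[row]]), row] <- lower[[row]]
  }
  r
}

#' Configuration for the synthetic six-descriptor generator
#'
#' Default marginal moments: E3s, HATS8u and Mor11v use the reported training
#' statistics (0.21 +/- 0.10, 0.33 +/- 0.13, 0.10 +/- 0.40). SPAN, MSD and
#' G3p moments are not reported anywhere, so the defaults (25 +/- 9,
#' 0.35 +/- 0.10, 0.15 +/- 0.05) are placeholders chosen to keep the linear
#' response inside the observed 1.0-5.7 activity range; they are
#' config-exposed, not literature values. The response default matches the
#' packaged data (mean 2.87, SD 1.00). The default noise SD, 0.43, is the
#' training RMSE scale of the reference model.
#'
#' @param corr 7x7 correlation matrix over (response, descriptors);
#'   default [qsbr_correlation()]. Slightly indefinite matrices are repaired
#'   by clipping negative eigenvalues at 1e-8 and renormalizing the diagonal.
#' @param means,sds Named length-7 vectors of marginal moments.
#' @param coeffs Published equation coefficients ([published_coefficients()]).
#' @param noise_sd Response noise SD for [gen_equation_response()].
#' @param n Sample count.
#' @param seed Integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(corr = qsbr_correlation(),
                         means = c(response = 2.87, SPAN = 25, Mor11v = 0.10,
                                   MSD = 0.35, HATS8u = 0.33, G3p = 0.15,
                                   E3s = 0.21),
                         sds = c(response = 1.00, SPAN = 9, Mor11v = 0.40,
                                 MSD = 0.10, HATS8u = 0.13, G3p = 0.05,
                                 E3s = 0.10),
                         coeffs = published_coefficients(),
                         noise_sd = 0.43, n = 181, seed = 1L) {
  stopifnot(is.matrix(corr), nrow(corr) == 7, ncol(corr) == 7,
            all(abs(diag(corr) - 1) < 1e-12),
            all(abs(corr - t(corr)) < 1e-12),
            length(means) == 7, length(sds) == 7, all(sds > 0),
            noise_sd >= 0, n >= 1)
  structure(list(corr = corr, means = means, sds = sds, coeffs = coeffs,
                 noise_sd = noise_sd, n = n, seed = as.integer(seed)),
            class = "synth_config")
}

# repair a near-PSD correlation matrix by clipping negative eigenvalues
repair_psd <- function(corr, clip = 1e-8, max_shift = 0.05) {
  e <- eigen(corr, symmetric = TRUE)
  if (min(e$values) >= 0) return(corr)
  if (min(e$values) < -max_shift) {
    stop("correlation matrix is far from positive semi-definite")
  }
  vals <- pmax(e$values, clip)
  m <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(m))
  m <- m / tcrossprod(d)
  dimnames(m) <- dimnames(corr)
  m
}

#' Draw descriptors and response from the configured joint distribution
#'
#' Multivariate normal draws with the configured correlation matrix and
#' marginal moments. This mode is used for correlation-recovery checks:
#' at n = 20000 the sample correlations reproduce the configured ones to
#' about +/- 0.02.
#'
#' @param config A [synth_config()].
#' @return A list: `descriptors` (n x 6 matrix, columns SPAN, Mor11v, MSD,
#'   HATS8u, G3p, E3s), `response` (length n), `provenance = "synthetic"`.
#' @export
gen_joint <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  corr <- repair_psd(config$corr)
  sigma <- diag(config$sds) %*% corr %*% diag(config$sds)
  x <- with_seed(config$seed,
                 MASS::mvrnorm(config$n, mu = config$means, Sigma = sigma))
  x <- matrix(x, nrow = config$n, dimnames = list(NULL, names(config$means)))
  list(descriptors = x[, -1, drop = FALSE], response = x[, 1],
       provenance = "synthetic")
}

#' Response from the published equation plus Gaussian noise
#'
#' Applies the published six-descriptor linear equation to a descriptor
#' matrix and adds N(0, noise_sd^2) noise. With `noise_sd = 0` a refit MLR
#' recovers the coefficients to machine precision; this mode drives the
#' coefficient-recovery checks.
#'
#' @param descriptors Matrix/data.frame with columns named exactly
#'   SPAN, Mor11v, MSD, HATS8u, G3p, E3s.
#' @param coeffs Coefficients as in [published_coefficients()].
#' @param noise_sd Noise standard deviation (>= 0).
#' @param seed Integer seed for the noise draw.
#' @return Numeric response vector.
#' @export
gen_equation_response <- function(descriptors,
                                  coeffs = published_coefficients(),
                                  noise_sd = 0.43, seed = 1L) {
  descriptors <- as.matrix(descriptors)
  missing <- setdiff(names(coeffs$slopes), colnames(descriptors))
  if (length(missing) > 0) {
    stop("descriptor column(s) missing: ", paste(missing, collapse = ", "))
  }
  mu <- coeffs$intercept +
    drop(descriptors[, names(coeffs$slopes), drop = FALSE] %*% coeffs$slopes)
  if (noise_sd > 0) {
    mu <- mu + with_seed(seed, stats::rnorm(length(mu), 0, noise_sd))
  }
  mu
}

#' Wide descriptor matrix with planted signal, duplicates and near-constants
#'
#' Test harness for the selection cascade: a wide matrix at the scale of a
#' filtered descriptor pool (a few hundred columns) with a known set of
#' informative columns driving a linear response, optional near- or exact
#' duplicate columns (for the intercorrelation filter) and near-constant
#' columns (for the repeated-value frequency rule).
#'
#' @param n Rows (molecules).
#' @param p Total columns before redundancy columns are appended.
#' @param n_informative Number of planted informative columns (placed first,
#'   named `inf1..`); the rest are independent noise.
#' @param noise_sd Response noise SD (default 0.43, the training RMSE scale).
#' @param redundancy List: `n_dup` exact/near duplicates of informative
#'   columns (correlation `dup_r`, default 1.0) and `n_const` near-constant
#'   columns with `const_frac` repeated values (default 0.95).
#' @param beta Slope given to every informative column (default 1).
#' @param seed Integer seed.
#' @return List: `descriptors`, `response`, `truth` (logical per column,
#'   TRUE for informative), `provenance = "synthetic"`.
#' @export
gen_wide_matrix <- function(n, p, n_informative, noise_sd = 0.43,
                            redundancy = list(n_dup = 0, dup_r = 1.0,
                                              n_const = 0, const_frac = 0.95),
                            beta = 1, seed = 1L) {
  stopifnot(n_informative <= p, n >= 2)
  defaults <- list(n_dup = 0, dup_r = 1.0, n_const = 0, const_frac = 0.95)
  redundancy <- utils::modifyList(defaults, redundancy)
  with_seed(seed, {
    x <- matrix(stats::rnorm(n * p), n, p)
    colnames(x) <- c(if (n_informative > 0) paste0("inf", seq_len(n_informative)),
                     if (p > n_informative)
                       paste0("noise", seq_len(p - n_informative)))
    truth <- c(rep(TRUE, n_informative), rep(FALSE, p - n_informative))
    y <- if (n_informative > 0) {
      drop(x[, seq_len(n_informative), drop = FALSE] %*%
             rep(beta, n_informative))
    } else numeric(n)
    if (noise_sd > 0) y <- y + stats::rnorm(n, 0, noise_sd)
    if (redundancy$n_dup > 0) {
      src <- rep_len(seq_len(max(n_informative, 1)), redundancy$n_dup)
      dup <- sapply(src, function(j) {
        base <- x[, j]
        if (redundancy$dup_r >= 1) base
        else {
          r <- redundancy$dup_r
          r * scale(base)[, 1] + sqrt(1 - r^2) * stats::rnorm(n)
        }
      })
      colnames(dup) <- paste0("dup", seq_len(redundancy$n_dup))
      x <- cbind(x, dup)
      truth <- c(truth, rep(FALSE, redundancy$n_dup))
    }
    if (redundancy$n_const > 0) {
      cc <- sapply(seq_len(redundancy$n_const), function(j) {
        v <- rep(0, n)
        k <- max(1, round(n * (1 - redundancy$const_frac)))
        v[sample.int(n, k)] <- stats::rnorm(k)
        v
      })
      colnames(cc) <- paste0("const", seq_len(redundancy$n_const))
      x <- cbind(x, cc)
      truth <- c(truth, rep(FALSE, redundancy$n_const))
    }
    names(truth) <- colnames(x)
    list(descriptors = x, response = y, truth = truth,
         provenance = "synthetic")
  })
}

#' Generate a toy conformer
#'
#' Small synthetic 3D structures for descriptor property tests: a straight
#' chain, a planar ring, or a random coil, with chain connectivity and unit
#' (carbon) atoms.
#'
#' @param n_atoms Number of atoms (>= 1).
#' @param geometry One of "line", "ring", "random".
#' @param spacing Bond length in Angstrom (default 1.5).
#' @param seed Integer seed (random geometry only).
#' @return A [conformer()] of carbon atoms.
#' @export
gen_conformer <- function(n_atoms, geometry = c("line", "ring", "random"),
                          spacing = 1.5, seed = 1L) {
  geometry <- match.arg(geometry)
  stopifnot(n_atoms >= 1)
  coords <- switch(geometry,
    line = cbind(spacing * (seq_len(n_atoms) - 1), 0, 0),
    ring = {
      theta <- 2 * pi * (seq_len(n_atoms) - 1) / max(n_atoms, 1)
      rad <- if (n_atoms > 1) spacing / (2 * sin(pi / n_atoms)) else 0
      cbind(rad * cos(theta), rad * sin(theta), 0)
    },
    random = with_seed(seed, matrix(stats::rnorm(n_atoms * 3, sd = 2),
                                    ncol = 3)))
  bonds <- if (n_atoms > 1) cbind(seq_len(n_atoms - 1), 2:n_atoms) else
    matrix(integer(0), 0, 2)
  if (geometry == "ring" && n_atoms > 2) bonds <- rbind(bonds, c(n_atoms, 1))
  conformer(elements = rep("C", n_atoms), coords = coords, bonds = bonds)
}
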