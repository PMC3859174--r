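#' Load a peptide bitterness dataset
#'
#' Reads a CSV of peptide bitterness records: one row per peptide with its
#' one-letter sequence, observed bitterness potency log(1/T) (T the human
#' sensory threshold concentration in mol/L), a partition label
#' (training/test/validation) and, optionally, per-model predictions and
#' individual percentage deviations (IPD).
#'
#' Duplicate (sequence, partition, observed) triples are legal — panel data
#' contain repeated sequences with distinct activities — and are only flagged
#' in the `"duplicates"` attribute, never dropped.
#'
#' @param source Path to a CSV file with columns `sequence`, `partition`,
#'   `observed` and optionally `pred_mlr`, `pred_svm`, `pred_ann`,
#'   `ipd_mlr`, `ipd_svm`, `ipd_ann`. Missing predictions are empty fields.
#' @return A `data.frame` of class `bitter_dataset` with one row per record
#'   and an attribute `duplicates` giving row indices of repeated
#'   (sequence, partition, observed) triples.
#' @examples
#' d <- load_dataset(bitter_fixture_path())
#' table(d$partition)
#' @export
load_dataset <- function(source) {
  d <- utils::read.csv(source, stringsAsFactors = FALSE,
                       colClasses = "character")
  mandatory <- c("sequence", "partition", "observed")
  missing <- setdiff(mandatory, names(d))
  if (length(missing) > 0) {
    stop("dataset format error: missing mandatory column(s) ",
         paste(missing, collapse = ", "))
  }
  numeric_cols <- intersect(
    c("observed", "pred_mlr", "pred_svm", "pred_ann",
      "ipd_mlr", "ipd_svm", "ipd_ann"), names(d))
  for (col in numeric_cols) {
    raw <- d[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(val))
    if (col == "observed" && length(bad) > 0) {
      stop("non-numeric 'observed' value at row ", bad[1])
    }
    val[!nzchar(raw)] <- NA_real_
    d[[col]] <- val
  }
  bad_part <- setdiff(unique(d$partition),
                      c("training", "test", "validation"))
  if (length(bad_part) > 0) {
    stop("unknown partition label(s): ", paste(bad_part, collapse = ", "))
  }
  key <- paste(d$sequence, d$partition, d$observed, sep = "\r")
  dup <- which(duplicated(key))
  attr(d, "duplicates") <- dup
  class(d) <- c("bitter_dataset", "data.frame")
  d
}

#' Write a peptide bitterness dataset
#'
#' Inverse of [load_dataset()]; missing predictions are written as empty
#' fields so that a write/load round trip is lossless.
#'
#' @param dataset A data frame as returned by [load_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   na = "", quote = FALSE)
  invisible(path)
}

#' Path to the packaged peptide bitterness table
#'
#' The packaged fixture holds 227 peptides/amino acids (181 training, 36
#' test, 10 validation) with observed log(1/T) in 1.00-5.70 and the
#' reference MLR/SVM/ANN predictions and IPD values.
#'
#' @return Path to the installed CSV.
#' @export
bitter_fixture_path <- function() {
  system.file("extdata", "bitter_peptides.csv", package = "bitterQSBR",
              mustWork = TRUE)
}

#' Flag response outliers by standard score
#'
#' Computes z-scores against the series mean and standard deviation and flags
#' points at or beyond the cutoff. On the packaged bitterness responses at the
#' conventional cutoff of 3 no point is flagged.
#'
#' @param responses Numeric vector, length >= 3, nonzero variance.
#' @param threshold Absolute z-score cutoff (default 3).
#' @return Integer vector of flagged indices (possibly empty).
#' @export
screen_outliers <- function(responses, threshold = 3) {
  if (length(responses) < 3) stop("need at least 3 responses")
  s <- stats::sd(responses)
  if (!is.finite(s) || s == 0) stop("degenerate input: zero variance")
  z <- (responses - mean(responses)) / s
  which(abs(z) >= threshold)
}

#' Principal-component scores of a descriptor matrix
#'
#' Columns are standardized internally; the sign of each component is fixed
#' so that its largest-magnitude loading is positive, making scores
#' reproducible across platforms.
#'
#' @param matrix Numeric matrix (rows = molecules, columns = descriptors).
#' @param n_components Number of leading components to return.
#' @return n x n_components score matrix.
#' @export
pca_scores <- function(matrix, n_components = 2) {
  matrix <- as.matrix(matrix)
  if (n_components < 1 || n_components > ncol(matrix)) {
    stop("n_components must be in 1..ncol(matrix)")
  }
  pc <- stats::prcomp(matrix, center = TRUE, scale. = TRUE)
  if (n_components > length(pc$sdev) ||
      pc$sdev[n_components] < 1e-10 * pc$sdev[1]) {
    stop("n_components exceeds the rank of the matrix")
  }
  flip <- apply(pc$rotation[, seq_len(n_components), drop = FALSE], 2,
                function(v) sign(v[which.max(abs(v))]))
  sweep(pc$x[, seq_len(n_components), drop = FALSE], 2, flip, `*`)
}

#' Split molecules into training/test/validation via k-means clustering
#'
#' Clusters the standardized feature block (descriptors plus response) with
#' k-means so that every cluster is a homogeneous neighbourhood, then
#' allocates each cluster's members to the three partitions in the requested
#' proportions. This keeps every partition representative of the whole
#' chemical space. k-means++ seeding; Euclidean distance; deterministic
#' given `seed`.
#'
#' Within a cluster the members most typical of the cluster (closest to its
#' centroid) are assigned to training first, then test, then validation;
#' per-cluster counts are the largest-remainder rounding of the requested
#' fractions, so realized fractions deviate from requested by at most one
#' record per cluster.
#'
#' @param features Numeric matrix or data.frame of descriptors; the response
#'   may be bound in as an extra column by the caller.
#' @param n_clusters Number of clusters (default 10).
#' @param fractions Named or positional proportions for
#'   (training, test, validation); need not sum exactly to 1 (renormalized).
#' @param seed Integer seed controlling k-means++ initialization.
#' @return A list of class `bitter_partitioning`: `labels` (factor of
#'   training/test/validation per row), `cluster` (k-means cluster id),
#'   `n_clusters`, `seed`.
#' @export
kmeans_partition <- function(features, n_clusters = 10,
                             fractions = c(training = 0.79, test = 0.16,
                                           validation = 0.05),
                             seed = 1L) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n_clusters > n) stop("n_clusters exceeds the number of rows")
  if (n_clusters < 1) stop("n_clusters must be >= 1")
  fractions <- fractions / sum(fractions)
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  xs <- scale(x, center = TRUE, scale = sds)

  km <- with_seed(seed, {
    centers <- kmeanspp_centers(xs, n_clusters)
    if (n_clusters == n) {
      list(cluster = seq_len(n), centers = xs)
    } else {
      stats::kmeans(xs, centers = centers, iter.max = 100)
    }
  })

  labels <- character(n)
  parts <- c("training", "test", "validation")
  for (k in seq_len(n_clusters)) {
    idx <- which(km$cluster == k)
    m <- length(idx)
    counts <- largest_remainder(fractions * m)
    # order members by distance to the centroid: most typical go to training
    ctr <- colMeans(xs[idx, , drop = FALSE])
    d2 <- colSums((t(xs[idx, , drop = FALSE]) - ctr)^2)
    idx <- idx[order(d2, idx)]
    labels[idx] <- rep(parts, times = counts)
  }
  structure(list(labels = factor(labels, levels = parts),
                 cluster = km$cluster,
                 n_clusters = n_clusters, seed = seed),
            class = "bitter_partitioning")
}

# k-means++ initial centers (Arthur & Vassilvitskii seeding)
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  if (k == 1) return(centers)
  d2 <- colSums((t(x) - centers[1, ])^2)
  for (j in 2:k) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    i <- sample.int(n, 1, prob = prob)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
  }
  centers
}

# round a vector of expected counts to integers preserving the total
largest_remainder <- function(target) {
  base <- floor(target)
  rem <- target - base
  short <- round(sum(target)) - sum(base)
  if (short > 0) {
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[top] <- base[top] + 1
  }
  as.integer(base)
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
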