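#' SPAN size descriptor
#'
#' Radius of the smallest sphere centered at the geometric center
#' (unweighted centroid) that encloses all atoms: the maximum
#' centroid-to-atom distance, in Angstrom. Grows with molecular size, which
#' makes it a convenient size measure for peptides and other macromolecules.
#'
#' @param conf A [conformer()].
#' @return Nonnegative scalar, Angstrom.
#' @export
span <- function(conf) {
  ctr <- colMeans(conf$coords)
  sqrt(max(colSums((t(conf$coords) - ctr)^2)))
}

#' Balaban mean-square-distance (MSD) index
#'
#' Square root of the mean squared topological distance over all ordered
#' atom pairs: sqrt( sum_ij d_ij^2 / (A (A - 1)) ). Decreases with branching
#' within an isomeric series and with growing atom count.
#'
#' @param adjacency Symmetric 0/1 adjacency matrix of a connected graph with
#'   at least 2 atoms, or a [conformer()].
#' @return Positive scalar, dimensionless.
#' @export
msd_index <- function(adjacency) {
  if (inherits(adjacency, "conformer")) {
    adjacency <- adjacency_matrix(adjacency)
  }
  a <- nrow(adjacency)
  if (a < 2) stop("MSD needs at least 2 atoms")
  d <- topological_distances(adjacency)
  if (any(!is.finite(d))) stop("MSD is undefined for a disconnected graph")
  sqrt(sum(d^2) / (a * (a - 1)))
}

#' 3D-MoRSE descriptor
#'
#' Electron-diffraction-style scattering sum over unordered atom pairs:
#' sum_{i<j} w_i w_j sin(s r_ij) / (s r_ij), with the s = 0 kernel defined
#' as 1. The conventional names are one-based in s: Mor01 is s = 0, so
#' Mor11 is s = 10 inverse Angstrom. The `s` argument here is the physical
#' scattering parameter in inverse Angstrom, not the one-based index —
#' an off-by-one here silently changes every value.
#'
#' @param conf A [conformer()] with at least 2 atoms.
#' @param s Scattering parameter in inverse Angstrom (0..31).
#' @param weight Weighting scheme passed to [atom_weights()].
#' @return Scalar, dimensionless.
#' @export
morse <- function(conf, s, weight = c("u", "v", "p", "s")) {
  weight <- match.arg(weight)
  w <- atom_weights(conf, weight)
  n <- nrow(conf$coords)
  if (n < 2) stop("3D-MoRSE needs at least 2 atoms")
  d <- as.matrix(stats::dist(conf$coords))
  iu <- which(upper.tri(d))
  r <- d[iu]
  kern <- if (s == 0) rep(1, length(r)) else {
    k <- sin(s * r) / (s * r)
    k[r == 0] <- 1
    k
  }
  ww <- tcrossprod(w)[iu]
  sum(ww * kern)
}

#' Mor11v: 3D-MoRSE at s = 10 1/Angstrom, van der Waals volume weighted
#'
#' @param conf A [conformer()].
#' @return Scalar, dimensionless.
#' @export
mor11v <- function(conf) morse(conf, s = 10, weight = "v")

#' Directional WHIM indices
#'
#' Weighted holistic invariant molecular indices from a weighted-covariance
#' principal component analysis of the centered coordinates. Per axis
#' m = 1..3 the function reports the eigenvalue (lambda, size), the
#' eigenvalue proportion (theta, shape), the accessibility/emptiness index
#' E_m (inverse weighted kurtosis of the scores) and the symmetry index
#' G_m in (0, 1].
#'
#' Symmetry counts an atom as "symmetric" along an axis when another atom
#' mirrors its score (t_j ~ -t_i) or it lies on the axis plane (t_i ~ 0);
#' G_m = 1 / (1 - ((n_s/n) log2(n_s/n) + (n_a/n) log2(1/n))) with the usual
#' 0 log 0 = 0 convention, so a fully centrosymmetric score distribution
#' gives G = 1.
#'
#' Planar or collinear geometries have no defined third axis; the affected
#' E/G entries are reported as 0 with `degenerate = TRUE` rather than as an
#' error, so batch runs survive flat molecules.
#'
#' @param conf A [conformer()] with at least 3 atoms for a defined third
#'   axis.
#' @param weight Weighting scheme passed to [atom_weights()].
#' @param sym_tol Relative tolerance for the symmetry match, as a fraction
#'   of the axis score spread (default 0.05).
#' @return List with `lambda`, `theta`, `E`, `G` (length-3 vectors) and
#'   `degenerate` (logical).
#' @export
whim_directional <- function(conf, weight = c("u", "v", "p", "s"),
                             sym_tol = 0.05) {
  weight <- match.arg(weight)
  w <- atom_weights(conf, weight)
  n <- nrow(conf$coords)
  sw <- sum(w)
  ctr <- colSums(conf$coords * w) / sw
  xc <- sweep(conf$coords, 2, ctr)
  cov <- crossprod(xc * w, xc) / sw
  e <- eigen(cov, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  scores <- xc %*% e$vectors
  degenerate <- lambda < 1e-10 * max(lambda, 1e-300)

  E <- G <- numeric(3)
  for (m in 1:3) {
    t <- scores[, m]
    if (degenerate[m]) next
    m4 <- sum(w * t^4) / sw
    E[m] <- if (m4 > 0) lambda[m]^2 / m4 else 0
    tol <- sym_tol * (max(t) - min(t))
    sym <- vapply(seq_len(n), function(i) {
      abs(t[i]) <= tol || any(abs(t[-i] + t[i]) <= tol)
    }, logical(1))
    n_s <- sum(sym)
    n_a <- n - n_s
    h <- 0
    if (n_s > 0) h <- h + (n_s / n) * log2(n_s / n)
    if (n_a > 0) h <- h + (n_a / n) * log2(1 / n)
    G[m] <- 1 / (1 - h)
  }
  list(lambda = lambda, theta = if (sum(lambda) > 0) lambda / sum(lambda)
       else rep(0, 3), E = E, G = G, degenerate = any(degenerate))
}

#' E3s: third-axis WHIM accessibility, electrotopological-state weighted
#'
#' @param conf A [conformer()].
#' @return Scalar; 0 for degenerate (planar/collinear) geometry.
#' @export
e3s <- function(conf) whim_directional(conf, weight = "s")$E[3]

#' G3p: third-axis WHIM symmetry, polarizability weighted
#'
#' @param conf A [conformer()].
#' @return Scalar in [0, 1]; 0 for degenerate geometry.
#' @export
g3p <- function(conf) whim_directional(conf, weight = "p")$G[3]

#' Atom leverages from the molecular influence matrix
#'
#' Diagonal of H = M (M'M)^-1 M' with M the centered coordinates; the
#' leverages of a non-planar conformer sum to 3 (trace of a rank-3
#' projector). Rank-deficient (planar/collinear) coordinate blocks use the
#' pseudoinverse, so the sum drops to the actual rank.
#'
#' @param conf A [conformer()].
#' @return Numeric vector of per-atom leverages.
#' @export
leverages <- function(conf) {
  m <- sweep(conf$coords, 2, colMeans(conf$coords))
  g <- crossprod(m)
  ginv <- MASS::ginv(g)
  rowSums((m %*% ginv) * m)
}

#' HATS leverage autocorrelation (GETAWAY family)
#'
#' Sum of (h_i w_i)(h_j w_j) over unordered atom pairs at topological
#' distance `lag`, with h the molecular-influence-matrix leverages; at
#' `lag = 0` the sum runs over the atoms themselves, (h_i w_i)^2. HATS8u is
#' lag 8, unweighted: any conformer whose graph diameter is below 8 scores
#' exactly 0.
#'
#' @param conf A [conformer()] with a connected bond graph.
#' @param lag Topological distance (>= 0).
#' @param weight Weighting scheme passed to [atom_weights()].
#' @return Nonnegative scalar.
#' @export
hats <- function(conf, lag, weight = c("u", "v", "p", "s")) {
  weight <- match.arg(weight)
  w <- atom_weights(conf, weight)
  h <- leverages(conf)
  if (lag == 0) return(sum((h * w)^2))
  d <- topological_distances(adjacency_matrix(conf))
  if (any(!is.finite(d))) stop("HATS is undefined for a disconnected graph")
  hw <- h * w
  iu <- which(upper.tri(d) & d == lag)
  if (length(iu) == 0) return(0)
  sum(tcrossprod(hw)[iu])
}

#' HATS8u: unweighted leverage autocorrelation at lag 8
#'
#' @param conf A [conformer()].
#' @return Nonnegative scalar.
#' @export
hats8u <- function(conf) hats(conf, lag = 8, weight = "u")

#' Compute the six bitterness-equation descriptors
#'
#' Assembles SPAN, Mor11v, MSD, HATS8u, G3p and E3s for one conformer, in
#' the column order expected by [predict_published()].
#'
#' @param conf A [conformer()] with a connected bond graph and >= 2 atoms.
#' @return Named numeric vector (SPAN, Mor11v, MSD, HATS8u, G3p, E3s).
#' @export
compute_six <- function(conf) {
  c(SPAN = span(conf), Mor11v = mor11v(conf), MSD = msd_index(conf),
    HATS8u = hats8u(conf), G3p = g3p(conf), E3s = e3s(conf))
}
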