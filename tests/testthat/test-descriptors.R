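test_that("span equals the brute-force maximum centroid distance", {
  expect_equal(span(gen_conformer(1)), 0)
  two <- conformer(c("C", "C"), rbind(c(0, 0, 0), c(2, 0, 0)),
                   cbind(1L, 2L))
  expect_equal(span(two), 1.0)
  set.seed(12)
  conf <- conformer(rep("C", 50), matrix(rnorm(150, sd = 3), ncol = 3),
                    cbind(1:49, 2:50))
  ctr <- colMeans(conf$coords)
  oracle <- max(apply(conf$coords, 1, function(r) sqrt(sum((r - ctr)^2))))
  expect_equal(span(conf), oracle, tolerance = 1e-12)
})

test_that("msd index matches hand values and decreases with branching", {
  expect_equal(msd_index(gen_conformer(2, "line")), 1.0)
  expect_equal(msd_index(gen_conformer(3, "line")), sqrt(2))
  # 5-atom star vs path, from hand-built distance matrices:
  # star ordered sum 2*(4*1 + 6*4) = 56 -> sqrt(56/20); path -> sqrt(100/20)
  star <- conformer(rep("C", 5), matrix(0, 5, 3),
                    cbind(rep(1L, 4), 2:5))
  expect_equal(msd_index(star), sqrt(56 / 20))
  expect_equal(msd_index(gen_conformer(5, "line")), sqrt(100 / 20))
  expect_lt(msd_index(star), msd_index(gen_conformer(5, "line")))
  disconnected <- conformer(rep("C", 3), matrix(rnorm(9), 3, 3),
                            cbind(1L, 2L))
  expect_error(msd_index(disconnected), "disconnected")
})

test_that("msd decreases when an edge shortens any shortest path", {
  # brute force over small path graphs plus a chord
  for (n in 4:8) {
    base <- gen_conformer(n, "line")
    with_chord <- conformer(base$elements, base$coords,
                            rbind(base$bonds, c(1L, as.integer(n))))
    expect_lt(msd_index(with_chord), msd_index(base))
  }
})

test_that("path graph maximizes msd over all trees on <= 7 nodes", {
  # enumerate labelled trees via Pruefer sequences
  for (n in c(5, 6, 7)) {
    msd_path <- msd_index(gen_conformer(n, "line"))
    seqs <- expand.grid(rep(list(seq_len(n)), n - 2))
    vals <- apply(as.matrix(seqs), 1, function(pruefer) {
      degree <- rep(1L, n) + tabulate(pruefer, n)
      edges <- matrix(0L, n - 1, 2)
      ptr <- pruefer
      for (i in seq_len(n - 2)) {
        # smallest leaf not appearing in the rest of the sequence
        leaf <- min(setdiff(which(degree == 1L), ptr))
        edges[i, ] <- c(leaf, ptr[1])
        degree[leaf] <- 0L
        degree[ptr[1]] <- degree[ptr[1]] - 1L
        ptr <- ptr[-1]
      }
      edges[n - 1, ] <- which(degree == 1L)
      conf <- conformer(rep("C", n), matrix(0, n, 3), edges)
      msd_index(conf)
    })
    expect_equal(max(vals), msd_path, tolerance = 1e-12)
  }
})

test_that("3d-morse matches the closed form and its s = 0 convention", {
  two <- conformer(c("C", "C"), rbind(c(0, 0, 0), c(1, 0, 0)),
                   cbind(1L, 2L))
  expect_equal(morse(two, s = 0), 1.0)
  expect_equal(morse(two, s = 10), sin(10) / 10, tolerance = 1e-12)
  expect_equal(mor11v(two), sin(10) / 10, tolerance = 1e-12)
  # unit-weight pair at arbitrary distance: direct evaluation
  r <- 2.37
  pair <- conformer(c("C", "C"), rbind(c(0, 0, 0), c(r, 0, 0)),
                    cbind(1L, 2L))
  expect_equal(morse(pair, s = 7), sin(7 * r) / (7 * r), tolerance = 1e-12)
})

test_that("whim eigenvalues match a dense eigensolver on the weighted covariance", {
  conf <- mixed_conformer(seed = 21, n = 10)
  for (wt in c("u", "p", "s")) {
    w <- atom_weights(conf, wt)
    ctr <- colSums(conf$coords * w) / sum(w)
    xc <- sweep(conf$coords, 2, ctr)
    oracle <- sort(eigen(t(xc * w) %*% xc / sum(w))$values,
                   decreasing = TRUE)
    expect_equal(whim_directional(conf, wt)$lambda, oracle,
                 tolerance = 1e-10)
  }
})

test_that("whim handles planar geometry as a flagged degenerate case", {
  flat <- conformer(rep("C", 6),
                    cbind(c(0, 1, 2, 0, 1, 2), c(0, 0, 0, 1, 1, 1), 0),
                    cbind(1:5, 2:6))
  w <- whim_directional(flat)
  expect_true(w$degenerate)
  expect_equal(w$lambda[3], 0)
  expect_equal(w$E[3], 0)
  expect_equal(w$G[3], 0)
  expect_equal(e3s(flat), 0)
})

test_that("whim symmetry index is 1 for centrosymmetric scores and in (0,1]", {
  line <- gen_conformer(7, "line")
  w <- whim_directional(line)
  expect_equal(w$G[1], 1)   # scores symmetric around the centroid
  conf <- mixed_conformer(seed = 33, n = 12)
  g <- whim_directional(conf, "p")$G
  expect_true(all(g >= 0 & g <= 1))
  expect_true(g3p(conf) >= 0 && g3p(conf) <= 1)
})

test_that("leverages form a rank-3 projector diagonal and drive hats", {
  conf <- mixed_conformer(seed = 5, n = 12)
  expect_equal(sum(leverages(conf)), 3, tolerance = 1e-10)
  # brute-force influence matrix
  m <- sweep(conf$coords, 2, colMeans(conf$coords))
  hmat <- m %*% solve(t(m) %*% m) %*% t(m)
  expect_equal(leverages(conf), diag(hmat), tolerance = 1e-10)

  # diameter below the lag gives exactly zero
  expect_equal(hats(gen_conformer(8, "line"), lag = 8), 0)
  # 9-atom chain: single terminal pair at lag 8
  chain <- gen_conformer(9, "line")
  h <- leverages(chain)
  expect_equal(hats8u(chain), h[1] * h[9], tolerance = 1e-12)
  # brute-force pair enumeration at an interior lag
  d <- bitterQSBR:::topological_distances(
    bitterQSBR:::adjacency_matrix(conf))
  w <- atom_weights(conf, "v")
  hv <- leverages(conf) * w
  oracle <- 0
  for (i in 1:11) for (j in (i + 1):12) {
    if (d[i, j] == 3) oracle <- oracle + hv[i] * hv[j]
  }
  expect_equal(hats(conf, 3, "v"), oracle, tolerance = 1e-12)
})

test_that("all six descriptors are invariant to rigid motion and relabeling", {
  conf <- mixed_conformer(seed = 8, n = 11)
  base <- compute_six(conf)
  moved <- rigid_motion(conf, seed = 2)
  expect_equal(compute_six(moved), base, tolerance = 1e-8)
  set.seed(14)
  perm <- sample(11)
  relabeled <- permute_atoms(conf, perm)
  expect_equal(compute_six(relabeled), base, tolerance = 1e-8)
})

test_that("compute_six composes the individual descriptors and tracks size", {
  chain <- gen_conformer(9, "line")
  six <- compute_six(chain)
  expect_equal(six[["SPAN"]], span(chain))
  expect_equal(six[["MSD"]], msd_index(chain))
  expect_equal(six[["HATS8u"]], hats8u(chain))
  expect_equal(six[["Mor11v"]], mor11v(chain))
  longer <- gen_conformer(12, "line")
  expect_gt(span(longer), span(chain))
})

test_that("conformer io round-trips through xyz and reads sdf", {
  conf <- mixed_conformer(seed = 4, n = 6)
  tmp <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_conformer(conf, tmp)
  back <- read_xyz_conformer(tmp, paste0(tmp, ".bonds"))
  expect_equal(back$elements, conf$elements)
  expect_equal(back$coords, conf$coords, tolerance = 1e-6)
  expect_equal(compute_six(back), compute_six(conf), tolerance = 1e-4)

  sdf <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(
    "propane", "  synthetic", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.2500    1.2990    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  1  0  0  0  0",
    "M  END", "$$$$"), sdf)
  mol <- read_sdf_conformer(sdf)
  expect_equal(mol$elements, c("C", "C", "C"))
  expect_equal(nrow(mol$bonds), 2)
  expect_equal(msd_index(mol), sqrt(2), tolerance = 1e-12)
})
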