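# shared fixtures built in code

fixture_dataset <- function() load_dataset(bitter_fixture_path())

# rigid rotation + translation of a conformer's coordinates
rigid_motion <- function(conf, seed = 1) {
  set.seed(seed)
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  rot <- qr.Q(qr_dec)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  conf$coords <- conf$coords %*% rot +
    matrix(rnorm(3, sd = 5), nrow(conf$coords), 3, byrow = TRUE)
  conf
}

# relabel atoms by a permutation, keeping the molecule identical
permute_atoms <- function(conf, perm) {
  inv <- order(perm)
  conformer(conf$elements[perm], conf$coords[perm, , drop = FALSE],
            matrix(inv[conf$bonds], ncol = 2))
}

# small mixed-element conformer for weighted-descriptor tests
mixed_conformer <- function(seed = 7, n = 10) {
  set.seed(seed)
  conformer(sample(c("C", "N", "O", "S"), n, replace = TRUE),
            matrix(rnorm(n * 3, sd = 2), ncol = 3),
            cbind(seq_len(n - 1), 2:n))
}
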