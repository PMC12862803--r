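# Shared fixture builders. Everything is generated in code at test time.

# a small random structure with elements from `elements`
random_structure <- function(n = 5, elements = c("H", "O", "S"), spread = 3,
                             id = NULL) {
  mol_structure(sample(elements, n, replace = TRUE),
                matrix(stats::runif(n * 3, -spread, spread), n, 3),
                id = id)
}

# random labeled dataset of random structures
random_dataset <- function(n_structures = 4, ...) {
  structures <- lapply(seq_len(n_structures), function(i) {
    random_structure(sample(2:6, 1), id = sprintf("fx%03d", i), ...)
  })
  mol_dataset(structures,
              y_high = stats::rnorm(n_structures),
              y_low = stats::rnorm(n_structures))
}

# random PSD kernel matrix via explicit feature map; returns both
random_psd_kernel <- function(n, p = 3) {
  phi <- matrix(stats::rnorm(n * p), n, p)
  list(K = tcrossprod(phi), phi = phi)
}

# apply a random rigid rotation + translation to a structure
rigid_move <- function(structure, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(stats::rnorm(9), 3, 3)
  R <- qr.Q(qr(M))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- stats::rnorm(3, sd = 5)
  mol_structure(structure$elements,
                structure$coordinates %*% R +
                  matrix(shift, nrow(structure$coordinates), 3, byrow = TRUE),
                composition = structure$composition, id = structure$id)
}

# squared pairwise distances via stats::dist (independent oracle)
cross_dist2_oracle <- function(X) as.matrix(stats::dist(X))^2

# brute-force k nearest neighbors (independent of the package's index code)
oracle_knn <- function(X, q, k) {
  d <- sqrt(colSums((t(X) - q)^2))
  ord <- order(d, seq_len(nrow(X)))[seq_len(k)]
  list(idx = ord, dist = d[ord])
}

# tiny default generator config for fast synthetic datasets in tests
test_generator_config <- function(n_structures = 40, seed = 1, ...) {
  generator_config(n_structures = n_structures, seed = seed, ...)
}
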