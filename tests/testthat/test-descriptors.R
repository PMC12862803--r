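test_that("Coulomb matrix matches hand-computed values", {
  h <- mol_structure("H", matrix(0, 1, 3))
  v <- coulomb_matrix(h, max_atoms = 3)$vector
  expect_length(v, 6)  # upper triangle of 3x3
  expect_equal(sort(v, decreasing = TRUE)[1], 0.5)  # 0.5 * 1^2.4
  expect_equal(sum(v != 0), 1)

  h2 <- mol_structure(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  v2 <- coulomb_matrix(h2, max_atoms = 2)$vector
  # upper triangle by column: (1,1), (1,2), (2,2); off-diagonal is
  # Z^2 / (0.74 Angstrom in Bohr)
  expect_equal(v2[c(1, 3)], c(0.5, 0.5))
  expect_equal(v2[2], 1 / (0.74 * 1.8897259886), tolerance = 1e-10)
  expect_equal(v2[2], 0.71511, tolerance = 1e-4)
})

test_that("Coulomb matrix is invariant to atom order and errors on overflow", {
  set.seed(2)
  s <- random_structure(6)
  perm <- sample(6)
  sp <- mol_structure(s$elements[perm], s$coordinates[perm, ])
  expect_equal(coulomb_matrix(s, 8)$vector, coulomb_matrix(sp, 8)$vector)
  expect_error(coulomb_matrix(s, 5), "max_atoms")
})

test_that("bag of bonds matches the pair-term oracle and pads bags", {
  h2 <- mol_structure(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  v <- bag_of_bonds(h2, c("H:H" = 3))$vector
  expect_equal(v, c(1 / (0.74 * 1.8897259886), 0, 0), tolerance = 1e-10)

  single <- mol_structure("O", matrix(0, 1, 3))
  expect_equal(bag_of_bonds(single, c("H:H" = 2, "H:O" = 2))$vector,
               rep(0, 4))

  set.seed(3)
  s <- random_structure(5)
  sizes <- bob_bag_sizes(mol_dataset(list(s)))
  perm <- sample(5)
  sp <- mol_structure(s$elements[perm], s$coordinates[perm, ])
  expect_equal(bag_of_bonds(s, sizes)$vector, bag_of_bonds(sp, sizes)$vector)
  expect_error(bag_of_bonds(s, sizes[-1]), "not covered|overflow")
})

test_that("local many-body descriptor: isolated atom, bin-center closed form", {
  params <- manybody_params("H", cutoff = 4, n_radial = 4, n_angular = 3)
  lone <- mol_structure("H", matrix(0, 1, 3))
  expect_equal(local_manybody(lone, params)$per_atom[1, ],
               rep(0, length(local_manybody(lone, params)$per_atom[1, ])))

  # diatomic at a radial bin center: Gaussian factor 1, value = f_cut(r)
  r <- params$radial_centers[2]
  di <- mol_structure(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, r)))
  rep_ <- local_manybody(di, params)$per_atom
  fcut <- 0.5 * (1 + cos(pi * r / 4))
  expect_equal(rep_[1, 2], fcut, tolerance = 1e-12)
  expect_true(all(rep_[1, ] <= 1 + 1e-12))
})

test_that("descriptors are invariant to rigid rotation and translation", {
  set.seed(4)
  s <- random_structure(7, spread = 2)
  params <- manybody_params(unique(s$elements), cutoff = 6, n_radial = 8,
                            n_angular = 6)
  base_local <- local_manybody(s, params)$per_atom
  base_cm <- coulomb_matrix(s, 7)$vector
  sizes <- bob_bag_sizes(mol_dataset(list(s)))
  base_bob <- bag_of_bonds(s, sizes)$vector
  for (trial in 1:5) {
    sm <- rigid_move(s)
    expect_equal(local_manybody(sm, params)$per_atom, base_local,
                 tolerance = 1e-8)
    expect_equal(coulomb_matrix(sm, 7)$vector, base_cm, tolerance = 1e-8)
    expect_equal(bag_of_bonds(sm, sizes)$vector, base_bob, tolerance = 1e-8)
  }
})

test_that("many-body entries are non-negative and bounded by neighbor count", {
  set.seed(5)
  for (trial in 1:5) {
    s <- random_structure(sample(3:8, 1), spread = 2)
    params <- manybody_params(c("H", "O", "S"), cutoff = 6, n_radial = 6,
                              n_angular = 4)
    m <- local_manybody(s, params)$per_atom
    expect_true(all(m >= 0))
    # each two-body entry sums Gaussians * f_cut over <= n-1 neighbors
    expect_true(all(m[, 1:18] <= n_atoms(s) - 1 + 1e-12))
  }
})

test_that("globalize sums atom rows and is additive beyond the cutoff", {
  set.seed(6)
  s <- random_structure(4, spread = 1.5)
  params <- manybody_params(c("H", "O", "S"), cutoff = 5, n_radial = 6,
                            n_angular = 4)
  single <- mol_structure(s$elements[1], s$coordinates[1, , drop = FALSE])
  g1 <- globalize(local_manybody(single, params))
  expect_equal(g1$vector, local_manybody(single, params)$per_atom[1, ])

  # two copies far beyond the cutoff: global vector doubles
  far <- mol_structure(c(s$elements, s$elements),
                       rbind(s$coordinates, s$coordinates + 100))
  g_one <- globalize(local_manybody(s, params))$vector
  g_two <- globalize(local_manybody(far, params))$vector
  expect_equal(g_two, 2 * g_one, tolerance = 1e-10)

  # row permutation leaves the sum unchanged
  loc <- local_manybody(s, params)
  perm <- sample(nrow(loc$per_atom))
  loc$per_atom <- loc$per_atom[perm, , drop = FALSE]
  loc$elements <- loc$elements[perm]
  expect_equal(globalize(loc)$vector, g_one)
})

test_that("feature schema is fixed across a dataset", {
  set.seed(7)
  ds <- mol_dataset(lapply(1:5, function(i) random_structure(sample(2:6, 1))))
  for (method in c("coulomb", "bob")) {
    X <- global_features(ds, method)
    expect_equal(nrow(X), 5)
    expect_true(all(is.finite(X)))
  }
  X <- global_features(ds, "manybody", cutoff = 5, n_radial = 4,
                       n_angular = 3)
  expect_equal(nrow(X), 5)
})

test_that("representation export/import round trips and validates ids", {
  set.seed(8)
  ds <- mol_dataset(lapply(1:3, function(i)
    random_structure(3, id = paste0("s", i))))
  locs <- local_features(ds, cutoff = 5, n_radial = 4, n_angular = 3)
  ids <- paste0("s", 1:3)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_representations(locs, ids, f)
  back <- import_representations(f, ids)
  for (i in 1:3) {
    expect_equal(unname(back[[i]]$per_atom), unname(locs[[i]]$per_atom),
                 tolerance = 1e-10)
    expect_identical(back[[i]]$elements, locs[[i]]$elements)
  }
  expect_error(import_representations(f, c(ids, "s9")), "s9")
  expect_warning(import_representations(f, ids[1:2]), "ignoring")
})
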