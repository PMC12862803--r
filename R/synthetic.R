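# Synthetic molecular-cluster data with two correlated label levels.
#
# Clusters are assembled from a small library of rigid, stylized molecular
# units (an S-centered "SA" unit, a 3-atom "W" unit, a 4-atom "AM" unit),
# placed at random positions/orientations in a box, and labeled with a smooth
# Morse-sum interatomic potential evaluated at a "high" and a perturbed "low"
# level so that the high-low residual is smoother than the raw label -- the
# premise behind delta-learning.

#' Default rigid-unit library
#'
#' Stylized molecular units (shapes are schematic, not chemically accurate):
#' `SA` is an S atom with four O at ~1.45 A (tetrahedral), `W` is a bent
#' 3-atom O-H2 unit, `AM` a pyramidal N-H3 unit.
#'
#' @return Named list; each element has `elements` and an N x 3 `coordinates`
#'   matrix (Angstrom, unit centroid near origin).
#' @export
default_unit_library <- function() {
  # tetrahedral directions
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  sa <- rbind(c(0, 0, 0), 1.45 * tet)
  w <- rbind(c(0, 0, 0),
             0.96 * c(sin(52.25 * pi / 180), cos(52.25 * pi / 180), 0),
             0.96 * c(-sin(52.25 * pi / 180), cos(52.25 * pi / 180), 0))
  am_ang <- 107 * pi / 180
  am <- rbind(c(0, 0, 0),
              1.01 * c(sin(am_ang) * cos(0), sin(am_ang) * sin(0), cos(am_ang)),
              1.01 * c(sin(am_ang) * cos(2 * pi / 3), sin(am_ang) * sin(2 * pi / 3), cos(am_ang)),
              1.01 * c(sin(am_ang) * cos(4 * pi / 3), sin(am_ang) * sin(4 * pi / 3), cos(am_ang)))
  list(
    SA = list(elements = c("S", "O", "O", "O", "O"), coordinates = sa),
    W = list(elements = c("O", "H", "H"), coordinates = w),
    AM = list(elements = c("N", "H", "H", "H"), coordinates = am)
  )
}

#' Default Morse parameters per element pair
#'
#' Well depths D_e (kcal/mol) in the 2-8 range, equilibrium distances r_e
#' (Angstrom) in 1.5-3.0, widths alpha (1/Angstrom) near 1.0 -- a bounded,
#' smooth, soft-walled pair potential whose length scales match descriptor
#' locality and keep intra-unit contacts off the repulsive wall, so cluster
#' energies are negative and decrease with cluster size.
#'
#' @param elements Character vector of element symbols covered.
#' @return Data frame with columns `e1`, `e2`, `D_e`, `alpha`, `r_e`.
#' @export
default_morse_params <- function(elements = c("H", "O", "N", "S")) {
  base <- list(
    "H:H" = c(2.0, 1.1, 2.4), "H:N" = c(4.0, 1.0, 2.0),
    "H:O" = c(5.0, 1.0, 1.8), "H:S" = c(3.0, 0.9, 2.4),
    "N:N" = c(5.0, 1.0, 2.7), "N:O" = c(5.5, 1.0, 2.5),
    "N:S" = c(6.0, 0.9, 2.6), "O:O" = c(4.0, 1.0, 2.8),
    "O:S" = c(6.0, 0.9, 2.2), "S:S" = c(8.0, 0.9, 3.0)
  )
  pairs <- t(utils::combn(sort(elements), 2))
  pairs <- rbind(pairs, cbind(sort(elements), sort(elements)))
  key <- apply(pairs, 1, function(p) paste(sort(p), collapse = ":"))
  vals <- t(vapply(key, function(k) {
    if (!is.null(base[[k]])) base[[k]] else c(3.0, 1.0, 2.5)
  }, numeric(3)))
  data.frame(e1 = pairs[, 1], e2 = pairs[, 2],
             D_e = vals[, 1], alpha = vals[, 2], r_e = vals[, 3],
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic cluster generator
#'
#' @param unit_library Named list of rigid units (see
#'   [default_unit_library()]).
#' @param composition_distribution Named numeric vector of probabilities over
#'   composition strings; must sum to 1.
#' @param n_structures Number of clusters to generate.
#' @param placement_box Edge length (Angstrom) of the cubic placement box.
#' @param min_distance Minimum inter-unit atomic distance (Angstrom) enforced
#'   during placement.
#' @param jitter_sd Per-coordinate Gaussian jitter (Angstrom) applied after
#'   placement.
#' @param morse_params Data frame of Morse parameters (see
#'   [default_morse_params()]); the high level of theory.
#' @param eps_atom Named numeric vector of per-element atomic reference
#'   energies (kcal/mol).
#' @param pair_cutoff Pair-interaction cutoff (Angstrom) for the label
#'   potential.
#' @param low_rel_shift Relative perturbation of the Morse parameters that
#'   defines the low level of theory.
#' @param low_offset_per_unit Named numeric vector: smooth per-composition
#'   offset of the low level, in kcal/mol per unit of each type.
#' @param noise_sd Gaussian noise sd (kcal/mol) added to the low-level label.
#' @param seed Master seed; all generator randomness flows from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(unit_library = default_unit_library(),
                             composition_distribution = c(
                               "(SA)1(W)1" = 0.20, "(SA)1(W)2" = 0.20,
                               "(SA)2(W)1" = 0.15, "(SA)2(W)2" = 0.15,
                               "(SA)2(W)3" = 0.10, "(SA)3(W)3" = 0.08,
                               "(SA)3(W)4" = 0.07, "(SA)4(W)5" = 0.05),
                             n_structures = 100L,
                             placement_box = 9.0,
                             min_distance = 2.2,
                             jitter_sd = 0.05,
                             morse_params = default_morse_params(),
                             eps_atom = c(H = -5, O = -12, N = -14, S = -20),
                             pair_cutoff = 12.0,
                             low_rel_shift = 0.08,
                             low_offset_per_unit = c(SA = 0.8, W = 0.4, AM = 0.6),
                             noise_sd = 0.5,
                             seed = 1L) {
  p <- composition_distribution
  if (abs(sum(p) - 1) > 1e-8) stop("composition probabilities must sum to 1")
  if (min_distance <= 0) stop("min_distance must be positive")
  if (any(morse_params$D_e <= 0)) stop("Morse D_e must be positive")
  cfg <- list(unit_library = unit_library,
              composition_distribution = p,
              n_structures = as.integer(n_structures),
              placement_box = placement_box,
              min_distance = min_distance,
              jitter_sd = jitter_sd,
              morse_params = morse_params,
              eps_atom = eps_atom,
              pair_cutoff = pair_cutoff,
              low_rel_shift = low_rel_shift,
              low_offset_per_unit = low_offset_per_unit,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

# derive a deterministic 32-bit sub-seed from (seed, stream name)
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 7919 + h * 104729) %% 2147483647)
}

random_rotation <- function() {
  # uniform rotation from a normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
  )
}

#' Generate random rigid-unit clusters
#'
#' Samples a composition per structure, places whole rigid units at random
#' positions and orientations in a cubic box subject to a minimum inter-unit
#' atomic distance (rejection sampling, at most 1000 attempts per unit), then
#' applies Gaussian coordinate jitter. Deterministic for a given config seed.
#'
#' @param config A `generator_config`.
#' @return An unlabeled `mol_dataset` with composition metadata attached.
#' @export
generate_clusters <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(derive_seed(config$seed, "placement"))
  comps <- names(config$composition_distribution)
  half <- config$placement_box / 2
  structures <- vector("list", config$n_structures)
  for (i in seq_len(config$n_structures)) {
    comp_name <- sample(comps, 1L, prob = config$composition_distribution)
    comp <- parse_composition(comp_name)
    unit_names <- rep(names(comp), times = comp)
    placed_coords <- matrix(numeric(0), ncol = 3)
    elements <- character()
    for (u in unit_names) {
      unit <- config$unit_library[[u]]
      if (is.null(unit)) stop("unit '", u, "' not in unit library")
      ok <- FALSE
      for (attempt in seq_len(1000L)) {
        R <- random_rotation()
        center <- stats::runif(3, -half, half)
        cand <- unit$coordinates %*% t(R) +
          matrix(center, nrow(unit$coordinates), 3, byrow = TRUE)
        if (nrow(placed_coords) == 0L) { ok <- TRUE; break }
        d2min <- min(cross_dist2(cand, placed_coords))
        if (d2min >= config$min_distance^2) { ok <- TRUE; break }
      }
      if (!ok) {
        stop("failed to place unit '", u, "' after 1000 attempts; ",
             "try a larger placement_box")
      }
      placed_coords <- rbind(placed_coords, cand)
      elements <- c(elements, unit$elements)
    }
    placed_coords <- placed_coords +
      matrix(stats::rnorm(length(placed_coords), sd = config$jitter_sd),
             nrow(placed_coords), 3)
    structures[[i]] <- mol_structure(elements, placed_coords,
                                     composition = comp,
                                     id = sprintf("s%05d", i))
  }
  mol_dataset(structures)
}

# squared cross distances between row sets
cross_dist2 <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

morse_lookup <- function(morse_params) {
  key <- paste(pmin(morse_params$e1, morse_params$e2),
               pmax(morse_params$e1, morse_params$e2), sep = ":")
  rownames(morse_params) <- key
  morse_params
}

# sum of Morse pair energies + atomic reference energies for one structure
potential_energy <- function(structure, morse, eps_atom, cutoff) {
  el <- structure$elements
  n <- length(el)
  e <- sum(eps_atom[el])
  if (anyNA(e)) stop("missing eps_atom for element(s): ",
                     paste(unique(el[is.na(eps_atom[el])]), collapse = ", "))
  if (n >= 2L) {
    d2 <- cross_dist2(structure$coordinates, structure$coordinates)
    idx <- which(upper.tri(d2), arr.ind = TRUE)
    r <- sqrt(d2[idx])
    keep <- r <= cutoff
    if (any(keep)) {
      idx <- idx[keep, , drop = FALSE]
      r <- r[keep]
      key <- paste(pmin(el[idx[, 1]], el[idx[, 2]]),
                   pmax(el[idx[, 1]], el[idx[, 2]]), sep = ":")
      pars <- morse[key, , drop = FALSE]
      if (anyNA(pars$D_e)) stop("missing Morse parameters for pair(s): ",
                                paste(unique(key[is.na(pars$D_e)]), collapse = ", "))
      expo <- exp(-pars$alpha * (r - pars$r_e))
      e <- e + sum(pars$D_e * ((1 - expo)^2 - 1))
    }
  }
  e
}

#' Label structures at two correlated levels of theory
#'
#' The high-level label is a sum of per-element reference energies and Morse
#' pair energies within `pair_cutoff`. The low level evaluates the same
#' functional with relatively perturbed Morse parameters, adds a smooth
#' per-composition offset, and Gaussian noise. The residual
#' `y_high - y_low` is by construction much smoother than `y_high`; if a
#' noise draw ever violates `var(residual) < var(y_high)`, the noise is
#' redrawn from the next sub-seed.
#'
#' @param dataset A `mol_dataset` (labels, if any, are replaced).
#' @param config The `generator_config` used to generate it.
#' @return The dataset with `y_high` and `y_low` filled in.
#' @export
label_energies <- function(dataset, config) {
  stopifnot(inherits(config, "generator_config"))
  n <- length(dataset)
  if (n < 1L) stop("dataset has no structures")
  morse_hi <- morse_lookup(config$morse_params)
  morse_lo <- morse_hi
  s <- config$low_rel_shift
  morse_lo$D_e <- morse_lo$D_e * (1 + s)
  morse_lo$alpha <- morse_lo$alpha * (1 - s / 2)
  morse_lo$r_e <- morse_lo$r_e * (1 + s / 4)
  y_high <- vapply(dataset$structures, potential_energy, numeric(1),
                   morse = morse_hi, eps_atom = config$eps_atom,
                   cutoff = config$pair_cutoff)
  y_smooth_low <- vapply(dataset$structures, potential_energy, numeric(1),
                         morse = morse_lo, eps_atom = config$eps_atom,
                         cutoff = config$pair_cutoff)
  offset <- vapply(dataset$structures, function(st) {
    if (is.null(st$composition)) return(0)
    off <- config$low_offset_per_unit[names(st$composition)]
    off[is.na(off)] <- 0
    sum(off * as.integer(st$composition))
  }, numeric(1))
  for (try in 0:9) {
    set.seed(derive_seed(config$seed, paste0("label_noise", try)))
    y_low <- y_smooth_low + offset + stats::rnorm(n, sd = config$noise_sd)
    if (n < 2L || stats::var(y_high - y_low) < stats::var(y_high)) break
  }
  mol_dataset(dataset$structures, y_high = y_high, y_low = y_low)
}

#' Generate and label a synthetic cluster dataset in one call
#'
#' @param config A `generator_config`.
#' @return A labeled `mol_dataset` with `y_high` and `y_low`.
#' @export
synthetic_dataset <- function(config = generator_config()) {
  label_energies(generate_clusters(config), config)
}
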