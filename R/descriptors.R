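# Molecular descriptors: Coulomb matrix, bag of bonds, and a smeared
# 2-/3-body local descriptor with a global-by-summation variant.
#
# Coordinates are Angstrom everywhere in the package; the charge-over-distance
# descriptors (CM, BoB) convert to Bohr internally, following the convention
# of the descriptor literature.

#' Angstrom-to-Bohr conversion factor
#' @keywords internal
.ang2bohr <- 1.8897259886

#' Sorted Coulomb matrix descriptor
#'
#' Builds the Coulomb matrix `M_ii = 0.5 Z_i^2.4`,
#' `M_ij = Z_i Z_j / r_ij` (r in Bohr), sorts rows/columns by descending row
#' norm for atom-order invariance, zero-pads to `max_atoms`, and flattens the
#' upper triangle (including the diagonal) into a fixed-length vector.
#'
#' @param structure A `mol_structure`.
#' @param max_atoms Padding size; must be >= the structure's atom count.
#' @return A `global_representation`: list with `vector` and `schema`.
#' @export
coulomb_matrix <- function(structure, max_atoms) {
  n <- n_atoms(structure)
  if (n > max_atoms) {
    stop("structure has ", n, " atoms but max_atoms = ", max_atoms)
  }
  z <- atomic_numbers(structure$elements)
  M <- matrix(0, max_atoms, max_atoms)
  r <- sqrt(cross_dist2(structure$coordinates, structure$coordinates)) * .ang2bohr
  cm <- outer(z, z) / pmax(r, .Machine$double.eps)
  diag(cm) <- 0.5 * z^2.4
  ord <- order(-sqrt(rowSums(cm^2)))
  M[seq_len(n), seq_len(n)] <- cm[ord, ord]
  vec <- M[upper.tri(M, diag = TRUE)]
  structure(list(vector = vec,
                 schema = list(kind = "coulomb", max_atoms = max_atoms)),
            class = "global_representation")
}

#' Bag-of-bonds descriptor
#'
#' For every unordered element pair present, collects the pair terms
#' `Z_i Z_j / r_ij` (r in Bohr), sorts them in descending order, zero-pads to
#' the bag size, and concatenates the bags in lexicographic pair order.
#'
#' @param structure A `mol_structure`.
#' @param bag_sizes Named integer vector; names are element pairs like
#'   `"H:O"` (alphabetical order within the pair), values the bag lengths.
#'   See [bob_bag_sizes()] to derive them from a dataset.
#' @return A `global_representation`.
#' @export
bag_of_bonds <- function(structure, bag_sizes) {
  el <- structure$elements
  z <- atomic_numbers(el)
  n <- length(el)
  pairs_present <- character(0)
  vals <- list()
  if (n >= 2L) {
    idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
    r <- sqrt(cross_dist2(structure$coordinates,
                          structure$coordinates))[idx] * .ang2bohr
    key <- paste(pmin(el[idx[, 1]], el[idx[, 2]]),
                 pmax(el[idx[, 1]], el[idx[, 2]]), sep = ":")
    v <- z[idx[, 1]] * z[idx[, 2]] / r
    vals <- split(v, key)
    pairs_present <- names(vals)
  }
  missing <- setdiff(pairs_present, names(bag_sizes))
  if (length(missing) > 0L) {
    stop("element pair(s) not covered by bag_sizes: ",
         paste(missing, collapse = ", "))
  }
  bags <- lapply(sort(names(bag_sizes)), function(p) {
    x <- sort(vals[[p]] %||% numeric(0), decreasing = TRUE)
    size <- bag_sizes[[p]]
    if (length(x) > size) {
      stop("bag '", p, "' overflows: ", length(x), " > ", size)
    }
    c(x, rep(0, size - length(x)))
  })
  structure(list(vector = unlist(bags),
                 schema = list(kind = "bob",
                               bag_sizes = bag_sizes[sort(names(bag_sizes))])),
            class = "global_representation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bag sizes covering a whole dataset
#'
#' @param dataset A `mol_dataset`.
#' @return Named integer vector usable as `bag_sizes` in [bag_of_bonds()],
#'   sized to the dataset maximum per pair so all structures fit one schema.
#' @export
bob_bag_sizes <- function(dataset) {
  counts <- list()
  for (s in dataset$structures) {
    el <- s$elements
    n <- length(el)
    if (n < 2L) next
    idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
    key <- paste(pmin(el[idx[, 1]], el[idx[, 2]]),
                 pmax(el[idx[, 1]], el[idx[, 2]]), sep = ":")
    tab <- table(key)
    for (p in names(tab)) {
      counts[[p]] <- max(counts[[p]] %||% 0L, as.integer(tab[[p]]))
    }
  }
  out <- unlist(counts[sort(names(counts))])
  if (is.null(out)) integer(0) else out
}

#' Parameters for the smeared 2-/3-body local descriptor
#'
#' @param element_set Character vector: the union of elements across the
#'   dataset (fixes the schema so all structures produce aligned vectors).
#' @param cutoff Radial cutoff r_c in Angstrom.
#' @param n_radial Number of radial bins per neighbor element.
#' @param radial_width Gaussian width of the radial smearing; defaults to the
#'   bin spacing.
#' @param n_angular Number of angular bins on `[0, pi]` per unordered
#'   neighbor-element pair.
#' @param angular_width Gaussian width of the angular smearing; defaults to
#'   the angular bin spacing.
#' @return A list of validated parameters (class `manybody_params`).
#' @export
manybody_params <- function(element_set, cutoff = 8.0, n_radial = 24L,
                            radial_width = NULL, n_angular = 12L,
                            angular_width = NULL) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (n_radial < 1L || n_angular < 1L) stop("need at least one bin")
  element_set <- sort(unique(normalize_elements(element_set)))
  spacing <- cutoff / n_radial
  centers <- seq(spacing, cutoff, length.out = n_radial)
  ang_spacing <- pi / max(1L, n_angular - 1L)
  ang_centers <- seq(0, pi, length.out = n_angular)
  # unordered element pairs incl. same-element
  ep <- expand.grid(a = element_set, b = element_set, stringsAsFactors = FALSE)
  ep <- ep[ep$a <= ep$b, ]
  pair_names <- paste(ep$a, ep$b, sep = ":")
  structure(list(element_set = element_set,
                 cutoff = cutoff,
                 radial_centers = centers,
                 radial_width = radial_width %||% spacing,
                 angular_centers = ang_centers,
                 angular_width = angular_width %||% ang_spacing,
                 pair_names = sort(pair_names)),
            class = "manybody_params")
}

# smooth cosine cutoff, 0 beyond r_c
f_cut <- function(r, r_c) ifelse(r < r_c, 0.5 * (1 + cos(pi * r / r_c)), 0)

#' Smeared 2-/3-body local atomic-environment descriptor
#'
#' Per atom, the two-body channels are Gaussian-smeared radial histograms of
#' neighbor distances, one block per neighbor element; the three-body
#' channels are Gaussian-smeared angular histograms of neighbor-pair angles,
#' one block per unordered neighbor-element pair. All contributions are
#' damped by the smooth cosine cutoff
#' `f_cut(r) = 0.5 (1 + cos(pi r / r_c))` for `r < r_c`, else 0. Channels for
#' elements absent from a structure are zero, keeping the schema fixed
#' across a dataset.
#'
#' @param structure A `mol_structure`.
#' @param params A `manybody_params` object.
#' @return A `local_representation`: list with `per_atom` (N x p matrix),
#'   `elements` (per row), and `schema`.
#' @export
local_manybody <- function(structure, params) {
  stopifnot(inherits(params, "manybody_params"))
  el <- structure$elements
  n <- length(el)
  if (n < 1L) stop("structure must have at least one atom")
  if (any(!is.finite(structure$coordinates))) stop("non-finite coordinate")
  extra <- setdiff(unique(el), params$element_set)
  if (length(extra) > 0L) {
    stop("element(s) outside descriptor schema: ", paste(extra, collapse = ", "))
  }
  es <- params$element_set
  nr <- length(params$radial_centers)
  na <- length(params$angular_centers)
  n2 <- length(es) * nr
  n3 <- length(params$pair_names) * na
  out <- matrix(0, n, n2 + n3)
  rc <- params$cutoff
  d <- sqrt(cross_dist2(structure$coordinates, structure$coordinates))
  w2 <- params$radial_width
  wa <- params$angular_width
  for (a in seq_len(n)) {
    nb <- which(d[a, ] < rc & seq_len(n) != a)
    if (length(nb) == 0L) next
    r <- d[a, nb]
    fc <- f_cut(r, rc)
    # two-body: per neighbor element block
    g <- exp(-(outer(r, params$radial_centers, "-"))^2 / (2 * w2^2)) * fc
    for (e in unique(el[nb])) {
      rows <- el[nb] == e
      block <- (match(e, es) - 1L) * nr
      out[a, (block + 1L):(block + nr)] <-
        colSums(g[rows, , drop = FALSE])
    }
    # three-body: angles over neighbor pairs
    if (length(nb) >= 2L) {
      pr <- utils::combn(seq_along(nb), 2)
      b <- nb[pr[1, ]]; cc <- nb[pr[2, ]]
      rb <- d[a, b]; rcc <- d[a, cc]; rbc <- d[cbind(b, cc)]
      cosang <- (rb^2 + rcc^2 - rbc^2) / (2 * rb * rcc)
      cosang <- pmin(1, pmax(-1, cosang))
      theta <- acos(cosang)
      fcp <- f_cut(rb, rc) * f_cut(rcc, rc)
      ga <- exp(-(outer(theta, params$angular_centers, "-"))^2 / (2 * wa^2)) * fcp
      pk <- paste(pmin(el[b], el[cc]), pmax(el[b], el[cc]), sep = ":")
      for (p in unique(pk)) {
        rows <- pk == p
        block <- n2 + (match(p, params$pair_names) - 1L) * na
        out[a, (block + 1L):(block + na)] <-
          colSums(ga[rows, , drop = FALSE])
      }
    }
  }
  structure(list(per_atom = out, elements = el, schema = params),
            class = "local_representation")
}

#' Collapse a local representation into a global one
#'
#' Sums the per-atom environment vectors; for extensive properties the sum
#' plays the role the atomic decomposition plays in the extensive kernel.
#'
#' @param local A `local_representation`.
#' @return A `global_representation` with the same schema.
#' @export
globalize <- function(local) {
  stopifnot(inherits(local, "local_representation"))
  if (nrow(local$per_atom) < 1L) stop("empty local representation")
  structure(list(vector = colSums(local$per_atom), schema = local$schema),
            class = "global_representation")
}

#' Global feature matrix for a dataset
#'
#' Convenience wrapper producing one fixed-length feature row per structure.
#' The schema (padding size, bag sizes, element set) is derived from the full
#' dataset before any train/test split so all vectors align.
#'
#' @param dataset A `mol_dataset`.
#' @param method `"coulomb"`, `"bob"`, or `"manybody"` (globalized 2-/3-body).
#' @param ... Passed to [manybody_params()] for `method = "manybody"`.
#' @return Numeric n x p matrix, one row per structure.
#' @export
global_features <- function(dataset, method = c("coulomb", "bob", "manybody"),
                            ...) {
  method <- match.arg(method)
  if (method == "coulomb") {
    mx <- max(vapply(dataset$structures, n_atoms, integer(1)))
    rows <- lapply(dataset$structures, function(s) coulomb_matrix(s, mx)$vector)
  } else if (method == "bob") {
    bs <- bob_bag_sizes(dataset)
    rows <- lapply(dataset$structures, function(s) bag_of_bonds(s, bs)$vector)
  } else {
    els <- unique(unlist(lapply(dataset$structures, `[[`, "elements")))
    params <- manybody_params(els, ...)
    rows <- lapply(dataset$structures,
                   function(s) globalize(local_manybody(s, params))$vector)
  }
  do.call(rbind, rows)
}

#' Local representations for every structure in a dataset
#'
#' @param dataset A `mol_dataset`.
#' @param ... Passed to [manybody_params()]; the element set is always the
#'   dataset union.
#' @return List of `local_representation`, one per structure, sharing one
#'   schema.
#' @export
local_features <- function(dataset, ...) {
  els <- unique(unlist(lapply(dataset$structures, `[[`, "elements")))
  params <- manybody_params(els, ...)
  lapply(dataset$structures, local_manybody, params = params)
}

# ---------------------------------------------------------------------------
# Import/export of externally computed per-atom representations

#' Export local representations to a delimited text file
#'
#' Tab-separated columns: structure id, atom index, element, then the feature
#' values. Readable back with [import_representations()], and an exchange
#' format for descriptor vectors computed by external codes.
#'
#' @param locals List of `local_representation`, one per structure.
#' @param ids Character vector of structure ids (same length).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_representations <- function(locals, ids, path) {
  stopifnot(length(locals) == length(ids))
  rows <- lapply(seq_along(locals), function(i) {
    m <- locals[[i]]$per_atom
    data.frame(id = ids[i], atom = seq_len(nrow(m)),
               element = locals[[i]]$elements, m,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import per-atom representations from a delimited text file
#'
#' @param path File written by [export_representations()] (or an external
#'   tool following the same layout).
#' @param ids Character vector of the dataset's structure ids, in dataset
#'   order; every id must appear in the file. Ids present in the file but not
#'   in `ids` are ignored with a warning.
#' @return List of `local_representation` aligned with `ids`.
#' @export
import_representations <- function(path, ids) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(ids, tab$id)
  if (length(missing) > 0L) {
    stop("representation file is missing structure id(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(unique(tab$id), ids)
  if (length(extra) > 0L) {
    warning("ignoring ", length(extra),
            " structure id(s) not in the dataset: ",
            paste(utils::head(extra, 5), collapse = ", "))
  }
  featcols <- setdiff(names(tab), c("id", "atom", "element"))
  lapply(ids, function(sid) {
    sub <- tab[tab$id == sid, , drop = FALSE]
    sub <- sub[order(sub$atom), , drop = FALSE]
    structure(list(per_atom = as.matrix(sub[, featcols, drop = FALSE]),
                   elements = sub$element,
                   schema = list(kind = "imported", features = featcols)),
              class = "local_representation")
  })
}
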