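# Molecular structures, labeled datasets, and multi-frame XYZ I/O.

#' Atomic numbers of the supported elements
#'
#' Named integer vector mapping element symbols (case-normalized, e.g. "H",
#' "Cl") to atomic numbers Z for the first four periods plus a few common
#' heavier elements. Used to validate element symbols and to compute
#' charge-based descriptors.
#'
#' @format Named integer vector.
#' @keywords internal
.atomic_numbers <- c(
  H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L, O = 8L,
  F = 9L, Ne = 10L, Na = 11L, Mg = 12L, Al = 13L, Si = 14L, P = 15L,
  S = 16L, Cl = 17L, Ar = 18L, K = 19L, Ca = 20L, Sc = 21L, Ti = 22L,
  V = 23L, Cr = 24L, Mn = 25L, Fe = 26L, Co = 27L, Ni = 28L, Cu = 29L,
  Zn = 30L, Ga = 31L, Ge = 32L, As = 33L, Se = 34L, Br = 35L, Kr = 36L,
  I = 53L
)

#' Normalize element symbols
#'
#' First letter upper case, remainder lower case ("cl" -> "Cl").
#'
#' @param symbols Character vector of element symbols.
#' @return Character vector of normalized symbols.
#' @keywords internal
normalize_elements <- function(symbols) {
  paste0(
    toupper(substr(symbols, 1L, 1L)),
    tolower(substr(symbols, 2L, nchar(symbols)))
  )
}

#' Look up atomic numbers
#'
#' @param symbols Character vector of element symbols (any case).
#' @return Integer vector of atomic numbers.
#' @export
atomic_numbers <- function(symbols) {
  symbols <- normalize_elements(symbols)
  z <- .atomic_numbers[symbols]
  if (anyNA(z)) {
    bad <- unique(symbols[is.na(z)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(z)
}

#' Create a molecular structure
#'
#' A structure is a list of element symbols with Cartesian coordinates in
#' Angstrom, optionally carrying a composition (unit name -> count, e.g.
#' `c(SA = 4, W = 5)`) and an opaque id.
#'
#' @param elements Character vector of element symbols.
#' @param coordinates Numeric N x 3 matrix of Cartesian coordinates (Angstrom).
#' @param composition Optional named integer vector of unit counts.
#' @param id Optional id string.
#' @return An object of class `mol_structure`.
#' @export
mol_structure <- function(elements, coordinates, composition = NULL, id = NULL) {
  elements <- normalize_elements(as.character(elements))
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  if (length(elements) < 1L) stop("structure must contain at least one atom")
  if (nrow(coordinates) != length(elements) || ncol(coordinates) != 3L) {
    stop("coordinates must be a ", length(elements), " x 3 matrix")
  }
  if (any(!is.finite(coordinates))) stop("non-finite coordinate")
  atomic_numbers(elements)  # validates symbols
  if (!is.null(composition)) {
    composition <- composition[order(names(composition))]
    storage.mode(composition) <- "integer"
  }
  structure(
    list(elements = elements, coordinates = coordinates,
         composition = composition, id = id),
    class = "mol_structure"
  )
}

#' @export
print.mol_structure <- function(x, ...) {
  cat("<mol_structure>", length(x$elements), "atoms:",
      paste(unique(x$elements), collapse = " "), "\n")
  if (!is.null(x$composition)) {
    cat("  composition:", format_composition(x$composition), "\n")
  }
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure A `mol_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(structure) length(structure$elements)

#' Create a labeled dataset of molecular structures
#'
#' Bundles structures with a high-level label vector (e.g. electronic binding
#' energies in kcal/mol) and optionally a second, low-level label vector for
#' delta-learning.
#'
#' @param structures List of `mol_structure` objects.
#' @param y_high Optional numeric vector of high-level labels (kcal/mol).
#' @param y_low Optional numeric vector of low-level labels (kcal/mol).
#' @return An object of class `mol_dataset`.
#' @export
mol_dataset <- function(structures, y_high = NULL, y_low = NULL) {
  if (!is.list(structures)) stop("structures must be a list")
  for (s in structures) {
    if (!inherits(s, "mol_structure")) stop("all structures must be mol_structure")
  }
  n <- length(structures)
  if (!is.null(y_high) && length(y_high) != n) {
    stop("y_high length ", length(y_high), " != structure count ", n)
  }
  if (!is.null(y_low) && length(y_low) != n) {
    stop("y_low length ", length(y_low), " != structure count ", n)
  }
  structure(
    list(structures = structures,
         y_high = if (!is.null(y_high)) as.numeric(y_high),
         y_low = if (!is.null(y_low)) as.numeric(y_low)),
    class = "mol_dataset"
  )
}

#' @export
length.mol_dataset <- function(x) length(x$structures)

#' @export
print.mol_dataset <- function(x, ...) {
  cat("<mol_dataset>", length(x), "structures;",
      if (is.null(x$y_high)) "unlabeled" else "labeled",
      if (!is.null(x$y_low)) "(+ low-level labels)" else "", "\n")
  invisible(x)
}

#' Subset a labeled dataset
#' @param x A `mol_dataset`.
#' @param i Index vector.
#' @param ... Unused.
#' @return A `mol_dataset` with the selected structures and labels.
#' @export
`[.mol_dataset` <- function(x, i, ...) {
  mol_dataset(x$structures[i],
              y_high = if (!is.null(x$y_high)) x$y_high[i],
              y_low = if (!is.null(x$y_low)) x$y_low[i])
}

# ---------------------------------------------------------------------------
# XYZ I/O

parse_comment_fields <- function(line) {
  toks <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  kv <- toks[grepl("=", toks, fixed = TRUE)]
  if (length(kv) == 0L) return(character())
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- keys
  vals
}

#' Read a multi-frame XYZ file into a labeled dataset
#'
#' Each frame is an atom count line, a comment line, and one `element x y z`
#' line per atom. Comment lines may carry whitespace-separated `key=value`
#' tokens; the token named by `label_key` (and optionally `low_key`) supplies
#' per-structure labels, `comp=` a composition string, and `id=` an id.
#' Unknown keys are ignored. Frames missing `label_key` yield an unlabeled
#' dataset.
#'
#' @param path Path to an XYZ file.
#' @param label_key Comment-line key holding the high-level label
#'   (default `"E_high"`).
#' @param low_key Comment-line key holding the low-level label for
#'   delta-learning (default `"E_low"`); only used if present in every frame.
#' @return A `mol_dataset`.
#' @export
read_xyz <- function(path, label_key = "E_high", low_key = "E_low") {
  lines <- readLines(path)
  structures <- list()
  y_high <- numeric()
  y_low <- numeric()
  n_high <- 0L
  n_low <- 0L
  pos <- 1L
  frame <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat < 1L) {
      stop("frame ", frame, ": invalid atom count line: ", lines[pos])
    }
    if (pos + 1L + nat > length(lines)) {
      stop("frame ", frame, ": declares ", nat,
           " atoms but file ends after ", length(lines) - pos - 1L, " atom lines")
    }
    fields <- parse_comment_fields(lines[pos + 1L])
    atom_lines <- lines[(pos + 2L):(pos + 1L + nat)]
    toks <- strsplit(trimws(atom_lines), "[[:space:]]+")
    nt <- lengths(toks)
    if (any(nt < 4L)) {
      stop("frame ", frame, ": atom line with fewer than 4 fields ",
           "(declared ", nat, " atoms)")
    }
    elements <- vapply(toks, `[[`, "", 1L)
    coords <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (any(!is.finite(coords))) {
      stop("frame ", frame, ": non-numeric coordinate")
    }
    comp <- if ("comp" %in% names(fields)) parse_composition(fields[["comp"]])
    id <- if ("id" %in% names(fields)) fields[["id"]]
    structures[[frame]] <- mol_structure(elements, coords,
                                         composition = comp, id = id)
    if (label_key %in% names(fields)) {
      y_high[frame] <- as.numeric(fields[[label_key]])
      n_high <- n_high + 1L
    } else y_high[frame] <- NA_real_
    if (!is.null(low_key) && low_key %in% names(fields)) {
      y_low[frame] <- as.numeric(fields[[low_key]])
      n_low <- n_low + 1L
    } else y_low[frame] <- NA_real_
    pos <- pos + 2L + nat
  }
  n <- length(structures)
  mol_dataset(structures,
              y_high = if (n_high == n && n > 0L) y_high,
              y_low = if (n_low == n && n > 0L) y_low)
}

#' Write a labeled dataset as a multi-frame XYZ file
#'
#' Labels, ids and compositions are serialized as `key=value` tokens on the
#' comment line (keys `E_high`, `E_low`, `id`, `comp`). Coordinates are
#' printed with 12 significant digits; labels with full double precision so
#' that a write/read round trip preserves them exactly.
#'
#' @param dataset A `mol_dataset`.
#' @param path Output file path.
#' @param label_key Comment key for the high-level label.
#' @param low_key Comment key for the low-level label.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(dataset, path, label_key = "E_high", low_key = "E_low") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  n <- length(dataset)
  for (i in seq_len(n)) {
    s <- dataset$structures[[i]]
    fields <- character()
    if (!is.null(s$id)) fields <- c(fields, paste0("id=", s$id))
    if (!is.null(s$composition)) {
      fields <- c(fields, paste0("comp=", format_composition(s$composition)))
    }
    if (!is.null(dataset$y_high)) {
      fields <- c(fields, sprintf("%s=%.17g", label_key, dataset$y_high[i]))
    }
    if (!is.null(dataset$y_low)) {
      fields <- c(fields, sprintf("%s=%.17g", low_key, dataset$y_low[i]))
    }
    writeLines(as.character(length(s$elements)), con)
    writeLines(paste(fields, collapse = " "), con)
    writeLines(sprintf("%s %.12g %.12g %.12g", s$elements,
                       s$coordinates[, 1], s$coordinates[, 2],
                       s$coordinates[, 3]), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Composition strings

#' Parse a cluster composition string
#'
#' Compositions are written in parenthesized unit-count notation, e.g.
#' `"(SA)4(W)5"` for a cluster of four sulfuric acid and five water units.
#'
#' @param name Composition string.
#' @return Named integer vector of positive unit counts.
#' @export
#' @examples
#' parse_composition("(SA)4(W)5")
parse_composition <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("composition must be a single non-empty string")
  }
  chars <- strsplit(name, "")[[1]]
  units <- character()
  counts <- integer()
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] != "(") stop("malformed composition '", name,
                              "': expected '(' at position ", i)
    j <- i + 1L
    unit <- ""
    while (j <= length(chars) && chars[j] != ")") {
      unit <- paste0(unit, chars[j])
      j <- j + 1L
    }
    if (j > length(chars)) stop("malformed composition '", name,
                                "': unterminated '('")
    if (!nzchar(unit)) stop("malformed composition '", name, "': empty unit name")
    j <- j + 1L
    digits <- ""
    while (j <= length(chars) && chars[j] %in% as.character(0:9)) {
      digits <- paste0(digits, chars[j])
      j <- j + 1L
    }
    if (!nzchar(digits)) stop("malformed composition '", name,
                              "': missing count after (", unit, ")")
    cnt <- as.integer(digits)
    if (cnt < 1L) stop("malformed composition '", name, "': zero count")
    if (unit %in% units) {
      counts[match(unit, units)] <- counts[match(unit, units)] + cnt
    } else {
      units <- c(units, unit)
      counts <- c(counts, cnt)
    }
    i <- j
  }
  names(counts) <- units
  counts[order(units)]
}

#' Format a composition map as a string
#'
#' Inverse of [parse_composition()]; units are emitted in alphabetical order
#' so equal compositions format identically.
#'
#' @param composition Named integer vector of unit counts.
#' @return Composition string such as `"(SA)4(W)5"`.
#' @export
format_composition <- function(composition) {
  composition <- composition[order(names(composition))]
  paste0(sprintf("(%s)%d", names(composition), as.integer(composition)),
         collapse = "")
}

#' Test whether two compositions are equal
#' @param a,b Named count vectors (or composition strings).
#' @return Logical.
#' @keywords internal
same_composition <- function(a, b) {
  if (is.character(a)) a <- parse_composition(a)
  if (is.character(b)) b <- parse_composition(b)
  a <- a[order(names(a))]
  b <- b[order(names(b))]
  length(a) == length(b) && all(names(a) == names(b)) &&
    all(as.integer(a) == as.integer(b))
}
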