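# Core S3 containers: atom_model, sphere_model, scatter_curve, sequence_counts.
# All coordinates in nm, Q in nm^-1.

#' Construct an atom model
#'
#' An `atom_model` is an ordered set of labelled 3-D atomic coordinates, the
#' in-memory form of the ATOM/HETATM content of a PDB file. Coordinates are
#' stored in nanometres.
#'
#' @param atoms data.frame with columns `resid` (upper-case 3-letter residue
#'   code), `x`, `y`, `z` (nm). Extra columns (`chain`, `resno`, `insert`) are
#'   retained when present.
#' @param source character scalar describing provenance (file path or fixture
#'   tag).
#' @return object of class `atom_model`.
#' @seealso [read_pdb_atoms()], [make_atom_cloud()]
#' @export
atom_model <- function(atoms, source = NA_character_) {
  stopifnot(is.data.frame(atoms))
  need <- c("resid", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0L)
    stop("atom_model: missing column(s): ", paste(miss, collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("atom_model: non-finite coordinates")
  atoms$resid <- toupper(as.character(atoms$resid))
  structure(list(atoms = atoms, source = source), class = "atom_model")
}

#' @export
print.atom_model <- function(x, ...) {
  cat(sprintf("atom_model: %d atoms, %d residue codes (source: %s)\n",
              nrow(x$atoms), length(unique(x$atoms$resid)), x$source))
  invisible(x)
}

#' Construct a sphere (bead) model
#'
#' A coarse-grained structure made of identical spheres placed at grid-box
#' centres. The sphere radius is always half the grid box side.
#'
#' @param centres numeric matrix (n x 3) of sphere centres in nm.
#' @param boxside grid box side length in nm; the common sphere radius is
#'   `boxside / 2`.
#' @param hydrated logical; `TRUE` once the hydration monolayer has been added.
#' @return object of class `sphere_model` with elements `centres`, `radius`,
#'   `boxside`, `hydrated`.
#' @seealso [grid_transform()], [hydrate_sphere_model()]
#' @export
sphere_model <- function(centres, boxside, hydrated = FALSE) {
  centres <- as.matrix(centres)
  if (length(centres) == 0L) centres <- matrix(numeric(0), ncol = 3)
  if (ncol(centres) != 3L) stop("sphere_model: centres must be n x 3")
  if (!is.numeric(boxside) || length(boxside) != 1L || boxside <= 0)
    stop("sphere_model: boxside must be a positive scalar")
  dimnames(centres) <- NULL
  structure(list(centres = centres, radius = boxside / 2,
                 boxside = boxside, hydrated = isTRUE(hydrated)),
            class = "sphere_model")
}

#' @export
print.sphere_model <- function(x, ...) {
  cat(sprintf("sphere_model: %d spheres, radius %.4f nm (boxside %.4f nm)%s\n",
              nrow(x$centres), x$radius, x$boxside,
              if (x$hydrated) ", hydrated" else ""))
  invisible(x)
}

#' Construct a scattering curve
#'
#' Paired arrays of scattering vector magnitude Q (nm^-1, strictly increasing)
#' and radially averaged intensity I (arbitrary units).
#'
#' @param q numeric vector, strictly increasing, all `>= 0` (nm^-1).
#' @param i numeric vector of intensities, same length as `q`.
#' @param kind `"theoretical"` or `"experimental"`.
#' @param smeared logical; `TRUE` once an instrumental smearing correction has
#'   been applied.
#' @param source optional provenance string.
#' @return object of class `scatter_curve`.
#' @export
scatter_curve <- function(q, i, kind = c("theoretical", "experimental"),
                          smeared = FALSE, source = NA_character_) {
  kind <- match.arg(kind)
  q <- as.numeric(q); i <- as.numeric(i)
  if (length(q) != length(i)) stop("scatter_curve: q and i differ in length")
  if (length(q) < 1L) stop("scatter_curve: empty curve")
  if (any(!is.finite(q)) || any(!is.finite(i)))
    stop("scatter_curve: non-finite values")
  if (any(q < 0)) stop("scatter_curve: negative Q")
  if (any(diff(q) <= 0)) stop("scatter_curve: q must be strictly increasing")
  structure(list(q = q, i = i, kind = kind, smeared = isTRUE(smeared),
                 source = source),
            class = "scatter_curve")
}

#' @export
print.scatter_curve <- function(x, ...) {
  cat(sprintf("scatter_curve (%s%s): %d points, Q in [%.4g, %.4g] nm^-1\n",
              x$kind, if (x$smeared) ", smeared" else "",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' Construct a residue-frequency map
#'
#' A macromolecular composition expressed as frequencies of 3-letter residue
#' or monosaccharide codes.
#'
#' @param counts named non-negative integer vector (names are 3-letter codes).
#' @param check_codes warn about codes missing from the default residue-volume
#'   table.
#' @return object of class `sequence_counts` (a named integer vector).
#' @seealso [read_sequence()], [dry_volume()]
#' @export
sequence_counts <- function(counts, check_codes = TRUE) {
  if (length(counts) == 0L) stop("sequence_counts: empty sequence")
  nm <- toupper(names(counts))
  if (is.null(nm) || any(nm == ""))
    stop("sequence_counts: all entries must be named by residue code")
  v <- as.numeric(counts)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    stop("sequence_counts: frequencies must be non-negative integers")
  out <- structure(as.integer(round(v)), names = nm, class = "sequence_counts")
  if (check_codes) {
    unknown <- setdiff(nm, names(residue_volume_table()))
    if (length(unknown) > 0L)
      warning("sequence_counts: code(s) not in the default residue-volume ",
              "table: ", paste(unknown, collapse = ", "))
  }
  out
}

#' @export
print.sequence_counts <- function(x, ...) {
  cat(sprintf("sequence_counts: %d residues over %d codes\n",
              sum(unclass(x)), length(x)))
  print(setNames(as.integer(x), names(x)))
  invisible(x)
}

# Coerce any point-bearing object to an n x 3 coordinate matrix (nm).
as_point_matrix <- function(x) {
  if (inherits(x, "atom_model")) {
    m <- as.matrix(x$atoms[, c("x", "y", "z")])
  } else if (inherits(x, "sphere_model")) {
    m <- x$centres
  } else if (is.matrix(x) && ncol(x) == 3L) {
    m <- x
  } else if (is.data.frame(x) && all(c("x", "y", "z") %in% names(x))) {
    m <- as.matrix(x[, c("x", "y", "z")])
  } else {
    stop("cannot interpret input as 3-D points ",
         "(need atom_model, sphere_model, n x 3 matrix or x/y/z data.frame)")
  }
  if (nrow(m) < 1L) stop("empty point set")
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}
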