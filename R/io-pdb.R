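# PDB input/output. Reading goes through bio3d; coordinates are converted from
# angstroms to nm at this single point. Sphere models are written with a
# hand-built fixed-column writer so that the sphere radius can be recorded in a
# REMARK header.

ANGSTROM_PER_NM <- 10

#' Read ATOM/HETATM records from a PDB file
#'
#' Parses all ATOM and HETATM records (other record types are ignored) in file
#' order and returns an [atom_model()] with coordinates in nanometres.
#'
#' @param path path to a PDB file with at least one ATOM/HETATM record.
#' @return an [atom_model()]; the `atoms` data.frame additionally carries
#'   `chain`, `resno` and `insert` columns for residue bookkeeping.
#' @export
read_pdb_atoms <- function(path) {
  if (!file.exists(path)) stop("read_pdb_atoms: file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("read_pdb_atoms: cannot parse '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(at) == 0L)
    stop("read_pdb_atoms: no ATOM/HETATM records in ", path)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (any(!is.finite(xyz)))
    stop("read_pdb_atoms: malformed coordinate fields in ", path)
  atom_model(data.frame(resid = toupper(at$resid),
                        x = at$x / ANGSTROM_PER_NM,
                        y = at$y / ANGSTROM_PER_NM,
                        z = at$z / ANGSTROM_PER_NM,
                        chain = at$chain,
                        resno = at$resno,
                        insert = at$insert,
                        stringsAsFactors = FALSE),
             source = path)
}

# One fixed-width ATOM record (standard PDB columns: serial 7-11, name 13-16,
# resName 18-20, chain 22, resSeq 23-26, x/y/z 31-54, element 77-78).
# Coordinates in angstroms. Residue/element fields are cosmetic placeholders.
format_atom_record <- function(serial, resno, x, y, z,
                               resid = "SER", elem = "C") {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, paste0(" ", elem), resid, "A",
          resno %% 10000L, x, y, z, 1.0, 0.0, elem)
}

#' Write a sphere model as a PDB file
#'
#' One ATOM record per sphere, fixed-width PDB columns, coordinates in
#' angstroms. The common sphere radius and grid box side (nm) are recorded in
#' REMARK lines. Element `C` and residue `SER` are cosmetic placeholders for
#' visualization only.
#'
#' @param model a non-empty [sphere_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sphere_model_pdb <- function(model, path) {
  stopifnot(inherits(model, "sphere_model"))
  n <- nrow(model$centres)
  if (n < 1L) stop("write_sphere_model_pdb: empty model")
  ang <- model$centres * ANGSTROM_PER_NM
  lines <- c(
    sprintf("REMARK SPHERE MODEL: %d spheres", n),
    sprintf("REMARK SPHERE RADIUS %.6f NM BOXSIDE %.6f NM HYDRATED %s",
            model$radius, model$boxside, if (model$hydrated) "YES" else "NO"),
    vapply(seq_len(n), function(k)
      format_atom_record(k, k, ang[k, 1], ang[k, 2], ang[k, 3]),
      character(1)),
    "END")
  res <- tryCatch(writeLines(lines, path),
                  error = function(e) stop("write_sphere_model_pdb: cannot ",
                                           "write '", path, "': ",
                                           conditionMessage(e)))
  invisible(path)
}

#' Write an atom model as a PDB file
#'
#' Support writer for synthetic fixtures and intermediate models: emits one
#' ATOM record per atom with coordinates converted from nm to angstroms.
#' Consecutive atoms are grouped into residues of `atoms_per_residue` so that
#' the written file carries a realistic residue count for sequence-derived
#' volume calculations (a protein packs roughly eight heavy atoms per residue).
#'
#' @param model an [atom_model()].
#' @param path output file path.
#' @param atoms_per_residue atoms grouped under one residue number.
#' @return `path`, invisibly.
#' @seealso [make_atom_cloud()]
#' @export
write_atom_pdb <- function(model, path, atoms_per_residue = 8L) {
  stopifnot(inherits(model, "atom_model"))
  at <- model$atoms
  if (nrow(at) < 1L) stop("write_atom_pdb: empty model")
  resno <- if ("resno" %in% names(at)) at$resno
           else (seq_len(nrow(at)) - 1L) %/% as.integer(atoms_per_residue) + 1L
  lines <- c(
    vapply(seq_len(nrow(at)), function(k)
      format_atom_record(k, resno[k],
                         at$x[k] * ANGSTROM_PER_NM,
                         at$y[k] * ANGSTROM_PER_NM,
                         at$z[k] * ANGSTROM_PER_NM,
                         resid = at$resid[k]),
      character(1)),
    "END")
  writeLines(lines, path)
  invisible(path)
}
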