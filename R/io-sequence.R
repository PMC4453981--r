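# Sequence input: FASTA (1-letter amino acids), PDB (one residue per unique
# chain/resno/insertion among ATOM/HETATM records) or YAML ("CODE: n" pairs,
# 3-letter codes). All three converge on a sequence_counts frequency map.

AA1_TO_AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
                E = "GLU", Q = "GLN", G = "GLY", H = "HIS", I = "ILE",
                L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
                S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Read a macromolecular sequence as residue frequencies
#'
#' Three input routes are supported. FASTA files carry 1-letter amino-acid
#' codes (all sequences in the file are pooled); PDB files contribute one
#' residue per unique (chain, residue number, insertion code) among ATOM and
#' HETATM records, so residues missing from the structure are not counted;
#' YAML files hold `CODE: frequency` pairs with 3-letter codes (extra
#' non-numeric metadata keys are ignored).
#'
#' @param path input file.
#' @param format one of `"fasta"`, `"pdb"`, `"yaml"`.
#' @return a [sequence_counts()] frequency map.
#' @export
read_sequence <- function(path, format = c("fasta", "pdb", "yaml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_sequence: file not found: ", path)
  switch(format,
         fasta = read_sequence_fasta(path),
         pdb = read_sequence_pdb(path),
         yaml = read_sequence_yaml(path))
}

read_sequence_fasta <- function(path) {
  fa <- tryCatch(bio3d::read.fasta(path),
                 error = function(e) stop("read_sequence: cannot parse FASTA '",
                                          path, "': ", conditionMessage(e)))
  letters1 <- toupper(as.vector(t(fa$ali)))
  letters1 <- letters1[!(letters1 %in% c("-", ".", ""))]
  if (length(letters1) == 0L) stop("read_sequence: empty sequence in ", path)
  unknown <- which(!(letters1 %in% names(AA1_TO_AA3)))
  if (length(unknown) > 0L)
    stop("read_sequence: unknown residue code '", letters1[unknown[1]],
         "' at sequence position ", unknown[1], " in ", path)
  tab <- table(AA1_TO_AA3[letters1])
  sequence_counts(setNames(as.integer(tab), names(tab)))
}

read_sequence_pdb <- function(path) {
  model <- read_pdb_atoms(path)
  at <- model$atoms
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  first <- !duplicated(key)
  tab <- table(at$resid[first])
  if (length(tab) == 0L) stop("read_sequence: empty sequence in ", path)
  sequence_counts(setNames(as.integer(tab), names(tab)))
}

read_sequence_yaml <- function(path) {
  y <- tryCatch(yaml::read_yaml(path),
                error = function(e) stop("read_sequence: cannot parse YAML '",
                                         path, "': ", conditionMessage(e)))
  if (!is.list(y) || length(y) == 0L)
    stop("read_sequence: empty sequence in ", path)
  scalar_num <- vapply(y, function(v) is.numeric(v) && length(v) == 1L,
                       logical(1))
  y <- y[scalar_num]  # extra metadata keys ignored
  if (length(y) == 0L) stop("read_sequence: no residue frequencies in ", path)
  sequence_counts(setNames(unlist(y), names(y)))
}

#' Write residue frequencies as YAML
#'
#' Emits one `CODE: n` pair per line, sorted by code. The output is exactly
#' inverted by `read_sequence(path, format = "yaml")`, so FASTA or PDB derived
#' compositions can be edited by hand (e.g. to append glycan residues) and fed
#' back in.
#'
#' @param counts a non-empty [sequence_counts()] (or named integer vector).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
sequence_to_yaml <- function(counts, path) {
  if (!inherits(counts, "sequence_counts"))
    counts <- sequence_counts(counts, check_codes = FALSE)
  if (length(counts) == 0L) stop("sequence_to_yaml: empty counts")
  ord <- order(names(counts))
  res <- tryCatch(
    writeLines(sprintf("%s: %d", names(counts)[ord],
                       as.integer(counts)[ord]), path),
    error = function(e) stop("sequence_to_yaml: cannot write '", path, "': ",
                             conditionMessage(e)))
  invisible(path)
}
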