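# Sequence-derived macromolecular properties: unhydrated (dry) and hydrated
# volumes, molecular weight, partial specific volume, bound-water count and
# 280 nm absorption coefficient. The dry volume is the quantity that
# constrains sphere-model construction; the hydrated volume constrains the
# hydration-shell filtering cutoff.

# Hydration physics: a monolayer of bound water in a defined hydrogen-bond
# arrangement occupies 0.0245 nm^3 per molecule (bulk water: 0.0299 nm^3);
# roughly 0.3 g of water binds per gram of protein or glycoprotein.
SHELL_WATER_VOLUME_NM3 <- 0.0245
BULK_WATER_VOLUME_NM3 <- 0.0299
HYDRATION_RATIO_G_PER_G <- 0.3
WATER_MOLAR_MASS <- 18.015
AVOGADRO <- 6.02214076e23

# Standard average residue masses (g/mol): free monomer minus one water.
# Monosaccharides are the anhydro (glycosidic-linked) masses.
RESIDUE_MASSES <- c(
  ALA = 71.0788, ARG = 156.1875, ASN = 114.1038, ASP = 115.0886,
  CYS = 103.1388, GLN = 128.1307, GLU = 129.1155, GLY = 57.0519,
  HIS = 137.1411, ILE = 113.1594, LEU = 113.1594, LYS = 128.1741,
  MET = 131.1926, PHE = 147.1766, PRO = 97.1167, SER = 87.0782,
  THR = 101.1051, TRP = 186.2132, TYR = 163.1760, VAL = 99.1326,
  FUC = 146.1430, GAL = 162.1406, GLC = 162.1406, MAN = 162.1406,
  NAG = 203.1950, NGA = 203.1950, SIA = 291.2579)

.volume_cache <- new.env(parent = emptyenv())

#' Residue volume table
#'
#' Loads a named set of per-residue volumes (units: 1e-3 nm^3 per residue)
#' from the packaged YAML data file. The default `"consensus"` set holds the
#' consensus unhydrated crystal-structure volumes for the 20 amino acids and 7
#' monosaccharides; it is the only set wired into the modelling workflows, but
#' alternative sets can be added to the YAML file under their own label.
#'
#' @param set parameter-set label.
#' @param file optional path to an alternative YAML volume file
#'   (`label -> code -> value` layout).
#' @return named numeric vector of volumes (1e-3 nm^3) with attribute `"set"`.
#' @export
residue_volume_table <- function(set = "consensus", file = NULL) {
  if (is.null(file)) {
    key <- paste0("pkg:", set)
    if (!is.null(.volume_cache[[key]])) return(.volume_cache[[key]])
    file <- system.file("extdata", "residue_volumes.yml", package = "sasbead",
                        mustWork = TRUE)
  } else {
    key <- NULL
  }
  all_sets <- yaml::read_yaml(file)
  if (is.null(all_sets[[set]]))
    stop("residue_volume_table: no parameter set '", set, "' in ", file)
  v <- unlist(all_sets[[set]])
  if (any(v <= 0)) stop("residue_volume_table: non-positive volume in set '",
                        set, "'")
  out <- structure(as.numeric(v), names = toupper(names(v)), set = set)
  if (!is.null(key)) .volume_cache[[key]] <- out
  out
}

#' Volume of a single residue
#'
#' @param code 3-letter residue/monosaccharide code.
#' @param table a [residue_volume_table()].
#' @return tabulated volume in 1e-3 nm^3.
#' @export
residue_volume <- function(code, table = residue_volume_table()) {
  code <- toupper(code)
  if (!(code %in% names(table)))
    stop("residue_volume: unknown residue code '", code, "'")
  unname(table[[code]])
}

as_counts <- function(counts) {
  if (!inherits(counts, "sequence_counts"))
    counts <- sequence_counts(counts, check_codes = FALSE)
  if (sum(unclass(counts)) < 1L)
    stop("sequence has zero total residues")
  counts
}

#' Unhydrated (dry) macromolecular volume from sequence
#'
#' Sum of the unhydrated residue volumes over the composition, converted to
#' nm^3.
#'
#' @param counts a [sequence_counts()] composition.
#' @param table a [residue_volume_table()].
#' @return dry volume in nm^3.
#' @export
dry_volume <- function(counts, table = residue_volume_table()) {
  counts <- as_counts(counts)
  unknown <- setdiff(names(counts), names(table))
  if (length(unknown) > 0L)
    stop("dry_volume: unknown residue code(s): ",
         paste(unknown, collapse = ", "))
  sum(as.numeric(counts) * table[names(counts)]) * 1e-3
}

#' Bound-water molecules per macromolecule
#'
#' About `hydration_ratio` grams of water bind per gram of protein or
#' glycoprotein; the count is `ratio * M / M_water`.
#'
#' @param molecular_weight macromolecular weight, g/mol (positive).
#' @param hydration_ratio g water bound per g macromolecule (default 0.3).
#' @param water_molar_mass g/mol (default 18.015).
#' @return number of bound water molecules (dimensionless).
#' @export
bound_water_count <- function(molecular_weight,
                              hydration_ratio = HYDRATION_RATIO_G_PER_G,
                              water_molar_mass = WATER_MOLAR_MASS) {
  if (!is.numeric(molecular_weight) || molecular_weight <= 0)
    stop("bound_water_count: molecular weight must be positive")
  if (hydration_ratio < 0) stop("bound_water_count: negative hydration ratio")
  hydration_ratio * molecular_weight / water_molar_mass
}

#' Hydrated macromolecular volume
#'
#' Dry volume plus the volume of the bound-water monolayer at 0.0245 nm^3 per
#' bound water molecule (the shell value; bulk water occupies 0.0299 nm^3).
#'
#' @param dry dry volume, nm^3 (positive).
#' @param waters bound-water count (non-negative).
#' @param shell_water_volume nm^3 per bound water (default 0.0245).
#' @return hydrated volume in nm^3.
#' @export
hydrated_volume <- function(dry, waters,
                            shell_water_volume = SHELL_WATER_VOLUME_NM3) {
  if (!is.numeric(dry) || dry <= 0) stop("hydrated_volume: dry volume must ",
                                         "be positive")
  if (!is.numeric(waters) || waters < 0)
    stop("hydrated_volume: negative water count")
  dry + waters * shell_water_volume
}

#' Molecular weight from sequence
#'
#' Sum of standard average residue masses (monomer minus one water; anhydro
#' masses for monosaccharides) plus one water per polypeptide chain for the
#' termini.
#'
#' @param counts a [sequence_counts()] composition.
#' @param n_chains number of polypeptide chains (default 1).
#' @return molecular weight in g/mol.
#' @export
molecular_weight <- function(counts, n_chains = 1L) {
  counts <- as_counts(counts)
  unknown <- setdiff(names(counts), names(RESIDUE_MASSES))
  if (length(unknown) > 0L)
    stop("molecular_weight: unknown residue code(s): ",
         paste(unknown, collapse = ", "))
  sum(as.numeric(counts) * RESIDUE_MASSES[names(counts)]) +
    18.0153 * n_chains
}

#' Partial specific volume
#'
#' `v_bar = N_A * V / M` with V converted from nm^3 to cm^3; for globular
#' proteins this typically falls in the 0.70-0.76 cm^3/g band.
#'
#' @param dry_volume dry volume per molecule, nm^3 (positive).
#' @param molecular_weight g/mol (positive).
#' @return partial specific volume in cm^3/g.
#' @export
partial_specific_volume <- function(dry_volume, molecular_weight) {
  if (!is.numeric(dry_volume) || dry_volume <= 0)
    stop("partial_specific_volume: volume must be positive")
  if (!is.numeric(molecular_weight) || molecular_weight <= 0)
    stop("partial_specific_volume: molecular weight must be positive")
  AVOGADRO * dry_volume * 1e-21 / molecular_weight
}

#' 280 nm absorption coefficient (1%, 1 cm)
#'
#' Standard extinction model: 5500 (Trp), 1490 (Tyr) and 62.5 (half-cystine,
#' i.e. all cysteines assumed disulfide-bonded) M^-1 cm^-1, converted to the
#' absorbance of a 1% (10 g/l) solution in a 1 cm cell.
#'
#' @param counts a [sequence_counts()] composition.
#' @param mw optional precomputed molecular weight (g/mol).
#' @return A(280 nm, 1%, 1 cm); zero for chromophore-free sequences.
#' @export
absorption_coefficient <- function(counts, mw = molecular_weight(counts)) {
  counts <- as_counts(counts)
  n_of <- function(code) if (code %in% names(counts))
    as.numeric(counts[[code]]) else 0
  eps_molar <- 5500 * n_of("TRP") + 1490 * n_of("TYR") + 62.5 * n_of("CYS")
  10 * eps_molar / mw
}

#' Full sequence-derived property bundle
#'
#' Computes the quantities needed to constrain sphere-model construction and
#' report solution properties: dry and hydrated volumes, molecular weight,
#' partial specific volume, bound-water count and absorption coefficient.
#'
#' @param counts a [sequence_counts()] composition.
#' @param table a [residue_volume_table()].
#' @param n_chains polypeptide chains for terminal waters (default 1).
#' @param hydration_ratio g water / g macromolecule (default 0.3).
#' @param shell_water_volume nm^3 per bound water (default 0.0245).
#' @return object of class `macromol_props`.
#' @export
macromolecule_properties <- function(counts,
                                     table = residue_volume_table(),
                                     n_chains = 1L,
                                     hydration_ratio = HYDRATION_RATIO_G_PER_G,
                                     shell_water_volume =
                                       SHELL_WATER_VOLUME_NM3) {
  counts <- as_counts(counts)
  dry <- dry_volume(counts, table)
  mw <- molecular_weight(counts, n_chains)
  waters <- bound_water_count(mw, hydration_ratio)
  structure(list(
    dry_volume = dry,
    hydrated_volume = hydrated_volume(dry, waters, shell_water_volume),
    molecular_weight = mw,
    partial_specific_volume = partial_specific_volume(dry, mw),
    bound_water_count = waters,
    absorption_coefficient = absorption_coefficient(counts, mw),
    n_residues = sum(unclass(counts)),
    volume_set = attr(table, "set")), class = "macromol_props")
}

#' @export
print.macromol_props <- function(x, ...) {
  writeLines(property_report(x, mode = "project"))
  invisible(x)
}

#' Formatted property report
#'
#' Field selection follows the four output modes: `"model"` reports the
#' macromolecular volume only; `"auc"` reports molecular weight, absorption
#' coefficient and partial specific volume; `"project"` reports all four;
#' `"classic"` is a superset of `"project"` with labelled extras (bound-water
#' count, hydrated volume).
#'
#' @param props a [macromolecule_properties()] result.
#' @param mode one of `"project"`, `"model"`, `"auc"`, `"classic"`.
#' @return character vector of report lines.
#' @export
property_report <- function(props,
                            mode = c("project", "model", "auc", "classic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(props, "macromol_props"))
  l_vol <- sprintf("Macromolecular volume (unhydrated): %.4f nm^3",
                   props$dry_volume)
  l_mw <- sprintf("Molecular weight: %.1f g/mol", props$molecular_weight)
  l_abs <- sprintf("Absorption coefficient (280 nm, 1%%, 1 cm): %.3f",
                   props$absorption_coefficient)
  l_psv <- sprintf("Partial specific volume: %.4f cm^3/g",
                   props$partial_specific_volume)
  extras <- c(sprintf("Bound water molecules (0.3 g/g): %.1f",
                      props$bound_water_count),
              sprintf("Hydrated volume: %.4f nm^3", props$hydrated_volume),
              sprintf("Hydrated/dry volume ratio: %.4f",
                      props$hydrated_volume / props$dry_volume),
              sprintf("Residues: %d", props$n_residues),
              sprintf("Residue volume set: %s", props$volume_set))
  switch(mode,
         model = l_vol,
         auc = c(l_mw, l_abs, l_psv),
         project = c(l_mw, l_abs, l_psv, l_vol),
         classic = c(l_mw, l_abs, l_psv, l_vol, extras))
}
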