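# End-to-end workflows: iterate a directory of candidate PDB models through the
# X-ray branch (grid transform -> hydrate -> Debye curve) and the neutron
# branch (dry grid transform -> Debye curve -> optional smearing), compare each
# theoretical curve with every experimental curve via the R factor, and write
# the two tab-separated summary tables plus <method>/models and
# <method>/curves trees. Also the parameter-optimization workflow and the
# R-vs-Rg plot table.

read_curve_input <- function(x) {
  if (inherits(x, "scatter_curve")) return(x)
  read_experimental_curve(x)
}

curve_label <- function(x, k) {
  if (inherits(x, "scatter_curve")) {
    if (!is.na(x$source)) tools::file_path_sans_ext(basename(x$source))
    else sprintf("curve%d", k)
  } else {
    tools::file_path_sans_ext(basename(x))
  }
}

safe_num <- function(expr)
  tryCatch(suppressWarnings(expr), error = function(e) NA_real_)

# Guinier summary of one curve under the parameter windows; NA where a fit is
# not defined (e.g. no rxs blocks, or positive slope).
curve_guinier_row <- function(curve, params) {
  rg <- safe_num(guinier_rg(curve, params$rg$fitmin, params$rg$fitmax)$rg)
  rxs1 <- if (!is.null(params$rxs1))
    safe_num(guinier_rxs(curve, params$rxs1$fitmin, params$rxs1$fitmax,
                         rg_window = c(params$rg$fitmin,
                                       params$rg$fitmax))$rxs)
  else NA_real_
  rxs2 <- if (!is.null(params$rxs2))
    safe_num(guinier_rxs(curve, params$rxs2$fitmin, params$rxs2$fitmax,
                         rg_window = c(params$rg$fitmin,
                                       params$rg$fitmax))$rxs)
  else NA_real_
  c(rg = rg, rxs1 = rxs1, rxs2 = rxs2)
}

#' Analyse a directory of atomistic models against experimental curves
#'
#' For every PDB file in `pdb_dir` (processed in sorted name order, so runs
#' are deterministic) the X-ray branch grid-transforms the atoms, hydrates the
#' sphere model, computes the Debye curve and compares it with every X-ray
#' experimental curve; the neutron branch uses the dry (unhydrated) model --
#' the hydration shell is invisible to SANS in heavy water -- and applies
#' Gaussian beam smearing when `curve.smear` is set. A branch with no
#' experimental curves is skipped. Sphere models and curves are written under
#' `<output_dir>/<method>/models` and `<output_dir>/<method>/curves`
#' (`method` = `xray` or `neutron`), together with two tab-separated tables:
#' `expt_summary.tsv` (Guinier Rg/Rxs of each experimental curve) and
#' `model_comparison.tsv` (per model and branch: sphere-model Rg, curve
#' Guinier values, model volume, and R factor and scale factor eta against
#' each experimental curve). A model that yields zero spheres at the given
#' cutoff is recorded as a failed row and the run continues.
#'
#' @param params a [sas_params()] bundle.
#' @param pdb_dir directory containing at least one `.pdb` file.
#' @param xray_curves,neutron_curves experimental curves for each branch:
#'   file paths or [scatter_curve()] objects (either branch may be empty, not
#'   both).
#' @param output_dir output directory (created if missing).
#' @param baseline_fraction optional flat incoherent baseline added to the
#'   *written* neutron curves after R-factor fitting is complete (never
#'   before); 0 disables.
#' @param dry_neutron keep the neutron branch on unhydrated models (default
#'   `TRUE`); override only for methodological experiments.
#' @return invisibly, a list with `expt_summary` and `model_comparison`
#'   data.frames (also written as TSV) and `output_dir`.
#' @export
analyse_directory <- function(params, pdb_dir, xray_curves = list(),
                              neutron_curves = list(), output_dir,
                              baseline_fraction = 0, dry_neutron = TRUE) {
  stopifnot(inherits(params, "sas_params"))
  pdbs <- sort(list.files(pdb_dir, pattern = "\\.pdb$", ignore.case = TRUE,
                          full.names = TRUE))
  if (length(pdbs) == 0L)
    stop("analyse_directory: no PDB files in ", pdb_dir)
  if (length(xray_curves) == 0L && length(neutron_curves) == 0L)
    stop("analyse_directory: no experimental curves supplied to either ",
         "branch")
  branches <- list()
  if (length(xray_curves) > 0L)
    branches$xray <- lapply(xray_curves, read_curve_input)
  if (length(neutron_curves) > 0L)
    branches$neutron <- lapply(neutron_curves, read_curve_input)
  for (b in names(branches))
    names(branches[[b]]) <- vapply(seq_along(branches[[b]]), function(k)
      curve_label(if (b == "xray") xray_curves[[k]] else neutron_curves[[k]],
                  k), character(1))
  # one rfactor/eta column pair per experimental curve, shared by all rows;
  # a label used in both branches gets a branch suffix to stay unique
  all_labels <- unlist(lapply(names(branches), function(b)
    setNames(names(branches[[b]]), rep(b, length(branches[[b]])))))
  col_label <- function(b, nm)
    if (sum(all_labels == nm) > 1L) paste(nm, b, sep = "_") else nm
  rfac_cols <- unlist(lapply(names(branches), function(b)
    vapply(names(branches[[b]]), function(nm) col_label(b, nm),
           character(1))))

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (b in names(branches)) {
    dir.create(file.path(output_dir, b, "models"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(output_dir, b, "curves"), recursive = TRUE,
               showWarnings = FALSE)
  }

  # first output: Guinier analyses of the experimental curves
  expt_rows <- list()
  for (b in names(branches)) {
    for (nm in names(branches[[b]])) {
      g <- curve_guinier_row(branches[[b]][[nm]], params)
      expt_rows[[paste(b, nm)]] <-
        data.frame(file = nm, branch = b, rg_nm = g[["rg"]],
                   rxs1_nm = g[["rxs1"]], rxs2_nm = g[["rxs2"]],
                   stringsAsFactors = FALSE)
    }
  }
  expt_summary <- do.call(rbind, expt_rows)
  rownames(expt_summary) <- NULL

  qg <- q_grid(params)
  model_rows <- list()
  for (path in pdbs) {
    model_name <- tools::file_path_sans_ext(basename(path))
    atoms <- read_pdb_atoms(path)
    dry <- suppressWarnings(grid_transform(atoms, params$sphere$boxside,
                                           cutoff = params$sphere$cutoff))
    for (b in names(branches)) {
      row <- data.frame(model = model_name, branch = b, status = "ok",
                        n_spheres = NA_integer_, volume_nm3 = NA_real_,
                        rg_model_nm = NA_real_, rg_curve_nm = NA_real_,
                        rxs1_curve_nm = NA_real_, rxs2_curve_nm = NA_real_,
                        stringsAsFactors = FALSE)
      for (cl in rfac_cols) {
        row[[paste0("rfactor_", cl)]] <- NA_real_
        row[[paste0("eta_", cl)]] <- NA_real_
      }
      if (nrow(dry$centres) == 0L) {
        row$status <- "failed: no spheres at cutoff"
        model_rows[[paste(model_name, b)]] <- row
        next
      }
      model <- if (b == "xray")
        hydrate_sphere_model(dry, params$hydrate$cutoff)
      else if (dry_neutron) dry
      else hydrate_sphere_model(dry, params$hydrate$cutoff)
      hist <- distance_histogram(model, mode = "modern",
                                 nbins = params$curve$radbins)
      theo <- debye_curve(hist, qg)
      if (b == "neutron" && isTRUE(params$curve$smear))
        theo <- smear_curve(theo, params$curve$wavelength,
                            params$curve$spread, params$curve$divergence)
      g <- curve_guinier_row(theo, params)
      row$n_spheres <- nrow(model$centres)
      row$volume_nm3 <- sphere_model_volume(model)
      row$rg_model_nm <- sphere_rg(model)
      row$rg_curve_nm <- g[["rg"]]
      row$rxs1_curve_nm <- g[["rxs1"]]
      row$rxs2_curve_nm <- g[["rxs2"]]
      for (nm in names(branches[[b]])) {
        rf <- tryCatch(r_factor(theo, branches[[b]][[nm]],
                                params$rfac$qmin, params$rfac$qmax),
                       error = function(e) NULL)
        if (!is.null(rf)) {
          cl <- col_label(b, nm)
          row[[paste0("rfactor_", cl)]] <- rf$r_factor
          row[[paste0("eta_", cl)]] <- rf$eta
        }
      }
      write_sphere_model_pdb(model, file.path(output_dir, b, "models",
                                              paste0(model_name, ".pdb")))
      # incoherent baseline goes on the written curve only after fitting
      out_curve <- if (b == "neutron" && baseline_fraction > 0)
        apply_incoherent_baseline(theo, baseline_fraction)
      else theo
      write_curve(out_curve, file.path(output_dir, b, "curves",
                                       paste0(model_name, ".dat")))
      model_rows[[paste(model_name, b)]] <- row
    }
  }
  # fixed row order: model name, then branch
  model_comparison <- do.call(rbind, model_rows[order(names(model_rows))])
  rownames(model_comparison) <- NULL

  write.table(expt_summary, file.path(output_dir, "expt_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(model_comparison,
              file.path(output_dir, "model_comparison.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_manifest(params, output_dir, baseline_fraction, dry_neutron,
                     names(branches))
  invisible(list(expt_summary = expt_summary,
                 model_comparison = model_comparison,
                 output_dir = output_dir))
}

write_run_manifest <- function(params, output_dir, baseline_fraction,
                               dry_neutron, branches) {
  lines <- c(
    "run manifest",
    sprintf("branches: %s", paste(branches, collapse = ", ")),
    sprintf("sphere.boxside: %g nm", params$sphere$boxside),
    sprintf("sphere.cutoff: %d (inclusive, count >= cutoff)",
            params$sphere$cutoff),
    sprintf("hydrate.cutoff: %d", params$hydrate$cutoff),
    sprintf("curve: qmax %g nm^-1, npoints %d, radbins %d (modern binning)",
            params$curve$qmax, params$curve$npoints, params$curve$radbins),
    sprintf("smear: %s%s", params$curve$smear,
            if (isTRUE(params$curve$smear))
              sprintf(" (wavelength %g nm, spread %g, divergence %g rad)",
                      params$curve$wavelength, params$curve$spread,
                      params$curve$divergence) else ""),
    sprintf("incoherent baseline fraction: %g (applied after fitting)",
            baseline_fraction),
    sprintf("neutron branch model: %s",
            if (dry_neutron) "dry (unhydrated)" else "hydrated (override)"),
    sprintf("rfactor window: [%g, %g] nm^-1", params$rfac$qmin,
            params$rfac$qmax))
  writeLines(lines, file.path(output_dir, "run_manifest.txt"))
}

#' Optimize sphere-model parameters against sequence-derived volumes
#'
#' Computes the target dry and hydrated volumes from the sequence (taken from
#' the structure's own ATOM/HETATM records unless a separate FASTA/YAML
#' sequence file is supplied, e.g. when residues are missing from the model),
#' finds the grid box side that best reproduces the dry volume, then hydrates
#' the resulting model at each candidate cutoff and reports the volume table
#' from which the user picks the hydration cutoff. The chosen values are meant
#' to be copied into the YAML parameter file. If the supplied sequence differs
#' from the structure's residue count by more than `mismatch_warn`, a warning
#' advises completing the input model (extra volume cannot be placed
#' correctly by the optimizer alone).
#'
#' @param params a [sas_params()] bundle (supplies the grid cutoff).
#' @param pdb_path PDB structure with no overlapping atoms.
#' @param sequence_path optional FASTA (`.fa`/`.fas`/`.fasta`) or YAML
#'   (`.yml`/`.yaml`) sequence file.
#' @param output_path optional path for the tab-separated report.
#' @param cutoff_candidates hydration cutoffs to tabulate (default `1:14`).
#' @param mismatch_warn residue-count mismatch fraction that triggers the
#'   warning (default 0.05).
#' @return list with `boxside`, `side_rel_error`, targets, `best_cutoff`,
#'   `cutoff_table` and the `properties` bundle.
#' @export
optimize_params_workflow <- function(params, pdb_path, sequence_path = NULL,
                                     output_path = NULL,
                                     cutoff_candidates = 1:14,
                                     mismatch_warn = 0.05) {
  stopifnot(inherits(params, "sas_params"))
  atoms <- read_pdb_atoms(pdb_path)
  counts_struct <- read_sequence(pdb_path, "pdb")
  counts <- counts_struct
  if (!is.null(sequence_path)) {
    fmt <- switch(tolower(tools::file_ext(sequence_path)),
                  fa = , fas = , fasta = "fasta",
                  yml = , yaml = "yaml",
                  pdb = "pdb",
                  stop("optimize_params_workflow: cannot infer sequence ",
                       "format from extension of ", sequence_path))
    counts <- read_sequence(sequence_path, fmt)
    n_seq <- sum(unclass(counts))
    n_struct <- sum(unclass(counts_struct))
    if (abs(n_seq - n_struct) / max(n_seq, n_struct) > mismatch_warn)
      warning(sprintf(paste0("optimize_params_workflow: sequence (%d ",
                             "residues) and structure (%d residues) differ ",
                             "by more than %.0f%%; consider completing the ",
                             "input model so the extra volume is placed ",
                             "correctly"),
                      n_seq, n_struct, 100 * mismatch_warn))
  }
  props <- macromolecule_properties(counts)
  opt_side <- optimize_box_side(atoms, props$dry_volume,
                                cutoff = params$sphere$cutoff)
  dry <- grid_transform(atoms, opt_side$boxside,
                        cutoff = params$sphere$cutoff)
  opt_cut <- optimize_hydration_cutoff(dry, props$hydrated_volume,
                                       cutoff_candidates)
  if (!is.null(output_path)) {
    hdr <- c(sprintf("# target dry volume: %.4f nm^3", props$dry_volume),
             sprintf("# target hydrated volume: %.4f nm^3",
                     props$hydrated_volume),
             sprintf("# optimized boxside: %.4f nm (achieved dry volume %.4f",
                     opt_side$boxside, opt_side$achieved_volume),
             sprintf("#   nm^3, rel. error %.2f%%)",
                     100 * opt_side$rel_error),
             sprintf("# best hydration cutoff: %d", opt_cut$best_cutoff),
             "cutoff\tvolume_nm3\tn_spheres")
    body <- sprintf("%d\t%.6f\t%d", opt_cut$table$cutoff,
                    opt_cut$table$volume, opt_cut$table$n_spheres)
    writeLines(c(hdr, body), output_path)
  }
  list(boxside = opt_side$boxside,
       side_rel_error = opt_side$rel_error,
       achieved_dry_volume = opt_side$achieved_volume,
       target_dry_volume = props$dry_volume,
       target_hydrated_volume = props$hydrated_volume,
       best_cutoff = opt_cut$best_cutoff,
       cutoff_table = opt_cut$table,
       properties = props)
}

#' R factor versus Rg table for fit-progression plots
#'
#' Reshapes the model-comparison table into one (Rg, R factor) pair per model
#' and experimental curve, sorted by Rg, with the best-fitting model (minimum
#' R factor) flagged per curve. Plots of R versus Rg show whether a modelling
#' search is converging toward the experimental structure.
#'
#' @param records the `model_comparison` data.frame from
#'   [analyse_directory()] (at least one row).
#' @return data.frame with columns `expt`, `model`, `branch`, `rg_nm`,
#'   `r_factor_pct`, `eta`, `best`.
#' @export
r_vs_rg_table <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("r_vs_rg_table: empty input")
  rcols <- grep("^rfactor_", names(records), value = TRUE)
  if (length(rcols) == 0L)
    stop("r_vs_rg_table: no rfactor_* columns in input")
  out <- list()
  for (rc in rcols) {
    nm <- sub("^rfactor_", "", rc)
    ec <- paste0("eta_", nm)
    ok <- !is.na(records[[rc]])
    if (!any(ok)) next
    df <- data.frame(expt = nm,
                     model = records$model[ok],
                     branch = records$branch[ok],
                     rg_nm = records$rg_curve_nm[ok],
                     r_factor_pct = records[[rc]][ok],
                     eta = records[[ec]][ok],
                     stringsAsFactors = FALSE)
    df <- df[order(df$rg_nm), , drop = FALSE]
    df$best <- df$r_factor_pct == min(df$r_factor_pct)
    out[[nm]] <- df
  }
  if (length(out) == 0L)
    stop("r_vs_rg_table: no usable R-factor values")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
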