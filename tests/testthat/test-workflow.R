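# End-to-end directory analysis: branch behaviour, determinism, model
# discrimination, failure handling; plus the parameter-optimization workflow
# and the R-vs-Rg plot table.

# Shared scenario: two ball models of different size; the "experimental"
# X-ray curve is generated from model A through the identical processing
# chain, so A must self-fit with R ~ 0 and beat B.
setup_workflow_dir <- function(root, params) {
  pdb_dir <- file.path(root, "pdbs")
  dir.create(pdb_dir, recursive = TRUE, showWarnings = FALSE)
  a <- make_atom_cloud("ball", n = 2500, radius = 1.5, seed = 1)
  b <- make_atom_cloud("ball", n = 2500, radius = 2.5, seed = 2)
  write_atom_pdb(a, file.path(pdb_dir, "model_a.pdb"))
  write_atom_pdb(b, file.path(pdb_dir, "model_b.pdb"))
  dry_a <- grid_transform(read_pdb_atoms(file.path(pdb_dir, "model_a.pdb")),
                          params$sphere$boxside, params$sphere$cutoff)
  wet_a <- hydrate_sphere_model(dry_a, params$hydrate$cutoff)
  theo_a <- debye_curve(distance_histogram(wet_a,
                                           nbins = params$curve$radbins),
                        q_grid(params))
  xray <- file.path(root, "xray_from_a.dat")
  write_curve(make_experimental_curve(theo_a, noise_fraction = 0), xray)
  neut_a <- debye_curve(distance_histogram(dry_a,
                                           nbins = params$curve$radbins),
                        q_grid(params))
  neutron <- file.path(root, "neutron_from_a.dat")
  write_curve(make_experimental_curve(neut_a, noise_fraction = 0), neutron)
  list(pdb_dir = pdb_dir, xray = xray, neutron = neutron)
}

test_that("analyse_directory discriminates models and self-fits at R = 0", {
  root <- withr::local_tempdir()
  params <- make_test_params()
  sc <- setup_workflow_dir(root, params)
  res <- analyse_directory(params, sc$pdb_dir, xray_curves = list(sc$xray),
                           neutron_curves = list(sc$neutron),
                           output_dir = file.path(root, "out"))
  mc <- res$model_comparison
  expect_equal(nrow(mc), 4L)          # 2 models x 2 branches
  xr <- mc[mc$branch == "xray", ]
  ra <- xr$rfactor_xray_from_a[xr$model == "model_a"]
  rb <- xr$rfactor_xray_from_a[xr$model == "model_b"]
  expect_lt(ra, 1e-6)                  # self comparison
  expect_equal(xr$eta_xray_from_a[xr$model == "model_a"], 1,
               tolerance = 1e-6)
  expect_lt(ra, rb)                    # discrimination
  nr <- mc[mc$branch == "neutron", ]
  expect_lt(nr$rfactor_neutron_from_a[nr$model == "model_a"], 1e-6)

  # first output: one row per experimental file with Guinier values
  expect_equal(sort(res$expt_summary$file),
               c("neutron_from_a", "xray_from_a"))
  expect_true(all(is.finite(res$expt_summary$rg_nm)))

  # file tree: models and curves per branch
  for (b in c("xray", "neutron")) {
    expect_true(file.exists(file.path(root, "out", b, "models",
                                      "model_a.pdb")))
    expect_true(file.exists(file.path(root, "out", b, "curves",
                                      "model_b.dat")))
  }
  expect_true(file.exists(file.path(root, "out", "run_manifest.txt")))
})

test_that("two identical runs produce byte-identical summary tables", {
  root <- withr::local_tempdir()
  params <- make_test_params()
  sc <- setup_workflow_dir(root, params)
  analyse_directory(params, sc$pdb_dir, list(sc$xray), list(sc$neutron),
                    file.path(root, "out1"))
  analyse_directory(params, sc$pdb_dir, list(sc$xray), list(sc$neutron),
                    file.path(root, "out2"))
  for (f in c("expt_summary.tsv", "model_comparison.tsv"))
    expect_identical(readLines(file.path(root, "out1", f)),
                     readLines(file.path(root, "out2", f)))
})

test_that("x-ray results are unchanged by adding neutron curves", {
  root <- withr::local_tempdir()
  params <- make_test_params()
  sc <- setup_workflow_dir(root, params)
  both <- analyse_directory(params, sc$pdb_dir, list(sc$xray),
                            list(sc$neutron), file.path(root, "both"))
  xonly <- analyse_directory(params, sc$pdb_dir, list(sc$xray), list(),
                             file.path(root, "xonly"))
  cols <- c("model", "n_spheres", "volume_nm3", "rg_model_nm", "rg_curve_nm",
            "rfactor_xray_from_a", "eta_xray_from_a")
  expect_equal(both$model_comparison[both$model_comparison$branch == "xray",
                                     cols],
               xonly$model_comparison[, cols], ignore_attr = TRUE)
})

test_that("unsmeared neutron branch passes the dry Debye curve through", {
  root <- withr::local_tempdir()
  params <- make_test_params()   # smear = FALSE
  sc <- setup_workflow_dir(root, params)
  res <- analyse_directory(params, sc$pdb_dir, list(), list(sc$neutron),
                           file.path(root, "out"))
  written <- read_experimental_curve(file.path(root, "out", "neutron",
                                               "curves", "model_a.dat"))
  dry_a <- grid_transform(read_pdb_atoms(file.path(sc$pdb_dir,
                                                   "model_a.pdb")),
                          params$sphere$boxside, params$sphere$cutoff)
  direct <- debye_curve(distance_histogram(dry_a,
                                           nbins = params$curve$radbins),
                        q_grid(params))
  expect_equal(written$i, direct$i, tolerance = 1e-7)
})

test_that("smeared neutron branch differs from the dry curve", {
  root <- withr::local_tempdir()
  params <- make_test_params(curve = list(smear = TRUE))
  sc <- setup_workflow_dir(root, params)
  res <- analyse_directory(params, sc$pdb_dir, list(), list(sc$neutron),
                           file.path(root, "out"))
  written <- read_experimental_curve(file.path(root, "out", "neutron",
                                               "curves", "model_a.dat"))
  dry_a <- grid_transform(read_pdb_atoms(file.path(sc$pdb_dir,
                                                   "model_a.pdb")),
                          params$sphere$boxside, params$sphere$cutoff)
  direct <- debye_curve(distance_histogram(dry_a,
                                           nbins = params$curve$radbins),
                        q_grid(params))
  expect_gt(max(abs(written$i - direct$i)), 1e-6)
})

test_that("a model with zero spheres is recorded as failed, run continues", {
  root <- withr::local_tempdir()
  pdb_dir <- file.path(root, "pdbs")
  dir.create(pdb_dir)
  write_atom_pdb(make_atom_cloud("ball", n = 1200, radius = 1.2, seed = 4),
                 file.path(pdb_dir, "good.pdb"))
  # 3 atoms cannot reach an occupancy cutoff of 20
  write_atom_pdb(make_atom_cloud("ball", n = 3, radius = 1.2, seed = 5),
                 file.path(pdb_dir, "tiny.pdb"))
  params <- make_test_params(sphere = list(cutoff = 20L))
  cur <- file.path(root, "x.dat")
  dry <- grid_transform(read_pdb_atoms(file.path(pdb_dir, "good.pdb")),
                        params$sphere$boxside, params$sphere$cutoff)
  wet <- hydrate_sphere_model(dry, params$hydrate$cutoff)
  write_curve(debye_curve(distance_histogram(wet,
                                             nbins = params$curve$radbins),
                          q_grid(params)), cur)
  res <- analyse_directory(params, pdb_dir, list(cur), list(),
                           file.path(root, "out"))
  mc <- res$model_comparison
  expect_equal(nrow(mc), 2L)
  expect_match(mc$status[mc$model == "tiny"], "failed")
  expect_equal(mc$status[mc$model == "good"], "ok")
  expect_true(is.finite(mc$rfactor_x[mc$model == "good"]))
})

test_that("optimize_params_workflow recovers targets and warns on mismatch", {
  root <- withr::local_tempdir()
  # the cloud is oversampled for stable gridding, so group atoms into
  # residues at the rate that makes the sequence-derived dry volume equal
  # the geometric envelope volume (self-consistent structure + sequence)
  ball <- make_atom_cloud("ball", n = 13000, radius = 2, seed = 11)
  apr <- round(13000 * residue_volume("ALA") * 1e-3 /
                 attr(ball, "true_volume"))
  pdb <- file.path(root, "ball.pdb")
  write_atom_pdb(ball, pdb, atoms_per_residue = apr)
  params <- make_test_params()
  res <- optimize_params_workflow(params, pdb,
                                  output_path = file.path(root, "opt.dat"))
  expect_lt(res$side_rel_error, 0.02)
  expect_equal(nrow(res$cutoff_table), 14L)
  report <- readLines(file.path(root, "opt.dat"))
  expect_equal(sum(!startsWith(report, "#")) - 1L, 14L)  # header + rows

  # sequence larger than the structure by >5% -> warning, still proceeds
  yml <- file.path(root, "seq.yml")
  n_res <- ceiling(13000 / apr)
  sequence_to_yaml(c(ALA = ceiling(n_res * 1.15)), yml)
  expect_warning(
    res2 <- optimize_params_workflow(params, pdb, sequence_path = yml),
    "differ by more than")
  expect_true(is.finite(res2$boxside))
})

test_that("r_vs_rg_table reshapes, sorts and flags the best model", {
  rec <- data.frame(model = c("m1", "m2", "m3"), branch = "xray",
                    rg_curve_nm = c(3.2, 2.1, 2.7),
                    rfactor_x = c(9.5, 2.2, 5.0),
                    eta_x = c(1, 1, 1), stringsAsFactors = FALSE)
  tab <- r_vs_rg_table(rec)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$rg_nm, sort(rec$rg_curve_nm))
  expect_equal(tab$model[tab$best], "m2")
  expect_error(r_vs_rg_table(rec[0, ]), "empty")
})
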