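# Independent oracles and fixture builders shared across the test files.
# The oracles are deliberately naive (all-pairs sums, key-string box counts)
# so they share no code with the implementation they check.

# Exact Debye sum over all sphere pairs (including self terms), no histogram.
bf_debye <- function(centres, r, q) {
  D <- as.matrix(dist(centres))
  n <- nrow(centres)
  vapply(q, function(qq) {
    x <- qq * D
    sinc <- ifelse(x == 0, 1, sin(x) / x)
    ff <- (3 * (sin(qq * r) - qq * r * cos(qq * r)) / (qq * r)^3)^2
    ff * sum(sinc) / n^2
  }, numeric(1))
}

# Brute-force grid occupancy: string keys per box, threshold count >= cutoff.
bf_grid_centres <- function(pts, side, cutoff) {
  org <- c(min(pts[, 1]), min(pts[, 2]), min(pts[, 3]))
  ijk <- floor(sweep(pts, 2, org) / side + 1e-9)
  key <- apply(ijk, 1, paste, collapse = ",")
  tab <- table(key)
  keep <- names(tab)[tab >= cutoff]
  if (length(keep) == 0) return(matrix(numeric(0), ncol = 3))
  ijk_keep <- do.call(rbind, lapply(strsplit(keep, ","), as.numeric))
  sweep((ijk_keep + 0.5) * side, 2, org, "+")
}

# Nearest theoretical Q per experimental Q, ties toward lower Q (O(n*m) scan).
bf_nearest <- function(qe, qt) {
  vapply(qe, function(q) {
    d <- abs(qt - q)
    which(d == min(d))[1]
  }, integer(1))
}

# Dense sphere-filled ball: lattice sphere centres within radius R.
ball_sphere_model <- function(R, s) {
  ax <- seq(-R, R, by = s)
  g <- as.matrix(expand.grid(ax, ax, ax))
  sphere_model(g[rowSums(g^2) <= R^2, ], s)
}

# Random sphere model on a continuous cloud (seeded).
random_sphere_model <- function(n, seed, extent = 4, boxside = 0.5) {
  withr::with_seed(seed,
    sphere_model(matrix(runif(3 * n, 0, extent), ncol = 3), boxside))
}

# Full parameter bundle for workflow tests, overridable per field.
make_test_params <- function(...) {
  base <- list(
    wide = list(qmin = 0.05, qmax = 1.6),
    rg = list(qmin = 0.0, qmax = 0.5, fitmin = 0.1, fitmax = 0.4),
    rxs1 = list(qmin = 0.3, qmax = 0.9, fitmin = 0.45, fitmax = 0.7),
    rxs2 = list(qmin = 0.6, qmax = 1.4, fitmin = 0.75, fitmax = 1.1),
    sphere = list(cutoff = 1L, boxside = 0.5),
    hydrate = list(positions = 26L, cutoff = 5L),
    curve = list(qmax = 1.6, npoints = 80L, radbins = 300L, smear = FALSE,
                 wavelength = 0.6, spread = 0.1, divergence = 0.016),
    rfac = list(qmin = 0.1, qmax = 1.6))
  mods <- list(...)
  for (blk in names(mods)) base[[blk]] <- modifyList(base[[blk]], mods[[blk]])
  sas_params(base)
}

# Minimal hand-written PDB text fixture (independent of the package writer).
write_raw_pdb <- function(path, resids, xyz_ang, types = NULL,
                          resno = seq_along(resids), chain = "A") {
  if (is.null(types)) types <- rep("ATOM  ", length(resids))
  lines <- sprintf(
    "%-6s%5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    types, seq_along(resids), resids, chain, resno,
    xyz_ang[, 1], xyz_ang[, 2], xyz_ang[, 3])
  writeLines(c(lines, "END"), path)
  path
}
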