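# Seeded synthetic inputs with known analytic geometry, so every modelling
# stage can be exercised against closed-form truth: uniform balls
# (Rg = sqrt(3/5) R), rods (Rg^2 = L^2/12 + a^2/2), dumbbells (parallel-axis
# theorem) and regular lattices. Atom clouds are sampled at protein-like
# heavy-atom density and written to PDB with 8 atoms per residue, so the
# sequence-derived dry volume of a ball fixture approximates its geometric
# volume.

#' Generate a synthetic atom cloud with known geometry
#'
#' Uniformly samples points inside the named shape with a fixed seed. The
#' analytic radius of gyration and envelope volume are attached as attributes
#' (`"true_rg"`, `"true_volume"`) for recovery tests:
#' ball `Rg = sqrt(3/5) R`, rod `Rg^2 = L^2/12 + a^2/2`, dumbbell of two balls
#' at separation D `Rg^2 = (3/5) R^2 + (D/2)^2`. The `"lattice"` shape is a
#' deterministic cubic grid (no randomness) whose exact point Rg is recorded.
#'
#' @param shape one of `"ball"`, `"rod"`, `"dumbbell"`, `"lattice"`.
#' @param n number of atoms (`>= 1`).
#' @param radius ball (or dumbbell lobe, or rod cross-section) radius, nm.
#' @param length rod length, nm.
#' @param separation dumbbell centre-to-centre distance, nm.
#' @param spacing lattice spacing, nm.
#' @param seed integer RNG seed; the same seed always reproduces the same
#'   coordinates.
#' @return an [atom_model()] (residues `ALA`) with attributes `true_rg`
#'   (nm), `true_volume` (nm^3) and `fixture_spec`.
#' @export
make_atom_cloud <- function(shape = c("ball", "rod", "dumbbell", "lattice"),
                            n = 5000L, radius = 2, length = 6,
                            separation = 6, spacing = 0.5, seed = 1L) {
  shape <- match.arg(shape)
  n <- as.integer(n)
  if (n < 1L) stop("make_atom_cloud: need at least 1 point")
  sample_ball <- function(m, R) {
    rr <- R * runif(m)^(1 / 3)
    dir <- matrix(rnorm(3 * m), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    dir * rr
  }
  if (shape == "lattice") {
    k <- ceiling(n^(1 / 3))
    g <- as.matrix(expand.grid(seq_len(k), seq_len(k), seq_len(k)))[seq_len(n),
                                                                    ,
                                                                    drop =
                                                                      FALSE]
    pts <- (g - 1) * spacing
    ctr <- colMeans(pts)
    true_rg <- sqrt(mean(rowSums(sweep(pts, 2, ctr)^2)))
    true_vol <- n * spacing^3
  } else {
    pts <- withr::with_seed(as.integer(seed), switch(
      shape,
      ball = sample_ball(n, radius),
      rod = {
        rho <- radius * sqrt(runif(n))
        phi <- runif(n, 0, 2 * pi)
        cbind(rho * cos(phi), rho * sin(phi),
              runif(n, -length / 2, length / 2))
      },
      dumbbell = {
        n1 <- n %/% 2L
        b <- sample_ball(n, radius)
        shift <- rep(c(-separation / 2, separation / 2),
                     c(n1, n - n1))
        b[, 1] <- b[, 1] + shift
        b
      }))
    true_rg <- switch(shape,
                      ball = sqrt(3 / 5) * radius,
                      rod = sqrt(length^2 / 12 + radius^2 / 2),
                      dumbbell = sqrt(0.6 * radius^2 + (separation / 2)^2))
    true_vol <- switch(shape,
                       ball = (4 / 3) * pi * radius^3,
                       rod = pi * radius^2 * length,
                       dumbbell = 2 * (4 / 3) * pi * radius^3)
  }
  out <- atom_model(data.frame(resid = "ALA", x = pts[, 1], y = pts[, 2],
                               z = pts[, 3], stringsAsFactors = FALSE),
                    source = sprintf("fixture:%s(n=%d,seed=%d)", shape, n,
                                     as.integer(seed)))
  attr(out, "true_rg") <- true_rg
  attr(out, "true_volume") <- true_vol
  attr(out, "fixture_spec") <- list(shape = shape, n = n, radius = radius,
                                    length = length, separation = separation,
                                    spacing = spacing, seed = as.integer(seed))
  out
}

#' Synthetic "experimental" curve with multiplicative noise
#'
#' Takes a (typically theoretical) curve and applies multiplicative Gaussian
#' noise of fractional standard deviation `noise_fraction`; zero noise returns
#' the curve unchanged except for its provenance labels. Seeded and
#' reproducible.
#'
#' @param curve a [scatter_curve()].
#' @param noise_fraction fractional noise sd (`>= 0`).
#' @param seed integer RNG seed.
#' @return an experimental-kind [scatter_curve()].
#' @export
make_experimental_curve <- function(curve, noise_fraction = 0, seed = 1L) {
  stopifnot(inherits(curve, "scatter_curve"))
  if (!is.numeric(noise_fraction) || noise_fraction < 0)
    stop("make_experimental_curve: negative noise fraction")
  i <- if (noise_fraction == 0) curve$i
       else withr::with_seed(as.integer(seed),
                             curve$i * (1 + rnorm(length(curve$i), 0,
                                                  noise_fraction)))
  scatter_curve(curve$q, i, kind = "experimental", smeared = curve$smeared,
                source = sprintf("synthetic(noise=%g,seed=%d)",
                                 noise_fraction, as.integer(seed)))
}
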