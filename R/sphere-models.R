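# Grid transformation of atom clouds into bead models, the four-step
# hydration-monolayer algorithm, sphere-model volume/Rg, and the cube-side /
# hydration-cutoff optimizers that tie model volumes to the sequence-derived
# targets.

#' Grid transformation: points to sphere model
#'
#' Builds a 3-D histogram of the input points on a regular grid of cubic boxes
#' of side `boxside`, anchored by default at the per-axis minimum coordinate.
#' Every box whose occupancy reaches the cutoff contributes one sphere at the
#' box centre with radius `boxside / 2`.
#'
#' The threshold is inclusive by default (`count >= cutoff`); `strict = TRUE`
#' switches to a strictly-greater-than rule (`count > cutoff`).
#'
#' @param x points: an [atom_model()], [sphere_model()] (its centres), n x 3
#'   matrix or data.frame with x/y/z columns; coordinates in nm.
#' @param boxside grid box side in nm (positive).
#' @param cutoff occupancy threshold (integer `>= 1`); typical atomistic
#'   gridding uses 4.
#' @param strict use `count > cutoff` instead of `count >= cutoff`.
#' @param origin optional fixed grid origin `c(x, y, z)` (nm) for
#'   reproducible grids across related models; must not exceed the point
#'   minimum on any axis.
#' @param warn_empty warn (default) when no box reaches the cutoff; the empty
#'   model is returned either way so callers can record the failure.
#' @return a [sphere_model()]; attribute `"box_counts"` holds the occupancy of
#'   each retained box (same order as the centres, sorted by grid index).
#' @export
grid_transform <- function(x, boxside, cutoff = 4L, strict = FALSE,
                           origin = NULL, warn_empty = TRUE) {
  pts <- as_point_matrix(x)
  if (!is.numeric(boxside) || length(boxside) != 1L || boxside <= 0)
    stop("grid_transform: boxside must be a positive scalar")
  cutoff <- as.integer(cutoff)
  if (is.na(cutoff) || cutoff < 1L) stop("grid_transform: cutoff must be >= 1")
  if (is.null(origin)) {
    origin <- c(min(pts[, 1]), min(pts[, 2]), min(pts[, 3]))
  } else {
    stopifnot(is.numeric(origin), length(origin) == 3L)
    if (any(origin > apply(pts, 2, min) + 1e-12))
      stop("grid_transform: origin must not exceed the point minimum")
  }
  # box index per axis; the small epsilon keeps lattice-aligned points (e.g.
  # sphere centres during hydration regridding) from straddling a boundary
  idx <- floor(sweep(pts, 2, origin) / boxside + 1e-9)
  idx[idx < 0] <- 0
  ext <- c(max(idx[, 1]), max(idx[, 2]), max(idx[, 3])) + 1
  lin <- idx[, 1] + ext[1] * (idx[, 2] + ext[2] * idx[, 3])
  cnt <- table(lin)
  keep <- if (strict) cnt > cutoff else cnt >= cutoff
  key <- sort(as.numeric(names(cnt)[keep]))
  if (length(key) == 0L) {
    if (warn_empty)
      warning("grid_transform: no grid box reached the occupancy cutoff (",
              cutoff, "); returning an empty model")
    out <- sphere_model(matrix(numeric(0), ncol = 3), boxside)
    attr(out, "box_counts") <- integer(0)
    return(out)
  }
  k3 <- key %/% (ext[1] * ext[2])
  k2 <- (key %% (ext[1] * ext[2])) %/% ext[1]
  k1 <- key %% ext[1]
  centres <- cbind(origin[1] + (k1 + 0.5) * boxside,
                   origin[2] + (k2 + 0.5) * boxside,
                   origin[3] + (k3 + 0.5) * boxside)
  out <- sphere_model(centres, boxside)
  attr(out, "box_counts") <-
    as.integer(cnt[match(as.character(key), names(cnt))])
  out
}

#' Sphere-model volume
#'
#' The model volume is the sum over the component spheres. Two conventions are
#' supported: the default `"box"` convention counts each sphere as its full
#' grid box (`n * boxside^3`, self-consistent with grid occupancy); the
#' literal `"sphere"` convention sums inscribed-sphere volumes
#' (`n * (4/3) * pi * (boxside/2)^3`).
#'
#' @param model a non-empty [sphere_model()].
#' @param convention `"box"` (default) or `"sphere"`.
#' @return volume in nm^3.
#' @export
sphere_model_volume <- function(model, convention = c("box", "sphere")) {
  stopifnot(inherits(model, "sphere_model"))
  convention <- match.arg(convention)
  n <- nrow(model$centres)
  if (n < 1L) stop("sphere_model_volume: empty model")
  switch(convention,
         box = n * model$boxside^3,
         sphere = n * (4 / 3) * pi * model$radius^3)
}

#' Candidate hydration positions around one sphere
#'
#' The 26 positions lie on the corners, edge mid-points and face centres of a
#' cube of side four times the sphere radius centred on the sphere: the offsets
#' `{-2r, 0, +2r}^3` excluding the null offset (8 corners + 12 edge mid-points
#' + 6 face centres).
#'
#' @param centre numeric length-3 sphere centre (nm).
#' @param radius sphere radius (nm, positive).
#' @return 26 x 3 matrix of candidate hydration-sphere centres.
#' @export
hydration_positions <- function(centre, radius) {
  stopifnot(is.numeric(centre), length(centre) == 3L)
  if (!is.numeric(radius) || radius <= 0)
    stop("hydration_positions: radius must be positive")
  s <- 2 * radius
  off <- as.matrix(expand.grid(x = c(-s, 0, s), y = c(-s, 0, s),
                               z = c(-s, 0, s)))
  off <- off[rowSums(off != 0) > 0L, , drop = FALSE]
  dimnames(off) <- NULL
  sweep(off, 2, centre, "+")
}

# Filter-grid origin aligned so existing sphere centres sit at box centres:
# the centres already lie on a lattice of pitch boxside, so anchoring at
# (min centre - boxside/2) regrids without displacing them.
aligned_origin <- function(centres, boxside) {
  c(min(centres[, 1]), min(centres[, 2]), min(centres[, 3])) - boxside / 2
}

#' Hydrate a sphere model (four-step monolayer algorithm)
#'
#' Step 1 surrounds every dry sphere with its 26 candidate hydration spheres
#' (see [hydration_positions()]). Step 2 removes excess candidates with a grid
#' conversion at the same box side as the dry model and occupancy cutoff
#' `hydration_cutoff` (typically 10-12, tuned so the hydrated volume matches
#' the sequence-derived target). Step 3 adds the original dry spheres back, as
#' extended structural features can be lost in Step 2. Step 4 applies a final
#' grid conversion with cutoff 1 to remove overlapping spheres. The filter
#' grids are anchored so every existing centre sits exactly at a box centre,
#' which both preserves the dry centres in the output and makes Step 4 an
#' exact deduplication.
#'
#' @param dry a non-empty unhydrated [sphere_model()].
#' @param hydration_cutoff Step 2 occupancy cutoff (integer `>= 1`).
#' @return hydrated [sphere_model()] (superset in extent of `dry`).
#' @export
hydrate_sphere_model <- function(dry, hydration_cutoff = 11L) {
  stopifnot(inherits(dry, "sphere_model"))
  if (nrow(dry$centres) < 1L) stop("hydrate_sphere_model: empty model")
  hydration_cutoff <- as.integer(hydration_cutoff)
  if (is.na(hydration_cutoff) || hydration_cutoff < 1L)
    stop("hydrate_sphere_model: hydration_cutoff must be >= 1")
  s <- dry$boxside
  cand <- do.call(rbind, lapply(seq_len(nrow(dry$centres)), function(k)
    hydration_positions(dry$centres[k, ], dry$radius)))
  expanded <- rbind(dry$centres, cand)                              # Step 1
  org <- aligned_origin(expanded, s)
  step2 <- grid_transform(expanded, s, cutoff = hydration_cutoff,   # Step 2
                          origin = org, warn_empty = FALSE)
  pts3 <- rbind(dry$centres, step2$centres)                         # Step 3
  step4 <- grid_transform(pts3, s, cutoff = 1L, origin = org)       # Step 4
  sphere_model(step4$centres, s, hydrated = TRUE)
}

#' Radius of gyration of a sphere model
#'
#' Root mean squared distance of the sphere centres from their centroid
#' (point-scatterer convention, matching the Debye treatment of the spheres).
#' Optionally the parallel-axis self-term of a uniform sphere, `(3/5) r^2`,
#' is added inside the root.
#'
#' @param model a non-empty [sphere_model()].
#' @param include_sphere_term add the `(3/5) r^2` self-term (default `FALSE`).
#' @return Rg in nm.
#' @export
sphere_rg <- function(model, include_sphere_term = FALSE) {
  stopifnot(inherits(model, "sphere_model"))
  n <- nrow(model$centres)
  if (n < 1L) stop("sphere_rg: empty model")
  ctr <- colMeans(model$centres)
  rg2 <- mean(rowSums(sweep(model$centres, 2, ctr)^2))
  if (include_sphere_term) rg2 <- rg2 + 0.6 * model$radius^2
  sqrt(rg2)
}

#' Optimize the grid box side against a target dry volume
#'
#' Searches for the cube side whose grid-transformed model volume (box
#' convention) best matches the sequence-derived dry volume. The objective
#' `|V(side) - target|` is piecewise-constant in the side with many local
#' plateaus, so a deterministic two-stage grid scan is used: a coarse pass at
#' 0.01 nm over the full range followed by a fine pass at `resolution` around
#' the coarse optimum.
#'
#' @param atoms an [atom_model()] (or point matrix).
#' @param target_dry_volume target volume in nm^3 (positive).
#' @param cutoff grid occupancy cutoff used during the search.
#' @param side_range search bracket for the box side, nm.
#' @param resolution fine-scan step, nm (default 1e-3).
#' @param warn_threshold warn when the best achievable relative volume error
#'   exceeds this fraction (the best side is still returned).
#' @return list with `boxside`, `achieved_volume`, `target_volume`,
#'   `rel_error`, `n_spheres` and the coarse `search_table`.
#' @export
optimize_box_side <- function(atoms, target_dry_volume, cutoff = 4L,
                              side_range = c(0.1, 1.5), resolution = 1e-3,
                              warn_threshold = 0.02) {
  pts <- as_point_matrix(atoms)
  if (!is.numeric(target_dry_volume) || target_dry_volume <= 0)
    stop("optimize_box_side: target volume must be positive")
  if (nrow(pts) < 2L)
    warning("optimize_box_side: degenerate input (fewer than 2 points); ",
            "the optimized side is not meaningful")
  stopifnot(length(side_range) == 2L, side_range[1] > 0,
            side_range[1] < side_range[2])
  vol_at <- function(side) {
    m <- grid_transform(pts, side, cutoff = cutoff, warn_empty = FALSE)
    if (nrow(m$centres) == 0L) 0 else sphere_model_volume(m, "box")
  }
  coarse <- seq(side_range[1], side_range[2], by = 0.01)
  v_coarse <- vapply(coarse, vol_at, numeric(1))
  best_c <- coarse[which.min(abs(v_coarse - target_dry_volume))]
  fine <- seq(max(side_range[1], best_c - 0.01),
              min(side_range[2], best_c + 0.01), by = resolution)
  v_fine <- vapply(fine, vol_at, numeric(1))
  k <- which.min(abs(v_fine - target_dry_volume))
  best <- fine[k]
  achieved <- v_fine[k]
  rel <- abs(achieved - target_dry_volume) / target_dry_volume
  if (rel > warn_threshold)
    warning(sprintf(paste0("optimize_box_side: best achievable volume ",
                           "deviates %.1f%% from target (threshold %.1f%%)"),
                    100 * rel, 100 * warn_threshold))
  n_best <- round(achieved / best^3)
  list(boxside = best, achieved_volume = achieved,
       target_volume = target_dry_volume, rel_error = rel,
       n_spheres = as.integer(n_best),
       search_table = data.frame(boxside = coarse, volume = v_coarse))
}

#' Optimize the hydration cutoff against a target hydrated volume
#'
#' Hydrates the dry model at every candidate Step 2 cutoff, reports the
#' resulting volume table (non-increasing in the cutoff) and returns the
#' cutoff whose hydrated-model volume is closest to the sequence-derived
#' hydrated volume (ties resolved toward the lower cutoff).
#'
#' @param dry a non-empty unhydrated [sphere_model()].
#' @param target_hydrated_volume target volume in nm^3 (positive).
#' @param cutoff_candidates integer candidates (default `1:14`, spanning the
#'   typical 10-12 band).
#' @return list with `best_cutoff`, `achieved_volume`, `rel_error` and the
#'   full `table` (`cutoff`, `volume`, `n_spheres`).
#' @export
optimize_hydration_cutoff <- function(dry, target_hydrated_volume,
                                      cutoff_candidates = 1:14) {
  stopifnot(inherits(dry, "sphere_model"))
  if (length(cutoff_candidates) < 1L)
    stop("optimize_hydration_cutoff: empty candidate list")
  if (!is.numeric(target_hydrated_volume) || target_hydrated_volume <= 0)
    stop("optimize_hydration_cutoff: target volume must be positive")
  cutoff_candidates <- sort(unique(as.integer(cutoff_candidates)))
  models <- lapply(cutoff_candidates,
                   function(k) hydrate_sphere_model(dry, k))
  vols <- vapply(models, sphere_model_volume, numeric(1))
  tab <- data.frame(cutoff = cutoff_candidates, volume = vols,
                    n_spheres = vapply(models,
                                       function(m) nrow(m$centres),
                                       integer(1)))
  k <- which.min(abs(vols - target_hydrated_volume))
  list(best_cutoff = cutoff_candidates[k], achieved_volume = vols[k],
       rel_error = abs(vols[k] - target_hydrated_volume) /
         target_hydrated_volume,
       table = tab)
}
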