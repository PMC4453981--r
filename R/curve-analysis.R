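# Guinier analyses and curve comparison. Rg comes from the slope of
# ln I vs Q^2 (slope = -Rg^2/3) in the low-Q region; for elongated particles
# the cross-sectional Rxs comes from ln(I*Q) vs Q^2 (slope = -Rxs^2/2) in a
# higher, non-overlapping window. Model-vs-experiment agreement is scored with
# a crystallographic-style R factor after nearest-Q grid matching.

guinier_window <- function(curve, fitmin, fitmax, label) {
  stopifnot(inherits(curve, "scatter_curve"))
  if (!is.numeric(fitmin) || !is.numeric(fitmax) || fitmin >= fitmax)
    stop(label, ": need fitmin < fitmax")
  sel <- which(curve$q >= fitmin & curve$q <= fitmax)
  if (length(sel) < 3L)
    stop(label, ": fewer than 3 points in the fit window [", fitmin, ", ",
         fitmax, "]")
  if (any(curve$i[sel] <= 0))
    stop(label, ": non-positive intensity inside the fit window")
  sel
}

#' Guinier fit for the radius of gyration
#'
#' Unweighted least-squares fit of `ln I` against `Q^2` over the window
#' `[fitmin, fitmax]`; `Rg = sqrt(-3 * slope)` and `I(0) = exp(intercept)`.
#' The Guinier approximation holds for `Q * Rg` roughly within 0.5-1.5; a
#' warning is issued when the fitted window falls outside that band.
#'
#' @param curve a [scatter_curve()] with positive intensities in the window.
#' @param fitmin,fitmax fit window in Q (nm^-1).
#' @return object of class `guinier_fit` with `rg` (nm), `i0`, `window`,
#'   `npoints`, `qrg_range` and `r_squared`.
#' @export
guinier_rg <- function(curve, fitmin, fitmax) {
  sel <- guinier_window(curve, fitmin, fitmax, "guinier_rg")
  x <- curve$q[sel]^2
  y <- log(curve$i[sel])
  fit <- lm(y ~ x)
  slope <- coef(fit)[[2]]
  if (slope >= 0)
    stop("guinier_rg: non-negative slope in the fit window; Rg is undefined ",
         "(window too high in Q or rising intensity)")
  rg <- sqrt(-3 * slope)
  qrg <- range(curve$q[sel]) * rg
  if (qrg[1] < 0.5 || qrg[2] > 1.5)
    warning(sprintf("guinier_rg: Q*Rg range [%.2f, %.2f] extends outside ",
                    qrg[1], qrg[2]),
            "the 0.5-1.5 validity band of the Guinier approximation")
  structure(list(type = "rg", rg = rg, i0 = exp(coef(fit)[[1]]),
                 window = c(fitmin, fitmax), npoints = length(sel),
                 qrg_range = qrg, r_squared = cor(x, y)^2),
            class = "guinier_fit")
}

#' Guinier fit for the cross-sectional radius of gyration
#'
#' For elongated macromolecules: unweighted least-squares fit of `ln(I * Q)`
#' against `Q^2`; `Rxs = sqrt(-2 * slope)`. The fit window must lie entirely
#' above (and not overlap) the Rg window when one is supplied, since the two
#' analyses probe different Q regimes.
#'
#' @param curve a [scatter_curve()].
#' @param fitmin,fitmax fit window in Q (nm^-1).
#' @param rg_window optional `c(fitmin, fitmax)` of the Rg analysis for the
#'   non-overlap validation.
#' @return object of class `guinier_fit` with `rxs` (nm) and fit metadata.
#' @export
guinier_rxs <- function(curve, fitmin, fitmax, rg_window = NULL) {
  if (!is.null(rg_window)) {
    stopifnot(length(rg_window) == 2L)
    if (fitmin < rg_window[2])
      stop("guinier_rxs: fit window [", fitmin, ", ", fitmax, "] overlaps ",
           "or underlies the Rg window [", rg_window[1], ", ", rg_window[2],
           "]; the cross-sectional fit must use a higher, disjoint Q range")
  }
  sel <- guinier_window(curve, fitmin, fitmax, "guinier_rxs")
  x <- curve$q[sel]^2
  y <- log(curve$i[sel] * curve$q[sel])
  fit <- lm(y ~ x)
  slope <- coef(fit)[[2]]
  if (slope >= 0)
    stop("guinier_rxs: non-negative slope in the fit window; Rxs is ",
         "undefined")
  structure(list(type = "rxs", rxs = sqrt(-2 * slope),
                 i0 = exp(coef(fit)[[1]]),
                 window = c(fitmin, fitmax), npoints = length(sel),
                 r_squared = cor(x, y)^2),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  if (x$type == "rg") {
    cat(sprintf(paste0("Guinier fit: Rg = %.4f nm, I(0) = %.4g ",
                       "(%d points, Q in [%.3g, %.3g], Q*Rg %.2f-%.2f, ",
                       "R^2 = %.4f)\n"),
                x$rg, x$i0, x$npoints, x$window[1], x$window[2],
                x$qrg_range[1], x$qrg_range[2], x$r_squared))
  } else {
    cat(sprintf(paste0("Cross-section Guinier fit: Rxs = %.4f nm ",
                       "(%d points, Q in [%.3g, %.3g], R^2 = %.4f)\n"),
                x$rxs, x$npoints, x$window[1], x$window[2], x$r_squared))
  }
  invisible(x)
}

#' Match a theoretical curve onto an experimental Q grid
#'
#' For every experimental Q inside `[qmin, qmax]`, pairs the experimental
#' intensity with the theoretical intensity at the closest theoretical Q (ties
#' broken toward the lower Q). This lets one theoretical curve be compared
#' with multiple experimental data sets on their own grids.
#'
#' @param theoretical,experimental [scatter_curve()] objects.
#' @param qmin,qmax comparison window (nm^-1).
#' @return list with `q_expt`, `i_expt`, `q_theo`, `i_theo` and the matched
#'   theoretical indices `idx`; one entry per experimental point in the
#'   window.
#' @export
match_q_grid <- function(theoretical, experimental, qmin, qmax) {
  stopifnot(inherits(theoretical, "scatter_curve"),
            inherits(experimental, "scatter_curve"))
  if (qmin >= qmax) stop("match_q_grid: need qmin < qmax")
  qe_sel <- which(experimental$q >= qmin & experimental$q <= qmax)
  if (length(qe_sel) == 0L)
    stop("match_q_grid: no experimental points in the window [", qmin, ", ",
         qmax, "]")
  qt <- theoretical$q
  if (max(qt) < qmin || min(qt) > qmax)
    stop("match_q_grid: theoretical and experimental Q ranges do not ",
         "overlap inside the window")
  qe <- experimental$q[qe_sel]
  pos <- findInterval(qe, qt)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(qt))
  d_lo <- abs(qe - qt[lo])
  d_hi <- abs(qt[hi] - qe)
  idx <- ifelse(d_lo <= d_hi, lo, hi)   # tie -> lower Q
  list(q_expt = qe, i_expt = experimental$i[qe_sel],
       q_theo = qt[idx], i_theo = theoretical$i[idx], idx = idx)
}

#' R factor between theoretical and experimental curves
#'
#' Crystallographic-style goodness of fit on the matched Q grid:
#' `R(eta) = 100 * sum | |I_expt| - eta * |I_theo| | / sum |I_expt|`,
#' minimized over the scale factor `eta > 0` that matches the theoretical
#' curve to the experimental one. `R(eta)` is piecewise-linear and convex in
#' eta, so the exact minimum is found on the finite breakpoint set
#' `eta_k = |I_expt,k| / |I_theo,k|` (ties resolved toward the smaller eta);
#' lower R means a better fit.
#'
#' @param theoretical,experimental [scatter_curve()] objects.
#' @param qmin,qmax comparison window (nm^-1).
#' @return object of class `rfactor_result` with `r_factor` (percent), `eta`,
#'   `window` and matched point count `npoints`.
#' @export
r_factor <- function(theoretical, experimental, qmin, qmax) {
  m <- match_q_grid(theoretical, experimental, qmin, qmax)
  ie <- abs(m$i_expt)
  it <- abs(m$i_theo)
  denom <- sum(ie)
  if (denom <= 0) stop("r_factor: experimental intensities sum to zero in ",
                       "the comparison window")
  ok <- it > 0 & ie > 0
  if (!any(ok)) stop("r_factor: no usable matched pairs (all intensities ",
                     "zero)")
  etas <- sort(unique(ie[ok] / it[ok]))
  r_of <- function(eta) 100 * sum(abs(ie - eta * it)) / denom
  rs <- vapply(etas, r_of, numeric(1))
  k <- which.min(rs)                     # first minimum -> smallest eta
  structure(list(r_factor = rs[k], eta = etas[k], window = c(qmin, qmax),
                 npoints = length(ie)),
            class = "rfactor_result")
}

#' @export
print.rfactor_result <- function(x, ...) {
  cat(sprintf("R factor: %.4f%% (eta = %.6g, %d points, Q in [%.3g, %.3g])\n",
              x$r_factor, x$eta, x$npoints, x$window[1], x$window[2]))
  invisible(x)
}
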