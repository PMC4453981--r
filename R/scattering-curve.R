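# Theoretical scattering curves from sphere models. The Debye double sum over
# sphere pairs is accelerated by a pair-distance histogram:
#
#   I(Q)/I(0) = g(Q) * [ 1/n + (2/n^2) * sum_j A_j sin(Q d_j)/(Q d_j) ]
#
# with g(Q) the squared form factor of a uniform sphere of radius r. Since
# sum_j A_j = n(n-1)/2, the bracket tends to 1 as Q -> 0.

#' Pair-distance histogram of a sphere model
#'
#' Builds the histogram of all n(n-1)/2 inter-sphere distances. In `"classic"`
#' mode the histogram has 400 equal bins (unless overridden) of user-supplied
#' width starting from zero; a pair distance beyond the last bin is an error
#' (reporting the overflow count), never silent truncation. In `"modern"` mode
#' the bin width is derived from the minimum and maximum pair distances, which
#' the `nbins` bins span exactly; when all pair distances coincide the
#' histogram collapses to a single bin at that distance.
#'
#' @param model a [sphere_model()] with at least 2 spheres.
#' @param mode `"modern"` (default) or `"classic"`.
#' @param nbins number of bins (modern mode; classic default 400).
#' @param bin_width bin width in nm (required in classic mode).
#' @return object of class `distance_histogram`: bin centres `d` (nm), integer
#'   `counts`, `nbins`, sphere count `n`, `bin_width`, `mode`. Counts sum to
#'   n(n-1)/2.
#' @export
distance_histogram <- function(model, mode = c("modern", "classic"),
                               nbins = NULL, bin_width = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "sphere_model"))
  n <- nrow(model$centres)
  if (n < 2L) stop("distance_histogram: need at least 2 spheres")
  d <- as.numeric(dist(model$centres))
  npairs <- n * (n - 1) / 2
  if (mode == "classic") {
    if (is.null(nbins)) nbins <- 400L
    nbins <- as.integer(nbins)
    if (is.null(bin_width))
      stop("distance_histogram: classic mode requires a user-defined ",
           "bin_width")
    stopifnot(bin_width > 0, nbins >= 1L)
    over <- sum(d > nbins * bin_width)
    if (over > 0L)
      stop("distance_histogram: ", over, " pair distance(s) beyond the ",
           "classic histogram range (", nbins, " bins x ", bin_width,
           " nm); increase bin_width")
    idx <- pmax(ceiling(d / bin_width), 1L)  # bins (0, w], (w, 2w], ...
    counts <- tabulate(idx, nbins)
    centres <- (seq_len(nbins) - 0.5) * bin_width
  } else {
    if (is.null(nbins)) nbins <- 400L
    nbins <- as.integer(nbins)
    stopifnot(nbins >= 1L)
    dmin <- min(d); dmax <- max(d)
    if (dmax - dmin < 1e-12) {           # degenerate: all pairs equidistant
      nbins <- 1L
      counts <- length(d)
      centres <- dmin
      bin_width <- 0
    } else {
      bin_width <- (dmax - dmin) / nbins
      idx <- pmin(floor((d - dmin) / bin_width) + 1L, nbins)
      counts <- tabulate(idx, nbins)
      centres <- dmin + (seq_len(nbins) - 0.5) * bin_width
    }
  }
  stopifnot(sum(counts) == npairs)
  structure(list(d = centres, counts = as.integer(counts),
                 nbins = length(centres), n = n, bin_width = bin_width,
                 mode = mode, radius = model$radius),
            class = "distance_histogram")
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf(paste0("distance_histogram (%s): %d bins, %d spheres, ",
                     "%d pair distances in [%.4g, %.4g] nm\n"),
              x$mode, x$nbins, x$n, sum(x$counts),
              min(x$d[x$counts > 0]), max(x$d[x$counts > 0])))
  invisible(x)
}

#' Squared form factor of a uniform sphere
#'
#' `g(Q) = [3 (sin(Qr) - Qr cos(Qr)) / (Qr)^3]^2`, with the series limit
#' `g(0) = 1`; the amplitude is series-expanded below `Qr = 1e-3` for
#' numerical stability. Its first zero lies at `Qr ~ 4.4934` (the first root
#' of `tan x = x`).
#'
#' @param q scattering vector magnitudes, nm^-1 (non-negative, vectorized).
#' @param r sphere radius, nm (positive).
#' @return dimensionless values in `[0, 1]`.
#' @export
squared_form_factor <- function(q, r) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("squared_form_factor: radius must be a positive scalar")
  if (any(q < 0)) stop("squared_form_factor: negative Q")
  x <- q * r
  amp <- ifelse(x < 1e-3,
                1 - x^2 / 10,
                3 * (sin(x) - x * cos(x)) / x^3)
  amp^2
}

#' Theoretical scattering curve via the sphere-adapted Debye equation
#'
#' Evaluates the normalized intensity
#' `I(Q)/I(0) = g(Q) * [1/n + (2/n^2) sum_j A_j sin(Q d_j)/(Q d_j)]`
#' from a pair-distance histogram; the `1/n` term carries the sphere
#' self-correlations, and the normalization tends to 1 as Q tends to 0.
#'
#' @param hist a [distance_histogram()].
#' @param r sphere radius in nm (defaults to the radius recorded in the
#'   histogram).
#' @param q vector of Q values (nm^-1, strictly increasing, positive).
#' @return a theoretical [scatter_curve()] normalized to I(0) = 1.
#' @export
debye_curve <- function(hist, q, r = hist$radius) {
  stopifnot(inherits(hist, "distance_histogram"))
  if (is.null(r) || !is.numeric(r) || r <= 0)
    stop("debye_curve: sphere radius must be positive")
  if (length(hist$counts) < 1L || sum(hist$counts) < 1L)
    stop("debye_curve: empty histogram")
  q <- as.numeric(q)
  if (any(q <= 0)) stop("debye_curve: Q grid must be positive (the Q = 0 ",
                        "limit is 1 by construction)")
  n <- hist$n
  nz <- hist$counts > 0
  dd <- hist$d[nz]
  aa <- hist$counts[nz]
  qd <- outer(q, dd)
  sinc <- ifelse(qd < 1e-6, 1 - qd^2 / 6, sin(qd) / qd)
  s <- 1 / n + (2 / n^2) * as.numeric(sinc %*% aa)
  scatter_curve(q, squared_form_factor(q, r) * s, kind = "theoretical")
}

#' Gaussian smearing width for SANS instrumental resolution
#'
#' Beam-divergence and wavelength-spread contributions are treated as FWHM
#' widths, added in quadrature and converted to a Gaussian standard
#' deviation:
#' `sigma(Q) = sqrt[((4 pi / lambda) dtheta)^2 + (Q dlambda/lambda)^2] /
#' (2 sqrt(2 ln 2))`.
#' This is a stated convention of the package; instrument-exact resolution
#' functions can be injected via the `sigma_fun` argument of
#' [smear_curve()].
#'
#' @param q Q values, nm^-1.
#' @param wavelength neutron wavelength lambda, nm.
#' @param spread fractional wavelength spread (FWHM of dlambda/lambda).
#' @param divergence beam angular divergence (FWHM of dtheta, radians).
#' @return sigma(Q) in nm^-1, same length as `q`.
#' @export
smearing_sigma <- function(q, wavelength, spread, divergence) {
  stopifnot(wavelength > 0, spread >= 0, divergence >= 0)
  fwhm <- sqrt(((4 * pi / wavelength) * divergence)^2 + (q * spread)^2)
  fwhm / (2 * sqrt(2 * log(2)))
}

#' Apply Gaussian beam smearing to a theoretical curve
#'
#' Convolves the curve with a unit-area Gaussian of Q-dependent standard
#' deviation (see [smearing_sigma()]), evaluated as a discrete convolution on
#' the curve's own Q grid with reflective edge handling. Points whose sigma is
#' negligible are passed through unchanged, so the zero-width limit is the
#' identity; the kernel is renormalized at every point, so constant curves are
#' preserved exactly.
#'
#' @param curve an unsmeared theoretical [scatter_curve()].
#' @param wavelength,spread,divergence instrument settings (see
#'   [smearing_sigma()]); all must be positive.
#' @param sigma_fun optional replacement resolution function
#'   `function(q) -> sigma` overriding the built-in convention.
#' @return smeared [scatter_curve()] (`smeared` flag set).
#' @export
smear_curve <- function(curve, wavelength, spread, divergence,
                        sigma_fun = NULL) {
  stopifnot(inherits(curve, "scatter_curve"))
  if (curve$smeared) stop("smear_curve: curve is already smeared")
  if (is.null(sigma_fun)) {
    if (wavelength <= 0 || spread < 0 || divergence < 0)
      stop("smear_curve: smearing parameters must be positive")
    sig <- smearing_sigma(curve$q, wavelength, spread, divergence)
  } else {
    sig <- sigma_fun(curve$q)
  }
  q <- curve$q; i <- curve$i; nq <- length(q)
  if (nq < 3L) stop("smear_curve: curve shorter than the kernel support")
  if (max(sig) > (max(q) - min(q)))
    warning("smear_curve: kernel width exceeds the curve's Q range; edge ",
            "handling dominates the result")
  # reflective padding at both ends
  q_ext <- c(2 * q[1] - q[nq:2], q, 2 * q[nq] - q[(nq - 1):1])
  i_ext <- c(i[nq:2], i, i[(nq - 1):1])
  out <- i
  active <- sig > 1e-12
  if (any(active)) {
    for (k in which(active)) {
      w <- dnorm(q_ext, mean = q[k], sd = sig[k])
      out[k] <- sum(w * i_ext) / sum(w)
    }
  }
  scatter_curve(q, out, kind = curve$kind, smeared = TRUE,
                source = curve$source)
}

#' Flat incoherent-scattering baseline correction
#'
#' Adds a flat baseline of `fraction * I(0)` to every point, compensating the
#' incoherent scattering of residual protons in heavy-water SANS samples.
#' Typical corrections are 0.5-1.5% of I(0); the function warns above that
#' band and rejects fractions beyond 5%. By convention this correction is
#' applied to the reported theoretical curve only *after* R-factor fitting is
#' complete (the workflow enforces the ordering).
#'
#' @param curve a [scatter_curve()]; I(0) is taken as the intensity at the
#'   lowest Q (1 for normalized theoretical curves).
#' @param fraction baseline as a fraction of I(0), in `[0, 0.05]`.
#' @return corrected [scatter_curve()].
#' @export
apply_incoherent_baseline <- function(curve, fraction) {
  stopifnot(inherits(curve, "scatter_curve"))
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction < 0)
    stop("apply_incoherent_baseline: fraction must be non-negative")
  if (fraction > 0.05)
    stop("apply_incoherent_baseline: fraction above 5% of I(0) is not ",
         "an incoherent baseline")
  if (fraction > 0.015)
    warning("apply_incoherent_baseline: fraction above the typical ",
            "0.5-1.5% band")
  scatter_curve(curve$q, curve$i + fraction * curve$i[1], kind = curve$kind,
                smeared = curve$smeared, source = curve$source)
}
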