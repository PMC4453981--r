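# Distance histograms, the form factor, the Debye curve against the exact
# all-pairs oracle, smearing, baseline, Guinier fits and the R factor.

test_that("distance_histogram counts all pairs in both modes", {
  two <- sphere_model(rbind(c(0, 0, 0), c(1, 0, 0)), 0.5)
  h <- distance_histogram(two, "modern", nbins = 10)
  expect_equal(h$nbins, 1L)       # degenerate range collapses to one bin
  expect_equal(sum(h$counts), 1L)
  expect_equal(h$d[h$counts > 0], 1)

  # 4 collinear equidistant spheres: counts {3,2,1} at {s, 2s, 3s}
  four <- sphere_model(cbind(0:3 * 0.8, 0, 0), 0.5)
  h4 <- distance_histogram(four, "modern", nbins = 3)
  expect_equal(h4$counts, c(3L, 2L, 1L))
  d_pairs <- as.numeric(dist(four$centres))
  expect_equal(sort(unique(round(d_pairs, 9))), c(0.8, 1.6, 2.4))

  # classic mode: default 400 bins, user width, starts at zero
  hc <- distance_histogram(four, "classic", bin_width = 0.01)
  expect_equal(hc$nbins, 400L)
  expect_equal(sum(hc$counts), 6L)
  expect_error(distance_histogram(four, "classic"), "bin_width")
  expect_error(distance_histogram(four, "classic", bin_width = 0.001),
               "beyond the classic histogram range")
  expect_error(
    distance_histogram(sphere_model(matrix(0, 1, 3), 0.5), "modern"),
    "at least 2")
})

test_that("histogram counts always sum to n(n-1)/2", {
  for (seed in c(2, 5, 9)) {
    m <- random_sphere_model(withr::with_seed(seed, sample(3:80, 1)),
                             seed = seed)
    n <- nrow(m$centres)
    h <- distance_histogram(m, "modern", nbins = 37)
    expect_equal(sum(h$counts), n * (n - 1) / 2)
  }
})

test_that("squared form factor has the right limits and zeros", {
  expect_equal(squared_form_factor(0, 0.25), 1)
  # first zero of the sphere amplitude at Qr = 4.4934...
  x0 <- 4.493409457909064
  expect_lt(squared_form_factor(x0 / 0.25, 0.25), 1e-12)
  qr <- seq(0, 50, length.out = 5000)
  g <- squared_form_factor(qr, 1)
  expect_true(all(g >= 0 & g <= 1 + 1e-12))
  # series branch continuous at the switch point
  expect_equal(squared_form_factor(1e-3 / 0.3 - 1e-9, 0.3),
               squared_form_factor(1e-3 / 0.3 + 1e-9, 0.3),
               tolerance = 1e-9)
  expect_error(squared_form_factor(-1, 0.5), "negative")
  expect_error(squared_form_factor(1, -0.5), "positive")
})

test_that("debye_curve is normalized and matches the two-sphere closed form", {
  m <- random_sphere_model(40, seed = 21)
  h <- distance_histogram(m, "modern", nbins = 500)
  expect_equal(debye_curve(h, 1e-6)$i, 1, tolerance = 1e-6)

  d <- 1.3; r <- 0.25
  two <- sphere_model(rbind(c(0, 0, 0), c(d, 0, 0)), 2 * r)
  h2 <- distance_histogram(two, "modern", nbins = 5)
  q <- seq(0.05, 2, length.out = 60)
  got <- debye_curve(h2, q, r = r)$i
  want <- squared_form_factor(q, r) * 0.5 * (1 + sin(q * d) / (q * d))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("histogrammed Debye matches the exact all-pairs sum within 1%", {
  q <- seq(0.04, 2, length.out = 50)
  for (seed in c(3, 14)) {
    n <- withr::with_seed(seed, sample(20:120, 1))
    m <- random_sphere_model(n, seed = seed + 100, extent = 3)
    h <- distance_histogram(m, "modern", nbins = 2000)
    got <- debye_curve(h, q, r = 0.25)$i
    want <- bf_debye(m$centres, 0.25, q)
    expect_lt(max(abs(got - want) / abs(want)), 0.01)
  }
})

test_that("smearing has delta-kernel, unit-area and variance properties", {
  q <- seq(0.01, 2, length.out = 400)
  cur <- scatter_curve(q, exp(-q^2 / 0.5))
  # sigma -> 0 is the identity
  sm0 <- smear_curve(cur, wavelength = 0.6, spread = 1e-12,
                     divergence = 1e-12)
  expect_equal(sm0$i, cur$i, tolerance = 1e-9)
  expect_true(sm0$smeared)
  # constant curves are preserved by the unit-area kernel
  cst <- scatter_curve(q, rep(2.5, length(q)))
  smc <- smear_curve(cst, 0.6, 0.1, 0.016)
  expect_equal(smc$i, cst$i, tolerance = 1e-12)
  # Gaussian peak: output variance = input variance + sigma^2
  # (spread = 0 gives a constant sigma from the divergence term alone)
  s_in <- 0.05
  peak <- scatter_curve(q, dnorm(q, 1, s_in))
  div <- 0.004
  sig <- smearing_sigma(1, 0.6, 0, div)
  out <- smear_curve(peak, 0.6, spread = 1e-15, divergence = div)
  moment <- function(w) {
    mu <- sum(q * w) / sum(w)
    sum((q - mu)^2 * w) / sum(w)
  }
  expect_equal(moment(out$i), moment(peak$i) + sig^2, tolerance = 0.05)
  # double smearing is rejected
  expect_error(smear_curve(sm0, 0.6, 0.1, 0.016), "already smeared")
})

test_that("smearing softens oscillatory features", {
  q <- seq(0.01, 2, length.out = 500)
  osc <- scatter_curve(q, 1 + 0.5 * sin(25 * q))
  sm <- smear_curve(osc, 0.6, 0.1, 0.016)
  curv <- function(i) max(abs(diff(i, differences = 2)))
  expect_lt(curv(sm$i), curv(osc$i))
})

test_that("incoherent baseline is a flat post-fit addition", {
  q <- seq(0.05, 1.5, length.out = 30)
  cur <- scatter_curve(q, exp(-q))
  expect_equal(apply_incoherent_baseline(cur, 0)$i, cur$i)
  up <- apply_incoherent_baseline(scatter_curve(q, exp(-q) / exp(-q[1])),
                                  0.01)
  expect_equal(up$i - exp(-q) / exp(-q[1]), rep(0.01, length(q)))
  expect_error(apply_incoherent_baseline(cur, -0.01), "non-negative")
  expect_error(apply_incoherent_baseline(cur, 0.2), "not")
  expect_warning(apply_incoherent_baseline(cur, 0.03), "typical")
})

test_that("guinier_rg recovers exact synthetic parameters", {
  rg <- 3; i0 <- 2.5
  q <- seq(0.01, 0.6, length.out = 200)
  cur <- scatter_curve(q, i0 * exp(-rg^2 * q^2 / 3))
  fit <- suppressWarnings(guinier_rg(cur, 0.1, 0.4))
  expect_equal(fit$rg, 3, tolerance = 1e-6)
  expect_equal(fit$i0, 2.5, tolerance = 1e-6)
  expect_error(guinier_rg(cur, 0.1, 0.105), "fewer than 3")
  rising <- scatter_curve(q, exp(+q^2))
  expect_error(suppressWarnings(guinier_rg(rising, 0.1, 0.4)), "slope")
  neg <- scatter_curve(q, cos(10 * q))
  expect_error(suppressWarnings(guinier_rg(neg, 0.1, 0.4)), "non-positive")
})

test_that("guinier_rg warns outside the Q*Rg validity band", {
  q <- seq(0.01, 2, length.out = 500)
  cur <- scatter_curve(q, exp(-9 * q^2 / 3))
  expect_warning(guinier_rg(cur, 0.02, 0.3), "0.5-1.5")
  expect_silent(guinier_rg(cur, 0.2, 0.45))
})

test_that("guinier_rxs recovers rod parameters and validates windows", {
  rxs <- 1.5
  q <- seq(0.2, 1.2, length.out = 150)
  cur <- scatter_curve(q, 4 * exp(-rxs^2 * q^2 / 2) / q)
  fit <- guinier_rxs(cur, 0.4, 0.8)
  expect_equal(fit$rxs, 1.5, tolerance = 1e-6)
  expect_error(guinier_rxs(cur, 0.25, 0.8, rg_window = c(0.1, 0.3)),
               "overlap")
  rising <- scatter_curve(q, exp(q^2) / q)
  expect_error(guinier_rxs(rising, 0.4, 0.8), "slope")
})

test_that("match_q_grid pairs nearest Q with ties toward lower Q", {
  theo <- scatter_curve(c(0.10, 0.20, 0.30), c(1, 2, 3))
  expt <- scatter_curve(c(0.10, 0.20, 0.30), c(9, 9, 9),
                        kind = "experimental")
  m <- match_q_grid(theo, expt, 0.05, 0.35)
  expect_equal(m$i_theo, c(1, 2, 3))

  tie <- scatter_curve(c(0.15, 0.35), c(7, 7), kind = "experimental")
  m2 <- match_q_grid(theo, tie, 0.05, 0.4)
  expect_equal(m2$q_theo[1], 0.10)   # 0.15 ties between 0.10 and 0.20

  for (seed in c(4, 8)) {
    withr::with_seed(seed, {
      qt <- sort(runif(40, 0, 2)); qe <- sort(runif(25, 0.1, 1.9))
    })
    theo_r <- scatter_curve(qt, seq_along(qt))
    expt_r <- scatter_curve(qe, rep(1, 25), kind = "experimental")
    m3 <- match_q_grid(theo_r, expt_r, 0, 2)
    expect_equal(m3$idx, bf_nearest(qe, qt))
  }
  expect_error(match_q_grid(theo, expt, 0.9, 1.0), "no experimental points")
})

test_that("r_factor identity, pure scale, and grid-scan agreement", {
  q <- seq(0.05, 1.5, length.out = 80)
  theo <- scatter_curve(q, exp(-q^2) + 0.01)
  self <- scatter_curve(q, theo$i, kind = "experimental")
  rf <- r_factor(theo, self, 0.05, 1.5)
  expect_equal(rf$r_factor, 0)
  expect_equal(rf$eta, 1)

  doubled <- scatter_curve(q, 2 * theo$i, kind = "experimental")
  rf2 <- r_factor(theo, doubled, 0.05, 1.5)
  expect_equal(rf2$r_factor, 0)
  expect_equal(rf2$eta, 2)

  pert <- make_experimental_curve(theo, noise_fraction = 0.05, seed = 6)
  rfp <- r_factor(theo, pert, 0.05, 1.5)
  eta_grid <- seq(0.5, 2, by = 1e-5)
  r_of <- function(eta)
    100 * sum(abs(abs(pert$i) - eta * abs(theo$i))) / sum(abs(pert$i))
  rs <- vapply(eta_grid, r_of, numeric(1))
  expect_equal(rfp$r_factor, min(rs), tolerance = 1e-4)
  expect_equal(rfp$eta, eta_grid[which.min(rs)], tolerance = 1e-3)
  expect_lte(rfp$r_factor, min(rs) + 1e-9)   # exact minimizer never above
})
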