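test_that("dipole sampling is uniform on the sphere and reproducible", {
  set.seed(101)
  d <- sample_dipole(1e6)
  # E[cos^2 theta cos^2 phi] = 1/3 on the sphere, so E[N_x] = N_max / 3
  v <- cos(d$theta)^2 * cos(d$phi)^2
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 1 / 3), 3 * se)
  # sin(theta) uniform on [-1, 1]
  ks <- suppressWarnings(ks.test(sin(d$theta), "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
  # seeding contract
  set.seed(5); a <- sample_dipole(10)
  set.seed(5); b <- sample_dipole(10)
  set.seed(6); c_ <- sample_dipole(10)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$phi[1], c_$phi[1])))
})

test_that("expected photons follow the dipole projection", {
  acq <- default_acq(1e4)
  ex <- expected_photons(data.frame(phi = c(0, pi / 4, 1.2),
                                    theta = c(0, 0, pi / 2)), acq)
  expect_equal(ex$N_x_true[1:2], c(1e4, 5000))
  expect_equal(ex$N_y_true[1:2], c(0, 5000))
  expect_equal(unlist(ex[3, ]), c(N_x_true = 0, N_y_true = 0),
               tolerance = 1e-12)
  # arbitrary dipoles always land inside the triangle N_x + N_y <= N_max
  set.seed(1)
  acq2 <- default_acq(20000)
  ex2 <- expected_photons(sample_dipole(500), acq2)
  expect_true(all(ex2$N_x_true + ex2$N_y_true <= 20000 + 1e-9))
})

test_that("photon-count density matches the closed form and normalizes", {
  M <- 1e4
  expect_equal(photon_density(M / 2, M, M), 0)         # outside the region
  expect_equal(photon_density(M / 3, M / 3, M), sqrt(27) / (2 * pi * M^2))
  expect_identical(photon_density(0, M / 2, M), Inf)   # boundary sentinel
  # 2D quadrature: integrate the inner variable analytically-free via
  # nested numeric integration
  inner <- function(nx) {
    vapply(nx, function(x) {
      stats::integrate(function(ny) photon_density(x, ny, M), 0, M - x,
                       rel.tol = 1e-8)$value
    }, numeric(1))
  }
  total <- stats::integrate(inner, 0, M, rel.tol = 1e-6)$value
  expect_equal(total, 1, tolerance = 1e-3)
})

test_that("simulated expected intensities follow the analytic density", {
  # chi-square goodness of fit on strictly interior grid cells
  M <- 1e4
  acq <- default_acq(M)
  set.seed(202)
  ex <- expected_photons(sample_dipole(2e5), acq)
  k <- 8
  br <- seq(0, M, length.out = k + 1)
  cells <- expand.grid(i = 1:(k - 2), j = 1:(k - 2))
  cells <- cells[cells$i + cells$j <= k - 2, ]  # closure inside the triangle
  probs <- mapply(function(i, j) {
    # nested adaptive quadrature over the cell
    inner <- function(x) vapply(x, function(xx) {
      stats::integrate(function(y) photon_density(xx, y, M),
                       br[j], br[j + 1], rel.tol = 1e-9)$value
    }, numeric(1))
    stats::integrate(inner, br[i], br[i + 1], rel.tol = 1e-8)$value
  }, cells$i, cells$j)
  ci <- findInterval(ex$N_x_true, br, rightmost.closed = TRUE)
  cj <- findInterval(ex$N_y_true, br, rightmost.closed = TRUE)
  key <- paste(ci, cj)
  counts <- vapply(paste(cells$i, cells$j),
                   function(kk) sum(key == kk), numeric(1))
  inside <- sum(counts)
  expected <- probs / sum(probs) * inside
  chi2 <- sum((counts - expected)^2 / expected)
  p <- pchisq(chi2, df = length(counts) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("intensity noise follows the printed CRLB formula", {
  acq0 <- default_acq(1e4, b = 0)
  expect_equal(intensity_noise_sd(1e4, acq0), 100)  # shot-noise limit
  acqb <- default_acq(1e4, b = 100)
  expect_equal(intensity_noise_sd(1e4, acqb), 132.616345285, tolerance = 1e-9)
  # strictly increasing in b at fixed N
  dn <- vapply(c(0, 10, 50, 100, 300),
               function(b) intensity_noise_sd(5e3, default_acq(1e4, b = b)),
               numeric(1))
  expect_true(all(diff(dn) > 0))
  expect_error(intensity_noise_sd(0, acq0), "positive")
  # grid agreement with an independent scalar re-implementation
  grid <- expand.grid(N = c(300, 1e3, 1e4, 1e5), b = c(0, 1, 30, 300))
  got <- mapply(function(N, b) intensity_noise_sd(N, default_acq(1e5, b = b)),
                grid$N, grid$b)
  want <- mapply(oracle_dN, grid$N, grid$b)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("localization precision follows the summed-frame CRLB", {
  acq0 <- default_acq(1e4, b = 0)
  expect_equal(localization_precision(1e4, acq0),
               sqrt((160^2 + 100^2 / 12) / 1e4), tolerance = 1e-12)
  # b = 0 scaling law and the large-N limit
  expect_equal(localization_precision(2e4, acq0),
               localization_precision(1e4, acq0) / sqrt(2), tolerance = 1e-12)
  expect_lt(localization_precision(1e12, acq0), 1e-3)
  expect_error(localization_precision(-1, acq0), "positive")
  grid <- expand.grid(N = c(300, 1e3, 1e4, 1e5), b = c(0, 1, 30, 300))
  got <- mapply(function(N, b) {
    localization_precision(N, default_acq(1e5, b = b))
  }, grid$N, grid$b)
  expect_equal(got, mapply(oracle_dx, grid$N, grid$b), tolerance = 1e-12)
})

test_that("minimum photon threshold inverts the precision curve", {
  acq0 <- default_acq(1e4, b = 0)
  expect_equal(acq0$N_min, (160^2 + 100^2 / 12) / 100, tolerance = 1e-9)
  # inversion property at nonzero background, 1e-9 relative
  for (b in c(10, 100, 300)) {
    acq <- default_acq(1e4, b = b)
    expect_equal(localization_precision(acq$N_min, acq), acq$dx_max,
                 tolerance = 1e-9)
  }
  # N_min increases with background, decreases with a looser cutoff
  nm <- vapply(c(0, 50, 150, 300),
               function(b) default_acq(1e4, b = b)$N_min, numeric(1))
  expect_true(all(diff(nm) > 0))
  expect_lt(default_acq(1e4, dx_max = 1e4)$N_min, 1)
})

test_that("blink counts are moment-matched, rounded and floored at 1", {
  # the moment-matched underlying parameters
  mu <- log(6.4^2 / sqrt(6.4^2 + 5^2))
  s2 <- log(1 + 5^2 / 6.4^2)
  set.seed(77)
  m <- draw_blink_count(1e6)
  expect_true(all(m >= 1))
  # oracle mean of the rounded-and-floored distribution via plnorm
  k <- 1:5000
  pk <- plnorm(k + 0.5, mu, sqrt(s2)) - plnorm(k - 0.5, mu, sqrt(s2))
  pk[1] <- plnorm(1.5, mu, sqrt(s2))
  mean_oracle <- sum(k * pk)
  se <- sd(m) / sqrt(length(m))
  expect_lt(abs(mean(m) - mean_oracle), 3 * se)
})

test_that("per-blink emission draws respect the detection contract", {
  acq <- default_acq(1e4)
  set.seed(9)
  em <- draw_emission(sample_dipole(2e4), acq)
  expect_true(all(em$N_x_true + em$N_y_true <= acq$N_max + 1e-9))
  expect_true(all(em$N_x_obs >= 0 & em$N_y_obs >= 0))
  expect_identical(em$accepted, em$N_total >= acq$N_min)
  expect_true(all(is.na(em$dx[!em$accepted])))
  expect_true(all(em$dx[em$accepted] <= acq$dx_max + 1e-9))
})
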