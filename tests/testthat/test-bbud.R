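# helper: gaussian UD built directly on a grid
gaussian_ud <- function(sd_km = 3, cell_km = 0.5, half_w = 15) {
  x <- seq(-half_w, half_w, by = cell_km)
  z <- dnorm(x, 0, sd_km) %o% dnorm(x, 0, sd_km)
  ud_grid(x, x, z / sum(z), cell_km)
}

test_that("bridge step density matches brute-force numerical integration", {
  # dense quadrature vs independent per-cell integration over alpha
  x <- seq(-4, 4, by = 0.4)
  y <- seq(-3, 5, by = 0.4)
  z1 <- c(-2, 0); z2 <- c(2, 1.5)
  T_hr <- 6; s1 <- 0.8; e1 <- 0.5; e2 <- 1.0
  got <- bb_step_density(z1, z2, 0, T_hr, s1, e1, e2, x, y,
                         alpha_steps = 2000)
  oracle <- matrix(0, length(y), length(x))
  for (r in seq_along(y)) {
    for (cc in seq_along(x)) {
      oracle[r, cc] <- T_hr * integrate(function(a) {
        mx <- (1 - a) * z1[1] + a * z2[1]
        my <- (1 - a) * z1[2] + a * z2[2]
        v <- T_hr * a * (1 - a) * s1^2 + (1 - a)^2 * e1^2 + a^2 * e2^2
        dnorm(x[cc], mx, sqrt(v)) * dnorm(y[r], my, sqrt(v))
      }, 0, 1, rel.tol = 1e-10)$value
    }
  }
  expect_lt(max(abs(got - oracle)) / max(oracle), 1e-4)
})

test_that("bridge variance limits behave at the endpoints", {
  # stationary fix pair with sig1 = 0: density is a mixture of gaussians
  # centred at z with variance between s^2/2 and s^2
  x <- seq(-5, 5, by = 0.25)
  s <- 1.2
  dens <- bb_step_density(c(0, 0), c(0, 0), 0, 1, 0, s, s, x, x,
                          alpha_steps = 501)
  dens <- dens / sum(dens)
  # radial second moment of the mixture: E sigma^2(a) = 2 * s^2 * 1/3... the
  # profile must sit between the two bounding gaussians
  lo <- dnorm(x, 0, sqrt(s^2 / 2)) %o% dnorm(x, 0, sqrt(s^2 / 2))
  hi <- dnorm(x, 0, s) %o% dnorm(x, 0, s)
  peak <- dens[x == 0, x == 0]
  expect_lt(peak, max(lo / sum(lo)))
  expect_gt(peak, max(hi / sum(hi)))
  expect_warning(bb_step_density(c(0, 0), c(1, 1), 5, 5, 1, 1, 1, x, x),
                 "nonpositive")
})

test_that("monthly UDs are normalized with nested isopleths", {
  p <- sim_track_params(n_animals = 1, n_days = 40, seed = 21,
                        outlier_fraction = 0)
  tr <- sda_filter(simulate_tracks(p))$track
  uds <- bb_ud(tr, sig1 = 2, cell_km = 2)
  expect_gt(length(uds), 1)
  for (ud in uds) {
    expect_lt(abs(sum(ud$z) - 1), 1e-6)
    i50 <- isopleth(ud, 0.50)
    i90 <- isopleth(ud, 0.90)
    expect_true(all(i90$mask[i50$mask]))
    expect_lte(i50$area_km2, i90$area_km2)
  }
})

test_that("single-step UD equals the normalized step density", {
  tr <- data.frame(animal_id = rep("A", 2),
                   date = as.POSIXct("2000-09-12", tz = "UTC") + c(0, 7200),
                   lon = c(-157, -156.9), lat = c(58, 58.02),
                   lc = c("3", "3"), hauled_out = c(FALSE, FALSE))
  uds <- bb_ud(tr, sig1 = 1, cell_km = 0.5, by_month = FALSE)
  expect_length(uds, 1)
  ud <- uds[[1]]
  ctr <- ud$center
  xy <- phocatools:::project_aeqd(tr$lon, tr$lat, ctr[1], ctr[2])
  dens <- bb_step_density(xy[1, ], xy[2, ], 0, 2, 1, 0.5, 0.5, ud$x, ud$y)
  expect_equal(ud$z, dens / sum(dens), tolerance = 1e-10)
})

test_that("isopleths pick the smallest high-density cell set", {
  # uniform UD over 100 cells: the 50% region is exactly 50 cells
  x <- seq(0.5, 9.5, by = 1)
  z <- matrix(0, 10, 10)
  z[1:10, 1:10] <- 1 / 100
  ud <- ud_grid(x, x, z, 1)
  expect_equal(sum(isopleth(ud, 0.5)$mask), 50)
  # level 1 takes every nonzero cell
  z2 <- matrix(0, 10, 10); z2[3:6, 3:6] <- 1 / 16
  ud2 <- ud_grid(x, x, z2, 1)
  expect_equal(sum(isopleth(ud2, 1.0)$mask), 16)
  expect_error(isopleth(ud, 1.5), "level")
  # gaussian UD: 90%/50% area ratio approximates ln(0.1)/ln(0.5)
  g <- gaussian_ud()
  ratio <- isopleth(g, 0.9)$area_km2 / isopleth(g, 0.5)$area_km2
  expect_equal(ratio, log(0.10) / log(0.50), tolerance = 0.03)
})

test_that("grid refinement and quadrature refinement are stable", {
  tr <- data.frame(animal_id = rep("A", 6),
                   date = as.POSIXct("2000-09-12", tz = "UTC") +
                     (0:5) * 10800,
                   lon = -157 + c(0, 0.03, 0.05, 0.09, 0.12, 0.15),
                   lat = 58 + c(0, 0.01, 0.03, 0.02, 0.05, 0.04),
                   lc = rep("1", 6), hauled_out = rep(FALSE, 6))
  a1 <- isopleth(bb_ud(tr, sig1 = 1, cell_km = 1, by_month = FALSE)[[1]],
                 0.5)$area_km2
  a2 <- isopleth(bb_ud(tr, sig1 = 1, cell_km = 0.5, by_month = FALSE)[[1]],
                 0.5)$area_km2
  expect_lt(abs(a2 - a1) / a1, 0.05)
  u25 <- bb_ud(tr, sig1 = 1, cell_km = 1, by_month = FALSE,
               alpha_steps = 25)[[1]]
  u50 <- bb_ud(tr, sig1 = 1, cell_km = 1, by_month = FALSE,
               alpha_steps = 50)[[1]]
  expect_lt(0.5 * sum(abs(u25$z - u50$z)), 1e-3)
})

test_that("sig1 likelihood responds to data as expected", {
  # coincident fixes: no motion, estimate collapses to the lower bound
  tr <- data.frame(animal_id = rep("A", 9),
                   date = as.POSIXct("2000-09-12", tz = "UTC") + (0:8) * 3600,
                   lon = rep(-157, 9), lat = rep(58, 9),
                   lc = rep("3", 9), hauled_out = rep(FALSE, 9))
  expect_warning(est <- estimate_sig1(tr, interval = c(0.01, 10)), "boundary")
  expect_equal(as.numeric(est), 0.01)
  # doubling sig2 with positions fixed lowers the recovered sig1
  set.seed(2)
  n <- 200
  xy <- apply(matrix(rnorm(2 * n, 0, 1.5), n, 2), 2, cumsum)
  ll <- phocatools:::unproject_aeqd(xy[, 1], xy[, 2], -157, 58)
  tr2 <- data.frame(animal_id = rep("A", n),
                    date = as.POSIXct("2000-09-12", tz = "UTC") +
                      (0:(n - 1)) * 3600,
                    lon = ll[, "lon"], lat = ll[, "lat"],
                    lc = rep("3", n), hauled_out = rep(FALSE, n))
  e_small <- estimate_sig1(tr2, error_model = argos_error_model())
  e_big <- estimate_sig1(tr2,
    error_model = argos_error_model(overrides = c("3" = 1.0)))
  expect_lt(as.numeric(e_big), as.numeric(e_small))
  expect_error(estimate_sig1(tr2[1:2, ]), "at least 3")
})

test_that("land subtraction intersects cell centers with polygons", {
  g <- gaussian_ud(sd_km = 2, cell_km = 0.5, half_w = 8)
  g$center <- c(lon = -157, lat = 58)
  iso <- isopleth(g, 0.9)
  km_per_deg_lat <- 111.19
  ring_far <- cbind(lon = c(-150, -149, -149, -150, -150),
                    lat = c(50, 50, 51, 51, 50))
  iso_far <- subtract_land(iso, list(ring_far))
  expect_equal(iso_far$area_km2_sea, iso$area_km2)
  # polygon covering everything: area goes to zero
  ring_all <- cbind(lon = c(-158, -156, -156, -158, -158),
                    lat = c(57.5, 57.5, 58.5, 58.5, 57.5))
  iso_all <- subtract_land(iso, list(ring_all))
  expect_equal(iso_all$area_km2_sea, 0)
  # half-plane east of center: area halves within one cell row
  east <- cbind(lon = c(-157, -155, -155, -157, -157),
                lat = c(57, 57, 59, 59, 57))
  iso_half <- subtract_land(iso, list(east))
  expect_lt(abs(iso_half$area_km2_sea - iso$area_km2 / 2),
            sqrt(iso$area_km2) * g$cell_km * 2)
})

test_that("overlap fractions cover identity, disjoint and containment", {
  x <- seq(0.5, 19.5, by = 1)
  z_a <- matrix(0, 20, 20); z_a[1:4, 1:4] <- 1 / 16
  z_b <- matrix(0, 20, 20); z_b[1:8, 1:8] <- 1 / 64
  z_c <- matrix(0, 20, 20); z_c[11:14, 11:14] <- 1 / 16
  ia <- isopleth(ud_grid(x, x, z_a, 1), 1.0)
  ib <- isopleth(ud_grid(x, x, z_b, 1), 1.0)
  ic <- isopleth(ud_grid(x, x, z_c, 1), 1.0)
  expect_equal(unname(overlap_fraction(ia, ia)), c(1, 1))
  expect_equal(unname(overlap_fraction(ia, ic)), c(0, 0))
  expect_equal(unname(overlap_fraction(ia, ib)), c(1, 0.25))
  other <- isopleth(ud_grid(x + 1, x, z_a, 1), 1.0)
  expect_error(overlap_fraction(ia, other), "grid")
})
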