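test_that("track simulator is deterministic and honors degenerate settings", {
  p <- sim_track_params(n_animals = 2, n_days = 10, seed = 1)
  expect_identical(simulate_tracks(p), simulate_tracks(p))

  zero_err <- setNames(rep(0, 7), c("3", "2", "1", "0", "A", "B", "Z"))
  p0 <- sim_track_params(n_animals = 2, n_days = 10, seed = 5,
                         class_error_km = zero_err, outlier_fraction = 0)
  tr <- simulate_tracks(p0)
  expect_equal(tr$lon, tr$true_lon, tolerance = 1e-9)
  expect_equal(tr$lat, tr$true_lat, tolerance = 1e-9)
  expect_false(any(tr$is_outlier))

  pb <- sim_track_params(n_animals = 1, n_days = 10, seed = 2,
                         class_probs = c("3" = 0, "2" = 0, "1" = 0, "0" = 0,
                                         "A" = 0, "B" = 1, "Z" = 0))
  expect_true(all(simulate_tracks(pb)$lc == "B"))

  expect_error(sim_track_params(haulout_sites = data.frame(lon = numeric(),
                                                           lat = numeric())),
               "haulout_sites")
  expect_error(sim_track_params(class_probs = c("3" = 1)), "class_probs")
})

test_that("simulated tracks are time-ordered with haul-outs at sites", {
  p <- sim_track_params(n_animals = 3, n_days = 15, seed = 8)
  tr <- simulate_tracks(p)
  for (id in unique(tr$animal_id)) {
    sub <- tr[tr$animal_id == id, ]
    expect_false(is.unsorted(as.numeric(sub$date)))
  }
  ho <- tr[tr$hauled_out, ]
  d_site <- sapply(seq_len(nrow(ho)), function(i) {
    min(great_circle_km(ho$true_lon[i], ho$true_lat[i],
                        p$haulout_sites$lon, p$haulout_sites$lat))
  })
  expect_true(all(d_site < 0.01)) # truth sits exactly on a site
  # outliers displaced by at least outlier_km from the error-free position
  out <- tr[tr$is_outlier, ]
  if (nrow(out) > 0) {
    d_true <- great_circle_km(out$lon, out$lat, out$true_lon, out$true_lat)
    expect_true(all(d_true >= p$outlier_km * 0.5))
  }
})

test_that("generated class frequencies converge to class_probs", {
  p <- sim_track_params(n_animals = 12, n_days = 110,
                        fix_rate_per_day = 10, seed = 33)
  tr <- simulate_tracks(p)
  expect_gt(nrow(tr), 10000)
  obs <- table(factor(tr$lc, levels = names(p$class_probs)))
  gof <- suppressWarnings(chisq.test(obs, p = p$class_probs))
  expect_gt(gof$p.value, 0.001)
})

test_that("dive simulator is deterministic, with focus rising in concentration", {
  cov <- simulate_covariates(4, seed = 1)
  p <- sim_dive_params(n_days = 3, seed = 10)
  expect_identical(simulate_dive_histograms(p, cov),
                   simulate_dive_histograms(p, cov))

  # single-bin limit
  p_inf <- sim_dive_params(n_days = 3, focus_concentration = Inf, seed = 4)
  h <- simulate_dive_histograms(p_inf, cov)
  per_int <- tapply(h$count > 0, interaction(h$animal_id, h$interval_start,
                                             h$bin_type), sum)
  expect_true(all(per_int <= 1))

  mean_focus <- function(conc, seed) {
    h <- simulate_dive_histograms(
      sim_dive_params(n_days = 13, focus_concentration = conc, seed = seed,
                      effects = list(species = 0, sex = 0, month = 0)),
      simulate_covariates(4, seed = 1))
    mean(dive_summary(h)$dive_focus, na.rm = TRUE)
  }
  f <- vapply(c(0.5, 4, 30), mean_focus, numeric(1), seed = 21)
  expect_true(all(diff(f) > 0))

  expect_error(sim_dive_params(dives_per_interval = 0), "positive")
  expect_error(sim_dive_params(depth_bin_edges = 1:5), "11")
})

test_that("genotype simulator builds HW populations, F1s and diagnostic loci", {
  p <- sim_genotype_params(n_loci = 12, alleles_per_locus = 4,
                           diagnostic = TRUE, n_per_species = c(8, 8),
                           n_f1 = 5, missing_rate = 0, seed = 2)
  g <- simulate_genotypes(p)
  expect_identical(g$genotypes, simulate_genotypes(p)$genotypes)
  half <- 2
  a_alleles <- 1:half
  b_alleles <- (half + 1):4
  pure_a <- g$truth$origin == "A"
  pure_b <- g$truth$origin == "B"
  expect_true(all(g$genotypes[pure_a, , ] %in% a_alleles))
  expect_true(all(g$genotypes[pure_b, , ] %in% b_alleles))
  # every F1 heterozygous species-A/species-B at every diagnostic locus
  f1 <- which(g$truth$origin == "F1")
  expect_length(f1, 5)
  for (i in f1) {
    expect_true(all(g$genotypes[i, , 1] %in% a_alleles))
    expect_true(all(g$genotypes[i, , 2] %in% b_alleles))
  }
  # missing entries flagged as NA at roughly the requested rate
  gm <- simulate_genotypes(sim_genotype_params(n_loci = 50,
                                               n_per_species = c(20, 20),
                                               missing_rate = 0.1, seed = 3))
  expect_lt(abs(mean(is.na(gm$genotypes)) - 0.1), 0.02)
  expect_error(sim_genotype_params(alleles_per_locus = 1), "at least 2")
})
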