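# shared synthetic repeated-measures table
sim_response_table <- function(n_animals, n_obs, beta_species = 0,
                               sd_animal = 0.3, sd_resid = 0.4, seed = 1,
                               phi = 0) {
  set.seed(seed)
  cov <- simulate_covariates(n_animals, seed = seed)
  d <- do.call(rbind, lapply(seq_len(n_animals), function(i) {
    data.frame(animal_id = cov$animal_id[i], species = cov$species[i],
               sex = cov$sex[i], mass = cov$mass[i],
               month = month_factor(as.Date("2000-09-15") +
                                      round(seq(0, 100, length.out = n_obs))),
               time_hr = seq(0, 100 * 24, length.out = n_obs),
               stringsAsFactors = FALSE)
  }))
  b <- rnorm(n_animals, 0, sd_animal)
  eps <- unlist(lapply(seq_len(n_animals), function(i) {
    if (phi > 0) as.vector(arima.sim(list(ar = phi), n_obs,
                                     sd = sd_resid * sqrt(1 - phi^2)))
    else rnorm(n_obs, 0, sd_resid)
  }))
  d$y <- 0.2 + beta_species * (d$species == "spotted") +
    b[as.integer(factor(d$animal_id))] + eps
  d
}

test_that("candidate sets follow the documented enumeration rules", {
  ud <- build_candidate_set("ud")
  dist <- build_candidate_set("distance")
  dive <- build_candidate_set("dive")
  labels <- function(s) vapply(s, `[[`, "", "label")

  # brute-force combinatorial count: all subsets of 4 mains (16) plus an
  # interaction variant for every subset containing species and month (4)
  mains <- c("species", "month", "sex", "mass")
  all_subsets <- unlist(lapply(0:4, function(k)
    utils::combn(mains, k, simplify = FALSE)), recursive = FALSE)
  n_inter <- sum(vapply(all_subsets, function(s)
    all(c("species", "month") %in% s), logical(1)))
  expect_length(ud, length(all_subsets) + n_inter)
  expect_length(dive, length(all_subsets) + n_inter)
  expect_length(dist, 1 + 4 + 6 + 4)

  expect_true("null" %in% labels(dist))
  expect_true("species" %in% labels(dist))
  # hierarchy: interaction only with both mains present
  for (s in c(ud, dive, dist)) {
    if ("species:month" %in% s$fixed) {
      expect_true(all(c("species", "month") %in% s$fixed))
    }
  }
  expect_true(all(vapply(dist, `[[`, "", "correlation") == "ar1"))
  expect_true(all(vapply(dive, `[[`, "", "correlation") == "car1"))
  expect_error(build_candidate_set("nope"))
})

test_that("AICc and weights match hand computation", {
  expect_equal(aicc(-100, 3, 50), 206.5217, tolerance = 1e-4)
  expect_equal(aicc(-100, 3, 50), 200 + 6 + 24 / 46, tolerance = 1e-10)
  # n -> infinity limit reduces to AIC
  expect_equal(aicc(-100, 3, 1e9), 206, tolerance = 1e-6)
  # monotone penalty in k at equal loglik
  expect_true(all(diff(aicc(rep(-50, 4), 1:4, 30)) > 0))
  expect_warning(bad <- aicc(-10, 10, 11), "unusable")
  expect_true(is.na(bad))

  expect_equal(aicc_weights(0), 1.0)
  expect_equal(aicc_weights(c(100, 102)), c(0.7311, 0.2689), tolerance = 1e-4)
  set.seed(8)
  for (rep in 1:20) {
    w <- aicc_weights(runif(sample(2:10, 1), 100, 150))
    expect_equal(sum(w), 1)
  }
})

test_that("model averaging follows natural averaging with unconditional SE", {
  mk <- function(label, beta, se, loglik, k = 3, n = 60) {
    structure(list(spec = list(fixed = names(beta), correlation = "none",
                               label = label),
                   label = label, loglik = loglik, k = k, n = n,
                   beta = beta, se = se), class = "fitted_model")
  }
  # identical estimates across models: average is that estimate
  f1 <- mk("a", c("(Intercept)" = 1, x = 2), c("(Intercept)" = 0.1, x = 0.2),
           loglik = -50)
  f2 <- mk("b", c("(Intercept)" = 1, x = 2), c("(Intercept)" = 0.1, x = 0.2),
           loglik = -51)
  avg <- model_average(list(f1, f2))
  expect_equal(avg$beta[avg$term == "x"], 2)
  expect_equal(avg$se[avg$term == "x"], 0.2)

  # two models with renormalized weights (0.75, 0.25), beta (1, 3) -> 1.5
  # choose logliks so raw AICc weights are exactly 3:1
  delta <- 2 * log(3)
  g1 <- mk("a", c(x = 1.0), c(x = 0.5), loglik = -50)
  g2 <- mk("b", c(x = 3.0), c(x = 0.5), loglik = -50 - delta / 2)
  avg2 <- model_average(list(g1, g2), coverage = 1)
  expect_equal(avg2$beta[avg2$term == "x"], 0.75 * 1 + 0.25 * 3,
               tolerance = 1e-10)
  # Burnham-Anderson unconditional SE
  bbar <- 1.5
  se_exp <- 0.75 * sqrt(0.25 + (1 - bbar)^2) + 0.25 * sqrt(0.25 + (3 - bbar)^2)
  expect_equal(avg2$se[avg2$term == "x"], se_exp, tolerance = 1e-10)
  expect_equal(avg2$lower[avg2$term == "x"], bbar - 1.96 * se_exp,
               tolerance = 1e-3)

  # a dominant model (weight >= 0.95) is the whole average
  h1 <- mk("big", c(x = 2.5), c(x = 0.3), loglik = -10)
  h2 <- mk("small", c(x = 9), c(x = 0.3), loglik = -40)
  avg3 <- model_average(list(h1, h2))
  expect_equal(avg3$beta[avg3$term == "x"], 2.5)
  expect_equal(avg3$n_models[avg3$term == "x"], 1)
})

test_that("null model on a single animal reduces to the response mean", {
  d <- data.frame(animal_id = rep("A", 20), y = rnorm(20, 5))
  fits <- fit_candidates(d, list(list(fixed = character(0),
                                      correlation = "none", label = "null")),
                         response = "y")
  expect_equal(unname(fits[[1]]$beta["(Intercept)"]), mean(d$y),
               tolerance = 1e-6)
})

test_that("AR1 structure is preferred on autocorrelated data", {
  wins <- 0
  for (seed in 1:10) {
    d <- sim_response_table(8, 30, seed = seed + 100, phi = 0.8)
    specs <- list(list(fixed = character(0), correlation = "none",
                       label = "null"),
                  list(fixed = character(0), correlation = "ar1",
                       label = "null+ar1"))
    fits <- fit_candidates(d, specs, "y")
    tab <- model_selection_table(fits)
    if (tab$model[1] == "null+ar1") wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("transform helpers clip boundaries and order months", {
  expect_equal(logit_focus(0.5, 10), 0)
  # p = 0 clips to 1/(4N)
  expect_equal(logit_focus(0, 10), log((1 / 40) / (1 - 1 / 40)))
  expect_equal(logit_focus(1, 10), -logit_focus(0, 10))
  m <- month_factor(as.Date(c("2000-09-15", "2000-10-15", "2000-12-01")))
  expect_equal(levels(m)[1], "Sep")
  expect_equal(as.character(m), c("Sep", "Oct", "Dec"))
})
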