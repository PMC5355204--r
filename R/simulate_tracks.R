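# Simulator for Argos-like seal tracks: a two-state process alternating
# haul-out bouts with at-sea trips (correlated random walk with a homeward
# drift), observed through class-specific isotropic positional error at
# irregular (Poisson) fix times. Every record carries its generating truth
# so downstream filters and estimators can be scored against it.

ARGOS_CLASSES <- c("3", "2", "1", "0", "A", "B", "Z")

# Class mix approximating an unfiltered Argos dataset dominated by
# low-quality codes; error SDs follow the 68th-percentile double-tagging
# estimates used for sig2 (Z has no published error; 15 km is a
# deliberately gross value since Z fixes are discarded unconditionally).
default_class_probs <- function() {
  c("3" = 0.046, "2" = 0.078, "1" = 0.135, "0" = 0.096,
    "A" = 0.247, "B" = 0.393, "Z" = 0.005)
}

default_class_error_km <- function() {
  c("3" = 0.5, "2" = 1, "1" = 1.2, "0" = 4.2, "A" = 6.2, "B" = 10.3,
    "Z" = 15)
}

#' Parameters for the Argos track simulator
#'
#' Builds a validated parameter set for [simulate_tracks()]. Defaults
#' emulate coastal seals tagged in early September: short foraging trips
#' from a couple of haul-out sites, ~8 fixes/day, and an Argos class mix
#' dominated by low-quality codes.
#'
#' @param n_animals Number of animals.
#' @param start_date Start of tracking (coerced to UTC `POSIXct`).
#' @param n_days Days of tracking per animal.
#' @param haulout_sites Data frame with columns `lon`, `lat` of terrestrial
#'   haul-out sites (at least one).
#' @param trip_rate Expected number of at-sea trips initiated per day.
#' @param trip_duration_days Mean at-sea bout duration (days, exponential).
#' @param trip_step_km Mean at-sea step length per typical inter-fix gap.
#' @param turn_concentration Directional persistence of the at-sea walk in
#'   \[0, 1\]; 1 is straight-line movement, 0 uncorrelated headings.
#' @param fix_rate_per_day Poisson rate of Argos fixes per day.
#' @param class_probs Named probability vector over classes 3,2,1,0,A,B,Z.
#' @param class_error_km Named map class -> isotropic positional error SD (km).
#' @param outlier_fraction Proportion of fixes displaced by a gross error.
#' @param outlier_km Minimum displacement magnitude of an outlier (km).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return An object of class `sim_track_params`.
#' @export
sim_track_params <- function(n_animals = 10,
                             start_date = "2000-09-12",
                             n_days = 60,
                             haulout_sites = data.frame(
                               lon = c(-157.40, -157.72),
                               lat = c(58.22, 57.60)),
                             trip_rate = 1.0,
                             trip_duration_days = 0.5,
                             trip_step_km = 6,
                             turn_concentration = 0.7,
                             fix_rate_per_day = 8,
                             class_probs = default_class_probs(),
                             class_error_km = default_class_error_km(),
                             outlier_fraction = 0.02,
                             outlier_km = 100,
                             seed = 1L) {
  if (!is.data.frame(haulout_sites) || nrow(haulout_sites) < 1 ||
      !all(c("lon", "lat") %in% names(haulout_sites))) {
    stop("haulout_sites must be a data frame with >= 1 row and columns lon, lat",
         call. = FALSE)
  }
  check_lonlat(haulout_sites$lon, haulout_sites$lat, "haul-out site")
  if (!setequal(names(class_probs), ARGOS_CLASSES)) {
    stop("class_probs must be named with classes ", paste(ARGOS_CLASSES, collapse = ","),
         call. = FALSE)
  }
  class_probs <- class_probs[ARGOS_CLASSES]
  if (abs(sum(class_probs) - 1) > 1e-8 || any(class_probs < 0)) {
    stop("class_probs must be nonnegative and sum to 1", call. = FALSE)
  }
  if (!all(ARGOS_CLASSES %in% names(class_error_km))) {
    stop("class_error_km must cover all classes", call. = FALSE)
  }
  stopifnot(n_animals >= 1, n_days > 0, trip_rate > 0,
            trip_duration_days > 0, trip_step_km >= 0,
            turn_concentration >= 0, turn_concentration <= 1,
            fix_rate_per_day > 0, outlier_fraction >= 0,
            outlier_fraction <= 1, outlier_km >= 0,
            all(class_error_km[ARGOS_CLASSES] >= 0))
  structure(list(
    n_animals = as.integer(n_animals),
    start_date = as.POSIXct(start_date, tz = "UTC"),
    n_days = n_days,
    haulout_sites = haulout_sites,
    trip_rate = trip_rate,
    trip_duration_days = trip_duration_days,
    trip_step_km = trip_step_km,
    turn_concentration = turn_concentration,
    fix_rate_per_day = fix_rate_per_day,
    class_probs = class_probs,
    class_error_km = class_error_km[ARGOS_CLASSES],
    outlier_fraction = outlier_fraction,
    outlier_km = outlier_km,
    seed = as.integer(seed)), class = "sim_track_params")
}

#' Simulate Argos seal tracks with known truth
#'
#' Generates per-animal location tables from a two-state movement process:
#' haul-out bouts (animal sits at a haul-out site) alternating with at-sea
#' trips modelled as a correlated random walk that drifts back toward the
#' home site as the trip ends. Fix times are a Poisson process; each fix
#' gets an Argos quality class and isotropic positional error with the
#' class-specific SD, applied in a local azimuthal-equidistant plane. A
#' fraction of fixes is additionally displaced by a gross outlier error.
#'
#' @param params A [sim_track_params()] object.
#' @return A `seal_tracks` data frame with columns `animal_id`, `date`
#'   (POSIXct UTC), `lon`, `lat` (observed), `lc` (class), `hauled_out`,
#'   `true_lon`, `true_lat`, `is_outlier`. Rows are time-ordered within
#'   animal.
#' @export
simulate_tracks <- function(params) {
  stopifnot(inherits(params, "sim_track_params"))
  p <- params
  set.seed(p$seed)
  animal_seeds <- sample.int(1e8L, p$n_animals)
  lon0 <- mean(p$haulout_sites$lon)
  lat0 <- mean(p$haulout_sites$lat)
  sites_xy <- project_aeqd(p$haulout_sites$lon, p$haulout_sites$lat, lon0, lat0)

  out <- vector("list", p$n_animals)
  for (i in seq_len(p$n_animals)) {
    set.seed(animal_seeds[i])
    out[[i]] <- simulate_one_track(p, i, sites_xy, lon0, lat0)
  }
  tracks <- do.call(rbind, out)
  rownames(tracks) <- NULL
  class(tracks) <- c("seal_tracks", "data.frame")
  attr(tracks, "projection_center") <- c(lon = lon0, lat = lat0)
  tracks
}

simulate_one_track <- function(p, animal_index, sites_xy, lon0, lat0) {
  mean_haul <- max(1 / p$trip_rate - p$trip_duration_days, 0.05)

  # alternating-renewal bout schedule, starting hauled out; animals are
  # site-faithful (one haul-out site per deployment), as coastal harbor
  # and spotted seals are over a season
  bout_start <- 0
  hauled <- TRUE
  sched <- list()
  site <- sample.int(nrow(sites_xy), 1)
  while (bout_start < p$n_days) {
    dur <- if (hauled) rexp(1, 1 / mean_haul) else rexp(1, 1 / p$trip_duration_days)
    sched[[length(sched) + 1]] <- list(start = bout_start, end = bout_start + dur,
                                       hauled = hauled, site = site)
    bout_start <- bout_start + dur
    hauled <- !hauled
  }

  # Poisson fix times over the deployment (days since start); whole
  # seconds, kept strictly increasing so speeds are always defined
  t <- cumsum(rexp(ceiling(p$n_days * p$fix_rate_per_day * 2) + 20,
                   p$fix_rate_per_day))
  t <- t[t < p$n_days]
  if (length(t) == 0) t <- runif(1, 0, p$n_days)
  t_sec <- round(t * 86400)
  for (j in seq_along(t_sec)[-1]) {
    if (t_sec[j] <= t_sec[j - 1]) t_sec[j] <- t_sec[j - 1] + 1
  }
  t <- t_sec / 86400
  n <- length(t)

  bout_of <- function(tt) {
    for (b in seq_along(sched)) {
      if (tt >= sched[[b]]$start && tt < sched[[b]]$end) return(b)
    }
    length(sched)
  }
  bid <- vapply(t, bout_of, integer(1))

  true_xy <- matrix(0, n, 2)
  hauled_out <- logical(n)
  dt_ref <- 1 / p$fix_rate_per_day
  heading_sd <- (1 - p$turn_concentration) * pi

  for (b in seq_along(sched)) {
    in_bout <- which(bid == b)
    bout <- sched[[b]]
    if (bout$hauled) {
      if (length(in_bout)) {
        true_xy[in_bout, 1] <- sites_xy[bout$site, 1]
        true_xy[in_bout, 2] <- sites_xy[bout$site, 2]
        hauled_out[in_bout] <- TRUE
      }
      next
    }
    if (!length(in_bout)) next
    # at-sea trip: a smooth foraging loop (outbound leg, lateral sweep,
    # return) plus bridged correlated-random-walk jitter, evaluated on a
    # fine time grid. The loop starts and ends at the haul-out site, so
    # the true path is continuous across bout boundaries and turnarounds
    # are gradual rather than hairpin reversals.
    start <- as.numeric(sites_xy[bout$site, ])
    dur <- bout$end - bout$start
    grid <- sort(unique(c(seq(bout$start, bout$end,
                              length.out = max(8, ceiling(dur / dt_ref) + 1)),
                          t[in_bout])))
    m <- length(grid)
    dts <- diff(grid)
    frac <- (grid - bout$start) / dur
    # loop envelope: maximum range set by cruising speed over the bout
    theta0 <- runif(1, -pi, pi)
    u_out <- c(sin(theta0), cos(theta0))
    u_lat <- c(cos(theta0), -sin(theta0))
    r_max <- max(p$trip_step_km / dt_ref * dur / pi, 0.1) * runif(1, 0.6, 1.4)
    w_lat <- sample(c(-1, 1), 1) * runif(1, 0.25, 0.5)
    base <- outer(r_max * sin(pi * frac), u_out) +
      outer(w_lat * r_max * sin(2 * pi * frac), u_lat)
    # bridged CRW jitter for small-scale irregularity (gamma steps: light
    # tail keeps true swim speeds physiological)
    steps <- rgamma(m - 1, shape = 2,
                    scale = pmax(0.25 * p$trip_step_km * dts / dt_ref,
                                 1e-9) / 2)
    theta <- runif(1, -pi, pi) +
      cumsum(rnorm(m - 1, 0, heading_sd * sqrt(pmax(dts, 1e-12) / dt_ref)))
    w <- rbind(c(0, 0),
               cbind(cumsum(steps * sin(theta)), cumsum(steps * cos(theta))))
    w <- w - outer(frac, w[m, ])
    path <- cbind(start[1] + base[, 1] + w[, 1],
                  start[2] + base[, 2] + w[, 2])
    at <- match(t[in_bout], grid)
    true_xy[in_bout, ] <- path[at, , drop = FALSE]
    hauled_out[in_bout] <- FALSE
  }

  lc <- sample(ARGOS_CLASSES, n, replace = TRUE, prob = p$class_probs)
  err_sd <- p$class_error_km[lc]
  obs_xy <- true_xy + cbind(rnorm(n, 0, err_sd), rnorm(n, 0, err_sd))
  is_outlier <- runif(n) < p$outlier_fraction
  n_out <- sum(is_outlier)
  if (n_out > 0) {
    mag <- p$outlier_km * (1 + rexp(n_out))
    ang <- runif(n_out, -pi, pi)
    obs_xy[is_outlier, ] <- obs_xy[is_outlier, , drop = FALSE] +
      cbind(mag * sin(ang), mag * cos(ang))
  }

  true_ll <- unproject_aeqd(true_xy[, 1], true_xy[, 2], lon0, lat0)
  obs_ll <- unproject_aeqd(obs_xy[, 1], obs_xy[, 2], lon0, lat0)

  data.frame(
    animal_id = sprintf("SIM%02d", animal_index),
    date = p$start_date + round(t * 86400),
    lon = obs_ll[, "lon"], lat = obs_ll[, "lat"],
    lc = lc, hauled_out = hauled_out,
    true_lon = true_ll[, "lon"], true_lat = true_ll[, "lat"],
    is_outlier = is_outlier,
    stringsAsFactors = FALSE)
}

#' Simulate per-animal covariates
#'
#' Animal-level covariates (species, sex, body mass) matching the study
#' design the analysis modules expect: two sibling species sampled at a
#' shared haul-out, with mass in the juvenile/subadult range.
#'
#' @param n_animals Number of animals.
#' @param prop_spotted Proportion assigned to the second species.
#' @param seed Integer seed.
#' @return Data frame with `animal_id`, `species` (factor harbor/spotted),
#'   `sex` (factor F/M), `mass` (kg).
#' @export
simulate_covariates <- function(n_animals = 10, prop_spotted = 0.3, seed = 1L) {
  set.seed(seed)
  n_spot <- round(n_animals * prop_spotted)
  species <- factor(c(rep("harbor", n_animals - n_spot), rep("spotted", n_spot)),
                    levels = c("harbor", "spotted"))
  data.frame(
    animal_id = sprintf("SIM%02d", seq_len(n_animals)),
    species = species,
    sex = factor(sample(c("F", "M"), n_animals, replace = TRUE),
                 levels = c("F", "M")),
    mass = round(pmin(pmax(rnorm(n_animals, 48, 12), 28), 75), 1),
    stringsAsFactors = FALSE)
}
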