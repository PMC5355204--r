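# Simulator for satellite-linked dive-recorder (SDR) histogram files:
# dive counts in 10 depth bins and 10 duration bins per 6-hr interval,
# multinomial within interval, with a Dirichlet-distributed bin profile
# whose peakedness is controlled by a single concentration parameter.

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Parameters for the dive-histogram simulator
#'
#' @param depth_bin_edges 11 strictly increasing depths (m) bounding the 10
#'   depth bins. The tag format fixes 10 bins; edges are programmable on
#'   real tags and have no canonical default.
#' @param duration_bin_edges 11 strictly increasing durations (min).
#' @param dives_per_interval Expected dives per 6-hr interval (Poisson mean).
#' @param focus_concentration Nonnegative concentration controlling how
#'   peaked the bin probabilities are around the focal bin. 0 gives
#'   symmetric Dirichlet noise around a flat profile; `Inf` puts every dive
#'   in the focal bin.
#' @param effects Named list of additive focal-bin shifts:
#'   `species` (applied to the second species), `sex` (applied to males),
#'   `month` (per month since the first month). Shifts are rounded and
#'   clamped to bins 1..10.
#' @param n_days Days of data per animal (4 intervals/day).
#' @param start_date First interval start (UTC).
#' @param base_focal_bin Focal bin for the reference animal in the first
#'   month.
#' @param seed Integer seed.
#' @return An object of class `sim_dive_params`.
#' @export
sim_dive_params <- function(depth_bin_edges = c(0, 4, 10, 20, 30, 40, 50, 60, 70, 85, 100),
                            duration_bin_edges = c(0, 1, 2, 3, 4, 5, 6, 8, 10, 15, 20),
                            dives_per_interval = 40,
                            focus_concentration = 8,
                            effects = list(species = 1, sex = 0, month = 0.5),
                            n_days = 60,
                            start_date = "2000-09-12",
                            base_focal_bin = 3,
                            seed = 1L) {
  for (edges in list(depth_bin_edges, duration_bin_edges)) {
    if (length(edges) != 11 || any(diff(edges) <= 0)) {
      stop("bin edges must be 11 strictly increasing values (10 bins)",
           call. = FALSE)
    }
  }
  if (dives_per_interval <= 0) {
    stop("dives_per_interval must be positive", call. = FALSE)
  }
  stopifnot(focus_concentration >= 0, n_days > 0,
            base_focal_bin >= 1, base_focal_bin <= 10)
  structure(list(
    depth_bin_edges = depth_bin_edges,
    duration_bin_edges = duration_bin_edges,
    dives_per_interval = dives_per_interval,
    focus_concentration = focus_concentration,
    effects = effects,
    n_days = n_days,
    start_date = as.POSIXct(start_date, tz = "UTC"),
    base_focal_bin = base_focal_bin,
    seed = as.integer(seed)), class = "sim_dive_params")
}

sim_one_histogram <- function(n_dives, focal, conc) {
  counts <- integer(10)
  if (n_dives == 0) return(counts)
  if (is.infinite(conc)) {
    counts[focal] <- n_dives
    return(counts)
  }
  p <- rdirichlet1(0.5 + conc * (seq_len(10) == focal))
  as.integer(rmultinom(1, n_dives, p))
}

#' Simulate binned dive histograms
#'
#' For every animal and 6-hr interval, draws a Poisson number of dives and
#' distributes them multinomially over 10 depth bins and 10 duration bins.
#' Bin probabilities are Dirichlet draws concentrated on a focal bin, whose
#' position shifts additively with species, sex and month, so the expected
#' dive-focus statistic rises with `focus_concentration` and carries the
#' configured covariate effects.
#'
#' @param params A [sim_dive_params()] object.
#' @param covariates Data frame with `animal_id`, `species`, `sex` (and
#'   optionally `mass`) per animal, e.g. from [simulate_covariates()].
#' @return A data frame in long histogram form: `animal_id`,
#'   `interval_start` (POSIXct UTC), `bin_type` (depth/duration),
#'   `bin_index` 1-10, `bin_lower`, `bin_upper`, `count`. The per-interval
#'   focal bin used for generation is attached as attribute `truth`.
#' @export
simulate_dive_histograms <- function(params, covariates) {
  stopifnot(inherits(params, "sim_dive_params"))
  need <- c("animal_id", "species", "sex")
  if (!is.data.frame(covariates) || !all(need %in% names(covariates))) {
    stop("covariates must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  p <- params
  set.seed(p$seed)
  n_int <- p$n_days * 4L
  interval_start <- p$start_date + (seq_len(n_int) - 1L) * 6 * 3600
  month0 <- as.integer(format(interval_start[1], "%m"))
  month_shift <- as.integer(format(interval_start, "%m")) - month0

  rows <- vector("list", nrow(covariates))
  truth <- vector("list", nrow(covariates))
  spp <- covariates$species
  spp2 <- levels(factor(spp))[min(2, nlevels(factor(spp)))]
  for (a in seq_len(nrow(covariates))) {
    shift <- p$effects$species * (as.character(spp[a]) == spp2) +
      p$effects$sex * (as.character(covariates$sex[a]) == "M")
    focal <- round(p$base_focal_bin + shift + p$effects$month * month_shift)
    focal <- pmin(pmax(focal, 1L), 10L)
    n_dives <- rpois(n_int, p$dives_per_interval)
    dep <- matrix(0L, n_int, 10)
    dur <- matrix(0L, n_int, 10)
    for (k in seq_len(n_int)) {
      dep[k, ] <- sim_one_histogram(n_dives[k], focal[k], p$focus_concentration)
      dur[k, ] <- sim_one_histogram(n_dives[k],
                                    pmin(pmax(focal[k] - 1L, 1L), 10L),
                                    p$focus_concentration)
    }
    id <- covariates$animal_id[a]
    rows[[a]] <- rbind(
      histogram_long(id, interval_start, "depth", p$depth_bin_edges, dep),
      histogram_long(id, interval_start, "duration", p$duration_bin_edges, dur))
    truth[[a]] <- data.frame(animal_id = id, interval_start = interval_start,
                             focal_bin = focal, n_dives = n_dives,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

histogram_long <- function(id, interval_start, type, edges, counts) {
  n_int <- length(interval_start)
  data.frame(
    animal_id = id,
    interval_start = rep(interval_start, each = 10),
    bin_type = type,
    bin_index = rep(seq_len(10), times = n_int),
    bin_lower = rep(edges[1:10], times = n_int),
    bin_upper = rep(edges[2:11], times = n_int),
    count = as.integer(t(counts)),
    stringsAsFactors = FALSE)
}
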