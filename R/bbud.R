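# Brownian bridge utilization distributions on a planar km grid.
#
# Each step between successive fixes contributes the alpha-quadrature
# average of bivariate normal densities along the conditioned bridge:
# at bridge fraction alpha, mean (1-a) z_i + a z_j and isotropic variance
#   sigma^2(a) = T a (1-a) sig1^2 + (1-a)^2 sig2_i^2 + a^2 sig2_j^2,
# with T the step duration. Contributions are duration-weighted and the
# grid is normalized to unit mass. All computation happens in a local
# azimuthal-equidistant plane (km) centered on the data.

#' Argos location-error model (sig2)
#'
#' Per-class isotropic location error SDs in km, following 68th-percentile
#' errors from GPS double-tagging: 3 = 0.5, 2 = 1, 1 = 1.2, 0 = 4.2,
#' A = 6.2, B = 10.3 km.
#'
#' @param overrides Optional named vector replacing individual classes.
#' @return Named numeric vector class -> sig2 (km).
#' @export
argos_error_model <- function(overrides = NULL) {
  m <- c("3" = 0.5, "2" = 1, "1" = 1.2, "0" = 4.2, "A" = 6.2, "B" = 10.3)
  if (!is.null(overrides)) {
    if (any(!names(overrides) %in% names(m)) || any(overrides <= 0)) {
      stop("error model overrides must be positive and named by class",
           call. = FALSE)
    }
    m[names(overrides)] <- overrides
  }
  m
}

#' Construct a utilization-distribution grid
#'
#' @param x,y Cell-center coordinates (km, strictly increasing, even
#'   spacing equal to `cell_km`).
#' @param z Matrix of cell probabilities (rows = y, cols = x); must be
#'   nonnegative and sum to 1 within 1e-6.
#' @param cell_km Cell size in km.
#' @param center Projection center `c(lon, lat)` (optional).
#' @param label Grouping label (animal / species / month), optional.
#' @return A `ud_grid` object.
#' @export
ud_grid <- function(x, y, z, cell_km, center = NULL, label = NULL) {
  stopifnot(is.matrix(z), nrow(z) == length(y), ncol(z) == length(x),
            cell_km > 0)
  if (any(z < 0) || abs(sum(z) - 1) > 1e-6) {
    stop("UD cell probabilities must be nonnegative and sum to 1 +- 1e-6",
         call. = FALSE)
  }
  structure(list(x = x, y = y, z = z, cell_km = cell_km, center = center,
                 label = label), class = "ud_grid")
}

#' @export
print.ud_grid <- function(x, ...) {
  cat(sprintf("Utilization distribution%s: %d x %d cells of %.2f km, mass %.6f\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              nrow(x$z), ncol(x$z), x$cell_km, sum(x$z)))
  invisible(x)
}

#' Brownian-bridge density contribution of a single step
#'
#' Evaluates the duration-weighted quadrature average of the bridge's
#' bivariate-normal position density over a grid of cell centers, for one
#' step from planar point `z1` at time `t1_hr` to `z2` at `t2_hr`.
#'
#' @param z1,z2 Planar endpoints, `c(x, y)` in km.
#' @param t1_hr,t2_hr Times in hours; `t2_hr > t1_hr`.
#' @param sig1 Motion variance parameter (km per sqrt hour).
#' @param sig2_1,sig2_2 Location error SDs of the two fixes (km).
#' @param x,y Grid cell-center coordinate vectors (km).
#' @param alpha_steps Number of midpoint quadrature points along the bridge.
#' @return Matrix (length(y) x length(x)) of unnormalized density,
#'   weighted by the step duration.
#' @export
bb_step_density <- function(z1, z2, t1_hr, t2_hr, sig1, sig2_1, sig2_2,
                            x, y, alpha_steps = 25) {
  if (t2_hr <= t1_hr) {
    warning("step with nonpositive duration skipped")
    return(matrix(0, length(y), length(x)))
  }
  stopifnot(alpha_steps >= 3, sig1 >= 0, sig2_1 > 0, sig2_2 > 0)
  T_hr <- t2_hr - t1_hr
  acc <- matrix(0, length(y), length(x))
  for (k in seq_len(alpha_steps)) {
    a <- (k - 0.5) / alpha_steps
    mu <- (1 - a) * z1 + a * z2
    s2 <- T_hr * a * (1 - a) * sig1^2 + (1 - a)^2 * sig2_1^2 + a^2 * sig2_2^2
    s <- sqrt(s2)
    acc <- acc + dnorm(y, mu[2], s) %o% dnorm(x, mu[1], s)
  }
  acc * (T_hr / alpha_steps)
}

# Likelihood of sig1 under the leave-one-out bridge scheme: every second
# fix is predicted from its two neighbours at its time fraction alpha.
sig1_loglik <- function(sig1, xy, t_hr, sig2) {
  n <- nrow(xy)
  idx <- seq(2, n - 1, by = 2)
  ll <- 0
  for (i in idx) {
    T_hr <- t_hr[i + 1] - t_hr[i - 1]
    if (T_hr <= 0) next
    a <- (t_hr[i] - t_hr[i - 1]) / T_hr
    mu <- (1 - a) * xy[i - 1, ] + a * xy[i + 1, ]
    s2 <- T_hr * a * (1 - a) * sig1^2 +
      (1 - a)^2 * sig2[i - 1]^2 + a^2 * sig2[i + 1]^2
    ll <- ll + dnorm(xy[i, 1], mu[1], sqrt(s2), log = TRUE) +
      dnorm(xy[i, 2], mu[2], sqrt(s2), log = TRUE)
  }
  ll
}

#' Maximum-likelihood estimate of the motion variance parameter sig1
#'
#' Leave-one-out likelihood: each odd-indexed fix is scored under the
#' Brownian bridge formed by its two neighbours (at its own time fraction),
#' and sig1 maximizes the summed log density over a search interval.
#'
#' @param track A single animal's time-sorted `seal_tracks` rows.
#' @param error_model Named class -> sig2 map, see [argos_error_model()].
#' @param interval Search interval for sig1 (km per sqrt hour).
#' @return The ML sig1 (numeric scalar), with attribute `loglik`. Warns
#'   and returns the boundary when the optimum lies on it (flat or
#'   degenerate likelihood).
#' @export
estimate_sig1 <- function(track, error_model = argos_error_model(),
                          interval = c(1e-3, 20)) {
  df <- as.data.frame(track)
  if (nrow(df) < 3) stop("need at least 3 fixes to estimate sig1", call. = FALSE)
  if (length(unique(df$animal_id)) > 1) {
    stop("estimate_sig1 expects a single animal's track", call. = FALSE)
  }
  lon0 <- mean(df$lon); lat0 <- mean(df$lat)
  xy <- project_aeqd(df$lon, df$lat, lon0, lat0)
  t_hr <- as.numeric(df$date - df$date[1], units = "hours")
  sig2 <- unname(error_model[as.character(df$lc)])
  if (any(is.na(sig2))) stop("error model missing a class present in track",
                             call. = FALSE)
  opt <- optimize(sig1_loglik, interval, xy = xy, t_hr = t_hr, sig2 = sig2,
                  maximum = TRUE, tol = 1e-6)
  est <- opt$maximum
  span <- diff(interval)
  if (est - interval[1] < 1e-4 * span || interval[2] - est < 1e-4 * span) {
    # boundary: report the better endpoint (optimize never returns one)
    ll_lo <- sig1_loglik(interval[1], xy, t_hr, sig2)
    ll_hi <- sig1_loglik(interval[2], xy, t_hr, sig2)
    est <- if (ll_lo >= ll_hi) interval[1] else interval[2]
    warning("sig1 likelihood maximized at the search boundary (", est, ")")
  }
  structure(est, loglik = sig1_loglik(est, xy, t_hr, sig2))
}

#' Brownian-bridge utilization distributions
#'
#' Accumulates per-step bridge densities for one animal's filtered track
#' (or a pooled multi-animal track set for group-level surfaces; steps are
#' never bridged across animals) onto a shared planar grid and normalizes
#' each partition to unit mass. Steps are partitioned by the calendar
#' month (UTC) of the step's start; steps longer than `max_gap_hr` are
#' excluded as uninformative.
#'
#' @param track Filtered `seal_tracks` rows.
#' @param sig1 Motion variance parameter (km per sqrt hour), e.g. from
#'   [estimate_sig1()]; either a scalar or a named vector per animal.
#' @param error_model Named class -> sig2 map (km).
#' @param cell_km Grid cell size (km).
#' @param alpha_steps Quadrature points per step.
#' @param max_gap_hr Longest step duration included (hours).
#' @param by_month Partition by calendar month of step start (UTC); if
#'   `FALSE` a single surface labelled `"all"` is returned.
#' @param margin_km Grid margin beyond the fixes; defaults to three times
#'   the largest sig2 in use.
#' @param grid Optional list `list(x, y, center)` forcing a shared grid
#'   geometry (e.g. to compare species on one grid).
#' @return A named list of `ud_grid` objects (one per month with >= 2
#'   fixes; months with fewer are omitted with a warning).
#' @export
bb_ud <- function(track, sig1, error_model = argos_error_model(),
                  cell_km = 1, alpha_steps = 25, max_gap_hr = 24,
                  by_month = TRUE, margin_km = NULL, grid = NULL) {
  df <- as.data.frame(track)
  if (nrow(df) < 2) stop("need at least 2 fixes", call. = FALSE)
  sig2_all <- unname(error_model[as.character(df$lc)])
  if (any(is.na(sig2_all))) stop("error model missing a class present in track",
                                 call. = FALSE)
  if (is.null(margin_km)) margin_km <- 3 * max(sig2_all)

  if (is.null(grid)) {
    lon0 <- mean(df$lon); lat0 <- mean(df$lat)
    xy <- project_aeqd(df$lon, df$lat, lon0, lat0)
    gx <- grid_axis(xy[, 1], cell_km, margin_km)
    gy <- grid_axis(xy[, 2], cell_km, margin_km)
  } else {
    lon0 <- grid$center[1]; lat0 <- grid$center[2]
    xy <- project_aeqd(df$lon, df$lat, lon0, lat0)
    gx <- grid$x; gy <- grid$y
  }

  # enumerate steps within animals
  steps <- list()
  for (id in unique(df$animal_id)) {
    idx <- which(df$animal_id == id)
    if (length(idx) < 2) next
    s1 <- sig1_for(sig1, id)
    for (k in seq_len(length(idx) - 1)) {
      i <- idx[k]; j <- idx[k + 1]
      T_hr <- as.numeric(df$date[j] - df$date[i], units = "hours")
      if (T_hr <= 0) {
        warning("step with nonpositive duration skipped (", id, ")")
        next
      }
      if (T_hr > max_gap_hr) next
      steps[[length(steps) + 1]] <- list(
        i = i, j = j, T_hr = T_hr, sig1 = s1,
        month = format(df$date[i], "%Y-%m", tz = "UTC"))
    }
  }
  if (length(steps) == 0) stop("no usable steps in track", call. = FALSE)
  months <- if (by_month) sort(unique(vapply(steps, `[[`, "", "month")))
            else "all"

  out <- list()
  for (m in months) {
    sel <- if (by_month) Filter(function(s) s$month == m, steps) else steps
    n_fix <- length(unique(unlist(lapply(sel, function(s) c(s$i, s$j)))))
    if (n_fix < 2) {
      warning("month ", m, " has fewer than 2 fixes; omitted")
      next
    }
    acc <- matrix(0, length(gy), length(gx))
    for (s in sel) {
      acc <- acc + bb_step_density(
        xy[s$i, ], xy[s$j, ], 0, s$T_hr, s$sig1,
        sig2_all[s$i], sig2_all[s$j], gx, gy, alpha_steps)
    }
    tot <- sum(acc)
    if (tot <= 0) {
      warning("month ", m, " produced zero mass on the grid; omitted")
      next
    }
    out[[m]] <- ud_grid(gx, gy, acc / tot, cell_km,
                        center = c(lon = lon0, lat = lat0), label = m)
  }
  out
}

grid_axis <- function(v, cell_km, margin_km) {
  lo <- floor((min(v) - margin_km) / cell_km) * cell_km
  hi <- ceiling((max(v) + margin_km) / cell_km) * cell_km
  seq(lo + cell_km / 2, hi, by = cell_km)
}

sig1_for <- function(sig1, id) {
  if (length(sig1) == 1 && is.null(names(sig1))) return(as.numeric(sig1))
  if (!id %in% names(sig1)) stop("no sig1 supplied for animal ", id,
                                 call. = FALSE)
  as.numeric(sig1[[id]])
}

#' Extract an isopleth (smallest region holding a probability level)
#'
#' Cells are ranked by descending probability (ties broken by row then
#' column) and accumulated until the cumulative mass reaches `level`.
#'
#' @param ud A `ud_grid`.
#' @param level Probability level in (0, 1\]; 0.50 and 0.90 are the usual
#'   home-range and range-use levels.
#' @return An `isopleth` object: cell mask, `area_km2`, and grid geometry;
#'   `area_km2_sea` is filled by [subtract_land()].
#' @export
isopleth <- function(ud, level) {
  stopifnot(inherits(ud, "ud_grid"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level > 1) {
    stop("level must be a single value in (0, 1]", call. = FALSE)
  }
  z <- ud$z
  rows <- as.vector(row(z)); cols <- as.vector(col(z)); zv <- as.vector(z)
  ord <- order(-zv, rows, cols)
  cum <- cumsum(zv[ord])
  k <- which(cum >= level - 1e-12)[1]
  chosen <- ord[seq_len(k)]
  chosen <- chosen[zv[chosen] > 0]
  mask <- matrix(FALSE, nrow(z), ncol(z))
  mask[chosen] <- TRUE
  structure(list(level = level, mask = mask,
                 area_km2 = sum(mask) * ud$cell_km^2,
                 area_km2_sea = NA_real_,
                 x = ud$x, y = ud$y, cell_km = ud$cell_km,
                 center = ud$center, label = ud$label),
            class = "isopleth")
}

#' @export
print.isopleth <- function(x, ...) {
  cat(sprintf("%.0f%% isopleth%s: %d cells, %.1f km2%s\n",
              100 * x$level,
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              sum(x$mask), x$area_km2,
              if (is.na(x$area_km2_sea)) ""
              else sprintf(" (%.1f km2 after land subtraction)", x$area_km2_sea)))
  invisible(x)
}

#' Subtract land from an isopleth
#'
#' Intersects the isopleth's cells with a set of land polygons and records
#' the land-free area. Cell membership is decided at the cell center under
#' the even-odd rule, so polygon holes subtract naturally.
#'
#' @param iso An `isopleth`.
#' @param land A `land_polygons` object from [read_land_geojson()], or a
#'   list of two-column lon/lat ring matrices.
#' @return The isopleth with `area_km2_sea` filled in and the land mask
#'   attached as `mask_sea`.
#' @export
subtract_land <- function(iso, land) {
  stopifnot(inherits(iso, "isopleth"))
  if (!length(land)) stop("land polygon set is empty", call. = FALSE)
  if (is.null(iso$center)) {
    stop("isopleth carries no projection center; cannot place polygons",
         call. = FALSE)
  }
  rings <- lapply(land, function(m) {
    if (!is.matrix(m) || ncol(m) < 2 || nrow(m) < 3) {
      stop("invalid land polygon ring", call. = FALSE)
    }
    project_aeqd(m[, 1], m[, 2], iso$center[1], iso$center[2])
  })
  idx <- which(iso$mask, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    iso$area_km2_sea <- 0
    iso$mask_sea <- iso$mask
    return(iso)
  }
  px <- iso$x[idx[, 2]]
  py <- iso$y[idx[, 1]]
  on_land <- points_in_rings(px, py, rings)
  mask_sea <- iso$mask
  mask_sea[idx[on_land, , drop = FALSE]] <- FALSE
  iso$mask_sea <- mask_sea
  iso$area_km2_sea <- sum(mask_sea) * iso$cell_km^2
  iso
}

#' Overlap fractions between two isopleths
#'
#' Shared-area fractions on a common grid: the intersection area divided
#' by each isopleth's own area.
#'
#' @param iso_a,iso_b `isopleth` objects on identical grid geometry.
#' @param use_sea If `TRUE`, use land-subtracted masks (both must have
#'   been through [subtract_land()]).
#' @return Named numeric vector `c(frac_a, frac_b)` =
#'   (area(a&b)/area(a), area(a&b)/area(b)); `NaN` for an empty isopleth.
#' @export
overlap_fraction <- function(iso_a, iso_b, use_sea = FALSE) {
  stopifnot(inherits(iso_a, "isopleth"), inherits(iso_b, "isopleth"))
  if (!isTRUE(all.equal(iso_a$x, iso_b$x)) ||
      !isTRUE(all.equal(iso_a$y, iso_b$y)) ||
      iso_a$cell_km != iso_b$cell_km) {
    stop("isopleths are not on the same grid geometry", call. = FALSE)
  }
  ma <- if (use_sea) iso_a$mask_sea else iso_a$mask
  mb <- if (use_sea) iso_b$mask_sea else iso_b$mask
  if (use_sea && (is.null(ma) || is.null(mb))) {
    stop("use_sea requires both isopleths to have been through subtract_land",
         call. = FALSE)
  }
  inter <- sum(ma & mb)
  c(frac_a = inter / sum(ma), frac_b = inter / sum(mb))
}
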