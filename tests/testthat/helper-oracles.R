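# Independent reference implementations used as test oracles. These are
# deliberately naive (plain loops, own spherical trig) and share no code
# with the package internals.

# haversine distance, km, R = 6371
oracle_haversine <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

# initial great-circle bearing from point 1 to point 2, degrees
oracle_bearing <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  y <- sin((lon2 - lon1) * rad) * cos(lat2 * rad)
  x <- cos(lat1 * rad) * sin(lat2 * rad) -
    sin(lat1 * rad) * cos(lat2 * rad) * cos((lon2 - lon1) * rad)
  (atan2(y, x) / rad) %% 360
}

# turning angle at b: deviation of b->c from the continuation of a->b,
# using the reverse-bearing identity for the arrival direction at b
oracle_turn_angle <- function(lon_a, lat_a, lon_b, lat_b, lon_c, lat_c) {
  incoming <- (oracle_bearing(lon_b, lat_b, lon_a, lat_a) + 180) %% 360
  outgoing <- oracle_bearing(lon_b, lat_b, lon_c, lat_c)
  d <- abs(outgoing - incoming) %% 360
  if (d > 180) d <- 360 - d
  d
}

# Naive reimplementation of the SDA filter contract for a single animal:
# drop duplicate timestamps keeping the better class, drop Z, then repeat
# (speed pass, angle pass) until stable. Everything recomputed from
# scratch with the oracle trig above.
oracle_sda_filter <- function(df, vmax = 2.5, keep_km = 5,
                              rules = list(c(2.5, 165), c(5, 155))) {
  quality <- c("3", "2", "1", "0", "A", "B", "Z")
  if (anyDuplicated(df$date)) {
    ord <- order(as.numeric(df$date), match(df$lc, quality))
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(as.numeric(df$date)), , drop = FALSE]
  }
  df <- df[df$lc != "Z", , drop = FALSE]
  repeat {
    changed <- FALSE
    # speed pass: compare to previous retained fix
    if (nrow(df) >= 2) {
      keep <- rep(TRUE, nrow(df))
      last <- 1
      for (i in 2:nrow(df)) {
        d <- oracle_haversine(df$lon[last], df$lat[last], df$lon[i], df$lat[i])
        dt <- as.numeric(df$date[i]) - as.numeric(df$date[last])
        v <- if (dt > 0) d * 1000 / dt else Inf
        if (v > vmax && d > keep_km) {
          keep[i] <- FALSE
          changed <- TRUE
        } else {
          last <- i
        }
      }
      df <- df[keep, , drop = FALSE]
    }
    # angle pass: previous retained neighbour, immediate next neighbour
    if (nrow(df) >= 3) {
      keep <- rep(TRUE, nrow(df))
      prev <- 1
      for (i in 2:(nrow(df) - 1)) {
        leg <- oracle_haversine(df$lon[prev], df$lat[prev], df$lon[i], df$lat[i])
        same_ab <- df$lon[prev] == df$lon[i] && df$lat[prev] == df$lat[i]
        same_bc <- df$lon[i] == df$lon[i + 1] && df$lat[i] == df$lat[i + 1]
        bad <- FALSE
        if (!same_ab && !same_bc) {
          ang <- oracle_turn_angle(df$lon[prev], df$lat[prev],
                                   df$lon[i], df$lat[i],
                                   df$lon[i + 1], df$lat[i + 1])
          for (r in rules) {
            if (leg > r[1] && ang > r[2]) bad <- TRUE
          }
        }
        if (bad) {
          keep[i] <- FALSE
          changed <- TRUE
        } else {
          prev <- i
        }
      }
      df <- df[keep, , drop = FALSE]
    }
    if (!changed) return(df)
  }
}

# random jittery test track around a point, some fixes far-flung
random_test_track <- function(n, seed) {
  set.seed(seed)
  base_lon <- -157 + runif(1, -1, 1)
  base_lat <- 58 + runif(1, -0.5, 0.5)
  t <- as.POSIXct("2000-09-12", tz = "UTC") +
    cumsum(round(rexp(n, 1 / 7200)))
  lon <- base_lon + cumsum(rnorm(n, 0, 0.03))
  lat <- base_lat + cumsum(rnorm(n, 0, 0.015))
  big <- runif(n) < 0.12
  lon[big] <- lon[big] + runif(sum(big), -1.5, 1.5)
  lat[big] <- lat[big] + runif(sum(big), -0.8, 0.8)
  data.frame(
    animal_id = "T1", date = t, lon = lon, lat = lat,
    lc = sample(c("3", "2", "1", "0", "A", "B", "Z"), n, replace = TRUE,
                prob = c(0.1, 0.1, 0.15, 0.1, 0.2, 0.3, 0.05)),
    hauled_out = FALSE, stringsAsFactors = FALSE)
}

# random 10-bin dive histogram with at least 2 dives
random_histogram <- function(seed) {
  set.seed(seed)
  n <- sample(2:60, 1)
  as.vector(rmultinom(1, n, prob = rgamma(10, shape = runif(1, 0.2, 3))))
}

# probability two dives drawn without replacement share a bin, by
# explicit enumeration over the expanded dive list
oracle_same_bin_probability <- function(counts) {
  bins <- rep(seq_along(counts), counts)
  n <- length(bins)
  same <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && bins[i] == bins[j]) same <- same + 1
    }
  }
  same / (n * (n - 1))
}
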