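# Speed-distance-angle (SDA) filter for Argos locations. Three rules:
# (1) class-Z fixes are always removed; (2) a fix implying a swim speed
# above the maximum from the previous *retained* fix is removed unless it
# lies within the keep radius of that fix; (3) an interior fix whose
# turning angle exceeds a rule's angle while the incoming leg exceeds the
# rule's length is removed. Speed and angle passes repeat until no fix is
# removed (fixpoint), so secondary spikes uncovered by earlier removals
# are also caught.

LC_QUALITY_ORDER <- c("3", "2", "1", "0", "A", "B", "Z")

#' Speed-distance-angle filter for Argos tracks
#'
#' Removes implausible fixes from time-sorted Argos tracks. Exactly
#' simultaneous duplicate timestamps are resolved first by keeping the
#' higher-quality class. Class-Z fixes are removed unconditionally. Then,
#' iterated to a fixpoint per animal: a speed pass removes each fix whose
#' implied speed from the previous retained fix exceeds `max_speed_mps`
#' unless it lies within `keep_radius_km` of that fix (the first fix is
#' exempt); an angle pass removes each interior fix whose turning angle
#' exceeds an `angle_rules` threshold while the incoming retained leg
#' exceeds that rule's length (first and last fixes are exempt — no angle
#' is defined there). Haul-out fixes are filtered like any other fix.
#' Retained fixes keep their original order and coordinates.
#'
#' @param track A `seal_tracks` data frame (possibly several animals),
#'   time-sorted within animal.
#' @param max_speed_mps Maximum plausible swim speed (m/s).
#' @param keep_radius_km Distance under which a high-speed fix is retained
#'   (fast fixes recorded in quick succession).
#' @param angle_rules List of `c(leg_km, angle_deg)` pairs; a fix is
#'   removed when its angle exceeds `angle_deg` and the incoming leg
#'   exceeds `leg_km` for any rule.
#' @return A list with `track` (retained `seal_tracks`) and `report`
#'   (a `filter_report`).
#' @export
sda_filter <- function(track,
                       max_speed_mps = 2.5,
                       keep_radius_km = 5,
                       angle_rules = list(c(2.5, 165), c(5, 155))) {
  df <- as.data.frame(track)
  need <- c("animal_id", "date", "lon", "lat", "lc")
  if (!all(need %in% names(df))) {
    stop("track must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  n_input <- nrow(df)
  report <- empty_filter_report(n_input)
  if (n_input == 0) {
    cls <- class(track)
    return(list(track = track, report = report))
  }
  keep_all <- logical(0)
  out <- vector("list", 0)
  for (id in unique(df$animal_id)) {
    sub <- df[df$animal_id == id, , drop = FALSE]
    if (is.unsorted(as.numeric(sub$date))) {
      stop("track for animal ", id, " is not time-sorted", call. = FALSE)
    }
    res <- sda_filter_one(sub, max_speed_mps, keep_radius_km, angle_rules)
    out[[length(out) + 1]] <- res$track
    report <- merge_filter_reports(report, res$report)
  }
  retained <- do.call(rbind, out)
  rownames(retained) <- NULL
  class(retained) <- c("seal_tracks", "data.frame")
  report$removed_fraction <-
    if (n_input > 0) (n_input - nrow(retained)) / n_input else 0
  list(track = retained, report = report)
}

sda_filter_one <- function(sub, max_speed_mps, keep_radius_km, angle_rules) {
  removed_class <- function(lc) {
    tab <- table(factor(lc, levels = LC_QUALITY_ORDER))
    as.numeric(tab)
  }
  rep <- empty_filter_report(nrow(sub))

  # duplicate timestamps: keep the higher-quality class
  if (anyDuplicated(sub$date)) {
    qual <- match(sub$lc, LC_QUALITY_ORDER)
    ord <- order(as.numeric(sub$date), qual)
    sub_o <- sub[ord, , drop = FALSE]
    keep <- !duplicated(as.numeric(sub_o$date))
    dropped <- sub_o[!keep, , drop = FALSE]
    rep$n_removed_dup <- nrow(dropped)
    rep$removed_by_class <- rep$removed_by_class + removed_class(dropped$lc)
    sub <- sub_o[keep, , drop = FALSE]
  }

  is_z <- sub$lc == "Z"
  rep$n_removed_z <- sum(is_z)
  rep$removed_by_class <- rep$removed_by_class + removed_class(sub$lc[is_z])
  sub <- sub[!is_z, , drop = FALSE]

  repeat {
    removed_any <- FALSE

    # speed pass: forward scan against previous retained fix
    n <- nrow(sub)
    if (n >= 2) {
      keep <- rep(TRUE, n)
      last <- 1L
      for (i in 2:n) {
        d_km <- great_circle_km(sub$lon[last], sub$lat[last],
                                sub$lon[i], sub$lat[i])
        dt_s <- as.numeric(sub$date[i]) - as.numeric(sub$date[last])
        sp <- if (dt_s > 0) d_km * 1000 / dt_s else Inf
        if (sp > max_speed_mps && d_km > keep_radius_km) {
          keep[i] <- FALSE
        } else {
          last <- i
        }
      }
      if (any(!keep)) {
        removed_any <- TRUE
        rep$n_removed_speed <- rep$n_removed_speed + sum(!keep)
        rep$removed_by_class <- rep$removed_by_class +
          removed_class(sub$lc[!keep])
        sub <- sub[keep, , drop = FALSE]
      }
    }

    # angle pass: forward scan; previous neighbor is the last retained fix,
    # next neighbor the immediately following fix of the current sequence
    n <- nrow(sub)
    if (n >= 3) {
      keep <- rep(TRUE, n)
      prev <- 1L
      for (i in 2:(n - 1)) {
        leg <- great_circle_km(sub$lon[prev], sub$lat[prev],
                               sub$lon[i], sub$lat[i])
        ang <- turning_angle_deg(sub$lon[prev], sub$lat[prev],
                                 sub$lon[i], sub$lat[i],
                                 sub$lon[i + 1], sub$lat[i + 1])
        bad <- FALSE
        if (!is.na(ang)) {
          for (rule in angle_rules) {
            if (leg > rule[1] && ang > rule[2]) bad <- TRUE
          }
        }
        if (bad) keep[i] <- FALSE else prev <- i
      }
      if (any(!keep)) {
        removed_any <- TRUE
        rep$n_removed_angle <- rep$n_removed_angle + sum(!keep)
        rep$removed_by_class <- rep$removed_by_class +
          removed_class(sub$lc[!keep])
        sub <- sub[keep, , drop = FALSE]
      }
    }

    if (!removed_any) break
  }
  list(track = sub, report = rep)
}

empty_filter_report <- function(n_input) {
  structure(list(
    n_input = n_input,
    n_removed_dup = 0L,
    n_removed_z = 0L,
    n_removed_speed = 0L,
    n_removed_angle = 0L,
    removed_fraction = 0,
    removed_by_class = setNames(numeric(length(LC_QUALITY_ORDER)),
                                LC_QUALITY_ORDER)),
    class = "filter_report")
}

merge_filter_reports <- function(a, b) {
  a$n_removed_dup <- a$n_removed_dup + b$n_removed_dup
  a$n_removed_z <- a$n_removed_z + b$n_removed_z
  a$n_removed_speed <- a$n_removed_speed + b$n_removed_speed
  a$n_removed_angle <- a$n_removed_angle + b$n_removed_angle
  a$removed_by_class <- a$removed_by_class + b$removed_by_class
  a
}

#' @export
print.filter_report <- function(x, ...) {
  total <- x$n_removed_dup + x$n_removed_z + x$n_removed_speed +
    x$n_removed_angle
  cat("SDA filter report\n")
  cat(sprintf("  input fixes: %d\n", x$n_input))
  cat(sprintf("  removed: %d (%.1f%%)  [dup %d, Z %d, speed %d, angle %d]\n",
              total, 100 * x$removed_fraction, x$n_removed_dup,
              x$n_removed_z, x$n_removed_speed, x$n_removed_angle))
  nz <- x$removed_by_class[x$removed_by_class > 0]
  if (length(nz)) {
    cat("  removals by class:",
        paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert a filter report to a one-row data frame
#'
#' @param x A `filter_report`.
#' @param ... Unused.
#' @export
as.data.frame.filter_report <- function(x, ...) {
  data.frame(n_input = x$n_input, n_removed_dup = x$n_removed_dup,
             n_removed_z = x$n_removed_z, n_removed_speed = x$n_removed_speed,
             n_removed_angle = x$n_removed_angle,
             removed_fraction = x$removed_fraction)
}
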