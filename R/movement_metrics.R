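# Distance-from-haul-out metrics: at-sea bouts are maximal runs of
# at-sea fixes delimited by hauled-out fixes, anchored at the last
# haul-out fix preceding the bout; distances are great-circle from the
# anchor to every fix in the bout.

#' Segment a track into at-sea bouts
#'
#' Maximal runs of at-sea fixes delimited by hauled-out fixes. Each bout
#' is anchored at the last haul-out fix that precedes it. A leading
#' at-sea run with no prior haul-out has no anchor and is dropped with a
#' warning.
#'
#' @param track A `seal_tracks` data frame (one or more animals) with a
#'   logical `hauled_out` column, time-sorted within animal.
#' @return A list of `at_sea_bout` objects, each a list with `animal_id`,
#'   `bout_id`, `anchor` (one-row data frame), and `fixes` (data frame of
#'   the bout's at-sea fixes). A track with no haul-out fix yields no
#'   bouts, with a warning.
#' @export
segment_bouts <- function(track) {
  df <- as.data.frame(track)
  if (!"hauled_out" %in% names(df)) {
    stop("track must carry a hauled_out flag", call. = FALSE)
  }
  bouts <- list()
  for (id in unique(df$animal_id)) {
    sub <- df[df$animal_id == id, , drop = FALSE]
    if (is.unsorted(as.numeric(sub$date))) {
      stop("track for animal ", id, " is not time-sorted", call. = FALSE)
    }
    if (!any(sub$hauled_out)) {
      warning("animal ", id, " has no haul-out fix; no bouts segmented")
      next
    }
    r <- rle(sub$hauled_out)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    bout_id <- 0L
    for (k in seq_along(r$values)) {
      if (r$values[k]) next # haul-out run
      if (k == 1) {
        warning("animal ", id,
                ": leading at-sea fixes precede any haul-out; dropped")
        next
      }
      bout_id <- bout_id + 1L
      anchor_idx <- ends[k - 1] # last haul-out fix before the bout
      bouts[[length(bouts) + 1]] <- structure(list(
        animal_id = id,
        bout_id = bout_id,
        anchor = sub[anchor_idx, , drop = FALSE],
        fixes = sub[starts[k]:ends[k], , drop = FALSE]),
        class = "at_sea_bout")
    }
  }
  bouts
}

#' Distances from the last haul-out within at-sea bouts
#'
#' Great-circle distance (km) from each bout's anchoring haul-out fix to
#' every at-sea fix in the bout, plus a flag for the fix at maximum
#' distance.
#'
#' @param bouts A list of `at_sea_bout` objects from [segment_bouts()],
#'   or a single bout.
#' @return Data frame with `animal_id`, `bout_id`, `date`, `dist_km`,
#'   `is_bout_max` (one `TRUE` per bout; the earliest in case of exact
#'   ties).
#' @export
haulout_distances <- function(bouts) {
  if (inherits(bouts, "at_sea_bout")) bouts <- list(bouts)
  if (length(bouts) == 0) {
    return(data.frame(animal_id = character(), bout_id = integer(),
                      date = as.POSIXct(character(), tz = "UTC"),
                      dist_km = numeric(), is_bout_max = logical()))
  }
  rows <- lapply(bouts, function(b) {
    stopifnot(inherits(b, "at_sea_bout"), nrow(b$fixes) >= 1)
    d <- great_circle_km(b$anchor$lon, b$anchor$lat, b$fixes$lon, b$fixes$lat)
    is_max <- seq_along(d) == which.max(d)
    data.frame(animal_id = b$animal_id, bout_id = b$bout_id,
               date = b$fixes$date, dist_km = d, is_bout_max = is_max,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
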