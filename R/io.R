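# Readers and writers for the plain-text interchange formats used across
# the pipeline: Argos location CSV, dive-histogram CSV, STRUCTURE-dialect
# genotype text, GeoJSON land polygons and ESRI ASCII grids.

#' Write / read the Argos location CSV dialect
#'
#' Columns: `animal_id`, `date` (ISO-8601 UTC), `lon`, `lat`, `lc`
#' (3/2/1/0/A/B/Z), `hauled_out` (0/1). Truth columns from the simulator
#' (`true_lon`, `true_lat`, `is_outlier`) are preserved when present.
#'
#' @param tracks A `seal_tracks` data frame (or compatible).
#' @param path File path.
#' @return `read_locations()` returns a `seal_tracks` data frame.
#' @export
write_locations <- function(tracks, path) {
  df <- as.data.frame(tracks)
  df$date <- format(df$date, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  df$hauled_out <- as.integer(df$hauled_out)
  if ("is_outlier" %in% names(df)) df$is_outlier <- as.integer(df$is_outlier)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_locations
#' @export
read_locations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = c(lc = "character"))
  df$date <- as.POSIXct(df$date, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  df$hauled_out <- as.logical(df$hauled_out)
  if ("is_outlier" %in% names(df)) df$is_outlier <- as.logical(df$is_outlier)
  class(df) <- c("seal_tracks", "data.frame")
  df
}

#' Write / read the dive-histogram CSV dialect
#'
#' Long form: `animal_id`, `interval_start` (ISO-8601 UTC), `bin_type`
#' (depth/duration), `bin_index` 1-10, `bin_lower`, `bin_upper`, `count`.
#'
#' @param hist Long histogram data frame from [simulate_dive_histograms()].
#' @param path File path.
#' @export
write_dive_histograms <- function(hist, path) {
  df <- as.data.frame(hist)
  df$interval_start <- format(df$interval_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dive_histograms
#' @export
read_dive_histograms <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$interval_start <- as.POSIXct(df$interval_start,
                                  format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  df
}

#' Write / read STRUCTURE-dialect genotype files
#'
#' Two rows per individual (one per allele copy), whitespace-separated:
#' individual label, then one integer allele call per locus, -9 for
#' missing.
#'
#' @param sim A `sim_genotypes` object, or a list with elements `genotypes`
#'   (ind x loci x 2 array) and `truth$id`.
#' @param path File path.
#' @return `read_structure()` returns an individuals x loci x 2 integer
#'   array with `NA` for missing, individual labels as rownames on the
#'   first dimension.
#' @export
write_structure <- function(sim, path) {
  geno <- sim$genotypes
  ids <- sim$truth$id
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(dim(geno)[1])) {
    for (a in 1:2) {
      calls <- geno[i, , a]
      calls[is.na(calls)] <- -9L
      writeLines(paste(c(ids[i], calls), collapse = " "), con)
    }
  }
  invisible(path)
}

#' @rdname write_structure
#' @export
read_structure <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 2 != 0) {
    stop("STRUCTURE file must contain two rows per individual", call. = FALSE)
  }
  parts <- strsplit(trimws(lines), "\\s+")
  n_ind <- length(lines) / 2
  n_loci <- length(parts[[1]]) - 1
  geno <- array(NA_integer_, dim = c(n_ind, n_loci, 2))
  ids <- character(n_ind)
  for (i in seq_len(n_ind)) {
    for (a in 1:2) {
      p <- parts[[2 * (i - 1) + a]]
      if (length(p) != n_loci + 1) {
        stop("inconsistent locus count in STRUCTURE file", call. = FALSE)
      }
      ids[i] <- p[1]
      calls <- as.integer(p[-1])
      calls[calls == -9L] <- NA_integer_
      geno[i, , a] <- calls
    }
  }
  dimnames(geno) <- list(ids, NULL, NULL)
  geno
}

#' Read land polygons from GeoJSON
#'
#' Parses Polygon / MultiPolygon geometries (WGS84 lon/lat) from a GeoJSON
#' file or Feature(Collection) into a list of rings. Holes are retained;
#' containment tests use the even-odd rule, so holes subtract naturally.
#'
#' @param path Path to a GeoJSON file.
#' @return A list of class `land_polygons`; each element is a two-column
#'   matrix (`lon`, `lat`) of one ring.
#' @export
read_land_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rings <- list()
  add_geom <- function(geom) {
    if (is.null(geom$type)) stop("invalid GeoJSON geometry", call. = FALSE)
    ring_mat <- function(r) {
      m <- do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
      colnames(m) <- c("lon", "lat")
      m
    }
    if (geom$type == "Polygon") {
      for (r in geom$coordinates) rings[[length(rings) + 1]] <<- ring_mat(r)
    } else if (geom$type == "MultiPolygon") {
      for (poly in geom$coordinates) {
        for (r in poly) rings[[length(rings) + 1]] <<- ring_mat(r)
      }
    } else {
      stop("unsupported GeoJSON geometry type: ", geom$type, call. = FALSE)
    }
  }
  if (identical(gj$type, "FeatureCollection")) {
    for (f in gj$features) add_geom(f$geometry)
  } else if (identical(gj$type, "Feature")) {
    add_geom(gj$geometry)
  } else {
    add_geom(gj)
  }
  for (m in rings) check_lonlat(m[, "lon"], m[, "lat"], "land polygon vertex")
  structure(rings, class = "land_polygons")
}

# Even-odd ray-casting point-in-polygon over a set of rings. Points and
# rings share one planar coordinate system. Vectorised over points.
points_in_rings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- length(x)
    if (n < 3) next
    j <- n
    for (k in seq_len(n)) {
      crosses <- ((y[k] > py) != (y[j] > py)) &
        (px < (x[j] - x[k]) * (py - y[k]) / (y[j] - y[k]) + x[k])
      inside <- xor(inside, crosses)
      j <- k
    }
  }
  inside
}

#' Write a utilization distribution as an ESRI ASCII grid
#'
#' Cell probabilities on the planar (km) analysis grid; coordinates are the
#' local azimuthal-equidistant plane of the UD, with the projection center
#' recorded in a comment-free companion attribute (grids are interchange
#' artifacts, not georeferenced products).
#'
#' @param ud A `ud_grid` object.
#' @param path File path.
#' @export
write_esri_ascii <- function(ud, path) {
  stopifnot(inherits(ud, "ud_grid"))
  z <- ud$z
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(z)),
    paste("nrows", nrow(z)),
    paste("xllcorner", min(ud$x) - ud$cell_km / 2),
    paste("yllcorner", min(ud$y) - ud$cell_km / 2),
    paste("cellsize", ud$cell_km),
    "NODATA_value -9999"), con)
  for (r in rev(seq_len(nrow(z)))) {
    writeLines(paste(format(z[r, ], scientific = TRUE, digits = 7),
                     collapse = " "), con)
  }
  invisible(path)
}
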