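# Summary statistics for binned SDR dive histograms: mean and maximum
# depth/duration, the dive-focus index, and the focal depth. A histogram
# here is 10 counts n_1..n_10 with bin bounds; undefined values propagate
# as NA, never as zeros.

check_hist <- function(counts, lower = NULL, upper = NULL) {
  if (length(counts) != 10 || any(counts < 0) || any(counts != round(counts))) {
    stop("a dive histogram has exactly 10 nonnegative integer counts",
         call. = FALSE)
  }
  if (!is.null(lower)) {
    if (length(lower) != 10 || length(upper) != 10 ||
        any(upper <= lower) || any(diff(lower) <= 0)) {
      stop("bin bounds must be 10 strictly increasing, non-degenerate bins",
           call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Mean depth or duration from a binned histogram
#'
#' Sum of counts times bin midpoints divided by the total number of dives.
#' The per-dive values inside a bin are unobserved; the bin midpoint
#' stands in for the bin's central value.
#'
#' @param counts Integer vector of 10 dive counts.
#' @param lower,upper Bin bounds (length 10 each).
#' @return Weighted mean, or `NA` when no dives were recorded.
#' @export
mean_from_bins <- function(counts, lower, upper) {
  check_hist(counts, lower, upper)
  N <- sum(counts)
  if (N < 1) return(NA_real_)
  mid <- (lower + upper) / 2
  sum(counts * mid) / N
}

#' Maximum depth or duration from a binned histogram
#'
#' Upper bound of the deepest (longest) non-empty bin.
#'
#' @inheritParams mean_from_bins
#' @return Upper bound of the last non-empty bin, `NA` when empty.
#' @export
max_from_bins <- function(counts, lower, upper) {
  check_hist(counts, lower, upper)
  if (sum(counts) < 1) return(NA_real_)
  upper[max(which(counts > 0))]
}

#' Dive focus index
#'
#' Finite-sample-corrected concentration of dives across bins:
#' \deqn{\sum_{i=1}^{10} n_i (n_i - 1) / [N (N - 1)]}
#' the probability that two dives drawn without replacement fall in the
#' same bin. 1 when all dives share one bin, 0 when every dive is alone
#' in its bin; values above 0.50 indicate diving concentrated in a single
#' bin.
#'
#' @param counts Integer vector of 10 dive counts.
#' @return Focus in \[0, 1\]; `NA` when fewer than 2 dives were recorded
#'   (the correction divides by N - 1).
#' @export
dive_focus <- function(counts) {
  check_hist(counts)
  N <- sum(counts)
  if (N < 2) return(NA_real_)
  sum(counts * (counts - 1)) / (N * (N - 1))
}

#' Focal depth (dominant bin) of a histogram
#'
#' Defined only when the dive focus exceeds 0.50: the bin holding the most
#' dives, reported as its midpoint. A tie for the largest count resolves
#' to the shallower (shorter) bin and is flagged.
#'
#' @inheritParams mean_from_bins
#' @return A list with `value` (bin midpoint or `NA`), `bin` (index or
#'   `NA`) and `tie` (logical).
#' @export
focal_depth <- function(counts, lower, upper) {
  check_hist(counts, lower, upper)
  f <- dive_focus(counts)
  if (is.na(f) || f <= 0.50) {
    return(list(value = NA_real_, bin = NA_integer_, tie = FALSE))
  }
  top <- which(counts == max(counts))
  bin <- top[1]
  list(value = (lower[bin] + upper[bin]) / 2, bin = as.integer(bin),
       tie = length(top) > 1)
}

#' Per-interval dive summaries from long histogram data
#'
#' Computes, for every animal and 6-hr interval: mean and max depth (from
#' the depth histogram), mean and max duration (from the duration
#' histogram), dive focus and focal depth (from the depth histogram).
#' Intervals lacking a histogram type get `NA` for its statistics.
#'
#' @param hist Long histogram data frame (see
#'   [simulate_dive_histograms()] / [read_dive_histograms()]). Proportion-
#'   type histograms (non-integer `count`) are not supported here; the
#'   focus statistic is defined on dive counts.
#' @return Data frame with one row per animal x interval: `animal_id`,
#'   `interval_start`, `n_dives`, `mean_depth`, `max_depth`,
#'   `mean_duration`, `max_duration`, `dive_focus`, `focal_depth`,
#'   `focal_bin`, `focal_tie`.
#' @export
dive_summary <- function(hist) {
  need <- c("animal_id", "interval_start", "bin_type", "bin_index",
            "bin_lower", "bin_upper", "count")
  if (!all(need %in% names(hist))) {
    stop("histogram table must contain ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(hist$animal_id, as.numeric(hist$interval_start),
                     drop = TRUE)
  pieces <- split(seq_len(nrow(hist)), key)
  rows <- lapply(pieces, function(ii) {
    h <- hist[ii, , drop = FALSE]
    dep <- h[h$bin_type == "depth", , drop = FALSE]
    dur <- h[h$bin_type == "duration", , drop = FALSE]
    out <- data.frame(animal_id = h$animal_id[1],
                      interval_start = h$interval_start[1],
                      n_dives = NA_integer_,
                      mean_depth = NA_real_, max_depth = NA_real_,
                      mean_duration = NA_real_, max_duration = NA_real_,
                      dive_focus = NA_real_, focal_depth = NA_real_,
                      focal_bin = NA_integer_, focal_tie = FALSE,
                      stringsAsFactors = FALSE)
    if (nrow(dep) == 10) {
      dep <- dep[order(dep$bin_index), ]
      out$n_dives <- sum(dep$count)
      out$mean_depth <- mean_from_bins(dep$count, dep$bin_lower, dep$bin_upper)
      out$max_depth <- max_from_bins(dep$count, dep$bin_lower, dep$bin_upper)
      out$dive_focus <- dive_focus(dep$count)
      fd <- focal_depth(dep$count, dep$bin_lower, dep$bin_upper)
      out$focal_depth <- fd$value
      out$focal_bin <- fd$bin
      out$focal_tie <- fd$tie
    }
    if (nrow(dur) == 10) {
      dur <- dur[order(dur$bin_index), ]
      out$mean_duration <- mean_from_bins(dur$count, dur$bin_lower,
                                          dur$bin_upper)
      out$max_duration <- max_from_bins(dur$count, dur$bin_lower,
                                        dur$bin_upper)
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$animal_id, out$interval_start), ]
  rownames(out) <- NULL
  out
}
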