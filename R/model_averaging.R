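# AICc-based multimodel inference for the derived responses: candidate
# sets of linear mixed models (random intercept per animal, optional AR1
# or continuous-time AR1 residual correlation), AICc scores and weights,
# and model-averaged coefficients over the smallest subset of top models
# holding 95% of the weight, with Burnham-Anderson unconditional SEs.
# Model fitting delegates to nlme (ML); the transformation, correlation
# selection, AICc, weighting and averaging logic live here.

MODEL_TERMS <- c("species", "month", "sex", "mass")

#' Enumerate a candidate model set
#'
#' Deterministic enumerations for the three analyses:
#' * `ud` (monthly UD areas): every additive subset of
#'   species/month/sex/mass (16 models, including the null), plus a
#'   species x month interaction variant of every subset containing both
#'   main effects (4 more); no residual correlation.
#' * `distance` (distances from haul-out): the null, all single-term
#'   models and all 2- and 3-term additive subsets (15 models); AR1
#'   residual correlation within animal.
#' * `dive` (dive statistics): as `ud`, with continuous-time AR1
#'   correlation on the interval midpoint time within animal.
#'
#' An interaction never appears without both of its main effects.
#'
#' @param analysis One of `"ud"`, `"distance"`, `"dive"`.
#' @return A list of model specs: each has `fixed` (character vector of
#'   terms), `correlation` (`"none"`, `"ar1"`, `"car1"`) and `label`.
#' @export
build_candidate_set <- function(analysis = c("ud", "distance", "dive")) {
  analysis <- match.arg(analysis)
  subsets <- function(max_size) {
    out <- list(character(0))
    for (size in seq_len(max_size)) {
      cmb <- utils::combn(MODEL_TERMS, size, simplify = FALSE)
      out <- c(out, cmb)
    }
    out
  }
  corr <- switch(analysis, ud = "none", distance = "ar1", dive = "car1")
  sets <- switch(analysis,
    ud = ,
    dive = {
      base <- subsets(4)
      inter <- Filter(function(s) all(c("species", "month") %in% s), base)
      c(base, lapply(inter, function(s) c(s, "species:month")))
    },
    distance = subsets(3))
  lapply(sets, function(s) {
    label <- if (length(s) == 0) "null" else paste(s, collapse = " + ")
    list(fixed = s, correlation = corr, label = label)
  })
}

#' Small-sample Akaike information criterion
#'
#' `-2 loglik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters (fixed effects plus
#'   variance/correlation parameters).
#' @param n Number of observations.
#' @return AICc; `NA` with a warning when `n <= k + 1` (the correction is
#'   undefined and the model unusable).
#' @export
aicc <- function(loglik, k, n) {
  out <- -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  bad <- n <= k + 1
  if (any(bad)) {
    warning("AICc undefined for n <= k + 1; model(s) flagged unusable")
    out[bad] <- NA_real_
  }
  out
}

#' Akaike weights from AICc values
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AICc_i - min(AICc)`. `NA` entries (unusable models) receive
#' weight 0.
#'
#' @param aicc_values Numeric vector of AICc scores.
#' @return Weights summing to 1.
#' @export
aicc_weights <- function(aicc_values) {
  if (length(aicc_values) < 1) stop("need at least one model", call. = FALSE)
  w <- rep(0, length(aicc_values))
  ok <- !is.na(aicc_values)
  d <- aicc_values[ok] - min(aicc_values[ok])
  w[ok] <- exp(-d / 2)
  w / sum(w)
}

#' Fit a candidate set of mixed models
#'
#' Fits each spec by maximum likelihood as a linear mixed model with a
#' random intercept per animal and the spec's residual correlation
#' structure (AR1 ordered within animal, or continuous-time AR1 on a time
#' covariate within animal). The response is used as supplied: apply any
#' log/logit transformation beforehand (see [logit_focus()]). When the
#' random intercept is inestimable (e.g. a single animal) the model falls
#' back to a generalized least squares fit with the same correlation.
#' Models that fail to converge are dropped with a warning.
#'
#' @param data Data frame with `animal_id`, the response, the covariates
#'   used by the specs (`species`, `month`, `sex`, `mass`), and, for
#'   `car1` specs, a numeric time column. Rows must be time-ordered
#'   within animal for the correlation structures to make sense.
#' @param specs Candidate list from [build_candidate_set()] (or a subset).
#' @param response Name of the (already transformed) response column.
#' @param time_col Name of the numeric time column for `car1` specs.
#' @return A list of `fitted_model` objects: `spec`, `label`, `loglik`,
#'   `k`, `n`, `beta`, `se`.
#' @export
fit_candidates <- function(data, specs, response, time_col = "time_hr") {
  stopifnot(is.data.frame(data), response %in% names(data))
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  data$animal_id <- factor(data$animal_id)
  fits <- list()
  for (spec in specs) {
    terms <- if (length(spec$fixed)) spec$fixed else "1"
    form <- stats::reformulate(terms, response = response)
    corr <- switch(spec$correlation,
      none = NULL,
      ar1 = nlme::corAR1(form = stats::as.formula("~ 1 | animal_id")),
      car1 = {
        if (!time_col %in% names(data)) {
          stop("car1 correlation needs a numeric time column '", time_col, "'",
               call. = FALSE)
        }
        nlme::corCAR1(form = stats::as.formula(
          paste("~", time_col, "| animal_id")))
      },
      stop("unknown correlation structure: ", spec$correlation, call. = FALSE))
    fit <- tryCatch(
      nlme::lme(fixed = form, random = ~ 1 | animal_id, data = data,
                correlation = corr, method = "ML",
                control = nlme::lmeControl(opt = "optim", maxIter = 100,
                                           msMaxIter = 100, returnObject = TRUE)),
      error = function(e) tryCatch(
        nlme::gls(model = form, data = data, correlation = corr,
                  method = "ML"),
        error = function(e2) NULL))
    if (is.null(fit)) {
      warning("model '", spec$label, "' failed to converge; dropped")
      next
    }
    ll <- logLik(fit)
    beta <- if (inherits(fit, "lme")) nlme::fixef(fit) else coef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    fits[[length(fits) + 1]] <- structure(list(
      spec = spec, label = spec$label,
      loglik = as.numeric(ll), k = attr(ll, "df"),
      n = nrow(data), beta = beta, se = se), class = "fitted_model")
  }
  if (!length(fits)) stop("no model in the candidate set converged",
                          call. = FALSE)
  fits
}

#' Model-selection table
#'
#' @param fits List of `fitted_model` objects from [fit_candidates()].
#' @return Data frame with `model`, `k`, `n`, `loglik`, `AICc`, `delta`,
#'   `weight`, sorted by AICc.
#' @export
model_selection_table <- function(fits) {
  tab <- data.frame(
    model = vapply(fits, `[[`, "", "label"),
    k = vapply(fits, `[[`, 0, "k"),
    n = vapply(fits, `[[`, 0, "n"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    stringsAsFactors = FALSE)
  tab$AICc <- aicc(tab$loglik, tab$k, tab$n)
  tab$delta <- tab$AICc - min(tab$AICc, na.rm = TRUE)
  tab$weight <- aicc_weights(tab$AICc)
  tab <- tab[order(tab$AICc), ]
  rownames(tab) <- NULL
  tab
}

#' Model-averaged coefficients with 95% confidence intervals
#'
#' Ranks the fitted models by AICc weight, keeps the smallest prefix whose
#' cumulative weight reaches `coverage` (renormalizing within it), and
#' averages each coefficient over the selected models that contain it
#' (natural averaging, weights renormalized over those models).
#' Unconditional standard errors include the between-model variance
#' component: `SE = sum w_i sqrt(SE_i^2 + (beta_i - beta_bar)^2)`.
#' Confidence intervals are normal-approximation `beta_bar +- z SE`; an
#' effect is flagged significant when its interval excludes zero.
#'
#' @param fits List of `fitted_model` objects.
#' @param coverage Cumulative-weight cutoff for the averaged subset.
#' @param conf_level Confidence level for the intervals.
#' @return Data frame with `term`, `beta`, `se`, `lower`, `upper`,
#'   `significant`, `weight_sum` (summed renormalized weight of models
#'   containing the term) and `n_models`.
#' @export
model_average <- function(fits, coverage = 0.95, conf_level = 0.95) {
  stopifnot(length(fits) >= 1, coverage > 0, coverage <= 1)
  w <- aicc_weights(vapply(fits, function(f) aicc(f$loglik, f$k, f$n),
                           numeric(1)))
  ord <- order(-w)
  cum <- cumsum(w[ord])
  n_sel <- which(cum >= coverage - 1e-12)[1]
  sel <- ord[seq_len(n_sel)]
  w_sel <- w[sel] / sum(w[sel])
  fits_sel <- fits[sel]

  terms <- unique(unlist(lapply(fits_sel, function(f) names(f$beta))))
  z <- qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(terms, function(term) {
    has <- vapply(fits_sel, function(f) term %in% names(f$beta), logical(1))
    wt <- w_sel[has] / sum(w_sel[has])
    b <- vapply(fits_sel[has], function(f) unname(f$beta[term]), numeric(1))
    s <- vapply(fits_sel[has], function(f) unname(f$se[term]), numeric(1))
    b_bar <- sum(wt * b)
    se_bar <- sum(wt * sqrt(s^2 + (b - b_bar)^2))
    lower <- b_bar - z * se_bar
    upper <- b_bar + z * se_bar
    data.frame(term = term, beta = b_bar, se = se_bar,
               lower = lower, upper = upper,
               significant = (lower > 0 | upper < 0),
               weight_sum = sum(w_sel[has]), n_models = sum(has),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Logit transform for dive-focus values with boundary adjustment
#'
#' Focus values of exactly 0 or 1 occur in finite samples; before the
#' logit they are clipped to `[1/(4N), 1 - 1/(4N)]`, with N the number of
#' dives behind each value.
#'
#' @param p Focus values in \[0, 1\].
#' @param n_dives Dive counts behind each value (recycled).
#' @return `log(p / (1 - p))` after clipping.
#' @export
logit_focus <- function(p, n_dives) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), all(n_dives >= 2, na.rm = TRUE))
  eps <- 1 / (4 * n_dives)
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' Month factor with September reference
#'
#' Converts dates (or month abbreviations) to a factor whose reference
#' level is September, so model coefficients are Oct/Nov/Dec contrasts.
#'
#' @param x POSIXct/Date vector, or character month abbreviations.
#' @return Factor with levels ordered Sep, Oct, Nov, Dec, then any others
#'   present in calendar order.
#' @export
month_factor <- function(x) {
  mon <- if (inherits(x, c("POSIXct", "POSIXlt", "Date"))) {
    format(x, "%b", tz = "UTC")
  } else {
    as.character(x)
  }
  all_levels <- format(seq(as.Date("2000-01-15"), by = "month",
                           length.out = 12), "%b")
  present <- all_levels[all_levels %in% unique(mon)]
  ref_order <- c("Sep", "Oct", "Nov", "Dec")
  lev <- c(intersect(ref_order, present), setdiff(present, ref_order))
  factor(mon, levels = lev)
}
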