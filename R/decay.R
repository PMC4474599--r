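#' Normalize a densitometry timecourse
#'
#' Standard densitometry practice for chase assays: band intensity is
#' divided by the loading-control intensity (when present) and scaled so
#' the time-zero value is 1.
#'
#' @param tc A data frame with columns `time` (hours, strictly increasing,
#'   including 0), `intensity` (non-negative band densitometry) and
#'   optionally `loading` (positive loading-control densitometry).
#' @return The same tibble with `intensity` normalized (and `loading`
#'   dropped).
#' @examples
#' normalize_timecourse(data.frame(time = c(0, 1), intensity = c(10, 5)))
#' @export
normalize_timecourse <- function(tc) {
  tc <- as_tibble(tc)
  if (!all(c("time", "intensity") %in% names(tc))) {
    abort("Timecourse needs columns `time` and `intensity`.",
          class = "ligasetrap_validation_error")
  }
  if (nrow(tc) < 2 || any(diff(tc$time) <= 0) || !0 %in% tc$time) {
    abort("Times must be strictly increasing, include 0, and have >= 2 points.",
          class = "ligasetrap_validation_error")
  }
  if (any(tc$intensity < 0)) {
    abort("Band intensities must be non-negative.",
          class = "ligasetrap_validation_error")
  }
  y <- tc$intensity
  if ("loading" %in% names(tc)) {
    if (any(tc$loading <= 0)) {
      abort("Loading-control intensities must be positive.",
            class = "ligasetrap_validation_error")
    }
    y <- y / tc$loading
  }
  y0 <- y[tc$time == 0][1]
  if (y0 <= 0) {
    abort("Time-zero intensity must be positive after loading correction.",
          class = "ligasetrap_validation_error")
  }
  out <- tc[setdiff(names(tc), "loading")]
  out$intensity <- y / y0
  out
}

#' Fit a first-order decay rate and half-life
#'
#' Least-squares line through log(intensity) versus time, restricted to
#' the stated window — the log-linear part of the chase. The decay rate is
#' k = -slope (clipped at 0) and the half-life is ln(2)/k. Fits with
#' k below `k_min` are flagged stable and report an infinite half-life.
#' Points at or below the intensity `floor` are excluded with a warning
#' (log of a near-zero band quantitation is meaningless).
#'
#' @param tc A timecourse as in [normalize_timecourse()]; normalized
#'   automatically unless `normalize = FALSE`.
#' @param window Two-element numeric window in hours (inclusive); the
#'   default 0-2 h targets the early log-linear phase.
#' @param floor Intensity floor below which points are dropped.
#' @param k_min Decay rate (per hour) below which the protein is flagged
#'   stable.
#' @param normalize Normalize the timecourse before fitting.
#' @return An object of class `decay_fit` with fields `k` (per hour),
#'   `half_life` (hours; `Inf` when stable), `stable`, `r_squared`,
#'   `window`, `n_points`, and the underlying `lm` fit. [tidy()],
#'   [glance()] and [autoplot()] methods are available.
#' @examples
#' fit <- fit_halflife(data.frame(time = 0:2, intensity = c(1, 0.5, 0.25)))
#' glance(fit)
#' @export
fit_halflife <- function(tc, window = c(0, 2), floor = 0.01,
                         k_min = 0.01, normalize = TRUE) {
  if (normalize) tc <- normalize_timecourse(tc)
  tc <- as_tibble(tc)
  stopifnot(length(window) == 2, window[2] > window[1])
  inside <- tc$time >= window[1] & tc$time <= window[2]
  use <- tc[inside, ]
  floored <- use$intensity <= floor
  if (any(floored)) {
    warn(sprintf("%d point(s) at or below the intensity floor %.3g dropped.",
                 sum(floored), floor))
    use <- use[!floored, ]
  }
  if (nrow(use) < 2) {
    abort("Fewer than 2 usable points inside the fitting window.",
          class = "ligasetrap_fit_error")
  }
  fit <- lm(log(intensity) ~ time, data = use)
  slope <- unname(coef(fit)[["time"]])
  k <- max(0, -slope)
  stable <- k <= k_min
  res <- stats::residuals(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((log(use$intensity) - mean(log(use$intensity)))^2)
  r2 <- if (ss_tot <= .Machine$double.eps) {
    if (ss_res <= 1e-12) 1 else 0
  } else {
    max(0, min(1, 1 - ss_res / ss_tot))
  }
  structure(
    list(k = k, half_life = if (stable) Inf else log(2) / k,
         stable = stable, r_squared = r2,
         window = as.numeric(window), n_points = nrow(use),
         k_min = k_min, fit = fit, data = tc),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> k = %.4g /h, half-life = %s, R^2 = %.3f (%d points, %g-%g h)%s\n",
    x$k,
    if (x$stable) "stable" else sprintf("%.3g h", x$half_life),
    x$r_squared, x$n_points, x$window[1], x$window[2],
    if (x$stable) " [flagged stable]" else ""
  ))
  invisible(x)
}

#' @rdname fit_halflife
#' @param x,object A `decay_fit`.
#' @param ... Unused.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @rdname fit_halflife
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(k = x$k, half_life = x$half_life, stable = x$stable,
         r_squared = x$r_squared, n_points = x$n_points,
         window_start = x$window[1], window_end = x$window[2])
}

#' @rdname fit_halflife
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  dat <- object$data
  pred <- tibble(
    time = seq(object$window[1], object$window[2], length.out = 50)
  )
  pred$intensity <- exp(stats::predict(object$fit, newdata = pred))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$intensity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pred, colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "time (h)", y = "normalized intensity",
      title = if (object$stable) "flagged stable"
              else sprintf("half-life %.2f h (k = %.3f /h)",
                           object$half_life, object$k)
    ) +
    ggplot2::theme_minimal()
}

#' Classify stabilization between two chase conditions
#'
#' Ratio of half-lives (treated over reference) mapped onto the
#' yes/partial/no vocabulary used for knockdown and cullin-inhibitor chase
#' comparisons: `"yes"` at or above `full_threshold` (default 2.0),
#' `"partial"` at or above `partial_threshold` (default 1.3), otherwise
#' `"no"`. A treated fit flagged stable yields class `"stable"` (the
#' protein does not decay under treatment); thresholds are exposed because
#' published labels of this kind are assigned by inspection.
#'
#' @param fit_treated,fit_reference [fit_halflife()] results for the
#'   treated and reference condition.
#' @param full_threshold,partial_threshold Ratio thresholds for the
#'   `"yes"` and `"partial"` classes.
#' @return A one-row tibble with `ratio` and `class`.
#' @export
stabilization_ratio <- function(fit_treated, fit_reference,
                                full_threshold = 2.0,
                                partial_threshold = 1.3) {
  stopifnot(inherits(fit_treated, "decay_fit"),
            inherits(fit_reference, "decay_fit"))
  if (fit_treated$stable && fit_reference$stable) {
    return(tibble(ratio = NA_real_, class = "stable"))
  }
  if (fit_treated$stable) {
    return(tibble(ratio = Inf, class = "stable"))
  }
  ratio <- fit_treated$half_life / fit_reference$half_life
  cls <- if (ratio >= full_threshold) "yes"
         else if (ratio >= partial_threshold) "partial"
         else "no"
  tibble(ratio = ratio, class = cls)
}

#' Translation-rate recovery ratios from bulk densitometry
#'
#' Puromycin-incorporation (SUnSET-style) lane densitometry expressed
#' relative to the untreated reference: purely arithmetic normalization of
#' total-lane signal.
#'
#' @param signal A data frame with columns `condition` and `densitometry`.
#' @param reference Name of the reference condition (default
#'   `"untreated"`).
#' @return The tibble with an added `ratio` column
#'   (`densitometry / densitometry[reference]`).
#' @examples
#' translation_recovery_ratio(
#'   data.frame(condition = c("untreated", "CPT"),
#'              densitometry = c(100, 20)))
#' @export
translation_recovery_ratio <- function(signal, reference = "untreated") {
  signal <- as_tibble(signal)
  if (!all(c("condition", "densitometry") %in% names(signal))) {
    abort("`signal` needs columns `condition` and `densitometry`.",
          class = "ligasetrap_validation_error")
  }
  ref <- signal$densitometry[signal$condition == reference]
  if (length(ref) == 0 || is.na(ref[1]) || ref[1] <= 0) {
    abort(paste0("Reference condition '", reference,
                 "' missing or non-positive."),
          class = "ligasetrap_validation_error")
  }
  dplyr::mutate(signal, ratio = .data$densitometry / ref[1])
}
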