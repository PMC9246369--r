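#' Local-quadratic smoothing of a turbidity trace
#'
#' Savitzky-Golay smoothing (local quadratic least squares) on the trace's
#' fixed grid. Endpoints are handled by the filter's startup/shutdown
#' projections, so exact quadratics (and constants) are reproduced to
#' machine precision everywhere.
#'
#' @param trace a `turbidity_trace`.
#' @param window window length in points; odd, >= 3, < trace length.
#' @return The smoothed `turbidity_trace` on the same grid.
#' @export
smooth_trace <- function(trace, window = 5) {
  n <- length(trace$time)
  if (n < 3L) stop("trace too short to smooth", call. = FALSE)
  if (window %% 2 == 0 || window < 3 || window >= n)
    stop("window must be odd, >= 3 and < trace length", call. = FALSE)
  sm <- signal::sgolayfilt(trace$turbidity, p = 2, n = window)
  out <- trace
  out$turbidity <- as.numeric(sm)
  out
}

# Smoothed first derivative (AU/s) on the trace grid; assumes a uniform
# grid (the plate-reader read interval). Non-uniform grids use the median
# spacing, which is exact for our fixed-interval data.
smoothed_derivative <- function(trace, window = 5) {
  dt <- stats::median(diff(trace$time))
  as.numeric(signal::sgolayfilt(trace$turbidity, p = 2, n = window, m = 1,
                                ts = dt))
}

#' Segment a trace into growth phases
#'
#' Identifies maximal growth phases as intervals around local maxima of
#' the smoothed derivative that (a) exceed 10% of the global derivative
#' maximum, and (b) are separated from neighbouring peaks by a valley
#' below 50% of the smaller adjacent peak. Weaker or unseparated peaks are
#' merged into a single phase. Used for biphasic traces, where the kinetic
#' statistics are taken from the second phase.
#'
#' A detected phase must also account for a non-negligible share of the
#' total turbidity rise (`min_rise` of the smoothed range, default 10%);
#' derivative blips that contribute almost no rise — measurement noise
#' rather than growth phases — are merged into their neighbours.
#'
#' Segmentation operates on a derivative smoothed at a coarser scale than
#' the rate estimate (`seg_window`, by default about an eighth of the
#' trace length): growth phases in these assays last hours, so a coarse
#' derivative separates them while absorbing reader noise that would
#' otherwise split the main rise.
#'
#' @param trace a `turbidity_trace` (smoothed internally).
#' @param window smoothing window for the rate scale (points).
#' @param min_rise minimum fraction of the total turbidity rise a phase
#'   must contribute (default 0.1).
#' @param seg_window smoothing window for segmentation (odd; default
#'   `max(window, ~n/8)`).
#' @return A data.frame with columns `phase`, `start_idx`, `end_idx`,
#'   `start_s`, `end_s`, `peak_idx`, `peak_rate`; one row per phase,
#'   ordered by time. Always returns at least one phase.
#' @export
segment_phases <- function(trace, window = 5, min_rise = 0.1,
                           seg_window = NULL) {
  n <- length(trace$time)
  if (is.null(seg_window)) {
    seg_window <- max(window, 2L * (ceiling(n / 16)) + 1L)
    seg_window <- min(seg_window, if (n %% 2 == 0) n - 1L else n - 2L)
  }
  d <- smoothed_derivative(trace, seg_window)
  one_phase <- function() data.frame(
    phase = 1L, start_idx = 1L, end_idx = n,
    start_s = trace$time[1L], end_s = trace$time[n],
    peak_idx = which.max(d), peak_rate = max(d),
    start_rate = d[1L], end_rate = d[n])
  if (n < 5L || max(d) <= 0) return(one_phase())

  # strict-plateau-tolerant local maxima (interior or boundary)
  is_peak <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) d[i - 1L] else -Inf
    right <- if (i < n) d[i + 1L] else -Inf
    d[i] >= left && d[i] > right || (d[i] > left && d[i] >= right)
  }, logical(1L))
  peaks <- which(is_peak & d >= 0.1 * max(d))
  if (length(peaks) <= 1L) return(one_phase())

  # merge peaks not separated by a deep enough valley
  keep <- peaks[1L]
  for (pk in peaks[-1L]) {
    prev <- keep[length(keep)]
    valley <- min(d[prev:pk])
    if (valley < 0.5 * min(d[prev], d[pk])) {
      keep <- c(keep, pk)
    } else if (d[pk] > d[prev]) {
      keep[length(keep)] <- pk
    }
  }

  # drop phases that contribute a negligible share of the total rise
  sm <- smooth_trace(trace, window)$turbidity
  total_rise <- max(sm) - min(sm)
  phase_table <- function(keep) {
    bounds <- integer(0)
    if (length(keep) > 1L)
      for (j in seq_len(length(keep) - 1L)) {
        seg <- keep[j]:keep[j + 1L]
        bounds <- c(bounds, seg[which.min(d[seg])])
      }
    starts <- c(1L, bounds)
    ends <- c(bounds, n)
    data.frame(phase = seq_along(keep), start_idx = starts,
               end_idx = ends, start_s = trace$time[starts],
               end_s = trace$time[ends], peak_idx = keep,
               peak_rate = d[keep], start_rate = d[starts],
               end_rate = d[ends])
  }
  if (total_rise > 0) {
    repeat {
      if (length(keep) <= 1L) break
      tab <- phase_table(keep)
      rises <- sm[tab$end_idx] - sm[tab$start_idx]
      weak <- which(rises < min_rise * total_rise)
      if (length(weak) == 0L) break
      drop <- weak[which.min(rises[weak])]
      keep <- keep[-drop]
    }
  }
  if (length(keep) == 1L) return(one_phase())
  phase_table(keep)
}

#' Tangent-method kinetic statistics of a turbidity trace
#'
#' Implements the tangent method: the slope of the best-fit tangent to the
#' steepest part of the curve is the maximum aggregation rate, and the
#' x-intercept of that tangent (where it crosses the baseline) is the
#' apparent lag time. The steepest point is located on the smoothed
#' derivative within the selected phase; when the derivative shows a clear
#' interior peak, the estimate is refined by fitting a four-parameter
#' logistic to the phase and taking its analytic inflection tangent
#' (`max_rate = L k / 4` at `t0`), which makes the estimator exact on
#' sigmoidal curves regardless of the read interval. On non-sigmoidal
#' traces (e.g. linear ramps), or when the refinement fit is poor, the
#' discrete tangent anchored at the steepest sample is used.
#'
#' @param trace a `turbidity_trace`.
#' @param phase_rule `"global_max"` (default), `"second_phase"`, or a
#'   phase index. `"second_phase"` selects the second phase when the trace
#'   is biphasic and falls back to the only phase otherwise.
#' @param window smoothing window (points).
#' @param baseline baseline turbidity (AU); default `"first3"` = mean of
#'   the first three readings.
#' @param refine logical; apply the logistic refinement (default `TRUE`).
#' @return A `tangent_fit` object: list with `max_rate` (AU/s),
#'   `t_at_max` (s), `lag_time` (s; may be negative, flagged), `baseline`
#'   (AU), `phase_index`, `n_phases`, `method` ("logistic" or "discrete"),
#'   `rmse` (refinement residual RMSE, NA for discrete), and
#'   `negative_lag` flag.
#' @export
tangent_fit <- function(trace, phase_rule = c("global_max", "second_phase"),
                        window = 5, baseline = "first3", refine = TRUE) {
  n <- length(trace$time)
  if (n < 8L) stop("trace too short for tangent fit (need >= 8 points)",
                   call. = FALSE)
  if (identical(baseline, "first3"))
    baseline <- mean(trace$turbidity[1:3])

  phases <- segment_phases(trace, window)
  n_phases <- nrow(phases)
  if (is.numeric(phase_rule)) {
    idx <- as.integer(phase_rule)
    if (idx < 1L || idx > n_phases)
      stop("phase index out of range", call. = FALSE)
  } else {
    phase_rule <- match.arg(phase_rule)
    idx <- if (phase_rule == "second_phase" && n_phases >= 2L) 2L
    else if (phase_rule == "second_phase") 1L
    else phases$phase[which.max(phases$peak_rate)]
  }
  ph <- phases[idx, ]
  d <- smoothed_derivative(trace, window)
  sm <- smooth_trace(trace, window)
  seg <- ph$start_idx:ph$end_idx
  # steepest point located on the robust segmentation-scale derivative;
  # the fine-window derivative supplies the discrete slope value there
  i_max <- ph$peak_idx
  rate0 <- max(d[i_max], ph$peak_rate)
  if (rate0 <= 0) stop("no growth phase: derivative <= 0 everywhere",
                       call. = FALSE)

  out <- list(max_rate = rate0, t_at_max = trace$time[i_max],
              baseline = baseline, phase_index = idx, n_phases = n_phases,
              method = "discrete", rmse = NA_real_)
  anchor_tau <- sm$turbidity[i_max]

  # logistic refinement: only for a clear interior derivative peak (on
  # the segmentation-scale derivative, which is stable under noise)
  interior <- i_max > ph$start_idx + 1L && i_max < ph$end_idx - 1L
  peaked <- ph$peak_rate > 1.25 * min(ph$start_rate, ph$end_rate)
  if (refine && interior && peaked) {
    fit <- try(fit_phase_logistic(trace, seg, rate0, i_max), silent = TRUE)
    if (!inherits(fit, "try-error") && !is.null(fit)) {
      out$max_rate <- fit$L * fit$k / 4
      out$t_at_max <- fit$t0
      out$method <- "logistic"
      out$rmse <- fit$rmse
      anchor_tau <- fit$base + fit$L / 2
    }
  }

  out$lag_time <- out$t_at_max - (anchor_tau - baseline) / out$max_rate
  out$negative_lag <- out$lag_time < 0
  if (out$negative_lag)
    warning("apparent lag time is negative; reported as-is", call. = FALSE)
  class(out) <- "tangent_fit"
  out
}

# Four-parameter logistic fit over one phase of a trace. Returns NULL when
# the converged fit does not describe the phase well (fraction of variance
# unexplained > 2%), so the caller falls back to the discrete tangent.
fit_phase_logistic <- function(trace, seg, rate0, i_max) {
  tt <- trace$time[seg]
  yy <- trace$turbidity[seg]
  L0 <- max(yy) - min(yy)
  if (L0 <= 0) return(NULL)
  k0 <- max(4 * rate0 / L0, 1e-8)
  start <- list(base = min(yy), L = L0, k = k0, t0 = trace$time[i_max])
  fit <- try(minpack.lm::nlsLM(
    yy ~ base + L / (1 + exp(-k * (tt - t0))), start = start,
    lower = c(base = -Inf, L = 0, k = 0, t0 = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  cf <- as.list(stats::coef(fit))
  res <- stats::resid(fit)
  rmse <- sqrt(mean(res^2))
  ss_tot <- sum((yy - mean(yy))^2)
  if (ss_tot > 0 && sum(res^2) / ss_tot > 0.02) return(NULL)
  list(base = cf$base, L = cf$L, k = cf$k, t0 = cf$t0, rmse = rmse)
}

#' Endpoint turbidity
#'
#' Mean of the final readings of a trace (the end-of-incubation turbidity).
#'
#' @param trace a `turbidity_trace`.
#' @param tail_points number of final readings to average (default 3).
#' @return AU.
#' @export
endpoint_turbidity <- function(trace, tail_points = 3) {
  n <- length(trace$turbidity)
  if (tail_points < 1 || tail_points > n)
    stop("tail_points must be in [1, trace length]", call. = FALSE)
  mean(trace$turbidity[(n - tail_points + 1L):n])
}

#' Endpoint turbidity vs soluble fraction correlation
#'
#' Ordinary least squares line and Pearson correlation between endpoint
#' turbidity and the fraction of protein remaining soluble across a panel
#' of conditions; used to check that turbidity is proportional to
#' aggregated (insoluble) mass.
#'
#' @param endpoints endpoint turbidities (AU).
#' @param soluble_fractions matching soluble fractions.
#' @return List with `slope`, `intercept`, `r`.
#' @export
turbidity_soluble_correlation <- function(endpoints, soluble_fractions) {
  if (length(endpoints) != length(soluble_fractions) ||
      length(endpoints) < 3L)
    stop("need >= 3 matched pairs", call. = FALSE)
  if (stats::var(endpoints) == 0 || stats::var(soluble_fractions) == 0)
    stop("zero variance in inputs", call. = FALSE)
  fit <- stats::lm(endpoints ~ soluble_fractions)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = stats::cor(endpoints, soluble_fractions))
}

#' Dose-response analysis of tangent-fit statistics
#'
#' Normalizes maximum aggregation rates to the (mean) zero-dose rate,
#' expresses lag-time changes as percent of the zero-dose lag, and
#' optionally fits the saturable inhibition curve
#' `rate = R0 / (1 + d / K_I)` to the raw rates, returning `K_I` with its
#' standard error. The fit estimates the zero-dose scale `R0` jointly
#' rather than dividing every observation by a single noisy zero-dose
#' reading: normalizing first would correlate all residuals with the
#' zero-dose error and understate the uncertainty of `K_I`.
#' Replicated doses are allowed and each observation enters the fit.
#'
#' @param doses inhibitor doses (mM); must include dose 0 (replicates
#'   allowed).
#' @param max_rates maximum rates (AU/s), one per entry of `doses`.
#' @param lags apparent lag times (s), one per entry (optional).
#' @param fit_K_I logical; fit the inhibition constant (default `TRUE`).
#' @return A `dose_response` object: data.frame of `dose`,
#'   `normalized_rate`, `lag_change_pct`, with attributes `K_I`,
#'   `K_I_se` and `K_I_flag` (`"ok"`, `"infinite"` for a flat response, or
#'   `"not_fit"`).
#' @export
dose_response <- function(doses, max_rates, lags = NULL, fit_K_I = TRUE) {
  if (length(doses) != length(max_rates))
    stop("doses and max_rates must have equal length", call. = FALSE)
  i0 <- which(doses == 0)
  if (length(i0) < 1L)
    stop("a zero dose is required", call. = FALSE)
  r0 <- mean(max_rates[i0])
  if (r0 <= 0) stop("zero-dose rate must be > 0", call. = FALSE)
  norm <- max_rates / r0
  lagpct <- if (is.null(lags)) rep(NA_real_, length(doses)) else {
    lag0 <- mean(lags[i0])
    if (lag0 == 0) rep(NA_real_, length(doses))
    else 100 * (lags - lag0) / lag0
  }
  res <- data.frame(dose = doses, normalized_rate = norm,
                    lag_change_pct = lagpct)
  K <- NA_real_; Kse <- NA_real_; flag <- "not_fit"
  if (fit_K_I) {
    nz <- doses > 0
    n_nz <- length(unique(doses[nz]))
    if (all(abs(norm[nz] - 1) < 1e-9)) {
      flag <- "infinite"
    } else if (n_nz == 1L && sum(nz) == 1L) {
      # closed form from the single nonzero dose
      r <- norm[nz]
      K <- doses[nz] * r / (1 - r)
      flag <- "ok"
    } else {
      K0 <- stats::median(doses[nz])
      fit <- try(minpack.lm::nlsLM(max_rates ~ R0 / (1 + doses / K),
                                   start = list(R0 = r0, K = K0),
                                   lower = c(R0 = 0, K = 1e-9)),
                 silent = TRUE)
      if (!inherits(fit, "try-error")) {
        K <- unname(stats::coef(fit)[["K"]])
        Kse <- unname(summary(fit)$coefficients["K", 2L])
        flag <- "ok"
      }
    }
  }
  attr(res, "K_I") <- K
  attr(res, "K_I_se") <- Kse
  attr(res, "K_I_flag") <- flag
  class(res) <- c("dose_response", "data.frame")
  res
}
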