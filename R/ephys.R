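#' Voltage-clamp current trace around a puff application
#'
#' @param neuron_id Single string.
#' @param samples Current samples in pA (inward negative, as recorded at
#'   -60 mV holding).
#' @param sample_rate Sampling rate in Hz.
#' @param puff_time Time of the agonist puff in seconds from trace start.
#' @param holding_mV Holding potential metadata (default -60).
#' @return Object of class `current_trace`.
#' @export
current_trace <- function(neuron_id, samples, sample_rate, puff_time,
                          holding_mV = -60) {
  stopifnot(is.character(neuron_id), length(neuron_id) == 1L,
            sample_rate > 0, length(samples) > 0)
  dur <- length(samples) / sample_rate
  if (puff_time < 0 || puff_time > dur)
    stop("puff_time outside trace span for neuron ", neuron_id)
  structure(list(neuron_id = neuron_id, samples = as.numeric(samples),
                 sample_rate = sample_rate, puff_time = puff_time,
                 holding_mV = holding_mV),
            class = "current_trace")
}

#' Juxtacellular spike train around an i.v. injection
#'
#' @param neuron_id Single string.
#' @param spike_times Sorted spike times in seconds.
#' @param injection_time Time of the i.v. injection (s).
#' @param baseline_span Length of the pre-injection baseline (s); default
#'   300 (a 5-min baseline precedes the injection).
#' @return Object of class `spike_train`.
#' @export
spike_train <- function(neuron_id, spike_times, injection_time,
                        baseline_span = 300) {
  stopifnot(is.character(neuron_id), length(neuron_id) == 1L,
            baseline_span > 0)
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times))
    stop("spike times must be sorted for neuron ", neuron_id)
  if (injection_time < baseline_span)
    stop("injection_time must allow a full baseline span")
  structure(list(neuron_id = neuron_id, spike_times = spike_times,
                 injection_time = injection_time,
                 baseline_span = baseline_span),
            class = "spike_train")
}

#' Read spike trains from one-time-per-line text files
#'
#' @param paths Character vector of file paths; each file holds one spike
#'   time (s) per line. Neuron ids default to the file base names.
#' @param injection_time,baseline_span Passed to [spike_train()].
#' @return List of [spike_train] objects.
#' @export
read_spike_trains <- function(paths, injection_time, baseline_span = 300) {
  lapply(paths, function(p) {
    spike_train(sub("\\.[^.]*$", "", basename(p)),
                sort(as.numeric(readLines(p))), injection_time,
                baseline_span)
  })
}

#' Peak puff-evoked current amplitude
#'
#' Baseline is the median current over the second preceding the puff;
#' the response is the largest inward (downward) deflection of the
#' smoothed trace within `window` seconds after the puff, reported as a
#' positive pA magnitude (the "-pA" convention for inward currents). The
#' trace is boxcar-smoothed over `smooth_s` seconds before peak picking —
#' the raw sample minimum over thousands of points would otherwise be
#' biased by the noise floor; 20 ms is short against the transient's
#' rise and decay times so the peak itself is barely attenuated. Deflections not exceeding
#' `noise_k` baseline standard deviations — including purely outward
#' ones — give amplitude 0 and direction `"none"`.
#'
#' @param trace A [current_trace].
#' @param window Response window after the puff (s).
#' @param smooth_s Boxcar smoothing window (s) applied before peak
#'   extraction; 0 disables smoothing.
#' @param noise_k Detection threshold in baseline s.d. units.
#' @return List of class `evoked_response`: `neuron_id`, `kind =
#'   "current"`, `amplitude` (pA magnitude), `baseline` (pA), `direction`
#'   (`"activated"` for an inward current, else `"none"`), `window`.
#' @export
puff_current_amplitude <- function(trace, window = 3, smooth_s = 0.02,
                                   noise_k = 4) {
  sr <- trace$sample_rate
  sm <- trace$samples
  k <- max(1L, round(smooth_s * sr))
  if (k > 1L) {
    sm <- as.numeric(stats::filter(sm, rep(1 / k, k), sides = 2))
    edge <- is.na(sm)
    sm[edge] <- trace$samples[edge]
  }
  t <- (seq_along(sm) - 1) / sr
  pre <- sm[t >= trace$puff_time - 1 & t < trace$puff_time]
  if (length(pre) < 2L)
    stop("need at least 1 s of pre-puff data")
  if (trace$puff_time + window > t[length(t)] + 1 / sr)
    stop("response window exceeds the trace")
  post <- sm[t > trace$puff_time & t <= trace$puff_time + window]
  baseline <- stats::median(pre)
  noise <- stats::sd(pre)
  inward <- baseline - min(post)
  if (!is.finite(inward) || inward <= noise_k * noise)
    return(structure(list(neuron_id = trace$neuron_id, kind = "current",
                          amplitude = 0, baseline = baseline,
                          direction = "none", window = window),
                     class = "evoked_response"))
  structure(list(neuron_id = trace$neuron_id, kind = "current",
                 amplitude = inward, baseline = baseline,
                 direction = "activated", window = window),
            class = "evoked_response")
}

#' Percent firing-rate change from baseline after an i.v. injection
#'
#' Baseline rate is the spike count over the pre-injection baseline span
#' divided by that span. The post-injection rate excursion is read off
#' binned rates (`bin_s`-second bins over `post_s` seconds after the
#' injection): the response is the bin rate deviating most from baseline,
#' and the direction is `"activated"` / `"inhibited"` when that deviation
#' exceeds `sig_k` standard deviations of the binned baseline rates
#' (default 3, conservative because the excursion is the most extreme of
#' many scanned bins); with
#' no excursion beyond that band the direction is `"none"` and the
#' response is the mean post-injection bin rate (the extremum of a flat
#' rate is upward-biased by selection and is not a response). The change
#' is `100 * (response - baseline) / baseline`
#' percent; undefined (flagged `NA`) when the baseline rate is 0.
#'
#' @param train A [spike_train].
#' @param bin_s Bin width (s) for the smoothed rate.
#' @param post_s Post-injection window length (s).
#' @param sig_k Direction threshold in baseline-bin s.d. units.
#' @return List of class `evoked_response`: `neuron_id`, `kind = "rate"`,
#'   `amplitude` (percent change, signed), `baseline` (Hz), `response`
#'   (Hz), `direction`, `window`.
#' @export
firing_rate_change <- function(train, bin_s = 10, post_s = 180,
                               sig_k = 3) {
  inj <- train$injection_time
  base_lo <- inj - train$baseline_span
  base_spikes <- train$spike_times[train$spike_times >= base_lo &
                                   train$spike_times < inj]
  baseline <- length(base_spikes) / train$baseline_span
  bin_rate <- function(lo, hi) {
    breaks <- seq(lo, hi, by = bin_s)
    if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
    counts <- graphics::hist(
      train$spike_times[train$spike_times >= lo & train$spike_times < hi],
      breaks = breaks, plot = FALSE)$counts
    counts / diff(breaks)
  }
  base_bins <- bin_rate(base_lo, inj)
  post_bins <- bin_rate(inj, inj + post_s)
  band <- sig_k * stats::sd(base_bins)
  dev <- post_bins - baseline
  k <- which.max(abs(dev))
  if (abs(dev[k]) > band) {
    response <- post_bins[k]
    direction <- if (dev[k] > 0) "activated" else "inhibited"
  } else {
    # no excursion beyond the noise band: report the mean post rate (a
    # null response) instead of the extremum, which would be biased
    response <- mean(post_bins)
    direction <- "none"
  }
  amplitude <- if (baseline > 0)
    100 * (response - baseline) / baseline else NA_real_
  structure(list(neuron_id = train$neuron_id, kind = "rate",
                 amplitude = amplitude, baseline = baseline,
                 response = response, direction = direction,
                 window = post_s),
            class = "evoked_response")
}

#' @export
print.evoked_response <- function(x, ...) {
  if (x$kind == "current")
    cat(sprintf("<evoked_response> %s: %.1f pA inward (baseline %.1f pA, %s)\n",
                x$neuron_id, x$amplitude, x$baseline, x$direction))
  else
    cat(sprintf("<evoked_response> %s: %+.1f%% from %.2f Hz baseline (%s)\n",
                x$neuron_id, x$amplitude, x$baseline, x$direction))
  invisible(x)
}

#' Ordinary least-squares covariate regression
#'
#' Regression of a per-animal (or per-neuron) response on a covariate,
#' e.g. mean evoked current against the nicotine dose consumed over the
#' last 24 h (log scale). Built on [stats::lm()]; reports both the raw and
#' the adjusted coefficient of determination, the F statistic with
#' `(1, n - 2)` degrees of freedom and its two-sided p.
#'
#' @param x Covariate values.
#' @param y Response values.
#' @param log_x Log10-transform `x` first (requires positive `x`).
#' @return List of class `bc_regression`: `slope`, `intercept`,
#'   `r_squared`, `adj_r_squared`, `f`, `df`, `p_value`, `n`.
#' @export
covariate_regression <- function(x, y, log_x = FALSE) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired finite values")
  if (log_x) {
    if (any(x <= 0)) stop("log_x requires positive covariate values")
    x <- log10(x)
  }
  if (stats::sd(x) == 0) stop("zero variance in covariate")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = s$r.squared,
                 adj_r_squared = s$adj.r.squared,
                 f = unname(s$fstatistic[1L]),
                 df = c(1, n - 2),
                 p_value = stats::pf(s$fstatistic[1L], 1, n - 2,
                                     lower.tail = FALSE),
                 n = n),
            class = "bc_regression")
}

#' R-squared and adjusted R-squared from a printed F statistic
#'
#' For a simple regression, `R^2 = F / (F + df2)` and
#' `adjusted R^2 = 1 - (1 - R^2) (n - 1) / (n - 2)` with `n = df2 + 2`.
#' Useful to check the internal consistency of reported statistics.
#'
#' @param f F statistic with `(1, df2)` degrees of freedom.
#' @param df2 Denominator degrees of freedom.
#' @return Named list: `r_squared`, `adj_r_squared`, `n`.
#' @export
r_squared_from_f <- function(f, df2) {
  r2 <- f / (f + df2)
  n <- df2 + 2
  list(r_squared = r2,
       adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2),
       n = n)
}

#' Per-animal mean responses from a per-neuron table
#'
#' Dose-current correlations are computed per animal, not per neuron;
#' this collapses a per-neuron response table to per-mouse means so the
#' regression cannot be driven by pseudo-replication.
#'
#' @param responses Data frame with columns `mouse_id` and `value`.
#' @return Data frame `mouse_id`, `value` (mean), `n_neurons`.
#' @export
per_mouse_means <- function(responses) {
  out <- do.call(rbind, lapply(split(responses, responses$mouse_id),
    function(s) data.frame(mouse_id = s$mouse_id[1L],
                           value = mean(s$value), n_neurons = nrow(s),
                           stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
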