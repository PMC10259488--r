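#' Behavioral archetype parameters for the cohort generator
#'
#' Drinking is simulated at bout level: each bottle receives a Poisson
#' number of bouts per day with gamma-distributed volumes, scaled to a
#' day-level target volume that carries lognormal day-to-day variability
#' (`day_cv`). The archetype defines how the day targets evolve with the
#' schedule:
#' \describe{
#'   \item{`tracker`}{drinks a fixed drug-bottle volume (`drug_volume`
#'     ml/day) from whichever side holds nicotine; intake therefore rises
#'     in proportion to concentration. If `plateau_intake` is finite the
#'     drug volume is capped at `plateau_intake * 25 / conc` ml so intake
#'     plateaus (a titrating non-avoider).}
#'   \item{`side_biased`}{drinks `preference_strength` of its total volume
#'     from a fixed physical side regardless of content (passive
#'     consumption).}
#'   \item{`avoider_abrupt`}{behaves like a moderate tracker until the
#'     concentration first reaches `aversion_threshold` µg/ml; it drinks
#'     normally on that first day (experiencing the new dose), then — with
#'     `persistence` — collapses drug-bottle drinking to `residual_volume`
#'     ml/day for the rest of the task.}
#'   \item{`avoider_low`}{only ever sips the drug bottle
#'     (`drug_volume` small), keeping intake below the 2 mg/kg/day
#'     constitutive-avoider ceiling throughout.}
#'   \item{`pct_schedule`}{drug-bottle share follows an explicit per-drug-day
#'     percent path (`pct_path`), used for the minipump-pretreatment
#'     single-step protocols.}
#' }
#' Habituation drinking is balanced: the left-side share is drawn once per
#' mouse from `hab_pct_range`, safely inside the 20/80% exclusion window.
#'
#' @param archetype One of `"tracker"`, `"side_biased"`,
#'   `"avoider_abrupt"`, `"avoider_low"`, `"pct_schedule"`.
#' @param total_volume Baseline total daily fluid (ml).
#' @param drug_volume Target drug-bottle volume (ml/day) where applicable.
#' @param residual_volume Post-collapse drug-bottle volume (ml/day).
#' @param preference_side,preference_strength Side-biased drinking.
#' @param aversion_threshold Concentration (µg/ml) triggering collapse.
#' @param persistence Keep the collapse for the rest of the task.
#' @param plateau_intake Intake cap (mg/kg/day) for titrating trackers.
#' @param pct_path Per-drug-day percent drug consumption targets.
#' @param hab_pct Habituation left-side share (%); drawn from
#'   `hab_pct_range` when `NA`.
#' @param hab_pct_range Range for the habituation share draw.
#' @param day_cv Lognormal day-to-day coefficient of variation of volumes.
#' @param bouts_per_day Mean drinking bouts per bottle per day.
#' @param bout_shape Gamma shape of within-day bout volumes.
#' @return Named list of class `archetype_params` with attribute
#'   `true_label` (`"avoider"` or `"non_avoider"`).
#' @export
archetype_params <- function(archetype = c("tracker", "side_biased",
                                           "avoider_abrupt", "avoider_low",
                                           "pct_schedule"),
                             total_volume = 4.5, drug_volume = 2.75,
                             residual_volume = 0.05,
                             preference_side = "left",
                             preference_strength = 0.85,
                             aversion_threshold = 200, persistence = TRUE,
                             plateau_intake = Inf, pct_path = NULL,
                             hab_pct = NA_real_,
                             hab_pct_range = c(42, 58), day_cv = 0.12,
                             bouts_per_day = 20, bout_shape = 3) {
  archetype <- match.arg(archetype)
  stopifnot(total_volume > 0, drug_volume >= 0, residual_volume >= 0,
            preference_strength >= 0, preference_strength <= 1,
            aversion_threshold >= 0, day_cv >= 0, bouts_per_day >= 1)
  if (archetype == "pct_schedule" && is.null(pct_path))
    stop("pct_schedule archetype needs a pct_path")
  label <- if (archetype %in% c("avoider_abrupt", "avoider_low"))
    "avoider" else "non_avoider"
  structure(list(archetype = archetype, total_volume = total_volume,
                 drug_volume = drug_volume,
                 residual_volume = residual_volume,
                 preference_side = preference_side,
                 preference_strength = preference_strength,
                 aversion_threshold = aversion_threshold,
                 persistence = persistence, plateau_intake = plateau_intake,
                 pct_path = pct_path, hab_pct = hab_pct,
                 hab_pct_range = hab_pct_range, day_cv = day_cv,
                 bouts_per_day = bouts_per_day, bout_shape = bout_shape),
            class = "archetype_params", true_label = label)
}

# Deterministic per-day (left, right) volume targets implied by an
# archetype and a schedule; nominal 25 g body weight for intake-capped
# volumes. Day noise and bout structure are applied afterwards.
archetype_day_targets <- function(p, sched, hab_pct) {
  n <- nrow(sched)
  v_left <- numeric(n); v_right <- numeric(n)
  drug_day_idx <- 0L
  trigger_day <- if (p$archetype == "avoider_abrupt") {
    hit <- sched$day[sched$concentration >= p$aversion_threshold &
                     sched$concentration > 0]
    if (length(hit)) hit[1L] else Inf
  } else Inf
  for (i in seq_len(n)) {
    conc <- sched$concentration[i]
    if (conc == 0) {
      v_left[i] <- p$total_volume * hab_pct / 100
      v_right[i] <- p$total_volume * (1 - hab_pct / 100)
      next
    }
    drug_day_idx <- drug_day_idx + 1L
    side <- sched$side[i]
    if (p$archetype == "side_biased") {
      pref <- p$preference_strength * p$total_volume
      rest <- p$total_volume - pref
      v_left[i] <- if (p$preference_side == "left") pref else rest
      v_right[i] <- if (p$preference_side == "left") rest else pref
      next
    }
    v_drug <- switch(p$archetype,
      tracker = min(p$drug_volume,
                    p$plateau_intake * 25 / conc),
      avoider_abrupt = if (p$persistence && sched$day[i] > trigger_day)
        p$residual_volume else p$drug_volume,
      avoider_low = p$drug_volume,
      pct_schedule = p$total_volume *
        p$pct_path[min(drug_day_idx, length(p$pct_path))] / 100)
    v_veh <- max(p$total_volume - v_drug, 0.3)
    v_left[i] <- if (side == "left") v_drug else v_veh
    v_right[i] <- if (side == "left") v_veh else v_drug
  }
  data.frame(day = sched$day, v_left = v_left, v_right = v_right)
}

# Turn one day's bottle volume into bout events within the day span.
bouts_for_day <- function(volume, span, p) {
  if (volume <= 0) return(NULL)
  n <- max(1L, stats::rpois(1L, p$bouts_per_day))
  raw <- stats::rgamma(n, shape = p$bout_shape)
  minutes <- sort(sample(seq(span[1L], span[2L] - 1L), n))
  data.frame(minute = minutes, vol = volume * raw / sum(raw))
}

#' Simulate one mouse's drinking log, weights, and ground-truth label
#'
#' Draws bout-structured minute-resolution drinking under the given
#' archetype and schedule. Body weight starts near 25 g and evolves as a
#' slow random walk, recorded every other day. All randomness flows from
#' the current R RNG state (or `seed` when given), so a fixed seed yields
#' identical output.
#'
#' @param params An [archetype_params()].
#' @param sched A [schedule].
#' @param mouse_id Identifier for the generated mouse.
#' @param seed Optional integer seed.
#' @return List: `log` ([drink_log]), `record` ([mouse_record]),
#'   `true_label` (`"avoider"` / `"non_avoider"`), `archetype`.
#' @export
simulate_mouse <- function(params, sched, mouse_id = "m1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hab_pct <- if (is.finite(params$hab_pct)) params$hab_pct
             else stats::runif(1L, params$hab_pct_range[1L],
                               params$hab_pct_range[2L])
  targets <- archetype_day_targets(params, sched, hab_pct)
  spans <- day_span(sched, sched$day)
  sdlog <- sqrt(log(1 + params$day_cv^2))
  events <- vector("list", nrow(sched) * 2L)
  for (i in seq_len(nrow(sched))) {
    noise <- stats::rlnorm(2L, -sdlog^2 / 2, sdlog)
    bl <- bouts_for_day(targets$v_left[i] * noise[1L], spans[i, ], params)
    br <- bouts_for_day(targets$v_right[i] * noise[2L], spans[i, ], params)
    if (!is.null(bl)) bl$side <- "left"
    if (!is.null(br)) br$side <- "right"
    # heartbeat row at the day's last minute so every day has coverage
    hb <- data.frame(minute = spans[i, 2L] - 1L, vol = 0, side = "left")
    events[[2L * i - 1L]] <- rbind(bl, br)
    events[[2L * i]] <- hb
  }
  ev <- do.call(rbind, events)
  inc_left <- tapply(ifelse(ev$side == "left", ev$vol, 0), ev$minute, sum)
  inc_right <- tapply(ifelse(ev$side == "right", ev$vol, 0), ev$minute, sum)
  minutes <- as.numeric(names(inc_left))
  o <- order(minutes)
  log <- drink_log(mouse_id, minutes[o],
                   round(cumsum(as.numeric(inc_left)[o]), 3),
                   round(cumsum(as.numeric(inc_right)[o]), 3))

  weigh_days <- seq(1L, nrow(sched), by = 2L)
  w <- 25 + stats::rnorm(1L, 0, 1.2) +
    cumsum(stats::rnorm(length(weigh_days), 0, 0.15))
  w <- pmax(w, 18)
  names(w) <- weigh_days
  rec <- mouse_record(mouse_id, round(w, 1), tags = params$archetype)
  list(log = log, record = rec,
       true_label = attr(params, "true_label"),
       archetype = params$archetype)
}

# Archetype mixture of the 35-mouse reference cohort: 18 non-avoiders
# (6 trackers, 5 side-biased, 7 titrating plateau trackers) and 17
# avoiders (12 abrupt at the 100->200 step, one each at 100, 50 and
# 10 µg/ml, 2 constitutive low-intake), with per-mouse parameter jitter.
reference_archetypes <- function() {
  specs <- list()
  add <- function(n, f) for (k in seq_len(n)) specs[[length(specs) + 1L]] <<- f
  add(6L, function() archetype_params("tracker",
        drug_volume = stats::rnorm(1L, 2.6, 0.25),
        total_volume = stats::rnorm(1L, 4.6, 0.3)))
  add(5L, function() archetype_params("side_biased",
        total_volume = stats::rnorm(1L, 3.6, 0.25),
        preference_side = sample(c("left", "right"), 1L),
        preference_strength = stats::runif(1L, 0.82, 0.9)))
  add(7L, function() archetype_params("tracker",
        drug_volume = stats::rnorm(1L, 2.3, 0.2),
        plateau_intake = stats::rnorm(1L, 14.5, 1.2),
        total_volume = stats::rnorm(1L, 4.4, 0.3)))
  thresholds <- c(rep(200, 12L), 100, 50, 10)
  for (th in thresholds)
    add(1L, local({
      th0 <- th
      function() archetype_params("avoider_abrupt",
        aversion_threshold = th0,
        drug_volume = stats::rnorm(1L, 1.7, 0.15),
        residual_volume = stats::runif(1L, 0.003, 0.008),
        total_volume = stats::rnorm(1L, 4.0, 0.25))
    }))
  add(2L, function() archetype_params("avoider_low",
        drug_volume = stats::runif(1L, 0.1, 0.17),
        total_volume = stats::rnorm(1L, 3.8, 0.25)))
  specs
}

#' The fixed-seed 35-mouse synthetic reference cohort
#'
#' Thirty-five mice with the archetype mixture described in
#' [reference_archetypes()] under the standard ascending schedule
#' (habituation, then 10/50/100/200 µg/ml for 4 days each). Group-level
#' drinking is calibrated by moment matching so that, through the full
#' pipeline, avoiders average about 2.6 and non-avoiders about 16.9
#' mg/kg/day at the 200 µg/ml condition. Deterministic under a fixed
#' seed; ground-truth labels are attached.
#'
#' @param seed Integer seed (documented default 101).
#' @param sched Optional [schedule]; default [two_bottle_schedule()].
#' @return List: `logs` (named list of [drink_log]), `records` (named list
#'   of [mouse_record]), `truth` (data frame `mouse_id`, `archetype`,
#'   `true_label`), `schedule`.
#' @export
reference_cohort <- function(seed = 101, sched = two_bottle_schedule()) {
  set.seed(seed)
  specs <- reference_archetypes()
  ids <- sprintf("m%02d", seq_along(specs))
  sims <- lapply(seq_along(specs), function(i)
    simulate_mouse(specs[[i]](), sched, mouse_id = ids[i]))
  list(logs = stats::setNames(lapply(sims, `[[`, "log"), ids),
       records = stats::setNames(lapply(sims, `[[`, "record"), ids),
       truth = data.frame(
         mouse_id = ids,
         archetype = vapply(sims, `[[`, "", "archetype"),
         true_label = vapply(sims, `[[`, "", "true_label"),
         stringsAsFactors = FALSE),
       schedule = sched)
}

#' Minipump-pretreatment cohorts for the single-step protocol
#'
#' Cohorts for the modified task (habituation, then 100 µg/ml directly)
#' after chronic minipump pretreatment. Percent-consumption day paths are
#' calibrated to the reported group trajectories: saline-pretreated mice
#' drop abruptly when nicotine appears (condition mean ~23.0%), while
#' nicotine-pretreated mice decline only gradually (condition mean
#' ~41.2%), reflecting tolerance to nicotine's aversive effect.
#'
#' @param treatment `"saline"` or `"nicotine"` pretreatment.
#' @param n Number of mice (defaults: 23 saline, 25 nicotine).
#' @param seed Integer seed.
#' @param sched Optional [schedule]; default [single_step_schedule()].
#' @return Same layout as [reference_cohort()].
#' @export
minipump_cohort <- function(treatment = c("saline", "nicotine"), n = NULL,
                            seed = 101,
                            sched = single_step_schedule(100)) {
  treatment <- match.arg(treatment)
  if (is.null(n)) n <- if (treatment == "saline") 23L else 25L
  set.seed(seed)
  base_path <- if (treatment == "saline") c(40, 18, 17, 17)
               else c(50, 44, 37, 34)
  ids <- sprintf("%s%02d", substr(treatment, 1, 3), seq_len(n))
  sims <- lapply(seq_len(n), function(i) {
    jitter <- stats::rnorm(1L, 1, 0.1)
    path <- pmin(pmax(base_path * jitter, 1), 95)
    p <- archetype_params("pct_schedule", pct_path = path,
                          total_volume = stats::rnorm(1L, 4.2, 0.3),
                          hab_pct_range = c(44, 56))
    simulate_mouse(p, sched, mouse_id = ids[i])
  })
  list(logs = stats::setNames(lapply(sims, `[[`, "log"), ids),
       records = stats::setNames(lapply(sims, `[[`, "record"), ids),
       truth = data.frame(
         mouse_id = ids, archetype = "pct_schedule",
         true_label = NA_character_, stringsAsFactors = FALSE),
       schedule = sched)
}

#' Synthetic puff-evoked current traces with ground truth
#'
#' Per-neuron peak amplitudes are lognormal (given mean and coefficient of
#' variation); each trace is a double-exponential inward transient (rise
#' 50 ms, decay 500 ms by default) on a noisy holding-current baseline.
#'
#' @param n Number of neurons.
#' @param mean_amplitude Group mean peak amplitude (pA, inward magnitude).
#' @param cv Coefficient of variation of amplitudes across neurons.
#' @param seed Optional integer seed.
#' @param sample_rate Hz.
#' @param pre_s,post_s Seconds before / after the puff.
#' @param rise_s,decay_s Transient time constants (s).
#' @param baseline_pA Holding current level.
#' @param noise_sd Additive Gaussian noise s.d. (pA).
#' @return List: `traces` (list of [current_trace]), `truth` (numeric
#'   programmed amplitudes).
#' @export
simulate_current_traces <- function(n, mean_amplitude, cv = 0.4,
                                    seed = NULL, sample_rate = 2000,
                                    pre_s = 2, post_s = 5,
                                    rise_s = 0.05, decay_s = 0.5,
                                    baseline_pA = -20, noise_sd = 5) {
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  amps <- if (mean_amplitude > 0)
    stats::rlnorm(n, log(mean_amplitude) - sdlog^2 / 2, sdlog)
  else rep(0, n)
  t_post <- seq(0, post_s, by = 1 / sample_rate)[-1L]
  shape <- exp(-t_post / decay_s) - exp(-t_post / rise_s)
  shape <- shape / max(shape)
  n_pre <- pre_s * sample_rate
  traces <- lapply(seq_len(n), function(i) {
    sig <- c(rep(0, n_pre), -amps[i] * shape)
    current_trace(sprintf("n%03d", i),
                  baseline_pA + sig + stats::rnorm(length(sig), 0, noise_sd),
                  sample_rate, puff_time = pre_s)
  })
  list(traces = traces, truth = amps)
}

#' Synthetic peri-injection spike trains with ground truth
#'
#' Inhomogeneous Poisson trains: constant baseline rate before the
#' injection, then a smooth excursion (linear ramp, hold, exponential
#' decay) to `1 + delta_pct/100` times baseline, clamped at zero.
#' Generated by thinning.
#'
#' @param baseline_rates Per-neuron baseline rates (Hz).
#' @param delta_pct Per-neuron programmed percent rate changes (signed;
#'   0 = homogeneous train).
#' @param seed Optional integer seed.
#' @param baseline_span Pre-injection baseline (s).
#' @param post_s Post-injection span to simulate (s).
#' @param ramp_s,hold_s,decay_s Excursion kinetics (s).
#' @return List: `trains` (list of [spike_train]), `truth` (data frame
#'   `baseline_rate`, `delta_pct`).
#' @export
simulate_spike_trains <- function(baseline_rates, delta_pct, seed = NULL,
                                  baseline_span = 300, post_s = 240,
                                  ramp_s = 10, hold_s = 80, decay_s = 60) {
  stopifnot(length(baseline_rates) == length(delta_pct))
  if (!is.null(seed)) set.seed(seed)
  inj <- baseline_span
  total <- baseline_span + post_s
  trains <- lapply(seq_along(baseline_rates), function(i) {
    r0 <- baseline_rates[i]
    frac <- delta_pct[i] / 100
    rate_at <- function(t) {
      s <- t - inj
      mod <- ifelse(s < 0, 0,
             ifelse(s < ramp_s, s / ramp_s,
             ifelse(s < ramp_s + hold_s, 1,
                    exp(-(s - ramp_s - hold_s) / decay_s))))
      pmax(r0 * (1 + frac * mod), 0)
    }
    rmax <- max(r0, r0 * (1 + max(frac, 0)))
    if (rmax <= 0) {
      spikes <- numeric(0)
    } else {
      n_cand <- stats::rpois(1L, rmax * total)
      cand <- sort(stats::runif(n_cand, 0, total))
      spikes <- cand[stats::runif(n_cand) < rate_at(cand) / rmax]
    }
    spike_train(sprintf("n%03d", i), spikes, injection_time = inj,
                baseline_span = baseline_span)
  })
  list(trains = trains,
       truth = data.frame(baseline_rate = baseline_rates,
                          delta_pct = delta_pct))
}

#' Group-calibrated ephys ensemble
#'
#' Convenience wrapper drawing a full group: puff-current traces with the
#' group's amplitude distribution and spike trains with the group's
#' rate-change distribution (a `frac_inhibited` share of neurons gets a
#' negative excursion).
#'
#' @param n_neurons Neurons per modality.
#' @param current_mean_pA Group mean evoked-current amplitude (pA).
#' @param current_cv Amplitude coefficient of variation.
#' @param rate_change_mean,rate_change_sd Normal distribution of percent
#'   rate changes for activated neurons.
#' @param baseline_rate_mean Mean baseline firing (Hz, gamma with shape 4).
#' @param frac_inhibited Fraction of neurons with sign-flipped excursions.
#' @param seed Optional integer seed.
#' @return List: `currents` (see [simulate_current_traces()]), `rates`
#'   (see [simulate_spike_trains()]).
#' @export
simulate_ephys_group <- function(n_neurons, current_mean_pA,
                                 current_cv = 0.4, rate_change_mean = 80,
                                 rate_change_sd = 30,
                                 baseline_rate_mean = 6,
                                 frac_inhibited = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  currents <- simulate_current_traces(n_neurons, current_mean_pA,
                                      cv = current_cv)
  deltas <- stats::rnorm(n_neurons, rate_change_mean, rate_change_sd)
  flip <- stats::runif(n_neurons) < frac_inhibited
  deltas[flip] <- -pmin(abs(deltas[flip]), 95)
  rates <- simulate_spike_trains(
    stats::rgamma(n_neurons, shape = 4, rate = 4 / baseline_rate_mean),
    deltas)
  list(currents = currents, rates = rates)
}
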