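#' Cumulative volume at a minute, by carry-forward
#'
#' Cumulative encoding makes gaps harmless: the volume at minute `t` is the
#' last observed cumulative value at or before `t`, and 0 before the first
#' observation (bottles start untouched).
#'
#' @param log A [drink_log].
#' @param minute Minute(s) since experiment start.
#' @return Two-column matrix `left`, `right` of cumulative ml.
#' @keywords internal
cumulative_at <- function(log, minute) {
  idx <- findInterval(minute, log$minute)
  left <- c(0, log$volume_left)[idx + 1L]
  right <- c(0, log$volume_right)[idx + 1L]
  cbind(left = left, right = right)
}

#' Daily intake and percent-consumption metrics for one mouse
#'
#' For each schedule day, the volume drunk from each bottle is the
#' increment of its cumulative series over the day span. Nicotine intake is
#' `vol_drug_ml * concentration / weight_g` in mg of nicotine per kg body
#' weight per day (µg/ml x ml = µg; /1000 -> mg; weight/1000 -> kg), using
#' the day's carried-forward body weight. Percent nicotine consumption is
#' the drug-bottle volume as a percentage of total fluid drunk that day.
#'
#' On habituation days (concentration 0) intake is 0 by definition;
#' `pct_drug` is computed against the *virtual* drug side (the task's
#' alternation pattern continued backwards) when
#' `habituation_pct = "virtual"` (default, needed for water-vs-water
#' pseudo-ternary points), or left `NA` when `"na"`.
#'
#' A day with no log observation inside its span is flagged missing
#' (`missing = TRUE`, metric columns `NA`) rather than scored as zero
#' drinking. A day in which nothing was drunk has `pct_drug = NA` as well:
#' no preference can be read off zero fluid.
#'
#' @param log A [drink_log].
#' @param sched A [schedule].
#' @param rec A [mouse_record] supplying body weights.
#' @param habituation_pct `"virtual"` or `"na"` (see above).
#' @return Data frame, one row per schedule day: `mouse_id`, `day`,
#'   `condition_id`, `concentration`, `drug_side` (virtual on habituation
#'   days), `vol_left`, `vol_right`, `vol_drug_ml`, `vol_vehicle_ml`,
#'   `pct_drug`, `pct_left`, `intake_mg_per_kg`, `weight_g`, `missing`.
#' @export
daily_metrics <- function(log, sched, rec,
                          habituation_pct = c("virtual", "na")) {
  habituation_pct <- match.arg(habituation_pct)
  span <- day_span(sched, sched$day)
  # day d covers integer minutes [start, end); boundary values taken at
  # end-1 and start-1 so increments partition the series exactly
  at_end <- cumulative_at(log, span[, "end"] - 1)
  at_start <- cumulative_at(log, span[, "start"] - 1)
  vol_left <- at_end[, "left"] - at_start[, "left"]
  vol_right <- at_end[, "right"] - at_start[, "right"]
  covered <- vapply(seq_len(nrow(sched)), function(i)
    any(log$minute >= span[i, "start"] & log$minute < span[i, "end"]),
    logical(1))

  side_used <- ifelse(sched$concentration > 0, sched$side,
                      sched$virtual_side)
  vol_drug <- ifelse(side_used == "left", vol_left, vol_right)
  vol_veh <- ifelse(side_used == "left", vol_right, vol_left)
  total <- vol_left + vol_right
  pct_drug <- ifelse(total > 0, 100 * vol_drug / total, NA_real_)
  if (habituation_pct == "na")
    pct_drug[sched$concentration == 0] <- NA_real_
  pct_left <- ifelse(total > 0, 100 * vol_left / total, NA_real_)
  weight <- weight_on_day(rec, sched$day)
  intake <- vol_drug * sched$concentration / weight

  out <- data.frame(
    mouse_id = attr(log, "mouse_id"), day = sched$day,
    condition_id = sched$condition_id, concentration = sched$concentration,
    drug_side = side_used, vol_left = vol_left, vol_right = vol_right,
    vol_drug_ml = vol_drug, vol_vehicle_ml = vol_veh, pct_drug = pct_drug,
    pct_left = pct_left, intake_mg_per_kg = intake, weight_g = weight,
    missing = !covered, stringsAsFactors = FALSE)
  num <- c("vol_left", "vol_right", "vol_drug_ml", "vol_vehicle_ml",
           "pct_drug", "pct_left", "intake_mg_per_kg")
  out[!covered, num] <- NA_real_
  out
}

#' Per-condition summaries: mean intake, mean percent, side-wise percents
#'
#' Unweighted means over the condition's non-missing days. `pct_c1` and
#' `pct_c2` are the percent drug consumption averaged separately over days
#' with the drug bottle on the left (c1) and right (c2) physical side;
#' a side with no usable day yields `NA` for that component.
#'
#' @param daily Output of [daily_metrics()] (one or several mice).
#' @param sched The [schedule] the metrics were computed under.
#' @return Data frame, one row per mouse x condition: `mouse_id`,
#'   `condition_id`, `concentration`, `n_days`, `n_used`, `mean_intake`,
#'   `mean_pct`, `pct_c1`, `pct_c2`.
#' @export
condition_summaries <- function(daily, sched) {
  conds <- unique(sched$condition_id)
  pieces <- lapply(split(daily, daily$mouse_id), function(d) {
    do.call(rbind, lapply(conds, function(cid) {
      dd <- d[d$condition_id == cid & !d$missing, , drop = FALSE]
      n_days <- sum(d$condition_id == cid)
      mean_or_na <- function(x) if (any(!is.na(x))) mean(x, na.rm = TRUE)
                                else NA_real_
      data.frame(
        mouse_id = d$mouse_id[1L], condition_id = cid,
        concentration = sched$concentration[match(cid, sched$condition_id)],
        n_days = n_days, n_used = nrow(dd),
        mean_intake = mean_or_na(dd$intake_mg_per_kg),
        mean_pct = mean_or_na(dd$pct_drug),
        pct_c1 = mean_or_na(dd$pct_drug[dd$drug_side == "left"]),
        pct_c2 = mean_or_na(dd$pct_drug[dd$drug_side == "right"]),
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Habituation side preference
#'
#' Volume-weighted percent of total habituation fluid drunk from the left
#' bottle, used for the side-bias exclusion rule.
#'
#' @param daily Output of [daily_metrics()] for one mouse.
#' @return Percent left-side preference in `[0, 100]`, or `NA` if the
#'   mouse drank nothing during habituation.
#' @export
habituation_preference <- function(daily) {
  h <- daily[daily$concentration == 0 & !daily$missing, , drop = FALSE]
  tot <- sum(h$vol_left + h$vol_right)
  if (!nrow(h) || !is.finite(tot) || tot <= 0) return(NA_real_)
  100 * sum(h$vol_left) / tot
}

#' Consecutive-day intake differences over the drug phase
#'
#' Differences in daily nicotine intake between consecutive drug days
#' (habituation excluded): positive differences mark an increase in
#' intake, negative a decrease. Each difference is labeled with whether a
#' concentration increase occurred at, or one day before, the later day of
#' the pair, so that classification can anchor "abrupt" drops to
#' concentration steps. Missing days break the chain (no difference is
#' computed across a gap).
#'
#' @param daily Output of [daily_metrics()] for one mouse.
#' @return List of class `intake_deltas`: `mouse_id`, `deltas` (data frame
#'   `from_day`, `to_day`, `delta`, `after_increase`), `min_delta`,
#'   `max_delta`.
#' @export
intake_deltas <- function(daily) {
  d <- daily[daily$concentration > 0 & !daily$missing, , drop = FALSE]
  d <- d[order(d$day), , drop = FALSE]
  if (nrow(d) < 2L)
    stop("need at least 2 drug days with data to compute intake deltas")
  i <- seq_len(nrow(d) - 1L)
  consec <- d$day[i + 1L] == d$day[i] + 1L
  if (!any(consec))
    stop("no pair of consecutive drug days with data")
  from <- d$day[i][consec]; to <- d$day[i + 1L][consec]
  delta <- (d$intake_mg_per_kg[i + 1L] - d$intake_mg_per_kg[i])[consec]
  # concentration increase at day x: conc(x) > conc(x - 1)
  conc_of <- function(day) d$concentration[match(day, d$day)]
  inc_at <- function(day) {
    prev <- conc_of(day - 1)
    now <- conc_of(day)
    !is.na(prev) & !is.na(now) & now > prev
  }
  after_increase <- inc_at(to) | inc_at(from)
  structure(list(
    mouse_id = d$mouse_id[1L],
    deltas = data.frame(from_day = from, to_day = to, delta = delta,
                        after_increase = after_increase),
    min_delta = min(delta), max_delta = max(delta)),
    class = "intake_deltas")
}

#' Intake adjustment across concentration transitions
#'
#' For each transition between drug conditions, compares intake on the
#' last day before the step with intake on each of `lag_days` days after
#' it. A transition is flagged as rapidly adjusted (titration) when intake
#' on the `lag_days`-th post-step day is within `tolerance` (relative) of
#' the pre-step condition mean.
#'
#' @param daily Output of [daily_metrics()] for one mouse.
#' @param sched The [schedule].
#' @param lag_days Days after the transition to report (default 1).
#' @param tolerance Relative tolerance for the rapid-adjustment flag.
#' @return Data frame, one row per drug-to-drug transition: `mouse_id`,
#'   `conc_from`, `conc_to`, `pre_mean`, `pre_last`, `post_1` ...,
#'   `rapid`.
#' @export
titration_response <- function(daily, sched, lag_days = 1,
                               tolerance = 0.25) {
  drug <- sched[sched$concentration > 0, , drop = FALSE]
  conds <- unique(drug$condition_id)
  if (length(conds) < 2L)
    return(data.frame(mouse_id = character(), conc_from = numeric(),
                      conc_to = numeric(), pre_mean = numeric(),
                      pre_last = numeric(), rapid = logical()))
  rows <- lapply(seq_len(length(conds) - 1L), function(k) {
    pre_days <- drug$day[drug$condition_id == conds[k]]
    post_days <- drug$day[drug$condition_id == conds[k + 1L]]
    get <- function(day) {
      v <- daily$intake_mg_per_kg[match(day, daily$day)]
      v[daily$missing[match(day, daily$day)]] <- NA_real_
      v
    }
    pre <- get(pre_days)
    pre_mean <- if (any(!is.na(pre))) mean(pre, na.rm = TRUE) else NA_real_
    post <- get(post_days[seq_len(min(lag_days, length(post_days)))])
    rapid <- is.finite(pre_mean) && pre_mean > 0 &&
      is.finite(post[length(post)]) &&
      abs(post[length(post)] - pre_mean) <= tolerance * pre_mean
    row <- data.frame(
      mouse_id = daily$mouse_id[1L],
      conc_from = drug$concentration[match(conds[k], drug$condition_id)],
      conc_to = drug$concentration[match(conds[k + 1L], drug$condition_id)],
      pre_mean = pre_mean, pre_last = pre[length(pre)],
      stringsAsFactors = FALSE)
    for (j in seq_along(post)) row[[paste0("post_", j)]] <- post[j]
    row$rapid <- rapid
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
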