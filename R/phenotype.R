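#' Parameters of the avoider/non-avoider classification
#'
#' The published phenotype definitions are narrative; these four numeric
#' parameters operationalise them. `low_intake_ceiling` (mg/kg/day) is the
#' stated constitutive-avoider ceiling: mice whose daily intake never
#' exceeds it are avoiders regardless of dynamics. `noise_band`
#' (mg/kg/day) separates real day-to-day intake changes from measurement
#' noise. `quit_level` (fraction of the pre-drop condition-mean intake)
#' defines how low intake must stay after an abrupt drop to count as
#' durable cessation. `avoid_pct` (%) is the percent-consumption level
#' below which a condition counts as avoided when estimating the per-mouse
#' aversion threshold. `bias_low`/`bias_high` (%) bound the habituation
#' side-preference exclusion window (strict inequalities; the boundary is
#' kept).
#'
#' @param low_intake_ceiling,noise_band,quit_level,avoid_pct,bias_low,bias_high
#'   See description.
#' @return Named list of class `phenotype_params`.
#' @export
phenotype_params <- function(low_intake_ceiling = 2, noise_band = 0.5,
                             quit_level = 0.2, avoid_pct = 20,
                             bias_low = 20, bias_high = 80) {
  stopifnot(low_intake_ceiling > 0, noise_band >= 0,
            quit_level > 0, quit_level < 1,
            avoid_pct > 0, avoid_pct < 100, bias_low < bias_high)
  structure(list(low_intake_ceiling = low_intake_ceiling,
                 noise_band = noise_band, quit_level = quit_level,
                 avoid_pct = avoid_pct, bias_low = bias_low,
                 bias_high = bias_high),
            class = "phenotype_params")
}

#' Habituation side-bias exclusion
#'
#' Mice with a strong side bias during the water-vs-water habituation
#' period (side preference below 20% or above 80%) are excluded from
#' analysis; the boundaries themselves are kept (strict inequalities). An
#' undefined preference (no habituation drinking) also excludes.
#'
#' @param habituation_pct Habituation side preference in percent
#'   (either side's share; the rule is symmetric).
#' @param params A [phenotype_params()].
#' @return List: `keep` (logical), `reason` (`""`, `"side_bias"` or
#'   `"no habituation drinking"`).
#' @export
exclude_side_bias <- function(habituation_pct,
                              params = phenotype_params()) {
  if (!is.finite(habituation_pct))
    return(list(keep = FALSE, reason = "no habituation drinking"))
  if (habituation_pct < params$bias_low || habituation_pct > params$bias_high)
    return(list(keep = FALSE, reason = "side_bias"))
  list(keep = TRUE, reason = "")
}

#' Classify one mouse as avoider or non-avoider
#'
#' Rules, in order of precedence:
#' \enumerate{
#'   \item `low_intake`: daily intake never exceeded
#'     `low_intake_ceiling` (constitutive avoider);
#'   \item `abrupt_drop`: a consecutive-day intake decrease larger than
#'     `noise_band`, occurring at or within one day after a concentration
#'     increase, with intake staying below `quit_level` times the
#'     pre-drop condition-mean intake for the remainder of the task
#'     (durable cessation; avoider);
#'   \item `plateau`: the final condition's intake is flat (all
#'     within-condition day-to-day changes within `noise_band`) — the
#'     consumption has stopped rising (titration plateau; non-avoider);
#'   \item `monotone_increase`: otherwise non-avoider; the rule label is
#'     `monotone_increase` when intake rose over the task
#'     (`min_delta > -noise_band`, or final condition mean above the first
#'     drug condition mean), else `plateau`.
#' }
#' Rule precedence for mice that both stay low and drop is `low_intake`
#' first — an operational choice, documented rather than asserted.
#'
#' @param daily Output of [daily_metrics()] for one mouse.
#' @param sched The [schedule].
#' @param params A [phenotype_params()].
#' @return List of class `phenotype_call`: `mouse_id`, `label`
#'   (`"avoider"` / `"non_avoider"`), `rule`, `features` (named list:
#'   `min_delta`, `max_delta`, `max_intake`, `final_pct`,
#'   `habituation_pct`), `aversion_threshold_conc` (µg/ml or `NA`).
#' @export
classify_avoider <- function(daily, sched, params = phenotype_params()) {
  drug <- daily[daily$concentration > 0 & !daily$missing, , drop = FALSE]
  drug <- drug[order(drug$day), , drop = FALSE]
  if (nrow(drug) < 2L)
    stop("classification needs at least 2 drug days with data for mouse ",
         daily$mouse_id[1L])
  dl <- intake_deltas(daily)
  conds <- unique(sched$condition_id[sched$concentration > 0])
  last_cond <- conds[length(conds)]
  cond_mean <- function(cid) {
    v <- drug$intake_mg_per_kg[drug$condition_id == cid]
    if (length(v)) mean(v) else NA_real_
  }
  feats <- list(
    min_delta = dl$min_delta, max_delta = dl$max_delta,
    max_intake = max(drug$intake_mg_per_kg),
    final_pct = {
      v <- drug$pct_drug[drug$condition_id == last_cond]
      if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_
    },
    habituation_pct = habituation_preference(daily))

  finish <- function(label, rule) {
    thr <- if (label == "avoider")
      aversion_threshold(condition_summaries(daily, sched), sched, params)
    else NA_real_
    structure(list(mouse_id = daily$mouse_id[1L], label = label,
                   rule = rule, features = feats,
                   aversion_threshold_conc = thr),
              class = "phenotype_call")
  }

  # 1. constitutive low intake
  if (feats$max_intake < params$low_intake_ceiling)
    return(finish("avoider", "low_intake"))

  # 2. abrupt, durable drop anchored to a concentration increase
  dd <- dl$deltas
  cand <- which(dd$delta < -params$noise_band & dd$after_increase)
  for (k in cand) {
    to_day <- dd$to_day[k]
    # reference level: mean intake of the condition preceding the
    # concentration increase tied to this drop
    inc_day <- to_day
    if (sched$concentration[match(to_day, sched$day)] ==
        sched$concentration[match(to_day - 1L, sched$day)])
      inc_day <- dd$from_day[k]
    ref_cond <- sched$condition_id[match(inc_day - 1L, sched$day)]
    ref <- cond_mean(ref_cond)
    if (!is.finite(ref) || ref <= 0) ref <-
      drug$intake_mg_per_kg[match(dd$from_day[k], drug$day)]
    quit_at <- params$quit_level * ref
    later <- drug$intake_mg_per_kg[drug$day >= to_day]
    if (is.finite(quit_at) && quit_at > 0 && all(later < quit_at))
      return(finish("avoider", "abrupt_drop"))
  }

  # 3./4. non-avoider: plateau vs continuing increase
  last_days <- drug$intake_mg_per_kg[drug$condition_id == last_cond]
  flat_last <- length(last_days) >= 2L &&
    all(abs(diff(last_days)) <= params$noise_band)
  if (flat_last)
    return(finish("non_avoider", "plateau"))
  rising <- dl$min_delta > -params$noise_band ||
    (is.finite(cond_mean(conds[1L])) &&
     cond_mean(last_cond) > cond_mean(conds[1L]) + params$noise_band)
  finish("non_avoider", if (rising) "monotone_increase" else "plateau")
}

#' Per-mouse aversion-threshold concentration
#'
#' For an avoider, the lowest nicotine concentration whose condition-mean
#' percent consumption falls below `avoid_pct` and stays below it for all
#' later conditions — the concentration at which aversion was triggered.
#' `NA` when no such concentration exists.
#'
#' @param summaries Output of [condition_summaries()] for one mouse.
#' @param sched The [schedule].
#' @param params A [phenotype_params()].
#' @return Concentration in µg/ml, or `NA`.
#' @export
aversion_threshold <- function(summaries, sched,
                               params = phenotype_params()) {
  conds <- unique(sched$condition_id[sched$concentration > 0])
  pct <- summaries$mean_pct[match(conds, summaries$condition_id)]
  conc <- summaries$concentration[match(conds, summaries$condition_id)]
  below <- is.finite(pct) & pct < params$avoid_pct
  # lowest concentration from which every later condition is avoided
  ok <- rev(cumprod(rev(below))) == 1
  if (!any(ok)) return(NA_real_)
  conc[which(ok)[1L]]
}

#' Phenotype an entire cohort
#'
#' Applies the habituation side-bias exclusion, then the avoider
#' classification, to every mouse.
#'
#' @param daily_all [daily_metrics()] rows for all mice (stacked).
#' @param sched The [schedule].
#' @param params A [phenotype_params()].
#' @return Data frame, one row per mouse: `mouse_id`, `label` (`avoider`,
#'   `non_avoider`, `excluded`), `rule`, `min_delta`, `max_delta`,
#'   `max_intake`, `final_pct`, `habituation_pct`,
#'   `aversion_threshold_conc`.
#' @export
phenotype_cohort <- function(daily_all, sched,
                             params = phenotype_params()) {
  rows <- lapply(split(daily_all, daily_all$mouse_id), function(d) {
    hab <- habituation_preference(d)
    ex <- exclude_side_bias(hab, params)
    if (!ex$keep)
      return(data.frame(mouse_id = d$mouse_id[1L], label = "excluded",
                        rule = "side_bias_exclusion", min_delta = NA_real_,
                        max_delta = NA_real_, max_intake = NA_real_,
                        final_pct = NA_real_, habituation_pct = hab,
                        aversion_threshold_conc = NA_real_,
                        stringsAsFactors = FALSE))
    cl <- classify_avoider(d, sched, params)
    data.frame(mouse_id = cl$mouse_id, label = cl$label, rule = cl$rule,
               min_delta = cl$features$min_delta,
               max_delta = cl$features$max_delta,
               max_intake = cl$features$max_intake,
               final_pct = cl$features$final_pct,
               habituation_pct = cl$features$habituation_pct,
               aversion_threshold_conc = cl$aversion_threshold_conc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Phenotype counts and proportions per group
#'
#' Tabulates avoiders and non-avoiders (excluded mice dropped) per group;
#' the 2x2 avoider-by-group count table feeds [chi_squared_yates()].
#'
#' @param calls Output of [phenotype_cohort()].
#' @param grouping Optional named character vector `mouse_id -> group`;
#'   one group when omitted.
#' @return Data frame: `group`, `n`, `n_avoider`, `n_non_avoider`,
#'   `prop_avoider`.
#' @export
cohort_phenotype_table <- function(calls, grouping = NULL) {
  calls <- calls[calls$label != "excluded", , drop = FALSE]
  grp <- if (is.null(grouping)) rep("all", nrow(calls))
         else unname(grouping[calls$mouse_id])
  out <- do.call(rbind, lapply(split(calls, grp), function(s)
    data.frame(group = grp[match(s$mouse_id[1L], calls$mouse_id)],
               n = nrow(s), n_avoider = sum(s$label == "avoider"),
               n_non_avoider = sum(s$label == "non_avoider"),
               prop_avoider = mean(s$label == "avoider"),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
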