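#' Run the full behavioral pipeline on a cohort
#'
#' Convenience wrapper chaining [daily_metrics()], [condition_summaries()],
#' [phenotype_cohort()] and [ternary_points()] over every mouse of a
#' cohort list as produced by [reference_cohort()] / [minipump_cohort()]
#' (or assembled by hand: named `logs`, `records`, `schedule`).
#'
#' @param cohort List with `logs`, `records`, `schedule`.
#' @param params A [phenotype_params()].
#' @return List: `daily` (stacked per-day metrics), `summaries`
#'   (per mouse x condition), `phenotypes` (per mouse),
#'   `points` (pseudo-ternary points), `schedule`.
#' @export
cohort_pipeline <- function(cohort, params = phenotype_params()) {
  sched <- cohort$schedule
  ids <- names(cohort$logs)
  daily <- do.call(rbind, lapply(ids, function(id)
    daily_metrics(cohort$logs[[id]], sched, cohort$records[[id]])))
  summaries <- condition_summaries(daily, sched)
  phenotypes <- phenotype_cohort(daily, sched, params)
  points <- ternary_points(summaries)
  list(daily = daily, summaries = summaries, phenotypes = phenotypes,
       points = points, schedule = sched)
}

#' Group mean intake at a given concentration
#'
#' Mean (and s.e.m.) over mice of the per-mouse condition-mean intake at
#' one concentration, split by phenotype label or an arbitrary grouping.
#'
#' @param pipeline Output of [cohort_pipeline()].
#' @param concentration Concentration (µg/ml) selecting the condition.
#' @param by `"label"` (phenotype) or a named vector `mouse_id -> group`.
#' @return Data frame `group`, `mean_intake`, `sem`, `n`.
#' @export
group_mean_intake <- function(pipeline, concentration, by = "label") {
  s <- pipeline$summaries
  s <- s[s$concentration == concentration & is.finite(s$mean_intake), ,
         drop = FALSE]
  grp <- if (identical(by, "label")) {
    lab <- pipeline$phenotypes$label
    names(lab) <- pipeline$phenotypes$mouse_id
    unname(lab[s$mouse_id])
  } else unname(by[s$mouse_id])
  s <- s[!is.na(grp) & grp != "excluded", , drop = FALSE]
  grp <- grp[!is.na(grp) & grp != "excluded"]
  out <- do.call(rbind, lapply(split(s$mean_intake, grp), function(v)
    data.frame(mean_intake = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                     else 0,
               n = length(v))))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out
}
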