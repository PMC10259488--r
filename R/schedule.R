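#' Experiment schedule: concentration and drug side per day
#'
#' A `schedule` records, for each experimental day, the nicotine
#' concentration in the drug bottle (µg/ml) and which physical side holds
#' it. During habituation (concentration 0, both bottles water) the side is
#' `"none"`, but a *virtual* side is still assigned by continuing the
#' task's alternation pattern backwards, so that habituation side
#' preferences and water-vs-water pseudo-ternary points can be computed.
#' Condition identifiers are derived as maximal runs of equal
#' concentration.
#'
#' @param day Integer vector of 1-based day indices (consecutive from 1).
#' @param concentration Nicotine concentration (µg/ml) per day, `>= 0`.
#' @param side `"left"`, `"right"` or `"none"` per day; must not be
#'   `"none"` on a day with positive concentration.
#' @param vehicle Description of the vehicle solution.
#' @param day_offset_minutes Offset of the day boundary from experiment
#'   start (minutes); day d spans minutes
#'   `[1440 (d-1) + offset, 1440 d + offset)`.
#' @return Object of class `schedule`: a data frame with columns `day`,
#'   `concentration`, `side`, `virtual_side`, `condition_id` and attributes
#'   `vehicle`, `day_offset_minutes`.
#' @export
schedule <- function(day, concentration, side,
                     vehicle = "2% saccharine", day_offset_minutes = 0) {
  day <- as.integer(day)
  concentration <- as.numeric(concentration)
  side <- as.character(side)
  n <- length(day)
  if (n == 0L) stop("empty schedule")
  if (!identical(day, seq_len(n)))
    stop("schedule days must be consecutive 1-based indices")
  if (length(concentration) != n || length(side) != n)
    stop("schedule columns must have equal length")
  if (any(concentration < 0)) stop("negative concentration in schedule")
  if (!all(side %in% c("left", "right", "none")))
    stop("side must be left, right or none")
  if (any(concentration > 0 & side == "none"))
    stop("drug side missing on a day with positive concentration")

  # condition ids: maximal runs of equal concentration
  run <- cumsum(c(TRUE, diff(concentration) != 0))
  condition_id <- vapply(seq_len(n), function(i) {
    if (concentration[i] == 0) sprintf("hab%02d", run[i])
    else sprintf("nic%g_%02d", concentration[i], run[i])
  }, character(1))

  # virtual side: actual side where defined, else alternation pattern
  # continued backwards from the first defined day (default left)
  virtual <- side
  if (any(side == "none")) {
    first_def <- which(side != "none")[1L]
    pattern <- if (is.na(first_def)) "left" else side[first_def]
    other <- if (pattern == "left") "right" else "left"
    idx <- which(side == "none")
    # alternate every other day, aligned to the 2-day swap blocks
    block <- ((idx - 1L) %/% 2L) %% 2L
    virtual[idx] <- ifelse(block == 0L, pattern, other)
  }

  out <- data.frame(day = day, concentration = concentration, side = side,
                    virtual_side = virtual, condition_id = condition_id,
                    stringsAsFactors = FALSE)
  attr(out, "vehicle") <- vehicle
  attr(out, "day_offset_minutes") <- day_offset_minutes
  class(out) <- c("schedule", "data.frame")
  out
}

#' Standard ascending-concentration two-bottle choice schedule
#'
#' Builds the canonical paradigm: a water-vs-water habituation block, then
#' consecutive conditions at increasing nicotine concentrations, the
#' bottles being swapped every other day to control for side bias.
#'
#' @param habituation_days Days of water vs water before the drug phase.
#' @param concentrations Nicotine concentrations (µg/ml), one condition each.
#' @param days_per_concentration Days spent at each concentration.
#' @param start_side Side holding nicotine on the first drug day.
#' @param swap_every Days between bottle swaps (2 = every other day).
#' @inheritParams schedule
#' @return A [schedule].
#' @examples
#' sched <- two_bottle_schedule()
#' table(sched$condition_id)
#' @export
two_bottle_schedule <- function(habituation_days = 4,
                                concentrations = c(10, 50, 100, 200),
                                days_per_concentration = 4,
                                start_side = "left", swap_every = 2,
                                vehicle = "2% saccharine",
                                day_offset_minutes = 0) {
  n_drug <- length(concentrations) * days_per_concentration
  conc <- c(rep(0, habituation_days),
            rep(concentrations, each = days_per_concentration))
  other <- if (start_side == "left") "right" else "left"
  drug_sides <- ifelse((((seq_len(n_drug) - 1L) %/% swap_every) %% 2L) == 0L,
                       start_side, other)
  side <- c(rep("none", habituation_days), drug_sides)
  schedule(seq_along(conc), conc, side, vehicle = vehicle,
           day_offset_minutes = day_offset_minutes)
}

#' Single-step exposure schedule
#'
#' Habituation followed directly by one high concentration, as used to
#' probe aversion without gradual exposure (e.g. after chronic minipump
#' pretreatment).
#'
#' @param concentration The single nicotine concentration (µg/ml).
#' @param drug_days Days at that concentration.
#' @inheritParams two_bottle_schedule
#' @return A [schedule].
#' @export
single_step_schedule <- function(concentration = 100, habituation_days = 4,
                                 drug_days = 4, start_side = "left",
                                 swap_every = 2, vehicle = "2% saccharine") {
  two_bottle_schedule(habituation_days = habituation_days,
                      concentrations = concentration,
                      days_per_concentration = drug_days,
                      start_side = start_side, swap_every = swap_every,
                      vehicle = vehicle)
}

#' Read a schedule from YAML
#'
#' Layout:
#' ```yaml
#' vehicle: 2% saccharine
#' day_offset_minutes: 0
#' days:
#'   - {day: 1, concentration: 0, side: none}
#'   - {day: 5, concentration: 10, side: left}
#' ```
#'
#' @param path Path to the YAML file.
#' @return A [schedule].
#' @export
read_schedule <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$days) || length(y$days) == 0L)
    stop("schedule file has no days: ", path)
  d <- do.call(rbind, lapply(y$days, function(r)
    data.frame(day = r$day, concentration = r$concentration,
               side = as.character(r$side), stringsAsFactors = FALSE)))
  d <- d[order(d$day), , drop = FALSE]
  schedule(d$day, d$concentration, d$side,
           vehicle = if (is.null(y$vehicle)) "2% saccharine" else y$vehicle,
           day_offset_minutes =
             if (is.null(y$day_offset_minutes)) 0 else y$day_offset_minutes)
}

#' Write a schedule to YAML
#' @param sched A [schedule].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(sched, path) {
  y <- list(vehicle = attr(sched, "vehicle"),
            day_offset_minutes = attr(sched, "day_offset_minutes"),
            days = lapply(seq_len(nrow(sched)), function(i)
              list(day = sched$day[i],
                   concentration = sched$concentration[i],
                   side = sched$side[i])))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @export
print.schedule <- function(x, ...) {
  conds <- unique(x$condition_id)
  cat("<schedule>", nrow(x), "days,", length(conds), "conditions:",
      paste(conds, collapse = ", "), "\n")
  invisible(x)
}

#' Span of a day in log minutes
#' @param sched A [schedule].
#' @param day Day index (vectorised).
#' @return Two-column matrix `start`, `end`: minutes `[start, end)`.
#' @keywords internal
day_span <- function(sched, day) {
  off <- attr(sched, "day_offset_minutes")
  if (is.null(off)) off <- 0
  cbind(start = 1440 * (day - 1) + off, end = 1440 * day + off)
}
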