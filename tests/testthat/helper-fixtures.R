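# Small fixtures built in code.

# A hand-sized log: one mouse, known per-day volumes.
toy_log <- function(mouse_id = "t1") {
  # day 1: 1.0 ml left + 0.5 ml right; day 2: 0.2 left + 2.0 right
  drink_log(mouse_id,
            minute = c(10, 500, 1300, 1439, 1500, 2200, 2879),
            volume_left = c(0.4, 0.8, 1.0, 1.0, 1.1, 1.2, 1.2),
            volume_right = c(0.1, 0.3, 0.5, 0.5, 1.0, 2.0, 2.5))
}

toy_schedule <- function() {
  schedule(day = 1:2, concentration = c(100, 100),
           side = c("left", "right"))
}

toy_record <- function(mouse_id = "t1", w = c("1" = 25.0)) {
  mouse_record(mouse_id, w)
}

# Build a drink_log directly from per-day (left, right) volume targets,
# one observation per day at the day's last minute (deterministic).
log_from_daily_volumes <- function(mouse_id, v_left, v_right) {
  n <- length(v_left)
  drink_log(mouse_id, minute = 1440 * seq_len(n) - 1,
            volume_left = cumsum(v_left), volume_right = cumsum(v_right))
}

# Daily-metrics table straight from intake/percent targets, bypassing the
# log layer, for classifier unit tests.
daily_from_intake <- function(intake, sched, pct = NULL, mouse_id = "x1",
                              weight = 25) {
  stopifnot(length(intake) == nrow(sched))
  vol_drug <- ifelse(sched$concentration > 0,
                     intake * weight / pmax(sched$concentration, 1), 1.5)
  if (is.null(pct)) pct <- ifelse(sched$concentration > 0, 50, 50)
  total <- ifelse(pct > 0, vol_drug / (pct / 100), vol_drug + 2)
  v_veh <- pmax(total - vol_drug, 0)
  side <- ifelse(sched$concentration > 0, sched$side, sched$virtual_side)
  data.frame(mouse_id = mouse_id, day = sched$day,
             condition_id = sched$condition_id,
             concentration = sched$concentration, drug_side = side,
             vol_left = ifelse(side == "left", vol_drug, v_veh),
             vol_right = ifelse(side == "left", v_veh, vol_drug),
             vol_drug_ml = vol_drug, vol_vehicle_ml = v_veh,
             pct_drug = pct, pct_left = 50,
             intake_mg_per_kg = intake, weight_g = weight,
             missing = FALSE, stringsAsFactors = FALSE)
}

# Independent brute-force daily volumes: per-minute increments summed
# inside the day span, reconstructing the full minute grid.
brute_daily_volumes <- function(log, sched) {
  full <- 0:(1440 * nrow(sched) - 1)
  step <- function(v) {
    idx <- findInterval(full, log$minute)
    c(0, v)[idx + 1L]
  }
  cl <- step(log$volume_left); cr <- step(log$volume_right)
  inc_l <- diff(c(0, cl)); inc_r <- diff(c(0, cr))
  day <- full %/% 1440 + 1
  data.frame(day = sort(unique(day)),
             v_left = as.numeric(tapply(inc_l, day, sum)),
             v_right = as.numeric(tapply(inc_r, day, sum)))
}

# Mirror a cohort left<->right: logs, schedule sides.
mirror_cohort <- function(cohort) {
  flip <- function(s) c(left = "right", right = "left", none = "none")[s]
  logs <- lapply(cohort$logs, function(l) {
    drink_log(attr(l, "mouse_id"), l$minute, l$volume_right, l$volume_left)
  })
  sc <- cohort$schedule
  sched <- schedule(sc$day, sc$concentration, unname(flip(sc$side)),
                    vehicle = attr(sc, "vehicle"),
                    day_offset_minutes = attr(sc, "day_offset_minutes"))
  list(logs = logs, records = cohort$records, truth = cohort$truth,
       schedule = sched)
}
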