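test_that("daily metrics compute intake and percent consumption per day", {
  dm <- daily_metrics(toy_log(), toy_schedule(), toy_record())
  # day 1, drug left: 1.0 ml at 100 µg/ml, 25 g -> 4 mg/kg/day
  expect_equal(dm$vol_drug_ml[1], 1.0)
  expect_equal(dm$intake_mg_per_kg[1], 1.0 * 100 / 25)
  expect_equal(dm$pct_drug[1], 100 * 1.0 / 1.5)
  # day 2, drug right: 2.0 ml
  expect_equal(dm$vol_drug_ml[2], 2.0)
  expect_equal(dm$pct_drug[2], 100 * 2.0 / 2.2)

  # forced arithmetic: 2.5 ml at 100 µg/ml, 25 g -> 10 mg/kg/day
  log <- log_from_daily_volumes("f", 2.5, 1.5)
  sched <- schedule(1, 100, "left")
  dm2 <- daily_metrics(log, sched, toy_record("f"))
  expect_equal(dm2$intake_mg_per_kg, 10)
  # equal volumes -> 50%
  dm3 <- daily_metrics(log_from_daily_volumes("f", 2, 2), sched,
                       toy_record("f"))
  expect_equal(dm3$pct_drug, 50)
})

test_that("habituation days have zero intake and optional virtual-side percent", {
  sched <- two_bottle_schedule(habituation_days = 2,
                               concentrations = 100,
                               days_per_concentration = 2)
  log <- log_from_daily_volumes("h", c(1, 1, 1, 1), c(1, 3, 1, 1))
  dm <- daily_metrics(log, sched, toy_record("h"))
  expect_equal(dm$intake_mg_per_kg[1:2], c(0, 0))
  expect_equal(dm$pct_drug[1], 50)   # virtual side left on day 1
  dm_na <- daily_metrics(log, sched, toy_record("h"),
                         habituation_pct = "na")
  expect_true(all(is.na(dm_na$pct_drug[1:2])))
})

test_that("uncovered days are flagged missing, not scored as zero", {
  # no observation at all during day 2
  log <- drink_log("g", c(100, 1439, 2900, 4319),
                   c(0.5, 1.0, 1.4, 2.0), c(0.2, 0.4, 0.8, 1.0))
  sched <- schedule(1:3, c(100, 100, 100), c("left", "left", "right"))
  dm <- daily_metrics(log, sched, toy_record("g"))
  expect_false(dm$missing[1])
  expect_true(dm$missing[2])
  expect_true(is.na(dm$intake_mg_per_kg[2]))
  # condition mean uses remaining days only
  cs <- condition_summaries(dm, sched)
  expect_equal(cs$n_used, 2L)
  expect_equal(cs$mean_intake,
               mean(dm$intake_mg_per_kg[c(1, 3)]))
})

test_that("volumes are conserved and metrics match a brute-force per-minute oracle", {
  set.seed(23)
  sched <- two_bottle_schedule(habituation_days = 1,
                               concentrations = c(50, 100),
                               days_per_concentration = 2)
  for (rep in 1:10) {
    n <- sample(30:80, 1)
    minutes <- sort(sample(0:(1440 * 5 - 1), n))
    log <- drink_log("o", minutes,
                     cumsum(round(runif(n, 0, 0.1), 3)),
                     cumsum(round(runif(n, 0, 0.1), 3)))
    dm <- daily_metrics(log, sched, toy_record("o"))
    oracle <- brute_daily_volumes(log, sched)
    expect_equal(dm$vol_left, oracle$v_left, tolerance = 1e-9)
    expect_equal(dm$vol_right, oracle$v_right, tolerance = 1e-9)
    # conservation: drug + vehicle = both-bottle increment
    expect_equal(dm$vol_drug_ml + dm$vol_vehicle_ml,
                 dm$vol_left + dm$vol_right, tolerance = 1e-9)
  }
})

test_that("condition summaries average by side to give (%c1, %c2)", {
  sched <- schedule(1:4, rep(100, 4), c("left", "left", "right", "right"))
  dm <- daily_from_intake(rep(5, 4), sched, pct = c(90, 92, 10, 8))
  cs <- condition_summaries(dm, sched)
  expect_equal(cs$pct_c1, 91)
  expect_equal(cs$pct_c2, 9)
  expect_equal(cs$mean_pct, 50)
  # mean intake of (8, 10, 12, 10) is 10
  cs2 <- condition_summaries(daily_from_intake(c(8, 10, 12, 10), sched),
                             sched)
  expect_equal(cs2$mean_intake, 10)
})

test_that("intake deltas cover drug days only with min/max extraction", {
  sched <- schedule(1:5, c(0, 50, 50, 50, 50),
                    c("none", "left", "left", "right", "right"))
  dm <- daily_from_intake(c(0, 2, 4, 3, 5), sched)
  dl <- intake_deltas(dm)
  expect_equal(dl$deltas$delta, c(2, -1, 2))
  expect_equal(dl$min_delta, -1)
  expect_equal(dl$max_delta, 2)
  # monotone series: min positive; constant low series: both near zero
  expect_gt(intake_deltas(daily_from_intake(c(0, 1, 2, 3, 4),
                                            sched))$min_delta, 0)
  dl0 <- intake_deltas(daily_from_intake(c(0, 0.5, 0.5, 0.5, 0.5), sched))
  expect_equal(dl0$min_delta, 0)
  expect_equal(dl0$max_delta, 0)
  # fewer than 2 drug days errors
  s1 <- schedule(1:2, c(0, 50), c("none", "left"))
  expect_error(intake_deltas(daily_from_intake(c(0, 1), s1)),
               "at least 2 drug days")
})

test_that("titration transitions are flagged by intake adjustment speed", {
  sched <- two_bottle_schedule(habituation_days = 0,
                               concentrations = c(50, 100),
                               days_per_concentration = 2)
  rec <- toy_record("t")
  # schedule sides are L, L, R, R: put the target volume on the drug side
  # perfect titrator: drug-side volume halves when concentration doubles
  log <- log_from_daily_volumes("t", c(2, 2, 1, 1), c(1, 1, 1, 1))
  tr <- titration_response(daily_metrics(log, sched, rec), sched)
  expect_true(tr$rapid)
  expect_equal(tr$post_1, tr$pre_mean, tolerance = 1e-9)
  # constant-volume drinker: intake doubles across the step
  log2 <- log_from_daily_volumes("t", c(2, 2, 1, 1), c(1, 1, 2, 2))
  tr2 <- titration_response(daily_metrics(log2, sched, rec), sched)
  expect_false(tr2$rapid)
  expect_equal(tr2$post_1 / tr2$pre_mean, 2, tolerance = 1e-9)
})

test_that("relabeling sides leaves intake and deltas unchanged, swaps side percents", {
  set.seed(41)
  sched <- two_bottle_schedule()
  p <- archetype_params("tracker", drug_volume = 2.5)
  sim <- simulate_mouse(p, sched, "s1", seed = 77)
  coh <- list(logs = list(s1 = sim$log), records = list(s1 = sim$record),
              schedule = sched)
  mir <- mirror_cohort(coh)
  dm <- daily_metrics(coh$logs$s1, coh$schedule, sim$record)
  dm2 <- daily_metrics(mir$logs[[1]], mir$schedule, sim$record)
  expect_equal(dm2$intake_mg_per_kg, dm$intake_mg_per_kg, tolerance = 1e-9)
  expect_equal(dm2$pct_drug, dm$pct_drug, tolerance = 1e-9)
  cs <- condition_summaries(dm, coh$schedule)
  cs2 <- condition_summaries(dm2, mir$schedule)
  expect_equal(cs2$pct_c1, cs$pct_c2, tolerance = 1e-9)
  expect_equal(cs2$pct_c2, cs$pct_c1, tolerance = 1e-9)
  expect_equal(intake_deltas(dm2)$deltas$delta,
               intake_deltas(dm)$deltas$delta, tolerance = 1e-9)
})

test_that("intake scales linearly in concentration and inversely in weight", {
  log <- log_from_daily_volumes("u", c(2, 2), c(1, 1))
  s100 <- schedule(1:2, c(100, 100), c("left", "right"))
  s200 <- schedule(1:2, c(200, 200), c("left", "right"))
  i100 <- daily_metrics(log, s100, toy_record("u"))$intake_mg_per_kg
  i200 <- daily_metrics(log, s200, toy_record("u"))$intake_mg_per_kg
  expect_equal(i200, 2 * i100)
  heavy <- toy_record("u", c("1" = 50.0))
  expect_equal(daily_metrics(log, s100, heavy)$intake_mg_per_kg, i100 / 2)
})
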