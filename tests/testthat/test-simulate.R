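test_that("generated logs always satisfy the cumulative-volume invariants", {
  sched <- two_bottle_schedule()
  set.seed(51)
  for (arch in c("tracker", "side_biased", "avoider_abrupt",
                 "avoider_low")) {
    sim <- simulate_mouse(archetype_params(arch), sched, "inv")
    log <- sim$log
    expect_true(!is.unsorted(log$minute, strictly = TRUE))
    expect_true(all(diff(log$volume_left) >= 0))
    expect_true(all(diff(log$volume_right) >= 0))
    # every schedule day has coverage
    dm <- daily_metrics(log, sched, sim$record)
    expect_false(any(dm$missing))
  }
})

test_that("the same seed reproduces the cohort exactly", {
  a <- reference_cohort(seed = 52)
  b <- reference_cohort(seed = 52)
  expect_identical(a$logs, b$logs)
  expect_identical(a$records, b$records)
  c <- reference_cohort(seed = 53)
  expect_false(identical(a$logs, c$logs))
})

test_that("limiting archetypes hit their nominal choice patterns", {
  sched <- two_bottle_schedule()
  # pure tracker: high drug preference at every condition
  set.seed(54)
  sim <- simulate_mouse(
    archetype_params("tracker", drug_volume = 4.2, total_volume = 4.4),
    sched, "tr")
  cs <- condition_summaries(daily_metrics(sim$log, sched, sim$record),
                            sched)
  drug <- cs[cs$concentration > 0, ]
  expect_true(all(drug$mean_pct > 85))

  # fixed-side drinker: one side-wise percent high, the other low
  set.seed(55)
  sb <- simulate_mouse(
    archetype_params("side_biased", preference_side = "left",
                     preference_strength = 0.97), sched, "sb")
  css <- condition_summaries(daily_metrics(sb$log, sched, sb$record),
                             sched)
  drg <- css[css$concentration > 0, ]
  expect_true(all(drg$pct_c1 > 90))
  expect_true(all(drg$pct_c2 < 10))
})

test_that("abrupt-avoider simulation closes the loop with the classifier", {
  sched <- two_bottle_schedule()
  set.seed(56)
  sim <- simulate_mouse(
    archetype_params("avoider_abrupt", aversion_threshold = 200,
                     drug_volume = 1.7, residual_volume = 0.005),
    sched, "av")
  dm <- daily_metrics(sim$log, sched, sim$record)
  cl <- classify_avoider(dm, sched)
  expect_equal(cl$label, "avoider")
  expect_equal(cl$rule, "abrupt_drop")
  expect_equal(cl$aversion_threshold_conc, 200)
})

test_that("the reference cohort has the documented composition and calibration", {
  coh <- reference_cohort(seed = 101)
  expect_equal(nrow(coh$truth), 35L)
  expect_equal(sum(coh$truth$true_label == "avoider"), 17L)
  pl <- cohort_pipeline(coh)
  # nobody excluded: habituation preferences all inside (20, 80)
  expect_equal(sum(pl$phenotypes$label == "excluded"), 0L)
  hab <- pl$phenotypes$habituation_pct
  expect_true(all(hab > 20 & hab < 80))
  gi <- group_mean_intake(pl, 200)
  non <- gi$mean_intake[gi$group == "non_avoider"]
  expect_lt(abs(non - 16.9) / 16.9, 0.15)
})

test_that("tracker cohorts titrate rapidly at the 50 to 100 step", {
  sched <- two_bottle_schedule()
  set.seed(57)
  rapid <- vapply(1:12, function(i) {
    sim <- simulate_mouse(
      archetype_params("tracker", drug_volume = 2.4,
                       plateau_intake = 5),
      sched, sprintf("t%02d", i))
    dm <- daily_metrics(sim$log, sched, sim$record)
    tr <- titration_response(dm, sched, tolerance = 0.35)
    tr$rapid[tr$conc_from == 50 & tr$conc_to == 100]
  }, logical(1))
  # titrating trackers hold intake through the step on the first day
  expect_gte(mean(rapid), 0.5)
})

test_that("avoider trajectories collapse toward the zero-consumption apex", {
  coh <- reference_cohort(seed = 58)
  pl <- cohort_pipeline(coh)
  lab <- stats::setNames(pl$phenotypes$label, pl$phenotypes$mouse_id)
  g <- group_apex_distances(pl$points, lab)
  d0 <- g[g$apex == "zero" & g$group == "avoider", ]
  expect_lt(d0$mean[d0$concentration == 200],
            d0$mean[d0$concentration == 0])
  # side-biased mice stay near the side apex throughout
  # side-biased mice stay near the side apex across all drug conditions
  arch <- stats::setNames(coh$truth$archetype, coh$truth$mouse_id)
  gs <- group_apex_distances(pl$points, arch)
  ds <- gs[gs$apex == "side" & gs$group == "side_biased" &
           gs$concentration > 0, ]
  expect_true(all(ds$mean < 40))
  expect_lt(max(ds$mean) - min(ds$mean), 15)
})

test_that("ephys ensembles attach usable ground truth", {
  g <- simulate_ephys_group(12, current_mean_pA = 200, seed = 59,
                            frac_inhibited = 0.25)
  expect_length(g$currents$traces, 12L)
  expect_length(g$rates$trains, 12L)
  expect_equal(mean(g$currents$truth), 200, tolerance = 0.5)
  expect_gte(sum(g$rates$truth$delta_pct < 0), 1L)
  # zero-amplitude group extracts near-zero amplitudes
  z <- simulate_current_traces(10, 0, seed = 60)
  az <- vapply(z$traces,
               function(tr) puff_current_amplitude(tr)$amplitude,
               numeric(1))
  expect_true(all(az < 10))
})
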