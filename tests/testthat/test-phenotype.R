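std_sched <- two_bottle_schedule()

# intake trajectory across the 20-day standard task (4 hab + 16 drug)
intake_traj <- function(drug) c(rep(0, 4), drug)

test_that("habituation side-bias exclusion uses strict 20/80 bounds", {
  expect_true(exclude_side_bias(50)$keep)
  expect_false(exclude_side_bias(19.9)$keep)
  expect_false(exclude_side_bias(80.1)$keep)
  # boundaries themselves are kept
  expect_true(exclude_side_bias(20)$keep)
  expect_true(exclude_side_bias(80)$keep)
  ex <- exclude_side_bias(NA_real_)
  expect_false(ex$keep)
  expect_match(ex$reason, "no habituation drinking")
})

test_that("constitutively low intake classifies as avoider via the 2 mg/kg/day ceiling", {
  dm <- daily_from_intake(intake_traj(rep(1.5, 16)), std_sched)
  cl <- classify_avoider(dm, std_sched)
  expect_equal(cl$label, "avoider")
  expect_equal(cl$rule, "low_intake")
})

test_that("abrupt durable drop after a concentration step classifies as avoider", {
  # rises 2 -> 6 -> 12, collapses right after the 100 -> 200 step
  drug <- c(2, 2.2, 2.4, 2.5, 6, 6.2, 6.1, 6.3, 12, 12.2, 12.1, 12.3,
            13, 0.3, 0.2, 0.2)
  pct <- c(rep(50, 4), rep(45, 13), rep(2, 3))
  dm <- daily_from_intake(intake_traj(drug), std_sched, pct = pct)
  cl <- classify_avoider(dm, std_sched)
  expect_equal(cl$label, "avoider")
  expect_equal(cl$rule, "abrupt_drop")
  expect_equal(cl$aversion_threshold_conc, 200)
})

test_that("a transient dip that recovers is not durable cessation", {
  drug <- c(2, 2.2, 2.4, 2.5, 6, 6.2, 6.1, 6.3, 12, 12.2, 12.1, 12.3,
            4, 13, 14, 15)
  dm <- daily_from_intake(intake_traj(drug), std_sched)
  cl <- classify_avoider(dm, std_sched)
  expect_equal(cl$label, "non_avoider")
})

test_that("continuous increase and plateau both classify as non-avoider", {
  rising <- seq(1, 17, length.out = 16)
  cl <- classify_avoider(daily_from_intake(intake_traj(rising),
                                           std_sched), std_sched)
  expect_equal(cl$label, "non_avoider")
  expect_equal(cl$rule, "monotone_increase")
  expect_true(is.na(cl$aversion_threshold_conc))

  plat <- c(seq(1, 12, length.out = 12), 12.1, 12.2, 12.1, 12.2)
  cl2 <- classify_avoider(daily_from_intake(intake_traj(plat),
                                            std_sched), std_sched)
  expect_equal(cl2$label, "non_avoider")
  expect_equal(cl2$rule, "plateau")
})

test_that("aversion threshold is the lowest durably avoided concentration", {
  # avoided from the very first drug condition
  sm <- data.frame(mouse_id = "a",
                   condition_id = unique(std_sched$condition_id),
                   concentration = c(0, 10, 50, 100, 200),
                   mean_pct = c(50, 5, 4, 2, 1))
  expect_equal(aversion_threshold(sm, std_sched), 10)
  # only the last condition avoided
  sm$mean_pct <- c(50, 45, 44, 40, 3)
  expect_equal(aversion_threshold(sm, std_sched), 200)
  # a dip that recovers does not set the threshold
  sm$mean_pct <- c(50, 10, 45, 40, 3)
  expect_equal(aversion_threshold(sm, std_sched), 200)
  # never durably below: none
  sm$mean_pct <- c(50, 45, 44, 40, 30)
  expect_true(is.na(aversion_threshold(sm, std_sched)))
})

test_that("classification is invariant to side relabeling and volume rescaling", {
  coh <- reference_cohort(seed = 11)
  pl <- cohort_pipeline(coh)
  mir <- cohort_pipeline(mirror_cohort(coh))
  expect_equal(mir$phenotypes$label, pl$phenotypes$label)
  expect_equal(mir$phenotypes$rule, pl$phenotypes$rule)

  # uniform rescaling of volumes and weights cancels in mg/kg
  scale_cohort <- function(coh, f) {
    logs <- lapply(coh$logs, function(l)
      drink_log(attr(l, "mouse_id"), l$minute, f * l$volume_left,
                f * l$volume_right))
    records <- lapply(coh$records, function(r) {
      w <- f * r$weights
      names(w) <- r$weight_days
      mouse_record(r$mouse_id, w, r$tags)
    })
    list(logs = logs, records = records, schedule = coh$schedule)
  }
  sc <- cohort_pipeline(scale_cohort(coh, 2))
  expect_equal(sc$phenotypes$label, pl$phenotypes$label)
})

test_that("the classifier recovers generator labels on random cohorts", {
  seeds <- 300 + seq_len(25)
  acc <- vapply(seeds, function(s) {
    coh <- reference_cohort(seed = s)
    ph <- cohort_pipeline(coh)$phenotypes
    truth <- coh$truth$true_label[match(ph$mouse_id, coh$truth$mouse_id)]
    mean(ph$label == truth)
  }, numeric(1))
  # avoider recall/precision bundled into per-cohort label accuracy
  expect_gte(mean(acc), 0.9)
  expect_gte(min(acc), 0.8)
})

test_that("phenotype tables count avoiders per group", {
  calls <- data.frame(
    mouse_id = sprintf("m%d", 1:6),
    label = c("avoider", "non_avoider", "excluded", "avoider",
              "non_avoider", "non_avoider"),
    stringsAsFactors = FALSE)
  tab <- cohort_phenotype_table(
    calls, grouping = c(m1 = "wt", m2 = "wt", m3 = "wt", m4 = "ko",
                        m5 = "ko", m6 = "ko"))
  expect_equal(tab$n[tab$group == "wt"], 2L)
  expect_equal(tab$n_avoider[tab$group == "wt"], 1L)
  expect_equal(tab$prop_avoider[tab$group == "ko"], 1 / 3)
})
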