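test_that("puff amplitude extraction handles flat, stepped, and offset traces", {
  sr <- 2000
  flat <- current_trace("f", rep(-20, 10 * sr), sr, puff_time = 2)
  r <- puff_current_amplitude(flat)
  expect_equal(r$amplitude, 0)
  expect_equal(r$direction, "none")

  # baseline -10 pA stepping to -260 pA: amplitude 250 by arithmetic
  samples <- c(rep(-10, 2 * sr), rep(-260, 2 * sr))
  stepped <- current_trace("s", samples, sr, puff_time = 2)
  rs <- puff_current_amplitude(stepped, window = 1.5)
  expect_equal(rs$amplitude, 250, tolerance = 1e-6)
  expect_equal(rs$direction, "activated")

  # window exceeding the trace errors
  expect_error(puff_current_amplitude(stepped, window = 5), "exceeds")

  # invariance to a constant offset on the whole trace
  shifted <- current_trace("s2", samples + 120, sr, puff_time = 2)
  expect_equal(puff_current_amplitude(shifted, window = 1.5)$amplitude,
               rs$amplitude, tolerance = 1e-9)

  # an outward-going deflection is not a response
  outward <- current_trace("o", c(rep(-20, 2 * sr), rep(180, 2 * sr)),
                           sr, puff_time = 2)
  ro <- puff_current_amplitude(outward, window = 1.5)
  expect_equal(ro$amplitude, 0)
  expect_equal(ro$direction, "none")
})

test_that("programmed transient amplitudes are recovered from noisy traces", {
  sim <- simulate_current_traces(25, 250, cv = 0, seed = 301,
                                 noise_sd = 5)
  amps <- vapply(sim$traces,
                 function(tr) puff_current_amplitude(tr)$amplitude,
                 numeric(1))
  # each programmed 250 pA peak recovered within a noise-derived band
  expect_true(all(abs(amps - 250) < 3 * 5))
  expect_equal(mean(amps), 250, tolerance = 0.02)
})

test_that("firing-rate change recovers programmed rate excursions", {
  up <- simulate_spike_trains(rep(4, 30), rep(100, 30), seed = 302,
                              hold_s = 60)
  res <- lapply(up$trains, firing_rate_change)
  d <- vapply(res, `[[`, numeric(1), "amplitude")
  expect_true(all(vapply(res, `[[`, "", "direction") == "activated"))
  # extremum read-out overshoots a step modestly; centred near +100
  expect_equal(mean(d), 100, tolerance = 0.35)

  down <- simulate_spike_trains(rep(4, 30), rep(-50, 30), seed = 303)
  resd <- lapply(down$trains, firing_rate_change)
  dd <- vapply(resd, `[[`, numeric(1), "amplitude")
  dirs <- vapply(resd, `[[`, "", "direction")
  expect_gte(mean(dirs == "inhibited"), 0.9)
  expect_equal(mean(dd), -50, tolerance = 0.4)

  # zero baseline flags the change as undefined
  silent <- spike_train("z", numeric(0), injection_time = 300)
  expect_true(is.na(firing_rate_change(silent)$amplitude))
})

test_that("homogeneous Poisson trains yield rate changes centred on zero", {
  set.seed(101)
  h <- simulate_spike_trains(rep(5, 200), rep(0, 200))
  d <- vapply(h$trains,
              function(x) firing_rate_change(x)$amplitude, numeric(1))
  expect_lt(abs(mean(d)), 5)
})

test_that("recovered rate changes track programmed ground truth across a group", {
  set.seed(304)
  prog <- rnorm(40, 60, 40)
  tr <- simulate_spike_trains(rgamma(40, 4, 4 / 6), prog)
  rec <- vapply(tr$trains,
                function(x) firing_rate_change(x)$amplitude, numeric(1))
  slope <- unname(coef(lm(rec ~ prog))[2])
  expect_equal(slope, 1, tolerance = 0.35)
  expect_gt(cor(rec, prog), 0.8)
})

test_that("covariate regression reports internally consistent statistics", {
  set.seed(15)
  x <- runif(14, 1, 20)
  y <- 3 * x + rnorm(14, 0, 5)
  r <- covariate_regression(x, y)
  # F = R^2 / (1 - R^2) * (n - 2) and the adjusted R^2 identity, exactly
  expect_equal(r$f, r$r_squared / (1 - r$r_squared) * (r$n - 2),
               tolerance = 1e-9)
  expect_equal(r$adj_r_squared,
               1 - (1 - r$r_squared) * (r$n - 1) / (r$n - 2),
               tolerance = 1e-9)
  # perfectly collinear pairs
  expect_equal(
    suppressWarnings(covariate_regression(1:5, 2 * (1:5))$r_squared), 1)
  expect_error(covariate_regression(rep(3, 5), rnorm(5)), "zero variance")
  expect_error(covariate_regression(c(-1, 2, 3), rnorm(3), log_x = TRUE),
               "positive")
})

test_that("per-mouse averaging shields the dose-current regression from pseudo-replication", {
  set.seed(16)
  neurons <- data.frame(
    mouse_id = rep(sprintf("m%d", 1:8), times = sample(3:9, 8, TRUE)))
  dose <- stats::setNames(runif(8, 0.5, 15), sprintf("m%d", 1:8))
  neurons$value <- 400 - 60 * log10(dose[neurons$mouse_id]) +
    rnorm(nrow(neurons), 0, 40)
  per_mouse <- per_mouse_means(neurons)
  r1 <- covariate_regression(dose[per_mouse$mouse_id], per_mouse$value,
                             log_x = TRUE)
  # shuffling neurons within mice leaves the per-mouse regression unchanged
  shuffled <- neurons[sample(nrow(neurons)), ]
  pm2 <- per_mouse_means(shuffled)
  r2 <- covariate_regression(dose[pm2$mouse_id], pm2$value, log_x = TRUE)
  expect_equal(r1$slope, r2$slope, tolerance = 1e-9)
  expect_equal(r1$r_squared, r2$r_squared, tolerance = 1e-9)
  expect_lt(r1$slope, 0)
})

test_that("time-reversing a baseline-only train leaves changes centred on zero", {
  set.seed(17)
  h <- simulate_spike_trains(rep(6, 60), rep(0, 60))
  fwd <- vapply(h$trains,
                function(x) firing_rate_change(x)$amplitude, numeric(1))
  rev_d <- lapply(h$trains, function(x) {
    span <- x$injection_time + 240
    spike_train(x$neuron_id, sort(span - x$spike_times),
                injection_time = x$injection_time)
  })
  bwd <- vapply(rev_d,
                function(x) firing_rate_change(x)$amplitude, numeric(1))
  expect_lt(abs(mean(c(fwd, bwd))), 6)
})
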