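test_that("segmentation recovers the constructed cycle count and is deterministic", {
  tr <- make_trace(synthetic_trace_spec(duration = 12, step_period = 0.55,
                                        duty_cycle = 0.6))
  cyc <- segment_cycles(tr)
  expect_identical(nrow(cyc), as.integer(tr$truth$n_cycles_R))
  expect_true(all(cyc$duration == 1.1))
  cyc2 <- segment_cycles(tr)
  expect_identical(cyc, cyc2)
  # constant loading (no unloading) yields no cycles
  trc <- tr
  trc$grf[, "grf_R_vertical"] <- 800
  expect_message(c0 <- segment_cycles(trc), "fewer than 2")
  expect_identical(nrow(c0), 0L)
})

test_that("cycle normalization is exact on affine signals", {
  n <- 400
  start <- 100L; end <- 210L
  const <- rep(3.5, n)
  expect_identical(normalize_cycle(const, start, end), rep(3.5, 101))
  ramp <- seq_len(n) * 0.25
  out <- normalize_cycle(ramp, start, end)
  expected <- ramp[start] + (ramp[end] - ramp[start]) * (0:100) / 100
  expect_equal(out, expected, tolerance = 1e-12)
})

test_that("cycle normalization of a sine stays within the interpolation bound", {
  n <- 400
  start <- 50L; end <- 160L  # 110-sample cycle
  t <- seq_len(n)
  f <- sin(2 * pi * (t - start) / (end - start))
  out <- normalize_cycle(f, start, end)
  analytic <- sin(2 * pi * (0:100) / 100)
  h <- 2 * pi / (end - start)
  expect_lt(max(abs(out - analytic)), h^2 / 8 + 1e-12)
})

test_that("toe-off fractions reproduce the constructed duty cycles", {
  for (duty in c(0.60, 0.70, 0.56)) {
    tr <- make_trace(synthetic_trace_spec(duration = 12, step_period = 0.5,
                                          duty_cycle = duty))
    cyc <- segment_cycles(tr)
    to <- vapply(seq_len(nrow(cyc)), function(i) {
      toe_off_fraction(tr$grf[, "grf_R_vertical"], cyc$start_step[i],
                       cyc$end_step[i])
    }, numeric(1))
    expect_equal(to, rep(duty * 100, nrow(cyc)), tolerance = 1e-12)
  }
  # chatter near the threshold is debounced to a single toe-off
  tr <- make_trace(synthetic_trace_spec(duration = 8, step_period = 0.5,
                                        duty_cycle = 0.6))
  cyc <- segment_cycles(tr)
  g <- tr$grf[, "grf_R_vertical"]
  mid <- cyc$start_step[1] + 30
  g[mid] <- 0  # a one-sample dropout inside stance
  to <- toe_off_fraction(g, cyc$start_step[1], cyc$end_step[1])
  expect_equal(to, 60, tolerance = 1e-12)
  # never-unloading cycle is flagged undefined
  g2 <- rep(500, 400)
  expect_warning(to2 <- toe_off_fraction(g2, 10L, 210L), "undefined")
  expect_true(is.na(to2))
})

test_that("ensemble statistics follow the two-sample closed form", {
  tr <- make_trace(synthetic_trace_spec(duration = 12, step_period = 0.55))
  cyc <- segment_cycles(tr)
  es <- ensemble_stats(tr, cycles = cyc)
  expect_identical(es$n_cycles, nrow(cyc))
  # identical cycles: SD identically zero
  expect_true(all(es$sd$grf == 0))
  # two curves differing by +2 deg everywhere: mean halfway, SD = sqrt(2)
  a <- sin(0:100 / 16) * 10
  curves <- rbind(a, a + 2)
  expect_equal(colMeans(curves), a + 1, tolerance = 1e-12)
  expect_equal(apply(curves, 2, sd), rep(sqrt(2), 101), tolerance = 1e-12)
  # permutation invariance of the summary
  tr2 <- tr
  cyc_perm <- cyc[rev(seq_len(nrow(cyc))), ]
  es2 <- ensemble_stats(tr2, cycles = cyc_perm)
  expect_equal(es2$mean, es$mean, tolerance = 1e-12)
  expect_equal(es2$sd, es$sd, tolerance = 1e-12)
  expect_equal(es2$toe_off_pct, es$toe_off_pct)
})

test_that("mean forward speed equals displacement over stepping duration", {
  tr <- make_trace(synthetic_trace_spec(duration = 12, step_period = 0.55,
                                        pelvis_speed = 1.37))
  es <- ensemble_stats(tr)
  expect_equal(es$mean_speed, 1.37, tolerance = 0.01)
})

test_that("segmentation and normalization commute with time shifts", {
  spec <- synthetic_trace_spec(duration = 14, step_period = 0.55,
                               duty_cycle = 0.6)
  tr <- make_trace(spec)
  # shift by exactly one gait cycle: drop the first 110 rows
  shift <- 110L
  tr_s <- tr
  tr_s$time <- tr$time[seq_len(length(tr$time) - shift)]
  tr_s$q <- tr$q[-(1:shift), ]
  tr_s$qdot <- tr$qdot[-(1:shift), ]
  tr_s$grf <- tr$grf[-(1:shift), ]
  tr_s$excitations <- tr$excitations[-(1:shift), ]
  cyc <- segment_cycles(tr)
  cyc_s <- segment_cycles(tr_s)
  expect_identical(cyc$start_step[-1] - shift,
                   cyc_s$start_step[seq_len(nrow(cyc) - 1)])
  k1 <- normalize_cycle(tr$grf[, "grf_R_vertical"], cyc$start_step[2],
                        cyc$end_step[2])
  k2 <- normalize_cycle(tr_s$grf[, "grf_R_vertical"],
                        cyc_s$start_step[1], cyc_s$end_step[1])
  expect_equal(k1, k2, tolerance = 1e-12)
})

test_that("correlation handles identity, negation, and a hand-computed case", {
  x <- sin(0:100 / 12)
  expect_equal(correlate_curves(x, x), 1, tolerance = 1e-12)
  expect_equal(correlate_curves(x, -x), -1, tolerance = 1e-12)
  # 5-point toy vectors against the covariance-ratio formula by hand
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 1, 4, 3, 7)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(correlate_curves(a, b), num / den, tolerance = 1e-14)
  # symmetry and affine invariance
  expect_equal(correlate_curves(a, b), correlate_curves(b, a))
  expect_equal(correlate_curves(2.5 * a + 3, b), correlate_curves(a, b),
               tolerance = 1e-12)
  # zero variance is an error, not a silent zero
  expect_error(correlate_curves(rep(1, 5), b), "zero variance")
})

test_that("reference kinematics load from CSV and correlate per joint", {
  path <- tempfile(fileext = ".csv")
  pc <- seq(0, 100, by = 2)
  write.csv(data.frame(percent_cycle = pc,
                       hip_deg = 30 * cos(2 * pi * pc / 100),
                       knee_deg = 30 + 30 * sin(2 * pi * pc / 100),
                       ankle_deg = 10 * sin(4 * pi * pc / 100)),
            path, row.names = FALSE)
  ref <- read_reference_kinematics(path)
  expect_length(ref$hip, 101)
  fake_summary <- list(mean = list(hip = ref$hip, knee = ref$knee,
                                   ankle = -ref$ankle))
  r <- kinematic_correlations(fake_summary, ref)
  expect_equal(unname(r), c(1, 1, -1), tolerance = 1e-9)
  expect_error(read_reference_kinematics(
    {p2 <- tempfile(fileext = ".csv")
     write.csv(data.frame(percent_cycle = pc), p2, row.names = FALSE)
     p2}), "missing columns")
  unlink(path)
})
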