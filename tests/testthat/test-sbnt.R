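# SBNT analysis: flow QC, closing-volume detection against the exhaustive
# oracle, phase III fitting, classification, and curve-level invariances.

test_that("flow validation counts mid-expiration samples in the window", {
  v <- seq(0, 4, by = 0.01)
  ok <- validate_flow(sbnt_curve(v, rep(20, length(v)),
                                 flow = rep(0.4, length(v)),
                                 vital_capacity = 4))
  expect_true(ok$ok)
  expect_equal(ok$fraction, 1)
  bad <- validate_flow(sbnt_curve(v, rep(20, length(v)),
                                  flow = rep(0.8, length(v)),
                                  vital_capacity = 4))
  expect_false(bad$ok)
  expect_equal(bad$fraction, 0)
  # 5% of mid-expiration samples out of range still passes
  flow <- rep(0.4, length(v))
  mid <- which(v >= 1 & v <= 3)
  flow[mid[seq_len(ceiling(0.05 * length(mid)))]] <- 0.6
  part <- validate_flow(sbnt_curve(v, rep(20, length(v)), flow = flow,
                                   vital_capacity = 4))
  expect_true(part$ok)
  expect_equal(part$fraction, 0.95, tolerance = 0.01)
  # no flow trace: not assessed
  na_res <- validate_flow(sbnt_curve(v, rep(20, length(v)),
                                     vital_capacity = 4))
  expect_true(is.na(na_res$ok))
})

test_that("a noiseless kinked curve yields the exact closing volume", {
  curve <- two_line_curve(vc = 4, s1 = 2, s2 = 12, breakpoint = 3.2)
  res <- detect_closing_volume(curve)
  expect_equal(res$closing_volume, 0.8)
  expect_equal(res$breakpoint, 3.2)
  expect_equal(res$slope_phase3, 2, tolerance = 1e-8)
  expect_equal(res$slope_phase4, 12, tolerance = 1e-8)
})

test_that("a purely linear curve reports no phase IV", {
  curve <- two_line_curve(s1 = 2, s2 = 2, breakpoint = 3.2, noise_sd = 0.05,
                          seed = 3)
  res <- detect_closing_volume(curve)
  expect_equal(res$closing_volume, 0)
  expect_equal(res$breakpoint, 4)
})

test_that("the internal breakpoint search matches the exhaustive lm oracle", {
  for (s in 1:5) {
    curve <- two_line_curve(vc = 4, step = 0.02, s1 = 1.5, s2 = 9,
                            breakpoint = 3.1, noise_sd = 0.1, seed = s)
    res <- detect_closing_volume(curve)
    v <- curve$expired_volume
    y <- curve$n2
    win <- v >= 2
    cands <- v[win][seq(4, sum(win) - 4)]
    expect_equal(res$breakpoint, breakpoint_oracle(v[win], y[win], cands))
  }
})

test_that("phase III fits recover exact slopes and flag short windows", {
  curve <- two_line_curve(s1 = 2.5, s2 = 2.5, breakpoint = 3)
  p3 <- fit_phase3(curve, closing_volume = 0)
  expect_equal(p3$dn2, 2.5, tolerance = 1e-10)
  expect_equal(p3$r2, 1)
  flat <- sbnt_curve(seq(0, 4, 0.01), rep(25, 401), vital_capacity = 4)
  expect_equal(fit_phase3(flat, 0)$dn2, 0)
  expect_error(fit_phase3(curve, closing_volume = 2.5), "too short")
})

test_that("obstruction classification is strict at the cutoff", {
  expect_true(classify_obstruction(3.0))
  expect_false(classify_obstruction(2.5))
  expect_false(classify_obstruction(1.0))
  expect_true(classify_obstruction(2.0, cutoff = 1.5))
})

test_that("analyze_curve composes the stages and classifies correctly", {
  hi <- generate_sbnt_curve(sbnt_spec(phase3_slope = 3, seed = 1))
  lo <- generate_sbnt_curve(sbnt_spec(phase3_slope = 1.5, seed = 1))
  expect_true(analyze_curve(hi$curve)$obstructed)
  expect_false(analyze_curve(lo$curve)$obstructed)
  res <- analyze_curve(hi$curve)
  expect_true(res$flow_ok)
  expect_lt(abs(res$closing_volume - 0.8), 0.1)
})

test_that("adding a constant to N2 changes neither dN2 nor closing volume", {
  sim <- generate_sbnt_curve(sbnt_spec(phase3_slope = 2, noise_sd = 0.05,
                                       seed = 6))
  shifted <- sbnt_curve(sim$curve$expired_volume, sim$curve$n2 + 7,
                        flow = sim$curve$flow,
                        vital_capacity = sim$curve$vital_capacity)
  a <- analyze_curve(sim$curve)
  b <- analyze_curve(shifted)
  expect_equal(a$dn2, b$dn2, tolerance = 1e-9)
  expect_equal(a$closing_volume, b$closing_volume)
})

test_that("slope recovery is effectively unbiased at protocol noise", {
  err <- vapply(1:200, function(s) {
    sim <- generate_sbnt_curve(sbnt_spec(phase3_slope = 3, noise_sd = 0.05,
                                         seed = 4000 + s))
    analyze_curve(sim$curve)$dn2 - 3
  }, numeric(1))
  expect_lt(abs(mean(err)), 0.02)
})

test_that("short or truncated curves are rejected with clear errors", {
  v <- seq(0, 2, 0.01) # spans only 50% of VC 4
  expect_error(detect_closing_volume(sbnt_curve(v, rep(20, length(v)),
                                                vital_capacity = 4)),
               "60%")
  v2 <- seq(0, 4, 0.5)
  expect_error(detect_closing_volume(sbnt_curve(v2, rep(20, length(v2)),
                                                vital_capacity = 4)),
               "search")
})
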