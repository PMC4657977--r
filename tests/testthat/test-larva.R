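test_that("segment lengths are conserved over long simulations", {
  tr <- simulate_larva(larva_params(), odour_field_gaussian(c(0, 0), 10),
                       arena_rectangle(100, 65), duration = 10000, seed = 4,
                       init = list(position = c(-20, 5), orientation = 30))
  expect_equal(nrow(tr), 100001)
  sl <- segment_lengths(tr)
  expect_lt(max(abs(sl$head - 2)), 1e-9)
  expect_lt(max(abs(sl$body - 2)), 1e-9)
  expect_true(all(abs(tr$theta_deg) <= 120 + 1e-9))
})

test_that("a run with no casting and no termination is exactly straight", {
  p <- larva_params(r_run_termination_base = 0, weathervane_casting = FALSE)
  tr <- simulate_larva(p, odour_field_uniform(), duration = 50, seed = 1,
                       init = list(position = c(0, 0), orientation = 0))
  expect_true(all(tr$mode == 0))
  expect_identical(unique(tr$mid_y_mm), 0)
  expect_identical(unique(tr$alpha_deg), 0)
  expect_equal(tr$mid_x_mm[nrow(tr)], 50, tolerance = 1e-9)
})

test_that("the body realigns with a held head orientation (trailer kinematics)", {
  # head orientation frozen in the world (weathervaning off), initial bend 60 deg
  p <- larva_params(r_run_termination_base = 1e-9, weathervane_casting = FALSE)
  tr <- simulate_larva(p, odour_field_uniform(), duration = 30, seed = 1,
                       init = list(position = c(0, 0), orientation = 0, theta = 60))
  expect_true(all(tr$mode == 0))
  # |theta| decays monotonically (non-increasing) and ends < 5 deg after >= 5 body lengths
  th <- tr$theta_deg
  expect_true(all(diff(abs(th)) <= 1e-9))
  expect_lt(abs(th[101]), 5) # 10 s = 10 mm = 5 body lengths
  # the final heading equals the held head orientation
  expect_equal(tr$alpha_deg[nrow(tr)], 60, tolerance = 0.1)

  # mirror symmetry: theta -> -theta reflects the path about the x axis
  tr2 <- simulate_larva(p, odour_field_uniform(), duration = 30, seed = 1,
                        init = list(position = c(0, 0), orientation = 0, theta = -60))
  expect_equal(tr2$mid_y_mm, -tr$mid_y_mm, tolerance = 1e-9)
  expect_equal(tr2$mid_x_mm, tr$mid_x_mm, tolerance = 1e-9)
})

test_that("weathervane casting traces a 20-degree triangle wave when pausing is disabled", {
  p <- larva_params(r_run_termination_base = 0,
                    r_weathervane_cast_termination_base = 0)
  tr <- simulate_larva(p, odour_field_uniform(), duration = 20, seed = 6,
                       init = list(position = c(0, 0), orientation = 0))
  th <- tr$theta_deg
  expect_true(all(abs(th) <= 20 + 1e-9))
  expect_equal(max(th), 20, tolerance = 1e-9)
  expect_equal(min(th), -20, tolerance = 1e-9)
  # slope is ~6 deg per step (60 deg/s), modulated slightly by the body
  # realigning under the head, and smaller only at the reversal clamps
  d <- diff(th)[-1]
  expect_true(all(abs(d) <= 6 + 1.5))
  expect_gt(mean(abs(d) > 4.5), 0.8)
})

test_that("head casts sweep at 240 deg/s between +/-120 with reversals", {
  # force permanent casting: cast termination can never fire
  p <- larva_params(r_cast_termination_base = 0, weathervane_casting = FALSE)
  tr <- simulate_larva(p, odour_field_uniform(), duration = 120, seed = 3)
  cast <- tr$mode == 1
  expect_gt(sum(cast), 500)
  th <- tr$theta_deg[cast]
  expect_true(all(abs(th) <= 120 + 1e-9))
  expect_equal(max(abs(th)), 120)
  d <- abs(diff(th))
  # per-step change is the full 24 deg except at the clamping reversals
  expect_true(all(d <= 24 + 1e-9))
  expect_gt(mean(abs(d - 24) < 1e-9), 0.8)
})

test_that("runs never terminate during the refractory period", {
  # enormous termination rate: every run ends at the first eligible draw
  p <- larva_params(r_run_termination_base = 1e6)
  tr <- uniform_larva(duration = 200, seed = 8, params = p)
  r <- rle(tr$mode)
  run_blocks <- r$lengths[r$values == 0]
  if (tr$mode[nrow(tr)] == 0) run_blocks <- run_blocks[-length(run_blocks)]
  expect_gt(length(run_blocks), 10)
  # every completed run lasts exactly t_min_run + one step
  expect_true(all(run_blocks * 0.1 > 1))
  expect_true(all(run_blocks * 0.1 <= 1.1 + 1e-9))
})

test_that("head-cast episodes terminate outward between 37 and 120 degrees", {
  tr <- simulate_larva(larva_params(), odour_field_gaussian(c(0, 0), 10),
                       duration = 2000, seed = 10,
                       init = list(position = c(-15, 0), orientation = 90))
  ang <- abs(cast_termination_angles(tr))
  expect_gt(length(ang), 50)
  expect_true(all(ang >= 37 - 1e-9))
  expect_true(all(ang <= 120 + 1e-9))
})

test_that("the first cast after a run heads to the side the head points", {
  tr <- uniform_larva(duration = 3000, seed = 12)
  m <- tr$mode
  n <- length(m)
  k <- which(m[-n] == 0 & m[-1] == 1)
  k <- k[k < n - 1]
  th0 <- tr$theta_deg[k + 1]  # head angle at run termination
  sweep <- tr$theta_deg[k + 2] - tr$theta_deg[k + 1]
  nz <- th0 != 0
  expect_gt(sum(nz), 100)
  expect_true(all(sign(sweep[nz]) == sign(th0[nz])))
})

test_that("identical seeds replay bit-identically; different seeds do not", {
  a <- uniform_larva(duration = 60, seed = 5, index = 3)
  b <- uniform_larva(duration = 60, seed = 5, index = 3)
  cc <- uniform_larva(duration = 60, seed = 5, index = 4)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$mid_x_mm, cc$mid_x_mm))
})

test_that("with kernels zeroed the state machine ignores the landscape", {
  p0 <- configure_mechanisms(larva_params(), scaling = 0)
  f1 <- odour_field_uniform()
  f2 <- odour_field_gaussian(c(5, 5), 15)
  a <- simulate_larva(p0, f1, duration = 120, seed = 9,
                      init = list(position = c(0, 0), orientation = 45))
  b <- simulate_larva(p0, f2, duration = 120, seed = 9,
                      init = list(position = c(0, 0), orientation = 45))
  expect_identical(a$mid_x_mm, b$mid_x_mm)
  expect_identical(a$mode, b$mode)
  expect_identical(a$theta_deg, b$theta_deg)
  # in the gradient the perceptual signal differs, but rates stay at base
  expect_false(all(b$phi == 0))
  expect_true(all(b$r_run == 0.148))
})

test_that("wall responses keep the larva in the arena, casts flip direction", {
  arena <- arena_circle(45)
  p <- larva_params()
  tr <- simulate_larva(p, odour_field_uniform(), arena, duration = 1000, seed = 2,
                       init = list(position = c(40, 0), orientation = 0))
  # head may overhang only transiently; centroid stays essentially inside
  d <- sqrt(tr$mid_x_mm^2 + tr$mid_y_mm^2)
  expect_true(all(d <= 45 + 0.5))
  expect_gt(max(d), 40) # it did reach the wall
  # in an unbounded arena the same larva just keeps going
  fr <- simulate_larva(p, odour_field_uniform(), arena_none(), duration = 1000,
                       seed = 2, init = list(position = c(40, 0), orientation = 0))
  expect_gt(max(sqrt(fr$mid_x_mm^2 + fr$mid_y_mm^2)), 46)
})

test_that("zero-gradient run terminations follow the base-rate hazard", {
  durs <- c()
  for (i in 1:60)
    durs <- c(durs, completed_run_durations(uniform_larva(300, seed = 21, index = i)))
  waits <- durs - 1
  expect_gt(length(waits), 1500)
  expect_equal(mean(waits), 1 / 0.148, tolerance = 0.05)
  # memoryless beyond the refractory period: P(W > 2w) ~ P(W > w)^2
  surv <- function(w) mean(waits > w)
  expect_equal(surv(8), surv(4)^2, tolerance = 0.05)
})
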