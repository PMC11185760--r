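test_that("likelihood filtering is strict at the 0.90 boundary", {
  pose <- hand_pose(1:3, 1:3, likelihood = c(0.95, 0.89, 0.90))
  filt <- filter_pose(pose)
  expect_equal(filt$parts$center$valid, c(TRUE, FALSE, TRUE))
  all_good <- filter_pose(hand_pose(1:5, 1:5, likelihood = 1))
  expect_true(all(all_good$parts$nose$valid))
  expect_error(filter_pose(pose, threshold = 1.5), "\\[0, 1\\]")
})

test_that("planted sub-threshold noise fraction is removed by the filter", {
  sch <- make_schedule(scale = 1 / 4)
  pose <- simulate_pose_track(group_spec(), sch, cage_geometry(), seed = 9,
                              config = sim_config(likelihood_noise = 0.10))
  filt <- filter_pose(pose)
  removed <- mean(!unlist(lapply(filt$parts, function(p) p$valid)))
  expect_lt(abs(removed - 0.10), 0.005)
})

test_that("speed series and motion classes follow their definitions", {
  expect_equal(speed_series(rep(3, 10), rep(4, 10), 0:9)[-1], rep(0, 9))
  sp <- speed_series(c(0, 5, 10), c(0, 0, 0), 0:2)
  expect_equal(sp, c(NA, 5, 5))
  # invalid gaps propagate
  sp2 <- speed_series(c(0, 5, 10), c(0, 0, 0), 0:2,
                      valid = c(TRUE, FALSE, TRUE))
  expect_true(all(is.na(sp2)))
  cls <- classify_motion(c(0, 1.99, 2, 9.9, 10, 39, 50, 80, 200))
  expect_equal(as.character(cls),
               c("still", "still", "scoot", "scoot", "move", "move",
                 "burst", "escape", "escape"))
  expect_error(classify_motion(1, thresholds = c(5, 4, 3, 2)), "increasing")
})

test_that("interval percentages, acclimation and habituation are exact", {
  t <- 0:119
  q <- c(rep(TRUE, 30), rep(FALSE, 30), rep(TRUE, 60))
  expect_equal(interval_percent(q, t, c(0, 60)), 50)
  expect_equal(interval_percent(rep(TRUE, 120), t, c(0, 120)), 100)
  expect_true(is.na(interval_percent(q, t, c(200, 300))))
  # acclimation: last minus first 10-minute bin of hour 1
  sch <- make_schedule()
  tt <- 0:3599
  act <- c(rep(TRUE, 480), rep(FALSE, 3600 - 480))     # 80% of bin 1
  act[3000 + seq_len(120)] <- TRUE                      # 20% of bin 6
  expect_equal(acclimation(act, tt, sch), -60)
  expect_equal(acclimation(rep(TRUE, 3600), tt, sch), 0)
  # habituation: the 10-minute post-onset window
  t2 <- seq(43000, 44000)
  q2 <- t2 >= 43200 & t2 < 43440   # active 240 of the 600 s window
  expect_equal(habituation(q2, t2, 43200, sch), 40)
  expect_equal(habituation(rep(FALSE, length(t2)), t2, 43200, sch), 0)
})

test_that("location parameters match their definitions at fixed points", {
  geom <- cage_geometry()
  wc <- geom$window_center
  pose <- filter_pose(hand_pose(rep(wc[[1]], 50), rep(wc[[2]], 50),
                                likelihood = 1))
  loc <- location_params(pose, geom)
  expect_equal(unname(loc["Window"]), 100)
  expect_equal(unname(loc["DWindow"]), 0)
  expect_equal(unname(loc["Home"]), 0)
  # center parked at the hut center with the nose outside: Peek = 100
  hut_c <- colMeans(geom$hut)
  pk <- hand_pose(rep(hut_c[1], 20), rep(hut_c[2], 20), likelihood = 1,
                  nose_dx = 200)
  pk$parts$nose$y <- rep(max(geom$hut[, 2]) + 5, 20)
  pk$parts$nose$x <- rep(hut_c[1], 20)
  loc2 <- location_params(filter_pose(pk), geom)
  expect_equal(unname(loc2["Home"]), 100)
  expect_equal(unname(loc2["Peek"]), 100)
})

test_that("window partner is conditional on the focal mouse's visits", {
  geom <- cage_geometry()
  wc <- geom$window_center
  far <- c(30, 30)
  a <- filter_pose(hand_pose(c(rep(wc[[1]], 40), rep(far[1], 60)),
                             c(rep(wc[[2]], 40), rep(far[2], 60))))
  never <- filter_pose(hand_pose(rep(far[1], 100), rep(far[2], 100)))
  expect_equal(as.numeric(window_partner(a, never, geom)), 0)
  sync <- filter_pose(hand_pose(c(rep(wc[[1]], 40), rep(far[1], 60)),
                                c(rep(wc[[2]], 40), rep(far[2], 60))))
  expect_equal(as.numeric(window_partner(a, sync, geom)), 100)
  half <- filter_pose(hand_pose(c(rep(wc[[1]], 20), rep(far[1], 80)),
                                c(rep(wc[[2]], 20), rep(far[2], 80))))
  expect_equal(as.numeric(window_partner(a, half, geom)), 50)
  short <- filter_pose(hand_pose(1:5, 1:5))
  expect_error(window_partner(a, short, geom), "time grid")
})

test_that("planted partner co-occurrence is recovered", {
  sch <- make_schedule()  # full assay: enough visit bouts to average over
  geom <- cage_geometry()
  pose <- simulate_pose_track(group_spec(), sch, geom, seed = 41)
  partner <- simulate_pose_track(group_spec(), sch, geom, seed = 42)
  partner <- correlate_window_visits(partner, pose, geom, cooc = 0.5,
                                     seed = 43)
  wp <- window_partner(filter_pose(pose), filter_pose(partner), geom)
  expect_lt(abs(as.numeric(wp) - 50), 3)
})

test_that("the assembled parameter vector has 67 entries with exact structure", {
  sch <- make_schedule(scale = 1 / 60)
  geom <- cage_geometry()
  pose <- simulate_pose_track(group_spec("AD", "young"), sch, geom, seed = 13)
  partner <- simulate_pose_track(group_spec(), sch, geom, seed = 14)
  track <- truth_track(pose, geom)
  pv <- compute_param_vector(track, filter_pose(pose), filter_pose(partner),
                             geom, sch)
  expect_length(pv, 67)
  expect_equal(sum(startsWith(names(pv), "fiji_")), 15)
  expect_equal(sum(startsWith(names(pv), "dlc_")), 52)
  # Out = Wall + Window exactly; N-D differences exact
  expect_equal(pv[["fiji_Out"]], pv[["fiji_Wall"]] + pv[["fiji_Window"]])
  expect_equal(pv[["fiji_N-D"]], pv[["fiji_MN"]] - pv[["fiji_MD"]])
  expect_equal(pv[["dlc_MN-D"]], pv[["dlc_MN"]] - pv[["dlc_MD"]])
  expect_equal(pv[["dlc_SpN-D"]], pv[["dlc_SpN"]] - pv[["dlc_SpD"]])
  # quadrant occupancies sum to 100
  expect_equal(pv[["fiji_Home"]] + pv[["fiji_Wall"]] + pv[["fiji_Food"]] +
                 pv[["fiji_Window"]], 100)
})

test_that("a parked mouse zeroes the movement family", {
  geom <- cage_geometry()
  sch <- make_schedule(scale = 1 / 60)
  n <- length(schedule_times(sch))
  hut_c <- colMeans(geom$hut)
  track <- data.frame(time_s = schedule_times(sch), x = NA_real_,
                      y = NA_real_, head_x = NA_real_, head_y = NA_real_,
                      area = NA_real_, elongation = NA_real_,
                      in_hut = TRUE, quadrant = NA_character_)
  class(track) <- c("mouse_track", "data.frame")
  tp <- tracking_params(track, geom, sch)
  expect_equal(unname(tp["Home"]), 100)
  expect_true(is.na(tp[["M1"]]))  # no visible frame: undefined, not zero
  pose <- filter_pose(hand_pose(rep(hut_c[1], n), rep(hut_c[2], n),
                                time_s = schedule_times(sch), nose_dx = 0))
  pp <- pose_params(pose, NULL, geom, sch)
  expect_equal(unname(pp["M1"]), 0)
  expect_equal(unname(pp["Home"]), 100)
  expect_equal(unname(pp["Sp1"]), 0)
})

test_that("every parameter equals an independent brute-force recount", {
  # 1000-frame hand-constructed assay on a shrunken schedule
  sch <- make_schedule(scale = 1000 / 79200)
  geom <- cage_geometry()
  n <- 1000
  t <- schedule_times(sch)
  set.seed(99)
  x <- cumsum(sample(c(0, 1, 3, 12, 45, 90), n, replace = TRUE))
  x <- 20 + (x %% 180)
  y <- 30 + (cumsum(sample(0:2, n, replace = TRUE)) %% 250)
  lik <- sample(c(1, 0.95, 0.5), n, replace = TRUE, prob = c(0.8, 0.1, 0.1))
  pose <- filter_pose(hand_pose(x, y, likelihood = lik, time_s = t))
  pp <- pose_params(pose, NULL, geom, sch)

  # oracle: plain loops, coded independently of the package internals
  valid <- lik >= 0.9
  sp <- rep(NA_real_, n)
  for (i in 2:n) if (valid[i] && valid[i - 1])
    sp[i] <- sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2) / (t[i] - t[i - 1])
  cls <- rep(NA_character_, n)
  for (i in 1:n) if (!is.na(sp[i]))
    cls[i] <- if (sp[i] < 2) "still" else if (sp[i] < 10) "scoot" else
      if (sp[i] < 40) "move" else if (sp[i] < 80) "burst" else "escape"
  pct <- function(sel, what) {
    den <- sum(!is.na(cls[sel]))
    if (den == 0) return(NA_real_)
    100 * sum(cls[sel] %in% what, na.rm = TRUE) / den
  }
  hour <- 3600 * sch$scale
  moving <- c("scoot", "move", "burst", "escape")
  expect_equal(pp[["M1"]], pct(t < hour, moving))
  expect_equal(pp[["Sc7"]], pct(t >= 6 * hour & t < 7 * hour, "scoot"))
  day <- (t < 6 * hour) | (t >= 18 * hour)
  expect_equal(pp[["BD"]], pct(day, "burst"))
  expect_equal(pp[["EN"]], pct(!day, "escape"))
  expect_equal(pp[["MN"]], pct(!day, moving))
  on <- 12 * hour
  expect_equal(pp[["HMM"]], pct(t >= on & t < on + 600 * sch$scale, moving))
  expect_equal(pp[["HL2Sc"]],
               pct(t >= 16 * hour & t < 16 * hour + 600 * sch$scale, "scoot"))
  expect_equal(pp[["Sp1"]], mean(sp[t < hour], na.rm = TRUE))
  bin <- 600 * sch$scale
  expect_equal(pp[["AM"]],
               pct(t >= hour - bin & t < hour, moving) - pct(t < bin, moving))
  # location block against direct recounts
  dw <- sqrt((x - geom$window_center[[1]])^2 + (y - geom$window_center[[2]])^2)
  expect_equal(pp[["Window"]], 100 * sum(dw[valid] <= 40) / sum(valid))
  expect_equal(pp[["DWindow"]], mean(dw[valid]))
  wd <- pmin(x, geom$width - x, y, geom$height - y)
  expect_equal(pp[["Wall"]], mean(wd[valid]))

  # tracking-derived family on the same trajectory, all frames visible
  trk <- data.frame(time_s = t, x = x, y = y, head_x = x, head_y = y,
                    area = 600, elongation = 1.3, in_hut = FALSE,
                    quadrant = assign_quadrant(x, y, geom))
  class(trk) <- c("mouse_track", "data.frame")
  tp <- tracking_params(trk, geom, sch)
  spd <- c(NA, sqrt(diff(x)^2 + diff(y)^2) / diff(t))
  mv <- spd >= 2
  expect_equal(tp[["M7"]],
               100 * sum(mv[t >= 6 * hour & t < 7 * hour], na.rm = TRUE) /
                 sum(!is.na(spd) & t >= 6 * hour & t < 7 * hour))
  qd <- assign_quadrant(x, y, geom)
  expect_equal(tp[["Home"]], 100 * mean(qd == "home"))
  expect_equal(tp[["Wall"]], 100 * mean(qd == "wall"))
})

test_that("parameters are translation-invariant and distances scale", {
  sch <- make_schedule(scale = 500 / 79200)
  geomA <- cage_geometry(width = 240, height = 320)
  set.seed(7)
  n <- 500
  x <- 40 + cumsum(stats::rnorm(n)) %% 100
  y <- 40 + cumsum(stats::rnorm(n)) %% 100
  t <- schedule_times(sch)
  ppA <- pose_params(filter_pose(hand_pose(x, y, time_s = t)), NULL,
                     geomA, sch)
  # spatial rescaling: distance parameters double, percentages need a
  # doubled window radius to remain comparable
  geomC <- cage_geometry(width = 480, height = 640, window_radius = 80)
  ppC <- pose_params(filter_pose(hand_pose(2 * x, 2 * y, time_s = t)), NULL,
                     geomC, sch, thresholds = 2 * c(2, 10, 40, 80))
  for (d in c("Wall", "Food", "DWindow", "Sp1", "SpD"))
    expect_equal(ppC[[d]], 2 * ppA[[d]], tolerance = 1e-9)
  expect_equal(ppC[["M1"]], ppA[["M1"]])
  expect_equal(ppC[["Window"]], ppA[["Window"]])
})

test_that("motion-class shares sum to 100 per interval", {
  sch <- make_schedule(scale = 1 / 60)
  pose <- simulate_pose_track(group_spec("AD", "aged"), sch,
                              cage_geometry(), seed = 55)
  pose <- filter_pose(pose)
  ctr <- pose$parts$center
  sp <- speed_series(ctr$x, ctr$y, pose$time_s, ctr$valid)
  cls <- classify_motion(sp)
  shares <- vapply(levels(cls), function(l)
    interval_percent(cls == l, pose$time_s, c(0, sch$total_duration)),
    numeric(1))
  expect_equal(sum(shares), 100)
})
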