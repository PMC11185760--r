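test_that("run compliance enforces direction and the 10-second limit", {
  ok <- hand_run(rep(c("RF", "RH", "LF", "LH"), 3),
                 start = (0:11) * 0.25, end = (0:11) * 0.25 + 0.15)
  expect_true(validate_run(ok))
  slow <- hand_run(rep(c("RF", "RH", "LF", "LH"), 3),
                   start = 0:11, end = 0:11 + 0.5)
  v <- validate_run(slow)
  expect_false(as.logical(v))
  expect_match(attr(v, "reasons"), "duration", all = FALSE)
  back <- hand_run(c("RF", "LH", "RF", "LH"), start = c(0, 1, 2, 3),
                   end = c(0.5, 1.5, 2.5, 3.5), x = c(0, 10, 2, 12))
  vb <- validate_run(back)
  expect_false(as.logical(vb))
  expect_match(attr(vb, "reasons"), "reversal", all = FALSE)
  expect_error(gait_run(data.frame()))
})

test_that("paw timing follows the stand / step-cycle definitions", {
  r <- hand_run(c("RF", "RF"), start = c(0, 0.5), end = c(0.2, 0.7))
  tim <- paw_timing(r, "RF")
  expect_equal(unname(tim), c(0.2, 0.5, 0.3))
  # periodic gait with period T gives step_cycle T exactly
  rT <- hand_run(rep("LH", 5), start = (0:4) * 0.8, end = (0:4) * 0.8 + 0.3)
  expect_equal(unname(paw_timing(rT, "LH")["step_cycle"]), 0.8)
  expect_true(is.na(paw_timing(rT, "RF")[["step_cycle"]]))
})

test_that("run statistics satisfy cadence x duration = steps", {
  r <- hand_run(rep(c("RF", "RH", "LF", "LH"), 3),
                start = seq(0, by = 3 / 11, length.out = 12),
                end = seq(0, by = 3 / 11, length.out = 12) + 0.1)
  rs <- run_stats(r)
  expect_equal(unname(rs["number_of_steps"]), 12)
  expect_equal(unname(rs["duration"]), 3)
  expect_equal(unname(rs["cadence"]), 4)
  expect_equal(rs[["cadence"]] * rs[["duration"]], rs[["number_of_steps"]])
  one <- hand_run("RF", 0, 0.3)
  expect_error(run_stats(one), "zero-duration")
})

test_that("support percentages partition the run", {
  # all four paws down for the whole run
  four <- hand_run(c("RF", "LF", "RH", "LH"), start = rep(0, 4),
                   end = rep(2, 4))
  sp <- support_percentages(four)
  expect_equal(unname(sp["four"]), 100)
  expect_equal(sum(sp), 100)
  # alternating diagonal pairs only
  diag2 <- hand_run(c("RF", "LH", "LF", "RH", "RF", "LH"),
                    start = c(0, 0, 1, 1, 2, 2),
                    end = c(1, 1, 2, 2, 3, 3))
  spd <- support_percentages(diag2)
  expect_equal(unname(spd["diagonal"]), 100)
  # girdle pairs
  gird <- hand_run(c("RF", "LF"), start = c(0, 0), end = c(1, 1))
  expect_equal(unname(support_percentages(gird)["girdle"]), 100)
})

test_that("support percentages match a per-millisecond discretized oracle", {
  set.seed(12)
  n <- 40
  paw <- sample(c("RF", "LF", "RH", "LH"), n, replace = TRUE)
  start <- round(cumsum(stats::runif(n, 0, 0.2)), 3)
  end <- round(start + stats::runif(n, 0.05, 0.4), 3)
  r <- hand_run(paw, start, end, x = seq_len(n))
  sp <- support_percentages(r)
  expect_equal(sum(sp), 100, tolerance = 1e-9)
  # oracle: sample the contact state every millisecond
  ms <- seq(r$run_start_s + 5e-4, r$run_end_s, by = 1e-3)
  classify <- function(paws) {
    k <- length(paws)
    if (k == 0) "zero" else if (k == 1) "single" else if (k == 3) "three"
    else if (k == 4) "four" else {
      s <- paste(sort(paws), collapse = "-")
      if (s %in% c("LF-RF", "LH-RH")) "girdle"
      else if (s %in% c("RF-RH", "LF-LH")) "lateral" else "diagonal"
    }
  }
  cls <- vapply(ms, function(t)
    classify(unique(paw[start <= t & end > t])), character(1))
  oracle <- 100 * table(factor(cls, levels = names(sp))) / length(ms)
  expect_equal(as.numeric(sp), as.numeric(oracle), tolerance = 0.2)
})

test_that("each pure normal pattern scores 100% NSSP and repeats score 0", {
  for (p in c("Ca", "Cb", "Aa", "Ab", "Ra", "Rb")) {
    run <- simulate_footfalls(p, 16, seed = 1)
    expect_equal(as.numeric(step_sequence_nssp(run)), 100,
                 info = paste("pattern", p))
  }
  rep4 <- hand_run(rep("RF", 8), start = 0:7 * 0.2, end = 0:7 * 0.2 + 0.1)
  expect_equal(as.numeric(step_sequence_nssp(rep4)), 0)
  short <- hand_run(c("RF", "LF", "RH"), start = c(0, 0.1, 0.2),
                    end = c(0.3, 0.4, 0.5))
  expect_true(is.na(step_sequence_nssp(short)))
})

test_that("NSSP on a shuffled sequence equals an exhaustive window oracle", {
  # independent oracle: the 24 normal windows written out explicitly
  normal <- c("RF-LF-RH-LH", "LF-RH-LH-RF", "RH-LH-RF-LF", "LH-RF-LF-RH",
              "LF-RF-LH-RH", "RF-LH-RH-LF", "LH-RH-LF-RF", "RH-LF-RF-LH",
              "RF-RH-LF-LH", "RH-LF-LH-RF", "LF-LH-RF-RH", "LH-RF-RH-LF",
              "LF-RH-RF-LH", "RH-RF-LH-LF", "RF-LH-LF-RH", "LH-LF-RH-RF",
              "RF-LF-LH-RH", "LF-LH-RH-RF", "LH-RH-RF-LF", "RH-RF-LF-LH",
              "LF-RF-RH-LH", "RF-RH-LH-LF", "RH-LH-LF-RF", "LH-LF-RF-RH")
  set.seed(77)
  for (rep in 1:5) {
    paw <- sample(c("RF", "LF", "RH", "LH"), 20, replace = TRUE)
    r <- hand_run(paw, start = (0:19) * 0.2, end = (0:19) * 0.2 + 0.1,
                  x = 1:20)
    wins <- vapply(seq_len(17), function(i)
      paste(paw[i:(i + 3)], collapse = "-") %in% normal, logical(1))
    expect_equal(as.numeric(step_sequence_nssp(r)), 100 * mean(wins))
  }
})

test_that("base of support and paw angles match construction", {
  w <- 26
  r <- hand_run(rep(c("RH", "LH"), 4), start = (0:7) * 0.3,
                end = (0:7) * 0.3 + 0.1, x = 1:8,
                y = rep(c(w / 2, -w / 2), 4))
  expect_equal(base_of_support(r, "hind"), w)
  expect_true(is.na(base_of_support(r, "front")))
  same <- hand_run(rep(c("RH", "LH"), 4), start = (0:7) * 0.3,
                   end = (0:7) * 0.3 + 0.1, x = 1:8, y = 0)
  expect_equal(base_of_support(same, "hind"), 0)
  # prints aligned with a straight run give 0 degrees; a 25-degree print
  # reports 25
  straight <- hand_run(rep(c("RF", "RH", "LF", "LH"), 3),
                       start = (0:11) * 0.2, end = (0:11) * 0.2 + 0.1,
                       x = 1:12, y = 0, print_orientation = 0)
  expect_equal(paw_angle_body_axis(straight), rep(0, 12))
  tilted <- hand_run(rep(c("RF", "RH", "LF", "LH"), 3),
                     start = (0:11) * 0.2, end = (0:11) * 0.2 + 0.1,
                     x = 1:12, y = 0, print_orientation = 25)
  expect_equal(paw_angle_body_axis(tilted), rep(25, 12))
})

test_that("gait tables average compliant runs and exclude sparse animals", {
  mk <- function(seed) simulate_footfalls("Aa", 16, seed = seed,
                                          jitter_sd = 0.005)
  runs <- list(
    good = list(mk(1), mk(2), mk(3)),
    mixed = list(mk(4), mk(5), mk(6),
                 simulate_footfalls("Aa", 13, run_speed = 1, seed = 7,
                                    step_cycle_s = 4)),
    sparse = list(mk(8), mk(9)))
  tab <- gait_table(runs, min_runs = 3)
  expect_setequal(tab$animal, c("good", "mixed"))
  expect_equal(attr(tab, "excluded"), "sparse")
  expect_equal(tab$nssp, c(100, 100))
  # three identical runs equal the single-run values
  same <- gait_table(list(a = list(mk(1), mk(1), mk(1))))
  one <- gait_table(list(a = list(mk(1))), min_runs = 1)
  expect_equal(same[, -1], one[, -1])
  expect_equal(same$cadence * same$duration, same$number_of_steps)
})

test_that("simulator ground-truth gait parameters are recovered", {
  spec <- print_spec(); spec$jitter <- 0
  run <- simulate_footfalls("Ab", 20, spec = spec, seed = 5,
                            step_cycle_s = 0.5, duty_factor = 0.6)
  tim <- paw_timing(run, "LF")
  expect_equal(unname(tim["stand"]), 0.3, tolerance = 1e-9)
  expect_equal(unname(tim["step_cycle"]), 0.5, tolerance = 1e-9)
  expect_equal(base_of_support(run, "front"),
               unname(spec$base_of_support["front"]))
  expect_equal(unname(run_stats(run)["number_of_steps"]), 20)
})
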