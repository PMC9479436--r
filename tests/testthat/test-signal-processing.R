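# Detection rules and day assembly: non-wear, sleep, intensity bands,
# day segmentation and the validity filters.

make_epochs <- function(n_min, epoch_s = 5, start = utc("2021-05-03 23:00:00"),
                        sd = 40, rng = 200, angle = NULL, enmo = 10) {
  n <- n_min * 60 / epoch_s
  if (is.null(angle)) angle <- ifelse(seq_len(n) %% 2 == 0, 20, -20)
  data.frame(
    timestamp = start + (seq_len(n) - 1) * epoch_s,
    enmo = rep_len(enmo, n), arm_angle = rep_len(angle, n),
    sd_x = sd, sd_y = sd, sd_z = sd,
    range_x = rng, range_y = rng, range_z = rng
  )
}

test_that("non-wear blocks follow the two-of-three-axes rule", {
  # constant signal for 2 h: everything non-wear
  ep <- make_epochs(120, sd = 0, rng = 0)
  expect_true(all(!detect_nonwear(ep)))
  # two axes under the SD threshold, ranges high: non-wear
  ep2 <- make_epochs(120)
  ep2$sd_x <- 5; ep2$sd_y <- 5; ep2$sd_z <- 40
  expect_true(all(!detect_nonwear(ep2)))
  # all axes above both thresholds: wear
  ep3 <- make_epochs(120, sd = 20, rng = 60)
  expect_true(all(detect_nonwear(ep3)))
  # two axes under the range threshold alone suffices
  ep4 <- make_epochs(120, sd = 20)
  ep4$range_x <- 30; ep4$range_y <- 30; ep4$range_z <- 200
  expect_true(all(!detect_nonwear(ep4)))
  # only one axis quiet: still wear
  ep5 <- make_epochs(120, sd = 20, rng = 60)
  ep5$sd_x <- 5
  expect_true(all(detect_nonwear(ep5)))
  # timestamp gaps are reported
  gap <- make_epochs(60)
  gap <- gap[-10, ]
  expect_error(detect_nonwear(gap), "gap")
})

test_that("sleep detection keeps calm spans inside the logged window only", {
  bed <- utc("2021-05-03 23:00:00")
  wake <- bed + 480 * 60
  # constant angle all night: the whole window is sleep
  ep <- make_epochs(600, angle = -35)
  asleep <- detect_sleep(ep, bed, wake)
  inwin <- ep$timestamp >= bed & ep$timestamp < wake
  expect_true(all(asleep[inwin]))
  expect_true(all(!asleep[!inwin]))

  # a 10-min oscillation mid-night is excluded, flanks kept
  ep2 <- make_epochs(600, angle = -35)
  osc <- ep2$timestamp >= bed + 240 * 60 & ep2$timestamp < bed + 250 * 60
  ep2$arm_angle[osc] <- ifelse(seq_len(sum(osc)) %% 2 == 0, 20, -20)
  asleep2 <- detect_sleep(ep2, bed, wake)
  expect_true(all(!asleep2[osc]))
  before <- ep2$timestamp >= bed & ep2$timestamp < bed + 239 * 60
  after <- ep2$timestamp >= bed + 251 * 60 & ep2$timestamp < wake
  expect_true(all(asleep2[before]))
  expect_true(all(asleep2[after]))

  # calm angles entirely outside the window yield zero sleep
  ep3 <- make_epochs(600)  # oscillating throughout
  calm3 <- ep3$timestamp < bed + 60 * 60
  ep3$arm_angle[calm3] <- -35  # calm hour before this logged window
  asleep3 <- detect_sleep(ep3, bed + 300 * 60, bed + 400 * 60)
  expect_equal(sum(asleep3), 0)
  # calm spans shorter than 5 min never count
  ep4 <- make_epochs(600)
  calm <- ep4$timestamp >= bed + 100 * 60 & ep4$timestamp < bed + 104 * 60
  ep4$arm_angle[calm] <- -35
  expect_equal(sum(detect_sleep(ep4, bed, wake)), 0)
  # missing log: no sleep
  expect_equal(sum(detect_sleep(ep, bed[NA_integer_], wake)), 0)
})

test_that("intensity classification honours the exact cut-point semantics", {
  got <- classify_intensity(c(0, 29.999, 30, 100.599, 100.6, 250))
  expect_equal(as.character(got), c("SED", "SED", "LPA", "LPA", "MVPA", "MVPA"))
  expect_error(classify_intensity(c(-1, 10)), "nonnegative")
})

test_that("day segmentation is fencepost-correct over bedtimes", {
  bed <- utc("2021-05-03 23:00:00")
  logs <- data.frame(bedtime = bed + c(0, 1440, 2 * 1440 - 60) * 60)
  w <- segment_days(logs)
  expect_equal(nrow(w), 2)
  expect_equal(as.numeric(difftime(w$end, w$start, units = "hours")), c(24, 23))
  logs7 <- data.frame(bedtime = bed + (0:6) * 86400)
  expect_equal(nrow(segment_days(logs7)), 6)
  expect_error(segment_days(data.frame(bedtime = bed)), "two")
  expect_error(segment_days(data.frame(bedtime = c(bed + 3600, bed))), "increasing")
})

test_that("processing a simulated stream recovers the generating composition", {
  bed <- utc("2021-05-03 23:00:00")
  target <- c(480, 660, 250, 50)
  wk <- simulate_week_stream(rbind(target), bed, epoch_s = 5, seed = 31)
  days <- process_epoch_stream(wk$epochs, wk$logs)
  expect_equal(unname(unlist(days[1, c("sleep", "sed", "lpa", "mvpa")])),
               target, tolerance = 1 / 12)  # within one 5-s epoch per part
  expect_true(days$valid[1])
  # partition property: parts + non-wear = day length
  expect_equal(days$sleep + days$sed + days$lpa + days$mvpa + days$nonwear_min,
               days$day_length_min)
})

test_that("injected non-wear is detected, excluded, and never inflates behaviours", {
  bed <- utc("2021-05-03 23:00:00")
  target <- c(480, 660, 250, 50)
  nw <- data.frame(start_min = 600, dur_min = 60)
  wk0 <- simulate_week_stream(rbind(target), bed, seed = 77)
  wk1 <- simulate_week_stream(rbind(target), bed, seed = 77, nonwear = list(nw))
  d0 <- process_epoch_stream(wk0$epochs, wk0$logs)
  d1 <- process_epoch_stream(wk1$epochs, wk1$logs)
  expect_equal(d1$nonwear_min, 60, tolerance = 1e-9)
  for (k in c("sleep", "sed", "lpa", "mvpa"))
    expect_true(d1[[k]] <= d0[[k]] + 1e-9)
  expect_equal(d1$sleep + d1$sed + d1$lpa + d1$mvpa + d1$nonwear_min,
               d1$day_length_min)
  # an all-day non-wear stream gives a zero composition flagged invalid
  ep <- wk0$epochs
  ep[, c("sd_x", "sd_y", "sd_z")] <- 0
  ep[, c("range_x", "range_y", "range_z")] <- 0
  d_all <- process_epoch_stream(ep, wk0$logs)
  expect_equal(unname(unlist(d_all[1, c("sleep", "sed", "lpa", "mvpa")])),
               rep(0, 4))
  expect_false(d_all$valid[1])
})

test_that("round trip holds across random day compositions", {
  bed <- utc("2021-05-03 23:00:00")
  for (s in 1:6) {
    target <- random_day_target(400 + s)
    wk <- simulate_week_stream(rbind(target), bed, seed = 500 + s)
    days <- process_epoch_stream(wk$epochs, wk$logs)
    expect_equal(unname(unlist(days[1, c("sleep", "sed", "lpa", "mvpa")])),
                 unname(target), tolerance = 1 / 12)
  }
})

test_that("validity and inclusion rules behave exactly at their boundaries", {
  # waking wear 599 vs 600 minutes
  base <- data.frame(participant = "P1", wave = "pre", valid = TRUE)
  ep <- make_epochs(1440, sd = 20, rng = 60, enmo = 10)
  # make all but the first 599/600 waking minutes non-wear
  win <- data.frame(start = ep$timestamp[1], end = ep$timestamp[1] + 1440 * 60)
  asleep <- rep(FALSE, nrow(ep))
  for (wear_min in c(599, 600)) {
    wear <- seq_len(nrow(ep)) <= wear_min * 12
    d <- compute_day_composition(ep, win, wear, asleep)
    expect_equal(d$waking_wear_min, wear_min)
    expect_identical(d$valid, wear_min >= 600)
  }
  expect_error(compute_day_composition(ep, data.frame(start = win$end + 10,
                                                      end = win$end + 20),
                                       rep(TRUE, nrow(ep)), asleep), "empty")

  # >= 4 valid days in both waves
  mk <- function(id, n_pre, n_post, valid_pre = n_pre, valid_post = n_post) {
    rbind(
      data.frame(participant = id, wave = "pre", valid = seq_len(n_pre) <= valid_pre),
      data.frame(participant = id, wave = "post", valid = seq_len(n_post) <= valid_post)
    )
  }
  days <- rbind(mk("A", 4, 4), mk("B", 7, 7, valid_post = 3), mk("C", 3, 7))
  days <- rbind(days, data.frame(participant = "D", wave = "pre", valid = rep(TRUE, 7)))
  res <- filter_participants(days)
  expect_identical(res$included, "A")
  expect_setequal(res$exclusions$participant, c("B", "C", "D"))
  expect_match(res$exclusions$reason[res$exclusions$participant == "D"],
               "missing wave")
  # empty input
  empty <- filter_participants(days[0, ])
  expect_length(empty$included, 0)
})
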