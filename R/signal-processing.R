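# Epoch-summary processing: non-wear detection, log-guided sleep
# detection, ENMO intensity classification, bedtime-to-bedtime day
# segmentation and per-day composition assembly with validity filters.

epoch_seconds <- function(epochs) {
  ts <- as.numeric(epochs$timestamp)
  if (length(ts) < 2L) stop("need at least two epochs")
  d <- diff(ts)
  if (any(abs(d - d[1L]) > 1e-6)) {
    i <- which(abs(d - d[1L]) > 1e-6)[1L]
    stop(sprintf("gap in epoch timestamps between %s and %s",
                 format(epochs$timestamp[i]), format(epochs$timestamp[i + 1L])))
  }
  d[1L]
}

#' Detect non-wear from 60-min window signal features
#'
#' Works on 15-min blocks: a block is non-wear when, over its centred
#' 60-min window, the per-axis standard deviation is below `sd_crit`
#' (13 mg) for at least two of the three axes, or the per-axis value range
#' is below `range_crit` (50 mg) for at least two axes. The window
#' statistics are the `sd_*` / `range_*` columns carried on the epoch
#' records (summarised by their per-axis median over the window).
#'
#' @param epochs Epoch data.frame (equally spaced, time-ordered) with
#'   columns `timestamp`, `sd_x/y/z`, `range_x/y/z`.
#' @param block_min Block length in minutes (default 15).
#' @param window_min Evaluation window centred on the block (default 60).
#' @param sd_crit,range_crit Thresholds in mg (defaults 13 and 50).
#' @return Logical vector, `TRUE` where the epoch is worn.
#' @export
detect_nonwear <- function(epochs, block_min = 15, window_min = 60,
                           sd_crit = 13, range_crit = 50) {
  es <- epoch_seconds(epochs)
  n <- nrow(epochs)
  t0 <- as.numeric(epochs$timestamp[1L])
  rel <- as.numeric(epochs$timestamp) - t0
  block <- floor(rel / (block_min * 60))
  wear <- rep(TRUE, n)
  sd_cols <- as.matrix(epochs[, c("sd_x", "sd_y", "sd_z")])
  rg_cols <- as.matrix(epochs[, c("range_x", "range_y", "range_z")])
  half <- window_min * 60 / 2
  for (b in unique(block)) {
    idx <- which(block == b)
    center <- mean(range(rel[idx])) + es / 2
    win <- which(rel >= center - half & rel < center + half)
    sd_med <- apply(sd_cols[win, , drop = FALSE], 2L, stats::median)
    rg_med <- apply(rg_cols[win, , drop = FALSE], 2L, stats::median)
    if (sum(sd_med < sd_crit) >= 2L || sum(rg_med < range_crit) >= 2L)
      wear[idx] <- FALSE
  }
  wear
}

#' Detect sleep inside the logged bed window
#'
#' Sleep is any maximal span of at least `min_span_min` minutes inside
#' `[bedtime, waketime)` over which no epoch-to-epoch arm-angle change
#' exceeds `max_change` degrees. Epochs outside the logged window are
#' never sleep; a missing log (NA bedtime or waketime) yields no sleep.
#'
#' @param epochs Epoch data.frame with `timestamp` and `arm_angle`.
#' @param bedtime,waketime POSIXct limits of the logged night.
#' @param max_change Maximum tolerated angle change in degrees (default 5).
#' @param min_span_min Minimum calm span length in minutes (default 5).
#' @return Logical vector, `TRUE` where the epoch is classified asleep.
#' @export
detect_sleep <- function(epochs, bedtime, waketime, max_change = 5,
                         min_span_min = 5) {
  es <- epoch_seconds(epochs)
  asleep <- rep(FALSE, nrow(epochs))
  if (is.na(bedtime) || is.na(waketime)) return(asleep)
  inwin <- which(epochs$timestamp >= bedtime & epochs$timestamp < waketime)
  if (length(inwin) < 2L) return(asleep)
  ang <- epochs$arm_angle[inwin]
  calm_step <- c(TRUE, abs(diff(ang)) <= max_change)
  # spans break where the step into an epoch is large
  span_id <- cumsum(!calm_step)
  min_len <- ceiling(min_span_min * 60 / es)
  for (sid in unique(span_id)) {
    members <- which(span_id == sid)
    if (length(members) >= min_len) asleep[inwin[members]] <- TRUE
  }
  asleep
}

#' Classify waking intensity from ENMO
#'
#' Sedentary below 30 mg, light activity from 30 up to (not including)
#' 100.6 mg, moderate-to-vigorous at or above 100.6 mg.
#'
#' @param enmo Numeric vector of ENMO values in mg; must be nonnegative.
#' @param cuts Length-2 cut points (defaults `c(30, 100.6)`).
#' @return Factor with levels `SED`, `LPA`, `MVPA`.
#' @export
classify_intensity <- function(enmo, cuts = c(30, 100.6)) {
  if (any(!is.finite(enmo)) || any(enmo < 0)) stop("ENMO must be finite and nonnegative")
  factor(ifelse(enmo >= cuts[2L], "MVPA", ifelse(enmo >= cuts[1L], "LPA", "SED")),
         levels = c("SED", "LPA", "MVPA"))
}

#' Segment a stream into bedtime-to-bedtime measurement days
#'
#' @param logs Daily-log data.frame with a `bedtime` column (POSIXct),
#'   one row per night plus a closing bedtime row; consecutive bedtimes
#'   delimit the days.
#' @return Data.frame with `day`, `start`, `end` (end exclusive); the
#'   windows partition the covered timeline.
#' @export
segment_days <- function(logs) {
  bt <- logs$bedtime
  if (length(bt) < 2L) stop("need at least two logged bedtimes")
  if (any(diff(as.numeric(bt)) <= 0)) stop("bedtimes must be strictly increasing")
  data.frame(day = seq_len(length(bt) - 1L),
             start = bt[-length(bt)], end = bt[-1L])
}

#' Assemble one day's 4-part composition
#'
#' Counts minutes inside one bedtime-to-bedtime window: sleep is worn
#' sleep; SED/LPA/MVPA are counted over worn waking epochs; non-wear
#' minutes are excluded from all four parts. A day is valid when waking
#' wear time reaches `min_wear_min` (600 min = 10 h).
#'
#' @param epochs Epoch data.frame.
#' @param window One row of [segment_days()] output (`start`, `end`).
#' @param wear Logical wear mask from [detect_nonwear()].
#' @param asleep Logical sleep mask from [detect_sleep()].
#' @param min_wear_min Waking-wear validity threshold in minutes.
#' @return One-row data.frame: `day_length_min`, `sleep`, `sed`, `lpa`,
#'   `mvpa`, `nonwear_min`, `waking_wear_min`, `valid`.
#' @export
compute_day_composition <- function(epochs, window, wear, asleep,
                                    min_wear_min = 600) {
  es <- epoch_seconds(epochs)
  idx <- which(epochs$timestamp >= window$start & epochs$timestamp < window$end)
  if (length(idx) == 0L) stop("empty day window")
  per_min <- es / 60
  w <- wear[idx]; sl <- asleep[idx]
  intensity <- classify_intensity(epochs$enmo[idx])
  waking <- w & !sl
  counts <- table(intensity[waking])
  out <- data.frame(
    day_length_min = length(idx) * per_min,
    sleep = sum(w & sl) * per_min,
    sed = as.numeric(counts["SED"]) * per_min,
    lpa = as.numeric(counts["LPA"]) * per_min,
    mvpa = as.numeric(counts["MVPA"]) * per_min,
    nonwear_min = sum(!w) * per_min
  )
  out$waking_wear_min <- out$sed + out$lpa + out$mvpa
  out$valid <- out$waking_wear_min >= min_wear_min
  out
}

#' Process an epoch stream into daily compositions
#'
#' Runs non-wear detection, per-night sleep detection, intensity
#' classification and day segmentation, returning one row per
#' bedtime-to-bedtime day.
#'
#' @param epochs Epoch data.frame for one participant-wave.
#' @param logs Daily logs (`bedtime`, `waketime`; final row closes the
#'   last day). A night with a missing log contributes no sleep and is
#'   noted in the `missing_log` column.
#' @param min_wear_min Validity threshold (default 600).
#' @return Data.frame of day compositions with a `valid` flag.
#' @export
process_epoch_stream <- function(epochs, logs, min_wear_min = 600) {
  wear <- detect_nonwear(epochs)
  windows <- segment_days(logs)
  rows <- vector("list", nrow(windows))
  for (d in seq_len(nrow(windows))) {
    bt <- logs$bedtime[d]
    wt <- logs$waketime[d]
    asleep <- detect_sleep(epochs, bt, wt)
    row <- compute_day_composition(epochs, windows[d, ], wear, asleep,
                                   min_wear_min)
    row$day <- windows$day[d]
    row$missing_log <- is.na(wt)
    rows[[d]] <- row
  }
  out <- do.call(rbind, rows)
  out[, c("day", "day_length_min", "sleep", "sed", "lpa", "mvpa",
          "nonwear_min", "waking_wear_min", "valid", "missing_log")]
}

#' Apply the minimum-valid-days inclusion rule
#'
#' A participant is retained only with at least `min_valid_days` valid
#' days at the pre wave AND at the post wave; participants missing a wave
#' are excluded with a logged reason.
#'
#' @param days Data.frame with `participant`, `wave` (`"pre"`/`"post"`)
#'   and logical `valid`, one row per measured day.
#' @param min_valid_days Threshold (default 4).
#' @return List with `included` (character vector of participant ids) and
#'   `exclusions` (data.frame of `participant`, `reason`).
#' @export
filter_participants <- function(days, min_valid_days = 4L) {
  ids <- unique(days$participant)
  included <- character(0)
  excl <- list()
  for (id in ids) {
    sub <- days[days$participant == id, ]
    n_pre <- sum(sub$valid[sub$wave == "pre"])
    n_post <- sum(sub$valid[sub$wave == "post"])
    if (!any(sub$wave == "pre") || !any(sub$wave == "post")) {
      excl[[id]] <- "missing wave"
    } else if (n_pre < min_valid_days || n_post < min_valid_days) {
      excl[[id]] <- sprintf("fewer than %d valid days (pre=%d, post=%d)",
                            min_valid_days, n_pre, n_post)
    } else {
      included <- c(included, id)
    }
  }
  exclusions <- if (length(excl))
    data.frame(participant = names(excl), reason = unlist(excl),
               row.names = NULL, stringsAsFactors = FALSE)
  else data.frame(participant = character(0), reason = character(0))
  list(included = included, exclusions = exclusions)
}
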