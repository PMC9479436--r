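# Synthetic cohorts and wrist-accelerometer epoch streams with known
# ground truth, so every downstream stage (processing, description,
# modelling) is testable without any external data.

#' Published group mean compositions used as simulation anchors
#'
#' The pre- and post-retirement compositional means (minutes, scaled to
#' 1440) for each gender-by-occupation group, plus the printed change
#' rows, as reported for the retiring Finnish public-sector cohort the
#' package emulates.
#'
#' @param what `"means"` for the before/after group means, `"change"` for
#'   the printed change rows (after minus before, integer minutes).
#' @return A data.frame with columns `group`, (`wave`,) `sleep`, `sed`,
#'   `lpa`, `mvpa`.
#' @export
reference_group_means <- function(what = c("means", "change")) {
  what <- match.arg(what)
  groups <- c("all", "women", "women_nonmanual", "women_manual",
              "men", "men_nonmanual", "men_manual")
  before <- rbind(
    sleep = c(478, 480, 482, 475, 464, 455, 482),
    sed   = c(672, 663, 684, 622, 726, 749, 677),
    lpa   = c(239, 246, 228, 284, 200, 188, 228),
    mvpa  = c(50, 50, 46, 58, 50, 49, 53)
  )
  after <- rbind(
    sleep = c(515, 518, 517, 520, 492, 487, 504),
    sed   = c(667, 659, 660, 658, 711, 721, 690),
    lpa   = c(217, 221, 221, 221, 194, 189, 206),
    mvpa  = c(42, 42, 42, 41, 42, 43, 40)
  )
  change <- rbind(
    sleep = c(36, 38, 36, 45, 29, 32, 22),
    sed   = c(-6, -4, -24, 36, -15, -28, 13),
    lpa   = c(-22, -25, -6, -64, -6, 1, -23),
    mvpa  = c(-8, -9, -5, -17, -8, -5, -13)
  )
  if (what == "change") {
    out <- data.frame(group = groups, t(change))
    rownames(out) <- NULL
    return(out)
  }
  out <- rbind(
    data.frame(group = groups, wave = "pre", t(before)),
    data.frame(group = groups, wave = "post", t(after))
  )
  rownames(out) <- NULL
  out
}

#' Stratum labels of the simulated cohort
#' @return Data.frame with `stratum`, `gender`, `occupation` for the four
#'   gender-by-occupation cells.
#' @export
cohort_strata <- function() {
  data.frame(
    stratum = c("women_nonmanual", "women_manual", "men_nonmanual", "men_manual"),
    gender = c("woman", "woman", "man", "man"),
    occupation = c("nonmanual", "manual", "nonmanual", "manual"),
    stringsAsFactors = FALSE
  )
}

default_group_means <- function() {
  ref <- reference_group_means("means")
  pre <- ref[ref$wave == "pre" & ref$group %in% cohort_strata()$stratum, ]
  m <- as.matrix(pre[, behavior_parts()])
  rownames(m) <- pre$group
  m[cohort_strata()$stratum, , drop = FALSE]
}

default_change_perturbations <- function() {
  ref <- reference_group_means("means")
  strata <- cohort_strata()$stratum
  pre <- ref[ref$wave == "pre", ]
  post <- ref[ref$wave == "post", ]
  m <- t(vapply(strata, function(g) {
    perturb_diff(unlist(post[post$group == g, behavior_parts()]),
                 unlist(pre[pre$group == g, behavior_parts()]))
  }, numeric(4L)))
  colnames(m) <- behavior_parts()
  m
}

#' Configuration of the synthetic two-wave cohort
#'
#' Describes a cohort observed at two waves one year apart (pre/post a
#' life transition) in four gender-by-occupation strata. Day compositions
#' are logistic-normal: participant effects, participant-specific change
#' (slope) and day-to-day noise are independent normals in the 3-D
#' balance-coordinate space of `default_sbp()`, mapped back to the simplex.
#'
#' Defaults: stratum sizes (308, 164, 54, 25) and group means/change
#' perturbations taken from [reference_group_means()]; between-person and
#' slope SDs calibrated so simulated fixed-effect confidence intervals
#' resemble the published ones; day-level SDs are the package's own choice
#' (see the methods vignette).
#'
#' @param n_per_stratum Integer count per stratum, length 1 or 4
#'   (order: women non-manual, women manual, men non-manual, men manual).
#' @param group_means 4 x 4 matrix of stratum mean compositions
#'   (minutes summing to 1440), rows in stratum order.
#' @param change_perturbations 4 x 4 matrix of stratum change compositions
#'   applied at the post wave (closed; `rep(1/4, 4)` is no change).
#' @param between_sd,within_sd,slope_sd Length-3 nonnegative SDs of the
#'   participant effect, day noise and participant change, in
#'   balance-coordinate units.
#' @param days_per_wave Valid measurement days simulated per wave.
#' @param day_length_jitter_sd SD (minutes) of a per-day jitter of the
#'   day length around 1440; default 0 (exact 24-h days).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return Object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_per_stratum = c(308, 164, 54, 25),
                          group_means = default_group_means(),
                          change_perturbations = default_change_perturbations(),
                          between_sd = c(0.50, 0.42, 0.15),
                          within_sd = c(0.35, 0.60, 0.20),
                          slope_sd = c(0.60, 0.50, 0.17),
                          days_per_wave = 7L,
                          day_length_jitter_sd = 0,
                          seed = 1L) {
  if (length(n_per_stratum) == 1L) n_per_stratum <- rep(n_per_stratum, 4L)
  stopifnot(length(n_per_stratum) == 4L)
  if (any(n_per_stratum < 1L)) stop("n_per_stratum must be at least 1")
  group_means <- as.matrix(group_means)
  stopifnot(nrow(group_means) == 4L, ncol(group_means) == 4L)
  if (any(group_means <= 0)) stop("group means must be strictly positive")
  if (any(abs(rowSums(group_means) - 1440) > 2))
    stop("each group mean must sum to 1440 minutes (within tolerance)")
  change_perturbations <- as.matrix(change_perturbations)
  stopifnot(nrow(change_perturbations) == 4L, ncol(change_perturbations) == 4L)
  if (any(change_perturbations <= 0)) stop("change perturbations must be strictly positive")
  for (v in list(between_sd = between_sd, within_sd = within_sd, slope_sd = slope_sd)) {
    stopifnot(length(v) == 3L)
    if (any(v < 0)) stop("SDs must be nonnegative")
  }
  if (days_per_wave < 1L) stop("days_per_wave must be at least 1")
  structure(list(
    n_per_stratum = as.integer(n_per_stratum),
    group_means = group_means,
    change_perturbations = close_composition(change_perturbations, 1),
    between_sd = between_sd, within_sd = within_sd, slope_sd = slope_sd,
    days_per_wave = as.integer(days_per_wave),
    day_length_jitter_sd = day_length_jitter_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("synthetic two-wave cohort config\n")
  cat(sprintf("  participants: %s (total %d), %d days/wave, seed %d\n",
              paste(x$n_per_stratum, collapse = "/"), sum(x$n_per_stratum),
              x$days_per_wave, x$seed))
  invisible(x)
}

#' Simulate a two-wave cohort of daily movement-behaviour compositions
#'
#' For participant i in stratum s with balance-coordinate stratum mean
#' `mu_s` and change `delta_s` (the balance coordinates of the stratum's
#' change perturbation), day d at the pre wave is
#' `ilr_inverse(mu_s + b_i + e_id)` and at the post wave
#' `ilr_inverse(mu_s + delta_s + b_i + u_i + e_id)`, scaled to minutes;
#' `b_i`, `u_i`, `e_id` are independent centred normals with the
#' configured SDs.
#'
#' @param config A [cohort_config()].
#' @return Data.frame with one row per participant-wave-day: columns
#'   `participant`, `gender`, `occupation`, `stratum`, `wave`
#'   (`"pre"`/`"post"`), `day`, and minute columns `sleep`, `sed`, `lpa`,
#'   `mvpa` summing to the day length (1440 unless jittered). The config
#'   is attached as attribute `"config"`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  strata <- cohort_strata()
  part <- default_sbp()
  mu <- ilr_transform(config$group_means, part)
  delta <- ilr_transform(config$change_perturbations, part)
  seeds <- split_seed(config$seed, nrow(strata))
  out <- vector("list", nrow(strata))
  pid0 <- 0L
  for (s in seq_len(nrow(strata))) {
    n <- config$n_per_stratum[s]
    m <- config$days_per_wave
    out[[s]] <- with_seed(seeds[s], {
      b <- matrix(stats::rnorm(n * 3L, 0, rep(config$between_sd, each = n)), n, 3L)
      u <- matrix(stats::rnorm(n * 3L, 0, rep(config$slope_sd, each = n)), n, 3L)
      waves <- lapply(c("pre", "post"), function(w) {
        e <- matrix(stats::rnorm(n * m * 3L, 0, rep(config$within_sd, each = n * m)),
                    n * m, 3L)
        base <- b[rep(seq_len(n), each = m), , drop = FALSE]
        z <- sweep(base + e, 2L, mu[s, ], "+")
        if (w == "post")
          z <- z + sweep(u[rep(seq_len(n), each = m), , drop = FALSE], 2L, delta[s, ], "+")
        day_len <- rep(1440, n * m)
        if (config$day_length_jitter_sd > 0)
          day_len <- pmax(600, day_len + stats::rnorm(n * m, 0, config$day_length_jitter_sd))
        comp <- ilr_inverse(z, part, kappa = 1) * day_len
        data.frame(
          participant = sprintf("P%04d", pid0 + rep(seq_len(n), each = m)),
          gender = strata$gender[s], occupation = strata$occupation[s],
          stratum = strata$stratum[s], wave = w, day = rep(seq_len(m), n),
          comp, stringsAsFactors = FALSE
        )
      })
      do.call(rbind, waves)
    })
    pid0 <- pid0 + n
  }
  cohort <- do.call(rbind, out)
  rownames(cohort) <- NULL
  cohort$wave <- factor(cohort$wave, levels = c("pre", "post"))
  attr(cohort, "config") <- config
  cohort
}

#' Force MVPA to zero on selected person-days
#'
#' Scenario generator for exercising zero replacement: sets MVPA to 0 on
#' `n_days` randomly chosen rows (the removed minutes are moved into SED
#' so the day total is preserved), mimicking rounded-zero MVPA days.
#'
#' @param cohort Cohort data.frame from [simulate_cohort()].
#' @param n_days Number of person-day rows to zero (default 6).
#' @param seed Integer seed.
#' @return The cohort with zeros planted; chosen row indices in attribute
#'   `"zeroed_rows"`.
#' @export
force_mvpa_zero <- function(cohort, n_days = 6L, seed = 1L) {
  stopifnot(n_days <= nrow(cohort))
  idx <- with_seed(seed, sample.int(nrow(cohort), n_days))
  cohort$sed[idx] <- cohort$sed[idx] + cohort$mvpa[idx]
  cohort$mvpa[idx] <- 0
  attr(cohort, "zeroed_rows") <- idx
  cohort
}

# ---- epoch-level simulation -------------------------------------------

enmo_bands <- function() {
  # half-open intensity bands in mg: SED [0, 30), LPA [30, 100.6), MVPA >= 100.6
  list(sed = c(0, 29.9), lpa = c(30, 100.5), mvpa = c(100.6, 400))
}

#' Simulate a wrist-accelerometer epoch stream realizing a day composition
#'
#' Generates epoch summaries (timestamp, ENMO in mg, arm angle in degrees,
#' per-axis SD and range in mg over the surrounding 60-min window) for one
#' bedtime-to-bedtime day whose processed composition equals `target`.
#' Sleep epochs lie inside the logged bed window with arm-angle changes
#' well under 5 deg; in-bed wake and daytime epochs carry jittery angles
#' and ENMO values drawn inside the correct intensity band; optional
#' injected non-wear blocks carry per-axis SD < 13 mg and range < 50 mg
#' and overwrite whatever behaviour occupied those minutes.
#'
#' @param target Named or ordered 4-vector (sleep, sed, lpa, mvpa) of
#'   minutes; the day length is `sum(target)`.
#' @param log List/row with POSIXct `bedtime` and `waketime`; sleep must
#'   fit in the window and any in-bed wake time is sedentary, so
#'   `target["sed"]` must cover the window minutes beyond sleep.
#' @param epoch_s Epoch length in seconds; must divide 60 (default 5).
#' @param seed Integer seed.
#' @param nonwear Optional data.frame with `start_min`, `dur_min`
#'   (offsets from the day start) of non-wear blocks to inject.
#' @return Data.frame of epoch records: `timestamp`, `enmo`, `arm_angle`,
#'   `sd_x/y/z`, `range_x/y/z`.
#' @export
simulate_epoch_stream <- function(target, log, epoch_s = 5L, seed = 1L,
                                  nonwear = NULL) {
  target <- as.numeric(target)
  stopifnot(length(target) == 4L)
  if (any(target < 0)) stop("target minutes must be nonnegative")
  if (60L %% epoch_s != 0L) stop("epoch_s must divide 60 seconds")
  day_min <- sum(target)
  if (day_min <= 0) stop("target day length must be positive")
  window_min <- as.numeric(difftime(log$waketime, log$bedtime, units = "mins"))
  if (window_min < 0) stop("waketime must follow bedtime")
  sleep_min <- target[1L]
  if (sleep_min > window_min + epoch_s / 60)
    stop("target sleep exceeds the logged bed window")
  inbed_wake <- window_min - sleep_min
  if (target[2L] < inbed_wake - epoch_s / 60)
    stop("in-bed wake minutes exceed the sedentary budget of the target")
  per_min <- 60L %/% epoch_s
  n_ep <- round(day_min * per_min)
  ts <- log$bedtime + (seq_len(n_ep) - 1L) * epoch_s

  with_seed(seed, {
    # minute-level behaviour schedule: sleep block at bedtime, in-bed wake
    # (sedentary) until waketime, then remaining SED/LPA/MVPA minutes
    # shuffled in 10-min bouts across the waking day.
    n_sleep <- round(sleep_min)
    n_inbed <- round(inbed_wake)
    rest <- c(sed = round(target[2L]) - n_inbed,
              lpa = round(target[3L]), mvpa = round(target[4L]))
    rest["sed"] <- round(day_min) - n_sleep - n_inbed - rest[["lpa"]] - rest[["mvpa"]]
    labels <- unlist(lapply(names(rest), function(k) rep(k, max(0L, rest[[k]]))))
    bouts <- split(labels, ceiling(seq_along(labels) / 10))
    day_labels <- unlist(bouts[sample.int(length(bouts))], use.names = FALSE)
    minute_lab <- c(rep("sleep", n_sleep), rep("sed", n_inbed), day_labels)
    minute_lab <- minute_lab[seq_len(round(day_min))]
    lab <- rep(minute_lab, each = per_min)[seq_len(n_ep)]

    bands <- enmo_bands()
    enmo <- numeric(n_ep)
    enmo[lab == "sleep"] <- stats::runif(sum(lab == "sleep"), 0, 5)
    for (k in c("sed", "lpa", "mvpa")) {
      i <- lab == k
      enmo[i] <- stats::runif(sum(i), bands[[k]][1L], bands[[k]][2L])
    }
    angle <- numeric(n_ep)
    asleep <- lab == "sleep"
    angle[asleep] <- -35 + cumsum(stats::runif(sum(asleep), -0.05, 0.05))
    awake_n <- sum(!asleep)
    # alternating large swings: no 5-min span of awake epochs stays within 5 deg
    angle[!asleep] <- ifelse(seq_len(awake_n) %% 2L == 0L, 20, -20) +
      stats::runif(awake_n, -3, 3)
    sds <- matrix(stats::runif(n_ep * 3L, 20, 60), n_ep, 3L)
    rngs <- matrix(stats::runif(n_ep * 3L, 100, 300), n_ep, 3L)

    epochs <- data.frame(
      timestamp = ts, enmo = enmo, arm_angle = angle,
      sd_x = sds[, 1L], sd_y = sds[, 2L], sd_z = sds[, 3L],
      range_x = rngs[, 1L], range_y = rngs[, 2L], range_z = rngs[, 3L]
    )
    if (!is.null(nonwear)) {
      for (r in seq_len(nrow(nonwear))) {
        i0 <- round(nonwear$start_min[r] * per_min) + 1L
        i1 <- min(n_ep, i0 + round(nonwear$dur_min[r] * per_min) - 1L)
        idx <- seq(i0, i1)
        epochs$enmo[idx] <- 0
        epochs$arm_angle[idx] <- epochs$arm_angle[pmax(1L, i0 - 1L)]
        epochs[idx, c("sd_x", "sd_y", "sd_z")] <- stats::runif(3L * length(idx), 0, 5)
        epochs[idx, c("range_x", "range_y", "range_z")] <- stats::runif(3L * length(idx), 0, 20)
      }
    }
    epochs
  })
}

#' Simulate a multi-day epoch stream for one participant-wave
#'
#' Chains [simulate_epoch_stream()] over the rows of `targets`, producing
#' one continuous stream plus the matching daily log (one row per night
#' and a closing bedtime row with `NA` waketime marking the end of the
#' last day).
#'
#' @param targets Matrix/data.frame of day compositions (minutes), one row
#'   per day, columns (sleep, sed, lpa, mvpa).
#' @param first_bedtime POSIXct start of the first day.
#' @param epoch_s Epoch length in seconds.
#' @param seed Integer seed.
#' @param nonwear Optional list (one element per day) of non-wear block
#'   data.frames passed through to [simulate_epoch_stream()].
#' @return List with `epochs` and `logs` (columns `date`, `bedtime`,
#'   `waketime`).
#' @export
simulate_week_stream <- function(targets, first_bedtime, epoch_s = 5L,
                                 seed = 1L, nonwear = NULL) {
  targets <- as.matrix(targets)
  n_days <- nrow(targets)
  seeds <- split_seed(seed, n_days)
  bed <- first_bedtime
  eps <- vector("list", n_days)
  logs <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    wake <- bed + round(targets[d, 1L]) * 60
    lg <- list(bedtime = bed, waketime = wake)
    nw <- if (is.null(nonwear)) NULL else nonwear[[d]]
    eps[[d]] <- simulate_epoch_stream(targets[d, ], lg, epoch_s, seeds[d],
                                      nonwear = nw)
    logs[[d]] <- data.frame(date = as.Date(bed), bedtime = bed, waketime = wake)
    bed <- bed + round(sum(targets[d, ])) * 60
  }
  logs <- do.call(rbind, logs)
  logs <- rbind(logs, data.frame(date = as.Date(bed), bedtime = bed,
                                 waketime = bed[NA_integer_]))
  list(epochs = do.call(rbind, eps), logs = logs)
}
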