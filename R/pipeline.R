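# Orchestration: simulate -> (process) -> screen -> describe -> model,
# with CSV/JSON artifacts, a run log of every exclusion, and full
# reproducibility from one seed.

group_rows <- function(cohort) {
  list(
    all = rep(TRUE, nrow(cohort)),
    women = cohort$gender == "woman",
    women_nonmanual = cohort$gender == "woman" & cohort$occupation == "nonmanual",
    women_manual = cohort$gender == "woman" & cohort$occupation == "manual",
    men = cohort$gender == "man",
    men_nonmanual = cohort$gender == "man" & cohort$occupation == "nonmanual",
    men_manual = cohort$gender == "man" & cohort$occupation == "manual"
  )
}

#' Group-wise compositional means and change rows
#'
#' For each gender/occupation group and wave, the compositional mean of
#' the day compositions rescaled to 1440 min, plus a change block of
#' after-minus-before differences. By convention the change is computed
#' from the unrounded means and then rounded to integer minutes
#' (`change_convention = "unrounded"`, the default); subtracting the
#' already-rounded means (`"rounded"`) can differ by one minute.
#'
#' @param cohort Day-level data.frame with `gender`, `occupation`, `wave`
#'   and strictly positive minute columns `sleep`, `sed`, `lpa`, `mvpa`.
#' @param change_convention `"unrounded"` or `"rounded"`.
#' @return List with `means` (group x wave compositional means, exact and
#'   rounded) and `change` (per group, integer minutes).
#' @export
describe_cohort <- function(cohort, change_convention = c("unrounded", "rounded")) {
  change_convention <- match.arg(change_convention)
  parts <- behavior_parts()
  groups <- group_rows(cohort)
  means <- list()
  change <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    if (!any(sel)) {
      warning(sprintf("group %s is empty; omitted", g))
      next
    }
    mw <- lapply(c("pre", "post"), function(w) {
      rows <- sel & cohort$wave == w
      if (!any(rows)) return(NULL)
      compositional_mean(cohort[rows, parts], kappa = 1440)
    })
    if (is.null(mw[[1L]]) || is.null(mw[[2L]])) {
      warning(sprintf("group %s is missing a wave; omitted", g))
      next
    }
    means[[g]] <- data.frame(group = g, wave = c("pre", "post"),
                             rbind(mw[[1L]], mw[[2L]]), row.names = NULL)
    diffs <- if (change_convention == "unrounded") round(mw[[2L]] - mw[[1L]])
             else round(mw[[2L]]) - round(mw[[1L]])
    change[[g]] <- data.frame(group = g, t(diffs), row.names = NULL)
  }
  means <- do.call(rbind, means)
  rownames(means) <- NULL
  means[, parts] <- round(means[, parts], 4)
  change <- do.call(rbind, change)
  rownames(change) <- NULL
  list(means = means, change = change)
}

#' Ternary coordinates and confidence regions for all sub-compositions
#'
#' For each group and wave, computes the four leave-one-out 3-part
#' sub-compositions of the group's day compositions and a bootstrapped
#' confidence region around each sub-compositional mean.
#'
#' @param cohort Day-level data.frame (strictly positive parts).
#' @param level Coverage probability (default 0.95).
#' @param n_boot Bootstrap resamples per region.
#' @param seed Integer seed.
#' @return Nested list `group -> wave -> triple` of
#'   [confidence_region()] objects.
#' @export
ternary_summaries <- function(cohort, level = 0.95, n_boot = 500, seed = 1L) {
  parts <- behavior_parts()
  groups <- group_rows(cohort)
  seeds <- split_seed(seed, length(groups) * 2L * 4L)
  k <- 0L
  out <- list()
  for (g in names(groups)) {
    for (w in c("pre", "post")) {
      rows <- groups[[g]] & cohort$wave == w
      if (sum(rows) < 3L) next
      subs <- subcompositions(as.matrix(cohort[rows, parts]))
      for (tr in names(subs)) {
        k <- k + 1L
        out[[g]][[w]][[tr]] <- confidence_region(subs[[tr]], level = level,
                                                 n_boot = n_boot,
                                                 seed = seeds[k])
      }
    }
  }
  out
}

regions_to_json <- function(regions, path) {
  flat <- list()
  for (g in names(regions)) for (w in names(regions[[g]]))
    for (tr in names(regions[[g]][[w]])) {
      r <- regions[[g]][[w]][[tr]]
      flat[[length(flat) + 1L]] <- list(
        group = g, wave = w, triple = tr, level = r$level,
        degenerate = r$degenerate,
        center = as.list(round(r$center, 6)),
        boundary = round(unname(r$boundary), 6)
      )
    }
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param cohort Arguments passed to [cohort_config()] (list), or an
#'   existing config object.
#' @param outlier_screen Run the log-contrast outlier screen (default TRUE).
#' @param outlier_threshold Robust-z cutoff (default 3.5).
#' @param zero_days Person-days on which MVPA is forced to zero before
#'   screening, exercising zero replacement (default 6).
#' @param aggregation Model-frame aggregation (`"day_level"`/`"wave_mean"`).
#' @param n_boot Bootstrap resamples per ternary region.
#' @param regions Compute ternary confidence regions (default TRUE).
#' @param min_valid_days Inclusion threshold on valid days per wave.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, cohort = list(),
                            outlier_screen = TRUE, outlier_threshold = 3.5,
                            zero_days = 6L,
                            aggregation = "day_level", n_boot = 200L,
                            regions = TRUE, min_valid_days = 4L) {
  seeds <- split_seed(seed, 4L)
  cfg <- if (inherits(cohort, "cohort_config")) cohort
         else do.call(cohort_config, c(cohort, list(seed = seeds[1L])))
  structure(list(seed = as.integer(seed), cohort = cfg,
                 outlier_screen = outlier_screen,
                 outlier_threshold = outlier_threshold,
                 zero_days = as.integer(zero_days),
                 aggregation = aggregation, n_boot = as.integer(n_boot),
                 regions = regions,
                 min_valid_days = as.integer(min_valid_days),
                 stage_seeds = seeds),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `cohort` key holds [cohort_config()] arguments (matrices given as
#' lists of rows).
#'
#' @param path YAML file path.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort)) {
    for (k in c("group_means", "change_perturbations"))
      if (!is.null(y$cohort[[k]]))
        y$cohort[[k]] <- do.call(rbind, y$cohort[[k]])
    for (k in c("between_sd", "within_sd", "slope_sd"))
      if (!is.null(y$cohort[[k]])) y$cohort[[k]] <- as.numeric(y$cohort[[k]])
    y$cohort$seed <- NULL
  }
  do.call(pipeline_config, y[setdiff(names(y), "out_dir")])
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a day-level cohort, plants and imputes MVPA
#' zeros, applies the validity and minimum-valid-days filters and the
#' outlier screen, writes group-wise descriptive tables, ternary regions
#' and the mixed-model report, and logs every exclusion count. The run is
#' reproducible from the seed.
#'
#' @param config A [pipeline_config()] (or YAML path).
#' @param out_dir Output directory for artifacts (created if needed).
#' @param cohort Optional pre-built day-level cohort data.frame; when
#'   supplied the simulation stage is skipped.
#' @return Invisible list with the cohort, describe tables, model report,
#'   region summaries and the run log.
#' @export
run_pipeline <- function(config, out_dir = tempfile("coda24_run_"),
                         cohort = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = config$seed)
  stage <- "simulate"
  result <- tryCatch({
    if (is.null(cohort)) cohort <- simulate_cohort(config$cohort)
    log$n_simulated_participants <- length(unique(cohort$participant))
    log$n_person_days <- nrow(cohort)

    stage <- "screen"
    if (config$zero_days > 0L && is.null(attr(cohort, "zeroed_rows")))
      cohort <- force_mvpa_zero(cohort, min(config$zero_days, nrow(cohort)),
                                seed = config$stage_seeds[2L])
    log$n_zero_mvpa_days <- sum(cohort$mvpa == 0)
    parts <- behavior_parts()
    cohort[, parts] <- replace_zeros(as.matrix(cohort[, parts]))
    if (is.null(cohort$valid)) cohort$valid <- TRUE
    log$n_invalid_days <- sum(!cohort$valid)
    keep <- filter_participants(cohort, config$min_valid_days)
    log$n_excluded_too_few_days <- nrow(keep$exclusions)
    cohort <- cohort[cohort$participant %in% keep$included & cohort$valid, ]
    if (nrow(cohort) == 0L)
      stop("no participants remain after the validity filters")

    log$n_outliers_flagged <- 0L
    log$outlier_screen <- config$outlier_screen
    if (config$outlier_screen) {
      wm <- stats::aggregate(cohort[, parts],
                             by = list(participant = cohort$participant,
                                       wave = cohort$wave),
                             FUN = function(x) exp(mean(log(x))))
      pre <- wm[wm$wave == "pre", ]
      post <- wm[wm$wave == "post", ]
      post <- post[match(pre$participant, post$participant), ]
      flags <- flag_outliers(as.matrix(pre[, parts]), as.matrix(post[, parts]),
                             threshold = config$outlier_threshold)
      out_ids <- pre$participant[flags]
      log$n_outliers_flagged <- length(out_ids)
      log$outlier_ids <- as.character(out_ids)
      cohort <- cohort[!cohort$participant %in% out_ids, ]
    }
    log$n_included_participants <- length(unique(cohort$participant))
    utils::write.csv(cohort, file.path(out_dir, "day_compositions.csv"),
                     row.names = FALSE)

    stage <- "describe"
    desc <- describe_cohort(cohort)
    utils::write.csv(desc$means, file.path(out_dir, "group_means.csv"),
                     row.names = FALSE)
    utils::write.csv(desc$change, file.path(out_dir, "group_changes.csv"),
                     row.names = FALSE)
    regions <- NULL
    if (config$regions) {
      regions <- ternary_summaries(cohort, n_boot = config$n_boot,
                                   seed = config$stage_seeds[3L])
      regions_to_json(regions, file.path(out_dir, "ternary_regions.json"))
    }

    stage <- "model"
    frame <- build_model_frame(cohort, aggregation = config$aggregation)
    report <- run_all_models(frame)
    utils::write.csv(as.data.frame(report),
                     file.path(out_dir, "fixed_effects.csv"),
                     row.names = FALSE)
    writeLines(format_report(report), file.path(out_dir, "fixed_effects.txt"))

    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
    list(cohort = cohort, describe = desc, report = report,
         regions = regions, log = log, out_dir = out_dir)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(result)
}

#' Pretty-print the model report as a text table
#' @param report Output of [run_all_models()].
#' @return Character vector of lines.
#' @export
format_report <- function(report) {
  lines <- c("Estimated fixed effects (logratio units), Wald 95% CIs")
  for (k in unique(report$coordinate)) {
    sub <- report[report$coordinate == k, ]
    lines <- c(lines, sprintf("Coordinate %d: %s", k, sub$coordinate_name[1L]))
    for (m in unique(sub$model)) {
      lines <- c(lines, sprintf("  Model %d", m))
      rows <- sub[sub$model == m, ]
      lines <- c(lines, sprintf("    %-24s %7.3f  [%6.3f, %6.3f]  p=%s",
                                rows$term, rows$estimate, rows$ci_lower,
                                rows$ci_upper,
                                ifelse(rows$p_value < 0.001, "<0.001",
                                       sprintf("%.3f", rows$p_value))))
    }
  }
  lines
}

#' Write / read day-composition CSV
#'
#' Plain-text schema: one row per participant-wave-day with minute
#' columns `sleep`, `sed`, `lpa`, `mvpa`.
#'
#' @param cohort Day-level data.frame.
#' @param path CSV path.
#' @return `read_day_compositions` returns the data.frame with `wave`
#'   releveled to (pre, post).
#' @export
write_day_compositions <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_day_compositions
#' @export
read_day_compositions <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$wave <- factor(x$wave, levels = c("pre", "post"))
  x
}

#' Write / read epoch-stream CSV
#'
#' Epoch schema: `timestamp` (ISO 8601), `enmo` (mg), `arm_angle`
#' (degrees), `sd_x/y/z` and `range_x/y/z` (mg, 60-min window features).
#' Log schema: `date`, `bedtime`, `waketime` (ISO 8601; final row closes
#' the last day with an empty waketime).
#'
#' @param epochs,logs Data.frames as produced by [simulate_week_stream()].
#' @param path CSV path.
#' @export
write_epoch_stream <- function(epochs, path) {
  epochs$timestamp <- format(epochs$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(epochs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_epoch_stream
#' @export
read_epoch_stream <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$timestamp <- as.POSIXct(x$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  x
}

#' @rdname write_epoch_stream
#' @export
write_daily_logs <- function(logs, path) {
  logs$bedtime <- format(logs$bedtime, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  logs$waketime <- ifelse(is.na(logs$waketime), "",
                          format(logs$waketime, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  utils::write.csv(logs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_epoch_stream
#' @export
read_daily_logs <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$bedtime <- as.POSIXct(x$bedtime, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  x$waketime <- as.POSIXct(ifelse(x$waketime == "", NA, x$waketime),
                           format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  x$date <- as.Date(x$date)
  x
}
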