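# Per-balance longitudinal linear mixed models: change in each balance
# coordinate across the transition, with gender and occupation as
# moderators, random intercept and random time-slope per participant.

#' Build the long-format model frame of balance coordinates
#'
#' One row per (participant, wave[, day]) with the three balance
#' coordinates, `time` coded 0 (pre) / 1 (post), and gender/occupation
#' factors (reference levels: woman, non-manual). `day_level` keeps every
#' day; `wave_mean` collapses each participant-wave to its compositional
#' mean before transforming (identical to averaging the day coordinates,
#' a property of the geometric mean).
#'
#' @param cohort Day-level data.frame (as from [simulate_cohort()] or the
#'   processing module) with `participant`, `gender`, `occupation`,
#'   `wave`, and strictly positive minute columns `sleep`, `sed`, `lpa`,
#'   `mvpa` (apply [replace_zeros()] first if needed).
#' @param partition An [sbp()] (default [default_sbp()]).
#' @param aggregation `"day_level"` (default) or `"wave_mean"`.
#' @return Data.frame with `participant`, `gender`, `occupation`, `wave`,
#'   `time`, `z1`, `z2`, `z3`; aggregation recorded in attribute
#'   `"aggregation"`.
#' @export
build_model_frame <- function(cohort, partition = default_sbp(),
                              aggregation = c("day_level", "wave_mean")) {
  aggregation <- match.arg(aggregation)
  parts <- behavior_parts()
  if (any(cohort[, parts] <= 0))
    stop("cohort contains zero parts; apply replace_zeros() before modelling")
  both <- tapply(as.character(cohort$wave), cohort$participant,
                 function(w) all(c("pre", "post") %in% w))
  dropped <- names(both)[!both]
  if (length(dropped)) {
    message(sprintf("dropping %d participant(s) missing a wave", length(dropped)))
    cohort <- cohort[!cohort$participant %in% dropped, ]
  }
  if (aggregation == "wave_mean") {
    key <- interaction(cohort$participant, cohort$wave, drop = TRUE)
    agg <- lapply(split(seq_len(nrow(cohort)), key), function(i) {
      row <- cohort[i[1L], c("participant", "gender", "occupation", "wave")]
      cbind(row, t(compositional_mean(cohort[i, parts], kappa = 1440)))
    })
    cohort <- do.call(rbind, agg)
    rownames(cohort) <- NULL
  }
  z <- ilr_transform(as.matrix(cohort[, parts]), partition)
  frame <- data.frame(
    participant = cohort$participant,
    gender = factor(cohort$gender, levels = c("woman", "man")),
    occupation = factor(cohort$occupation, levels = c("nonmanual", "manual")),
    wave = cohort$wave,
    time = as.integer(as.character(cohort$wave) == "post"),
    z1 = z[, 1L], z2 = z[, 2L], z3 = z[, 3L]
  )
  attr(frame, "aggregation") <- aggregation
  attr(frame, "coordinate_names") <- rownames(partition)
  frame
}

model_formula <- function(coordinate, level, random, model2_terms) {
  fixed <- switch(level,
    "time + gender + occupation",
    if (model2_terms == "time_interactions")
      "time + gender + occupation + time:gender + time:occupation"
    else
      "time + gender + occupation + gender:occupation + time:gender + time:occupation",
    "time * gender * occupation"
  )
  stats::as.formula(sprintf("z%d ~ %s + %s", coordinate, fixed, random))
}

tidy_term_names <- function(x) {
  x <- gsub("genderman", "gender", x, fixed = TRUE)
  x <- gsub("occupationmanual", "occupation", x, fixed = TRUE)
  x <- sub("^\\(Intercept\\)$", "intercept", x)
  x
}

#' Fit the linear mixed model for one balance coordinate
#'
#' Model levels follow the published analysis plan: level 1 has `time`,
#' `gender` and `occupation`; level 2 adds `time:gender` and
#' `time:occupation` (a variant additionally including
#' `gender:occupation` is available via `model2_terms`); level 3 is the
#' full `time * gender * occupation` factorial. Each participant gets a
#' random intercept and, with day-level data, a random slope of time
#' (correlated by default). Estimation is REML via `lme4::lmer`;
#' confidence intervals and p-values use the Wald normal approximation.
#' If the random-slope fit fails to converge it is refit with a random
#' intercept only and flagged.
#'
#' @param frame Model frame from [build_model_frame()].
#' @param coordinate Balance coordinate to model (1, 2 or 3).
#' @param level Model level (1, 2 or 3).
#' @param random `"auto"` (slope for day-level frames, intercept-only for
#'   wave means), `"slope"`, or `"intercept"`; `"slope_uncorrelated"`
#'   drops the intercept-slope correlation.
#' @param model2_terms `"time_interactions"` (default) or
#'   `"gender_occupation"` for the variant level-2 term set.
#' @param conf_level Confidence level (default 0.95).
#' @return Data.frame of class `"fixed_effect_table"`: `term`, `estimate`
#'   (logratio units), `ci_lower`, `ci_upper`, `p_value`; attributes
#'   `n_participants`, `n_obs`, `converged`, `singular`, `coordinate`,
#'   `level`.
#' @export
fit_coordinate_model <- function(frame, coordinate = 1, level = 1,
                                 random = c("auto", "slope", "intercept",
                                            "slope_uncorrelated"),
                                 model2_terms = c("time_interactions",
                                                  "gender_occupation"),
                                 conf_level = 0.95) {
  random <- match.arg(random)
  model2_terms <- match.arg(model2_terms)
  stopifnot(coordinate %in% 1:3, level %in% 1:3)
  if (random == "auto")
    random <- if (identical(attr(frame, "aggregation"), "wave_mean"))
      "intercept" else "slope"
  rterm <- switch(random,
                  slope = "(1 + time | participant)",
                  slope_uncorrelated = "(1 | participant) + (0 + time | participant)",
                  intercept = "(1 | participant)")
  fit_one <- function(rt) {
    f <- model_formula(coordinate, level, rt, model2_terms)
    ok <- TRUE
    fit <- withCallingHandlers(
      lme4::lmer(f, data = frame, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) ok <<- FALSE
        invokeRestart("muffleWarning")
      })
    list(fit = fit, converged = ok)
  }
  res <- fit_one(rterm)
  if (!res$converged && random != "intercept") {
    res <- fit_one("(1 | participant)")
    res$converged <- FALSE
  }
  fit <- res$fit
  co <- summary(fit)$coefficients
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(
    term = tidy_term_names(rownames(co)),
    estimate = unname(est),
    ci_lower = unname(est - zc * se),
    ci_upper = unname(est + zc * se),
    std_error = unname(se),
    p_value = unname(2 * stats::pnorm(-abs(est / se))),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out,
            class = c("fixed_effect_table", "data.frame"),
            n_participants = length(unique(frame$participant)),
            n_obs = nrow(frame),
            converged = res$converged,
            singular = lme4::isSingular(fit),
            coordinate = coordinate, level = level,
            coordinate_name = attr(frame, "coordinate_names")[coordinate])
}

#' @export
print.fixed_effect_table <- function(x, ...) {
  cat(sprintf("fixed effects — coordinate %d (%s), model %d%s\n",
              attr(x, "coordinate"),
              attr(x, "coordinate_name") %||% "", attr(x, "level"),
              if (!isTRUE(attr(x, "converged"))) " [refit: intercept only]" else ""))
  df <- as.data.frame(x)
  df$estimate <- sprintf("%.3f", df$estimate)
  df$ci <- sprintf("[%.3f, %.3f]", x$ci_lower, x$ci_upper)
  df$p <- ifelse(x$p_value < 0.001, "<0.001", sprintf("%.3f", x$p_value))
  print(df[, c("term", "estimate", "ci", "p")], row.names = FALSE)
  invisible(x)
}

#' Fit the full report: three coordinates by three model levels
#'
#' Mirrors the published table layout: for each balance coordinate, the
#' level-1 rows report `time`, `gender` and `occupation`; level 2
#' contributes the `time:gender` and `time:occupation` interactions;
#' level 3 the three-way `time:gender:occupation` term.
#'
#' @inheritParams fit_coordinate_model
#' @return Data.frame with `coordinate`, `coordinate_name`, `model`,
#'   `term`, `estimate`, `ci_lower`, `ci_upper`, `p_value` (18 rows with
#'   the defaults). Individual fits are attached as attribute `"fits"`.
#' @export
run_all_models <- function(frame, random = "auto",
                           model2_terms = "time_interactions") {
  focal <- list(`1` = c("time", "gender", "occupation"),
                `2` = c("time:gender", "time:occupation"),
                `3` = c("time:gender:occupation"))
  rows <- list()
  fits <- list()
  for (k in 1:3) {
    for (lv in 1:3) {
      tab <- fit_coordinate_model(frame, coordinate = k, level = lv,
                                  random = random, model2_terms = model2_terms)
      fits[[sprintf("z%d_m%d", k, lv)]] <- tab
      keep <- tab[tab$term %in% focal[[as.character(lv)]], ]
      keep <- cbind(coordinate = k,
                    coordinate_name = attr(tab, "coordinate_name"),
                    model = lv, keep)
      rows[[length(rows) + 1L]] <- keep
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
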