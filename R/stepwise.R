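#' Default candidate predictors for the stepwise base model
#'
#' The clinical, dosimetric and seasonal predictors offered to the
#' stepwise search: age, diabetes, smoking status, BMI, surgery type,
#' BED, IMRT, the four chemotherapy flags, day length, latitude, maximum
#' solar elevation, the mean treatment time term and the treatment-time
#' spread.
#'
#' @param endpoint `"erythema"` (time enters as raw mean solar time, i.e.
#'   distance from a midnight origin) or `"atrophy"` (time enters as
#'   `time_distance` from the peak origin).
#' @return Character vector of column names.
#' @export
base_model_candidates <- function(endpoint = c("erythema", "atrophy")) {
  endpoint <- match.arg(endpoint)
  time_term <- if (endpoint == "erythema") "mean_solar_time" else
    "time_distance"
  c("age", "diabetes", "smoking", "bmi", "surgery", "bed", "imrt",
    "neoadj_anthra", "neoadj_non_anthra", "adj_anthra", "adj_non_anthra",
    "day_length_mean", "latitude", "max_elevation_mean",
    time_term, "sd_solar_time")
}

#' Bidirectional AIC stepwise selection with p-value pruning
#'
#' Starting from the full candidate model, repeatedly evaluates every
#' single-term move -- dropping a current term or adding an absent
#' candidate -- and takes the move with the lowest AIC, until no move
#' improves it. Remaining terms with a Wald p >= `p_remove` are then
#' dropped one at a time (largest p first, refitting after each drop).
#' Terms listed in `forced` are never removed.
#'
#' @param data Analysis table with an `outcome` column.
#' @param candidates Candidate term names (columns of `data`).
#' @param forced Terms that must stay in the model.
#' @param outcome Outcome column name.
#' @param p_remove Wald significance threshold for the pruning stage.
#' @param start Initial term set; defaults to all candidates.
#' @param origin Optional time origin stored on the returned fit.
#' @return A `tox_fit` for the selected model, with attribute `trace`
#'   (tibble of accepted moves and AICs).
#' @export
stepwise_select <- function(data, candidates, forced = character(),
                            outcome = "outcome", p_remove = 0.05,
                            start = candidates, origin = NULL) {
  candidates <- unique(c(candidates, forced))
  current <- unique(c(start, forced))
  fit <- fit_terms(data, current, outcome)
  trace <- list(tibble::tibble(move = "start",
                               term = NA_character_, aic = fit$aic))
  repeat {
    moves <- c(
      lapply(setdiff(current, forced), function(t)
        list(move = "drop", term = t, terms = setdiff(current, t))),
      lapply(setdiff(candidates, current), function(t)
        list(move = "add", term = t, terms = c(current, t)))
    )
    if (!length(moves)) break
    aics <- vapply(moves, function(m) {
      f <- try(fit_terms(data, m$terms, outcome), silent = TRUE)
      if (inherits(f, "try-error")) Inf else f$aic
    }, numeric(1))
    best <- which.min(aics)
    if (!length(best) || aics[best] >= fit$aic - 1e-8) break
    current <- moves[[best]]$terms
    fit <- fit_terms(data, current, outcome)
    trace <- c(trace, list(tibble::tibble(
      move = moves[[best]]$move, term = moves[[best]]$term, aic = fit$aic
    )))
  }
  # prune statistically non-significant survivors, largest p first
  repeat {
    droppable <- setdiff(current, forced)
    if (!length(droppable)) break
    ps <- vapply(droppable, function(t) wald_term_p(fit$model, t),
                 numeric(1))
    if (max(ps) < p_remove) break
    worst <- droppable[which.max(ps)]
    current <- setdiff(current, worst)
    if (!length(current)) {
      current <- character()
      fit <- fit_terms(data, "1", outcome)
      break
    }
    fit <- fit_terms(data, current, outcome)
    trace <- c(trace, list(tibble::tibble(
      move = "prune", term = worst, aic = fit$aic
    )))
  }
  fit$origin <- origin
  attr(fit, "trace") <- do.call(rbind, trace)
  fit
}

fit_terms <- function(data, terms, outcome) {
  f <- if (!length(terms)) {
    stats::reformulate("1", response = outcome)
  } else {
    stats::reformulate(terms, response = outcome)
  }
  fit_logistic(f, data)
}

#' AIC scan for the peak-toxicity time origin
#'
#' For each candidate origin t0 on a grid over the day, recodes the time
#' term as |mean solar time - t0|, refits the model template, and records
#' the AIC; the arg-min origin estimates the time of day at which toxicity
#' peaks. Interactions written against `time_distance` are rebuilt at
#' every origin. Ties are broken toward the earliest origin; origins whose
#' fit fails are recorded and excluded from the arg-min.
#'
#' @param data Analysis table with a `mean_solar_time` column.
#' @param terms Model terms, including `"time_distance"` (and optionally
#'   interactions such as `"snp:time_distance"`). The time term itself is
#'   always retained while scanning.
#' @param outcome Outcome column name.
#' @param grid_step Grid spacing in hours; must divide 24 evenly.
#' @param time_col Column holding each patient's mean solar time.
#' @return A `time_scan` object: `profile` (tibble origin/aic/ok),
#'   `best_origin`, `best_aic`.
#' @export
scan_time_origin <- function(data, terms, outcome = "outcome",
                             grid_step = 0.5,
                             time_col = "mean_solar_time") {
  if (abs(24 / grid_step - round(24 / grid_step)) > 1e-9) {
    stop("`grid_step` must divide 24 evenly", call. = FALSE)
  }
  if (!any(grepl("time_distance", terms))) {
    stop("model template must use the `time_distance` term", call. = FALSE)
  }
  origins <- seq(0, 24 - grid_step, by = grid_step)
  aics <- vapply(origins, function(t0) {
    d <- data
    d$time_distance <- abs(d[[time_col]] - t0)
    f <- try(fit_terms(d, terms, outcome), silent = TRUE)
    if (inherits(f, "try-error")) NA_real_ else f$aic
  }, numeric(1))
  if (all(is.na(aics))) {
    stop("model fit failed at every candidate origin", call. = FALSE)
  }
  best <- which(aics == min(aics, na.rm = TRUE))[1]
  structure(
    list(
      profile = tibble::tibble(origin = origins, aic = aics,
                               ok = !is.na(aics)),
      best_origin = origins[best],
      best_aic = aics[best]
    ),
    class = "time_scan"
  )
}

#' @export
print.time_scan <- function(x, ...) {
  ok <- x$profile$ok
  cat("Time-origin AIC scan over", nrow(x$profile), "origins (",
      sum(!ok), "failed )\n")
  cat("Arg-min origin:", x$best_origin, "h solar, AIC",
      format(x$best_aic, digits = 6), "\n")
  cat("AIC range:", format(range(x$profile$aic[ok]), digits = 6), "\n")
  invisible(x)
}
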