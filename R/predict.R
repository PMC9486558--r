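#' Predicted toxicity probability at a treatment time
#'
#' Inverse-logit of the fitted linear predictor with the time term recoded
#' as |time - origin|; the 95% interval comes from the delta method on the
#' linear predictor using the fit's coefficient covariance (the standard
#' GLM prediction band).
#'
#' @param fit A `tox_fit`.
#' @param profile Named list fixing every non-time model covariate (e.g.
#'   `list(bmi = 26.5, bed = 94, surgery = "wle")`).
#' @param time Treatment time(s), decimal solar hours in \[0, 24).
#' @param genotype Optional named value(s) merged into the profile, e.g.
#'   `c(rs1801260 = 2)`.
#' @param origin Time origin in hours; defaults to the origin stored on
#'   the fit.
#' @return Tibble: `time`, `prob`, `lo`, `hi`.
#' @export
predict_prob <- function(fit, profile, time, genotype = NULL,
                         origin = NULL) {
  origin <- resolve_origin(fit, origin)
  stopifnot(all(time >= 0 & time < 24))
  nd <- build_newdata(fit, profile, genotype, time, origin)
  X <- lp_design(fit, nd)
  eta <- as.numeric(X %*% stats::coef(fit$model))
  se <- sqrt(rowSums((X %*% stats::vcov(fit$model)) * X))
  tibble::tibble(
    time = time,
    prob = stats::plogis(eta),
    lo = stats::plogis(eta - 1.96 * se),
    hi = stats::plogis(eta + 1.96 * se)
  )
}

resolve_origin <- function(fit, origin) {
  if (is.null(origin)) origin <- fit$origin
  if (is.null(origin)) {
    stop("no time origin stored on the fit; pass `origin`", call. = FALSE)
  }
  stopifnot(origin >= 0, origin < 24)
  origin
}

build_newdata <- function(fit, profile, genotype, time, origin) {
  vals <- c(as.list(profile), as.list(genotype))
  vals$time_distance <- abs(time - origin)
  needed <- setdiff(all.vars(stats::formula(fit$model))[-1],
                    names(vals))
  if (length(needed)) {
    stop("profile is missing model term(s): ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(vals)
}

lp_design <- function(fit, newdata) {
  tt <- stats::delete.response(stats::terms(fit$model))
  mf <- stats::model.frame(tt, newdata, xlev = fit$model$xlevels)
  stats::model.matrix(tt, mf, contrasts.arg = fit$model$contrasts)
}

#' Genotype-conditional risk curves over the day
#'
#' Predicted probability (with 95% band) over a grid of treatment times,
#' for each requested genotype dosage or composite score. Curves are
#' symmetric about the time origin by construction; heterozygote curves
#' lie between the homozygote curves at every time.
#'
#' @inheritParams predict_prob
#' @param genotype_col Name of the dosage/score column in the model.
#' @param dosages Dosage values to draw curves for (e.g. `0:2` or
#'   `c(0, 3, 6)`).
#' @param times Time grid (hours); default half-hourly over 06:00-20:00.
#' @return Tibble: `dosage`, `time`, `prob`, `lo`, `hi`.
#' @export
risk_curve <- function(fit, profile, genotype_col, dosages,
                       times = seq(6, 20, by = 0.5), origin = NULL) {
  out <- lapply(dosages, function(g) {
    gn <- stats::setNames(list(g), genotype_col)
    p <- predict_prob(fit, profile, times, genotype = gn, origin = origin)
    p$dosage <- g
    p
  })
  res <- do.call(rbind, out)
  res[, c("dosage", "time", "prob", "lo", "hi")]
}

#' Treatment time at which genotypes carry equal risk
#'
#' With a SNP main-effect odds ratio and a SNP-by-time interaction odds
#' ratio, the genotype terms cancel at a distance of
#' -ln(OR_snp) / ln(OR_interaction) hours from the peak origin; at that
#' time every genotype has the same predicted risk (covariances aside).
#'
#' @param snp_or Per-dosage main-effect odds ratio.
#' @param interaction_or Per-dosage-per-hour interaction odds ratio
#'   (must differ from 1 unless `snp_or` is 1).
#' @param origin Peak-toxicity origin in hours.
#' @return List: `distance` (hours), `before` and `after` (the mirrored
#'   clock times), `exists` (FALSE when the terms never cancel at a
#'   non-negative distance).
#' @examples
#' equalization_time(0.616, 1.13, 15.5) # ~3.96 h before/after 15:30
#' @export
equalization_time <- function(snp_or, interaction_or, origin) {
  stopifnot(snp_or > 0, interaction_or > 0, origin >= 0, origin < 24)
  if (interaction_or == 1) {
    if (snp_or == 1) {
      return(list(distance = 0, before = origin, after = origin,
                  exists = TRUE))
    }
    return(list(distance = NA_real_, before = NA_real_, after = NA_real_,
                exists = FALSE))
  }
  d <- -log(snp_or) / log(interaction_or)
  if (d < 0) {
    return(list(distance = d, before = NA_real_, after = NA_real_,
                exists = FALSE))
  }
  list(distance = d, before = (origin - d) %% 24,
       after = (origin + d) %% 24, exists = TRUE)
}

#' Optimal treatment time for a genotype within a daytime window
#'
#' Because each genotype's risk curve is monotone in |t - origin|, the
#' minimizer over a window is one of the window endpoints or the origin
#' itself; the three candidates are evaluated and the best returned.
#' Recommendations are restricted to the window -- by default 08:00-18:00
#' solar, roughly the span of observed treatment times -- and are not
#' extrapolated to night hours.
#'
#' @inheritParams predict_prob
#' @param genotype Named dosage value(s), as in [predict_prob()].
#' @param window `c(start, end)` hours within \[0, 24), start < end.
#' @return List: `time`, `prob`, `flat` (TRUE when the curve is flat over
#'   the window, in which case the window start is returned by
#'   convention).
#' @export
optimal_time <- function(fit, profile, genotype = NULL,
                         window = c(8, 18), origin = NULL) {
  origin <- resolve_origin(fit, origin)
  stopifnot(length(window) == 2, window[1] < window[2],
            all(window >= 0 & window < 24))
  cand <- window
  if (origin > window[1] && origin < window[2]) cand <- c(cand, origin)
  p <- predict_prob(fit, profile, cand, genotype = genotype,
                    origin = origin)
  flat <- diff(range(p$prob)) < 1e-10
  if (flat) {
    return(list(time = window[1], prob = p$prob[1], flat = TRUE))
  }
  k <- which.min(p$prob)
  list(time = cand[k], prob = p$prob[k], flat = FALSE)
}

#' Risk difference between two treatment times
#'
#' predict_prob(t1) - predict_prob(t2) with a delta-method 95% interval
#' using the full covariance between the two linear predictors.
#'
#' @inheritParams optimal_time
#' @param t1,t2 Treatment times (hours).
#' @return List: `diff`, `lo`, `hi`, `p1`, `p2`.
#' @export
risk_difference <- function(fit, profile, genotype = NULL, t1, t2,
                            origin = NULL) {
  origin <- resolve_origin(fit, origin)
  nd <- build_newdata(fit, profile, genotype, c(t1, t2), origin)
  X <- lp_design(fit, nd)
  V <- stats::vcov(fit$model)
  eta <- as.numeric(X %*% stats::coef(fit$model))
  p <- stats::plogis(eta)
  grad <- p[1] * (1 - p[1]) * X[1, ] - p[2] * (1 - p[2]) * X[2, ]
  se <- sqrt(as.numeric(t(grad) %*% V %*% grad))
  d <- p[1] - p[2]
  list(diff = d, lo = d - 1.96 * se, hi = d + 1.96 * se,
       p1 = p[1], p2 = p[2])
}
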