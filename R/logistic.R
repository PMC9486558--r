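#' Fit a fixed-effects logistic toxicity model
#'
#' Maximum-likelihood logistic regression (binomial GLM, logit link) with
#' Wald inference on the odds-ratio scale, the presentation used throughout
#' the package. Fitting is by iteratively reweighted least squares with a
#' tight convergence tolerance; perfect separation and singular designs
#' are surfaced as errors naming the offending term rather than silently
#' returning degenerate estimates.
#'
#' @param formula Model formula; the response must be binary 0/1.
#' @param data Complete-case analysis table.
#' @param origin Optional time origin (hours) the `time_distance` column
#'   was built from; stored for downstream prediction.
#' @return A `tox_fit` object: list with `model` (the glm), `tidy`
#'   (tibble of term, estimate, se, or, ci_lo, ci_hi, p), `aic`, `loglik`,
#'   `n`, `origin`.
#' @export
fit_logistic <- function(formula, data, origin = NULL) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("outcome has a single class; nothing to fit", call. = FALSE)
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, family = stats::binomial(), data = data,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("singular design; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  if (sep_warn && max(abs(cf[-1])) > 10) {
    stop("perfect (or quasi-perfect) separation detected; offending term: ",
         names(cf[-1])[which.max(abs(cf[-1]))], call. = FALSE)
  }
  new_tox_fit(fit, origin = origin)
}

new_tox_fit <- function(fit, origin = NULL) {
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- cf / se
  tidy <- tibble::tibble(
    term = names(cf),
    estimate = unname(cf),
    se = unname(se),
    or = exp(unname(cf)),
    ci_lo = exp(unname(cf - 1.96 * se)),
    ci_hi = exp(unname(cf + 1.96 * se)),
    p = 2 * stats::pnorm(-abs(unname(z)))
  )
  structure(
    list(model = fit, tidy = tidy, aic = stats::AIC(fit),
         loglik = as.numeric(stats::logLik(fit)),
         n = stats::nobs(fit), origin = origin),
    class = "tox_fit"
  )
}

#' @export
print.tox_fit <- function(x, ...) {
  cat("Logistic toxicity model (n =", x$n, ", AIC =",
      format(x$aic, digits = 6), ")\n")
  if (!is.null(x$origin)) cat("Time origin:", x$origin, "h solar\n")
  t <- x$tidy
  t$or <- round(t$or, 3)
  t$ci <- sprintf("(%.3g-%.3g)", t$ci_lo, t$ci_hi)
  t$p <- signif(t$p, 2)
  print(as.data.frame(t[, c("term", "or", "ci", "p")]), row.names = FALSE)
  invisible(x)
}

# Wald chi-square p-value for all coefficients belonging to one model term
# (handles multi-level factors as a joint test).
wald_term_p <- function(fit, term) {
  mm <- stats::model.matrix(fit)
  assign <- attr(mm, "assign")
  labels <- attr(stats::terms(fit), "term.labels")
  k <- match(term, labels)
  if (is.na(k)) stop("term not in model: ", term, call. = FALSE)
  idx <- which(assign == k)
  cf <- stats::coef(fit)[idx]
  V <- stats::vcov(fit)[idx, idx, drop = FALSE]
  stat <- as.numeric(t(cf) %*% solve(V) %*% cf)
  stats::pchisq(stat, df = length(idx), lower.tail = FALSE)
}

#' Augment a base model with one SNP and its time interaction
#'
#' Adds the SNP's allele-2 dosage and a dosage-by-time-distance product to
#' the base term set and refits. No multiple-testing correction is
#' applied; candidate SNPs are assessed one at a time.
#'
#' @param base A `tox_fit`, or a character vector of base terms.
#' @param data Analysis table containing the dosage column.
#' @param snp Name of the dosage column.
#' @param time_col Name of the time-distance column the interaction is
#'   built on (must be part of the base model).
#' @param outcome Outcome column name (used when `base` is a term vector).
#' @param interaction If FALSE, add the dosage main effect only (the form
#'   used for the acute-erythema SNP model).
#' @return A `tox_fit` including `snp` and (by default) `snp:time_col`
#'   terms.
#' @export
augment_with_snp <- function(base, data, snp, time_col = "time_distance",
                             outcome = "outcome", interaction = TRUE) {
  if (inherits(base, "tox_fit")) {
    terms <- attr(stats::terms(base$model), "term.labels")
    outcome <- all.vars(stats::formula(base$model))[1]
    origin <- base$origin
  } else {
    terms <- base
    origin <- NULL
  }
  if (!time_col %in% terms) {
    stop("base model must contain the time term `", time_col, "`",
         call. = FALSE)
  }
  new_terms <- c(terms, snp,
                 if (interaction) paste0(snp, ":", time_col))
  f <- stats::reformulate(new_terms, response = outcome)
  fit_logistic(f, data, origin = origin)
}

#' Latent-scale intraclass correlation of a random-intercept logistic model
#'
#' sigma^2 / (sigma^2 + pi^2/3), the share of latent (logistic-scale)
#' variance attributable to the clustering unit.
#'
#' @param random_intercept_sd Random-intercept standard deviation, >= 0.
#' @return ICC in \[0, 1).
#' @examples
#' latent_icc(0.59) # ~0.096, i.e. 0.1 to one decimal
#' @export
latent_icc <- function(random_intercept_sd) {
  stopifnot(all(random_intercept_sd >= 0))
  s2 <- random_intercept_sd^2
  s2 / (s2 + pi^2 / 3)
}

#' Mixed-effects confirmation fit with a site random intercept
#'
#' Random-intercept logistic regression maximizing the Laplace-approximated
#' marginal likelihood (lme4), with the recruitment centre as the sole
#' random effect -- the confirmatory analysis guarding against unmodelled
#' between-centre differences.
#'
#' @param formula Fixed-effects part, as for [fit_logistic()].
#' @param data Analysis table.
#' @param group Column identifying the site (>= 2 distinct values).
#' @param nAGQ Number of adaptive Gauss-Hermite quadrature points; 1 is the
#'   Laplace approximation.
#' @return A `tox_mixed_fit`: `tidy` (fixed effects, OR scale),
#'   `ranef_sd`, `icc`, `aic`, `n`, `model`.
#' @export
fit_mixed_logistic <- function(formula, data, group = "site_name",
                               nAGQ = 1L) {
  if (length(unique(data[[group]])) < 2) {
    stop("mixed model needs at least 2 sites", call. = FALSE)
  }
  terms <- attr(stats::terms(formula), "term.labels")
  outcome <- all.vars(formula)[1]
  f <- stats::as.formula(paste(
    outcome, "~", paste(c(terms, sprintf("(1 | %s)", group)),
                        collapse = " + ")
  ))
  fit <- lme4::glmer(f, data = data, family = stats::binomial(),
                     nAGQ = nAGQ)
  msgs <- fit@optinfo$conv$lme4$messages
  code <- fit@optinfo$conv$opt
  if (!is.null(code) && code != 0) {
    stop("mixed model did not converge (optimizer code ", code, "): ",
         paste(msgs, collapse = "; "), call. = FALSE)
  }
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  tidy <- tibble::tibble(
    term = names(cf), estimate = unname(cf), se = unname(se),
    or = exp(unname(cf)),
    ci_lo = exp(unname(cf - 1.96 * se)),
    ci_hi = exp(unname(cf + 1.96 * se)),
    p = 2 * stats::pnorm(-abs(unname(cf / se)))
  )
  sd_site <- sqrt(as.numeric(lme4::VarCorr(fit)[[group]][1, 1]))
  structure(
    list(model = fit, tidy = tidy, ranef_sd = sd_site,
         icc = latent_icc(sd_site), aic = stats::AIC(fit),
         n = stats::nobs(fit)),
    class = "tox_mixed_fit"
  )
}

#' @export
print.tox_mixed_fit <- function(x, ...) {
  cat("Mixed-effects logistic model (n =", x$n, ", AIC =",
      format(x$aic, digits = 6), ")\n")
  cat("Site random intercept sd:", round(x$ranef_sd, 3),
      " latent ICC:", round(x$icc, 3), "\n")
  t <- x$tidy
  t$or <- round(t$or, 3)
  t$p <- signif(t$p, 2)
  print(as.data.frame(t[, c("term", "or", "p")]), row.names = FALSE)
  invisible(x)
}
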