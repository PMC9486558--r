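#' Repeated stratified cross-validated AUC
#'
#' Repeated k-fold cross-validation stratified by the outcome: within each
#' repeat, cases and non-cases are independently partitioned into folds,
#' the model is fit on k-1 folds and the rank-based AUC computed on the
#' held-out fold. The summary is the mean over all folds and repeats with
#' an empirical 95% interval of the fold AUCs. Fold assignment is made in
#' patient-id order when a `patient_id` column is present, so results are
#' invariant to row ordering.
#'
#' @param formula Model formula.
#' @param data Analysis table.
#' @param folds Number of folds (default 4).
#' @param repeats Number of repeats (default 100).
#' @param seed Integer seed for the fold draws.
#' @return List: `mean_auc`, `ci` (2.5/97.5 percentiles of fold AUCs),
#'   `fold_aucs` (tibble repeat/fold/auc), `folds`, `repeats`, `seed`.
#' @export
cv_auc <- function(formula, data, folds = 4, repeats = 100, seed = 1) {
  outcome <- all.vars(formula)[1]
  y <- data[[outcome]]
  if (min(table(y)) < folds) {
    stop("too few cases in the rarer class to stratify into ", folds,
         " folds", call. = FALSE)
  }
  ord <- if ("patient_id" %in% names(data)) {
    order(data[["patient_id"]])
  } else {
    seq_len(nrow(data))
  }
  data <- data[ord, , drop = FALSE]
  y <- data[[outcome]]
  res <- withr::with_seed(seed, {
    out <- vector("list", repeats)
    for (r in seq_len(repeats)) {
      repeat {
        fold_id <- stratified_folds(y, folds)
        aucs <- rep(NA_real_, folds)
        ok <- TRUE
        for (k in seq_len(folds)) {
          test <- fold_id == k
          if (length(unique(y[test])) < 2 ||
              length(unique(y[!test])) < 2) {
            ok <- FALSE
            break
          }
          fit <- stats::glm(formula, stats::binomial(),
                            data = data[!test, , drop = FALSE])
          p <- stats::predict(fit, newdata = data[test, , drop = FALSE],
                              type = "response")
          aucs[k] <- rank_auc(y[test], p)
        }
        if (ok) break
        warning("degenerate fold drawn; repeat redrawn", call. = FALSE)
      }
      out[[r]] <- tibble::tibble(rep = r, fold = seq_len(folds),
                                 auc = aucs)
    }
    do.call(rbind, out)
  })
  list(
    mean_auc = mean(res$auc),
    ci = stats::quantile(res$auc, c(0.025, 0.975), names = FALSE),
    fold_aucs = res, folds = folds, repeats = repeats, seed = seed
  )
}

stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold_id
}

# Rank-based AUC (identical to the Mann-Whitney statistic); pROC is used
# as an independent cross-check in the test suite.
rank_auc <- function(y, score) {
  r <- rank(score)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
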