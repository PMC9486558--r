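#' Simulation-based significance threshold for a per-allele test
#'
#' For a single-SNP per-allele logistic association of given effect size,
#' sample size, outcome prevalence and minor allele frequency, finds by
#' simulation the significance threshold alpha at which the Wald test
#' attains the target power. Genotypes are drawn under Hardy-Weinberg,
#' outcomes from the logistic model with intercept solved for the marginal
#' prevalence; one set of replicate p-values is simulated and alpha is
#' located by bisection on the empirical power curve (common random
#' numbers across evaluations).
#'
#' @param n Cohort size per replicate.
#' @param prevalence Marginal outcome prevalence in (0, 1).
#' @param or Per-allele odds ratio.
#' @param maf Allele frequency of the tested allele.
#' @param target_power Power to attain (default 0.80).
#' @param n_reps Simulation replicates (>= 2000 recommended).
#' @param seed Integer seed.
#' @return List: `alpha` (NA if the target power is unattainable at
#'   alpha <= 0.5), `attainable`, `power_at_alpha`, `mc_ci` (binomial 95%
#'   interval on the power at the returned alpha), `n_reps`, `seed`.
#' @export
power_alpha <- function(n, prevalence, or, maf, target_power = 0.8,
                        n_reps = 2000, seed = 1) {
  stopifnot(n > 0, prevalence > 0, prevalence < 1, or > 0,
            maf > 0, maf < 1, target_power > 0, target_power < 1)
  beta <- log(or)
  gp <- hwe_genotype_probs(maf)
  b0 <- stats::uniroot(
    function(b) sum(gp * stats::plogis(b + beta * 0:2)) - prevalence,
    c(-30, 30)
  )$root
  pvals <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      g <- sample(0:2, n, replace = TRUE, prob = gp)
      y <- stats::rbinom(n, 1, stats::plogis(b0 + beta * g))
      if (length(unique(y)) < 2 || length(unique(g)) < 2) return(NA_real_)
      fit <- stats::glm(y ~ g, family = stats::binomial())
      s <- summary(fit)$coefficients
      s["g", "Pr(>|z|)"]
    }, numeric(1))
  })
  pvals <- pvals[!is.na(pvals)]
  power_at <- function(a) mean(pvals <= a)
  if (power_at(0.5) < target_power) {
    return(list(alpha = NA_real_, attainable = FALSE,
                power_at_alpha = power_at(0.5),
                mc_ci = binom_ci(power_at(0.5), length(pvals)),
                n_reps = length(pvals), seed = seed))
  }
  lo <- 0
  hi <- 0.5
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (power_at(mid) >= target_power) hi <- mid else lo <- mid
  }
  alpha <- hi
  list(alpha = alpha, attainable = TRUE,
       power_at_alpha = power_at(alpha),
       mc_ci = binom_ci(power_at(alpha), length(pvals)),
       n_reps = length(pvals), seed = seed)
}

binom_ci <- function(p, n) {
  se <- sqrt(p * (1 - p) / n)
  c(max(0, p - 1.96 * se), min(1, p + 1.96 * se))
}
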