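#' Published odds-ratio sets from the multi-centre breast cohort analysis
#'
#' The fixed-effects logistic models reported for the REQUITE breast
#' cohort, on the log-odds scale, used as generating truths by the
#' synthetic-cohort recovery experiments. Intercepts were not published;
#' they are calibrated to the endpoint prevalence by
#' [calibrate_intercept()].
#'
#' Available sets:
#' * `erythema_base` -- acute erythema, no SNP: BMI 1.04, BED 1.02 per Gy,
#'   mean solar treatment time 1.05 per hour (midnight origin),
#'   treatment-time SD 0.64.
#' * `erythema_per3` -- erythema plus the PER3 rs2087947 T dosage (1.27).
#' * `atrophy_base` -- late atrophy, no SNP: BMI 1.06, BED 1.02,
#'   wide local excision 2.13, time-from-15:30 0.939 per hour.
#' * `atrophy_clock` -- plus CLOCK rs1801260 G dosage 0.616 and
#'   dosage-by-time interaction 1.13.
#' * `atrophy_per3` -- plus PER3 rs2087947 T dosage 0.653, interaction 1.10.
#' * `atrophy_rasd1` -- plus RASD1 rs11545787 A dosage 0.557,
#'   interaction 1.15.
#' * `atrophy_prs` -- plus the 3-SNP unweighted composite score 0.619,
#'   score-by-time interaction 1.12 (time term 0.772).
#'
#' @param model One of the set names above.
#' @return List: `endpoint`, `origin` (hours), `prevalence`, `terms`
#'   (named log odds ratios over analysis-table columns), and optionally
#'   `snp` (list `col`, `freq`, `main`, `interaction`, `composite`).
#' @export
requite_coefficients <- function(model = c("atrophy_base",
                                           "atrophy_clock",
                                           "atrophy_per3",
                                           "atrophy_rasd1",
                                           "atrophy_prs",
                                           "erythema_base",
                                           "erythema_per3")) {
  model <- match.arg(model)
  ery <- function(terms, snp = NULL) {
    list(endpoint = "erythema", origin = 0, prevalence = 0.20,
         terms = terms, snp = snp)
  }
  atr <- function(time_or, snp = NULL,
                  surgery_or = 2.13) {
    list(endpoint = "atrophy", origin = 15.5, prevalence = 0.35,
         terms = c(bmi = log(1.06), bed = log(1.02),
                   surgery_wle = log(surgery_or),
                   time_distance = log(time_or)),
         snp = snp)
  }
  switch(
    model,
    erythema_base = ery(c(bmi = log(1.04), bed = log(1.02),
                          mean_solar_time = log(1.05),
                          sd_solar_time = log(0.64))),
    erythema_per3 = ery(
      c(bmi = log(1.04), bed = log(1.02),
        mean_solar_time = log(1.05), sd_solar_time = log(0.645)),
      snp = list(col = "rs2087947", freq = 0.31, main = log(1.27),
                 interaction = 0, composite = FALSE)
    ),
    atrophy_base = atr(0.939),
    atrophy_clock = atr(0.874, surgery_or = 2.17,
                        snp = list(col = "rs1801260", freq = 0.27,
                                   main = log(0.616),
                                   interaction = log(1.13),
                                   composite = FALSE)),
    atrophy_per3 = atr(0.88, surgery_or = 2.19,
                       snp = list(col = "rs2087947", freq = 0.31,
                                  main = log(0.653),
                                  interaction = log(1.10),
                                  composite = FALSE)),
    atrophy_rasd1 = atr(0.867, surgery_or = 2.22,
                        snp = list(col = "rs11545787", freq = 0.25,
                                   main = log(0.557),
                                   interaction = log(1.15),
                                   composite = FALSE)),
    atrophy_prs = atr(0.772, surgery_or = 2.17,
                      snp = list(col = "prs3", freq = NA_real_,
                                 main = log(0.619),
                                 interaction = log(1.12),
                                 composite = TRUE))
  )
}
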