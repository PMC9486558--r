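#' Hardy-Weinberg genotype probabilities
#'
#' Expected genotype frequencies ((1-q)^2, 2q(1-q), q^2) for allele-2
#' frequency q under random mating.
#'
#' @param allele2_freq Frequency of allele 2, strictly inside (0, 1).
#'   Vectorized.
#' @return For scalar input, a named numeric triple `p0`, `p1`, `p2`
#'   (dosage of allele 2); for vector input, a matrix with one row per
#'   frequency.
#' @examples
#' hwe_genotype_probs(0.31)
#' @export
hwe_genotype_probs <- function(allele2_freq) {
  if (any(allele2_freq <= 0 | allele2_freq >= 1)) {
    stop("`allele2_freq` must be strictly inside (0, 1)", call. = FALSE)
  }
  q <- allele2_freq
  m <- cbind(p0 = (1 - q)^2, p1 = 2 * q * (1 - q), p2 = q^2)
  if (length(q) == 1) m[1, ] else m
}

#' Distribution of an unweighted composite genotype score
#'
#' Probability of each integer score 0..2k for k unlinked SNPs, obtained
#' by convolving the per-SNP Hardy-Weinberg genotype distributions. The
#' three circadian SNPs behind the published composite score sit on
#' chromosomes 1, 4 and 17, so independence holds exactly.
#'
#' @param allele2_freqs Allele-2 frequencies, one per SNP.
#' @return Named numeric vector of probabilities over scores `0..2k`,
#'   summing to 1.
#' @examples
#' d <- composite_score_distribution(c(0.27, 0.31, 0.25))
#' round(d * 10000) # 1427 patients per 10,000 at score 0, 4 at score 6
#' @export
composite_score_distribution <- function(allele2_freqs) {
  if (!length(allele2_freqs)) {
    stop("need at least one SNP", call. = FALSE)
  }
  dist <- 1
  for (q in allele2_freqs) {
    p <- hwe_genotype_probs(q)
    # polynomial convolution over integer dosages 0, 1, 2
    n <- length(dist) + 2
    nd <- numeric(n)
    for (g in 0:2) {
      nd[seq_along(dist) + g] <- nd[seq_along(dist) + g] + dist * p[g + 1]
    }
    dist <- nd
  }
  names(dist) <- 0:(length(dist) - 1)
  dist
}

#' Unweighted polygenic risk score
#'
#' Sum of allele-2 dosages across the composite SNP set (0-6 for the
#' three-SNP circadian score; fractional for imputed dosages). Any missing
#' dosage makes the score missing -- genotypes are never imputed here.
#'
#' @param dosages Numeric matrix or data frame, one column per SNP, values
#'   in \[0, 2\].
#' @return Numeric vector of scores, NA where any dosage is missing.
#' @export
unweighted_prs <- function(dosages) {
  m <- as.matrix(dosages)
  if (any(m < 0 | m > 2, na.rm = TRUE)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  score <- rowSums(m)
  score[!stats::complete.cases(m)] <- NA_real_
  unname(score)
}

#' Weighted polygenic score from precomputed per-SNP weights
#'
#' Sum of weight x dosage over the SNPs shared between the weight set and
#' the dosage matrix. A missing dosage contributes its SNP's expected
#' dosage, 2 x allele-2 frequency, times the weight (mean imputation for
#' the score only; the dosage itself stays missing).
#'
#' @param dosages Named numeric vector (or one-row matrix) of dosages.
#' @param weights Named numeric vector of per-SNP effects.
#' @param allele2_freqs Named frequencies used for the mean-imputation of
#'   missing dosage terms; required only when dosages are missing.
#' @return Scalar score.
#' @export
weighted_prs <- function(dosages, weights, allele2_freqs = NULL) {
  dosages <- unlist(dosages)
  shared <- intersect(names(weights), names(dosages))
  if (!length(shared)) {
    stop("no SNPs shared between weights and dosages", call. = FALSE)
  }
  d <- dosages[shared]
  if (anyNA(d)) {
    if (is.null(allele2_freqs)) {
      stop("missing dosages need `allele2_freqs` for mean imputation",
           call. = FALSE)
    }
    nai <- names(d)[is.na(d)]
    d[nai] <- 2 * allele2_freqs[nai]
  }
  sum(weights[shared] * d)
}

#' Candidate circadian SNPs of the analysis
#'
#' The seven candidate variants with their allele-2 frequencies in the
#' European cohort; `composite` flags the three SNPs (CLOCK rs1801260,
#' PER3 rs2087947, RASD1 rs11545787) that form the unweighted composite
#' score.
#'
#' @return Tibble: `rsid`, `gene`, `allele1`, `allele2`, `allele2_freq`,
#'   `chronotype_or` (NA where not GWAS-derived), `composite`.
#' @export
circadian_snps <- function() {
  tibble::tibble(
    rsid = c("rs2087947", "rs1801260", "rs13116075", "rs11121022",
             "rs55694368", "rs11545787", "rs3583328"),
    gene = c("PER3", "CLOCK", "NOCT", "VAMP3", "PER2", "RASD1", "HCRTR2"),
    allele1 = c("C", "A", "A", "A", "G", "G", "G"),
    allele2 = c("T", "G", "G", "C", "T", "A", "C"),
    allele2_freq = c(0.31, 0.27, 0.15, 0.42, 0.11, 0.25, 0.23),
    chronotype_or = c(NA, NA, NA, 1.07, 0.86, 1.08, 0.92),
    composite = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
}

#' Read a SNP definition table
#'
#' Delimited text with columns `rsid`, `gene`, `allele1`, `allele2`,
#' `allele2_freq` and optionally `chronotype_or`, `composite`.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Tibble as [circadian_snps()].
#' @export
read_snp_defs <- function(path, sep = "\t") {
  x <- tibble::as_tibble(utils::read.delim(path, sep = sep,
                                           stringsAsFactors = FALSE))
  need <- c("rsid", "gene", "allele1", "allele2", "allele2_freq")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("SNP table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$allele2_freq <= 0 | x$allele2_freq >= 1)) {
    stop("allele2_freq must be inside (0, 1)", call. = FALSE)
  }
  x
}

#' Read a genotype dosage matrix from delimited text
#'
#' First column `patient_id`, remaining columns one per rsid with allele-2
#' dosages in \[0, 2\] (fractional allowed for imputed genotypes). Missing
#' entries stay NA; they are never zero-filled.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Tibble with `patient_id` and one numeric column per SNP.
#' @export
read_dosage_matrix <- function(path, sep = "\t") {
  x <- tibble::as_tibble(utils::read.delim(path, sep = sep,
                                           stringsAsFactors = FALSE,
                                           check.names = FALSE))
  if (names(x)[1] != "patient_id") {
    stop("dosage matrix must start with a `patient_id` column",
         call. = FALSE)
  }
  vals <- as.matrix(x[, -1, drop = FALSE])
  if (any(vals < 0 | vals > 2, na.rm = TRUE)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  x
}

#' Read allele-2 dosages from the DS field of a VCF
#'
#' Thin wrapper over the vcfR package for imputed-dosage VCFs; available
#' when vcfR is installed.
#'
#' @param path VCF file path (plain or gzipped).
#' @return Tibble with `patient_id` and one column per variant ID.
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF dosages requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  out <- tibble::as_tibble(t(ds))
  tibble::add_column(out, patient_id = colnames(ds), .before = 1)
}
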