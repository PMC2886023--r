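#' Minor allele frequency from dosages or genotype counts
#'
#' @param genotypes Numeric vector of allele dosages (0/1/2, `NA` allowed).
#'   Alternatively pass `counts`.
#' @param counts Genotype counts `c(n_AA, n_Aa, n_aa)` instead of per-animal
#'   dosages.
#' @return List with `maf` (frequency of the less frequent allele), `n`
#'   (non-missing animals), `counts`, and `monomorphic` flag (MAF 0; no
#'   estimable association, reported `n/a` downstream).
#' @examples
#' minor_allele_frequency(c(0, 0, 1, 2))
#' minor_allele_frequency(counts = c(2, 1, 1))
#' @export
minor_allele_frequency <- function(genotypes = NULL, counts = NULL) {
  if (is.null(counts)) {
    g <- genotypes[!is.na(genotypes)]
    if (!length(g)) .stopf("all genotypes are missing")
    if (any(!g %in% c(0, 1, 2))) .stopf("dosages must be 0, 1 or 2")
    counts <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  }
  counts <- as.numeric(counts)
  if (length(counts) != 3L || any(counts < 0))
    .stopf("counts must be three non-negative integers")
  n <- as.integer(sum(counts))
  if (n < 1L) .stopf("no genotyped animals")
  p <- (2 * counts[3L] + counts[2L]) / (2 * n)
  maf <- min(p, 1 - p)
  list(maf = maf, n = n,
       counts = c(n_AA = counts[1L], n_Aa = counts[2L], n_aa = counts[3L]),
       monomorphic = maf == 0)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test of genotype frequencies given the observed allele
#' counts: all heterozygote counts compatible with the allele counts are
#' enumerated, each configuration's probability under the null
#' \deqn{P(n_{Aa} \mid n, n_A) = \frac{n!}{n_{AA}!\,n_{Aa}!\,n_{aa}!}
#'   \; 2^{n_{Aa}} \; \frac{n_A!\, n_a!}{(2n)!}}
#' is computed, and the p-value is the sum of probabilities of
#' configurations no more probable than the observed one (Fisher-style
#' two-sided exact p). Monomorphic SNPs return p = 1.
#'
#' @param counts Genotype counts `c(n_AA, n_Aa, n_aa)` (names optional).
#' @param midp If `TRUE`, subtract half the probability of the observed
#'   configuration (mid-p variant; off by default).
#' @return The exact p-value.
#' @examples
#' hwe_exact_test(c(3, 5, 2))
#' @export
hwe_exact_test <- function(counts, midp = FALSE) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts)))
    .stopf("counts must be three non-negative integers (n_AA, n_Aa, n_aa)")
  n <- sum(counts)
  if (n == 0L) .stopf("no genotyped animals")
  nA <- 2 * counts[1L] + counts[2L]
  na <- 2 * counts[3L] + counts[2L]
  if (nA == 0 || na == 0) return(1)
  het_max <- min(nA, na)
  hets <- seq(het_max %% 2, het_max, by = 2)  # parity fixed by allele counts
  log_p <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((na - hets) / 2 + 1) + hets * log(2) +
    lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  probs <- exp(log_p)
  obs <- which(hets == counts[2L])
  p_obs <- probs[obs]
  p <- sum(probs[probs <= p_obs * (1 + 1e-9)])
  if (midp) p <- p - 0.5 * p_obs
  min(1, p)
}

#' Additive allele-dosage regression of residual fleece-rot score
#'
#' Simple linear regression of the residual score on the number of copies
#' of the counted allele (genotypes coded 0, 1, 2), assuming heterozygote
#' values midway between the homozygotes. The slope is the allelic
#' substitution effect (average change in score per allele copy), its
#' p-value comes from a two-sided t-test with n - 2 degrees of freedom, and
#' the SNP's effect is also expressed as the percentage of phenotypic
#' variance explained (R^2). Animals with missing genotype are excluded
#' pairwise.
#'
#' @param residuals Named numeric vector of residual scores.
#' @param dosage Named numeric vector of allele dosages (0/1/2, `NA`
#'   allowed); names are matched to `residuals`.
#' @return One-row data frame: `n`, `maf`, `hwe_p`, `beta`, `se`,
#'   `r2_percent`, `p_value`, `monomorphic`.
#' @export
additive_regression <- function(residuals, dosage) {
  common <- intersect(names(residuals), names(dosage))
  if (length(common) == 0L)
    .stopf("no animals shared between residuals and genotypes")
  y <- residuals[common]
  x <- dosage[common]
  ok <- !is.na(x) & is.finite(y)
  y <- y[ok]; x <- x[ok]
  mafr <- minor_allele_frequency(x)
  hwe <- hwe_exact_test(mafr$counts)
  if (length(y) < 3L || mafr$monomorphic || var(x) == 0) {
    return(data.frame(n = mafr$n, maf = mafr$maf, hwe_p = hwe,
                      beta = NA_real_, se = NA_real_, r2_percent = NA_real_,
                      p_value = NA_real_, monomorphic = TRUE))
  }
  if (var(y) < .Machine$double.eps) {
    # constant response: slope and explained variance are exactly zero
    return(data.frame(n = length(y), maf = mafr$maf, hwe_p = hwe,
                      beta = 0, se = 0, r2_percent = 0, p_value = 1,
                      monomorphic = FALSE))
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  data.frame(n = length(y), maf = mafr$maf, hwe_p = hwe,
             beta = unname(coef(fit)[2L]), se = sm$coefficients[2L, 2L],
             r2_percent = 100 * sm$r.squared,
             p_value = sm$coefficients[2L, 4L], monomorphic = FALSE)
}

#' Per-SNP association across populations and traits
#'
#' Runs [additive_regression()] for every SNP in every population and
#' trait, mirroring the study layout in which the Trangie resistant line,
#' Trangie susceptible line and the Armidale flock were analysed
#' separately. Each result row carries the QC summaries (n, MAF, exact HWE
#' p) and the additive-model estimates; SNPs monomorphic in a population
#' are reported without estimates there but normally elsewhere.
#'
#' @param populations Named list; each element is a list with `residuals`
#'   (data frame `animal`, `residual_prewet`, `residual_postwet`,
#'   `residual_diff`, e.g. from [residualize_scores()]) and `genotypes`
#'   (animal x SNP dosage matrix).
#' @param traits Traits to analyse (default all three).
#' @param alpha Per-test significance level for the report flag (no
#'   multiple-testing correction, as in the tabulated study results; a
#'   Benjamini-Hochberg column is emitted alongside).
#' @return Data frame with one row per SNP x population x trait:
#'   `snp_id`, `population`, `trait`, `n`, `maf`, `hwe_p`, `beta`, `se`,
#'   `r2_percent`, `p_value`, `p_bh`, `significant`, `monomorphic`.
#' @export
run_association <- function(populations,
                            traits = c("prewet", "postwet", "diff"),
                            alpha = 0.05) {
  rows <- list()
  for (pop in names(populations)) {
    el <- populations[[pop]]
    res <- el$residuals
    geno <- el$genotypes
    shared <- intersect(res$animal, rownames(geno))
    if (!length(shared))
      .stopf("population '%s': no animals both genotyped and phenotyped", pop)
    for (tr in traits) {
      col <- paste0("residual_", tr)
      if (!col %in% names(res))
        .stopf("population '%s': residual column %s missing", pop, col)
      rvec <- setNames(res[[col]], res$animal)[shared]
      for (snp in colnames(geno)) {
        dose <- setNames(geno[shared, snp], shared)
        est <- additive_regression(rvec, dose)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(snp_id = snp, population = pop, trait = tr,
                           stringsAsFactors = FALSE), est)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  for (key in unique(paste(out$population, out$trait))) {
    i <- paste(out$population, out$trait) == key
    out$p_bh[i] <- p.adjust(out$p_value[i], "BH")
  }
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  rownames(out) <- NULL
  out
}
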