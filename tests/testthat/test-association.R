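test_that("minor allele frequency handles counts, dosages and edge cases", {
  expect_equal(minor_allele_frequency(counts = c(2, 1, 1))$maf, 3 / 8)
  mono <- minor_allele_frequency(rep(0, 10))
  expect_equal(mono$maf, 0)
  expect_true(mono$monomorphic)
  expect_equal(minor_allele_frequency(rep(1, 8))$maf, 0.5)
  expect_equal(minor_allele_frequency(c(0, 1, 2, NA, NA))$n, 3)
  expect_error(minor_allele_frequency(c(NA_real_, NA_real_)), "missing")
})

test_that("HWE exact test agrees with the enumeration oracle on all small tables", {
  # single heterozygote: only one configuration exists
  expect_equal(hwe_exact_test(c(0, 1, 0)), 1)
  expect_equal(hwe_exact_test(c(3, 5, 2)), hwe_enum_oracle(3, 5, 2),
               tolerance = 1e-12)
  # exhaustive scan over every genotype table with n <= 12
  for (n in 2:12) {
    for (nAA in 0:n) for (nAa in 0:(n - nAA)) {
      naa <- n - nAA - nAa
      expect_equal(hwe_exact_test(c(nAA, nAa, naa)),
                   hwe_enum_oracle(nAA, nAa, naa), tolerance = 1e-10)
    }
  }
  expect_error(hwe_exact_test(c(-1, 2, 3)), "non-negative")
  # monomorphic: p = 1
  expect_equal(hwe_exact_test(c(10, 0, 0)), 1)
  # mid-p variant is strictly smaller when the observed table has mass
  expect_lt(hwe_exact_test(c(3, 5, 2), midp = TRUE),
            hwe_exact_test(c(3, 5, 2)))
})

test_that("HWE exact p matches a Monte-Carlo allele permutation", {
  counts <- c(12, 18, 20)
  set.seed(77)
  n <- sum(counts)
  alleles <- rep(0:1, c(2 * counts[1] + counts[2], 2 * counts[3] + counts[2]))
  B <- 1e5
  p_obs <- hwe_enum_oracle(counts[1], counts[2], counts[3])
  stat <- replicate(B, {
    a <- sample(alleles)
    het <- sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
    het
  })
  # probability of each het count under permutation; MC estimate of the
  # exact p as the mass of tables no more probable than observed
  tab <- table(stat) / B
  probs <- as.numeric(tab)
  p_mc <- sum(probs[probs <= probs[names(tab) == as.character(counts[2])] +
                      1e-9])
  se <- sqrt(p_mc * (1 - p_mc) / B)
  expect_lt(abs(hwe_exact_test(counts) - p_mc), 3 * se + 1e-3)
})

test_that("type-I error of the HWE test is controlled at HWE-simulated SNPs", {
  set.seed(1234)
  rej <- mean(replicate(2000, {
    g <- rbinom(100, 2, 0.3)
    hwe_exact_test(c(sum(g == 0), sum(g == 1), sum(g == 2))) < 0.05
  }))
  expect_lte(rej, 0.06)
  expect_gte(rej, 0.01)
})

test_that("additive regression recovers trivial and perfect-fit cases", {
  res <- setNames(rep(1.3, 30), sprintf("a%02d", 1:30))
  dose <- setNames(rep(0:2, 10), names(res))
  flat <- additive_regression(res, dose)
  expect_equal(flat$beta, 0, tolerance = 1e-12)
  expect_equal(flat$r2_percent, 0, tolerance = 1e-8)
  perfect <- suppressWarnings(
    additive_regression(setNames(as.numeric(dose), names(dose)), dose))
  expect_equal(perfect$beta, 1, tolerance = 1e-12)
  expect_equal(perfect$r2_percent, 100, tolerance = 1e-8)
})

test_that("r2 equals squared correlation and recoding flips only the sign of beta", {
  set.seed(9)
  ids <- sprintf("a%03d", 1:200)
  dose <- setNames(rbinom(200, 2, 0.35), ids)
  res <- setNames(0.4 * dose + rnorm(200), ids)
  fit <- additive_regression(res, dose)
  expect_equal(fit$r2_percent, 100 * cor(dose, res)^2, tolerance = 1e-10)
  flipped <- additive_regression(res, setNames(2 - dose, ids))
  expect_equal(flipped$beta, -fit$beta, tolerance = 1e-10)
  expect_equal(flipped$p_value, fit$p_value, tolerance = 1e-10)
  expect_equal(flipped$r2_percent, fit$r2_percent, tolerance = 1e-10)
  # algebraic identity: r2 = 100 * beta^2 var(x) / var(y)
  expect_equal(fit$r2_percent,
               100 * fit$beta^2 * var(dose) / var(res), tolerance = 1e-6)
})

test_that("missing genotypes are excluded pairwise and monomorphic SNPs flagged", {
  ids <- sprintf("a%02d", 1:20)
  res <- setNames(rnorm(20), ids)
  dose <- setNames(c(rep(NA, 5), rbinom(15, 2, 0.4)), ids)
  fit <- additive_regression(res, dose)
  expect_identical(fit$n, 15L)
  mono <- additive_regression(res, setNames(rep(0, 20), ids))
  expect_true(mono$monomorphic)
  expect_true(is.na(mono$beta))
  expect_equal(mono$hwe_p, 1)
})

test_that("planted allelic substitution effect is recovered through the full pipeline", {
  pop <- simulate_population(population_sim_config(
    n_founders = 800, n_generations = 1, offspring_per_mating = 3, h2 = 0,
    score_mean = c(prewet = 2.5, postwet = 2.5), score_sd = 1.0,
    snp_specs = data.frame(snp_id = c("s1", "s2"), maf = c(0.5, 0.3),
                           beta = c(1.0, 0)),
    seed = 11))
  expect_gte(nrow(pop$phenotypes), 1900L)
  rel <- build_relationship(pop$pedigree)
  rr <- residualize_scores(pop$phenotypes, rel)
  res <- run_association(list(
    flock = list(residuals = rr$residuals, genotypes = pop$genotypes)))
  hit <- res[res$snp_id == "s1" & res$trait == "postwet", ]
  expect_lt(abs(hit$beta - 1.0), 3 * hit$se)
  expect_lt(hit$p_value, 1e-10)
  # r2 identity on the reported numbers
  expect_equal(hit$r2_percent,
               100 * cor(rr$residuals$residual_postwet[
                 match(rownames(pop$genotypes), rr$residuals$animal)],
                 pop$genotypes[, "s1"])^2,
               tolerance = 1e-6)
})

test_that("a SNP monomorphic in one population is n/a there and estimated elsewhere", {
  set.seed(5)
  ids1 <- sprintf("p1_%02d", 1:40)
  ids2 <- sprintf("p2_%02d", 1:40)
  make_pop <- function(ids, dose) list(
    residuals = data.frame(animal = ids,
                           residual_prewet = rnorm(length(ids)),
                           residual_postwet = rnorm(length(ids)),
                           residual_diff = rnorm(length(ids))),
    genotypes = matrix(dose, ncol = 1, dimnames = list(ids, "snpX")))
  pops <- list(line1 = make_pop(ids1, rep(0, 40)),
               line2 = make_pop(ids2, rbinom(40, 2, 0.4)))
  res <- run_association(pops)
  expect_true(all(is.na(res$beta[res$population == "line1"])))
  expect_true(all(res$monomorphic[res$population == "line1"]))
  expect_true(all(!is.na(res$beta[res$population == "line2"])))
  expect_error(run_association(list(bad = list(
    residuals = pops$line1$residuals, genotypes = pops$line2$genotypes))),
    "no animals")
})

test_that("run_association on a single population delegates to additive_regression", {
  set.seed(2)
  ids <- sprintf("a%02d", 1:50)
  resid <- data.frame(animal = ids, residual_prewet = rnorm(50),
                      residual_postwet = rnorm(50), residual_diff = rnorm(50))
  geno <- matrix(rbinom(50, 2, 0.3), ncol = 1, dimnames = list(ids, "s1"))
  res <- run_association(list(p = list(residuals = resid, genotypes = geno)),
                         traits = "prewet")
  direct <- additive_regression(setNames(resid$residual_prewet, ids),
                                setNames(geno[, 1], ids))
  expect_equal(res$beta, direct$beta)
  expect_equal(res$p_value, direct$p_value)
  expect_equal(res$hwe_p, direct$hwe_p)
})
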