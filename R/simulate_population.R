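#' Configuration for the pedigreed population simulator
#'
#' Describes a multi-generation sheep population with a heritable latent
#' fleece-rot liability, environmental fixed effects, and biallelic SNPs
#' with optional planted additive effects. The latent liability is expressed
#' directly on the 0-5 score scale (mean/SD configurable), so SNP effects
#' (`beta`) are in score units per allele copy.
#'
#' @param n_founders Founder animals (generation 0).
#' @param n_generations Generations bred beyond the founders.
#' @param offspring_per_mating Offspring per mating pair.
#' @param h2 Narrow-sense heritability of the latent liability, in `[0, 1)`.
#' @param score_mean Named numeric, latent mean for `prewet` and `postwet`.
#' @param score_sd Latent phenotypic SD (score units); polygenic variance is
#'   `h2 * score_sd^2`, trait residual variance `(1 - h2) * score_sd^2`.
#' @param site_sd SD of the per-site scoring noise added before rounding.
#' @param n_sites Number of scored fleece sites (backline positions).
#' @param n_flocks Number of flocks animals are allocated to.
#' @param fixed_effects List of named effect vectors for `flock`, `sex`,
#'   `birth_type`, `rear_type` plus a numeric `dob_slope` (score units per
#'   day of birth-date deviation).
#' @param snp_specs Data frame with columns `snp_id`, `maf` in `(0, 0.5]`,
#'   `beta` (additive effect, score units per copy of the counted allele).
#' @param seed Integer seed.
#' @return A list of class `"fr_pop_config"`.
#' @export
population_sim_config <- function(n_founders = 80L,
                                  n_generations = 2L,
                                  offspring_per_mating = 2L,
                                  h2 = 0.3,
                                  score_mean = c(prewet = 1.5, postwet = 3.0),
                                  score_sd = 1.2,
                                  site_sd = 0.25,
                                  n_sites = 4L,
                                  n_flocks = 2L,
                                  fixed_effects = list(
                                    flock = NULL, sex = c(F = 0, M = 0),
                                    birth_type = c(single = 0, twin = 0),
                                    rear_type = c(single = 0, twin = 0),
                                    dob_slope = 0),
                                  snp_specs = data.frame(
                                    snp_id = "snp1", maf = 0.3, beta = 0),
                                  seed = 1L) {
  if (!is.finite(h2) || h2 < 0 || h2 >= 1) .stopf("h2 must be in [0, 1)")
  if (nrow(snp_specs) &&
      (any(snp_specs$maf <= 0) || any(snp_specs$maf > 0.5)))
    .stopf("SNP MAFs must be in (0, 0.5]")
  if (is.null(fixed_effects$flock))
    fixed_effects$flock <- setNames(rep(0, n_flocks),
                                    sprintf("F%d", seq_len(n_flocks)))
  if (is.null(fixed_effects$dob_slope)) fixed_effects$dob_slope <- 0
  structure(list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    offspring_per_mating = as.integer(offspring_per_mating),
    h2 = h2, score_mean = score_mean, score_sd = score_sd,
    site_sd = site_sd, n_sites = as.integer(n_sites),
    n_flocks = as.integer(n_flocks),
    fixed_effects = fixed_effects, snp_specs = snp_specs,
    seed = as.integer(seed)
  ), class = "fr_pop_config")
}

#' Simulate a pedigreed population with fleece-rot scores and SNP genotypes
#'
#' Breeds `n_generations` of random matings from unrelated founders, drops
#' breeding values through the pedigree (founders `N(0, h2 * sd^2)`,
#' offspring = parent average + Mendelian-sampling deviate), draws SNP
#' genotypes at Hardy-Weinberg proportions, and builds pre- and post-wetting
#' fleece-rot scores: a latent liability per trait (fixed effects + SNP
#' dosage effects + breeding value + trait residual) is replicated over
#' `n_sites` scoring sites with site noise, rounded and clamped to 0-5, and
#' the final score is the maximum over sites.
#'
#' @param cfg A [population_sim_config()].
#' @return List with `pedigree` (`animal`, `sire`, `dam`, `sex`,
#'   `generation`), `phenotypes` (fixed-effect covariates, per-site scores,
#'   `fr_prewet`, `fr_postwet`, `fr_diff = fr_postwet - fr_prewet`),
#'   `genotypes` (animal x SNP minor-allele dosage matrix), and `truth`
#'   (breeding values, latent liabilities, SNP betas, config).
#' @examples
#' pop <- simulate_population(population_sim_config(n_founders = 20, seed = 3))
#' head(pop$phenotypes)
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "fr_pop_config"))
  set.seed(.child_seed(cfg$seed, "population"))
  s2a <- cfg$h2 * cfg$score_sd^2
  s2e <- (1 - cfg$h2) * cfg$score_sd^2

  id <- sprintf("ID%05d", seq_len(cfg$n_founders))
  ped <- data.frame(animal = id, sire = NA_character_, dam = NA_character_,
                    sex = sample(c("M", "F"), cfg$n_founders, replace = TRUE),
                    generation = 0L, stringsAsFactors = FALSE)
  u <- setNames(rnorm(cfg$n_founders, 0, sqrt(s2a)), id)
  next_id <- cfg$n_founders

  for (g in seq_len(cfg$n_generations)) {
    prev <- ped[ped$generation == g - 1L, ]
    sires <- prev$animal[prev$sex == "M"]
    dams <- prev$animal[prev$sex == "F"]
    if (!length(sires) || !length(dams))
      .stopf("generation %d has no available sires or dams", g)
    n_mat <- max(1L, length(dams))
    mate_s <- sample(sires, n_mat, replace = TRUE)
    mate_d <- sample(dams, n_mat, replace = FALSE)
    for (m in seq_len(n_mat)) {
      for (o in seq_len(cfg$offspring_per_mating)) {
        next_id <- next_id + 1L
        kid <- sprintf("ID%05d", next_id)
        ped <- rbind(ped, data.frame(
          animal = kid, sire = mate_s[m], dam = mate_d[m],
          sex = sample(c("M", "F"), 1L), generation = g,
          stringsAsFactors = FALSE))
        # Mendelian sampling variance sigma2_a / 2 (non-inbred parents)
        u[kid] <- 0.5 * (u[mate_s[m]] + u[mate_d[m]]) +
          rnorm(1L, 0, sqrt(s2a / 2))
      }
    }
  }
  n <- nrow(ped)
  animals <- ped$animal

  flock <- sample(sprintf("F%d", seq_len(cfg$n_flocks)), n, replace = TRUE)
  birth_type <- sample(c("single", "twin"), n, replace = TRUE)
  rear_type <- ifelse(birth_type == "twin" & runif(n) < 0.8, "twin", "single")
  dob <- ped$generation * 365 + sample.int(60L, n, replace = TRUE)

  fe <- cfg$fixed_effects
  xb <- fe$flock[flock] + fe$sex[ped$sex] + fe$birth_type[birth_type] +
    fe$rear_type[rear_type] + fe$dob_slope * (dob - mean(dob))

  specs <- cfg$snp_specs
  geno <- matrix(NA_integer_, n, nrow(specs),
                 dimnames = list(animals, specs$snp_id))
  gval <- numeric(n)
  for (j in seq_len(nrow(specs))) {
    geno[, j] <- rbinom(n, 2L, specs$maf[j])
    # centred contribution: configured score_mean stays the population mean
    # whatever effects are planted
    gval <- gval + (geno[, j] - 2 * specs$maf[j]) * specs$beta[j]
  }

  score_from_latent <- function(latent) {
    sites <- matrix(latent, n, cfg$n_sites) +
      matrix(rnorm(n * cfg$n_sites, 0, cfg$site_sd), n, cfg$n_sites)
    sites <- round(.clamp(sites, 0, 5))
    list(sites = sites, fr = apply(sites, 1L, max))
  }
  latent_pre <- cfg$score_mean[["prewet"]] + xb + gval + u[animals] +
    rnorm(n, 0, sqrt(s2e))
  latent_post <- cfg$score_mean[["postwet"]] + xb + gval + u[animals] +
    rnorm(n, 0, sqrt(s2e))
  pre <- score_from_latent(latent_pre)
  post <- score_from_latent(latent_post)

  phen <- data.frame(animal = animals, flock = flock, sex = ped$sex,
                     dob = dob, birth_type = birth_type,
                     rear_type = rear_type, stringsAsFactors = FALSE)
  colnames(pre$sites) <- sprintf("site_prewet_%d", seq_len(cfg$n_sites))
  colnames(post$sites) <- sprintf("site_postwet_%d", seq_len(cfg$n_sites))
  phen <- cbind(phen, pre$sites, post$sites)
  phen$fr_prewet <- pre$fr
  phen$fr_postwet <- post$fr
  phen$fr_diff <- post$fr - pre$fr

  list(pedigree = ped, phenotypes = phen, genotypes = geno,
       truth = list(breeding_values = u[animals],
                    latent_prewet = setNames(latent_pre, animals),
                    latent_postwet = setNames(latent_post, animals),
                    fixed_part = setNames(xb, animals),
                    snp_specs = specs, sigma2_a = s2a, sigma2_e = s2e),
       config = cfg)
}
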