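#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates the stages in dependency order — simulate (optional),
#' preprocess, normalize, differential expression, enrichment on the
#' expression branch; residualize and associate on the phenotype branch —
#' writing every output as TSV/YAML into the output directory together with
#' a manifest recording the seed, per-stage child seeds, input file hashes
#' and row counts. Reruns with the same configuration and seed are
#' bit-identical for deterministic stages.
#'
#' The configuration is a named list (or path to a YAML file) with
#' elements:
#' \describe{
#'   \item{out_dir}{output directory (created).}
#'   \item{seed}{global integer seed, expanded to per-stage child seeds.}
#'   \item{simulate}{optional list with `arrays` and/or `population`
#'     sub-lists of arguments for [array_sim_config()] /
#'     [population_sim_config()]; when present the simulated tables feed
#'     the downstream stages.}
#'   \item{observations, sample_sheet, pedigree, phenotypes, genotypes,
#'     annotation}{paths to input TSVs (used when not simulating).}
#'   \item{de}{list: `alpha` (default 0.01), `pooled` flag.}
#'   \item{enrichment}{list: `alpha` (default 0.01).}
#'   \item{association}{list: `alpha` (default 0.05).}
#'   \item{stages}{character vector to restrict which stages run.}
#' }
#'
#' @param config Named list or path to a YAML config file.
#' @return Invisibly, the manifest list (also written to
#'   `out_dir/manifest.yaml`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% "fleecerot_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||%
    c("simulate", "normalize", "de", "enrich", "residualize", "associate")
  manifest <- list(seed = seed, stages = list(), inputs = list(),
                   artifacts = character(0L))
  t0 <- Sys.time()
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    write_table_tsv(x, path)
    manifest$artifacts <<- c(manifest$artifacts, path)
    path
  }
  log_stage <- function(stage, ...) {
    msg <- sprintf(...)
    message(sprintf("[%s] %s", stage, msg))
    manifest$stages[[stage]] <<- msg
  }
  note_input <- function(path) {
    if (!file.exists(path)) .stopf("input file not found: %s", path)
    manifest$inputs[[path]] <<- unname(tools::md5sum(path))
    path
  }

  obs <- norm_fit <- calls <- NULL
  pop <- residuals_tbl <- geno <- NULL

  if ("simulate" %in% stages && !is.null(config$simulate)) {
    sim_cfg <- config$simulate
    if (!is.null(sim_cfg$arrays)) {
      acfg <- do.call(array_sim_config,
                      c(sim_cfg$arrays,
                        list(seed = .child_seed(seed, "arrays"))))
      sim <- simulate_intensities(acfg)
      obs <- sim$observations
      emit(obs, "observations.tsv")
      log_stage("simulate_arrays", "%d observations, %d genes",
                nrow(obs), acfg$n_genes)
    }
    if (!is.null(sim_cfg$population)) {
      pcfg <- do.call(population_sim_config,
                      c(sim_cfg$population,
                        list(seed = .child_seed(seed, "population"))))
      pop <- simulate_population(pcfg)
      emit(pop$pedigree, "pedigree.tsv")
      emit(pop$phenotypes, "phenotypes.tsv")
      emit(pop$genotypes, "genotypes.tsv")
      geno <- pop$genotypes
      log_stage("simulate_population", "%d animals, %d SNPs",
                nrow(pop$pedigree), ncol(pop$genotypes))
    }
  }

  if (is.null(obs) && !is.null(config$observations))
    obs <- read.delim(note_input(config$observations),
                      stringsAsFactors = FALSE)

  if ("normalize" %in% stages && !is.null(obs)) {
    norm_fit <- fit_mixed_model(obs)
    emit(data.frame(component = names(norm_fit$components),
                    variance = as.numeric(norm_fit$components)),
         "variance_components.tsv")
    emit(data.frame(gene_id = rownames(norm_fit$normalized),
                    norm_fit$normalized, check.names = FALSE),
         "normalized_expression.tsv")
    log_stage("normalize", "REML logL %.2f after %d evaluations",
              norm_fit$diagnostics$logL, norm_fit$diagnostics$evals)
  }

  if ("de" %in% stages && !is.null(norm_fit)) {
    de_alpha <- config$de$alpha %||% 0.01
    norm <- norm_fit$normalized
    times <- c("T0", "T1", "T2")
    have <- times[vapply(times, function(tm) {
      !inherits(try(weighted_contrast(norm, tm), silent = TRUE), "try-error")
    }, logical(1L))]
    measures <- lapply(setNames(have, have),
                       function(tm) weighted_contrast(norm, tm))
    calls <- call_significant(measures, alpha = de_alpha,
                              pooled = isTRUE(config$de$pooled))
    emit(calls, "de_calls.tsv")
    n_de <- vapply(split(calls$significant, calls$time), sum, 1L)
    if (all(n_de >= 1L)) {
      summ <- chance_call_summary(nrow(norm), de_alpha, n_de)
      yaml::write_yaml(list(
        n_tests = summ$n_tests, alpha = summ$alpha,
        expected_chance_calls = summ$expected_chance_calls,
        n_de = as.list(summ$n_de),
        fpr_percent = as.list(summ$fpr_percent),
        overlap_counts = as.list(de_overlap(calls)$counts)),
        file.path(out_dir, "de_summary.yaml"))
      manifest$artifacts <- c(manifest$artifacts,
                              file.path(out_dir, "de_summary.yaml"))
    }
    log_stage("de", "calls per time: %s",
              paste(names(n_de), n_de, sep = "=", collapse = ", "))
  }

  if ("enrich" %in% stages && !is.null(calls) &&
      !is.null(config$annotation)) {
    ann <- read_annotation(note_input(config$annotation))
    de_set <- unique(calls$gene_id[calls$significant])
    enr <- over_representation(de_set, unique(calls$gene_id), ann,
                               alpha = config$enrichment$alpha %||% 0.01)
    emit(enr, "enrichment.tsv")
    log_stage("enrich", "%d terms tested, %d significant",
              nrow(enr), sum(enr$significant))
  }

  if ("residualize" %in% stages) {
    ped <- phen <- NULL
    if (!is.null(pop)) {
      ped <- pop$pedigree; phen <- pop$phenotypes
    } else if (!is.null(config$pedigree) && !is.null(config$phenotypes)) {
      ped <- read_pedigree(note_input(config$pedigree))
      phen <- read_phenotypes(note_input(config$phenotypes))
    }
    if (!is.null(ped)) {
      rel <- build_relationship(ped)
      rr <- residualize_scores(phen, rel)
      residuals_tbl <- rr$residuals
      emit(residuals_tbl, "residual_scores.tsv")
      log_stage("residualize", "h2 estimates: %s",
                paste(sprintf("%s=%.2f", names(rr$fits),
                              vapply(rr$fits, `[[`, 1, "h2")),
                      collapse = ", "))
    }
  }

  if ("associate" %in% stages && !is.null(residuals_tbl)) {
    if (is.null(geno) && !is.null(config$genotypes))
      geno <- read_genotypes(note_input(config$genotypes))
    if (!is.null(geno)) {
      assoc <- run_association(
        list(all = list(residuals = residuals_tbl, genotypes = geno)),
        alpha = config$association$alpha %||% 0.05)
      emit(assoc, "association.tsv")
      log_stage("associate", "%d SNP x trait tests, %d significant",
                nrow(assoc), sum(assoc$significant))
    }
  }

  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$child_seeds <- list(
    arrays = .child_seed(seed, "arrays"),
    population = .child_seed(seed, "population"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
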