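#' Variance components of the normalization model
#'
#' Container for the six variance parameters of the ANOVA mixed-effect
#' normalization model on the log2-intensity scale: between-gene (`G`),
#' between-gene within-array (`AG`), within-dye (`DG`), within-flock (`FG`),
#' within-treatment (`TG`) interactions, and the within-gene residual (`e`).
#'
#' @param G,AG,DG,FG,TG,e Non-negative variances (log2 scale squared).
#' @return A named numeric vector of class `"fr_varcomp"`.
#' @examples
#' variance_components(TG = 0.5)
#' @export
variance_components <- function(G = 0.2, AG = 0.05, DG = 0.05, FG = 0.05,
                                TG = 0.2, e = 0.05) {
  vc <- c(G = G, AG = AG, DG = DG, FG = FG, TG = TG, e = e)
  if (any(!is.finite(vc)) || any(vc < 0))
    .stopf("variance components must be finite and >= 0")
  structure(vc, class = "fr_varcomp")
}

#' Default treatment labels of the hybridisation design
#'
#' Ten treatments: highly/lowly resistant (RH/RL) and highly/lowly
#' susceptible (SH/SL) sub-lines at time points T0 and T1, plus the high
#' sub-lines only at T2 (RH2, SH2) — the low sub-lines were not sampled at
#' the recovery time point.
#'
#' @return Character vector of treatment labels.
#' @export
default_treatments <- function() {
  c("RH0", "RL0", "SH0", "SL0", "RH1", "RL1", "SH1", "SL1", "RH2", "SH2")
}

#' Build a circular alternate dye-swap loop design
#'
#' Arranges RNA samples in a cycle so that each sample is hybridised exactly
#' twice, once labelled red (Cy5) and once green (Cy3): array i carries
#' sample i in the red channel and sample i+1 (cyclically) in the green
#' channel.
#'
#' @param samples Data frame with columns `sample_id`, `treatment`, `flock`.
#' @return Data frame with columns `array_id`, `red_sample`, `green_sample`.
#' @export
make_loop_design <- function(samples) {
  k <- nrow(samples)
  if (k < 2L) .stopf("a loop design needs at least 2 samples")
  data.frame(
    array_id = sprintf("A%02d", seq_len(k)),
    red_sample = samples$sample_id,
    green_sample = samples$sample_id[c(seq_len(k)[-1L], 1L)],
    stringsAsFactors = FALSE
  )
}

# each sample must appear exactly once per channel (loop property:
# in-degree = out-degree = 1 on the hybridisation graph)
.check_loop <- function(loop, sample_ids) {
  for (ch in c("red_sample", "green_sample")) {
    tab <- table(loop[[ch]])
    if (any(tab > 1L))
      .stopf("design error: sample(s) %s used more than once in the %s channel",
             paste(names(tab)[tab > 1L], collapse = ", "),
             sub("_sample", "", ch))
  }
  bad <- setdiff(unique(c(loop$red_sample, loop$green_sample)), sample_ids)
  if (length(bad))
    .stopf("design error: loop references undeclared sample(s): %s",
           paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Configuration for the two-colour array simulator
#'
#' Defines the hybridisation loop, the number of genes/blocks/flocks, the
#' generative variance components and any planted differential-expression
#' shifts. Defaults mirror the study design: the ten sub-line-by-time
#' treatments of [default_treatments()] with three biological replicates on
#' a circular alternate dye-swap loop.
#'
#' @param n_genes Number of genes spotted (one probe per gene here; probe
#'   multiplicity is exercised by the preprocessing simulator).
#' @param treatments Treatment labels (sub-line x time).
#' @param n_replicates Biological replicates per treatment; samples =
#'   treatments x replicates.
#' @param n_blocks_per_array Printing blocks per array; genes are assigned to
#'   blocks round-robin as in a printed layout.
#' @param n_flocks Number of source flocks; replicates are rotated over
#'   flocks.
#' @param samples Optional custom sample sheet (`sample_id`, `treatment`,
#'   `flock`); overrides `treatments`/`n_replicates`.
#' @param loop_design Optional custom loop (`array_id`, `red_sample`,
#'   `green_sample`); defaults to [make_loop_design()] on the samples.
#' @param mu Overall mean log2 intensity.
#' @param sigma2_C Variance of the comparison-group (array x block x dye)
#'   fixed-effect values, drawn once per level.
#' @param components A [variance_components()] object — the generative truth.
#' @param planted_de Named list: gene id -> named numeric of per-treatment
#'   additive log2 shifts.
#' @param seed Integer seed.
#' @return A list of class `"fr_array_config"`.
#' @export
array_sim_config <- function(n_genes = 100L,
                             treatments = default_treatments(),
                             n_replicates = 3L,
                             n_blocks_per_array = 4L,
                             n_flocks = 3L,
                             samples = NULL,
                             loop_design = NULL,
                             mu = 8,
                             sigma2_C = 0.25,
                             components = variance_components(),
                             planted_de = list(),
                             seed = 1L) {
  if (is.null(samples)) {
    samples <- expand.grid(rep = seq_len(n_replicates), treatment = treatments,
                           stringsAsFactors = FALSE)
    samples <- data.frame(
      sample_id = sprintf("%s_r%d", samples$treatment, samples$rep),
      treatment = samples$treatment,
      flock = sprintf("F%d", ((samples$rep - 1L) %% n_flocks) + 1L),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(loop_design)) loop_design <- make_loop_design(samples)
  .check_loop(loop_design, samples$sample_id)
  if (length(planted_de)) {
    shifts <- unlist(planted_de)
    if (any(!is.finite(shifts))) .stopf("planted_de shifts must be finite")
  }
  structure(list(
    n_genes = as.integer(n_genes), samples = samples,
    loop_design = loop_design,
    n_blocks_per_array = as.integer(n_blocks_per_array),
    mu = mu, sigma2_C = sigma2_C,
    components = components, planted_de = planted_de,
    seed = as.integer(seed)
  ), class = "fr_array_config")
}

#' Simulate loop-design two-colour intensities with known ground truth
#'
#' Draws every random effect of the normalization model from zero-mean
#' normals with the configured variance components and assembles one
#' background-corrected log2 intensity per (array, dye, gene):
#' `Y = mu + C + G + AG + DG + FG + TG (+ planted shift) + e`.
#' The comparison-group values `C` (one per array x block x dye) are drawn
#' once and treated downstream as fixed-effect levels.
#'
#' @param cfg An [array_sim_config()].
#' @return A list with `observations` (data frame: `array_id`, `block_id`,
#'   `dye`, `gene_id`, `flock_id`, `treatment_id`, `log2_intensity`),
#'   `truth` (all drawn effect values, keyed), and `config`.
#' @examples
#' sim <- simulate_intensities(array_sim_config(n_genes = 20, seed = 7))
#' head(sim$observations)
#' @export
simulate_intensities <- function(cfg) {
  stopifnot(inherits(cfg, "fr_array_config"))
  set.seed(.child_seed(cfg$seed, "intensities"))
  vc <- cfg$components
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  blocks <- ((seq_len(cfg$n_genes) - 1L) %% cfg$n_blocks_per_array) + 1L
  names(blocks) <- genes
  samples <- cfg$samples
  rownames(samples) <- samples$sample_id
  loop <- cfg$loop_design
  arrays <- loop$array_id
  treatments <- unique(samples$treatment)
  flocks <- unique(samples$flock)
  dyes <- c("red", "green")

  draw <- function(ids, s2) setNames(rnorm(length(ids), 0, sqrt(s2)), ids)
  G <- draw(genes, vc["G"])
  AG <- matrix(rnorm(length(arrays) * length(genes), 0, sqrt(vc["AG"])),
               length(arrays), length(genes), dimnames = list(arrays, genes))
  DG <- matrix(rnorm(2L * length(genes), 0, sqrt(vc["DG"])),
               2L, length(genes), dimnames = list(dyes, genes))
  FG <- matrix(rnorm(length(flocks) * length(genes), 0, sqrt(vc["FG"])),
               length(flocks), length(genes), dimnames = list(flocks, genes))
  TG <- matrix(rnorm(length(treatments) * length(genes), 0, sqrt(vc["TG"])),
               length(treatments), length(genes),
               dimnames = list(treatments, genes))

  shift <- matrix(0, length(treatments), length(genes),
                  dimnames = dimnames(TG))
  for (g in names(cfg$planted_de)) {
    if (!g %in% genes)
      .stopf("planted_de references unknown gene '%s'", g)
    s <- cfg$planted_de[[g]]
    bad <- setdiff(names(s), treatments)
    if (length(bad))
      .stopf("planted_de for gene '%s' references unknown treatment(s) %s",
             g, paste(bad, collapse = ", "))
    shift[names(s), g] <- s
  }

  # one reading per (array, dye, gene); dye channel determines the sample
  grid <- expand.grid(gene_id = genes, dye = dyes, array_id = arrays,
                      stringsAsFactors = FALSE)
  sample_of <- ifelse(grid$dye == "red",
                      loop$red_sample[match(grid$array_id, loop$array_id)],
                      loop$green_sample[match(grid$array_id, loop$array_id)])
  grid$treatment_id <- samples[sample_of, "treatment"]
  grid$flock_id <- samples[sample_of, "flock"]
  grid$block_id <- blocks[grid$gene_id]

  clev <- unique(paste(grid$array_id, grid$block_id, grid$dye, sep = ":"))
  Ceff <- setNames(rnorm(length(clev), 0, sqrt(cfg$sigma2_C)), clev)
  ckey <- paste(grid$array_id, grid$block_id, grid$dye, sep = ":")

  y <- cfg$mu + Ceff[ckey] + G[grid$gene_id] +
    AG[cbind(grid$array_id, grid$gene_id)] +
    DG[cbind(grid$dye, grid$gene_id)] +
    FG[cbind(grid$flock_id, grid$gene_id)] +
    TG[cbind(grid$treatment_id, grid$gene_id)] +
    shift[cbind(grid$treatment_id, grid$gene_id)] +
    rnorm(nrow(grid), 0, sqrt(vc["e"]))

  obs <- data.frame(
    array_id = grid$array_id, block_id = grid$block_id, dye = grid$dye,
    gene_id = grid$gene_id, flock_id = grid$flock_id,
    treatment_id = grid$treatment_id,
    log2_intensity = as.numeric(y), stringsAsFactors = FALSE
  )
  list(observations = obs,
       truth = list(mu = cfg$mu, C = Ceff, G = G, AG = AG, DG = DG, FG = FG,
                    TG = TG, planted = shift, components = vc),
       config = cfg)
}
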