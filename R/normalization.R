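#' Specification of the ANOVA normalization model
#'
#' The normalization model for background-corrected log2 intensities is
#' `Y = mu + C + G + AG + DG + FG + TG + e`, where `C` is the fixed
#' comparison-group effect (readings from the same array slide, printing
#' block and dye channel), `G` the random gene effect, and `AG`, `DG`,
#' `FG`, `TG` the random interactions of gene with array, dye, flock and
#' treatment. Treatment is breed line by time point; by default the ten
#' sub-line labels of [default_treatments()] are used as-is, while
#' `treatment_coding = "line_time"` collapses sub-lines to six
#' line-by-time levels (R0, S0, R1, S1, R2, S2).
#'
#' @param randoms Random interaction terms to fit (default all of
#'   `"G"`, `"AG"`, `"DG"`, `"FG"`, `"TG"`).
#' @param treatment_coding `"subline"` (use `treatment_id` as given) or
#'   `"line_time"` (collapse to line x time).
#' @return A list of class `"fr_model_spec"`.
#' @export
model_spec <- function(randoms = c("G", "AG", "DG", "FG", "TG"),
                       treatment_coding = c("subline", "line_time")) {
  randoms <- match.arg(randoms, c("G", "AG", "DG", "FG", "TG"),
                       several.ok = TRUE)
  structure(list(randoms = randoms,
                 treatment_coding = match.arg(treatment_coding)),
            class = "fr_model_spec")
}

#' Collapse sub-line treatment labels to line-by-time labels
#'
#' Maps e.g. `RH0`/`RL0` to `R0`: first character is the breed line
#' (R = resistant, S = susceptible), last character the time point.
#'
#' @param treatment_id Character vector of sub-line labels.
#' @return Character vector of line-by-time labels.
#' @export
recode_line_time <- function(treatment_id) {
  paste0(substr(treatment_id, 1L, 1L),
         substr(treatment_id, nchar(treatment_id), nchar(treatment_id)))
}

# build fixed and random design matrices for the normalization model
.norm_design <- function(obs, spec) {
  trt <- obs$treatment_id
  if (spec$treatment_coding == "line_time") trt <- recode_line_time(trt)
  Cfac <- droplevels(interaction(obs$array_id, obs$block_id, obs$dye,
                                 sep = ":", drop = TRUE))
  Zc <- .fac_sparse(Cfac)
  # intercept + all-but-first comparison-group indicators: full rank
  X <- cbind(Matrix::Matrix(1, nrow(obs), 1, sparse = TRUE,
                            dimnames = list(NULL, "(mu)")),
             Zc[, -1L, drop = FALSE])
  gene <- factor(obs$gene_id)
  fac_of <- list(
    G = gene,
    AG = interaction(obs$array_id, obs$gene_id, sep = ":", drop = TRUE),
    DG = interaction(obs$dye, obs$gene_id, sep = ":", drop = TRUE),
    FG = interaction(obs$flock_id, obs$gene_id, sep = ":", drop = TRUE),
    TG = interaction(trt, obs$gene_id, sep = ":", drop = TRUE)
  )
  Zlist <- lapply(fac_of[spec$randoms], .fac_sparse)
  list(X = X, Zlist = Zlist, gene_levels = levels(gene),
       treatment_levels = unique(trt))
}

#' Fit the REML normalization model and extract normalized expression
#'
#' Estimates the six variance components of the normalization model by
#' restricted maximum likelihood and solves Henderson's mixed-model
#' equations at the estimates. The REML criterion is evaluated exactly via
#' sparse Cholesky factorizations of the mixed-model equations, with the
#' residual variance profiled out, and maximised over log variance ratios
#' by quasi-Newton iteration; the best-so-far restricted log-likelihood
#' trace is monotone by construction. The BLUP solutions of the
#' treatment-by-gene (`TG`) effect are returned as the normalized mean
#' expression of each gene in each condition.
#'
#' @param obs Observation data frame (see [to_observations()] /
#'   [simulate_intensities()]).
#' @param spec A [model_spec()].
#' @param maxit Maximum quasi-Newton iterations.
#' @param floor_frac Variance-component floor as a fraction of total
#'   variance (components cannot go negative; near-zero components are
#'   reported at the floor).
#' @param start_lambda Optional named starting variance ratios.
#' @return Object of class `"fr_mixed_fit"`: `components` (a
#'   [variance_components()]), `normalized` (gene x treatment matrix of TG
#'   BLUPs), `solutions` (fixed effects and all random-effect BLUPs),
#'   and `diagnostics` (`logL`, `evals`, `converged`, `grad_norm`,
#'   `logl_trace`).
#' @examples
#' sim <- simulate_intensities(array_sim_config(
#'   n_genes = 15, treatments = c("RH0", "SH0"), n_replicates = 2, seed = 1))
#' fit <- fit_mixed_model(sim$observations)
#' fit$components
#' @export
fit_mixed_model <- function(obs, spec = model_spec(), maxit = 200L,
                            floor_frac = 1e-8, start_lambda = NULL) {
  stopifnot(inherits(spec, "fr_model_spec"))
  des <- .norm_design(obs, spec)
  for (k in names(des$Zlist))
    if (ncol(des$Zlist[[k]]) < 2L)
      .stopf("random factor %s has fewer than 2 levels", k)
  y <- obs$log2_intensity
  if (any(!is.finite(y))) .stopf("log2 intensities must be finite")
  setup <- .mme_setup(des$X, des$Zlist, y)
  vtot <- var(y)

  # degenerate data: no residual variation at all
  if (!is.finite(vtot) || vtot < 1e-14) {
    K <- length(des$Zlist)
    tiny <- floor_frac * max(vtot, 1e-14)
    sol <- solve_mme(des$X, des$Zlist, y, rep(1e8, K))
    return(structure(list(
      components = .make_varcomp(setNames(rep(tiny, K), names(des$Zlist)),
                                 tiny),
      lambdas = setNames(rep(1e8, K), names(des$Zlist)),
      normalized = .tg_matrix(sol$random$TG, des),
      solutions = c(list(fixed = sol$fixed), sol$random),
      diagnostics = list(logL = NA_real_, evals = 0L, converged = TRUE,
                         grad_norm = 0, logl_trace = numeric(0L),
                         note = "degenerate input: zero total variance"),
      spec = spec, n = setup$n, p = setup$p), class = "fr_mixed_fit"))
  }

  K <- length(des$Zlist)
  start <- if (is.null(start_lambda)) rep(log(5), K) else log(start_lambda)
  opt <- .reml_optimize(setup, start, maxit = maxit)
  if (!opt$converged)
    .warnf("REML did not converge within %d iterations (%s); returning last iterate",
           maxit, opt$message)
  final <- .reml_crit(opt$par, setup)
  sigma2e <- final$sigma2e
  comps <- sigma2e / final$lambdas
  floor_val <- floor_frac * (sigma2e + sum(comps))
  comps <- pmax(comps, floor_val)
  names(comps) <- names(des$Zlist)

  sol <- solve_mme(des$X, des$Zlist, y, final$lambdas)
  comp_obj <- .make_varcomp(comps, max(sigma2e, floor_val))
  structure(list(
    components = comp_obj,
    lambdas = setNames(final$lambdas, names(des$Zlist)),
    normalized = .tg_matrix(sol$random$TG, des),
    solutions = c(list(fixed = sol$fixed), sol$random),
    residuals = sol$residuals,
    diagnostics = list(logL = -0.5 * opt$value, evals = opt$evals,
                       converged = opt$converged, grad_norm = opt$grad_norm,
                       logl_trace = opt$logl_trace),
    spec = spec, n = setup$n, p = setup$p), class = "fr_mixed_fit")
}

# assemble a variance_components() object, zero-filling random terms that
# were not in the fitted spec
.make_varcomp <- function(comps, e) {
  full <- c(G = 0, AG = 0, DG = 0, FG = 0, TG = 0)
  full[names(comps)] <- comps
  variance_components(G = full[["G"]], AG = full[["AG"]], DG = full[["DG"]],
                      FG = full[["FG"]], TG = full[["TG"]], e = e)
}

# reshape the TG BLUP vector (levels "treatment:gene") into a gene x
# treatment matrix
.tg_matrix <- function(tg, des) {
  if (is.null(tg)) return(NULL)
  parts <- strsplit(names(tg), ":", fixed = TRUE)
  trt <- vapply(parts, `[`, "", 1L)
  gene <- vapply(parts, `[`, "", 2L)
  out <- matrix(NA_real_, length(des$gene_levels), length(des$treatment_levels),
                dimnames = list(des$gene_levels, des$treatment_levels))
  out[cbind(gene, trt)] <- tg
  out
}

#' @exportS3Method base::print
print.fr_mixed_fit <- function(x, ...) {
  cat("REML normalization fit:", x$n, "observations,",
      nrow(x$normalized), "genes,", ncol(x$normalized), "treatments\n")
  cat("variance components:\n")
  print(round(unclass(x$components), 6))
  cat(sprintf("restricted logL %.3f after %d evaluations (converged: %s)\n",
              x$diagnostics$logL, x$diagnostics$evals,
              x$diagnostics$converged))
  invisible(x)
}
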