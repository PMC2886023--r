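#' Aggregate per-site fleece-rot scores
#'
#' Fleece rot is scored 0-5 at up to four backline sites (neck, wither,
#' loin, rump); an animal's final score is the highest score at any one
#' site, a measure of overall susceptibility.
#'
#' @param site_scores Numeric vector (1-4 sites) or matrix (animals x
#'   sites) of scores in `{0,...,5}`.
#' @return The maximum score (per animal for a matrix).
#' @examples
#' aggregate_scores(c(0, 2, 1, 3))
#' @export
aggregate_scores <- function(site_scores) {
  v <- as.numeric(site_scores)
  if (any(!is.finite(v)) || any(v < 0 | v > 5))
    .stopf("site scores must lie in 0..5")
  if (is.matrix(site_scores)) return(apply(site_scores, 1L, max))
  max(v)
}

#' Residual fleece-rot score
#'
#' The residual score is the observed score minus the model correction for
#' environmental fixed effects and the polygenic component; e.g. an
#' observed score of 1 with a correction of 3 gives a residual of -2, so
#' residuals need not fall in the original 0-5 range.
#'
#' @param observed Observed fleece-rot score(s).
#' @param correction Model correction(s) (fitted fixed + polygenic part).
#' @return `observed - correction`.
#' @examples
#' residual_score(1, 3)
#' @export
residual_score <- function(observed, correction) {
  if (any(!is.finite(observed)) || any(!is.finite(correction)))
    .stopf("observed and correction must be finite")
  observed - correction
}

# fixed-effect design for the animal model: flock, sex, birth type and rear
# type as factors (levels with <2 observed categories dropped), DOB as a
# centred covariate
.animal_fixed_design <- function(phen) {
  terms <- list()
  assign <- character(0L)
  X <- matrix(1, nrow(phen), 1L, dimnames = list(NULL, "(intercept)"))
  assign <- "(intercept)"
  for (fct in c("flock", "sex", "birth_type", "rear_type")) {
    if (!fct %in% names(phen)) next
    f <- factor(phen[[fct]])
    if (nlevels(f) < 2L) next
    M <- model.matrix(~f)[, -1L, drop = FALSE]
    colnames(M) <- paste0(fct, levels(f)[-1L])
    X <- cbind(X, M)
    assign <- c(assign, rep(fct, ncol(M)))
  }
  if ("dob" %in% names(phen)) {
    X <- cbind(X, dob = phen$dob - mean(phen$dob))
    assign <- c(assign, "dob")
  }
  list(X = X, assign = assign)
}

#' Fit the pedigree animal model to a fleece-rot trait
#'
#' Mixed model `y = X b + Z u + e` with fixed effects of flock, sex, birth
#' type, rear type and a date-of-birth covariate, and a random animal
#' (polygenic) effect with covariance `sigma2_a * A`, `A` the numerator
#' relationship matrix. The variance ratio `lambda = sigma2_e / sigma2_a`
#' is estimated by REML (exact restricted likelihood through the sparse
#' mixed-model equations with `A^-1`, profiled residual variance, 1-D
#' search over log lambda); solutions then come from Henderson's equations.
#' The per-animal residual `e = y - X b - Z u` is the residual fleece-rot
#' score used for SNP association. Ordinal scores are treated as numeric,
#' consistent with interpreting an allele substitution effect in score
#' units.
#'
#' If REML fails, the model is refit at a fixed fallback heritability
#' (default 0.3) with a warning.
#'
#' @param phenotypes Data frame with `animal`, the fixed-effect columns
#'   present, and the trait columns `fr_prewet`, `fr_postwet`, `fr_diff`.
#' @param relationship A [build_relationship()] object covering all
#'   phenotyped animals.
#' @param trait One of `"prewet"`, `"postwet"`, `"diff"`.
#' @param fallback_h2 Heritability used if REML fails.
#' @param wald_alpha Level for the Wald screen of fixed effects.
#' @param drop_nonsignificant If `TRUE`, refit after dropping fixed factors
#'   whose Wald test exceeds `wald_alpha` (DOB and intercept always kept).
#' @return Object of class `"fr_animal_fit"`: `h2`, `sigma2_a`, `sigma2_e`,
#'   `lambda`, `fixed` (solutions), `wald` (per-factor tests), `u`
#'   (breeding values), `residuals` (named by animal), `fitted`, `logL`,
#'   `converged`, `trait`.
#' @export
fit_animal_model <- function(phenotypes, relationship,
                             trait = c("prewet", "postwet", "diff"),
                             fallback_h2 = 0.3, wald_alpha = 0.05,
                             drop_nonsignificant = FALSE) {
  trait <- match.arg(trait)
  stopifnot(inherits(relationship, "fr_pedigree"))
  ycol <- paste0("fr_", trait)
  if (!ycol %in% names(phenotypes)) .stopf("phenotypes lack column %s", ycol)
  phen <- phenotypes[is.finite(phenotypes[[ycol]]), , drop = FALSE]
  missing_ped <- setdiff(phen$animal, relationship$animals)
  if (length(missing_ped))
    .stopf("animal(s) missing from the pedigree: %s",
           paste(head(missing_ped, 5L), collapse = ", "))
  y <- phen[[ycol]]
  des <- .animal_fixed_design(phen)
  if (nrow(phen) <= ncol(des$X))
    .stopf("fewer observations than fixed-effect parameters")

  Z <- .fac_sparse(factor(phen$animal, levels = relationship$animals))
  Ainv <- relationship$A_inverse
  ldA <- -as.numeric(Matrix::determinant(Ainv, logarithm = TRUE)$modulus)

  fit_at <- function(X, lam) {
    solve_mme(X, list(animal = Z), y, lam, list(Ainv))
  }
  X <- methods::as(Matrix::Matrix(des$X, sparse = TRUE), "generalMatrix")
  setup <- .mme_setup(X, list(animal = Z), y)

  est <- tryCatch({
    opt <- optimize(function(ll) .reml_crit(ll, setup, list(Ainv), ldA)$crit,
                    interval = c(-12, 12), tol = 1e-9)
    if (!is.finite(opt$objective)) stop("non-finite REML criterion")
    r <- .reml_crit(opt$minimum, setup, list(Ainv), ldA)
    list(lambda = exp(opt$minimum), sigma2e = r$sigma2e,
         logL = -0.5 * r$crit, converged = TRUE)
  }, error = function(e) {
    .warnf("animal-model REML failed (%s); falling back to h2 = %.2f",
           conditionMessage(e), fallback_h2)
    list(lambda = (1 - fallback_h2) / fallback_h2, sigma2e = NA_real_,
         logL = NA_real_, converged = FALSE)
  })
  lambda <- est$lambda
  sol <- fit_at(des$X, lambda)
  if (!est$converged || is.na(est$sigma2e)) {
    est$sigma2e <- sum(sol$residuals^2) / (length(y) - ncol(des$X))
  }
  sigma2_a <- est$sigma2e / lambda
  h2 <- sigma2_a / (sigma2_a + est$sigma2e)

  wald <- .wald_tests(des, sol, setup, lambda, list(Ainv), est$sigma2e)
  if (drop_nonsignificant) {
    drop <- wald$factor[wald$p_value > wald_alpha &
                        !wald$factor %in% c("(intercept)", "dob")]
    if (length(drop)) {
      keep <- !des$assign %in% drop
      des$X <- des$X[, keep, drop = FALSE]
      des$assign <- des$assign[keep]
      X <- methods::as(Matrix::Matrix(des$X, sparse = TRUE), "generalMatrix")
      setup <- .mme_setup(X, list(animal = Z), y)
      sol <- fit_at(des$X, lambda)
    }
  }

  u <- sol$random$animal
  structure(list(
    trait = trait, h2 = h2, sigma2_a = sigma2_a, sigma2_e = est$sigma2e,
    lambda = lambda, fixed = sol$fixed, wald = wald,
    u = u,
    residuals = setNames(sol$residuals, phen$animal),
    fitted = setNames(sol$fitted, phen$animal),
    logL = est$logL, converged = est$converged,
    n = length(y)), class = "fr_animal_fit")
}

# Wald chi-square screen per fixed factor, using the fixed-effect block of
# the inverse coefficient matrix scaled by sigma2_e
.wald_tests <- function(des, sol, setup, lambda, Kinv_list, sigma2e) {
  C <- .mme_coefmat(setup, lambda, Kinv_list)
  p <- ncol(des$X)
  Cinv_fixed <- as.matrix(Matrix::solve(C, Matrix::Diagonal(n = nrow(C))[, seq_len(p)]))[seq_len(p), , drop = FALSE]
  vb <- sigma2e * Cinv_fixed
  factors <- setdiff(unique(des$assign), "(intercept)")
  rows <- lapply(factors, function(fct) {
    j <- which(des$assign == fct)
    b <- sol$fixed[j]
    W <- tryCatch(as.numeric(b %*% solve(vb[j, j, drop = FALSE], b)),
                  error = function(e) NA_real_)
    data.frame(factor = fct, df = length(j), chisq = W,
               p_value = pchisq(W, length(j), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Residual fleece-rot scores for all traits
#'
#' Convenience wrapper fitting the animal model to the pre-wetting,
#' post-wetting and difference traits and returning the residual scores in
#' one table. The difference trait is post-wetting minus pre-wetting (the
#' change induced by the wetting challenge); set `diff_sign = -1` for the
#' opposite convention.
#'
#' @param phenotypes,relationship As in [fit_animal_model()].
#' @param diff_sign `+1` (post - pre, default) or `-1`.
#' @param ... Passed to [fit_animal_model()].
#' @return List with `residuals` (data frame `animal`,
#'   `residual_prewet`, `residual_postwet`, `residual_diff`) and `fits`
#'   (the three `fr_animal_fit` objects).
#' @export
residualize_scores <- function(phenotypes, relationship, diff_sign = 1,
                               ...) {
  fits <- lapply(c("prewet", "postwet", "diff"), function(tr)
    fit_animal_model(phenotypes, relationship, tr, ...))
  names(fits) <- c("prewet", "postwet", "diff")
  res <- data.frame(animal = phenotypes$animal, stringsAsFactors = FALSE)
  for (tr in names(fits)) {
    r <- fits[[tr]]$residuals[res$animal]
    if (tr == "diff") r <- diff_sign * r
    res[[paste0("residual_", tr)]] <- as.numeric(r)
  }
  list(residuals = res, fits = fits)
}

#' @exportS3Method base::print
print.fr_animal_fit <- function(x, ...) {
  cat(sprintf("animal model (%s): n = %d, h2 = %.3f (sigma2_a = %.4f, sigma2_e = %.4f)\n",
              x$trait, x$n, x$h2, x$sigma2_a, x$sigma2_e))
  invisible(x)
}
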