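# shared small simulated instance (cheap to fit, < 200 observations so the
# dense oracles stay tractable)
tiny_sim <- function(seed = 5, n_genes = 6) {
  simulate_intensities(array_sim_config(
    n_genes = n_genes, treatments = c("RH0", "SH0", "RH1", "SH1"),
    n_replicates = 1, n_blocks_per_array = 2, n_flocks = 2, seed = seed,
    components = variance_components(G = 0.3, AG = 0.1, DG = 0.05,
                                     FG = 0.08, TG = 0.2, e = 0.1)))
}

test_that("sparse REML criterion equals the dense restricted likelihood", {
  obs <- tiny_sim()$observations
  des <- dense_norm_design(obs)
  pkg_des <- fleecerot:::.norm_design(obs, model_spec())
  setup <- fleecerot:::.mme_setup(pkg_des$X, pkg_des$Zlist, obs$log2_intensity)
  for (comps in list(
    c(G = .3, AG = .1, DG = .05, FG = .08, TG = .2, e = .1),
    c(G = .5, AG = .02, DG = .15, FG = .3, TG = .08, e = .25))) {
    lam <- comps["e"] / comps[c("G", "AG", "DG", "FG", "TG")]
    r <- fleecerot:::.reml_crit(log(lam), setup)
    df <- setup$n - setup$p
    sparse_crit <- df * log(comps["e"]) + r$logdet -
      sum(setup$q * log(lam)) + r$sigma2e * df / comps["e"]
    expect_equal(unname(sparse_crit), dense_reml_crit(des, comps),
                 tolerance = 1e-8)
  }
})

test_that("converged REML matches a Nelder-Mead search of the dense criterion", {
  sim <- tiny_sim(seed = 8)
  obs <- sim$observations
  fit <- fit_mixed_model(obs)
  des <- dense_norm_design(obs)
  # independent maximisation of the dense criterion over log variances
  oracle <- optim(log(c(G = .3, AG = .1, DG = .05, FG = .08, TG = .2, e = .1)),
                  function(lv) dense_reml_crit(des, exp(lv)),
                  method = "Nelder-Mead",
                  control = list(maxit = 4000, reltol = 1e-12))
  pkg_crit <- dense_reml_crit(des, unclass(fit$components))
  # package optimum must be at least as good (within numerical slack)
  expect_lte(pkg_crit, oracle$value + 1e-3)
})

test_that("MME solutions equal dense GLS on instances under 200 observations", {
  sim <- tiny_sim(seed = 3)
  obs <- sim$observations
  expect_lte(nrow(obs), 200L)
  comps <- c(G = .3, AG = .1, DG = .05, FG = .08, TG = .2, e = .1)
  pkg_des <- fleecerot:::.norm_design(obs, model_spec())
  lam <- comps["e"] / comps[c("G", "AG", "DG", "FG", "TG")]
  sol <- solve_mme(pkg_des$X, pkg_des$Zlist, obs$log2_intensity, lam)
  des <- dense_norm_design(obs)
  # align the dense X (treatment contrasts on C) with the package's
  gls <- dense_gls(des$X, des$Zs, obs$log2_intensity, as.list(comps))
  expect_equal(unname(sol$fixed), unname(gls$b), tolerance = 1e-6)
  for (k in names(pkg_des$Zlist)) {
    o <- gls$u[[k]]
    names(o) <- colnames(des$Zs[[k]])
    # dense model.matrix levels are "interaction(...)"-style; match by BLUP sort
    expect_equal(sort(unname(sol$random[[k]])), sort(unname(o)),
                 tolerance = 1e-6)
  }
  expect_lt(sol$rel_residual, 1e-8)
})

test_that("limiting variance ratios behave as expected in the solver", {
  set.seed(2)
  g <- gl(4, 10)
  y <- rnorm(40) + rep(c(1, -1, 2, 0), each = 10)
  X <- matrix(1, 40, 1)
  Z <- list(grp = fac_indicator(g))
  # lambda -> 0: BLUPs approach per-level means minus the fixed part
  lo <- solve_mme(X, Z, y, 1e-10)
  raw <- tapply(y, g, mean) - lo$fixed[1]
  expect_equal(unname(lo$random$grp), unname(as.numeric(raw)), tolerance = 1e-5)
  # lambda -> Inf: full shrinkage to zero
  hi <- solve_mme(X, Z, y, 1e10)
  expect_lt(max(abs(hi$random$grp)), 1e-6)
  expect_error(solve_mme(X, Z, y, -1), "positive")
})

test_that("raising the residual variance shrinks the TG solutions toward zero", {
  # scaling sigma2_e up with components fixed multiplies every variance
  # ratio: the penalized norm of the random effects (the provable
  # regularization-path quantity) and the TG norm both decrease, and in the
  # limit every solution vanishes
  obs <- tiny_sim(seed = 13)$observations
  pkg_des <- fleecerot:::.norm_design(obs, model_spec())
  base_lam <- c(G = 1, AG = 2, DG = 2, FG = 2, TG = 0.5)
  norms <- vapply(c(1, 2, 5, 10, 50), function(f) {
    sol <- solve_mme(pkg_des$X, pkg_des$Zlist, obs$log2_intensity,
                     base_lam * f)
    pen <- sum(vapply(names(base_lam), function(k)
      base_lam[[k]] * sum(sol$random[[k]]^2), numeric(1)))
    c(tg = sqrt(sum(sol$random$TG^2)), pen = pen,
      maxtg = max(abs(sol$random$TG)))
  }, numeric(3))
  expect_true(all(diff(norms["pen", ]) < 0))
  expect_true(all(diff(norms["tg", ]) < 0))
  expect_lt(norms["maxtg", 5], 0.15 * norms["maxtg", 1])
})

test_that("relabelling genes permutes the solutions identically", {
  sim <- tiny_sim(seed = 21)
  obs <- sim$observations
  fit1 <- fit_mixed_model(obs)
  perm <- obs
  relabel <- setNames(sprintf("z%04d", seq_len(6)), sprintf("g%04d", seq_len(6)))
  perm$gene_id <- unname(relabel[perm$gene_id])
  fit2 <- fit_mixed_model(perm)
  expect_equal(unclass(fit1$components), unclass(fit2$components),
               tolerance = 1e-5)
  expect_equal(unname(fit1$normalized[names(relabel), ]),
               unname(fit2$normalized[unname(relabel), ]), tolerance = 1e-5)
})

test_that("identical observations collapse all components to the floor", {
  obs <- tiny_sim()$observations
  obs$log2_intensity <- 8
  fit <- fit_mixed_model(obs)
  expect_true(all(unclass(fit$components) <= 1e-8))
  expect_true(all(abs(fit$normalized) < 1e-6))
})

test_that("restricted likelihood at the optimum is no worse than at the truth", {
  comps <- c(G = .2, AG = .05, DG = .05, FG = .05, TG = .3, e = .08)
  wins <- vapply(1:8, function(s) {
    sim <- simulate_intensities(array_sim_config(
      n_genes = 25, treatments = c("RH0", "SH0", "RH1", "SH1"),
      n_replicates = 1, n_blocks_per_array = 2, n_flocks = 2, seed = 100 + s,
      components = do.call(variance_components, as.list(comps))))
    obs <- sim$observations
    fit <- fit_mixed_model(obs)
    pkg_des <- fleecerot:::.norm_design(obs, model_spec())
    setup <- fleecerot:::.mme_setup(pkg_des$X, pkg_des$Zlist,
                                    obs$log2_intensity)
    lam_true <- comps["e"] / comps[c("G", "AG", "DG", "FG", "TG")]
    crit_at <- function(comps_eval, lam) {
      r <- fleecerot:::.reml_crit(log(lam), setup)
      df <- setup$n - setup$p
      df * log(comps_eval["e"]) + r$logdet - sum(setup$q * log(lam)) +
        r$sigma2e * df / comps_eval["e"]
    }
    fitted <- unclass(fit$components)
    lam_fit <- fitted["e"] / fitted[c("G", "AG", "DG", "FG", "TG")]
    crit_at(fitted, lam_fit) <= crit_at(comps, lam_true) + 1e-6
  }, logical(1L))
  expect_gte(mean(wins), 0.95)
})

test_that("line-time treatment coding collapses sub-lines", {
  expect_identical(recode_line_time(c("RH0", "RL0", "SH2")),
                   c("R0", "R0", "S2"))
  sim <- tiny_sim(seed = 30)
  fit <- fit_mixed_model(sim$observations,
                         model_spec(treatment_coding = "line_time"))
  expect_setequal(colnames(fit$normalized), c("R0", "S0", "R1", "S1"))
})

test_that("fit diagnostics expose a monotone best-so-far likelihood trace", {
  fit <- fit_mixed_model(tiny_sim(seed = 17)$observations)
  tr <- fit$diagnostics$logl_trace
  expect_true(all(diff(tr) >= 0))
  expect_true(fit$diagnostics$converged)
  expect_lt(fit$diagnostics$grad_norm, 1e-2)
})
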