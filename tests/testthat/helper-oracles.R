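# Independent oracles used across the suite. These deliberately take the
# slow, dense, brute-force route so they share no code with the package's
# sparse implementations.

# dense design matrices of the normalization model built with stats::model.matrix
dense_norm_design <- function(obs) {
  Cfac <- interaction(obs$array_id, obs$block_id, obs$dye, drop = TRUE)
  X <- stats::model.matrix(~Cfac)
  Zs <- list(
    G = stats::model.matrix(~ 0 + factor(gene_id), obs),
    AG = stats::model.matrix(~ 0 + interaction(array_id, gene_id, drop = TRUE), obs),
    DG = stats::model.matrix(~ 0 + interaction(dye, gene_id, drop = TRUE), obs),
    FG = stats::model.matrix(~ 0 + interaction(flock_id, gene_id, drop = TRUE), obs),
    TG = stats::model.matrix(~ 0 + interaction(treatment_id, gene_id, drop = TRUE), obs)
  )
  list(X = X, Zs = Zs, y = obs$log2_intensity)
}

# -2 restricted log-likelihood evaluated on the dense covariance
dense_reml_crit <- function(des, comps) {
  n <- length(des$y)
  V <- diag(n) * comps["e"]
  for (k in names(des$Zs)) V <- V + comps[k] * tcrossprod(des$Zs[[k]])
  Vi <- solve(V)
  XtViX <- t(des$X) %*% Vi %*% des$X
  P <- Vi - Vi %*% des$X %*% solve(XtViX) %*% t(des$X) %*% Vi
  as.numeric(determinant(V)$modulus + determinant(XtViX)$modulus +
               t(des$y) %*% P %*% des$y)
}

# dense GLS solutions: fixed effects and BLUPs u_k = s2_k Z_k' V^-1 (y - Xb)
dense_gls <- function(X, Zs, y, comps) {
  n <- length(y)
  V <- diag(n) * comps[["e"]]
  for (k in names(Zs)) V <- V + comps[[k]] * tcrossprod(Zs[[k]])
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  u <- lapply(names(Zs), function(k)
    as.numeric(comps[[k]] * t(Zs[[k]]) %*% Vi %*% r))
  names(u) <- names(Zs)
  list(b = as.numeric(b), u = u)
}

# relationship coefficients by direct recursion on the pedigree
# (independent of the package's iterative tabular construction)
kinship_recursive <- function(ped) {
  s <- setNames(ped$sire, ped$animal)
  d <- setNames(ped$dam, ped$animal)
  memo <- new.env(parent = emptyenv())
  born <- setNames(seq_len(nrow(ped)), ped$animal)
  a <- function(x, y) {
    if (is.na(x) || is.na(y)) return(0)
    key <- paste(sort(c(x, y)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (x == y) {
      1 + 0.5 * a(s[[x]], d[[x]])
    } else {
      # recurse on the younger animal
      yng <- if (born[[x]] > born[[y]]) x else y
      old <- if (identical(yng, x)) y else x
      0.5 * (a(old, s[[yng]]) + a(old, d[[yng]]))
    }
    memo[[key]] <- val
    val
  }
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) for (j in seq_len(i))
    A[i, j] <- A[j, i] <- a(ped$animal[i], ped$animal[j])
  A
}

# random multi-generation pedigree, parents always listed before offspring
random_pedigree <- function(n_founders, n_extra, seed) {
  set.seed(seed)
  ids <- sprintf("P%03d", seq_len(n_founders + n_extra))
  ped <- data.frame(animal = ids,
                    sire = NA_character_, dam = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in (n_founders + 1L):(n_founders + n_extra)) {
    ped$sire[i] <- sample(ids[seq_len(i - 1L)], 1L)
    ped$dam[i] <- sample(setdiff(ids[seq_len(i - 1L)], ped$sire[i]), 1L)
  }
  ped
}

# upper-tail hypergeometric probability by explicit combinatorial sum
hyper_upper_enum <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# HWE exact p by enumeration over heterozygote counts with the conditional
# multinomial probability written out directly in factorials
hwe_enum_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (nA - h) / 2; bb <- (na - h) / 2
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n))
  }, numeric(1))
  p_obs <- pr[hets == nAa]
  sum(pr[pr <= p_obs + 1e-12])
}

# small long-format probe table used by the IO tests
make_probe_table <- function(n_probes = 6, n_arrays = 2, seed = 1,
                             genes = NULL) {
  set.seed(seed)
  probes <- sprintf("p%02d", seq_len(n_probes))
  if (is.null(genes)) genes <- sprintf("gene%02d", seq_len(n_probes))
  grid <- expand.grid(probe_id = probes,
                      array_id = sprintf("A%d", seq_len(n_arrays)),
                      dye = c("red", "green"), stringsAsFactors = FALSE)
  grid$gene_id <- genes[match(grid$probe_id, probes)]
  grid$block_id <- 1L
  grid$background <- 50
  grid$foreground <- 50 + 2^stats::rnorm(nrow(grid), 8, 1)
  grid$snr <- stats::runif(nrow(grid), 1, 30)
  grid
}
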