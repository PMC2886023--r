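#' Weighted resistant-vs-susceptible contrast of normalized expression
#'
#' Computes, per gene, the difference between the normalized mean
#' expression of the resistant and susceptible breed lines at one time
#' point. High sub-lines carry twice the weight of low sub-lines (they
#' carry the larger information content about the line difference):
#' \deqn{T0: (2\,RH0 + RL0)/3 - (2\,SH0 + SL0)/3}
#' \deqn{T1: (2\,RH1 + RL1)/3 - (2\,SH1 + SL1)/3}
#' \deqn{T2: RH2 - SH2}
#' At T2 only the high sub-lines were sampled, so the contrast is the plain
#' high-line difference.
#'
#' @param norm Gene x treatment matrix of normalized expression (TG BLUPs
#'   from [fit_mixed_model()]).
#' @param time One of `"T0"`, `"T1"`, `"T2"`.
#' @return Named numeric vector of differential-expression measures (log2
#'   units), positive when expression is higher in the resistant line.
#' @export
weighted_contrast <- function(norm, time = c("T0", "T1", "T2")) {
  time <- match.arg(time)
  need <- switch(time,
                 T0 = c("RH0", "RL0", "SH0", "SL0"),
                 T1 = c("RH1", "RL1", "SH1", "SL1"),
                 T2 = c("RH2", "SH2"))
  miss <- setdiff(need, colnames(norm))
  if (length(miss))
    .stopf("normalized expression lacks treatment column(s) required for %s: %s",
           time, paste(miss, collapse = ", "))
  if (time == "T2") return(norm[, "RH2"] - norm[, "SH2"])
  r <- (2 * norm[, need[1L]] + norm[, need[2L]]) / 3
  s <- (2 * norm[, need[3L]] + norm[, need[4L]]) / 3
  r - s
}

# signed fold-change convention: 2^de for up in RES, negative reciprocal
# (-2^-de) for down, e.g. de = -0.6 -> "-1.52-fold"
.signed_fold_change <- function(de) ifelse(de >= 0, 2^de, -(2^(-de)))

#' Call differentially expressed genes by the standard-deviation rule
#'
#' Standardizes the differential-expression measures of each time point by
#' their empirical mean and SD over genes and flags genes whose measure
#' lies beyond `z_crit` standard deviations from the mean, where `z_crit`
#' is the two-sided normal critical value at `alpha` rounded to two
#' decimals — 2.58 at `alpha = 0.01`.
#'
#' @param de_measures Named list of per-gene contrast vectors keyed by time
#'   (e.g. the output of [weighted_contrast()] for `"T0"`, `"T1"`, `"T2"`),
#'   or a single numeric vector.
#' @param alpha Two-sided significance level (default 0.01).
#' @param pooled If `TRUE`, use one mean/SD pooled over all time points
#'   instead of per-time-point moments.
#' @return Data frame with columns `gene_id`, `time`, `de_measure`, `z`,
#'   `fold_change`, `significant`.
#' @export
call_significant <- function(de_measures, alpha = 0.01, pooled = FALSE) {
  if (is.numeric(de_measures)) de_measures <- list(T0 = de_measures)
  if (any(vapply(de_measures, length, 1L) < 10L))
    .stopf("need at least 10 genes per time point to estimate the SD")
  zc <- de_threshold(alpha)
  all_vals <- unlist(de_measures, use.names = FALSE)
  out <- lapply(names(de_measures), function(tm) {
    de <- de_measures[[tm]]
    m <- if (pooled) mean(all_vals) else mean(de)
    s <- if (pooled) sd(all_vals) else sd(de)
    if (!is.finite(s) || s == 0) {
      .warnf("zero SD of DE measures at %s: no gene called significant", tm)
      z <- rep(0, length(de))
    } else z <- (de - m) / s
    data.frame(gene_id = names(de), time = tm, de_measure = as.numeric(de),
               z = as.numeric(z),
               fold_change = .signed_fold_change(as.numeric(de)),
               significant = abs(z) > zc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Two-sided normal critical value of the call rule
#'
#' @param alpha Significance level.
#' @return `qnorm(1 - alpha/2)` rounded to two decimals (2.58 at 0.01).
#' @export
de_threshold <- function(alpha = 0.01) round(qnorm(1 - alpha / 2), 2L)

#' Expected chance calls and false-positive-rate accounting
#'
#' With `n_tests` independent gene tests at level `alpha`, the expected
#' number of significant calls under the global null is
#' `round(n_tests * alpha)`; the false positive rate at each time point is
#' that expectation as a (rounded) percentage of the calls actually made,
#' capped at 100. Because genes co-express, the true number of independent
#' tests is smaller, so these rates are upper limits.
#'
#' @param n_tests Number of genes tested.
#' @param alpha Significance level.
#' @param n_de Named integer vector of significant calls per time point.
#' @return List of class `"fr_de_summary"` with `n_tests`, `alpha`,
#'   `expected_chance_calls`, `n_de`, and `fpr_percent` per time point.
#' @examples
#' chance_call_summary(3238, 0.01, c(T0 = 40, T1 = 72, T2 = 66))
#' @export
chance_call_summary <- function(n_tests, alpha, n_de) {
  if (any(n_de < 1L)) .stopf("each time point needs at least one call")
  expected <- round(n_tests * alpha)
  fpr <- pmin(round(100 * expected / n_de), 100)
  structure(list(n_tests = n_tests, alpha = alpha,
                 expected_chance_calls = expected,
                 n_de = n_de, fpr_percent = fpr),
            class = "fr_de_summary")
}

#' @exportS3Method base::print
print.fr_de_summary <- function(x, ...) {
  cat(sprintf("%d tests at alpha = %g: %d calls expected by chance\n",
              x$n_tests, x$alpha, x$expected_chance_calls))
  for (tm in names(x$n_de))
    cat(sprintf("  %s: %d called, estimated FPR %d%%\n",
                tm, x$n_de[[tm]], x$fpr_percent[[tm]]))
  invisible(x)
}

#' Overlap of significant gene sets across time points
#'
#' @param calls Output of [call_significant()].
#' @return List with per-time significant gene sets and the sizes of every
#'   intersection region (Venn counts).
#' @export
de_overlap <- function(calls) {
  sets <- lapply(split(calls, calls$time),
                 function(d) d$gene_id[d$significant])
  times <- names(sets)
  regions <- list()
  for (k in seq_along(times)) {
    combos <- utils::combn(times, k, simplify = FALSE)
    for (cc in combos) {
      inside <- Reduce(intersect, sets[cc])
      outside <- unlist(sets[setdiff(times, cc)], use.names = FALSE)
      regions[[paste(cc, collapse = "&")]] <- setdiff(inside, outside)
    }
  }
  list(sets = sets, regions = regions,
       counts = vapply(regions, length, integer(1L)))
}
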