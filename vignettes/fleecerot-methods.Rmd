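---
title: "Models and methods behind fleecerot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fleecerot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fleecerot)
```

# The problem

Fleece rot is a bacterial skin disease of sheep triggered by prolonged
fleece wetting; it is scored 0–5 at four backline sites and the animal's
score is the worst site. Selection lines divergent for resistance (RES)
versus susceptibility (SUS) differ in their skin transcriptome response to a
controlled wetting challenge, and candidate genes from that response can be
followed up with SNP association in pedigreed flocks. `fleecerot`
implements the full statistical chain — two-colour array normalization,
differential-expression calling, enrichment, pedigree residualization of
scores, and per-SNP association — together with simulators that generate
every input with known ground truth.

# The normalization model

Expression readings come from a **circular alternate dye-swap loop**: each
RNA sample is labelled once with Cy5 (red) and once with Cy3 (green) and
therefore appears on exactly two arrays. One background-corrected log2
reading per (array, dye, gene) is modelled as

$$ Y_{ijkftm} = \mu + C_{ijk} + G_m + AG_{im} + DG_{km} + FG_{fm} + TG_{tm} + e $$

* $C_{ijk}$ — fixed *comparison group*: readings from the same array slide
  $i$, printing block $j$ and dye channel $k$. This term carries all
  intensity-scale artefacts shared by co-printed, co-scanned spots, which
  is what makes the fit a normalization.
* $G_m$ — random gene effect (overall abundance of gene $m$).
* $AG$, $DG$, $FG$, $TG$ — random interactions of gene with array, dye,
  flock and treatment; treatment is breed line × time point.
* $e$ — residual.

All random terms are independent zero-mean normals with per-term variances
$\sigma^2_G, \sigma^2_{AG}, \sigma^2_{DG}, \sigma^2_{FG}, \sigma^2_{TG},
\sigma^2_e$ (log2-scale units squared). The BLUP solutions of $TG$ are the
normalized mean expression of each gene in each condition; contrasting them
between lines removes gene abundance ($G$), dye bias ($DG$), array effects
($AG$) and flock differences ($FG$) by construction.

## REML fitting

Variance components are estimated by restricted maximum likelihood. The
restricted log-likelihood is evaluated *exactly* through the sparse
Cholesky factorization of Henderson's mixed-model equations: with
$\lambda_k = \sigma^2_e/\sigma^2_k$ and coefficient matrix
$\mathbf{C} = [X\,Z]'[X\,Z] + \mathrm{blockdiag}(0, \lambda_k K_k^{-1})$,

$$ -2\,\ell_R = (n-p)\log\sigma^2_e + \log|\mathbf{C}|
   - \textstyle\sum_k (q_k \log\lambda_k - \log|K_k|) + y'Py + \text{const}, $$

and $\sigma^2_e$ is profiled out analytically
($\hat\sigma^2_e = (y'y - \hat\theta'W'y)/(n-p)$). The criterion is
maximised over the log variance ratios by bounded quasi-Newton iteration
(L-BFGS-B with finite-difference gradients, restarted from the incumbent if
the line search stalls). This is a deliberate design choice over
EM/average-information iteration: at desk scale a factorization-per-
evaluation search needs no trace terms (which would require inverse blocks
of $\mathbf{C}$), is exactly equivalent at the optimum, and its best-so-far
log-likelihood trace is monotone by construction, which the diagnostics
expose. The fixed comparison-group effect is not absorbed in a separate
pass; it sits in the sparse system, where the fill-reducing Cholesky
ordering absorbs it implicitly and exactly.

Numerical choices:

* **Component floor**: variances are parameters of a generative model, so
  negative estimates are not meaningful; components are floored at
  `1e-8` × total variance (variance ratios are bounded in
  $[e^{-25}, e^{25}]$ during the search).
* **Convergence**: L-BFGS-B terminates on its own criterion; a fit is also
  accepted when the numerical gradient norm at the final point is below
  `1e-2` (a flat likelihood plateau). Non-convergence returns the last
  iterate with a warning and `converged = FALSE`.
* **Degenerate input**: a zero-variance response short-circuits to floored
  components and zero solutions.
* **Treatment coding**: ten sub-line levels (RH/RL/SH/SL × T0/T1 plus
  RH2/SH2) by default because the contrasts are defined on sub-lines; a
  six-level line × time coding (`model_spec(treatment_coding =
  "line_time")`) is available because treatment can equally be read as
  line × time. The default is the coding the contrasts need.

Correctness is established in the test suite by (i) equality of the sparse
criterion with a dense-covariance evaluation of the restricted likelihood,
(ii) equality of MME solutions with dense GLS
($V = \sum_k \sigma^2_k Z_k Z_k' + \sigma^2_e I$) on instances ≤ 200
observations, (iii) comparison with an independent Nelder-Mead
maximisation of the dense criterion, and (iv) recovery of generative
variance components within 3 Monte-Carlo standard errors across 20
simulation seeds (200 genes × 8 arrays).

# Differential expression

The DE measure at each time point is a weighted contrast of the normalized
solutions, with the high sub-lines given twice the weight of the low
sub-lines (they are the more informative extremes of each line):

* T0: $(2\,RH0 + RL0)/3 - (2\,SH0 + SL0)/3$
* T1: $(2\,RH1 + RL1)/3 - (2\,SH1 + SL1)/3$
* T2: $RH2 - SH2$ (no low sub-lines were sampled at recovery)

A gene is called significant when its measure lies beyond 2.58 standard
deviations of the measure distribution — the two-sided normal critical
value at $\alpha = 0.01$ rounded to two decimals. The mean/SD are computed
per time point by default (the distribution "of the measures" is most
naturally per contrast); a pooled variant is a flag. With $n$ genes tested,
`round(n * alpha)` calls are expected under the global null, and the
per-time false positive rate is that expectation over the calls made
(capped at 100%); co-expression makes these upper bounds. Fold changes are
reported as $2^{de}$ with the negative-reciprocal convention for negative
measures (−1.52-fold style).

# Enrichment

Over-representation of annotation terms in the DE set uses the upper-tail
hypergeometric probability $P[X \ge k]$ against the fixed background of all
analysed genes, on flat gene→term pairs without ontology-graph
propagation. This is the target/background reduction of ranked-list GO
tools: with a fixed DE list and fixed background the test is exactly
hypergeometric. Raw p at $\alpha = 0.01$ drives the report flag (matching
the study convention); a Benjamini-Hochberg column is emitted alongside.

# The animal model

Fleece-rot scores are residualized before association with
$y = Xb + Zu + e$, where $X$ carries flock, sex, birth type, rear type and
a centred date-of-birth covariate, and $u \sim N(0, \sigma^2_a A)$ is the
polygenic effect with $A$ the numerator relationship matrix. Scores are
treated as numeric — the allelic substitution effect is interpreted in
score units, which presumes a numeric scale. $A$ is built by the tabular
method; its sparse inverse uses the pedigree rules on the
Mendelian-sampling variances. The inbreeding-aware rule
($d_i = \tfrac12 - \tfrac14(F_s + F_d)$, with $F$ read off the tabular
diagonal) is the default so that `A_inverse` is the exact inverse on any
pedigree — the simplified inbreeding-free rules are available as
`method = "simple"` but violate exactness once matings of relatives occur.

The single variance ratio $\lambda = \sigma^2_e/\sigma^2_a$ is estimated by
the same profiled REML criterion (1-D golden-section/parabolic search over
$\log\lambda \in [-12, 12]$); $h^2 = 1/(1+\lambda)$. If REML fails the
model refits at a fallback $h^2 = 0.3$ with a loud warning. The per-animal
residual $e = y - Xb - Zu$ is the *residual fleece-rot score*: observed
score minus the model correction, which can leave the 0–5 range (score 1
with correction 3 gives −2). The difference trait is post-wetting minus
pre-wetting (the change the challenge induces); `diff_sign = -1` gives the
opposite convention, which also appears in field use. Fixed-effect
relevance is screened by Wald tests at $\alpha = 0.05$; all factors are
kept by default (conservative and order-independent), with
`drop_nonsignificant = TRUE` as the alternative.

# SNP association

Per SNP and population: non-missing count $n$, minor allele frequency,
an exact Hardy-Weinberg test, and OLS of the residual score on allele
dosage 0/1/2 (heterozygotes midway between homozygotes — the additive
model). The slope $\beta$ is the allelic substitution effect; its p-value
uses the t distribution with $n-2$ df; $R^2$ (as a percentage) is the
phenotypic variance explained. Missing genotypes are dropped pairwise per
SNP (no imputation), which is why $n$ varies across SNPs. Monomorphic SNPs
are flagged and reported without estimates in that population while being
estimated normally elsewhere. Significance is flagged at per-test
P < 0.05 without multiple-testing correction, mirroring candidate-gene
reporting practice; a BH column is emitted for users who want it. Which
allele is counted only flips the sign of $\beta$; results are reported
relative to the minor allele.

The HWE exact test enumerates all heterozygote counts compatible with the
observed allele counts, scores each with the conditional probability
$P(n_{Aa}\mid n, n_A) = \frac{n!}{n_{AA}!n_{Aa}!n_{aa}!}2^{n_{Aa}}
\frac{n_A!n_a!}{(2n)!}$, and sums configurations no more probable than the
observed one (the common Fisher-style two-sided convention; a mid-p
variant is behind a flag, off by default). Monomorphic tables give p = 1.

# The simulators

`simulate_intensities()` uses the normalization model itself as the
generative law: all random effects are drawn from zero-mean normals at the
configured components, comparison-group values are drawn once per
array × block × dye level, and planted differential expression adds fixed
log2 shifts to chosen gene × treatment cells. The default design mirrors
the study layout: ten sub-line × time treatments, three biological
replicates rotated over three flocks, and a loop in which sample $i$ is red
on array $i$ and green on array $i+1$ — giving every sample exactly one
red and one green hybridisation (checked as a design invariant).

`simulate_population()` breeds random matings from unrelated founders,
drops breeding values through the pedigree (founder variance
$h^2 \sigma^2_P$, Mendelian-sampling variance half that), draws SNP
genotypes iid at Hardy-Weinberg proportions, and builds each trait's latent
liability directly on the score scale:
mean + fixed effects + centred SNP effects + breeding value + residual,
with $\sigma^2_P$ = `score_sd`². SNP contributions are centred
($(\text{dosage} - 2\,\mathrm{MAF})\beta$) so the configured score mean
stays the population mean whatever effects are planted. Observed site
scores replicate the liability over four sites with site noise
(SD 0.25), round and clamp to 0–5, and take the maximum — the worst-site
scoring rule.

Defaults are fixed once as the study conditions: pre-/post-wetting latent
means 1.5 and 3.0 (scores rise under the challenge), latent SD 1.2
(keeps the bulk of the distribution inside 0–5), $h^2 = 0.3$ as a
mid-range heritability for an ordinal disease score. Genotypes are drawn
iid rather than gene-dropped through the pedigree; this keeps the HWE
calibration of the generator exact and is the conservative choice for
association testing (no pedigree-induced genotype correlation).

## What the simulators do and do not emulate

The generators reproduce the *statistical* structure the pipeline assumes:
the crossed random-effect layout of the intensity model, the loop
topology, HWE genotypes, and a heritable ordinal score with known fixed
effects. They do not emulate spatial array artefacts, intensity-dependent
dye bias, probe cross-hybridisation, genotyping error, linkage between
SNPs, or genotype transmission through the pedigree. Passing recovery
tests therefore demonstrates that the estimators are correct under the
model's own assumptions — not that the model is robust to violations real
data can show.

## Discretisation and identifiability caveats

Two consequences of the generator's design surface in the tests and are
worth stating:

* **Ordinal attenuation.** Rounding, clamping and worst-site aggregation
  shrink the observed-scale heritability below the latent value (≈ 0.36
  observed for latent 0.4 at the defaults) and attenuate large planted SNP
  effects whenever dosage groups press against the 0/5 bounds. Recovery
  tests for $h^2$ use a ±0.1 band that absorbs this; SNP-effect recovery
  tests use mid-scale means and moderate effects where the mapping is
  close to linear over the bulk.
* **Residualization absorbs iid SNP effects at high $h^2$.** The polygenic
  BLUP of an animal without informative relatives shrinks its whole
  phenotypic deviation — including any iid SNP effect — by
  $1/(1+\lambda)$, so the residual-on-dosage slope is attenuated by about
  $\lambda/(1+\lambda)$ for weakly connected pedigrees. Exact recovery of a
  planted $\beta$ through the full residualize-then-regress route is
  therefore only identified at $h^2 = 0$, which is what the recovery tests
  simulate; with $h^2 > 0$ the route remains valid as a *test* (null
  calibration is unaffected) but the estimate is conservative.
* **Fixed-effect absorption of a lone DE gene.** The comparison-group
  means are fixed effects, so a single gene's planted shift moves its own
  group means by 1/(genes per block) and is attenuated accordingly. The
  end-to-end smoke test uses one printing block with 60 genes, making this
  < 2%.

# Problem sizes

The suites run at deliberately desk-sized conditions, chosen once: the
variance-recovery experiment uses 200 genes × 8 arrays × 20 seeds; the GLS
and dense-likelihood oracles run on ≤ 200-observation instances; the
animal-model recovery uses ~1,000-animal, 3-generation pedigrees; HWE
enumeration is checked exhaustively to n = 12 and on a complete lattice to
n = 50; the null-association calibration uses 50 replicates of 16 SNPs ×
3 traits × 3 populations.

# Known limitations

* No intensity-dependent (loess-style) normalization — the linear mixed
  model is the normalization, as in the study design it implements.
* Homogeneous residual variance across genes; no moderated-variance or
  permutation DE statistics.
* Single-trait animal model; no maternal effects or genomic relationship
  matrices.
* Enrichment treats annotation as flat; no GO-graph propagation and no
  ranked-list (mHG-style) statistic.
* The chance-call FPR treats genes as independent tests, which makes the
  reported rates upper bounds.
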