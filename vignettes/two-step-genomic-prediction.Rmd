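---
title: "Two-step genomic prediction of carcass traits: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step genomic prediction of carcass traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Carcass traits in beef cattle — rib eye area (REA, cm²), backfat thickness
(BFT, mm) and hot carcass weight (HCW, kg) — are measured *post mortem*, so
selection candidates can never have their own record. Genomic prediction
sidesteps this: marker effects estimated in a reference population of
slaughtered, genotyped animals yield a direct genomic value (DGV) for any
genotyped candidate. `genopred` implements the complete multiple-step
evaluation used for such traits in commercial *Bos indicus* populations
structured in paternal half-sib families, together with a synthetic-data
generator that reproduces the relevant population structure, because real
carcass datasets of this kind are proprietary and not deposited.

The pipeline is:

1. **Quality control** of dense SNP genotypes (`iterative_qc()`),
2. **Step 1** — a pedigree animal model (`animal_model()`) turning raw
   phenotypes into pseudo-phenotypes: estimated breeding values (EBV) and
   phenotypes adjusted for fixed effects (Y\*), with per-record weights,
3. **Step 2** — Bayesian whole-genome regression (`wgr()`) of the
   pseudo-phenotype on all markers simultaneously,
4. **Evaluation** — k-fold cross-validation (`run_cv()`) with accuracy,
   regression slope and MSE, plus genomic relationship summaries
   (`relationship_stats()`) describing how related validation animals are to
   the training set.

# Step 1: the animal model

The single-trait model is

$$y = X\beta + Za + e, \qquad a \sim N(0, A\sigma^2_a), \qquad
  e \sim N(0, I\sigma^2_e),$$

with contemporary group (CG: year × farm × management group; always ≥ 3
animals after `filter_outliers_cg()`, which also removes records beyond 3.5
within-CG SD) and age at slaughter as fixed effects, and `A` the pedigree
numerator relationship matrix. Sampling is Gibbs: single-site normal full
conditionals for β and `a` (using the sparse `A⁻¹` assembled directly from
the pedigree by Henderson's rules, inbreeding included), and scaled
inverse-chi-squared full conditionals for the variances.

Two numerical choices deserve explanation.

**Variance priors.** We fit with flat priors on both variance components
(the `df = -2`, scale-0 member of the scaled inverse-chi-squared family),
not the mode-at-half-phenotypic-variance priors that are sometimes used as
software defaults. The reason is measurable: in a paternal half-sib design
of ~2000 records the marginal likelihood of h² is nearly flat (a REML
profile moves by barely one log-likelihood unit between h² = 0.2 and 0.3),
so a prior whose implied h² mass centres on 0.5 drags the posterior mean
upward by ~0.1. With flat priors the posterior mode coincides with REML and
the posterior mean recovers simulated heritabilities of 0.08/0.17/0.20
within ±0.05 (mean over five replicate populations of n = 2000). Jeffreys
priors (`df = 0`) were rejected because their spike at zero traps the chain
for low-heritability traits. Informative priors remain available through
the `priors` argument.

**Mixing.** Single-site samplers mix notoriously slowly over
(a, σ²ₐ) because the two are strongly coupled a posteriori. After the
conjugate variance draws the sampler therefore performs an interweaving
(ASIS) move: the additive values are re-expressed as ã = a/σₐ, σₐ is
re-drawn from its (Metropolis-corrected) conditional in that ancillary
parameterisation, and the a are rescaled jointly. This makes desk-scale
chains (default 20,000 iterations, 4,000 burn-in, thin 10) behave like much
longer conventional chains; production analyses of this kind historically
used chains of 10⁶ iterations, which remain available via the chain
arguments. A split-chain z statistic on h² warns when a chain is still too
short.

From the fit come the pseudo-phenotypes of step 2:

* **EBV**, the posterior means of `a`; their accuracies
  $acc = \sqrt{1 - PEV/\sigma^2_g}$ use the per-animal prediction error
  variance (the variance of the retained posterior samples of `a`, which
  avoids forming the full inverse of the mixed-model coefficient matrix)
  and σ²_g = the posterior mean σ²ₐ of the same fit. The accuracies are the
  record weights when EBV is the response (`ebv_weights()`).
* **Y\*** = y − Xβ̂ (`adjusted_phenotype()`), which retains the additive
  value and residual. Its weights (`ystar_weights()`) are the square roots
  of the diagonal of Σ = (I−H) cov(y) (I−H)′, with H the hat matrix under
  V = ZGZ′ + R. The source description defines G and R as *diagonal*
  matrices of additive and residual variances, so V is diagonal and
  cov(y) = V; the diagonal of Σ then reduces exactly to
  $V_{ii} - x_i'(X'V^{-1}X)^{-1}x_i$, which is how we compute it —
  no per-block approximation is needed at this scale.

# Step 2: whole-genome regression

All three models share the likelihood
$y = 1\mu + Wg + e$, with W the 0/1/2 B-allele dosage matrix and
per-record weights entering as residual precisions,
$var(e_i) = \sigma^2_e / w_i^2$ (weights are SD-scale quantities — a
duplicated record is equivalent to a weight of √2, which the test suite
verifies against a duplicated-data oracle). They differ only in the marker
prior:

* **BRR** — $g_j \sim N(0, \sigma^2_\beta)$, with
  $\sigma^2_\beta \sim \chi^{-2}(df_\beta = 5, S_\beta)$;
* **BayesC** — a spike-and-slab mixture with mass 1−π at zero and a common
  slab variance; π ~ beta with prior mean π₀ = 0.5 and concentration
  p₀ = 10 (shapes p₀π₀ = 5 and p₀(1−π₀) = 5 — we read the (p₀, π₀)
  parameterisation as concentration and mean);
* **BL** — the Bayesian Lasso: double-exponential effects via the
  scale-mixture-of-normals representation, per-marker variances
  τ²ⱼσ²ₑ with inverse-Gaussian full conditionals and
  λ² ~ gamma(r = 1.1, s).

The hyperparameter scales implement the usual prior-R² split
(`default_hyperparameters()`, R² = 0.5 by default): S_e = var(y)(1−R²)(df_e+2)
and S_β = var(y)R²(df_β+2)/MSx with MSx = Σⱼ var(w·ⱼ). The gamma rate-scale
for the Lasso is not given in closed form anywhere we know of, so the
package adopts the convention s = (r−1)R²/(2(1−R²)MSx): the prior *mode* of
λ² is then exactly the value whose double-exponential marker variance
2σ²ₑ/λ² allocates R² of var(y) to the markers. Marker effects are updated
in fixed order per sweep for reproducibility (`random_order` shuffles).

The samplers are validated against conjugate oracles rather than other
software: with variances fixed, BRR posterior means must match the
closed-form ridge solution (correlation > 0.999), a p = 1 fit must match
the analytic normal posterior, and BayesC with π fixed at 1 must predict
identically to BRR.

DGV are computed as $DGV_i = \sum_j w_{ij}\hat g_j$. The printed form of
this equation omits the intercept, so `predict.wgr()` excludes it by
default (`include_intercept = TRUE` restores it); correlations and slopes
are unaffected by that choice.

# Evaluation

`run_cv()` assigns animals to k = 5 random folds (sizes within one of each
other), fits on four folds with the response-appropriate weights, and
computes per held-out fold: Pearson r between pseudo-phenotype and DGV;
accuracy (r/√h² for Y\*, approximating the correlation with the true
breeding value; r itself for EBV); the regression slope of pseudo-phenotype
on DGV (1 = no inflation); and MSE. The h² in the denominator is the step-1
posterior mean from the full data — pseudo-phenotypes and h² are *not*
re-estimated per fold, mirroring the multiple-step design. Aggregation is
the unweighted fold mean and the across-fold sample SD (k−1 denominator).
`relationship_stats()` reports, per validation animal, the maximum (maxr)
and the mean of the 5 and 10 highest genomic relationships to the training
set, averaged within and then across folds.

# The synthetic-data generator

`sim_halfsib_population()` emulates the study conditions the pipeline
assumes:

* **Pedigree**: ~294 sires and ~1546 dams for ~1756–2000 offspring; sires
  are assigned uniformly at random (family sizes ≈ Poisson with mean ~6);
  dams are used once when enough exist, recycled minimally otherwise.
  Nothing is simulated across generations (no selection or drift).
* **Genomes**: founder haplotypes from a block Gaussian copula — within
  `ld_block_len = 5` cM blocks the latent AR(1) correlation is
  `ld_rho = 0.93`, chosen once by calibration from {0.90, 0.93, 0.95, 0.96}
  (giving adjacent-marker r² of 0.289/0.314/0.333/0.343) to match the ~0.31
  average adjacent LD reported for dense bovine panels; across blocks
  markers are independent. Gene dropping uses Haldane recombination at
  0.01/cM. The desk default is 5,000 markers on 10 chromosomes of 100 cM,
  preserving n ≪ p; the acceptance analyses use a cattle-like karyotype
  (29 autosomes × 86 cM ≈ 25 Morgans) because the dispersion of realized
  half-sib relationships — variance ≈ 0.125/(total Morgans) on the sharing
  scale — depends on total map length, and the study species has 29
  autosomes.
* **Traits**: `n_qtl` markers (default 300) receive i.i.d. normal
  allele-substitution effects; the residual SD is scaled so the realized
  var(TBV)/var(TBV + e) equals the target h² exactly. Presets REA/BFT/HCW
  carry the published phenotypic scales (means 68.6/4.84/277.9, h²
  0.20/0.08/0.17). CG effects are N(0, cg_sd) with every group ≥ 3 animals;
  ages are N(731.9, 83) days truncated at ±3 SD with a linear slope on the
  trait.
* **Planted defects** (`inject_qc_defects()`): labeled low-MAF columns
  (exactly 1% B alleles), heterozygote-free HWE violations, low-call-rate
  markers and samples, duplicated positions, duplicated columns (r² = 1),
  and sub-threshold GenCall scores, so QC tests can assert an exact
  removed-equals-planted round trip. Duplicated pairs are placed in the
  interior of the first 100-SNP pruning window of each chromosome and
  protected from sample-missingness injection, so the documented
  tie-break (equal MAF → the later-positioned copy is pruned) stays
  deterministic.

What the generator does **not** emulate: skewed family sizes (real AI
populations have a few very large and many singleton families; we default
to uniform-random assignment), relationships among founders, genotyping
error beyond the scalar quality score, multi-generation selection, or sex
chromosomes. Tests passing on these simulations therefore demonstrate
correctness of the machinery under the stated population model, not
performance on any particular real herd.

One measurable consequence of the uniform family-size default: the
averaged maximum validation-to-training relationship in the simulated
design comes out at ≈ 0.284, the analytically expected value
0.25 + E[max over ~5 half-sibs] × SD(realized half-sib G) for Poisson-6
families on a 25-Morgan genome, slightly above the ≈ 0.25 reported for the
real population — whose much lower mean5 (0.19 vs our 0.22) indicates many
validation animals there had few close relatives in training, consistent
with a right-skewed family-size distribution.

# Quality control

`iterative_qc()` applies, in order within each iteration: non-autosomal
removal, GenCall score ≤ 0.70, duplicated genomic positions (both members
removed), MAF < 0.02, Hardy–Weinberg p < 10⁻⁵ (one-df χ² goodness-of-fit;
monomorphic markers return p = 1 and are left to the MAF filter), marker
call rate < 0.98, LD pruning (within non-overlapping 100-SNP windows per
chromosome, every pair with r² ≥ 0.995 loses its lower-MAF member; ties
drop the later-positioned marker), and individual call rate < 0.90. All
statistics are recomputed on the surviving matrix each iteration and the
process repeats to a fixpoint; each removed item records the first filter
that triggered it. The filter order follows the narrative order in which
such protocols are usually described; order only affects the recorded
reason, not the surviving set, except for LD tie-breaks. Missing genotypes
that survive QC are mean-imputed (`impute_genotypes()`) before any
regression or relationship matrix — fractional codes are intentional.

# Genomic relationships

`vanraden_g()` implements the single-denominator (method 1) estimator
G = MM′ / (2Σpⱼ(1−pⱼ)), with centering frequencies computed from the full
supplied panel (training and validation together), matching a single-G
workflow. Monomorphic markers are an error by design: QC must precede.
`pca_g()` provides the eigendecomposition used to check for population
stratification; it is property-tested (orthonormality, separation of
planted subpopulations) because no reference values exist for it.

# Problem sizes and runtimes

Defaults are chosen so the full test suite and the acceptance analyses run
comfortably on a single CPU: simulations of 400–2000 animals at 600–5000
markers, chains of 10³–3×10⁴ iterations. These are the package's desk-scale
working points; every chain length, population size and threshold is an
argument, and the historical production settings (10⁶-iteration chains,
hundreds of thousands of markers) are reachable by changing them.

# Known limitations

* Single-trait models only; the bivariate anchor-trait variant sometimes
  used for carcass weight (to correct for selection on an early-life trait)
  is out of scope, as are maternal and permanent-environment effects and
  genetic groups for unknown parents.
* No deregressed-EBV response (EBV and Y\* only), no BayesA/B/R variants,
  and no REML alternative to the Gibbs animal model.
* `GenCall` quality is modelled per marker, not per call — per-call scores
  are not representable in PED/MAP text.
* LD pruning windows advance by whole windows (non-overlapping), the
  simplest reading of "100-SNP windows"; survivors can therefore differ at
  window boundaries from sliding-window implementations.
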