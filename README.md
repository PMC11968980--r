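# grexcontact

Linking genetically regulated expression (GReX) of enhancer RNAs and
canonical genes to 3D chromatin contact frequency.

Enhancer RNAs (eRNAs) are short transcripts produced from active
enhancers; most are "2D" eRNAs under 2 kb. This package implements a
pipeline for asking whether the *genetic* component of eRNA and gene
expression predicts how often the genomic bins containing them touch in
3D, and for the association bookkeeping that situates eRNAs in
transcriptome-wide association studies (TWAS) of complex traits. It is
aimed at statistical and regulatory genomics researchers who want the
full chain — cis expression models, Hi-C matrix handling, neural and
classical contact-frequency models, attribution, and downstream tallies —
testable end to end on synthetic data, without access-restricted cohort
genotypes.

## What it computes

**Cis expression models.** Per transcript, an elastic net (mixing 0.5,
penalty by inner cross-validation) of covariate-residualized expression
on dosages within ±1 Mb of the TSS. Cross-validated R² comes from nested
CV; a transcript is *imputable* when out-of-fold R² > 0 with one-sided
p < 0.05. GReX is the dosage-weighted sum of model weights; cohort mean
GReX per transcript is the contact-model feature. A vectorized per-variant
cis-eQTL scan with Benjamini–Hochberg FDR is included.

**Contact pair assembly.** Binned contact matrices (cooler-dump text,
BEDPE or dense) are balanced by iterative correction (ICE) until bin
coverage equalizes, then intersected with eRNA/gene annotations; every
off-diagonal pixel with normalized contact ≥ 1 yields transcript pairs of
class enhancer–gene, gene–enhancer or enhancer–enhancer, with bin-start
distance and the contact value as the regression target.

**Contact-frequency models.** A fully connected network trained by
mini-batch gradient descent minimizing

    MSE = (1/n) Σ (Y_i − Ŷ_i)²   (+ λ₁ Σ|w| + λ₂ Σw²)

with performance measured as

    R² = 1 − Σ(Ŷ_i − Y_i)² / Σ(Y_i − Ȳ)²

Named presets reproduce the three tuned architectures (whole blood
2×120 hard-sigmoid NAdam; cerebellum 2×90 Softsign Adagrad; K562 run-on
2×150 ReLU Adagrad), and grid search with 5-fold CV ranks arbitrary
candidate spaces. Baselines: linear, polynomial, random forest, support
vector regression, gradient boosting.

**Evaluation.** Relative error E = |ŷ − y| / y per pair; exact
two-feature Shapley attribution via the four-coalition closed form
(φ₁ = ½[(f(x₁,b₂) − f(b₁,b₂)) + (f(x₁,x₂) − f(b₁,x₂))]); cross-tissue
transfer with the training tissue's feature scaling; distance–contact
Pearson correlations.

**Downstream bookkeeping.** Bonferroni thresholds (α / n_tests, further
divided by trait count for phenome-wide scans), GWAS locus classification
(eRNA-only / gene-only / both / neither), Mendelian-randomization causal
tallies, causal-contact intersection, epigenomic peak-overlap fractions,
eQTL set comparison (Jaccard, nearest-TSS distances, Mann–Whitney U), and
colocalization accounting at inclusive PP ≥ 0.7.

**Synthetic data.** `sim_config()` and friends generate genotypes,
annotations (eRNA median 550 bp, >90% under 2 kb), expression with
known cis architecture and heritability, and contact matrices with
distance decay plus a planted non-linear GReX link, so every stage has a
ground truth. See the methods vignette
(`vignettes/grex-contact-methods.Rmd`) for the generator's rationale and
its limits.

## Worked example

Benchmark the cerebellum-preset network against its noise ceiling on
20,000 synthetic contact pairs with a planted saturating-product link:

```r
library(grexcontact)

sp  <- simulate_pair_dataset(n_pairs = 20000, link_strength = 3,
                             noise_sd = 1, seed = 1)
spl <- split_train_test(sp$pairs, fraction = 0.8, seed = 1)

preset <- nn_preset("cerebellum", seed = 1)
fit  <- train_nn(spl$train, preset$architecture, preset$config)
pred <- predict(fit, spl$test)

cat("noiseless ceiling R2:", round(sp$ceiling, 3), "\n")
cat("network test R2:     ", round(evaluate_r2(spl$test$contact, pred), 3), "\n")

base <- fit_baseline_suite(spl$train,
                           families = c("linear", "gradient_boosting"),
                           seed = 1)
cat("linear test R2:      ",
    round(evaluate_r2(spl$test$contact, base$models$linear(spl$test)), 3), "\n")

shap <- shap_two_feature(fit, spl$test)
print(round(shap$contribution_pct, 2))

err <- relative_error_stats(spl$test, spl$test$contact, pred)
cat("median relative error:", round(err$median_error, 3), "\n")
```

Output:

```
noiseless ceiling R2: 0.58
network test R2:      0.564
linear test R2:       0
  upstream downstream
     49.55      50.45
median relative error: 0.14
```

The network recovers nearly all the predictable signal (0.564 of a 0.58
ceiling — the rest is irreducible noise), the linear baseline has no
skill because the planted link is orthogonal to linear trends, and the
two GReX features contribute almost symmetrically to the predictions.

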