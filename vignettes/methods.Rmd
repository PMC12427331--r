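---
title: "Genomic prediction with a masked 6-mer Transformer: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with a masked 6-mer Transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

snpformer predicts quantitative traits (the setting it is built for is pig
breeding: growth and reproduction traits measured on genotyped animals)
from biallelic SNP dosages with a two-stage Transformer, and benchmarks it
against the linear tools of genomic selection under an across-generation
validation scheme.  This vignette is the package's account of the science:
the models, their assumptions, the tunable parameters, and the places where
a design decision was genuinely open.

## The prediction problem

Genomic selection ranks candidate animals by predictions of their
phenotypic or genetic merit computed from genome-wide markers.  The
standard tool, GBLUP, is a linear mixed model on allele dosages: it can
capture at most the narrow-sense (additive) heritability $h^2$ of a trait,
which is why its test-set $R^2$ is expected to sit at or below $h^2$.
Dominance and epistatic variance are invisible to it.  The hypothesis
embodied in this package is that a sequence model over the genotype —
treated as a string of local haplotype symbols — can (a) learn the
correlation structure of the genome (linkage disequilibrium, local
haplotypes) from unlabelled genotypes alone, and (b) after supervised
fine-tuning, convert that structure plus non-additive signal into better
phenotype predictions than the linear baseline.

## Data model and preprocessing

Genotypes are coded 0/1/2 as counts of the **minor** allele
(`recode_to_minor()`), with missing calls as `NA`.  Quality control
(`apply_qc()`) removes SNPs with call rate below 95%, minor allele
frequency below 1%, or a 1-df Hardy–Weinberg chi-square p-value below
$10^{-6}$, then individuals with more than 10% missing genotypes over the
surviving SNPs; all inequalities are strict and each SNP is attributed to
the first rule it violates (call rate, then MAF, then HWE).  The SNP rules
are evaluated on the full individual set and the individual rule on the
surviving SNPs; the reverse order is available behind a flag
(`individuals_first`) because the two orders give slightly different
per-SNP statistics and the conventional choice is not universal.  The HWE
test is the standard goodness-of-fit chi-square without continuity
correction — the conventional array-QC test when only a p-value threshold
is given; an exact test would change decisions only for rare genotype
classes near the threshold.

Remaining missing genotypes (rare after the call-rate filter, under 5% of
entries by construction) are mean-imputed per SNP.  Linear models consume
the fractional means directly; tokenization needs a discrete alphabet, so
a second matrix rounds imputed values half-up to the nearest of
$\{0,1,2\}$.  Observed genotypes are never altered.

## Tokenization and the masked 6-mer objective

Each individual's SNP sequence (sorted by chromosome and position) is cut
into non-overlapping 6-mers: $3^6 = 729$ possible genotype words, plus
`[CLS]`, `[PAD]` and `[MASK]` for a 732-token vocabulary.  A trailing
remainder shorter than six SNPs is dropped rather than padded with an
invented allele (at most five SNPs per individual).  At most 10,240
genomic tokens are kept — enough for a 60K SNP array (52,842 post-QC SNPs
make 8,807 tokens) — truncating from the tail; `[CLS]` is prepended outside
that budget and `[PAD]` fills the remainder under a binary attention mask.
Tokenization spans chromosome boundaries by default (a boundary-respecting
mode was considered and rejected for the desk-scale genome of the
simulator, which carries a single pseudo-chromosome).

Pre-training corrupts each sequence with masked 6-mer prediction: 15% of
the genomic tokens are selected; 80% of those become `[MASK]`, 10% a random
genomic token, 10% stay unchanged, and the model must recover the original
token at every selected position under cross-entropy.  Counts are exact
(half-up rounding, remainder to the unchanged group) rather than Bernoulli
draws — the BERT-style masking convention permits either reading, and
exact counts make behaviour reproducible and testable.  Random replacements are
drawn from genomic tokens only, never specials.  The uniform-guessing
baseline is $\ln 732 \approx 6.60$ nats; any validation cross-entropy
materially below that demonstrates learned genomic structure; on the
simulator's LD-block genomes the tiny preset reaches about 4.6 nats within
ten epochs.

## Architecture

The encoder is a standard post-norm Transformer stack: token embeddings
plus learned absolute position embeddings (then LayerNorm and dropout),
and per layer multi-head self-attention followed by a feed-forward network,
each sub-layer wrapped with a residual connection and LayerNorm.  Post-norm
ordering follows the original-Transformer convention (pre-norm would be
the other defensible reading of "residual connections and layer
normalisation"); GELU (tanh form) is the activation, the convention of
the masked-LM lineage.  Defaults
mirror the full-scale configuration — 12 layers, hidden 768, 12 heads, FFN
3072, dropout 0.1 — and a `"tiny"` preset (2 layers, hidden 64, 4 heads,
FFN 128) is provided for CPU-scale work; every experiment in the test
suite uses the tiny preset.  The pre-training head is a single linear map
to vocabulary logits.  The regression head applies a LayerNorm and then
`linear(d,d) + tanh + linear(d,1)` to the final `[CLS]` state — standard
CLS pooling with one addition: the head-input LayerNorm standardises the
`[CLS]` features whatever the encoder's training history, so a freshly
initialised tanh pooler starts in its linear regime on top of an
MLM-trained encoder instead of saturating (without it, fine-tuning from a
pre-trained checkpoint wastes its first epochs re-scaling).  A single linear
layer would also have been a defensible regression head.

Weights are truncated-normal (sd 0.02).  The forward and backward passes
are compiled (RcppArmadillo) and templated on precision: single precision
for training throughput, double precision for the finite-difference
gradient verification in the test suite.  Analytic gradients for every
parameter tensor are checked against central differences to a relative
tolerance of $10^{-4}$.

## Training strategy

Both stages use AdamW (decoupled weight decay 0.01 on weight matrices and
embeddings, none on biases or LayerNorm parameters) with linear warmup and
linear decay to zero; cosine decay is available by flag.  Full-scale defaults: pre-training lr $10^{-4}$, 100 warmup steps, 100
epochs; fine-tuning lr $5\times10^{-4}$, 10 warmup steps, 50 epochs, MSE
loss, early stopping on validation $R^2$ with patience 10 (the patience is
this package's choice).  Note the default
fine-tuning rate *exceeds* the pre-training rate even though transfer
learning typically uses a smaller one; both are plain arguments, and the
benchmark protocol selects its own rates.  Masking is
resampled every epoch; the validation corruption is fixed across epochs so
the curve is comparable.  Model selection keeps the best-validation
checkpoint (lowest masked cross-entropy for pre-training, highest $R^2$
for fine-tuning); weights from epochs after the best one are never
returned.  Phenotypes are standardised on the training split only and
predictions mapped back.  `grid_search()` evaluates a hyperparameter grid
exhaustively and selects by validation $R^2$; the test set never enters
any stage before the final evaluation.

## Forward validation

Prediction must generalise to descendants, so splitting is by pedigree:
generation index (0 for founders, else one plus the maximum parental
index) orders individuals oldest-first with a stable id tie-break, and the
list is cut at 80% / 90%.  Closely related individuals spanning a boundary
defeat the purpose of the split, so by default any full-sib family (same
sire and dam) straddling a boundary is moved entirely into the *later*
partition — a test animal may share parents with a validation animal but
never contribute relatives backwards into training.  Only full sibs are
grouped: in livestock pedigrees half-sib families are enormous (one boar
sires hundreds of litters) and grouping them would collapse the split.
Counts therefore deviate from exact fractions by at most a family.  The
headline accuracy metric is the coefficient of determination
$R^2 = 1 - SSE/SST$ (the proportion of variance predicted; negative when
predictions are worse than the mean), with the squared Pearson correlation
reported secondarily and MSE alongside.

## Baselines

GBLUP uses the VanRaden method-1 relationship matrix
($G = ZZ'/2\sum p_j(1-p_j)$ on observed frequencies) and REML variance
components obtained from one spectral decomposition of the training
kinship and a 1-D search over $\log\lambda$, $\lambda = \sigma_e^2 /
\sigma_g^2$; a fixed-$h^2$ mode sets $\lambda = (1-h^2)/h^2$ directly.
Both modes are provided because the baseline protocol named the model but
not the variance-component estimator.  Predictions are
$\hat y = \mu + G_{\text{cross}}(G_{\text{train}} + \lambda I)^{-1}
(y - \mu)$, algebraically identical to ridge regression on centred
dosages — the test suite asserts that identity to $10^{-8}$ against a
dense oracle.  The Lasso baseline delegates the coordinate-descent path to
glmnet and selects its penalty by validation $R^2$ only.  Gradient-boosted
and recurrent baselines from the wider comparison literature are not
re-implemented (no architectural details to implement); the evaluation
utilities accept any externally produced prediction table.

## The synthetic population

The simulator is the package's testbed and defines the study conditions.
Founder genomes are built from per-block haplotype pools: each of `n_blocks`
LD blocks carries `haplotypes_per_block` founder haplotypes with
Dirichlet(1) frequencies, resampled until every implied MAF lies inside
`maf_bounds` (default 0.05–0.5, comfortably clear of the 1% QC cutoff).
Gametes copy whole block haplotypes — recombination acts only between
blocks with probability `recomb_prob` per boundary — so every inherited
block haplotype is an exact copy of a parental one (the Mendelian
invariant the tests check), and within-block LD is strong, the structure
the masked 6-mer objective is meant to learn.  Mating is random among the
previous generation with distinct parents; block size 6 aligns LD blocks
with token windows, which is the regime the tokenizer was designed around.

Traits are built as $y = g_{add} + g_{dom} + g_{epi} + e$.  Additive
effects are Gaussian at `n_causal_add` loci; dominance uses centred
heterozygosity indicators at the same loci; epistasis uses products of
centred dosages at `n_causal_pairs` locus pairs drawn *within* LD blocks
by default — local, haplotype-borne interactions, the kind a 6-mer token
can encode; genome-wide random pairing is available.  The non-additive
components are projected off the additive span of the involved loci and
their block-mates (the Cockerham-style orthogonal decomposition), so
"dominance" and "epistasis" mean variance a linear model on dosages
genuinely cannot reach; without that projection, allele-frequency
asymmetry lets dosage products leak additive-taggable variance.  All
components (and the Gaussian residual) are then Gram–Schmidt
orthogonalised in sample and rescaled so the realised phenotypic-variance
fractions equal `h2_additive`, `dominance_frac` and `epistasis_frac`
*exactly* in sample — exactness makes heritability-cap tests sharp.  These
fractions are phenotypic-variance shares; their sum is the broad-sense
heritability.  The 0.07–0.62 range of additive heritabilities spanned in
testing matches the range reported for the pig production traits this
package targets.

What the simulator does **not** emulate: realistic recombination maps,
mutation, selection and the resulting allele-frequency dynamics, breed
structure or admixture, genotyping error, and coalescent-exact LD decay.
Tests passing on these populations show the machinery is correct and that
the qualitative model ordering holds where non-additive, haplotype-local
signal exists; they do not certify effect sizes on real livestock data.

## The desk-scale benchmark

`run_benchmark()` reproduces the comparison protocol end to end on
simulated data: simulate, QC, impute, tokenize, forward-split, then GBLUP,
Lasso, a Transformer fine-tuned from scratch, and a pre-trained-then-
fine-tuned Transformer, evaluated by test-set $R^2$ over replicate seeds.
The protocol the acceptance suite runs uses 1,500 individuals (300
founders plus four generations of 300), 600 SNPs in 100 six-SNP blocks,
and a trait with additive fraction 0.10 and within-block epistatic
fraction 0.45 (60 causal SNPs, 40 pairs).  Phenotypes are recorded only
for the three youngest generations (900 of the 1,500 animals) while
pre-training uses all 1,500 genotypes unlabelled — the defining setting
for self-supervision, where unlabelled genotypes outnumber phenotype
records, and the regime in which a from-scratch model must learn its
token representations from far fewer examples.  Training uses the tiny
preset, 12 pre-training epochs (lr $3\times10^{-4}$, warmup 20) and 20
fine-tuning epochs for both arms (lr $10^{-3}$, warmup 10, no early
termination within the budget), batch size 64 — sizes chosen so a
replicate completes in a few minutes on one CPU.  At this scale the
replicate-to-replicate spread of forward-validated test $R^2$ is large
(the test generation holds 90 animals), so single-seed comparisons
between the two Transformer arms are uninformative; the suite compares
means over five replicate seeds.  The same scaling logic fixes the other
experiment sizes: the GBLUP heritability-cap and REML-recovery runs use
2,000 individuals and 1,000 SNPs over 20 replicate seeds; the
masked-LM-beats-uniform check uses 200 individuals, 600 SNPs and 30
epochs.

On these populations both Transformer arms clearly exceed GBLUP, which
hovers near zero (an additive fraction of 0.10 is barely detectable under
across-generation validation, and the epistatic 0.45 is invisible to it
by construction) — the desk-scale analogue of reading the
Transformer-minus-GBLUP gap as captured non-additive variance.  The
further margin of pre-training over from-scratch training, by contrast,
is *not* resolved at this scale: across protocol variants explored during
development the sign of the five-seed mean gap flips with seeds and
configuration, and under the fixed protocol the scratch arm comes out
slightly ahead.  The package reports this honestly rather than presenting
a tuned configuration: whatever self-supervision dividend exists for
full-scale genomic language models does not miniaturise to a 2-layer
encoder on 600 SNPs with these label counts, where random initialisation
adapts at least as fast as a masked-LM checkpoint and per-seed test noise
dwarfs the residual difference.

## Attention-based interpretation

`attention_region_scores()` summarises where the fine-tuned model looks:
the attention from the `[CLS]` query to each genomic token, averaged over
the heads of the last layer and over a cohort of individuals (default the
test set, to damp per-individual noise).  Scores are softmax mass, so they
live in $[0,1]$ and sum to at most one over genomic tokens.  The
aggregation recipe (CLS row, last layer, head mean) is this package's
choice — the attention-interpretation literature fixes no canonical
recipe — and the full token-by-token maps per layer remain available
(`plot_attention_map()`).  Because the model sees 6-mer tokens, importance
is resolved at the token-window level, never at single SNPs; `top_regions()`
thresholds at a score quantile and merges adjacent tokens into regions,
exportable as BED.  Gradient-based attributions (SHAP, integrated
gradients) are out of scope.

## Numerical choices and degenerate inputs

* LayerNorm $\varepsilon = 10^{-5}$; attention masking adds $-10^{30}$ to
  masked key columns before the softmax (rows of fully padded queries
  still normalise over unmasked keys).
* Half-up rounding (`floor(x + 0.5)`) everywhere an exact count is
  derived from a rate, avoiding R's banker's rounding.
* REML optimises $\log\lambda$ on $[-12, 12]$ after adding a $10^{-8}$
  jitter to the training kinship; a non-positive-semi-definite kinship
  after jitter is an error, not a warning.  The reported $h^2$ is
  $1/(1+\lambda)$, exact when the mean GRM diagonal is 1.
* Monomorphic SNPs get HWE chi-square 0 and p 1 (they are removed by the
  MAF rule anyway); a SNP with zero observed calls is removed by call
  rate with undefined MAF/HWE flagged as `NA`.
* Minor-allele recoding leaves exact frequency-0.5 ties unchanged, making
  the operation an involution off the tie.
* Ties in validation $R^2$ keep the earlier epoch; ties in attention
  ranking are broken by token order.
* Every stochastic step (simulation, masking, shuffling, dropout,
  initialisation) derives its stream from one user seed, so identical
  configurations reproduce byte-identical results on the same platform.

## Known limitations

Single-trait, single-environment prediction only; no fixed-effect
covariates in the mixed model beyond the intercept (the real datasets'
fixed effects are out of scope).  The Transformer implementation is
CPU-oriented and desk-scale; the full 12-layer configuration is
expressible but not trained here.  Attention scores are descriptive, not
causal attributions.  The simulator's epistasis model is a stand-in for
unknown real non-additive architecture — results on it bound what the
method can do when its assumptions hold, not what it will do on any given
breeding population.
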