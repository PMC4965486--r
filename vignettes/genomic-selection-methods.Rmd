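---
title: "Genomic selection with marker preselection: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection with marker preselection: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsmarker)
```

gsmarker implements the analysis chain used to evaluate genomic selection in
an inbred diversity panel — the motivating case is a soybean panel of 235
varieties from two ecotype groups (185 North-Spring-type and 50
Huanghuai-summer-type lines), phenotyped as entry means in up to 23 trial
locations and genotyped with a ~5.4k SNP chip. This vignette explains the
statistical models, the defaults, and the design decisions that were
genuinely open.

## The phenotypic mixed model

Entry means are modelled as

$$ y_{ij} = \mu + L_i + G_j + e_{ij}, $$

with location effects $L_i \sim N(0, \sigma^2_L)$, genotype effects
$G_j \sim N(0, \sigma^2_G)$ and residuals $e_{ij} \sim N(0, \sigma^2_e)$, no
genotype-by-location interaction term (one record per line and location
leaves no replication to separate an interaction from the residual).
`fit_varcomp()` estimates the three components by REML: EM updates on
Henderson's mixed-model equations, then a direct L-BFGS-B polish of the REML
profile likelihood on log-variances. The EM stage is retained (rather than
jumping straight to a general optimizer) because its iterates provably never
decrease the REML likelihood — a property the test suite asserts per
iteration — and because it is insensitive to poor starts; the polish then
supplies the last digits. Starting values are an even three-way split of the
phenotypic variance: method-of-moments starts can place a component exactly
on the zero boundary, which is a fixed point of the EM update. Convergence
is declared at a maximum relative component change below 1e-8 (500-iteration
cap); estimates that finish on the numerical floor are truncated to zero.

Broad-sense heritability is reported on the entry-mean basis,

$$ H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_e / l}, $$

with $l$ the number of distinct locations. This is the line-mean form
consistent with predicting means over $l$ trials; it is also what makes the
downstream ridge parameter coherent (below).

`compute_blues()` re-solves the same model with genotype fixed (cell-means
parameterization, so each BLUE estimates $\mu + G_j$) and location random at
the fitted variance ratio. On balanced complete data the BLUE reduces
exactly to the line's arithmetic mean — the test suite checks this identity
and, on unbalanced data, agreement with an explicit GLS inversion of the
full covariance matrix. The two-ecotype difference in BLUEs is assessed with
Welch's unequal-variance t test (`contrast_subpopulations()`): the group
sizes (185 vs 50) and dispersions differ enough that the pooled-variance
form would be hard to defend.

## RR-BLUP

With $y$ the vector of line BLUEs and $X$ the $n \times p$ dosage matrix,
`rrblup()` fits

$$ y = \mu \mathbf{1} + X\alpha + e, \qquad
   \alpha \sim N(0, I_p\, \sigma^2_G / p), \qquad
   e \sim N(0, I_n\, \sigma^2_e / l). $$

Marker-effect variance $\sigma^2_\alpha = \sigma^2_G / p$ spreads the
genotypic variance evenly over markers; the residual variance is
$\sigma^2_e / l$ because the BLUEs are means over $l$ locations. Both are
plugged in from the phenotypic analysis — the ridge parameter
$\lambda = (\sigma^2_e / l)/(\sigma^2_G / p)$ is *not* re-estimated inside
the prediction model. $(\hat\mu, \hat\alpha)$ solve Henderson's equations
with an unpenalized intercept; for $p > n$ the identical solution is
computed through the $n \times n$ kernel system
($V = XX' + \lambda I$, $\hat\mu = (1'V^{-1}1)^{-1}1'V^{-1}y$,
$\hat\alpha = X'V^{-1}(y - \hat\mu\mathbf{1})$). The algebraic identity of
the two routes is exercised over $n<p$, $n=p$, $n>p$ in the tests, to 1e-8
relative error.

Dosages are used as coded (0/2 for inbred homozygotes, fractional after mean
imputation); no column centering is applied. Because the intercept is
explicit and unpenalized, adding any constant to a marker's coding shifts
$\hat\mu$ and leaves predictions unchanged (asserted by test), so centering
is a no-op for prediction. Markers that are monomorphic in a training fold
are retained — their effects shrink to zero naturally, and keeping them
avoids fold-dependent marker sets.

## Cross-validated accuracy

`run_cv()` performs five-fold cross-validation: per replicate, lines are
partitioned into near-equal folds at random; marker effects are fitted on
four folds and used to predict the fifth; $r_{MP}$ is the Pearson
correlation between predicted and observed BLUEs. The default pools by
averaging the per-fold correlations (a pooled-over-lines variant is
available); per-fold averaging avoids artifacts from fold-specific means.
Accuracy is standardized as

$$ r_{GS} = r_{MP} / \sqrt{H^2}, $$

with $H^2$ fixed from the full-data fit for every fold and replicate — a
single printed heritability implies a single standardizer. $r_{GS}$ is not
truncated at 1; chance exceedances are counted and flagged, not hidden.
Replicate $r$ draws its folds from a named substream of the seed, so
replicate sets are reproducible independently of how many replicates are
requested. The calibration the standardization is meant to deliver —
that $r_{GS}$ estimates the correlation between predictions and true
genotypic values — is checked on simulated panels where the truth is known
(agreement within 0.05 at the package's reference conditions: 235 lines,
2000 markers, $H^2 = 0.63$, 200 QTL).

`cv_subpop_contrast()` contrasts accuracy within one subpopulation against a
size-matched random subset of the whole panel, re-drawn every replicate (the
re-draw averages away subset luck; drawing once would confound the contrast
with one arbitrary subset). The percent decrease
$100\,(r_{full} - r_{group})/r_{full}$ is positive when trait variance rides
on ecotype-differentiated loci — the mixed panel then predicts a
between-group component that within-group validation cannot use — and can
legitimately be negative for architectures shared across groups.

## Linkage disequilibrium and Gabriel blocks

The panel is inbred, so each line is treated as one haplotype (no EM
phasing; residual heterozygous calls are dropped pairwise with a warning).
For a marker pair, $r^2$ is the squared Pearson correlation of allele
vectors and $D' = |D|/D_{max}$ comes from the 2x2 haplotype table. The LD
decay curve is a local linear regression (tricube weights, span 0.3 by
default) of $r^2$ on physical distance, evaluated on a log-spaced grid and
clipped to $[0,1]$; the distance at which the fitted curve first drops below
$r^2 = 0.1$ summarizes the decay scale.

Block calling follows the Gabriel confidence-interval method as implemented
in Haploview 4.2: the likelihood of the four haplotype counts is evaluated
on a $|D'|$ grid of step 0.001 with allele frequencies fixed at their
observed values, normalized, and read off at cumulative mass 0.05 and 0.95
(a one-sided 90% interval). A pair is *strong LD* when the bounds reach
(0.70, 0.98), *strong recombination* when the upper bound is below 0.90,
otherwise uninformative; a candidate interval is a block when its outermost
pair is strong LD and at least 95% of its informative pairs are strong;
pairs with a marker under 5% MAF are excluded, candidates are capped at a
500 kb span, and non-overlapping blocks are kept greedily from the widest
span down. These thresholds are the published defaults; they are exposed in
`gabriel_params()` rather than hard-coded because the exact values the
original analysis ran with are not recorded. The caller is validated against
planted truth from the simulator, not against byte-compatibility with any
particular implementation; the planted-block experiments show one
systematic, definitional miss: a pair whose allele frequencies are strongly
opposed (e.g. 0.18 vs 0.82) has a tiny $D_{max}$, hence a wide CI even when
$D' = 1$ exactly, so a true block whose outermost pair is frequency-opposed
can be split. About 4% of planted blocks are affected at $n = 200$; the
recovery tests therefore require at least 80% of planted blocks per
simulation recovered to within one marker at both ends.

## Marker preselection

Three strategies produce subsets for the CV engine.

* **RSM** (random): sizes at 5%, 10%, ..., 100% of the panel (20 levels,
  `rsm_grid()`); a fresh uniform draw per replicate.
* **HBA** (haplotype-block-based): the pool is one randomly chosen SNP per
  block plus every non-block SNP (`hba_pool()`); sizes descend from the full
  pool in 20 equal steps of `round(|pool|/20)` — for a pool of 3554 markers
  this is the ladder 172, 350, ..., 3554 in steps of 178. The block
  representative is fixed per run by default (a per-replicate re-draw is a
  documented option); fixing it isolates the subset-size effect from
  representative churn.
* **ESM** (evenly spaced): deterministic; the subset size is allocated to
  chromosomes proportionally to marker counts (largest-remainder rounding),
  and within a chromosome markers nearest to the targets $(j - 0.5)/k$ of
  the chromosome span are taken, ties to the lower index. Even spacing in
  base pairs honors the positional intent; index-even spacing is the
  fallback when no map exists.

`density_sweep()` runs the full scheme-by-size grid. Two behavioral facts
are worth knowing before interpreting such sweeps. First, accuracy rises
steeply with subset size only up to a plateau (on the package's simulated
panels, roughly 40% density); past it, differences between sizes fall below
Monte-Carlo resolution, so monotonicity checks are run on the rising part of
the grid. Second, block de-duplication is *not* automatically an advantage
at a matched subset size: if causal variants are proportional to marker
count inside blocks, random sampling's over-investment in blocks is actually
efficient. The HBA advantage materializes when blocks are redundant
ascertainment of single loci — the regime the redundant-panel test
constructs (blocks of ten near-duplicate SNPs, causal loci drawn per locus,
not per marker).

## The synthetic panel generator

`simulate_genotypes()` builds inbred lines as recombinant mosaics of a
subpopulation-specific ancestral haplotype pool. Recombination happens only
at hotspot positions (Poisson along the chromosome, or fixed positions for
planted-truth experiments), so hotspot-delimited segments are the ground
truth against which the block caller is validated. Within a segment the
pool haplotypes are *comonotone*: haplotype $h$ carries the minor allele at
marker $j$ iff its segment score $u_h$ falls below the marker frequency
$f_j$. Nested allele sets give $|D'| = 1$ within segments in the
infinite-pool limit, which is precisely the block structure the Gabriel
method is designed to detect; a per-SNP copy-error probability (default 1%)
roughens this ideal. Subpopulation allele frequencies drift from common
ancestral frequencies by Balding-Nichols Beta sampling with parameter
$F_{st}$ — a one-parameter control of how far apart the ecotypes sit on PC1.
A mosaic-copying design was chosen over a coalescent simulator deliberately:
it is fast, dependency-free, and gives direct control over block boundaries,
which is what the validation needs. The cost is realism — no mutation-drift
equilibrium, no allele-frequency spectrum matching, no background LD between
segments — so passing block-recovery tests says the caller finds
hotspot-delimited structure, not that it reproduces any particular
organism's LD landscape.

`simulate_phenotypes()` inverts the phenotypic model: additive QTL effects
on genotyped SNPs (hidden-QTL robustness experiments are possible by
simulating a denser panel and passing a thinned copy to the analysis while
keeping the full matrix for the phenotype step), genetic values rescaled to
exactly
$\sigma^2_G$, location effects $N(0, \sigma^2_L)$, and entry-mean residuals
with $\sigma^2_e = \sigma^2_G\, l\, (1 - h^2)/h^2$ so that the entry-mean
heritability equals the target by construction. Default conditions mirror
the motivating panel: 235 lines split 185/50, $F_{st} = 0.1$, 23 locations,
target heritabilities 0.96 (plant-height-like) and 0.63 (yield-like),
location variance twice the genetic variance. All randomness flows from a
master seed through named substreams (genotypes, effects, locations,
residuals, CV replicates), so any stage can be regenerated independently and
the same seed is bit-reproducible.

## Problem sizes and reproducibility

The packaged experiments are scaled to desk hardware: panels of 150–235
lines with 300–2000 markers, 40–100 CV replicates, heritability-recovery
runs of 50 simulations. These sizes were chosen so the reference quantities
stabilize (Monte-Carlo SEs an order below the tolerances being checked)
while a full run of the suite plus the acceptance script stays within a few
minutes. `run_pipeline()` stitches the stages together from a YAML or list
config and writes a machine-readable `results.json`; re-running the same
config yields byte-identical artifacts, which the tests assert file by
file.

## Known limitations

* No genotype-by-location interaction, dominance or epistasis — by design,
  matching the entry-mean model.
* Mean imputation is the only missing-genotype method; it is deterministic
  and adequate for RR-BLUP but attenuates LD slightly at high missingness.
* MAF and PIC are computed on non-missing calls before imputation (whether
  the original analysis did so before or after is not recorded; before is
  the defensible choice since imputation re-uses the same frequencies).
* The Gabriel caller is validated against planted truth, not against any
  reference implementation's byte-level output; span-rule nuances of
  historical implementations (e.g. distance-dependent minimum informative
  counts) are subsumed into the 95% informative-fraction rule.
* The within-subpopulation accuracy contrast depends strongly on whether
  trait architecture is ecotype-differentiated; its sign is not a package
  invariant.
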