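---
title: "Statistical methods behind postgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind postgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postgwas)
```

# Scope

`postgwas` implements the statistical stages that follow a genome-wide
association scan of quantitative (or binary) traits: summary-statistic QC and
threshold bookkeeping, locus definition, approximate conditional analysis
against an LD reference panel, single-causal-variant Bayesian fine-mapping,
and two-trait colocalisation. Association testing itself (mixed models,
relatedness control) and heritability machinery are out of scope: the package
consumes per-variant marginal summaries (`beta`, `se`, `p`, `n`, `eaf`,
`info`) and a reference dosage matrix.

# Summary-statistic model and QC

Each variant carries a marginal additive effect $\beta_j$ with sampling
variance $V_j = se_j^2$; for case-control traits $\beta_j$ is a log odds
ratio. Records are validated on ingestion: `se > 0`, `eaf` in $[0,1]$, `p`
in $(0,1]$, and the stored p must agree with the two-sided normal p of
$\beta_j/se_j$ to $10^{-6}$ relative tolerance on the z-score (the tolerance
is floored at $|z| = 1$ so near-null records with heavily rounded p-values are
not rejected). This catches column mix-ups — the most common defect in
deposited files — without rejecting legitimately rounded data.

Default variant QC retains MAF $\ge 1\%$ and imputation quality $\ge 0.9$,
both boundaries inclusive for "pass" (the convention is *excluding* variants
*below* the cutoffs, so a variant at exactly 1% MAF survives). The MHC
(GRCh37 chr6:28,477,797–33,448,354, closed interval, 1-based) is masked by
default before locus work because its LD structure defeats both the
conditional analysis and the single-causal fine-mapping model.

The genomic-control statistic is
$\lambda_{GC} = \mathrm{median}\{(\beta_j/se_j)^2\} / 0.4549364$, using the
exact $\chi^2_1$ median rather than the rounded 0.456. It must be computed on
an LD-pruned variant set; the package deliberately leaves pruning to the
caller because pruning radius and panel are analysis decisions. Note the
sampling noise of a median: on $10^4$ independent null variants
$\mathrm{sd}(\lambda_{GC}) \approx 0.023$, so individual null scans routinely
fall outside $[0.97, 1.03]$; calibration claims should be made on the median
across scans (as `calibrate_null_gwas()` reports).

Bonferroni ledgers (`bonferroni_threshold()`) record $\alpha$, the test
count, and $\alpha/m$. The print method truncates the mantissa to three
significant figures instead of rounding: a printed threshold should never be
looser than the exact one, so `5e-8 / 11` prints as `4.54e-09`.

# LD panels, pruning, subsampling

The reference panel is a samples-by-variants dosage matrix (dosages rather
than hard calls, so imputed panels work unchanged). LD is the Pearson
correlation of dosage columns with pairwise-complete handling of missing
entries. Pruning is greedy keep-first in genomic order with a 1 Mb sliding
window, dropping a variant when $r^2 \ge r^2_{max}$ (default 0.8, i.e. the
"retain $r^2 < 0.8$" convention) with any retained variant. Greedy positional
scanning was chosen over MAF- or p-ordered scanning because it is
deterministic, order-reproducible, and matches common practice; the window
and ordering are parameters for users who prefer otherwise.

# Locus definition and approximate conditional analysis

Loci are built by repeatedly taking the smallest-p unassigned variant below
the threshold as an index and claiming everything within 500 kb; overlapping
windows merge transitively and the merged locus keeps the smallest-p index.
Merging prevents double-counting when two indexes tag one extended signal.

Within a locus, conditionally independent signals are found by forward
stepwise selection on joint fits reconstructed from summary data, the
standard summary-data conditional/joint construction: with per-variant
diagonal $D_j = 2 f_j (1-f_j)\, n$ and panel correlations $r_{jk}$,

$$X'X_{jk} = r_{jk}\sqrt{D_j D_k}, \qquad X'y_j = D_j \hat\beta_j,$$

joint estimates $b = (X'X)^{-1} X'y$ and standard errors from the residual
variance $(y'y - b'X'y)/(n - k - 1)$, where $y'y$ comes from the sdY relation
(below) for quantitative traits and is fixed at $n-1$ on the log-odds scale
for case-control traits. A candidate joins the model when its conditional p
is the smallest and below $10^{-8}$ and its $r^2$ with every selected variant
is below 0.9 (collinearity guard); variants whose summary and panel allele
frequencies differ by more than 0.2 are excluded up front as likely
mismatches. A final backward sweep enforces that every *reported* signal has
joint $p < 10^{-8}$ in the final model. With `var_from_panel = TRUE` the
diagonal uses empirical dosage variances instead of $2f(1-f)$; when the panel
is the association sample itself this makes the reconstruction algebraically
identical to `lm()` on raw genotypes (the package's oracle test), while the
Hardy–Weinberg form is the right default when the panel is external.
Numerical guards: joint LD matrices with reciprocal condition number below
$10^{-12}$ cause the candidate to be skipped with a log entry rather than
producing an unstable fit.

Nearest-gene annotation minimises the distance to the transcription start
site (strand-aware) on the lead's chromosome, reports distance 0 inside a
gene body, and breaks exact ties by smaller TSS then name — an arbitrary but
deterministic rule.

# Fine-mapping: Wakefield ABF with a null weight

For each variant the natural-log approximate Bayes factor under a
single-causal-variant model with normal effect prior $N(0, \omega)$ is

$$\Lambda_j = \tfrac12 \ln\frac{V_j}{V_j+\omega}
  + \frac{\omega\,\hat\beta_j^2}{2 V_j (V_j+\omega)}.$$

The prior variance follows the usual conventions: $\omega = 0.2^2$ on the
log-odds scale for case-control traits and $\omega = (0.15\,\sigma)^2$ for
quantitative traits, with the phenotype SD $\sigma$ recovered from the
summary statistics themselves by regressing $2 n_j f_j (1-f_j)$ on $1/V_j$
through the origin and taking the square root of the slope ($f_j$ is the
MAF). This inversion is exact when every variant's $V_j$ obeys the simple
regression relation and degrades gracefully under noise; a non-positive slope
signals inconsistent inputs and raises an error rather than a silent NaN.

Posteriors allow for no association in the region: with $l$ variants and a
null prior weight $\gamma$ (default 0.05, matching the expected false
discovery rate of loci discovered at $5\times10^{-8}$), the null
configuration gets unnormalised weight $\gamma$ (its Bayes factor is 1) and
each variant $\frac{1-\gamma}{l} e^{\Lambda_j}$; normalisation uses
log-sum-exp. The per-variant prior is uniform across the region — nothing in
the region's annotation justifies anything else at this level.

Credible sets sort variants by decreasing $\Lambda$ (ties: decreasing
$|\beta|/\sqrt V$, then position) and accumulate the *renormalised* masses
$\pi_j / (1 - \pi_0)$ until the running sum reaches $c = 0.95$. Two design
choices deserve note. First, sorting decreasing: accumulating from the
largest Bayes factors is the only direction under which the set is the
smallest one carrying $c$ of the mass. Second, renormalising over variants
before accumulation: this decouples set membership from $\gamma$ entirely
(the $\gamma$-dependent factor cancels in the ratio), guarantees a $c$-level
set exists even when $\pi_0 > 1 - c$, and leaves $\pi_0$ as a separately
reported gate for callers who want to suppress fine-mapping of weak regions.
Both choices are recorded in the JSON sidecar written next to every
fine-mapping output.

A consequence of the "accumulate until $\ge c$" rule worth stating plainly:
the set's realised mass overshoots $c$ by the boundary variant's mass, so
under a correctly specified generative model the frequentist coverage of the
set equals the *expected stopping mass*, which is above $c$ whenever
posteriors are concentrated. `calibrate_credible_sets()` measures this: at a
causal median $\chi^2$ of 30 over 50 LD-free variants the sets are often
singletons and empirical coverage sits near 0.98 rather than 0.95. That is a
property of every prefix-rule credible set, not an implementation artefact;
coverage can only be *at least* nominal.

# Colocalisation

For two traits over a shared region the five-configuration enumeration
(no association; trait 1 only; trait 2 only; distinct causal variants;
shared causal variant) uses per-variant log-ABFs per trait and per-variant
priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ (the conventional defaults,
configurable). All sums run in log space; the distinct-variant sum excludes
same-variant pairs, by direct enumeration of the $l^2$ ordered pairs for
$l \le 200$ and by log-space subtraction of the diagonal otherwise — the
enumeration guard exists because subtraction of nearly equal log-sums is
catastrophically cancellable exactly when one variant dominates both traits.
Harmonisation intersects on position, flips $\beta$ and complements `eaf`
when ref/alt are swapped between files, and drops strand-ambiguous (A/T,
C/G) variants with `eaf` in $[0.4, 0.6]$, where frequency cannot resolve
strand.

The decision rule declares strong colocalisation when
$PP_3 + PP_4 \ge 0.99$ and $PP_4 / PP_3 \ge 5$ ($PP_3 = 0$ counts as
satisfied). The mirrored `distinct` label (same sum, $PP_3/PP_4 \ge 5$) is a
reporting convenience of this package, flagged as such; everything else is
`inconclusive`.

# The synthetic GWAS generator

Every stage is testable without any genotype download because the generator
produces the structures the models assume. Genotypes come from a Gaussian
copula: per haplotype and per block, a latent AR(1) series with neighbour
correlation $\rho$ is thresholded at the MAF quantile and two haplotypes are
summed. This gives seed-stable, analytically checkable LD (the implied
genotype correlation of a pair is a bivariate-normal orthant probability, an
oracle the tests use) at a fraction of the cost of coalescent simulation —
the pipeline needs controlled LD, not population-genetic realism. Blocks
with $\rho = 0$ draw dosages directly as Binomial(2, maf); the draw order
(MAF spectrum from the config seed; then per block, two latent haplotype
matrices, column-major) is fixed and documented so identical seeds give
bit-identical panels across platforms.

Traits are additive with standardised causal genotypes and
$N(0, 1-h^2)$ noise, so trait variance is ~1; binary traits threshold the
liability at $\Phi^{-1}(1-\text{prevalence})$. Summary statistics are
vectorised per-variant OLS with two-sided normal p-values (so stored p and
$\beta/se$ are exactly consistent at any n); a logistic mode exists for
binary traits when log-odds fidelity matters more than speed. Monomorphic
realisations are emitted flagged (`info = 0`) so default QC removes them.

What the generator does *not* emulate: relatedness and population structure
(handled upstream by mixed models, out of scope), imputation error beyond
the `info` field, allele-frequency spectra with rare-variant mass, and
realistic recombination maps. Passing calibration here therefore validates
the statistical machinery under its own assumptions, not robustness to those
real-data complications.

## Study conditions used by the calibration experiments

The `calibrate_*` functions fix the simulation conditions once:

* credible-set calibration: 50 LD-free variants, causal index uniform,
  effect from the analysis prior, causal median $\chi^2 = 30$, 2,000
  replicates;
* signal recovery: $n = 5{,}000$, 100-variant loci, AR(1) $\rho = 0.9$
  blocks, 2 kb variant spacing, 1% variance explained per causal variant,
  200 replicates; recovery requires each causal tagged by a distinct signal
  at panel $r^2 \ge 0.8$;
* colocalisation: paired 5,000-sample studies, 200-variant regions in
  $\rho = 0.9$ blocks of 50, 1% variance explained, 200 replicates;
* null calibration: 50 scans of 10,000 independent variants at
  $n = 5{,}000$;
* sdY recovery: $n = 10{,}000$, 500 variants.

With 1% variance explained at $n = 5{,}000$ the causal joint z-statistic is
roughly $N(7.1, 1)$, so the probability of clearing the $10^{-8}$ joint
threshold is about 0.92 per causal variant (about 0.85 for both of two) —
recovery rates at these conditions measure statistical power at the stated
threshold, not implementation quality, and sit in that range by construction.

`scripts/acceptance.R` re-runs these experiments end to end from a single
command-line seed and writes the resulting quantities as JSON; it uses
smaller replicate counts (recorded in each entry's `n` field) than the test
suite, which runs the full counts above.

# Known limitations

* Single-causal-variant fine-mapping only; regions with multiple causal
  variants in LD should be conditioned first (the stepwise module exists for
  exactly that), and the MHC should stay masked.
* The conditional-analysis reconstruction assumes the panel LD matches the
  association sample; the 0.2 allele-frequency mismatch guard is a coarse
  defence, not a substitute for ancestry matching.
* Case-control traits are handled throughout on the log-odds scale with
  phenotypic variance fixed at 1; rare-disease, extreme-ascertainment
  designs may violate this.
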