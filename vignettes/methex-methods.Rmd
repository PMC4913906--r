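---
title: "Methods and design of the methex mQTL pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the methex mQTL pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methex)
```

# Scope

methex implements a complete methylation-QTL analysis for population
cohorts profiled on SNP arrays and CpG methylation arrays: cis/trans
association scanning with covariate adjustment, an LD-aware modified
Bonferroni correction, eQTL follow-up of significant mQTL SNPs,
SNP-phenotype association with sign-concordant external replication, a
four-condition causal inference test (CIT) over
genotype-methylation-phenotype triples, and genomic-context enrichment of
significant CpGs. A synthetic cohort generator reproduces the statistical
structure these analyses assume, so the whole chain is testable without
access to individual-level human data.

# The association model

Every scan fits, per SNP-feature pair, ordinary least squares of the
response (CpG M-value, transcript expression, or metabolic trait) on an
intercept, the additive minor-allele dosage (0/1/2), and covariates:

$$y_i = \beta_0 + \beta_g g_i + \mathbf{c}_i^\top \gamma + \varepsilon_i$$

with a two-sided t test on $\beta_g$ at $df = n - k - 2$, where $k$ counts
covariate columns after reference-coding categorical covariates
(sub-cohort). Methylation and expression scans adjust for age, BMI and
sub-cohort; phenotype scans adjust for age and sub-cohort, adding BMI only
for the glycaemic traits (fasting glucose, fasting insulin, HOMA-IR,
HOMA-B, HbA1c) and never when BMI or WHR is the response. Fasting insulin,
HOMA-B and HOMA-IR are natural-log transformed before analysis.

Genome-wide scanning uses the residualize-then-correlate formulation
popularized by matrix-based eQTL software: response and dosage matrices
are projected onto the orthogonal complement of the covariate design, and
per-pair correlations of residuals are converted to t statistics. By the
Frisch–Waugh–Lovell theorem this is algebraically identical to the
per-pair fit; the suite asserts agreement to $|\Delta t| < 10^{-8}$ for
arbitrary covariate sets, and the trans scan streams SNP chunks so the
full cross never needs to be materialized. Missing dosages are mean-imputed
per SNP (the common fast-scan behaviour, and the choice that keeps the
matrix and per-pair routes exactly equivalent); samples missing a response
or covariate are dropped. Chromosomes X and Y are scanned like autosomes.

**cis/trans.** A pair is cis when SNP and CpG share a chromosome and lie
within 500 kb (inclusive boundary); everything else, including
same-chromosome pairs beyond the window, is trans. Pair totals are kept as
doubles because genome-wide products (hundreds of billions) exceed R's
integer range; they remain exact below $2^{53}$.

# LD-aware multiple-testing correction

Bonferroni correction over all pairs would ignore linkage disequilibrium
between SNPs tested against the same CpG. The correction value is instead
a count of LD-pruned tests. Pruning is greedy pairwise tagging: SNPs are
visited in (chromosome, position, id) order and a SNP joins the tag set
unless an already-chosen tag within the pairwise window has dosage
$r^2 \ge 0.9$ with it. Then

* **cis**: for each CpG, the SNPs within 500 kb are pruned and counted;
  the correction value is the sum over CpGs (a cluster shared by several
  CpGs counts once per CpG).
* **trans**: analyzed CpGs × genome-wide tag count, minus the cis value.
* **eQTL follow-up**: per-transcript tag sums within 500 kb of the gene
  span (cis), or pruned significant-SNP count × transcript count (trans).

Significance is declared at strict $p < \alpha / \text{correction value}$
with $\alpha = 0.05$. Design choices that were genuinely open: the greedy
sweep order (position, ties by id) is a documented convention — tag
*counts*, not identities, drive the thresholds; the pairwise window for the
genome-wide tag set defaults to the cis window (500 kb) and is
configurable; $r^2$ is the squared Pearson correlation of unphased dosages
on pairwise-complete observations (composite LD), with zero-variance pairs
excluded from tagging decisions rather than treated as linked.

# Causal inference test

For a triple (G, M, P) the forward test asks whether methylation mediates
the genotype-phenotype association. Four conditions must all hold: (1) G
associated with M; (2) G associated with P; (3) G associated with M given
P; (4) G independent of P given M. Conditions 1–3 are nested-model F
tests; the omnibus causal p-value is the maximum of the four components
(an intersection–union test), so causality requires every condition.

Condition 4 must *reject* towards independence, so it is an equivalence
test and needs a reference distribution representing the no-mediation
alternative. We build surrogate genotypes
$G^* = \widehat{G}(P, C) + \text{permuted residuals}$: each surrogate
preserves the observed marginal G–P association but is conditionally
independent of M given P. The F statistic for adding $G^*$ to
$P \sim M + C$ is therefore large whenever a *direct* effect of the
observed strength would survive conditioning on M, and

$$p_4 = \frac{1}{B}\#\{F^*_b < F_{\text{obs}}\}$$

is near zero under complete mediation (the observed conditional F is
null-like while $F^*$ is large) and non-small when G really does act on P
directly. $B = 1000$ by default; a seed is required and $p_4$ is
reproducible bit-for-bit. An earlier candidate scheme — permuting residuals
of G given M, re-attached to the fitted values — was rejected during
design: it makes the observed and permuted statistics exchangeable under
the mediation null, so $p_4$ would be uniform there and the test would
have no power against the hypothesis it is supposed to support.

**Classification.** The omnibus runs in both directions: forward (M
mediates G→P) and reverse (P mediates G→M). A triple is *causal* when only
the forward omnibus is below $\alpha = 0.05$, *reactive* when only the
reverse is, *ambiguous* when both are, *independent* otherwise. Under pure
pleiotropy (G affects M and P separately) conditioning on a G-correlated
mediator attenuates the conditional F below the direct-effect reference in
both directions, so such triples land in *ambiguous* — the dual-direction
rule, not forward $p_4$ alone, is what keeps the causal call rate near
zero there (verified by simulation: ≤ 10% causal calls over 100 seeds).
No multiple-testing correction is applied to the omnibus p-values; records
report nominal values. CIT covariates follow the phenotype association
rule (age + sub-cohort, BMI for glycaemic traits).

# Preprocessing

* **Genotype QC**, in fixed order with first-rule-wins bookkeeping so the
  report reconciles exactly: missingness > 5%, then Hardy–Weinberg
  $p < 10^{-3}$ (plain 1-df chi-squared against expected counts from the
  observed allele frequency — no continuity correction or exact test,
  matching the array era's default and keeping a closed-form oracle; a
  monomorphic marker returns p = 1 by convention), then recomputed
  MAF < 0.05 (strict). An optional sample call-rate pre-filter (≥ 98%)
  uses the same report machinery.
* **Probe QC**: mean detection p > 0.01, then non-CpG probes
  ("ch."-prefixed), then SNP probes ("rs"-prefixed).
* **Intensity → M**: $M = \log_2\frac{\max(meth,0)+1}{\max(unmeth,0)+1}$.
  The published formula typesets ambiguously; this standard reading (with
  +1 floors making the transform total on background-subtracted
  intensities) is assumed and documented here.
* **Quantile normalization** forces every column onto the mean of the
  order statistics, averaging target values across ties — deterministic and
  idempotent.
* **Batch adjustment** is a per-feature location-scale match (each batch
  shifted/scaled to the pooled mean and SD). Empirical-Bayes shrinkage
  across features, as in COMBAT, is deliberately out of scope: the
  shrinkage is orthogonal to the statistical claims downstream, and the
  simple adjuster is dependency-free and exactly testable by its moment
  contract. It runs between QC and scanning, as batch correction does in
  array pipelines.

# Downstream bookkeeping

**Replication filter.** Internal SNP-trait associations (p < 0.05) are
looked up in an external summary-statistics table; the external sign is
harmonized to the internal effect (minor) allele, flipping when the source
reported the other allele. Replication requires internal p < 0.05,
external p < 0.05, and concordant sign (all strict). Strand-ambiguous
(A/T, C/G) SNPs are flagged but retained, since array-era lookups did not
consistently resolve them; harmonization is an involution, so the filter
is insensitive to which allele a source reports.

**Enrichment.** Significant CpGs are compared against all analyzed CpGs
per chromosome, gene region and island relation with 1-df Pearson
chi-squared tests on the 2×2 (in/out of category × significant/background)
table, substituting Fisher's exact test when any expected cell is below 5.
Multi-valued region annotations ("Body;TSS1500") contribute one count to
each distinct listed region. No correction across categories by default
(per-category significance is reported), with an optional BH column. The
distance over-representation test for significant cis pairs is a one-sided
Mann–Whitney test (significant distances stochastically smaller) — the
original analysis does not name its test, so this documented choice favours
a rank test robust to the skew of distance distributions.

**Catalog overlap.** Query SNPs are expanded to LD proxies
($r^2 > 0.8$, strict, within 500 kb) computed from the cohort's own
genotypes — a documented substitution for an external reference panel
lookup with the same parameters — and matched to catalog entries by SNP id.
Percentages are reported against the unique query and unique catalog SNP
counts.

# The synthetic cohort generator

The generator emulates exactly the structure the analyses consume:

* **Genotypes**: per-block latent-variant copying. Each block draws a MAF
  from (0.1, 0.5); per haplotype, a latent allele is copied by each SNP
  with probability $\sqrt{r}$ and redrawn otherwise, giving dosage
  correlation $r$ between any two SNPs of a block, Hardy–Weinberg
  equilibrium marginally, and independence across blocks. Only pairwise
  $r^2$ structure matters to the pipeline, so a coalescent simulator would
  add realism the downstream code cannot see. Positions are laid
  deterministically on the 22 autosomes with fixed 2 kb spacing (CpGs
  interleaved with an offset that keeps unplanted SNP-CpG distances away
  from 0/1), so cis/trans relationships are controlled by index arithmetic
  and planted "cis" pairs really are cis.
* **Methylation**: per-CpG baseline + planted additive dosage effects +
  age/BMI confounding + batch shift + Gaussian noise, on the M scale. A
  consistent intensity pair (unmethylated channel fixed at 1000, methylated
  back-solved as $\mathrm{round}(2^M(U+1)-1)$) makes the intensity-to-M
  transform exercisable and invertible on fixtures. Declared CpG-SNPs are
  co-located with their CpG and given a strong negative per-allele effect.
* **Phenotypes**: traits drawn around plausible adult reference values
  (log-normal for the strictly positive log-analyzed traits), with
  mediation triples rebuilt per model — causal ($P = \beta_{mp} M + \varepsilon$
  with M carrying the planted G effect), independent
  ($P = \beta_{gp} G + \varepsilon$, no M→P path), reactive (P from G, then
  the CpG overwritten as $\beta M + \varepsilon$ downstream of P).
* **External tables**: a summary-statistics table with true total-effect
  signs at small p for triple SNPs (plus random filler), and a
  catalog-style table of SNP/trait/p rows.

Each layer draws from its own sub-seed (master + small offset), so
re-generating one layer never perturbs another and everything is
reproducible end to end. Default desk scale is 200 samples, 5,000 SNPs,
2,000 CpGs, 500 transcripts (seed 20160620), which runs the full stage
chain in minutes; tests use smaller cohorts sized so each property is
measured in seconds.

What the generator does *not* emulate — and hence what green tests do not
show about real data: the bimodal beta-value distribution of real arrays,
cell-type composition, fine-scale LD decay and recombination hotspots,
population stratification, and probe cross-reactivity. Results on real
cohorts additionally depend on those, and on QC choices upstream of this
package.

# Numerical choices and degenerate inputs

* Output TSVs render doubles with 17 significant digits: write→read is the
  identity and repeated writes are byte-identical, which is what makes the
  end-to-end determinism contract (identical manifest ⇒ identical bytes)
  checkable.
* Zero-variance dosages yield flagged records (`zero_variance`) rather
  than errors in per-pair fits, and $r = 0$ exclusions in LD code.
* Correlations are clamped to $[-1, 1]$ before the t transform;
  $1 - r^2$ is floored at machine epsilon.
* Monomorphic markers: HWE p = 1; MAF undefined → removed by the MAF rule.
* Empty significant sets propagate as flagged summaries (distance
  analysis) or empty-but-typed record tables, never as errors.
* Quantile-normalization ties average the target values over tied ranks.

# Known limitations

* The location-scale batch adjuster does not pool information across
  features; with very few samples per batch it is noisier than
  empirical-Bayes alternatives.
* The CIT considers one SNP and one CpG at a time; multi-SNP or multi-CpG
  mediation is out of scope.
* Proxy LD from the cohort's own genotypes understates coverage relative
  to a large external reference panel at the same $r^2$ threshold.
* The permutation scheme for CIT condition 4 is a documented construction
  validated by simulation, not a claim of bit-compatibility with any
  particular historical implementation.
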