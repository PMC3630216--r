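---
title: "Case-only germline–somatic signature association: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-only germline–somatic signature association: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutsigscan)
```

## The design

Gastrointestinal stromal tumors are almost always driven by a somatic
mutation in *KIT* or *PDGFRA*, and the mutation class is clinically and
biologically meaningful: a deletion of *KIT* exon 11 codons 557–558 is a
different tumor phenotype from a *PDGFRA* exon 18 point mutation or a
wild-type tumor.  A case-only design treats these classes as mutational
signatures and asks whether inherited germline variation shifts the odds
of one signature relative to the rest.  There is no unaffected control
group: for each of seven mutually exclusive categories, the "cases" are
tumors in that category and the "referents" are all other tumors.

The seven categories, in fixed order, are: (i) *KIT* exon 11 deletions
whose codon span covers both 557 and 558, (ii) other *KIT* exon 11
deletions, (iii) *KIT* exon 11 insertions, (iv) *KIT* exon 11 point
mutations, (v) *KIT* exon 9/13/14/17 mutations of any type, (vi) *PDGFRA*
exon 12/18 mutations, (vii) wild type.  Non-exon-11 *KIT* mutations are
pooled because each exon alone is too rare to support a separate
dichotomy.  Two classification choices were genuinely open and are fixed
here as conventions:

* **Span-covers rule.**  A deletion spanning 557–558 *plus further
  codons* counts as category (i).  The alternative (exact-span matching)
  would push biologically equivalent super-spans into category (ii); the
  covering rule keeps the signature definition monotone in the span.
* **Exon 17.**  Category (v) admits *KIT* exon 17 even though such
  tumors may be absent from any given cohort; the classifier should be
  total on the record grammar rather than reject a grammatically valid
  exon.

## Quality control

Sample rules run first, in a fixed order so exclusions are attributable:
subjects with no somatic mutation record, then subjects with strictly
more than 10% missing genotype calls (a subject at exactly 10% is kept).
Variant rules run on the retained cohort after minor-allele orientation:
(1) mono-allelic, (2) MAF strictly below 5%, (3) poor array clustering,
(4) no minor-allele homozygote at some outcome level.  Each excluded
variant is attributed to the *first* rule it violates, which makes the
cascade's counts deterministic and conserving (excluded-per-rule plus
retained always equals the input).

Three conventions deserve note:

* **MAF denominators** exclude missing calls; allele frequencies are
  computed over non-missing calls of the analysis cohort.  A frequency
  tie at exactly 0.5 is broken lexicographically (the alphabetically
  first allele becomes "minor"), which makes orientation idempotent.
* **Poor clustering** is an array-intensity property that cannot be
  recomputed from dosages, so it is consumed as a boolean flag carried in
  the variant metadata.
* **The homozygote rule** is stated loosely in common usage ("no
  individuals homozygous for the minor allele at some levels of the
  outcome").  The default operationalization here excludes a variant
  when, for at least one of the seven dichotomies, either the case or the
  referent side contains zero minor-allele homozygotes.  This is
  configurable (`homozygote_rule = "none"` disables it) and the report
  records which rule fired, because on small cohorts the default rule is
  aggressive: with a 19-subject category and MAF 0.3, a variant has a
  ~17% chance of lacking a homozygote on the case side by chance alone.
  Analysts with small outcome strata should inspect the attribution
  table before accepting the default.

Binary "null genotype" assays (GSTM1/GSTT1 gene deletions detected by
absence of a PCR product) cannot distinguish one- from two-copy
carriers.  They are represented as pseudo-variants with dosage ∈ {0, 1},
1 marking the null genotype; their "MAF" is the null-genotype frequency
and the per-allele OR reduces to a carrier contrast.  In the
identity-by-state kernel they enter through the same 2 − |a − b| formula
for uniformity.

## Per-variant screening

For variant *g* and dichotomy *k*, the model is a maximum-likelihood
logistic regression

$$\operatorname{logit} P(y_i = 1) = \beta_0 + \beta_1 d_i +
\beta_2\,\text{race}_i + \beta_3\,\text{sex}_i + \beta_4\,\text{age}_i,$$

with $d_i \in \{0, 1, 2\}$ the minor-allele dosage.  $\exp(\beta_1)$ is
the per-allele odds ratio; the 1-df Wald test on $\beta_1$ is the trend
test; the interval is Wald ($\exp(\beta_1 \pm 1.96\,\mathrm{se})$), so CI
exclusion of 1 and p < 0.05 coincide exactly.  Age enters in years,
untransformed.  Fits are complete-case per variant: a missing dosage
drops a subject for that variant only.  Convergence uses a relative
log-likelihood tolerance of 1e-8 with a 100-iteration cap.
Quasi-complete separation is detected (boundary fitted probabilities)
and reported as a status with no estimate — a penalized fit would
silently change the estimand, which is worse than an honest flag.

Multiple testing is controlled by Benjamini–Hochberg step-up at
`fdr_q` (default 0.25, with 0.50 equally supported).  The default family
is *per outcome* — seven families of one-test-per-retained-variant —
matching how case-only results are read (one signature at a time); a
single pooled family is available via `family = "pooled"` since the
choice is not forced by theory.

## The gene-level kernel test

Variants are grouped by gene and tested jointly with a logistic
kernel-machine score test.  The model adds a subject-specific random
effect $h_i = h(z_{i1}, \dots, z_{ip})$ generated by a positive
semi-definite kernel, with variance component $\tau$; the null
$H_0\!: \tau = 0$ is tested by the score statistic

$$Q = (y - \hat\mu)^\top K (y - \hat\mu),$$

where $\hat\mu$ are the fitted probabilities of the covariate-only null
model.  $\tau$ is tested, never estimated.  The kernel is
identity-by-state,

$$K_{ij} = \frac{1}{2p} \sum_{s=1}^{p} \big(2 - |g_{is} - g_{js}|\big),$$

i.e. the number of alleles shared in state, normalized so
$K_{ii} = 1$ without missingness.  IBS makes no linearity assumption and
retains power under epistasis, which motivates it over the linear kernel
(also provided).  Missing dosages are mean-imputed per variant *for the
kernel only* — this keeps $K$ positive semi-definite and the subject set
fixed across genes, at the price of a mild attenuation; the per-variant
screen stays complete-case, and the divergence is deliberate.

Under $H_0$, $Q$ is approximately a mixture of chi-squares.  With
$V = \operatorname{diag}(\hat\mu_i(1 - \hat\mu_i))$ and the projection
$P_0 = V - VX(X^\top V X)^{-1} X^\top V$ (which annihilates the design
columns — verified numerically at 1e-6), the exact first two moments are

$$E[Q] = \operatorname{tr}(P_0 K), \qquad
\operatorname{Var}[Q] = 2\operatorname{tr}(P_0 K P_0 K),$$

and the default p-value matches them to a scaled chi-square
(Satterthwaite): $\kappa = \operatorname{Var}/2E$, $\nu = 2E^2 /
\operatorname{Var}$, $p = P(\chi^2_\nu > Q/\kappa)$.  These moments
absorb both the correlation between variants of a gene and any positive
rescaling of the kernel, so the p-value is invariant to kernel scale
(tested).  Two higher-accuracy modes exist:

* `method = "exact"` computes the tail of
  $\sum_j \lambda_j \chi^2_{1}$, with $\lambda_j$ the eigenvalues of
  $P_0^{1/2} K P_0^{1/2}$, by Imhof's numerical inversion
  (`integrate`, relative tolerance 1e-9; eigenvalues below
  $10^{-10}\max\lambda$ dropped).
* `permutation_p()` permutes outcome labels within deciles of the fitted
  probabilities (so covariates are respected approximately), with the
  add-one rule $p = (1 + \#\{Q^\ast \ge Q\})/(1 + B)$.

**A caveat on tiny samples.**  The permutation law conditions on the
observed case count; the analytic approximations target the
unconditional model null.  At n = 20 this conditioning gap alone moves
central p-values by up to ~0.1 even though the moment formulas are exact
(the moment-matched p tracks a parametric bootstrap of the null model to
~0.01 at the same n).  The gap shrinks below 0.02 by n ≈ 50 and below
0.01 by n ≈ 100, and the two p-values agree in rank (Spearman > 0.95)
throughout.  For cohorts of a few hundred subjects — the intended regime
— the moment-matched p is calibrated: its empirical type-I error at
α = 0.05 over 2000 null gene×outcome simulations at n = 300 sits inside
[0.035, 0.065].

Rank-1 sanity anchor: for a single-variant gene with the (unnormalized)
linear kernel $K = gg^\top$, $Q = S^2$ with
$S = g^\top(y - \hat\mu)$, $\nu = 1$ and the moment-matched p equals the
classical covariate-adjusted score test exactly (tested to 1e-10).

## The synthetic cohort generator

Because individual-level genotype and covariate data for the motivating
trial are not deposited, the generator *is* the study population for
testing purposes.  Its defaults encode the reference cohort: 279
subjects; two race strata at 82%/18%; a 39-gene candidate panel
(dioxin-response, xenobiotic metabolism and nucleotide-excision-repair
genes) of 225 variants including the two binary deletion assays; ages
truncated-normal on [18, 85] with mean 57 and SD 13 (median ≈ 58); 51%
male; tumor sites at 66/31/1/2% (stomach, small intestine, rectum,
other); and the seven-category outcome mix (66, 45, 28, 56, 19, 29,
36)/279.

Genotypes are drawn per stratum by thresholding a latent Gaussian vector
at the Hardy–Weinberg genotype-class quantiles $\Phi^{-1}((1-f)^2)$ and
$\Phi^{-1}((1-f)^2 + 2f(1-f))$, so marginals are exactly HWE at the
stratum allele frequency.  Within a gene, the latent vector has AR(1)
correlation ρ between adjacent variants (a Gaussian copula): simple,
controllable, and sufficient to exercise kernel tests that exploit LD.
The panel's real LD structure is unknown, so the default ρ = 0.5 is a
plausible middle value for within-gene candidate SNPs, not a calibrated
one — conclusions that depend on LD strength should vary it.  Reference
(white-stratum) allele frequencies are drawn uniform on [0.10, 0.50],
reflecting a panel designed with a 10% MAF floor; the other stratum adds
Gaussian noise (SD 0.08, clipped to [0.02, 0.6]) so race-stratified
frequency tests have real signal.

Outcomes follow a multinomial logit: baseline log-odds from the category
probabilities, plus dosage × log-OR for each planted effect targeted at
one category.  Because the planted contribution enters only the target
category's log-odds, the per-allele OR of the implied
category-vs-rest logistic contrast equals the planted value exactly —
which is what makes round-trip recovery a fair test (planted per-allele
OR 2.0 at n = 5000 is recovered within [1.75, 2.30] in ≳97% of
replicates).  The emitted record is a full gene/exon/type/codon-span
mutation consistent with the category, so the classifier is genuinely
exercised rather than bypassed.  Tumor site is independent of genotype
by default — a site-restricted subanalysis then tests a true null —
and site-dependent effects are opt-in through the spec.

All randomness flows from one integer seed through derived sub-streams;
the global RNG state is saved and restored around every draw.

What the generator does **not** emulate: haplotype-level structure and
recombination (the copula has no genetic map), population structure
beyond two labeled strata, genotyping batch effects, Hardy–Weinberg
violations, related subjects, and secondary/resistance mutations or
tumors with two primary mutations.  Passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to those real-data complications.

The engineered QC cohort (`qc_reference_cohort()`) is a separate,
deterministic construction: exact exclusion counts (52 + 2 subjects,
3 + 6 + 7 + 1 variants) with every *retained* variant given a
minor-allele homozygote in every category so that exactly one variant
violates the homozygote rule.  It validates the cascade's bookkeeping,
not any distributional claim.

## Problem sizes and numerical choices

The test suite and the reproduction script use problem sizes chosen to
give tight Monte-Carlo error while staying comfortably interactive:
2000 null gene×outcome simulations (n = 300, 5-variant genes) for kernel
calibration, 2000 null variants (n = 500) for trend-test calibration,
200 replicates at n = 5000 for OR recovery, 50,000 permutations for the
small-sample oracle, and 1000 random p-vectors for the BH/brute-force
identity.  Other fixed numerics: logistic convergence 1e-8 / 100
iterations; separation detected at fitted probabilities within 1e-10 of
the boundary; kernel PSD verified at smallest eigenvalue ≥ −1e-8;
degenerate kernels (nonpositive moments) yield a flagged `NA` rather
than a fabricated p.

## Known limitations

* The homozygote-rule default is one of several defensible readings of a
  terse filter description; its aggressiveness on small strata is
  documented above and in the QC report.
* Satterthwaite matching uses two moments; far-tail p-values (≪ 0.001)
  at small n are better served by `method = "exact"`.
* Mean imputation for kernels attenuates signal at high missingness;
  with ≥ a few percent missing calls, compare against the permutation
  mode.
* The FDR family choice (per-outcome vs pooled) changes which findings
  cross a given q; both are provided and the manifest records which ran.
* No variant weighting, burden tests, omnibus kernel combinations,
  haplotype models, or SNP×SNP / SNP×covariate interactions.
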