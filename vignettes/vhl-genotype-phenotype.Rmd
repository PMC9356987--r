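---
title: "Genotype-phenotype correlation analysis for germline VHL variants"
author: "vhlgp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-phenotype correlation analysis for germline VHL variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhlgp)
```

## The problem

Von Hippel-Lindau (VHL) disease is an autosomal dominant tumour
predisposition syndrome caused by germline inactivating variants in the
*VHL* tumour-suppressor gene, whose protein has 213 codons. Affected
individuals develop CNS hemangioblastomas (CHB), retinal angiomas (RA),
pheochromocytomas/paragangliomas (PPGL), renal cell carcinomas (RCC),
pancreatic neuroendocrine tumours (PNET) and pancreatic or renal cysts
(PCT, RCT), among rarer manifestations. Because VHL is rare and its case
reports are scattered across decades of literature, genotype-phenotype
analysis requires assembling heterogeneous curated cases -- reported at
patient, family, unique-variant or tumour resolution -- into consistent
analysis views and applying a battery of association analyses.

`vhlgp` implements that battery as a reusable, tested pipeline:

* cohort assembly with curation filters (common-population-variant
  exclusion at gnomAD allele frequency > 1%, the familial-variant
  assumption for untested kindred members, compound-heterozygote
  resolution);
* summary statistics per analysis level;
* pairwise phenotype co-occurrence ratios with low/moderate/high bands;
* per-codon missense hotspot testing, raw and BLOSUM90-weighted;
* truncating/non-truncating and protein-domain contingency analyses with
  Bonferroni-corrected post hocs;
* onset-age penetrance curves and all-pairs Kolmogorov-Smirnov tests;
* Jaccard-affinity spectral clustering of patients with eigengap model
  selection.

A synthetic cohort generator emulates the curated datasheet schema so the
whole pipeline can be exercised, and its operating characteristics
measured, without any external data.

## Cohort model and curation rules

A datasheet row is one curated case with a resolution tag (`patient`,
`family`, `variant`, `tumor`), a kindred id scoped to its source
publication, HGVS `c.`/`p.` descriptions against transcript NM_000551.3,
a declared variant type, demographics (sex and three age fields: onset,
death, last known), a pre-annotated gnomAD allele frequency, de novo
status, and a set of HPO terms.

Three analysis views are assembled. The patient view has one unit per
patient-resolution case. The family view aggregates patient cases by
(source, kindred) -- kindred ids are deliberately *not* matched across
sources, since cross-publication duplicate resolution happens upstream
during curation -- and admits a family only when at least one member is
genetically confirmed; phenotypes are unioned over members, and untested
members inherit the confirmed familial variant for analysis only.
Kindreds carrying two distinct confirmed variants are excluded and
flagged rather than arbitrated. The unique-variant view unions phenotypes
over all four resolutions, keyed by a normalized variant identity
(case-insensitive, whitespace-stripped, three-letter amino acids
canonicalized).

Records lacking any variant descriptor after the familial rescue, or any
mapped VHL phenotype group, are dropped into an exclusion ledger with
reason codes; records are conserved (kept + ledger = input). Missing
demographics are handled by pairwise deletion throughout: each statistic
uses every unit that has the fields it needs, with the denominator
reported alongside.

### HGVS-lite classification

`classifyVariant()` is intentionally a regular-grammar subset of HGVS:
protein substitutions (three- or one-letter), frameshifts, in-frame
deletions/duplications/insertions, delins, stop-codon extensions, and
coding-level intronic (offset 1-2 = splice site, deeper = intronic), UTR
and indel patterns (frame from length arithmetic; in-frame deletions
longer than 20 codons, or 60 nt at the coding level, are reported as
deletions proper). No transcript-sequence validation is attempted --
descriptions that defeat the grammar degrade to `unknown` unless the
datasheet declares a type. Truncating = stop-gained, frameshift,
deletion, exon loss, splice site, start-lost; non-truncating = missense,
in-frame indel, in-frame delins, stop-lost; synonymous, UTR, intronic and
unknown variants are excluded from the grouping. Start-lost is assigned
truncating (loss of initiation); stop-lost and in-frame delins are
assigned non-truncating; these three types are rare enough (well under 1%
of units) that the assignment does not move the contingency results, but
it is a configuration point worth knowing about.

### Phenotype mapping

HPO terms map onto combined phenotype groups through a bundled,
versioned TSV (`inst/extdata/hpo_phenotype_groups.tsv`). The CHB group
contains the three hemangioblastoma terms (HP:0009713, HP:0006880,
HP:0010797); the other groups are seeded with representative term ids.
The shipped table is a deliberately minimal seed: real curation should
extend it from a current HPO release (the mapping functions accept any
table with `hpo_id` and `group` columns). Every analysis in the package
depends only on the internal consistency of the mapping -- the simulator
emits terms from the same table -- not on ontology completeness.
Unmapped terms are carried and reported, never silently dropped.

## The statistics

### Co-occurrence ratios

For phenotypes $a, b$ with pair counts $C_{ab}$ (units carrying both),
the conditional ratio is $r_{ab} = C_{ab} / C_{aa}$, the fraction of
$a$-carriers that also carry $b$. Each row of $r$ is then min-max scaled
over $b \ne a$ to $[0, 1]$ *per manifestation*, and banded: low
$[0, 0.33]$, moderate $(0.33, 0.66]$, high $(0.66, 1]$. The conditional
form followed by per-row scaling is the simplest statistic consistent
with "pairwise likelihoods scaled per manifestation" and with asymmetric
per-manifestation heatmaps; since other scalings are conceivable, the
raw count and conditional matrices are always emitted alongside the
scaled one so alternatives can be audited. A row whose off-diagonal
ratios are constant cannot be scaled; it is set to 0 and flagged
degenerate. The diagonal is excluded from scaling.

### Hotspot tests

Under the null that $n$ missense observations fall evenly over the 213
codons, each codon count is $\mathrm{Binomial}(n, 1/213)$. The raw test
is the exact upper tail $P(X \ge c)$, Bonferroni-corrected over $m = 213$
tests (corrected level $\alpha/213 \approx 2.35\times10^{-4}$ at
$\alpha = 0.05$). Codons with $p \le (\alpha/213)\times10^{-4}$ -- four
orders of magnitude below the corrected level -- are flagged highly
significant.

The BLOSUM90-adjusted variant weights each observation by its
substitution radicality
$w = \big(b(r,r) - b(r,a)\big) / \bar W$,
where $b$ is the BLOSUM90 entry and $\bar W$ is the mean of
$b(r,r) - b(r,a)$ over all 380 ordered non-identical amino-acid pairs.
The normalization makes the cohort-average weight close to 1, so
cumulative scores are commensurate with raw counts (and naturally
non-integer). Because cumulative scores are non-integer, the binomial
tail is continued in its argument: with even-distribution mean
$\lambda = S/213$, the p-value is the gamma-distribution identity for
the Poisson upper tail, $p = P(\Gamma(\text{shape}=s) \le \lambda)$,
which equals $P(\mathrm{Pois}(\lambda) \ge s)$ exactly at integer $s$
and is 1 at $s = 0$. This is documented as a continuous approximation to
a binomial test on adjusted counts; the weight function is a plain
exported function (`blosumWeight`) so alternative severity weightings
can be swapped in. BLOSUM90 ships as a plain-text NCBI-format matrix.

### Contingency analyses

The phenotype-by-group table counts one increment per (unit, phenotype)
pair -- multi-phenotype units contribute to several rows, a
non-independence inherited from the study design and stated in reports.
The test is the Pearson chi-square *without* continuity correction (the
published statistic on the printed counts reproduces only without
correction), with $(r-1)(c-1)$ degrees of freedom. Post hocs compare
each pair of phenotype rows as a 2x2 at the corrected level
$\alpha/\binom{7}{2} = \alpha/21$. Domain tables place coding variants
in the alpha-domain (codons 156-204) versus beta-domain (63-143), and in
the HIF-alpha versus Elongin B/C binding sites; codon 79 belongs to both
functional sites and counts in both columns. Phenotype rows with no
observation in either region of a table are dropped from that test;
degenerate tables are reported untested rather than forced.

### Penetrance

Because the onset age of each successive manifestation is not available
in literature-curated data, penetrance uses patients with an *isolated*
phenotype: a patient contributes iff it carries exactly one phenotype
group and has an onset age. The curve is the plain empirical CDF among
those patients (no censoring model -- this is deliberately not a
Kaplan-Meier analysis), and the "50% threshold" is the first age at
which the ECDF reaches 0.5. Phenotypes with fewer than `min_n` patients
(default 5; the exact cutoff used upstream is unstated, so it is a
configuration parameter) are dropped with a warning. All-pairs
two-sample Kolmogorov-Smirnov tests are Bonferroni-corrected over
$k(k-1)/2$ pairs; exact p-values are used when $n_1 n_2 \le 10^4$ and
the pooled sample is tie-free, asymptotic otherwise (ages are integer
years, so ties dominate at scale).

### Spectral clustering

Patients with at least one phenotype are nodes; edges carry the Jaccard
similarity $|S_i \cap S_j| / |S_i \cup S_j|$ of their phenotype sets.
The full dense affinity is used -- phenotype sets are tiny, so
k-nearest-neighbour sparsification would only discard information. The
symmetric normalized Laplacian $L = I - D^{-1/2} A D^{-1/2}$ has its
eigenvalues in $[0, 2]$ with the multiplicity of 0 equal to the number
of connected components. The eigengap method scans
$g_i = \lambda_{i+1} - \lambda_i$ for $i = 2..k_{\max}$ (a one-cluster
answer is uninformative, so $K = 1$ is excluded; $k_{\max}$ defaults to
15) and returns the two largest-gap indices as candidate cluster counts,
ties broken toward smaller $K$. Clustering follows Ng-Jordan-Weiss:
rows of the bottom-$K$ eigenvector matrix are unit-normalized and
k-means is run with a fixed seed and 10 restarts (Lloyd iterations,
which are stable on the heavily duplicated rows produced by identical
phenotype sets; duplicates are kept as-is -- determinism is preferred
over jitter). Genotype information enters only the per-cluster profiles,
never the affinity, so genotype trends across clusters are findings
about the data, not artefacts of the algorithm.

## The synthetic cohort generator

`simulateCohort()` draws kindreds, assigns each a variant (type from a
mix echoing the large curated cohorts, missense about 62%; codons
uniform with planted hotspot multipliers, defaults 167 at 10x and 161 at
5x), renders the kindred at a sampled resolution, and draws members'
phenotypes independently per phenotype conditional on a latent genotype
class derived from the variant: truncating, non-truncating alpha-domain
(the "type 2-like" class with PPGL probability 0.75), non-truncating
beta-domain, or other. Onset age is the minimum of per-phenotype
Gaussian draws (PPGL and RA medians near 16, CHB 36, RCC 44, PCT 27
years), rounded to integer years to match literature granularity.
Field-level missingness (50% of onset ages, 35% of sex), a 25% rate of
untested non-index family members (exercising the familial rescue) and
a 1% rate of common population variants are injected. The seed fully
determines the output.

Conditional independence given the latent class is the simplest
structure that induces the co-occurrence, contingency and clustering
patterns the analyses target. It is also a real limitation: passing
recovery tests on these cohorts demonstrates that the machinery detects
the structure it is pointed at, not that real VHL data contains only
that structure. The generator deliberately does not emulate publication
bias, duplicated patients across sources, or curation noise.

## Numerical choices and degenerate inputs

* Exact binomial tails via the distribution function, cross-checked in
  the tests against independent log-space pmf summation.
* The gamma continuation of the Poisson tail for non-integer scores;
  score 0 maps to p = 1 by definition.
* Chi-square tests refuse zero marginals by naming the offending
  row/column; post hoc pairs with a zero marginal are reported untested.
* Percentages are rounded half-away-from-zero to one decimal in summary
  reports.
* Co-occurrence rows with constant ratios scale to 0 and are flagged.
* The common-variant exclusion is strict: allele frequency exactly 1% is
  kept.
* Eigengap ties break toward smaller K; k-means ties resolve by lowest
  within-cluster sum across 10 restarts under a fixed seed.

## Validation scale

The test suite validates each engine against independent oracles (pmf
summation, closed-form 2x2, permutation-exact KS over all $\binom{8}{4}$
splits) and measures operating characteristics on planted-structure
cohorts: family-wise error of the Bonferroni hotspot test over 1000
uniform-null replicates at 1339 observations, hotspot power at a 10x
planted codon with 500 observations, clustering recovery (adjusted Rand
index) on planted 2- and 4-class cohorts of 200 patients at 10%
phenotype noise, eigengap coverage over 100 runs at 5% noise, and KS
power for a Normal(18, 8) versus Normal(44, 10) onset shift at 100
patients per arm. These problem sizes were chosen to keep Monte-Carlo
standard errors small relative to the thresholds being checked while
keeping the default suite quick to run.

## A worked run

```{r, eval = FALSE}
library(vhlgp)
sim <- simulateCohort(simulationConfig(seed = 7, n_families = 400))
res <- runAll(sim$datasheet, outdir = "vhlgp_out", seed = 7)
res$cohort
res$patient$hotspots
res$patient$clusters
res$patient$penetrance
```

## Known limitations

* HGVS parsing is a regular grammar; exotic descriptions require a
  declared type.
* The bundled HPO mapping is a seed, not an ontology traversal; child
  terms absent from the table surface as "unmapped" until added.
* Multi-phenotype units make contingency rows non-independent; the
  chi-square p-values are descriptive in the same sense as in the
  original study design.
* Duplicate patients across publications are out of scope (resolved
  upstream during curation); kindred ids never match across sources.
* The co-occurrence scaling choice (conditional ratio, per-row min-max,
  diagonal excluded) is one of several defensible readings; raw
  matrices are emitted for auditability.
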