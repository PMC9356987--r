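# vhlgp

Genotype-phenotype correlation analysis for germline variants in the
*VHL* tumour-suppressor gene.

Von Hippel-Lindau (VHL) disease is a rare autosomal dominant
tumour-predisposition syndrome: germline inactivating variants in *VHL*
(a 213-codon protein) predispose carriers to CNS hemangioblastoma (CHB),
retinal angioma (RA), pheochromocytoma/paraganglioma (PPGL), renal cell
carcinoma (RCC), pancreatic neuroendocrine tumours (PNET) and pancreatic
or renal cysts (PCT, RCT). Because cases are scattered across decades of
heterogeneous literature, analysing the genotype-phenotype landscape
means assembling curated cases -- reported at patient, family,
unique-variant or tumour resolution -- into consistent views and running
a battery of association analyses over them. `vhlgp` is that battery,
built for statisticians and genetics researchers working with curated
rare-disease cohort datasheets.

## What it computes

Given a datasheet with one row per curated case (HGVS `c.`/`p.`
descriptions against NM_000551.3, HPO terms, kindred ids, demographics,
gnomAD allele frequency), the package:

* classifies variants with an HGVS-lite grammar and groups them into
  truncating / non-truncating / excluded;
* applies the curation filters (gnomAD AF > 1% exclusion,
  compound-heterozygote resolution, familial-variant rescue of untested
  kindred members) and aggregates patient-, family- and variant-level
  analysis units;
* computes pairwise phenotype **co-occurrence ratios**
  r[a,b] = C[a,b]/C[a,a], min-max scaled per manifestation and banded
  low/moderate/high at 0.33 and 0.66;
* tests every codon for **missense hotspots**: exact one-tailed binomial
  tail P(X >= c), X ~ Binomial(n, 1/213), Bonferroni-corrected over 213
  codons, plus a BLOSUM90 radicality-weighted variant with a continuous
  (gamma/Poisson) tail for non-integer cumulative scores;
* runs the **truncating/non-truncating x phenotype** Pearson chi-square
  (no continuity correction) with all-pairs post hocs at alpha/21, and
  the alpha-domain (codons 156-204) vs beta-domain (63-143) and
  HIF-alpha vs Elongin B/C binding-site contingency tests;
* builds **age-of-onset penetrance** ECDFs from isolated-phenotype
  patients with all-pairs two-sample Kolmogorov-Smirnov tests at
  alpha/15 (for 6 phenotypes);
* clusters patients by **Jaccard phenotype similarity** via
  Ng-Jordan-Weiss spectral clustering on the symmetric normalized
  Laplacian, with eigengap selection of two candidate cluster counts and
  per-cluster genotype/phenotype profiles;
* **simulates** datasheet-schema cohorts with planted hotspots, latent
  genotype classes and onset distributions, exporting ground truth for
  recovery tests.

## Worked example

```r
library(vhlgp)
sim <- simulateCohort(simulationConfig(seed = 7, n_families = 400))
res <- runAll(sim$datasheet, outdir = "vhlgp_out", seed = 7)
res$cohort
#> VHLCohort
#>   patients: 455  families: 333  unique variants: 337
#>   exclusions: common_population_variant=4, family_no_confirmed_member=1, no_phenotype=30
res$patient$hotspots
#> HotspotResult: 256 missense observations over 213 codons (alpha = 0.05)
#>   significant codons (p <= 0.000235): 167
res$patient$clusters
#> ClusterModel: 455 patients, eigengap K candidates = 2, 7
#>   K2 cluster sizes: 136, 319
res$patient$penetrance
#> PenetranceCurves (isolated-phenotype onset ages)
#>   CHB   n =   19  50% threshold = 34 years
#>   PPGL  n =   15  50% threshold = 15 years
#>   RCC   n =    8  50% threshold = 46 years
#>   ...
```

The simulator planted a 10x hotspot at codon 167; the binomial test
recovers exactly that codon at the corrected level 0.05/213 = 2.35e-4.
The eigengap proposes K = 2 (the PPGL/non-PPGL "type 2 / type 1" split)
as its leading candidate, and the penetrance curves reproduce the
planted early-PPGL (median 15y) versus late-RCC (median 46y) onset
structure.

The published patient-level contingency table is bundled as a reference
input:

```r
ct <- chi2Test(buildGroupTable(patients(buildCohort(table1Fixture()))),
               posthoc = TRUE)
ct
#> ContingencyResult: chi2 = 337, df = 6, p = 9.57e-70
#> ...
#> post hoc: 13/21 pairs significant at alpha/m = 0.00238
```

PPGL's truncating/non-truncating split differs from every other
phenotype (6/6 pairs significant), the classic VHL type 2 signature.

A thin command-line wrapper ships in `inst/cli/vhlgp.R`
(`simulate`, `validate`, `run-all` subcommands).

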