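---
title: "Methods: diversity, phasing and association in a candidate-gene cattle panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, phasing and association in a candidate-gene cattle panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplotrait)
```

## The setting

`haplotrait` implements the statistical workflow of a small candidate-gene
association study: a few hundred animals genotyped at a handful of biallelic
SNPs within one gene, with quantitative body-conformation measurements. The
concrete panel shipped with the package is the five-SNP myostatin (*GDF8*)
panel segregating in Chinese Dabieshan cattle (two exon-1 sites, two exon-3
sites and one 3'UTR site, n = 380 animals), but every function is generic
over an arbitrary `snp_panel()`.

The pipeline runs in the order a population geneticist would report it:

1. per-locus genotype/allele frequencies, diversity indices and
   Hardy-Weinberg tests (`summarize_loci()`);
2. pairwise linkage disequilibrium from two-locus EM (`ld_matrix()`);
3. multi-locus EM haplotype frequencies, a reporting floor, and
   maximum-posterior diplotype assignment (`em_haplotype_frequencies()`,
   `filter_haplotypes()`, `assign_diplotypes()`);
4. fixed-effects association of genotype and diplotype classes with each
   trait (`fit_trait_model()`, `association_report()`).

## Per-locus statistics

For allele frequencies $p_i$ obtained by gene counting, the package reports
expected homozygosity $H_o = \sum_i p_i^2$, gene heterozygosity (Nei gene
diversity) $H_e = 1 - H_o$, effective allele number $N_e = 1/\sum_i p_i^2$,
and polymorphism information content

$$\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2,$$

which for a biallelic locus reduces to $H_e - 2p^2q^2$. Two deliberate
conventions:

* **"$H_o$" is *expected* homozygosity**, not the observed heterozygote
  deficit ($H_o + H_e = 1$ holds identically). Observed heterozygosity is
  reported separately as `het_obs` to keep the two notions apart.
* **The Hardy-Weinberg $\chi^2$ test defaults to 2 degrees of freedom**
  (`df_mode = "paper"`), the convention of the POPGENE lineage of software
  this pipeline reproduces (3 genotype classes − 1). The textbook convention
  subtracts the estimated allele frequency as well, leaving 1 df; it is
  available as `df_mode = "standard"`. The statistic itself is the plain
  Pearson $\sum (O-E)^2/E$ with no continuity correction and no exact test,
  because that is what the reproduced workflow used. Monomorphic loci and
  zero expected counts are refused explicitly.

## EM haplotype-frequency estimation

The package's phasing is classic gene-counting EM over phase
configurations. An individual heterozygous at $h$ of the $L$ loci is
compatible with $2^{h-1}$ unordered haplotype pairs ($\max 16$ at $L=5$);
under random pairing a pair $(h,k)$ has probability $2f_hf_k$ ($f_h^2$ if
$h=k$). The E-step distributes each individual's unit weight over its
compatible pairs proportionally to these probabilities; the M-step sets each
$f_h$ to its expected share of the $2n$ gametes. The log-likelihood is
non-decreasing (asserted at every iteration in the test suite) and iteration
stops when it improves by less than `tol` (default $10^{-8}$) or at
`max_iter` (default 1000); a fit that hits the cap is returned with
`converged = FALSE`, never silently.

**Initialization and restarts.** EM starts at the linkage-equilibrium
product point. That point can be a stationary saddle: a sample consisting
only of double heterozygotes has two symmetric maxima (coupling and
repulsion) with the product point exactly between them. The default
therefore runs 5 restarts, the first unjittered and the rest multiplying
the start by $\exp(U(-0.5, 0.5))$ noise from a seed-derived stream, and
keeps the restart with the best final log-likelihood. This makes the escape
from the saddle deterministic and reproducible.

**Missing data.** Multi-locus EM uses listwise-complete cases at the chosen
loci; pairwise LD uses pairwise-complete cases per locus pair. This mirrors
what a genotype-table tool can do without imputation, and the loader
deliberately supports missingness without imputing (how failed sequencing
reactions were handled upstream is unknowable from a published table).

## Linkage disequilibrium

From two-locus gamete frequencies, $D = f_{AB} - p_Ap_B$, Lewontin's
$D' = |D|/D_{\max}$ with $D_{\max} = \min(p_Ap_b,\,p_ap_B)$ for $D>0$ and
$\min(p_Ap_B,\,p_ap_b)$ for $D<0$, and the squared allelic correlation
$r^2 = D^2/(p_A\,p_a\,p_B\,p_b)$. $D'$ at exactly $D=0$ is defined as 0 (the equilibrium
convention). Pairs with $r^2$ above 0.33 are flagged as in strong LD, the
threshold this literature uses for "sufficient for mapping". Summary means
are taken over all $L(L-1)/2$ pairs; `ld_means()` applies the same
summarization to an externally supplied (e.g. published) LD table. Both
$D'$ and $r^2$ are invariant to allele relabeling, which the suite checks
property-style.

## Haplotype reporting floor and diplotypes

Haplotypes below `min_freq` (default 5%) are dropped from reports *without
renormalizing* the survivors — the retained set is quoted on the original
frequency scale (so it sums to less than 100%), with the discarded count
and mass recorded. Diplotype assignment is maximum-posterior (hard
assignment, matching how such studies build their "combined haplotype"
classes), restricted to retained haplotypes; an individual incompatible
with every retained pair is assigned from the full set and flagged.
Posterior ties break to the lexicographically smallest pair label, so
assignment is deterministic. Class labels are the concatenated per-locus
genotype strings (reference allele first) rather than haplotype-pair names:
the published class strings and haplotype numbering cannot be reconciled
with each other, so genotype-derived labels are the only construction that
is internally consistent.

## The association model

Each trait is analyzed with the fixed-effects linear model

$$y_{ijk} = \mu + g_i + a_j + s_k + e_{ijk}$$

where $g_i$ is the genotype or diplotype class, $a_j$ the age class and
$s_k$ the sire. Two modelling decisions:

* **Sire is fitted as a fixed blocking factor.** The source workflow
  describes sire as a random effect but fitted the model in a
  point-and-click GLM; an OLS fixed-factor fit is the reproducible reading,
  and variance-component estimation is out of scope. With ~10 sires the
  fixed fit costs a few residual df and gives the same class contrasts.
* **Age is categorical** (age classes), since no continuous coding is
  published.

The overall class effect is the partial F-test of the class term against
the covariate-only model. Class summaries report both raw means ± SE and
least-squares means ± SE (via `emmeans`, averaging over the covariate
levels); with constant covariates the two coincide to numerical precision
(asserted in the tests). All $k(k-1)/2$ pairwise class contrasts within one
trait-by-marker analysis form the Bonferroni family
($p_{\mathrm{adj}} = \min(1, m\,p)$); families are *not* pooled across
traits or markers, matching per-column superscript-letter reporting.
Grouping letters come from deterministic insert-and-absorb over the
non-significant-pair graph in descending LS-mean order. Classes with fewer
than 2 observations are dropped with a note; rank-deficient designs (e.g. a
class confounded with a sire) raise an error naming the aliased
coefficients.

## The synthetic-herd generator

No raw genotype or phenotype data accompany the published tables, so the
generator is the package's stand-in study population and the substrate of
every end-to-end test.

* **Haplotype pool.** Gametes are drawn iid from a 12-haplotype pool: the
  five published haplotypes at their printed frequencies (31.5, 23.8, 23.5,
  5.8, 5.2%) plus seven *synthetic* rare haplotypes sharing the residual
  10.2% uniformly (≈1.46% each — safely under the 5% reporting floor,
  preserving the filtering behaviour; twelve haplotypes is the count
  reported segregating). The fillers are the first seven allele strings in
  reference-first binary enumeration order that avoid the published five:
  a deterministic, documented choice rather than a random one.
* **Random mating.** The two haplotype draws per individual are
  independent, so Hardy-Weinberg proportions hold at pool level by
  construction; the study publishes no inbreeding estimate to emulate.
  (Hardy-Weinberg *departures*, which the real data show at two loci, are
  therefore not a feature of the default generator — tests of the HWE
  machinery use explicit count configurations instead.)
* **Traits.** $y = \mathrm{baseline} + \mathrm{class\ shift} +
  \mathrm{age} + \mathrm{sire} + \mathcal{N}(0, \sigma)$, floored at 1 cm
  (lengths are positive; the floor sits ~4σ below the smallest baseline and
  is essentially never active). Baselines sit near the published class
  means; the residual SDs (10, 6, 5.5, 10, 15, 4.5, 2.5 cm for BL, WH, HH,
  HG, AGR, HW, PBW) are invented, chosen once so that class-mean standard
  errors at n = 380 land on the order the published tables show. Age and
  sire counts (4 classes, 10 sires) and their effect SDs (3 and 2 cm) are
  likewise invented, as nothing about the herd structure is published.
* **Determinism.** One seed governs a run; the trait stage uses a
  deterministically derived sub-stream (`seed + 1`) so genotypes are
  reproducible independent of whether traits are generated.

What passing tests on this generator demonstrate: correct frequency
recovery, correct EM behaviour under the panel's real LD structure, correct
type-I error and effect recovery of the association model under its own
assumptions. What they do not demonstrate: robustness to genotyping error,
population structure, non-Gaussian traits, or informative missingness —
none of which the generator emulates.

## Numerical and design notes

* All computation is in full precision; rounding (frequencies 2 d.p.,
  indices and LD 3 d.p., haplotype percentages 2 d.p., trait means 2 d.p.)
  happens only in `render_report()`. The published tables themselves
  illustrate why: their printed 2-d.p. genotype frequencies cannot
  reproduce their own printed $\chi^2$ values, so any fidelity check must
  run upstream of rounding.
* The EM phase-space enumeration collapses duplicate multi-locus genotypes
  before iterating, so cost scales with distinct genotypes (≤ $3^L$), not
  with herd size.
* Brute-force likelihood maximization over the haplotype simplex (grid plus
  Nelder-Mead polish under a softmax parameterization) lives in the test
  suite as an independent oracle for the EM, on instances of ≤ 3 loci and
  ≤ 12 individuals.
* Problem sizes used by the default test run: herds of 380 (the study
  size) for pipeline checks, 20k–100k draws for law-of-large-numbers
  checks, 2000 replicates of n = 380 for the F-test size calibration, ten
  seeded replicates for haplotype-frequency recovery.

## Worked example

```{r, eval = FALSE}
bundle <- run_pipeline(pipeline_config(out_dir = "report"))
render_report(bundle)$haplotypes
```

## Known limitations

* Biallelic SNPs only at the I/O layer; the diversity formulas generalize
  to more alleles but are untested beyond two (the motivating panel is
  entirely biallelic).
* No mixed models, no additive/dominance decomposition, no multi-marker
  joint models; one fixed-effects fit per trait per marker.
* No imputation; complete-case behaviour throughout, documented per stage.
* EM phasing is exact enumeration, appropriate for candidate-gene panels
  (L ≲ 15 heterozygous loci per individual), not a partition-ligation
  phaser for genome-scale data.
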