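---
title: "Continuous and linkage QTL mapping in triploid populations"
author: "triqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous and linkage QTL mapping in triploid populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triqtl)
```

# The problem

Triploid progeny of a tetraploid × diploid cross are the standard product
of polyploid crop breeding schemes (bananas being the motivating case),
but they are awkward material for QTL mapping. At a biallelic SNP a
triploid has four possible dosages (0–3 copies of the reference allele),
and calling them reliably from reduced-representation sequencing would
require depths of 60–80× — far beyond what low-cost
genotyping-by-sequencing delivers. `triqtl` implements the two
complementary strategies that make such populations mappable anyway:

1. **Continuous mapping**: skip dosage calling entirely and regress the
   trait on the per-individual reference-allele *frequency* estimated
   from the read counts, with an explicit correction for the attenuation
   the noisy frequencies cause.
2. **Simplex-marker linkage mapping**: restrict to markers where the
   tetraploid parent is homozygous and the diploid parent heterozygous
   (AAAA × RA), which segregate 1:1 in the offspring like a backcross, so
   the classical diploid linkage and interval-mapping machinery applies.

A synthetic-data generator with full known truth ties the two arms
together and is the basis of all validation.

# The synthetic cross generator

`cross_config()` + `simulate_cross()` generate a complete
4x × 2x → 3x experiment: parental genotypes, offspring meioses,
plot-level phenotypes and allelic read counts.

**Meiosis model.** The tetraploid's four homologs pair at random into
two bivalents at each meiosis (all three pairings equally likely); each
bivalent runs an independent no-interference (Poisson/Haldane) crossover
process, and one chromatid per bivalent enters the gamete. Double
reduction is not modelled. This yields the hypergeometric gamete law at
an unlinked marker — \(P(k) = \binom{g_4}{k}\binom{4-g_4}{2-k} / \binom{4}{2}\)
for a parent with dosage \(g_4\) — which is exactly the expectation that
makes an AAAA × RA marker segregate 1:1 (AAA : AAR) in the triploid
offspring. The diploid parent undergoes ordinary meiosis. The tests
verify the gamete laws against exhaustive enumeration and the pairwise
recombination fractions against the Haldane closed form.

**Parental dosage classes.** Each marker's (tetraploid, diploid) dosage
combination is drawn from a configurable 5 × 3 frequency table. The
default emulates a tetraploid that arose by whole-genome duplication of
a heterozygous diploid — nulliplex, duplex and quadruplex classes
dominate, simplex and triplex classes are rare — crossed to an unrelated
heterozygous diploid; roughly half the markers segregate. QTL markers
are forced to a configurable segregating class (default duplex × simplex,
giving offspring dosages 0–3).

**Phenotypes.** The latent plot value on the logit scale is
\(\mu + \sum_q \beta_q\,d_{iq} + g_i + b_{B} + r_{B:R} + e\), where
\(d_{iq}\) is the offspring dosage at QTL \(q\) and \(\beta_q\) its
effect per reference-allele copy, \(g_i \sim N(0, \sigma^2_{geno})\) a
polygenic deviation, \(b_B\) fixed batch effects,
\(r_{B:R} \sim N(0, \sigma^2_{rep})\) block-within-batch effects and
\(e \sim N(0, \sigma^2_{plot})\) the plot error. Observed percentages
are \(100\,\mathrm{logit}^{-1}(\cdot)\), so they always lie in (0, 100).
The design mirrors a pot-screening trial: four batches × two blocks ×
four plants per plot, with the offspring split across batches (planting
material rarely suffices for all batches) while parents and checks
recur in every batch and connect them. Defaults — 138 offspring, 11
chromosomes, ~37,000 markers (scaled down in examples), \(\mu = 0.25\),
\(\sigma^2_{geno} = 0.25\), \(\sigma^2_{rep} = 0.04\),
\(\sigma^2_{plot} = 0.16\), check offsets spanning resistant to
susceptible — were chosen once to produce heritabilities and trait
ranges typical of percentage damage traits in such trials.

**Read counts.** Depth per site and sample is negative-binomial
(default mean 20, size 5: low and variable, with occasional zeros that
become missing data); the reference count is
\(\mathrm{Bin}(d, p_g)\) with
\(p_g = (g/\mathrm{ploidy})(1-\varepsilon) + (1-g/\mathrm{ploidy})\varepsilon\)
and per-read error rate \(\varepsilon = 0.01\) by default. Neither the
depth distribution nor the error model is prescribed by the field —
both are explicit generator parameters, not claims.

All randomness flows from one seed through per-stage substreams, so a
configuration regenerates its data set exactly;
`write_cross_outputs()` emits VCF 4.2 (with per-sample AD), a phenotype
CSV and a truth JSON recording seed and configuration.

**What the generator does *not* emulate:** genotyping batch effects and
allele-specific (PCR) bias in the read counts, aneuploid or off-ploidy
offspring, double reduction, crossover interference, spatial field
trends, and trait distributions that are not logit-normal. Passing tests
therefore demonstrate correctness of the algorithms under this idealised
model, not robustness to those artefacts in real data.

# Phenotype analysis: the two-run procedure

Percentage traits are analysed on the logit scale. Plant records are
averaged to plot means before the transform (the plot is the
randomisation unit; the choice matters little because plants share the
plot value up to the optional plant variance). Proportions are clamped
to \([\delta, 1-\delta]\), \(\delta = 1/(4 \cdot n_{plants} \cdot 100)\)
(half a unit of the finest recordable percentage), so boundary
observations stay finite without discarding data.

* **Run 1** (`fit_variance_components()`): REML fit of
  `y ~ batch + genotype_extra + (1 | genotype_test) + (1 | block-within-batch)`.
  The segregating offspring ("test") are random, so their variance — and
  the entry-mean heritability
  \(H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e / r_h)\), with \(r_h\)
  the harmonic-mean number of plots per test genotype — can be
  estimated; parents and checks ("extra") are fixed. The fit uses `lme4`
  with tightened optimizer tolerances; on balanced designs it agrees
  with the ANOVA method-of-moments closed form to 1e-6, which the tests
  assert. Extras share one dummy level of the random factor (the
  standard trick for augmented designs); it is exact when no extras are
  present and innocuous otherwise.
* **Run 2** (`adjusted_means()`): generalized least squares with *all*
  genotypes fixed and the run-1 variance structure
  (\(\sigma^2_{rep}\) at block level + residual) frozen, yielding
  unshrunken adjusted means predicted at the average batch effect.
  Because the parents and checks recur in every batch, the design is
  connected and means of offspring grown in different batches are
  comparable; a rank-deficient (disconnected) design is refused rather
  than silently aliased.
* `lsd_compare()` turns the covariance of the means into pairwise LSDs
  \(t_{1-\alpha/2,\nu}\,\mathrm{SED}\) (min / average / max reported)
  and compact letters via maximal homogeneous intervals of the sorted
  means (insert-and-absorb; ties broken by genotype id, so output is
  deterministic).

Note that an entry-mean \(H^2\) of 0.4 caps the correlation between true
and estimated genotype effects at \(\sqrt{0.4} \approx 0.63\); the
recovery tests therefore interpret "heritability 0.4" as the plot-level
variance ratio, which at eight plots per genotype gives an entry-mean
reliability of ~0.84 and the expected rank correlation of ~0.9.

# Dosage calling and marker taxonomy

The genotype likelihood of dosage \(g\) is binomial in the reference
reads with success probability \(p_g\) as above — the standard
GATK-style read model. `call_dosage()` assigns the maximum-likelihood
dosage only when it is at least 10 times more likely than the runner-up,
otherwise the call is missing; symmetric read counts in a triploid
(e.g. 3:3) therefore never produce a call. At \(\varepsilon = 0.01\) and
mean depth 30 the diploid-parent call accuracy exceeds 99% (Monte-Carlo
tested on 10,000 draws).

`classify_parental_combination()` maps a (g4, g2) pair to its class
label (RRRR × RA, …) and segregation status: a marker segregates in
whichever parent is heterozygous; two identical homozygotes are
monomorphic, two different homozygotes polymorphic but non-segregating.
`expected_offspring_distribution()` convolves the two gamete laws;
`tabulate_combinations()` builds the 5 × 3 class table with totals per
status. Population allele frequency for the MAF filter (default 0.02)
is the unweighted mean of per-sample frequencies — pooling reads would
weight deep samples more. Missingness is filtered strictly below 10%.

# Continuous mapping

`genome_scan()` performs, per marker, the OLS regression of the
adjusted means on the allele frequencies (pairwise deletion of missing
frequencies; at least 3 complete pairs and non-zero frequency variance
required), with a two-sided p from the t distribution on \(n-2\) df
computed on the log scale so that extreme significance does not
underflow. The explained variance is \(100\,R^2\).

**Attenuation correction.** Writing \(f = g/3 + e\) with read-sampling
noise \(e\), the regression slope is shrunk by
\(\lambda = \mathrm{Var}(g/3) / (\mathrm{Var}(g/3) + \mathrm{Var}(e))\).
For a triploid family this package uses the closed form
\(\lambda = 1/(1 + 2/S_T)\) — an attenuation in (0, 1) that tends to 1
with depth — and reports \(\beta_{corr} = \beta_{raw}(1 + 2/S_T)\).
Because \(\mathrm{Var}(e) \propto E[1/d]\), the right depth average is
the *harmonic* mean \(S_T\), computed per marker over the samples with
reads (a global-\(S_T\) override exists). Effects are reported per
allele copy (slope × 1/3), matching the allele-substitution-effect
convention; the raw per-unit-frequency slope is available via
`effect_scale = "per_unit"`. The exact \(\lambda\) depends on the
segregation mix, so the closed form is mildly conservative for some
classes: across 200 simulated crosses at depth 20 the mean corrected
effect recovers a 0.8 logit-unit QTL to within ~3%, comfortably inside
the 10% recovery band the tests assert.

Significance uses the fixed threshold p < 0.001 with no
multiple-testing adjustment — the convention for this design, kept
deliberately; `manhattan_table()` / `plot_manhattan()` expose
\(-\log_{10}(p)\) with the threshold as metadata. The type-I error of
the scan is validated on null crosses with effectively unlinked markers
(1,000 cM spacing), where the binomial reference for the count of
false positives is valid; on a dense map, linkage disequilibrium
clusters the exceedances and no binomial band applies.

# Linkage map and interval mapping

Simplex AAAA × RA markers are recoded to carrier status of the diploid
parent's segregating allele (for RRRR × RA, the A allele), filtered on
missingness (< 10%) and 1:1 segregation
(\(\chi^2 = (n_0-n_1)^2/(n_0+n_1)\), 1 df, \(\alpha = 0.001\)).
Two-point recombination is the mismatch fraction folded at 1/2, with
phase (coupling/repulsion) from the mismatch majority and a binomial
LOD against r = 0.5. Grouping is the transitive closure at r ≤ 0.20
(single linkage — the simplest rule consistent with a bare threshold;
configurable), keeping groups of ≥ 10 markers. Ordering is greedy chain
construction refined by deterministic 2-opt on the sum of adjacent
recombination fractions (a physical order can be imposed instead);
positions are cumulative Haldane distances, and phases are propagated
along the order from the group anchor.

`sim_scan()` evaluates every 5 cM plus all marker positions. Carrier
probabilities conditional on the nearest non-missing flanking markers
use the standard backcross formulas under Haldane (single-flank beyond
the ends, prior 0.5 with no information), and the means are regressed
on them (Haley–Knott). Regression was chosen over EM mixture ML: at
these effect sizes the two agree closely, and it keeps the linkage arm
algebraically consistent with the continuous-mapping arm — at a fully
observed marker the scan statistic *equals* the single-marker
regression, which the tests assert exactly. Peaks are local maxima at
\(-\log_{10}(p) \ge 2\), thinned so that only the highest survives
within 30 cM (a dense grid otherwise reports a peak per noise wiggle).
`cim_scan()` adds the carrier expectations at cofactor positions
(default: the SIM peaks) as covariates, excluding cofactors within
10 cM (configurable) of the test position and dropping collinear ones
by rank check. `pairwise_ld()` gives coupling-phase \(r^2\) and its
decay with distance; `detect_translocation()` flags groups in which at
least two physical chromosomes each contribute ≥ 5% of the markers, so
a single misassigned marker does not raise a false alarm.

# Gene annotation

`parse_gff3()` extracts `gene` features (1-based inclusive coordinates,
as in GFF3; `genes_to_bed()` converts to 0-based half-open BED).
`closest_feature()` returns the gene minimising the bp gap to the SNP on
either strand — 0 inside a gene — replicating a closestBed-style query;
exact ties are all reported, ordered by gene id, and downstream tables
take the first. Distances bin as within-gene / < 1 kb / 1–4.5 kb /
> 4.5 kb, with exactly 1,000 bp falling in the second bin ("less than
1 kb" is strict). The implementation is verified exactly against a
brute-force scan on 1,000+ random instances.

# Numerical choices and problem sizes

* p-values are computed via `pt(log.p = TRUE)`; \(-\log_{10}(p)\) is
  exact far beyond double-precision underflow of p itself.
* REML uses `lme4` with `xtol_abs = ftol_abs = 1e-12`; singular fits
  (variance at the zero boundary) are accepted, matching the
  non-negativity constraint of REML.
* Adjacent recombination estimates are capped at 0.4999 before the
  Haldane transform so a stray estimate cannot produce an infinite map.
* The 2-opt ordering evaluates reversals by their two boundary edges
  (O(1) per candidate), making the refinement deterministic and fast.
* Validation problem sizes were chosen to estimate each property with
  comfortable Monte-Carlo margins at interactive runtimes: 200
  pipeline replicates for effect recovery (SE of the mean ≈ 0.006 on a
  target of 0.8), 20 × ~3,600 informative null markers for type-I
  calibration, 50 seeds for map recovery, and 10,000-draw checks for
  the gamete and dosage-calling laws.

# Known limitations

* The attenuation correction is the triploid closed form; other
  ploidies would need their own factor (the scan itself is
  ploidy-generic).
* Continuous mapping needs an external marker order (physical map); it
  does not estimate one, and it reports no dominance or epistasis.
* The linkage arm maps only simplex markers segregating in the diploid
  parent; duplex/triplex phasing and interference models (Kosambi) are
  out of scope.
* Multiallelic sites are dropped on VCF import.
* The two-run analysis assumes a connected design; fully disconnected
  batches are refused.
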