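---
title: "Designing an allopolyploid SNP array and calling genotypes from two-channel intensities"
author: "snppanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing an allopolyploid SNP array and calling genotypes from two-channel intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snppanel)
```

## The problem

Fixed SNP genotyping arrays interrogate a predetermined set of variant sites
with allele-specific probes and report, per sample and marker, two
fluorescence intensities: `X` for the A (reference) allele and `Y` for the B
(alternative) allele. Building a useful array for an allotetraploid crop such
as oilseed rape (genome AACC, a merger of two closely related progenitor
subgenomes) poses two linked problems that this package implements end to
end:

1. **Panel design** — reduce tens of millions of re-sequencing SNPs to a few
   tens of thousands of probes that are individually assayable (clean,
   genome-unique flanks), informative (common variation), non-redundant
   (linkage-disequilibrium aware) and evenly spread along the genome.
2. **Genotype calling** — turn `X/Y` intensities into genotype calls when a
   probe may hybridise to *both* homoeologous subgenome copies of its locus,
   so that instead of the three diploid clusters (AA, AB, BB) a marker can
   show up to five allele-dosage clusters (AAAA ... BBBB).

Because array-scale data (hundreds of cultivars, tens of thousands of
probes) cannot ship with a package, a first-class synthetic-data module
generates populations, crosses, and intensities with the statistical
structure each stage assumes, at desk scale.

## Panel design

### Filter cascades

Two cascades are implemented with full audit trails
(`filter_resequencing_snps()`, `filter_array_probes()`); each audit row
records `n_in`, `n_removed`, `n_out` and conservation is machine-checked.
Thresholds (in `filter_params()`) follow the published screen to the letter,
including its mixed strictness:

| rule | threshold | strictness |
|---|---|---|
| minor allele frequency (re-seq screen) | 0.05 | `>=` |
| mapping quality | 30 | `>=` (missing MQ fails) |
| second-allele carriers | 10 samples | `>=` |
| clean flanks | no other SNP within 50 bp | inclusive boundary |
| flank uniqueness | no second genomic match | identity `>= 0.85` rejects |
| call frequency (probe screen) | 0.8 | strictly `>` |
| cluster separation | 0.15 | `>=` |
| minor allele frequency (probe screen) | 0.05 | strictly `>` |
| probe spacing | 200 bp | distance must exceed 200 |
| design score | 0.6 | `>=` |

"Second allele present in at least 10 varieties" is read as *at least 10
samples carrying at least one copy of the minor allele* (the carrier
interpretation; counting only homozygotes would be the stricter alternative
and is not what a screen for usable polymorphism wants).

Flank uniqueness compares the 101-bp probe context (50-bp flanks plus the
variant base, forward strand only) against every other location in the
genome by *ungapped* identity — matching bases over the probe length — via
an exhaustive scan on chromosomes up to 200 kb and an exact 16-mer
seed-and-verify prefilter above that (the same structure BLAST-type searches
use, and with the same theoretical blind spot: a copy mutated in every seed
window is invisible; at the identity ceiling of 85% this is vanishingly rare
for random mutation placement). Gapped-alignment identity and E-values are
deliberately not reproduced; for substitution-only duplicates the ungapped
scan and a Smith–Waterman local alignment coincide, which is how the
acceptance suite cross-checks it.

### Binning, LD grouping, selection

The genome is tiled into 100-kb bins (0-based half-open). Within each bin —
bins are the grouping universe, groups never span bins — sites are grouped
greedily: the unassigned site with the highest MAF (ties: smaller position)
becomes a representative, every unassigned site with genotype-dosage
`r^2 >= 0.65` to it joins, repeat. Dosage `r^2` (squared Pearson correlation
of 0/1/2 vectors over pairwise-complete samples) is the standard phase-free
estimator for unphased calls; no haplotype EM is attempted. The greedy
ordering by MAF is a package choice (the criterion the selection stage
ranks by), fixed so the hand-traceable examples pin behaviour.

Selection (`select_panel()`) takes, per bin, up to five score-eligible sites
in decreasing MAF order, at most one per LD group while unrepresented
groups remain; bins inside a QTL window (interval ± 150 kb) have their
target raised to `max(target, 3)`, never exceeding the eligible candidates —
the `max()` resolution of the two density rules is a package choice, as the
source states both without resolving conflicts. A final global pass enforces
the 200-bp spacing, dropping the lower-MAF member of a conflict (consistent
with the screen's priority rule). `validate_panel()` re-checks score, caps,
spacing and the one-per-group preference from scratch on every emitted
manifest.

The proprietary assay design score is replaced by a documented surrogate
(`design_score_surrogate()`): start at 1.0; −0.2 if the GC fraction of the
101-mer leaves [0.30, 0.70]; −0.2 per non-overlapping 6-bp homopolymer
block; −0.5 for any ambiguity character; floored at 0. Only its thresholding
role (≥ 0.6) matters downstream.

## Genotype calling

### The theta/R model

Intensities are polar-transformed: `theta = (2/pi) * atan(Y/X)`,
`R = X + Y`. Under channel signal linear in allele dose with equal gains, a
B-dose of `g` out of ploidy `p` sits at `theta = (2/pi) * atan(g/(p-g))`:
`0, 1/2, 1` for diploid markers and `0, 0.205, 0.5, 0.795, 1` for
intergenomic (5-dosage) markers. Note the intermediate dosages do *not* sit
at `g/4` — the arctan transform is not linear in the allele ratio — and the
call maps use this transformed grid.

### Cluster-model fitting

Per marker, samples with `R` above background are clustered on theta
(`fit_cluster_model()`). The 1-D structure is exploited for determinism:
for each candidate `k` the sorted thetas are split at the `k−1` largest
gaps (exactly single-linkage clustering in one dimension; ties broken
toward the leftmost gap), each segmentation is scored as a Gaussian mixture
(cluster standard deviations floored at `min_sd = 0.01` so that exact
noise-free clusters remain finite-likelihood), and `k` is chosen by BIC
with `3k − 1` parameters. Two refinements matter in the limits:

* **Discrete data.** When the marker has at most `max_k` distinct theta
  values (the noise-free limit), every distinct value becomes its own
  cluster outright; BIC would otherwise merge a rare dosage class observed
  in one or two samples into its neighbour.
* **Coherence guard.** A marker whose every substantial cluster (≥ 3
  samples and ≥ 5% of the panel) is more diffuse than `max_sd = 0.1` has no
  credible signal clusters — background-ratio noise spreads theta an order
  of magnitude wider than any true genotype cluster — and is classed
  `no_signal`. Without this guard a panel of dead probes can produce
  accidental "monomorphic" fits.

Cluster quality uses two surrogates for unpublished vendor statistics: the
separation score is the minimum gap between adjacent ±2-sd theta envelopes
(floored at 0; defined as 1 for k < 2), and the training-quality score is
the mean silhouette of the theta assignment rescaled to [0, 1], thresholded
at 0.5. Both preserve the thresholding role, not the vendor's values.

### Classification and calling

`classify_marker()` maps a fit to
`no_signal / monomorphic / polymorphic_3 / intergenomic_5 / unclassifiable`:
k = 1 is monomorphic; k = 2–3 is diploid polymorphic provided the clusters
round to distinct AA/AB/BB positions; k = 4–5 is intergenomic; a collision
(two clusters rounding to the same code — exactly the "cannot distinguish
heterozygote from homozygote" failure mode of blended homoeologous signal)
or sub-threshold separation/quality is unclassifiable. `build_cluster_file()`
fits and classifies a reference panel, retains everything except
`no_signal` and `unclassifiable`, and emits a conserved audit
(`retained = input − no_signal − poor`). The background threshold is
relative — 10% of the panel-wide median marker R — so it survives arbitrary
intensity units; a panel consisting *only* of dead probes has no internal
reference scale, which is why the coherence guard above exists.

Calling (`call_genotypes()` / `predict()`) assigns the nearest cluster by
theta z-distance with a 3-sd no-call guard and a below-background no-call.
Replicate concordance reports discordant non-NC cells over the *total*
retained marker count (the convention under which 166 differing probes of
28,509 is 0.58%).

## Downstream analyses

* **BSA window scan** (`differential_scan()`): bulks are majority-consensus
  calls (`bulk_consensus()`) — pooled DNA on an array behaves like one
  sample; allele-frequency modelling of pools is deliberately out of scope.
  Differences are counted in 1-Mb half-open windows; the peak is the argmax
  (leftmost on ties).
* **Variety comparison** (`variety_compare()`): differing non-NC calls, the
  fraction over markers called in both (the denominator is reported
  explicitly rather than reproducing any published percentage whose
  denominator is unstated), and 100-kb bins hit.
* **GMO dilution** (`gmo_mixture_fraction()`, `gmo_detect()`): a `d:1`
  negative:positive mixture is reported as `100/d` percent — the only
  convention that prints 30:1 as 3.3%. The detection rule is a one-sided
  Mann–Whitney test at alpha 0.01 *and* a median-above-the-negative-99th-
  percentile guard; the source names no test, so this conservative pairing
  is a package convention.

## The synthetic world

`sim_config()` states the world once; nothing in it is tuned per test.

| parameter | default | why |
|---|---|---|
| `n_samples` | 200 | order of a modest diversity panel; the cluster-file tests use 192, the published reference-panel size |
| `site_density` | 1/kb | desk-scale thinning (real re-sequencing density is ~30× higher) |
| `n_founders` | 8 | few founder haplotypes per block give strong within-block LD |
| `maf_shape1/2` | 0.6 / 1.4 | Beta spectrum skewed toward rare alleles, support (0, 0.5] |
| `block_length_mean` | 50 kb | LD decay within a 100-kb bin is visible but incomplete |
| `recomb_rate` | 1e-8 /bp | ~1 cM/Mb, a generic plant-genome scale |
| `homoeolog_fraction` | 0.3 | a minority of candidate probes survive flank screening yet still cross-hybridise |
| `no_signal_fraction` | 5445/42090 | the no-signal rate observed on the real array |
| `signal_mean` | 2000 | full diploid signal, arbitrary fluorescence units |
| `noise_sd` | 20 (1%) | additive per-channel noise after bead-level averaging; gives theta cluster sd ≈ 0.01, typical of production arrays, and places the transgene detection limit between 1% and 3.3% mixture — the qualitative result the detection figure reports |
| `r_cv` | 0.1 | shared multiplicative R noise; cancels in theta, so R varies realistically while clusters stay tight |
| `background_mean` | 30 | dead-probe signal floor |

Populations are founder-haplotype mosaics: each chromosome is cut into
exponential-length blocks, each block carries `n_founders` founder
haplotypes, and each sample haplotype copies one founder per block. This
gives directly controllable within-block `r^2` against near-independence
across blocks with trivial, fully deterministic code; it makes no claim to
coalescent or demographic realism, and the homoeologous "shadow" locus is
an independent Hardy–Weinberg locus rather than a linked one — sufficient
to reproduce the cluster-blending geometry, which is all the calling engine
sees. A green simulation test therefore establishes that the algorithms
recover a stated statistical structure, not that they would survive every
pathology of real hybridisation chemistry (batch effects, affine channel
crosstalk, intensity saturation are all out of scope; raw X/Y are taken as
already normalised).

For the BSA acceptance world the cross uses `recomb_rate = 1e-6` (100
cM/Mb) and a causal locus fixed mid-window at chr01:4,500,000 on a 10-Mb
chromosome. The compression is deliberate and computed, not tuned: a BC2F1
bulk's consensus flips where the heterozygote fraction `(1−c)^2` crosses
0.5, i.e. at recombination fraction 0.29 ≈ 0.44 Morgan; for that flip
boundary to fall inside a 1-Mb scan window the map must put ~90 cM in a
megabase. At genome scale the same localisation comes from chromosome-long
maps; at desk scale it must come from map compression.

Determinism: one master seed; every generator derives an independent
sub-seed via `derive_seed()` (kept below 2^31), and all fitting is
seed-free (largest-gap segmentation, closed-form mixture scoring), so the
same inputs give byte-identical VCFs, intensity tables, cluster files and
call matrices.

## Known limitations

* The seed prefilter can in principle miss a duplicate mutated in every
  16-mer window; exhaustive scanning is used wherever tractable.
* Classes are mutually exclusive here; published three-way marker counts
  overlap and are not reproduced as printed.
* The one-per-group preference is validated on the emitted manifest; a
  spacing removal can, in contrived candidate sets, leave a group
  unrepresented after selection.
* `read_cluster_file()` restores cluster geometry and call maps exactly but
  takes calling thresholds from `calling_params()`, not from the file.
* The GMO detection limit is a property of the stated noise model; with
  noisier chemistry the same code yields a higher limit.
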