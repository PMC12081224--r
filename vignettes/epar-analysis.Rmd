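---
title: "Detecting and dating pseudoautosomal extensions with eparscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating pseudoautosomal extensions with eparscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eparscan)
```

## The problem

The major pseudoautosomal region (PAR1) at the tips of the human X and Y
short arms is the obligate crossover zone of male meiosis. Some Y
chromosomes carry an *extended* PAR (ePAR): non-allelic homologous
recombination (NAHR) between a PAR1-associated LTR6B retroelement on the Y
and a paralogous X-specific LTR6B moves ~115 kb of X material onto the Y,
shifting the pseudoautosomal boundary. The reciprocal product of the same
exchange is an X chromosome deleted for that interval.

`eparscan` implements the complete analysis chain for this system:

1. **Dosage screen** — detect ePAR carriers (males with two copies of the
   screened X interval), male deletion hemizygotes (zero copies) and female
   deletion carriers from SNP-array intensities.
2. **Junction analysis** — type recombinant LTR6B junction sequences,
   localize the crossover within the element, and test allele-sharing
   asymmetry between the parental elements.
3. **Lineage history** — assign Y haplogroups on a SNP-labelled reference
   phylogeny, count the minimum number of independent NAHR origins by
   irreversible parsimony, convert a reference phylogeny into a total
   generation count and an NAHR rate, and test Hardy-Weinberg equilibrium of
   the X deletion.
4. **Founder dating** — TMRCA of carrier clusters from Y-STR haplotypes
   (ASD method) and from SNP accumulation, plus founder-expansion folds.
5. **Phenome scan** — Firth-penalized logistic regression for binary traits
   and linear regression for quantitative traits, with Benjamini-Hochberg
   FDR control.
6. **Synthetic data** — generators with known truth for every stage, so the
   whole pipeline is testable without any cohort download.

## The dosage screen

### Intensity model and normalization

The screen assumes marker intensity is linear in copy number. The synthetic
generator draws

```
value = copy_signal * copies + background + N(0, noise_sd)
```

per marker. `background` models non-specific hybridization; it keeps
zero-copy intensities positive, which matters because the sex-balance
filter works on log2 ratios. No public noise parameters exist for the
screening array, so the defaults (`copy_signal = 1`, `noise_sd = 0.1`,
`background = 0.4`) were fixed once at values that give the visually clean
three-band separation typical of median-summarized array dosage data; they
are generator settings, not estimates from any cohort.

Normalization follows the *median of deviation from the median in females*:
per marker, subtract the female median; per sample, take the median of
those deviations across the ~60 informative markers in the screened
interval. On this scale two-copy samples centre at 0 and each copy lost
moves a sample down by one `copy_signal` unit. The construction is
invariant to any per-marker additive shift applied to all samples.

### Sex-balance filter

Samples with unbalanced sex chromosomes (e.g. 47,XXY) are removed before
classification: per sample, the median log2 ratio to the sex-matched
reference median is computed separately over X-flank and Y-flank markers,
excluding all PAR-associated markers, and both must lie within ±0.35. A
47,XXY male sits near +0.85 on the X-flank median and is excluded.

### Reference bands and calls

Reference samples are picked in one deterministic pass (nearest dosage
centre, anchored at the male and female medians), and the haploid and
diploid bands are their central 95% intervals — nearest-rank order
statistics by default (`lower = ceiling(0.025 n)`-th value), or
`mean ± 1.96 sd` with `ci_method = "gaussian"`. At least 40 reference
samples per band are required.

The deletion band defaults to the haploid band translated one copy-step
down, i.e. centred on the zero-copy dosage level. (An alternative sometimes
suggested — a fixed multiple of the haploid band *width* below the haploid
band — cannot work: band width is a noise-scale quantity while the
zero-copy class sits a full copy-signal lower, so such a band would be
empty of true deletions at any realistic noise level.) Bands must be
ordered deletion < haploid < diploid with no overlap; zero-width bands are
legal so that noiseless data remain classifiable.

Calls: males in the haploid band are `REF`, in the diploid band `EPAR`
("in the range expected for normal females"), in the deletion band
`DEL_HEMI`; females are `REF` / `HET_DEL` / `HOM_DEL` respectively;
everything else is `UNCLASSIFIED`, and balance-filter failures are
`EXCLUDED_IMBALANCE`. The classes partition the cohort, and male calls are
monotone in the normalized value.

Because the bands are *central 95%* intervals, about 5% of every true class
falls just outside its own band and is left `UNCLASSIFIED` whenever noise
is non-zero. Zero-noise cohorts are classified without error; at realistic
noise the screen recovers >90% of planted carriers with essentially no
wrong-class calls. This is the designed trade-off: the screen is a
candidate filter, and the published workflow likewise confirmed candidates
by junction PCR.

Incidence percentages use the non-excluded same-sex samples as the
denominator, matching the convention of reporting carrier rates among
successfully haplogrouped men. Raw proportions are always retained;
rounding is presentation-only.

## Junction analysis

The two parental LTR6B elements are held on a common 1-based coordinate
frame spanning the 559-bp maximal alignment, position 1 at the distal (5')
end. Gaps occur only at two variable-length sites (a distal `CCACAC` site
and a proximal `TTACAAGGTG` site), so aligning an observed junction is
deterministic: its total length (551/554/559 bp) identifies the
length-allele combination and therefore the gap columns. Lengths outside
the recognized classes are an error naming the observed length. The set of
recognized lengths is stored on the model rather than derived, because not
every allele combination is observed in nature.

Each catalog position is called `X` (matches an X-only allele), `Y`
(Y-only), `shared` (allele present in both parents) or `missing`. A
junction type is an *exact* sequence identity class — no mismatch tolerance
— matching how distinct junction structures are enumerated in practice.
Published canonical sequences keep their names; new types are numbered in
first-seen order (or lexicographic order with
`canonical_order = "sorted"`, which makes ids stable under input
reordering).

Crossover intervals: for an ePAR junction the crossover lies strictly
between the last informative position in the X state and the first in the Y
state (`FIXED_ONLY` uses fixed differences; `MAJOR_ALLELE` uses every
position where the parental major alleles differ, and can only narrow the
interval). Deletion junctions swap the parents; reciprocal products of one
exchange therefore yield identical intervals. Interleaved parental states
are *not* silently truncated — they raise an error flagging possible gene
conversion, since such exchanges are known to be complex.

Two observations represent the same rearranged chromosome only if they
share the junction type *and* the flanking-SNP haplotype (for deletion
junctions, two Y-PAR-derived distal SNPs and one X-derived proximal SNP).

The allele-sharing test classifies every shared-polymorphism position by
(i) X-minor = Y-major? and (ii) Y-minor = X-major?, and applies a
one-tailed Fisher exact test (upper hypergeometric tail on the joint cell)
for over-representation of the first relation. Degenerate margins return
p = 1 by convention.

## Lineage history

### Haplogroup assignment

A simplified tree-walk over a reference phylogeny whose branches carry
defining SNPs: every root-to-tip path is scored by derived minus ancestral
calls at its branch SNPs; the call is the deepest branch on the best path
that carries a derived call (ties: more derived calls, then lexicographic
label). Derived calls off the chosen path are reported as conflicts, never
dropped. All-ancestral genotypes return the root.

### Minimum origins by irreversible parsimony

For each junction type, presence is marked on the lineage tips carrying it,
and the minimum number of gains under a gain-only (no-loss) model is the
number of maximal subtrees whose tips are all present. Gain-only is the
right model because the same junction observed in disjoint haplogroups is
evidence of recurrence; a loss-permitting model would collapse everything
to a single ancient gain. Two caveats follow directly from the definition
and are worth stating because they are easy to get wrong:

* The count is *not* monotone in the presence set — adding a tip can
  complete a clade and merge several gains into one. It can never grow by
  more than one per added tip.
* When one NAHR event arises *within* the clade of an earlier one (nested
  events), the later junction replaces the earlier type on its subclade;
  the earlier type's presence is then a clade-with-a-hole and gain-only
  parsimony counts it more than once. "Minimum" is a lower bound only under
  non-nested origins, which is how the recovery tests plant events.

The bundled `extdata/epar_haplogroup_tree.nwk` encodes an ISOGG-consistent
topology for the ten ePAR-associated lineages (E1a-M132, I1a-Z58,
I1c-Z17954, I2a-M223, I2a-L233, I2a-L1294, K-M9, R1b-L52, R1b-U152,
R1b-CTS3655) interleaved with non-carrier relatives; marking the ten as
present yields a minimum of 10 independent origins.

### Generations and NAHR rate

A reference phylogeny with `S_total` SNPs and a mean of `s_tip_mean` SNPs
from root to tip contains `S_total / s_tip_mean` independent lineage
traversals; multiplied by `TMRCA / generation time` this gives the total
generations in the tree, and the number of independent origins divided by
that total is the NAHR rate per generation. With 60,555 SNPs, ~1,300 per
tip, a 190,000-year TMRCA and 31-year generations this is ~285,000
generations, and 18 origins give ~6.3 × 10⁻⁵ per generation. Values are
returned unrounded.

### Hardy-Weinberg on the X

The allele frequency is estimated jointly from hemizygous males and female
genotypes, `q = (m + het + 2 hom) / (n_males + 2 n_females)`, and the five
observed cells are compared to expectation by chi-square on 2 df (five
cells − two sex totals − one estimated parameter). At rare-allele
frequencies the expected homozygote count is far below 5, which makes the
chi-square conservative; a parametric-bootstrap p-value is available with
`mc = TRUE`. The statistic scales linearly when all counts share a common
factor, so "non-significance" at fixed proportions is sample-size-dependent
— as it should be.

## Founder dating

### ASD from Y-STRs

The founder-anchored average-squared-distance estimator: with founder
repeat `f_l`, `ASD_l = mean_i (a_il − f_l)²` has expectation `mu_l T` under
the strict single-step mutation model (every mutation ±1 repeat,
symmetric). The point estimate is the mean over loci of `ASD_l / mu_l` and
the quoted uncertainty is the standard deviation of those per-locus ratios
divided by `sqrt(L)` — the "±" convention is recorded in the output
metadata because inter-locus spread is the dominant error source in
star-like genealogies. The founder defaults to the per-locus modal repeat
(ties resolved toward the mean, then the smaller count) since carrier
clusters are dated around an inferred founder haplotype; a pairwise
variant (`ASD / 2 mu`) is available by flag. Missing repeat calls are
excluded per locus, not per sample.

The estimator is unbiased under the generator's own model: across 50
simulated star genealogies of 100 chromosomes with a 65-generation founder,
the mean estimate is within two standard errors of 65. The bundled 23-locus
panel (11 slower- plus 12 faster-mutating loci) carries literature-scale
forensic mutation rates; substitute calibrated rates where available, since
TMRCAs scale inversely with them.

### SNP accumulation

`T = n_snps / rate` with an exact Poisson 95% CI on the count via the
chi-square quantile relation, `[qchisq(.025, 2n)/2, qchisq(.975, 2(n+1))/2]
/ rate`. The interval attains (slightly over) nominal coverage, as exact
Poisson intervals do.

## Phenome scan

Model dispatch is a two-way rule: phenotypes whose non-missing values lie
in {0, 1} get Firth-penalized logistic regression, everything else linear
least squares (ordered-categorical handling is out of scope). The Firth
fit maximizes the Jeffreys-penalized likelihood with Newton steps on the
modified score (tolerance 1e-8, max 50 iterations, step-halving), keeping
estimates finite under complete separation; p-values are penalized
likelihood-ratio tests (coefficient fixed at 0, remaining coefficients
re-maximized, penalty from the full-design information) rather than Wald,
for separation robustness. Covariates are caller-supplied — restricted or
within-haplogroup comparisons are expressed through the exposure and
covariate choices. Each phenotype uses its complete cases; q-values are
Benjamini-Hochberg across the whole scan.

## What the generators do and do not emulate

* **Cohorts**: copy-number-proportional intensities with additive Gaussian
  noise, sex-balanced flank markers and a configurable aneuploid fraction.
  Not emulated: batch effects, GC waves, probe-specific variances — so a
  clean three-band separation here does not guarantee one on real arrays.
* **Genealogies**: star topologies only (the regime of a rapid founder
  expansion). Coalescent topology variation, multi-step STR mutations and
  rate heterogeneity beyond the per-locus table are not modelled, so the
  ASD calibration checks the estimator, not the demography.
* **Junctions**: a synthetic two-parent element pair with five fixed
  differences in the first 100 bp, 19 shared polymorphisms biased so the
  X-minor allele usually matches the Y-major (as in the real pair), and
  two length sites giving 551/554/559-bp classes. Sequences are synthetic,
  not the genomic elements; tests of typing and localization verify the
  machinery, not any cohort result.
* **Phenotypes**: Gaussian/Bernoulli traits with planted carrier effects
  and no trait-trait correlation, so FDR control results apply to the
  independent-trait setting.

## Reproducibility and problem sizes

Every stochastic operation takes an explicit seed; `run_pipeline()` derives
all stage seeds from one master seed and reruns are byte-identical. The
test suite sizes were chosen to make Monte-Carlo assertions sharp at
desk scale: 200 random trees for the parsimony oracle, 1,000 junction
round-trips, 5,000 Poisson-coverage replicates, 50 ASD seeds, 100 null
phenome scans, and one biobank-scale screen (218,282 males) for planted
frequency recovery.
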