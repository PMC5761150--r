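---
title: "Methods: diversity, runs of homozygosity and effective population size in rohdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, runs of homozygosity and effective population size in rohdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohdiv)
```

rohdiv implements the standard single-population genomic-diversity workflow
used in conservation genetics of dog breeds and other livestock: SNP-array
quality control, heterozygosity-based diversity indices, sliding-window
detection of runs of homozygosity (ROH), ROH-based inbreeding, and an
LD-based estimate of contemporary effective population size. The canonical
use case is a canine HD array panel (38 autosomes, ~170k SNPs before QC) on
a few dozen dogs of one breed. This vignette explains the models and every
tunable that matters, the choices made where the design was genuinely open,
and what the simulation-based validation does and does not demonstrate.

## Data model and quality control

Genotypes are held as a dosage matrix (individuals x loci) counting copies
of the B allele, with `NA` for failed calls. The B allele is always the
allele with the *lower sample frequency*; at an exact 50/50 tie the
lexicographically later label is designated B. This makes the coding
deterministic and invariant to which allele a PLINK file happens to list
first, which in turn makes file round-trips and dosage-based statistics
label-stable.

QC applies the usual array filters in a fixed order, each locus attributed
to the first filter that removes it: non-autosomal loci (unmapped labels,
then sex chromosomes), locus call rate below 0.95, minor allele frequency
below 0.05 (computed on non-missing calls), then individuals with *over*
10% missing genotypes. The locus thresholds are inclusive (a locus exactly
at 0.95 or 0.05 is kept) while the individual rule is strictly "over",
reading the conventional wording literally. Locus filters run before the
individual filter in a single pass; no iteration to convergence is
attempted, because the thresholds are loose enough that a second pass
virtually never changes anything (idempotence is tested).

## Diversity indices

Per locus with minor-allele frequency $q$ ($p = 1 - q$), observed
heterozygosity is the heterozygote fraction among non-missing calls and
expected heterozygosity is $H_E = 1 - p^2 - q^2$. The population inbreeding
index is the per-locus average

$$F_{IS} = \frac{1}{L}\sum_{l=1}^{L}\left(1 - \frac{H_{O_l}}{H_{E_l}}\right),$$

with loci monomorphic in the sample ($H_{E_l} = 0$) excluded from this
average only — the term is undefined there and inventing a value would bias
the index. Summary means are unweighted over loci; the dispersions reported
alongside are population standard deviations (divisor $L$).

Per-individual molecular inbreeding uses the method-of-moments
homozygosity-excess estimator
$F_i = (O_{hom} - E_{hom}) / (L_i - E_{hom})$, with
$E_{hom} = \sum_l (1 - 2 p_l q_l)$ taken over the individual's non-missing
loci at the full post-QC cohort's allele frequencies. Negative values mean
heterozygosity above Hardy-Weinberg expectation. The field reports
per-individual marker-based inbreeding under the same $F_{IS}$ name as the
population index; the two coincide only on average, so rohdiv exposes both
(`diversity_summary()$f_is` and `per_individual_F()`) and uses the
per-individual estimator wherever a per-animal value is needed, e.g. in the
correlation with ROH-based inbreeding.

## Runs of homozygosity

The caller reproduces the windowed procedure of the standard tooling. A
window of `window_snps = 50` consecutive SNPs slides along each chromosome;
a window is *homozygous* if it contains at most one heterozygous and at
most two missing calls. Each SNP receives the fraction of homozygous
windows among the windows that cover it (edge SNPs are covered by fewer
windows). A SNP can join a run when that fraction is at least
`window_threshold = 0.05` **and** its own call is not heterozygous — so
heterozygous calls always terminate runs, while missing calls already
tolerated by the window rule may sit inside one. Maximal stretches of such
SNPs are split wherever consecutive SNPs are more than 100 kb apart,
trimmed to the outermost homozygous non-missing call, and then gated:

* at least `min_snps` SNPs — by default the false-positive bound
  $s = \lceil \ln(\alpha / (N L)) / \ln(1 - \overline{H_O}) \rceil$
  with $\alpha = 0.05$, evaluated on the data at call time ($N$
  individuals, $L$ loci, mean observed heterozygosity). For a 48-dog,
  94k-SNP panel at $\overline{H_O} = 0.371$ this gives $s = 40$;
* at least 1 Mb long (lengths are 1-based inclusive,
  `end - start + 1`), excluding short LD-driven homozygous stretches;
* at most 50 kb per SNP (`length_bp / n_snps`), so sparse map regions
  cannot masquerade as ROH.

All thresholds are inclusive. Chromosomes with fewer SNPs than the window
are reported uncallable rather than scanned with a smaller window, which
would silently change sensitivity. The allowance wording "per run" that
circulates in the applied literature is implemented at window level, since
the cited sliding-window method defines it there; with hets hard-stopping
runs, a final segment can only contain missing calls the windows already
tolerated, and no extra segment-level cap is imposed.

Per-SNP incidence is the fraction of individuals with at least one segment
covering the SNP (overlapping segments of one individual count once), and
ROH islands are maximal stretches of consecutive SNPs with incidence at or
above 0.75 — the operational definition behind "a ROH shared by 75% of the
animals".

The caller is validated two ways: hand-constructed geometries (tracts at
the length gate, internal gaps, het interruptions) and, more stringently,
exact equality against an independent brute-force nested-loop
reimplementation of the same rules on hundreds of randomized ~200-SNP
instances.

## ROH-based inbreeding

$F_{ROH} = \sum L_{ROH} / L_{AUTO}$ per individual. $L_{AUTO}$ is computed
from the post-QC map as the sum over autosomes of (max position − min
position + 1) — the SNP-*covered* autosome length — rather than hard-coding
any array constant; the canine HD array covers about 2268.83 Mb. Using
covered length keeps the coefficient internally consistent on any input,
including reduced synthetic genomes. Individuals without segments get
$F_{ROH} = 0$, and a segment longer than its chromosome's covered span is
rejected as a consistency error.

## LD-based effective population size

SNPs are first thinned for multicollinearity: in 50-SNP windows advancing
by 5 SNPs along each chromosome, the locus with the highest variance
inflation factor (diagonal of the inverted window correlation matrix) is
removed, greedily, until all remaining VIFs are at or below 2; removals
persist across windows; ties go to the lower-MAF locus, then map order. A
tiny ridge keeps perfectly collinear windows invertible, which simply hands
the greedy step an effectively infinite VIF.

LD is then the squared Pearson correlation of dosage vectors
(Burrows-composite-equivalent for unphased data) over individuals complete
for the pair. Only pairs on *different chromosomes* enter the mean —
physical linkage inflates $r^2$ and would bias $N_e$ downward — and loci
under 5% MAF are excluded, since the estimator is strongly affected by rare
alleles. With $S$ the harmonic mean of per-pair sample sizes, the sampling
expectation $E[r^2|S] = 1/S + 3.19/S^2$ (for $S \ge 30$; otherwise
$0.0018 + 0.907/S + 4.44/S^2$) is subtracted and the drift relation
inverted:

$$\hat N_e = \frac{1/3 + \sqrt{1/9 - 2.76\, r^2_{drift}}}{2\, r^2_{drift}}$$

for random mating and $S \ge 30$; the small-sample constants are
$(0.308, 2.08)$ and the monogamy variants $(2/3, 7.2)$ and
$(0.618, 5.24)$. A non-positive drift component is flagged `infinite` (no
drift signal at this sample size), a negative discriminant `undefined`.
Only the point estimate is reported — no jackknife interval. Above 5000
usable loci the pair matrix is evenly thinned along the map to bound
memory at a few hundred MB; the pair count is already in the millions
there and the mean $r^2$ is insensitive to the thinning.

## The synthetic-data generator

Because array genotypes of real panels are rarely redistributable, every
stage is validated on generated data whose structure matches what the
analysis assumes:

* **Map**: per chromosome, inter-SNP gaps are exponential (a Poisson
  marker process) with configurable mean, truncated at the chromosome end.
  This deliberately produces occasional gaps beyond the caller's 100 kb
  rule and sparse stretches near the density gate — the edge cases a
  uniform grid would never exercise. The default scale is 5 chromosomes of
  100 Mb at 25 kb spacing; `canine_hd = TRUE` emulates the full
  38-autosome, ~2268.83 Mb, ~94k-SNP post-QC layout.
* **Genotypes**: per locus $q \sim U(0.05, 0.5)$ (or a beta spectrum),
  dosages binomial$(2, q)$ — exact Hardy-Weinberg — then 3% missingness
  and optional symmetric genotyping error. The uniform spectrum gives mean
  $H_O \approx 0.365$, close to the 0.37 seen on real canine HD data.
* **Planted tracts**: homozygous identical-by-descent segments with
  lengths drawn from the published breed ROH class mix (counts 3390 /
  1752 / 463 / 29 over 1–2, 2–4, 4–8 and 8–16 Mb), placed uniformly
  without overlap and at least 1 Mb apart so they are called as distinct
  runs; the final tract is trimmed so the planted total hits the
  per-individual target F_ROH exactly against the SNP-covered span.
  Within tracts the homozygous allele is drawn by population frequency
  ($P(\text{dosage } 0) \propto p^2$), keeping within-ROH allele
  composition realistic for incidence statistics, and missingness is
  re-applied.
* **Drift populations**: for the $N_e$ estimator, a diploid Wright-Fisher
  population of the requested size evolves for 10 generations (random
  parent pairs, one transmitted allele per locus per parent) before the
  sample is drawn as offspring of the final pool; the finite pool is what
  generates the $\approx 1/(3N_e)$ LD among unlinked loci that the
  estimator inverts. Above $N_e = 10^4$ the pedigree matrices become
  impractically large while drift LD is far below sampling noise, so
  frequencies drift by binomial sampling and the sample is drawn in
  Hardy-Weinberg proportions (an effectively infinite parent pool).

### Validation conditions, and what they show

The parameter-recovery experiment plants per-individual targets uniform in
[0.05, 0.225] — the range observed in the breed survey that motivated the
defaults — in 48 individuals over 5 x 52 Mb chromosomes at 13 kb mean
spacing (~20k SNPs), with no missingness or genotyping error, and demands
mean absolute error at most 0.01 and rank correlation at least 0.98 after
the full QC → caller → inbreeding pipeline. Two deliberate choices here:

* 13 kb mean spacing matches the canine HD array *as designed*
  (173,662 SNPs over 2268.83 Mb ≈ 13 kb); at the ~24 kb post-QC spacing an
  exponential map crosses the 100 kb gap rule at 2–3% of intervals, which
  fragments tracts for reasons that are properties of the map, not of the
  caller. The per-individual ±0.01 unit test uses 10 kb for the same
  reason.
* Missingness is disabled so the experiment isolates caller geometry:
  with 3% missingness and only 48 individuals, the 0.95 call-rate filter
  removes ~18% of loci at random, and triple-removals open artificial
  >100 kb gaps. That marker-loss pathway is real but belongs to QC, not to
  the caller; it is exercised separately under the null and in the
  gate-consistency tests, which run at 3% missingness.

Residual recovery error (~0.002–0.004 MAE) is dominated by chance
homozygous extension at tract edges (expected ~1.7 SNPs per side at
$H_O \approx 0.37$) minus the half-gap clipped at each boundary — a small
positive bias that grows with the number of tracts, hence with the target.

The null experiment (200 individuals, 5000 SNPs, 10 seeds) checks that
mean $F_{IS}$ and mean per-individual $F$ stay within ±0.02 of zero and
that *no* ROH are called: at 13 kb spacing the 1 Mb length gate needs ~77
consecutive non-heterozygous calls ($P \approx 10^{-15}$ per start), so
any called segment would be an implementation fault, not bad luck.

These tests validate geometry and calibration, not realism: generated data
have no LD beyond the planted tracts (real arrays do), no ascertainment
bias in the MAF spectrum, no clustering of missingness, and tracts with
hard edges rather than coalescent mosaics. Passing them shows the
estimators do what their definitions say under their own assumptions, not
that those assumptions hold in any particular breed.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive bp (PLINK MAP convention); BED export
  converts to 0-based half-open at write time.
* Frequency ties at 0.5 designate the lexicographically later allele as B;
  the greedy VIF tie goes to lower MAF, then map order; all gate
  thresholds are inclusive.
* Loci with zero non-missing calls carry an explicit `defined = FALSE`
  flag; downstream averages skip them rather than propagating `NaN`.
  Individuals with no usable loci get `NA` inbreeding.
* Zero variance in either inbreeding measure makes the correlation `NA`
  with a warning; fewer than 3 complete pairs is an error.
* An input emptied by QC raises an error naming the stage instead of
  returning an empty matrix.
* Pipeline runs are deterministic given the input: no stage draws random
  numbers; simulation seeds live only in the generator configuration.

## Problem sizes

The shipped test-suite and the reproduction script run at reduced scale,
chosen so each experiment's statistical target is still comfortably
resolvable: recovery at 48 x ~20k (5 chromosomes), the null at 200 x 5000,
the caller-vs-oracle comparison on 200 instances of up to 200 SNPs, and
$N_e$ on 50 sampled individuals x 2000 unlinked loci over 10–20 seeds. The
`canine_hd` generator configuration reproduces the full 38-autosome
layout for users who want the complete emulation.

## Known limitations

* Only biallelic, unphased, autosome-coded diploid data; no VCF input.
* ROH consensus across individuals is the incidence/island definition
  only; no overlap-clustering of segments or gene-level annotation.
* The per-individual marker-based F and the population $F_{IS}$ answer
  slightly different questions; correlations with $F_{ROH}$ use the
  former.
* $N_e$ is a point estimate under the standard bias correction; exact
  agreement with any particular external tool's value is not expected,
  as pair-inclusion rules and MAF screens differ between tools.
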