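---
title: "Methods: Argonaute/methylation colocalization and COBRA quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Argonaute/methylation colocalization and COBRA quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rddmcoloc)
```

## The scientific question

RNA-directed DNA methylation (RdDM) is a small-RNA-guided mechanism that
delivers de novo DNA methylation to homologous loci. In plants the
Argonaute protein AGO4 is a core effector; whether a human Argonaute
(AGO1--AGO4) plays an analogous role can be probed computationally by
asking whether AGO-bound genomic locations, as captured by CLIP
sequencing, colocalize with promoter DNA methylation measured on a
tiling microarray. `rddmcoloc` implements that colocalization analysis
end to end, together with the COBRA (combined bisulfite restriction
analysis) band-intensity formulas used to quantify global LINE-1 and Alu
methylation in the accompanying wet-lab readouts, and a synthetic-data
generator that plants known effects so every stage of the pipeline can
be validated against ground truth without any external download.

## Data model

**Probes and promoters.** Each promoter carries exactly 15 methylation
probes of 50 bp tiled over roughly 1.5 kb; the promoter boundary runs
from the start of probe 1 to the end of probe 15, and promoter-level
methylation is the sum of the 15 probe values (the mean is available;
the two are scale-equivalent for correlation). Coordinates are 0-based
half-open (BED-compatible) everywhere inside the package; conversion to
the 1-based closed convention happens only at the
GenomicRanges/rtracklayer boundary. The TSS is taken at the
transcription-proximal edge of the boundary (start for `+` promoters,
end for `-`), which matches the synthetic tiling layout; for real
arrays with a different probe placement the TSS column can be supplied
directly.

**Binding sites.** CLIP reads arrive as a two-table dialect: a mapped
sequences table (read id, sequence, copy count) and a genome mappings
table (one row per mapped location with mismatch/insertion/deletion
counts). A binding site is simply a read's mapped interval -- no peak
calling or merging -- because nothing finer-grained is identifiable from
mapped locations alone. Reads mapping to more than 30 genomic locations
are discarded (a read with exactly 30 survives). A location is a
*perfect* genome match iff it has zero mismatches, insertions and
deletions; *approximate* mode is the superset that keeps all locations.
Identical intervals aggregate, summing read copies into the site's
support. The default minimum binding length is 15 bp, with a sweep over
{1, 5, 10, 15, 20, 25} bp because the association strength is expected
to vary with binding length.

**Liftover.** Assembly conversion uses UCSC chain files through
`rtracklayer`, wrapped to reproduce UCSC liftOver's reject semantics: an
interval maps only if it lands in a single target range with its length
preserved (i.e. it lies wholly inside one aligned block). Intervals
straddling a gap, split across blocks, or outside all blocks are
reported unmapped -- never truncated -- and excluded with a count, since
silent truncation would shift probe centers and corrupt the distance
analysis. Reverse-strand chains re-express coordinates on the forward
target strand and flip the strand field.

## The colocalization statistics

Probes and sites are treated as numerical ranges; the distance between
two ranges is the distance between their centers, with the center of
`[start, end)` defined as `floor((start + end) / 2)` (deterministic
integer arithmetic; for 50-bp probes the floor is exact). Pairs on
different chromosomes get an infinite-distance sentinel rather than any
finite value.

Each probe is classified twice:

* **MET+/MET-** -- by default, MET+ iff the probe's methylation value
  strictly exceeds the median over all classified probes, with ties
  falling to MET-. The median split is scale-free and reproducible on
  arbitrary array units; an absolute threshold rule is available and is
  what the planted-truth analyses use (see below).
* **AGO+/AGO-** -- AGO+ iff the nearest binding-site center lies within
  `d_max` bp. `d_max` defaults to a sweep over {50, 100, 200, 500,
  1000} bp since no single proximity radius is canonical.

The 2x2 table (a = MET+AGO+, b = MET-AGO+, c = MET+AGO-, d = MET-AGO-)
yields

* odds ratio `OR = ad / (bc)`; if any cell is zero, 0.5 is added to all
  four cells (Haldane--Anscombe) and the result flagged;
* Wald 95% CI `exp(ln OR ± 1.96 sqrt(1/a + 1/b + 1/c + 1/d))` on the
  possibly corrected cells;
* Pearson chi-square `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on the
  raw cells with a 1-df upper-tail p-value. No Yates continuity
  correction is applied by default (the genome-scale tables that
  motivate this analysis make it irrelevant, and the uncorrected
  statistic is the one whose extremely small p-values such analyses
  report); it is available as an option. A zero margin leaves the
  chi-square undefined (reported as such) while the OR is still
  computed under the correction.

Promoters overlapped by sites of two or more distinct proteins are
excluded before tabulation to avoid attributing methylation to the
wrong protein; unbound promoters remain as the AGO- background. The
protein label is an open string rather than an AGO1--4 enum so control
proteins (e.g. PUMILIO2) run through the identical path. No
multiple-testing correction is applied across the sweep (raw p-values
are reported; Bonferroni over the sweep is a one-liner for the caller).

The promoter-level analysis correlates the number of binding sites
overlapping each promoter boundary with the promoter methylation
summary, reporting the sample Pearson r and the two-sided p-value from
`t = r sqrt((n-2)/(1-r^2))`. Two descriptive profiles complete the
picture: mean probe methylation within increasing proximity thresholds
(cumulative membership by construction), and a strand-aware histogram
of site centers relative to the TSS, signed along the gene's
orientation and split into sense/antisense.

## COBRA quantification

Each assay reads five gel bands. Band intensities are normalized by the
printed divisors into molar-equivalent components:

* LINE-1: bands 92, 60, 50, 42, 32 bp with divisors 92, 56, 48, 40, 28
  giving A--E, and `F = ((D + E) - (B + C)) / 2`; methylation percent
  `= (A + 2C + F) * 100 / (2A + 2B + 2C + 2F)`.
* Alu: bands 133, 90, 75, 58, 43 bp with letters A=133, B=58, C=75,
  D=90, E=43 (divisors equal to the sizes), `F = ((E + B) - (C + D)) /
  2`; percent `= (2F + D + C) * 100 / (2A + 2C + 2D + 2F)`.

The LINE-1 divisors differ from the fragment sizes and the Alu letters
are not in size order; both follow the printed normalization exactly.
The estimators are scale invariant (any common rescaling of a lane's
intensities cancels), so arbitrary densitometry units are fine.
Negative intensities from over-subtracted background are clamped to
zero with a warning; estimates outside [0, 100] from inconsistent real
lanes are reported as-is with a flag, never clamped, because silent
clamping would hide QC problems. A missing band is treated as zero
intensity and flagged.

**Forward models.** The synthetic gel generator draws per-molecule
two-CpG methylation patterns (LINE-1: both-methylated / hemimethylated
/ unmethylated; Alu: mm / mu / um / uu) and maps them to bands as:
LINE-1 mm -> 50 + 42, hemi -> uncut 92, uu -> 60 + 32; Alu mm -> 58 +
43 (plus an uncounted 32-bp middle fragment), mu -> 58 + 75, um -> 90 +
43, uu -> uncut 133. Emitted intensity is molar count x printed
divisor, optionally with multiplicative log-normal noise (mean 1,
configurable CV, default 0). These assignments are the unique ones
under which the printed formulas return exactly the true
methylated-CpG fraction for every composition -- solvable by linear
algebra over the pattern counts -- which makes the printed normalization
self-consistent and testable: under them F is identically zero for
noiseless LINE-1 lanes and equals the molar mm count for Alu lanes.
They are a modeling construct for estimator validation, not a claim
about TaqI/TasI chemistry, and every gel manifest carries a note to
that effect.

The delta-delta-Ct utility computes
`2^-((Ct_target,case - Ct_ref,case) - (Ct_target,control - Ct_ref,control))`.

## The synthetic generator and what passing tests mean

The generator plants known effects and writes a manifest from which
every planted quantity is recomputable (`verify_manifest()` asserts
this round trip):

* **Geometry** -- non-overlapping promoters on one synthetic chromosome
  (`chrS1`), 15 contiguous 100-bp steps each carrying a 50-bp probe
  (gapless tiling at span 750), random strand, intergenic gaps drawn
  from 500--2000 bp. Generation uses a single chromosome; the
  cross-chromosome distance sentinel is exercised with hand-built
  interval fixtures.
* **Probe-level association plant** -- an exact number of probes is
  designated AGO+ by placing one binding site whose center falls within
  ±25 bp of the probe center; latent MET+ is drawn with P(MET+ | AGO+)
  = 0.6367 and P(MET+ | AGO-) = 0.3000, a planted odds ratio of 4.089.
  Continuous methylation values are two well-separated Gaussian
  components (means 80 and 20, sd 5 on a 0--100 scale) around the
  latent status, so thresholding at 50 recovers the labels exactly.
  Because the probe step (100 bp) minus the jitter (25 bp) exceeds the
  labeling radius (50 bp), proximity labeling at 50 bp recovers exactly
  the planted AGO+ set -- the generator refuses configurations where
  labels could leak to neighboring probes. The planted-recovery
  analyses dichotomize at the generator's separation threshold rather
  than the median, because the latent MET+ fraction under these
  probabilities is 0.468, not 0.5, and a forced median split would
  misclassify the excess and bias the OR downward by design rather than
  by sampling.
* **Correlation plant** -- per promoter, site count k ~ Poisson(2) and
  methylation `y = 300 + 5 k + N(0, 41)`, spread evenly over the 15
  probes. The implied Pearson r is `5 sqrt(2) / sqrt(25*2 + 41^2) =
  0.170`; slope, noise and rate were chosen to land on that value with
  realistic site counts. The intercept of 300 exists only to keep probe
  values non-negative (clamping at 0 would otherwise perturb the
  correlation; at this intercept the clamping probability is ~1e-13 per
  promoter) and cancels out of the correlation.
* **CLIP reads** -- read lengths uniform on 10--40 bp (straddling the
  15-bp length filter), 15% of reads multimapping to 2--60 locations
  (straddling the 30-location cutoff), 30% of locations carrying edits
  (at least one mismatch/insertion/deletion). The manifest records the
  >30-location count and the surviving site count for every
  (min_length, match_mode) combination from the raw draws.
* **Determinism** -- every generator seeds the RNG explicitly
  (sub-generators at fixed offsets from the base seed), outputs record
  the seed in '#' header comments (TSVs) or the JSON manifest, and
  reruns are byte-identical. BED files are left comment-free for
  interoperability; their seeds live in the manifest.

What the synthetic data does *not* emulate: real sequence content (CpG
islands, repeat consensus), array measurement error structure
(spatial/batch effects, probe affinity), CLIP peak shape or
crosslinking bias, partial restriction digestion, or incomplete
bisulfite conversion. Passing the planted-recovery tests therefore
demonstrates that the statistical machinery is correct and unbiased
under the stated generative assumptions; it does not certify
performance on real arrays, where the MET split and `d_max` choices
interact with unmodeled noise.

## Problem sizes and numerical choices

The validation suite runs the planted-OR recovery at 50,000 probes per
arm (where three standard errors of the OR span about ±0.17), the
correlation recovery at 20,000 promoters (three standard errors of r
span about ±0.02), CI coverage at 500 replicates of 2,000 probes per
arm (binomial noise keeps 95% coverage inside 92--98%), and the COBRA
estimator identity at 1,000 randomized compositions per assay; these
sizes make the stochastic tolerances meaningful while keeping the whole
suite under a minute.

Other fixed choices: interval centers floor; ties at the MET median go
to MET-; the CI multiplier is the conventional 1.96 (not qnorm(0.975));
cross-chromosome distances are `Inf`, never a large finite number;
liftover rejects partial mappings; probes failing liftover would be
reported and excluded rather than guessed. Degenerate inputs
(all-equal methylation under the median rule, zero-variance t-test
differences, zero contingency margins, zero COBRA denominators, empty
site sets) are reported as undefined with notes instead of being
silently coerced.

## Limitations

The analysis is associational: colocalization odds ratios cannot
distinguish AGO-directed methylation from co-occurrence driven by
shared genomic covariates (CpG density, expression). Binding sites are
raw mapped intervals, so heavily sequenced loci contribute support, not
width. The genome-scale numbers reported for the original HEK293
datasets depend on archived array and CLIP downloads and on unstated
analysis constants (the exact `d_max`, the MET cutoff); this package
exposes those constants as sweeps and validates the machinery on
planted truth instead of attempting to reproduce archive-dependent
values.
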