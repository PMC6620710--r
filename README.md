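# rddmcoloc

Colocalization analysis of Argonaute (AGO1–AGO4) binding sites with
promoter DNA methylation, plus COBRA quantification of global LINE-1 /
Alu methylation.

## What this is for

RNA-directed DNA methylation (RdDM) posits that small-RNA-loaded
Argonaute proteins guide de novo DNA methylation to matching genomic
loci. A computational test of a human RdDM effector asks: do AGO
binding sites (CLIP-seq mapped reads) colocalize, genome wide, with
promoter methylation (MeDIP ChIP-chip tiling arrays of 15 × 50-bp
probes per promoter)? This package implements that test for
bioinformaticians working with probe-level methylation tables and
CLIP-style mapped reads:

- **Genomic core** — 0-based half-open intervals, probe/promoter
  validation (15 probes, 50 bp, ordered, non-overlapping), and UCSC
  chain-file liftover with liftOver-style reject semantics (partial
  mappings are reported unmapped, never truncated).
- **CLIP ingest** — multimapper filtering (reads mapped to > 30
  locations are dropped), perfect vs approximate genome-match
  classification (zero vs any mismatches/insertions/deletions), and
  collapse of read locations into binding sites with a binding-length
  sweep (default ≥ 15 bp).
- **Association statistics** — probes are labeled MET± (median split or
  absolute threshold) and AGO± (nearest site center within `d_max` bp);
  each 2×2 table yields `OR = ad/(bc)` with Haldane–Anscombe correction
  for zero cells, the Wald 95 % CI
  `exp(ln OR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`, and the uncorrected
  Pearson χ² `n(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))` on 1 df. Promoter
  level: Pearson r between the boundary-overlapping site count and the
  15-probe methylation sum; proximity and strand-aware TSS-relative
  profiles round out the picture.
- **COBRA quantification** — the printed band-intensity formulas:
  LINE-1 `(A + 2C + F)·100 / (2A + 2B + 2C + 2F)` with A–E = bands
  92, 60, 50, 42, 32 bp over divisors 92, 56, 48, 40, 28 and
  `F = ((D+E) − (B+C))/2`; Alu `(2F + D + C)·100 / (2A + 2C + 2D + 2F)`
  with A=133, B=58, C=75, D=90, E=43 and `F = ((E+B) − (C+D))/2`; plus
  ΔΔCt fold changes `2^−ΔΔCt`.
- **Synthetic data** — seeded generators with planted ground truth
  (odds ratio, correlation slope/noise, multimapper counts, gel
  pattern mixes) and manifests that `verify_manifest()` recomputes from
  the emitted files, so the whole pipeline is testable offline.

See `vignettes/rddm-colocalization.Rmd` for the full methods account.

## Worked example

The analysis is organised as numbered drivers under `analysis/`:

```sh
Rscript analysis/01_simulate.R      # planted synthetic inputs
Rscript analysis/02_ingest_clip.R   # multimapper filter + site sweep
Rscript analysis/03_association.R   # contingency sweep + correlation
Rscript analysis/04_cobra.R         # gel-lane estimates + ddCt
```

`03_association.R` prints (2,000 promoters, planted OR 4.089 at a 50-bp
proximity radius):

```
Contingency sweep (threshold MET split at 50):
 d_max     a     b    c     d odds_ratio ci_low ci_high    p_value
    50  9472  5528 4468 10532      4.039 3.8488   4.239  0.000e+00
   100 11285  9967 2655  6093      2.598 2.4644   2.740 2.148e-282
   200 13151 14258  789  1802      2.107 1.9311   2.298  1.486e-65
   500 13894 15966   46    94      1.778 1.2489   2.532  1.211e-03
  1000 13940 16059    0     1      2.604 0.1061  63.934  3.515e-01

Promoter-level Pearson correlation over 20000 promoters: r = 0.1717
(implied by the plant: 0.1700), p = 4.3e-132
```

Reading it: at the generator's own proximity radius the estimated odds
ratio (4.039) recovers the realized planted table exactly; widening the
radius dilutes the AGO+ class with unplanted neighbor probes, so the OR
decays toward 1 — the signature of a distance-dependent association.
The promoter-level r matches the closed-form value implied by the
planted Poisson/linear model. `04_cobra.R` prints per-lane estimates
averaging 69.90 % (LINE-1, planted 70 %) and 49.65 % (Alu, planted
50 %) under 3 % multiplicative lane noise.

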