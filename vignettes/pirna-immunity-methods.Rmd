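---
title: "Methods: strain-specific piRNA production and transposon immunity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-specific piRNA production and transposon immunity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem this package addresses

Drosophila strains differ heritably in how well they silence invading
transposable elements (TEs). For the I-element, a non-LTR retrotransposon,
this shows up as *reactivity*: the fraction of embryos that fail to hatch
when reactive-strain females are crossed to I-element-carrying males.
Immunity is conferred by PIWI-interacting RNAs (piRNAs), 24–29 nt germline
small RNAs produced from genomic piRNA clusters that carry ancient TE
fragments. Strains with abundant I-element-specific piRNAs are protected
(low reactivity); strains that transcribe the same cluster remnants poorly
are susceptible, even when their genomic I-element content is
indistinguishable.

`pirnaimmunity` re-implements the computational chain behind this kind of
study as a reusable pipeline — small-RNA preprocessing, TE and genome
mapping, cluster quantification, ping-pong analysis, DNA-seq copy-number
normalization, maternal-deposition ratios, differential piRNA abundance and
the reactivity–piRNA correlation — together with a synthetic-data generator
whose ground truth makes every stage verifiable offline.

## Read processing and mapping model

Reads are 3'-adapter-clipped (3'-most exact match of an adapter prefix,
minimum overlap 6; reads without a detectable adapter are discarded because
their insert boundary is unknown), then filtered with the strict `>18 nt`
rule (length ≥ 19) and an N ban. Internal coordinates are 0-based
half-open everywhere; BED is native, SAM/GFF are converted on ingestion.

Two mapping contracts are deliberately different, following standard piRNA
practice:

* **Canonical TEs, ≤ 3 mismatches.** Every best-stratum placement (minimal
  Hamming distance) on both strands of each family is reported. A read
  whose best stratum spans `k` families contributes weight `1/k` per
  family, split evenly over its positions within a family, so each mapped
  read carries total weight 1 and per-family RPM never double-counts
  (`multimap = "all"` disables the fractional split).
* **Genome, 0 mismatches.** All exact placements are found and the
  multiplicity (number of equally-best loci) recorded; cluster-level
  analyses use only multiplicity-1 ("single-mapped") reads, assigned to a
  cluster when ≥ 50% of the read overlaps it.

The mapper is a pigeonhole-seeded exact Hamming scanner (k-mer chunk
indexes at k = 6 and k = 4, brute force below 16 nt). It is checked
exhaustively against a naive all-positions scan in the test suite, and SAM
ingestion lets published alignments replace it bit-for-bit downstream.

**Library depth.** "Normalized to library depth" leaves the denominator
open. The default depth is the number of reads surviving clip + filter;
a genome-mapped denominator can be supplied explicitly to any
normalization via the `depth` argument.

## Ping-pong signature

For one TE, let `S(p)` and `A(q)` be the summed weights of sense and
antisense reads (24–29 nt) whose biological 5' ends sit at reference
positions `p` and `q`; for an antisense read the 5' end is the *rightmost*
base of its span. The overlap profile is

`counts[o] = sum_p S(p) * A(p + o - 1)`, for offsets `o = 1..30`,

so `counts[10]` counts pairs whose 5' ends overlap by exactly 10 nt — the
signature of ping-pong amplification. The profile is z-normalized with the
sample (n−1) SD over the 30-offset window (the window must exceed the read
length range; 30 is the conventional choice), and `z10` is the reported
signature. Pair weight is the product of the two read weights (all read
pairs); `species_mode` collapses duplicate 5'-position species first.
Between-strain similarity of amplification geometry is summarized by
Spearman correlations of z-profiles per TE.

## Normalizations

* `rpm = count / depth × 1e6`; `rpkm = rpm / (length/1000)`;
  `tpm = (count/length_kb) / Σ(count/length_kb) × 1e6`.
* **Copy-number normalization.** "Normalized to the log2-transformed
  genomic abundance" admits two readings. The default is the log-ratio,
  `log2(piRNA_RPM + pc) − log2(DNA_RPM + pc)`: it is scale-coherent (both
  axes of the source figures are log2 RPM) and invariant when both sides
  scale together. The literal `divide-by-log2` dialect is selectable and
  every output records which dialect produced it. The pseudocount defaults
  to 1 RPM.
* **Maternal deposition** is the ovary/embryo ratio of per-kilobase,
  depth-normalized expression. A within-panel TPM would renormalize each
  library over the TE features alone, so any uniform transmission factor
  `m` cancels and the ratio is blind to exactly the quantity it is meant
  to measure; the per-kilobase-per-million reading (which is how the
  source material uses "TPM") keeps the absolute scale. `value_col="tpm"`
  restores the literal reading.

## Statistics

* **Reactivity correlation**: average-rank Spearman rho; for the realistic
  regime of 4–8 strains the two-sided p enumerates all `n!` permutations
  (so p is a multiple of `1/n!`), larger panels use the t approximation.
  OLS of reactivity on piRNA abundance adds the slope, adjusted R² and a
  90% pointwise confidence band.
* **Wilcoxon rank-sum** (genomic occupancy): exact enumeration of all
  `C(n+m, n)` assignments (ties included, two-sided by doubling the
  smaller tail) up to `n + m = 20`, then the tie-corrected,
  continuity-corrected normal approximation. Per-position coverage values
  are autocorrelated, so these p-values are anti-conservative under an
  i.i.d. null; a 500-bp binned variant is available and flagged in the
  output, but the default stays faithful to the source procedure.
* **Differential abundance with pseudo-replicates**: the source delegates
  its DE details to supplementary material, so the method is defined here
  and tagged in every output: TMM size factors (trim 30% on M, 5% on A),
  a single common NB dispersion via method of moments on within-group
  variability, and an exact conditional NB test on the two group totals;
  BH FDR alongside raw p. With two strains per group treated as
  pseudo-replicates the dispersion absorbs both sampling and strain
  variation.

## The synthetic world

The generator emulates exactly the structure the analysis assumes, with
one chromosome assembled from: a dual-strand germline cluster carrying one
ancestral-TE fragment (30% of the canonical 2-kb sequence — the low end of
the allowed 30–80% so the ancestral family stays a minor fraction, ~4% of
cluster output) among larger fragments of three germline families; a
uni-strand germline cluster; a uni-strand somatic cluster holding all
somatic-TE fragments; two genic 3'UTR clusters; one full-length genomic
copy of each active TE (so fragment reads can be genomic multi-mappers);
and random intergenic background.

Key parameters and the conditions they encode:

| parameter | default | meaning |
|---|---|---|
| `primary_efficiency` (ε) | strain-specific, 0.8–5 | sampling efficiency of ancestral-TE cluster fragments |
| `pingpong_gain` (γ) | 1 | expected secondary reads per primary, active TEs |
| `maternal_transmission` (m) | 0.5 | fraction of ovary piRNA rate deposited in 0–2 h embryos |
| `p1U` | 0.9 | probability of a 5' U on primary reads (first base resampled) |
| background fraction | 0.10 | non-piRNA reads per ovary library (half 21-nt siRNA-like, half 18–23 nt) |
| per-base error | 0.001 | exercises the ≤3-mismatch path |
| `reactivity_slope` (λ) | 1e-5 | `reactivity = 100·exp(−λ·RPM) + noise`, clamped to [0, 100] |

Three modelling choices deserve their reasoning spelled out:

* **ε acts on the ancestral fragments, not on all cluster output.** All
  quantification is depth-normalized, so a factor applied to every source
  in a library cancels exactly (and TMM would likewise normalize it away
  in the DE stage). The biology being emulated is variation in I-element
  piRNA production specifically, so ε multiplies the ancestral-TE fragment
  weight. Raw RPM ratios between strains are still mildly compressed
  (ε = 5 gives ≈ 4.4-fold, log2 ≈ 2.1, because the weak library's
  denominator grows); TMM normalization in the DE stage corrects this and
  recovers log2FC ≈ log2 5 = 2.32.
* **Embryo libraries are composition-scaled.** Each maternal source enters
  the embryo library at `m ×` (a deposition-class factor: germline 1,
  intermediate 0.4, somatic 0.02 — somatic-cell piRNAs and genic 3'UTR
  piRNAs are essentially not deposited) times its ovary fraction, with
  non-piRNA background topping the library up to size. Ovary/embryo
  per-kilobase ratios for germline TEs therefore recover `1/m` exactly in
  expectation, and `m = 0` leaves a background-only embryo library.
* **Ping-pong injection is geometric, not phenomenological.** Each primary
  read on an active TE spawns `Poisson(γ)` partners on the opposite strand
  with 5' ends exactly 10 nt offset (within the fragment). Nothing else in
  the generator prefers offset 10, so a detected `z10` is attributable to
  the injected mechanism; uniform dual-strand sampling alone gives a flat
  profile (`|z10| < 3`).

**What a green test does not establish.** The generator has no 10A bias,
no phasing/trailing piRNAs, no miRNAs, no heterochromatic unassembled
copies, no expression-coupled copy-number feedback, and fragment sequences
are exact canonical substrings (real remnants are diverged). Passing
recovery tests shows the pipeline measures what the generator encodes; it
does not validate the biological model itself.

## Numerical choices and degenerate inputs

* z-scores are reported missing when the profile SD is 0; Spearman rho is
  missing for constant inputs; deposition ratios are flagged, not dropped,
  when the embryo value is 0, as are TEs with zero DNA RPM.
* The log2FC pseudocount is 0 when both group means are positive, 0.5
  otherwise (flagged by construction since a signed-infinite raw ratio is
  replaced).
* Exact-test tie handling: average ranks throughout; the Wilcoxon
  two-sided p doubles the smaller tail and caps at 1, which reproduces
  the textbook `{1,2,3} vs {4,5,6} → p = 0.1` case.
* All randomness flows from one integer seed; substreams are derived by
  stable string hashing (`substream_seed`) so adding a strain never
  reshuffles another strain's reads. Identical (config, seed) pairs give
  byte-identical outputs.

## Known limitations

* The reactivity link (negative exponential with Gaussian noise) is a
  stand-in: the source material shows only a monotone negative
  correlation, and no functional form is claimed.
* The Hamming mapper is ungapped by design (piRNA-scale reads); indels in
  real TE copies surface as unmapped reads, and an external aligner can be
  substituted through SAM ingestion.
* Coverage-based occupancy tests inherit the positional-autocorrelation
  caveat above.
* The DE method is a defined, tagged stand-in for unpublished
  supplementary settings; point estimates may shift against the original,
  though sign and significance are stable in simulation.

## Reproducing the acceptance evidence

`tests/testthat/test-acceptance.R` encodes the acceptance criteria
(oracle equivalence of the ping-pong counter on 200 random libraries,
exact-test enumeration fidelity, parameter recovery for the
primary-efficiency contrast at 2×10⁵ reads × 20 seeds, ping-pong z10
recovery over 50 seeds, end-to-end reactivity-correlation recovery over
100 seeds, copy-number invariance, and the closed-form calculators).
`scripts/acceptance.R --seed N --out results/acceptance.json` recomputes
the headline numbers at reduced seed counts within its runtime budget.
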