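---
title: "caninakit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{caninakit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caninakit)
```

# The Canina meiosis model

Pentaploid dogroses carry five chromosome copies per linkage group: two
near-identical haplotypes of one subgenome (h1/h2) and three divergent
single-copy subgenomes. Only the haplotype pair can form a bivalent at
meiosis I; the three univalents lack partners. The model encodes the
consequences:

- **Male meiosis** transmits exactly one bivalent haplotype per linkage
  group, drawn independently and uniformly; univalents never enter pollen.
- **Female meiosis** transmits one bivalent haplotype per linkage group plus
  every univalent, giving a 4x egg.
- **Fertilization** is the union of gamete copies; the offspring's
  bivalent-forming subgenome is re-derived as the subgenome present twice per
  linkage group.
- **Seed tissues** follow double fertilization: embryo = egg + sperm,
  endosperm = 2·egg + sperm. A 4x egg and 1x sperm predict a 9x/5x = 1.8
  endosperm/embryo DNA ratio; the diploid case gives 3x/2x = 1.5.
- **Hybrids** receive one copy of every maternal subgenome plus one copy of
  the paternal bivalent subgenome, so the shared subgenome shows doubled
  dosage.

Assumptions and deliberate simplifications: recombination within bivalents is
modelled only as the independent haplotype choice per linkage group — no
crossover breakpoints, because no quantity in scope depends on them.
Univalent lagging and elimination during male meiosis is represented only by
its outcome (univalents absent from pollen). Pollen viability is an observed
quantity, not derivable from the model, and is not simulated. Under selfing
the subgenome composition is a fixed point and univalents are
identical-by-descent from the founder, which the tests assert over ten
generations.

# The synthetic genome generator as a stated world

`genome_spec()` fixes the world the analyses are tested in; the defaults are
the stated conditions, not tuning knobs:

- 7 linkage groups × 5 chromosome copies; one duplicated subgenome
  (haplotype divergence 0.005, i.e. ~99.5% identity, inside the observed
  99–100% band) and three single-copy subgenomes whose per-subgenome
  divergences from a common ancestor (0.010, 0.017, 0.022, 0.026) place all
  pairwise identities in the observed 95–98% band.
- Chromosomes default to 1 Mb (real dogrose chromosomes are ~70 Mb); all
  sizes are configurable. Desk scaling is used in tests: 50 kb chromosomes
  for the read-based end-to-end analyses, 1 Mb for the centromere suite so
  that the 50 kb cenLTR array threshold of the classifier is meaningful at
  the default scale.
- The divergence model is i.i.d. substitutions, no indels. This keeps
  coordinates identical across chromosome copies (each SCO locus has exactly
  five placements) and makes mismatch counting a sufficient alignment score.
- Centromeres occupy 10% of the chromosome. The per-subgenome composition
  plan mirrors the bimodality observed in dogroses: ATHILA
  retrotransposon-based centromeres on the bivalent subgenome, large CANR4
  satellite arrays (55–95% of the centromere) on the permanent univalents,
  and one cenLTR tandem-array centromere on R4. ATHILA-based centromeres also
  carry a minor CANR4 array (2–10%): the published regression of CANR4 size
  on CENH3 abundance spans all 35 centromeres with a rank correlation near
  0.93, which is only attainable when satellite content varies on bivalent
  centromeres too, rather than being exactly zero.
- The CANR4 monomer is a synthetic ~160 bp stand-in embedding the real 22 bp
  probe sequence; the true monomer and higher-order repeat structure are not
  published, so only detectability semantics are guaranteed.
- Each ATHILA insertion carries an age drawn around the subgenome's planted
  age (0.7 Ma bivalent, 1.2 Ma univalent, ±20%); its two LTRs evolve
  independently from the element's LTR sequence under Jukes–Cantor dynamics
  at 1.3e-8 substitutions/site/year, so the pairwise LTR divergence encodes
  the age that the dating module must recover.
- cenLTR monomers derive from an ATHILA LTR (>75% identity) padded to a
  configurable monomer length within the observed 1,425–2,596 bp range.

The read simulator draws uniform fragment starts with substitution-only
errors, which matches what the inference consumes. Sources: whole genome,
bivalent subgenome only (pollen), SCO locus intervals on the bivalent
subgenome (target-enrichment pollen), or a per-subgenome dosage vector over
one representative chromosome per subgenome (hybrid reads). The last choice
defines the dosage reference: real pipelines map hybrid reads to a phased
assembly where reads from a single-copy subgenome split between near-identical
haplotypes; collapsing to one representative per subgenome reproduces the
published coverage-histogram reading without modelling mapping ambiguity.

ChIP tracks are flat H3 (value 1) and CENH3 enriched `snr`-fold inside truth
centromeres with multiplicative log-normal noise. CENH3 mass is coupled to
composition (`canr4_boost`): satellite centromeres attract more CENH3, and
the cenLTR centromere is set comparable to a mid-sized satellite centromere —
a global-maximum outlier at zero CANR4 would cap the achievable rank
correlation at ~0.84, inconsistent with the published ~0.93, so the paper's
own numbers pin this parameter. With `canr4_boost = 0` and zero noise the
log2 ratio is exactly log2(snr) inside and 0 outside, which the tests use as
the arithmetic check.

What a green test does *not* establish: the generator has no indels,
no structural variation, no Hi-C structure, no quality-score model, uniform
read sampling (no GC bias), and its centromere composition is far simpler
than real higher-order repeat structure. Green tests establish that the
*inference logic* is correct in a world obeying the model's assumptions, not
that the assumptions hold for any particular dataset.

# Pollen SCO inference

The decision layer is deliberately explicit:

1. **Genome-wide single-copy filter**: a locus is retained iff its hit count
   equals the number of chromosome copies per linkage group (five), with
   exactly one hit per subgenome/haplotype, all in one linkage group.
2. **Consensus**: per-locus majority-vote substitution consensus from pollen
   reads (depth ≥ 5 to substitute, reference base below). This replaces a
   full variant-calling/alternate-reference pipeline; its only downstream use
   is a sample-specific reference, for which majority consensus is
   equivalent in a substitution-only world.
3. **Alternative-placement filter**: records with exactly one alternative
   placement are *retained* (default `alt_hits = "==1"`). A bivalent-derived
   locus hits both near-identical haplotypes — primary on one, a single
   XA-style alternative on the other — so this retention reading is
   self-consistent; the source description is ambiguous, and `<=1` and `any`
   are selectable.
4. **Counting and calling**: per-chromosome counts (haplotype pairs also
   reported as means), winner = subgenome with the maximal aggregate count,
   `confident` iff the winner-minus-runner-up margin is at least half the
   total (default), lexicographic tie-break flagged ambiguous.

Mapping is done by a minimal seeded k-mer mapper (exact 17-mer anchors at 12
offsets, full-length mismatch scoring, identity floor 0.90, alternatives
within 0.01 identity of the primary). It exists so tests need no external
aligner; real SAM alignments with XA tags are accepted through
`read_sam_minimal()`. The mapper is validated against a brute-force
all-positions oracle in the tests.

# Hybrid dosage

Copy number is nearest-integer on the ratio of per-subgenome median window
depth to the median over the subgenomes assumed single-copy. Medians rather
than means resist centromeric repeat windows, and windows overlapping repeat
annotation by more than 50% are excluded outright. No HMM or segmentation:
the question is genome-wide dosage, not local CNV. A call is flagged
low-confidence when the ratio is farther than 0.25 from its nearest integer.
Parent-unique SNPs use symmetric-difference semantics on (position, allele);
a parent's allele counts as observed in the hybrid with a single supporting
read at an assessable position (depth ≥ `min_depth`).

# Centromere annotation

Peak calling is a documented mean + k·sd run-merge procedure (default k = 2,
merge gap 100 kb) instead of a heavyweight broad-peak caller; downstream
quantities depend only on peak spans. The centromere interval spans the
merged peak cluster containing the chromosome-wide enrichment argmax, so the
argmax is always inside the call. CENH3 abundance is the sum of positive
log2(CENH3/H3) values over the interval after per-track total-mass
normalization; summing raw values is selectable (`abundance = "raw"`), since
the published "normalized to coverage" phrasing admits both readings.
A chromosome-wise sd of zero (degenerate flat track) yields a "no
centromere" record rather than an error.

Classification: CANR4-based if the satellite covers ≥ 30% of the interval;
else cenLTR-based if the tandem array reaches 50 kb; else ATHILA-based at
≥ 20% retrotransposon content; else mixed. Thresholds are configurable and
echoed in the result. The regression of CENH3 abundance on CANR4 bp is
ordinary least squares with the Spearman rank correlation reported alongside;
a constant predictor returns missing values with a diagnostic rather than an
error.

Metaplots scale each arm telomere→centromere to [0, 1] with the centromere at
the enrichment argmax, bin, average p- and q-arms (mirroring), then average
chromosomes within a subgenome. All signals are min–max scaled to [0, 1] on
global extremes except methylation, which keeps raw percentages. Optional
spline smoothing (`spar`) only adds a `value_smooth` column — smoothing never
feeds quantitative outputs.

# LTR dating

`jc69_distance()` applies K = −(3/4)·ln(1 − (4/3)p), defined for p < 0.75
(saturation error beyond). `date_insertion()` computes T = K/(2r) with
r = 1.3e-8 substitutions/site/year by default. Mismatches are counted over
gap-free columns; pre-aligned input simply has gap columns excluded, since no
gap treatment is prescribed for the original procedure. Per-subgenome
summaries are medians with seeded percentile-bootstrap confidence intervals
(1,000 resamples). Fossil rescaling multiplies relative divergence times by
2.96/mean(calibration contrast); the calibration contrast is taken as
explicit input because its exact membership is not enumerable from the
source description.

# Numerical and design choices

- Coordinates are 0-based half-open internally everywhere; GFF3/SAM/VCF are
  converted at the I/O boundary. Strand matters only in FASTA extraction.
- All randomness flows from explicit seeds; every generator and bootstrap is
  bit-reproducible, and package functions restore the caller's RNG state.
- The mapper's identity floor (0.90) sits well below the largest
  subgenome-to-ancestor divergence (~3% plus read error) and well above
  random-match identity (~25%), so it is not a sensitive parameter.
- The `dosage` tolerance (0.25) is half the distance between adjacent
  copy-number ratios at a 1x baseline, the natural symmetric choice.
- Degenerate inputs error early with the offending field named: invalid
  generator specs, empty SNP sets, zero baseline depth, all-zero hit tables,
  saturated p-distances.

# Known limitations

- The package analyses the *model's* predictions and synthetic data shaped
  like dogrose genomes; assembling, phasing or annotating a real genome is
  out of scope (external assemblies, repeat annotations and alignments are
  consumed through the standard formats).
- The minimal mapper assumes substitution-only divergence; indel-rich real
  data should be aligned externally and imported.
- The SNP caller is a majority pileup caller, not a genotype-likelihood
  model.
- Centromere classification thresholds are scale-dependent (the 50 kb cenLTR
  array floor presumes roughly megabase-scale intervals at default desk
  scale or real-scale data; reduce `min_array` for smaller toy genomes).
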