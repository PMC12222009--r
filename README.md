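# caninakit

Dogroses (*Rosa* sect. *Caninae*) are pentaploids (2*n* = 5*x* = 35) that
reproduce sexually through *Canina* meiosis: in each of the 7 linkage groups,
one subgenome is present as two near-identical haplotypes that pair as a
bivalent, while the other three subgenome copies remain univalents. The 7
bivalent chromosomes segregate into both gametes; the 21 univalents pass only
through the egg. Pollen is therefore haploid (1*x*, 7 chromosomes) and eggs
are tetraploid (4*x*, 28 chromosomes), restoring 35 at fertilization.

`caninakit` implements this model and the genomic analyses that test it, for
researchers working on polyploid inheritance, centromere biology or dogrose
genomics:

- **Meiosis model** — gamete composition, seed-tissue ploidies
  (endosperm/embryo ratio = (2*e* + *s*)/(*e* + *s*) for egg ploidy *e* and
  sperm ploidy *s*), hybrid subgenome dosage vectors, multi-generation
  stability under selfing.
- **Pollen SCO inference** — identify the bivalent-forming subgenome from
  single-copy orthologue (SCO) loci sequenced from pollen: genome-wide
  single-copy filtering (exactly one hit per chromosome copy, one linkage
  group), majority-consensus references, retention of mappings with exactly
  one alternative placement (the second haplotype of the bivalent pair),
  per-chromosome counting and a margin-based call.
- **Hybrid dosage** — per-subgenome copy number from windowed read coverage
  (median ratio to a 1x baseline, nearest-integer call) and parent-unique SNP
  contributions.
- **Centromere analysis** — functional centromere intervals from
  log2(CENH3/H3) enrichment (mean + *k*·sd peak runs, merged, spanning the
  argmax), repeat composition in bp (CANR4 satellite / ATHILA
  retrotransposon / cenLTR tandem arrays), bimodal classification, CANR4 vs
  CENH3-abundance regression, telomere-to-centromere scaled metaplots and
  windowed CpG/CHG/CHH methylation summaries.
- **LTR dating** — Jukes–Cantor corrected divergence of paired LTRs,
  *K* = −(3/4)·ln(1 − (4/3)*p*), insertion time *T* = *K*/(2*r*) with
  *r* = 1.3 × 10⁻⁸ substitutions/site/year, fossil-calibrated rescaling
  (2.96 Ma) and per-subgenome median ages with bootstrap CIs.
- **Synthetic genomes** — a seeded generator emitting pentaploid bundles
  (FASTA, GFF3, BED, FASTQ, bedGraph, TSV) with full ground truth, so every
  analysis is testable without external data.

## Worked example

```r
library(caninakit)

# the inheritance arithmetic
k <- canina_karyotype()
sperm <- male_meiosis(k, seed = 1)    # 7 chromosomes, all S1
egg   <- female_meiosis(k, seed = 2)  # 28 chromosomes, one S1 + all univalents
endosperm_ploidy(egg, sperm)$ratio
#> [1] 1.8

predict_hybrid_dosage(canina_karyotype(), rubiginosa_karyotype())
#> R3 R4 S1 S2
#>  1  2  1  1

# a synthetic pentaploid and the pollen analysis on it
b <- generate_pentaploid(genome_spec(seed = 7, chromosome_length = 5e4,
                                     n_sco_loci = 3))
res <- run_pollen_bivalent(b, seed = 8)
res$call
#> <bivalent_call> S1 (confident): support 1.00, margin 1.00
```

The `1.8` is the endosperm/embryo DNA-content ratio expected from a 9*x*
endosperm (2 polar nuclei × 4*x* + 1*x* sperm) over a 5*x* embryo — the
flow-cytometric signature of sexual pentaploid reproduction (a diploid gives
1.5). The dosage vector says a canina × rubiginosa hybrid carries two R4
copies (one from each parent) and one of everything else, visible as doubled
R4 read coverage. The pollen call reports the bivalent-forming subgenome with
its hit support and winner-minus-runner-up margin.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-derives the model's headline predictions by running the package (male and
female gamete chromosome numbers from the default pentaploid karyotype, and
the endosperm/embryo ploidy ratios for the pentaploid and diploid crosses)
and writes them as JSON.

## Vignette

`vignettes/caninakit-methods.Rmd` documents the model assumptions, the
synthetic-data generator's stated world, numerical choices and known
limitations.
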